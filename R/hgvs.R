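#' HGVS substitution names
#'
#' Formatting and parsing of simple substitution HGVS names: `c.<pos><ref>><alt>`
#' for coding-level events and `p.<ref><codon><alt>` for protein-level changes.
#' Only single-nucleotide substitutions and single amino-acid replacements are
#' handled; indels, splice and intronic notation are flagged as unsupported so
#' that cohort readers can drop such records with an accounting trail rather
#' than fail.
#'
#' @name hgvs
NULL

AA3 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)

aa_to_one <- function(x) {
  out <- aa_to_one_or_na(x)
  if (anyNA(out)) {
    stop("unknown amino-acid code: ", paste(x[is.na(out)], collapse = ", "))
  }
  out
}

#' Format an HGVS coding-level substitution name
#'
#' @param pos 1-based CDS position.
#' @param ref,alt Single reference/alternate nucleotides.
#' @param transcript Optional accession prefixed to the name.
#' @return String such as `"c.743G>A"`.
#' @examples
#' format_hgvs_c(743, "G", "A")
#' @export
format_hgvs_c <- function(pos, ref, alt, transcript = NULL) {
  if (any(ref == alt)) stop("reference and alternate base are identical")
  name <- paste0("c.", pos, ref, ">", alt)
  if (!is.null(transcript)) name <- paste0(transcript, ":", name)
  name
}

#' Format an HGVS protein-level substitution name
#'
#' Synonymous changes are written `p.<ref><codon>=`; stops use `*`.
#'
#' @param ref_aa,alt_aa One-letter amino acids (`"*"` for stop).
#' @param codon 1-based codon number.
#' @param protein Optional accession prefixed to the name.
#' @return String such as `"p.R248Q"`.
#' @export
format_hgvs_p <- function(ref_aa, codon, alt_aa, protein = NULL) {
  alt <- ifelse(alt_aa == ref_aa, "=", alt_aa)
  name <- paste0("p.", ref_aa, codon, alt)
  if (!is.null(protein)) name <- paste0(protein, ":", name)
  name
}

#' Parse an HGVS substitution name
#'
#' Accepts `c.NNNX>Y` and `p.XnY` (one- or three-letter amino-acid codes,
#' `Ter`/`*` for stop), with an optional `accession:` prefix. Any other
#' variant class (intronic offsets, indels, duplications, frameshifts,
#' splice notation) yields an *unsupported* marker rather than an error, so
#' curation code can count and drop those records.
#'
#' @param text Character vector of HGVS names.
#' @return A data.frame with one row per input: `input`, `kind`
#'   (`"c"`, `"p"` or `"unsupported"`), `cds_position`, `ref_base`,
#'   `alt_base`, `ref_aa`, `codon_number`, `alt_aa`.
#' @examples
#' parse_hgvs(c("c.1010G>A", "p.Arg175His", "c.97-1G>A"))
#' @export
parse_hgvs <- function(text) {
  stopifnot(is.character(text))
  stripped <- sub("^[A-Za-z0-9_.]+:", "", trimws(text))
  out <- data.frame(
    input = text, kind = "unsupported",
    cds_position = NA_integer_, ref_base = NA_character_,
    alt_base = NA_character_,
    ref_aa = NA_character_, codon_number = NA_integer_,
    alt_aa = NA_character_,
    stringsAsFactors = FALSE
  )
  re_c <- "^c\\.([0-9]+)([ACGT])>([ACGT])$"
  is_c <- grepl(re_c, stripped)
  if (any(is_c)) {
    out$kind[is_c] <- "c"
    out$cds_position[is_c] <- as.integer(sub(re_c, "\\1", stripped[is_c]))
    out$ref_base[is_c] <- sub(re_c, "\\2", stripped[is_c])
    out$alt_base[is_c] <- sub(re_c, "\\3", stripped[is_c])
  }
  re_p <- "^p\\.\\(?([A-Za-z]{3}|[A-Z*])([0-9]+)([A-Za-z]{3}|[A-Z*=])\\)?$"
  is_p <- !is_c & grepl(re_p, stripped)
  if (any(is_p)) {
    ref1 <- aa_to_one_or_na(sub(re_p, "\\1", stripped[is_p]))
    alt <- sub(re_p, "\\3", stripped[is_p])
    alt1 <- ifelse(alt == "=", ref1, aa_to_one_or_na(alt))
    ok <- !is.na(ref1) & !is.na(alt1)
    idx <- which(is_p)[ok]
    if (length(idx)) {
      out$kind[idx] <- "p"
      out$ref_aa[idx] <- ref1[ok]
      out$codon_number[idx] <- as.integer(sub(re_p, "\\2", stripped[is_p]))[ok]
      out$alt_aa[idx] <- alt1[ok]
    }
  }
  out
}

aa_to_one_or_na <- function(x) {
  out <- rep(NA_character_, length(x))
  three <- nchar(x) == 3L
  key <- paste0(toupper(substr(x[three], 1, 1)), tolower(substr(x[three], 2, 3)))
  out[three] <- unname(AA3[key])
  one <- !three & x %in% c(unname(AA3), "*")
  out[one] <- x[one]
  out
}
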