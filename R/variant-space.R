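#' Enumerate every single-nucleotide substitution of a coding sequence
#'
#' For a CDS of length L nucleotides there are exactly 3L possible
#' single-nucleotide substitution events. Each event is translated in place
#' and classified as synonymous, missense, nonsense (gain of stop),
#' stop_loss or stop_retained. Distinct cDNA events producing the same
#' amino-acid replacement are deduplicated into the protein-level missense
#' space on the key (reference amino acid, codon number, alternate amino
#' acid).
#'
#' Counting conventions (both configurable):
#' * Non-synonymous substitutions in the initiator codon are counted as
#'   missense protein variants, flagged `start_codon = TRUE`
#'   (`count_start_codon = TRUE` by default).
#' * Stop-codon events are classified stop_loss / stop_retained and excluded
#'   from the missense protein space.
#'
#' @param cds A [coding_sequence()].
#' @param count_start_codon Count initiator-codon non-synonymous changes as
#'   missense.
#' @return An object of class `variant_space`: a list with
#'   \describe{
#'     \item{snvs}{data.frame of all 3L events (`cds_position`, `ref_base`,
#'       `alt_base`, `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`,
#'       `alt_aa`, `consequence`, `start_codon`, `hgvs_c`, `hgvs_p`)}
#'     \item{cdna_missense}{the missense subset of `snvs`}
#'     \item{protein_missense}{deduplicated protein-level missense variants}
#'     \item{index}{named list mapping each missense `hgvs_p` to the row
#'       indices of `snvs` producing it}
#'   }
#' @examples
#' vs <- enumerate_snvs(coding_sequence("ATGGCATGA"))
#' nrow(vs$snvs)              # 27 events for a 9-nt ORF
#' nrow(vs$protein_missense)  # 12 distinct amino-acid replacements
#' @export
enumerate_snvs <- function(cds, count_start_codon = TRUE) {
  stopifnot(inherits(cds, "coding_sequence"))
  bases <- strsplit(cds$bases, "")[[1L]]
  L <- length(bases)
  nt <- c("A", "C", "G", "T")
  # 3 alternates per position, in fixed A<C<G<T order
  alt_of <- lapply(nt, function(b) setdiff(nt, b))
  names(alt_of) <- nt

  pos <- rep(seq_len(L), each = 3L)
  ref <- bases[pos]
  alt <- unlist(alt_of[bases], use.names = FALSE)
  codon_index <- (pos + 2L) %/% 3L
  phase <- (pos - 1L) %% 3L + 1L

  codons <- codon_split(cds$bases)
  ref_codon <- codons[codon_index]
  alt_codon <- ref_codon
  substr(alt_codon, phase, phase) <- alt

  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)

  consequence <- ifelse(
    ref_aa == "*",
    ifelse(alt_aa == "*", "stop_retained", "stop_loss"),
    ifelse(alt_aa == "*", "nonsense",
           ifelse(ref_aa == alt_aa, "synonymous", "missense"))
  )
  start_codon <- codon_index == 1L & consequence == "missense"
  if (!count_start_codon) {
    consequence[start_codon] <- "start_lost"
    start_codon <- rep(FALSE, length(start_codon))
  }

  snvs <- data.frame(
    cds_position = pos, ref_base = ref, alt_base = alt,
    codon_index = codon_index, ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence,
    start_codon = start_codon,
    hgvs_c = paste0("c.", pos, ref, ">", alt),
    hgvs_p = format_hgvs_p(ref_aa, codon_index, alt_aa),
    stringsAsFactors = FALSE
  )

  mis <- snvs[snvs$consequence == "missense", , drop = FALSE]
  key <- paste(mis$ref_aa, mis$codon_index, mis$alt_aa)
  first <- !duplicated(key)
  protein_missense <- data.frame(
    ref_aa = mis$ref_aa[first], codon_number = mis$codon_index[first],
    alt_aa = mis$alt_aa[first], hgvs_p = mis$hgvs_p[first],
    start_codon = mis$start_codon[first],
    n_cdna = as.integer(table(key)[key[first]]),
    stringsAsFactors = FALSE
  )
  ord <- order(protein_missense$codon_number, protein_missense$alt_aa)
  protein_missense <- protein_missense[ord, , drop = FALSE]
  rownames(protein_missense) <- NULL

  index <- split(which(snvs$consequence == "missense"), mis$hgvs_p)

  structure(
    list(cds = cds, snvs = snvs, cdna_missense = mis,
         protein_missense = protein_missense, index = index),
    class = "variant_space"
  )
}

#' @export
print.variant_space <- function(x, ...) {
  cat("Variant space of", x$cds$id, "(", nchar(x$cds$bases), "nt )\n")
  cat("  substitution events:", nrow(x$snvs), "\n")
  tab <- table(x$snvs$consequence)
  for (k in names(tab)) cat(sprintf("    %-14s %d\n", k, tab[[k]]))
  cat("  cDNA missense events:", nrow(x$cdna_missense), "\n")
  cat("  distinct missense protein variants:", nrow(x$protein_missense), "\n")
  invisible(x)
}

#' @export
summary.variant_space <- function(object, ...) {
  c(
    snvs = nrow(object$snvs),
    synonymous = sum(object$snvs$consequence == "synonymous"),
    missense = sum(object$snvs$consequence == "missense"),
    nonsense = sum(object$snvs$consequence == "nonsense"),
    stop_loss = sum(object$snvs$consequence == "stop_loss"),
    stop_retained = sum(object$snvs$consequence == "stop_retained"),
    protein_missense = nrow(object$protein_missense)
  )
}

#' Write an enumerated variant space to TSV
#'
#' @param space A `variant_space`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_space <- function(space, path) {
  stopifnot(inherits(space, "variant_space"))
  df <- space$snvs[, c("hgvs_c", "hgvs_p", "codon_index", "ref_aa",
                       "alt_aa", "consequence")]
  names(df)[3] <- "codon"
  write_tsv(df, path)
}
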