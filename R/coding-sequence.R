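#' Construct a coding sequence object
#'
#' A `coding_sequence` is the in-frame open reading frame (ORF) of a
#' transcript: the nucleotide string from the initiator ATG through the stop
#' codon, in CDS (HGVS c.) coordinates.
#'
#' @param bases Single character string of A/C/G/T (case-insensitive).
#' @param id Transcript accession used in HGVS c. names.
#' @param protein_id Protein accession used in HGVS p. names.
#' @param require_start Require the first codon to be ATG.
#' @param require_stop Require the last codon to be a stop codon.
#' @return An object of class `coding_sequence` with fields `id`,
#'   `protein_id`, `bases` and `codon_table`.
#' @examples
#' cds <- coding_sequence("ATGGCATGA", id = "TX1")
#' n_codons(cds)
#' @export
coding_sequence <- function(bases, id = "CDS", protein_id = id,
                            require_start = TRUE, require_stop = TRUE) {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(gsub("[[:space:]]", "", bases))
  if (grepl("[^ACGT]", bases)) {
    stop("coding sequence contains non-ACGT characters")
  }
  if (nchar(bases) %% 3L != 0L) {
    stop("coding sequence length (", nchar(bases), ") is not divisible by 3")
  }
  if (nchar(bases) < 3L) stop("coding sequence must contain at least one codon")
  codons <- codon_split(bases)
  if (require_start && codons[1L] != "ATG") {
    stop("first codon is '", codons[1L], "', not a start codon (ATG)")
  }
  last <- codons[length(codons)]
  if (require_stop && !is_stop_codon(last)) {
    stop("last codon is '", last, "', not a stop codon")
  }
  structure(
    list(id = id, protein_id = protein_id, bases = bases,
         codon_table = "standard"),
    class = "coding_sequence"
  )
}

#' Read a coding sequence from a FASTA file
#'
#' Reads the first record of a FASTA file as an in-frame CDS.
#'
#' @param path Path to a FASTA file.
#' @param ... Passed on to [coding_sequence()].
#' @return A `coding_sequence`.
#' @export
read_cds_fasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
  id <- sub("\\s.*$", "", names(seqs)[1L])
  coding_sequence(as.character(seqs[[1L]]), id = id, ...)
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("Coding sequence ", x$id, ": ", nchar(x$bases), " nt (",
      n_codons(x), " codons)\n", sep = "")
  invisible(x)
}

#' Number of codons in a coding sequence
#' @param cds A `coding_sequence`.
#' @return Integer count of codons, including the stop codon.
#' @export
n_codons <- function(cds) nchar(cds$bases) %/% 3L

codon_split <- function(bases) {
  n <- nchar(bases) %/% 3L
  substring(bases, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# Codon -> one-letter amino acid ("*" for stop), standard code.
translate_codon <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}
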