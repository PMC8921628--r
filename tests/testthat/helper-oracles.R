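# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the enumeration oracle re-translates whole ORFs, the AUC
# oracle enumerates positive-negative pairs, the MDS oracle works from an
# explicit eigendecomposition.

GENCODE <- Biostrings::GENETIC_CODE

random_orf <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(names(GENCODE), stops)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}

translate_orf <- function(bases) {
  n <- nchar(bases) %/% 3L
  codons <- substring(bases, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(unname(GENCODE[codons]), collapse = "")
}

# every substitution of every base, classified by whole-ORF re-translation
oracle_enumerate <- function(bases) {
  ref_prot <- translate_orf(bases)
  out <- list()
  for (pos in seq_len(nchar(bases))) {
    ref <- substr(bases, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      mut <- bases
      substr(mut, pos, pos) <- alt
      alt_prot <- translate_orf(mut)
      codon <- (pos + 2L) %/% 3L
      ra <- substr(ref_prot, codon, codon)
      aa <- substr(alt_prot, codon, codon)
      consequence <-
        if (ra == "*") { if (aa == "*") "stop_retained" else "stop_loss" }
        else if (aa == "*") "nonsense"
        else if (ra == aa) "synonymous"
        else "missense"
      out[[length(out) + 1L]] <- data.frame(
        cds_position = pos, ref_base = ref, alt_base = alt,
        ref_aa = ra, alt_aa = aa, consequence = consequence,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# pairwise brute-force AUC, ties counting one half
oracle_auc <- function(scores, truth, positive = "D") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small imputed feature matrix with planted two-class signal
toy_features <- function(n = 60, p = 6, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("D", "ND"), length.out = n)
  x <- matrix(rnorm(n * p), n, p) + ifelse(y == "D", sep, 0)
  rownames(x) <- sprintf("p.T%03dX", seq_len(n))
  colnames(x) <- sprintf("f%02d", seq_len(p))
  list(x = x, y = stats::setNames(y, rownames(x)))
}
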