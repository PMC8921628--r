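#' Prevalence statistics over tumor-level records
#'
#' Two descriptive flags for likely constitutional polymorphisms hiding in
#' somatic mutation corpora: the germline-to-somatic (GVS) ratio, high when
#' a variant is over-represented among germline records, and the
#' multiple-mutation frequency (MMF), high when a variant tends to co-occur
#' with other variants of the same gene in one tumor (a passenger/SNP
#' signature).
#'
#' Tumor records are a data.frame with columns `sample_id`, `origin`
#' (`"somatic"`/`"germline"`) and `variants` (semicolon-joined protein
#' variant keys, unique within a record).
#'
#' @name prevalence_stats
NULL

as_tumor_records <- function(records) {
  records <- as.data.frame(records)
  require_columns(records, c("sample_id", "origin", "variants"),
                  "tumor record table")
  if (!all(records$origin %in% c("somatic", "germline"))) {
    stop("origin must be 'somatic' or 'germline'")
  }
  records$variant_list <- strsplit(as.character(records$variants), ";",
                                   fixed = TRUE)
  if (any(lengths(records$variant_list) == 0L)) {
    stop("every tumor record must carry at least one variant")
  }
  if (any(vapply(records$variant_list, anyDuplicated, integer(1)) > 0L)) {
    stop("variants must be unique within a tumor record")
  }
  records
}

#' Germline-to-somatic ratio of a variant
#'
#' Ratio of the variant's pseudocount-smoothed relative frequency among
#' germline records to that among somatic records:
#' `((g_v + a)/(G + a)) / ((s_v + a)/(S + a))` with pseudocount `a`, where
#' `g_v`/`s_v` count records of each compartment carrying the variant and
#' `G`/`S` are the compartment record totals. With `pseudocount = 0` the
#' statistic is antisymmetric under swapping compartments
#' (`gvs -> 1/gvs`); the default 0.5 keeps it finite for unseen variants.
#'
#' @param records Tumor record table (see [prevalence_stats]).
#' @param variant Protein variant key (vectorized).
#' @param pseudocount Additive smoothing constant (default 0.5).
#' @return Non-negative numeric vector.
#' @export
gvs_ratio <- function(records, variant, pseudocount = 0.5) {
  records <- as_tumor_records(records)
  germ <- records$origin == "germline"
  if (!any(germ) || all(germ)) {
    stop("records must contain both germline and somatic entries")
  }
  G <- sum(germ)
  S <- sum(!germ)
  vapply(variant, function(v) {
    has <- vapply(records$variant_list, function(l) v %in% l, logical(1))
    g_v <- sum(has & germ)
    s_v <- sum(has & !germ)
    ((g_v + pseudocount) / (G + pseudocount)) /
      ((s_v + pseudocount) / (S + pseudocount))
  }, numeric(1))
}

#' Multiple-mutation frequency of a variant
#'
#' Fraction of the tumors carrying a variant in which it co-occurs with at
#' least one other variant of the same gene. The denominator counts tumors
#' (records), not occurrence events.
#'
#' @param records Tumor record table.
#' @param variant Protein variant key (vectorized).
#' @return Fraction in `[0, 1]`, or `NA` for variants never observed.
#' @export
mmf <- function(records, variant) {
  records <- as_tumor_records(records)
  n_var <- lengths(records$variant_list)
  vapply(variant, function(v) {
    has <- vapply(records$variant_list, function(l) v %in% l, logical(1))
    if (!any(has)) return(NA_real_)
    sum(has & n_var > 1L) / sum(has)
  }, numeric(1))
}

#' Frequency ranking of an occurrence table
#'
#' @param occ Occurrence table (`variant`, `dataset_id`, `count`); counts
#'   are summed over datasets.
#' @return data.frame ordered by descending total count (ties in variant
#'   key order): `variant`, `count`, `log2_count` (`NA` for zero counts),
#'   `rank`.
#' @export
frequency_ranking <- function(occ) {
  occ <- as_occurrence_table(occ)
  totals <- tapply(occ$count, occ$variant, sum)
  df <- data.frame(variant = names(totals), count = as.numeric(totals),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$variant), , drop = FALSE]
  df$log2_count <- ifelse(df$count > 0, log2(df$count), NA_real_)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Read/write tumor record tables
#'
#' TSV with columns `sample_id`, `origin`, `variants` (semicolon-joined).
#'
#' @param path File path.
#' @param records Tumor record data.frame.
#' @return data.frame (read) or `path` invisibly (write).
#' @export
read_tumor_records <- function(path) {
  as_tumor_records(read_table_auto(path))[, c("sample_id", "origin", "variants")]
}

#' @rdname read_tumor_records
#' @export
write_tumor_records <- function(records, path) {
  write_tsv(records[, c("sample_id", "origin", "variants")], path)
}
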