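#' Familial-cancer (LFS-style) cohort validation
#'
#' Cohorts of cancer-predisposition families should carry only pathogenic,
#' functionally abnormal variants, so the harness scores the fraction of
#' distinct cohort variants predicted deleterious. Known founder variants
#' (over-represented for demographic reasons, e.g. p.R337H) and variants
#' later shown to be misidentified SNPs are removed from the denominator
#' first.
#'
#' @param cohort_variants Character vector of variant keys observed in the
#'   cohort (family-level duplicates allowed; deduplicated internally).
#' @param preds Prediction table (`variant`, `class`).
#' @param excluded_snps Variants to exclude as misidentified SNPs.
#' @param excluded_founders Founder variants to exclude.
#' @return A [validation_report()]; accuracy = predicted-D / remaining
#'   variants.
#' @export
lfs_validate <- function(cohort_variants, preds,
                         excluded_snps = character(),
                         excluded_founders = character()) {
  preds <- as_prediction_table(preds)
  variants <- unique(cohort_variants)
  n_distinct <- length(variants)

  for (what in list(c("misidentified SNP", "excluded_snps"),
                    c("founder variant", "excluded_founders"))) {
    lst <- get(what[2])
    absent <- setdiff(lst, variants)
    if (length(absent)) {
      warning(what[1], " exclusion names variant(s) absent from the cohort: ",
              paste(absent, collapse = ", "))
    }
  }
  variants <- setdiff(variants, c(excluded_snps, excluded_founders))

  cls <- stats::setNames(preds$class, preds$variant)
  missing <- setdiff(variants, names(cls))
  if (length(missing)) {
    stop("no prediction for cohort variant(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  correct <- sum(cls[variants] == "D")
  cm <- confusion(rep("D", length(variants)), cls[variants])
  validation_report(
    harness = "familial cancer cohort",
    cm = cm,
    accounting = list(
      n_distinct = n_distinct,
      n_excluded = n_distinct - length(variants),
      n_remaining = length(variants),
      n_correct = correct
    )
  )
}
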