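#' Summarize model predictions over a population frequency table
#'
#' Partitions the variants of a population database (allele counts or
#' frequencies from presumed-healthy individuals) by predicted class. Most
#' population variants should be non-deleterious; the deleterious remainder
#' flags either asymptomatic carriers of pathogenic variants or prediction
#' errors.
#'
#' @param pop_table data.frame with column `variant` plus any frequency
#'   columns (e.g. `allele_count`, `allele_freq`), carried through.
#' @param preds Prediction table (`variant`, `class`).
#' @return A [validation_report()] with `accounting` counts `n`, `n_D`,
#'   `n_ND` and extra element `table` (per-variant join of frequency and
#'   predicted class).
#' @export
summarize_population <- function(pop_table, preds) {
  pop_table <- as.data.frame(pop_table)
  require_columns(pop_table, "variant", "population table")
  preds <- as_prediction_table(preds)
  cls <- stats::setNames(preds$class, preds$variant)
  missing <- setdiff(pop_table$variant, names(cls))
  if (length(missing)) {
    stop("no prediction for population variant(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  out <- pop_table
  out$class <- unname(cls[pop_table$variant])
  validation_report(
    harness = "population database summary",
    accounting = list(n = nrow(out), n_D = sum(out$class == "D"),
                      n_ND = sum(out$class == "ND")),
    extra = list(table = out)
  )
}
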