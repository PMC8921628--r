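#' ClinVar-style curation and comparison
#'
#' Annotation tables use the five-tier ACMG vocabulary: Pathogenic (P),
#' Likely pathogenic (LP), Uncertain significance (VUS), Likely benign
#' (LB), Benign (B). For confusion-matrix comparison P/LP map to
#' deleterious (D) and B/LB to non-deleterious (ND); VUS records are
#' reported separately, split by the model's prediction.
#'
#' @name clinvar
NULL

CLINVAR_TIERS <- c("P", "LP", "VUS", "LB", "B")

as_clinvar_table <- function(tab) {
  tab <- as.data.frame(tab)
  require_columns(tab, c("variant", "tier"), "annotation table")
  if (is.null(tab$record_id)) tab$record_id <- seq_len(nrow(tab))
  if (is.null(tab$variant_class)) tab$variant_class <- "missense"
  bad <- !is.na(tab$tier) & !(tab$tier %in% CLINVAR_TIERS)
  if (any(bad)) {
    stop("unknown annotation tier(s): ",
         paste(unique(tab$tier[bad]), collapse = ", "))
  }
  tab
}

#' Curate a raw annotation table
#'
#' Three rules, applied with full accounting:
#' 1. same-variant records with discordant or absent tiers are collapsed to
#'    a single VUS record (conflict collapse happens first, so only
#'    same-tier copies count as duplicates);
#' 2. exact duplicate records of one variant sharing a tier are reduced to
#'    one;
#' 3. records whose variant is indel-derived (non-substitution) are
#'    removed.
#'
#' The operation is idempotent.
#'
#' @param raw data.frame with columns `variant`, `tier`, optionally
#'   `record_id` and `variant_class`
#'   (`missense`/`indel_derived`/`other`).
#' @return Curated data.frame with attribute `accounting`: list with
#'   `n_input`, `removed_duplicates`, `removed_indel`,
#'   `conflicts_collapsed`, `n_retained`.
#' @export
curate_clinvar <- function(raw) {
  raw <- as_clinvar_table(raw)
  if (nrow(raw) == 0L) stop("annotation table is empty")
  n_input <- nrow(raw)

  indel <- raw$variant_class == "indel_derived"
  removed_indel <- sum(indel)
  tab <- raw[!indel, , drop = FALSE]

  out <- list()
  removed_dup <- 0L
  conflicts <- 0L
  for (v in unique(tab$variant)) {
    rec <- tab[tab$variant == v, , drop = FALSE]
    tiers <- unique(rec$tier[!is.na(rec$tier)])
    if (length(tiers) != 1L || anyNA(rec$tier)) {
      # discordant or missing labels -> single VUS record
      if (nrow(rec) > 1L || length(tiers) != 1L) {
        conflicts <- conflicts + nrow(rec) - 1L
        rec <- rec[1L, , drop = FALSE]
        rec$tier <- "VUS"
      }
    } else if (nrow(rec) > 1L) {
      removed_dup <- removed_dup + nrow(rec) - 1L
      rec <- rec[1L, , drop = FALSE]
    }
    out[[v]] <- rec
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "accounting") <- list(
    n_input = n_input, removed_duplicates = removed_dup,
    removed_indel = removed_indel, conflicts_collapsed = conflicts,
    n_retained = nrow(out)
  )
  out
}

#' Compare curated annotations with model predictions
#'
#' Maps P/LP to D and B/LB to ND, computes the confusion matrix over
#' non-VUS records, and splits VUS records by predicted class.
#'
#' @param curated Curated annotation table (see [curate_clinvar()]).
#' @param preds data.frame with `variant` and `class` (`"D"`/`"ND"`)
#'   columns, e.g. from [predict_space()].
#' @return A [validation_report()] with extra element `vus` (counts
#'   `predicted_D`, `predicted_ND`) and uncovered-variant accounting.
#' @export
compare_clinvar <- function(curated, preds) {
  curated <- as_clinvar_table(curated)
  preds <- as_prediction_table(preds)
  cls <- stats::setNames(preds$class, preds$variant)

  covered <- curated$variant %in% names(cls)
  uncovered <- unique(curated$variant[!covered])
  if (length(uncovered)) {
    warning(length(uncovered),
            " annotated variant(s) have no prediction and were excluded: ",
            paste(utils::head(uncovered, 5), collapse = ", "))
  }
  tab <- curated[covered, , drop = FALSE]
  non_vus <- tab$tier != "VUS"
  if (any(non_vus & is.na(cls[tab$variant]))) stop("missing predicted class")
  truth <- ifelse(tab$tier[non_vus] %in% c("P", "LP"), "D", "ND")
  cm <- confusion(truth, cls[tab$variant[non_vus]])
  vus_cls <- cls[tab$variant[!non_vus]]
  validation_report(
    harness = "annotation database comparison",
    cm = cm,
    accounting = list(n_records = nrow(tab), n_non_vus = sum(non_vus),
                      n_vus = sum(!non_vus), n_uncovered = length(uncovered)),
    extra = list(vus = list(predicted_D = sum(vus_cls == "D"),
                            predicted_ND = sum(vus_cls == "ND")))
  )
}

as_prediction_table <- function(preds) {
  preds <- as.data.frame(preds)
  require_columns(preds, c("variant", "class"), "prediction table")
  if (!all(preds$class %in% c("D", "ND"))) {
    stop("predicted classes must be 'D' or 'ND'")
  }
  preds[!duplicated(preds$variant), , drop = FALSE]
}
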