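#' Training labels from multi-database prevalence
#'
#' The positive (deleterious, functionally abnormal) training set is the
#' *cancer-shared dataset* (CSD): protein variants observed at least once in
#' every one of several independent cancer mutation databases. Because those
#' databases come from different patients and sequencing pipelines, shared
#' variants are very unlikely to be artifacts or passengers. The negative
#' (functionally normal) set exploits mutational saturation: variants never
#' observed, or observed only once, across a very large corpus of tumors are
#' taken as non-oncogenic.
#'
#' @name cohort_labeling
NULL

#' Build the positive (CSD) training set
#'
#' @param occ Occurrence table: data.frame with columns `variant`,
#'   `dataset_id`, `count`. Multiple cDNA events mapping to the same protein
#'   variant should already be aggregated to one row per (variant, dataset).
#' @param dataset_ids Databases that must all contain the variant (>= 2).
#' @return Character vector of variant keys present at least once in every
#'   listed dataset.
#' @export
build_positive_set <- function(occ, dataset_ids) {
  occ <- as_occurrence_table(occ)
  if (length(dataset_ids) < 2L) {
    stop("the shared-dataset rule needs at least 2 dataset ids")
  }
  unknown <- setdiff(dataset_ids, unique(occ$dataset_id))
  if (length(unknown)) {
    stop("unknown dataset id(s): ", paste(unknown, collapse = ", "))
  }
  hit <- occ[occ$count >= 1L & occ$dataset_id %in% dataset_ids, ]
  n_hit <- tapply(hit$dataset_id, hit$variant,
                  function(d) length(unique(d)))
  sort(names(n_hit)[n_hit == length(dataset_ids)])
}

#' Build the negative training set (absent or near-absent variants)
#'
#' @param occ Occurrence table (see [build_positive_set()]).
#' @param space A [enumerate_snvs()] `variant_space`; only its missense
#'   protein variants are eligible.
#' @param max_total_count Maximum summed occurrence count across all
#'   datasets (default 1: never seen, or seen once).
#' @return Character vector of variant keys, with attribute `provenance`
#'   (named `"absent"`/`"singleton"`, or `"rare"` for counts > 1 when
#'   `max_total_count` is raised).
#' @export
build_negative_set <- function(occ, space, max_total_count = 1L) {
  occ <- as_occurrence_table(occ)
  stopifnot(inherits(space, "variant_space"))
  keys <- space$protein_missense$hgvs_p
  totals <- tapply(occ$count, occ$variant, sum)
  total <- ifelse(keys %in% names(totals), totals[keys], 0L)
  total[is.na(total)] <- 0L
  neg <- keys[total <= max_total_count]
  prov <- ifelse(total[keys %in% neg] == 0L, "absent",
                 ifelse(total[keys %in% neg] == 1L, "singleton", "rare"))
  ord <- order(neg)
  structure(neg[ord], provenance = stats::setNames(prov[ord], neg[ord]))
}

#' Assemble the labeled training cohort
#'
#' Removes hold-out variants (kept aside, e.g. for experimental validation)
#' from the positive and negative sets and accounts for every variant of the
#' enumerated space.
#'
#' @param pos,neg Character vectors of variant keys (disjoint).
#' @param holdout Character vector of variant keys to set aside.
#' @param space A `variant_space`.
#' @return An object of class `labeled_cohort`: list with `positives`,
#'   `negatives`, `holdout` (data.frame `variant`, `original_label`),
#'   `unlabeled`, and a `sizes` accounting list.
#' @export
assemble_cohort <- function(pos, neg, holdout = character(), space) {
  stopifnot(inherits(space, "variant_space"))
  overlap <- intersect(pos, neg)
  if (length(overlap)) {
    stop("labeling contradiction: variant(s) in both positive and negative set: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  keys <- space$protein_missense$hgvs_p
  sizes <- list(pos_before = length(pos), neg_before = length(neg))
  hold_lab <- ifelse(holdout %in% pos, "D",
                     ifelse(holdout %in% neg, "ND", "unlabeled"))
  pos2 <- setdiff(pos, holdout)
  neg2 <- setdiff(neg, holdout)
  sizes$pos_after <- length(pos2)
  sizes$neg_after <- length(neg2)
  sizes$holdout <- length(holdout)
  unlabeled <- setdiff(keys, c(pos2, neg2, holdout))
  structure(
    list(
      positives = sort(pos2), negatives = sort(neg2),
      holdout = data.frame(variant = holdout, original_label = hold_lab,
                           stringsAsFactors = FALSE),
      unlabeled = sort(unlabeled), sizes = sizes
    ),
    class = "labeled_cohort"
  )
}

#' @export
print.labeled_cohort <- function(x, ...) {
  s <- x$sizes
  cat("Labeled cohort\n")
  cat(sprintf("  positives (D):  %d (%d before hold-out removal)\n",
              s$pos_after, s$pos_before))
  cat(sprintf("  negatives (ND): %d (%d before hold-out removal)\n",
              s$neg_after, s$neg_before))
  cat(sprintf("  hold-out: %d   unlabeled: %d\n",
              s$holdout, length(x$unlabeled)))
  invisible(x)
}

#' Labels of a cohort as a two-column data.frame
#'
#' @param cohort A `labeled_cohort`.
#' @return data.frame with columns `variant` and `label` (`"D"`/`"ND"`).
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  data.frame(
    variant = c(cohort$positives, cohort$negatives),
    label = c(rep("D", length(cohort$positives)),
              rep("ND", length(cohort$negatives))),
    stringsAsFactors = FALSE
  )
}

as_occurrence_table <- function(occ) {
  occ <- as.data.frame(occ)
  require_columns(occ, c("variant", "dataset_id", "count"), "occurrence table")
  if (any(occ$count < 0)) stop("occurrence counts must be non-negative")
  if (anyDuplicated(occ[, c("variant", "dataset_id")])) {
    # aggregate duplicate (variant, dataset) rows, e.g. multiple cDNA events
    occ <- stats::aggregate(count ~ variant + dataset_id, occ, sum)
  }
  occ
}

#' Write a labeled cohort to TSV
#'
#' Columns: `variant`, `label` (D/ND), `provenance`
#' (CSD/negative/holdout/unlabeled).
#'
#' @param cohort A `labeled_cohort`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  seg <- function(variant, label, provenance) {
    data.frame(variant = variant, label = rep_len(label, length(variant)),
               provenance = rep_len(provenance, length(variant)),
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    seg(cohort$positives, "D", "CSD"),
    seg(cohort$negatives, "ND", "negative"),
    seg(cohort$holdout$variant, cohort$holdout$original_label, "holdout"),
    seg(cohort$unlabeled, NA_character_, "unlabeled")
  )
  write_tsv(df, path)
}
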