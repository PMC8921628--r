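#' Survival stratification by mutation class
#'
#' Tumor samples are partitioned into four categories by their mutation
#' status in the gene of interest: `no_mutation`, `missense_ND` (missense,
#' predicted functionally normal), `missense_D` (missense, predicted
#' functionally abnormal) and `truncating` (frameshift insertion/deletion,
#' nonsense, splice region or splice site). Samples carrying more than one
#' mutation, patients contributing more than one sample, and samples whose
#' only mutation is of another non-missense class are excluded.
#'
#' @name survival_stratification
NULL

# MAF-style Variant_Classification strings, matched case-insensitively
TRUNCATING_CLASSES <- c(
  "frame_shift_del", "frame_shift_ins", "frameshift_deletion",
  "frameshift_insertion", "nonsense_mutation", "nonsense",
  "splice_region", "splice_site"
)
MISSENSE_CLASSES <- c("missense_mutation", "missense")
KNOWN_CLASSES <- c(
  TRUNCATING_CLASSES, MISSENSE_CLASSES,
  "in_frame_del", "in_frame_ins", "silent", "nonstop_mutation",
  "translation_start_site", "5'utr", "3'utr", "intron", "other"
)

as_survival_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  # accept MAF-style column names
  ren <- c(Variant_Classification = "variant_class", HGVSp_Short = "hgvs_p",
           Tumor_Sample_Barcode = "sample_id")
  for (from in names(ren)) {
    if (from %in% names(cohort) && !(ren[[from]] %in% names(cohort))) {
      names(cohort)[names(cohort) == from] <- ren[[from]]
    }
  }
  require_columns(cohort, c("patient_id", "sample_id", "variant_class",
                            "time", "event", "tumor_type"),
                  "survival cohort")
  if (any(cohort$time < 0)) stop("survival times must be non-negative")
  if (!all(cohort$event %in% c(0L, 1L))) stop("event flag must be 0/1")
  cohort
}

#' Assign each tumor sample to a mutation-status category
#'
#' One input row per sample; `variant_class` and `hgvs_p` are
#' semicolon-joined over the sample's mutations (empty string = no
#' mutation).
#'
#' @param cohort data.frame with columns `patient_id`, `sample_id`,
#'   `variant_class`, `hgvs_p`, `time`, `event`, `tumor_type` (MAF-style
#'   names `Variant_Classification`, `HGVSp_Short`,
#'   `Tumor_Sample_Barcode` are recognized).
#' @param preds Prediction table (`variant`, `class`) covering the missense
#'   variants.
#' @return The cohort with a `category` column (`no_mutation`,
#'   `missense_ND`, `missense_D`, `truncating`, `excluded`) and an
#'   `exclusion_reason` column; attribute `accounting` counts each
#'   category and exclusion reason.
#' @export
categorize_survival <- function(cohort, preds) {
  cohort <- as_survival_cohort(cohort)
  preds <- as_prediction_table(preds)
  cls <- stats::setNames(preds$class, preds$variant)

  split_field <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
  }
  classes <- split_field(cohort$variant_class)
  hgvs <- if ("hgvs_p" %in% names(cohort)) split_field(cohort$hgvs_p)
          else rep(list(character()), nrow(cohort))
  n_mut <- lengths(classes)

  category <- rep(NA_character_, nrow(cohort))
  reason <- rep(NA_character_, nrow(cohort))

  multi_sample <- cohort$patient_id %in%
    names(which(table(cohort$patient_id) > 1L))
  category[multi_sample] <- "excluded"
  reason[multi_sample] <- "multiple_samples_per_patient"

  for (i in which(is.na(category))) {
    if (n_mut[i] == 0L) {
      category[i] <- "no_mutation"
    } else if (n_mut[i] > 1L) {
      category[i] <- "excluded"
      reason[i] <- "multiple_mutations"
    } else {
      vc <- tolower(classes[[i]])
      if (!(vc %in% KNOWN_CLASSES)) {
        warning("unknown variant class '", classes[[i]], "'; sample excluded")
        category[i] <- "excluded"
        reason[i] <- "unknown_variant_class"
      } else if (vc %in% TRUNCATING_CLASSES) {
        category[i] <- "truncating"
      } else if (vc %in% MISSENSE_CLASSES) {
        v <- if (length(hgvs[[i]])) hgvs[[i]][1L] else NA_character_
        p <- if (!is.na(v)) unname(cls[v]) else NA_character_
        if (is.na(p)) {
          category[i] <- "excluded"
          reason[i] <- "missense_without_prediction"
        } else {
          category[i] <- paste0("missense_", p)
        }
      } else {
        category[i] <- "excluded"
        reason[i] <- "other_non_missense_class"
      }
    }
  }
  cohort$category <- category
  cohort$exclusion_reason <- reason
  attr(cohort, "accounting") <- list(
    n_input = nrow(cohort),
    categories = as.list(table(category)),
    exclusions = as.list(table(reason))
  )
  cohort
}

#' Kaplan-Meier and proportional-hazards analysis of a categorized cohort
#'
#' Fits per-category Kaplan-Meier curves, pairwise two-group Cox
#' proportional-hazards comparisons (score-test p-values and hazard
#' ratios), and a multivariable Cox model over the missense samples with
#' prediction class and tumor type as covariates. Configured outlier tumor
#' types are removed before the multivariable fit.
#'
#' @param categorized Output of [categorize_survival()] (rows with category
#'   `"excluded"` are dropped).
#' @param exclude_tumor_types Tumor types removed before the multivariable
#'   fit (default `c("PCPG", "TGCT", "DLBC")`, small types with extreme
#'   survival).
#' @return Object of class `prof_survival`: `km` (a `survfit`),
#'   `pairwise` (data.frame of category pairs with `hr`, `p_value`; `NA`
#'   when a category has no events), `cox_multivariable` (a `coxph` fit or
#'   NULL), `category_counts`.
#' @export
survival_analyze <- function(categorized,
                             exclude_tumor_types = c("PCPG", "TGCT", "DLBC")) {
  df <- as.data.frame(categorized)
  df <- df[df$category != "excluded", , drop = FALSE]
  cats <- unique(df$category)
  if (length(cats) < 2L) {
    stop("need at least two mutation-status categories with samples")
  }
  events_per_cat <- tapply(df$event, df$category, sum)
  if (sum(events_per_cat > 0) < 2L) {
    stop("need at least two categories with observed events")
  }
  df$category <- factor(df$category)
  km <- survival::survfit(survival::Surv(time, event) ~ category, data = df)

  pairs <- utils::combn(sort(as.character(cats)), 2L)
  pairwise <- do.call(rbind, apply(pairs, 2L, function(pr) {
    sub <- df[df$category %in% pr, , drop = FALSE]
    if (any(tapply(sub$event, factor(sub$category, levels = pr), sum,
                   default = 0) == 0)) {
      return(data.frame(group1 = pr[1], group2 = pr[2], hr = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- survival::coxph(
      survival::Surv(time, event) ~ I(category == pr[2]), data = sub
    )
    sc <- summary(fit)
    data.frame(group1 = pr[1], group2 = pr[2],
               hr = unname(exp(stats::coef(fit)[1])),
               p_value = unname(sc$sctest["pvalue"]),
               stringsAsFactors = FALSE)
  }))

  mis <- df[df$category %in% c("missense_D", "missense_ND") &
              !(df$tumor_type %in% exclude_tumor_types), , drop = FALSE]
  cox_mv <- NULL
  if (length(unique(mis$category)) == 2L && sum(mis$event) > 0) {
    mis$category <- droplevels(factor(mis$category,
                                      levels = c("missense_ND", "missense_D")))
    cox_mv <- survival::coxph(
      survival::Surv(time, event) ~ category + factor(tumor_type), data = mis
    )
  }
  structure(
    list(km = km, pairwise = pairwise, cox_multivariable = cox_mv,
         category_counts = table(df$category),
         n_excluded_tumor_types = sum(df$tumor_type %in% exclude_tumor_types)),
    class = "prof_survival"
  )
}

#' @export
print.prof_survival <- function(x, ...) {
  cat("Survival stratification\n  category counts:\n")
  for (k in names(x$category_counts)) {
    cat(sprintf("    %-14s %d\n", k, x$category_counts[[k]]))
  }
  cat("  pairwise proportional-hazards comparisons:\n")
  print(x$pairwise, row.names = FALSE)
  if (!is.null(x$cox_multivariable)) {
    co <- summary(x$cox_multivariable)$coefficients
    i <- grep("^category", rownames(co))
    cat(sprintf("  multivariable (with tumor type): HR(D vs ND) %.3f, p %.4g\n",
                exp(co[i, "coef"]), co[i, "Pr(>|z|)"]))
  }
  invisible(x)
}

#' @export
plot.prof_survival <- function(x, ...) {
  graphics::plot(x$km, col = seq_along(x$category_counts), lwd = 2,
                 xlab = "time", ylab = "survival probability", ...)
  graphics::legend("bottomleft", legend = names(x$category_counts),
                   col = seq_along(x$category_counts), lwd = 2, bty = "n")
  invisible(x)
}
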