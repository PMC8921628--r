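#' Seeded generators for every pipeline input
#'
#' Every stage of the pipeline can be exercised without external data: the
#' generators emit occurrence tables, feature matrices, annotation tables,
#' tumor corpora and survival cohorts with the statistical structure of the
#' real inputs, plus a ground-truth manifest. All randomness flows from a
#' single seed, and identical seeds give identical output.
#'
#' @name synthetic_fixtures
NULL

#' Simulate a labeled training cohort with features
#'
#' Generates a missense variant universe in which a planted
#' cancer-shared-dataset (CSD) subset recurs in every cancer database, a
#' planted negative subset is absent or seen once, and the remainder shows
#' intermediate prevalence. Scores are drawn from class-conditional
#' Gaussians: functional-assay readouts are strongly bimodal in the latent
#' functionality class, computational scores carry weaker signal. A
#' configurable fraction of variants is "partial-function": their scores
#' sit midway between the two modes, emulating splice-affected,
#' oligomerization-domain and partial loss-of-function variants that
#' expression-based assays cannot resolve. The cell-cycle-arrest readout is
#' only observed inside a codon window (the DNA-binding domain in the real
#' assay); other scores go missing at random.
#'
#' Defaults mirror the real accounting: 2314 missense variants, 290 CSD
#' positives, 693 + 323 absent/singleton negatives, four databases.
#'
#' @param n_variants Size of the missense variant universe.
#' @param n_datasets Number of cancer databases.
#' @param csd_size,n_absent,n_singleton Planted set sizes.
#' @param separation_functional,separation_computational Distance between
#'   the class means of each score group, in units of the within-class
#'   standard deviation.
#' @param partial_rate Fraction of variants with intermediate
#'   ("partial-function") scores.
#' @param missing_rate Random missingness rate for ordinary scores.
#' @param arrest_window Codon interval (on a 1-393 protein) inside which
#'   the cell-cycle-arrest readout is observed.
#' @param n_codons Protein length used to place variants on codons.
#' @param seed Integer seed.
#' @return List with `occurrence` (data.frame `variant`, `dataset_id`,
#'   `count`), `features` (an unimputed [feature_matrix()] with the default
#'   42-feature spec), and `truth` (data.frame `variant`, `codon`,
#'   `latent_class` (`"D"`/`"ND"`), `partial`, `provenance`
#'   (`csd`/`absent`/`singleton`/`other`)).
#' @export
simulate_cohort <- function(n_variants = 2314L, n_datasets = 4L,
                            csd_size = 290L, n_absent = 693L,
                            n_singleton = 323L,
                            separation_functional = 4,
                            separation_computational = 1.5,
                            partial_rate = 0.07, missing_rate = 0.05,
                            arrest_window = c(94L, 312L),
                            n_codons = 393L, seed = 1L) {
  if (csd_size + n_absent + n_singleton > n_variants) {
    stop("planted set sizes exceed the number of variants")
  }
  set.seed(seed)
  variant <- sprintf("p.V%04dX", seq_len(n_variants))
  codon <- sample(seq_len(n_codons), n_variants, replace = TRUE)

  provenance <- rep("other", n_variants)
  planted <- sample(n_variants, csd_size + n_absent + n_singleton)
  provenance[planted[seq_len(csd_size)]] <- "csd"
  provenance[planted[csd_size + seq_len(n_absent)]] <- "absent"
  provenance[planted[csd_size + n_absent + seq_len(n_singleton)]] <- "singleton"

  latent <- ifelse(provenance == "csd", "D",
                   ifelse(provenance %in% c("absent", "singleton"), "ND",
                          sample(c("D", "ND"), n_variants, replace = TRUE)))
  partial <- stats::runif(n_variants) < partial_rate

  datasets <- paste0("db", seq_len(n_datasets))
  occ <- list()
  for (i in seq_len(n_variants)) {
    counts <- switch(
      provenance[i],
      csd = 1L + stats::rpois(n_datasets, lambda = exp(stats::rnorm(1, 1, 1.2))),
      absent = integer(n_datasets),
      singleton = {
        z <- integer(n_datasets)
        z[sample(n_datasets, 1L)] <- 1L
        z
      },
      other = {
        # intermediate prevalence: total >= 2 but never in all datasets
        z <- integer(n_datasets)
        k <- sample(n_datasets - 1L, 1L)
        z[sample(n_datasets, k)] <- 1L + stats::rpois(k, 2)
        if (sum(z) < 2L) z[which.max(z)] <- 2L
        z
      }
    )
    keep <- counts > 0L
    if (any(keep)) {
      occ[[length(occ) + 1L]] <- data.frame(
        variant = variant[i], dataset_id = datasets[keep],
        count = counts[keep], stringsAsFactors = FALSE
      )
    }
  }
  occ <- do.call(rbind, occ)
  rownames(occ) <- NULL

  spec <- default_feature_spec()
  values <- matrix(NA_real_, n_variants, nrow(spec),
                   dimnames = list(variant, spec$name))
  is_d <- latent == "D"
  for (j in seq_len(nrow(spec))) {
    sep <- if (spec$group[j] == "functional") separation_functional
           else separation_computational
    # orient so "deleterious" sits on the score's deleterious side
    mu_d <- if (spec$direction[j] == "lower_deleterious") 0 else sep
    mu_nd <- sep - mu_d
    mu <- ifelse(is_d, mu_d, mu_nd)
    mu[partial] <- sep / 2
    values[, j] <- stats::rnorm(n_variants, mean = mu, sd = 1)
  }

  arrest <- which(spec$name == "cell_cycle_arrest")
  outside <- codon < arrest_window[1] | codon > arrest_window[2]
  values[outside, arrest] <- NA_real_
  ordinary <- setdiff(seq_len(nrow(spec)), arrest)
  drop <- matrix(stats::runif(n_variants * length(ordinary)) < missing_rate,
                 n_variants, length(ordinary))
  values[, ordinary][drop] <- NA_real_

  list(
    occurrence = occ,
    features = feature_matrix(values, spec = spec),
    truth = data.frame(variant = variant, codon = codon,
                       latent_class = latent, partial = partial,
                       provenance = provenance, stringsAsFactors = FALSE)
  )
}

#' Simulate a tumor corpus for prevalence statistics
#'
#' Tumors carry one, two, or three-plus variants of the gene in configured
#' proportions (default 91/7/2%, the composition observed in large curated
#' corpora), with variants assigned uniformly from a pool and a configured
#' germline fraction.
#'
#' @param n_tumors Number of tumor records.
#' @param fractions Length-3 proportions of single/double/multi-variant
#'   tumors (must sum to 1).
#' @param variant_pool Variant keys to draw from.
#' @param germline_fraction Fraction of records flagged germline.
#' @param seed Integer seed.
#' @return Tumor record data.frame (`sample_id`, `origin`, `variants`).
#' @export
simulate_tumor_corpus <- function(n_tumors = 1000L,
                                  fractions = c(0.91, 0.07, 0.02),
                                  variant_pool = sprintf("p.V%04dX", 1:200),
                                  germline_fraction = 0.1, seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("tumor fractions must sum to 1")
  if (length(variant_pool) < 4L) stop("variant pool too small")
  set.seed(seed)
  n_var <- sample(c(1L, 2L, 3L), n_tumors, replace = TRUE, prob = fractions)
  extra <- n_var == 3L
  n_var[extra] <- 3L + stats::rpois(sum(extra), 0.5)
  data.frame(
    sample_id = sprintf("T%05d", seq_len(n_tumors)),
    origin = ifelse(stats::runif(n_tumors) < germline_fraction,
                    "germline", "somatic"),
    variants = vapply(n_var, function(k) {
      paste(sample(variant_pool, min(k, length(variant_pool))),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a survival cohort with category-dependent hazards
#'
#' Event times are exponential with rate `baseline_hazard * hr[category]`;
#' censoring is independent exponential, calibrated so roughly
#' `censor_rate` of samples are censored under the baseline hazard.
#'
#' @param n Number of samples.
#' @param category_probs Named probabilities over mutation-status
#'   categories.
#' @param hr Named hazard ratios per category (reference 1).
#' @param baseline_hazard Baseline event rate (events per time unit).
#' @param censor_rate Approximate fraction censored.
#' @param tumor_types Tumor type labels sampled uniformly.
#' @param seed Integer seed.
#' @return data.frame `patient_id`, `sample_id`, `variant_class`, `hgvs_p`,
#'   `time`, `event`, `tumor_type`, `category` (ground truth); missense
#'   rows carry synthetic variant keys named after their category so a
#'   matching prediction table is `attr(.., "preds")`.
#' @export
simulate_survival_cohort <- function(n = 2000L,
                                     category_probs = c(no_mutation = 0.68,
                                                        missense_ND = 0.01,
                                                        missense_D = 0.20,
                                                        truncating = 0.11),
                                     hr = c(no_mutation = 1,
                                            missense_ND = 1,
                                            missense_D = 2,
                                            truncating = 2),
                                     baseline_hazard = 0.1,
                                     censor_rate = 0.3,
                                     tumor_types = c("BRCA", "LUAD", "COAD",
                                                     "GBM", "UCEC"),
                                     seed = 1L) {
  stopifnot(abs(sum(category_probs) - 1) < 1e-8, all(hr > 0))
  if (censor_rate >= 1) {
    stop("censor_rate must be < 1: a fully censored cohort has no events")
  }
  set.seed(seed)
  category <- sample(names(category_probs), n, replace = TRUE,
                     prob = category_probs)
  rate <- baseline_hazard * unname(hr[category])
  t_event <- stats::rexp(n, rate)
  censor_hazard <- baseline_hazard * censor_rate / max(1 - censor_rate, 1e-9)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_hazard) else Inf
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  variant_class <- c(no_mutation = "", missense_ND = "Missense_Mutation",
                     missense_D = "Missense_Mutation",
                     truncating = "Nonsense_Mutation")[category]
  hgvs_p <- c(no_mutation = "", missense_ND = "p.SIM_ND",
              missense_D = "p.SIM_D", truncating = "")[category]
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    sample_id = sprintf("S%05d", seq_len(n)),
    variant_class = unname(variant_class), hgvs_p = unname(hgvs_p),
    time = time, event = event,
    tumor_type = sample(tumor_types, n, replace = TRUE),
    category = category, stringsAsFactors = FALSE
  )
  attr(out, "preds") <- data.frame(
    variant = c("p.SIM_ND", "p.SIM_D"), class = c("ND", "D"),
    stringsAsFactors = FALSE
  )
  out
}

#' Simulate a raw five-tier annotation table with curation defects
#'
#' Builds a table that curates to exactly
#' `n_records - n_same_label_duplicates - n_indel` records: a clean base of
#' distinct missense variants, plus duplicate records repeating an existing
#' variant with the same tier, indel-derived records, and optional
#' conflicting-label pairs.
#'
#' @param n_records Total raw records.
#' @param n_same_label_duplicates Duplicate records sharing their
#'   variant's tier.
#' @param n_indel Indel-derived records.
#' @param n_conflict Variants given a second record with a different tier.
#' @param tier_probs Tier distribution of the clean base.
#' @param variant_pool Optional variant keys for the clean base.
#' @param seed Integer seed.
#' @return data.frame `variant`, `tier`, `record_id`, `variant_class`.
#' @export
simulate_clinvar_table <- function(n_records = 778L,
                                   n_same_label_duplicates = 22L,
                                   n_indel = 8L, n_conflict = 0L,
                                   tier_probs = c(P = 0.15, LP = 0.07,
                                                  VUS = 0.71, LB = 0.04,
                                                  B = 0.03),
                                   variant_pool = NULL, seed = 1L) {
  n_base <- n_records - n_same_label_duplicates - n_indel - n_conflict
  if (n_base < 1L) stop("defect counts exceed the table size")
  set.seed(seed)
  if (is.null(variant_pool)) {
    variant_pool <- sprintf("p.C%04dV", seq_len(n_base))
  }
  if (length(variant_pool) < n_base) stop("variant pool too small")
  base <- data.frame(
    variant = variant_pool[seq_len(n_base)],
    tier = sample(names(tier_probs), n_base, replace = TRUE,
                  prob = tier_probs),
    variant_class = "missense", stringsAsFactors = FALSE
  )
  conf_idx <- if (n_conflict > 0) sample(n_base, n_conflict) else integer()
  dup_idx <- sample(setdiff(seq_len(n_base), conf_idx),
                    n_same_label_duplicates, replace = TRUE)
  dup <- base[dup_idx, , drop = FALSE]
  conflict <- base[conf_idx, , drop = FALSE]
  if (n_conflict > 0) {
    conflict$tier <- vapply(conflict$tier, function(t) {
      sample(setdiff(CLINVAR_TIERS, t), 1L)
    }, character(1))
  }
  indel <- data.frame(
    variant = sprintf("p.IND%03d", seq_len(n_indel)),
    tier = sample(names(tier_probs), n_indel, replace = TRUE,
                  prob = tier_probs),
    variant_class = "indel_derived", stringsAsFactors = FALSE
  )
  out <- rbind(base, dup, conflict, indel)
  out <- out[sample(nrow(out)), , drop = FALSE]
  out$record_id <- sprintf("RCV%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
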