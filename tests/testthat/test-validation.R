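test_that("annotation curation reproduces the 778 -> 748 accounting", {
  raw <- simulate_clinvar_table(n_records = 778, n_same_label_duplicates = 22,
                                n_indel = 8, seed = 17)
  expect_identical(nrow(raw), 778L)
  curated <- curate_clinvar(raw)
  acc <- attr(curated, "accounting")
  expect_identical(acc$removed_duplicates, 22L)
  expect_identical(acc$removed_indel, 8L)
  expect_identical(acc$n_retained, 748L)
  expect_identical(nrow(curated), 748L)
})

test_that("curation collapses conflicting labels to VUS and is idempotent", {
  raw <- data.frame(
    variant = c("p.A1B", "p.A1B", "p.C2D", "p.C2D", "p.E3F", "p.G4H", "p.G4H"),
    tier = c("P", "B", "LP", "LP", NA, "B", NA),
    variant_class = "missense", stringsAsFactors = FALSE
  )
  curated <- curate_clinvar(raw)
  tier_of <- stats::setNames(curated$tier, curated$variant)
  expect_identical(unname(tier_of["p.A1B"]), "VUS")  # P vs B conflict
  expect_identical(unname(tier_of["p.C2D"]), "LP")   # same-label duplicate
  expect_identical(unname(tier_of["p.E3F"]), "VUS")  # absent label
  expect_identical(unname(tier_of["p.G4H"]), "VUS")  # label + absent label
  expect_identical(nrow(curated), 4L)

  again <- curate_clinvar(curated)
  expect_identical(again$tier, curated$tier)
  expect_identical(again$variant, curated$variant)
  expect_identical(attr(again, "accounting")$removed_duplicates, 0L)

  expect_error(curate_clinvar(raw[0, ]), "empty")
  expect_error(curate_clinvar(data.frame(variant = "x", tier = "maybe")),
               "unknown annotation tier")
})

test_that("annotation comparison maps tiers, splits VUS and warns on gaps", {
  curated <- data.frame(
    variant = sprintf("p.M%03dX", 1:10),
    tier = c("P", "P", "LP", "B", "LB", "VUS", "VUS", "VUS", "B", "P"),
    stringsAsFactors = FALSE
  )
  preds <- data.frame(
    variant = sprintf("p.M%03dX", 1:10),
    class = c("D", "D", "ND", "ND", "ND", "D", "ND", "ND", "ND", "D")
  )
  rep <- compare_clinvar(curated, preds)
  expect_identical(rep$cm$tp, 3L)
  expect_identical(rep$cm$tn, 3L)
  expect_identical(rep$cm$fn, 1L)
  expect_identical(rep$cm$fp, 0L)
  expect_identical(rep$vus$predicted_D, 1L)
  expect_identical(rep$vus$predicted_ND, 2L)

  expect_warning(compare_clinvar(curated, preds[1:9, ]), "no prediction")

  all_vus <- curated
  all_vus$tier <- "VUS"
  rep2 <- compare_clinvar(all_vus, preds)
  expect_identical(rep2$cm$tp + rep2$cm$tn + rep2$cm$fp + rep2$cm$fn, 0L)
  expect_identical(rep2$vus$predicted_D + rep2$vus$predicted_ND, 10L)

  b_only <- data.frame(variant = preds$variant, tier = "B")
  all_d <- data.frame(variant = preds$variant, class = "D")
  rep3 <- compare_clinvar(b_only, all_d)
  expect_identical(rep3$metrics$specificity, 0)
})

test_that("familial-cohort validation reproduces the published accountings", {
  # 60 distinct variants, 2 misidentified SNPs removed, 54 predicted D
  variants <- sprintf("p.L%03dX", 1:60)
  snps <- variants[59:60]
  cls <- rep("D", 60)
  cls[c(55:58)] <- "ND"           # four genuine misses
  cls[59:60] <- "ND"              # the SNPs (excluded from the denominator)
  preds <- data.frame(variant = variants, class = cls)
  rep <- lfs_validate(variants, preds, excluded_snps = snps)
  expect_identical(rep$accounting$n_remaining, 58L)
  expect_identical(rep$accounting$n_correct, 54L)
  expect_identical(round(rep$metrics$accuracy, 1), 93.1)

  # 77 variants, 3 SNP exclusions, 71 predicted D -> 95.9%
  v2 <- sprintf("p.G%03dX", 1:77)
  cls2 <- c(rep("D", 71), rep("ND", 6))
  rep2 <- lfs_validate(v2, data.frame(variant = v2, class = cls2),
                       excluded_snps = v2[75:77])
  expect_identical(round(rep2$metrics$accuracy, 1), 95.9)

  # duplicated family records and ordering do not change the result
  rep3 <- lfs_validate(rev(c(variants, variants[1:20])), preds,
                       excluded_snps = snps)
  expect_identical(rep3$metrics$accuracy, rep$metrics$accuracy)

  # founder exclusion and all-correct edge
  rep4 <- lfs_validate(c("p.R337H", v2[1:5]),
                       data.frame(variant = c("p.R337H", v2[1:5]),
                                  class = "D"),
                       excluded_founders = "p.R337H")
  expect_identical(rep4$metrics$accuracy, 100)
  expect_warning(
    lfs_validate(v2[1:5], data.frame(variant = v2[1:5], class = "D"),
                 excluded_snps = "p.NOT_THERE"),
    "absent from the cohort"
  )
})

test_that("population summaries partition variants by predicted class", {
  pop <- data.frame(variant = sprintf("p.P%03dX", 1:196),
                    allele_freq = 10^runif(196, -6, -1))
  cls <- rep("ND", 196)
  cls[sample.int(196, 39)] <- "D"
  rep <- summarize_population(pop, data.frame(variant = pop$variant,
                                              class = cls))
  expect_identical(rep$accounting$n_D, 39L)
  expect_identical(rep$accounting$n_ND, 157L)
  expect_identical(rep$accounting$n_D + rep$accounting$n_ND,
                   rep$accounting$n)
  expect_identical(nrow(rep$table), 196L)

  empty <- summarize_population(pop[0, , drop = FALSE],
                                data.frame(variant = "x", class = "D"))
  expect_identical(empty$accounting$n, 0L)
  all_d <- summarize_population(pop, data.frame(variant = pop$variant,
                                                class = "D"))
  expect_identical(all_d$accounting$n_ND, 0L)
})

test_that("survival categorization applies the exclusion and class rules", {
  preds <- data.frame(variant = c("p.A1B", "p.C2D"), class = c("D", "ND"))
  cohort <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P7", "P8"),
    sample_id = paste0("S", 1:9),
    variant_class = c("", "Missense_Mutation", "Missense_Mutation",
                      "Nonsense_Mutation",
                      "Missense_Mutation;Nonsense_Mutation",
                      "In_Frame_Del", "Missense_Mutation", "",
                      "Splice_Site"),
    hgvs_p = c("", "p.A1B", "p.C2D", "", "p.A1B;", "", "p.A1B", "", ""),
    time = 1:9, event = 1L, tumor_type = "BRCA",
    stringsAsFactors = FALSE
  )
  cat_df <- categorize_survival(cohort, preds)
  expect_identical(cat_df$category,
                   c("no_mutation", "missense_D", "missense_ND", "truncating",
                     "excluded", "excluded", "excluded", "excluded",
                     "truncating"))
  expect_identical(cat_df$exclusion_reason[5], "multiple_mutations")
  expect_identical(cat_df$exclusion_reason[6], "other_non_missense_class")
  expect_identical(cat_df$exclusion_reason[7], "multiple_samples_per_patient")

  # disjoint exhaustive partition of input rows
  acc <- attr(cat_df, "accounting")
  expect_identical(sum(unlist(acc$categories)), nrow(cohort))

  # unknown class strings are excluded with a warning, not an error
  odd <- cohort[2, ]
  odd$variant_class <- "Weird_Class"
  expect_warning(categorize_survival(odd, preds), "unknown variant class")
})

test_that("survival analysis recovers a planted hazard ratio", {
  # balanced categories so every comparison has adequate events
  sim <- simulate_survival_cohort(
    n = 2000,
    category_probs = c(no_mutation = 0.4, missense_ND = 0.2,
                       missense_D = 0.2, truncating = 0.2),
    seed = 23
  )
  cat_df <- categorize_survival(sim[, setdiff(names(sim), "category")],
                                attr(sim, "preds"))
  # generator truth and categorization agree
  expect_identical(cat_df$category, sim$category)
  fit <- survival_analyze(cat_df)
  pw <- fit$pairwise
  row <- pw[pw$group1 == "missense_D" & pw$group2 == "missense_ND", ]
  # HR(ND vs D) is the inverse of the planted HR(D vs ND) = 2
  expect_lt(abs(1 / row$hr - 2) / 2, 0.35)
  expect_lt(row$p_value, 0.05)

  hr_mv <- exp(stats::coef(fit$cox_multivariable)[1])
  expect_gt(hr_mv, 1.7)
  expect_lt(hr_mv, 2.35)

  expect_error(
    survival_analyze(cat_df[cat_df$category == "missense_D", ]),
    "at least two"
  )
  expect_error(simulate_survival_cohort(n = 50, censor_rate = 1),
               "no events")
})

test_that("threshold adapters honour cutoffs, maps and uncertain bands", {
  revel_b <- threshold_rule("REVEL", "numeric_cutoff", cutoff = 0.5)
  revel_c <- threshold_rule("REVEL", "numeric_cutoff", cutoff = 0.7)
  scores <- data.frame(variant = "v", score = 0.6)
  expect_identical(classify_by_threshold(scores, revel_b)$class, "D")
  expect_identical(classify_by_threshold(scores, revel_c)$class, "ND")

  ma <- default_threshold_rules()$Mutassessor
  got <- classify_by_threshold(
    data.frame(variant = c("a", "b", "c"),
               score = c("medium", "neutral", NA)), ma
  )
  expect_identical(got$class, c("D", "ND", "uncertain"))
  expect_error(
    classify_by_threshold(data.frame(variant = "a", score = "spicy"), ma),
    "vocabulary"
  )

  # lower_deleterious flips the inequality; boundary is deleterious
  sift <- threshold_rule("SIFT", "numeric_cutoff", cutoff = 0.05,
                         direction = "lower_deleterious")
  got2 <- classify_by_threshold(
    data.frame(variant = c("a", "b", "c"), score = c(0.01, 0.05, 0.2)), sift
  )
  expect_identical(got2$class, c("D", "D", "ND"))

  band <- threshold_rule("EVE", "cutoff_with_uncertain_band",
                         cutoff = c(0.3, 0.7))
  got3 <- classify_by_threshold(
    data.frame(variant = c("a", "b", "c"), score = c(0.2, 0.5, 0.9)), band
  )
  expect_identical(got3$class, c("ND", "uncertain", "D"))

  # monotone contract: raising a score never flips D -> ND
  set.seed(2)
  s <- sort(runif(50))
  cls <- classify_by_threshold(data.frame(variant = seq_along(s), score = s),
                               revel_b)$class
  expect_true(all(diff(cls == "D") >= 0))
})

test_that("null survival comparisons are calibrated (quick check)", {
  # full 1000-replicate calibration runs in the acceptance suite
  set.seed(41)
  p <- replicate(200, {
    time <- rexp(80)
    cens <- rexp(80, 0.4)
    df <- data.frame(time = pmin(time, cens),
                     event = as.integer(time <= cens),
                     grp = rep(c("A", "B"), 40))
    fit <- survival::coxph(survival::Surv(time, event) ~ grp, data = df)
    summary(fit)$sctest["pvalue"]
  })
  expect_lt(mean(p < 0.05), 0.1)
})
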