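occ_fixture <- function() {
  data.frame(
    variant = c(rep("p.A1B", 4), rep("p.C2D", 3), "p.E3F", "p.G4H"),
    dataset_id = c("db1", "db2", "db3", "db4",
                   "db1", "db2", "db3", "db2", "db1"),
    count = c(2, 1, 5, 1, 3, 1, 1, 1, 5),
    stringsAsFactors = FALSE
  )
}

test_that("positive set requires presence in every dataset", {
  occ <- occ_fixture()
  expect_identical(build_positive_set(occ, paste0("db", 1:4)), "p.A1B")
  # p.C2D present in 3 of 4 only
  expect_identical(build_positive_set(occ, paste0("db", 1:3)),
                   c("p.A1B", "p.C2D"))
  expect_error(build_positive_set(occ, "db1"), "at least 2")
  expect_error(build_positive_set(occ, c("db1", "nope")), "unknown dataset")
  empty <- occ[0, ]
  expect_error(build_positive_set(empty, c("db1", "db2")), "unknown dataset")
})

test_that("negative set collects absent and singleton variants", {
  occ <- occ_fixture()
  vs <- enumerate_snvs(coding_sequence("ATGGCATGA"))
  # none of the fixture variants live in this space -> all 12 negatives absent
  neg <- build_negative_set(occ, vs)
  expect_identical(length(neg), 12L)
  expect_true(all(attr(neg, "provenance") == "absent"))

  # plant occurrences on real space variants
  occ2 <- rbind(occ, data.frame(variant = c("p.M1L", "p.A2T", "p.A2V"),
                                dataset_id = "db1", count = c(1, 5, 0)))
  neg2 <- build_negative_set(occ2, vs)
  expect_true("p.M1L" %in% neg2)      # singleton
  expect_true("p.A2V" %in% neg2)      # zero count row
  expect_false("p.A2T" %in% neg2)     # count 5: unlabeled
  prov <- attr(neg2, "provenance")
  expect_identical(unname(prov["p.M1L"]), "singleton")
  expect_identical(unname(prov["p.A2V"]), "absent")
})

test_that("labeling rules are monotone in their parameters", {
  sim <- simulate_cohort(n_variants = 150, csd_size = 20, n_absent = 40,
                         n_singleton = 20, seed = 9)
  occ <- sim$occurrence
  pos3 <- build_positive_set(occ, paste0("db", 1:3))
  pos4 <- build_positive_set(occ, paste0("db", 1:4))
  expect_true(all(pos4 %in% pos3))

  vs_keys <- sim$truth$variant
  fake_space <- structure(
    list(protein_missense = data.frame(hgvs_p = vs_keys)),
    class = "variant_space"
  )
  n1 <- build_negative_set(occ, fake_space, max_total_count = 1)
  n5 <- build_negative_set(occ, fake_space, max_total_count = 5)
  expect_true(all(n1 %in% n5))
})

test_that("planted CSD and negative sets are recovered exactly", {
  sim <- simulate_cohort(n_variants = 600, csd_size = 60, n_absent = 150,
                         n_singleton = 70, seed = 21)
  truth <- sim$truth
  pos <- build_positive_set(sim$occurrence, paste0("db", 1:4))
  expect_setequal(pos, truth$variant[truth$provenance == "csd"])

  fake_space <- structure(
    list(protein_missense = data.frame(hgvs_p = truth$variant)),
    class = "variant_space"
  )
  neg <- build_negative_set(sim$occurrence, fake_space)
  expect_setequal(neg, truth$variant[truth$provenance %in%
                                       c("absent", "singleton")])
})

test_that("cohort assembly removes hold-outs with full accounting", {
  sim <- simulate_cohort(n_variants = 400, csd_size = 50, n_absent = 100,
                         n_singleton = 50, seed = 4)
  truth <- sim$truth
  pos <- truth$variant[truth$provenance == "csd"]
  neg <- truth$variant[truth$provenance %in% c("absent", "singleton")]
  space <- structure(
    list(protein_missense = data.frame(hgvs_p = truth$variant)),
    class = "variant_space"
  )
  holdout <- c(pos[1:7], neg[1:5], setdiff(truth$variant, c(pos, neg))[1])
  cohort <- assemble_cohort(pos, neg, holdout, space)
  expect_identical(cohort$sizes$pos_after, 43L)
  expect_identical(cohort$sizes$neg_after, 145L)
  expect_identical(cohort$holdout$original_label,
                   c(rep("D", 7), rep("ND", 5), "unlabeled"))
  # partition of the full space
  all_keys <- c(cohort$positives, cohort$negatives,
                cohort$holdout$variant, cohort$unlabeled)
  expect_setequal(all_keys, truth$variant)
  expect_identical(anyDuplicated(all_keys), 0L)

  expect_error(assemble_cohort(pos, c(neg, pos[1]), character(), space),
               "contradiction")
  ident <- assemble_cohort(pos, neg, character(), space)
  expect_identical(sort(ident$positives), sort(pos))

  labs <- cohort_labels(cohort)
  expect_identical(nrow(labs), 43L + 145L)
  expect_setequal(unique(labs$label), c("D", "ND"))
})

test_that("occurrence rows for the same protein variant are aggregated", {
  occ <- data.frame(variant = c("p.A1B", "p.A1B"), dataset_id = "db1",
                    count = c(1, 1))
  occ <- rbind(occ, data.frame(variant = "p.A1B", dataset_id = "db2",
                               count = 1))
  expect_identical(build_positive_set(occ, c("db1", "db2")), "p.A1B")
  vs <- structure(list(protein_missense = data.frame(hgvs_p = "p.A1B")),
                  class = "variant_space")
  # summed count 3 > 1 -> not negative
  expect_identical(length(build_negative_set(occ, vs)), 0L)
})
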