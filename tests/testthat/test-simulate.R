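test_that("null-model genotype frequencies follow Hardy-Weinberg proportions", {
  panel <- one_snp_panel(0.3)
  cfg <- simulation_config(panel, 10000, 10000, seed = 101)
  co <- simulate_cohort(cfg)
  tab <- genotype_counts(co, "rs0000001")
  hwe_props <- c(0.49, 0.42, 0.09)
  for (g in c("case", "control")) {
    n <- sum(tab$counts[g, ])
    freq <- tab$counts[g, ] / n
    se <- sqrt(hwe_props * (1 - hwe_props) / n)
    expect_true(all(abs(freq - hwe_props) < 3 * se))
  }
})

test_that("missingness lands at the configured assay-failure rate", {
  panel <- toy_panel()
  cfg <- simulation_config(panel, 350, 490,
                           missing_rate = c(rs6013897 = 0.012),
                           seed = 202)
  co <- simulate_cohort(cfg)
  frac <- mean(is.na(co$subjects$rs6013897))
  se <- sqrt(0.012 * 0.988 / 840)
  expect_lt(abs(frac - 0.012), 3 * se)
  expect_true(all(!is.na(co$subjects$rs2282679)))
})

test_that("an identical seed reproduces a byte-identical cohort file", {
  cfg <- simulation_config(toy_panel(), 50, 70, missing_rate = 0.02,
                           seed = 303)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(simulate_cohort(cfg), f1)
  write_cohort(simulate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("unreachable quotas abort with diagnostics", {
  cfg <- simulation_config(one_snp_panel(), 1000, 10,
                           baseline_logit = -20, seed = 1)
  expect_error(simulate_cohort(cfg, max_batches = 2L),
               "quotas not reached.*case fraction")
})

test_that("single-SNP test is calibrated under the simulated null", {
  panel <- one_snp_panel(0.3)
  rejections <- vapply(1:500, function(s) {
    co <- simulate_cohort(simulation_config(panel, 120, 120, seed = s))
    single_snp_association(co, "rs0000001", "log-additive")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.08)
})

test_that("fixture expansion from genotype counts alone is marginal-exact", {
  tabs <- study_genotype_counts()
  co <- expand_fixture(tabs["rs12785878"],
                       panel = toy_panel()[1, ])
  expect_equal(nrow(co$subjects), 837)  # 350 cases + 487 genotyped controls
  got <- genotype_counts(co, "rs12785878")
  expect_equal(unname(got$counts["case", ]), c(114, 171, 65))
  expect_equal(unname(got$counts["control", ]), c(189, 221, 77))

  full <- expand_fixture(tabs)
  for (sid in names(tabs)) {
    expect_equal(genotype_counts(full, sid)$counts, tabs[[sid]]$counts,
                 ignore_attr = TRUE)
  }
})

test_that("burden-constrained expansion hits the published distribution exactly", {
  co <- expand_fixture(study_genotype_counts(),
                       burden_counts = study_burden_counts())
  # group sizes recover the true cohort once missingness is laid out
  expect_equal(unname(table(co$subjects$status)[c("case", "control")]),
               c(350L, 490L), ignore_attr = TRUE)
  scores <- burden_scores(co)
  expect_equal(sum(scores$status == "case"), 348)
  expect_equal(sum(scores$status == "control"), 478)
  expect_equal(burden_distribution(scores), study_burden_counts(),
               ignore_attr = TRUE)
  # per-SNP totals are exact; class counts are matched closely (the joint
  # distribution is unidentified from printed marginals)
  tabs <- study_genotype_counts()
  for (sid in names(tabs)) {
    got <- genotype_counts(co, sid)$counts
    expect_equal(rowSums(got), rowSums(tabs[[sid]]$counts))
    expect_lte(max(abs(got - tabs[[sid]]$counts)), 5)
  }
})

test_that("all-zero tables expand to an empty cohort", {
  zero <- genotype_count_table("rs0000001", c(0, 0, 0), c(0, 0, 0))
  co <- expand_fixture(list(zero), panel = one_snp_panel())
  expect_equal(nrow(co$subjects), 0)
})

test_that("a burden total exceeding the genotyped totals is rejected", {
  tab <- genotype_count_table("rs0000001", c(5, 0, 0), c(5, 0, 0))
  burden <- rbind(case = c(200, 0, 0), control = c(5, 0, 0))
  colnames(burden) <- as.character(0:2)
  expect_error(
    expand_fixture(list(tab), panel = one_snp_panel(),
                   burden_counts = burden),
    "inconsistent"
  )
})
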