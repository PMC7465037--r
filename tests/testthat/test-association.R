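test_that("2x2 odds ratios and Woolf intervals reproduce published cells", {
  # CYP2R1 recessive collapse
  r <- or_2x2(62, 288, 58, 431)
  expect_equal(round(r$or, 2), 1.60)
  expect_equal(round(r$ci_low, 2), 1.09)
  expect_equal(round(r$ci_high, 2), 2.36)
  # identity table: OR 1, CI symmetric about 1 on the log scale
  s <- or_2x2(10, 10, 10, 10)
  expect_equal(s$or, 1)
  expect_equal(log(s$ci_high), -log(s$ci_low))
  # dichotomized burden table
  b <- or_2x2(196, 152, 232, 246)
  expect_equal(round(b$or, 2), 1.37)
  expect_equal(round(b$ci_low, 2), 1.04)
})

test_that("zero cells are rejected unless the Haldane correction is asked for", {
  expect_error(or_2x2(0, 5, 5, 5), "zero cell")
  r <- or_2x2(0, 5, 5, 5, haldane = TRUE)
  expect_equal(r$or, (0.5 * 5.5) / (5.5 * 5.5))
})

test_that("collapsed-model logistic ORs equal 2x2 cross-product ratios", {
  set.seed(99)
  for (i in 1:100) {
    tab <- random_count_table()
    co <- cohort_from_counts(tab$case, tab$control)
    for (model in c("dominant", "recessive", "overdominant")) {
      fit <- single_snp_association(co, "rs0000001", model)
      cp <- tab$collapses[[model]]
      oracle <- or_2x2(cp[1], cp[2], cp[3], cp[4])
      expect_equal(fit$estimates$or[1], oracle$or, tolerance = 1e-7)
      # Wald SEs from the IRLS fixed point agree with the closed-form
      # Woolf SE to ~1e-6 relative, not machine precision
      expect_equal(fit$estimates$ci_low[1], oracle$ci_low,
                   tolerance = 1e-5)
      expect_equal(fit$estimates$ci_high[1], oracle$ci_high,
                   tolerance = 1e-5)
    }
  }
})

test_that("swapping group labels inverts the OR and flips the CI", {
  r <- or_2x2(62, 288, 58, 431)
  s <- or_2x2(58, 431, 62, 288)
  expect_equal(s$or, 1 / r$or)
  expect_equal(s$ci_low, 1 / r$ci_high)
  expect_equal(s$ci_high, 1 / r$ci_low)
})

test_that("intercept-only logistic fit recovers the case:control log odds", {
  y <- rep(c(1, 0), c(350, 487))
  f <- fit_logistic(y, matrix(numeric(0), nrow = 837, ncol = 0))
  expect_equal(unname(f$coefficients[1]), log(350 / 487), tolerance = 1e-8)
})

test_that("published single-model ORs come out of the expanded fixture", {
  co <- expand_fixture(study_genotype_counts())
  expect_equal(round(single_snp_association(
    co, "rs12785878", "dominant")$estimates$or, 2), 1.31)
  expect_equal(round(single_snp_association(
    co, "rs2282679", "recessive")$estimates$or, 2), 0.72)
  expect_equal(round(single_snp_association(
    co, "rs2060793", "recessive")$estimates$or, 2), 1.60)
  expect_equal(round(single_snp_association(
    co, "rs6013897", "recessive")$estimates$or, 2), 1.64)
  la <- single_snp_association(co, "rs12785878", "log-additive")
  expect_equal(round(la$estimates$or, 2), 1.20)
})

test_that("codominant reports two ORs and a 2-df likelihood-ratio p", {
  co <- expand_fixture(study_genotype_counts())
  r <- single_snp_association(co, "rs12785878", "codominant")
  expect_equal(nrow(r$estimates), 2)
  expect_equal(r$p_value, r$p_lrt)
  expect_true(all(r$estimates$ci_low <= r$estimates$or))
  expect_true(all(r$estimates$or <= r$estimates$ci_high))
})

test_that("codominant AIC is within 2 of every nested model's AIC", {
  co <- expand_fixture(study_genotype_counts())
  for (sid in co$panel$snp_id) {
    fits <- fit_all_models(co, sid)
    aic_codom <- fits$codominant$aic
    for (m in c("dominant", "recessive", "overdominant", "log-additive")) {
      expect_lte(aic_codom, fits[[m]]$aic + 2 + 1e-8)
    }
  }
})

test_that("AIC selection recovers the published best-model footnotes", {
  co <- expand_fixture(study_genotype_counts())
  expected <- c(rs12785878 = "dominant", rs2282679 = "recessive",
                rs2060793 = "recessive", rs6013897 = "recessive")
  for (sid in names(expected)) {
    sel <- select_best_model(fit_all_models(co, sid))
    expect_identical(sel$model, unname(expected[sid]))
    expect_false(sel$tie)
  }
})

test_that("AIC ties break by the fixed model order and are flagged", {
  # without heterozygotes, dominant and recessive encodings collapse to the
  # same binary design, so their fits tie exactly
  co <- cohort_from_counts(c(30, 0, 20), c(40, 0, 10))
  fits <- list(single_snp_association(co, "rs0000001", "dominant"),
               single_snp_association(co, "rs0000001", "recessive"))
  sel <- select_best_model(fits)
  expect_true(sel$tie)
  expect_identical(sel$model, "dominant")
})

test_that("AIC comparison refuses fits on differing subject subsets", {
  co <- expand_fixture(study_genotype_counts())
  a <- single_snp_association(co, "rs12785878", "dominant")
  b <- single_snp_association(co, "rs6013897", "recessive")
  expect_error(select_best_model(list(a, b)), "identical subject subsets")
})

test_that("a truly recessive signal is recognized by model selection", {
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 4000
    d <- stats::rbinom(n, 2, 0.4)
    y <- stats::rbinom(n, 1, stats::plogis(-0.5 + log(2.5) * (d == 2)))
    panel <- one_snp_panel(0.4)
    gstr <- c("AA", "AG", "GG")[d + 1]
    subjects <- data.frame(
      subject_id = sprintf("s%04d", 1:n),
      status = ifelse(y == 1, "case", "control"),
      sex = "male", age = 30, stringsAsFactors = FALSE
    )
    subjects[[panel$snp_id]] <- gstr
    co <- cohort(panel, subjects)
    select_best_model(fit_all_models(co, "rs0000001"))$model == "recessive"
  }, logical(1))
  expect_gte(sum(hits), 3)
})

test_that("sex/age adjustment changes the subset contract, not the engine", {
  cfg <- simulation_config(toy_panel(), 150, 150,
                           per_allele_log_or = c(rs2060793 = log(1.4)),
                           seed = 77)
  co <- simulate_cohort(cfg)
  un <- single_snp_association(co, "rs2060793", "log-additive")
  ad <- single_snp_association(co, "rs2060793", "log-additive",
                               covariates = c("sex", "age"))
  expect_false(un$adjusted)
  expect_true(ad$adjusted)
  expect_identical(ad$covariates, c("sex", "age"))
  # covariates carry no signal here, so estimates stay close
  expect_equal(log(ad$estimates$or), log(un$estimates$or), tolerance = 0.1)
})

test_that("Bonferroni thresholds and adjusted p-values behave as stated", {
  b <- bonferroni(c(0.018, 0.2, 0.9, 0.004), alpha = 0.05, m = 4)
  expect_equal(b$threshold, 0.0125)
  expect_identical(b$significant, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(b$adjusted_p, pmin(1, 4 * c(0.018, 0.2, 0.9, 0.004)))
  one <- bonferroni(0.03, alpha = 0.05, m = 1)
  expect_equal(one$threshold, 0.05)
  expect_equal(one$adjusted_p, 0.03)
})

test_that("per-allele effects are recovered without bias at large n", {
  panel <- one_snp_panel(0.3)
  est <- vapply(1:8, function(s) {
    cfg <- simulation_config(panel, 20000, 20000,
                             per_allele_log_or = log(1.5), seed = 400 + s)
    co <- simulate_cohort(cfg)
    log(single_snp_association(co, "rs0000001",
                               "log-additive")$estimates$or[1])
  }, numeric(1))
  expect_lt(abs(mean(est) - log(1.5)), 0.02)
})
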