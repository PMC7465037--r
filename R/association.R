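#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' Cross-product odds ratio with the log-scale (Woolf) 95% interval:
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d cell counts: case-exposed, case-unexposed,
#'   control-exposed, control-unexposed.
#' @param conf_level confidence level (multiplier from the normal
#'   quantile; 0.95 gives the fixed 1.96 of standard reporting).
#' @param haldane if `TRUE`, add 0.5 to every cell (Haldane-Anscombe)
#'   instead of rejecting zero cells.
#' @return List with `or`, `ci_low`, `ci_high`, `se_log_or`.
#' @export
or_2x2 <- function(a, b, c, d, conf_level = 0.95, haldane = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table; use haldane = TRUE for the +0.5 ",
           "correction")
    }
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  # the conventional fixed 1.96 at 95%, not qnorm(0.975), to match both
  # the logistic Wald intervals and published reporting practice
  z <- if (conf_level == 0.95) 1.96 else stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se), se_log_or = se)
}

#' Genetic-model encodings of minor-allele dosage
#'
#' Maps a 0/1/2 dosage vector onto the design column(s) of an inheritance
#' model: dominant (any minor allele), recessive (two copies),
#' overdominant (heterozygote), log-additive (dosage itself), codominant
#' (separate heterozygote and minor-homozygote indicators).
#'
#' @param d integer dosage vector (0/1/2, `NA` allowed).
#' @param model model name.
#' @return Numeric matrix with one column (two for codominant).
#' @export
encode_model <- function(d, model = genetic_models()) {
  model <- match.arg(model)
  switch(model,
    dominant = cbind(dominant = as.numeric(d >= 1)),
    recessive = cbind(recessive = as.numeric(d == 2)),
    overdominant = cbind(overdominant = as.numeric(d == 1)),
    `log-additive` = cbind(`log-additive` = as.numeric(d)),
    codominant = cbind(het = as.numeric(d == 1),
                       minor_hom = as.numeric(d == 2))
  )
}

#' The five inheritance models, in canonical order
#'
#' The fixed order is also the tie-break order of AIC model selection.
#'
#' @return Character vector of model names.
#' @export
genetic_models <- function() {
  c("codominant", "dominant", "recessive", "overdominant", "log-additive")
}

#' Maximum-likelihood logistic regression fit
#'
#' Thin wrapper over binomial [stats::glm()] (iteratively reweighted least
#' squares) returning coefficients, Wald standard errors, log-likelihood
#' and AIC, with explicit convergence and separation flags instead of
#' silent warnings.
#'
#' @param y binary outcome vector (1 = case).
#' @param X design matrix (no intercept column; one is added).
#' @return List with `coefficients`, `se`, `loglik`, `aic`, `n`,
#'   `converged`, `separation`, and the underlying `fit`.
#' @export
fit_logistic <- function(y, X) {
  if (length(unique(y)) < 2) stop("outcome has a single class")
  dat <- as.data.frame(X)
  dat$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  if (any(is.na(stats::coef(fit)))) stop("design matrix is rank deficient")
  coefs <- stats::coef(fit)
  separation <- any(abs(coefs) > 15)
  list(
    coefficients = coefs,
    se = sqrt(diag(stats::vcov(fit))),
    loglik = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    n = length(y),
    converged = fit$converged,
    separation = separation,
    fit = fit
  )
}

#' Single-SNP case-control association under one inheritance model
#'
#' Logistic regression of case status on the model-encoded genotype,
#' optionally adjusted for sex (indicator for male) and age (continuous
#' linear term), over subjects with complete data for the SNP and the
#' requested covariates. Odds ratios are exponentiated coefficients with
#' Wald 95% intervals; the model-level p-value is the Wald test for 1-df
#' encodings and the 2-df likelihood-ratio test for the codominant model
#' (the likelihood-ratio p is reported alongside for every model).
#'
#' @param x a `cohort`.
#' @param snp_id rsID in the panel.
#' @param model inheritance model name.
#' @param covariates subset of `c("sex", "age")`.
#' @return An `association_result`: list with the per-term `estimates`
#'   data.frame (or, ci_low, ci_high, p_wald), model-level `p_value` and
#'   `p_lrt`, `aic`, `n`, `adjusted`, flags, and the analyzed subject ids.
#' @export
single_snp_association <- function(x, snp_id,
                                   model = genetic_models(),
                                   covariates = character()) {
  stopifnot(inherits(x, "cohort"))
  model <- match.arg(model)
  if (!all(covariates %in% c("sex", "age"))) {
    stop("covariates must be a subset of c(\"sex\", \"age\")")
  }
  def <- panel_row(x$panel, snp_id)
  d <- dosage(x$subjects[[snp_id]], def$minor)
  keep <- !is.na(d)
  if ("sex" %in% covariates) keep <- keep & !is.na(x$subjects$sex)
  if ("age" %in% covariates) keep <- keep & !is.na(x$subjects$age)
  sub <- x$subjects[keep, , drop = FALSE]
  d <- d[keep]
  y <- as.numeric(sub$status == "case")

  X <- encode_model(d, model)
  geno_terms <- colnames(X)
  if ("sex" %in% covariates) X <- cbind(X, male = as.numeric(sub$sex == "male"))
  if ("age" %in% covariates) X <- cbind(X, age = sub$age)
  fit <- fit_logistic(y, X)

  # glm mangles column names into syntactic form; recover by position
  idx <- seq_along(geno_terms) + 1L
  est <- fit$coefficients[idx]
  se <- fit$se[idx]
  z <- est / se
  estimates <- data.frame(
    term = geno_terms,
    or = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se),
    p_wald = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )

  X0 <- X[, setdiff(colnames(X), geno_terms), drop = FALSE]
  fit0 <- if (ncol(X0) > 0) fit_logistic(y, X0) else {
    f <- suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
    list(loglik = as.numeric(stats::logLik(f)))
  }
  lr <- 2 * (fit$loglik - fit0$loglik)
  p_lrt <- stats::pchisq(max(lr, 0), df = length(geno_terms),
                         lower.tail = FALSE)

  res <- list(
    snp_id = def$snp_id, gene = def$gene, model = model,
    estimates = estimates,
    p_value = if (model == "codominant") p_lrt else estimates$p_wald[1],
    p_lrt = p_lrt,
    aic = fit$aic, loglik = fit$loglik, n = fit$n,
    adjusted = length(covariates) > 0, covariates = covariates,
    converged = fit$converged, separation = fit$separation,
    subject_ids = sub$subject_id
  )
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  adj <- if (x$adjusted) {
    paste0(" adjusted for ", paste(x$covariates, collapse = ", "))
  } else " unadjusted"
  cat(sprintf("%s (%s), %s model,%s, n = %d\n", x$snp_id, x$gene, x$model,
              adj, x$n))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-12s OR %.2f (95%% CI %.2f-%.2f)\n", est$term[i],
                est$or[i], est$ci_low[i], est$ci_high[i]))
  }
  cat(sprintf("  p = %.4f, AIC = %.2f\n", x$p_value, x$aic))
  invisible(x)
}

#' Fit all five inheritance models for one SNP
#'
#' @inheritParams single_snp_association
#' @return Named list of `association_result`s in canonical model order.
#' @export
fit_all_models <- function(x, snp_id, covariates = character()) {
  models <- genetic_models()
  stats::setNames(
    lapply(models, function(m) {
      single_snp_association(x, snp_id, m, covariates)
    }),
    models
  )
}

#' Select the best-fitting inheritance model by AIC
#'
#' Minimum-AIC selection over association results fitted on the identical
#' subject subset. Ties within `tol` are broken by the canonical model
#' order (codominant, dominant, recessive, overdominant, log-additive)
#' and flagged.
#'
#' @param results list of `association_result`s for one SNP.
#' @param tol AIC difference treated as a tie.
#' @return List with `model`, `aic`, `tie`, and the per-model `aic_table`.
#' @export
select_best_model <- function(results, tol = 1e-8) {
  stopifnot(length(results) >= 2)
  ids <- lapply(results, `[[`, "subject_ids")
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop("AIC comparison requires identical subject subsets across models")
  }
  nm <- vapply(results, `[[`, character(1), "model")
  ord <- match(genetic_models(), nm)
  ord <- ord[!is.na(ord)]
  results <- results[ord]
  aic <- vapply(results, `[[`, numeric(1), "aic")
  best <- which(aic <= min(aic) + tol)
  list(
    model = results[[best[1]]]$model,
    aic = aic[best[1]],
    tie = length(best) > 1,
    aic_table = data.frame(
      model = vapply(results, `[[`, character(1), "model"),
      aic = unname(aic), stringsAsFactors = FALSE
    )
  )
}

#' Bonferroni correction
#'
#' Family-wise error control by dividing the significance level by the
#' number of tests: threshold `alpha / m`, adjusted p `min(1, m * p)`.
#'
#' @param p_values numeric vector of raw p-values.
#' @param alpha family-wise significance level.
#' @param m family size (defaults to `length(p_values)`).
#' @return List with `threshold`, `significant` (logical), `adjusted_p`.
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  list(
    threshold = alpha / m,
    significant = p_values < alpha / m,
    adjusted_p = stats::p.adjust(p_values, method = "bonferroni", n = m)
  )
}
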