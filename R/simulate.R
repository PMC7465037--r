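#' Configuration for the cohort simulator
#'
#' Describes the generative model the downstream logistic analysis assumes:
#' genotypes drawn per SNP under Hardy-Weinberg equilibrium at the panel's
#' reference MAFs (independently across SNPs), a logistic disease liability
#' with per-allele log odds ratios and optional sex/age effects, and
#' per-SNP completely-at-random missingness emulating assay failure.
#' Cases and controls are sampled retrospectively from this prospective
#' population model until the quotas are filled.
#'
#' Per-group covariate summaries (`prop_male`, `age_mean`, `age_sd`) are
#' drawn per group after status assignment when both covariate effects are
#' zero (the default, where covariates are independent of status); when a
#' sex or age effect is nonzero, candidates draw covariates from the
#' control-group values (the population proxy) and group differences emerge
#' from the liability itself.
#'
#' @param panel a `snp_panel`; `ref_maf` supplies the simulation MAFs.
#' @param n_cases,n_controls group quotas (positive integers).
#' @param per_allele_log_or named numeric of per-minor-allele log odds
#'   ratios by `snp_id` (unnamed scalar recycled; default 0 = null model).
#' @param baseline_logit intercept of the disease liability.
#' @param sex_log_or log odds ratio for male sex.
#' @param age_log_or_per_year log odds ratio per year of age.
#' @param prop_male,age_mean,age_sd length-2 vectors named `case`/`control`.
#' @param missing_rate named numeric of per-SNP missing-call fractions
#'   (unnamed scalar recycled; default 0).
#' @param seed integer fixing all randomness of [simulate_cohort()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(panel, n_cases, n_controls,
                              per_allele_log_or = 0,
                              baseline_logit = log(350 / 490),
                              sex_log_or = 0, age_log_or_per_year = 0,
                              prop_male = c(case = 184 / 350,
                                            control = 246 / 490),
                              age_mean = c(case = 29.0, control = 32.2),
                              age_sd = c(case = 11.1, control = 11.2),
                              missing_rate = 0, seed = NULL) {
  validate_panel(panel)
  stopifnot(n_cases > 0, n_controls > 0)
  expand_by_snp <- function(x, what) {
    if (is.null(names(x)) && length(x) == 1) {
      x <- stats::setNames(rep(x, nrow(panel)), panel$snp_id)
    }
    out <- stats::setNames(rep(0, nrow(panel)), panel$snp_id)
    unknown <- setdiff(names(x), panel$snp_id)
    if (length(unknown) > 0) {
      stop("unknown snp_id in ", what, ": ", paste(unknown, collapse = ", "))
    }
    out[names(x)] <- x
    out
  }
  per_allele_log_or <- expand_by_snp(per_allele_log_or, "per_allele_log_or")
  missing_rate <- expand_by_snp(missing_rate, "missing_rate")
  if (any(missing_rate < 0) || any(missing_rate >= 1)) {
    stop("missing_rate must lie in [0, 1)")
  }
  grp2 <- function(x) {
    if (length(x) == 1) x <- c(case = unname(x), control = unname(x))
    x[c("case", "control")]
  }
  cfg <- list(
    panel = panel, n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    per_allele_log_or = per_allele_log_or,
    baseline_logit = baseline_logit, sex_log_or = sex_log_or,
    age_log_or_per_year = age_log_or_per_year,
    prop_male = grp2(prop_male), age_mean = grp2(age_mean),
    age_sd = grp2(age_sd), missing_rate = missing_rate, seed = seed
  )
  class(cfg) <- "simulation_config"
  cfg
}

rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(neg <- x < 0)) x[neg] <- stats::rnorm(sum(neg), mean, sd)
  x
}

#' Simulate a case-control cohort
#'
#' Draws candidate subjects from the prospective population model of
#' `config` (HWE genotypes, logistic liability) in batches and retains
#' them by outcome until the case and control quotas are filled —
#' the retrospective sampling design of a case-control study. Missing
#' calls are then masked per SNP, independently of status. Deterministic
#' given `config$seed`.
#'
#' @param config a `simulation_config`.
#' @param max_batches iteration cap before aborting with diagnostics.
#' @return A `cohort`.
#' @export
simulate_cohort <- function(config, max_batches = 1000L) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- config$panel
  K <- nrow(panel)
  use_cov <- config$sex_log_or != 0 || config$age_log_or_per_year != 0

  need <- c(case = config$n_cases, control = config$n_controls)
  got <- list(case = list(), control = list())
  n_got <- c(case = 0L, control = 0L)
  batch <- max(1000L, 2L * (config$n_cases + config$n_controls))
  n_drawn <- 0L; n_cases_seen <- 0L

  for (b in seq_len(max_batches)) {
    dos <- vapply(panel$ref_maf, function(m) stats::rbinom(batch, 2L, m),
                  integer(batch))
    dos <- matrix(dos, nrow = batch)
    lp <- config$baseline_logit +
      as.vector(dos %*% config$per_allele_log_or)
    if (use_cov) {
      male <- stats::rbinom(batch, 1L, config$prop_male[["control"]])
      age <- rnorm_trunc0(batch, config$age_mean[["control"]],
                          config$age_sd[["control"]])
      lp <- lp + config$sex_log_or * male +
        config$age_log_or_per_year * age
    } else {
      male <- rep(NA_integer_, batch); age <- rep(NA_real_, batch)
    }
    is_case <- stats::runif(batch) < stats::plogis(lp)
    n_drawn <- n_drawn + batch; n_cases_seen <- n_cases_seen + sum(is_case)
    for (g in c("case", "control")) {
      want <- need[[g]] - n_got[[g]]
      if (want <= 0L) next
      idx <- which(if (g == "case") is_case else !is_case)
      idx <- idx[seq_len(min(want, length(idx)))]
      if (length(idx) > 0L) {
        got[[g]][[length(got[[g]]) + 1L]] <-
          list(dos = dos[idx, , drop = FALSE], male = male[idx],
               age = age[idx])
        n_got[[g]] <- n_got[[g]] + length(idx)
      }
    }
    if (all(n_got >= need)) break
  }
  if (!all(n_got >= need)) {
    stop(sprintf(paste0(
      "case/control quotas not reached after %d candidates ",
      "(observed case fraction %.4f; have %d/%d cases, %d/%d controls); ",
      "adjust baseline_logit"),
      n_drawn, n_cases_seen / n_drawn, n_got[["case"]], need[["case"]],
      n_got[["control"]], need[["control"]]))
  }

  assemble <- function(g) {
    dos <- do.call(rbind, lapply(got[[g]], `[[`, "dos"))
    n <- nrow(dos)
    if (use_cov) {
      male <- unlist(lapply(got[[g]], `[[`, "male"))
      age <- unlist(lapply(got[[g]], `[[`, "age"))
    } else {
      male <- stats::rbinom(n, 1L, config$prop_male[[g]])
      age <- rnorm_trunc0(n, config$age_mean[[g]], config$age_sd[[g]])
    }
    df <- data.frame(
      subject_id = sprintf("%s_%05d", g, seq_len(n)),
      status = g, sex = ifelse(male == 1L, "male", "female"),
      age = round(age, 1), stringsAsFactors = FALSE
    )
    for (i in seq_len(K)) {
      gstr <- c(paste0(panel$major[i], panel$major[i]),
                paste0(panel$major[i], panel$minor[i]),
                paste0(panel$minor[i], panel$minor[i]))[dos[, i] + 1L]
      miss <- stats::runif(n) < config$missing_rate[i]
      gstr[miss] <- NA_character_
      df[[panel$snp_id[i]]] <- gstr
    }
    df
  }
  subjects <- rbind(assemble("case"), assemble("control"))
  cohort(panel, subjects)
}
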