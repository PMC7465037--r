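#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Compares observed genotype counts in one group against the proportions
#' (p^2, 2pq, q^2) expected from that group's own allele frequency, by a
#' chi-squared goodness-of-fit test on 1 degree of freedom (3 classes,
#' minus 1, minus 1 estimated allele frequency). No continuity correction.
#' A monomorphic group has nothing to test: chi2 = 0, flagged untestable.
#'
#' @param tab a `genotype_count_table`.
#' @param group `"case"` or `"control"`.
#' @return An `hwe_result`: list with `snp_id`, `group`, `chi2`, `df`,
#'   `p_value`, `expected` (the three expected counts, summing to the
#'   observed n), `n`, and `testable`.
#' @export
hwe_chi2 <- function(tab, group = c("case", "control")) {
  group <- match.arg(group)
  obs <- tab$counts[group, ]
  n <- sum(obs)
  if (n == 0) stop("no non-missing subjects in group '", group, "'")
  q <- (2 * obs[["minor_hom"]] + obs[["het"]]) / (2 * n)
  p <- 1 - q
  expected <- n * c(major_hom = p^2, het = 2 * p * q, minor_hom = q^2)
  if (q == 0 || q == 1) {
    res <- list(snp_id = tab$snp_id, group = group, chi2 = 0, df = 1L,
                p_value = NA_real_, expected = expected, n = n,
                testable = FALSE)
  } else {
    chi2 <- sum((obs - expected)^2 / expected)
    res <- list(snp_id = tab$snp_id, group = group, chi2 = chi2, df = 1L,
                p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                expected = expected, n = n, testable = TRUE)
  }
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE %s (%s): chi2 = %.4f, df = %d, p = %s%s\n",
              x$snp_id, x$group, x$chi2, x$df,
              ifelse(x$testable, sprintf("%.4f", x$p_value), "NA"),
              ifelse(x$testable, "", " (monomorphic, untestable)")))
  invisible(x)
}

#' HWE tests across a cohort
#'
#' Runs [hwe_chi2()] for every panel SNP in cases, controls or both.
#'
#' @param x a `cohort`.
#' @param groups character vector of groups to test (default both).
#' @return data.frame with one row per SNP x group.
#' @export
hwe_table <- function(x, groups = c("case", "control")) {
  stopifnot(inherits(x, "cohort"))
  rows <- lapply(x$panel$snp_id, function(sid) {
    tab <- genotype_counts(x, sid)
    do.call(rbind, lapply(groups, function(g) {
      r <- hwe_chi2(tab, g)
      data.frame(snp_id = r$snp_id, group = r$group, n = r$n,
                 chi2 = r$chi2, df = r$df, p_value = r$p_value,
                 testable = r$testable, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
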