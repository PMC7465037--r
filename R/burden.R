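#' Per-subject cumulative minor-allele burden
#'
#' Sums minor-allele dosage over every panel SNP (0..2K for K SNPs).
#' Subjects missing any genotype are excluded (complete-case rule) and
#' tallied per group in the `excluded_n` attribute.
#'
#' @param x a `cohort`.
#' @return data.frame with `subject_id`, `status`, `score`; attribute
#'   `excluded_n` gives excluded subjects per group.
#' @export
burden_scores <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (nrow(x$panel) == 0) stop("empty SNP panel")
  dm <- dosage_matrix(x)
  complete <- rowSums(is.na(dm)) == 0
  grp <- factor(x$subjects$status, c("case", "control"))
  out <- data.frame(
    subject_id = x$subjects$subject_id[complete],
    status = x$subjects$status[complete],
    score = as.integer(rowSums(dm[complete, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
  excl <- table(grp[!complete])
  attr(out, "excluded_n") <- c(case = unname(excl[["case"]]),
                               control = unname(excl[["control"]]))
  attr(out, "k_max") <- 2L * nrow(x$panel)
  out
}

#' Burden distribution by group
#'
#' Counts of completely genotyped subjects per total minor-allele count.
#'
#' @param scores output of [burden_scores()], or a `cohort`.
#' @return Integer matrix, rows `case`/`control`, columns `"0"`..`"2K"`;
#'   attribute `excluded_n` propagated when available.
#' @export
burden_distribution <- function(scores) {
  if (inherits(scores, "cohort")) scores <- burden_scores(scores)
  k_max <- attr(scores, "k_max")
  if (is.null(k_max)) k_max <- max(scores$score, 0L)
  m <- table(factor(scores$status, c("case", "control")),
             factor(scores$score, 0:k_max))
  m <- matrix(as.integer(m), nrow = 2,
              dimnames = list(c("case", "control"), as.character(0:k_max)))
  attr(m, "excluded_n") <- attr(scores, "excluded_n")
  m
}

#' Dichotomized burden test
#'
#' Splits subjects at `threshold` minor alleles (>= t vs < t) and compares
#' cases against controls on the resulting 2x2 table with a two-tailed
#' Pearson chi-squared test (no continuity correction) and the Woolf
#' odds-ratio interval of [or_2x2()].
#'
#' @param x a `cohort`, a [burden_scores()] data.frame, or a pre-tabulated
#'   count matrix as returned by [burden_distribution()] (so a printed
#'   distribution can be fed directly).
#' @param threshold integer dichotomization point t, in 1..2K.
#' @return A `burden_test` result: list with the distribution `counts`,
#'   `excluded_n`, `threshold`, the 2x2 `table`, group proportions above
#'   threshold, `or`, `ci_low`, `ci_high`, `chi2`, `p_value`.
#' @export
burden_test <- function(x, threshold = 3L) {
  counts <- if (is.matrix(x)) x else burden_distribution(x)
  k_max <- ncol(counts) - 1L
  if (threshold < 1 || threshold > k_max) {
    stop("threshold must lie in 1..", k_max)
  }
  ks <- as.integer(colnames(counts))
  hi <- ks >= threshold
  tab <- cbind(ge = rowSums(counts[, hi, drop = FALSE]),
               lt = rowSums(counts[, !hi, drop = FALSE]))
  if (any(colSums(tab) == 0)) {
    stop("degenerate margin: every subject falls on one side of the ",
         "threshold t = ", threshold)
  }
  if (any(rowSums(tab) == 0)) stop("a group has no scored subjects")
  orr <- or_2x2(tab["case", "ge"], tab["case", "lt"],
                tab["control", "ge"], tab["control", "lt"])
  chi <- stats::chisq.test(tab, correct = FALSE)
  res <- list(
    counts = counts,
    excluded_n = attr(counts, "excluded_n"),
    threshold = as.integer(threshold),
    table = tab,
    prop_ge = tab[, "ge"] / rowSums(tab),
    or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
    chi2 = unname(chi$statistic), p_value = unname(chi$p.value)
  )
  class(res) <- "burden_test"
  res
}

#' @export
print.burden_test <- function(x, ...) {
  cat(sprintf("burden test at >= %d minor alleles\n", x$threshold))
  cat(sprintf("  cases:    %d/%d (%.1f%%)\n", x$table["case", "ge"],
              sum(x$table["case", ]), 100 * x$prop_ge[["case"]]))
  cat(sprintf("  controls: %d/%d (%.1f%%)\n", x$table["control", "ge"],
              sum(x$table["control", ]), 100 * x$prop_ge[["control"]]))
  cat(sprintf("  OR %.2f (95%% CI %.2f-%.2f), chi2 = %.3f, p = %.4f\n",
              x$or, x$ci_low, x$ci_high, x$chi2, x$p_value))
  invisible(x)
}

#' Burden test across every possible threshold
#'
#' Emits the dichotomized test at each t in 1..2K, to expose the full
#' sweep rather than a single post-hoc cut.
#'
#' @param x as in [burden_test()].
#' @return data.frame with one row per testable threshold.
#' @export
burden_threshold_sweep <- function(x) {
  counts <- if (is.matrix(x)) x else burden_distribution(x)
  k_max <- ncol(counts) - 1L
  rows <- lapply(seq_len(k_max), function(t) {
    # extreme thresholds give sparse 2x2s; the sweep is exploratory output
    r <- tryCatch(suppressWarnings(burden_test(counts, t)),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(threshold = t, or = r$or, ci_low = r$ci_low,
               ci_high = r$ci_high, chi2 = r$chi2, p_value = r$p_value)
  })
  do.call(rbind, rows)
}
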