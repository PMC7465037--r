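# display rounding: half away from zero, so printed tables match the
# conventional rounding of published counts/percentages rather than
# banker's rounding
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt1 <- function(x) sprintf("%.1f", round_half_up(x, 1))
fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Run the full association study pipeline
#'
#' Executes, in order: Hardy-Weinberg tests in both groups, per-SNP
#' association under all five inheritance models (unadjusted and
#' covariate-adjusted), AIC model selection, Bonferroni correction of the
#' selected-model p-values, and the minor-allele burden analysis with its
#' dichotomized test. Deterministic given the cohort.
#'
#' @param x a `cohort`.
#' @param alpha family-wise significance level.
#' @param covariates adjustment covariates (default sex and age).
#' @param burden_threshold dichotomization point of the burden test.
#' @return A `study_report` list with `hwe`, `association` (per-SNP,
#'   per-model results), `model_selection`, `correction`, `burden`,
#'   `burden_sweep` and a reproducibility `manifest`.
#' @export
run_study <- function(x, alpha = 0.05, covariates = c("sex", "age"),
                      burden_threshold = 3L) {
  stopifnot(inherits(x, "cohort"))
  hwe <- hwe_table(x)

  association <- lapply(x$panel$snp_id, function(sid) {
    list(
      unadjusted = fit_all_models(x, sid, character()),
      adjusted = fit_all_models(x, sid, covariates)
    )
  })
  names(association) <- x$panel$snp_id

  model_selection <- lapply(association, function(a) {
    select_best_model(a$unadjusted)
  })
  selected_p <- vapply(x$panel$snp_id, function(sid) {
    association[[sid]]$unadjusted[[model_selection[[sid]]$model]]$p_value
  }, numeric(1))
  correction <- bonferroni(selected_p, alpha = alpha,
                           m = nrow(x$panel))
  correction$p_values <- selected_p

  burden <- burden_test(x, burden_threshold)
  sweep <- burden_threshold_sweep(burden$counts)

  report <- list(
    panel = x$panel,
    n = table(factor(x$subjects$status, c("case", "control"))),
    hwe = hwe,
    association = association,
    model_selection = model_selection,
    correction = correction,
    burden = burden,
    burden_sweep = sweep,
    manifest = list(
      n_subjects = nrow(x$subjects),
      n_snps = nrow(x$panel),
      alpha = alpha,
      covariates = covariates,
      burden_threshold = as.integer(burden_threshold),
      package_version = as.character(utils::packageVersion("vdburden")),
      r_version = R.version.string
    )
  )
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report:", x$n[["case"]], "cases /", x$n[["control"]],
      "controls,", nrow(x$panel), "SNPs\n")
  for (sid in x$panel$snp_id) {
    sel <- x$model_selection[[sid]]
    best <- x$association[[sid]]$unadjusted[[sel$model]]
    cat(sprintf("  %s (%s): best model %s, OR %.2f (%.2f-%.2f), p %.3f\n",
                sid, best$gene, sel$model, best$estimates$or[1],
                best$estimates$ci_low[1], best$estimates$ci_high[1],
                best$p_value))
  }
  cat(sprintf("  Bonferroni threshold %.4f; %d/%d SNPs significant\n",
              x$correction$threshold, sum(x$correction$significant),
              length(x$correction$significant)))
  cat(sprintf("  burden >= %d: OR %.2f (%.2f-%.2f), p %.3f\n",
              x$burden$threshold, x$burden$or, x$burden$ci_low,
              x$burden$ci_high, x$burden$p_value))
  invisible(x)
}

#' Render publication-style result tables
#'
#' Writes the per-SNP genotype/allele table (counts, percentages, the
#' selected-model and log-additive odds ratios with 95% CIs and p-values,
#' unadjusted and adjusted) and the burden distribution table with its
#' dichotomized rows, plus a full-precision companion TSV for each.
#' Display values are rounded half-away-from-zero (OR/CI to 2 decimals,
#' percentages to 1).
#'
#' @param report a `study_report`.
#' @param x the `cohort` the report was computed from (for count tables).
#' @param dir output directory (created if needed).
#' @param format `"tsv"`, `"markdown"`, or both.
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(report, x, dir,
                          format = c("tsv", "markdown")) {
  stopifnot(inherits(report, "study_report"), inherits(x, "cohort"))
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()

  fmt_or <- function(res, row = 1L) {
    sprintf("%s (%s-%s)", fmt2(res$estimates$or[row]),
            fmt2(res$estimates$ci_low[row]),
            fmt2(res$estimates$ci_high[row]))
  }

  rows <- list(); prec <- list()
  for (sid in report$panel$snp_id) {
    def <- panel_row(report$panel, sid)
    tab <- genotype_counts(x, sid)
    sel <- report$model_selection[[sid]]$model
    un <- report$association[[sid]]$unadjusted[[sel]]
    ad <- report$association[[sid]]$adjusted[[sel]]
    la_un <- report$association[[sid]]$unadjusted[["log-additive"]]
    la_ad <- report$association[[sid]]$adjusted[["log-additive"]]
    n_case <- sum(tab$counts["case", ])
    n_ctrl <- sum(tab$counts["control", ])
    geno_labels <- c(paste0(def$major, def$major),
                     paste0(def$major, def$minor),
                     paste0(def$minor, def$minor))
    for (g in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        snp = sid, gene = def$gene, row_type = "genotype",
        label = geno_labels[g],
        cases = sprintf("%d (%s)", tab$counts["case", g],
                        fmt1(100 * tab$counts["case", g] / n_case)),
        controls = sprintf("%d (%s)", tab$counts["control", g],
                           fmt1(100 * tab$counts["control", g] / n_ctrl)),
        or_ci = if (g == 3) fmt_or(un) else "",
        p = if (g == 3) fmt2(un$p_value) else "",
        adj_or_ci = if (g == 3) fmt_or(ad) else "",
        adj_p = if (g == 3) fmt2(ad$p_value) else "",
        model = if (g == 3) sel else "",
        stringsAsFactors = FALSE
      )
    }
    af_case <- allele_frequency(tab, "case")
    af_ctrl <- allele_frequency(tab, "control")
    allele_rows <- data.frame(
      snp = sid, gene = def$gene, row_type = "allele",
      label = c(def$major, def$minor),
      cases = sprintf("%d (%s)",
                      c(af_case$total - af_case$count, af_case$count),
                      fmt1(100 * c(1 - af_case$frequency,
                                   af_case$frequency))),
      controls = sprintf("%d (%s)",
                         c(af_ctrl$total - af_ctrl$count, af_ctrl$count),
                         fmt1(100 * c(1 - af_ctrl$frequency,
                                      af_ctrl$frequency))),
      or_ci = c("", fmt_or(la_un)),
      p = c("", fmt2(la_un$p_value)),
      adj_or_ci = c("", fmt_or(la_ad)),
      adj_p = c("", fmt2(la_ad$p_value)),
      model = c("", "log-additive"),
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1]] <- allele_rows
    prec[[length(prec) + 1]] <- data.frame(
      snp = sid, model = sel,
      or = un$estimates$or[1], ci_low = un$estimates$ci_low[1],
      ci_high = un$estimates$ci_high[1], p = un$p_value,
      adj_or = ad$estimates$or[1], adj_ci_low = ad$estimates$ci_low[1],
      adj_ci_high = ad$estimates$ci_high[1], adj_p = ad$p_value,
      la_or = la_un$estimates$or[1], la_p = la_un$p_value,
      maf_cases = af_case$frequency, maf_controls = af_ctrl$frequency,
      aic = un$aic, stringsAsFactors = FALSE
    )
  }
  table1 <- do.call(rbind, rows)
  table1_full <- do.call(rbind, prec)

  b <- report$burden
  k <- as.integer(colnames(b$counts))
  n_case <- sum(b$counts["case", ]); n_ctrl <- sum(b$counts["control", ])
  comp <- or_2x2(b$table["case", "lt"], b$table["case", "ge"],
                 b$table["control", "lt"], b$table["control", "ge"])
  table2 <- rbind(
    data.frame(
      label = as.character(k),
      cases = sprintf("%d (%s)", b$counts["case", ],
                      fmt1(100 * b$counts["case", ] / n_case)),
      controls = sprintf("%d (%s)", b$counts["control", ],
                         fmt1(100 * b$counts["control", ] / n_ctrl)),
      or_ci = "", p = "", stringsAsFactors = FALSE
    ),
    data.frame(
      label = c(sprintf("%d or less", b$threshold - 1L),
                sprintf("%d or more", b$threshold)),
      cases = sprintf("%d (%s)",
                      c(b$table["case", "lt"], b$table["case", "ge"]),
                      fmt1(100 * c(1 - b$prop_ge[["case"]],
                                   b$prop_ge[["case"]]))),
      controls = sprintf("%d (%s)",
                         c(b$table["control", "lt"],
                           b$table["control", "ge"]),
                         fmt1(100 * c(1 - b$prop_ge[["control"]],
                                      b$prop_ge[["control"]]))),
      or_ci = c(sprintf("%s (%s-%s)", fmt2(comp$or), fmt2(comp$ci_low),
                        fmt2(comp$ci_high)),
                sprintf("%s (%s-%s)", fmt2(b$or), fmt2(b$ci_low),
                        fmt2(b$ci_high))),
      p = rep(fmt2(b$p_value), 2),
      stringsAsFactors = FALSE
    )
  )
  table2_full <- data.frame(
    threshold = b$threshold, or = b$or, ci_low = b$ci_low,
    ci_high = b$ci_high, chi2 = b$chi2, p = b$p_value,
    prop_ge_cases = b$prop_ge[["case"]],
    prop_ge_controls = b$prop_ge[["control"]],
    complement_or = comp$or, stringsAsFactors = FALSE
  )

  write_one <- function(df, stem) {
    if ("tsv" %in% format) {
      p <- file.path(dir, paste0(stem, ".tsv"))
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <<- c(paths, p)
    }
    if ("markdown" %in% format) {
      p <- file.path(dir, paste0(stem, ".md"))
      writeLines(df_to_markdown(df), p)
      paths <<- c(paths, p)
    }
  }
  write_one(table1, "table_genotypes")
  write_one(table2, "table_burden")
  utils::write.table(table1_full, file.path(dir, "table_genotypes_full.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table2_full, file.path(dir, "table_burden_full.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$hwe, file.path(dir, "table_hwe.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, file.path(dir, c("table_genotypes_full.tsv",
                                     "table_burden_full.tsv",
                                     "table_hwe.tsv")))
  invisible(paths)
}

df_to_markdown <- function(df) {
  cells <- rbind(colnames(df), rep("---", ncol(df)),
                 as.matrix(format(df, trim = TRUE)))
  apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
}
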