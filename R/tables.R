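#' Published genotype counts for the four study SNPs
#'
#' The observed genotype distributions in 350 type 1 diabetes cases and 490
#' healthy controls, as printed in the study's genotype/allele table.
#' Per-SNP totals differ slightly because of assay failures (per-SNP
#' complete-case counting). These counts are the packaged fixture from which
#' every single-SNP result is recomputable.
#'
#' @return Named list of `genotype_count_table`s keyed by rsID.
#' @export
study_genotype_counts <- function() {
  p <- study_panel()
  tabs <- list(
    rs12785878 = genotype_count_table("rs12785878",
                                      c(114, 171, 65), c(189, 221, 77)),
    rs2282679 = genotype_count_table("rs2282679",
                                     c(175, 155, 20), c(231, 220, 38)),
    rs2060793 = genotype_count_table("rs2060793",
                                     c(119, 169, 62), c(182, 249, 58)),
    rs6013897 = genotype_count_table("rs6013897",
                                     c(197, 129, 22), c(291, 172, 19))
  )
  for (sid in names(tabs)) {
    i <- match(sid, p$snp_id)
    tabs[[sid]]$gene <- p$gene[i]
    tabs[[sid]]$major <- p$major[i]
    tabs[[sid]]$minor <- p$minor[i]
  }
  tabs
}

#' Published minor-allele burden distribution
#'
#' Counts of subjects by total number of minor alleles across the four SNPs
#' (0..8), among subjects with complete genotyping (348 cases, 478
#' controls), as printed in the study's cumulative-allele table.
#'
#' @return Integer matrix, rows `case`/`control`, columns `"0"`..`"8"`.
#' @export
study_burden_counts <- function() {
  m <- rbind(
    case    = c(15, 43, 94, 93, 74, 20, 9, 0, 0),
    control = c(13, 87, 146, 120, 83, 23, 6, 0, 0)
  )
  colnames(m) <- as.character(0:8)
  m
}

#' Study covariate summaries
#'
#' Per-group sex counts and age mean/SD of the study cohort, used to attach
#' synthetic covariates to fixture cohorts expanded from printed counts.
#'
#' @return List with `case` and `control` elements, each holding
#'   `n`, `prop_male`, `age_mean`, `age_sd`.
#' @export
study_covariate_summaries <- function() {
  list(
    case    = list(n = 350L, prop_male = 184 / 350, age_mean = 29.0,
                   age_sd = 11.1),
    control = list(n = 490L, prop_male = 246 / 490, age_mean = 32.2,
                   age_sd = 11.2)
  )
}

#' Per-SNP genotyping failure rates of the study assays
#'
#' @return Named numeric vector of missing-call fractions by rsID.
#' @export
study_missing_rates <- function() {
  c(rs12785878 = 0.004, rs2282679 = 0.001, rs2060793 = 0.001,
    rs6013897 = 0.012)
}
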