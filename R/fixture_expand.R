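#' Expand printed count tables into a subject-level fixture cohort
#'
#' Reconstructs an analyzable cohort from the marginal summaries a paper
#' prints, so every downstream stage runs without subject-level data.
#'
#' Without `burden_counts`, each group's size is the largest per-SNP
#' non-missing total and genotypes are laid out independently per SNP, so
#' every per-SNP genotype count table reproduces the input exactly (SNPs
#' with smaller totals receive missing calls). The joint distribution
#' across SNPs is arbitrary: such a fixture validates single-SNP
#' statistics only.
#'
#' With `burden_counts`, a joint assignment is constructed so that the
#' distribution of per-subject minor-allele totals among completely
#' genotyped subjects matches the supplied counts exactly, while per-SNP
#' genotype marginals are matched as closely as a greedy iterative
#' proportional assignment permits (the true joint distribution is not
#' recoverable from printed marginals). The group size becomes the
#' smallest size under which the implied missingness pattern is feasible
#' (every incompletely genotyped subject carries at least one missing
#' call).
#'
#' Synthetic sex and age are attached from per-group summary statistics;
#' they carry no information about genotype and do not reproduce any
#' covariate-adjusted estimate of the source study.
#'
#' @param tables list of `genotype_count_table`s, one per panel SNP.
#' @param panel a `snp_panel` covering the tables' SNPs.
#' @param burden_counts optional matrix of subjects per minor-allele total
#'   (rows `case`/`control`, columns `"0"`..`"2K"`).
#' @param covariates per-group covariate summaries, as
#'   [study_covariate_summaries()].
#' @param seed integer seed for the synthetic covariate draw.
#' @return A `cohort`.
#' @export
expand_fixture <- function(tables, panel = study_panel(),
                           burden_counts = NULL,
                           covariates = study_covariate_summaries(),
                           seed = 1L) {
  tab_ids <- vapply(tables, `[[`, character(1), "snp_id")
  if (!all(tab_ids %in% panel$snp_id)) {
    stop("tables contain SNPs not in panel: ",
         paste(setdiff(tab_ids, panel$snp_id), collapse = ", "))
  }
  panel <- panel[panel$snp_id %in% tab_ids, , drop = FALSE]
  class(panel) <- c("snp_panel", "data.frame")
  tables <- tables[match(panel$snp_id, tab_ids)]
  K <- nrow(panel)
  set.seed(seed)

  group_frame <- function(grp) {
    counts <- vapply(tables, function(t) t$counts[grp, ], numeric(3))
    counts <- matrix(as.integer(counts), nrow = 3,
                     dimnames = list(c("major_hom", "het", "minor_hom"),
                                     panel$snp_id))
    n_s <- colSums(counts)
    if (is.null(burden_counts)) {
      N <- max(n_s)
      dos <- matrix(NA_integer_, nrow = N, ncol = K)
      for (s in seq_len(K)) {
        if (n_s[s] > 0L) {
          dos[seq_len(n_s[s]), s] <- rep(0:2, counts[, s])
        }
      }
    } else {
      dos <- joint_assign(counts, burden_counts[grp, ])
      N <- nrow(dos)
    }
    cv <- covariates[[grp]]
    n_male <- round(N * cv$prop_male)
    df <- data.frame(
      subject_id = sprintf("%s_%04d", grp, seq_len(N)),
      status = rep(grp, N),
      sex = c(rep("male", n_male), rep("female", N - n_male)),
      age = round(rnorm_trunc0(N, cv$age_mean, cv$age_sd), 1),
      stringsAsFactors = FALSE
    )
    for (s in seq_len(K)) {
      gstr <- c(paste0(panel$major[s], panel$major[s]),
                paste0(panel$major[s], panel$minor[s]),
                paste0(panel$minor[s], panel$minor[s]))
      df[[panel$snp_id[s]]] <- as.character(
        ifelse(is.na(dos[, s]), NA_character_, gstr[dos[, s] + 1L])
      )
    }
    df
  }

  subjects <- rbind(group_frame("case"), group_frame("control"))
  cohort(panel, subjects)
}

# Smallest group size N at which the missingness pattern implied by per-SNP
# totals n_s and complete-case total C is realizable: N - C incomplete
# subjects, each holding >= 1 of the sum(N - n_s) missing calls, no SNP
# missing more calls than there are incomplete subjects.
feasible_group_size <- function(n_s, C) {
  for (N in seq(max(max(n_s), C), max(max(n_s), C) + 1000L)) {
    miss <- N - n_s
    incomplete <- N - C
    if (sum(miss) >= incomplete && max(miss) <= incomplete &&
        (incomplete > 0L || sum(miss) == 0L)) {
      return(N)
    }
  }
  stop("burden total inconsistent with per-SNP genotype totals")
}

# Joint dosage assignment for one group: burden distribution exact among
# complete cases, per-SNP genotype marginals approximated greedily.
joint_assign <- function(counts, burden) {
  K <- ncol(counts)
  n_s <- colSums(counts)
  C <- sum(burden)
  if (C == 0L && all(n_s == 0L)) {
    return(matrix(NA_integer_, nrow = 0, ncol = K))
  }
  N <- feasible_group_size(n_s, C)
  incomplete <- N - C
  miss <- N - n_s

  # distribute missing calls over incomplete subjects, covering each at
  # least once: each SNP fills subjects with the fewest assigned calls first
  miss_mat <- matrix(FALSE, nrow = incomplete, ncol = K)
  for (s in order(miss, decreasing = TRUE)) {
    if (miss[s] == 0L) next
    load <- rowSums(miss_mat)
    pick <- order(load, seq_len(incomplete))[seq_len(miss[s])]
    miss_mat[pick, s] <- TRUE
  }
  if (incomplete > 0L && any(rowSums(miss_mat) == 0L)) {
    stop("internal: missingness pattern left a subject fully genotyped")
  }

  remaining <- counts  # 3 x K pool of genotype-class slots

  # incomplete subjects consume observed calls from the largest pools
  dos_inc <- matrix(NA_integer_, nrow = incomplete, ncol = K)
  for (i in seq_len(incomplete)) {
    for (s in which(!miss_mat[i, ])) {
      cls <- which.max(remaining[, s])
      dos_inc[i, s] <- cls - 1L
      remaining[cls, s] <- remaining[cls, s] - 1L
    }
  }

  # complete subjects: per-subject dosage tuples summing exactly to the
  # target burden, chosen to deplete the marginal pools proportionally;
  # extreme burdens (fewest compatible tuples) are assigned first
  tuples_by_k <- tuples_for_panel(K)
  targets <- rep(seq_along(burden) - 1L, burden)
  targets <- targets[order(-abs(targets - K))]
  dos_com <- matrix(NA_integer_, nrow = C, ncol = K)
  for (i in seq_along(targets)) {
    tk <- tuples_by_k[[targets[i] + 1L]]
    idx <- cbind(as.vector(t(tk)) + 1L, rep(seq_len(K), nrow(tk)))
    pool <- matrix(remaining[idx], ncol = K, byrow = TRUE)
    score <- apply(pmax(pool, 0), 1, prod)
    if (all(score == 0)) {
      # pools exhausted for every compatible tuple: minimize the deficit
      score <- rowSums(pmax(pool, 0)) - rowSums(pool <= 0) * 1e-3
    }
    best <- which.max(score)
    dos_com[i, ] <- tk[best, ]
    remaining[cbind(tk[best, ] + 1L, seq_len(K))] <-
      remaining[cbind(tk[best, ] + 1L, seq_len(K))] - 1L
  }
  rbind(dos_com, dos_inc)
}

tuples_for_panel <- function(K) {
  grid <- as.matrix(expand.grid(rep(list(0:2), K)))
  storage.mode(grid) <- "integer"
  lapply(0:(2L * K), function(k) grid[rowSums(grid) == k, , drop = FALSE])
}
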