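# shared fixtures built in code

toy_panel <- function() {
  snp_panel(
    snp_id  = c("rs12785878", "rs2282679", "rs2060793", "rs6013897"),
    gene    = c("DHCR7", "GC", "CYP2R1", "CYP24A1"),
    major   = c("T", "T", "G", "T"),
    minor   = c("G", "G", "A", "A"),
    ref_maf = c(0.278, 0.288, 0.403, 0.197)
  )
}

one_snp_panel <- function(maf = 0.3) {
  snp_panel("rs0000001", "SIM", "A", "G", maf)
}

# build a one-SNP cohort directly from genotype-class counts
cohort_from_counts <- function(case_counts, control_counts,
                               panel = one_snp_panel()) {
  stopifnot(nrow(panel) == 1)
  gstr <- c(paste0(panel$major, panel$major),
            paste0(panel$major, panel$minor),
            paste0(panel$minor, panel$minor))
  geno <- c(rep(gstr, case_counts), rep(gstr, control_counts))
  n_case <- sum(case_counts)
  n <- n_case + sum(control_counts)
  subjects <- data.frame(
    subject_id = sprintf("s%05d", seq_len(n)),
    status = rep(c("case", "control"), c(n_case, n - n_case)),
    sex = rep(c("male", "female"), length.out = n),
    age = 30,
    stringsAsFactors = FALSE
  )
  subjects[[panel$snp_id]] <- geno
  cohort(panel, subjects)
}

# random genotype count tables whose collapsed 2x2s have no zero cell
random_count_table <- function() {
  repeat {
    cc <- sample(2:80, 3, replace = TRUE)
    ct <- sample(2:80, 3, replace = TRUE)
    collapses <- list(
      dominant = c(cc[2] + cc[3], cc[1], ct[2] + ct[3], ct[1]),
      recessive = c(cc[3], cc[1] + cc[2], ct[3], ct[1] + ct[2]),
      overdominant = c(cc[2], cc[1] + cc[3], ct[2], ct[1] + ct[3])
    )
    if (all(unlist(collapses) > 0)) {
      return(list(case = cc, control = ct, collapses = collapses))
    }
  }
}
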