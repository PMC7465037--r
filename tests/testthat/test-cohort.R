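test_that("genotype TSV reading encodes dosages and normalizes heterozygotes", {
  panel <- toy_panel()
  lines <- c(
    "subject_id\tstatus\tsex\tage\trs12785878\trs2282679\trs2060793\trs6013897",
    "S1\tcase\tmale\t17\tTG\tTT\tGA\tTA",
    "S2\tcontrol\tfemale\t40\tGT\tGG\tNA\tTT"
  )
  path <- withr::local_tempfile(lines = lines, fileext = ".tsv")
  co <- read_cohort(path, panel)

  dm <- dosage_matrix(co)
  expect_equal(unname(dm["S1", ]), c(1L, 0L, 1L, 1L))
  # unordered heterozygote GT normalizes to the same call as TG
  expect_identical(co$subjects$rs12785878[2], co$subjects$rs12785878[1])
  expect_identical(co$subjects$rs12785878[1], "TG")
  # missing token propagates
  expect_true(is.na(co$subjects$rs2060793[2]))
  expect_true(is.na(dm["S2", "rs2060793"]))
})

test_that("cohort writing round-trips genotypes, statuses and covariates", {
  set.seed(42)
  cfg <- simulation_config(toy_panel(), 40, 60,
                           missing_rate = 0.05, seed = 42)
  co <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path, toy_panel())
  expect_identical(back$subjects, co$subjects)
})

test_that("malformed input is rejected with a pointed error", {
  panel <- toy_panel()
  base <- "subject_id\tstatus\tsex\tage\trs12785878\trs2282679\trs2060793\trs6013897"
  write_and_read <- function(rows) {
    path <- withr::local_tempfile(lines = c(base, rows), fileext = ".tsv")
    read_cohort(path, panel)
  }
  expect_error(write_and_read("S1\tcase\tmale\t17\tTC\tTT\tGA\tTA"),
               "allele not in panel")
  expect_error(write_and_read(c("S1\tcase\tmale\t17\tTG\tTT\tGA\tTA",
                                "S1\tcase\tmale\t18\tTT\tTT\tGG\tTT")),
               "duplicate subject_id")
  expect_error(write_and_read("S1\tpatient\tmale\t17\tTG\tTT\tGA\tTA"),
               "unknown status")
  expect_error(write_and_read("S1\tcase\tm\t17\tTG\tTT\tGA\tTA"),
               "unknown sex")
})

test_that("genotype counts match a brute-force per-subject tally", {
  cfg <- simulation_config(toy_panel(), 80, 120,
                           missing_rate = 0.1, seed = 7)
  co <- simulate_cohort(cfg)
  for (i in seq_len(nrow(co$panel))) {
    sid <- co$panel$snp_id[i]
    tab <- genotype_counts(co, sid)
    # oracle: loop over subjects, count minor-allele characters by hand
    oracle <- matrix(0L, 2, 3,
                     dimnames = list(c("case", "control"), NULL))
    for (r in seq_len(nrow(co$subjects))) {
      g <- co$subjects[[sid]][r]
      if (is.na(g)) next
      k <- sum(strsplit(g, "")[[1]] == co$panel$minor[i])
      oracle[co$subjects$status[r], k + 1L] <-
        oracle[co$subjects$status[r], k + 1L] + 1L
    }
    expect_equal(unname(tab$counts), unname(oracle))
    # per-group sums equal non-missing n; allele counts sum to 2n
    for (g in c("case", "control")) {
      n <- sum(!is.na(co$subjects[[sid]][co$subjects$status == g]))
      expect_identical(sum(tab$counts[g, ]), n)
      af <- allele_frequency(tab, g)
      expect_identical(af$count + (af$total - af$count), 2L * n)
    }
  }
})

test_that("allele frequencies reproduce the published allele rows", {
  tabs <- study_genotype_counts()
  af <- allele_frequency(tabs$rs12785878, "case")
  expect_identical(af$count, 301L)
  expect_equal(round(af$frequency, 3), 0.430)
  af2 <- allele_frequency(tabs$rs6013897, "control")
  expect_identical(af2$count, 210L)
  expect_equal(round(af2$frequency, 3), 0.218)
})

test_that("degenerate tables are handled", {
  # all-missing SNP yields an all-zero table
  panel <- toy_panel()
  subjects <- data.frame(
    subject_id = c("a", "b"), status = c("case", "control"),
    sex = c("male", "female"), age = c(10, 20),
    rs12785878 = c("TT", "TG"), rs2282679 = c(NA, NA),
    rs2060793 = c("GG", "GA"), rs6013897 = c("TT", "TT"),
    stringsAsFactors = FALSE
  )
  co <- cohort(panel, subjects)
  tab <- genotype_counts(co, "rs2282679")
  expect_true(all(tab$counts == 0L))
  expect_error(allele_frequency(tab, "case"), "no non-missing")
  # monomorphic group is fine for counting
  mono <- genotype_count_table("rsX", c(10, 0, 0), c(5, 0, 0))
  expect_equal(allele_frequency(mono, "case")$frequency, 0)
})

test_that("the shipped panel file parses to the study panel", {
  path <- system.file("extdata", "vitd_panel.yaml", package = "vdburden")
  expect_identical(read_panel(path), study_panel())
  expect_error(snp_panel("rs1", "X", "A", "A", 0.3), "must differ")
  expect_error(snp_panel(c("rs1", "rs1"), "X", c("A", "C"), c("G", "T"),
                         0.3), "duplicate snp_id")
  expect_error(snp_panel("rs1", "X", "A", "G", 0.6), NA)
  expect_error(snp_panel("rs1", "X", "A", "G", 1.2), "ref_maf")
})

test_that("dosage counts minor-allele characters for all genotype classes", {
  panel <- toy_panel()
  for (i in seq_len(nrow(panel))) {
    M <- panel$major[i]; m <- panel$minor[i]
    genos <- c(paste0(M, M), paste0(M, m), paste0(m, m))
    expect_identical(dosage(genos, m), 0:2)
  }
  expect_true(is.na(dosage(NA_character_, "G")))
})
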