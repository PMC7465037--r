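#' Construct a cohort
#'
#' A cohort couples a SNP panel with a subject table: one row per subject
#' with id, case/control status, sex, age, and one genotype column per
#' panel SNP. Genotypes are stored as unphased two-character allele pairs
#' in canonical order (major allele first); missing calls are `NA`.
#'
#' @param panel a `snp_panel`.
#' @param subjects data.frame with columns `subject_id`, `status`
#'   (`"case"`/`"control"`), `sex` (`"male"`/`"female"`), `age`
#'   (non-negative years) and one character column per panel `snp_id`.
#' @return A `cohort` object.
#' @export
cohort <- function(panel, subjects) {
  validate_panel(panel)
  required <- c("subject_id", "status", "sex", "age")
  missing_cols <- setdiff(c(required, panel$snp_id), names(subjects))
  if (length(missing_cols) > 0) {
    stop("subjects table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  }
  if (!all(subjects$status %in% c("case", "control"))) {
    bad <- setdiff(unique(subjects$status), c("case", "control"))
    stop("unknown status token: ", paste(bad, collapse = ", "))
  }
  if (!all(subjects$sex %in% c("male", "female"))) {
    bad <- setdiff(unique(subjects$sex), c("male", "female"))
    stop("unknown sex token: ", paste(bad, collapse = ", "))
  }
  subjects$age <- as.numeric(subjects$age)
  if (any(!is.na(subjects$age) & subjects$age < 0)) stop("age must be >= 0")
  for (i in seq_len(nrow(panel))) {
    sid <- panel$snp_id[i]
    subjects[[sid]] <- normalize_genotypes(
      subjects[[sid]], panel$major[i], panel$minor[i], sid,
      subjects$subject_id
    )
  }
  out <- list(panel = panel, subjects = subjects)
  class(out) <- "cohort"
  out
}

# Canonical genotype encoding: two-character string, major allele first for
# heterozygotes ("TG", never "GT"). Accepts optional "/" separators.
normalize_genotypes <- function(geno, major, minor, snp_id, subject_ids) {
  geno <- as.character(geno)
  geno <- gsub("/", "", geno, fixed = TRUE)
  out <- rep(NA_character_, length(geno))
  ok <- !is.na(geno) & geno != ""
  if (any(ok & nchar(geno) != 2)) {
    bad <- which(ok & nchar(geno) != 2)[1]
    stop("malformed genotype '", geno[bad], "' for ", snp_id,
         " (subject ", subject_ids[bad], ")")
  }
  a1 <- toupper(substr(geno, 1, 1))
  a2 <- toupper(substr(geno, 2, 2))
  valid <- c(major, minor)
  bad <- ok & (!(a1 %in% valid) | !(a2 %in% valid))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("allele not in panel definition for ", snp_id, ": genotype '",
         geno[i], "' (subject ", subject_ids[i], "; expected alleles ",
         major, "/", minor, ")")
  }
  het <- ok & (a1 != a2)
  out[ok] <- paste0(a1[ok], a2[ok])
  out[het] <- paste0(major, minor)
  out
}

#' Read a subject-level genotype TSV into a cohort
#'
#' Expects a tab-separated file with header columns `subject_id`, `status`,
#' `sex`, `age`, then one column per panel SNP holding two-character allele
#' pairs (order-insensitive, optional `/` separator) or the missing token.
#'
#' @param path path to the TSV file.
#' @param panel a `snp_panel`; its `snp_id`s name the genotype columns.
#' @param missing_token string marking a failed genotype call (default "NA").
#' @return A `cohort`.
#' @export
read_cohort <- function(path, panel, missing_token = "NA") {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE)
  for (sid in intersect(panel$snp_id, names(raw))) {
    raw[[sid]][raw[[sid]] == missing_token] <- NA_character_
  }
  cohort(panel, raw)
}

#' Write a cohort to a subject-level genotype TSV
#'
#' Inverse of [read_cohort()]: the written file round-trips to an identical
#' cohort.
#'
#' @param x a `cohort`.
#' @param path output path.
#' @param missing_token string written for missing calls (default "NA").
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, missing_token = "NA") {
  stopifnot(inherits(x, "cohort"))
  out <- x$subjects[, c("subject_id", "status", "sex", "age", x$panel$snp_id)]
  for (sid in x$panel$snp_id) {
    out[[sid]][is.na(out[[sid]])] <- missing_token
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  n <- table(factor(x$subjects$status, c("case", "control")))
  cat("cohort:", nrow(x$subjects), "subjects (", n[["case"]], "cases,",
      n[["control"]], "controls ),", nrow(x$panel), "SNPs\n")
  invisible(x)
}

#' Minor-allele dosage of genotype calls
#'
#' Counts copies of the designated minor allele in each genotype string
#' (0, 1 or 2); missing calls propagate as `NA`.
#'
#' @param geno character vector of canonical genotype strings.
#' @param minor the minor allele base.
#' @return Integer vector of dosages.
#' @export
dosage <- function(geno, minor) {
  d <- vapply(strsplit(geno, ""), function(a) sum(a == minor), numeric(1))
  d[is.na(geno)] <- NA
  as.integer(d)
}

#' Minor-allele dosage matrix of a cohort
#'
#' @param x a `cohort`.
#' @return Integer matrix, subjects x SNPs, entries 0/1/2 or `NA`.
#' @export
dosage_matrix <- function(x) {
  stopifnot(inherits(x, "cohort"))
  m <- vapply(seq_len(nrow(x$panel)), function(i) {
    dosage(x$subjects[[x$panel$snp_id[i]]], x$panel$minor[i])
  }, integer(nrow(x$subjects)))
  m <- matrix(m, nrow = nrow(x$subjects),
              dimnames = list(x$subjects$subject_id, x$panel$snp_id))
  m
}

#' Genotype count table for one SNP
#'
#' Tallies subjects per genotype class (major homozygote, heterozygote,
#' minor homozygote) in cases and controls, over non-missing calls only
#' (per-SNP complete-case analysis). This 3x2 table is the substrate of
#' all per-SNP frequency and odds-ratio computation.
#'
#' @param x a `cohort`.
#' @param snp_id rsID present in the panel.
#' @return A `genotype_count_table`: list with `snp_id`, `gene`, the allele
#'   pair, and a 2x3 integer `counts` matrix (rows case/control, columns
#'   major_hom/het/minor_hom).
#' @export
genotype_counts <- function(x, snp_id) {
  stopifnot(inherits(x, "cohort"))
  def <- panel_row(x$panel, snp_id)
  d <- dosage(x$subjects[[snp_id]], def$minor)
  grp <- factor(x$subjects$status, c("case", "control"))
  counts <- table(grp, factor(d, 0:2))
  counts <- matrix(as.integer(counts), nrow = 2,
                   dimnames = list(c("case", "control"),
                                   c("major_hom", "het", "minor_hom")))
  structure(
    list(snp_id = def$snp_id, gene = def$gene, major = def$major,
         minor = def$minor, counts = counts),
    class = "genotype_count_table"
  )
}

#' Build a genotype count table directly from counts
#'
#' Used to feed printed 3x2 study tables into the pipeline without
#' subject-level data.
#'
#' @param snp_id rsID label.
#' @param case_counts,control_counts integer vectors
#'   (major_hom, het, minor_hom).
#' @param gene,major,minor optional annotations.
#' @return A `genotype_count_table`.
#' @export
genotype_count_table <- function(snp_id, case_counts, control_counts,
                                 gene = NA_character_, major = NA_character_,
                                 minor = NA_character_) {
  stopifnot(length(case_counts) == 3, length(control_counts) == 3)
  counts <- rbind(case = as.integer(case_counts),
                  control = as.integer(control_counts))
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  colnames(counts) <- c("major_hom", "het", "minor_hom")
  structure(
    list(snp_id = snp_id, gene = gene, major = major, minor = minor,
         counts = counts),
    class = "genotype_count_table"
  )
}

#' @export
print.genotype_count_table <- function(x, ...) {
  cat("genotype counts for", x$snp_id, "\n")
  print(x$counts)
  invisible(x)
}

#' Minor-allele count and frequency for one group
#'
#' @param tab a `genotype_count_table`.
#' @param group `"case"` or `"control"`.
#' @return List with `count` (minor-allele copies, `2*minor_hom + het`),
#'   `total` (2n chromosomes) and `frequency`.
#' @export
allele_frequency <- function(tab, group = c("case", "control")) {
  group <- match.arg(group)
  cts <- tab$counts[group, ]
  n <- sum(cts)
  if (n == 0) stop("no non-missing subjects in group '", group, "'")
  minor <- 2L * cts[["minor_hom"]] + cts[["het"]]
  list(count = minor, total = 2L * n, frequency = minor / (2 * n))
}
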