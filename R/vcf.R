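#' Read panel genotypes from a VCF file
#'
#' Minimal VCF ingestion for a candidate-SNP panel: biallelic records are
#' matched to the panel by ID, GT fields are mapped to allele pairs, and
#' `./.` becomes a missing call. Each matched record's REF/ALT pair must
#' equal the panel's major/minor pair (in either role); anything else is
#' rejected. Case/control status, sex and age are supplied separately
#' since VCF carries no phenotypes.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param panel a `snp_panel`; every panel SNP must appear in the VCF.
#' @param phenotypes data.frame with `subject_id`, `status`, `sex`, `age`;
#'   `subject_id` must match the VCF sample names.
#' @return A `cohort`.
#' @export
read_cohort_vcf <- function(path, panel, phenotypes) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)

  ph <- phenotypes
  ph$subject_id <- as.character(ph$subject_id)
  missing_samples <- setdiff(samples, ph$subject_id)
  if (length(missing_samples) > 0) {
    stop("VCF samples lack phenotype rows: ",
         paste(missing_samples, collapse = ", "))
  }
  subjects <- ph[match(samples, ph$subject_id), , drop = FALSE]

  for (i in seq_len(nrow(panel))) {
    sid <- panel$snp_id[i]
    j <- which(fix[, "ID"] == sid)
    if (length(j) == 0) stop("panel SNP absent from VCF: ", sid)
    if (length(j) > 1) stop("panel SNP duplicated in VCF: ", sid)
    ref <- fix[j, "REF"]; alt <- fix[j, "ALT"]
    if (grepl(",", alt, fixed = TRUE) || nchar(ref) != 1 ||
        nchar(alt) != 1) {
      stop("panel SNP ", sid, " is not a biallelic SNV in the VCF")
    }
    alleles <- c(ref, alt)
    if (!setequal(alleles, c(panel$major[i], panel$minor[i]))) {
      stop("VCF REF/ALT (", ref, "/", alt, ") do not match panel alleles ",
           panel$major[i], "/", panel$minor[i], " for ", sid)
    }
    calls <- gt[j, samples]
    geno <- rep(NA_character_, length(calls))
    ok <- !is.na(calls) & calls != "./." & calls != ".|."
    parts <- strsplit(gsub("|", "/", calls[ok], fixed = TRUE), "/",
                      fixed = TRUE)
    bad <- vapply(parts, function(p) {
      length(p) != 2 || !all(p %in% c("0", "1"))
    }, logical(1))
    if (any(bad)) {
      stop("unparseable GT for ", sid, ": ",
           paste(unique(calls[ok][bad]), collapse = ", "))
    }
    geno[ok] <- vapply(parts, function(p) {
      paste0(alleles[as.integer(p) + 1L], collapse = "")
    }, character(1))
    subjects[[sid]] <- geno
  }
  cohort(panel, subjects)
}
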