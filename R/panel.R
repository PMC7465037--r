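#' Define a SNP panel
#'
#' A panel is the set of biallelic loci the analysis runs over. Each SNP
#' carries its designated major and minor (risk) alleles and a reference
#' minor-allele frequency. The minor allele is declared from a reference
#' population, never inferred from the sample: this prevents allele flips
#' when the sample MAF is close to 0.5 and fixes the direction of the
#' burden score.
#'
#' @param snp_id character vector of rsIDs (must be unique).
#' @param gene character vector of gene symbols.
#' @param major single-base major allele per SNP.
#' @param minor single-base minor (risk) allele per SNP.
#' @param ref_maf reference minor-allele frequency per SNP, in (0, 1).
#' @return A `snp_panel`: a data.frame with one row per SNP.
#' @examples
#' snp_panel("rs12785878", "DHCR7", "T", "G", 0.278)
#' @export
snp_panel <- function(snp_id, gene, major, minor, ref_maf) {
  panel <- data.frame(
    snp_id = as.character(snp_id),
    gene = as.character(gene),
    major = toupper(as.character(major)),
    minor = toupper(as.character(minor)),
    ref_maf = as.numeric(ref_maf),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  required <- c("snp_id", "gene", "major", "minor", "ref_maf")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$snp_id)) {
    stop("duplicate snp_id in panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  if (!all(panel$major %in% bases) || !all(panel$minor %in% bases)) {
    stop("alleles must be single bases A/C/G/T")
  }
  if (any(panel$major == panel$minor)) {
    stop("major and minor alleles must differ for every SNP")
  }
  if (any(!is.finite(panel$ref_maf)) || any(panel$ref_maf <= 0) ||
      any(panel$ref_maf >= 1)) {
    stop("ref_maf must lie strictly between 0 and 1")
  }
  invisible(panel)
}

#' The four-SNP vitamin D pathway study panel
#'
#' DHCR7 rs12785878, GC rs2282679, CYP2R1 rs2060793 and CYP24A1 rs6013897,
#' with minor-allele designations and non-Finnish European reference MAFs
#' (0.278, 0.288, 0.403, 0.197).
#'
#' @return A `snp_panel` of the four loci.
#' @export
study_panel <- function() {
  snp_panel(
    snp_id  = c("rs12785878", "rs2282679", "rs2060793", "rs6013897"),
    gene    = c("DHCR7", "GC", "CYP2R1", "CYP24A1"),
    major   = c("T", "T", "G", "T"),
    minor   = c("G", "G", "A", "A"),
    ref_maf = c(0.278, 0.288, 0.403, 0.197)
  )
}

#' Read a SNP panel from YAML or JSON
#'
#' The file holds a list of records with fields `snp_id`, `gene`, `major`,
#' `minor`, `ref_maf`.
#'
#' @param path file path; format inferred from the `.json` extension,
#'   otherwise parsed as YAML (JSON being a YAML subset, either works).
#' @return A `snp_panel`.
#' @export
read_panel <- function(path) {
  records <- yaml::read_yaml(path)
  if (is.null(records) || length(records) == 0) stop("empty panel file: ", path)
  fields <- function(f) vapply(records, function(r) {
    if (is.null(r[[f]])) stop("panel record missing field '", f, "'")
    as.character(r[[f]])
  }, character(1))
  snp_panel(
    snp_id = fields("snp_id"), gene = fields("gene"),
    major = fields("major"), minor = fields("minor"),
    ref_maf = as.numeric(fields("ref_maf"))
  )
}

panel_row <- function(panel, snp_id) {
  i <- match(snp_id, panel$snp_id)
  if (is.na(i)) stop("unknown snp_id: ", snp_id)
  panel[i, , drop = FALSE]
}
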