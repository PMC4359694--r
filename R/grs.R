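#' Compute per-individual unweighted genetic risk scores
#'
#' For each individual, sums risk-allele dosages over the panel SNPs with a
#' genotype call (the unweighted GRS: every risk allele counts 1), counts the
#' non-missing SNPs, and forms the rate offset `log(2 * n_nonmissing)` — the
#' log of the number of allele slots actually observed — so downstream
#' Poisson models describe risk alleles per allele slot and missing genotypes
#' cost no observations.
#'
#' Individuals with no call at any panel SNP have no defined rate and are
#' dropped with a warning.
#'
#' @param genotypes Dosage matrix (individuals x SNPs), risk-allele oriented
#'   (see [orient_to_risk_allele()]); values 0/1/2 or `NA`.
#' @param panel A `snp_panel`; its SNPs must all be genotype columns.
#' @return Tibble `individual_id`, `disease_group`, `count`, `n_nonmissing`,
#'   `offset`.
#' @examples
#' g <- matrix(c(2L, 1L, 0L, NA), 1, dimnames = list("i1", paste0("rs", 1:4)))
#' p <- make_panel(tibble::tibble(
#'   snp_id = paste0("rs", 1:4), risk_allele = "A",
#'   disease_group = "t2d"), "t2d")
#' compute_grs(g, p)   # count 3 over 3 called SNPs, offset log(6)
#' @export
compute_grs <- function(genotypes, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  absent <- setdiff(panel$snps$snp_id, colnames(genotypes))
  if (length(absent) > 0) {
    abort(paste0("Panel SNP(s) absent from genotypes: ",
                 paste(absent, collapse = ", ")),
          class = "grsburden_panel_error")
  }
  G <- unclass(genotypes)[, panel$snps$snp_id, drop = FALSE]
  count <- as.integer(rowSums(G, na.rm = TRUE))
  n_nonmissing <- as.integer(rowSums(!is.na(G)))
  out <- tibble(
    individual_id = rownames(G),
    disease_group = panel$disease_group,
    count = count,
    n_nonmissing = n_nonmissing,
    offset = log(2 * n_nonmissing)
  )
  if (any(n_nonmissing == 0)) {
    warn(paste0(sum(n_nonmissing == 0),
                " individual(s) with no called panel SNP dropped from the GRS table."))
    out <- out[out$n_nonmissing > 0, , drop = FALSE]
  }
  out
}

#' Orient VCF hard-call genotypes to risk-allele dosages
#'
#' Converts GT hard calls to counts of the panel's risk allele: when the risk
#' allele is ALT the dosage is the ALT-allele count; when it is REF the count
#' is flipped (`2 - ALT count`). Strand-ambiguous SNPs (A/T or C/G) cannot be
#' oriented without strand information and are handled per policy: `"keep"`
#' trusts the file's strand (appropriate for simulated or same-platform
#' data), `"drop"` excludes them with a log entry (appropriate for
#' heterogeneous real catalogs).
#'
#' @param vcf_genotypes Either a path to a VCF (read with
#'   \pkg{vcfR}) or a list with elements `gt` (ALT-dosage matrix,
#'   individuals x SNPs), `ref`, `alt` (named per SNP).
#' @param panel A `snp_panel`.
#' @param ambiguous_policy `"keep"` or `"drop"`.
#' @return A dosage matrix restricted to oriented panel SNPs, with attribute
#'   `orientation_log` (tibble `snp_id`, `action`, `reason`).
#' @export
orient_to_risk_allele <- function(vcf_genotypes, panel,
                                  ambiguous_policy = c("keep", "drop")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(inherits(panel, "snp_panel"))
  if (is.character(vcf_genotypes) && length(vcf_genotypes) == 1L) {
    vcf_genotypes <- read_vcf_dosages(vcf_genotypes)
  }
  gt <- vcf_genotypes$gt
  ref <- vcf_genotypes$ref
  alt <- vcf_genotypes$alt

  snps <- panel$snps
  absent <- setdiff(snps$snp_id, colnames(gt))
  if (length(absent) > 0) {
    abort(paste0("Panel SNP(s) absent from VCF: ", paste(absent, collapse = ", ")),
          class = "grsburden_panel_error")
  }
  log <- tibble(snp_id = character(0), action = character(0), reason = character(0))
  out <- matrix(NA_integer_, nrow(gt), 0, dimnames = list(rownames(gt), NULL))
  for (k in seq_len(nrow(snps))) {
    id <- snps$snp_id[k]
    ra <- snps$risk_allele[k]
    ambiguous <- paste0(sort(c(ref[id], alt[id])), collapse = "") %in% c("AT", "CG")
    if (ambiguous && ambiguous_policy == "drop") {
      log <- bind_rows(log, tibble(snp_id = id, action = "removed",
                                   reason = "strand_ambiguous"))
      next
    }
    if (ra == alt[id]) {
      d <- gt[, id]
    } else if (ra == ref[id]) {
      d <- 2L - gt[, id]
    } else {
      abort(paste0("Risk allele ", ra, " of ", id,
                   " matches neither REF (", ref[id], ") nor ALT (", alt[id], ")."),
            class = "grsburden_orientation_error")
    }
    out <- cbind(out, d)
    colnames(out)[ncol(out)] <- id
    log <- bind_rows(log, tibble(snp_id = id, action = "kept",
                                 reason = if (ambiguous) "strand_ambiguous_kept" else "oriented"))
  }
  attr(out, "orientation_log") <- log
  out
}

# Read a VCF 4.2 into an ALT-dosage matrix keyed by rsID.
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           stringr::str_count(g, "1"))
  }
  gt <- apply(gt_raw, 2, alt_count)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(gt_raw), colnames(gt_raw)))
  ids <- v@fix[, "ID"]
  list(
    gt = t(gt) |> `colnames<-`(ids),
    ref = setNames(v@fix[, "REF"], ids),
    alt = setNames(v@fix[, "ALT"], ids)
  )
}

#' Write genotypes as a VCF 4.2 file
#'
#' One sample column per individual, GT field only, unphased hard calls.
#' SNPs are laid out on a single synthetic contig at consecutive positions;
#' REF/ALT come from the generator's `alleles` attribute (the risk allele may
#' be either).
#'
#' @param genotypes A `genotype_matrix` from [generate_genotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  alleles <- attr(genotypes, "alleles")
  if (is.null(alleles)) {
    abort("Genotypes lack the `alleles` attribute needed for VCF export.",
          class = "grsburden_format_error")
  }
  G <- unclass(genotypes)
  # dosages count risk alleles; GT is written in ALT counts
  risk_is_alt <- alleles$risk_allele == alleles$alt
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(G)), function(j) {
    d <- G[, j]
    alt_d <- if (risk_is_alt[j]) d else 2L - d
    gt <- ifelse(is.na(alt_d), "./.", gt_codes[alt_d + 1L])
    paste(c("chrS", j, alleles$snp_id[j], alleles$ref[j], alleles$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
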