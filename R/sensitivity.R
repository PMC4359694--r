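#' Refit after removing named SNPs from a panel
#'
#' The SNP-removal sensitivity analysis (e.g. dropping the APOE/TOMM40-region
#' SNPs rs2075650, rs769449 and rs7412 from an Alzheimer's panel): removes
#' the listed SNPs, recomputes every individual's count, non-missing SNP
#' number and offset on the reduced panel (the offset shrinks because fewer
#' allele slots remain), and refits the requested strata and models.
#'
#' @param panel A `snp_panel`.
#' @param genotypes Risk-allele-oriented dosage matrix.
#' @param individuals Pedigree tibble.
#' @param snp_list rsIDs to remove; SNPs not in the panel are skipped with a
#'   warning.
#' @param scenario Label written into the `scenario` column.
#' @inheritParams run_analysis_suite
#' @return Results tibble as from [run_analysis_suite()], with a leading
#'   `scenario` column (row-compatible with the primary results).
#' @export
remove_snps_and_refit <- function(panel, genotypes, individuals, snp_list,
                                  scenario = paste0("removed_", paste(snp_list, collapse = "_")),
                                  models = "poisson_glmm",
                                  strata = c("generation1", "generation2", "both"),
                                  kinship = NULL, adjusted = TRUE, nAGQ = 9) {
  stopifnot(inherits(panel, "snp_panel"))
  absent <- setdiff(snp_list, panel$snps$snp_id)
  if (length(absent) > 0) {
    warn(paste0("SNP(s) not in panel, skipped: ", paste(absent, collapse = ", ")))
  }
  reduced <- panel
  reduced$snps <- panel$snps[!panel$snps$snp_id %in% snp_list, , drop = FALSE]
  if (nrow(reduced$snps) == 0) {
    abort("Removing these SNPs leaves an empty panel.",
          class = "grsburden_panel_error")
  }
  reduced$provenance_log <- bind_rows(
    panel$provenance_log,
    tibble(snp_id = intersect(snp_list, panel$snps$snp_id),
           action = "removed", reason = "sensitivity_removal")
  )
  grs <- compute_grs(genotypes, reduced)
  res <- run_analysis_suite(individuals, grs, models = models, strata = strata,
                            kinship = kinship, adjusted = adjusted, nAGQ = nAGQ)
  mutate(res, scenario = scenario, .before = 1)
}

#' Substitute generation-1 controls with an external control cohort
#'
#' Drops the married-in generation-1 spouses and adds external controls
#' (e.g. a younger population-based referent sample) as singleton families
#' with `longevity_member = 0` and `generation = 1` — singleton clusters, the
#' same way married-in spouses enter the family models. When
#' `shared_snps_only` the genotypes are restricted to SNPs present in both
#' sets, so panels must be intersected downstream.
#'
#' @param individuals Pedigree tibble.
#' @param genotypes Dosage matrix for `individuals`.
#' @param external_controls List with `individuals` (tibble with
#'   `individual_id`, `sex`; no family links) and `genotypes` (dosage
#'   matrix).
#' @param shared_snps_only Restrict to SNPs available in both sets?
#' @return List with `individuals`, `genotypes` and `shared_snps`.
#' @export
substitute_controls <- function(individuals, genotypes, external_controls,
                                shared_snps_only = TRUE) {
  ext_ind <- external_controls$individuals
  ext_gt <- external_controls$genotypes
  stopifnot(all(ext_ind$individual_id == rownames(ext_gt)))

  shared <- intersect(colnames(genotypes), colnames(ext_gt))
  if (length(shared) == 0) {
    abort("No SNPs shared between the cohort and the external controls.",
          class = "grsburden_panel_error")
  }
  keep_snps <- if (shared_snps_only) shared else colnames(genotypes)

  keep_ind <- !(individuals$generation == 1L & individuals$longevity_member == 0L)
  base_ind <- individuals[keep_ind, , drop = FALSE]
  ext_rows <- tibble(
    family_id = paste0("EXT_", ext_ind$individual_id),
    individual_id = ext_ind$individual_id,
    father_id = "0", mother_id = "0",
    sex = ext_ind$sex,
    generation = 1L,
    role = factor("spouse_g1",
                  levels = c("proband", "sibling", "spouse_g1", "offspring", "spouse_g2")),
    longevity_member = 0L
  )
  new_ind <- bind_rows(base_ind, ext_rows)

  g1 <- unclass(genotypes)[base_ind$individual_id, intersect(keep_snps, colnames(genotypes)), drop = FALSE]
  g2 <- unclass(ext_gt)[, intersect(keep_snps, colnames(ext_gt)), drop = FALSE]
  common <- intersect(colnames(g1), colnames(g2))
  extra1 <- setdiff(colnames(g1), common)
  filled2 <- cbind(g2[, common, drop = FALSE],
                   matrix(NA_integer_, nrow(g2), length(extra1),
                          dimnames = list(rownames(g2), extra1)))
  new_gt <- rbind(g1[, c(common, extra1), drop = FALSE],
                  filled2[, c(common, extra1), drop = FALSE])

  list(individuals = new_ind, genotypes = new_gt, shared_snps = shared)
}
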