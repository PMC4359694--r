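#' Join a GRS table to the pedigree for modelling
#'
#' @param grs GRS tibble from [compute_grs()].
#' @param individuals Pedigree tibble from [generate_pedigrees()] (or the
#'   same shape).
#' @return Tibble ready for the `fit_*` functions: the GRS columns plus
#'   `family_id`, `sex`, `generation`, `longevity_member`.
#' @export
join_cohort <- function(grs, individuals) {
  inner_join(grs,
             select(individuals, "individual_id", "family_id", "sex",
                    "generation", "longevity_member"),
             by = "individual_id")
}

stratum_filter <- function(data, stratum) {
  switch(stratum,
    generation1 = filter(data, .data$generation == 1L),
    generation2 = filter(data, .data$generation == 2L),
    both = data,
    abort(paste0("Unknown stratum: ", stratum), class = "grsburden_model_error")
  )
}

fit_one <- function(data, model, covariates, kinship = NULL, nAGQ = 9) {
  switch(model,
    poisson_glmm = fit_poisson_glmm(data, covariates, nAGQ = nAGQ),
    poisson_glm = fit_poisson_glm(data, covariates),
    poisson_gee = fit_poisson_gee(data, covariates),
    lmm_kinship = fit_lmm_kinship(data, kinship, covariates),
    abort(paste0("Unknown model: ", model), class = "grsburden_model_error")
  )
}

fit_row <- function(fit, stratum, disease_group, covariates) {
  tibble(
    data_stratum = stratum,
    disease_group = disease_group,
    model = fit$model,
    covariates = paste(covariates, collapse = "+"),
    beta = unname(fit$beta["longevity_member"]),
    se = unname(fit$se["longevity_member"]),
    z = unname(fit$z_stat["longevity_member"]),
    p_lrt = fit$p_lrt,
    p_wald = unname(fit$p_wald["longevity_member"]),
    rate_ratio = fit$rate_ratio,
    n = fit$n_obs,
    n_families = fit$n_families,
    converged = fit$converged
  )
}

#' Run the full cross of disease groups, strata and models
#'
#' For every disease group, data stratum (generation 1, generation 2, both)
#' and requested model, fits the crude association of the familial longevity
#' indicator with the risk-allele rate and the sex-adjusted association
#' (generation-adjusted as well for the combined stratum). Age is never
#' included: it is confounded with the longevity indicator by design of the
#' study. Empty strata are skipped with a warning.
#'
#' @param individuals Pedigree tibble.
#' @param grs_tables A single GRS tibble (with `disease_group`) or a list of
#'   them, as from [compute_grs()].
#' @param models Character subset of
#'   `c("poisson_glmm", "poisson_glm", "poisson_gee", "lmm_kinship")`.
#' @param strata Character subset of
#'   `c("generation1", "generation2", "both")`.
#' @param kinship Kinship matrix; computed from `individuals` on demand when
#'   `lmm_kinship` is requested.
#' @param adjusted `TRUE` (default) also fits the covariate-adjusted models.
#' @param nAGQ Quadrature nodes for the GLMM.
#' @return Tibble with one row per fit: `data_stratum`, `disease_group`,
#'   `model`, `covariates`, `beta`, `se`, `z`, `p_lrt`, `p_wald`,
#'   `rate_ratio`, `n`, `n_families`, `converged`.
#' @export
run_analysis_suite <- function(individuals, grs_tables,
                               models = "poisson_glmm",
                               strata = c("generation1", "generation2", "both"),
                               kinship = NULL, adjusted = TRUE, nAGQ = 9) {
  grs <- if (is.data.frame(grs_tables)) grs_tables else bind_rows(grs_tables)
  if ("lmm_kinship" %in% models && is.null(kinship)) {
    kinship <- kinship_matrix(individuals)
  }
  joined <- join_cohort(grs, individuals)
  grid <- tidyr::expand_grid(
    disease_group = unique(grs$disease_group),
    stratum = strata,
    model = models
  )
  out <- purrr::pmap_dfr(grid, function(disease_group, stratum, model) {
    d <- stratum_filter(filter(joined, .data$disease_group == !!disease_group),
                        stratum)
    if (nrow(d) == 0 || dplyr::n_distinct(d$longevity_member) < 2) {
      warn(paste0("Stratum ", stratum, " empty (or single-group) for ",
                  disease_group, "; skipped."))
      return(tibble())
    }
    covar_sets <- list(character(0))
    if (adjusted) {
      covar_sets <- c(covar_sets,
                      list(if (stratum == "both") c("sex", "generation") else "sex"))
    }
    map_dfr(covar_sets, function(cv) {
      fit_row(fit_one(d, model, cv, kinship = kinship, nAGQ = nAGQ),
              stratum, disease_group, cv)
    })
  })
  out
}
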