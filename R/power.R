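# Family-structured power simulation: per family a Gaussian random intercept
# on the log scale, a linear predictor adding the longevity effect, a Poisson
# GRS draw per individual, then a Poisson GLMM fit and LRT.

#' Simulate one power-study replicate and fit the mixed model
#'
#' Per family, an intercept `b_f ~ N(log(2 m baseline_rate), family_intercept_sd^2)`
#' is drawn; each individual's linear predictor is
#' `b_f + beta * longevity_member`; their GRS is drawn from
#' `Poisson(exp(linear predictor))`. A Poisson mixed model with a per-family
#' random intercept and offset `log(2m)` (every simulated individual is fully
#' genotyped) is then fit and the longevity coefficient tested by LRT.
#'
#' Because the simulated model has no individual-level covariates, the fit
#' collapses individuals to family-by-longevity-status totals first (an exact
#' sufficient-statistic reduction for this likelihood: a sum of iid Poisson
#' counts sharing one random intercept is Poisson with the summed offset).
#'
#' @param individuals Pedigree tibble (uses `family_id`, `longevity_member`).
#' @param panel_size Number of SNPs m in the simulated GRS.
#' @param beta Longevity effect, log scale (e.g. `log(0.99)` for a 1 percent
#'   difference).
#' @param baseline_rate Per-allele-slot risk-allele rate in (0, 1); the
#'   intercept is `log(2 * panel_size * baseline_rate)`.
#' @param family_intercept_sd Log-scale SD of the family intercept.
#' @param rep_seed Integer seed for this replicate.
#' @param nAGQ Quadrature nodes for the fit (1 = Laplace, the default here:
#'   with hundreds of counts per family the integrand is near-Gaussian).
#' @return A `grs_fit`.
#' @export
simulate_one_replicate <- function(individuals, panel_size, beta,
                                   baseline_rate = 0.5,
                                   family_intercept_sd = 0.01,
                                   rep_seed = 1L, nAGQ = 1) {
  stopifnot(baseline_rate > 0, baseline_rate < 1, panel_size >= 1)
  if (exp(beta) * baseline_rate >= 1) {
    abort("Longevity effect pushes the per-slot rate to 1 or above.",
          class = "grsburden_config_error")
  }
  set.seed(rep_seed)
  fams <- unique(individuals$family_id)
  b <- setNames(rnorm(length(fams), log(2 * panel_size * baseline_rate),
                      family_intercept_sd), fams)
  lp <- b[individuals$family_id] + beta * individuals$longevity_member
  y <- rpois(nrow(individuals), exp(lp))

  sim <- tibble(
    family_id = individuals$family_id,
    longevity_member = individuals$longevity_member,
    count = y,
    offset = log(2 * panel_size)
  )
  collapsed <- sim |>
    group_by(.data$family_id, .data$longevity_member) |>
    summarise(n_ind = dplyr::n(), count = sum(.data$count), .groups = "drop") |>
    mutate(offset = log(.data$n_ind * 2 * panel_size))
  fit <- fit_poisson_glmm(collapsed, covariates = character(), nAGQ = nAGQ)
  fit$n_obs <- nrow(sim)
  fit
}

#' Estimate power over a grid of strata, panel sizes and effects
#'
#' Monte-Carlo power of the Poisson GLMM likelihood-ratio test for the
#' familial longevity coefficient: for each stratum x panel size x effect
#' cell, `n_reps` replicates are simulated with [simulate_one_replicate()]
#' and the rejection fraction at `alpha` reported with its binomial
#' Monte-Carlo standard error. Non-converged replicates are excluded from
#' the denominator (and counted).
#'
#' @param individuals Pedigree tibble defining the family structure (e.g.
#'   from [generate_pedigrees()] with the default emulation config).
#' @param panel_sizes Panel sizes m to simulate (defaults: the four
#'   disease-panel sizes).
#' @param effects Percent GRS differences; `beta = log(1 - percent/100)`.
#' @param strata Subset of `c("generation1", "generation2", "both")`.
#' @param baseline_rate,family_intercept_sd Simulation scale parameters, see
#'   [simulate_one_replicate()].
#' @param n_reps Replicates per cell.
#' @param alpha Two-sided significance level for the LRT.
#' @param seed Root seed; per-replicate seeds derive from it.
#' @param nAGQ Quadrature nodes per fit.
#' @return Tibble of class `grs_power`: `stratum`, `panel_size`, `effect_pct`,
#'   `beta`, `power`, `mc_se`, `n_reps`, `n_converged`.
#' @export
estimate_power <- function(individuals,
                           panel_sizes = c(93, 239, 155, 431),
                           effects = c(1, 5, 10),
                           strata = c("generation1", "generation2", "both"),
                           baseline_rate = 0.5,
                           family_intercept_sd = 0.01,
                           n_reps = 100, alpha = 0.05, seed = 1L, nAGQ = 1) {
  stopifnot(n_reps >= 1)
  grid <- tidyr::expand_grid(stratum = strata, panel_size = panel_sizes,
                             effect_pct = effects)
  out <- purrr::pmap_dfr(grid, function(stratum, panel_size, effect_pct) {
    beta <- log(1 - effect_pct / 100)
    ind <- stratum_filter(individuals, stratum)
    cell_seed <- stage_seed(seed, paste("power", stratum, panel_size, effect_pct))
    sig <- logical(n_reps)
    conv <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      fit <- simulate_one_replicate(ind, panel_size, beta,
                                    baseline_rate = baseline_rate,
                                    family_intercept_sd = family_intercept_sd,
                                    rep_seed = (cell_seed + r) %% .Machine$integer.max,
                                    nAGQ = nAGQ)
      conv[r] <- fit$converged
      sig[r] <- isTRUE(fit$p_lrt < alpha)
    }
    if (any(!conv)) {
      warn(paste0(sum(!conv), " non-converged replicate(s) excluded in cell ",
                  stratum, "/m=", panel_size, "/", effect_pct, "%."))
    }
    n_eff <- sum(conv)
    pw <- if (n_eff > 0) mean(sig[conv]) else NA_real_
    tibble(
      stratum = stratum, panel_size = panel_size, effect_pct = effect_pct,
      beta = beta, power = pw,
      mc_se = if (n_eff > 0) sqrt(pw * (1 - pw) / n_eff) else NA_real_,
      n_reps = n_reps, n_converged = n_eff
    )
  })
  class(out) <- c("grs_power", class(out))
  out
}

# Closed-form two-group Poisson Wald power with no random intercept:
# Var(beta_hat) = 1/sum(lambda_members) + 1/sum(lambda_controls).
# Internal truth standard for the simulation, not a user-facing feature.
analytic_power <- function(individuals, panel_size, beta, baseline_rate = 0.5,
                           alpha = 0.05) {
  n1 <- sum(individuals$longevity_member == 1)
  n0 <- sum(individuals$longevity_member == 0)
  lam0 <- 2 * panel_size * baseline_rate
  lam1 <- lam0 * exp(beta)
  se <- sqrt(1 / (n1 * lam1) + 1 / (n0 * lam0))
  z <- qnorm(1 - alpha / 2)
  pnorm(-z - beta / se) + 1 - pnorm(z - beta / se)
}
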