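#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model fit into one row per coefficient
#'
#' @param x A `grs_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`
#'   (Wald).
#' @method tidy grs_fit
#' @export
tidy.grs_fit <- function(x, ...) {
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$z_stat),
    p.value = unname(x$p_wald)
  )
}

#' One-row model summary
#'
#' @param x A `grs_fit`.
#' @param ... Unused.
#' @return Tibble `model`, `beta_longevity`, `se_longevity`, `z_longevity`,
#'   `p_lrt`, `p_wald`, `rate_ratio`, `percent_fewer`, `converged`, `n_obs`,
#'   `n_families`.
#' @method glance grs_fit
#' @export
glance.grs_fit <- function(x, ...) {
  tibble(
    model = x$model,
    beta_longevity = unname(x$beta["longevity_member"]),
    se_longevity = unname(x$se["longevity_member"]),
    z_longevity = unname(x$z_stat["longevity_member"]),
    p_lrt = x$p_lrt,
    p_wald = unname(x$p_wald["longevity_member"]),
    rate_ratio = x$rate_ratio,
    percent_fewer = round(100 * (1 - x$rate_ratio), 2),
    converged = x$converged,
    n_obs = x$n_obs,
    n_families = x$n_families
  )
}

#' Plot estimated power across panel sizes
#'
#' @param object A `grs_power` table from [estimate_power()].
#' @param ... Unused.
#' @return A ggplot: power (with 2 Monte-Carlo-SE ribbons) against panel
#'   size, coloured by stratum, faceted by effect size.
#' @method autoplot grs_power
#' @export
autoplot.grs_power <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$panel_size, y = .data$power,
                               colour = .data$stratum, group = .data$stratum)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$power - 2 * .data$mc_se, 0),
                   ymax = pmin(.data$power + 2 * .data$mc_se, 1),
                   fill = .data$stratum),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ effect_pct,
                        labeller = ggplot2::labeller(
                          effect_pct = function(v) paste0(v, "% GRS difference"))) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Panel size (SNPs)", y = "Estimated power",
                  colour = "Stratum", fill = "Stratum") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of risk-allele rates by longevity status
#'
#' Displays the per-individual risk-allele rate `count / (2 n_nonmissing)`
#' split by familial-longevity status, faceted by disease group — the
#' distributional display backing the rate models.
#'
#' @param grs GRS tibble joined to the pedigree (see [join_cohort()]).
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_grs_distribution <- function(grs, bins = 40) {
  grs |>
    mutate(
      rate = .data$count / (2 * .data$n_nonmissing),
      group = ifelse(.data$longevity_member == 1, "longevity member", "control")
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rate, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.55) +
    ggplot2::facet_wrap(~ disease_group, scales = "free") +
    ggplot2::labs(x = "Risk-allele rate (alleles per slot)", y = "Individuals",
                  fill = NULL) +
    ggplot2::theme_bw()
}
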