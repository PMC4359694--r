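# Model-fitting layer: four model families for comparing risk-allele rates
# between longevity members and married-in controls.  All fitters take the
# GRS table joined to the pedigree (columns count, offset, longevity_member,
# family_id, plus any covariates) and return a `grs_fit`.

new_grs_fit <- function(model, beta, se, p_lrt, converged, n_obs, n_families,
                        extra = list()) {
  z <- beta / se
  structure(
    c(list(
      model = model,
      beta = beta, se = se, z_stat = z,
      p_wald = 2 * pnorm(-abs(z)),
      p_lrt = p_lrt,
      rate_ratio = unname(exp(beta["longevity_member"])),
      converged = converged,
      n_obs = n_obs, n_families = n_families
    ), extra),
    class = "grs_fit"
  )
}

#' @export
print.grs_fit <- function(x, ...) {
  cat("<grs_fit> ", x$model, " | n = ", x$n_obs, " in ", x$n_families,
      " families", if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(tidy(x), ...)
  cat("rate ratio exp(beta_longevity) = ", format(x$rate_ratio, digits = 4),
      if (!is.na(x$p_lrt)) paste0(";  LRT p = ", format(x$p_lrt, digits = 3)),
      "\n", sep = "")
  invisible(x)
}

# glmer emits advisory warnings (rescaling, near-unidentifiability) freely on
# large-count Poisson fits; convergence status is read from @optinfo instead.
quiet_glmer <- function(expr) suppressMessages(suppressWarnings(expr))

check_model_data <- function(data, covariates, need_integer = TRUE) {
  needed <- c("count", "offset", "longevity_member", "family_id", covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Model data is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "grsburden_model_error")
  }
  if (need_integer && any(data$count != round(data$count))) {
    abort("Poisson models need integer counts.", class = "grsburden_model_error")
  }
  if (any(!is.finite(data$offset))) {
    abort("Offsets must be finite (drop individuals with no called SNP first).",
          class = "grsburden_model_error")
  }
  for (cv in covariates) {
    if (dplyr::n_distinct(data[[cv]]) < 2) {
      abort(paste0("Singular design; aliased column(s): ", cv),
            class = "grsburden_model_error")
    }
  }
  X <- model_matrix_for(data, covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("Singular design; aliased column(s): ",
                 paste(aliased, collapse = ", ")),
          class = "grsburden_model_error")
  }
  invisible(X)
}

model_matrix_for <- function(data, covariates) {
  rhs <- paste(c("longevity_member", covariates), collapse = " + ")
  stats::model.matrix(as.formula(paste("~", rhs)), data = data)
}

#' Fit a Poisson generalized linear model (family correlation ignored)
#'
#' Log-link Poisson regression of the risk-allele count on the familial
#' longevity indicator (plus covariates) with the allele-slot offset, by
#' IRLS. Within-family correlation is ignored, so its test statistics are
#' anti-conservative under family clustering — it is the baseline the
#' family-aware models are judged against.
#'
#' @param data Tibble with `count`, `offset`, `longevity_member`, `family_id`
#'   and any covariates.
#' @param covariates Character vector drawn from `c("sex", "generation")`.
#' @return A `grs_fit` with Wald and likelihood-ratio inference for the
#'   longevity coefficient.
#' @export
fit_poisson_glm <- function(data, covariates = character()) {
  check_model_data(data, covariates)
  rhs <- paste(c("longevity_member", covariates), collapse = " + ")
  full <- glm(as.formula(paste("count ~", rhs, "+ offset(offset)")),
              family = poisson(), data = data)
  red <- glm(as.formula(paste(
    "count ~", paste(c("1", covariates), collapse = " + "), "+ offset(offset)")),
    family = poisson(), data = data)
  lrt <- as.numeric(2 * (logLik(full) - logLik(red)))
  cf <- coef(full)
  new_grs_fit(
    model = "poisson_glm",
    beta = cf, se = sqrt(diag(vcov(full))),
    p_lrt = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
    converged = full$converged,
    n_obs = nrow(data), n_families = dplyr::n_distinct(data$family_id),
    extra = list(logLik = as.numeric(logLik(full)), fit = full)
  )
}

#' Fit a Poisson mixed-effects model with a per-family random intercept
#'
#' The primary analysis model: log-link Poisson regression of the risk-allele
#' count on the familial longevity indicator (plus covariates), with the
#' allele-slot offset and a Gaussian random intercept shared by family
#' members. The marginal likelihood integrates the random intercept by
#' adaptive Gauss-Hermite quadrature (`nAGQ` nodes; 1 = Laplace). Inference
#' for the longevity coefficient is by likelihood-ratio test against the
#' model without it (chi-squared, 1 df); Wald Z statistics are reported
#' alongside. The random-intercept variance is bounded at zero; at the
#' boundary the model reduces to the plain Poisson GLM.
#'
#' @inheritParams fit_poisson_glm
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature nodes (default 9).
#' @param ranef_variance `NULL` (estimate, the default) or `0` to fix the
#'   random-intercept variance at zero, which is exactly the nested Poisson
#'   GLM.
#' @return A `grs_fit`; `$varcomp` holds the random-intercept SD.
#' @export
fit_poisson_glmm <- function(data, covariates = character(), nAGQ = 9,
                             ranef_variance = NULL) {
  check_model_data(data, covariates)
  if (dplyr::n_distinct(data$family_id) < 2) {
    abort("Poisson GLMM needs at least 2 families.", class = "grsburden_model_error")
  }
  if (!is.null(ranef_variance)) {
    if (ranef_variance != 0) {
      abort("Only `ranef_variance = 0` (the nested GLM limit) can be fixed.",
            class = "grsburden_model_error")
    }
    out <- fit_poisson_glm(data, covariates)
    out$model <- "poisson_glmm"
    out$varcomp <- c(family_sd = 0)
    return(out)
  }
  rhs <- paste(c("longevity_member", covariates), collapse = " + ")
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore")
  full <- quiet_glmer(lme4::glmer(
    as.formula(paste("count ~", rhs, "+ (1 | family_id) + offset(offset)")),
    family = poisson(), data = data, nAGQ = nAGQ, control = ctrl))
  red <- quiet_glmer(lme4::glmer(
    as.formula(paste("count ~", paste(c("1", covariates), collapse = " + "),
                     "+ (1 | family_id) + offset(offset)")),
    family = poisson(), data = data, nAGQ = nAGQ, control = ctrl))
  lrt <- as.numeric(2 * (logLik(full) - logLik(red)))
  cf <- lme4::fixef(full)
  # advisory checks (scaling / near-unidentifiability) are not failures;
  # only optimizer non-convergence flags the fit
  msgs <- unlist(full@optinfo$conv$lme4$messages)
  converged <- full@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  # for nAGQ > 1 lme4 reports the log-likelihood relative to the saturated
  # model; add the saturated Poisson constant back so logLik is absolute
  ll_abs <- as.numeric(logLik(full)) +
    if (nAGQ > 1) sum(dpois(data$count, data$count, log = TRUE)) else 0
  new_grs_fit(
    model = "poisson_glmm",
    beta = cf, se = sqrt(diag(as.matrix(vcov(full)))),
    p_lrt = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
    converged = converged,
    n_obs = nrow(data), n_families = dplyr::n_distinct(data$family_id),
    extra = list(
      logLik = ll_abs,
      varcomp = c(family_sd = unname(attr(lme4::VarCorr(full)$family_id, "stddev"))),
      fit = full
    )
  )
}

# Marginal log-likelihood of the Poisson random-intercept model by dense-grid
# numerical integration; independent of lme4's quadrature.  Used as an
# internal cross-check (and by the test-suite oracle at coarser settings).
glmm_marginal_loglik <- function(data, covariates, beta, family_sd,
                                 grid_halfwidth = 8, grid_n = 4001) {
  X <- model_matrix_for(data, covariates)
  eta0 <- drop(X %*% beta[colnames(X)]) + data$offset
  if (family_sd == 0) {
    return(sum(dpois(data$count, exp(eta0), log = TRUE)))
  }
  b <- seq(-grid_halfwidth * family_sd, grid_halfwidth * family_sd,
           length.out = grid_n)
  wb <- dnorm(b, 0, family_sd)
  ll <- 0
  for (f in unique(data$family_id)) {
    i <- which(data$family_id == f)
    lp <- outer(eta0[i], b, "+")
    ll_b <- colSums(dpois(data$count[i], exp(lp), log = TRUE))
    m <- max(ll_b)
    integrand <- exp(ll_b - m) * wb
    ll <- ll + m + log(sum((integrand[-1] + integrand[-grid_n]) / 2 * diff(b)))
  }
  ll
}

#' Turn a longevity regression coefficient into a rate ratio
#'
#' The longevity coefficient is on the log scale, so `exp(beta)` is the ratio
#' of expected risk-allele counts between longevity members and controls, and
#' `100 * (1 - exp(beta))` is the percent fewer risk alleles carried by
#' members (negative = more).
#'
#' @param beta Longevity coefficient(s), log scale.
#' @return Tibble `beta`, `rate_ratio`, `percent_fewer` (percent, rounded to
#'   2 decimals for display).
#' @examples
#' rate_ratio_report(-0.01067)   # rate ratio 0.989, 1.06% fewer
#' @export
rate_ratio_report <- function(beta) {
  stopifnot(all(is.finite(beta)))
  tibble(
    beta = beta,
    rate_ratio = exp(beta),
    percent_fewer = round(100 * (1 - exp(beta)), 2)
  )
}
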