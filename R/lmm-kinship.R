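#' Fit a linear mixed model with kinship-structured covariance
#'
#' Models the risk-allele *rate* `count / (2 * n_nonmissing)` as
#' approximately Gaussian with covariance
#' `sigma_g^2 * 2 * Phi + sigma_e^2 * I`, where `Phi` is the pedigree kinship
#' matrix (so `2 * Phi` is the additive genetic relationship matrix). The
#' variance components are estimated by REML: the relationship matrix is
#' eigendecomposed once, the model is rotated to independence, and the
#' variance ratio is profiled out by one-dimensional optimisation. Inference
#' for the longevity coefficient is a Wald test from the GLS covariance.
#'
#' @param data Tibble with `count`, `n_nonmissing`, `individual_id`,
#'   `longevity_member`, `family_id` and any covariates.
#' @param kinship Kinship matrix from [kinship_matrix()], covering every
#'   `individual_id` (dimnames required).
#' @param covariates Character vector drawn from `c("sex", "generation")`.
#' @return A `grs_fit`; `$varcomp` holds `sigma2_g` and `sigma2_e`.
#' @export
fit_lmm_kinship <- function(data, kinship, covariates = character()) {
  needed <- c("count", "n_nonmissing", "individual_id", "longevity_member", covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Model data is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "grsburden_model_error")
  }
  if (is.null(dimnames(kinship)) ||
      !all(data$individual_id %in% rownames(kinship))) {
    abort("Kinship matrix ids do not cover the model data.",
          class = "grsburden_model_error")
  }
  A <- 2 * kinship[data$individual_id, data$individual_id]
  y <- data$count / (2 * data$n_nonmissing)
  X <- model_matrix_for(data, covariates)
  n <- length(y)
  p <- ncol(X)

  eig <- eigen(A, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  ys <- drop(crossprod(eig$vectors, y))
  Xs <- crossprod(eig$vectors, X)

  profile <- function(log_lambda) {
    lambda <- exp(log_lambda)
    w <- 1 / (lambda * d + 1)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- drop(crossprod(Xs, ys * w))
    beta <- solve(XtWX, XtWy)
    res <- ys - drop(Xs %*% beta)
    rss <- sum(w * res^2)
    sigma2_e <- rss / (n - p)
    reml <- -0.5 * ((n - p) * log(sigma2_e) - sum(log(w)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
    list(reml = as.numeric(reml), beta = beta, sigma2_e = sigma2_e,
         XtWX = XtWX, lambda = lambda)
  }
  opt <- optimize(function(l) -profile(l)$reml, interval = c(-12, 12))
  sol0 <- profile(-30)      # lambda ~ 0 boundary
  sol <- profile(opt$minimum)
  if (sol0$reml >= sol$reml) sol <- sol0   # variance component bounded at 0

  beta <- drop(sol$beta)
  names(beta) <- colnames(X)
  cov_beta <- sol$sigma2_e * solve(sol$XtWX)
  se <- sqrt(diag(cov_beta))
  names(se) <- colnames(X)
  sigma2_g <- if (sol$lambda < 1e-12) 0 else sol$lambda * sol$sigma2_e

  new_grs_fit(
    model = "lmm_kinship",
    beta = beta, se = se, p_lrt = NA_real_,
    converged = TRUE,
    n_obs = n,
    n_families = if ("family_id" %in% names(data)) {
      dplyr::n_distinct(data$family_id)
    } else NA_integer_,
    extra = list(varcomp = c(sigma2_g = sigma2_g, sigma2_e = sol$sigma2_e),
                 reml = sol$reml)
  )
}
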