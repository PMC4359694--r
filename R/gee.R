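#' Fit a Poisson GEE with exchangeable working correlation and sandwich
#' variance
#'
#' Marginal log-link Poisson model estimated by generalized estimating
#' equations with families as clusters. The exchangeable working correlation
#' and the scale are estimated by moment (Pearson-residual) estimators
#' between Fisher-scoring updates of the coefficients; standard errors come
#' from the robust (sandwich) covariance, so inference is valid even when the
#' working correlation is wrong. Wald inference only (GEE has no likelihood,
#' hence no LRT). Singleton families are allowed.
#'
#' @inheritParams fit_poisson_glm
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param tol Convergence tolerance on the coefficient update.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @return A `grs_fit`; `$alpha` is the working correlation estimate,
#'   `$ee_norm` the estimating-equation residual norm at the solution.
#' @export
fit_poisson_gee <- function(data, covariates = character(),
                            corstr = c("exchangeable", "independence"),
                            tol = 1e-12, max_iter = 100) {
  corstr <- match.arg(corstr)
  X <- check_model_data(data, covariates)
  if (dplyr::n_distinct(data$family_id) < 1) {
    abort("GEE needs at least one family.", class = "grsburden_model_error")
  }
  y <- data$count
  off <- data$offset
  cl <- split(seq_along(y), data$family_id)
  p <- ncol(X)
  n <- length(y)

  beta <- coef(glm(y ~ X - 1 + offset(off), family = poisson()))
  names(beta) <- colnames(X)
  alpha <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- exp(drop(X %*% beta) + off)
    r <- (y - mu) / sqrt(mu)
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (i in cl) {
        k <- length(i)
        if (k > 1) {
          num <- num + (sum(r[i])^2 - sum(r[i]^2)) / 2
          npairs <- npairs + k * (k - 1) / 2
        }
      }
      alpha <- if (npairs > p) num / (phi * (npairs - p)) else 0
      alpha <- min(max(alpha, -0.99), 0.99)
    }
    B <- matrix(0, p, p)
    u <- numeric(p)
    for (i in cl) {
      k <- length(i)
      Di <- X[i, , drop = FALSE] * mu[i]              # dmu/dbeta
      s <- sqrt(mu[i])
      # V^-1 = phi^-1 A^-1/2 R^-1 A^-1/2 with exchangeable R
      ri <- (y[i] - mu[i]) / s
      Zi <- Di / s                                    # A^-1/2 D
      if (k == 1 || alpha == 0) {
        Rinv_Z <- Zi
        Rinv_r <- ri
      } else {
        c1 <- 1 / (1 - alpha)
        c2 <- alpha / ((1 - alpha) * (1 + (k - 1) * alpha))
        Rinv_Z <- c1 * Zi - c2 * matrix(colSums(Zi), k, p, byrow = TRUE)
        Rinv_r <- c1 * ri - c2 * sum(ri)
      }
      B <- B + crossprod(Zi, Rinv_Z) / phi
      u <- u + drop(crossprod(Zi, Rinv_r)) / phi
    }
    delta <- solve(B, u)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  # sandwich: B^-1 (sum_i u_i u_i') B^-1 at the solution
  mu <- exp(drop(X %*% beta) + off)
  M <- matrix(0, p, p)
  B <- matrix(0, p, p)
  u_tot <- numeric(p)
  for (i in cl) {
    k <- length(i)
    s <- sqrt(mu[i])
    Zi <- (X[i, , drop = FALSE] * mu[i]) / s
    ri <- (y[i] - mu[i]) / s
    if (k == 1 || alpha == 0) {
      Rinv_Z <- Zi; Rinv_r <- ri
    } else {
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / ((1 - alpha) * (1 + (k - 1) * alpha))
      Rinv_Z <- c1 * Zi - c2 * matrix(colSums(Zi), k, p, byrow = TRUE)
      Rinv_r <- c1 * ri - c2 * sum(ri)
    }
    ui <- drop(crossprod(Zi, Rinv_r)) / phi
    M <- M + tcrossprod(ui)
    B <- B + crossprod(Zi, Rinv_Z) / phi
    u_tot <- u_tot + ui
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  se <- sqrt(diag(V))
  names(se) <- colnames(X)

  out <- new_grs_fit(
    model = "poisson_gee",
    beta = beta, se = se, p_lrt = NA_real_,
    converged = converged,
    n_obs = n, n_families = length(cl),
    extra = list(alpha = alpha, scale = phi,
                 ee_norm = sqrt(sum(u_tot^2)), vcov_robust = V)
  )
  out
}
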