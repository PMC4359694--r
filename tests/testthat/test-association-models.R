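test_that("two-group Poisson GLM equals the closed-form allele-rate ratio", {
  d <- make_model_data(seed = 1, n_fam = 60)
  fit <- fit_poisson_glm(d)
  cf <- oracle_two_group_beta(d$count, d$offset, d$longevity_member)
  expect_equal(unname(fit$beta["longevity_member"]), cf, tolerance = 1e-8)
  expect_equal(fit$rate_ratio, exp(cf), tolerance = 1e-8)
})

test_that("model data validation catches bad inputs", {
  d <- make_model_data(seed = 2, n_fam = 10)
  d_bad <- dplyr::mutate(d, count = count + 0.5)
  expect_error(fit_poisson_glm(d_bad), class = "grsburden_model_error")
  d_alias <- dplyr::mutate(d, sex = "M")
  expect_error(fit_poisson_glm(d_alias, covariates = "sex"), "sex",
               class = "grsburden_model_error")
  expect_error(fit_poisson_glm(dplyr::select(d, -count)),
               class = "grsburden_model_error")
  expect_error(fit_poisson_glmm(dplyr::mutate(d, family_id = "one")),
               class = "grsburden_model_error")
})

test_that("GLMM log-likelihood matches dense-grid numerical integration", {
  d <- make_model_data(seed = 3, n_fam = 5, fam_size = 4, family_sd = 0.3,
                       m = 10L)
  fit <- fit_poisson_glmm(d, nAGQ = 25)
  oracle <- grsburden:::glmm_marginal_loglik(
    d, character(0), fit$beta, fit$varcomp[["family_sd"]])
  expect_equal(fit$logLik, oracle, tolerance = 1e-4)
})

test_that("GLMM with variance fixed at zero is exactly the Poisson GLM", {
  d <- make_model_data(seed = 4, n_fam = 40)
  glmm0 <- fit_poisson_glmm(d, covariates = "sex", ranef_variance = 0)
  glm_fit <- fit_poisson_glm(d, covariates = "sex")
  expect_equal(glmm0$beta, glm_fit$beta, tolerance = 1e-6)
  expect_equal(glmm0$se, glm_fit$se, tolerance = 1e-6)
  expect_equal(glmm0$p_lrt, glm_fit$p_lrt, tolerance = 1e-6)
})

test_that("GLMM recovers the simulated longevity effect and family variance", {
  d <- make_model_data(seed = 5, n_fam = 400, fam_size = 6,
                       beta = log(0.99), family_sd = 0.05, m = 431L)
  fit <- fit_poisson_glmm(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["longevity_member"]] - log(0.99)),
            3 * fit$se[["longevity_member"]])
  expect_equal(fit$varcomp[["family_sd"]], 0.05, tolerance = 0.5)
  # LRT statistic is nonnegative, p in [0,1], and agrees with Wald within 2x
  expect_gte(fit$p_lrt, 0); expect_lte(fit$p_lrt, 1)
  ratio <- fit$p_lrt / fit$p_wald[["longevity_member"]]
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
})

test_that("GLMM quadrature is stable beyond 5 nodes", {
  d <- make_model_data(seed = 6, n_fam = 30, fam_size = 4, family_sd = 0.2,
                       m = 20L)
  lls <- vapply(c(5, 9, 15, 25),
                function(q) fit_poisson_glmm(d, nAGQ = q)$logLik, numeric(1))
  expect_lt(max(abs(diff(lls))), 1e-3)
})

test_that("GEE with singleton clusters reproduces the GLM exactly", {
  d <- make_model_data(seed = 7, n_fam = 80)
  d_single <- dplyr::mutate(d, family_id = individual_id)
  gee <- fit_poisson_gee(d_single, covariates = "sex")
  glm_fit <- fit_poisson_glm(d, covariates = "sex")
  expect_equal(gee$beta, glm_fit$beta, tolerance = 1e-6)
  expect_equal(gee$alpha, 0)
})

test_that("GEE matches an independent reference implementation", {
  # fixed fixture; reference values computed with statsmodels GEE
  # (Poisson family, exchangeable working correlation, robust covariance)
  d <- tibble::tibble(
    family_id = rep(sprintf("c%d", 1:6), each = 3),
    longevity_member = c(1, 1, 0, 1, 0, 0, 1, 1, 1, 0, 0, 0, 1, 0, 1, 0, 1, 0),
    count = c(5, 7, 4, 6, 3, 5, 8, 9, 7, 2, 4, 3, 6, 5, 7, 4, 6, 3),
    offset = log(10)
  )
  fit <- fit_poisson_gee(d)
  expect_equal(unname(fit$beta), c(-1.12835435, 0.83142394), tolerance = 1e-5)
  expect_equal(unname(fit$se), c(0.05507418, 0.09107943), tolerance = 1e-5)
  expect_equal(fit$alpha, -0.38294358, tolerance = 1e-5)
  # stationarity: estimating equations vanish at the reported solution
  expect_lt(fit$ee_norm, 1e-6)
  expect_true(is.na(fit$p_lrt))   # Wald-only inference
})

test_that("sandwich variance restores type-I error under family clustering", {
  n_sig_glm <- 0L; n_sig_gee <- 0L
  reps <- 120L
  for (s in seq_len(reps)) {
    d <- make_model_data(seed = 40000 + s, n_fam = 40, fam_size = 5,
                         beta = 0, family_sd = 0.08, m = 93L,
                         between_family = TRUE)
    glm_fit <- fit_poisson_glm(d)
    gee_fit <- fit_poisson_gee(d)
    if (glm_fit$p_wald[["longevity_member"]] < 0.05) n_sig_glm <- n_sig_glm + 1L
    if (gee_fit$p_wald[["longevity_member"]] < 0.05) n_sig_gee <- n_sig_gee + 1L
  }
  # naive GLM is anti-conservative under clustering; the sandwich is not
  expect_gt(n_sig_glm / reps, 0.09)
  expect_gt(n_sig_gee / reps, 0.01)
  expect_lt(n_sig_gee / reps, 0.11)
})

test_that("kinship LMM with unrelated individuals reduces to OLS", {
  d <- make_model_data(seed = 9, n_fam = 50)
  K <- diag(nrow(d)) / 2
  dimnames(K) <- list(d$individual_id, d$individual_id)
  lmm <- fit_lmm_kinship(d, K, covariates = "sex")
  ols <- lm(I(count / (2 * n_nonmissing)) ~ longevity_member + sex, data = d)
  expect_equal(unname(lmm$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(unname(lmm$se), unname(sqrt(diag(vcov(ols)))), tolerance = 1e-6)
  expect_error(fit_lmm_kinship(d, unname(K)), class = "grsburden_model_error")
})

test_that("kinship LMM recovers a genetic variance component", {
  cfg <- cohort_config(n_families = 250, seed = 17, missing_rate = 0)
  ped <- generate_pedigrees(cfg)
  K <- kinship_matrix(ped)
  A <- 2 * K
  # simulate a trait with known variance decomposition on the pedigree
  set.seed(99)
  s2g <- 4e-4; s2e <- 4e-4
  L <- chol(A + diag(1e-8, nrow(A)))
  gvals <- drop(crossprod(L, rnorm(nrow(A), 0, sqrt(s2g))))
  y_rate <- 0.5 + gvals + rnorm(nrow(A), 0, sqrt(s2e))
  m <- 500L
  d <- tibble::tibble(
    individual_id = ped$individual_id,
    family_id = ped$family_id,
    longevity_member = ped$longevity_member,
    count = as.integer(round(pmin(pmax(y_rate, 0), 1) * 2 * m)),
    n_nonmissing = m
  )
  fit <- fit_lmm_kinship(d, K)
  expect_equal(fit$varcomp[["sigma2_g"]], s2g, tolerance = 0.5)
  expect_gt(fit$varcomp[["sigma2_e"]], 0)
})

test_that("Poisson GLMM and kinship LMM agree in direction on one cohort", {
  cfg <- cohort_config(n_families = 150, seed = 23,
                       longevity_rate_ratio = 0.9, missing_rate = 0)
  ped <- generate_pedigrees(cfg)
  g <- generate_genotypes(ped, 60, cfg)
  g <- inject_longevity_effect(g, ped, 0.9, 0, seed = 23)
  panel <- make_panel(tibble::tibble(
    snp_id = colnames(g), risk_allele = attr(g, "alleles")$risk_allele,
    disease_group = "t2d"), "t2d")
  d <- join_cohort(compute_grs(g, panel), ped)
  glmm <- fit_poisson_glmm(d)
  lmm <- fit_lmm_kinship(d, kinship_matrix(ped))
  expect_lt(glmm$beta[["longevity_member"]], 0)
  expect_equal(sign(glmm$beta[["longevity_member"]]),
               sign(lmm$beta[["longevity_member"]]))
})

test_that("rate-ratio reporting matches hand arithmetic", {
  rep1 <- rate_ratio_report(-0.01067)
  expect_equal(rep1$rate_ratio, exp(-0.01067))
  expect_equal(round(rep1$rate_ratio, 3), 0.989)
  expect_equal(rep1$percent_fewer, 1.06)
  rep0 <- rate_ratio_report(0)
  expect_equal(rep0$rate_ratio, 1)
  expect_equal(rep0$percent_fewer, 0)
  expect_equal(rate_ratio_report(-0.00884)$percent_fewer, 0.88)
  expect_error(rate_ratio_report(Inf))
})

test_that("tidy and glance methods expose broom-style summaries", {
  d <- make_model_data(seed = 10, n_fam = 30)
  fit <- fit_poisson_glm(d, covariates = "sex")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 3L)
  expect_equal(td$statistic, td$estimate / td$std.error)
  gl <- glance(fit)
  expect_equal(gl$rate_ratio, exp(td$estimate[td$term == "longevity_member"]))
  expect_equal(nrow(gl), 1L)
})

test_that("the analysis suite mirrors the published table layout", {
  cfg <- cohort_config(n_families = 60, seed = 29, missing_rate = 0.01)
  ped <- generate_pedigrees(cfg)
  g <- generate_genotypes(ped, 40, cfg)
  alle <- attr(g, "alleles")
  panels <- list(
    make_panel(tibble::tibble(snp_id = colnames(g)[1:20],
                              risk_allele = alle$risk_allele[1:20],
                              disease_group = "alzheimers"), "alzheimers"),
    make_panel(tibble::tibble(snp_id = colnames(g)[21:40],
                              risk_allele = alle$risk_allele[21:40],
                              disease_group = "t2d"), "t2d")
  )
  grs <- purrr::map_dfr(panels, ~ compute_grs(g, .x))
  res <- run_analysis_suite(ped, grs, models = "poisson_glm")
  # 2 disease groups x 3 strata x (crude + adjusted)
  expect_equal(nrow(res), 12L)
  expect_setequal(unique(res$data_stratum), c("generation1", "generation2", "both"))
  expect_equal(res$rate_ratio, exp(res$beta))
  expect_true(all(res$covariates[res$data_stratum == "both" &
                                 res$covariates != ""] == "sex+generation"))
  # all four model families run through the same interface
  res4 <- run_analysis_suite(ped, dplyr::filter(grs, disease_group == "t2d"),
                             models = c("poisson_glm", "poisson_gee",
                                        "poisson_glmm", "lmm_kinship"),
                             strata = "both", adjusted = FALSE)
  expect_equal(sort(res4$model), sort(c("poisson_glm", "poisson_gee",
                                        "poisson_glmm", "lmm_kinship")))
})
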