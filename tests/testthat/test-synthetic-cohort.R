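test_that("default emulation config reproduces the two-generation cohort scale", {
  cfg <- cohort_config(seed = 101)
  ped <- generate_pedigrees(cfg)
  n_g1 <- sum(ped$generation == 1)
  n_g2 <- sum(ped$generation == 2)
  n_ctrl_g1 <- sum(ped$generation == 1 & ped$longevity_member == 0)
  # targets: 1562 G1 (about 175 controls) and 3102 G2
  expect_gt(n_g1, 1562 * 0.9); expect_lt(n_g1, 1562 * 1.1)
  expect_gt(n_g2, 3102 * 0.9); expect_lt(n_g2, 3102 * 1.1)
  expect_gt(n_ctrl_g1, 175 * 0.7); expect_lt(n_ctrl_g1, 175 * 1.3)
  sp_frac_g2 <- mean(ped$longevity_member[ped$generation == 2] == 0)
  expect_gt(sp_frac_g2, 0.34); expect_lt(sp_frac_g2, 0.46)
})

test_that("pedigree role invariants hold", {
  ped <- generate_pedigrees(cohort_config(n_families = 40, seed = 5))
  expect_true(all((ped$longevity_member == 1) ==
                  (ped$role %in% c("proband", "sibling", "offspring"))))
  probands <- dplyr::count(dplyr::filter(ped, role == "proband"), family_id)
  expect_true(all(probands$n == 1))
  expect_equal(dplyr::n_distinct(ped$family_id), 40L)
  spouses <- dplyr::filter(ped, role %in% c("spouse_g1", "spouse_g2"))
  expect_true(all(spouses$father_id == "0" & spouses$mother_id == "0"))
  # every offspring has a blood parent in the pedigree and a consistently
  # recorded second parent (enrolled spouse or shared latent id)
  offs <- dplyr::filter(ped, role == "offspring")
  in_ped <- offs$father_id %in% ped$individual_id |
    offs$mother_id %in% ped$individual_id
  expect_true(all(in_ped))
  expect_true(all(offs$father_id != "0" & offs$mother_id != "0"))
})

test_that("minimal family is a proband plus spouse", {
  cfg <- cohort_config(n_families = 1, g1_sibs_per_family = 0,
                       g2_offspring_per_family = 0, g1_spouse_rate = 1,
                       seed = 1)
  ped <- generate_pedigrees(cfg)
  expect_equal(nrow(ped), 2L)
  expect_setequal(as.character(ped$role), c("proband", "spouse_g1"))
})

test_that("fixed seed reproduces pedigree and genotypes byte-identically", {
  cfg <- cohort_config(n_families = 15, seed = 77)
  p1 <- generate_pedigrees(cfg)
  p2 <- generate_pedigrees(cfg)
  expect_identical(p1, p2)
  g1 <- generate_genotypes(p1, 30, cfg)
  g2 <- generate_genotypes(p2, 30, cfg)
  expect_identical(g1, g2)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(missing_rate = 1.2), class = "grsburden_config_error")
  expect_error(cohort_config(longevity_rate_ratio = 0), class = "grsburden_config_error")
  expect_error(cohort_config(g1_sibs_per_family = "two"), class = "grsburden_config_error")
  expect_error(count_dist("poisson", mean = -1), class = "grsburden_config_error")
})

test_that("Mendelian transmission is respected on a fixed trio", {
  trio <- tibble::tibble(
    family_id = "T", individual_id = c("dad", "mum", "kid"),
    father_id = c("0", "0", "dad"), mother_id = c("0", "0", "mum"),
    sex = c("M", "F", "M"), generation = c(1L, 1L, 2L),
    role = c("spouse_g1", "spouse_g1", "offspring"),
    longevity_member = c(0L, 0L, 1L)
  )
  cfg <- cohort_config(n_families = 1, missing_rate = 0, seed = 9)
  for (s in 1:5) {
    cfg$seed <- s
    g <- generate_genotypes(trio, 40, cfg)
    hom2 <- g["dad", ] == 2 & g["mum", ] == 2
    hom0 <- g["dad", ] == 0 & g["mum", ] == 0
    expect_true(all(g["kid", hom2] == 2))
    expect_true(all(g["kid", hom0] == 0))
    # child allele count never exceeds what the parents can transmit
    expect_true(all(g["kid", ] <= ceiling(g["dad", ] / 2) + ceiling(g["mum", ] / 2)))
  }
})

test_that("unlinked SNPs are empirically independent in founders", {
  cfg <- cohort_config(n_families = 100, g1_sibs_per_family = 0,
                       g2_offspring_per_family = 0, g1_spouse_rate = 1,
                       ld_block_sizes = 1, within_block_r2 = 0,
                       missing_rate = 0, seed = 31)
  ped <- generate_pedigrees(cfg)
  g <- generate_genotypes(ped, 400, cfg)
  r2 <- cor(unclass(g))^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.05)
})

test_that("within-block founder r2 hits the configured target", {
  cfg <- cohort_config(n_families = 2500, g1_sibs_per_family = 0,
                       g2_offspring_per_family = 0, g1_spouse_rate = 1,
                       ld_block_sizes = 3, within_block_r2 = 0.9,
                       missing_rate = 0, seed = 13)
  ped <- generate_pedigrees(cfg)   # 5000 founders
  g <- generate_genotypes(ped, 3, cfg)
  r2 <- cor(unclass(g))^2
  within <- r2[upper.tri(r2)]
  expect_true(all(within >= 0.8 & within <= 1.0))

  cfg$within_block_r2 <- 0.5
  g2 <- generate_genotypes(ped, 3, cfg)
  r2b <- cor(unclass(g2))^2
  expect_true(all(abs(r2b[upper.tri(r2b)] - 0.5) < 0.1))
})

test_that("missingness matches the configured rate", {
  cfg <- cohort_config(n_families = 50, missing_rate = 0.1, seed = 4)
  ped <- generate_pedigrees(cfg)
  g <- generate_genotypes(ped, 100, cfg)
  expect_equal(mean(is.na(g)), 0.1, tolerance = 0.1)
})

test_that("null longevity effect leaves genotypes untouched", {
  cfg <- cohort_config(n_families = 10, seed = 6)
  ped <- generate_pedigrees(cfg)
  g <- generate_genotypes(ped, 20, cfg)
  expect_identical(inject_longevity_effect(g, ped, rate_ratio = 1,
                                           family_intercept_sd = 0), g)
})

test_that("thinning reproduces the requested rate ratio in a founder population", {
  # brute force: unrelated individuals, half longevity members, rr = 0.90
  set.seed(2024)
  n <- 10000
  ind <- tibble::tibble(
    family_id = sprintf("s%05d", seq_len(n)),
    individual_id = sprintf("s%05d", seq_len(n)),
    longevity_member = rep(c(1L, 0L), n / 2)
  )
  p <- runif(50, 0.2, 0.8)
  G <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  dimnames(G) <- list(ind$individual_id, sprintf("rs%02d", 1:50))
  attr(G, "freq") <- setNames(p, colnames(G))
  out <- inject_longevity_effect(G, ind, rate_ratio = 0.90,
                                 family_intercept_sd = 0, seed = 8)
  ratio <- mean(rowSums(out[ind$longevity_member == 1, ])) /
    mean(rowSums(out[ind$longevity_member == 0, ]))
  mc_se <- 0.9 * sqrt(2) * sd(rowSums(G)) / mean(rowSums(G)) / sqrt(n / 2)
  expect_lt(abs(ratio - 0.90), 2 * mc_se + 0.005)
  # controls untouched under thinning
  expect_identical(out[ind$longevity_member == 0, ],
                   G[ind$longevity_member == 0, ])
})

test_that("boosting raises the rate ratio above one and errors when infeasible", {
  set.seed(11)
  n <- 6000
  ind <- tibble::tibble(
    family_id = sprintf("s%05d", seq_len(n)),
    individual_id = sprintf("s%05d", seq_len(n)),
    longevity_member = rep(c(1L, 0L), n / 2)
  )
  p <- rep(0.3, 40)
  G <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  dimnames(G) <- list(ind$individual_id, sprintf("rs%02d", 1:40))
  attr(G, "freq") <- setNames(p, colnames(G))
  out <- inject_longevity_effect(G, ind, rate_ratio = 1.5,
                                 family_intercept_sd = 0, seed = 3)
  ratio <- mean(rowSums(out[ind$longevity_member == 1, ])) /
    mean(rowSums(out[ind$longevity_member == 0, ]))
  expect_equal(ratio, 1.5, tolerance = 0.05)
  expect_error(
    inject_longevity_effect(G, ind, rate_ratio = 4, family_intercept_sd = 0),
    class = "grsburden_config_error"
  )
})

test_that("longevity effect at the study scale lands in the expected band", {
  cfg <- cohort_config(seed = 55, longevity_rate_ratio = 0.99,
                       family_intercept_sd = 0)
  ped <- generate_pedigrees(cfg)
  g <- generate_genotypes(ped, 431, cfg)
  g <- inject_longevity_effect(g, ped, 0.99, 0, seed = 55)
  counts <- rowSums(unclass(g), na.rm = TRUE)
  ratio <- mean(counts[ped$longevity_member == 1]) /
    mean(counts[ped$longevity_member == 0])
  expect_gt(ratio, 0.985)
  expect_lt(ratio, 0.995)
})

test_that("GRS counts are exchangeable between members and controls under the null", {
  rejections <- 0L
  for (s in 1:50) {
    cfg <- cohort_config(n_families = 40, seed = 1000 + s,
                         longevity_rate_ratio = 1, family_intercept_sd = 0,
                         missing_rate = 0)
    ped <- generate_pedigrees(cfg)
    g <- generate_genotypes(ped, 40, cfg)
    counts <- rowSums(unclass(g))
    p <- t.test(counts[ped$longevity_member == 1],
                counts[ped$longevity_member == 0])$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})
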