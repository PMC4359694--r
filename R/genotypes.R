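#' Simulate LD-blocked genotypes on a pedigree
#'
#' Founder haplotypes are drawn from a Gaussian-copula model: within each LD
#' block all SNPs share one allele frequency (drawn uniformly from
#' `allele_freq_range`) and a common latent correlation calibrated so the
#' squared Pearson correlation between founder dosages matches
#' `within_block_r2`; blocks are independent. Non-founders receive one whole
#' parental haplotype per block (blocks segregate as unlinked units, SNPs
#' within a block co-segregate), which induces both the within-block LD and
#' the kinship correlation the family models must absorb. Dosages count
#' copies of the risk allele (coded 1).
#'
#' @param pedigree Output of [generate_pedigrees()] (latent parents referenced
#'   there are simulated internally but not returned).
#' @param panel_size Number of SNPs.
#' @param config A [cohort_config()]; uses `allele_freq_range`,
#'   `ld_block_sizes` (recycled), `within_block_r2`, `missing_rate`, `seed`.
#' @param snp_ids Optional SNP ids (default `rs0000001 ...`).
#' @return An integer matrix (individuals x SNPs, dimnames set) with entries
#'   0/1/2 or `NA`, of class `genotype_matrix`, carrying attributes `freq`
#'   (founder risk-allele frequency per SNP), `block` (block index per SNP)
#'   and `alleles` (tibble `snp_id`, `ref`, `alt`, `risk_allele` for VCF
#'   export; the risk allele is randomly REF or ALT).
#' @examples
#' ped <- generate_pedigrees(cohort_config(n_families = 3, seed = 2))
#' g <- generate_genotypes(ped, panel_size = 8, cohort_config(n_families = 3, seed = 2))
#' dim(g)
#' @export
generate_genotypes <- function(pedigree, panel_size, config, snp_ids = NULL) {
  stopifnot(inherits(config, "cohort_config"), panel_size >= 1)
  set.seed(stage_seed(config$seed, "genotypes"))
  panel_size <- as.integer(panel_size)
  snp_ids <- snp_ids %||% sprintf("rs%07d", seq_len(panel_size))
  stopifnot(length(snp_ids) == panel_size)

  # Recycle the block-size pattern until the panel is covered.
  reps <- rep_len(config$ld_block_sizes, panel_size)
  block_of <- rep(seq_along(reps), reps)[seq_len(panel_size)]
  block_of <- match(block_of, unique(block_of))
  n_blocks <- max(block_of)
  block_freq <- runif(n_blocks, config$allele_freq_range[1], config$allele_freq_range[2])
  freq <- block_freq[block_of]

  ord <- pedigree_order(pedigree)
  n_all <- length(ord$ids)
  idx <- setNames(seq_len(n_all), ord$ids)

  # Haplotypes: two logical matrices (id x snp), TRUE = risk allele.
  h1 <- matrix(FALSE, n_all, panel_size)
  h2 <- matrix(FALSE, n_all, panel_size)

  founders <- which(ord$father == "0")   # spouses + latent sibship parents
  nf2 <- 2L * length(founders)
  for (b in seq_len(n_blocks)) {
    cols <- which(block_of == b)
    p <- block_freq[b]
    rho <- if (length(cols) == 1L || config$within_block_r2 == 0) 0 else
      copula_rho(sqrt(config$within_block_r2), p)
    q <- qnorm(p)
    w <- rnorm(nf2)
    z <- sqrt(rho) * matrix(w, nf2, length(cols)) +
      sqrt(1 - rho) * matrix(rnorm(nf2 * length(cols)), nf2, length(cols))
    alle <- z <= q
    h1[founders, cols] <- alle[seq_along(founders), , drop = FALSE]
    h2[founders, cols] <- alle[length(founders) + seq_along(founders), , drop = FALSE]
  }

  nonfounders <- which(ord$father != "0")
  for (i in nonfounders) {
    fi <- idx[[ord$father[i]]]
    mi <- idx[[ord$mother[i]]]
    pick_f <- runif(n_blocks) < 0.5   # one whole haplotype per block per gamete
    pick_m <- runif(n_blocks) < 0.5
    use_f <- pick_f[block_of]
    use_m <- pick_m[block_of]
    h1[i, ] <- ifelse(use_f, h1[fi, ], h2[fi, ])
    h2[i, ] <- ifelse(use_m, h1[mi, ], h2[mi, ])
  }

  dos <- h1 + h2
  keep <- match(pedigree$individual_id, ord$ids)
  dos <- dos[keep, , drop = FALSE]
  dimnames(dos) <- list(pedigree$individual_id, snp_ids)

  if (config$missing_rate > 0) {
    dos[runif(length(dos)) < config$missing_rate] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  risk_base <- sample(bases, panel_size, replace = TRUE)
  other <- vapply(risk_base, function(b) sample(setdiff(bases, b), 1L), character(1))
  risk_is_alt <- runif(panel_size) < 0.5
  alleles <- tibble(
    snp_id = snp_ids,
    ref = ifelse(risk_is_alt, other, risk_base),
    alt = ifelse(risk_is_alt, risk_base, other),
    risk_allele = risk_base
  )

  structure(dos,
            freq = setNames(freq, snp_ids),
            block = setNames(block_of, snp_ids),
            alleles = alleles,
            class = c("genotype_matrix", class(dos)))
}

# Latent equicorrelation giving Pearson correlation `target_r` between two
# Bernoulli(p) indicators thresholded from a standard bivariate normal.
copula_rho <- function(target_r, p) {
  if (target_r <= 0) return(0)
  if (target_r >= 1) return(1)
  q <- qnorm(p)
  r_of_rho <- function(rho) {
    # P(Z1<=q, Z2<=q) under equicorrelation rho, by conditioning on Z1
    p11 <- stats::integrate(function(z) {
      pnorm((q - rho * z) / sqrt(1 - rho^2)) * dnorm(z)
    }, -8, q)$value
    (p11 - p^2) / (p * (1 - p))
  }
  stats::uniroot(function(rho) r_of_rho(rho) - target_r,
                 lower = 1e-6, upper = 1 - 1e-6, tol = 1e-6)$root
}

#' Inject a multiplicative familial-longevity effect into genotypes
#'
#' Applies per-allele-slot binomial thinning (rate ratio below 1) or boosting
#' (above 1) to the dosages of longevity members, so that within a family the
#' expected risk-allele count of members is `rate_ratio * exp(b_f)` times that
#' of the untouched married-in controls, where `b_f ~ N(0, family_intercept_sd^2)`
#' is a shared per-family log-scale shift. Thinning keeps each carried risk
#' allele independently with probability `r_f`; boosting converts each empty
#' allele slot at SNP j with probability `(r_f - 1) p_j / (1 - p_j)`, which
#' multiplies the per-slot rate `p_j` by exactly `r_f` while keeping dosages
#' integer.
#'
#' @param genotypes A `genotype_matrix` (needs the `freq` attribute when
#'   boosting).
#' @param individuals Pedigree tibble aligned to the genotype rows (uses
#'   `family_id`, `longevity_member`).
#' @param rate_ratio Positive multiplicative effect on the per-slot rate
#'   (`exp(beta)`); 1 returns the input unchanged when `family_intercept_sd`
#'   is 0.
#' @param family_intercept_sd Log-scale SD of the per-family shift.
#' @param seed Integer seed.
#' @return The modified `genotype_matrix`.
#' @export
inject_longevity_effect <- function(genotypes, individuals, rate_ratio,
                                    family_intercept_sd = 0, seed = 1L) {
  stopifnot(rate_ratio > 0, family_intercept_sd >= 0)
  stopifnot(all(rownames(genotypes) == individuals$individual_id))
  if (rate_ratio == 1 && family_intercept_sd == 0) return(genotypes)
  set.seed(stage_seed(seed, "longevity_effect"))

  fams <- unique(individuals$family_id)
  b <- setNames(rnorm(length(fams), 0, family_intercept_sd), fams)
  r_f <- rate_ratio * exp(b[individuals$family_id])
  freq <- attr(genotypes, "freq")
  if (any(r_f > 1)) {
    if (is.null(freq)) {
      abort("Boosting (rate ratio above 1) needs the `freq` attribute on the genotypes.",
            class = "grsburden_config_error")
    }
    if (max(r_f) * max(freq) > 1) {
      abort("Longevity rate ratio pushes a per-slot allele rate above 1.",
            class = "grsburden_config_error")
    }
  }

  out <- unclass(genotypes)
  members <- which(individuals$longevity_member == 1L)
  m <- ncol(genotypes)
  for (i in members) {
    x <- out[i, ]
    ok <- !is.na(x)
    if (r_f[i] <= 1) {
      x[ok] <- rbinom(sum(ok), x[ok], r_f[i])
    } else {
      q <- (r_f[i] - 1) * freq / (1 - freq)
      x[ok] <- x[ok] + rbinom(sum(ok), 2L - x[ok], q[ok])
    }
    out[i, ] <- x
  }
  attributes(out) <- attributes(genotypes)
  out
}
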