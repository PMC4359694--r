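#' Specify a count distribution for family composition
#'
#' Family composition parameters (siblings per family, offspring per family)
#' are given as small distribution specs: either a Poisson with a given mean,
#' or a fixed count.
#'
#' @param dist `"poisson"` or `"fixed"`.
#' @param mean Mean of the Poisson (ignored for `"fixed"`).
#' @param size Fixed count (ignored for `"poisson"`).
#' @return A list of class `count_dist`.
#' @examples
#' count_dist("poisson", mean = 1.4)
#' count_dist("fixed", size = 2)
#' @export
count_dist <- function(dist = c("poisson", "fixed"), mean = NULL, size = NULL) {
  dist <- match.arg(dist)
  if (dist == "poisson") {
    if (is.null(mean) || !is.numeric(mean) || mean < 0) {
      abort("`mean` must be a nonnegative number for a poisson count_dist.",
            class = "grsburden_config_error")
    }
  } else {
    if (is.null(size) || !is.numeric(size) || size < 0 || size != round(size)) {
      abort("`size` must be a nonnegative integer for a fixed count_dist.",
            class = "grsburden_config_error")
    }
  }
  structure(list(dist = dist, mean = mean, size = size), class = "count_dist")
}

as_count_dist <- function(x, what = "distribution") {
  if (inherits(x, "count_dist")) return(x)
  if (is.numeric(x) && length(x) == 1L && x >= 0) {
    # Bare integers are exact counts; non-integers are Poisson means.
    if (x == round(x)) return(count_dist("fixed", size = x))
    return(count_dist("poisson", mean = x))
  }
  abort(paste0("Invalid ", what, " spec; use count_dist() or a nonnegative number."),
        class = "grsburden_config_error")
}

draw_counts <- function(spec, n) {
  if (spec$dist == "fixed") rep(as.integer(spec$size), n) else rpois(n, spec$mean)
}

expected_count <- function(spec) {
  if (spec$dist == "fixed") spec$size else spec$mean
}

#' Configuration for the synthetic two-generation family cohort
#'
#' Collects every knob of the synthetic cohort generator: family structure,
#' founder allele frequencies, LD block layout, the multiplicative familial
#' longevity effect on the per-allele-slot risk-allele rate, per-family
#' random-intercept spread, genotype missingness, and the seed.
#'
#' Defaults emulate a two-generation family longevity study: 583 families;
#' generation 1 of probands, full siblings and married-in spouses totalling
#' about 1562 individuals of whom about 175 are spousal controls; generation 2
#' of offspring plus their spouses totalling about 3102 individuals with a
#' 0.40 spouse fraction.
#'
#' @param n_families Number of families.
#' @param g1_sibs_per_family Siblings of the proband per family; a
#'   [count_dist()] or a number (integer = fixed, fractional = Poisson mean).
#' @param g1_spouse_rate Probability that each generation-1 blood member has an
#'   enrolled (married-in) spouse.
#' @param g2_offspring_per_family Offspring per family; a [count_dist()] or
#'   number.
#' @param spouse_fraction_g2 Target fraction of generation 2 made up of
#'   married-in spouses; each offspring is assigned an enrolled spouse with
#'   probability `spouse_fraction_g2 / (1 - spouse_fraction_g2)`.
#' @param allele_freq_range Range (low, high) for founder risk-allele
#'   frequencies, drawn uniformly per LD block.
#' @param ld_block_sizes Integer vector of LD block sizes, recycled across the
#'   panel.
#' @param within_block_r2 Target squared correlation between founder dosages of
#'   SNPs in the same block, in `[0, 1]`.
#' @param longevity_rate_ratio Multiplicative effect (`exp(beta)`) of familial
#'   longevity on the per-allele-slot risk-allele rate; 1 is the null.
#' @param family_intercept_sd Log-scale SD of the per-family random intercept
#'   applied with the longevity effect.
#' @param missing_rate Fraction of genotype calls set to missing.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_families = 10, seed = 1)
#' cfg$n_families
#' @export
cohort_config <- function(n_families = 583,
                          g1_sibs_per_family = count_dist("poisson", mean = 1.379),
                          g1_spouse_rate = 0.126,
                          g2_offspring_per_family = count_dist("poisson", mean = 3.192),
                          spouse_fraction_g2 = 0.40,
                          allele_freq_range = c(0.1, 0.9),
                          ld_block_sizes = c(1, 1, 2, 1, 3, 1, 1, 2, 1, 1),
                          within_block_r2 = 0.5,
                          longevity_rate_ratio = 1,
                          family_intercept_sd = 0.01,
                          missing_rate = 0.01,
                          seed = 1L) {
  if (!is.numeric(n_families) || n_families < 1) {
    abort("`n_families` must be a positive integer.", class = "grsburden_config_error")
  }
  if (spouse_fraction_g2 < 0 || spouse_fraction_g2 >= 0.5) {
    abort("`spouse_fraction_g2` must be in [0, 0.5) (each offspring has at most one spouse).",
          class = "grsburden_config_error")
  }
  if (length(allele_freq_range) != 2L || any(allele_freq_range <= 0) ||
      any(allele_freq_range >= 1) || diff(allele_freq_range) < 0) {
    abort("`allele_freq_range` must be an increasing pair inside (0, 1).",
          class = "grsburden_config_error")
  }
  if (within_block_r2 < 0 || within_block_r2 > 1) {
    abort("`within_block_r2` must be in [0, 1].", class = "grsburden_config_error")
  }
  if (longevity_rate_ratio <= 0) {
    abort("`longevity_rate_ratio` must be positive.", class = "grsburden_config_error")
  }
  if (family_intercept_sd < 0) {
    abort("`family_intercept_sd` must be nonnegative.", class = "grsburden_config_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).", class = "grsburden_config_error")
  }
  structure(
    list(
      n_families = as.integer(n_families),
      g1_sibs_per_family = as_count_dist(g1_sibs_per_family, "g1_sibs_per_family"),
      g1_spouse_rate = g1_spouse_rate,
      g2_offspring_per_family = as_count_dist(g2_offspring_per_family,
                                              "g2_offspring_per_family"),
      spouse_fraction_g2 = spouse_fraction_g2,
      allele_freq_range = allele_freq_range,
      ld_block_sizes = as.integer(ld_block_sizes),
      within_block_r2 = within_block_r2,
      longevity_rate_ratio = longevity_rate_ratio,
      family_intercept_sd = family_intercept_sd,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}
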