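# Independent oracles used across tests.  These deliberately use naive
# algorithms (exhaustive enumeration, per-element loops) so they share no
# code path with the package implementations they check.

# Exact kinship by exhaustive gene-drop enumeration: every non-founder has
# 4 equally likely transmission patterns (which paternal and which maternal
# allele was inherited); phi(a, b) is the average probability that a random
# allele from a equals a random allele from b over all patterns.  Exact for
# small pedigrees (cost 4^n_nonfounders).
oracle_kinship <- function(ped) {
  ids <- unique(c(ped$individual_id,
                  setdiff(c(ped$father_id, ped$mother_id), "0")))
  fa <- setNames(rep("0", length(ids)), ids)
  mo <- fa
  fa[ped$individual_id] <- ped$father_id
  mo[ped$individual_id] <- ped$mother_id
  ordered <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    ready <- remaining[(fa[remaining] == "0" | fa[remaining] %in% ordered) &
                       (mo[remaining] == "0" | mo[remaining] %in% ordered)]
    stopifnot(length(ready) > 0)
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  founders <- ordered[fa[ordered] == "0"]
  nonf <- ordered[fa[ordered] != "0"]
  k <- length(nonf)
  stopifnot(k <= 8)   # 4^k enumeration
  n_combo <- 4^k
  n <- length(ordered)
  Ksum <- matrix(0, n, n, dimnames = list(ordered, ordered))
  combo <- rep(1L, k)
  for (ci in seq_len(n_combo)) {
    al <- list()
    for (f in founders) al[[f]] <- paste0(f, c("a", "b"))
    if (k > 0) {
      digits <- ((ci - 1) %/% 4^(seq_len(k) - 1)) %% 4   # 0..3 per non-founder
      for (j in seq_len(k)) {
        id <- nonf[j]
        pf <- al[[fa[id]]][1 + digits[j] %% 2]
        pm <- al[[mo[id]]][1 + digits[j] %/% 2]
        al[[id]] <- c(pf, pm)
      }
    }
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        Ksum[a, b] <- Ksum[a, b] +
          mean(outer(al[[ordered[a]]], al[[ordered[b]]], "=="))
      }
    }
  }
  K <- Ksum / n_combo
  K[ped$individual_id, ped$individual_id, drop = FALSE]
}

# Per-row loop summation of risk-allele counts (never uses rowSums).
oracle_grs_counts <- function(G, snp_ids) {
  out <- integer(nrow(G))
  for (i in seq_len(nrow(G))) {
    s <- 0L
    for (j in snp_ids) {
      v <- G[i, j]
      if (!is.na(v)) s <- s + v
    }
    out[i] <- s
  }
  setNames(out, rownames(G))
}

# Closed-form two-group Poisson rate-model coefficient (no covariates).
oracle_two_group_beta <- function(count, offset, group) {
  r1 <- sum(count[group == 1]) / sum(exp(offset[group == 1]))
  r0 <- sum(count[group == 0]) / sum(exp(offset[group == 0]))
  log(r1 / r0)
}

# Clustered Poisson count data with a log-normal family intercept; the
# shape every model fitter expects.
make_model_data <- function(seed, n_fam = 50, fam_size = 4, beta = 0,
                            family_sd = 0, m = 93L, baseline_rate = 0.5,
                            between_family = FALSE) {
  set.seed(seed)
  n <- n_fam * fam_size
  fam <- rep(sprintf("f%04d", seq_len(n_fam)), each = fam_size)
  b <- rep(rnorm(n_fam, 0, family_sd), each = fam_size)
  # between_family: longevity status constant within a family, the layout
  # under which ignoring the family intercept inflates naive test statistics
  longevity <- if (between_family) {
    rep(rep(c(1, 0), length.out = n_fam), each = fam_size)
  } else {
    rep(c(1, 1, 1, 0), length.out = n)
  }
  d <- tibble::tibble(
    family_id = fam,
    individual_id = sprintf("i%05d", seq_len(n)),
    longevity_member = longevity,
    sex = sample(c("M", "F"), n, replace = TRUE),
    generation = rep(rep(1:2, length.out = fam_size), n_fam),
    n_nonmissing = m,
    offset = log(2 * m)
  )
  d$count <- rpois(n, exp(log(baseline_rate) + d$offset + b +
                          beta * d$longevity_member))
  d
}
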