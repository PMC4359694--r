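#' Simulate an engineered GWAS-catalog fixture with known panel arithmetic
#'
#' Builds a synthetic association catalog plus a reference genotype matrix
#' whose LD structure is engineered so that the panel pipeline produces
#' panels of exactly known sizes: within each disease group a chosen number
#' of SNPs is a perfect dosage copy of a partner SNP (r-squared 1), so LD
#' pruning at any threshold removes exactly one SNP per engineered pair and
#' the pruned panel size is deterministic even though which member drops is
#' seeded-random.
#'
#' Default group composition mirrors a four-disease age-related burden
#' analysis: Alzheimer's 103 catalog + 10 literature records with 20 LD
#' removals (panel 93), cardiovascular/stroke 329 with 90 removals (panel
#' 239), type 2 diabetes 210 with 55 removals (panel 155), cancers 489 with
#' 58 removals (panel 431), plus 12 unmapped ("other") records, for 1143
#' significant catalog records in total and 918 SNPs across the four default
#' panels.
#'
#' @param seed Integer seed.
#' @param n_individuals Reference individuals for the LD genotypes.
#' @param groups Data frame `disease_group`, `n_catalog`, `n_literature`,
#'   `n_ld_pairs` overriding the default composition.
#' @param n_insignificant Extra records above the significance threshold
#'   (exercise the p-value filter).
#' @return List: `catalog` (record tibble, catalog rows only), `literature`
#'   (literature record tibble), `genotypes` (dosage matrix over all SNPs),
#'   `groups` (the composition used, with the expected pruned panel size).
#' @export
simulate_catalog_fixture <- function(seed = 1L, n_individuals = 200,
                                     groups = NULL, n_insignificant = 25) {
  set.seed(stage_seed(seed, "catalog_fixture"))
  groups <- groups %||% tibble(
    disease_group = c("alzheimers", "cvd_stroke", "t2d", "cancer", "other"),
    n_catalog = c(103L, 329L, 210L, 489L, 12L),
    n_literature = c(10L, 0L, 0L, 0L, 0L),
    n_ld_pairs = c(20L, 90L, 55L, 58L, 0L)
  )
  groups$panel_size <- groups$n_catalog + groups$n_literature - groups$n_ld_pairs

  trait_of <- c(alzheimers = "Alzheimer's disease",
                cvd_stroke = "Coronary heart disease",
                t2d = "Type 2 diabetes",
                cancer = "Breast cancer",
                other = "Height")
  bases <- c("A", "C", "G", "T")

  n_total <- sum(groups$n_catalog) + sum(groups$n_literature)
  rs_ids <- sprintf("rs%07d", sample.int(9.9e6, n_total + n_insignificant))
  k <- 0L
  rows <- map_dfr(seq_len(nrow(groups)), function(gi) {
    g <- groups[gi, ]
    n <- g$n_catalog + g$n_literature
    ids <- rs_ids[k + seq_len(n)]
    k <<- k + n
    risk <- sample(bases, n, replace = TRUE)
    other_a <- vapply(risk, function(b) sample(setdiff(bases, b), 1L), character(1))
    tibble(
      snp_id = ids,
      trait = trait_of[[g$disease_group]],
      disease_group = g$disease_group,
      p_value = 10^runif(n, -30, log10(5e-8) - 0.01),
      risk_allele = risk,
      allele_list = map2(risk, other_a, c),
      source = rep(c("catalog", "literature"),
                   c(g$n_catalog, g$n_literature))
    )
  })
  insig <- tibble(
    snp_id = rs_ids[n_total + seq_len(n_insignificant)],
    trait = "Type 2 diabetes",
    disease_group = "t2d",
    p_value = 10^runif(n_insignificant, -7, -5),
    risk_allele = sample(bases, n_insignificant, replace = TRUE),
    allele_list = map(seq_len(n_insignificant), ~ sample(bases, 2)),
    source = "catalog"
  )
  catalog <- bind_rows(rows[rows$source == "catalog", ], insig)
  literature <- rows[rows$source == "literature", ]

  # Independent reference genotypes, then copy dosages to engineer the LD
  # pairs (partner and copy both inside the same disease group, pairs
  # disjoint so pruning always removes exactly one per pair).
  all_ids <- c(rows$snp_id, insig$snp_id)
  p <- runif(length(all_ids), 0.1, 0.9)
  G <- vapply(p, function(pp) rbinom(n_individuals, 2L, pp),
              integer(n_individuals))
  dimnames(G) <- list(sprintf("ref%04d", seq_len(n_individuals)), all_ids)
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    if (g$n_ld_pairs == 0) next
    ids <- rows$snp_id[rows$disease_group == g$disease_group]
    pick <- sample(ids, 2L * g$n_ld_pairs)
    keepers <- pick[seq_len(g$n_ld_pairs)]
    copies <- pick[g$n_ld_pairs + seq_len(g$n_ld_pairs)]
    G[, copies] <- G[, keepers]
  }

  list(catalog = catalog, literature = literature, genotypes = G,
       groups = groups)
}

#' Write catalog records as a GWAS-catalog-dialect TSV
#'
#' Columns `SNPS`, `DISEASE/TRAIT`, `P-VALUE`, `STRONGEST SNP-RISK ALLELE`
#' (`rsID-A`, `rsID-?` when no risk allele) and `ALLELES`.
#'
#' @param records Record tibble (as from [simulate_catalog_fixture()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(records, path) {
  out <- tibble(
    SNPS = records$snp_id,
    `DISEASE/TRAIT` = records$trait,
    `P-VALUE` = formatC(records$p_value, format = "e", digits = 2),
    `STRONGEST SNP-RISK ALLELE` = paste0(
      records$snp_id, "-",
      ifelse(is.na(records$risk_allele), "?", records$risk_allele)),
    ALLELES = map_chr(records$allele_list, paste, collapse = "/")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Build the four default disease panels from a catalog fixture
#'
#' Convenience wrapper running the full panel pipeline — significance /
#' risk-allele / biallelic filtering, literature merge, LD pruning — for each
#' disease group of a [simulate_catalog_fixture()] result.
#'
#' @param fixture List from [simulate_catalog_fixture()].
#' @param p_threshold Significance threshold.
#' @param r2_threshold LD pruning threshold.
#' @param seed Seed for the pruning drop choices.
#' @return Named list of pruned `snp_panel`s (the `other` group is not
#'   panelled).
#' @export
build_default_panels <- function(fixture, p_threshold = 5e-8,
                                 r2_threshold = 0.8, seed = 1L) {
  filt <- filter_records(bind_rows(fixture$catalog), p_threshold = p_threshold)
  merged <- merge_supplemental(filt$records, fixture$literature)
  groups <- setdiff(unique(merged$disease_group), "other")
  panels <- map(groups, function(g) {
    ld_prune(make_panel(merged, g), fixture$genotypes,
             r2_threshold = r2_threshold, seed = seed)
  })
  setNames(panels, groups)
}
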