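#' Generate synthetic two-generation family pedigrees
#'
#' Builds the family structure the disease-burden analysis assumes: per
#' family, one proband, a random number of full siblings, married-in
#' generation-1 spouses, generation-2 offspring of generation-1 couples, and
#' married-in generation-2 spouses. Probands, siblings and offspring are
#' "longevity members"; married-in spouses are the controls.
#'
#' Proband and siblings share a pair of *latent* (unenrolled) parents whose
#' ids appear in the `father_id`/`mother_id` columns but have no row of their
#' own; likewise an offspring whose enrolled parent has no enrolled spouse
#' gets a latent second parent. These latent ids are what make full siblings
#' recognisable as such by [kinship_matrix()] and by the Mendelian genotype
#' simulator. True founders with no recorded parent (all spouses) carry
#' `"0"`, following PLINK `.fam` conventions.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per enrolled individual and columns
#'   `family_id`, `individual_id`, `father_id`, `mother_id`, `sex` (`"M"` /
#'   `"F"`), `generation` (1 or 2), `role` (`proband`, `sibling`, `spouse_g1`,
#'   `offspring`, `spouse_g2`) and `longevity_member` (1 for proband and blood
#'   relatives, 0 for married-in controls).
#' @examples
#' ped <- generate_pedigrees(cohort_config(n_families = 5, seed = 7))
#' dplyr::count(ped, generation, longevity_member)
#' @export
generate_pedigrees <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(stage_seed(config$seed, "pedigree"))
  nf <- config$n_families
  fam_ids <- sprintf("F%04d", seq_len(nf))

  n_sibs <- draw_counts(config$g1_sibs_per_family, nf)
  n_offs <- draw_counts(config$g2_offspring_per_family, nf)
  p_spouse_g2 <- config$spouse_fraction_g2 / (1 - config$spouse_fraction_g2)

  one_family <- function(f) {
    fam <- fam_ids[f]
    lat_f <- paste0(fam, "_LF")   # latent founder father of the sibship
    lat_m <- paste0(fam, "_LM")
    blood_ids <- c(paste0(fam, "_P"),
                   if (n_sibs[f] > 0) paste0(fam, "_S", seq_len(n_sibs[f])))
    blood_sex <- sample(c("M", "F"), length(blood_ids), replace = TRUE)
    g1 <- tibble(
      family_id = fam, individual_id = blood_ids,
      father_id = lat_f, mother_id = lat_m,
      sex = blood_sex, generation = 1L,
      role = c("proband", rep("sibling", length(blood_ids) - 1L)),
      longevity_member = 1L
    )

    has_spouse <- runif(length(blood_ids)) < config$g1_spouse_rate
    sp <- tibble(
      family_id = character(0), individual_id = character(0),
      father_id = character(0), mother_id = character(0),
      sex = character(0), generation = integer(0), role = character(0),
      longevity_member = integer(0)
    )
    if (any(has_spouse)) {
      sp <- tibble(
        family_id = fam,
        individual_id = paste0(blood_ids[has_spouse], "SP"),
        father_id = "0", mother_id = "0",
        sex = ifelse(blood_sex[has_spouse] == "M", "F", "M"),
        generation = 1L, role = "spouse_g1", longevity_member = 0L
      )
    }

    # Offspring are assigned to a uniformly chosen G1 blood member; the second
    # parent is that member's spouse, enrolled if present, latent otherwise.
    offs <- tibble()
    g2sp <- tibble()
    if (n_offs[f] > 0) {
      parent_idx <- sample.int(length(blood_ids), n_offs[f], replace = TRUE)
      other_parent <- ifelse(has_spouse[parent_idx],
                             paste0(blood_ids[parent_idx], "SP"),
                             paste0(blood_ids[parent_idx], "LS"))
      p1_sex <- blood_sex[parent_idx]
      off_ids <- paste0(fam, "_O", seq_len(n_offs[f]))
      off_sex <- sample(c("M", "F"), n_offs[f], replace = TRUE)
      offs <- tibble(
        family_id = fam, individual_id = off_ids,
        father_id = ifelse(p1_sex == "M", blood_ids[parent_idx], other_parent),
        mother_id = ifelse(p1_sex == "M", other_parent, blood_ids[parent_idx]),
        sex = off_sex, generation = 2L, role = "offspring",
        longevity_member = 1L
      )
      married <- runif(n_offs[f]) < p_spouse_g2
      if (any(married)) {
        g2sp <- tibble(
          family_id = fam,
          individual_id = paste0(off_ids[married], "SP"),
          father_id = "0", mother_id = "0",
          sex = ifelse(off_sex[married] == "M", "F", "M"),
          generation = 2L, role = "spouse_g2", longevity_member = 0L
        )
      }
    }
    bind_rows(g1, sp, offs, g2sp)
  }

  ped <- map_dfr(seq_len(nf), one_family)
  ped$role <- factor(ped$role,
                     levels = c("proband", "sibling", "spouse_g1", "offspring", "spouse_g2"))
  ped
}

# All ids that play a parental role but have no row: latent founders whose
# genotypes must still be simulated and whose kinship contributions counted.
latent_parent_ids <- function(pedigree) {
  refs <- union(pedigree$father_id, pedigree$mother_id)
  setdiff(refs, c(pedigree$individual_id, "0"))
}

# Topological order over enrolled + latent ids, parents first.
pedigree_order <- function(pedigree) {
  ids <- c(latent_parent_ids(pedigree), pedigree$individual_id)
  father <- setNames(rep("0", length(ids)), ids)
  mother <- father
  father[pedigree$individual_id] <- pedigree$father_id
  mother[pedigree$individual_id] <- pedigree$mother_id
  ordered <- character(0)
  placed <- setNames(rep(FALSE, length(ids)), ids)
  remaining <- ids
  while (length(remaining) > 0) {
    ready <- remaining[
      (father[remaining] == "0" | placed[father[remaining]]) &
      (mother[remaining] == "0" | placed[mother[remaining]])
    ]
    if (length(ready) == 0) {
      abort("Pedigree contains a cycle.", class = "grsburden_pedigree_error")
    }
    ordered <- c(ordered, ready)
    placed[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  list(ids = ordered, father = father[ordered], mother = mother[ordered])
}
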