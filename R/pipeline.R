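# Orchestration: one config, one seed, all stages, plain-text outputs and a
# JSON manifest.  Each stage derives its own seed from the root seed so
# results are idempotent for a fixed configuration.

#' Default end-to-end run configuration
#'
#' A nested list (serialisable to/from YAML) driving [run_pipeline()]:
#' cohort settings, panel thresholds, model list, sensitivity scenarios and
#' the power grid. The default is a small demonstration cohort; set
#' `cohort = cohort_config()` defaults for the full-size emulation.
#'
#' @param seed Root seed; every stage seed derives from it.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = seed,
    cohort = list(n_families = 60),
    panels = list(p_threshold = 5e-8, r2_threshold = 0.8),
    models = list("poisson_glmm"),
    strata = list("generation1", "generation2", "both"),
    sensitivity = list(remove_snps = list(n_remove = 3)),
    power = list(panel_sizes = list(93, 431), effects = list(1, 10),
                 strata = list("both"), n_reps = 20,
                 baseline_rate = 0.5, family_intercept_sd = 0.01)
  )
}

#' Run the whole disease-burden pipeline from one configuration
#'
#' Stages: simulate the cohort (pedigree, genotypes, longevity effect),
#' build LD-pruned disease panels from an engineered catalog fixture, score
#' every individual, fit the association models across strata, run the
#' SNP-removal sensitivity scenario, estimate power, and write every result
#' as TSV plus a JSON manifest (stage seeds, file row counts, package
#' version). Rerunning with the same config reproduces the files
#' byte-identically.
#'
#' @param config Nested list as from [default_run_config()], or a path to a
#'   YAML file with the same structure.
#' @param output_dir Directory for outputs (created if needed).
#' @return The manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_run_config(), output_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_run_config(), config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  files <- character(0)
  add_file <- function(path) files <<- c(files, path)

  stage <- "simulate"
  res <- tryCatch({
    ccfg <- do.call(cohort_config, c(cfg$cohort, list(seed = seed)))
    ped <- generate_pedigrees(ccfg)

    stage <- "build-panels"
    fixture <- simulate_catalog_fixture(seed = seed)
    panels <- build_default_panels(fixture,
                                   p_threshold = cfg$panels$p_threshold,
                                   r2_threshold = cfg$panels$r2_threshold,
                                   seed = seed)
    total_snps <- sum(map_int(panels, ~ nrow(.x$snps)))
    panel_tbl <- map_dfr(panels, function(p) {
      mutate(p$snps, disease_group = p$disease_group)
    })
    add_file(write_tsv_file(panel_tbl, file.path(output_dir, "panels.tsv")))
    add_file(write_tsv_file(
      map_dfr(panels, function(p) mutate(p$provenance_log, disease_group = p$disease_group)),
      file.path(output_dir, "panel_provenance.tsv")))

    stage <- "score"
    all_snps <- panel_tbl$snp_id
    gt <- generate_genotypes(ped, length(all_snps), ccfg, snp_ids = all_snps)
    gt <- inject_longevity_effect(gt, ped, ccfg$longevity_rate_ratio,
                                  ccfg$family_intercept_sd, seed = seed)
    add_file(write_pedigree_tsv(ped, file.path(output_dir, "pedigree.tsv")))
    add_file(write_dosage_tsv(gt, file.path(output_dir, "dosages.tsv")))
    grs <- map_dfr(panels, ~ compute_grs(gt, .x))
    add_file(write_tsv_file(grs, file.path(output_dir, "grs.tsv")))

    stage <- "fit"
    results <- run_analysis_suite(ped, grs,
                                  models = unlist(cfg$models),
                                  strata = unlist(cfg$strata))
    add_file(write_tsv_file(results, file.path(output_dir, "association_results.tsv")))

    stage <- "sensitivity"
    ad <- panels[["alzheimers"]]
    drop_ids <- head(ad$snps$snp_id, cfg$sensitivity$remove_snps$n_remove)
    sens <- remove_snps_and_refit(ad, gt, ped, drop_ids,
                                  models = unlist(cfg$models),
                                  strata = unlist(cfg$strata))
    add_file(write_tsv_file(sens, file.path(output_dir, "sensitivity_results.tsv")))

    stage <- "power"
    pw <- estimate_power(ped,
                         panel_sizes = unlist(cfg$power$panel_sizes),
                         effects = unlist(cfg$power$effects),
                         strata = unlist(cfg$power$strata),
                         baseline_rate = cfg$power$baseline_rate,
                         family_intercept_sd = cfg$power$family_intercept_sd,
                         n_reps = cfg$power$n_reps,
                         seed = stage_seed(seed, "power_stage"))
    add_file(write_tsv_file(pw, file.path(output_dir, "power_results.tsv")))
    list(total_snps = total_snps)
  }, error = function(e) {
    abort(paste0("Pipeline failed at stage '", stage, "': ", conditionMessage(e)),
          class = "grsburden_pipeline_error", parent = e)
  })

  manifest <- list(
    package = "grsburden",
    version = as.character(utils::packageVersion("grsburden")),
    seed = seed,
    total_panel_snps = res$total_snps,
    files = map(setNames(files, basename(files)), function(f) {
      list(path = basename(f), rows = length(readLines(f)) - 1L)
    })
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  inform(paste0("Pipeline outputs written to ", output_dir, " (",
                length(files) + 1L, " files)."))
  invisible(manifest)
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Write a pedigree as an extended .fam-style TSV
#'
#' Tab-separated columns `family_id`, `individual_id`, `father_id`,
#' `mother_id`, `sex`, `generation`, `role`, `longevity_member`; missing
#' parents are `"0"` as in PLINK `.fam` files.
#'
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  readr::write_tsv(mutate(pedigree, role = as.character(.data$role)), path,
                   progress = FALSE)
  invisible(path)
}

#' Read a pedigree TSV written by [write_pedigree_tsv()]
#' @param path File path.
#' @return Pedigree tibble.
#' @export
read_pedigree_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    family_id = "c", individual_id = "c", father_id = "c", mother_id = "c",
    sex = "c", generation = "i", role = "c", longevity_member = "i"
  ), progress = FALSE)
}

#' Write a dosage matrix as TSV (individuals in rows)
#' @param genotypes Dosage matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- as.data.frame(unclass(genotypes), check.names = FALSE)
  df <- cbind(individual_id = rownames(genotypes), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#' @param path File path.
#' @return Dosage matrix with individual ids as rownames.
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = "c", .default = "i"), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$individual_id
  m
}
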