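#' Default trait-keyword to disease-group mapping
#'
#' Maps free-text trait descriptions to the four age-related disease groups
#' used for the GRS panels. The mapping is a plain tibble of lower-case
#' keywords — edit or replace it to suit a different catalog vintage.
#'
#' @return Tibble with columns `keyword`, `disease_group`.
#' @export
default_trait_map <- function() {
  tribble_map <- list(
    alzheimers = c("alzheimer"),
    cvd_stroke = c("coronary", "cardiovascular", "myocardial", "stroke",
                   "heart disease", "atrial fibrillation"),
    t2d        = c("type 2 diabetes", "type ii diabetes"),
    cancer     = c("cancer", "carcinoma", "melanoma", "leukemia", "lymphoma",
                   "glioma", "myeloma", "neuroblastoma")
  )
  map_dfr(names(tribble_map), function(g) {
    tibble(keyword = tribble_map[[g]], disease_group = g)
  })
}

assign_disease_group <- function(trait, trait_map = default_trait_map()) {
  lt <- tolower(trait)
  out <- rep("other", length(trait))
  # later keywords never override an earlier hit
  for (i in rev(seq_len(nrow(trait_map)))) {
    out[grepl(trait_map$keyword[i], lt, fixed = TRUE)] <- trait_map$disease_group[i]
  }
  out
}

#' Parse a GWAS-catalog-format association table
#'
#' Reads the 2014 GWAS Catalog TSV dialect: columns `SNPS`, `DISEASE/TRAIT`,
#' `P-VALUE`, `STRONGEST SNP-RISK ALLELE` (risk allele encoded as
#' `rsID-A`; `rsID-?` means unknown), and optionally `ALLELES` (comma- or
#' slash-separated list used to flag multiallelic SNPs).
#'
#' @param path Path to the tab-separated file (header required).
#' @param trait_map Keyword table from [default_trait_map()] (or your own).
#' @return Tibble of catalog records: `snp_id`, `trait`, `disease_group`,
#'   `p_value`, `risk_allele` (`NA` when unparseable), `allele_list`
#'   (list-column), `source = "catalog"`.
#' @export
parse_catalog <- function(path, trait_map = default_trait_map()) {
  if (!file.exists(path)) {
    abort(paste0("Catalog file not found: ", path), class = "grsburden_format_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("SNPS", "DISEASE/TRAIT", "P-VALUE", "STRONGEST SNP-RISK ALLELE")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Catalog is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "grsburden_format_error")
  }
  risk_raw <- raw[["STRONGEST SNP-RISK ALLELE"]]
  risk <- stringr::str_match(risk_raw, "-([ACGT])$")[, 2]
  alleles <- if ("ALLELES" %in% names(raw)) {
    stringr::str_split(raw[["ALLELES"]], "[,/]")
  } else {
    map(risk, function(r) if (is.na(r)) character(0) else r)
  }
  tibble(
    snp_id = stringr::str_extract(raw[["SNPS"]], "rs\\d+"),
    trait = raw[["DISEASE/TRAIT"]],
    disease_group = assign_disease_group(raw[["DISEASE/TRAIT"]], trait_map),
    p_value = as.numeric(raw[["P-VALUE"]]),
    risk_allele = risk,
    allele_list = map(alleles, function(a) a[nzchar(a)]),
    source = "catalog"
  )
}

#' Filter catalog records to genome-wide significant, risk-allele-bearing,
#' biallelic SNPs
#'
#' Keeps records with `p_value < p_threshold` (strict), a parsed risk allele,
#' and at most two common alleles (unless `allow_multiallelic`); then
#' collapses duplicate rsIDs within a disease group to the smallest p-value.
#' Every removal is logged with its reason, so kept + removed = input.
#'
#' @param records Tibble from [parse_catalog()] (or the same shape).
#' @param p_threshold Genome-wide significance threshold (default `5e-8`).
#' @param allow_multiallelic Keep SNPs with more than two listed alleles?
#' @return List with `records` (kept tibble) and `log` (tibble `snp_id`,
#'   `action`, `reason`).
#' @export
filter_records <- function(records, p_threshold = 5e-8, allow_multiallelic = FALSE) {
  stopifnot(p_threshold > 0)
  n_alleles <- map_int(records$allele_list, length)
  reason <- rep(NA_character_, nrow(records))
  reason[records$p_value >= p_threshold] <- "not_genome_wide_significant"
  reason[is.na(reason) & is.na(records$risk_allele)] <- "no_risk_allele"
  if (!allow_multiallelic) {
    reason[is.na(reason) & n_alleles > 2] <- "multiallelic"
  }
  kept <- records[is.na(reason), , drop = FALSE]

  # duplicate rsIDs within a disease group: keep the smallest p-value
  kept <- kept |>
    mutate(.ord = row_number()) |>
    group_by(.data$disease_group, .data$snp_id) |>
    mutate(.dup = rank(.data$p_value, ties.method = "first") > 1L) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")
  dup_log <- kept |>
    filter(.data$.dup) |>
    transmute(.data$snp_id, action = "removed", reason = "duplicate_rsid")
  kept <- kept |> filter(!.data$.dup) |> select(-".dup")

  log <- bind_rows(
    tibble(snp_id = records$snp_id[!is.na(reason)], action = "removed",
           reason = reason[!is.na(reason)]),
    dup_log,
    tibble(snp_id = kept$snp_id, action = "kept", reason = "passed_filters")
  )
  list(records = kept, log = log)
}

#' Merge supplemental literature SNPs into the catalog records
#'
#' Unions literature-review records (`source = "literature"`) with filtered
#' catalog records. Duplicated rsIDs within a disease group resolve in favour
#' of the catalog entry; a duplicate with a conflicting risk allele is an
#' error.
#'
#' @param records Catalog records (kept tibble from [filter_records()]).
#' @param literature_records Tibble of the same shape with
#'   `source = "literature"`.
#' @return Combined tibble;
#'   `nrow = nrow(records) + number of literature records not already present`.
#' @export
merge_supplemental <- function(records, literature_records) {
  if (nrow(literature_records) == 0) return(records)
  stopifnot(all(literature_records$source == "literature"))
  key <- paste(records$disease_group, records$snp_id)
  lkey <- paste(literature_records$disease_group, literature_records$snp_id)
  dup <- lkey %in% key
  if (any(dup)) {
    cat_ra <- setNames(records$risk_allele, key)
    conflict <- literature_records$risk_allele[dup] != cat_ra[lkey[dup]]
    if (any(conflict)) {
      abort(paste0("Conflicting risk alleles between catalog and literature for: ",
                   paste(literature_records$snp_id[dup][conflict], collapse = ", ")),
            class = "grsburden_merge_error")
    }
  }
  bind_rows(records, literature_records[!dup, , drop = FALSE])
}

#' Assemble records into a disease-specific SNP panel
#'
#' @param records Merged record tibble for one disease group.
#' @param disease_group Group label; records from other groups are dropped.
#' @return A `snp_panel`: list with `disease_group`, `snps` (tibble `snp_id`,
#'   `risk_allele`) and `provenance_log`.
#' @export
make_panel <- function(records, disease_group) {
  recs <- records[records$disease_group == disease_group, , drop = FALSE]
  if (anyDuplicated(recs$snp_id)) {
    abort("Duplicate rsIDs in panel input; run filter_records()/merge_supplemental() first.",
          class = "grsburden_panel_error")
  }
  structure(
    list(
      disease_group = disease_group,
      snps = tibble(snp_id = recs$snp_id, risk_allele = recs$risk_allele),
      provenance_log = tibble(snp_id = recs$snp_id, action = "kept",
                              reason = "panel_input")
    ),
    class = "snp_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", x$disease_group, ": ", nrow(x$snps), " SNPs\n", sep = "")
  invisible(x)
}
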