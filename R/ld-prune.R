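#' Prune a SNP panel for linkage disequilibrium
#'
#' Computes pairwise r-squared as the squared Pearson correlation of dosage
#' vectors over individuals with calls at both SNPs, then iteratively removes
#' SNPs until no pair exceeds `r2_threshold`: at each step the violating pair
#' that is first in rsID order is taken and one member is dropped by a seeded
#' fair coin. Iterating to closure (rather than a single pass over pairs)
#' guarantees the postcondition even for chained LD (A-B and B-C both above
#' threshold). Zero-variance SNPs correlate with nothing (r2 treated as 0,
#' with a warning).
#'
#' @param panel A `snp_panel` from [make_panel()].
#' @param genotypes Dosage matrix (individuals x SNPs) covering every panel
#'   SNP.
#' @param r2_threshold Squared-correlation threshold in (0, 1]; pairs strictly
#'   above it are in LD.
#' @param seed Integer seed for the drop choice; fixed seed gives an
#'   identical pruned panel.
#' @return The pruned `snp_panel`; each removal is appended to
#'   `provenance_log` with the partner SNP in the reason.
#' @export
ld_prune <- function(panel, genotypes, r2_threshold = 0.8, seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"), r2_threshold > 0, r2_threshold <= 1)
  absent <- setdiff(panel$snps$snp_id, colnames(genotypes))
  if (length(absent) > 0) {
    abort(paste0("Panel SNP(s) absent from genotypes: ",
                 paste(absent, collapse = ", ")),
          class = "grsburden_panel_error")
  }
  ids <- sort(panel$snps$snp_id)
  G <- unclass(genotypes)[, ids, drop = FALSE]
  storage.mode(G) <- "double"
  vv <- apply(G, 2, function(x) var(x, na.rm = TRUE))
  if (any(is.na(vv) | vv == 0)) {
    warn(paste0("Zero-variance SNP(s) treated as r2 = 0: ",
                paste(ids[is.na(vv) | vv == 0], collapse = ", ")))
  }
  r2 <- suppressWarnings(cor(G, use = "pairwise.complete.obs"))^2
  r2[!is.finite(r2)] <- 0
  diag(r2) <- 0

  set.seed(stage_seed(seed, "ld_prune"))
  removed <- tibble(snp_id = character(0), action = character(0),
                    reason = character(0))
  alive <- rep(TRUE, length(ids))
  names(alive) <- ids
  repeat {
    sub <- r2[alive, alive, drop = FALSE]
    viol <- which(sub > r2_threshold, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (nrow(viol) == 0) break
    nms <- rownames(sub)
    pair_key <- paste(nms[viol[, 1]], nms[viol[, 2]])
    first <- viol[order(pair_key)[1], ]
    pair <- c(nms[first[1]], nms[first[2]])
    drop_id <- pair[sample.int(2L, 1L)]
    keep_id <- setdiff(pair, drop_id)
    alive[drop_id] <- FALSE
    removed <- bind_rows(removed, tibble(
      snp_id = drop_id, action = "removed",
      reason = paste0("ld_r2_above_", r2_threshold, "_with_", keep_id)
    ))
  }
  kept_ids <- names(alive)[alive]
  out <- panel
  out$snps <- panel$snps[panel$snps$snp_id %in% kept_ids, , drop = FALSE]
  out$provenance_log <- bind_rows(panel$provenance_log, removed)
  out
}

#' Restrict a panel to a published GRS SNP list
#'
#' Re-creates the "published GRS" secondary analyses: intersects the panel
#' with a published SNP list after applying per-SNP exclusion flags (no
#' catalog risk allele, ambiguous coding, multiple risk alleles, poor
#' imputation quality).
#'
#' @param panel A `snp_panel`.
#' @param published_list Tibble with `snp_id` and `exclusion` (`NA`/`"none"` =
#'   usable; any other value names the reason the SNP cannot enter the score).
#' @return The restricted `snp_panel`; the provenance log records every
#'   published SNP's disposition (kept, excluded with its flag, or absent
#'   from the panel).
#' @export
published_grs_subset <- function(panel, published_list) {
  stopifnot(inherits(panel, "snp_panel"))
  if (nrow(published_list) == 0) {
    out <- panel
    out$snps <- panel$snps[0, , drop = FALSE]
    out$provenance_log <- bind_rows(
      panel$provenance_log,
      tibble(snp_id = panel$snps$snp_id, action = "removed",
             reason = "not_in_published_grs")
    )
    return(out)
  }
  excl <- published_list[["exclusion"]] %||% rep(NA_character_, nrow(published_list))
  usable <- is.na(excl) | excl == "none"
  in_panel <- published_list$snp_id %in% panel$snps$snp_id
  keep_ids <- published_list$snp_id[usable & in_panel]

  disposition <- tibble(
    snp_id = published_list$snp_id,
    action = ifelse(usable & in_panel, "kept", "removed"),
    reason = dplyr::case_when(
      !usable ~ paste0("published_exclusion_", excl),
      !in_panel ~ "absent_from_panel",
      TRUE ~ "published_grs_member"
    )
  )
  out <- panel
  out$snps <- panel$snps[panel$snps$snp_id %in% keep_ids, , drop = FALSE]
  out$provenance_log <- bind_rows(
    panel$provenance_log, disposition,
    tibble(snp_id = setdiff(panel$snps$snp_id, published_list$snp_id),
           action = "removed", reason = "not_in_published_grs")
  )
  out
}
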