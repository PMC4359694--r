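#' Kinship coefficient matrix from a pedigree
#'
#' Computes the kinship coefficient phi(i, j) — the probability that one
#' allele sampled from i and one from j at a locus are identical by descent —
#' by the standard recursion over a parents-first ordering:
#' phi(i, i) = 1/2 (1 + phi(father_i, mother_i)) and
#' phi(i, j) = 1/2 (phi(father_i, j) + phi(mother_i, j)) for j preceding i.
#' Latent parents referenced by id (see [generate_pedigrees()]) enter the
#' recursion, so full siblings get phi = 1/4 even though their parents are
#' unenrolled; the returned matrix covers only the enrolled individuals.
#'
#' @param pedigree Tibble with `individual_id`, `father_id`, `mother_id`
#'   (`"0"` = no parent; ids without a row of their own are treated as
#'   unrelated founders).
#' @return A symmetric positive semidefinite matrix with dimnames
#'   `individual_id`; founder diagonal is 0.5.
#' @examples
#' ped <- tibble::tibble(
#'   individual_id = c("f", "m", "c"),
#'   father_id = c("0", "0", "f"),
#'   mother_id = c("0", "0", "m")
#' )
#' kinship_matrix(ped)["f", "c"]   # parent-child: 0.25
#' @export
kinship_matrix <- function(pedigree) {
  ord <- pedigree_order(pedigree)
  n <- length(ord$ids)
  K <- matrix(0, n, n, dimnames = list(ord$ids, ord$ids))
  fa <- match(ord$father, ord$ids)   # NA for founders
  mo <- match(ord$mother, ord$ids)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        v <- 0.5 * (K[fa[i], prev] + K[mo[i], prev])
        K[i, prev] <- v
        K[prev, i] <- v
      }
    }
  }
  keep <- match(pedigree$individual_id, ord$ids)
  K[keep, keep, drop = FALSE]
}
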