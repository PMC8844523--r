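#' Expected kinship matrix from pedigree structure
#'
#' Computes the expected kinship coefficient phi for every pair of pedigree
#' members by the classical founder recursion: for a founder f,
#' `phi(f, f) = 1/2` and `phi(f, g) = 0` for any other founder g; for a
#' non-founder i with parents p and q, `phi(i, i) = 1/2 + phi(p, q)/2` and,
#' for any individual j processed before i, `phi(i, j) = (phi(p, j) +
#' phi(q, j)) / 2`. Because members are processed parents-first, "processed
#' before" covers every non-descendant of i, which is all the recursion
#' requires. Inbred (looped) pedigrees are handled by the same recursion with
#' no special casing; inbreeding shows up as a self-kinship above 1/2.
#'
#' @param ped A `kin_pedigree` from [fam2ped()] or [build_pedigree()].
#' @return A symmetric numeric matrix with member ids as dimnames; diagonal
#'   entries are `(1 + F_i) / 2` where `F_i` is the inbreeding coefficient.
#' @examples
#' fam <- read_fam(system.file("extdata", "3gens.fam", package = "kinfolk"))
#' ped1 <- fam2ped(fam)$ped[[1]]
#' kinship_matrix(ped1)["testped1_g1-b1-s1", "testped1_g3-b1-i1"]
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "kin_pedigree"))
  m <- ped$members
  n <- nrow(m)
  idx <- stats::setNames(seq_len(n), m$id)
  dad <- unname(idx[m$dadid])
  mom <- unname(idx[m$momid])
  if (any(!is.na(dad) & dad >= seq_len(n)) || any(!is.na(mom) & mom >= seq_len(n))) {
    stop("pedigree members are not parent-first ordered; rebuild with build_pedigree()",
      call. = FALSE
    )
  }
  phi <- matrix(0, n, n, dimnames = list(m$id, m$id))
  for (i in seq_len(n)) {
    if (is.na(dad[i])) {
      phi[i, i] <- 0.5
    } else {
      p <- dad[i]
      q <- mom[i]
      phi[i, i] <- 0.5 + 0.5 * phi[p, q]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        phi[i, j] <- 0.5 * (phi[p, j] + phi[q, j])
        phi[j, i] <- phi[i, j]
      }
    }
  }
  phi
}

#' Pairwise expected kinship coefficients for one family
#'
#' Expands the kinship matrix of a single pedigree into a tidy pair table with
#' one row per unordered pair of members, self-pairs included: `n(n+1)/2` rows
#' for `n` members. Within each pair ids are sorted lexicographically and the
#' table is sorted by `(id1, id2)`; row order is a canonical presentation, not
#' part of the semantics.
#'
#' @inheritParams kinship_matrix
#' @return A tibble with columns `id1`, `id2`, `k`.
#' @examples
#' fam <- read_fam(system.file("extdata", "3gens.fam", package = "kinfolk"))
#' ped2kinpair(fam2ped(fam)$ped[[1]])
#' @export
ped2kinpair <- function(ped) {
  phi <- kinship_matrix(ped)
  ids <- rownames(phi)
  ut <- upper.tri(phi, diag = TRUE)
  pos <- which(ut, arr.ind = TRUE)
  a <- ids[pos[, 1L]]
  b <- ids[pos[, 2L]]
  tibble::tibble(
    id1 = pmin(a, b),
    id2 = pmax(a, b),
    k = phi[pos]
  ) |>
    dplyr::arrange(.data$id1, .data$id2)
}

#' Pairwise expected kinship for every family in a pedigree collection
#'
#' Maps [ped2kinpair()] over the families of a nested pedigree tibble and
#' binds the results, tagging each row with its family id. Only within-family
#' pairs are produced; individuals in different families are unrelated by
#' construction and are omitted rather than listed with k = 0.
#'
#' @param peds Nested tibble from [fam2ped()] (columns `fid`, `ped`).
#' @return A tibble with columns `fid`, `id1`, `id2`, `k`.
#' @examples
#' fam <- read_fam(system.file("extdata", "3gens.fam", package = "kinfolk"))
#' kinpairs_all(fam2ped(fam))
#' @export
kinpairs_all <- function(peds) {
  stopifnot(nrow(peds) > 0L, all(c("fid", "ped") %in% names(peds)))
  peds |>
    dplyr::mutate(pairs = purrr::map(.data$ped, ped2kinpair)) |>
    dplyr::select("fid", "pairs") |>
    tidyr::unnest("pairs")
}
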