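#' Generate multi-family, multi-generation pedigree records
#'
#' Builds synthetic `.fam` records with a fixed, fully deterministic family
#' structure: generation 1 is a founder couple; each middle generation has
#' two branches, each consisting of an in-lineage child of the previous
#' generation's couple plus a married-in founder spouse; the final generation
#' has one unmarried child per couple. With `n_generations = 3` this yields
#' 8 members per family (2 + 4 + 2), the classic three-generation test
#' pedigree containing parent-offspring, full-sibling, avuncular,
#' grandparent, and first-cousin pairs. Ids follow the
#' `"<prefix><family>_g<generation>-b<branch>-<i|s>1"` convention (`i` =
#' in-lineage, `s` = married-in spouse).
#'
#' @param n_families Number of families to generate.
#' @param n_generations Number of generations (at least 2; 2 gives a trio).
#' @param prefix Family id prefix (families are numbered `prefix1`,
#'   `prefix2`, ...).
#' @return A tibble of `.fam` records (columns as in [read_fam()]) that
#'   validates under [fam2ped()].
#' @examples
#' make_families(n_families = 8, n_generations = 3)
#' @export
make_families <- function(n_families = 8, n_generations = 3, prefix = "testped") {
  stopifnot(n_families >= 1, n_generations >= 2)
  one_family <- function(f) {
    fid <- paste0(prefix, f)
    mid <- function(g, b, who) paste0(fid, "_g", g, "-b", b, "-", who, "1")
    rows <- list(tibble::tibble(
      id = c(mid(1, 1, "s"), mid(1, 1, "i")),
      dadid = NA_character_, momid = NA_character_,
      sex = c(1L, 2L)
    ))
    # one couple feeds both branches of the next generation
    couple <- c(dad = mid(1, 1, "s"), mom = mid(1, 1, "i"))
    couples <- list(`1` = couple)
    for (g in seq_len(n_generations - 1L) + 1L) {
      last <- g == n_generations
      new_couples <- list()
      rows_g <- list()
      b_out <- 0L
      for (b in names(couples)) {
        parents <- couples[[b]]
        n_children <- if (last) 1L else if (g == 2L) 2L else 1L
        for (ch in seq_len(n_children)) {
          b_out <- b_out + 1L
          child_sex <- if (last) c(2L, 1L)[(b_out - 1L) %% 2L + 1L] else 2L
          child <- mid(g, b_out, "i")
          rows_g[[length(rows_g) + 1L]] <- tibble::tibble(
            id = child, dadid = parents[["dad"]], momid = parents[["mom"]],
            sex = child_sex
          )
          if (!last) {
            spouse <- mid(g, b_out, "s")
            rows_g[[length(rows_g) + 1L]] <- tibble::tibble(
              id = spouse, dadid = NA_character_, momid = NA_character_,
              sex = 1L
            )
            new_couples[[as.character(b_out)]] <- c(dad = spouse, mom = child)
          }
        }
      }
      # spouse listed before the in-lineage member within a branch, as in
      # conventional .fam fixtures (founders first is all that matters)
      rows_g <- dplyr::bind_rows(rows_g) |>
        dplyr::arrange(.data$id)
      rows[[length(rows) + 1L]] <- rows_g
      couples <- new_couples
    }
    dplyr::bind_rows(rows) |>
      dplyr::mutate(fid = fid, affected = 1L, .before = 1L)
  }
  purrr::map(seq_len(n_families), one_family) |>
    dplyr::bind_rows() |>
    dplyr::select("fid", "id", "dadid", "momid", "sex", "affected")
}

#' Build a synthetic monotone genetic map
#'
#' Uniform grid of map points per chromosome with genetic position linear in
#' physical position: chromosome `c` spans `[1, length_bp]` bp and
#' `[0, length_cm]` cM with `n_points` evenly spaced points.
#'
#' @param n_chr Number of chromosomes (labelled `"1"`, `"2"`, ...).
#' @param length_cm Genetic length of each chromosome, cM.
#' @param length_bp Physical length of each chromosome, bp.
#' @param n_points Map points per chromosome (at least 2).
#' @return A `genetic_map` tibble (columns `chr`, `cm`, `bp`).
#' @export
make_map <- function(n_chr = 2, length_cm = 100, length_bp = 1e8, n_points = 101) {
  stopifnot(n_chr >= 1, length_cm > 0, length_bp > 1, n_points >= 2)
  one <- function(c) {
    tibble::tibble(
      chr = as.character(c),
      cm = seq(0, length_cm, length.out = n_points),
      bp = round(seq(1, length_bp, length.out = n_points))
    )
  }
  out <- purrr::map(seq_len(n_chr), one) |> dplyr::bind_rows()
  class(out) <- c("genetic_map", class(out))
  out
}

#' Gene-drop IBD segments down a pedigree
#'
#' Simulates transmission of founder haplotypes down a pedigree over a
#' genetic map and reports the maximal segments each pair of members shares
#' identical by descent, at haplotype-pair resolution (the hap-IBD
#' convention; regions of double sharing appear as two overlapping records).
#'
#' Founder haplotypes carry globally unique integer labels, so sharing can
#' only arise through transmission. Each meiosis places crossovers as a
#' Poisson process on the genetic scale (rate 1 per Morgan, no interference)
#' and splices the parental haplotype mosaics accordingly. Segment physical
#' coordinates are obtained by inverse interpolation of the map; genetic
#' lengths are exact differences of genetic positions.
#'
#' @param ped A `kin_pedigree`.
#' @param map A `genetic_map`; every chromosome is simulated.
#' @param seed Optional integer seed (applied locally; the caller's RNG
#'   state is untouched).
#' @param founder_label_offset Integer added to founder haplotype labels so
#'   that segments from different simulations or families can be pooled
#'   without accidental label collisions.
#' @return A tibble of shared segments: `id1`, `hap1`, `id2`, `hap2`, `chr`,
#'   `start`, `end` (bp), `length` (cM), with `id1 <= id2`. Pairs sharing
#'   nothing contribute no rows.
#' @examples
#' fam <- make_families(n_families = 1, n_generations = 2)
#' ped <- fam2ped(fam)$ped[[1]]
#' seg <- gene_drop(ped, make_map(n_chr = 1), seed = 1)
#' ibd2kin(seg, make_map(n_chr = 1))
#' @export
gene_drop <- function(ped, map, seed = NULL, founder_label_offset = 0L) {
  stopifnot(inherits(ped, "kin_pedigree"))
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(seed)
  }
  m <- ped$members
  n <- nrow(m)
  idx <- stats::setNames(seq_len(n), m$id)
  dad <- unname(idx[m$dadid])
  mom <- unname(idx[m$momid])
  chroms <- unique(map$chr)

  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    sub <- map[map$chr == chr, ]
    if (nrow(sub) < 2L) {
      stop("chromosome ", sQuote(chr), " has fewer than 2 map points", call. = FALSE)
    }
    L <- max(sub$cm) - min(sub$cm)
    cm0 <- min(sub$cm)
    # haplotype mosaic: list(end = cM breakpoints ending at L, lab = labels)
    haps <- vector("list", n) # each: list of two mosaics
    next_label <- founder_label_offset
    for (i in seq_len(n)) {
      if (is.na(dad[i])) {
        haps[[i]] <- list(
          list(end = L, lab = next_label + 1L),
          list(end = L, lab = next_label + 2L)
        )
        next_label <- next_label + 2L
      } else {
        haps[[i]] <- list(
          meiosis(haps[[dad[i]]], L),
          meiosis(haps[[mom[i]]], L)
        )
      }
    }
    segs <- collect_shared_segments(haps, m$id, L)
    if (nrow(segs) > 0L) {
      # cM positions (relative to chromosome start) -> bp via the inverse map
      segs$start_bp <- round(stats::approx(sub$cm, sub$bp,
        xout = cm0 + segs$start_cm,
        ties = "ordered", rule = 2
      )$y)
      segs$end_bp <- round(stats::approx(sub$cm, sub$bp,
        xout = cm0 + segs$end_cm,
        ties = "ordered", rule = 2
      )$y)
      segs$chr <- chr
    }
    out[[ci]] <- segs
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      id1 = character(), hap1 = integer(), id2 = character(), hap2 = integer(),
      chr = character(), start = double(), end = double(), length = double()
    ))
  }
  out |>
    dplyr::transmute(
      id1 = .data$id1, hap1 = .data$hap1, id2 = .data$id2, hap2 = .data$hap2,
      chr = .data$chr, start = .data$start_bp, end = .data$end_bp,
      length = .data$end_cm - .data$start_cm
    ) |>
    dplyr::arrange(.data$id1, .data$id2, .data$chr, .data$start)
}

# one meiosis: recombine a parent's two haplotype mosaics into a gamete.
# crossovers ~ Poisson(L/100) on the genetic scale (cM), random phase.
meiosis <- function(parent_haps, L) {
  n_x <- stats::rpois(1L, L / 100)
  cuts <- if (n_x > 0L) sort(stats::runif(n_x, 0, L)) else numeric(0)
  phase <- sample.int(2L, 1L)
  bounds <- c(cuts, L)
  sources <- rep(c(phase, 3L - phase), length.out = length(bounds))
  ends <- numeric(0)
  labs <- integer(0)
  lo <- 0
  for (j in seq_along(bounds)) {
    hi <- bounds[j]
    if (hi > lo) {
      piece <- mosaic_slice(parent_haps[[sources[j]]], lo, hi)
      ends <- c(ends, piece$end)
      labs <- c(labs, piece$lab)
    }
    lo <- hi
  }
  # merge adjacent runs with identical labels
  keep <- c(labs[-length(labs)] != labs[-1L], TRUE)
  list(end = ends[keep], lab = labs[keep])
}

# restrict a mosaic to [lo, hi): segment ends clipped to hi
mosaic_slice <- function(hap, lo, hi) {
  first <- findInterval(lo, hap$end, left.open = TRUE) + 1L
  last <- findInterval(hi, hap$end, left.open = TRUE) + 1L
  last <- min(last, length(hap$end))
  ends <- pmin(hap$end[first:last], hi)
  list(end = ends, lab = hap$lab[first:last])
}

# pairwise maximal shared intervals between all haplotype pairs of distinct
# individuals; positions in cM relative to chromosome start
collect_shared_segments <- function(haps, ids, L) {
  n <- length(haps)
  acc <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      for (hi in 1:2) {
        for (hj in 1:2) {
          sh <- shared_intervals(haps[[i]][[hi]], haps[[j]][[hj]])
          if (nrow(sh) > 0L) {
            a <- ids[i]
            b <- ids[j]
            if (a <= b) {
              sh$id1 <- a
              sh$hap1 <- hi
              sh$id2 <- b
              sh$hap2 <- hj
            } else {
              sh$id1 <- b
              sh$hap1 <- hj
              sh$id2 <- a
              sh$hap2 <- hi
            }
            acc[[length(acc) + 1L]] <- sh
          }
        }
      }
    }
  }
  if (length(acc) == 0L) {
    return(tibble::tibble(
      start_cm = double(), end_cm = double(),
      id1 = character(), hap1 = integer(), id2 = character(), hap2 = integer()
    ))
  }
  dplyr::bind_rows(acc)
}

# maximal intervals where two mosaics carry the same founder label
shared_intervals <- function(h1, h2) {
  cuts <- sort(unique(c(0, h1$end, h2$end)))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1L]
  mid <- (starts + ends) / 2
  lab1 <- h1$lab[findInterval(mid, h1$end, left.open = TRUE) + 1L]
  lab2 <- h2$lab[findInterval(mid, h2$end, left.open = TRUE) + 1L]
  same <- lab1 == lab2
  if (!any(same)) {
    return(tibble::tibble(start_cm = double(), end_cm = double()))
  }
  # merge adjacent shared intervals (they may share different founder labels
  # only across a breakpoint where sharing switches; merge only equal labels)
  r <- rle(ifelse(same, lab1, -1L))
  pos <- cumsum(r$lengths)
  first <- c(1L, pos[-length(pos)] + 1L)
  keep <- r$values != -1L
  tibble::tibble(
    start_cm = starts[first[keep]],
    end_cm = ends[pos[keep]]
  )
}

#' Single-locus gene-dropping Monte-Carlo kinship oracle
#'
#' Estimates the kinship coefficient of every pair in a pedigree by dropping
#' two uniquely labelled alleles per founder down the pedigree many times and
#' averaging, per replicate, the probability that a random allele from one
#' individual is identical by descent to a random allele from the other
#' (`(1/4) * sum of the four allele comparisons`; for self-pairs this equals
#' `1/2 + F/2`). This is an independent check of [kinship_matrix()]: it
#' shares no code with the recursion.
#'
#' @param ped A `kin_pedigree`.
#' @param n_rep Number of transmission replicates.
#' @param seed Optional integer seed (applied locally).
#' @return A tibble with columns `id1`, `id2` (canonical order, self-pairs
#'   included), `k_hat` (Monte-Carlo mean), and `se` (its standard error).
#' @export
drop_alleles <- function(ped, n_rep = 10000, seed = NULL) {
  stopifnot(inherits(ped, "kin_pedigree"), n_rep >= 1)
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(seed)
  }
  m <- ped$members
  n <- nrow(m)
  idx <- stats::setNames(seq_len(n), m$id)
  dad <- unname(idx[m$dadid])
  mom <- unname(idx[m$momid])
  a1 <- matrix(0L, n_rep, n)
  a2 <- matrix(0L, n_rep, n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(dad[i])) {
      a1[, i] <- lab + 1L
      a2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick_d <- stats::runif(n_rep) < 0.5
      pick_m <- stats::runif(n_rep) < 0.5
      a1[, i] <- ifelse(pick_d, a1[, dad[i]], a2[, dad[i]])
      a2[, i] <- ifelse(pick_m, a1[, mom[i]], a2[, mom[i]])
    }
  }
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  res <- purrr::map(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]
    j <- pairs[r, 2L]
    x <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
      (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
    a <- m$id[i]
    b <- m$id[j]
    tibble::tibble(
      id1 = min(a, b), id2 = max(a, b),
      k_hat = mean(x), se = stats::sd(x) / sqrt(n_rep)
    )
  })
  dplyr::bind_rows(res) |> dplyr::arrange(.data$id1, .data$id2)
}

#' Randomly degrade class labels
#'
#' Each label is independently replaced, with probability `flip_rate`, by a
#' uniform draw from the distinct observed labels (the draw may coincide
#' with the original, so the expected fraction actually changed is
#' `flip_rate * (1 - 1/n_distinct)`). Used to manufacture imperfect
#' predictions for benchmarking a classifier against known truth.
#'
#' @param labels Vector of class labels.
#' @param flip_rate Per-label replacement probability in `[0, 1]`.
#' @param seed Optional integer seed (applied locally).
#' @return Vector of the same length and type as `labels`.
#' @examples
#' flip_labels(rep(c("1", "2", "unrelated"), 10), flip_rate = 0.2, seed = 42)
#' @export
flip_labels <- function(labels, flip_rate = 0.2, seed = NULL) {
  stopifnot(length(labels) > 0L, flip_rate >= 0, flip_rate <= 1)
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(seed)
  }
  u <- unique(labels)
  hit <- stats::runif(length(labels)) < flip_rate
  repl <- u[sample.int(length(u), length(labels), replace = TRUE)]
  out <- labels
  out[hit] <- repl[hit]
  out
}

#' Write segments in hap-IBD output format
#'
#' Writes the 8-column tab-delimited hap-IBD segment format (id1, hap1, id2,
#' hap2, chr, start, end, cM length), gzipped when `file` ends in `.gz`.
#' Segments lacking haplotype columns (e.g. normalized [read_ibd()] output)
#' are written with haplotype index 1.
#'
#' @param segments Segment tibble from [gene_drop()] or [read_ibd()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ibd <- function(segments, file) {
  out <- segments
  if (!"hap1" %in% names(out)) out$hap1 <- 1L
  if (!"hap2" %in% names(out)) out$hap2 <- 1L
  out <- out[c("id1", "hap1", "id2", "hap2", "chr", "start", "end", "length")]
  readr::write_tsv(out, file, col_names = FALSE)
  invisible(file)
}
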