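#' Read pairwise IBD segments
#'
#' Reads identity-by-descent segment tables in either of two dialects:
#' `source = "hapibd"` for hap-IBD output (tab-delimited, no header, 8
#' columns: id1, haplotype1, id2, haplotype2, chromosome, physical start,
#' physical end, genetic length in cM; usually gzipped) and
#' `source = "pedsim"` for ped-sim simulated `.seg` files (9 columns: id1,
#' id2, chromosome, physical start, physical end, IBD type, genetic start,
#' genetic end, genetic length).
#'
#' Both dialects are normalized to one record per shared haplotype-pair
#' segment. hap-IBD already reports at haplotype-pair resolution, so its
#' haplotype index columns are simply dropped. A ped-sim `IBD2` segment means
#' the pair shares on both haplotype pairs over the span, so it is emitted
#' twice; `IBD1` once. Multiple (possibly physically overlapping) records per
#' pair are therefore expected and legal. Pair ids are canonically ordered
#' (`id1 <= id2` lexicographically) within each record.
#'
#' @param file Path to a segment file, plain text or gzipped.
#' @param source Either `"hapibd"` or `"pedsim"`.
#' @return A tibble with columns `id1`, `id2`, `chr` (character), `start`,
#'   `end` (physical bp, start <= end), `length` (genetic cM as reported in
#'   the file).
#' @seealso [ibd2kin()] to convert shared segments to kinship, [read_map()].
#' @export
read_ibd <- function(file, source = c("hapibd", "pedsim")) {
  source <- match.arg(source)
  if (!file.exists(file)) {
    stop("IBD segment file not found: ", file, call. = FALSE)
  }
  ncols <- if (source == "hapibd") 8L else 9L
  lines <- readr::read_lines(file)
  lines <- lines[!grepl("^\\s*$", lines)]
  empty <- tibble::tibble(
    id1 = character(), id2 = character(), chr = character(),
    start = double(), end = double(), length = double()
  )
  if (length(lines) == 0L) {
    return(empty)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != ncols)) {
    bad <- which(nf != ncols)[1L]
    stop("line ", bad, ": expected ", ncols, " fields for source=\"", source,
      "\", got ", nf[bad],
      call. = FALSE
    )
  }
  mat <- matrix(unlist(fields), ncol = ncols, byrow = TRUE)
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(x)) {
      stop("line ", which(is.na(x))[1L], ": non-numeric ", what, call. = FALSE)
    }
    x
  }
  if (source == "hapibd") {
    out <- tibble::tibble(
      id1 = mat[, 1L], id2 = mat[, 3L], chr = normalize_chr(mat[, 5L]),
      start = num(6L, "start"), end = num(7L, "end"),
      length = num(8L, "genetic length")
    )
  } else {
    type <- mat[, 6L]
    if (!all(type %in% c("IBD1", "IBD2"))) {
      stop("line ", which(!type %in% c("IBD1", "IBD2"))[1L],
        ": IBD type must be IBD1 or IBD2",
        call. = FALSE
      )
    }
    out <- tibble::tibble(
      id1 = mat[, 1L], id2 = mat[, 2L], chr = normalize_chr(mat[, 3L]),
      start = num(4L, "start"), end = num(5L, "end"),
      length = num(9L, "genetic length")
    )
    # IBD2 = sharing on both haplotype pairs: emit the record twice
    out <- out[rep(seq_len(nrow(out)), times = 1L + (type == "IBD2")), ]
  }
  if (any(out$start < 0 | out$end < out$start)) {
    bad <- which(out$start < 0 | out$end < out$start)[1L]
    stop("line ", bad, ": negative or inverted physical coordinates", call. = FALSE)
  }
  if (any(out$length < 0)) {
    stop("line ", which(out$length < 0)[1L], ": negative genetic length",
      call. = FALSE
    )
  }
  swap <- out$id1 > out$id2
  tmp <- out$id1[swap]
  out$id1[swap] <- out$id2[swap]
  out$id2[swap] <- tmp
  out
}

normalize_chr <- function(chr) {
  sub("^chr", "", as.character(chr), ignore.case = TRUE)
}

#' Read a genetic map
#'
#' Reads a genetic map giving genetic position (cM) as a function of physical
#' position (bp), per chromosome. Two whitespace-delimited dialects are
#' auto-detected by column count: 3 columns `(chr, cM, bp)`, or 4-column
#' PLINK `.map` `(chr, marker id, cM, bp)` whose marker ids are dropped.
#'
#' Rows are sorted by (chromosome, bp) and the map is validated: physical
#' positions strictly increasing and genetic positions non-decreasing within
#' each chromosome.
#'
#' @param file Path to a map file, plain or gzipped.
#' @return A tibble with columns `chr` (character, `"chr"` prefixes
#'   stripped), `cm`, `bp`, of class `genetic_map`.
#' @export
read_map <- function(file) {
  if (!file.exists(file)) {
    stop("map file not found: ", file, call. = FALSE)
  }
  lines <- readr::read_lines(file)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    stop("empty genetic map: ", file, call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- unique(lengths(fields))
  if (length(nf) != 1L || !nf %in% c(3L, 4L)) {
    stop("genetic map must have uniformly 3 columns (chr, cM, bp) or ",
      "4 PLINK .map columns (chr, id, cM, bp)",
      call. = FALSE
    )
  }
  mat <- matrix(unlist(fields), ncol = nf, byrow = TRUE)
  cm_col <- if (nf == 3L) 2L else 3L
  bp_col <- if (nf == 3L) 3L else 4L
  out <- tibble::tibble(
    chr = normalize_chr(mat[, 1L]),
    cm = as.numeric(mat[, cm_col]),
    bp = as.numeric(mat[, bp_col])
  )
  if (anyNA(out$cm) || anyNA(out$bp)) {
    stop("non-numeric genetic or physical position in map", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$chr, .data$bp)
  bad <- out |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(
      mono = all(diff(.data$bp) > 0) && all(diff(.data$cm) >= 0)
    ) |>
    dplyr::filter(!.data$mono)
  if (nrow(bad) > 0L) {
    stop("genetic map not monotone (bp strictly increasing, cM non-decreasing)",
      " on chromosome(s): ", paste(bad$chr, collapse = ", "),
      call. = FALSE
    )
  }
  class(out) <- c("genetic_map", class(out))
  out
}

#' Write a genetic map in 3-column format
#'
#' @param map A `genetic_map` tibble (columns `chr`, `cm`, `bp`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_map <- function(map, file) {
  readr::write_delim(map[c("chr", "cm", "bp")], file,
    delim = " ",
    col_names = FALSE
  )
  invisible(file)
}

#' Interpolate genetic position from physical position
#'
#' Linear interpolation of the genetic map between flanking map points.
#' Physical positions before the first or after the last map point clamp to
#' the boundary genetic position (no extrapolation), so off-map coordinates
#' can never produce negative genetic lengths.
#'
#' @param map A `genetic_map` from [read_map()] or [make_map()].
#' @param chr Chromosome label (matched after stripping any `"chr"` prefix).
#' @param bp Numeric vector of physical positions.
#' @return Numeric vector of genetic positions in cM.
#' @export
interpolate_cm <- function(map, chr, bp) {
  chr <- normalize_chr(chr)
  sub <- map[map$chr == chr, ]
  if (nrow(sub) == 0L) {
    stop("chromosome ", sQuote(chr), " absent from genetic map", call. = FALSE)
  }
  if (nrow(sub) < 2L) {
    stop("chromosome ", sQuote(chr), " has fewer than 2 map points; ",
      "cannot interpolate",
      call. = FALSE
    )
  }
  stats::approx(sub$bp, sub$cm, xout = bp, method = "linear", rule = 2, ties = "ordered")$y
}

#' Convert shared IBD segments to kinship coefficients
#'
#' Sums the genetic length shared identical-by-descent by each pair of
#' individuals and scales it to a kinship coefficient. Segment genetic
#' lengths are recomputed from the supplied map as
#' `interpolate_cm(end) - interpolate_cm(start)` rather than trusted from the
#' input file, which makes the required consistency between the map used for
#' segment inference and the map used here explicit; a discrepancy of more
#' than 1 cM between a recomputed and a reported length raises a warning
#' (map-resolution noise stays silent).
#'
#' With segments at haplotype-pair resolution, the kinship estimate is
#' `sum(shared cM) / (4 * total map length)`, the total map length summed
#' over all chromosomes in the map. Complete sharing of one haplotype
#' (parent-offspring) then yields 0.25 and complete sharing of both (self,
#' identical twins) 0.5.
#'
#' @param .ibd_data Segment tibble from [read_ibd()] or [gene_drop()].
#' @param .map A `genetic_map` covering every chromosome in `.ibd_data`.
#' @return A tibble with one row per observed pair: `id1`, `id2`, `kinship`,
#'   sorted by pair. Pairs with no segments do not appear.
#' @examples
#' map <- make_map(n_chr = 1, length_cm = 100, length_bp = 1e6)
#' seg <- tibble::tibble(
#'   id1 = "a", id2 = "b", chr = "1",
#'   start = 1, end = 1e6, length = 100
#' )
#' ibd2kin(seg, map) # one full haplotype shared: kinship 0.25
#' @export
ibd2kin <- function(.ibd_data, .map) {
  stopifnot(all(c("id1", "id2", "chr", "start", "end") %in% names(.ibd_data)))
  seg <- .ibd_data
  if (nrow(seg) == 0L) {
    return(tibble::tibble(id1 = character(), id2 = character(), kinship = double()))
  }
  seg$chr <- normalize_chr(seg$chr)
  missing_chr <- setdiff(unique(seg$chr), unique(.map$chr))
  if (length(missing_chr) > 0L) {
    stop("segment chromosome(s) absent from map: ",
      paste(missing_chr, collapse = ", "),
      call. = FALSE
    )
  }
  total_cm <- .map |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(len = max(.data$cm) - min(.data$cm)) |>
    dplyr::pull(.data$len) |>
    sum()
  if (total_cm <= 0) {
    stop("genetic map has zero total length", call. = FALSE)
  }
  seg <- seg |>
    dplyr::group_by(.data$chr) |>
    dplyr::mutate(
      cm_len = interpolate_cm(.map, .data$chr[1L], .data$end) -
        interpolate_cm(.map, .data$chr[1L], .data$start)
    ) |>
    dplyr::ungroup()
  if ("length" %in% names(seg)) {
    disc <- abs(seg$cm_len - seg$length)
    if (any(disc > 1, na.rm = TRUE)) {
      warning(sum(disc > 1, na.rm = TRUE), " segment(s) with recomputed genetic",
        " length differing from the reported length by more than 1 cM;",
        " check that this map produced the segments",
        call. = FALSE
      )
    }
  }
  seg |>
    dplyr::mutate(
      pair1 = pmin(.data$id1, .data$id2),
      pair2 = pmax(.data$id1, .data$id2)
    ) |>
    dplyr::group_by(id1 = .data$pair1, id2 = .data$pair2) |>
    dplyr::summarise(kinship = sum(.data$cm_len) / (4 * total_cm), .groups = "drop") |>
    dplyr::arrange(.data$id1, .data$id2)
}

#' Histogram of pairwise kinship estimates with degree boundaries
#'
#' @param kin Tibble from [ibd2kin()] (column `kinship`).
#' @param max_degree Degree resolution whose inference bounds to overlay.
#' @return A ggplot object.
#' @export
plot_kinship <- function(kin, max_degree = 3) {
  bounds <- dibble(max_degree)$l
  bounds <- bounds[bounds > 0]
  ggplot2::ggplot(kin, ggplot2::aes(x = .data$kinship)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey40") +
    ggplot2::geom_vline(xintercept = bounds, linetype = "dashed") +
    ggplot2::labs(
      x = "estimated kinship coefficient", y = "pairs",
      title = "Pairwise kinship with degree inference boundaries"
    ) +
    ggplot2::theme_minimal()
}
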