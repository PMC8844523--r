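#' Read a PLINK-style .fam pedigree file
#'
#' Reads the six-column PLINK `.fam` format (family ID, individual ID, father
#' ID, mother ID, sex, phenotype) into a tibble with one row per individual.
#' Fields are separated by any run of spaces or tabs; files may be plain text
#' or gzipped. The literal parent token `"0"` (or an empty field) is parsed to
#' `NA`, the PLINK convention for a missing parent.
#'
#' @param file Path to a `.fam` file (plain or gzipped).
#'
#' @return A tibble with columns `fid`, `id`, `dadid`, `momid` (character;
#'   `NA` for missing parents), `sex` (integer: 1 = male, 2 = female, other =
#'   unknown), and `affected` (integer phenotype code).
#'
#' @details `.fam` files carry no header. A first line whose sex field is not
#'   an integer is rejected with an explicit "no header expected" error rather
#'   than being silently dropped.
#'
#' @seealso [fam2ped()] to validate and structure the records per family,
#'   [write_fam()] for the round-trip writer.
#' @examples
#' famfile <- system.file("extdata", "3gens.fam", package = "kinfolk")
#' read_fam(famfile)
#' @export
read_fam <- function(file) {
  if (!file.exists(file)) {
    stop("fam file not found: ", file, call. = FALSE)
  }
  lines <- readr::read_lines(file)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      fid = character(), id = character(),
      dadid = character(), momid = character(),
      sex = integer(), affected = integer()
    ))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- which(nf < 6L)[1L]
    stop("line ", bad, ": expected at least 6 whitespace-delimited fields, got ",
      nf[bad],
      call. = FALSE
    )
  }
  mat <- vapply(fields, function(x) x[1:6], character(6))
  parse_int_col <- function(x, what) {
    ok <- grepl("^-?[0-9]+$", x)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      hint <- if (bad == 1L) {
        " (.fam files have no header line)"
      } else {
        ""
      }
      stop("line ", bad, ": non-integer ", what, " value ", sQuote(x[bad]),
        hint,
        call. = FALSE
      )
    }
    as.integer(x)
  }
  out <- tibble::tibble(
    fid = mat[1L, ],
    id = mat[2L, ],
    dadid = dplyr::na_if(mat[3L, ], "0"),
    momid = dplyr::na_if(mat[4L, ], "0"),
    sex = parse_int_col(mat[5L, ], "sex"),
    affected = parse_int_col(mat[6L, ], "affected")
  )
  out$dadid[out$dadid == ""] <- NA_character_
  out$momid[out$momid == ""] <- NA_character_
  if (any(out$id == "")) {
    stop("line ", which(out$id == "")[1L], ": empty individual id", call. = FALSE)
  }
  dup <- duplicated(paste(out$fid, out$id, sep = "\r"))
  if (any(dup)) {
    stop("duplicated (fid, id): ",
      paste(out$fid[dup], out$id[dup], sep = "/", collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Write pedigree records back to .fam format
#'
#' Inverse of [read_fam()]: missing parents are written as `"0"`. Re-reading
#' the written file reproduces the input records field for field.
#'
#' @param fam A tibble of pedigree records as returned by [read_fam()].
#' @param file Output path; a `.gz` suffix writes a gzipped file.
#' @return `file`, invisibly.
#' @export
write_fam <- function(fam, file) {
  stopifnot(all(c("fid", "id", "dadid", "momid", "sex", "affected") %in% names(fam)))
  out <- fam |>
    dplyr::mutate(
      dadid = dplyr::coalesce(.data$dadid, "0"),
      momid = dplyr::coalesce(.data$momid, "0")
    ) |>
    dplyr::select("fid", "id", "dadid", "momid", "sex", "affected")
  readr::write_delim(out, file, delim = " ", col_names = FALSE)
  invisible(file)
}

#' Validate .fam records and structure them per family
#'
#' Collapses a tibble of pedigree records (one row per individual, possibly
#' many families) into a nested tibble with one row per family: the raw member
#' rows and a validated pedigree object whose members are ordered parents
#' before children.
#'
#' Validation enforces the rules the downstream kinship recursion needs: each
#' individual has either both parents present or both missing; every parent id
#' resolves to a member of the same family; the recorded father is not female
#' and the recorded mother is not male (checked only where sex is known); and
#' the parent-child relation is acyclic.
#'
#' @param fam A tibble of records as returned by [read_fam()].
#' @param fix_parents If `TRUE`, repair two common defects instead of erroring:
#'   a single-parent row gains a synthetic founder of the appropriate sex
#'   (deterministic id `"<child id>_padded"`), and a parent referenced but
#'   absent from the family is added as a founder with unknown phenotype.
#' @return A tibble with one row per family: `fid`, `data` (list column of
#'   member tibbles), and `ped` (list column of `kin_pedigree` objects).
#' @examples
#' fam <- read_fam(system.file("extdata", "3gens.fam", package = "kinfolk"))
#' fam2ped(fam)
#' @export
fam2ped <- function(fam, fix_parents = FALSE) {
  if (nrow(fam) == 0L) {
    stop("no pedigree records supplied", call. = FALSE)
  }
  fam |>
    tidyr::nest(.by = "fid") |>
    dplyr::mutate(
      ped = purrr::map2(.data$data, .data$fid, build_pedigree,
        fix_parents = fix_parents
      )
    ) |>
    dplyr::select("fid", "data", "ped")
}

#' Construct a validated single-family pedigree
#'
#' Lower-level constructor behind [fam2ped()]; takes the member rows of one
#' family and returns a `kin_pedigree` with members topologically ordered
#' (every parent precedes its children).
#'
#' @param members Tibble of member rows (columns `id`, `dadid`, `momid`,
#'   `sex`, `affected`; an `fid` column is ignored in favour of `fid`).
#' @param fid Family identifier.
#' @inheritParams fam2ped
#' @return A `kin_pedigree`: a list with elements `fid`, `members` (ordered
#'   tibble), and `founder_ids`.
#' @export
build_pedigree <- function(members, fid = "F1", fix_parents = FALSE) {
  m <- tibble::as_tibble(members)
  m$fid <- NULL
  req <- c("id", "dadid", "momid", "sex", "affected")
  stopifnot(all(req %in% names(m)))
  m <- m[req]

  single <- xor(is.na(m$dadid), is.na(m$momid))
  if (any(single)) {
    if (!fix_parents) {
      stop("family ", fid, ": individual(s) with exactly one recorded parent: ",
        paste(m$id[single], collapse = ", "),
        "; supply both or neither (or use fix_parents = TRUE)",
        call. = FALSE
      )
    }
    for (i in which(single)) {
      pad_id <- paste0(m$id[i], "_padded")
      pad_sex <- if (is.na(m$dadid[i])) 1L else 2L
      if (is.na(m$dadid[i])) m$dadid[i] <- pad_id else m$momid[i] <- pad_id
      m <- dplyr::add_row(m,
        id = pad_id, dadid = NA_character_, momid = NA_character_,
        sex = pad_sex, affected = NA_integer_
      )
    }
  }

  refs <- unique(stats::na.omit(c(m$dadid, m$momid)))
  absent <- setdiff(refs, m$id)
  if (length(absent) > 0L) {
    if (!fix_parents) {
      stop("family ", fid, ": parent id(s) referenced but not present: ",
        paste(absent, collapse = ", "),
        call. = FALSE
      )
    }
    is_dad <- absent %in% m$dadid
    m <- dplyr::add_row(m,
      id = absent, dadid = NA_character_, momid = NA_character_,
      sex = ifelse(is_dad, 1L, 2L), affected = NA_integer_
    )
  }

  # father must not be recorded female, mother not male (unknown sex passes)
  sex_of <- stats::setNames(m$sex, m$id)
  bad_dad <- !is.na(m$dadid) & sex_of[m$dadid] == 2L
  bad_mom <- !is.na(m$momid) & sex_of[m$momid] == 1L
  if (any(bad_dad, na.rm = TRUE) || any(bad_mom, na.rm = TRUE)) {
    offenders <- unique(c(m$dadid[which(bad_dad)], m$momid[which(bad_mom)]))
    stop("family ", fid, ": parent sex inconsistent with role for: ",
      paste(offenders, collapse = ", "),
      call. = FALSE
    )
  }

  ord <- toposort_members(m, fid)
  m <- m[ord, ]
  founders <- m$id[is.na(m$dadid) & is.na(m$momid)]
  structure(
    list(fid = fid, members = m, founder_ids = founders),
    class = "kin_pedigree"
  )
}

# Kahn topological sort over the parent -> child relation; errors on cycles.
toposort_members <- function(m, fid) {
  n <- nrow(m)
  idx <- stats::setNames(seq_len(n), m$id)
  dad <- unname(idx[m$dadid])
  mom <- unname(idx[m$momid])
  indeg <- ifelse(is.na(dad), 0L, 1L) + ifelse(is.na(mom), 0L, 1L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(dad[i], mom[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0L) {
    i <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("family ", fid, ": cycle detected in parent-child relation involving: ",
      paste(m$id[setdiff(seq_len(n), ord)], collapse = ", "),
      call. = FALSE
    )
  }
  ord
}

#' @export
print.kin_pedigree <- function(x, ...) {
  cat(
    "<kin_pedigree> family", x$fid, "with", nrow(x$members), "members (",
    length(x$founder_ids), "founders )\n"
  )
  invisible(x)
}

#' Flatten a pedigree collection back to .fam records
#'
#' @param peds Nested tibble from [fam2ped()], or a single `kin_pedigree`.
#' @return A tibble of `.fam` records suitable for [write_fam()].
#' @export
ped2fam <- function(peds) {
  if (inherits(peds, "kin_pedigree")) {
    peds <- tibble::tibble(fid = peds$fid, ped = list(peds))
  }
  peds |>
    dplyr::mutate(rows = purrr::map(.data$ped, function(p) p$members)) |>
    dplyr::select("fid", "rows") |>
    tidyr::unnest("rows")
}
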