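#' Degree inference table
#'
#' Builds the degree inference tibble: for each relationship degree d up to
#' `max_degree`, the expected kinship coefficient `k = 2^-(d+1)` together with
#' the lower and upper inference bounds `l = 2^-(d+3/2)` and `u = 2^-(d+1/2)`
#' of Manichaikul et al. (the geometric midpoints between adjacent expected
#' values, so that `l * u = k^2`). Degree 0 is self/identity/monozygotic
#' twins; its upper bound is extended to 1 so that estimated coefficients
#' above the theoretical maximum of 0.5 (floating point noise, stochastic
#' estimators) still classify as degree 0. Anything more distant than
#' `max_degree` is the unrelated band, encoded with `degree = NA`, `k = 0`,
#' and a lower bound of -1 so that negative moment-estimator kinship values
#' classify as unrelated.
#'
#' Adjacent rows tile `(-1, 1]` exactly: the upper bound of each degree equals
#' the lower bound of the degree above it.
#'
#' @param max_degree Largest degree to resolve (default 3). Must be an
#'   integer in `[1, 11]`; values of 10 or more trigger a warning because the
#'   inference ranges become vanishingly narrow, and 12 or more is an error.
#' @return A tibble with `max_degree + 2` rows and columns `degree` (integer,
#'   `NA` for unrelated), `k`, `l`, `u`.
#' @examples
#' dibble()
#' dibble(max_degree = 5)
#' @export
dibble <- function(max_degree = 3) {
  check_max_degree(max_degree)
  d <- 0:max_degree
  out <- tibble::tibble(
    degree = c(d, NA_integer_),
    k = c(2^-(d + 1), 0),
    l = c(2^-(d + 1.5), -1),
    u = c(1, 2^-(d[-1] + 0.5), 2^-(max_degree + 1.5))
  )
  out
}

check_max_degree <- function(max_degree) {
  if (length(max_degree) != 1L || !is.numeric(max_degree) ||
    !is.finite(max_degree) || max_degree != as.integer(max_degree)) {
    stop("max_degree must be a single integer", call. = FALSE)
  }
  if (max_degree < 1) {
    stop("max_degree must be at least 1", call. = FALSE)
  }
  if (max_degree >= 12) {
    stop("max_degree must be less than 12: inference ranges degenerate",
      call. = FALSE
    )
  }
  if (max_degree >= 10) {
    warning("max_degree >= 10: inference ranges are extremely narrow ",
      "and degree calls will be unstable",
      call. = FALSE
    )
  }
  invisible(max_degree)
}

#' Infer relationship degree from a kinship coefficient
#'
#' Classifies kinship coefficients into relationship degrees using the
#' inference ranges of [dibble()]. Each interval is closed below and open
#' above (`l <= k < u`), except degree 0 which is closed at its upper bound of
#' 1. Values in the unrelated band (below the lowest resolved degree's bound,
#' including negative estimates) return `NA`.
#'
#' @param k Numeric vector of kinship coefficients; the function is
#'   vectorized over `k`.
#' @inheritParams dibble
#' @return Integer vector of the same length as `k`: the inferred degree, or
#'   `NA` for unrelated (and, with a warning, for non-finite input).
#' @examples
#' kin2degree(0.25, max_degree = 3)
#' kin2degree(0.0312, max_degree = 3) # beyond resolution: NA
#' kin2degree(0.0312, max_degree = 5)
#' @export
kin2degree <- function(k, max_degree = 3) {
  check_max_degree(max_degree)
  stopifnot(is.numeric(k))
  if (any(!is.finite(k))) {
    warning("non-finite kinship values classified as NA", call. = FALSE)
  }
  d <- 0:max_degree
  # breaks between degree d and d+1 are the shared bounds 2^-(d + 3/2);
  # each inference interval is closed below, open above
  breaks <- c(-Inf, 2^-(rev(d) + 1.5), Inf)
  cls <- findInterval(k, breaks, left.open = FALSE) - 1L
  deg <- max_degree + 1L - cls
  deg[deg > max_degree] <- NA_integer_
  deg[!is.finite(k)] <- NA_integer_
  deg[is.finite(k) & k > 1] <- NA_integer_ # above the closed degree-0 cap
  as.integer(deg)
}

#' Visualize degree inference ranges
#'
#' Plots the expected kinship coefficient and inference interval of each
#' relationship degree on a log2 axis, making the geometric-midpoint
#' construction visible.
#'
#' @param d A degree inference table from [dibble()].
#' @return A ggplot object.
#' @export
plot_dibble <- function(d = dibble()) {
  dd <- d |>
    dplyr::mutate(
      label = ifelse(is.na(.data$degree), "unrelated", as.character(.data$degree)),
      l_plot = pmax(.data$l, 2^-(nrow(d) + 1.5))
    )
  ggplot2::ggplot(dd, ggplot2::aes(y = stats::reorder(.data$label, -.data$k))) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$l_plot, xmax = .data$u)) +
    ggplot2::geom_point(ggplot2::aes(x = pmax(.data$k, 2^-(nrow(dd) + 2)))) +
    ggplot2::scale_x_continuous(
      trans = "log2",
      labels = function(x) signif(x, 3)
    ) +
    ggplot2::labs(
      x = "kinship coefficient (log2 scale)", y = "relationship degree",
      title = "Degree inference ranges"
    ) +
    ggplot2::theme_minimal()
}
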