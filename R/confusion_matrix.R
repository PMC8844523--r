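#' Benchmark predicted against true relationship degrees
#'
#' Full contingency-table benchmarking of a degree classifier. Returns the
#' four pieces a benchmarking workflow needs: an accuracy block (overall
#' accuracy with an exact Clopper-Pearson 95% interval, the no-information
#' "guessing" rate, and a one-sided exact binomial p-value of accuracy
#' against guessing), per-class contingency statistics with a macro-average
#' row, the predicted-by-target contingency table itself, and the reciprocal
#' RMSE of [recip_rmse()].
#'
#' The label universe is the union of labels observed in `target` and
#' `prediction`, ordered with numeric degree labels first (ascending) and any
#' non-numeric label (e.g. `"unrelated"`) last. A label present only in the
#' predictions contributes a zero-count target column rather than an error; a
#' class with zero target and zero predicted count is dropped from the
#' per-class statistics.
#'
#' @param prediction Vector of predicted class labels (degrees as strings or
#'   integers, and/or `"unrelated"`).
#' @param target Vector of true class labels, same length.
#' @param longer If `TRUE`, return the per-class statistics in long format
#'   (columns `Statistic`, `Class`, `Value`) instead of one row per class.
#' @return An object of class `kin_confusion`: a list with elements
#'   `Accuracy` (one-row tibble), `Other` (per-class statistics tibble),
#'   `Table` (contingency matrix, predicted rows by target columns), and
#'   `recip_rmse` (numeric scalar).
#' @examples
#' truth <- c("0", "1", "1", "2", "unrelated", "unrelated")
#' pred <- c("0", "1", "2", "2", "unrelated", "3")
#' confusion_matrix(prediction = pred, target = truth)
#' @seealso [recip_rmse()], [tidy.kin_confusion()], [glance.kin_confusion()],
#'   [autoplot.kin_confusion()]
#' @export
confusion_matrix <- function(prediction, target, longer = FALSE) {
  if (length(target) == 0L) {
    stop("no label pairs supplied", call. = FALSE)
  }
  if (length(prediction) != length(target)) {
    stop("prediction and target must have the same length", call. = FALSE)
  }
  prediction <- as.character(prediction)
  target <- as.character(target)
  levs <- degree_label_levels(c(target, prediction))
  tab <- table(
    Predicted = factor(prediction, levels = levs),
    Target = factor(target, levels = levs)
  )
  n <- sum(tab)
  correct <- sum(diag(tab))
  accuracy <- correct / n
  guessing <- max(colSums(tab)) / n
  ci <- stats::binom.test(correct, n)$conf.int
  pval <- stats::binom.test(correct, n, p = guessing, alternative = "greater")$p.value
  acc_tbl <- tibble::tibble(
    Accuracy = accuracy,
    `Accuracy LL` = ci[1L],
    `Accuracy UL` = ci[2L],
    `Accuracy Guessing` = guessing,
    `Accuracy P-value` = pval
  )

  keep <- colSums(tab) + rowSums(tab) > 0
  stats_tbl <- class_stats(tab[keep, keep, drop = FALSE])
  if (longer) {
    stats_tbl <- stats_tbl |>
      tidyr::pivot_longer(-"Class", names_to = "Statistic", values_to = "Value") |>
      dplyr::select("Statistic", "Class", "Value") |>
      dplyr::arrange(.data$Statistic)
  }

  out <- list(
    Accuracy = acc_tbl,
    Other = stats_tbl,
    Table = unclass(tab),
    recip_rmse = recip_rmse(target = target, prediction = prediction)
  )
  class(out) <- "kin_confusion"
  out
}

# numeric degree labels sorted ascending, everything else (unrelated) last
degree_label_levels <- function(labels) {
  u <- unique(labels)
  is_num <- grepl("^[0-9]+$", u)
  c(sort(as.integer(u[is_num])), sort(u[!is_num]))
}

# per-class one-vs-rest statistics from a square contingency table
# (predicted rows x target columns), plus an unweighted macro-average row
class_stats <- function(tab) {
  n <- sum(tab)
  classes <- colnames(tab)
  per <- purrr::map(classes, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[cl, ]) - tp
    fn <- sum(tab[, cl]) - tp
    tn <- n - tp - fp - fn
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    ppv <- tp / (tp + fp)
    npv <- tn / (tn + fn)
    tibble::tibble(
      Class = cl,
      N = tp + fn,
      `Sensitivity/Recall/TPR` = sens,
      `Specificity/TNR` = spec,
      `PPV/Precision` = ppv,
      NPV = npv,
      `F1/Dice` = 2 * ppv * sens / (ppv + sens),
      Prevalence = (tp + fn) / n,
      `Detection Rate` = tp / n,
      `Detection Prevalence` = (tp + fp) / n,
      `Balanced Accuracy` = (sens + spec) / 2,
      FDR = 1 - ppv,
      FOR = 1 - npv,
      `FPR/Fallout` = 1 - spec,
      FNR = 1 - sens
    )
  })
  per <- dplyr::bind_rows(per)
  avg <- per |>
    dplyr::summarise(dplyr::across(-"Class", mean)) |>
    dplyr::mutate(Class = "Average", .before = 1L)
  dplyr::bind_rows(per, avg)
}

#' Reciprocal RMSE between predicted and true relationship degrees
#'
#' Root-mean-square error of reciprocal-transformed degrees,
#' `sqrt(mean((1/(T + 0.5) - 1/(P + 0.5))^2))` over all label pairs. The
#' reciprocal transform makes confusing close relatives (degree 0 vs 1) far
#' costlier than confusing distant ones (degree 4 vs 5), which plain accuracy
#' treats identically; the +0.5 offset keeps degree 0 finite.
#'
#' Labels must be numeric degree strings or `"unrelated"`; unrelated is
#' scored as one degree beyond the deepest resolved degree
#' (`max_degree + 1`).
#'
#' @param target,prediction Vectors of class labels, same length.
#' @param max_degree Degree assigned past the resolved range: `"unrelated"`
#'   maps to `max_degree + 1`. Defaults to the largest numeric degree
#'   observed in the labels.
#' @return A non-negative scalar; 0 iff every prediction matches its target.
#' @examples
#' recip_rmse(target = c("0", "1"), prediction = c("0", "unrelated"))
#' @export
recip_rmse <- function(target, prediction, max_degree = NULL) {
  stopifnot(length(target) == length(prediction), length(target) > 0L)
  t_lab <- as.character(target)
  p_lab <- as.character(prediction)
  all_lab <- c(t_lab, p_lab)
  bad <- !grepl("^[0-9]+$", all_lab) & all_lab != "unrelated"
  if (any(bad)) {
    stop("labels must be numeric degrees or \"unrelated\"; offending label: ",
      sQuote(all_lab[bad][1L]),
      call. = FALSE
    )
  }
  if (is.null(max_degree)) {
    nums <- suppressWarnings(as.integer(all_lab[grepl("^[0-9]+$", all_lab)]))
    max_degree <- if (length(nums)) max(nums) else 0L
  }
  to_deg <- function(x) {
    d <- rep(max_degree + 1L, length(x))
    num <- x != "unrelated"
    d[num] <- as.integer(x[num])
    d
  }
  tt <- to_deg(t_lab)
  pp <- to_deg(p_lab)
  sqrt(mean((1 / (tt + 0.5) - 1 / (pp + 0.5))^2))
}

#' @export
print.kin_confusion <- function(x, ...) {
  cat("Benchmark of degree classification\n\n$Accuracy\n")
  print(x$Accuracy)
  cat("\n$Other\n")
  print(x$Other)
  cat("\n$Table\n")
  print(x$Table)
  cat("\n$recip_rmse\n")
  print(x$recip_rmse)
  invisible(x)
}

#' Tidy per-class benchmark statistics
#'
#' Broom-style accessor: the per-class contingency statistics of a
#' [confusion_matrix()] result in long format, one row per (statistic,
#' class).
#'
#' @param x A `kin_confusion` object.
#' @param ... Unused.
#' @return A tibble with columns `statistic`, `class`, `value`.
#' @method tidy kin_confusion
#' @export
tidy.kin_confusion <- function(x, ...) {
  other <- x$Other
  if (!all(c("Statistic", "Class", "Value") %in% names(other))) {
    other <- other |>
      tidyr::pivot_longer(-"Class", names_to = "Statistic", values_to = "Value")
  }
  other |>
    dplyr::transmute(
      statistic = .data$Statistic,
      class = .data$Class,
      value = .data$Value
    )
}

#' One-row summary of a degree-classification benchmark
#'
#' @param x A `kin_confusion` object.
#' @param ... Unused.
#' @return A one-row tibble: accuracy, its 95% bounds, guessing rate,
#'   p-value, number of pairs, and reciprocal RMSE.
#' @method glance kin_confusion
#' @export
glance.kin_confusion <- function(x, ...) {
  tibble::tibble(
    accuracy = x$Accuracy$Accuracy,
    conf.low = x$Accuracy$`Accuracy LL`,
    conf.high = x$Accuracy$`Accuracy UL`,
    guessing = x$Accuracy$`Accuracy Guessing`,
    p.value = x$Accuracy$`Accuracy P-value`,
    n = sum(x$Table),
    recip_rmse = x$recip_rmse
  )
}

#' Contingency heatmap for a degree-classification benchmark
#'
#' @param object A `kin_confusion` object.
#' @param ... Unused.
#' @return A ggplot tile plot of the predicted-by-target table.
#' @method autoplot kin_confusion
#' @export
autoplot.kin_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(object$Table))
  names(df) <- c("Predicted", "Target", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Target, y = .data$Predicted)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n), color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$Table))) +
    ggplot2::labs(title = "Predicted vs. true relationship degree") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
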