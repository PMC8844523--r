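test_that("reference confusion table reproduces its hand-verified statistics", {
  pairs <- expand_confusion_table(reference_confusion_table())
  cm <- confusion_matrix(prediction = pairs$predicted, target = pairs$target)

  expect_equal(cm$Accuracy$Accuracy, 234 / 288)
  expect_equal(cm$Accuracy$`Accuracy Guessing`, 1 / 3)
  expect_equal(signif(cm$Accuracy$`Accuracy LL`, 3), 0.763)
  expect_equal(signif(cm$Accuracy$`Accuracy UL`, 3), 0.856)
  expect_equal(signif(cm$Accuracy$`Accuracy P-value`, 3), 1.09e-62)

  expect_equal(unclass(reference_confusion_table()), cm$Table)

  stats3 <- cm$Other[cm$Other$Class == "3", ]
  expect_equal(stats3$N, 8)
  expect_equal(stats3$`Sensitivity/Recall/TPR`, 0.75)
  expect_equal(stats3$`PPV/Precision`, 0.25)
  expect_equal(stats3$`F1/Dice`, 0.375)
  expect_equal(signif(stats3$`Specificity/TNR`, 3), 0.936)
  expect_equal(signif(stats3$NPV, 3), 0.992)
  stats0 <- cm$Other[cm$Other$Class == "0", ]
  expect_equal(stats0$`Sensitivity/Recall/TPR`, 0.75)

  expect_equal(cm$recip_rmse, 0.4665970746, tolerance = 1e-9)
})

test_that("per-class statistics satisfy their accounting identities", {
  pairs <- expand_confusion_table(reference_confusion_table())
  cm <- confusion_matrix(prediction = pairs$predicted, target = pairs$target)
  per <- cm$Other[cm$Other$Class != "Average", ]
  avg <- cm$Other[cm$Other$Class == "Average", ]

  # macro average is the unweighted mean of the class rows
  expect_equal(
    as.numeric(avg[-1]),
    unname(colMeans(as.matrix(per[-1])))
  )
  # detection rates sum to the overall accuracy
  expect_equal(sum(per$`Detection Rate`), cm$Accuracy$Accuracy)
  expect_equal(sum(per$Prevalence), 1)
  # complementary statistics
  expect_equal(per$FDR, 1 - per$`PPV/Precision`)
  expect_equal(per$FNR, 1 - per$`Sensitivity/Recall/TPR`)
  expect_equal(per$`FPR/Fallout`, 1 - per$`Specificity/TNR`)
  expect_equal(
    per$`Balanced Accuracy`,
    (per$`Sensitivity/Recall/TPR` + per$`Specificity/TNR`) / 2
  )
})

test_that("statistics agree with caret's confusionMatrix", {
  skip_if_not_installed("caret")
  labs <- c("0", "1", "2", "unrelated")
  set <- withr::with_seed(5, list(
    target = sample(labs, 400, replace = TRUE, prob = c(.3, .3, .2, .2)),
    predicted = sample(labs, 400, replace = TRUE)
  ))
  cm <- confusion_matrix(prediction = set$predicted, target = set$target)
  ref <- caret::confusionMatrix(
    data = factor(set$predicted, levels = labs),
    reference = factor(set$target, levels = labs)
  )
  expect_equal(cm$Accuracy$Accuracy, unname(ref$overall["Accuracy"]))
  expect_equal(cm$Accuracy$`Accuracy LL`, unname(ref$overall["AccuracyLower"]))
  expect_equal(cm$Accuracy$`Accuracy UL`, unname(ref$overall["AccuracyUpper"]))
  expect_equal(
    cm$Accuracy$`Accuracy Guessing`,
    unname(ref$overall["AccuracyNull"])
  )
  expect_equal(
    cm$Accuracy$`Accuracy P-value`,
    unname(ref$overall["AccuracyPValue"])
  )
  per <- cm$Other[cm$Other$Class != "Average", ]
  expect_equal(per$`Sensitivity/Recall/TPR`, unname(ref$byClass[, "Sensitivity"]))
  expect_equal(per$`Specificity/TNR`, unname(ref$byClass[, "Specificity"]))
  expect_equal(per$`PPV/Precision`, unname(ref$byClass[, "Pos Pred Value"]))
  expect_equal(per$`F1/Dice`, unname(ref$byClass[, "F1"]))
  expect_equal(per$`Balanced Accuracy`, unname(ref$byClass[, "Balanced Accuracy"]))
})

test_that("perfect predictions score accuracy 1 and reciprocal RMSE 0", {
  target <- rep(c("0", "1", "2", "unrelated"), times = c(5, 7, 3, 10))
  cm <- confusion_matrix(prediction = target, target = target)
  expect_equal(cm$Accuracy$Accuracy, 1)
  per <- cm$Other[cm$Other$Class != "Average", ]
  expect_true(all(per$`Sensitivity/Recall/TPR` == 1))
  expect_equal(cm$recip_rmse, 0)
})

test_that("reciprocal RMSE matches direct substitution and is symmetric", {
  # single pair, degree 0 called as 1: |1/0.5 - 1/1.5| = 4/3
  expect_equal(recip_rmse(target = "0", prediction = "1"), 4 / 3)
  expect_equal(recip_rmse(target = "1", prediction = "0"), 4 / 3)

  pairs <- expand_confusion_table(reference_confusion_table())
  fwd <- recip_rmse(target = pairs$target, prediction = pairs$predicted)
  rev <- recip_rmse(target = pairs$predicted, prediction = pairs$target)
  expect_equal(fwd, rev)
  perm <- withr::with_seed(3, sample(length(pairs$target)))
  expect_equal(
    recip_rmse(target = pairs$target[perm], prediction = pairs$predicted[perm]),
    fwd
  )
})

test_that("misclassifying close relatives costs more than distant ones", {
  pen <- function(a, b) recip_rmse(target = a, prediction = b, max_degree = 10)
  base <- pen("0", "1")
  for (d in 1:8) {
    expect_gt(base, pen(as.character(d), as.character(d + 1)))
  }
  # and the penalty decays monotonically along the degree ladder
  steps <- vapply(
    0:8,
    function(d) pen(as.character(d), as.character(d + 1)),
    numeric(1)
  )
  expect_true(all(diff(steps) < 0))
})

test_that("longer format and label-universe handling work", {
  cm <- confusion_matrix(
    prediction = c("0", "3", "1"), # "3" never appears as a target
    target = c("0", "1", "1"),
    longer = TRUE
  )
  expect_equal(names(cm$Other), c("Statistic", "Class", "Value"))
  expect_true("3" %in% colnames(cm$Table))
  expect_equal(sum(cm$Table[, "3"]), 0)

  wide <- confusion_matrix(prediction = c("0", "3", "1"), target = c("0", "1", "1"))
  long_from_wide <- tidy(wide)
  expect_equal(
    dplyr::arrange(tidy(cm), .data$statistic, .data$class),
    dplyr::arrange(long_from_wide, .data$statistic, .data$class)
  )
  g <- glance(wide)
  expect_equal(g$accuracy, 2 / 3)
  expect_equal(g$n, 3L)
})

test_that("degenerate and invalid inputs are rejected cleanly", {
  expect_error(confusion_matrix(character(0), character(0)), "no label pairs")
  expect_error(confusion_matrix("0", c("0", "1")), "same length")
  expect_error(
    recip_rmse(target = "first", prediction = "0"),
    "first"
  )
})
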