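lung_lda_cm <- function()
  confusion_matrix(
    rep(c("adeno", "neuro", "squam"), times = c(999, 999, 999)),
    c(rep("adeno", 989), rep("squam", 10),
      rep("adeno", 1), rep("neuro", 998),
      rep("adeno", 16), rep("squam", 983)),
    class_names = c("adeno", "neuro", "squam"))

test_that("confusion matrix follows the rows-true / columns-predicted convention", {
  cm <- lung_lda_cm()
  expect_equal(sum(cm), 2997)
  expect_equal(unname(diag(unclass(cm))), c(989, 998, 983))
  expect_equal(unclass(cm)["adeno", "squam"], 10, ignore_attr = TRUE)
  expect_equal(unclass(cm)["squam", "adeno"], 16, ignore_attr = TRUE)
  y <- factor(c("a", "a", "b"))
  expect_equal(sum(confusion_matrix(y, factor(c("a", "b", "b")))), 3)
  expect_error(confusion_matrix(y, factor(c("a", "b", "z")),
                                class_names = c("a", "b")), "outside")
})

test_that("the published 3-class worked example reproduces its printed metrics", {
  ov <- overall_metrics(lung_lda_cm())
  expect_equal(round(ov$accuracy, 2), 99.10)
  expect_equal(round(ov$uar, 2), 99.10)
  expect_equal(round(ov$uap, 2), 99.10)
  expect_equal(round(ov$f1, 2), 99.10)
})

test_that("overall metrics on hand-computed and degenerate matrices", {
  ov <- overall_metrics(matrix(c(3, 1, 2, 4), 2, 2, byrow = TRUE))
  expect_equal(round(ov$accuracy, 2), 70.00)
  expect_equal(round(ov$uar, 2), 70.83)      # (3/4 + 4/6)/2
  expect_equal(round(ov$uap, 2), 70.00)      # (3/5 + 4/5)/2
  ident <- overall_metrics(diag(5))
  expect_equal(unlist(ident[c("accuracy", "uar", "uap", "f1")]),
               c(accuracy = 100, uar = 100, uap = 100, f1 = 100))
  expect_warning(overall_metrics(matrix(c(2, 1, 0, 0), 2, 2, byrow = TRUE)),
                 "absent")
})

test_that("per-class metrics: printed sensitivity and hand-computed cells", {
  # 997 of 999 correct -> 99.80% sensitivity
  cm <- matrix(c(997, 2, 5, 95), 2, 2, byrow = TRUE)
  pc <- per_class_metrics(cm)
  expect_equal(round(pc$sensitivity[1], 2), 99.80)

  pc2 <- per_class_metrics(matrix(c(3, 1, 2, 4), 2, 2, byrow = TRUE))
  expect_equal(round(pc2$sensitivity[1], 2), 75.00)
  expect_equal(round(pc2$specificity[1], 2), 66.67)
  expect_equal(round(pc2$precision[1], 2), 60.00)
  # macro row is the unweighted mean of per-class values
  expect_equal(pc2$sensitivity[3], mean(pc2$sensitivity[1:2]))

  perfect <- per_class_metrics(diag(c(5, 7)))
  expect_true(all(unlist(perfect[1:2, -1]) == 100))
})

test_that("UAR and UAP equal accuracy for symmetric balanced matrices", {
  cm <- matrix(c(90, 10, 10, 90), 2, 2)
  ov <- overall_metrics(cm)
  expect_equal(ov$uar, ov$accuracy)
  expect_equal(ov$uap, ov$accuracy)
})

test_that("Wilson intervals reproduce published values and basic properties", {
  expect_equal(wilson_interval(6400, 6400), c(lower = 99.94, upper = 100.00))
  expect_equal(wilson_interval(4186, 4261), c(lower = 97.80, upper = 98.59))
  # (0, n) mirrors (n, n) around 50
  lo <- wilson_interval(0, 123); hi <- wilson_interval(123, 123)
  expect_equal(unname(lo), rev(100 - unname(hi)))
  # interval contains the point estimate and stays in [0, 100]
  set.seed(2)
  for (i in 1:25) {
    n <- sample(5:500, 1); s <- sample(0:n, 1)
    ci <- wilson_interval(s, n)
    expect_true(ci["lower"] <= 100 * s / n + 1e-9)
    expect_true(ci["upper"] >= 100 * s / n - 1e-9)
    expect_true(ci["lower"] >= 0 && ci["upper"] <= 100)
  }
  expect_error(wilson_interval(1, 0), "positive")
})

test_that("McNemar counts, statistic and symmetry", {
  mk <- function(pa, pb, truth) list(
    A = gptnext:::prediction_set(truth, pa, "A"),
    B = gptnext:::prediction_set(truth, pb, "B"))
  truth <- factor(rep("x", 20), levels = c("x", "y"))
  # b = 10 (A right, B wrong), c = 0
  p <- mk(truth, factor(c(rep("y", 10), rep("x", 10)), levels = c("x", "y")),
          truth)
  res <- mcnemar(p$A, p$B)
  expect_equal(res$b, 10); expect_equal(res$c, 0)
  expect_equal(res$chi2, 8.1)              # (10 - 1)^2 / 10
  swapped <- mcnemar(p$B, p$A)
  expect_equal(swapped$chi2, res$chi2)
  expect_equal(swapped$p, res$p)

  same <- mcnemar(p$A, p$A)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)

  # b = c, uncorrected -> chi2 = 0, p = 1
  pa <- factor(c("y", "x", rep("x", 18)), levels = c("x", "y"))
  pb <- factor(c("x", "y", rep("x", 18)), levels = c("x", "y"))
  bc <- mcnemar(gptnext:::prediction_set(truth, pa, "A"),
                gptnext:::prediction_set(truth, pb, "B"), correction = FALSE)
  expect_equal(bc$chi2, 0); expect_equal(bc$p, 1)
})

test_that("McNemar agrees with the stats-package implementation", {
  set.seed(14)
  truth <- factor(sample(c("a", "b"), 120, TRUE))
  predA <- factor(ifelse(runif(120) < 0.8, as.character(truth),
                         sample(c("a", "b"), 120, TRUE)))
  predB <- factor(ifelse(runif(120) < 0.6, as.character(truth),
                         sample(c("a", "b"), 120, TRUE)))
  ours <- mcnemar(gptnext:::prediction_set(truth, predA, "A"),
                  gptnext:::prediction_set(truth, predB, "B"))
  tab <- table(A = predA == truth, B = predB == truth)
  ref <- stats::mcnemar.test(tab)
  expect_equal(ours$chi2, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
})

test_that("metrics_report assembles all published-table components", {
  set.seed(15)
  truth <- factor(sample(c("a", "b", "c"), 90, TRUE))
  pred <- factor(ifelse(runif(90) < 0.9, as.character(truth),
                        sample(c("a", "b", "c"), 90, TRUE)),
                 levels = levels(truth))
  rep_ <- metrics_report(gptnext:::prediction_set(truth, pred, "test"))
  expect_s3_class(rep_, "gptnext_report")
  expect_equal(sum(rep_$confusion), 90)
  expect_true(all(c("accuracy", "uar", "uap", "f1") %in% names(rep_$overall)))
  expect_equal(nrow(rep_$per_class), 4)  # 3 classes + macro
  expect_true(rep_$ci["lower"] <= rep_$overall$accuracy)
  expect_output(print(rep_), "UAR")
})
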