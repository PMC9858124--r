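test_that("confusion counts match hand enumeration", {
  cc <- confusion_counts(rep("tremor", 10), rep("tremor", 10))
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 10, tn = 0, fp = 0, fn = 0))
  y <- c("tremor", "tremor", "tremor", "no_tremor", "no_tremor")
  p <- c("tremor", "tremor", "no_tremor", "tremor", "no_tremor")
  cc2 <- confusion_counts(y, p)
  expect_equal(unlist(cc2[c("tp", "fn", "fp", "tn")]),
               c(tp = 2, fn = 1, fp = 1, tn = 1))
  inv <- confusion_counts(y, ifelse(y == "tremor", "no_tremor", "tremor"))
  expect_equal(inv$tp + inv$tn, 0)
  expect_error(confusion_counts(c("a", "b", "c"), c("a", "b", "c")),
               "binary")
})

test_that("the five scores match direct arithmetic on the worked example", {
  cc <- structure(list(tp = 8, tn = 6, fp = 2, fn = 4, n = 20),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$precision, 0.8, tolerance = 1e-4)
  expect_equal(m$recall, 0.6667, tolerance = 1e-4)
  expect_equal(m$f1, 0.7273, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.7, tolerance = 1e-4)
  expect_equal(m$specificity, 0.75, tolerance = 1e-4)

  perfect <- classification_metrics(
    structure(list(tp = 50, tn = 50, fp = 0, fn = 0, n = 100),
              class = "confusion_counts"))
  expect_equal(unlist(perfect[c("precision", "recall", "specificity",
                                "accuracy", "f1")]),
               c(precision = 1, recall = 1, specificity = 1, accuracy = 1,
                 f1 = 1))
  sym <- classification_metrics(
    structure(list(tp = 1, tn = 1, fp = 1, fn = 1, n = 4),
              class = "confusion_counts"))
  expect_true(all(unlist(sym[c("precision", "recall", "specificity",
                               "accuracy", "f1")]) == 0.5))
})

test_that("zero-denominator metrics report 0 with a flag", {
  m <- classification_metrics(
    structure(list(tp = 0, tn = 10, fp = 0, fn = 0, n = 10),
              class = "confusion_counts"))
  expect_equal(m$precision, 0)
  expect_true("precision" %in% m$undefined)
  expect_equal(m$specificity, 1)
})

test_that("metric formulas agree with brute-force counting on random labels", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    y <- sample(c("tremor", "no_tremor"), n, replace = TRUE)
    p <- sample(c("tremor", "no_tremor"), n, replace = TRUE)
    m <- classification_metrics(confusion_counts(y, p))
    # independent oracle: direct counting over the label vectors
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (y[j] == "tremor" && p[j] == "tremor") tp <- tp + 1
      else if (y[j] == "no_tremor" && p[j] == "no_tremor") tn <- tn + 1
      else if (y[j] == "no_tremor" && p[j] == "tremor") fp <- fp + 1
      else fn <- fn + 1
    }
    expect_equal(c(m$counts$tp, m$counts$tn, m$counts$fp, m$counts$fn),
                 c(tp, tn, fp, fn))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$accuracy, (tp + tn) / n)
    # harmonic-mean bound
    expect_lte(m$f1, 2 * min(m$precision, m$recall) + 1e-12)
    # balanced test sets: accuracy is the mean of recall and specificity
    if (tp + fn == tn + fp && tp + fn > 0) {
      expect_equal(m$accuracy, (m$recall + m$specificity) / 2)
    }
  }
})

test_that("comparison report aggregates with population SD", {
  mk <- function(f1, model, modality) {
    tp <- round(100 * f1)  # crude counts giving the wanted f1 scale
    structure(list(precision = f1, recall = f1, specificity = f1,
                   accuracy = f1, f1 = f1, counts = NULL, model = model,
                   modality = modality, undefined = character(0)),
              class = "metrics_report")
  }
  single <- compare_reports(list(mk(0.9, "knn", "kinematics")))
  expect_equal(single$by_model$f1_mean, 0.9)
  expect_equal(single$by_model$f1_sd, 0)

  reps <- list(mk(0.9, "knn", "kinematics"), mk(0.8, "knn", "envelope"),
               mk(0.7, "knn", "raw"))
  cmp <- compare_reports(reps)
  expect_equal(cmp$by_model$f1_mean, 0.8)
  expect_equal(cmp$by_model$f1_sd, sqrt(mean((c(0.9, 0.8, 0.7) - 0.8)^2)))
  expect_equal(dim(cmp$f1_matrix), c(1, 3))

  expect_error(compare_reports(list()), "empty")
  expect_error(compare_reports(list(mk(0.9, "knn", "kinematics"),
                                    mk(0.8, "knn", "kinematics"))),
               "duplicate")
})
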