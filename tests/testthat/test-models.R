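# A small linearly-inseparable-but-easy dataset: tremor windows carry a
# 6 Hz oscillation with random phase, controls carry smooth noise.
make_osc_dataset <- function(n, wl = 50, amp = 0.25, seed = 1) {
  set.seed(seed)
  t <- (seq_len(wl) - 1) / 50
  x <- matrix(rnorm(n * wl, 0.5, 0.05), n, wl)
  y <- rep(c("tremor", "no_tremor"), length.out = n)
  for (i in which(y == "tremor")) {
    x[i, ] <- x[i, ] + amp * sin(2 * pi * 6 * t + runif(1, 0, 2 * pi))
  }
  list(x = x, y = y)
}

test_that("single-point grid is selected verbatim with one CV row", {
  d <- make_osc_dataset(120)
  space <- data.frame(neighbors = 3, leaf_size = 30, metric = "euclidean",
                      stringsAsFactors = FALSE)
  m <- tune_classical("knn", d$x, d$y, space = space, k = 5, seed = 2)
  expect_equal(nrow(m$cv_table), 1)
  expect_equal(m$params$neighbors, 3)
  expect_equal(m$selection_metric, "f1")
})

test_that("1-NN memorizes its training data", {
  d <- make_osc_dataset(60)
  space <- data.frame(neighbors = 1, leaf_size = 30, metric = "euclidean",
                      stringsAsFactors = FALSE)
  m <- tune_classical("knn", d$x, d$y, space = space, k = 5, seed = 2)
  expect_equal(predict(m, d$x), d$y)
})

test_that("chebyshev distances match a direct R computation", {
  set.seed(3)
  a <- matrix(rnorm(40), 8, 5)
  b <- matrix(rnorm(30), 6, 5)
  D <- tremorclass:::knn_distance(a, b, "chebyshev")
  ref <- outer(seq_len(6), seq_len(8),
               Vectorize(function(i, j) max(abs(b[i, ] - a[j, ]))))
  expect_equal(D, ref, tolerance = 1e-12)
  # euclidean path against dist()
  De <- tremorclass:::knn_distance(a, a, "euclidean")
  expect_equal(De, as.matrix(dist(a)), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("all classical families separate the oscillation dataset", {
  d <- make_osc_dataset(300, seed = 5)
  test <- make_osc_dataset(100, seed = 6)
  for (fam in c("knn", "svm", "rf")) {
    m <- tune_classical(fam, d$x, d$y, k = 5, seed = 2)
    f1 <- classification_metrics(
      confusion_counts(test$y, predict(m, test$x)))$f1
    expect_gt(f1, 0.9)
    expect_true(all(c("cv_f1_mean") %in% names(m$cv_table)))
  }
})

test_that("cross-validation guards against degenerate fold counts", {
  d <- make_osc_dataset(10)
  expect_error(tune_classical("knn", d$x, d$y, k = 10, seed = 1), "folds")
})

test_that("LSTM gradients match central finite differences", {
  set.seed(7)
  H <- 3
  u <- function(nr, nc) matrix(rnorm(nr * nc, 0, 0.4), nr, nc)
  w <- list(W1 = u(4 * H, 1), U1 = u(4 * H, H), b1 = rnorm(4 * H, 0, 0.2),
            W2 = u(4 * H, H), U2 = u(4 * H, H), b2 = rnorm(4 * H, 0, 0.2),
            wout = rnorm(H, 0, 0.4), bout = 0.1)
  X <- matrix(rnorm(4 * 6), 4, 6)
  y <- c(1, 0, 1, 0)
  lg <- tremorclass:::lstm_loss_grad_cpp(w, X, y)
  eps <- 1e-6
  for (nm in names(w)) {
    for (i in sample(length(w[[nm]]), min(4, length(w[[nm]])))) {
      wp <- w; wm <- w
      wp[[nm]][i] <- wp[[nm]][i] + eps
      wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (tremorclass:::lstm_loss_grad_cpp(wp, X, y)$loss -
              tremorclass:::lstm_loss_grad_cpp(wm, X, y)$loss) / (2 * eps)
      expect_equal(lg$grad[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("LSTM training is deterministic and checkpoints on validation loss", {
  d <- make_osc_dataset(200, seed = 8)
  v <- make_osc_dataset(60, seed = 9)
  m1 <- train_lstm(d$x, d$y, v$x, v$y, hidden_size = 8, epochs = 6, seed = 4)
  m2 <- train_lstm(d$x, d$y, v$x, v$y, hidden_size = 8, epochs = 6, seed = 4)
  expect_identical(m1$val_loss, m2$val_loss)
  expect_identical(m1$weights, m2$weights)
  expect_equal(m1$best_val_loss, min(m1$val_loss))
  expect_equal(m1$val_loss[m1$best_epoch], m1$best_val_loss)
})

test_that("LSTM degenerate target: constant labels drive loss to zero", {
  set.seed(10)
  x <- matrix(rnorm(80 * 20, 0.5, 0.1), 80, 20)
  y <- rep("tremor", 80)
  m <- train_lstm(x, y, x[1:10, ], y[1:10], hidden_size = 6, epochs = 50,
                  seed = 1)
  expect_lt(min(m$train_loss), 0.05)  # below any nondegenerate entropy
})

test_that("LSTM predictions: sigmoid range, permutation equivariance, guards", {
  d <- make_osc_dataset(200, seed = 11)
  v <- make_osc_dataset(60, seed = 12)
  m <- train_lstm(d$x, d$y, v$x, v$y, hidden_size = 8, epochs = 4, seed = 2)
  s <- predict(m, v$x, type = "score")
  expect_true(all(s > 0 & s < 1))
  perm <- sample(nrow(v$x))
  expect_identical(predict(m, v$x)[perm], predict(m, v$x[perm, ]))
  expect_error(predict(m, v$x[, 1:10]), "length")
  expect_error(train_lstm(d$x, d$y, d$x[0, , drop = FALSE], character(0),
                          epochs = 1), "validation")
})

test_that("shuffled labels yield chance-level scores (leakage guard)", {
  d <- make_osc_dataset(600, seed = 13)
  set.seed(14)
  y_shuf <- sample(d$y)
  tr <- 1:420
  te <- 421:600
  for (fam in c("knn", "svm", "rf")) {
    m <- tune_classical(fam, d$x[tr, ], y_shuf[tr], k = 5, seed = 3)
    f1 <- classification_metrics(
      confusion_counts(y_shuf[te], predict(m, d$x[te, ])))$f1
    expect_gt(f1, 0.35)
    expect_lt(f1, 0.65)
  }
})

test_that("test partitions are read exactly once per evaluation", {
  d <- make_osc_dataset(200, seed = 15)
  tr <- 1:140
  te <- 141:200
  guard <- tremorclass:::counted_view(d$x[te, ])
  m <- tune_classical("knn", d$x[tr, ], d$y[tr], k = 5, seed = 1)
  pred <- predict(m, guard$get())
  classification_metrics(confusion_counts(d$y[te], pred))
  expect_identical(guard$reads(), 1L)
})
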