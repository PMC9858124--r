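# Classifier families: distance-weighted KNN (exact brute-force search),
# RBF SVM (e1071), random forest (ranger), each tuned by stratified 10-fold
# cross-validated grid search on mean F1, plus prediction methods.

#' Default hyperparameter grids
#'
#' Compact grids around the operating points that work well for one-second
#' tremor windows. KNN fixes distance weighting; exact neighbour search
#' makes the tree leaf size a bookkeeping parameter that cannot change
#' predictions (it is kept in the grid for provenance). SVM fixes the RBF
#' kernel; RF fixes the minimum samples per leaf at 2 and the square-root
#' feature rule.
#'
#' @param family `"knn"`, `"svm"`, `"rf"` or `"lstm"`.
#' @return A data frame (one row per grid point) for the classical
#'   families, or a list of vectors for `"lstm"`.
#' @export
default_hyperparam_space <- function(family = c("knn", "svm", "rf", "lstm")) {
  family <- match.arg(family)
  switch(family,
    knn = expand.grid(neighbors = c(2, 3, 6, 10), leaf_size = 30,
                      metric = c("euclidean", "chebyshev"),
                      stringsAsFactors = FALSE),
    svm = expand.grid(cost = c(1, 10), gamma = c(1, 0.1, 0.01)),
    rf = expand.grid(trees = c(100, 110), max_features = "sqrt",
                     min_samples_leaf = 2, stringsAsFactors = FALSE),
    lstm = list(hidden_size = c(20, 35, 50),
                learning_rate = c(0.005, 0.001, 0.0001)))
}

# ---- distance-weighted KNN (exact search) --------------------------------

knn_distance <- function(train_x, test_x, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
      2 * tcrossprod(test_x, train_x)
    sqrt(pmax(d2, 0))
  } else if (metric == "chebyshev") {
    t(chebyshev_dist_cpp(train_x, test_x))
  } else {
    stop("unsupported metric: ", metric)
  }
}

# Distance-weighted vote (weight 1/d). Test points coincident with training
# points are decided by the zero-distance neighbours alone, as in standard
# distance-weighted KNN implementations.
knn_vote <- function(D, train_y, k) {
  apply(D, 1, function(d) {
    nb <- order(d)[seq_len(k)]
    dz <- d[nb]
    if (any(dz == 0)) {
      ties <- table(train_y[nb[dz == 0]])
    } else {
      ties <- tapply(1 / dz, train_y[nb], sum)
    }
    names(ties)[which.max(ties)]
  })
}

# ---- family back-ends -----------------------------------------------------

fit_family <- function(family, x, y, par, seed) {
  yf <- factor(y, levels = c("no_tremor", "tremor"))
  switch(family,
    knn = list(train_x = x, train_y = yf, k = par$neighbors,
               metric = par$metric),
    svm = e1071::svm(x = x, y = yf, kernel = "radial", cost = par$cost,
                     gamma = par$gamma, scale = FALSE),
    rf = ranger::ranger(
      x = as.data.frame(x), y = yf, num.trees = par$trees,
      mtry = max(1L, floor(sqrt(ncol(x)))), min.bucket = par$min_samples_leaf,
      seed = seed, num.threads = 1)
  )
}

predict_family <- function(family, fit, x) {
  switch(family,
    knn = knn_vote(knn_distance(fit$train_x, x, fit$metric), fit$train_y,
                   fit$k),
    svm = as.character(predict(fit, x)),
    rf = as.character(predict(fit, as.data.frame(x),
                              num.threads = 1)$predictions)
  )
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune a classical classifier by cross-validated grid search
#'
#' Exhaustive search over the hyperparameter grid with stratified k-fold
#' cross-validation (default k = 10); the selection metric is the mean F1
#' score across folds (Tremor positive). The winning configuration is refit
#' on the full training partition. Inputs are the flat window sample
#' vectors; no features are extracted.
#'
#' @param family `"knn"`, `"svm"` or `"rf"`.
#' @param x Training windows, n x window_len matrix (normalized).
#' @param y Training labels (`"tremor"`/`"no_tremor"`).
#' @param space Hyperparameter grid (default [default_hyperparam_space()]).
#' @param k Number of cross-validation folds (default 10).
#' @param seed Integer seed (fold assignment and stochastic fits).
#' @return A `tremor_model`: `family`, `params` (winning row), `fit`,
#'   `cv_table` (grid with mean CV F1 per point), `selection_metric`.
#' @export
tune_classical <- function(family = c("knn", "svm", "rf"), x, y,
                           space = NULL, k = 10, seed = 1L) {
  family <- match.arg(family)
  if (is.null(space)) space <- default_hyperparam_space(family)
  y <- as.character(y)
  if (min(table(y)) < k) stop("fewer samples per class than folds")
  fold <- stratified_folds(y, k, seed)

  cv_f1 <- matrix(NA_real_, nrow(space), k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (family == "knn") {
      # distances are shared across neighbour counts: compute once per metric
      for (metric in unique(space$metric)) {
        D <- knn_distance(x[tr, , drop = FALSE], x[!tr, , drop = FALSE],
                          metric)
        yf <- factor(y[tr], levels = c("no_tremor", "tremor"))
        for (g in which(space$metric == metric)) {
          pred <- knn_vote(D, yf, space$neighbors[g])
          cv_f1[g, f] <- classification_metrics(
            confusion_counts(y[!tr], pred))$f1
        }
      }
    } else {
      for (g in seq_len(nrow(space))) {
        fit <- fit_family(family, x[tr, , drop = FALSE], y[tr],
                          space[g, , drop = FALSE], seed + f)
        pred <- predict_family(family, fit, x[!tr, , drop = FALSE])
        cv_f1[g, f] <- classification_metrics(
          confusion_counts(y[!tr], pred))$f1
      }
    }
  }
  cv_table <- cbind(space, cv_f1_mean = rowMeans(cv_f1))
  best <- which.max(cv_table$cv_f1_mean)
  fit <- fit_family(family, x, y, space[best, , drop = FALSE], seed)
  structure(list(family = family, params = space[best, , drop = FALSE],
                 fit = fit, cv_table = cv_table, selection_metric = "f1",
                 seed = seed),
            class = c(paste0("tremor_", family), "tremor_model"))
}

#' Train the two-layer LSTM classifier
#'
#' Scalar-input sequences feed two stacked LSTM layers of equal hidden
#' size; a linear readout of the last hidden state of layer 2, squashed by a
#' sigmoid, gives the tremor probability. Training minimises binary
#' cross-entropy with Adam and backpropagation through time. After every
#' epoch the validation loss is evaluated and the parameters are
#' checkpointed whenever it improves; the returned model carries the best
#' checkpoint. Fully deterministic for a fixed seed (seeded initialisation,
#' ordered batches).
#'
#' @param x_train,y_train Training windows (n x window_len) and labels.
#' @param x_val,y_val Validation windows and labels (checkpoint criterion).
#' @param hidden_size Hidden units per LSTM layer (both layers equal;
#'   default 35).
#' @param learning_rate Adam learning rate (default 0.005).
#' @param epochs Maximum training epochs (default 50).
#' @param batch_size Mini-batch size (default 64).
#' @param seed Integer seed.
#' @return A `tremor_lstm` model with `weights` (best checkpoint),
#'   `train_loss`/`val_loss` trajectories and `best_epoch`.
#' @export
train_lstm <- function(x_train, y_train, x_val, y_val, hidden_size = 35,
                       learning_rate = 0.005, epochs = 50, batch_size = 64,
                       seed = 1L) {
  if (!nrow(x_val)) stop("empty validation set")
  ytr <- as.numeric(as.character(y_train) == "tremor")
  yvl <- as.numeric(as.character(y_val) == "tremor")
  # internal input standardization (training-partition statistics, stored
  # with the model): [0,1]-normalized windows fluctuate by only a few
  # hundredths, too small to drive the recurrent weights
  mu <- mean(x_train)
  sdv <- stats::sd(as.numeric(x_train))
  if (sdv == 0) stop("degenerate training windows (zero variance)")
  x_train <- (x_train - mu) / sdv
  x_val <- (x_val - mu) / sdv
  H <- hidden_size
  set.seed(seed)
  u <- function(nr, nc, fan_in = H) {
    matrix(stats::runif(nr * nc, -1 / sqrt(fan_in), 1 / sqrt(fan_in)), nr, nc)
  }
  # fan-in-scaled uniform init: the scalar input weights use fan_in = 1, so
  # the input drive matches the recurrent drive in magnitude (a uniform
  # 1/sqrt(H) bound leaves the scalar input ~sqrt(H) times too weak to
  # escape the 0.693 BCE plateau within a desk-scale epoch budget)
  init <- list(W1 = u(4 * H, 1, fan_in = 1), U1 = u(4 * H, H),
               b1 = u(4 * H, 1)[, 1],
               W2 = u(4 * H, H), U2 = u(4 * H, H), b2 = u(4 * H, 1)[, 1],
               wout = u(H, 1)[, 1], bout = stats::runif(1, -1 / sqrt(H), 1 / sqrt(H)))
  # forget-gate bias offset of +1: keeps early memory open and markedly
  # speeds up learning of oscillatory temporal structure
  fg <- (H + 1):(2 * H)
  init$b1[fg] <- init$b1[fg] + 1
  init$b2[fg] <- init$b2[fg] + 1
  order_mat <- t(vapply(seq_len(epochs), function(e) sample(nrow(x_train)),
                        integer(nrow(x_train))))
  res <- lstm_train_cpp(x_train, ytr, x_val, yvl, init, order_mat,
                        as.integer(batch_size), learning_rate)
  structure(list(family = "lstm", input_len = ncol(x_train),
                 params = list(hidden_size = H,
                               learning_rate = learning_rate,
                               epochs = epochs, batch_size = batch_size),
                 input_stats = c(mean = mu, sd = sdv),
                 weights = res$weights, train_loss = res$train_loss,
                 val_loss = res$val_loss, best_epoch = res$best_epoch,
                 best_val_loss = res$best_val_loss, seed = seed),
            class = c("tremor_lstm", "tremor_model"))
}

#' Predict tremor labels from a trained model
#'
#' Classical models apply their native decision rule; the LSTM thresholds
#' its sigmoid score at 0.5. Predictions are stateless across instances.
#'
#' @param object A `tremor_model`.
#' @param newdata Windows matrix with the model's input length.
#' @param type `"label"` (default) or `"score"` (LSTM probability; classical
#'   families return the label either way).
#' @param ... Unused.
#' @return Character vector of labels, or numeric scores for the LSTM with
#'   `type = "score"`.
#' @export
predict.tremor_model <- function(object, newdata, type = c("label", "score"),
                                 ...) {
  type <- match.arg(type)
  expected <- model_input_len(object)
  if (ncol(newdata) != expected) {
    stop("window length ", ncol(newdata), " does not match the model input ",
         "length ", expected)
  }
  if (object$family == "lstm") {
    newdata <- (newdata - object$input_stats[["mean"]]) /
      object$input_stats[["sd"]]
    scores <- as.numeric(lstm_predict_cpp(object$weights, newdata))
    if (type == "score") return(scores)
    return(ifelse(scores > 0.5, "tremor", "no_tremor"))
  }
  predict_family(object$family, object$fit, newdata)
}

model_input_len <- function(model) {
  switch(model$family,
         knn = ncol(model$fit$train_x),
         svm = ncol(model$fit$SV),
         rf = model$fit$num.independent.variables,
         lstm = model$input_len)
}

#' @export
print.tremor_model <- function(x, ...) {
  cat("Tremor classifier:", x$family, "\n")
  if (x$family == "lstm") {
    cat(sprintf("  hidden %d, lr %g, best epoch %d (val loss %.4f)\n",
                x$params$hidden_size, x$params$learning_rate, x$best_epoch,
                x$best_val_loss))
  } else {
    cat("  selected:", paste(names(x$params), unlist(x$params),
                             sep = "=", collapse = ", "),
        sprintf(" (mean CV f1 %.3f)\n",
                max(x$cv_table$cv_f1_mean)))
  }
  invisible(x)
}
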