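#' Round half away from zero to a number of decimals
#'
#' Percentages in all reports use one-decimal half-up rounding (so
#' 63/85 prints as 74.1).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Random training/testing partition
#'
#' Each sample is assigned independently to the training group with
#' probability `train_probability` (non-stratified). If either side
#' comes out empty, the draw is repeated with the seed incremented.
#'
#' @param n number of samples (>= 2).
#' @param train_probability probability of landing in training,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` index vectors and `summary`
#'   (counts plus percentages to one decimal).
#' @export
random_split <- function(n, train_probability = 0.7, seed = 1) {
  stopifnot(train_probability > 0, train_probability < 1)
  if (n < 2L) stop("need at least 2 samples to split")
  s <- seed
  repeat {
    set.seed(s)
    in_train <- stats::runif(n) < train_probability
    if (any(in_train) && any(!in_train)) break
    s <- s + 1L
  }
  train <- which(in_train)
  test <- which(!in_train)
  pct_train <- round_half_up(100 * length(train) / n, 1)
  list(train = train, test = test,
       summary = data.frame(
         group = c("training", "testing"),
         n = c(length(train), length(test)),
         percentage = c(pct_train, round_half_up(100 - pct_train, 1))))
}

#' Per-class and overall percent correct
#'
#' @param model a trained [mlp_train()] model.
#' @param X raw feature matrix/data.frame.
#' @param labels true class labels (no missing values).
#' @return list with `per_class` (data.frame: class, n, correct,
#'   accuracy) and `overall` (percent, one decimal).
#' @export
per_class_accuracy <- function(model, X, labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("unlabelled rows in accuracy evaluation")
  pred <- mlp_predict(model, X)$class
  classes <- sort(unique(labels))
  per <- do.call(rbind, lapply(classes, function(cl) {
    idx <- labels == cl
    data.frame(class = cl, n = sum(idx), correct = sum(pred[idx] == cl),
               accuracy = round_half_up(100 * mean(pred[idx] == cl), 1),
               stringsAsFactors = FALSE)
  }))
  list(per_class = per,
       overall = round_half_up(100 * mean(pred == labels), 1))
}

#' Summarize per-run cross-validation accuracies
#'
#' @param train_acc,test_acc per-run training and testing accuracies
#'   (percent).
#' @param n_train,n_test optional per-run group sizes.
#' @return list of class `cv_report` with the per-run table (`runs`)
#'   and `mean_test` / `mean_train`, one decimal, half-up.
#' @export
cv_report <- function(train_acc, test_acc, n_train = NA, n_test = NA) {
  stopifnot(length(train_acc) == length(test_acc))
  structure(list(
    runs = data.frame(run = seq_along(test_acc),
                      n_train = n_train, n_test = n_test,
                      train_acc = train_acc, test_acc = test_acc),
    mean_train = round_half_up(mean(train_acc), 1),
    mean_test = round_half_up(mean(test_acc), 1)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  print(x$runs, row.names = FALSE)
  cat(sprintf("mean training %.1f%%, mean testing %.1f%%\n",
              x$mean_train, x$mean_test))
  invisible(x)
}

#' Repeated random-split cross-validation
#'
#' `n_runs` independent random partitions (run `r` uses seed
#' `seed + r`); for each, a fresh network is trained on the training
#' group and evaluated on both groups. This repeated random
#' subsampling scheme -- groups re-picked randomly for every run -- is
#' the package's "tenfold cross-validation"; a disjoint k-fold mode is
#' available via `mode = "kfold"`.
#'
#' @param X raw feature matrix/data.frame.
#' @param labels class labels, one per row.
#' @param n_runs number of runs/folds (default 10).
#' @param train_probability per-sample training probability (random
#'   mode; default 0.7).
#' @param hidden hidden-layer width (default 10).
#' @param cfg a [train_config()].
#' @param seed root seed.
#' @param mode `"random"` (default) or `"kfold"`.
#' @return a [cv_report()].
#' @export
repeated_cv <- function(X, labels, n_runs = 10, train_probability = 0.7,
                        hidden = 10, cfg = train_config(), seed = 1,
                        mode = c("random", "kfold")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  stopifnot(n >= 2L, n_runs >= 1L)
  if (mode == "kfold") {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(n_runs), n))
  }
  res <- lapply(seq_len(n_runs), function(r) {
    if (mode == "random") {
      sp <- random_split(n, train_probability, seed + r)
      tr <- sp$train; te <- sp$test
    } else {
      te <- which(fold == r); tr <- which(fold != r)
    }
    model <- mlp_train(X[tr, , drop = FALSE], labels[tr], hidden = hidden,
                       cfg = cfg, seed = seed + r)
    acc_tr <- per_class_accuracy(model, X[tr, , drop = FALSE],
                                 labels[tr])$overall
    acc_te <- per_class_accuracy(model, X[te, , drop = FALSE],
                                 labels[te])$overall
    c(n_train = length(tr), n_test = length(te),
      train = acc_tr, test = acc_te)
  })
  m <- do.call(rbind, res)
  cv_report(m[, "train"], m[, "test"], m[, "n_train"], m[, "n_test"])
}

#' Permutation variable importance
#'
#' Raw importance of a feature is the mean increase in total
#' cross-entropy over `n_permutations` random shuffles of that feature
#' column (negative means clamp at zero); normalized importance scales
#' the raw values so the largest is 100%. This permutation scheme
#' replaces the undocumented importance algorithm of commercial
#' statistical suites; the normalization is identical.
#'
#' @param model trained [mlp_train()] model.
#' @param X raw feature matrix/data.frame.
#' @param labels class labels.
#' @param n_permutations shuffles per feature (default 100).
#' @param seed integer seed.
#' @return data.frame of class `importance_table`: `feature`, `raw`,
#'   `normalized` (percent, one decimal), sorted by decreasing
#'   importance.
#' @export
variable_importance <- function(model, X, labels, n_permutations = 100,
                                seed = 1) {
  stopifnot(inherits(model, "mlp_model"), n_permutations >= 1)
  X <- as.matrix(X)
  labels <- as.character(labels)
  y <- match(labels, model$classes)
  if (anyNA(y)) stop("labels outside the model's classes")
  base <- cross_entropy(mlp_predict(model, X)$prob, y)
  set.seed(seed)
  n <- nrow(X)
  raw <- vapply(seq_len(ncol(X)), function(j) {
    inc <- vapply(seq_len(n_permutations), function(k) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(n), j]
      cross_entropy(mlp_predict(model, Xp)$prob, y) - base
    }, numeric(1))
    max(mean(inc), 0)
  }, numeric(1))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(X)))
  norm <- if (max(raw) > 0) 100 * raw / max(raw) else rep(0, length(raw))
  out <- data.frame(feature = nm, raw = raw,
                    normalized = round_half_up(norm, 1),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$raw), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}
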