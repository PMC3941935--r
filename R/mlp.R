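#' Fit feature standardization parameters
#'
#' Per-feature mean and sample standard deviation (n - 1 denominator),
#' computed from training rows only; applied as `(x - mean) / sd`.
#'
#' @param X numeric matrix or data.frame of training features
#'   (>= 2 rows).
#' @return list of class `standardization` with `mean` and `sd`
#'   vectors. Errors on a constant column, naming the feature.
#' @export
standardize_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("standardization needs at least 2 training rows")
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- paste0("column ", bad)
    stop("constant feature column(s): ", paste(nm, collapse = ", "))
  }
  structure(list(mean = m, sd = s), class = "standardization")
}

#' Apply standardization parameters
#' @param X feature matrix/data.frame.
#' @param params a [standardize_fit()] result.
#' @return standardized matrix.
#' @export
standardize_apply <- function(X, params) {
  stopifnot(inherits(params, "standardization"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Training configuration for the batch gradient-descent trainer
#'
#' @param step initial step size of each iteration (default 0.5).
#' @param backtrack_factor multiplicative step reduction when a step
#'   fails to decrease the loss (default 0.5).
#' @param max_backtracks halvings tried per iteration before declaring
#'   convergence (default 30).
#' @param max_iter iteration cap (default 5000).
#' @param tol relative loss-improvement tolerance (default 1e-8).
#' @param init_range weights initialized uniformly in
#'   `[-init_range, init_range]` (default 0.5).
#' @return list of class `train_config`.
#' @export
train_config <- function(step = 0.5, backtrack_factor = 0.5,
                         max_backtracks = 30, max_iter = 5000,
                         tol = 1e-8, init_range = 0.5) {
  stopifnot(step > 0, backtrack_factor > 0, backtrack_factor < 1,
            tol >= 0, max_iter >= 1)
  structure(list(step = step, backtrack_factor = backtrack_factor,
                 max_backtracks = max_backtracks, max_iter = max_iter,
                 tol = tol, init_range = init_range),
            class = "train_config")
}

.mlp_init <- function(n_in, n_hidden, n_out, init_range, seed) {
  set.seed(seed)
  r <- function(n) stats::runif(n, -init_range, init_range)
  list(W1 = matrix(r(n_in * n_hidden), n_in, n_hidden),
       b1 = r(n_hidden),
       W2 = matrix(r(n_hidden * n_out), n_hidden, n_out),
       b2 = r(n_out))
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

.forward_raw <- function(w, X) {
  H <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  P <- .softmax_rows(sweep(H %*% w$W2, 2, w$b2, "+"))
  list(H = H, P = P)
}

#' Forward pass of the perceptron
#'
#' Hidden layer: hyperbolic tangent of an affine map; output layer:
#' softmax of an affine map, so every output lies in (0, 1) and the
#' outputs sum to 1.
#'
#' @param model a trained [mlp_train()] model.
#' @param features one standardized feature vector, or a matrix of
#'   standardized rows, with the model's input width.
#' @return probability vector (or matrix of row-probabilities) over the
#'   model's classes.
#' @export
mlp_forward <- function(model, features) {
  stopifnot(inherits(model, "mlp_model"))
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else
    as.matrix(features)
  if (ncol(X) != nrow(model$weights$W1)) {
    stop("expected ", nrow(model$weights$W1), " features, got ", ncol(X))
  }
  P <- .forward_raw(model$weights, X)$P
  colnames(P) <- model$classes
  if (nrow(P) == 1L) drop(P) else P
}

#' Cross-entropy loss
#'
#' `-ln p(true class)` per sample, summed over the batch; probabilities
#' are clamped below at 1e-12 so the loss stays finite.
#'
#' @param probs probability vector (one sample) or matrix (rows =
#'   samples).
#' @param true_idx integer class index (or vector) into the columns of
#'   `probs`.
#' @return total loss (>= 0).
#' @export
cross_entropy <- function(probs, true_idx) {
  P <- if (is.null(dim(probs))) matrix(probs, nrow = 1) else as.matrix(probs)
  if (any(true_idx < 1L | true_idx > ncol(P))) {
    stop("class index out of range")
  }
  p_true <- P[cbind(seq_len(nrow(P)), true_idx)]
  sum(-log(pmax(p_true, 1e-12)))
}

# analytic gradient of the total cross-entropy wrt all weights/biases
.mlp_gradient <- function(w, X, Y) {
  f <- .forward_raw(w, X)
  dZ <- f$P - Y
  dH <- (dZ %*% t(w$W2)) * (1 - f$H^2)
  list(W1 = crossprod(X, dH), b1 = colSums(dH),
       W2 = crossprod(f$H, dZ), b2 = colSums(dZ))
}

.mlp_loss <- function(w, X, Y) {
  cross_entropy(.forward_raw(w, X)$P, max.col(Y, ties.method = "first"))
}

#' Train the multilayer perceptron
#'
#' Architecture: `n_features -> hidden (tanh) -> K (softmax)` with bias
#' terms in both layers. Training is full-batch gradient descent on the
#' total cross-entropy with backtracking step halving, so every
#' accepted iteration strictly reduces the loss; training stops when no
#' step in the backtracking schedule reduces the loss any further, when
#' the relative improvement falls below `cfg$tol`, or at
#' `cfg$max_iter`. Standardization is fitted on the training rows and
#' stored in the model.
#'
#' @param X training features (matrix or data.frame of raw,
#'   unstandardized values).
#' @param labels character/factor vector of class labels, one per row;
#'   every class must occur at least once.
#' @param hidden hidden-layer width (default 10).
#' @param cfg a [train_config()].
#' @param seed integer seed for the weight initialization.
#' @return list of class `mlp_model`: `weights`, `classes`,
#'   `standardization`, `seed`, `cfg`, and the strictly decreasing
#'   `loss_trajectory`.
#' @export
mlp_train <- function(X, labels, hidden = 10, cfg = train_config(),
                      seed = 1) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (anyNA(labels)) stop("unlabelled training rows")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes with samples")
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  y <- match(labels, classes)
  Y <- matrix(0, nrow(Xs), length(classes))
  Y[cbind(seq_len(nrow(Xs)), y)] <- 1

  w <- .mlp_init(ncol(Xs), hidden, length(classes), cfg$init_range, seed)
  loss <- .mlp_loss(w, Xs, Y)
  traj <- loss
  for (it in seq_len(cfg$max_iter)) {
    g <- .mlp_gradient(w, Xs, Y)
    step <- cfg$step
    accepted <- FALSE
    for (bt in seq_len(cfg$max_backtracks)) {
      w_new <- list(W1 = w$W1 - step * g$W1, b1 = w$b1 - step * g$b1,
                    W2 = w$W2 - step * g$W2, b2 = w$b2 - step * g$b2)
      loss_new <- .mlp_loss(w_new, Xs, Y)
      if (is.finite(loss_new) && loss_new < loss) {
        accepted <- TRUE
        break
      }
      step <- step * cfg$backtrack_factor
    }
    if (!accepted) break
    rel <- (loss - loss_new) / max(loss, .Machine$double.eps)
    w <- w_new
    loss <- loss_new
    traj <- c(traj, loss)
    if (rel < cfg$tol) break
  }
  structure(list(weights = w, classes = classes, standardization = std,
                 hidden = hidden, seed = seed, cfg = cfg,
                 loss_trajectory = traj),
            class = "mlp_model")
}

#' Predict class labels and probabilities from raw features
#' @param model a trained [mlp_train()] model.
#' @param X raw (unstandardized) feature matrix or data.frame.
#' @return list with `class` (character vector) and `prob` (matrix).
#' @export
mlp_predict <- function(model, X) {
  stopifnot(inherits(model, "mlp_model"))
  Xs <- standardize_apply(as.matrix(X), model$standardization)
  P <- mlp_forward(model, Xs)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1, dimnames = list(NULL,
                                   model$classes))
  list(class = model$classes[max.col(P, ties.method = "first")], prob = P)
}

#' Check the analytic backpropagation gradient
#'
#' Compares the analytic gradient of the total cross-entropy with
#' central finite differences (`h = 1e-6`) over every weight and bias.
#'
#' @param model an [mlp_train()] model (trained or freshly initialized).
#' @param X standardized feature batch.
#' @param labels class labels matching the model's classes.
#' @param h finite-difference step (default 1e-6).
#' @return maximum relative discrepancy over all parameters.
#' @export
gradient_check <- function(model, X, labels, h = 1e-6) {
  stopifnot(inherits(model, "mlp_model"))
  X <- as.matrix(X)
  y <- match(as.character(labels), model$classes)
  Y <- matrix(0, nrow(X), length(model$classes))
  Y[cbind(seq_len(nrow(X)), y)] <- 1
  w <- model$weights
  g <- .mlp_gradient(w, X, Y)
  max_rel <- 0
  for (nm in names(w)) {
    for (i in seq_along(w[[nm]])) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      num <- (.mlp_loss(wp, X, Y) - .mlp_loss(wm, X, Y)) / (2 * h)
      ana <- g[[nm]][i]
      rel <- abs(num - ana) / max(abs(num) + abs(ana), 1e-8)
      if (rel > max_rel) max_rel <- rel
    }
  }
  max_rel
}

#' Serialize / restore a model as JSON
#' @param model an [mlp_train()] model.
#' @param path JSON file path.
#' @export
write_mlp_json <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(
    input = nrow(model$weights$W1), hidden = model$hidden,
    output = length(model$classes), classes = model$classes,
    W1 = as.vector(t(model$weights$W1)), b1 = model$weights$b1,
    W2 = as.vector(t(model$weights$W2)), b2 = model$weights$b2,
    standardization_mean = unname(model$standardization$mean),
    standardization_sd = unname(model$standardization$sd),
    seed = model$seed, cfg = unclass(model$cfg)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- list(
    W1 = matrix(o$W1, o$input, o$hidden, byrow = TRUE),
    b1 = o$b1,
    W2 = matrix(o$W2, o$hidden, o$output, byrow = TRUE),
    b2 = o$b2
  )
  std <- structure(list(mean = o$standardization_mean,
                        sd = o$standardization_sd),
                   class = "standardization")
  structure(list(weights = w, classes = o$classes, standardization = std,
                 hidden = o$hidden, seed = o$seed,
                 cfg = do.call(train_config, o$cfg),
                 loss_trajectory = numeric(0)),
            class = "mlp_model")
}
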