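test_that("standardization uses training statistics and rejects constants", {
  p <- standardize_fit(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  expect_equal(unname(p$mean["a"]), 2)
  expect_equal(unname(p$sd["a"]), 1)  # sample sd, n - 1 denominator
  Z <- standardize_apply(cbind(a = c(1, 2, 3), b = c(10, 20, 60)), p)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-10)
  expect_error(standardize_fit(cbind(a = c(1, 2), flat = c(5, 5))), "flat")
})

test_that("forward pass is a proper softmax probability map", {
  toy <- make_toy_classes()
  model <- mlp_train(toy$X, toy$labels, hidden = 4,
                     cfg = train_config(max_iter = 5), seed = 1)
  # zero weights: uniform output regardless of input
  zero <- model
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  expect_equal(unname(mlp_forward(zero, rep(0, 9))), rep(0.5, 2))

  set.seed(3)
  for (k in 1:20) {
    m <- model
    m$weights <- lapply(m$weights, function(w) w + rnorm(length(w)))
    P <- mlp_forward(m, matrix(rnorm(27), 3, 9))
    expect_true(all(P > 0 & P < 1))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    # shift invariance of softmax: adding c to output biases
    m2 <- m
    m2$weights$b2 <- m2$weights$b2 + 7.3
    expect_equal(mlp_forward(m2, rep(0.5, 9)), mlp_forward(m, rep(0.5, 9)),
                 tolerance = 1e-12)
  }
  expect_error(mlp_forward(model, rep(0, 5)), "expected 9 features")
})

test_that("cross-entropy matches closed forms and clamps", {
  expect_equal(cross_entropy(c(1, 0), 1), 0)
  expect_equal(cross_entropy(rep(0.2, 5), 3), log(5))
  p <- c(1e-20, 1 - 1e-20)
  expect_equal(cross_entropy(p, 1), -log(1e-12))  # clamped, finite
  expect_error(cross_entropy(c(0.5, 0.5), 3), "out of range")
})

test_that("backprop gradient matches central finite differences", {
  set.seed(41)
  X <- matrix(rnorm(8 * 9), 8, 9)
  labels <- sample(letters[1:5], 8, TRUE)
  labels[1:5] <- letters[1:5]  # every class present
  model <- mlp_train(X, labels, hidden = 10,
                     cfg = train_config(max_iter = 3), seed = 7)
  # random network: keeps per-parameter gradients away from the
  # floating-point noise floor of the finite-difference quotient
  model$weights <- lapply(model$weights,
                          function(w) w + rnorm(length(w), 0, 0.3))
  Xs <- standardize_apply(X, model$standardization)
  expect_lt(gradient_check(model, Xs, labels), 1e-6)
  # zero-weight model: gradients finite and matching too
  model$weights <- lapply(model$weights, function(w) w * 0)
  expect_lt(gradient_check(model, Xs, labels), 1e-6)
})

test_that("training strictly decreases the loss and is deterministic", {
  toy <- make_toy_classes(n_per = 20, sep = 6)
  m1 <- mlp_train(toy$X, toy$labels, hidden = 10,
                  cfg = train_config(max_iter = 200), seed = 5)
  expect_true(all(diff(m1$loss_trajectory) < 0))
  acc <- per_class_accuracy(m1, toy$X, toy$labels)
  expect_equal(acc$overall, 100)
  # bit-identical rerun under the same seed
  m2 <- mlp_train(toy$X, toy$labels, hidden = 10,
                  cfg = train_config(max_iter = 200), seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_error(mlp_train(toy$X, rep("one", nrow(toy$X))), "two classes")
})

test_that("per_class_accuracy reports class and overall percentages", {
  toy <- make_toy_classes(sep = 8)
  model <- mlp_train(toy$X, toy$labels, cfg = train_config(max_iter = 300),
                     seed = 2)
  acc <- per_class_accuracy(model, toy$X, toy$labels)
  expect_true(all(acc$per_class$accuracy >= 0 &
                  acc$per_class$accuracy <= 100))
  expect_gte(acc$overall, min(acc$per_class$accuracy))
  expect_lte(acc$overall, max(acc$per_class$accuracy))
  # arithmetic on a constructed confusion: 4/5 and 5/5 -> 80, 100, 90
  labs <- rep(c("a", "b"), each = 5)
  pred <- labs; pred[1] <- "b"
  expect_equal(round_half_up(100 * mean(pred[labs == "a"] == "a"), 1), 80)
  expect_equal(round_half_up(100 * mean(pred == labs), 1), 90)
  expect_error(per_class_accuracy(model, toy$X,
                                  c(NA, toy$labels[-1])), "unlabelled")
})

test_that("model JSON serialization round-trips predictions", {
  toy <- make_toy_classes()
  model <- mlp_train(toy$X, toy$labels, cfg = train_config(max_iter = 50),
                     seed = 3)
  f <- tempfile(fileext = ".json")
  write_mlp_json(model, f)
  back <- read_mlp_json(f)
  expect_equal(mlp_predict(back, toy$X)$prob, mlp_predict(model, toy$X)$prob,
               tolerance = 1e-12)
  unlink(f)
})

test_that("random_split is a seeded Bernoulli partition", {
  sp <- random_split(85, 0.7, seed = 4)
  expect_setequal(c(sp$train, sp$test), 1:85)
  expect_equal(sp$summary$n, c(length(sp$train), length(sp$test)))
  expect_equal(sum(sp$summary$percentage), 100)
  sp2 <- random_split(85, 0.7, seed = 4)
  expect_identical(sp$train, sp2$train)
  expect_error(random_split(1, 0.7, 1), "at least 2")
  # both sides always non-empty even at extreme probability
  sp3 <- random_split(3, 0.99, seed = 1)
  expect_gt(length(sp3$test), 0)
})

test_that("repeated_cv aggregates per-run accuracies", {
  toy <- make_toy_classes(n_per = 15, sep = 7)
  rep1 <- repeated_cv(toy$X, toy$labels, n_runs = 3,
                      cfg = train_config(max_iter = 150), seed = 11)
  expect_equal(nrow(rep1$runs), 3)
  expect_true(all(rep1$runs$test_acc >= 0 & rep1$runs$test_acc <= 100))
  expect_equal(rep1$mean_test,
               round_half_up(mean(rep1$runs$test_acc), 1))
  one <- repeated_cv(toy$X, toy$labels, n_runs = 1,
                     cfg = train_config(max_iter = 150), seed = 11)
  expect_equal(one$mean_test, one$runs$test_acc[1])
  # k-fold mode covers every sample exactly once
  kf <- repeated_cv(toy$X, toy$labels, n_runs = 3, mode = "kfold",
                    cfg = train_config(max_iter = 150), seed = 11)
  expect_equal(sum(kf$runs$n_test), nrow(toy$X))
})

test_that("cv_report mean is the one-decimal arithmetic mean of runs", {
  accs <- c(50, 60, 71)
  rep <- cv_report(rep(100, 3), accs)
  expect_equal(rep$mean_test, round_half_up(mean(accs), 1))
  same <- cv_report(rep(90, 4), rep(88, 4))
  expect_equal(same$mean_test, 88)
})

test_that("permutation importance isolates informative features", {
  toy <- make_toy_classes(n_per = 15, sep = 6)
  model <- mlp_train(toy$X, toy$labels, cfg = train_config(max_iter = 200),
                     seed = 9)
  # silencing a feature's outgoing hidden weights kills its importance
  silenced <- model
  silenced$weights$W1[3, ] <- 0
  imp <- variable_importance(silenced, toy$X, toy$labels,
                             n_permutations = 20, seed = 1)
  expect_lt(imp$raw[imp$feature == "f3"], 1e-9)
  expect_equal(max(imp$normalized), 100)
  imp2 <- variable_importance(silenced, toy$X, toy$labels,
                              n_permutations = 20, seed = 1)
  expect_identical(imp, imp2)
})

test_that("importance of a label-independent feature shrinks with n_permutations", {
  set.seed(55)
  toy <- make_toy_classes(n_per = 20, sep = 6)
  X <- cbind(toy$X[, 1:8], noise = rnorm(40))
  model <- mlp_train(X, toy$labels, cfg = train_config(max_iter = 200),
                     seed = 10)
  imp_few <- variable_importance(model, X, toy$labels,
                                 n_permutations = 3, seed = 2)
  imp_many <- variable_importance(model, X, toy$labels,
                                  n_permutations = 150, seed = 2)
  r_many <- imp_many$normalized[imp_many$feature == "noise"]
  expect_lt(r_many, 15)  # near-zero share for pure noise
})
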