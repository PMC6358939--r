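# Extreme learning machine: hidden layer, pseudoinverse solve, training,
# prediction, capacity behaviour.

test_that("hidden-layer initialization is seeded, bounded and correctly shaped", {
  h <- elm_init_hidden(19, 70, seed = 3)
  expect_equal(dim(h$A), c(70, 19))
  expect_length(h$B, 70)
  expect_true(all(abs(h$A) <= 1) && all(abs(h$B) <= 1))
  expect_identical(h, elm_init_hidden(19, 70, seed = 3))
  expect_false(identical(h$A, elm_init_hidden(19, 70, seed = 4)$A))
  expect_error(elm_init_hidden(0, 5), "positive")
  expect_error(elm_init_hidden(5, 0), "positive")
})

test_that("hidden output evaluates the sigmoid node function", {
  # zero weights and biases -> G(0) = 0.5 everywhere
  H0 <- elm_hidden_output(matrix(0, 3, 2), rep(0, 3), matrix(rnorm(10), 5, 2))
  expect_true(all(H0 == 0.5))
  expect_equal(dim(H0), c(5, 3))
  # scalar case: x = (1, 2), a = (0.5, -0.25), b = 0.1
  H <- elm_hidden_output(matrix(c(0.5, -0.25), 1, 2), 0.1,
                         matrix(c(1, 2), 1, 2))
  expect_equal(H[1, 1], 1 / (1 + exp(-0.1)), tolerance = 1e-12)
  expect_equal(H[1, 1], 0.52498, tolerance = 1e-5)
  expect_error(elm_hidden_output(matrix(0, 3, 2), rep(0, 3),
                                 matrix(0, 5, 4)), "dimension")
  # radial-basis node peaks at its centre
  Hr <- elm_hidden_output(matrix(c(1, 2), 1, 2), 0.7,
                          matrix(c(1, 2), 1, 2), activation = "radbas")
  expect_equal(Hr[1, 1], 1)
})

test_that("beta solve matches direct inversion and the least-squares oracle", {
  set.seed(7)
  # square invertible system
  H <- matrix(rnorm(25), 5, 5)
  T_mat <- matrix(rnorm(15), 5, 3)
  expect_equal(elm_solve_beta(H, T_mat), solve(H, T_mat), tolerance = 1e-9)
  # overdetermined: residual equals the normal-equations solution's
  H2 <- matrix(rnorm(100), 20, 5)
  T2 <- matrix(rnorm(40), 20, 2)
  beta <- elm_solve_beta(H2, T2)
  beta_ne <- solve(t(H2) %*% H2, t(H2) %*% T2)
  expect_equal(beta, beta_ne, tolerance = 1e-8)
  expect_equal(norm(H2 %*% beta - T2, "F"), norm(H2 %*% beta_ne - T2, "F"),
               tolerance = 1e-9)
  expect_error(elm_solve_beta(matrix(numeric(0), 0, 0), T2), "non-empty")
})

test_that("rank-deficient systems get the minimum-norm least-squares solution", {
  set.seed(8)
  H <- matrix(rnorm(40), 10, 4)
  H <- cbind(H, H[, 4]) # duplicated column -> rank 4
  T_mat <- matrix(rnorm(20), 10, 2)
  beta <- elm_solve_beta(H, T_mat)
  expect_true(all(is.finite(beta)))
  res <- norm(H %*% beta - T_mat, "F")
  # any nullspace perturbation keeps the residual but inflates the norm
  null_vec <- c(0, 0, 0, 1, -1) / sqrt(2)
  for (a in c(-0.5, 0.3, 1)) {
    alt <- beta + null_vec %o% rep(a, 2)
    expect_equal(norm(H %*% alt - T_mat, "F"), res, tolerance = 1e-9)
    expect_gt(norm(alt, "F"), norm(beta, "F"))
  }
})

test_that("training interpolates when capacity allows and separates easy classes", {
  set.seed(12)
  X <- rbind(matrix(rnorm(60, mean = -3), 30, 2),
             matrix(rnorm(60, mean = 3), 30, 2))
  y <- rep(1:2, each = 30)
  model <- elm_train(X, y, n_hidden = 20, seed = 5)
  expect_identical(elm_predict(model, X), y)
  # exact interpolation: hidden nodes >= samples, full row rank
  Xs <- X[1:15, ]; ys <- y[1:15]
  m2 <- elm_train(Xs, ys, n_hidden = 30, seed = 6, n_classes = 2)
  H <- elm_hidden_output(m2$A, m2$B, Xs)
  T_mat <- matrix(0, 15, 2); T_mat[cbind(1:15, ys)] <- 1
  expect_lt(norm(H %*% m2$beta - T_mat, "F"), 1e-6)
  # single-sample degenerate model reproduces its label
  m1 <- elm_train(matrix(c(1, 2), 1, 2), 2L, n_hidden = 5, seed = 1,
                  n_classes = 3)
  expect_identical(elm_predict(m1, matrix(c(1, 2), 1, 2)), 2L)
  # one-class degenerate problem always answers class 1
  m0 <- elm_train(X, rep(1L, 60), n_hidden = 5, seed = 2)
  expect_true(all(elm_predict(m0, X) == 1L))
})

test_that("predictions are row-independent and equivariant to label permutation", {
  set.seed(13)
  X <- matrix(rnorm(120), 40, 3)
  y <- sample(1:3, 40, replace = TRUE)
  model <- elm_train(X, y, n_hidden = 25, seed = 9)
  pred <- elm_predict(model, X)
  perm <- sample(40)
  expect_identical(elm_predict(model, X[perm, ]), pred[perm])
  # relabeling classes 1<->3 permutes beta columns and predictions
  relab <- c(3L, 2L, 1L)
  model2 <- elm_train(X, relab[y], n_hidden = 25, seed = 9)
  expect_equal(model2$beta, model$beta[, relab], tolerance = 1e-9)
  expect_identical(elm_predict(model2, X), relab[pred])
})

test_that("fixed seeds make training and the accuracy sweep reproducible", {
  set.seed(30)
  X <- matrix(rnorm(400), 100, 4)
  y <- 1L + (X[, 1] + 0.2 * rnorm(100) > 0)
  m1 <- elm_train(X, y, n_hidden = 15, seed = 21)
  m2 <- elm_train(X, y, n_hidden = 15, seed = 21)
  expect_identical(m1$A, m2$A)
  expect_identical(m1$beta, m2$beta)
  tab <- elm_accuracy_sweep(X, y, sample_sizes = c(40, 60),
                            hidden_sizes = c(5, 15), n_repeats = 2, seed = 2)
  tab2 <- elm_accuracy_sweep(X, y, sample_sizes = c(40, 60),
                             hidden_sizes = c(5, 15), n_repeats = 2, seed = 2)
  expect_identical(tab, tab2)
  expect_error(elm_accuracy_sweep(X, y, sample_sizes = 100,
                                  hidden_sizes = 10), "held-out")
})

test_that("the operating point separates postures well on a scaled-down design", {
  # 300 frames at reduced rendering resolution; the full-design capacity
  # comparison lives with the end-to-end validation
  ds <- generate_posture_dataset(5, 10, 1:6, seed = 8)
  X <- dataset_features(ds, upsample = 8)
  tab <- elm_accuracy_sweep(X, ds$labels, sample_sizes = 200,
                            hidden_sizes = 70, n_repeats = 5, seed = 4)
  expect_gt(tab$accuracy, 0.9)
})
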