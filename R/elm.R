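# Extreme learning machine: a single-hidden-layer feedforward network whose
# hidden weights are random and fixed, and whose output weights are the
# minimum-norm least-squares solution of H beta = T obtained from the
# Moore-Penrose pseudoinverse. No iterative training.

#' Randomly initialize the ELM hidden layer
#'
#' Draws the input weights `A` (one row per hidden node) and biases `B`
#' uniformly on `[-1, 1]` from a seeded generator.
#'
#' @param n Input dimension (>= 1).
#' @param n_hidden Number of hidden nodes (>= 1).
#' @param seed Integer seed (optional).
#' @return List with `A` (`n_hidden x n`) and `B` (length `n_hidden`).
#' @export
elm_init_hidden <- function(n, n_hidden, seed = NULL) {
  n <- as.integer(n); n_hidden <- as.integer(n_hidden)
  if (is.na(n) || n < 1L || is.na(n_hidden) || n_hidden < 1L) {
    stop_domain("`n` and `n_hidden` must be positive integers")
  }
  with_seed(seed, {
    A <- matrix(runif(n_hidden * n, -1, 1), n_hidden, n)
    B <- runif(n_hidden, -1, 1)
    list(A = A, B = B)
  })
}

elm_activations <- c("sigmoid", "radbas")

#' Hidden-layer output matrix
#'
#' Computes `H[j, i] = G(a_i, b_i, x_j)` for every sample `x_j` (row of `X`)
#' and hidden node `i`. For the sigmoid activation `G = 1 / (1 + exp(-(a_i .
#' x_j + b_i)))`; for the radial basis activation `G = exp(-b_i^2 * ||x_j -
#' a_i||^2)`.
#'
#' @param A `n_hidden x n` input weight matrix.
#' @param B Length-`n_hidden` bias vector.
#' @param X `N x n` input matrix (or a single vector).
#' @param activation `"sigmoid"` (default) or `"radbas"`.
#' @return `N x n_hidden` matrix `H`.
#' @export
elm_hidden_output <- function(A, B, X, activation = "sigmoid") {
  activation <- match.arg(activation, elm_activations)
  X <- rbind(X)
  if (ncol(X) != ncol(A)) {
    stop_domain(sprintf("input dimension %d does not match the %d model inputs",
                        ncol(X), ncol(A)))
  }
  if (length(B) != nrow(A)) stop_domain("length(B) must equal nrow(A)")
  if (activation == "sigmoid") {
    Z <- X %*% t(A)
    Z <- sweep(Z, 2, B, "+")
    1 / (1 + exp(-Z))
  } else {
    # squared distances ||x_j - a_i||^2 via the expansion x'x - 2 x'a + a'a
    d2 <- outer(rowSums(X^2), rep(1, nrow(A))) - 2 * X %*% t(A) +
      outer(rep(1, nrow(X)), rowSums(A^2))
    exp(-sweep(pmax(d2, 0), 2, B^2, "*"))
  }
}

#' Minimum-norm least-squares output weights
#'
#' Solves `H beta = T` for the output weights via the Moore-Penrose
#' pseudoinverse, `beta = H^+ T`, computed from the singular value
#' decomposition with a relative cutoff of `1e-12` on the singular values.
#' Among all least-squares minimizers this solution has minimal Frobenius
#' norm.
#'
#' @param H `N x n_hidden` hidden output matrix.
#' @param T_mat `N x m` target matrix (one-hot rows for classification).
#' @param svd_tol Relative singular-value cutoff.
#' @return `n_hidden x m` weight matrix.
#' @export
elm_solve_beta <- function(H, T_mat, svd_tol = 1e-12) {
  H <- rbind(H); T_mat <- rbind(T_mat)
  if (length(H) == 0L) stop_domain("`H` must be non-empty")
  if (nrow(H) != nrow(T_mat)) stop_domain("H and T must have equal row counts")
  s <- svd(H)
  keep <- s$d > svd_tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(H), ncol(T_mat)))
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% T_mat))
}

#' Train an extreme learning machine classifier
#'
#' The three-step ELM algorithm: assign the hidden input weights and biases
#' randomly, compute the hidden output matrix `H`, and solve the output
#' weights `beta = H^+ T` in closed form against the one-hot target matrix.
#'
#' @param X `N x n` numeric feature matrix.
#' @param labels Integer class labels in `1..m`.
#' @param n_hidden Number of hidden nodes (default 70).
#' @param activation `"sigmoid"` (default) or `"radbas"`.
#' @param seed Integer seed for the hidden-layer initialization.
#' @param n_classes Number of classes `m`; defaults to `max(labels)`.
#' @param scaler Optional `feature_scaler` applied to `X` now and to new data
#'   in [elm_predict()].
#' @return An object of class `elm_model` with elements `A`, `B`, `beta`,
#'   `activation`, `n_hidden`, `n_classes`, `seed`, `feature_order`,
#'   `scaler`.
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' m <- elm_train(X, rep(1:2, each = 20), n_hidden = 10, seed = 1)
#' mean(elm_predict(m, X) == rep(1:2, each = 20))
elm_train <- function(X, labels, n_hidden = 70L, activation = "sigmoid",
                      seed = NULL, n_classes = NULL, scaler = NULL) {
  X <- rbind(X)
  labels <- as.integer(labels)
  if (nrow(X) < 1L) stop_domain("training set must contain at least one sample")
  if (length(labels) != nrow(X)) stop_domain("one label per row of X required")
  m <- if (is.null(n_classes)) max(labels) else as.integer(n_classes)
  if (any(labels < 1L | labels > m)) stop_domain("labels must lie in 1..n_classes")
  activation <- match.arg(activation, elm_activations)
  if (!is.null(scaler)) X <- apply_scaler(scaler, X)
  hidden <- elm_init_hidden(ncol(X), n_hidden, seed)
  H <- elm_hidden_output(hidden$A, hidden$B, X, activation)
  T_mat <- matrix(0, nrow(X), m)
  T_mat[cbind(seq_len(nrow(X)), labels)] <- 1
  beta <- elm_solve_beta(H, T_mat)
  structure(
    list(A = hidden$A, B = hidden$B, beta = beta, activation = activation,
         n_hidden = as.integer(n_hidden), n_classes = m,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         feature_order = colnames(X), scaler = scaler),
    class = "elm_model"
  )
}

#' Predict class labels with a trained ELM
#'
#' Scores `hidden_output(X) %*% beta` and returns the arg-max class per row;
#' ties resolve to the smallest class index.
#'
#' @param model An `elm_model`.
#' @param X Feature matrix (or single vector) with the model's input
#'   dimension.
#' @return Integer vector of predicted labels in `1..m`.
#' @export
elm_predict <- function(model, X) {
  stopifnot(inherits(model, "elm_model"))
  X <- rbind(X)
  if (!is.null(model$scaler)) X <- apply_scaler(model$scaler, X)
  H <- elm_hidden_output(model$A, model$B, X, model$activation)
  scores <- H %*% model$beta
  max.col(scores, ties.method = "first")
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d inputs -> %d hidden (%s) -> %d classes\n",
              ncol(x$A), x$n_hidden, x$activation, x$n_classes))
  invisible(x)
}

#' Accuracy sweep over training-set size and hidden-node count
#'
#' For every combination of training-set size and hidden-node count, draws a
#' random training subset of that size, trains an ELM and scores it on the
#' held-out remainder; repeats `n_repeats` times with fresh draws and fresh
#' hidden layers and reports the mean held-out accuracy per cell.
#'
#' @param X Feature matrix.
#' @param labels Integer class labels.
#' @param sample_sizes Training-set sizes to test.
#' @param hidden_sizes Hidden-node counts to test.
#' @param n_repeats Repeats per cell (default 10).
#' @param seed Integer base seed; repeat `r` uses `seed + r`.
#' @param activation Activation function name.
#' @param scale Normalize features with a scaler fitted on each training
#'   draw (default TRUE).
#' @return Data frame with columns `sample_size`, `n_hidden`, `accuracy`.
#' @export
elm_accuracy_sweep <- function(X, labels, sample_sizes = seq(100, 800, 100),
                               hidden_sizes = seq(30, 120, 10),
                               n_repeats = 10L, seed = 1L,
                               activation = "sigmoid", scale = TRUE) {
  X <- rbind(X)
  n <- nrow(X)
  if (max(sample_sizes) >= n) {
    stop_domain("the dataset must exceed the largest training size to leave a held-out pool")
  }
  grid <- expand.grid(sample_size = as.integer(sample_sizes),
                      n_hidden = as.integer(hidden_sizes))
  m <- max(as.integer(labels))
  acc <- matrix(NA_real_, nrow(grid), n_repeats)
  for (r in seq_len(n_repeats)) {
    split_seed <- as.integer(seed) + r
    train_idx_all <- with_seed(split_seed, sample.int(n, max(sample_sizes)))
    for (g in seq_len(nrow(grid))) {
      size <- grid$sample_size[g]
      idx <- train_idx_all[seq_len(size)]
      scaler <- if (scale) fit_scaler(X[idx, , drop = FALSE]) else NULL
      model <- elm_train(X[idx, , drop = FALSE], labels[idx],
                         n_hidden = grid$n_hidden[g], activation = activation,
                         seed = split_seed * 1000L + grid$n_hidden[g],
                         n_classes = m, scaler = scaler)
      pred <- elm_predict(model, X[-idx, , drop = FALSE])
      acc[g, r] <- mean(pred == labels[-idx])
    }
  }
  grid$accuracy <- rowMeans(acc)
  grid
}
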