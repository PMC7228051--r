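# MLP link/path scorer: input -> hidden (ReLU) -> 2 softplus output units.
# Trained as a classifier: the two softplus activations are normalised to a
# probability simplex for the cross-entropy loss, and the *unnormalised*
# positive-unit activation is the ranking score, which keeps scores
# positive and unbounded.

#' MLP scorer configuration
#'
#' @param input_dim dimension of the combined node-vector input.
#' @param hidden_units size of the single hidden layer.
#' @param seed integer seed for weight initialisation.
#' @export
mlp_config <- function(input_dim, hidden_units = 100L, seed = 1L) {
  cfg <- list(input_dim = as.integer(input_dim),
              hidden_units = as.integer(hidden_units),
              seed = as.integer(seed))
  if (cfg$input_dim < 1 || cfg$hidden_units < 1)
    lbd_stop("lbd_config_error", "mlp_config: dims must be positive")
  cfg
}

mlp_init <- function(cfg) {
  d <- cfg$input_dim; h <- cfg$hidden_units
  glorot <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  list(W1 = glorot(d, h), b1 = numeric(h),
       W2 = glorot(h, 2L), b2 = numeric(2L))
}

# Forward pass; X is n x d. Returns hidden activations, pre-activations Z
# (n x 2) and softplus activations S (n x 2).
mlp_forward <- function(params, X) {
  H <- relu(sweep(X %*% params$W1, 2, params$b1, `+`))
  Z <- sweep(H %*% params$W2, 2, params$b2, `+`)
  list(H = H, Z = Z, S = softplus(Z))
}

# Mean cross-entropy of the normalised softplus outputs against labels
# (0/1); y indexes the true unit (col 1 = negative, col 2 = positive).
mlp_loss <- function(params, X, y) {
  fw <- mlp_forward(params, X)
  P <- fw$S / rowSums(fw$S)
  idx <- cbind(seq_along(y), y + 1L)
  -mean(log(pmax(P[idx], 1e-12)))
}

mlp_grad <- function(params, X, y) {
  n <- nrow(X)
  fw <- mlp_forward(params, X)
  S <- fw$S
  rs <- rowSums(S)
  idx <- cbind(seq_len(n), y + 1L)
  # dL/dS_k = (1/rs - [k == y]/S_y) / n  for the mean loss
  dS <- matrix(1 / rs, n, 2)
  dS[idx] <- dS[idx] - 1 / S[idx]
  dS <- dS / n
  dZ <- dS * sigmoid(fw$Z)               # softplus' = logistic
  dW2 <- crossprod(fw$H, dZ)
  db2 <- colSums(dZ)
  dH <- dZ %*% t(params$W2)
  dH[fw$H <= 0] <- 0                     # ReLU gate
  dW1 <- crossprod(X, dH)
  db1 <- colSums(dH)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Train the MLP link/path scorer
#'
#' @param examples classification examples from [build_link_examples()] or
#'   [build_path_examples()]: list with `features` (n x d matrix) and
#'   `label` (0/1).
#' @param config an [mlp_config()]; its `input_dim` must match the features.
#' @param train an [train_config()].
#' @return An object of class `lbd_mlp` carrying the final parameters, the
#'   per-epoch mean training loss, and parameter checkpoints every
#'   `eval_interval_epochs` (each a list `epoch`, `params`).
#' @export
train_mlp <- function(examples, config, train = train_config()) {
  X <- examples$features
  y <- as.integer(examples$label)
  if (ncol(X) != config$input_dim)
    lbd_stop("lbd_config_error", "train_mlp: feature dim %d != input_dim %d",
             ncol(X), config$input_dim)
  with_lbd_seed(config$seed * 131L + train$seed, {
    params <- mlp_init(config)
    st <- adam_init(params)
    losses <- numeric(train$epochs)
    checkpoints <- list()
    for (ep in seq_len(train$epochs)) {
      for (b in epoch_batches(nrow(X), train$batch_size)) {
        g <- mlp_grad(params, X[b, , drop = FALSE], y[b])
        upd <- adam_step(params, g, st, train$learning_rate)
        params <- upd$params; st <- upd$state
      }
      losses[ep] <- mlp_loss(params, X, y)
      if (ep %% train$eval_interval_epochs == 0L || ep == train$epochs)
        checkpoints[[length(checkpoints) + 1L]] <-
          list(epoch = ep, params = params)
    }
    structure(list(config = config, params = params, losses = losses,
                   checkpoints = checkpoints),
              class = c("lbd_mlp", "lbd_scorer"))
  })
}

#' Score feature vectors with a trained scorer
#'
#' Deterministic at inference; accepts a single feature vector, a matrix of
#' row vectors, or (for the CNN) a window matrix or list of windows.
#'
#' @param scorer a trained `lbd_mlp` or `lbd_cnn`.
#' @param features input features matching the scorer's contract.
#' @return numeric vector of nonnegative scores.
#' @export
score <- function(scorer, features) UseMethod("score")

#' @export
score.lbd_mlp <- function(scorer, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != scorer$config$input_dim)
    lbd_stop("lbd_config_error", "score: feature dim %d != input_dim %d",
             ncol(features), scorer$config$input_dim)
  drop(mlp_forward(scorer$params, features)$S[, 2])
}

# Score with an explicit parameter set (used when ranking checkpoints).
mlp_score_params <- function(params, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  drop(mlp_forward(params, features)$S[, 2])
}

#' @export
print.lbd_mlp <- function(x, ...) {
  cat(sprintf("<lbd_mlp> %d -> %d -> 2 (softplus), %d epochs, final loss %.4f\n",
              x$config$input_dim, x$config$hidden_units,
              length(x$losses), x$losses[length(x$losses)]))
  invisible(x)
}
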