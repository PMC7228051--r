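# CNN path-stack scorer: a stacked window of combined path vectors ->
# batch-normalised convolution (filters span the full vector width and
# slide only down the stack) -> ReLU -> global max pooling over stack
# positions -> fully connected layer -> single softplus output. Trained
# pointwise with mean squared error against Jaccard ratings.

#' CNN scorer configuration
#'
#' @param width width of the stacked window (the combined vector dimension).
#' @param window_height rows per window; paths beyond this are folded in by
#'   elementwise window summation (see [pack_windows()]).
#' @param conv_height convolution kernel height (kernel width is always the
#'   full window width).
#' @param conv_filters number of convolution filters.
#' @param fc_units units in the fully connected layer.
#' @param seed integer seed for weight initialisation.
#' @export
cnn_config <- function(width, window_height = 50L, conv_height = 7L,
                       conv_filters = 128L, fc_units = 128L, seed = 1L) {
  cfg <- list(width = as.integer(width),
              window_height = as.integer(window_height),
              conv_height = as.integer(conv_height),
              conv_filters = as.integer(conv_filters),
              fc_units = as.integer(fc_units), seed = as.integer(seed))
  if (any(unlist(cfg[1:5]) < 1))
    lbd_stop("lbd_config_error", "cnn_config: dims must be positive")
  if (cfg$conv_height > cfg$window_height)
    lbd_stop("lbd_config_error",
             "cnn_config: conv_height %d exceeds window_height %d",
             cfg$conv_height, cfg$window_height)
  cfg
}

#' Pack path vectors into one fixed-size window
#'
#' The ordered path vectors are chunked into consecutive windows of
#' `height` rows; the final partial window is zero-padded to `height`; all
#' windows are then summed elementwise into a single `height x d` window.
#' With 175 paths and height 50 this sums 3 full windows plus one window
#' holding 25 paths and 25 zero rows.
#'
#' @param path_vectors numeric matrix, one path vector per row (or a list
#'   of equal-length vectors).
#' @param height window height.
#' @return `height x d` matrix with attributes `n_windows` (number of
#'   summed windows) and `pad_rows` (zero rows in the final window).
#' @export
pack_windows <- function(path_vectors, height) {
  if (is.list(path_vectors)) path_vectors <- do.call(rbind, path_vectors)
  if (is.null(dim(path_vectors))) path_vectors <- matrix(path_vectors, nrow = 1)
  n <- nrow(path_vectors)
  if (!n) lbd_stop("lbd_config_error", "pack_windows: empty path list")
  height <- as.integer(height)
  n_win <- ceiling(n / height)
  pad <- n_win * height - n
  if (pad) path_vectors <- rbind(path_vectors,
                                 matrix(0, pad, ncol(path_vectors)))
  out <- matrix(0, height, ncol(path_vectors))
  for (w in seq_len(n_win))
    out <- out + path_vectors[((w - 1) * height + 1):(w * height), , drop = FALSE]
  attr(out, "n_windows") <- as.integer(n_win)
  attr(out, "pad_rows") <- as.integer(pad)
  out
}

cnn_init <- function(cfg) {
  hW <- cfg$conv_height * cfg$width
  glorot <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  list(Wc = glorot(hW, cfg$conv_filters),
       gamma = rep(1, cfg$conv_filters), beta = numeric(cfg$conv_filters),
       W2 = glorot(cfg$conv_filters, cfg$fc_units), b2 = numeric(cfg$fc_units),
       W3 = glorot(cfg$fc_units, 1L), b3 = 0)
}

# Column indices extracting the column-major flattening of the h x W patch
# starting at stack position p from a flattened H x W window.
cnn_unfold_index <- function(cfg) {
  P <- cfg$window_height - cfg$conv_height + 1L
  t(vapply(seq_len(P), function(p)
    as.vector(outer(p:(p + cfg$conv_height - 1L),
                    (seq_len(cfg$width) - 1L) * cfg$window_height, `+`)),
    integer(cfg$conv_height * cfg$width)))
}

# Forward pass. Xf: n x (H*W) matrix of flattened windows. In training mode
# batch statistics normalise the conv output; in eval mode running stats do.
cnn_forward <- function(params, cfg, Xf, run_stats, train_mode) {
  n <- nrow(Xf)
  P <- cfg$window_height - cfg$conv_height + 1L
  Fk <- cfg$conv_filters
  idx <- cnn_unfold_index(cfg)
  A <- Xf[, as.vector(idx), drop = FALSE]          # n x (P * hW), p fastest
  dim(A) <- c(n, P, ncol(idx))
  A <- aperm(A, c(2, 1, 3))
  dim(A) <- c(P * n, ncol(idx))                    # rows: p fastest within i
  C <- A %*% params$Wc
  if (train_mode) {
    mu <- colMeans(C)
    va <- colMeans(sweep(C, 2, mu)^2)
  } else {
    mu <- run_stats$mean
    va <- run_stats$var
  }
  invstd <- 1 / sqrt(va + 1e-5)
  Chat <- sweep(sweep(C, 2, mu), 2, invstd, `*`)
  Bn <- sweep(sweep(Chat, 2, params$gamma, `*`), 2, params$beta, `+`)
  R <- relu(Bn)
  Rarr <- R; dim(Rarr) <- c(P, n, Fk)
  M <- apply(Rarr, c(2, 3), max)                   # n x F global max pool
  amax <- apply(Rarr, c(2, 3), which.max)
  if (n == 1) { M <- matrix(M, 1); amax <- matrix(amax, 1) }
  Z2 <- sweep(M %*% params$W2, 2, params$b2, `+`)
  H2 <- relu(Z2)
  Z3 <- drop(H2 %*% params$W3) + params$b3
  out <- softplus(Z3)
  list(U = A, C = C, mu = mu, va = va, invstd = invstd, Chat = Chat,
       Bn = Bn, M = M, amax = amax, H2 = H2, Z3 = Z3, out = out,
       P = P, n = n)
}

cnn_loss <- function(params, cfg, Xf, rating, run_stats, train_mode = TRUE) {
  fw <- cnn_forward(params, cfg, Xf, run_stats, train_mode)
  mean((fw$out - rating)^2)
}

cnn_grad <- function(params, cfg, Xf, rating, run_stats) {
  fw <- cnn_forward(params, cfg, Xf, run_stats, train_mode = TRUE)
  n <- fw$n; P <- fw$P; Fk <- cfg$conv_filters
  dout <- 2 * (fw$out - rating) / n
  dz3 <- dout * sigmoid(fw$Z3)
  dW3 <- crossprod(fw$H2, dz3)
  db3 <- sum(dz3)
  dH2 <- outer(dz3, drop(params$W3))
  dH2[fw$H2 <= 0] <- 0
  dW2 <- crossprod(fw$M, dH2)
  db2 <- colSums(dH2)
  dM <- dH2 %*% t(params$W2)                       # n x F
  dR <- matrix(0, P * n, Fk)
  rows <- (rep(seq_len(n), Fk) - 1L) * P + as.vector(fw$amax)
  dR[cbind(rows, rep(seq_len(Fk), each = n))] <- as.vector(dM)
  dBn <- dR
  dBn[fw$Bn <= 0] <- 0                             # ReLU gate
  dgamma <- colSums(dBn * fw$Chat)
  dbeta <- colSums(dBn)
  dChat <- sweep(dBn, 2, params$gamma, `*`)
  Mrows <- P * n
  s1 <- colSums(dChat)
  s2 <- colSums(dChat * fw$Chat)
  dC <- sweep(sweep(sweep(dChat * Mrows, 2, s1, `-`) -
                      sweep(fw$Chat, 2, s2, `*`),
                    2, fw$invstd, `*`), 2, rep(Mrows, Fk), `/`)
  dWc <- crossprod(fw$U, dC)
  list(grads = list(Wc = dWc, gamma = dgamma, beta = dbeta,
                    W2 = dW2, b2 = db2, W3 = dW3, b3 = db3),
       batch_mean = fw$mu, batch_var = fw$va)
}

flatten_windows <- function(windows, cfg) {
  Xf <- t(vapply(windows, function(w) {
    if (!identical(dim(w), c(cfg$window_height, cfg$width)))
      lbd_stop("lbd_config_error",
               "window is %s but scorer expects %d x %d",
               paste(dim(w), collapse = " x "),
               cfg$window_height, cfg$width)
    as.vector(w)
  }, numeric(cfg$window_height * cfg$width)))
  if (length(windows) == 1L) Xf <- matrix(Xf, nrow = 1)
  Xf
}

#' Train the CNN path-stack scorer
#'
#' @param examples regression examples from [build_stack_examples()]: list
#'   with `windows` (list of `window_height x width` matrices) and `rating`
#'   (reals in `[0, 1]`, the Jaccard index of the A--C link).
#' @param config a [cnn_config()].
#' @param train a [train_config()] (learning rate 1e-5 is the full-scale
#'   default for this model).
#' @return An object of class `lbd_cnn` with final parameters, batch-norm
#'   running statistics, per-epoch training MSE (in original rating units),
#'   and checkpoints.
#'
#' @details Ratings are standardised internally to `[0, 1]` span (divided
#'   by their maximum) for optimisation and predictions are mapped back at
#'   inference. Jaccard ratings of real co-occurrence graphs are tiny
#'   (often < 0.1), which otherwise starves the softplus output unit of
#'   gradient; the transform is linear, so rankings are unaffected.
#' @export
train_cnn <- function(examples, config, train = train_config(learning_rate = 1e-5)) {
  Xf <- flatten_windows(examples$windows, config)
  r0 <- as.numeric(examples$rating)
  rating_scale <- if (max(r0) > 0) 1 / max(r0) else 1
  r <- r0 * rating_scale
  with_lbd_seed(config$seed * 131L + train$seed, {
    params <- cnn_init(config)
    st <- adam_init(params)
    run_stats <- list(mean = numeric(config$conv_filters),
                      var = rep(1, config$conv_filters))
    losses <- numeric(train$epochs)
    checkpoints <- list()
    for (ep in seq_len(train$epochs)) {
      for (b in epoch_batches(nrow(Xf), train$batch_size)) {
        g <- cnn_grad(params, config, Xf[b, , drop = FALSE], r[b], run_stats)
        run_stats$mean <- 0.9 * run_stats$mean + 0.1 * g$batch_mean
        run_stats$var <- 0.9 * run_stats$var + 0.1 * g$batch_var
        upd <- adam_step(params, g$grads, st, train$learning_rate)
        params <- upd$params; st <- upd$state
      }
      losses[ep] <- cnn_loss(params, config, Xf, r, run_stats,
                             train_mode = FALSE) / rating_scale^2
      if (ep %% train$eval_interval_epochs == 0L || ep == train$epochs)
        checkpoints[[length(checkpoints) + 1L]] <-
          list(epoch = ep, params = params, run_stats = run_stats,
               rating_scale = rating_scale)
    }
    structure(list(config = config, params = params, run_stats = run_stats,
                   rating_scale = rating_scale, losses = losses,
                   checkpoints = checkpoints),
              class = c("lbd_cnn", "lbd_scorer"))
  })
}

#' @export
score.lbd_cnn <- function(scorer, features) {
  if (is.matrix(features)) features <- list(features)
  Xf <- flatten_windows(features, scorer$config)
  sc <- if (is.null(scorer$rating_scale)) 1 else scorer$rating_scale
  cnn_score_params(scorer$params, scorer$config, scorer$run_stats, Xf) / sc
}

cnn_score_params <- function(params, cfg, run_stats, Xf) {
  cnn_forward(params, cfg, Xf, run_stats, train_mode = FALSE)$out
}

#' @export
print.lbd_cnn <- function(x, ...) {
  cat(sprintf(
    "<lbd_cnn> window %dx%d, %d filters (kernel %dx%d), fc %d; final MSE %.5f\n",
    x$config$window_height, x$config$width, x$config$conv_filters,
    x$config$conv_height, x$config$width, x$config$fc_units,
    x$losses[length(x$losses)]))
  invisible(x)
}
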