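# Shared neural-network machinery: activations, Adam optimiser state, and
# the training configuration common to the MLP and CNN scorers.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
relu <- function(x) pmax(x, 0)

# Adam: one moment pair per parameter matrix, standard bias correction.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / b1t) / (sqrt(state$v[[k]] / b2t) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration for the neural scorers
#'
#' Defaults follow the full-scale protocol (batch 100, 200,000 examples,
#' 150 epochs, Adam, learning rate 1e-4 for the MLP and 1e-5 for the CNN,
#' checkpoint every 5 epochs); scale `train_set_size` and `epochs` down for
#' desk-size experiments.
#'
#' @param batch_size minibatch size.
#' @param train_set_size number of training examples to build.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param eval_interval_epochs checkpoint spacing (5 for case replication,
#'   25 for time-sliced runs).
#' @param seed integer seed for shuffling and initialisation.
#' @export
train_config <- function(batch_size = 100L, train_set_size = 200000L,
                         epochs = 150L, learning_rate = 1e-4,
                         eval_interval_epochs = 5L, seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size),
              train_set_size = as.integer(train_set_size),
              epochs = as.integer(epochs),
              learning_rate = learning_rate,
              eval_interval_epochs = as.integer(eval_interval_epochs),
              seed = as.integer(seed))
  if (any(unlist(cfg[c(1, 2, 3, 5)]) < 1) || learning_rate <= 0)
    lbd_stop("lbd_config_error", "train_config: all settings must be positive")
  cfg
}

# Iterate minibatches of a shuffled index vector.
epoch_batches <- function(n, batch_size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}
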