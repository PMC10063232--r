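#' Training configuration
#'
#' Optimiser schedule and batching settings.  Defaults are the published
#' full-scale settings: Adam(0.9, 0.999, 1e-8) at a peak learning rate of
#' 1.5e-3 with 3000 linear warmup steps, exponential decay by 0.997 every
#' 1000 steps, and gradient clipping at global norm 1.  Batch size is dynamic:
#' records are bucketed by length under a per-batch token budget, so short
#' sequences share large batches and long ones go nearly alone.
#'
#' @param train_steps number of optimiser steps.
#' @param learning_rate peak learning rate.
#' @param decay_rate,decay_steps exponential decay after warmup:
#'   `learning_rate * decay_rate^((step - warmup_steps)/decay_steps)`.
#' @param warmup_steps linear warmup length (must be < `train_steps`).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @param gradient_clip global-norm clip value.
#' @param token_budget maximum `max_length x batch_size` per batch.
#' @param staircase if `TRUE`, the decay exponent is floored to an integer;
#'   default is the continuous (smoother) exponent.
#' @param seed integer seed for batch shuffling.
#' @export
train_config <- function(train_steps, learning_rate = 1.5e-3,
                         decay_rate = 0.997, decay_steps = 1000L,
                         warmup_steps = 3000L, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         gradient_clip = 1.0, token_budget = 2048L,
                         staircase = FALSE, seed = 1L) {
  stopifnot(train_steps >= 0L, learning_rate > 0, decay_rate > 0,
            decay_steps > 0, warmup_steps >= 0,
            train_steps == 0L || warmup_steps < train_steps,
            gradient_clip > 0, token_budget >= 1L)
  structure(list(train_steps = as.integer(train_steps),
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps),
                 warmup_steps = as.integer(warmup_steps),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, gradient_clip = gradient_clip,
                 token_budget = as.integer(token_budget),
                 staircase = isTRUE(staircase), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a step
#'
#' Linear warmup from 0 to the peak rate over `warmup_steps`, then
#' exponential decay; continuous at the warmup boundary and monotone
#' decreasing afterwards.
#'
#' @param config a [train_config()].
#' @param step step number (vectorised, >= 0).
#' @export
lr_at_step <- function(config, step) {
  stopifnot(all(step >= 0))
  w <- config$warmup_steps
  expo <- (step - w) / config$decay_steps
  if (config$staircase) expo <- floor(expo)
  ifelse(step <= w,
         if (w > 0) config$learning_rate * step / w else config$learning_rate,
         config$learning_rate * config$decay_rate^expo)
}

#' Multi-label binary cross-entropy
#'
#' Mean over the vocabulary of `-(y log p + (1-y) log(1-p))`, probabilities
#' clamped to `[eps, 1-eps]`.  The mean (rather than sum) keeps learning
#' rates transferable across vocabulary sizes.
#'
#' @param p numeric vector of probabilities over the vocabulary.
#' @param y 0/1 vector (or logical) of the same length.
#' @param eps clamp value.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  stopifnot(length(p) == length(y))
  p <- pmin(pmax(p, eps), 1 - eps)
  y <- as.numeric(y)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Length-dynamic batching
#'
#' Buckets records by length so that every batch satisfies
#' `max(length) * batch_size <= token_budget` (the cost of a padded batch),
#' with every record appearing exactly once and batch order shuffled by
#' `seed`.
#'
#' @param lengths integer sequence lengths.
#' @param token_budget per-batch token budget (>= `max(lengths)`).
#' @param seed integer seed for the shuffle.
#' @return list of integer index vectors into `lengths`.
#' @export
make_batches <- function(lengths, token_budget, seed = 1L) {
  if (length(lengths) == 0L) return(list())
  if (max(lengths) > token_budget)
    stop(sprintf("record of length %d exceeds the token budget %d",
                 max(lengths), token_budget))
  ord <- order(lengths, seq_along(lengths))
  batches <- list()
  cur <- integer(0)
  for (i in ord) {
    # ascending order: lengths[i] is the running max of the candidate batch
    if (length(cur) > 0L && lengths[i] * (length(cur) + 1L) > token_budget) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0)
    }
    cur <- c(cur, i)
  }
  batches[[length(batches) + 1L]] <- cur
  withr::with_seed(as.integer(seed), sample(batches))
}

label_matrix <- function(labels_list, vocabulary) {
  Y <- matrix(0, length(labels_list), length(vocabulary))
  idx <- lapply(labels_list, function(l) match(l, vocabulary))
  for (i in seq_along(idx)) {
    if (anyNA(idx[[i]]))
      stop("record labelled outside the model vocabulary: ",
           paste(labels_list[[i]][is.na(idx[[i]])], collapse = ", "))
    Y[i, idx[[i]]] <- 1
  }
  Y
}

#' Train a model
#'
#' Adam with linear warmup, exponential decay, and global-norm gradient
#' clipping, over length-bucketed dynamic batches.  Deterministic given the
#' configuration seed on a single device.
#'
#' @param model a `protfun_model` (e.g. from [build_model()]).
#' @param corpus a `protein_corpus`; every record label must be in the model
#'   vocabulary.
#' @param config a [train_config()].
#' @param checkpoint_path if non-`NULL`, a checkpoint is written here every
#'   `checkpoint_every` steps and at the end.
#' @param checkpoint_every checkpoint period in steps.
#' @param verbose print progress every 500 steps.
#' @return list with `model` (trained) and `log`, a data frame of per-step
#'   `loss` and `lr`.
#' @export
train_model <- function(model, corpus, config, checkpoint_path = NULL,
                        checkpoint_every = 1000L, verbose = FALSE) {
  stopifnot(inherits(model, "protfun_model"), inherits(config, "train_config"))
  if (config$train_steps == 0L)
    return(list(model = model, log = data.frame(step = integer(0),
                                                loss = numeric(0),
                                                lr = numeric(0))))
  enc <- lapply(corpus$sequence, seq_to_int)
  lens <- lengths(enc)
  Yall <- label_matrix(corpus$labels, model$config$vocabulary)
  batches <- make_batches(lens, config$token_budget, config$seed)
  theta <- model$theta
  m <- v <- numeric(length(theta))
  log_loss <- log_lr <- numeric(config$train_steps)
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; eps <- config$adam_eps
  bi <- 0L; epoch <- 0L
  for (step in seq_len(config$train_steps)) {
    bi <- bi + 1L
    if (bi > length(batches)) {
      epoch <- epoch + 1L
      batches <- withr::with_seed(config$seed + epoch, sample(batches))
      bi <- 1L
    }
    idx <- batches[[bi]]
    g <- cpp_batch_grad(theta, model$dims, enc[idx],
                        Yall[idx, , drop = FALSE])
    if (!is.finite(g$loss))
      stop(sprintf("non-finite loss at step %d; aborting training", step))
    grad <- g$grad
    gn <- sqrt(sum(grad^2))
    if (gn > config$gradient_clip) grad <- grad * (config$gradient_clip / gn)
    lr <- lr_at_step(config, step)
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    mhat <- m / (1 - b1^step)
    vhat <- v / (1 - b2^step)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    log_loss[step] <- g$loss
    log_lr[step] <- lr
    if (verbose && step %% 500L == 0L)
      message(sprintf("step %d  loss %.4f  lr %.2e", step, g$loss, lr))
    if (!is.null(checkpoint_path) && step %% checkpoint_every == 0L) {
      model$theta <- theta
      save_model(model, checkpoint_path)
    }
  }
  model$theta <- theta
  if (!is.null(checkpoint_path)) save_model(model, checkpoint_path)
  list(model = model,
       log = data.frame(step = seq_len(config$train_steps),
                        loss = log_loss, lr = log_lr))
}
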