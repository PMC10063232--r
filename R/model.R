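#' Model configuration
#'
#' Hyperparameters of the dilated residual convolutional network.  The
#' defaults are the full-scale settings (1100 filters, 5 residual blocks);
#' desk-scale experiments use smaller values such as `filters = 64,
#' num_res_layers = 2`.
#'
#' The network is: an initial kernel-size, dilation-1 convolution lifting the
#' 20-dim one-hot input to `filters` channels; `num_res_layers` pre-activation
#' bottleneck residual blocks `x + P(relu(N(D(relu(N(x))))))` where `D` is a
#' dilated convolution to `filters * bottleneck_factor` channels and `P` a
#' kernel-1 width-restoring convolution; a masked mean pool over positions;
#' and an affine head to one logit per vocabulary label, squashed
#' element-wise by a sigmoid.  Block `k` (1-indexed) uses dilation
#' `dilation_rate^(k - first_dilated_layer + 1)` for
#' `k >= first_dilated_layer`, else 1 (defaults: 1, 3, 9, 27, 81).
#'
#' @param vocabulary ordered character vector of label ids; fixed at
#'   construction, duplicate-free.
#' @param filters number of channels carried by the residual stack.
#' @param kernel_size convolution kernel width (odd).
#' @param num_res_layers number of residual blocks.
#' @param dilation_rate geometric growth factor of the dilation schedule.
#' @param first_dilated_layer first block (1-indexed) with dilation > 1.
#' @param bottleneck_factor width multiplier inside a block, in (0, 1].
#' @param norm `"none"` (default) or `"layer"` (per-position normalisation
#'   over channels).  Layer normalisation rescales every position's feature
#'   vector to unit variance, which erases the amplitude contrast between
#'   informative and background positions that mean pooling relies on; at
#'   desk scale this stalls learning, so the unnormalised stack is the
#'   default (see the methods vignette).
#' @return an object of class `model_config`.
#' @export
model_config <- function(vocabulary, filters = 1100L, kernel_size = 9L,
                         num_res_layers = 5L, dilation_rate = 3L,
                         first_dilated_layer = 2L, bottleneck_factor = 0.5,
                         norm = c("none", "layer")) {
  norm <- match.arg(norm)
  vocabulary <- as.character(vocabulary)
  stopifnot(length(vocabulary) >= 1L, !anyDuplicated(vocabulary),
            filters >= 1L, kernel_size >= 1L, kernel_size %% 2L == 1L,
            num_res_layers >= 0L, dilation_rate >= 1L,
            first_dilated_layer >= 1L,
            bottleneck_factor > 0, bottleneck_factor <= 1)
  structure(list(vocabulary = vocabulary,
                 filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 num_res_layers = as.integer(num_res_layers),
                 dilation_rate = as.integer(dilation_rate),
                 first_dilated_layer = as.integer(first_dilated_layer),
                 bottleneck_factor = bottleneck_factor,
                 norm = norm),
            class = "model_config")
}

config_dims <- function(config) {
  c(filters = config$filters,
    bottleneck = max(1L, as.integer(round(config$filters * config$bottleneck_factor))),
    kernel = config$kernel_size,
    vocab = length(config$vocabulary),
    blocks = config$num_res_layers,
    rate = config$dilation_rate,
    first_dilated = config$first_dilated_layer,
    norm = if (config$norm == "layer") 1L else 0L)
}

#' Theoretical receptive-field radius
#'
#' Residues farther than this many positions from position `i` cannot
#' influence the per-residue feature at `i`.
#' @param config a [model_config()].
#' @export
receptive_field_radius <- function(config) {
  half <- config$kernel_size %/% 2L
  dil <- vapply(seq_len(config$num_res_layers), function(l) {
    if (l < config$first_dilated_layer) 1
    else config$dilation_rate^(l - config$first_dilated_layer + 1L)
  }, 0)
  as.integer(half * (1 + sum(dil)))
}

seq_to_int <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, .AA)
  if (anyNA(code))
    stop(sprintf("nonstandard residue '%s' at position %d",
                 chars[which(is.na(code))[1L]], which(is.na(code))[1L]))
  as.integer(code) - 1L
}

#' One-hot sequence encoding
#'
#' @param seq amino-acid sequence over the 20 standard letters.
#' @return an L x 20 matrix with a single 1 per row; columns are the
#'   amino-acid letters in alphabetical order.
#' @export
encode_sequence <- function(seq) {
  code <- seq_to_int(seq)
  out <- matrix(0, length(code), 20L, dimnames = list(NULL, .AA))
  out[cbind(seq_along(code), code + 1L)] <- 1
  out
}

#' @rdname encode_sequence
#' @param encoding an L x 20 one-hot matrix.
#' @export
decode_encoding <- function(encoding) {
  stopifnot(ncol(encoding) == 20L, all(rowSums(encoding) == 1))
  paste(.AA[max.col(encoding)], collapse = "")
}

#' Build a model with seeded He initialisation
#'
#' Convolution and head weights are drawn fan-in scaled (He-style for the
#' ReLU stack); normalisation gains start at 1, biases at 0.  The same seed
#' always yields the same parameters.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return an object of class `protfun_model`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  dims <- config_dims(config)
  shapes <- cpp_param_shapes(dims)
  theta <- withr::with_seed(as.integer(seed), {
    unlist(lapply(shapes, function(s) {
      n <- s$nrow * s$ncol
      switch(s$kind,
             conv = stats::rnorm(n, sd = sqrt(2 / s$ncol)),
             head = stats::rnorm(n, sd = sqrt(1 / s$ncol)),
             gain = rep(1, n),
             bias = rep(0, n))
    }))
  })
  structure(list(config = config, dims = dims, theta = theta),
            class = "protfun_model")
}

#' @export
print.protfun_model <- function(x, ...) {
  cat(sprintf(paste0("<protfun_model> %d filters, %d residual blocks, kernel %d,",
                     " %d labels, %s parameters\n"),
              x$config$filters, x$config$num_res_layers, x$config$kernel_size,
              length(x$config$vocabulary),
              format(length(x$theta), big.mark = ",")))
  invisible(x)
}

# head weights as a V x F matrix (used by the head itself and by CAM)
head_weights <- function(model) {
  d <- model$dims
  nhead <- d[["vocab"]] * d[["filters"]] + d[["vocab"]]
  w <- model$theta[seq.int(length(model$theta) - nhead + 1L,
                           length.out = d[["vocab"]] * d[["filters"]])]
  matrix(w, d[["vocab"]], d[["filters"]],
         dimnames = list(model$config$vocabulary, NULL))
}

head_bias <- function(model) {
  d <- model$dims
  b <- model$theta[seq.int(length(model$theta) - d[["vocab"]] + 1L,
                           length.out = d[["vocab"]])]
  names(b) <- model$config$vocabulary
  b
}

#' Run the network on one sequence
#'
#' @param model a `protfun_model`.
#' @param seq an amino-acid sequence.
#' @param pad number of masked padding positions appended (for testing that
#'   padding inside a batch cannot change the outputs).
#' @param features if `TRUE`, also return the L x filters per-residue feature
#'   matrix that feeds the mean pool.
#' @return list with `logits`, `probabilities` (named by vocabulary),
#'   `embedding` (length `filters`), and optionally `features`.
#' @export
model_forward <- function(model, seq, pad = 0L, features = FALSE) {
  stopifnot(inherits(model, "protfun_model"))
  out <- cpp_forward_one(model$theta, model$dims, seq_to_int(seq),
                         as.integer(pad), isTRUE(features))
  names(out$logits) <- names(out$probabilities) <- model$config$vocabulary
  out
}

#' Per-label probabilities for many sequences
#'
#' @param model a `protfun_model`.
#' @param x a `protein_corpus` or character vector of sequences.
#' @return matrix of probabilities, one row per sequence, one column per
#'   vocabulary label.
#' @export
predict_proba <- function(model, x) {
  seqs <- if (inherits(x, "protein_corpus")) x$sequence else as.character(x)
  if (length(seqs) == 0L) stop("empty batch")
  nm <- if (inherits(x, "protein_corpus")) x$accession else names(x)
  enc <- lapply(seqs, seq_to_int)
  out <- cpp_predict_many(model$theta, model$dims, enc)
  dimnames(out$probabilities) <- list(nm, model$config$vocabulary)
  out$probabilities
}

#' Threshold the per-label probabilities of one sequence
#'
#' Returns all labels with predicted probability at or above the confidence
#' threshold; lowering the threshold trades precision for recall.
#'
#' @inheritParams model_forward
#' @param threshold confidence threshold in \[0, 1\].
#' @export
predict_labels <- function(model, seq, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  p <- model_forward(model, seq)$probabilities
  names(p)[p >= threshold]
}

#' Long-format prediction set for evaluation
#'
#' One row per (accession, label) pair with the model's probability, the form
#' consumed by [pr_curve()] and written by the `predict` CLI subcommand.
#'
#' @inheritParams predict_proba
#' @export
prediction_set <- function(model, x) {
  p <- predict_proba(model, x)
  data.frame(accession = rep(rownames(p), times = ncol(p)),
             label = rep(colnames(p), each = nrow(p)),
             score = as.vector(p),
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a versioned list holding the configuration and the flat
#' parameter vector.
#' @param model a `protfun_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "protfun_checkpoint", version = 1L,
               config = unclass(model$config), theta = model$theta),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "protfun_checkpoint"))
    stop("not a protfun checkpoint: ", path)
  cfg <- do.call(model_config, x$config[c("vocabulary", "filters", "kernel_size",
                                          "num_res_layers", "dilation_rate",
                                          "first_dilated_layer",
                                          "bottleneck_factor", "norm")])
  structure(list(config = cfg, dims = config_dims(cfg), theta = x$theta),
            class = "protfun_model")
}
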