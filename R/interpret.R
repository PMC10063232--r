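#' Class activation map over residues
#'
#' For a mean-pooling network with an affine output head, the logit of class
#' `c` decomposes exactly over positions: `z_c = mean_i(W[,c] . F_i) + b_c`,
#' where `F_i` is the per-residue feature at position `i`.  The per-residue,
#' per-class score `s[i, c] = W[,c] . F_i` is therefore an exact attribution
#' of the logit to sequence positions (no gradient approximation is needed),
#' and is what this function returns.
#'
#' @param model a `protfun_model`.
#' @param seq an amino-acid sequence.
#' @param classes label ids (subset of the vocabulary) to map.
#' @return an object of class `activation_map`: `scores` (L x classes
#'   matrix), `classes`, `bias` (per-class head bias), `logits`, and
#'   `normalized` (`FALSE`; see [normalize_cam()]).
#' @export
cam <- function(model, seq, classes) {
  stopifnot(inherits(model, "protfun_model"), length(classes) >= 1L)
  unknown <- setdiff(classes, model$config$vocabulary)
  if (length(unknown))
    stop("unknown class(es): ", paste(unknown, collapse = ", "))
  fw <- model_forward(model, seq, features = TRUE)
  W <- head_weights(model)[classes, , drop = FALSE]
  scores <- fw$features %*% t(W)
  colnames(scores) <- classes
  structure(list(scores = scores, classes = classes,
                 bias = head_bias(model)[classes],
                 logits = fw$logits[classes], normalized = FALSE),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map>%s %d positions x %d class(es): %s\n",
              if (x$normalized) " (normalized)" else "",
              nrow(x$scores), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Cross-class normalisation of an activation map
#'
#' Makes each class's localisation more specific by subtracting, at every
#' residue, the mean score of all *other* mapped classes:
#' `n[i, c] = s[i, c] - mean(s[i, c'] : c' != c)`.  With exactly two classes
#' this is the pairwise difference (antisymmetric), which prevents a shared
#' high-activation region from being attributed to both functions.
#'
#' @param map an [cam()] activation map with at least two classes.
#' @export
normalize_cam <- function(map) {
  stopifnot(inherits(map, "activation_map"))
  k <- length(map$classes)
  if (k < 2L) stop("cross-class normalisation needs at least 2 classes")
  s <- map$scores
  other_mean <- (rowSums(s) - s) / (k - 1)
  map$scores <- s - other_mean
  map$normalized <- TRUE
  map
}

#' Centre of mass of a per-residue score track
#'
#' Weights are the scores clipped at zero; the centre of mass is
#' `sum(i * w_i) / sum(w_i)` over 0-based positions.  If no score is
#' positive, the raw scores shifted to non-negative are used instead; a
#' completely flat zero track is an error ("no signal").
#'
#' @param scores numeric vector of per-residue scores.
#' @return fractional 0-based position.
#' @export
center_of_mass <- function(scores) {
  stopifnot(length(scores) >= 1L)
  w <- pmax(scores, 0)
  if (sum(w) <= 0) w <- scores - min(scores)
  if (sum(w) <= 0) stop("no signal: all scores equal")
  pos <- seq_along(scores) - 1
  sum(pos * w) / sum(w)
}

#' Order the two functional domains of a bifunctional protein
#'
#' Mirrors the coarse localisation experiment: the candidate set is proteins
#' on which exactly two leaf classes are predicted above the threshold; for
#' those, the two classes' cross-class-normalised activation maps are reduced
#' to centres of mass and ordered along the sequence (ascending; centre-of-
#' mass ties fall back to label id for determinism).
#'
#' @param model a `protfun_model`.
#' @param seq an amino-acid sequence.
#' @param leaves character vector of leaf label ids among which predictions
#'   are counted (the most specific level of the hierarchy).
#' @param threshold prediction threshold (default 0.5).
#' @param use_normalized order by normalised (default) or raw CAM scores.
#' @return list `order` (the two labels, N- to C-terminal), `com` (named
#'   centres of mass), `probabilities` (the two leaf probabilities).
#' @export
order_domains <- function(model, seq, leaves, threshold = 0.5,
                          use_normalized = TRUE) {
  p <- model_forward(model, seq)$probabilities[leaves]
  pred <- names(p)[p >= threshold]
  if (length(pred) != 2L)
    stop(sprintf("expected exactly 2 predicted leaf classes at threshold %g, got %d",
                 threshold, length(pred)))
  m <- cam(model, seq, pred)
  if (use_normalized) m <- normalize_cam(m)
  com <- vapply(pred, function(cl) center_of_mass(m$scores[, cl]), 0)
  ord <- order(com, pred)
  list(order = pred[ord], com = com, probabilities = p[pred])
}

#' Pooled sequence embedding
#'
#' The penultimate-layer representation: the masked mean over positions of
#' the per-residue features, a single `filters`-dimensional vector per
#' protein (1100-dimensional at the default configuration).
#'
#' @param model a `protfun_model`.
#' @param x a `protein_corpus` or character vector of sequences.
#' @return matrix, one row per sequence, `filters` columns.
#' @export
embed <- function(model, x) {
  seqs <- if (inherits(x, "protein_corpus")) x$sequence else as.character(x)
  if (length(seqs) == 0L) stop("empty batch")
  nm <- if (inherits(x, "protein_corpus")) x$accession else names(x)
  out <- cpp_predict_many(model$theta, model$dims, lapply(seqs, seq_to_int))
  rownames(out$embeddings) <- nm
  out$embeddings
}

#' Probe an embedding space with a simple supervised classifier
#'
#' Trains a small random-forest classifier on frozen embeddings for a binary
#' label the embedding model was never supervised on, and reports test-fold
#' precision, recall and F1.  A high score shows the embedding space carries
#' that property; a shuffled-label control should fall to the base rate.
#'
#' @param embeddings numeric matrix (rows = examples).
#' @param labels logical (or 0/1) vector, one per row.
#' @param train_fraction fraction of examples used to fit the probe.
#' @param ntree random-forest size.
#' @param seed integer seed (controls the train/test split and the forest).
#' @return list `precision`, `recall`, `f1`, `n_train`, `n_test`.
#' @export
embedding_probe <- function(embeddings, labels, train_fraction = 0.2,
                            ntree = 100L, seed = 1L) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("embedding_probe requires the randomForest package")
  labels <- as.logical(labels)
  stopifnot(nrow(embeddings) == length(labels), !anyNA(labels))
  withr::with_seed(as.integer(seed), {
    n <- length(labels)
    tr <- sample(n, max(2L, round(train_fraction * n)))
    if (length(unique(labels[tr])) < 2L)
      stop("single-class training data; cannot fit a probe")
    fit <- randomForest::randomForest(
      x = embeddings[tr, , drop = FALSE],
      y = factor(labels[tr], levels = c(FALSE, TRUE)),
      ntree = ntree)
    pred <- stats::predict(fit, embeddings[-tr, , drop = FALSE]) == "TRUE"
    truth <- labels[-tr]
    tp <- sum(pred & truth)
    precision <- if (sum(pred) > 0) tp / sum(pred) else 1
    recall <- if (sum(truth) > 0) tp / sum(truth) else 1
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    list(precision = precision, recall = recall, f1 = f1,
         n_train = length(tr), n_test = n - length(tr))
  })
}
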