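# The package's desk-scale reproducibility study: one seeded synthetic
# proteome, one small trained network, and the evaluation harnesses the
# README and scripts/acceptance.R report on.  Kept in the package (rather
# than in the script) so the exact study conditions are versioned, tested
# and callable.

#' Desk-scale synthetic study
#'
#' Builds the package's reference benchmark — a 4-level ontology with
#' branching 2 x 3 x 4 (24 leaves, 33 labels); 2000 sequences of length
#' 100-600 with 10% bifunctional records, 10% non-enzymes and 5% motif
#' mutation noise; an 80/10/10 random split — and trains a 64-filter,
#' 2-residual-block network on the training fold for `train_steps` steps
#' (published optimiser constants; desk-scale warmup 500 and token budget
#' 4096, see the methods vignette).
#'
#' @param seed integer; drives corpus generation, the split, initialisation
#'   and batching.
#' @param train_steps optimiser steps (5000 for the reference study).
#' @param learning_rate peak learning rate of the desk-scale schedule.
#' @param verbose print training progress.
#' @return list with the ontology (`graph`), generator output (`syn`),
#'   `split`, fold corpora (`train`, `dev`, `test`), the trained `model` and
#'   the training `log`.
#' @export
run_desk_study <- function(seed = 1L, train_steps = 5000L,
                           learning_rate = 5e-3, verbose = FALSE) {
  seed <- as.integer(seed)
  graph <- make_ontology(4L, c(2L, 3L, 4L))
  syn <- make_corpus(graph, n = 2000L, length_range = c(100L, 600L),
                     bifunctional_fraction = 0.1, nonenzyme_fraction = 0.1,
                     mutation_rate = 0.05, motif_length = 12L, seed = seed)
  split <- random_split(syn$corpus, seed = seed)
  folds <- lapply(c(train = "train", dev = "dev", test = "test"),
                  function(f) corpus_fold(syn$corpus, split, f))
  cfg <- model_config(graph$labels, filters = 64L, num_res_layers = 2L)
  tcfg <- train_config(train_steps = train_steps,
                       learning_rate = learning_rate,
                       warmup_steps = min(500L, max(0L, train_steps - 1L)),
                       token_budget = 4096L, seed = seed)
  fit <- train_model(build_model(cfg, seed = seed), folds$train, tcfg,
                     verbose = verbose)
  c(list(graph = graph, syn = syn, split = split, model = fit$model,
         log = fit$log), folds)
}

#' Domain-ordering accuracy on bifunctional records
#'
#' Applies [order_domains()] to every record: candidates are records where
#' exactly two leaf classes are predicted above the threshold and the
#' predicted pair equals the planted pair; a candidate is correct when the
#' predicted N-to-C order matches the planted span order.
#'
#' @param model a trained `protfun_model`.
#' @param syn_bi a [make_corpus()] result with bifunctional records.
#' @param leaves leaf label ids of the ontology.
#' @param threshold prediction threshold (0.5, the published candidate rule).
#' @return list `accuracy`, `n_candidates`, `n_records`, `n_correct`.
#' @export
ordering_accuracy <- function(model, syn_bi, leaves, threshold = 0.5) {
  truth_by <- split(syn_bi$truth, syn_bi$truth$accession)
  n_cand <- 0L; n_corr <- 0L
  for (i in seq_len(nrow(syn_bi$corpus))) {
    acc <- syn_bi$corpus$accession[i]
    od <- tryCatch(
      order_domains(model, syn_bi$corpus$sequence[i], leaves, threshold),
      error = function(e) NULL)
    if (is.null(od)) next
    tr <- truth_by[[acc]]
    if (is.null(tr) || nrow(tr) != 2L) next
    tr <- tr[order(tr$start), ]
    if (!setequal(od$order, tr$label)) next  # wrong pair: not a candidate
    n_cand <- n_cand + 1L
    if (identical(od$order, tr$label)) n_corr <- n_corr + 1L
  }
  list(accuracy = if (n_cand > 0L) n_corr / n_cand else NA_real_,
       n_candidates = n_cand, n_records = nrow(syn_bi$corpus),
       n_correct = n_corr)
}
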