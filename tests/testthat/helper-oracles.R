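# Shared fixtures and independent brute-force oracles.  The oracles use only
# base R (no igraph, no package internals) so they stay independent of the
# implementation paths they check.

ec_tree <- function() {
  parse_ontology(data.frame(
    child  = c("EC:3.2.1.2", "EC:3.2.1.-", "EC:3.2.-.-"),
    parent = c("EC:3.2.1.-", "EC:3.2.-.-", "EC:3.-.-.-")), "EC-like")
}

# random DAG edge list: nodes N1..Nn, edges only from lower to higher index
# (child -> parent), so acyclicity holds by construction
random_dag_edges <- function(n, p = 0.15) {
  ids <- sprintf("N%02d", seq_len(n))
  from <- NULL; to <- NULL
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (stats::runif(1) < p) { from <- c(from, ids[i]); to <- c(to, ids[j]) }
  }
  if (is.null(from))  # ensure non-empty
    { from <- ids[1L]; to <- ids[2L] }
  data.frame(child = from, parent = to, stringsAsFactors = FALSE)
}

# plain recursive DFS reachability over the parent map
oracle_ancestors <- function(edges, node) {
  seen <- character(0)
  walk <- function(x) {
    for (p in edges$parent[edges$child == x]) {
      if (!(p %in% seen)) { seen <<- c(seen, p); walk(p) }
    }
  }
  walk(node)
  sort(seen)
}

# iterate parent-adding to a fixed point
oracle_propagate <- function(edges, labels) {
  cur <- unique(labels)
  repeat {
    nxt <- unique(c(cur, edges$parent[edges$child %in% cur]))
    if (length(nxt) == length(cur)) return(sort(cur))
    cur <- nxt
  }
}

# direct recount of micro precision/recall at one threshold
oracle_pr_at <- function(pred, truth, thr) {
  pk <- paste(pred$accession, pred$label)
  tk <- unique(paste(truth$accession, truth$label))
  predicted <- pk[pred$score >= thr]
  tp <- sum(predicted %in% tk)
  fp <- length(predicted) - tp
  fn <- length(tk) - tp
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 1,
       recall = tp / length(tk), tp = tp, fp = fp, fn = fn)
}

# random prediction/truth instance over a small accession x label grid
random_eval_case <- function(n_acc = 8, n_lab = 5) {
  acc <- sprintf("P%02d", seq_len(n_acc))
  lab <- sprintf("L%d", seq_len(n_lab))
  grid <- expand.grid(accession = acc, label = lab,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pred <- grid[stats::runif(nrow(grid)) < 0.7, , drop = FALSE]
  pred$score <- round(stats::runif(nrow(pred)), 2)  # duplicated scores likely
  truth <- grid[stats::runif(nrow(grid)) < 0.3, , drop = FALSE]
  if (nrow(truth) == 0L) truth <- grid[1L, , drop = FALSE]
  rownames(pred) <- rownames(truth) <- NULL
  list(pred = pred, truth = truth)
}

# small random model over a tiny vocabulary, for structural checks
tiny_model <- function(vocab = c("A", "B", "C"), filters = 12, blocks = 2,
                       seed = 1, norm = "layer") {
  build_model(model_config(vocab, filters = filters, num_res_layers = blocks,
                           norm = norm), seed = seed)
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
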