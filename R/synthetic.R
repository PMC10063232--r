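#' Synthetic label hierarchy
#'
#' Builds a complete rooted tree of synthetic labels with EC-style path names
#' (root `S:0`, then `S:1`, `S:1.2`, ...).  `branching` may be a single factor
#' (a uniform tree with `branching^(levels-1)` leaves) or a vector of
#' per-level factors of length `levels - 1` (e.g. `c(2, 3, 4)` gives a
#' 4-level tree with 24 leaves).
#'
#' @param levels number of levels including the root (>= 2).
#' @param branching children per node: scalar or vector of length `levels - 1`.
#' @return a [label_graph][parse_ontology] with namespace `"synthetic"`.
#' @export
make_ontology <- function(levels, branching) {
  stopifnot(levels >= 2L)
  branching <- as.integer(branching)
  if (length(branching) == 1L) branching <- rep(branching, levels - 1L)
  stopifnot(length(branching) == levels - 1L, all(branching >= 2L))
  parents <- "S:0"
  edges <- NULL
  for (lev in seq_len(levels - 1L)) {
    kids <- unlist(lapply(parents, function(p) {
      stem <- if (identical(p, "S:0")) "S:" else paste0(p, ".")
      paste0(stem, seq_len(branching[lev]))
    }))
    edges <- rbind(edges, data.frame(
      child = kids, parent = rep(parents, each = branching[lev]),
      stringsAsFactors = FALSE))
    parents <- kids
  }
  parse_ontology(edges, "synthetic")
}

mutate_motif <- function(motif, rate) {
  if (rate <= 0) return(motif)
  hit <- stats::runif(length(motif)) < rate
  if (any(hit)) {
    motif[hit] <- vapply(motif[hit],
                         function(a) sample(setdiff(.AA, a), 1L), "")
  }
  motif
}

#' Synthetic proteome with planted motifs
#'
#' Generates `n` variable-length sequences over the 20-letter alphabet with
#' i.i.d. uniform background composition.  Each leaf label of `graph` gets a
#' random motif; class membership is determined by planting that motif (with
#' per-position substitution noise) at a uniformly random position.  A
#' fraction of records are bifunctional (two motifs from two distinct leaves
#' at non-overlapping positions, in uniformly random order) and a fraction
#' carry no motif and no labels (non-enzymes).  Everything is a deterministic
#' function of `seed`.
#'
#' The uniform background is deliberately uninformative so that recovering
#' the planted classes measures model skill, not composition bias.
#'
#' @param graph a [label_graph][parse_ontology]; motifs are attached to its leaves.
#' @param n number of records.
#' @param length_range integer (min, max) sequence length; bifunctional
#'   records are drawn from lengths that fit two motifs.
#' @param bifunctional_fraction fraction of records with two planted motifs.
#' @param nonenzyme_fraction fraction of records with no motif and no labels.
#' @param mutation_rate per-position substitution probability within a
#'   planted motif, in \[0, 0.5).
#' @param motif_length motif length (>= 5).
#' @param motifs optional motif table from a previous [make_corpus()] call
#'   (`label`, `motif` columns covering every leaf).  Supplying it generates
#'   new records from the *same* motif universe, e.g. held-out bifunctional
#'   evaluation sets for a model trained on an earlier corpus.
#' @param seed integer seed.
#' @return list with `corpus` (a `protein_corpus`), `truth` (data frame
#'   `accession`, `label`, `start`, `end`; 0-based half-open spans), and
#'   `motifs` (data frame `label`, `motif`, `mutation_rate`).
#' @export
make_corpus <- function(graph, n, length_range = c(100L, 600L),
                        bifunctional_fraction = 0.1,
                        nonenzyme_fraction = 0.1,
                        mutation_rate = 0.05, motif_length = 12L,
                        motifs = NULL, seed = 1L) {
  stopifnot(n >= 1L, motif_length >= 5L,
            mutation_rate >= 0, mutation_rate < 0.5,
            bifunctional_fraction >= 0, nonenzyme_fraction >= 0,
            bifunctional_fraction + nonenzyme_fraction <= 1)
  lo <- as.integer(length_range[1L]); hi <- as.integer(length_range[2L])
  leaves <- graph_leaves(graph)
  if (length(leaves) < 2L) stop("ontology must have at least 2 leaves")
  if (!is.null(motifs)) {
    stopifnot(all(leaves %in% motifs$label))
    mstr <- motifs$motif[match(leaves, motifs$label)]
    stopifnot(length(unique(nchar(mstr))) == 1L)
    m <- nchar(mstr[1L])
  } else {
    m <- as.integer(motif_length)
  }
  if (hi < 2L * m + 2L) stop("max length too short to fit motifs (need >= 2*motif_length + 2)")
  if (lo < m) stop("min length shorter than the motif")
  withr::with_seed(as.integer(seed), {
    motifs <- if (is.null(motifs)) {
      t(vapply(leaves, function(l) sample(.AA, m, replace = TRUE),
               character(m)))
    } else {
      mm <- do.call(rbind, strsplit(mstr, ""))
      rownames(mm) <- leaves
      mm
    }
    n_non <- round(n * nonenzyme_fraction)
    n_bi <- round(n * bifunctional_fraction)
    type <- sample(rep(c("none", "bi", "single"),
                       c(n_non, n_bi, n - n_non - n_bi)))
    acc <- sprintf("SYN%05d", seq_len(n))
    seqs <- character(n)
    leaf_labels <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      if (type[i] == "bi") {
        L <- sample(seq.int(max(lo, 2L * m + 2L), hi), 1L)
      } else {
        L <- sample(seq.int(lo, hi), 1L)
      }
      bg <- sample(.AA, L, replace = TRUE)
      if (type[i] == "none") {
        seqs[i] <- paste(bg, collapse = "")
        leaf_labels[[i]] <- character(0)
        next
      }
      k <- if (type[i] == "bi") 2L else 1L
      who <- sample(length(leaves), k)
      starts <- plant_positions(L, m, k)
      for (j in seq_len(k)) {
        mm <- mutate_motif(motifs[who[j], ], mutation_rate)
        bg[(starts[j] + 1L):(starts[j] + m)] <- mm
      }
      seqs[i] <- paste(bg, collapse = "")
      leaf_labels[[i]] <- leaves[who]
      truth[[i]] <- data.frame(accession = acc[i], label = leaves[who],
                               start = starts, end = starts + m,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
    rownames(truth) <- NULL
    corpus <- protein_corpus(acc, seqs, graph, leaf_labels = leaf_labels)
    list(corpus = corpus,
         truth = truth,
         motifs = data.frame(label = leaves,
                             motif = apply(motifs, 1L, paste, collapse = ""),
                             mutation_rate = mutation_rate,
                             stringsAsFactors = FALSE))
  })
}

# k non-overlapping 0-based starts for motifs of length m in a sequence of
# length L; uniform by rejection, with a deterministic fallback for tight fits
plant_positions <- function(L, m, k) {
  if (k == 1L) return(sample.int(L - m + 1L, 1L) - 1L)
  for (it in seq_len(100L)) {
    s <- sort(sample.int(L - m + 1L, k) - 1L)
    if (all(diff(s) >= m)) return(sample(s))  # random plant order
  }
  c(0L, L - m)
}

#' Read / write a planted-truth TSV (`accession<TAB>label<TAB>start<TAB>end`)
#'
#' Spans are 0-based half-open.
#' @param truth the `truth` data frame from [make_corpus()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    col.names = c("accession", "label", "start", "end"),
                    colClasses = c("character", "character", "integer", "integer"))
}
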