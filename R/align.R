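# BLOSUM62 restricted to the 20 standard residues, in alphabet order
blosum62_matrix <- function() {
  B <- get(utils::data("BLOSUM62", package = "Biostrings",
                       envir = environment()), envir = environment())
  m <- B[.AA, .AA]
  storage.mode(m) <- "integer"
  m
}

#' Smith-Waterman local alignment score
#'
#' Affine-gap (Gotoh) local alignment with BLOSUM62 and BLAST-convention gap
#' costs (a gap of length g costs `gap_open + g * gap_extend`; defaults
#' 11/1).  Score only, no traceback.
#'
#' @param query,subject amino-acid sequences.
#' @param gap_open,gap_extend gap penalties (positive).
#' @return the optimal local alignment raw score (integer, >= 0).
#' @export
sw_score <- function(query, subject, gap_open = 11L, gap_extend = 1L) {
  cpp_sw_score(seq_to_int(query), seq_to_int(subject), blosum62_matrix(),
               as.integer(gap_open), as.integer(gap_extend))
}

#' Convert a raw alignment score to a bit-score
#'
#' `S' = (lambda * S - ln K) / ln 2` with the standard BLOSUM62 gapped
#' Karlin-Altschul constants as defaults, making scores comparable across
#' searches.
#'
#' @param score raw alignment score(s).
#' @param lambda,K Karlin-Altschul parameters.
#' @export
bit_score <- function(score, lambda = 0.267, K = 0.041) {
  (lambda * score - log(K)) / log(2)
}

#' Top hit of a query against a training database
#'
#' Finds the highest-scoring training sequence for each query by local
#' alignment; the bit-score of the top match is later used as the
#' label-transfer confidence.  Backends: `"builtin"` (the package's
#' Smith-Waterman) or `"blastp"` (external NCBI BLAST+, if installed).  Ties
#' are broken by subject accession, lexicographically.
#'
#' @param queries a `protein_corpus` or named character vector of sequences.
#' @param train_db a `protein_corpus` (the training fold).
#' @param backend `"builtin"` or `"blastp"`.
#' @param gap_open,gap_extend gap penalties for the builtin backend.
#' @return data frame `accession`, `subject`, `score`, `bit_score`; queries
#'   with no positive-scoring alignment are absent.
#' @export
top_hits <- function(queries, train_db, backend = c("builtin", "blastp"),
                     gap_open = 11L, gap_extend = 1L) {
  backend <- match.arg(backend)
  if (nrow(train_db) == 0L) stop("empty training database")
  qseq <- if (inherits(queries, "protein_corpus")) {
    stats::setNames(queries$sequence, queries$accession)
  } else {
    stopifnot(!is.null(names(queries)))
    queries
  }
  if (backend == "blastp") return(top_hits_blastp(qseq, train_db))
  ord <- order(train_db$accession)  # lexicographic tie-break: first max wins
  db <- train_db[ord, , drop = FALSE]
  hits <- cpp_top_hits(lapply(qseq, seq_to_int),
                       lapply(db$sequence, seq_to_int),
                       blosum62_matrix(),
                       as.integer(gap_open), as.integer(gap_extend))
  found <- hits[, 1L] > 0L
  data.frame(accession = names(qseq)[found],
             subject = db$accession[hits[found, 1L]],
             score = hits[found, 2L],
             bit_score = bit_score(hits[found, 2L]),
             stringsAsFactors = FALSE)
}

top_hits_blastp <- function(qseq, train_db) {
  blastp <- Sys.which("blastp")
  makedb <- Sys.which("makeblastdb")
  if (!nzchar(blastp) || !nzchar(makedb))
    stop("blastp backend requested but NCBI BLAST+ is not on the PATH")
  dir <- tempfile("blastdb")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  dbfa <- file.path(dir, "db.fa"); qfa <- file.path(dir, "q.fa")
  write_fasta(stats::setNames(train_db$sequence, train_db$accession), dbfa)
  write_fasta(qseq, qfa)
  system2(makedb, c("-in", dbfa, "-dbtype", "prot"), stdout = FALSE)
  out <- system2(blastp, c("-query", qfa, "-db", dbfa,
                           "-outfmt", shQuote("6 qseqid sseqid bitscore score"),
                           "-max_target_seqs", "5"), stdout = TRUE)
  if (length(out) == 0L)
    return(data.frame(accession = character(0), subject = character(0),
                      score = numeric(0), bit_score = numeric(0)))
  tab <- utils::read.table(text = out, sep = "\t",
                           col.names = c("accession", "subject", "bit_score",
                                         "score"),
                           colClasses = c("character", "character", "numeric",
                                          "numeric"))
  tab <- tab[order(tab$accession, -tab$bit_score, tab$subject), ]
  tab <- tab[!duplicated(tab$accession), c("accession", "subject", "score",
                                           "bit_score")]
  rownames(tab) <- NULL
  tab
}

#' Transfer labels from top hits
#'
#' Every label of a query's top-hit training sequence is assigned the same
#' confidence: the bit-score of that match.  Queries without a hit receive no
#' predictions.  If the training labels are ancestor-closed, so is the
#' transferred set.
#'
#' @param hits data frame from [top_hits()].
#' @param train_corpus the training `protein_corpus` whose (ancestor-closed)
#'   labels are transferred.
#' @return a prediction data frame (`accession`, `label`, `score`).
#' @export
transfer_labels <- function(hits, train_corpus) {
  lab_of <- stats::setNames(train_corpus$labels, train_corpus$accession)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    labs <- lab_of[[hits$subject[i]]]
    if (is.null(labs) || length(labs) == 0L) return(NULL)
    data.frame(accession = hits$accession[i], label = labs,
               score = hits$bit_score[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(0), label = character(0),
                      score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Alignment-baseline prediction set
#'
#' Convenience wrapper: top hit per query, then label transfer with bit-score
#' confidence.
#' @inheritParams top_hits
#' @param train_corpus the training `protein_corpus` (database and labels).
#' @export
align_baseline <- function(queries, train_corpus,
                           backend = c("builtin", "blastp")) {
  transfer_labels(top_hits(queries, train_corpus, backend = backend),
                  train_corpus)
}

#' Combine alignment and network predictions
#'
#' Rescales each transferred bit-score by the (ensembled) network probability
#' for the same label: `score = bit_score * p`.  By default only labels in
#' the transferred top-hit set are kept (a network probability is looked up
#' for each, 0 if absent); with `union = TRUE`, network predictions for
#' labels outside the transferred set are appended with their probability as
#' the score.
#'
#' @param blast_pred prediction data frame from [align_baseline()].
#' @param cnn_pred network prediction data frame (probabilities in \[0, 1\]).
#' @param union keep network-only labels too (see above).
#' @export
combine_predictions <- function(blast_pred, cnn_pred, union = FALSE) {
  check_pred_frame(blast_pred)
  check_pred_frame(cnn_pred)
  pkey <- pair_key(cnn_pred$accession, cnn_pred$label)
  p_of <- stats::setNames(cnn_pred$score, pkey)
  bkey <- pair_key(blast_pred$accession, blast_pred$label)
  p <- p_of[bkey]
  p[is.na(p)] <- 0
  out <- data.frame(accession = blast_pred$accession,
                    label = blast_pred$label,
                    score = blast_pred$score * unname(p),
                    stringsAsFactors = FALSE)
  if (union) {
    extra <- cnn_pred[!(pkey %in% bkey) &
                        cnn_pred$accession %in% blast_pred$accession, ,
                      drop = FALSE]
    out <- rbind(out, extra[c("accession", "label", "score")])
  }
  rownames(out) <- NULL
  out
}

#' Approximate sequence clustering for small corpora
#'
#' Single-linkage clustering at a configurable similarity threshold, using
#' the builtin local aligner: two sequences are linked when their alignment
#' score reaches `threshold` times the smaller self-alignment score.  This is
#' a stand-in for externally computed identity clusterings (e.g. UniRef50
#' tables), intended only for small synthetic corpora; real cluster tables
#' should be consumed via [clustered_split()] directly.
#'
#' @param corpus a `protein_corpus`.
#' @param threshold fraction of the smaller self-score required to link two
#'   sequences (in (0, 1]).
#' @return named character vector mapping accession to cluster id.
#' @export
approx_clusters <- function(corpus, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(corpus)
  enc <- lapply(corpus$sequence, seq_to_int)
  sub <- blosum62_matrix()
  self <- vapply(enc, function(s) cpp_sw_score(s, s, sub, 11L, 1L), 0L)
  edges <- NULL
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      sc <- cpp_sw_score(enc[[i]], enc[[j]], sub, 11L, 1L)
      if (sc >= threshold * min(self[i], self[j]))
        edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::graph_from_edgelist(
    rbind(cbind(seq_len(n), seq_len(n)), edges), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_len(n)]
  stats::setNames(sprintf("C%04d", comp), corpus$accession)
}
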