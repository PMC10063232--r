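#' @useDynLib protfun, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical alphabet: the 20 standard amino acids, alphabetical one-letter codes
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.FOLDS <- c("train", "dev", "test")

#' Construct a protein corpus
#'
#' A corpus is a data frame with one row per protein: `accession`, `sequence`,
#' `is_fragment`, a list column `leaf_labels` (as annotated) and a list column
#' `labels` (the ancestor closure of `leaf_labels` under `graph`).  Labels not
#' present in the ontology are rejected outright rather than dropped, because
#' silently dropped labels corrupt later evaluation.
#'
#' @param accession character vector of unique ids.
#' @param sequence character vector of amino-acid sequences.
#' @param graph a [label_graph][parse_ontology] used for ancestor closure.
#' @param leaf_labels list of character vectors (one per record, may be empty).
#' @param is_fragment logical; fragments are removed by [filter_records()].
#' @return a `protein_corpus` data frame.
#' @export
protein_corpus <- function(accession, sequence, graph, leaf_labels = NULL,
                           is_fragment = FALSE) {
  n <- length(accession)
  stopifnot(length(sequence) == n, !anyNA(accession), !anyNA(sequence))
  if (anyDuplicated(accession)) stop("duplicate accessions in corpus")
  if (any(!nzchar(sequence))) stop("empty sequence(s): ",
                                   paste(accession[!nzchar(sequence)], collapse = ", "))
  if (is.null(leaf_labels)) leaf_labels <- rep(list(character(0)), n)
  stopifnot(length(leaf_labels) == n)
  is_fragment <- rep_len(as.logical(is_fragment), n)
  labels <- lapply(leaf_labels, function(l) propagate(graph, l))
  out <- data.frame(accession = as.character(accession),
                    sequence = toupper(as.character(sequence)),
                    is_fragment = is_fragment,
                    stringsAsFactors = FALSE)
  out$leaf_labels <- lapply(leaf_labels, function(l) sort(unique(as.character(l))))
  out$labels <- labels
  class(out) <- c("protein_corpus", "data.frame")
  out
}

#' Read sequences and annotations into a corpus
#'
#' @param fasta path to a FASTA file of amino-acid sequences; record ids are
#'   accessions (text up to the first whitespace).
#' @param labels path to a label TSV
#'   (`accession<TAB>is_fragment(0/1)<TAB>comma-separated leaf labels`, no
#'   header) or an equivalent data frame.  The label field may be empty
#'   (a protein with no annotated function, e.g. a non-enzyme).
#' @param graph a [label_graph][parse_ontology].
#' @return a `protein_corpus` in FASTA file order.
#' @export
read_corpus <- function(fasta, labels, graph) {
  seqs <- read_fasta(fasta)
  lab <- if (is.character(labels) && length(labels) == 1L)
    read_label_table(labels) else as.data.frame(labels, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "is_fragment", "leaf_labels") %in% names(lab)))
  missing_seq <- setdiff(lab$accession, names(seqs))
  if (length(missing_seq))
    stop("accession(s) in label table but not in FASTA: ",
         paste(missing_seq, collapse = ", "))
  missing_lab <- setdiff(names(seqs), lab$accession)
  if (length(missing_lab))
    stop("accession(s) in FASTA but not in label table: ",
         paste(missing_lab, collapse = ", "))
  lab <- lab[match(names(seqs), lab$accession), ]
  ll <- lab$leaf_labels
  if (!is.list(ll)) ll <- parse_label_field(ll)
  protein_corpus(lab$accession, unname(seqs), graph,
                 leaf_labels = ll, is_fragment = as.logical(lab$is_fragment))
}

parse_label_field <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings; sequences are written wrapped at 60 columns.
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read / write the label TSV
#'
#' Format: `accession<TAB>is_fragment(0/1)<TAB>comma-separated leaf labels`,
#' no header; the third field may be empty.
#' @param path file path.
#' @export
read_label_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "", colClasses = "character",
                         col.names = c("accession", "is_fragment", "labels"),
                         fill = TRUE)
  data.frame(accession = x$accession,
             is_fragment = x$is_fragment %in% c("1", "TRUE", "true"),
             leaf_labels = I(parse_label_field(x$labels)),
             stringsAsFactors = FALSE)
}

#' @rdname read_label_table
#' @param corpus a `protein_corpus`.
#' @export
write_label_table <- function(corpus, path) {
  lab <- vapply(corpus$leaf_labels, paste, "", collapse = ",")
  utils::write.table(
    data.frame(corpus$accession, as.integer(corpus$is_fragment), lab),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter a corpus to standard sequences
#'
#' Removes records whose sequence contains anything outside the 20 standard
#' amino-acid letters (B, J, O, U, X, Z, gaps, ...) and records flagged as
#' fragments.  Filtering is total and idempotent.
#'
#' @param corpus a `protein_corpus`.
#' @return list with `kept` (the filtered corpus) and `report`, a data frame
#'   of rejected accessions and the reason (`"nonstandard residue"` or
#'   `"fragment"`; a record failing both is reported as nonstandard).
#' @export
filter_records <- function(corpus) {
  bad_res <- grepl(sprintf("[^%s]", paste(.AA, collapse = "")), corpus$sequence)
  frag <- corpus$is_fragment & !bad_res
  reject <- bad_res | frag
  report <- data.frame(
    accession = corpus$accession[reject],
    reason = ifelse(bad_res[reject], "nonstandard residue", "fragment"),
    stringsAsFactors = FALSE)
  kept <- corpus[!reject, , drop = FALSE]
  class(kept) <- c("protein_corpus", "data.frame")
  list(kept = kept, report = report)
}

new_split <- function(fold_of, provenance, seed) {
  stopifnot(all(fold_of %in% .FOLDS))
  structure(list(fold_of = fold_of, provenance = provenance, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  tb <- table(factor(x$fold_of, levels = .FOLDS))
  cat(sprintf("<dataset_split> %s (seed %s): train %d / dev %d / test %d\n",
              x$provenance, format(x$seed), tb[1L], tb[2L], tb[3L]))
  invisible(x)
}

split_accessions <- function(corpus) {
  if (inherits(corpus, "protein_corpus")) corpus$accession
  else as.character(corpus)
}

#' Random train/dev/test split
#'
#' Assigns each accession to a fold by a salted hash of the accession mapped
#' to \[0, 1) and thresholded at the cumulative fractions.  The assignment is
#' a deterministic function of (accession, seed) alone, so it is stable under
#' record reordering and across machines.
#'
#' @param corpus a `protein_corpus` or a character vector of accessions.
#' @param fractions length-3 numeric summing to 1: train, dev, test shares
#'   (default 0.8/0.1/0.1).
#' @param seed integer hash salt.
#' @return a `dataset_split`: named character vector `fold_of` plus provenance.
#' @export
random_split <- function(corpus, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  acc <- split_accessions(corpus)
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  u <- cpp_hash01(acc, as.integer(seed))
  cuts <- cumsum(fractions)
  fold <- ifelse(u < cuts[1L], "train", ifelse(u < cuts[2L], "dev", "test"))
  names(fold) <- acc
  new_split(fold, "random", as.integer(seed))
}

#' Cluster-aware train/dev/test split
#'
#' Whole clusters (e.g. sequence-identity clusters standing in for UniRef50)
#' are assigned to folds so that no cluster straddles a fold boundary, and
#' per-fold sequence counts come out approximately equal: clusters are sorted
#' by size (largest first, ties broken by a salted hash) and greedily given to
#' the currently smallest fold.
#'
#' @inheritParams random_split
#' @param clusters named character vector mapping accession to cluster id, a
#'   two-column data frame, or the path of an `accession<TAB>cluster` TSV.
#' @export
clustered_split <- function(corpus, clusters, seed = 1L) {
  acc <- split_accessions(corpus)
  cl <- read_cluster_map(clusters)
  missing <- setdiff(acc, names(cl))
  if (length(missing))
    stop("no cluster id for accession(s): ", paste(missing, collapse = ", "))
  cl <- cl[acc]
  sizes <- table(cl)
  ids <- names(sizes)
  ord <- order(-as.integer(sizes), cpp_hash01(ids, as.integer(seed)), ids)
  ids <- ids[ord]
  fill <- c(train = 0L, dev = 0L, test = 0L)
  cl_fold <- character(length(ids))
  names(cl_fold) <- ids
  for (id in ids) {
    f <- .FOLDS[which.min(fill)]
    cl_fold[id] <- f
    fill[f] <- fill[f] + as.integer(sizes[id])
  }
  fold <- cl_fold[cl]
  names(fold) <- acc
  new_split(fold, "clustered", as.integer(seed))
}

read_cluster_map <- function(clusters) {
  if (is.character(clusters) && length(clusters) == 1L && file.exists(clusters)) {
    x <- utils::read.table(clusters, sep = "\t", header = FALSE, quote = "",
                           colClasses = "character",
                           col.names = c("accession", "cluster"))
    stats::setNames(x$cluster, x$accession)
  } else if (is.data.frame(clusters)) {
    stats::setNames(as.character(clusters[[2L]]), as.character(clusters[[1L]]))
  } else {
    stopifnot(!is.null(names(clusters)))
    stats::setNames(as.character(clusters), names(clusters))
  }
}

#' Split statistics, including impossible test pairs
#'
#' Reports per-fold sequence counts, per-fold label vocabulary sizes and
#' example-label pair counts (over ancestor-closed labels), and the
#' *impossible* set: test labels that never occur in the training fold, and
#' the test example-label pairs carrying such labels.  Impossible pairs bound
#' the recall attainable by any method trained on the training fold.
#'
#' @param split a `dataset_split`.
#' @param corpus the `protein_corpus` it partitions.
#' @return a list of class `split_stats`.
#' @export
split_stats <- function(split, corpus) {
  stopifnot(inherits(split, "dataset_split"))
  fold <- split$fold_of[corpus$accession]
  if (anyNA(fold)) stop("split does not cover every accession in the corpus")
  vocab <- function(f) unique(unlist(corpus$labels[fold == f]))
  pairs <- function(f) sum(lengths(corpus$labels[fold == f]))
  train_vocab <- vocab("train")
  test_labels_list <- corpus$labels[fold == "test"]
  test_vocab <- unique(unlist(test_labels_list))
  impossible <- sort(setdiff(test_vocab, train_vocab))
  imp_pairs <- sum(vapply(test_labels_list,
                          function(l) sum(l %in% impossible), 0L))
  structure(list(
    n = vapply(.FOLDS, function(f) sum(fold == f), 0L),
    label_vocab = vapply(.FOLDS, function(f) length(vocab(f)), 0L),
    example_label_pairs = vapply(.FOLDS, pairs, 0L),
    impossible_test_labels = impossible,
    n_impossible_test_labels = length(impossible),
    n_impossible_test_pairs = imp_pairs), class = "split_stats")
}

#' @export
print.split_stats <- function(x, ...) {
  cat("<split_stats>\n")
  cat("  sequences:            ", paste(sprintf("%s=%d", .FOLDS, x$n), collapse = "  "), "\n")
  cat("  label vocabulary:     ", paste(sprintf("%s=%d", .FOLDS, x$label_vocab), collapse = "  "), "\n")
  cat("  example-label pairs:  ", paste(sprintf("%s=%d", .FOLDS, x$example_label_pairs), collapse = "  "), "\n")
  cat(sprintf("  impossible test labels: %d; impossible test pairs: %d\n",
              x$n_impossible_test_labels, x$n_impossible_test_pairs))
  invisible(x)
}

#' Read / write a fold assignment TSV (`accession<TAB>fold`)
#'
#' @param split a `dataset_split`.
#' @param path file path.
#' @export
write_split <- function(split, path) {
  utils::write.table(data.frame(names(split$fold_of), split$fold_of),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @param provenance recorded provenance for the re-read split.
#' @param seed recorded seed.
#' @export
read_split <- function(path, provenance = "random", seed = NA_integer_) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         colClasses = "character",
                         col.names = c("accession", "fold"))
  new_split(stats::setNames(x$fold, x$accession), provenance, seed)
}

#' Subset a corpus by fold
#'
#' @param corpus a `protein_corpus`.
#' @param split a `dataset_split`.
#' @param fold `"train"`, `"dev"` or `"test"`.
#' @export
corpus_fold <- function(corpus, split, fold = .FOLDS) {
  fold <- match.arg(fold)
  keep <- split$fold_of[corpus$accession] == fold
  out <- corpus[keep, , drop = FALSE]
  class(out) <- c("protein_corpus", "data.frame")
  out
}

#' Truth table of example-label pairs
#'
#' Long-format ground truth (`accession`, `label`) over ancestor-closed
#' labels, as consumed by [pr_curve()].
#' @param corpus a `protein_corpus`.
#' @export
corpus_truth <- function(corpus) {
  data.frame(
    accession = rep(corpus$accession, lengths(corpus$labels)),
    label = unlist(corpus$labels, use.names = FALSE),
    stringsAsFactors = FALSE)
}
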