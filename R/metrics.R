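pair_key <- function(accession, label) paste(accession, label, sep = "\r")

check_pred_frame <- function(pred) {
  stopifnot(is.data.frame(pred),
            all(c("accession", "label", "score") %in% names(pred)))
  if (any(!is.finite(pred$score))) stop("non-finite prediction score(s)")
  if (anyDuplicated(pair_key(pred$accession, pred$label)))
    stop("duplicate (accession, label) pairs in predictions")
  pred
}

#' Micro-averaged precision/recall curve
#'
#' Sweeps the confidence threshold over every distinct score (exact sweep up
#' to 1e6 pairs, then a 501-point grid on the score range) and counts
#' true/false positives and false negatives over example-label pairs, pooled
#' across all examples (micro averaging).  At a threshold above every score
#' nothing is predicted; precision there is 1 by convention
#' (`precision_when_empty`).
#'
#' @param pred data frame `accession`, `label`, `score` (one row per scored
#'   pair; higher = more confident).
#' @param truth data frame `accession`, `label` of true pairs.
#' @param precision_when_empty precision reported when no pair is predicted.
#' @return a data frame of class `pr_curve` with columns `threshold`,
#'   `precision`, `recall`, `tp`, `fp`, `fn`, in decreasing threshold order.
#' @export
pr_curve <- function(pred, truth, precision_when_empty = 1) {
  check_pred_frame(pred)
  if (!is.data.frame(truth) || nrow(truth) == 0L) stop("empty truth")
  truth_keys <- unique(pair_key(truth$accession, truth$label))
  total_true <- length(truth_keys)
  is_true <- pair_key(pred$accession, pred$label) %in% truth_keys
  ord <- order(-pred$score)
  sc <- pred$score[ord]
  tp_cum <- cumsum(is_true[ord])
  n_cum <- seq_along(sc)
  if (length(unique(sc)) > 1e6) {
    thr <- seq(max(sc), min(sc), length.out = 501L)
    last <- findInterval(-thr, -sc)  # predictions with score >= thr
  } else {
    last <- which(!duplicated(sc, fromLast = TRUE))  # last index per distinct score
    thr <- sc[last]
  }
  tp <- tp_cum[pmax(last, 1L)] * (last > 0L)
  n <- n_cum[pmax(last, 1L)] * (last > 0L)
  fp <- n - tp
  out <- data.frame(threshold = thr,
                    precision = ifelse(n > 0, tp / n, precision_when_empty),
                    recall = tp / total_true,
                    tp = tp, fp = fp, fn = total_true - tp)
  # endpoint: a threshold above every score predicts nothing
  out <- rbind(data.frame(threshold = Inf, precision = precision_when_empty,
                          recall = 0, tp = 0L, fp = 0L, fn = total_true),
               out)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Fmax: the maximum F1 across thresholds
#'
#' F1 is the harmonic mean `2PR/(P+R)` of micro precision and recall (0 when
#' both are 0); ties are broken toward the higher threshold.
#'
#' @param curve a [pr_curve()].
#' @return an object of class `fmax_result`: `fmax`, `threshold`,
#'   `precision`, `recall`, and optionally `ci`.
#' @export
fmax <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"), nrow(curve) > 0L)
  pr <- curve$precision + curve$recall
  f1 <- ifelse(pr > 0, 2 * curve$precision * curve$recall / pr, 0)
  best <- which(f1 == max(f1))
  i <- best[which.max(curve$threshold[best])]
  structure(list(fmax = f1[i], threshold = curve$threshold[i],
                 precision = curve$precision[i], recall = curve$recall[i],
                 ci = NULL),
            class = "fmax_result")
}

#' @export
print.fmax_result <- function(x, ...) {
  cat(sprintf("Fmax = %.4f at threshold %.4g (precision %.4f, recall %.4f)",
              x$fmax, x$threshold, x$precision, x$recall))
  if (!is.null(x$ci))
    cat(sprintf("  [%d%% CI %.4f-%.4f]", round(100 * x$ci$level),
                x$ci$low, x$ci$high))
  cat("\n")
  invisible(x)
}

#' @rdname fmax
#' @inheritParams pr_curve
#' @export
fmax_score <- function(pred, truth) fmax(pr_curve(pred, truth))

#' Bootstrap confidence interval for an evaluation statistic
#'
#' Nonparametric percentile bootstrap over test examples: accessions are
#' resampled with replacement and the statistic recomputed on each resample.
#'
#' @inheritParams pr_curve
#' @param statistic function of `(pred, truth)` returning a number or an
#'   `fmax_result` (default: Fmax).
#' @param reps number of resamples.
#' @param level interval level (default 0.95).
#' @param seed integer seed.
#' @return list `low`, `high`, `level`, `reps`.
#' @export
bootstrap_ci <- function(pred, truth, statistic = fmax_score, reps = 1000L,
                         level = 0.95, seed = 1L) {
  stopifnot(reps >= 2L)
  accs <- unique(c(pred$accession, truth$accession))
  pred_by <- split(seq_len(nrow(pred)), pred$accession)
  truth_by <- split(seq_len(nrow(truth)), truth$accession)
  stat_num <- function(p, t) {
    s <- statistic(p, t)
    if (inherits(s, "fmax_result")) s$fmax else as.numeric(s)
  }
  vals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(reps), function(r) {
      take <- sample(accs, length(accs), replace = TRUE)
      relabel <- function(df, by) {
        rows <- lapply(seq_along(take), function(k) {
          i <- by[[take[k]]]
          if (is.null(i)) return(NULL)
          d <- df[i, , drop = FALSE]
          d$accession <- paste0(d$accession, "#", k)
          d
        })
        do.call(rbind, rows)
      }
      stat_num(relabel(pred, pred_by), relabel(truth, truth_by))
    }, 0)
  })
  q <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  list(low = q[1L], high = q[2L], level = level, reps = as.integer(reps))
}

#' Average an ensemble of prediction sets
#'
#' Element-wise arithmetic mean of the members' scores; the members must
#' cover exactly the same (accession, label) pairs.
#'
#' @param preds list of prediction data frames (`accession`, `label`, `score`).
#' @export
ensemble_mean <- function(preds) {
  stopifnot(is.list(preds), length(preds) >= 1L)
  preds <- lapply(preds, check_pred_frame)
  base <- preds[[1L]]
  ord <- order(base$accession, base$label)
  base <- base[ord, , drop = FALSE]
  keys <- pair_key(base$accession, base$label)
  total <- base$score
  for (p in preds[-1L]) {
    p <- p[order(p$accession, p$label), , drop = FALSE]
    if (!identical(pair_key(p$accession, p$label), keys))
      stop("ensemble members do not cover the same (accession, label) pairs")
    total <- total + p$score
  }
  base$score <- total / length(preds)
  rownames(base) <- NULL
  base
}

#' Naive label-frequency baseline
#'
#' Every test accession receives, for every label seen in training, the same
#' score: the fraction of training records annotated with that label.  This
#' is the no-information control any sequence-aware method must beat.
#'
#' @param train_corpus a `protein_corpus` (training fold, ancestor-closed
#'   labels).
#' @param test_accessions character vector of test accessions.
#' @export
naive_baseline <- function(train_corpus, test_accessions) {
  n_train <- nrow(train_corpus)
  counts <- table(unlist(train_corpus$labels))
  labels <- names(counts)
  freq <- as.numeric(counts) / n_train
  data.frame(accession = rep(test_accessions, each = length(labels)),
             label = rep(labels, times = length(test_accessions)),
             score = rep(freq, times = length(test_accessions)),
             stringsAsFactors = FALSE)
}

#' Read / write a predictions TSV (`accession<TAB>label<TAB>score`)
#'
#' @param pred prediction data frame.
#' @param path file path.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(pred[c("accession", "label", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    col.names = c("accession", "label", "score"),
                    colClasses = c("character", "character", "numeric"))
}
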