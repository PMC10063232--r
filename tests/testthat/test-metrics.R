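test_that("a perfect scorer gives precision = recall = 1 at positive thresholds", {
  truth <- data.frame(accession = c("P1", "P1", "P2"),
                      label = c("A", "B", "A"))
  all_pairs <- expand.grid(accession = c("P1", "P2"), label = c("A", "B"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(all_pairs$accession, all_pairs$label)
  all_pairs$score <- as.numeric(key %in% paste(truth$accession, truth$label))
  cv <- pr_curve(all_pairs, truth)
  at1 <- cv[cv$threshold == 1, ]
  expect_equal(at1$precision, 1)
  expect_equal(at1$recall, 1)
  expect_equal(fmax(cv)$fmax, 1)
})

test_that("the worked one-example curve counts pairs correctly", {
  truth <- data.frame(accession = "P1", label = "A")
  pred <- data.frame(accession = "P1", label = c("A", "B"),
                     score = c(0.9, 0.4))
  cv <- pr_curve(pred, truth)
  # at t = 0.5 only A predicted: P = 1, R = 1; at t = 0.3 both: P = 0.5, R = 1
  expect_equal(cv$precision[cv$threshold == 0.9], 1)
  expect_equal(cv$recall[cv$threshold == 0.9], 1)
  expect_equal(cv$precision[cv$threshold == 0.4], 0.5)
  expect_equal(cv$recall[cv$threshold == 0.4], 1)
  res <- fmax(cv)
  expect_equal(res$fmax, 1)
  expect_gt(res$threshold, 0.4)  # ties break toward the higher threshold
  # missing true pair bounds recall: truth {A, B}, only A scored
  res2 <- fmax_score(data.frame(accession = "P1", label = "A", score = 0.9),
                     data.frame(accession = "P1", label = c("A", "B")))
  expect_equal(res2$fmax, 2 / 3)
  expect_error(pr_curve(pred, data.frame()), "empty truth")
})

test_that("pr_curve equals a brute-force recount at every distinct score", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      case <- random_eval_case()
      cv <- pr_curve(case$pred, case$truth)
      expect_true(all(diff(cv$recall) >= 0))  # decreasing threshold order
      expect_true(all(cv$tp + cv$fn == length(unique(
        paste(case$truth$accession, case$truth$label)))))
      for (thr in unique(case$pred$score)) {
        o <- oracle_pr_at(case$pred, case$truth, thr)
        row <- cv[which(cv$threshold == thr), ]
        expect_equal(row$precision, o$precision)
        expect_equal(row$recall, o$recall)
        expect_equal(row$tp, o$tp)
        expect_equal(row$fp, o$fp)
      }
      f <- fmax(cv)
      expect_gte(f$fmax, 0); expect_lte(f$fmax, 1)
    }
  })
})

test_that("bootstrap CI is deterministic, degenerate on constants, and covers the estimate", {
  withr::with_seed(5, case <- random_eval_case(12, 4))
  ci1 <- bootstrap_ci(case$pred, case$truth, reps = 100, seed = 7)
  ci2 <- bootstrap_ci(case$pred, case$truth, reps = 100, seed = 7)
  expect_identical(ci1, ci2)
  const <- bootstrap_ci(case$pred, case$truth,
                        statistic = function(p, t) 0.42, reps = 50, seed = 1)
  expect_equal(const$low, 0.42)
  expect_equal(const$high, 0.42)
  # half perfectly scored, half random: interval contains the point estimate
  withr::with_seed(9, {
    truth <- data.frame(accession = rep(sprintf("P%02d", 1:20), each = 2),
                        label = rep(c("A", "B"), 20))
    pred <- expand.grid(accession = sprintf("P%02d", 1:20),
                        label = c("A", "B", "C"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    perfect <- pred$accession %in% sprintf("P%02d", 1:10)
    istrue <- paste(pred$accession, pred$label) %in%
      paste(truth$accession, truth$label)
    pred$score <- ifelse(perfect, as.numeric(istrue), stats::runif(nrow(pred)))
    point <- fmax_score(pred, truth)$fmax
    ci <- bootstrap_ci(pred, truth, reps = 200, seed = 3)
    expect_lte(ci$low, point)
    expect_gte(ci$high, point)
  })
})

test_that("ensemble averaging is elementwise and the identity on duplicates", {
  p1 <- data.frame(accession = "P1", label = c("A", "B"), score = c(0.2, 0.6))
  expect_equal(ensemble_mean(list(p1, p1, p1))$score, p1$score)
  p2 <- data.frame(accession = "P1", label = c("A", "B"), score = c(0.8, 0.0))
  expect_equal(ensemble_mean(list(p1, p2))$score, c(0.5, 0.3))
  withr::with_seed(2, {
    members <- lapply(1:5, function(i) {
      d <- random_eval_case(5, 3)$pred
      d[order(d$accession, d$label), c("accession", "label")]
    })
    base <- members[[1L]]
    keep <- Reduce(intersect, lapply(members, function(d)
      paste(d$accession, d$label)))
    base <- base[paste(base$accession, base$label) %in% keep, ]
    sets <- lapply(1:5, function(i) {
      b <- base; b$score <- stats::runif(nrow(b)); b
    })
    avg <- ensemble_mean(sets)
    manual <- rowMeans(vapply(sets, function(s)
      s$score[order(s$accession, s$label)], numeric(nrow(base))))
    expect_equal(avg$score, manual)
  })
  p3 <- data.frame(accession = "P9", label = "A", score = 1)
  expect_error(ensemble_mean(list(p1, p3)), "same")
})

test_that("the naive frequency baseline scores labels by training prevalence only", {
  g <- ec_tree()
  corp <- protein_corpus(c("T1", "T2", "T3", "T4"),
                         replicate(4, random_aa_seq(20)), g,
                         leaf_labels = list("EC:3.2.1.2", "EC:3.2.1.2",
                                            "EC:3.2.1.2", character(0)))
  nb <- naive_baseline(corp, c("Q1", "Q2"))
  expect_equal(unique(nb$score[nb$label == "EC:3.2.1.2"]), 0.75)
  expect_equal(unique(nb$score[nb$label == "EC:3.-.-.-"]), 0.75)
  expect_false("missing" %in% nb$label)   # absent labels are simply not scored
  # identical score vector for every accession
  expect_equal(nb$score[nb$accession == "Q1"], nb$score[nb$accession == "Q2"])
})

test_that("prediction TSVs round-trip", {
  pred <- data.frame(accession = c("P1", "P2"), label = c("A", "B"),
                     score = c(0.25, 12.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(pred, path)
  expect_equal(read_predictions(path), pred, ignore_attr = TRUE)
})
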