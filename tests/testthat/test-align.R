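test_that("Smith-Waterman scores match the Biostrings aligner on random pairs", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  withr::with_seed(19, {
    for (i in 1:15) {
      a <- random_aa_seq(sample(20:80, 1))
      b <- random_aa_seq(sample(20:80, 1))
      if (i %% 3 == 0) {  # make some related pairs with indels
        b <- paste0(substr(a, 1, 30), random_aa_seq(10), substr(a, 31, nchar(a)))
      }
      ours <- sw_score(a, b)
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
        substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE)
      expect_equal(ours, ref)
    }
  })
})

test_that("top hits find the identical sequence and break ties lexicographically", {
  g <- ec_tree()
  withr::with_seed(4, {
    q <- "ACDEFGHIKLM"
    db <- protein_corpus(
      c("T_ident", "T_rev", "T_rand"),
      c(q, paste(rev(strsplit(q, "")[[1]]), collapse = ""), random_aa_seq(11)),
      g)
    hits <- top_hits(c(Q1 = q), db)
    expect_equal(hits$subject, "T_ident")
    expect_equal(hits$bit_score, bit_score(hits$score))
    # exact duplicate subjects: lexicographically first accession wins
    db2 <- protein_corpus(c("Tb", "Ta"), c(q, q), g)
    expect_equal(top_hits(c(Q1 = q), db2)$subject, "Ta")
  })
})

test_that("builtin top hits agree with an exhaustive all-pairs scan", {
  g <- ec_tree()
  withr::with_seed(27, {
    db <- protein_corpus(sprintf("T%02d", 1:20),
                         replicate(20, random_aa_seq(sample(30:60, 1))), g)
    queries <- stats::setNames(replicate(10, random_aa_seq(sample(30:60, 1))),
                               sprintf("Q%02d", 1:10))
    hits <- top_hits(queries, db)
    for (qn in names(queries)) {
      scores <- vapply(db$sequence, function(s) sw_score(queries[[qn]], s), 0L)
      best <- max(scores)
      expect_equal(hits$score[hits$accession == qn], best)
      expect_equal(hits$subject[hits$accession == qn],
                   sort(db$accession[scores == best])[1L])
    }
  })
})

test_that("self-alignment dominates cross-hits", {
  withr::with_seed(8, {
    seqs <- replicate(6, random_aa_seq(40))
    for (i in 1:6) {
      self <- sw_score(seqs[i], seqs[i])
      for (j in seq_len(6)[-i]) expect_gte(self, sw_score(seqs[i], seqs[j]))
    }
  })
})

test_that("label transfer assigns the top hit's full (closed) label set at its bit-score", {
  g <- ec_tree()
  train <- protein_corpus(c("T1", "T2"),
                          c("ACDEFGHIKLMNPQRSTVWY", "MKVLMKVLMKVL"), g,
                          leaf_labels = list("EC:3.2.1.2", character(0)))
  hits <- data.frame(accession = "Q1", subject = "T1", score = 100,
                     bit_score = bit_score(100))
  pred <- transfer_labels(hits, train)
  expect_setequal(pred$label, propagate(g, "EC:3.2.1.2"))
  expect_true(all(pred$score == bit_score(100)))
  # ancestor closure is preserved
  for (l in pred$label)
    expect_true(all(ancestors(g, l) %in% pred$label))
  # no-hit query: empty predictions
  expect_equal(nrow(transfer_labels(hits[0, ], train)), 0L)
})

test_that("self-lookup label transfer is perfect (test = train)", {
  g <- make_ontology(3, c(2, 2))
  syn <- make_corpus(g, 25, c(60, 120), nonenzyme_fraction = 0, seed = 12)
  pred <- align_baseline(syn$corpus, syn$corpus)
  expect_equal(fmax_score(pred, corpus_truth(syn$corpus))$fmax, 1)
})

test_that("bit-score conversion follows the Karlin-Altschul form", {
  expect_equal(bit_score(0), -log(0.041) / log(2))
  expect_equal(bit_score(100), (0.267 * 100 - log(0.041)) / log(2))
  expect_true(all(diff(bit_score(c(10, 50, 100))) > 0))
})

test_that("combining rescales bit-scores by network probabilities", {
  blast <- data.frame(accession = "Q1", label = c("A", "B"),
                      score = c(100, 100))
  cnn <- data.frame(accession = "Q1", label = c("A", "B", "C"),
                    score = c(0.5, 1, 0.9))
  comb <- combine_predictions(blast, cnn)
  expect_equal(comb$score[comb$label == "A"], 50)
  expect_equal(comb$score[comb$label == "B"], 100)
  expect_false("C" %in% comb$label)            # top-hit label set only
  comb_u <- combine_predictions(blast, cnn, union = TRUE)
  expect_true("C" %in% comb_u$label)
  # all-ones probabilities preserve the BLAST ranking exactly
  withr::with_seed(14, {
    blast2 <- data.frame(accession = rep(sprintf("Q%d", 1:6), each = 2),
                         label = rep(c("A", "B"), 6),
                         score = stats::runif(12, 10, 200))
    ones <- blast2; ones$score <- 1
    comb2 <- combine_predictions(blast2, ones)
    expect_equal(order(comb2$score), order(blast2$score))
    expect_equal(comb2$score, blast2$score)
    # scores bounded by the bit-score and nonnegative
    half <- blast2; half$score <- stats::runif(12)
    comb3 <- combine_predictions(blast2, half)
    expect_true(all(comb3$score >= 0 & comb3$score <= blast2$score))
  })
})

test_that("the external blastp backend agrees on an easy self-hit", {
  g <- ec_tree()
  withr::with_seed(33, {
    db <- protein_corpus(sprintf("T%02d", 1:5),
                         replicate(5, random_aa_seq(60)), g,
                         leaf_labels = rep(list("EC:3.2.1.2"), 5))
    hits <- top_hits(stats::setNames(db$sequence[3], "Q1"), db,
                     backend = "blastp")
    expect_equal(hits$subject, "T03")
  })
})

test_that("approximate single-linkage clustering groups near-identical sequences", {
  g <- ec_tree()
  withr::with_seed(41, {
    base1 <- random_aa_seq(60); base2 <- random_aa_seq(60)
    tweak <- function(s) {
      x <- strsplit(s, "")[[1]]
      i <- sample(60, 3)
      x[i] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 3, replace = TRUE)
      paste(x, collapse = "")
    }
    corp <- protein_corpus(sprintf("S%d", 1:4),
                           c(base1, tweak(base1), base2, tweak(base2)), g)
    cl <- approx_clusters(corp, threshold = 0.7)
    expect_equal(cl[["S1"]], cl[["S2"]])
    expect_equal(cl[["S3"]], cl[["S4"]])
    expect_false(cl[["S1"]] == cl[["S3"]])
  })
})
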