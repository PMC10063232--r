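test_that("the CAM-logit identity holds structurally on random models", {
  withr::with_seed(51, {
    for (blocks in c(1, 3)) {
      m <- tiny_model(vocab = sprintf("L%d", 1:5), filters = 16,
                      blocks = blocks, seed = blocks)
      for (i in 1:5) {
        s <- random_aa_seq(sample(15:60, 1))
        am <- cam(m, s, sprintf("L%d", 1:5))
        recon <- colMeans(am$scores) + am$bias
        expect_equal(as.numeric(recon), as.numeric(am$logits),
                     tolerance = 1e-4)
      }
    }
  })
})

test_that("zero head weights give an identically zero map; unknown classes error", {
  m <- tiny_model(vocab = c("A", "B"), filters = 8)
  d <- m$dims
  V <- d[["vocab"]]
  nhead <- V * d[["filters"]] + V
  start <- length(m$theta) - nhead  # head weights are V x F, column-major
  m$theta[start + 1L + (seq_len(d[["filters"]]) - 1L) * V] <- 0  # class A row
  am <- cam(m, random_aa_seq(20), c("A", "B"))
  expect_true(all(am$scores[, "A"] == 0))
  expect_error(cam(m, "ACD", "Z"), "unknown class")
})

test_that("cross-class normalisation subtracts the mean of the other classes", {
  m <- structure(list(), class = "activation_map")  # direct arithmetic cases
  m$scores <- cbind(A = c(3, 1), B = c(1, 1))
  m$classes <- c("A", "B"); m$normalized <- FALSE
  n <- normalize_cam(m)
  expect_equal(n$scores[, "A"], c(2, 0))
  expect_equal(n$scores[, "B"], c(-2, 0))
  expect_equal(n$scores[, "A"], -n$scores[, "B"])  # 2-class antisymmetry
  # all-equal scores normalise to zero
  m$scores <- cbind(A = c(2, 2), B = c(2, 2))
  expect_true(all(normalize_cam(m)$scores == 0))
  # 3 classes: brute-force per-residue subtraction
  withr::with_seed(3, {
    m$scores <- matrix(stats::rnorm(30), 10, 3,
                       dimnames = list(NULL, c("A", "B", "C")))
    m$classes <- c("A", "B", "C")
    n <- normalize_cam(m)
    for (i in 1:10) for (cl in 1:3)
      expect_equal(n$scores[i, cl],
                   m$scores[i, cl] - mean(m$scores[i, -cl]))
  })
  m$classes <- "A"; m$scores <- m$scores[, 1, drop = FALSE]
  expect_error(normalize_cam(m), "at least 2")
})

test_that("centre of mass weights clipped-positive scores over 0-based positions", {
  expect_equal(center_of_mass(rep(1, 5)), 2)
  expect_equal(center_of_mass(c(0, 0, 1, 0, 0)), 2)
  expect_equal(center_of_mass(c(1, 3)), 0.75)
  # negatives are clipped before weighting
  expect_equal(center_of_mass(c(-5, 2, -5, 2, -5)), 2)
  # all-negative scores fall back to shifted raw scores
  expect_equal(center_of_mass(c(-3, -1)), 1)
  expect_error(center_of_mass(c(0, 0, 0)), "no signal")
})

test_that("embeddings equal the pooled features and are deterministic", {
  m <- tiny_model(vocab = c("A", "B"), filters = 10)
  s <- random_aa_seq(30)
  E <- embed(m, c(x = s, y = s))
  expect_equal(ncol(E), 10L)
  expect_equal(E["x", ], E["y", ])
  fw <- model_forward(m, s, features = TRUE)
  expect_equal(unname(E["x", ]), as.numeric(colMeans(fw$features)))
})

test_that("order_domains enforces the exactly-two-predictions candidate rule", {
  m <- tiny_model(vocab = c("A", "B", "C"), filters = 8)
  s <- random_aa_seq(40)
  p <- model_forward(m, s)$probabilities
  # thresholds engineered to select 3, 1 and 2 leaf classes
  expect_error(order_domains(m, s, c("A", "B", "C"), threshold = min(p)),
               "exactly 2")
  expect_error(order_domains(m, s, c("A", "B", "C"), threshold = max(p)),
               "exactly 2")
  thr <- sort(p, decreasing = TRUE)[2L]
  od <- order_domains(m, s, c("A", "B", "C"), threshold = thr)
  expect_length(od$order, 2L)
  expect_setequal(od$order, names(sort(p, decreasing = TRUE))[1:2])
  expect_equal(od$order, od$order[order(od$com[od$order], od$order)])
})

test_that("an embedding probe separates a planted property and collapses under shuffling", {
  withr::with_seed(61, {
    n <- 120
    lab <- stats::runif(n) < 0.4
    emb <- matrix(stats::rnorm(n * 8), n, 8)
    emb[lab, 1:2] <- emb[lab, 1:2] + 2.5   # property is linearly embedded
    res <- embedding_probe(emb, lab, train_fraction = 0.3, seed = 2)
    expect_gt(res$f1, 0.85)
    shuffled <- embedding_probe(emb, sample(lab), train_fraction = 0.3, seed = 2)
    expect_lt(shuffled$f1, res$f1 - 0.2)
    # determinism
    res2 <- embedding_probe(emb, lab, train_fraction = 0.3, seed = 2)
    expect_identical(res, res2)
    expect_error(embedding_probe(emb, rep(TRUE, n)), "single-class")
  })
})
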