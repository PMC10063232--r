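make_files <- function(dir, seqs, labels_df) {
  fa <- file.path(dir, "c.fasta"); tsv <- file.path(dir, "l.tsv")
  write_fasta(seqs, fa)
  writeLines(sprintf("%s\t%d\t%s", labels_df$accession,
                     labels_df$is_fragment, labels_df$labels), tsv)
  list(fasta = fa, labels = tsv)
}

test_that("read_corpus joins FASTA and label table with ancestor closure", {
  g <- ec_tree()
  dir <- withr::local_tempdir()
  f <- make_files(dir,
                  c(P1 = "ACDEFGHIKLMNPQRSTVWY", P2 = "MKVL"),
                  data.frame(accession = c("P1", "P2"), is_fragment = 0L,
                             labels = c("EC:3.2.1.2", "")))
  corp <- read_corpus(f$fasta, f$labels, g)
  expect_equal(nrow(corp), 2L)
  expect_length(corp$labels[[1L]], 4L)      # leaf + 3 ancestors
  expect_length(corp$labels[[2L]], 0L)      # a non-enzyme
  expect_equal(corp$accession, c("P1", "P2"))  # file order
})

test_that("corpus building fails fast on mismatches and unknown labels", {
  g <- ec_tree()
  dir <- withr::local_tempdir()
  f <- make_files(dir, c(P1 = "MKVL"),
                  data.frame(accession = c("P1", "P9"), is_fragment = 0L,
                             labels = c("", "")))
  expect_error(read_corpus(f$fasta, f$labels, g), "P9")
  f2 <- make_files(dir, c(P1 = "MKVL"),
                   data.frame(accession = "P1", is_fragment = 0L,
                              labels = "EC:9.9.9.9"))
  expect_error(read_corpus(f2$fasta, f2$labels, g), "EC:9.9.9.9")
})

test_that("filter_records drops nonstandard residues and fragments, totally and idempotently", {
  g <- ec_tree()
  corp <- protein_corpus(c("A1", "A2", "A3", "A4"),
                         c("ACDEFGHIKLMNPQRSTVWY", "ACDEFXGHIK",
                           "MKULV", "MKVLM"),
                         g, is_fragment = c(FALSE, FALSE, FALSE, TRUE))
  res <- filter_records(corp)
  expect_equal(res$kept$accession, "A1")
  expect_equal(sort(res$report$reason),
               c("fragment", "nonstandard residue", "nonstandard residue"))
  again <- filter_records(res$kept)
  expect_equal(again$kept$accession, res$kept$accession)
  expect_equal(nrow(again$report), 0L)
})

test_that("planted nonstandard sequences are counted exactly by the filter", {
  g <- ec_tree()
  withr::with_seed(5, {
    seqs <- vapply(1:100, function(i) random_aa_seq(30), "")
    bad <- sample(100, 10)
    for (i in bad) {
      s <- strsplit(seqs[i], "")[[1]]
      s[sample(30, 1)] <- "U"
      seqs[i] <- paste(s, collapse = "")
    }
    corp <- protein_corpus(sprintf("Q%03d", 1:100), seqs, g)
    res <- filter_records(corp)
    expect_equal(nrow(res$kept), 90L)
    expect_setequal(res$report$accession, sprintf("Q%03d", bad))
  })
})

test_that("random_split is deterministic, order-independent and near the 80/10/10 fractions", {
  acc <- sprintf("P%05d", 1:10000)
  s1 <- random_split(acc, seed = 3)
  s2 <- random_split(rev(acc), seed = 3)
  expect_equal(s1$fold_of[acc], s2$fold_of[acc])        # order-independent
  expect_equal(random_split(acc, seed = 3)$fold_of, s1$fold_of)
  tb <- table(s1$fold_of)
  expect_lt(abs(tb[["train"]] - 8000), 100)             # within 1% of n
  expect_lt(abs(tb[["dev"]] - 1000), 100)
  expect_lt(abs(tb[["test"]] - 1000), 100)
  expect_false(identical(random_split(acc, seed = 4)$fold_of, s1$fold_of))
  # degenerate fractions
  expect_true(all(random_split(acc, c(1, 0, 0))$fold_of == "train"))
  expect_error(random_split(acc, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("clustered_split keeps clusters whole and balances fold sizes", {
  expect_setequal(
    unname(clustered_split(c("a", "b", "c"),
                           c(a = "c1", b = "c2", c = "c3"))$fold_of),
    c("train", "dev", "test"))
  cl <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B",
          C1 = "C", C2 = "C", D1 = "D", D2 = "D")
  sp <- clustered_split(names(cl), cl, seed = 1)
  for (cid in unique(cl))
    expect_length(unique(sp$fold_of[names(cl)[cl == cid]]), 1L)
  # 300 clusters with geometric sizes: folds within 5% of n/3
  withr::with_seed(8, {
    sizes <- pmin(1L + stats::rgeom(300, 0.3), 15L)
    acc <- sprintf("P%05d", seq_len(sum(sizes)))
    clmap <- stats::setNames(rep(sprintf("C%03d", 1:300), sizes), acc)
    sp2 <- clustered_split(acc, clmap, seed = 2)
    tb <- table(sp2$fold_of)
    expect_true(all(abs(tb - length(acc) / 3) <= 0.05 * length(acc) / 3))
  })
  expect_error(clustered_split(c("x", "y"), c(x = "c1")), "y")
})

test_that("split_stats reports impossible test labels/pairs that match a set-difference recount", {
  g <- make_ontology(3, c(2, 2))
  withr::with_seed(21, {
    leaves <- graph_leaves(g)
    n <- 60
    corp <- protein_corpus(sprintf("P%03d", 1:n),
                           vapply(1:n, function(i) random_aa_seq(25), ""), g,
                           leaf_labels = lapply(1:n, function(i)
                             sample(leaves, sample(0:2, 1))))
    sp <- random_split(corp, seed = 2)
    st <- split_stats(sp, corp)
    fold <- sp$fold_of[corp$accession]
    train_vocab <- unique(unlist(corp$labels[fold == "train"]))
    test_lab <- corp$labels[fold == "test"]
    imp <- sort(setdiff(unique(unlist(test_lab)), train_vocab))
    expect_equal(st$impossible_test_labels, imp)
    expect_equal(st$n_impossible_test_pairs,
                 sum(unlist(test_lab) %in% imp))
    expect_equal(sum(st$n), n)  # folds partition the corpus
    # identical train and test vocabularies -> none impossible
    same <- split_stats(
      new_split <- random_split(corp, c(1, 0, 0), seed = 1), corp)
    expect_equal(length(same$impossible_test_labels), 0L)
  })
})

test_that("split TSV round-trips", {
  sp <- random_split(sprintf("P%02d", 1:20), seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, path)
  sp2 <- read_split(path)
  expect_equal(sp2$fold_of, sp$fold_of)
})
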