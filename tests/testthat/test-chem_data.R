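test_that("tanimoto_similarity matches set arithmetic and handles edge cases", {
  expect_equal(tanimoto_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_error(tanimoto_similarity(numeric(4), numeric(4)), "undefined")
  expect_error(tanimoto_similarity(c(1, 0), c(1, 0, 0)), "length")
  ## oracle agreement on 1000 random pairs
  withr::with_seed(11, {
    for (i in 1:1000) {
      a <- rbinom(40, 1, 0.25); b <- rbinom(40, 1, 0.25)
      if (sum(a) == 0) a[1] <- 1
      if (sum(b) == 0) b[2] <- 1
      expect_equal(tanimoto_similarity(a, b), tanimoto_oracle(a, b))
    }
  })
})

test_that("leader clustering obeys its contract and matches the brute-force pass", {
  ## identical fingerprints collapse to one cluster
  same <- matrix(rep(c(1, 0, 1, 1, 0, 0), 8), 8, 6, byrow = TRUE)
  expect_equal(leader_cluster(same, 0.9), rep(0L, 8))
  ## pairwise disjoint fingerprints stay singletons
  expect_equal(leader_cluster(diag(6), 0.6), 0:5)
  expect_equal(leader_cluster(matrix(0, 0, 4)), integer(0))
  ## brute-force oracle over the same (identity) ordering
  fps <- random_fps(20, 48, 0.2, seed = 7)
  expect_equal(leader_cluster(fps, 0.4),
               leader_oracle(fps, 0.4, seq_len(20)))
  ## and over a seeded shuffled ordering
  ord <- withr::with_seed(5L, sample.int(20))
  expect_equal(leader_cluster(fps, 0.4, order_seed = 5L),
               leader_oracle(fps, 0.4, ord))
  expect_error(leader_cluster(rbind(fps, 0), 0.4), "all-zero")
})

test_that("leader radius and determinism invariants hold over random data", {
  for (seed in 1:6) {
    fps <- random_fps(40, 64, 0.12, seed = seed)
    thr <- c(0.3, 0.5)[seed %% 2 + 1]
    cl <- leader_cluster(fps, thr, order_seed = seed)
    expect_identical(cl, leader_cluster(fps, thr, order_seed = seed))
    ord <- withr::with_seed(as.integer(seed), sample.int(40))
    ## leaders in creation order carry cluster ids 0, 1, 2, ...
    leaders <- ord[!duplicated(cl[ord])]
    leaders <- leaders[order(cl[leaders])]
    ## every compound within the threshold sphere of its own leader
    leader_row <- leaders[cl + 1L]
    sims <- vapply(seq_len(40), function(i)
      tanimoto_oracle(fps[i, ], fps[leader_row[i], ]), numeric(1))
    expect_true(all(1 - sims <= 1 - thr + 1e-12))
    ## leaders mutually below threshold
    if (length(leaders) > 1) {
      for (i in seq_along(leaders)[-1]) for (j in seq_len(i - 1)) {
        expect_lt(tanimoto_oracle(fps[leaders[i], ], fps[leaders[j], ]), thr)
      }
    }
    ## cluster ids contiguous from zero
    expect_setequal(unique(cl), seq_len(length(unique(cl))) - 1L)
  }
})

test_that("fold assignment is cluster-atomic, balanced and reproducible", {
  ## five singleton clusters, five folds: one compound per fold
  f <- assign_folds(0:4, n_folds = 5, seed = 1)
  expect_setequal(f, 0:4)
  ## 100 singleton clusters balance exactly
  f <- assign_folds(0:99, n_folds = 5, seed = 2)
  expect_equal(unname(tabulate(f + 1L, 5)), rep(20L, 5))
  ## atomicity on heavy-tailed clusters, several seeds
  for (seed in 1:5) {
    cl <- withr::with_seed(seed, sample.int(12, 200, replace = TRUE,
                                            prob = rexp(12))) - 1L
    f <- assign_folds(cl, seed = seed)
    expect_true(all(tapply(f, cl, function(x) length(unique(x))) == 1))
    expect_identical(f, assign_folds(cl, seed = seed))
  }
  expect_warning(assign_folds(c(0, 0, 1), n_folds = 5, seed = 1), "empty")
})

test_that("make_split partitions the folds 3/1/1", {
  s <- make_split(3, 4)
  expect_equal(s$train_folds, 0:2)
  expect_equal(make_split(0, 1)$train_folds, 2:4)
  expect_error(make_split(2, 2), "differ")
  expect_error(make_split(0, 5), "0..4")
  for (v in 0:4) for (t in setdiff(0:4, v)) {
    s <- make_split(v, t)
    expect_setequal(c(s$train_folds, s$valid_fold, s$test_fold), 0:4)
    expect_length(s$train_folds, 3)
  }
})

test_that("MTX + label and split-table files round-trip", {
  gen <- toy_dataset(n = 60, d = 32, k = 8, seed = 2)
  td <- withr::local_tempdir()
  mtx <- file.path(td, "x.mtx"); lab <- file.path(td, "y.txt")
  write_feature_mtx(gen$data, mtx, lab)
  back <- read_feature_mtx(mtx, lab)
  expect_equal(as.matrix(back$features), as.matrix(gen$data$features))
  expect_equal(back$labels, gen$data$labels)
  sp <- file.path(td, "split.tsv")
  write_split_table(gen$data, sp)
  tab <- read_split_table(sp)
  expect_equal(tab$cluster_id, gen$data$cluster_id)
  expect_equal(tab$fold_id, gen$data$fold_id)
  expect_error(read_feature_mtx(file.path(td, "nope.mtx"), lab), "no such file")
})

test_that("compound tables are labelled by the pIC50 threshold and bad rows skipped", {
  td <- withr::local_tempdir()
  path <- file.path(td, "tab.csv")
  writeLines(c("smiles,pic50",
               "AAA,5.5", "BBB,5.4999", "CCC,7.1", "XXX,6.0"), path)
  ## deterministic stand-in fingerprinter: bits from character codes,
  ## NULL for the sentinel bad structure
  fp <- function(s) if (s == "XXX") NULL else (utf8ToInt(s) %% 64)
  expect_warning(
    d <- load_compound_table(path, "smiles", "pic50", pic50_threshold = 5.5,
                             n_bits = 64, fingerprinter = fp),
    "skipped")
  expect_equal(length(d$labels), 3)
  expect_equal(d$labels, c(1, 0, 1))   # >= threshold is active
  expect_error(load_compound_table(path, "smiles", "missing",
                                   fingerprinter = fp), "missing column")
  ## binary label column used verbatim
  path2 <- file.path(td, "tab2.tsv")
  writeLines(c("smiles\tactive", "AAA\t1", "BBB\t0"), path2)
  d2 <- load_compound_table(path2, "smiles", "active", n_bits = 64,
                            fingerprinter = fp)
  expect_equal(d2$labels, c(1, 0))
})

test_that("the OpenBabel circular fingerprinter featurizes SMILES and rejects garbage", {
  fp <- ob_ecfp6_fingerprinter(n_bits = 32768)
  bits <- fp("c1ccccc1O")                 # phenol
  expect_true(is.numeric(bits) && length(bits) > 0)
  expect_true(all(bits >= 0 & bits < 32768))
  expect_identical(bits, fp("c1ccccc1O")) # deterministic
  expect_true(is.null(fp("not_a_smiles((((")))
})

test_that("dataset construction rejects inconsistent inputs", {
  X <- random_fps(10, 16, seed = 3)
  expect_error(bioactivity_dataset(X, rep(1, 9)), "length")
  expect_error(bioactivity_dataset(X, rep(2, 10)), "0/1")
  ## a cluster spanning two folds is rejected
  expect_error(bioactivity_dataset(X, rbinom(10, 1, 0.5),
                                   cluster_id = rep(0L, 10),
                                   fold_id = c(rep(0L, 5), rep(1L, 5))),
               "spans")
})
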