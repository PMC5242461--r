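# Fitch length, MP search, bootstrap, consensus, RF distance.

aa_matrix <- function(taxa, cols) {
  matrix(cols, nrow = length(taxa), dimnames = list(taxa, NULL))
}

test_that("hand-countable Fitch lengths", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  cm <- character_matrix(letters[1:4],
                         aa = aa_matrix(letters[1:4], c("A", "A", "C", "C")))
  expect_equal(fitch_length(tr, cm), 1)
  # invariant column contributes nothing on any tree
  cm0 <- character_matrix(letters[1:4],
                          aa = aa_matrix(letters[1:4], rep("G", 4)))
  expect_equal(fitch_length(tr, cm0), 0)
  # missing data are any-state
  cmq <- character_matrix(letters[1:4],
                          aa = aa_matrix(letters[1:4], c("A", "?", "C", "C")))
  expect_equal(fitch_length(tr, cmq), 1)
})

test_that("Fitch equals brute-force ancestral enumeration on random data", {
  set.seed(53)
  for (rep in 1:10) {
    taxa <- sprintf("t%d", 1:6)
    tr <- ape::rtree(6, tip.label = taxa)
    X <- matrix(sample(c("A", "C", "G", "T", "-"), 6 * 20, TRUE,
                       prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                nrow = 6, dimnames = list(taxa, NULL))
    cm <- character_matrix(taxa, aa = X)
    expect_equal(fitch_length(tr, cm), bf_fitch_length(tr, X), info = rep)
  }
})

test_that("Fitch agrees with phangorn and is invariant to rooting", {
  set.seed(59)
  taxa <- sprintf("t%d", 1:8)
  X <- matrix(sample(AA20, 8 * 30, TRUE), nrow = 8,
              dimnames = list(taxa, NULL))
  cm <- character_matrix(taxa, aa = X)
  pd <- phangorn::phyDat(X, type = "AA")
  for (rep in 1:5) {
    tr <- ape::rtree(8, tip.label = sample(taxa))
    expect_equal(fitch_length(tr, cm),
                 phangorn::parsimony(tr, pd, method = "fitch"))
    rerooted <- ape::root(ape::unroot(tr), outgroup = "t3",
                          resolve.root = TRUE)
    expect_equal(fitch_length(rerooted, cm), fitch_length(tr, cm))
  }
})

test_that("heuristic search matches exhaustive enumeration at 6-7 taxa", {
  set.seed(61)
  for (rep in 1:6) {
    n <- sample(6:7, 1)
    taxa <- sprintf("t%d", seq_len(n))
    X <- matrix(sample(c("A", "C", "G", "T"), n * 15, TRUE), nrow = n,
                dimnames = list(taxa, NULL))
    cm <- character_matrix(taxa, aa = X)
    all_trees <- phangorn::allTrees(n, tip.label = taxa)
    exhaustive <- min(vapply(all_trees, fitch_length, 0, matrix = cm))
    res <- search_mp(cm, search_config(n_starts = 5, seed = rep))
    expect_equal(res$length, exhaustive, info = rep)
  }
})

test_that("search is deterministic and ties keep duplicate taxa together", {
  taxa <- sprintf("t%d", 1:6)
  X <- matrix(sample(c("A", "C"), 6 * 12, TRUE), nrow = 6,
              dimnames = list(taxa, NULL))
  X["t2", ] <- X["t1", ]  # identical rows
  cm <- character_matrix(taxa, aa = X)
  r1 <- search_mp(cm, search_config(n_starts = 4, seed = 9))
  r2 <- search_mp(cm, search_config(n_starts = 4, seed = 9))
  expect_identical(lapply(r1$trees, ape::write.tree),
                   lapply(r2$trees, ape::write.tree))
  sib_key <- paste(sort(setdiff(taxa, c("t1", "t2"))), collapse = ";")
  for (tr in r1$trees) {
    # t1 and t2 are sisters in every optimal tree (zero-cost pairing); the
    # bipartition is stored by its side away from the reference taxon t1
    expect_true(sib_key %in% gsphylo:::.bipartitions_phylo(tr))
  }
})

test_that("search length never exceeds the true simulated tree's length", {
  truth <- simulate_family(simulation_config(seed = 7))
  mm <- study_mm_partition(truth)
  cm <- build_combined_matrix(truth$alignment, mm)
  res <- search_mp(cm, search_config(n_starts = 3, seed = 2))
  expect_lte(res$length, fitch_length(truth$tree, cm))
})

test_that("bootstrap: clean signal gives 100, no signal gives a star", {
  taxa <- letters[1:4]
  # every column supports ((a,b),(c,d))
  X <- matrix(rep(c("A", "A", "C", "C"), 12), nrow = 4, byrow = FALSE,
              dimnames = list(taxa, NULL))
  bs <- bootstrap_mp(character_matrix(taxa, aa = X), replicates = 40,
                     seed = 3)
  expect_equal(unname(bs$supports), 100)
  expect_equal(names(bs$supports), "c;d")

  Xinv <- matrix("A", nrow = 4, ncol = 12, dimnames = list(taxa, NULL))
  bs0 <- bootstrap_mp(character_matrix(taxa, aa = Xinv), replicates = 20,
                      seed = 4)
  expect_length(bs0$supports, 0L)
  expect_equal(bs0$tree$Nnode, 1L)  # star consensus
})

test_that("bootstrap support tracks the column-resampling binomial oracle", {
  set.seed(67)
  taxa <- letters[1:4]
  # 1 informative column among 10: a replicate supports {a,b} iff it draws
  # that column at least once; p = 1 - (9/10)^10
  X <- cbind(matrix("A", 4, 9), c("C", "C", "A", "A"))
  rownames(X) <- taxa
  bs <- bootstrap_mp(character_matrix(taxa, aa = X), replicates = 200,
                     seed = 5)
  p <- 1 - (9 / 10)^10
  sigma <- sqrt(p * (1 - p) / 200)
  support <- if ("c;d" %in% names(bs$supports)) {
    bs$supports[["c;d"]] / 100
  } else 0
  expect_lte(abs(support - p), 3 * sigma + 1e-9)
})

test_that("majority-rule consensus matches direct bipartition counting", {
  set.seed(71)
  taxa <- sprintf("t%d", 1:8)
  trees <- lapply(1:20, function(i) ape::rtree(8, tip.label = sample(taxa)))
  cons <- majority_rule_consensus(trees, threshold = 0.5)
  # independent count via ape::prop.part, normalising clades to the split
  # side away from the smallest label and summing complementary entries
  pp <- ape::prop.part(lapply(trees, ape::unroot))
  labs <- attr(pp, "labels")
  counts <- attr(pp, "number")
  ref <- min(labs)
  keys <- vapply(pp, function(idx) {
    side <- sort(labs[idx])
    if (ref %in% side) side <- sort(setdiff(labs, side))
    paste(side, collapse = ";")
  }, "")
  agg <- tapply(counts, keys, sum)
  sizes <- lengths(strsplit(names(agg), ";"))
  want <- names(agg)[agg / 20 > 0.5 & sizes >= 2 & sizes <= 6]
  expect_setequal(gsphylo:::.bipartitions_phylo(cons), want)

  # identical inputs reproduce the tree with frequency 1 everywhere
  t1 <- ape::rtree(6)
  consI <- majority_rule_consensus(list(t1, t1, t1), threshold = 0.5)
  expect_equal(rf_distance(consI, t1), 0)
  expect_true(all(as.numeric(consI$node.label[-1]) == 1))

  # three maximally conflicting quartets give a star
  q <- lapply(c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));"),
              function(s) ape::read.tree(text = s))
  star <- majority_rule_consensus(q, threshold = 0.5)
  expect_equal(star$Nnode, 1L)
})

test_that("RF distance equals explicit bipartition set differences", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  set.seed(73)
  for (rep in 1:10) {
    taxa <- sprintf("t%d", 1:8)
    x <- ape::rtree(8, tip.label = sample(taxa))
    y <- ape::rtree(8, tip.label = sample(taxa))
    expect_equal(rf_distance(x, y), as.integer(phangorn::RF.dist(x, y)),
                 info = rep)
  }
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "taxon")
})
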