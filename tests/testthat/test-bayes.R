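# Pruning likelihood, MCMC sampler, ASDSF, posterior consensus.

test_that("analytic limits: near-zero branches on an invariant column", {
  taxa <- letters[1:4]
  tr <- ape::read.tree(text = "((a:1e-9,b:1e-9):1e-9,c:1e-9,d:1e-9);")
  part <- matrix("G", 4, 1, dimnames = list(taxa, NULL))
  mk <- substitution_model("binary")
  # all mass on the observed state: log pi_G = log 0.5
  expect_equal(pruning_loglik(tr, part, mk), log(0.5), tolerance = 1e-6)
})

test_that("two-taxon likelihood matches the closed-form 2-state formula", {
  mk <- substitution_model("binary")
  for (t12 in c(0.05, 0.3, 1.2)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t12 / 2, t12 / 2))
    match_col <- matrix(c("G", "G"), 2, 1, dimnames = list(c("a", "b"), NULL))
    mismatch <- matrix(c("G", "T"), 2, 1, dimnames = list(c("a", "b"), NULL))
    p_match <- (1 + exp(-2 * t12)) / 2
    expect_equal(pruning_loglik(tr, match_col, mk), log(0.5 * p_match),
                 tolerance = 1e-10)
    expect_equal(pruning_loglik(tr, mismatch, mk), log(0.5 * (1 - p_match)),
                 tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force summation on 4-taxon fixtures", {
  set.seed(79)
  taxa <- letters[1:4]
  for (rep in 1:3) {
    tr <- ape::rtree(4, tip.label = taxa)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
    # binary partition, 3 columns, including missing data
    Xb <- matrix(sample(c("G", "T"), 12, TRUE), 4, 3,
                 dimnames = list(taxa, NULL))
    Xb[1, 2] <- "?"
    mk <- substitution_model("binary")
    want <- sum(vapply(1:3, function(j) {
      states <- stats::setNames(Xb[, j], taxa)
      states[states == "?"] <- NA
      log(bf_column_lik(tr, states, c("G", "T")))
    }, 0))
    expect_equal(pruning_loglik(tr, Xb, mk), want, tolerance = 1e-9)
    # amino-acid partition under the 20-state equal-rates model
    Xa <- matrix(sample(AA20, 12, TRUE), 4, 3, dimnames = list(taxa, NULL))
    aa <- substitution_model("aa")
    want_aa <- sum(vapply(1:3, function(j) {
      log(bf_column_lik(tr, stats::setNames(Xa[, j], taxa), AA20))
    }, 0))
    expect_equal(pruning_loglik(tr, Xa, aa), want_aa, tolerance = 1e-9)
  }
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  set.seed(83)
  taxa <- sprintf("t%d", 1:6)
  tr <- ape::rtree(6, tip.label = taxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  X <- matrix(sample(AA20, 6 * 20, TRUE), 6, dimnames = list(taxa, NULL))
  aa <- substitution_model("aa")
  base <- pruning_loglik(tr, X, aa)
  for (og in c("t2", "t5")) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                          resolve.root = TRUE)
    expect_equal(pruning_loglik(rerooted, X, aa), base, tolerance = 1e-8)
  }
})

test_that("states outside the model alphabet are rejected", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  part <- matrix(c("G", "T", "Z"), 3, 1, dimnames = list(letters[1:3], NULL))
  expect_error(pruning_loglik(tr, part, substitution_model("binary")),
               "alphabet")
})

test_that("custom exchangeability models keep detailed balance", {
  expect_error(substitution_model("binary",
                                  exchangeabilities = matrix(1:4, 2)),
               "symmetric")
  mk2 <- substitution_model("binary",
                            exchangeabilities = matrix(c(0, 1, 1, 0), 2),
                            freqs = c(0.5, 0.5))
  # rows of Q sum to zero and detailed balance pi_i q_ij = pi_j q_ji
  expect_true(all(abs(rowSums(mk2$Q)) < 1e-12))
  P <- gsphylo:::.model_pmat(mk2, 0.37)
  Peq <- gsphylo:::.model_pmat(substitution_model("binary"), 0.37)
  expect_equal(P, Peq, tolerance = 1e-9)
})

test_that("same seed gives an identical sample stream", {
  truth <- simulate_family(simulation_config(seed = 9))
  cm <- character_matrix(names(truth$alignment),
                         aa = gsphylo:::.as_aln_matrix(truth$alignment))
  cfg <- mcmc_config(generations = 400, sample_interval = 20, n_runs = 1,
                     seed = 5)
  r1 <- run_mcmc(cm, cfg)
  r2 <- run_mcmc(cm, cfg)
  expect_identical(r1$runs[[1]]$topology, r2$runs[[1]]$topology)
  expect_identical(r1$runs[[1]]$loglik, r2$runs[[1]]$loglik)
})

test_that("an empty MM partition does not perturb the AA-only posterior", {
  truth <- simulate_family(simulation_config(seed = 9))
  aa <- gsphylo:::.as_aln_matrix(truth$alignment)
  cm_aa <- character_matrix(rownames(aa), aa = aa)
  cm_both <- character_matrix(rownames(aa), aa = aa,
                              mm = matrix(character(0), nrow(aa), 0,
                                          dimnames = list(rownames(aa), NULL)))
  cfg <- mcmc_config(generations = 300, sample_interval = 20, n_runs = 1,
                     seed = 6)
  expect_identical(run_mcmc(cm_aa, cfg)$runs[[1]]$topology,
                   run_mcmc(cm_both, cfg)$runs[[1]]$topology)
})

test_that("ASDSF: identical runs give 0; fully conflicting quartets give 0.5", {
  # construct results directly from the definition's ingredients
  mk_run <- function(bips) {
    list(topology = rep("x", length(bips)), newick = rep("x", length(bips)),
         loglik = numeric(length(bips)), generation = seq_along(bips),
         bipartitions = bips)
  }
  same <- structure(list(
    runs = list(mk_run(list("c;d", "c;d", "b;d", "c;d")),
                mk_run(list("c;d", "c;d", "b;d", "c;d"))),
    config = mcmc_config(generations = 100, sample_interval = 25,
                         burnin_fraction = 0),
    taxa = letters[1:4]), class = "mcmc_result")
  expect_equal(asdsf(same), 0)
  conflict <- structure(list(
    runs = list(mk_run(list("c;d", "c;d", "c;d", "c;d")),
                mk_run(list("b;d", "b;d", "b;d", "b;d"))),
    config = mcmc_config(generations = 100, sample_interval = 25,
                         burnin_fraction = 0),
    taxa = letters[1:4]), class = "mcmc_result")
  # each conflicting split: frequencies (1, 0) -> population sd 0.5
  expect_equal(asdsf(conflict), 0.5)
  expect_error(asdsf(structure(list(runs = same$runs[1]),
                               class = "mcmc_result")), "2 runs")
})

test_that("chains converge on an easy matrix: ASDSF shrinks below 0.05", {
  # every stem long enough to be decisive at 200 columns
  easy_tree <- paste0(
    "(((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2):0.2,",
    "((E:0.3,F:0.3):0.2,G:0.5):0.2,H:0.7);")
  truth <- simulate_family(simulation_config(
    tree_shape = "fixed_newick", newick = easy_tree, taxon_count = 8,
    substitution_rate = 1,
    loss_events = list(list(clade = c("A", "B"), feature = "intron5"),
                       list(clade = "A", feature = "cys_pair2")),
    seed = 10))
  mm <- study_mm_partition(truth)
  cm <- build_combined_matrix(truth$alignment, mm)
  short <- run_mcmc(cm, mcmc_config(generations = 1000, sample_interval = 10,
                                    n_runs = 2, seed = 8))
  res <- run_mcmc(cm, mcmc_config(generations = 12000, sample_interval = 30,
                                  n_runs = 2, seed = 8))
  expect_lt(asdsf(res), 0.05)
  expect_lt(asdsf(res), asdsf(short) + 1e-12)
  # posterior consensus of an informative matrix recovers the true topology
  pc <- posterior_consensus(res)
  expect_equal(rf_distance(pc, truth$tree), 0)
  pps <- as.numeric(pc$node.label[-1])
  expect_true(all(pps >= 0.5 & pps <= 1))
})

test_that("posterior mode equals prior-weighted marginal likelihoods (4 taxa)", {
  # numerical check of sampler correctness: on 4 taxa the posterior over the
  # 3 topologies is proportional to the marginal likelihood under the
  # exponential branch-length prior, here estimated by Monte Carlo
  set.seed(89)
  taxa <- letters[1:4]
  Xb <- matrix(c("G", "G", "T", "T",
                 "G", "G", "T", "T",
                 "G", "T", "G", "T"), 4, 3,
               dimnames = list(taxa, NULL))
  cm <- character_matrix(taxa, mm = Xb)
  mk <- substitution_model("binary")
  newicks <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  marg <- vapply(newicks, function(nw) {
    # unroot first: the chain state space is the 5-edge unrooted tree
    base <- ape::unroot(ape::read.tree(text = nw))
    liks <- replicate(10000, {
      tr <- base
      tr$edge.length <- stats::rexp(nrow(base$edge), 10)
      exp(pruning_loglik(tr, Xb, mk))
    })
    mean(liks)
  }, 0)
  want <- marg / sum(marg)
  res <- run_mcmc(cm, mcmc_config(generations = 40000, sample_interval = 4,
                                  n_runs = 1, seed = 13))
  canon <- vapply(newicks, function(nw) {
    gsphylo:::.ut_canon(gsphylo:::.phylo_to_utree(ape::read.tree(text = nw)))
  }, "")
  tops <- res$runs[[1]]$topology[2501:10000]  # drop burn-in
  got <- vapply(canon, function(cc) mean(tops == cc), 0)
  expect_lt(max(abs(got - want)), 0.06)
})
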