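# Lightweight Bayesian inference over combined matrices: Felsenstein pruning
# likelihood (amino acids under an equal-rates or user-supplied reversible
# model; MM characters under the 2-state Mk model), Metropolis-Hastings MCMC
# over (topology, branch lengths), split-frequency convergence and posterior
# consensus.

#' Substitution model for the pruning likelihood
#'
#' Equal-rates models use the closed-form Jukes-Cantor-type transition
#' probability on k states, normalised so branch lengths are expected
#' substitutions per site.  A reversible empirical model can be supplied as a
#' symmetric exchangeability matrix plus stationary frequencies.
#'
#' @param states `"aa"` (20 states) or `"binary"` (2-state Mk on G/T).
#' @param exchangeabilities Optional symmetric k x k matrix of relative rates
#'   (diagonal ignored); `NULL` for equal rates.
#' @param freqs Stationary frequencies (default equal, must sum to 1).
#' @return Object of class `substitution_model`.
#' @export
substitution_model <- function(states = c("aa", "binary"),
                               exchangeabilities = NULL, freqs = NULL) {
  states <- match.arg(states)
  alphabet <- if (states == "aa") .AA20 else c("G", "T")
  k <- length(alphabet)
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  if (length(freqs) != k || abs(sum(freqs) - 1) > 1e-8 || any(freqs <= 0)) {
    stop("freqs must be ", k, " positive values summing to 1")
  }
  model <- list(states = states, alphabet = alphabet, k = k, freqs = freqs,
                type = if (is.null(exchangeabilities)) "equal" else "custom")
  if (!is.null(exchangeabilities)) {
    R <- as.matrix(exchangeabilities)
    if (!isTRUE(all.equal(R, t(R)))) stop("exchangeability matrix must be symmetric")
    Q <- R * rep(freqs, each = k)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    mu <- -sum(freqs * diag(Q))   # expected substitutions per unit time
    Q <- Q / mu
    model$eigen <- eigen(Q)
    model$Q <- Q
  }
  structure(model, class = "substitution_model")
}

# Transition probability matrix for branch length t.
.model_pmat <- function(model, t) {
  k <- model$k
  if (model$type == "equal") {
    a <- exp(-k * t / (k - 1))
    P <- matrix((1 - a) / k, k, k)
    diag(P) <- diag(P) + a
    P
  } else {
    eg <- model$eigen
    P <- Re(eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors))
    P[P < 0] <- 0
    P
  }
}

# Pack one partition into per-pattern tip conditionals.
# Returns list(tipL = list over taxa of k x npat 0/1 matrices, weights).
.pack_likelihood <- function(X, model) {
  if (!ncol(X)) return(NULL)
  k <- model$k
  keys <- apply(X, 2L, paste, collapse = "\r")
  uk <- unique(keys)
  weights <- as.numeric(tabulate(match(keys, uk), nbins = length(uk)))
  first <- match(uk, keys)
  Xu <- X[, first, drop = FALSE]
  tipL <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    L <- matrix(0, k, length(uk))
    st <- match(Xu[i, ], model$alphabet)
    miss <- is.na(st)
    if (any(!miss)) L[cbind(st[!miss], which(!miss))] <- 1
    L[, miss] <- 1  # missing data marginalised
    bad <- miss & !(Xu[i, ] %in% .MISSING_CHARS)
    if (any(bad)) {
      stop("state '", Xu[i, which(bad)[1L]], "' outside the model alphabet")
    }
    tipL[[i]] <- L
  }
  names(tipL) <- rownames(X)
  list(tipL = tipL, weights = weights, npat = length(uk))
}

# Pruning log-likelihood on a utree with branch lengths in elen.
# Fast path without per-node rescaling; falls back to the scaled recursion if
# any site likelihood underflows.  For equal-rates models
# P(t) = a I + (1 - a)/k J, so P %*% L reduces to a column-sum broadcast.
.ut_loglik <- function(tr, pk, model) {
  if (is.null(pk)) return(0)
  k <- model$k
  npat <- pk$npat
  equal <- model$type == "equal"
  rec <- function(node, parent) {
    L <- NULL
    for (nb in tr$adj[[node]]) {
      if (nb == parent) next
      child <- if (nb <= tr$n_tip) pk$tipL[[tr$labels[nb]]] else rec(nb, node)
      t_ <- tr$elen[[.ut_ekey(node, nb)]]
      if (equal) {
        a <- exp(-k * t_ / (k - 1))
        contrib <- a * child +
          rep(((1 - a) / k) * .colSums(child, k, npat), each = k)
      } else {
        contrib <- .model_pmat(model, t_) %*% child
      }
      L <- if (is.null(L)) contrib else L * contrib
    }
    L
  }
  L0 <- rec(tr$n_tip + 1L, 0L)
  site <- as.vector(model$freqs %*% L0)
  if (all(site > 0) && all(is.finite(site))) {
    return(sum(pk$weights * log(site)))
  }
  .ut_loglik_scaled(tr, pk, model)
}

# Scaled pruning recursion, robust to underflow on large trees.
.ut_loglik_scaled <- function(tr, pk, model) {
  k <- model$k
  logsc <- numeric(pk$npat)
  rec <- function(node, parent) {
    if (node <= tr$n_tip) return(pk$tipL[[tr$labels[node]]])
    L <- NULL
    for (nb in tr$adj[[node]]) {
      if (nb == parent) next
      child <- rec(nb, node)
      P <- .model_pmat(model, tr$elen[[.ut_ekey(node, nb)]])
      contrib <- P %*% child
      L <- if (is.null(L)) contrib else L * contrib
    }
    mx <- apply(L, 2L, max)
    mx[mx == 0] <- 1
    logsc <<- logsc + log(mx)
    L / rep(mx, each = k)
  }
  L0 <- rec(tr$n_tip + 1L, 0L)
  site <- as.vector(model$freqs %*% L0)
  sum(pk$weights * (log(site) + logsc))
}

#' Felsenstein pruning log-likelihood
#'
#' Sum over columns of the log of the pruned likelihood; gaps and `?` are
#' marginalised.  For reversible models the value is invariant under
#' re-rooting.
#'
#' @param tree `phylo` with strictly positive branch lengths.
#' @param partition Character matrix (rows = taxa) of aligned states.
#' @param model A [substitution_model()] matching the partition's state space.
#' @return Log-likelihood.
#' @export
pruning_loglik <- function(tree, partition, model) {
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths")
  }
  if (!setequal(tree$tip.label, rownames(partition))) {
    stop("tree leaves do not match partition taxa")
  }
  ut <- .phylo_to_utree(tree)
  pk <- .pack_likelihood(partition, model)
  .ut_loglik(ut, pk, model)
}

#' MCMC configuration
#'
#' @param generations Number of Metropolis-Hastings proposals per run.
#' @param sample_interval Record a sample every this many generations.
#' @param burnin_fraction Fraction of samples discarded by the summaries.
#' @param n_runs Independent runs with distinct seed offsets (default 2).
#' @param proposal_weights Named weights for the `topology` (NNI) and
#'   `blen` (branch-length multiplier) moves; default 1:3.
#' @param tuning Multiplier tuning constant (default 2).
#' @param blen_prior_mean Mean of the exponential branch-length prior.
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @export
mcmc_config <- function(generations = 20000L, sample_interval = 20L,
                        burnin_fraction = 0.25, n_runs = 2L,
                        proposal_weights = c(topology = 1, blen = 3),
                        tuning = 2, blen_prior_mean = 0.1, seed = 1L) {
  if (generations < sample_interval) stop("generations must be >= sample_interval")
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must be in [0, 1)")
  }
  if (any(proposal_weights <= 0)) stop("proposal weights must be positive")
  list(generations = as.integer(generations),
       sample_interval = as.integer(sample_interval),
       burnin_fraction = burnin_fraction, n_runs = as.integer(n_runs),
       proposal_weights = proposal_weights, tuning = tuning,
       blen_prior_mean = blen_prior_mean, seed = as.integer(seed))
}

# Random resolved starting topology on the ambient RNG stream.
.random_utree <- function(labels, blen = 0.1) {
  n <- length(labels)
  ord <- sample.int(n)
  tr <- .ut_new(labels, ord[1:3], lengths = TRUE)
  for (t in tr$adj[[n + 1L]]) tr$elen[.ut_ekey(t, n + 1L)] <- blen
  for (k in seq_along(ord)[-(1:3)]) {
    edges <- .ut_edges(tr)
    i <- sample.int(nrow(edges), 1L)
    tr <- .ut_insert_tip(tr, edges[i, 1L], edges[i, 2L], ord[k])
    tr$elen[] <- blen
  }
  tr
}

#' Bayesian MCMC over topology and branch lengths
#'
#' Metropolis-Hastings sampler targeting the joint posterior of the combined
#' matrix: amino-acid partition likelihood times MM-partition (2-state Mk)
#' likelihood, uniform prior over topologies, independent exponential priors
#' on branch lengths.  Moves: random NNI on an internal edge and a
#' branch-length multiplier with tuning constant `config$tuning`.  Runs
#' `config$n_runs` independent chains; deterministic given `config$seed`.
#'
#' @param matrix A [character_matrix()] with at least 4 taxa (either
#'   partition may be empty; with both empty the target is the prior).
#' @param config An [mcmc_config()].
#' @param aa_model Optional [substitution_model()] for the amino-acid
#'   partition (default equal-rates 20-state).
#' @return Object of class `mcmc_result`: per-run samples (`topology`
#'   canonical strings, `newick`, `loglik`, `generation`, bipartition keys per
#'   sample), acceptance rates, and the config.
#' @export
run_mcmc <- function(matrix, config = mcmc_config(), aa_model = NULL) {
  taxa <- matrix$taxa
  if (length(taxa) < 4L) stop("MCMC needs at least 4 taxa")
  if (is.null(aa_model)) aa_model <- substitution_model("aa")
  mk <- substitution_model("binary")
  pk_aa <- if (ncol(matrix$aa)) .pack_likelihood(matrix$aa, aa_model) else NULL
  pk_mm <- if (ncol(matrix$mm)) .pack_likelihood(matrix$mm, mk) else NULL
  ll_fun <- function(tr) {
    .ut_loglik(tr, pk_aa, aa_model) + .ut_loglik(tr, pk_mm, mk)
  }
  rate <- 1 / config$blen_prior_mean
  pw <- config$proposal_weights / sum(config$proposal_weights)
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    runs[[r]] <- .with_seed(config$seed + r - 1L, {
      tr <- .random_utree(taxa)
      ll <- ll_fun(tr)
      n_samp <- config$generations %/% config$sample_interval
      samp_topo <- character(n_samp)
      samp_newick <- character(n_samp)
      samp_ll <- numeric(n_samp)
      samp_gen <- integer(n_samp)
      samp_bip <- vector("list", n_samp)
      acc <- c(topology = 0L, blen = 0L)
      prop <- c(topology = 0L, blen = 0L)
      si <- 0L
      internal_edge_list <- function(tr) {
        ed <- .ut_edges(tr)
        ed[ed[, 1L] > tr$n_tip & ed[, 2L] > tr$n_tip, , drop = FALSE]
      }
      for (g in seq_len(config$generations)) {
        if (stats::runif(1) < pw[["topology"]]) {
          prop["topology"] <- prop["topology"] + 1L
          ie <- internal_edge_list(tr)
          if (nrow(ie)) {
            i <- if (nrow(ie) == 1L) 1L else sample.int(nrow(ie), 1L)
            cand <- .ut_nni(tr, ie[i, 1L], ie[i, 2L],
                            sample.int(2L, 1L), sample.int(2L, 1L))
            ll2 <- ll_fun(cand)
            if (log(stats::runif(1)) < ll2 - ll) {
              tr <- cand; ll <- ll2
              acc["topology"] <- acc["topology"] + 1L
            }
          }
        } else {
          prop["blen"] <- prop["blen"] + 1L
          ek <- names(tr$elen)[sample.int(length(tr$elen), 1L)]
          old <- tr$elen[[ek]]
          mult <- exp(config$tuning * (stats::runif(1) - 0.5))
          cand <- tr
          cand$elen[[ek]] <- old * mult
          ll2 <- ll_fun(cand)
          dlp <- stats::dexp(old * mult, rate, log = TRUE) -
            stats::dexp(old, rate, log = TRUE)
          if (log(stats::runif(1)) < ll2 - ll + dlp + log(mult)) {
            tr <- cand; ll <- ll2
            acc["blen"] <- acc["blen"] + 1L
          }
        }
        if (g %% config$sample_interval == 0L) {
          si <- si + 1L
          samp_topo[si] <- .ut_canon(tr)
          samp_newick[si] <- .ut_newick(tr, lengths = TRUE)
          samp_ll[si] <- ll
          samp_gen[si] <- g
          samp_bip[[si]] <- .ut_bipartitions(tr)
        }
      }
      list(topology = samp_topo, newick = samp_newick, loglik = samp_ll,
           generation = samp_gen, bipartitions = samp_bip,
           acceptance = ifelse(prop > 0L, acc / prop, NA_real_))
    })
  }
  structure(list(runs = runs, config = config, taxa = taxa),
            class = "mcmc_result")
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat(sprintf("MCMC: %d run(s) x %d generations, %d samples each\n",
              length(x$runs), x$config$generations,
              length(x$runs[[1L]]$topology)))
  invisible(x)
}

.post_burnin <- function(run, burnin_fraction) {
  n <- length(run$topology)
  drop <- floor(n * burnin_fraction)
  if (drop >= n) stop("burn-in leaves no samples")
  (drop + 1L):n
}

#' Average standard deviation of split frequencies (ASDSF)
#'
#' For every bipartition seen in any run, its post-burn-in sample frequency is
#' computed per run; the ASDSF is the mean, over bipartitions reaching
#' `min_freq` in at least one run, of the across-run (population) standard
#' deviation of those frequencies.  The convergence diagnostic of
#' two-run Bayesian analyses: values near 0 indicate agreeing runs.
#'
#' @param result An `mcmc_result` with at least 2 runs.
#' @param burnin_fraction Override of the config's burn-in fraction.
#' @param min_freq Frequency floor below which (in all runs) a bipartition is
#'   excluded (default 0.10).
#' @return The ASDSF (0 if no bipartition passes the floor).
#' @export
asdsf <- function(result, burnin_fraction = NULL, min_freq = 0.1) {
  if (length(result$runs) < 2L) stop("asdsf needs at least 2 runs")
  if (is.null(burnin_fraction)) burnin_fraction <- result$config$burnin_fraction
  freq_tabs <- lapply(result$runs, function(run) {
    idx <- .post_burnin(run, burnin_fraction)
    keys <- unlist(run$bipartitions[idx])
    if (is.null(keys)) keys <- character(0)
    table(keys) / length(idx)
  })
  all_keys <- unique(unlist(lapply(freq_tabs, names)))
  if (!length(all_keys)) return(0)
  fmat <- vapply(freq_tabs, function(tb) {
    f <- as.numeric(tb[all_keys])
    f[is.na(f)] <- 0
    f
  }, numeric(length(all_keys)))
  fmat <- matrix(fmat, nrow = length(all_keys))
  keep <- apply(fmat, 1L, max) >= min_freq
  if (!any(keep)) return(0)
  sds <- apply(fmat[keep, , drop = FALSE], 1L, function(f) {
    sqrt(mean((f - mean(f))^2))
  })
  mean(sds)
}

#' Posterior consensus tree with clade probabilities
#'
#' Pools the post-burn-in samples of all runs and returns the majority-rule
#' consensus; internal node labels are bipartition posterior probabilities in
#' `[0, 1]`.
#'
#' @param result An `mcmc_result`.
#' @param burnin_fraction Override of the config's burn-in fraction.
#' @return A `phylo` with posterior probabilities as `node.label`.
#' @export
posterior_consensus <- function(result, burnin_fraction = NULL) {
  if (is.null(burnin_fraction)) burnin_fraction <- result$config$burnin_fraction
  keys <- unlist(lapply(result$runs, function(run) {
    idx <- .post_burnin(run, burnin_fraction)
    unlist(run$bipartitions[idx])
  }))
  total <- sum(vapply(result$runs, function(run) {
    length(.post_burnin(run, burnin_fraction))
  }, 0L))
  taxa <- sort(result$taxa)
  if (is.null(keys) || !length(keys)) {
    return(.build_consensus_tree(taxa, taxa[1L], list(), numeric(0)))
  }
  tab <- table(keys) / total
  sel <- .select_compatible(names(tab), as.numeric(tab))
  pp <- as.numeric(tab[sel])
  clusters <- lapply(sel, function(k) strsplit(k, ";", fixed = TRUE)[[1L]])
  keep <- pp > 0.5
  .build_consensus_tree(taxa, taxa[1L], clusters[keep], pp[keep])
}
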