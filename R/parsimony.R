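# Maximum parsimony: Fitch scoring, heuristic search, bootstrap, consensus.

# Pack a character_matrix into site-pattern bitmasks for Fitch scoring.
# Gaps and '?'/'X' are missing data (any state), never a 21st state.
.pack_matrix <- function(cm) {
  X <- .cm_all(cm)
  if (!ncol(X)) {
    return(list(masks = matrix(integer(0), nrow = length(cm$taxa), ncol = 0L,
                               dimnames = list(cm$taxa, NULL)),
                weights = numeric(0)))
  }
  keys <- apply(X, 2L, paste, collapse = "\r")
  uk <- unique(keys)
  weights <- as.numeric(tabulate(match(keys, uk), nbins = length(uk)))
  first <- match(uk, keys)
  masks <- matrix(1L, nrow = nrow(X), ncol = length(uk),
                  dimnames = list(cm$taxa, NULL))
  for (p in seq_along(uk)) {
    col <- X[, first[p]]
    obs <- sort(setdiff(unique(col), .MISSING_CHARS))
    if (!length(obs)) next  # all-missing column: leave as a single dummy state
    full <- bitwShiftL(1L, length(obs)) - 1L
    msk <- bitwShiftL(1L, match(col, obs) - 1L)
    msk[is.na(msk)] <- full
    masks[, p] <- msk
  }
  list(masks = masks, weights = weights)
}

# Fitch parsimony length on a utree, vectorised over site patterns.
# Rooting at the internal node adjacent to tip 1 and folding children
# sequentially is equivalent to rooting on one of that node's edges.
.ut_fitch <- function(tr, masks, weights) {
  if (!ncol(masks)) return(0)
  score <- 0
  rec <- function(node, parent) {
    if (node <= tr$n_tip) return(masks[node, ])
    cur <- NULL
    for (nb in tr$adj[[node]]) {
      if (nb == parent) next
      ch <- rec(nb, node)
      if (is.null(cur)) {
        cur <- ch
      } else {
        inter <- bitwAnd(cur, ch)
        z <- inter == 0L
        if (any(z)) {
          score <<- score + sum(weights[z])
          inter[z] <- bitwOr(cur[z], ch[z])
        }
        cur <- inter
      }
    }
    cur
  }
  # root at internal node n_tip + 1, which exists in complete and in
  # partially built (stepwise-addition) trees alike
  rec(tr$n_tip + 1L, 0L)
  score
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of state changes over all columns (amino acid and MM alike,
#' unordered states; gaps and `?` treated as missing data) computed by the
#' Fitch bottom-up intersection/union pass.  Invariant under re-rooting.
#'
#' @param tree A `phylo` whose tip labels equal the matrix taxa.
#' @param matrix A [character_matrix()].
#' @return Integer-valued parsimony length.
#' @export
fitch_length <- function(tree, matrix) {
  if (!setequal(tree$tip.label, matrix$taxa)) {
    stop("tree leaves do not match matrix taxa")
  }
  pk <- .pack_matrix(matrix)
  ut <- .phylo_to_utree(tree)
  .ut_fitch(ut, pk$masks[ut$labels, , drop = FALSE], pk$weights)
}

#' Heuristic search configuration
#'
#' @param n_starts Random-addition replicates (>= 1).
#' @param swap Branch-swapping neighbourhood: `"SPR"` (default) or `"NNI"`.
#' @param max_rounds Cap on swap rounds per start.
#' @param seed RNG seed for the random addition orders.
#' @export
search_config <- function(n_starts = 10L, swap = c("SPR", "NNI"),
                          max_rounds = 100L, seed = 1L) {
  swap <- match.arg(swap)
  if (n_starts < 1L) stop("n_starts must be >= 1")
  list(n_starts = as.integer(n_starts), swap = swap,
       max_rounds = as.integer(max_rounds), seed = seed)
}

# Greedy stepwise addition: insert each taxon (in `ord`) on the edge that
# minimises the Fitch length.  `masks` rows are in taxon-index order.
.stepwise_add <- function(masks, weights, labels, ord) {
  tr <- .ut_new(labels, ord[1:3])
  for (k in seq_along(ord)[-(1:3)]) {
    tip <- ord[k]
    edges <- .ut_edges(tr)
    best <- NULL
    best_score <- Inf
    for (i in seq_len(nrow(edges))) {
      cand <- .ut_insert_tip(tr, edges[i, 1L], edges[i, 2L], tip)
      sc <- .ut_fitch(cand, masks, weights)
      if (sc < best_score) { best_score <- sc; best <- cand }
    }
    tr <- best
  }
  tr
}

.nni_neighbors <- function(tr) {
  out <- list()
  edges <- .ut_edges(tr)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    if (u <= tr$n_tip || v <= tr$n_tip) next
    out[[length(out) + 1L]] <- .ut_nni(tr, u, v, 1L)
    out[[length(out) + 1L]] <- .ut_nni(tr, u, v, 2L)
  }
  out
}

# Nearest-neighbour interchange across internal edge (u, v): swap the
# `choice`-th non-v neighbour of u with the `choice_c`-th non-u neighbour of
# v.  For enumeration choice_c = 1 suffices (the two `choice` values yield
# the two alternative topologies); the MCMC draws both uniformly so that the
# swap is self-inverse with equal forward and reverse selection probability.
.ut_nni <- function(tr, u, v, choice, choice_c = 1L) {
  nbu <- tr$adj[[u]]; nbu <- nbu[nbu != v]
  nbv <- tr$adj[[v]]; nbv <- nbv[nbv != u]
  b <- nbu[choice]; cc <- nbv[choice_c]
  tr$adj[[u]][tr$adj[[u]] == b] <- cc
  tr$adj[[v]][tr$adj[[v]] == cc] <- b
  tr$adj[[b]][tr$adj[[b]] == u] <- v
  tr$adj[[cc]][tr$adj[[cc]] == v] <- u
  if (!is.null(tr$elen)) {
    kub <- .ut_ekey(u, b); kvc <- .ut_ekey(v, cc)
    lb <- tr$elen[[kub]]; lc <- tr$elen[[kvc]]
    tr$elen <- tr$elen[!names(tr$elen) %in% c(kub, kvc)]
    tr$elen[.ut_ekey(v, b)] <- lb
    tr$elen[.ut_ekey(u, cc)] <- lc
  }
  tr
}

# All subtree-prune-regraft neighbours (includes the NNI neighbourhood).
.spr_neighbors <- function(tr) {
  out <- list()
  edges <- .ut_edges(tr)
  for (i in seq_len(nrow(edges))) {
    for (dir in 1:2) {
      u <- edges[i, dir]; v <- edges[i, 3L - dir]
      if (u <= tr$n_tip) next  # junction node must be internal to splice
      pruned <- .ut_nodes_below(tr, v, u)
      nbu <- tr$adj[[u]]; nbu <- nbu[nbu != v]
      x <- nbu[1L]; y <- nbu[2L]
      base <- tr
      base$adj[[u]] <- integer(0)
      base$adj[[x]][base$adj[[x]] == u] <- y
      base$adj[[y]][base$adj[[y]] == u] <- x
      # candidate regraft edges: edges of the remaining component, minus the
      # spliced edge (x, y) which would recreate the original tree
      rem <- setdiff(seq_along(tr$adj), c(pruned, u))
      for (j in seq_len(nrow(edges))) {
        a <- edges[j, 1L]; b <- edges[j, 2L]
        if (!(a %in% rem) || !(b %in% rem)) next
        if ((a == x && b == y) || (a == y && b == x)) next
        if (a == u || b == u) next
        cand <- base
        cand$adj[[u]] <- c(a, b, v)
        cand$adj[[a]][cand$adj[[a]] == b] <- u
        cand$adj[[b]][cand$adj[[b]] == a] <- u
        out[[length(out) + 1L]] <- cand
      }
      # the spliced edge (x, y) exists only in `base`; regrafting there is the
      # original tree, so it is correctly excluded
    }
  }
  out
}

.hill_climb <- function(tr, masks, weights, swap, max_rounds) {
  cur_score <- .ut_fitch(tr, masks, weights)
  neigh_fun <- if (swap == "SPR") .spr_neighbors else .nni_neighbors
  ties <- list()
  for (round in seq_len(max_rounds)) {
    nb <- neigh_fun(tr)
    if (!length(nb)) break
    scores <- vapply(nb, .ut_fitch, 0, masks = masks, weights = weights)
    best <- min(scores)
    if (best < cur_score) {
      tr <- nb[[which.min(scores)]]
      cur_score <- best
    } else {
      ties <- nb[scores == cur_score]
      break
    }
  }
  list(tree = tr, score = cur_score, ties = ties)
}

#' Maximum-parsimony heuristic search
#'
#' For each start: stepwise random-order taxon addition (greedy best
#' insertion), then hill-climbing branch swapping (SPR by default, NNI as the
#' cheap option) to a local optimum.  All distinct optimal topologies found
#' across starts (including equal-length neighbours of the local optima) are
#' returned.  Deterministic given `config$seed`.
#'
#' @param matrix A [character_matrix()] with at least 4 taxa.
#' @param config A [search_config()].
#' @return Object of class `mp_result`: `trees` (list of unrooted `phylo`),
#'   `length` (best Fitch length), `n_starts`.
#' @export
search_mp <- function(matrix, config = search_config()) {
  if (length(matrix$taxa) < 4L) {
    stop("maximum parsimony search needs at least 4 taxa")
  }
  res <- .with_seed(config$seed, .search_mp_nostream(matrix, config))
  structure(c(res, list(n_starts = config$n_starts)), class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf("MP search: best length %g, %d optimal topolog%s (%d starts)\n",
              x$length, length(x$trees),
              if (length(x$trees) == 1L) "y" else "ies", x$n_starts))
  invisible(x)
}

#' Nonparametric parsimony bootstrap
#'
#' Resamples columns with replacement jointly across the combined partitions,
#' runs [search_mp()] per replicate, counts each replicate's bipartitions
#' from the strict consensus of that replicate's optima, and returns the
#' >=50% majority-rule consensus with bipartition frequencies as percent
#' supports.
#'
#' @param matrix A [character_matrix()].
#' @param replicates Number of bootstrap replicates.
#' @param config [search_config()] applied within each replicate (default: a
#'   single random-addition start per replicate).
#' @param seed RNG seed for resampling and per-replicate searches.
#' @return Object of class `bootstrap_result`: `tree` (majority-rule
#'   consensus `phylo` with percent supports as node labels), `supports`
#'   (named vector, percent per bipartition), `replicates`.
#' @export
bootstrap_mp <- function(matrix, replicates = 1000L,
                         config = search_config(n_starts = 1L),
                         seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  X <- .cm_all(matrix)
  nc <- ncol(X)
  taxa <- matrix$taxa
  .with_seed(seed, {
    counts <- new.env(parent = emptyenv())
    for (r in seq_len(replicates)) {
      idx <- sample.int(nc, nc, replace = TRUE)
      bm <- character_matrix(taxa, aa = X[, idx, drop = FALSE])
      rep_cfg <- config
      rep_cfg$seed <- NULL  # stay on the replicate stream
      res <- .search_mp_nostream(bm, rep_cfg)
      keysets <- lapply(res$trees, .bipartitions_phylo)
      strict <- Reduce(intersect, keysets)
      for (k in strict) {
        counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      }
    }
    keys <- ls(counts)
    freq <- vapply(keys, function(k) counts[[k]], 0L) / replicates
    sel <- .select_compatible(keys[freq >= 0.5], freq[freq >= 0.5])
    supports <- 100 * freq[sel]
    clusters <- lapply(sel, function(k) strsplit(k, ";", fixed = TRUE)[[1L]])
    tree <- .build_consensus_tree(sort(taxa), sort(taxa)[1L], clusters,
                                  unname(supports))
    structure(list(tree = tree, supports = supports, replicates = replicates),
              class = "bootstrap_result")
  })
}

# Frequency-ordered greedy selection of mutually compatible bipartitions
# (relevant only at frequency exactly 0.5, where conflicts are possible; on
# reference-excluded clusters compatibility is nested-or-disjoint).
.select_compatible <- function(keys, freq) {
  if (!length(keys)) return(character(0))
  clusters <- lapply(keys, function(k) strsplit(k, ";", fixed = TRUE)[[1L]])
  ord <- order(-freq, -vapply(clusters, length, 0L), keys)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      inter <- length(intersect(clusters[[i]], clusters[[j]]))
      nested <- inter == length(clusters[[i]]) || inter == length(clusters[[j]])
      if (inter > 0L && !nested) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  keys[sort(kept)]
}

# search_mp without seed management: runs on the ambient RNG stream.
.search_mp_nostream <- function(matrix, config) {
  n <- length(matrix$taxa)
  pk <- .pack_matrix(matrix)
  best_score <- Inf
  found <- list()
  for (s in seq_len(config$n_starts)) {
    ord <- sample.int(n)
    tr <- .stepwise_add(pk$masks, pk$weights, matrix$taxa, ord)
    hc <- .hill_climb(tr, pk$masks, pk$weights, config$swap, config$max_rounds)
    for (ct in c(list(hc$tree), hc$ties)) {
      sc <- .ut_fitch(ct, pk$masks, pk$weights)
      if (sc < best_score) { best_score <- sc; found <- list() }
      if (sc == best_score) found[[.ut_canon(ct)]] <- ct
    }
  }
  list(trees = lapply(found, .utree_to_phylo), length = best_score)
}
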