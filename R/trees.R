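# Internal unrooted-tree toolkit.
#
# Trees under heuristic search and MCMC are held in a light adjacency
# representation ("utree"): tips are nodes 1..n_tip (labelled), internal nodes
# n_tip+1..2*n_tip-2, `adj` is a list of integer neighbour vectors, and
# optional branch lengths live in `elen`, a numeric vector named by the
# canonical edge key "min-max".  The public interface everywhere uses ape
# `phylo` objects; conversions are at the boundary.

.ut_ekey <- function(u, v) {
  if (u < v) paste0(u, "-", v) else paste0(v, "-", u)
}

.ut_new <- function(labels, first3, lengths = FALSE) {
  n <- length(labels)
  tr <- list(
    n_tip = n,
    labels = labels,
    adj = vector("list", 2L * n - 2L),
    elen = if (lengths) stats::setNames(numeric(0), character(0)) else NULL,
    next_internal = n + 2L
  )
  hub <- n + 1L
  tr$adj[[hub]] <- as.integer(first3)
  for (t in first3) tr$adj[[t]] <- hub
  if (lengths) {
    for (t in first3) tr$elen[.ut_ekey(t, hub)] <- 0.1
  }
  tr
}

# Subdivide edge (u,v) with a fresh internal node and hang `tip` from it.
.ut_insert_tip <- function(tr, u, v, tip) {
  w <- tr$next_internal
  tr$next_internal <- w + 1L
  tr$adj[[u]][tr$adj[[u]] == v] <- w
  tr$adj[[v]][tr$adj[[v]] == u] <- w
  tr$adj[[w]] <- c(u, v, tip)
  tr$adj[[tip]] <- w
  if (!is.null(tr$elen)) {
    old <- tr$elen[[.ut_ekey(u, v)]]
    tr$elen <- tr$elen[names(tr$elen) != .ut_ekey(u, v)]
    tr$elen[.ut_ekey(u, w)] <- old / 2
    tr$elen[.ut_ekey(v, w)] <- old / 2
    tr$elen[.ut_ekey(tip, w)] <- 0.1
  }
  tr
}

.ut_edges <- function(tr) {
  from <- integer(0)
  to <- integer(0)
  for (u in seq_along(tr$adj)) {
    nb <- tr$adj[[u]]
    keep <- nb > u
    if (any(keep)) {
      from <- c(from, rep.int(u, sum(keep)))
      to <- c(to, nb[keep])
    }
  }
  cbind(from, to)
}

# Tips reachable from `node` when arriving from `parent`.
.ut_tips_below <- function(tr, node, parent) {
  if (node <= tr$n_tip) return(node)
  out <- integer(0)
  stack <- list(c(node, parent))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top[1L]; pa <- top[2L]
    for (nb in tr$adj[[nd]]) {
      if (nb == pa) next
      if (nb <= tr$n_tip) out <- c(out, nb)
      else stack[[length(stack) + 1L]] <- c(nb, nd)
    }
  }
  out
}

# All nodes (tips and internal) on the `node` side of edge (parent, node).
.ut_nodes_below <- function(tr, node, parent) {
  out <- node
  stack <- list(c(node, parent))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top[1L]; pa <- top[2L]
    for (nb in tr$adj[[nd]]) {
      if (nb == pa) next
      out <- c(out, nb)
      if (nb > tr$n_tip) stack[[length(stack) + 1L]] <- c(nb, nd)
    }
  }
  out
}

.ut_newick <- function(tr, lengths = FALSE) {
  rec <- function(node, parent) {
    if (node <= tr$n_tip) {
      s <- tr$labels[node]
    } else {
      kids <- tr$adj[[node]]
      kids <- kids[kids != parent]
      s <- paste0("(", paste(vapply(kids, rec, "", node), collapse = ","), ")")
    }
    if (lengths && parent != 0L) {
      s <- paste0(s, ":", format(tr$elen[[.ut_ekey(node, parent)]], digits = 12))
    }
    s
  }
  root <- tr$adj[[1L]][1L]
  paste0(rec(root, 0L), ";")
}

# Canonical label-sorted topology string; used to deduplicate topologies.
.ut_canon <- function(tr) {
  rec <- function(node, parent) {
    if (node <= tr$n_tip) return(tr$labels[node])
    kids <- tr$adj[[node]]
    kids <- kids[kids != parent]
    paste0("(", paste(sort(vapply(kids, rec, "", node)), collapse = ","), ")")
  }
  ref <- which(tr$labels == min(tr$labels))[1L]
  paste0(tr$labels[ref], "|", rec(tr$adj[[ref]][1L], ref))
}

# Non-trivial bipartition keys: for every internal edge, the sorted labels of
# the side NOT containing the reference tip (lexicographically smallest label).
.ut_bipartitions <- function(tr) {
  ref <- which(tr$labels == min(tr$labels))[1L]
  edges <- .ut_edges(tr)
  keys <- character(0)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    if (u <= tr$n_tip || v <= tr$n_tip) next
    side_v <- .ut_tips_below(tr, v, u)
    side <- if (ref %in% side_v) setdiff(seq_len(tr$n_tip), side_v) else side_v
    if (length(side) < 2L || length(side) > tr$n_tip - 2L) next
    keys <- c(keys, paste(sort(tr$labels[side]), collapse = ";"))
  }
  keys
}

.phylo_to_utree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a phylo object")
  if (length(phy$tip.label) > 2L && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  adj <- vector("list", m)
  elen <- NULL
  has_len <- !is.null(phy$edge.length)
  if (has_len) elen <- stats::setNames(numeric(0), character(0))
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    if (has_len) elen[.ut_ekey(a, b)] <- phy$edge.length[i]
  }
  list(n_tip = n, labels = phy$tip.label, adj = adj, elen = elen,
       next_internal = m + 1L)
}

.utree_to_phylo <- function(tr, lengths = !is.null(tr$elen)) {
  ape::read.tree(text = .ut_newick(tr, lengths = lengths))
}

.bipartitions_phylo <- function(phy) {
  if (length(phy$tip.label) < 4L) return(character(0))
  .ut_bipartitions(.phylo_to_utree(phy))
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Counts the non-trivial bipartitions present in one tree but not the other
#' (the symmetric difference).  Trees must be on the same taxon set; rooted
#' trees are unrooted first.
#'
#' @param tree1,tree2 `phylo` objects with identical tip labels.
#' @return Integer symmetric-difference count.
#' @export
rf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees are on different taxon sets")
  }
  b1 <- .bipartitions_phylo(tree1)
  b2 <- .bipartitions_phylo(tree2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Build a (possibly multifurcating) consensus phylo from compatible clusters.
# `clusters` is a list of character vectors of tip labels, none containing
# `ref`; `freqs` are the matching frequencies used as node labels.
.build_consensus_tree <- function(labels, ref, clusters, freqs, digits = 3L) {
  ord <- order(vapply(clusters, length, 0L), decreasing = TRUE)
  clusters <- clusters[ord]
  freqs <- freqs[ord]
  nc <- length(clusters)
  # parent[i] = smallest cluster strictly containing cluster i (0 = root);
  # clusters are size-sorted so the last superset seen is the smallest
  parent <- rep.int(0L, nc)
  for (i in seq_len(nc)) {
    for (j in seq_len(i - 1L)) {
      inter <- length(intersect(clusters[[i]], clusters[[j]]))
      if (inter == length(clusters[[i]])) {
        parent[i] <- j
      } else if (inter > 0L) {
        stop("incompatible clusters in consensus input")
      }
    }
  }
  build <- function(i) {
    members <- if (i == 0L) setdiff(labels, ref) else clusters[[i]]
    kids <- which(parent == i & seq_len(nc) > i)
    kid_strs <- character(0)
    used <- character(0)
    for (k in kids) {
      kid_strs <- c(kid_strs, build(k))
      used <- c(used, clusters[[k]])
    }
    loose <- setdiff(members, used)
    parts <- c(kid_strs, sort(loose))
    inner <- paste(parts, collapse = ",")
    if (i == 0L) {
      paste0("(", inner, ",", ref, ");")
    } else {
      paste0("(", inner, ")", format(freqs[i], digits = digits))
    }
  }
  ape::read.tree(text = build(0L))
}

#' Majority-rule consensus of a set of trees
#'
#' Returns the tree containing exactly the non-trivial bipartitions whose
#' frequency among the input trees exceeds `threshold` (with `threshold = 1`
#' interpreted as the strict consensus: bipartitions present in every tree).
#' Bipartition frequencies are attached as internal node labels.
#'
#' @param trees List of `phylo` objects on identical taxa.
#' @param threshold Proportion in `[0.5, 1]`.
#' @param percent Report frequencies as percentages rather than proportions.
#' @return A `phylo` object, multifurcating where support is lacking, with
#'   `node.label` holding bipartition frequencies.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5, percent = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees given")
  labels <- sort(trees[[1L]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, labels)) stop("trees are on different taxon sets")
  }
  if (threshold < 0.5 || threshold > 1) {
    stop("threshold must be in [0.5, 1]")
  }
  keys <- unlist(lapply(trees, .bipartitions_phylo))
  tab <- table(keys) / length(trees)
  keep <- if (threshold == 1) tab >= 1 else tab > threshold
  tab <- tab[keep]
  ref <- labels[1L]
  clusters <- lapply(names(tab), function(k) strsplit(k, ";", fixed = TRUE)[[1L]])
  freqs <- as.numeric(tab)
  if (percent) freqs <- 100 * freqs
  .build_consensus_tree(labels, ref, clusters, freqs)
}
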