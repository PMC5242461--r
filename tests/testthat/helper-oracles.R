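# Independent oracles used across the suite.  Deliberately naive: these
# re-derive expected values by enumeration or direct definition, never by
# calling the code paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# --- motif matching ------------------------------------------------------

# Recursive matcher for the dash-token motif grammar; returns all
# non-overlapping leftmost-shortest hits as (start, end) pairs.
bf_motif_hits <- function(seq, pattern) {
  tokens <- strsplit(pattern, "-", fixed = TRUE)[[1L]]
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(s)
  # shortest match length of tokens[ti..] starting at position p, or NA
  match_from <- function(p, ti) {
    if (ti > length(tokens)) return(p - 1L)  # end position of the match
    tk <- tokens[ti]
    if (tk == "x") {
      if (p > n) return(NA_integer_)
      return(match_from(p + 1L, ti + 1L))
    }
    if (grepl("^x\\(", tk)) {
      ij <- as.integer(strsplit(gsub("[x()]", "", tk), ",")[[1L]])
      if (length(ij) == 1L) ij <- c(ij, ij)
      for (w in ij[1L]:ij[2L]) {
        if (p + w - 1L > n) break
        res <- match_from(p + w, ti + 1L)
        if (!is.na(res)) return(res)
      }
      return(NA_integer_)
    }
    if (grepl("^\\[", tk)) {
      cls <- strsplit(gsub("[][]", "", tk), "")[[1L]]
      if (p > n || !(s[p] %in% cls)) return(NA_integer_)
      return(match_from(p + 1L, ti + 1L))
    }
    w <- nchar(tk)
    if (p + w - 1L > n) return(NA_integer_)
    if (paste(s[p:(p + w - 1L)], collapse = "") != tk) return(NA_integer_)
    match_from(p + w, ti + 1L)
  }
  hits <- NULL
  p <- 1L
  while (p <= n) {
    e <- match_from(p, 1L)
    if (!is.na(e)) {
      hits <- rbind(hits, c(p, e))
      p <- e + 1L
    } else {
      p <- p + 1L
    }
  }
  hits
}

# --- local alignment -----------------------------------------------------

# Global affine-gap alignment score of two (short) strings; gap of length L
# costs open + ext * L.  Plain three-matrix DP, no local resets.
bf_global_affine <- function(q, t, S, open, ext) {
  qv <- strsplit(q, "", fixed = TRUE)[[1L]]
  tv <- strsplit(t, "", fixed = TRUE)[[1L]]
  n <- length(qv); m <- length(tv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)
  F_ <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (j in seq_len(m)) E[1L, j + 1L] <- -open - ext * j
  for (i in seq_len(n)) F_[i + 1L, 1L] <- -open - ext * i
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      prev <- max(M[i - 1L, j - 1L], E[i - 1L, j - 1L], F_[i - 1L, j - 1L])
      M[i, j] <- prev + S[qv[i - 1L], tv[j - 1L]]
      E[i, j] <- max(M[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F_[i, j] <- max(M[i - 1L, j] - open - ext, F_[i - 1L, j] - ext)
    }
  }
  max(M[n + 1L, m + 1L], E[n + 1L, m + 1L], F_[n + 1L, m + 1L])
}

# Brute-force best local alignment score: maximise the global affine score
# over every pair of non-empty substrings.  Only viable for tiny inputs.
bf_local_score <- function(q, t, S, open, ext) {
  best <- 0
  nq <- nchar(q); nt <- nchar(t)
  for (i1 in 1:nq) for (i2 in i1:nq) {
    qs <- substr(q, i1, i2)
    for (j1 in 1:nt) for (j2 in j1:nt) {
      sc <- bf_global_affine(qs, substr(t, j1, j2), S, open, ext)
      if (sc > best) best <- sc
    }
  }
  best
}

# --- parsimony -----------------------------------------------------------

# Minimum changes of one column on a tree by enumerating every assignment of
# observed states to internal nodes (and to missing-data tips).
bf_column_changes <- function(phy, states) {
  # states: named by tip label; NA = missing
  obs <- sort(unique(stats::na.omit(states)))
  if (length(obs) <= 1L) return(0L)
  n <- length(phy$tip.label)
  nodes <- n + seq_len(phy$Nnode)
  miss_tips <- which(is.na(states[phy$tip.label]))
  vars <- c(nodes, miss_tips)
  k <- length(obs)
  best <- Inf
  idx <- rep(1L, length(vars))
  repeat {
    assign_ <- integer(n + phy$Nnode)
    assign_[match(phy$tip.label, phy$tip.label)] <- match(states[phy$tip.label], obs)
    assign_[vars] <- idx
    changes <- sum(assign_[phy$edge[, 1L]] != assign_[phy$edge[, 2L]])
    if (changes < best) best <- changes
    pos <- 1L
    while (pos <= length(vars)) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= k) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > length(vars)) break
  }
  best
}

bf_fitch_length <- function(phy, X) {
  # X: character matrix rows = taxa; '?' and '-' missing
  total <- 0L
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    col[col %in% c("-", "?", "X")] <- NA
    total <- total + bf_column_changes(phy, stats::setNames(col, rownames(X)))
  }
  total
}

# --- likelihood ----------------------------------------------------------

# Equal-rates k-state transition probability, written out independently.
bf_ptrans <- function(k, t, same) {
  a <- exp(-k * t / (k - 1))
  if (same) 1 / k + (1 - 1 / k) * a else (1 - a) / k
}

# Brute-force likelihood of one column by summing over all internal-node
# state assignments of a rooted version of the tree.
bf_column_lik <- function(phy, states, alphabet) {
  if (length(phy$tip.label) > 2L && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  k <- length(alphabet)
  n <- length(phy$tip.label)
  nnode <- phy$Nnode
  tipstate <- match(states[phy$tip.label], alphabet)
  total <- 0
  idx <- rep(1L, nnode)
  repeat {
    state_of <- function(node) {
      if (node <= n) tipstate[node] else idx[node - n]
    }
    p <- 1 / k  # uniform root frequency at node n+1
    for (e in seq_len(nrow(phy$edge))) {
      a <- state_of(phy$edge[e, 1L])
      b <- state_of(phy$edge[e, 2L])
      t_ <- phy$edge.length[e]
      if (is.na(b)) {  # missing tip: marginalise = sum over states = 1
        next
      }
      if (is.na(a)) stop("internal state NA")
      p <- p * bf_ptrans(k, t_, a == b)
    }
    total <- total + p
    pos <- 1L
    while (pos <= nnode) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= k) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > nnode) break
  }
  total
}

# --- study feature extraction (shared by pipeline-level tests) -----------

# Run the feature chain on a synthetic_truth: infer gene models, annotate
# introns, cluster, detect cysteines, and code the six-character study scheme
# (cysteine pairs + introns 1-4; intron 5 lies outside the analysed region).
study_mm_partition <- function(truth, cys_min_fraction = 0.85) {
  anns <- lapply(names(truth$genomic), function(tx) {
    gm <- infer_gene_model(truth$genomic[[tx]], truth$cds[[tx]], gene_id = tx)
    annotate_introns(gm, truth$genomic[[tx]])
  })
  names(anns) <- names(truth$genomic)
  ich <- cluster_homologous_introns(truth$alignment, anns)
  cys <- detect_conserved_cysteines(truth$alignment, cys_min_fraction)
  n_intron_chars <- min(length(ich), 4L)
  code_characters(ich[seq_len(n_intron_chars)], cys$pairs,
                  names(truth$alignment))
}
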