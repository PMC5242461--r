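# Study orchestration: build the three matrices, run the analysis grid
# (MP, MP-bootstrap and Bayesian cells on protein / MM / combined matrices),
# and report clade relationships against a configured outgroup.

#' The default eight-cell analysis grid
#'
#' Maximum parsimony and parsimony bootstrap on each of the protein, MM and
#' combined matrices, plus Bayesian analyses of the protein and combined
#' matrices: eight trees in total.
#'
#' @return Data frame with columns `method` and `matrix`.
#' @export
default_grid <- function() {
  data.frame(
    method = c("MP", "MP", "MP",
               "MP-bootstrap", "MP-bootstrap", "MP-bootstrap",
               "Bayes", "Bayes"),
    matrix = c("protein", "MM", "combined",
               "protein", "MM", "combined",
               "protein", "combined"),
    stringsAsFactors = FALSE)
}

#' Build the protein / MM / combined matrices of a study
#'
#' @param aa_alignment Protein MSA (named character vector, `AAStringSet` or
#'   matrix).
#' @param mm_partition G/T/? matrix from [code_characters()].
#' @return Named list of three [character_matrix()] objects: `protein`, `MM`,
#'   `combined`.
#' @export
build_study_matrices <- function(aa_alignment, mm_partition) {
  aa <- .as_aln_matrix(aa_alignment)
  combined <- build_combined_matrix(aa, mm_partition)
  list(protein = character_matrix(combined$taxa, aa = combined$aa),
       MM = character_matrix(combined$taxa, mm = combined$mm),
       combined = combined)
}

# One grid cell -> one tree.
.run_cell <- function(method, cm, seed, bootstrap_replicates, mcmc, search,
                      boot_search) {
  if (method == "MP") {
    search$seed <- seed
    res <- search_mp(cm, search)
    if (length(res$trees) == 1L) res$trees[[1L]] else {
      majority_rule_consensus(res$trees, threshold = 1)
    }
  } else if (method == "MP-bootstrap") {
    bootstrap_mp(cm, replicates = bootstrap_replicates, config = boot_search,
                 seed = seed)$tree
  } else if (method == "Bayes") {
    mcmc$seed <- seed
    posterior_consensus(run_mcmc(cm, mcmc))
  } else {
    stop("unknown grid method: ", method)
  }
}

#' Run the full analysis grid
#'
#' Executes every cell of the grid on the named matrices, writes one Newick
#' tree per cell plus a JSON manifest (config fingerprint, per-cell seeds,
#' package version) sufficient to re-run bit-identically.  A failing cell is
#' recorded and the grid continues.
#'
#' @param matrices Named list from [build_study_matrices()] (or any list of
#'   [character_matrix()] objects covering the grid's `matrix` names).
#' @param grid Data frame of cells (default [default_grid()]).
#' @param out_dir Output directory for trees and the manifest.
#' @param seed Base seed; cell i uses `seed + i`.
#' @param bootstrap_replicates Replicates for bootstrap cells.
#' @param mcmc [mcmc_config()] for Bayesian cells.
#' @param search [search_config()] for MP cells.
#' @param boot_search [search_config()] applied within each bootstrap
#'   replicate; the default single random-addition start per replicate is the
#'   standard bootstrap practice.
#' @return Object of class `grid_report`: data frame `cells` (method, matrix,
#'   file, status, error), list `trees`, path `manifest`.
#' @export
run_grid <- function(matrices, grid = default_grid(), out_dir,
                     seed = 1L, bootstrap_replicates = 100L,
                     mcmc = mcmc_config(), search = search_config(),
                     boot_search = search_config(n_starts = 1L)) {
  if (anyDuplicated(paste(grid$method, grid$matrix))) {
    stop("grid cells must be unique")
  }
  missing_m <- setdiff(unique(grid$matrix), names(matrices))
  if (length(missing_m)) {
    stop("grid names matrices that were not supplied: ",
         paste(missing_m, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trees <- vector("list", nrow(grid))
  status <- character(nrow(grid))
  errors <- rep(NA_character_, nrow(grid))
  files <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    method <- grid$method[i]
    mname <- grid$matrix[i]
    files[i] <- file.path(out_dir, sprintf("tree_%02d_%s_%s.nwk", i,
                                           gsub("[^A-Za-z]", "", method), mname))
    res <- tryCatch({
      tree <- .run_cell(method, matrices[[mname]], seed + i,
                        bootstrap_replicates, mcmc, search, boot_search)
      ape::write.tree(tree, files[i])
      trees[[i]] <- tree
      "ok"
    }, error = function(e) {
      errors[i] <<- conditionMessage(e)
      "failed"
    })
    status[i] <- res
  }
  cfg_string <- jsonlite::toJSON(list(
    grid = grid, seed = seed, bootstrap_replicates = bootstrap_replicates,
    mcmc = mcmc[setdiff(names(mcmc), "proposal_weights")],
    proposal_weights = as.list(mcmc$proposal_weights),
    search = search, boot_search = boot_search), auto_unbox = TRUE,
    digits = NA)
  manifest <- list(
    package = "gsphylo",
    version = as.character(utils::packageVersion("gsphylo")),
    config_hash = .fnv1a(as.character(cfg_string)),
    seed = seed,
    cell_seeds = seed + seq_len(nrow(grid)),
    cells = grid, files = basename(files), status = status)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  structure(list(
    cells = data.frame(grid, file = files, status = status, error = errors,
                       stringsAsFactors = FALSE),
    trees = trees, manifest = manifest_path, n_failed = sum(status != "ok")),
    class = "grid_report")
}

#' @export
print.grid_report <- function(x, ...) {
  cat(sprintf("analysis grid: %d cells, %d failed\n",
              nrow(x$cells), x$n_failed))
  print(x$cells[, c("method", "matrix", "status")])
  invisible(x)
}

# Tip sets below every node of a rooted tree, indexed by node number.
.tips_below_all <- function(phy) {
  n <- length(phy$tip.label)
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]; child <- po$edge[i, 2L]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

# Node ancestors (rooted phylo): parent lookup.
.parents <- function(phy) {
  p <- integer(length(phy$tip.label) + phy$Nnode)
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

#' Clade-relationship verdicts on one tree
#'
#' Roots the tree at the configured outgroup, then reports for each named
#' group whether it is monophyletic, the taxon set of its sister clade (the
#' sibling of its MRCA), and for each ordered pair (A, B) whether A is
#' embedded in B: MRCA(A) is a strict descendant of MRCA(B).
#'
#' @param tree A `phylo` containing all group taxa and the outgroup.
#' @param groups Named list of disjoint taxon-label vectors.
#' @param outgroup Tip label used to root the tree.
#' @param embedded_pairs Optional 2-column matrix/data frame of group-name
#'   pairs to test; default all ordered pairs.
#' @return List with `monophyletic` (named logical), `sister` (named list of
#'   taxon vectors), `embedded` (named logical, names `"A_in_B"`).
#' @export
test_clade_relationships <- function(tree, groups, outgroup,
                                     embedded_pairs = NULL) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not in tree")
  gnames <- names(groups)
  if (is.null(gnames) || any(!nzchar(gnames))) stop("groups must be named")
  for (a in seq_along(groups)) {
    missing_t <- setdiff(groups[[a]], tree$tip.label)
    if (length(missing_t)) {
      stop("group '", gnames[a], "' has taxa absent from the tree: ",
           paste(missing_t, collapse = ", "))
    }
    for (b in seq_len(a - 1L)) {
      if (length(intersect(groups[[a]], groups[[b]]))) {
        stop("groups must be disjoint")
      }
    }
  }
  rooted <- ape::root(ape::unroot(tree), outgroup = outgroup,
                      resolve.root = TRUE)
  sets <- .tips_below_all(rooted)
  parents <- .parents(rooted)
  n <- length(rooted$tip.label)
  mrca_of <- function(taxa) {
    if (length(taxa) == 1L) return(match(taxa, rooted$tip.label))
    ape::getMRCA(rooted, taxa)
  }
  is_ancestor <- function(anc, node) {   # strict ancestry
    while (parents[node] != 0L) {
      node <- parents[node]
      if (node == anc) return(TRUE)
    }
    FALSE
  }
  mono <- logical(length(groups))
  sister <- vector("list", length(groups))
  names(mono) <- names(sister) <- gnames
  for (gi in seq_along(groups)) {
    nd <- mrca_of(groups[[gi]])
    mono[gi] <- setequal(sets[[nd]], groups[[gi]])
    par <- parents[nd]
    if (par == 0L) {
      sister[[gi]] <- character(0)
    } else {
      sibs <- rooted$edge[rooted$edge[, 1L] == par, 2L]
      sibs <- sibs[sibs != nd]
      sister[[gi]] <- sort(unique(unlist(sets[sibs])))
    }
  }
  if (is.null(embedded_pairs)) {
    embedded_pairs <- expand.grid(A = gnames, B = gnames,
                                  stringsAsFactors = FALSE)
    embedded_pairs <- embedded_pairs[embedded_pairs$A != embedded_pairs$B, ,
                                     drop = FALSE]
  }
  emb <- logical(nrow(embedded_pairs))
  if (nrow(embedded_pairs)) {
    names(emb) <- paste0(embedded_pairs[[1L]], "_in_", embedded_pairs[[2L]])
  }
  for (i in seq_len(nrow(embedded_pairs))) {
    na_ <- mrca_of(groups[[embedded_pairs[[1L]][i]]])
    nb_ <- mrca_of(groups[[embedded_pairs[[2L]][i]]])
    emb[i] <- is_ancestor(nb_, na_)
  }
  list(monophyletic = mono, sister = sister, embedded = emb)
}

#' Tally clade-relationship verdicts across trees
#'
#' @param trees List of `phylo` objects (e.g. `grid_report$trees`).
#' @param groups,outgroup,embedded_pairs As in [test_clade_relationships()].
#' @return Data frame with one row per verdict and columns `verdict`,
#'   `n_true`, `n_trees`.
#' @export
tally_relationships <- function(trees, groups, outgroup,
                                embedded_pairs = NULL) {
  trees <- Filter(Negate(is.null), trees)
  verdicts <- lapply(trees, test_clade_relationships, groups = groups,
                     outgroup = outgroup, embedded_pairs = embedded_pairs)
  keys <- c(paste0("monophyletic:", names(groups)),
            paste0("embedded:", names(verdicts[[1L]]$embedded)))
  vals <- vapply(verdicts, function(v) {
    c(v$monophyletic, v$embedded)
  }, numeric(length(keys)))
  vals <- matrix(vals, nrow = length(keys))
  data.frame(verdict = keys, n_true = rowSums(vals),
             n_trees = length(trees), stringsAsFactors = FALSE)
}
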