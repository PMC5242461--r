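# Simulation of gene families with known truth.
#
# A family is evolved along a known tree from a root protein carrying the
# structural features the downstream analyses look for: conserved intron
# positions with fixed phases, cysteine pairs, short invariant motifs and a
# furin cleavage site.  Implanted feature sites are frozen (never substituted)
# so that "conserved in all sequences" holds exactly unless a configured loss
# event removes the feature in a clade.  Clade losses are instantaneous on the
# clade stem and never regained (Dollo-like).

# Default study tree: a UPK-like clade sister to a PTPRQ-like gene, embedded
# within a larger PTPR-like radiation, with a distant outgroup.
.STUDY_NEWICK <- paste0(
  "((((upk3a:0.15,upk3b:0.15):0.1,(upk2a:0.2,upk2b:0.2):0.05):0.1,",
  "ptprq:0.3):0.1,((ptprb:0.25,ptprj:0.25):0.1,(ptpro:0.3,ptprh:0.3):0.05)",
  ":0.1,outgroup:0.8);"
)

#' Configuration for a synthetic gene family
#'
#' The defaults encode the study conditions exercised throughout the package:
#' a 10-taxon family on a fixed tree in which a four-gene UPK-like clade sits
#' inside a PTPR-like radiation, 200-residue proteins, five conserved introns
#' with phases (1, 1, 2, 1, 2), two conserved cysteine pairs, an invariant
#' `NGPL` motif directly after the fourth cysteine (forming the
#' C3-x(n)-C4-NGPL signature), a furin site after the second cysteine, and two
#' clade losses: the UPK2-like pair loses intron 5 (the cytoplasmic-tail exon
#' junction) and one UPK2a-like gene loses the C3-C4 cysteine pair.
#'
#' @param taxon_count Number of tips (used when `tree_shape` is
#'   `"random_birth_death"`; must be at least 3).
#' @param tree_shape `"fixed_newick"` (use `newick`) or
#'   `"random_birth_death"`.
#' @param newick Newick string with branch lengths for the fixed tree.
#' @param birth_rate,death_rate Birth-death rates per unit time for random
#'   trees.
#' @param tree_height Random trees are rescaled to this root-to-tip height.
#' @param min_branch Floor applied to random-tree branch lengths after
#'   rescaling (fraction of `tree_height`); guarantees every internal edge
#'   carries resolvable signal, as in a radiation with substantial stems.
#' @param protein_length Number of residues in every protein.
#' @param substitution_rate Expected substitutions per site per unit branch
#'   length.
#' @param intron_spec Data frame with columns `cds_offset` (nucleotides of CDS
#'   5' of the intron, strictly increasing, in `[1, 3L-1]`) and `phase`
#'   (`cds_offset %% 3`).
#' @param cysteine_pairs List of length-2 integer vectors: residue positions
#'   of each disulfide-forming pair, N-terminal pair first.
#' @param motif_spec List of `list(pattern =, anchor =)` entries; `pattern`
#'   is a literal residue string implanted at 1-based position `anchor`.
#' @param furin_spec `list(position =, pattern = "R-x-[RK]-R")` or `NULL`; a
#'   concrete instance of the cleavage motif is implanted at `position`.
#' @param loss_events List of `list(clade =, feature =)`; `clade` is either a
#'   character vector of tip labels (the loss applies to the MRCA clade of
#'   those tips) or `list(size = c(min, max))` to pick a clade of that size at
#'   random; `feature` is one of `"intronK"`, `"cys_pairK"`, `"motifK"`,
#'   `"furin"`.  `NULL` selects defaults appropriate to the tree shape.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(taxon_count = 10L,
                              tree_shape = c("fixed_newick", "random_birth_death"),
                              newick = .STUDY_NEWICK,
                              birth_rate = 1,
                              death_rate = 0.5,
                              tree_height = 1,
                              min_branch = 0.15,
                              protein_length = 200L,
                              substitution_rate = 2,
                              intron_spec = data.frame(
                                cds_offset = c(52L, 145L, 260L, 361L, 476L),
                                phase = c(1L, 1L, 2L, 1L, 2L)),
                              cysteine_pairs = list(c(30L, 45L), c(110L, 150L)),
                              motif_spec = list(list(pattern = "NGPL", anchor = 151L)),
                              furin_spec = list(position = 50L, pattern = "R-x-[RK]-R"),
                              loss_events = NULL,
                              seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  if (is.null(loss_events)) {
    loss_events <- if (tree_shape == "fixed_newick" && identical(newick, .STUDY_NEWICK)) {
      list(list(clade = c("upk2a", "upk2b"), feature = "intron5"),
           list(clade = "upk2a", feature = "cys_pair2"))
    } else {
      list(list(clade = list(size = c(2L, 3L)), feature = "intron5"),
           list(clade = list(size = c(1L, 1L)), feature = "cys_pair2"))
    }
  }
  cfg <- structure(list(
    taxon_count = as.integer(taxon_count), tree_shape = tree_shape,
    newick = newick, birth_rate = birth_rate, death_rate = death_rate,
    tree_height = tree_height, min_branch = min_branch,
    protein_length = as.integer(protein_length),
    substitution_rate = substitution_rate, intron_spec = intron_spec,
    cysteine_pairs = cysteine_pairs, motif_spec = motif_spec,
    furin_spec = furin_spec, loss_events = loss_events,
    seed = as.integer(seed)), class = "sim_config")
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  L <- cfg$protein_length
  if (cfg$taxon_count < 3L) stop("taxon_count must be >= 3")
  if (cfg$birth_rate < 0 || cfg$death_rate < 0 || cfg$substitution_rate < 0) {
    stop("rates must be >= 0")
  }
  off <- cfg$intron_spec$cds_offset
  if (length(off)) {
    if (any(diff(off) <= 0)) stop("intron offsets must be strictly increasing")
    if (any(off < 1L | off >= 3L * L)) {
      stop("intron offsets must lie in [1, 3*protein_length - 1]")
    }
    if (any(cfg$intron_spec$phase != off %% 3L)) {
      stop("intron phase must equal cds_offset %% 3")
    }
  }
  cys <- unlist(cfg$cysteine_pairs)
  if (length(cys)) {
    if (any(cys < 1L | cys > L)) stop("cysteine positions outside the protein")
    if (anyDuplicated(cys)) stop("cysteine pair positions must be distinct")
    for (p in cfg$cysteine_pairs) {
      if (length(p) != 2L || p[1L] >= p[2L]) {
        stop("each cysteine pair must be two increasing positions")
      }
    }
  }
  .implant_map(cfg)  # errors on residue collisions
  invisible(cfg)
}

# Position -> set of allowed residues implied by the implanted features.
# Errors (naming the collision) if two features demand conflicting residues.
.implant_map <- function(cfg) {
  req <- list()
  claim <- function(pos, allowed, feature) {
    if (pos < 1L || pos > cfg$protein_length) {
      stop(sprintf("feature %s extends outside the protein (position %d)",
                   feature, pos))
    }
    key <- as.character(pos)
    prev <- req[[key]]
    if (is.null(prev)) {
      req[[key]] <<- list(allowed = allowed, feature = feature)
    } else {
      inter <- intersect(prev$allowed, allowed)
      if (!length(inter)) {
        stop(sprintf(
          "infeasible configuration: %s and %s require different residues at position %d",
          prev$feature, feature, pos))
      }
      req[[key]] <<- list(allowed = inter,
                          feature = paste(prev$feature, feature, sep = "+"))
    }
  }
  for (i in seq_along(cfg$cysteine_pairs)) {
    p <- cfg$cysteine_pairs[[i]]
    claim(p[1L], "C", sprintf("cys_pair%d", i))
    claim(p[2L], "C", sprintf("cys_pair%d", i))
  }
  for (i in seq_along(cfg$motif_spec)) {
    ms <- cfg$motif_spec[[i]]
    letters_ <- strsplit(ms$pattern, "", fixed = TRUE)[[1L]]
    if (!all(letters_ %in% .AA20)) {
      stop("motif_spec patterns must be literal residue strings")
    }
    for (k in seq_along(letters_)) {
      claim(ms$anchor + k - 1L, letters_[k], sprintf("motif%d", i))
    }
  }
  if (!is.null(cfg$furin_spec)) {
    p0 <- cfg$furin_spec$position
    claim(p0, "R", "furin")
    # the wildcard position excludes C so a frozen cysteine column cannot
    # arise outside the configured pairs
    claim(p0 + 1L, setdiff(.AA20, "C"), "furin")
    claim(p0 + 2L, c("R", "K"), "furin")
    claim(p0 + 3L, "R", "furin")
  }
  req
}

#' Evolve a protein sequence along one branch
#'
#' Under the default equal-rates model each free (non-frozen) site is,
#' independently, redrawn uniformly from the 20 residues with probability
#' `1 - exp(-branch_length)`.  Frozen sites never change.
#'
#' @param protein Protein sequence (single string).
#' @param branch_length Expected substitutions per site (>= 0).
#' @param model Substitution model id; only `"equal"` is defined.
#' @param frozen Integer vector of 1-based residue positions immune to change.
#' @return The child protein sequence.
#' @export
evolve_protein <- function(protein, branch_length, model = "equal",
                           frozen = integer(0)) {
  if (!identical(model, "equal")) stop("unknown substitution model id: ", model)
  if (branch_length < 0) stop("branch_length must be >= 0")
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  free <- setdiff(seq_along(aa), frozen)
  p <- 1 - exp(-branch_length)
  hit <- free[stats::runif(length(free)) < p]
  if (length(hit)) aa[hit] <- sample(.AA20, length(hit), replace = TRUE)
  paste(aa, collapse = "")
}

# Synonymous codon table (stops excluded), uniform usage.
.syn_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

#' Reverse-translate a protein and insert introns
#'
#' Codons are drawn uniformly from the synonymous set.  Each intron begins
#' with the canonical `GT` donor and ends with the `AG` acceptor; intron
#' bodies are drawn from `{A, C, T}` so that donor/acceptor dinucleotides
#' occur only at the true splice sites, which makes the exon chaining of
#' [infer_gene_model()] unambiguous.
#'
#' @param protein Protein sequence (no stop codon).
#' @param intron_spec Data frame with `cds_offset` (and optionally `phase`)
#'   columns, as in [simulation_config()]; `NULL` for an intronless gene.
#' @param gene_id Identifier stored in the gene model.
#' @param intron_length_range Intron lengths are drawn uniformly from this
#'   range (minimum 8 nt).
#' @return `list(genomic =, cds =, model =)` where `model` is a [gene_model()].
#' @export
build_gene <- function(protein, intron_spec = NULL, gene_id = "gene",
                       intron_length_range = c(60L, 120L)) {
  syn <- .syn_codons()
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  if (!all(aa %in% .AA20)) stop("protein contains non-standard residues")
  codons <- vapply(aa, function(a) {
    cs <- syn[[a]]
    cs[sample.int(length(cs), 1L)]
  }, "")
  cds <- paste(codons, collapse = "")
  n <- nchar(cds)
  offsets <- if (is.null(intron_spec)) integer(0) else as.integer(intron_spec$cds_offset)
  if (length(offsets)) {
    if (any(diff(offsets) <= 0)) stop("intron offsets must be strictly increasing")
    if (any(offsets < 1L | offsets > n - 1L)) {
      stop("intron offset not in [1, 3L - 1]")
    }
  }
  bounds <- c(0L, offsets, n)
  exon_seqs <- substring(cds, head(bounds, -1L) + 1L, bounds[-1L])
  if (length(intron_length_range) == 1L) {
    intron_length_range <- rep(intron_length_range, 2L)
  }
  if (intron_length_range[1L] < 8L) stop("introns must be at least 8 nt")
  genomic_parts <- character(0)
  exons <- matrix(0L, nrow = length(exon_seqs), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  gpos <- 0L
  for (i in seq_along(exon_seqs)) {
    exons[i, ] <- c(gpos, gpos + nchar(exon_seqs[i]))
    genomic_parts <- c(genomic_parts, exon_seqs[i])
    gpos <- gpos + nchar(exon_seqs[i])
    if (i < length(exon_seqs)) {
      len <- sample(seq(intron_length_range[1L], intron_length_range[2L]), 1L)
      body <- paste(sample(c("A", "C", "T"), len - 4L, replace = TRUE),
                    collapse = "")
      intron <- paste0("GT", body, "AG")
      genomic_parts <- c(genomic_parts, intron)
      gpos <- gpos + len
    }
  }
  list(genomic = paste(genomic_parts, collapse = ""), cds = cds,
       model = gene_model(gene_id, exons))
}

# Resolve a loss-event clade selector to a tip-label set on a rooted tree.
.resolve_clade <- function(tree, clade) {
  if (is.character(clade)) {
    if (!all(clade %in% tree$tip.label)) {
      stop("loss event names tips absent from the tree: ",
           paste(setdiff(clade, tree$tip.label), collapse = ", "))
    }
    if (length(clade) == 1L) return(clade)
    mrca <- ape::getMRCA(tree, clade)
    return(ape::extract.clade(tree, mrca)$tip.label)
  }
  if (is.list(clade) && !is.null(clade$size)) {
    n <- length(tree$tip.label)
    rng <- clade$size
    # candidate clades: single tips and every non-root internal node
    nodes <- c(seq_len(n), (n + 2L):(n + tree$Nnode))
    sizes <- vapply(nodes, function(nd) {
      if (nd <= n) 1L else length(ape::extract.clade(tree, nd)$tip.label)
    }, 0L)
    cand <- nodes[sizes >= rng[1L] & sizes <= rng[2L]]
    if (!length(cand)) {
      # fall back to the smallest non-root clade available
      cand <- nodes[which.min(sizes)]
    }
    nd <- cand[sample.int(length(cand), 1L)]
    return(if (nd <= n) tree$tip.label[nd]
           else ape::extract.clade(tree, nd)$tip.label)
  }
  stop("clade selector must be a tip-label vector or list(size = c(min, max))")
}

#' Simulate a gene family with known truth
#'
#' Evolves a protein family along the configured tree, freezes the implanted
#' feature sites, applies clade loss events, reverse-translates every leaf
#' protein into a genomic sequence with canonical splice sites, and returns
#' the complete ground truth.  With `out_dir` set, a plain-text file bundle is
#' written: `genomic.fa`, `cds.fa`, `protein.fa`, `aligned.fa`,
#' `true_tree.nwk`, `features.tsv` and `config.json`.
#'
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory for the file bundle.
#' @return An object of class `synthetic_truth`: fields `tree` (phylo with
#'   branch lengths, the true tree), `proteins`, `cds`, `genomic` (named
#'   character vectors), `alignment` (identical to `proteins`; the simulator
#'   introduces no indels, so the true alignment is the sequences themselves),
#'   `gene_models` (list of [gene_model()]), `feature_table` (long data frame
#'   `gene_id`, `feature_id`, `present`), `loss_clades`, `frozen_sites` and
#'   `config`.
#' @export
simulate_family <- function(config = simulation_config(), out_dir = NULL) {
  .validate_sim_config(config)
  .with_seed(config$seed, {
    # --- tree ---
    tree <- if (config$tree_shape == "fixed_newick") {
      phy <- ape::read.tree(text = config$newick)
      if (is.null(phy$edge.length)) stop("fixed tree must have branch lengths")
      phy
    } else {
      phy <- ape::rphylo(config$taxon_count, config$birth_rate,
                         config$death_rate)
      phy$tip.label <- sprintf("t%d", seq_len(config$taxon_count))
      depth <- max(ape::node.depth.edgelength(phy))
      phy$edge.length <- phy$edge.length / depth * config$tree_height
      floor_ <- config$min_branch * config$tree_height
      phy$edge.length[phy$edge.length < floor_] <- floor_
      phy
    }
    rooted <- if (ape::is.rooted(tree)) tree else {
      # root arbitrarily for clade bookkeeping; truth topology is unchanged
      ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
    }
    tips <- tree$tip.label

    # --- feature bookkeeping ---
    n_intron <- nrow(config$intron_spec)
    feature_ids <- c(
      if (length(config$cysteine_pairs)) sprintf("cys_pair%d", seq_along(config$cysteine_pairs)),
      if (n_intron) sprintf("intron%d", seq_len(n_intron)),
      if (length(config$motif_spec)) sprintf("motif%d", seq_along(config$motif_spec)),
      if (!is.null(config$furin_spec)) "furin")
    loss_clades <- list()
    lost <- matrix(FALSE, nrow = length(tips), ncol = length(feature_ids),
                   dimnames = list(tips, feature_ids))
    for (ev in config$loss_events) {
      if (!ev$feature %in% feature_ids) {
        stop("loss event refers to unknown feature: ", ev$feature)
      }
      members <- .resolve_clade(rooted, ev$clade)
      loss_clades[[ev$feature]] <- union(loss_clades[[ev$feature]], members)
      lost[members, ev$feature] <- TRUE
    }

    # --- root protein with implanted, frozen features ---
    # the background excludes cysteine so the configured pairs are the only
    # conserved-cysteine signal (controlled truth); drift can still introduce
    # transient cysteines at free sites
    req <- .implant_map(config)
    aa <- sample(setdiff(.AA20, "C"), config$protein_length, replace = TRUE)
    frozen <- integer(0)
    for (key in names(req)) {
      pos <- as.integer(key)
      allowed <- req[[key]]$allowed
      aa[pos] <- if (length(allowed) == 1L) allowed else {
        allowed[sample.int(length(allowed), 1L)]
      }
      frozen <- c(frozen, pos)
    }
    root_protein <- paste(aa, collapse = "")

    # --- evolve along the tree (preorder) ---
    n <- length(tips)
    seqs <- vector("character", n + tree$Nnode)
    seqs[n + 1L] <- root_protein
    # cladewise edge order visits parents before children
    cw <- ape::reorder.phylo(tree, "cladewise")
    for (i in seq_len(nrow(cw$edge))) {
      par <- cw$edge[i, 1L]; child <- cw$edge[i, 2L]
      bl <- cw$edge.length[i] * config$substitution_rate
      seqs[child] <- evolve_protein(seqs[par], bl, frozen = frozen)
    }
    proteins <- seqs[seq_len(n)]
    names(proteins) <- tips

    # --- apply sequence-level losses (cysteine pairs, motifs, furin) ---
    prot_mat <- do.call(rbind, strsplit(proteins, "", fixed = TRUE))
    rownames(prot_mat) <- tips
    for (i in seq_along(config$cysteine_pairs)) {
      fid <- sprintf("cys_pair%d", i)
      who <- tips[lost[, fid]]
      if (length(who)) {
        repl <- sample(setdiff(.AA20, "C"), 2L, replace = TRUE)
        prot_mat[who, config$cysteine_pairs[[i]][1L]] <- repl[1L]
        prot_mat[who, config$cysteine_pairs[[i]][2L]] <- repl[2L]
      }
    }
    for (i in seq_along(config$motif_spec)) {
      fid <- sprintf("motif%d", i)
      who <- tips[lost[, fid]]
      if (length(who)) {
        ms <- config$motif_spec[[i]]
        w <- nchar(ms$pattern)
        old <- strsplit(ms$pattern, "", fixed = TRUE)[[1L]]
        repl <- vapply(old, function(ch) sample(setdiff(.AA20, ch), 1L), "")
        prot_mat[who, ms$anchor:(ms$anchor + w - 1L)] <-
          matrix(repl, nrow = length(who), ncol = w, byrow = TRUE)
      }
    }
    if (!is.null(config$furin_spec) && any(lost[, "furin"])) {
      who <- tips[lost[, "furin"]]
      p0 <- config$furin_spec$position
      prot_mat[who, p0 + 3L] <- sample(setdiff(.AA20, c("R", "K")), 1L)
    }
    proteins <- apply(prot_mat, 1L, paste, collapse = "")

    # --- genes: reverse-translate, insert non-lost introns ---
    gene_models <- list()
    genomic <- character(0)
    cds <- character(0)
    for (tp in tips) {
      keep <- rep(TRUE, n_intron)
      if (n_intron) {
        for (k in seq_len(n_intron)) {
          fid <- sprintf("intron%d", k)
          if (fid %in% feature_ids && lost[tp, fid]) keep[k] <- FALSE
        }
      }
      spec_t <- if (n_intron) config$intron_spec[keep, , drop = FALSE] else NULL
      g <- build_gene(proteins[[tp]], spec_t, gene_id = tp)
      gene_models[[tp]] <- g$model
      genomic[tp] <- g$genomic
      cds[tp] <- g$cds
    }

    feature_table <- data.frame(
      gene_id = rep(tips, each = length(feature_ids)),
      feature_id = rep(feature_ids, times = length(tips)),
      stringsAsFactors = FALSE)
    feature_table$present <- as.integer(!lost[cbind(
      match(feature_table$gene_id, tips),
      match(feature_table$feature_id, feature_ids))])

    truth <- structure(list(
      tree = tree, proteins = proteins, alignment = proteins,
      cds = cds, genomic = genomic, gene_models = gene_models,
      feature_table = feature_table, loss_clades = loss_clades,
      frozen_sites = sort(frozen), config = config),
      class = "synthetic_truth")

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      .write_fasta(as.list(genomic), file.path(out_dir, "genomic.fa"))
      .write_fasta(as.list(cds), file.path(out_dir, "cds.fa"))
      .write_fasta(as.list(proteins), file.path(out_dir, "protein.fa"))
      .write_fasta(as.list(truth$alignment), file.path(out_dir, "aligned.fa"))
      ape::write.tree(tree, file.path(out_dir, "true_tree.nwk"))
      utils::write.table(feature_table, file.path(out_dir, "features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cfg_out <- config
      cfg_out$intron_spec <- as.list(config$intron_spec)
      jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    truth
  })
}
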