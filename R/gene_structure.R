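# Exon/intron reconstruction and intron-phase annotation.
#
# Coordinates: genomic intervals are 0-based half-open on the plus strand
# (minus-strand genes are reverse-complemented on ingest); protein residues
# and CDS offsets are 1-based.  Intron phase is the CDS offset modulo 3:
# phase 0 falls between codons, phase 1 after the first nucleotide of a codon
# and phase 2 after the second.

#' Gene model: ordered exon blocks on a genomic sequence
#'
#' @param gene_id Identifier.
#' @param exons Two-column matrix (`start`, `end`) of 0-based half-open
#'   genomic intervals, strictly increasing and non-overlapping.
#' @param strand `"+"` after canonicalization.
#' @return Object of class `gene_model` with fields `gene_id`, `exons`,
#'   `cds_offsets` (cumulative CDS nucleotides at each exon start) and
#'   `cds_length`.
#' @export
gene_model <- function(gene_id, exons, strand = "+") {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1L) {
    if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
      stop("exons must be non-overlapping and strictly increasing")
    }
  }
  lens <- exons[, 2L] - exons[, 1L]
  total <- sum(lens)
  if (total %% 3L != 0L) stop("sum of exon lengths must be divisible by 3")
  structure(list(gene_id = gene_id, exons = exons,
                 cds_offsets = c(0L, cumsum(lens))[seq_len(nrow(exons))],
                 cds_length = total, strand = strand),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s': %d exon(s), CDS %d nt\n",
              x$gene_id, nrow(x$exons), x$cds_length))
  invisible(x)
}

# Longest common prefix of gv[gpos..] and cv[cpos..] (character vectors).
.lcp <- function(gv, cv, gpos, cpos) {
  nmax <- min(length(gv) - gpos + 1L, length(cv) - cpos + 1L)
  if (nmax <= 0L) return(0L)
  eq <- gv[gpos:(gpos + nmax - 1L)] == cv[cpos:(cpos + nmax - 1L)]
  mism <- which(!eq)
  if (!length(mism)) nmax else mism[1L] - 1L
}

#' Reconstruct the exon/intron structure of a gene
#'
#' Chains the CDS against the genomic sequence as an exact ordered
#' concatenation of genomic substrings, preferring the maximal-exon-length
#' chaining: exons are extended greedily from the CDS 5' end and shortened
#' (with backtracking) only when no downstream chaining completes.  Candidate
#' splice boundaries must carry the canonical `GT` donor and `AG` acceptor
#' (optionally also a `GC` donor) and introns must be at least
#' `min_intron_length` nucleotides.
#'
#' @param genomic Genomic DNA sequence (single string).
#' @param cds CDS sequence; length must be divisible by 3 and the CDS must be
#'   an exact concatenation of genomic substrings (clean real data or
#'   simulator output).
#' @param gene_id Identifier for the returned model.
#' @param strand `"+"` or `"-"`; minus-strand genomic input is
#'   reverse-complemented before chaining.
#' @param min_intron_length Minimum intron length in nucleotides.
#' @param allow_gc_donor Also accept `GC` donors (non-default).
#' @return A [gene_model()].
#' @export
infer_gene_model <- function(genomic, cds, gene_id = "gene", strand = "+",
                             min_intron_length = 8L, allow_gc_donor = FALSE) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (identical(strand, "-")) {
    genomic <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genomic)))
  }
  gv <- strsplit(toupper(genomic), "", fixed = TRUE)[[1L]]
  cv <- strsplit(toupper(cds), "", fixed = TRUE)[[1L]]
  nc <- length(cv)
  donors <- if (allow_gc_donor) c("GT", "GC") else "GT"
  deepest <- 0L  # rightmost CDS offset ever matched, for error reporting

  chain <- function(gpos, cpos, exons) {
    L <- .lcp(gv, cv, gpos, cpos)
    if (cpos + L - 1L > deepest) deepest <<- cpos + L - 1L
    if (cpos + L - 1L == nc) {
      # final exon consumes the CDS; maximal-length preference keeps all of L
      return(rbind(exons, c(gpos - 1L, gpos - 1L + L)))
    }
    if (L == 0L) return(NULL)
    for (l in L:1L) {
      e <- gpos + l  # 1-based genomic position just after the exon
      if (e + 1L > length(gv)) next
      if (!paste0(gv[e], gv[e + 1L]) %in% donors) next
      nxt <- cpos + l  # next CDS position to match
      # acceptor AG must end at p - 1; exon resumes at p
      p_min <- e + min_intron_length
      if (p_min > length(gv)) next
      for (p in p_min:length(gv)) {
        if (gv[p - 2L] != "A" || gv[p - 1L] != "G") next
        if (gv[p] != cv[nxt]) next
        res <- chain(p, nxt, rbind(exons, c(gpos - 1L, gpos - 1L + l)))
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }

  exons <- chain(1L, 1L, matrix(integer(0), ncol = 2L))
  if (is.null(exons)) {
    cond <- structure(
      list(message = sprintf(
        "no valid exon chaining: CDS unmatchable from offset %d", deepest + 1L),
        call = sys.call(-1L), cds_offset = deepest + 1L),
      class = c("gsphylo_chain_error", "error", "condition"))
    stop(cond)
  }
  gene_model(gene_id, exons)
}

#' Annotate the introns of a gene model
#'
#' Produces one annotation per internal exon boundary, ordered from the N to
#' the C terminus.  `phase` is `cds_offset %% 3`; `residue_index` is the
#' 1-based protein position containing the junction (for phases 1 and 2) or
#' immediately preceding it (phase 0).  The `canonical` flag is true iff the
#' donor is `GT` (optionally `GC`) and the acceptor is `AG`.
#'
#' @param model A [gene_model()].
#' @param genomic The genomic sequence the model refers to (plus strand).
#' @param allow_gc_donor Count `GC` donors as canonical.
#' @return Data frame with columns `intron_index`, `cds_offset`,
#'   `residue_index`, `phase`, `donor`, `acceptor`, `canonical`; zero rows for
#'   single-exon genes.
#' @export
annotate_introns <- function(model, genomic, allow_gc_donor = FALSE) {
  k <- nrow(model$exons)
  if (k < 2L) {
    return(data.frame(intron_index = integer(0), cds_offset = integer(0),
                      residue_index = integer(0), phase = integer(0),
                      donor = character(0), acceptor = character(0),
                      canonical = logical(0)))
  }
  lens <- model$exons[, 2L] - model$exons[, 1L]
  cds_offset <- cumsum(lens)[-k]
  phase <- cds_offset %% 3L
  residue_index <- ifelse(phase == 0L, cds_offset %/% 3L,
                          cds_offset %/% 3L + 1L)
  donor <- substring(genomic, model$exons[-k, 2L] + 1L, model$exons[-k, 2L] + 2L)
  acceptor <- substring(genomic, model$exons[-1L, 1L] - 1L, model$exons[-1L, 1L])
  donors_ok <- if (allow_gc_donor) donor %in% c("GT", "GC") else donor == "GT"
  data.frame(intron_index = seq_len(k - 1L), cds_offset = cds_offset,
             residue_index = as.integer(residue_index), phase = phase,
             donor = donor, acceptor = acceptor,
             canonical = donors_ok & acceptor == "AG")
}

#' Group introns across sequences into homologous-intron characters
#'
#' Projects each sequence's intron residue positions onto alignment columns
#' and groups introns that share the same phase and (within
#' `column_tolerance`) the same projected column.  Every group, including
#' singletons, becomes one binary presence/absence character; characters are
#' numbered left to right along the alignment (`intron1`, `intron2`, ...).
#'
#' @param alignment Protein MSA (named character vector, `AAStringSet` or
#'   character matrix); rows must include every annotated sequence.
#' @param annotations Named list (by taxon) of [annotate_introns()] frames.
#' @param column_tolerance Maximum column difference for two introns to be
#'   merged (default 0: strictly conserved positions).
#' @return List of `intron_character` objects: `character_id`,
#'   `alignment_column`, `phase`, `member_map` (named logical over all
#'   alignment taxa).
#' @export
cluster_homologous_introns <- function(alignment, annotations,
                                       column_tolerance = 0L) {
  m <- .as_aln_matrix(alignment)
  taxa <- rownames(m)
  if (!all(names(annotations) %in% taxa)) {
    stop("annotated sequences missing from the alignment: ",
         paste(setdiff(names(annotations), taxa), collapse = ", "))
  }
  entries <- NULL
  for (tx in names(annotations)) {
    ann <- annotations[[tx]]
    if (!nrow(ann)) next
    cols <- which(m[tx, ] != "-")
    if (any(ann$residue_index > length(cols))) {
      stop(sprintf(
        "annotation for '%s' references residue %d beyond its ungapped length %d",
        tx, max(ann$residue_index), length(cols)))
    }
    entries <- rbind(entries, data.frame(
      taxon = tx, column = cols[ann$residue_index], phase = ann$phase))
  }
  if (is.null(entries)) return(list())
  chars <- list()
  for (ph in sort(unique(entries$phase))) {
    sub <- entries[entries$phase == ph, , drop = FALSE]
    sub <- sub[order(sub$column), , drop = FALSE]
    start <- 1L
    while (start <= nrow(sub)) {
      ref_col <- sub$column[start]
      in_grp <- sub$column - ref_col <= column_tolerance &
        sub$column >= ref_col
      grp <- sub[in_grp, , drop = FALSE]
      member <- stats::setNames(taxa %in% grp$taxon, taxa)
      chars[[length(chars) + 1L]] <- structure(list(
        character_id = NA_character_, alignment_column = ref_col,
        phase = ph, member_map = member), class = "intron_character")
      sub <- sub[!in_grp, , drop = FALSE]
    }
  }
  ord <- order(vapply(chars, function(x) x$alignment_column, 0),
               vapply(chars, function(x) x$phase, 0))
  chars <- chars[ord]
  for (i in seq_along(chars)) {
    chars[[i]]$character_id <- sprintf("intron%d", i)
  }
  chars
}

#' Write gene models as a GFF3-like TSV
#'
#' One exon per line: `gene_id`, `exon_index`, `start`, `end` (0-based
#' half-open), `strand`.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output file.
#' @export
write_gene_models_tsv <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(gm) {
    data.frame(gene_id = gm$gene_id, exon_index = seq_len(nrow(gm$exons)),
               start = gm$exons[, 1L], end = gm$exons[, 2L],
               strand = gm$strand)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
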