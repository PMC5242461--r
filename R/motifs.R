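# Sequence-feature detection: conserved cysteine pairs, signature motifs,
# furin cleavage sites, conserved alignment segments, TM-helix delineation.

#' Detect conserved cysteine columns and pair them N to C
#'
#' A column is a conserved-cysteine column iff the fraction of non-gap rows
#' carrying `C` is at least `min_fraction`.  Columns are numbered from the N
#' terminus and paired consecutively, (C1, C2), (C3, C4), ...; disulfide
#' partners are gained and lost as pairs, so each pair becomes one
#' presence/absence character whose per-taxon state requires `C` at both
#' columns.  A trailing unpaired column is reported but not made a character.
#'
#' @param alignment Protein MSA (named character vector, `AAStringSet` or
#'   character matrix).
#' @param min_fraction Minimum fraction of non-gap rows with `C` (default
#'   0.5).
#' @return List with `columns` (all conserved cysteine columns, N to C),
#'   `pairs` (list of `cys_character`: `pair_id`, `columns`, `member_map`)
#'   and `unpaired` (trailing column or empty).
#' @export
detect_conserved_cysteines <- function(alignment, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  m <- .as_aln_matrix(alignment)
  if (!nrow(m)) stop("alignment is empty")
  frac <- apply(m, 2L, function(col) {
    ng <- col != "-"
    if (!any(ng)) return(0)
    mean(col[ng] == "C")
  })
  cols <- which(frac >= min_fraction)
  npair <- length(cols) %/% 2L
  pairs <- vector("list", npair)
  for (i in seq_len(npair)) {
    ca <- cols[2L * i - 1L]
    cb <- cols[2L * i]
    member <- m[, ca] == "C" & m[, cb] == "C"
    names(member) <- rownames(m)
    pairs[[i]] <- structure(list(
      pair_id = sprintf("C%d-C%d", 2L * i - 1L, 2L * i),
      columns = c(ca, cb), member_map = member), class = "cys_character")
  }
  list(columns = cols, pairs = pairs,
       unpaired = if (length(cols) %% 2L) cols[length(cols)] else integer(0))
}

# Compile the motif grammar to a PCRE regex.  Tokens are dash-separated:
# literal residue runs, `x` (any residue), `x(i)` / `x(i,j)` (bounded
# wildcard runs, matched lazily so hits are leftmost-shortest), `[ABC]`
# (residue class).
.compile_motif <- function(pattern) {
  tokens <- strsplit(pattern, "-", fixed = TRUE)[[1L]]
  if (!length(tokens)) stop("empty motif pattern")
  parts <- character(length(tokens))
  for (i in seq_along(tokens)) {
    tk <- tokens[i]
    if (grepl("^[A-WYZ]+$", tk) && !grepl("x", tk)) {       # literal residues
      parts[i] <- tk
    } else if (tk == "x") {
      parts[i] <- "."
    } else if (grepl("^x\\(\\d+\\)$", tk)) {
      parts[i] <- sprintf(".{%s}", sub("^x\\((\\d+)\\)$", "\\1", tk))
    } else if (grepl("^x\\(\\d+,\\d+\\)$", tk)) {
      ij <- as.integer(strsplit(sub("^x\\((.*)\\)$", "\\1", tk), ",")[[1L]])
      if (ij[1L] > ij[2L]) {
        stop(sprintf("malformed motif pattern: token %d ('%s') has i > j", i, tk))
      }
      parts[i] <- sprintf(".{%d,%d}?", ij[1L], ij[2L])
    } else if (grepl("^\\[[A-Z]+\\]$", tk)) {
      parts[i] <- tk
    } else {
      stop(sprintf("malformed motif pattern: token %d ('%s')", i, tk))
    }
  }
  paste(parts, collapse = "")
}

#' Scan sequences for a motif
#'
#' Pattern grammar (dash-separated tokens): literal residues (`NGPL`), `x` for
#' any residue, `x(i)` / `x(i,j)` for bounded wildcard runs, `[AB]` for a
#' residue class.  All non-overlapping leftmost(-shortest) hits are reported
#' per sequence, e.g. the C3-x(n)-C4-NGPL signature is `"C-x(2,40)-C-N-G-P-L"`.
#'
#' @param sequences Named character vector or `AAStringSet` (a single unnamed
#'   string is accepted and called `"seq1"`).
#' @param pattern Motif expression.
#' @param pattern_id Identifier recorded with each hit (default: the pattern).
#' @return Data frame `taxon`, `start`, `end` (1-based inclusive),
#'   `pattern_id`, `match`.
#' @export
scan_motif <- function(sequences, pattern, pattern_id = pattern) {
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  }
  rx <- .compile_motif(pattern)
  out <- NULL
  for (nm in names(sequences)) {
    hits <- gregexpr(rx, sequences[[nm]], perl = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    len <- attr(hits, "match.length")
    out <- rbind(out, data.frame(
      taxon = nm, start = as.integer(hits), end = as.integer(hits) + len - 1L,
      pattern_id = pattern_id,
      match = substring(sequences[[nm]], hits, hits + len - 1L)))
  }
  if (is.null(out)) {
    out <- data.frame(taxon = character(0), start = integer(0),
                      end = integer(0), pattern_id = character(0),
                      match = character(0))
  }
  out
}

#' Find furin cleavage sites
#'
#' Reports every (including overlapping) match of the minimal furin
#' recognition motif R-x-\[RK\]-R; cleavage occurs after the final arginine.
#'
#' @param sequence Protein sequence (single string).
#' @return Data frame `start`, `end`, `cleave_after` (= `end`, the residue
#'   after which cleavage occurs), `site`.
#' @export
find_furin_sites <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  starts <- integer(0)
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      if (aa[i] == "R" && (aa[i + 2L] == "R" || aa[i + 2L] == "K") &&
          aa[i + 3L] == "R") {
        starts <- c(starts, i)
      }
    }
  }
  if (!length(starts)) {
    return(data.frame(start = integer(0), end = integer(0),
                      cleave_after = integer(0), site = character(0)))
  }
  data.frame(start = starts, end = starts + 3L, cleave_after = starts + 3L,
             site = substring(sequence, starts, starts + 3L))
}

#' Scan an alignment for conserved segments
#'
#' A column is conserved iff no row has a gap and at least `min_identity` of
#' the rows share the column's majority residue; maximal runs of at least
#' `min_length` conserved columns are reported.
#'
#' @param alignment Protein MSA.
#' @param min_length Minimum segment length in columns (default 4).
#' @param min_identity Minimum fraction of rows sharing the majority residue
#'   (default 0.7).
#' @return Data frame `start_col`, `end_col`, `length`.
#' @export
conserved_segment_scan <- function(alignment, min_length = 4L,
                                   min_identity = 0.7) {
  m <- .as_aln_matrix(alignment)
  if (!nrow(m)) stop("alignment is empty")
  good <- apply(m, 2L, function(col) {
    if (any(col == "-")) return(FALSE)
    max(table(col)) / length(col) >= min_identity
  })
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(start_col = starts[keep], end_col = ends[keep],
             length = r$lengths[keep])
}

# Kyte-Doolittle hydropathy values.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Locate the transmembrane helix by maximum hydropathy
#'
#' Convenience delineation for reporting region boundaries: the maximum-mean
#' Kyte-Doolittle window of `window` residues.  Not a substitute for proper
#' domain annotation.
#'
#' @param sequence Protein sequence.
#' @param window Window width in residues (default 19).
#' @return List `start`, `end`, `score` (mean hydropathy of the window).
#' @export
find_tm_helix <- function(sequence, window = 19L) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  h <- unname(.KD[aa])
  h[is.na(h)] <- 0
  if (length(h) < window) stop("sequence shorter than the window")
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):length(cs)] - cs[seq_len(length(cs) - window)]) /
    window
  i <- which.max(means)
  list(start = i, end = i + window - 1L, score = means[i])
}
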