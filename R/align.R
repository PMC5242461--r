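# Optimal local alignment with affine gaps (Smith-Waterman / Gotoh).

#' Scoring configuration for local alignment
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM250"`, loaded from Biostrings) or a symmetric numeric
#'   matrix with residue dimnames.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers); a gap
#'   of length L costs `gap_open + gap_extend * L`.
#' @return List used by [find_shared_region()].
#' @export
alignment_scoring <- function(matrix = "BLOSUM62", gap_open = 10,
                              gap_extend = 1) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    matrix <- get(matrix, envir = env)
  }
  if (!is.matrix(matrix) || is.null(dimnames(matrix))) {
    stop("scoring matrix must have residue dimnames")
  }
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

#' Best local alignment between two proteins
#'
#' Smith-Waterman dynamic programming with affine gaps (Gotoh's three-state
#' recursion).  Used to delineate shared regions such as the juxtamembrane
#' FN3-like + TM span common to UPK2/3 proteins and PTPRQ.  Among co-optimal
#' alignments, the one with the smallest target start (then smallest query
#' start) is returned.
#'
#' @param query,target Protein sequences (single strings).
#' @param scoring An [alignment_scoring()] configuration.
#' @return Object of class `local_alignment`: `score`, `query_span`,
#'   `target_span` (1-based inclusive), `query_aln`, `target_aln`.
#' @export
find_shared_region <- function(query, target, scoring = alignment_scoring()) {
  if (!nchar(query) || !nchar(target)) stop("empty sequence")
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  t <- strsplit(target, "", fixed = TRUE)[[1L]]
  S <- scoring$matrix
  bad_q <- setdiff(q, rownames(S)); bad_t <- setdiff(t, rownames(S))
  if (length(bad_q) || length(bad_t)) {
    stop("residues absent from the scoring matrix: ",
         paste(unique(c(bad_q, bad_t)), collapse = ", "))
  }
  go <- scoring$gap_open
  ge <- scoring$gap_extend
  n <- length(q); m <- length(t)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in query (consumes target)
  F_ <- matrix(NEG, n + 1L, m + 1L) # gap in target (consumes query)
  # traceback codes for H: 0 stop, 1 diagonal, 2 from F (up), 3 from E (left)
  TB <- matrix(0L, n + 1L, m + 1L)
  TE <- matrix(0L, n + 1L, m + 1L)  # 1 = opened here, 0 = extended
  TF <- matrix(0L, n + 1L, m + 1L)
  sub <- S[q, t, drop = FALSE]
  for (i in 2L:(n + 1L)) {
    Hi1 <- H[i - 1L, ]
    for (j in 2L:(m + 1L)) {
      e_open <- H[i, j - 1L] - go - ge
      e_ext <- E[i, j - 1L] - ge
      E[i, j] <- max(e_open, e_ext)
      TE[i, j] <- if (e_open >= e_ext) 1L else 0L
      f_open <- Hi1[j] - go - ge
      f_ext <- F_[i - 1L, j] - ge
      F_[i, j] <- max(f_open, f_ext)
      TF[i, j] <- if (f_open >= f_ext) 1L else 0L
      d <- Hi1[j - 1L] + sub[i - 1L, j - 1L]
      best <- 0; code <- 0L
      if (d > best) { best <- d; code <- 1L }
      if (F_[i, j] > best) { best <- F_[i, j]; code <- 2L }
      if (E[i, j] > best) { best <- E[i, j]; code <- 3L }
      H[i, j] <- best
      TB[i, j] <- code
    }
  }
  smax <- max(H)
  if (smax <= 0) {
    return(structure(list(score = 0, query_span = c(0L, 0L),
                          target_span = c(0L, 0L), query_aln = "",
                          target_aln = ""), class = "local_alignment"))
  }
  cells <- which(H == smax, arr.ind = TRUE)
  traceback <- function(i, j) {
    qa <- character(0); ta <- character(0)
    state <- "H"
    while (TRUE) {
      if (state == "H") {
        code <- TB[i, j]
        if (code == 0L) break
        if (code == 1L) {
          qa <- c(q[i - 1L], qa); ta <- c(t[j - 1L], ta)
          i <- i - 1L; j <- j - 1L
        } else if (code == 2L) state <- "F" else state <- "E"
      } else if (state == "F") {
        opened <- TF[i, j] == 1L
        qa <- c(q[i - 1L], qa); ta <- c("-", ta)
        i <- i - 1L
        if (opened) state <- "H"
      } else {
        opened <- TE[i, j] == 1L
        qa <- c("-", qa); ta <- c(t[j - 1L], ta)
        j <- j - 1L
        if (opened) state <- "H"
      }
    }
    list(qs = i, ts = j, qa = qa, ta = ta)
  }
  best <- NULL
  for (r in seq_len(nrow(cells))) {
    tb <- traceback(cells[r, 1L], cells[r, 2L])
    key <- c(tb$ts, tb$qs)
    if (is.null(best) || key[1L] < best$key[1L] ||
        (key[1L] == best$key[1L] && key[2L] < best$key[2L])) {
      best <- list(key = key, tb = tb, cell = cells[r, ])
    }
  }
  tb <- best$tb
  structure(list(
    score = smax,
    query_span = c(tb$qs, best$cell[[1L]] - 1L),
    target_span = c(tb$ts, best$cell[[2L]] - 1L),
    query_aln = paste(tb$qa, collapse = ""),
    target_aln = paste(tb$ta, collapse = "")), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment, score %g\n", x$score))
  cat(sprintf("query  %d-%d  %s\n", x$query_span[1L], x$query_span[2L],
              x$query_aln))
  cat(sprintf("target %d-%d  %s\n", x$target_span[1L], x$target_span[2L],
              x$target_aln))
  invisible(x)
}
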