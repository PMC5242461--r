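# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Coerce an alignment (AAStringSet, named character vector, or character
# matrix with one residue per cell) to a character matrix, rows = taxa.
.as_aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) {
      stop("alignment matrix must have taxon rownames")
    }
    return(alignment)
  }
  if (methods::is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  if (!is.character(alignment) || is.null(names(alignment))) {
    stop("alignment must be a named character vector, XStringSet or matrix")
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows differ in length; sequences are not aligned")
  }
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

.aln_to_strings <- function(m) {
  x <- apply(m, 1L, paste, collapse = "")
  names(x) <- rownames(m)
  x
}

# FNV-1a hash of a string; used for manifest config fingerprints.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- (h %% 4294967296)
    # xor on values >= 2^31 is out of bitwXor's range; emulate on the low byte
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b)
    # multiply by the FNV prime 16777619 mod 2^32, split to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# One-letter amino-acid alphabet used throughout (no ambiguity codes).
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.MISSING_CHARS <- c("-", "?", "X", "x", ".")

# Write named sequences as FASTA (plain text, 70-column wrap).
.write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    cat(">", nm, "\n", sep = "", file = con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = 70L)
    for (st in starts) {
      cat(substr(s, st, min(st + 69L, nchar(s))), "\n", sep = "", file = con)
    }
  }
  invisible(path)
}

.read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  names(seqs) <- names_
  seqs
}
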