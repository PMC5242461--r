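# Binary molecular-morphology (MM) character coding and partitioned matrices.
#
# Presence/absence features (homologous introns, cysteine pairs) are coded
# with the nucleotide letters G (present) and T (absent), so that combined
# amino-acid + MM matrices remain valid input for standard parsimony and
# Bayesian programs; internally the states are binary with G <-> present.

#' Code features as a binary MM partition
#'
#' One column per character: cysteine pairs first (N to C), then intron
#' characters in their left-to-right order.  States: `G` present, `T` absent,
#' `?` for taxa missing from a character's member map.
#'
#' @param intron_chars List of `intron_character` objects from
#'   [cluster_homologous_introns()].
#' @param cys_chars List of `cys_character` objects from
#'   [detect_conserved_cysteines()] (`$pairs`).
#' @param taxa Character vector giving the taxon order of the partition.
#' @return Character matrix (rows = taxa, columns = characters) with
#'   character ids as column names.
#' @export
code_characters <- function(intron_chars = list(), cys_chars = list(), taxa) {
  chars <- c(cys_chars, intron_chars)
  ids <- vapply(chars, function(x) {
    if (!is.null(x$pair_id)) x$pair_id else x$character_id
  }, "")
  if (anyDuplicated(ids)) {
    stop("duplicate character ids: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  }
  mm <- matrix("?", nrow = length(taxa), ncol = length(chars),
               dimnames = list(taxa, ids))
  for (k in seq_along(chars)) {
    mem <- chars[[k]]$member_map
    if (!all(names(mem) %in% taxa)) {
      stop("character '", ids[k], "' scores taxa outside the given set: ",
           paste(setdiff(names(mem), taxa), collapse = ", "))
    }
    mm[names(mem), k] <- ifelse(mem, "G", "T")
  }
  mm
}

#' Decode an MM partition back to a presence/absence table
#'
#' Inverse of [code_characters()] for fully scored matrices: `G` maps to
#' `TRUE`, `T` to `FALSE`, `?` to `NA`.
#'
#' @param mm Character matrix coded G/T/?.
#' @return Logical matrix of the same shape.
#' @export
decode_characters <- function(mm) {
  out <- matrix(NA, nrow = nrow(mm), ncol = ncol(mm), dimnames = dimnames(mm))
  out[mm == "G"] <- TRUE
  out[mm == "T"] <- FALSE
  out
}

#' Partitioned character matrix (amino acids + MM characters)
#'
#' @param taxa Taxon labels (sets the row order of both partitions).
#' @param aa Character matrix of aligned residues (rows = taxa), or `NULL`.
#' @param mm Character matrix of G/T/? MM characters (rows = taxa), or `NULL`.
#' @return Object of class `character_matrix` with fields `taxa`, `aa`, `mm`
#'   and `charsets` (1-based column ranges of each partition in the combined
#'   matrix).
#' @export
character_matrix <- function(taxa, aa = NULL, mm = NULL) {
  norm <- function(x, what) {
    if (is.null(x)) return(matrix(character(0), nrow = length(taxa), ncol = 0L,
                                  dimnames = list(taxa, NULL)))
    if (!is.matrix(x)) stop(what, " partition must be a character matrix")
    if (is.null(rownames(x))) stop(what, " partition must have taxon rownames")
    if (!setequal(rownames(x), taxa)) {
      stop(sprintf("%s partition taxa differ from the matrix taxa (only in %s: %s; only in partition: %s)",
                   what, "matrix",
                   paste(setdiff(taxa, rownames(x)), collapse = ","),
                   paste(setdiff(rownames(x), taxa), collapse = ",")))
    }
    x[taxa, , drop = FALSE]
  }
  aa <- norm(aa, "amino-acid")
  mm <- norm(mm, "MM")
  na <- ncol(aa); nm <- ncol(mm)
  charsets <- list()
  if (na) charsets$aa <- c(1L, na)
  if (nm) charsets$mm <- c(na + 1L, na + nm)
  structure(list(taxa = taxa, aa = aa, mm = mm, charsets = charsets),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa, %d AA columns + %d MM characters\n",
              length(x$taxa), ncol(x$aa), ncol(x$mm)))
  invisible(x)
}

#' Combine an amino-acid alignment with an MM partition
#'
#' @param aa_alignment Protein MSA (named character vector, `AAStringSet` or
#'   character matrix with taxon rownames).
#' @param mm_partition G/T/? matrix from [code_characters()]; may have zero
#'   columns.
#' @return A [character_matrix()] with charset metadata.
#' @export
build_combined_matrix <- function(aa_alignment, mm_partition) {
  aa <- .as_aln_matrix(aa_alignment)
  if (!setequal(rownames(aa), rownames(mm_partition))) {
    stop("taxon sets differ between partitions; only in alignment: ",
         paste(setdiff(rownames(aa), rownames(mm_partition)), collapse = ", "),
         "; only in MM partition: ",
         paste(setdiff(rownames(mm_partition), rownames(aa)), collapse = ", "))
  }
  character_matrix(rownames(aa), aa = aa, mm = mm_partition)
}

# Combined view: AA columns then MM columns.
.cm_all <- function(cm) cbind(cm$aa, cm$mm)

#' Write a character matrix as NEXUS
#'
#' DATA block (protein datatype: the G/T binary states are valid amino-acid
#' letters, which is the point of the G/T coding) followed by a SETS block
#' with `aa` and `mm` charsets.  [read_nexus()] round-trips the format
#' bit-identically.
#'
#' @param cm A [character_matrix()].
#' @param path Output file.
#' @export
write_nexus <- function(cm, path) {
  all_ <- .cm_all(cm)
  con <- file(path, "w")
  on.exit(close(con))
  w <- max(nchar(cm$taxa)) + 2L
  cat("#NEXUS\n\nBEGIN DATA;\n", file = con)
  cat(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;\n", length(cm$taxa), ncol(all_)),
      file = con)
  cat("  FORMAT DATATYPE=PROTEIN GAP=- MISSING=?;\n  MATRIX\n", file = con)
  for (tx in cm$taxa) {
    cat(sprintf("    %-*s%s\n", w, tx, paste(all_[tx, ], collapse = "")),
        file = con)
  }
  cat("  ;\nEND;\n", file = con)
  if (length(cm$charsets)) {
    cat("\nBEGIN SETS;\n", file = con)
    for (nm in names(cm$charsets)) {
      rg <- cm$charsets[[nm]]
      cat(sprintf("  CHARSET %s = %d-%d;\n", nm, rg[1L], rg[2L]), file = con)
    }
    cat("END;\n", file = con)
  }
  invisible(path)
}

#' Read a NEXUS character matrix written by [write_nexus()]
#'
#' @param path NEXUS file.
#' @return A [character_matrix()]; charsets named `aa` and `mm` are used to
#'   split the partitions (everything is treated as `aa` if no SETS block is
#'   present).
#' @export
read_nexus <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#NEXUS", lines[1L])) stop("not a NEXUS file: ", path)
  in_matrix <- FALSE
  taxa <- character(0)
  rows <- character(0)
  charsets <- list()
  for (ln in lines) {
    s <- trimws(ln)
    if (grepl("^MATRIX$", s, ignore.case = TRUE)) { in_matrix <- TRUE; next }
    if (in_matrix) {
      if (s == ";") { in_matrix <- FALSE; next }
      if (!nzchar(s)) next
      parts <- strsplit(s, "\\s+")[[1L]]
      taxa <- c(taxa, parts[1L])
      rows <- c(rows, paste(parts[-1L], collapse = ""))
      next
    }
    cs <- regmatches(s, regexec(
      "^CHARSET\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+);", s, ignore.case = TRUE))[[1L]]
    if (length(cs)) {
      charsets[[cs[2L]]] <- c(as.integer(cs[3L]), as.integer(cs[4L]))
    }
  }
  if (!length(taxa)) stop("no MATRIX block found in ", path)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- taxa
  if (!length(charsets)) charsets <- list(aa = c(1L, ncol(m)))
  aa <- if (!is.null(charsets$aa)) {
    m[, charsets$aa[1L]:charsets$aa[2L], drop = FALSE]
  } else NULL
  mm <- if (!is.null(charsets$mm)) {
    m[, charsets$mm[1L]:charsets$mm[2L], drop = FALSE]
  } else NULL
  character_matrix(taxa, aa = aa, mm = mm)
}

#' Write a character matrix as relaxed PHYLIP
#'
#' @param cm A [character_matrix()].
#' @param path Output file.
#' @export
write_phylip <- function(cm, path) {
  all_ <- .cm_all(cm)
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("%d %d\n", length(cm$taxa), ncol(all_)), file = con)
  w <- max(nchar(cm$taxa)) + 2L
  for (tx in cm$taxa) {
    cat(sprintf("%-*s%s\n", w, tx, paste(all_[tx, ], collapse = "")),
        file = con)
  }
  invisible(path)
}
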