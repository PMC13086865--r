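#' Parent protein with absolute residue numbering
#'
#' A parent protein is a sequence plus the absolute (1-based) residue index of
#' its first position, so that subpeptides carry coordinates in the numbering
#' of the full-length protein (e.g. a C-terminal domain starting at residue
#' 590 of its parent).
#'
#' @param id Identifier string.
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param numbering_offset Absolute residue index of sequence position 1.
#' @return An object of class `parent_protein` with elements `id`, `sequence`,
#'   `numbering_offset` and `length`.
#' @examples
#' p <- parent_protein("ct", "EIVVQDGITLITKEEASGSSVTAEEAKK", 676)
#' parent_residue(p, 14)  # absolute index 689
#' @export
parent_protein <- function(id, sequence, numbering_offset = 1L) {
  chars <- aa_chars(sequence)
  if (!length(chars)) stop("parent sequence must be non-empty")
  numbering_offset <- as.integer(numbering_offset)
  structure(
    list(id = as.character(id), sequence = paste(chars, collapse = ""),
         numbering_offset = numbering_offset, length = length(chars)),
    class = "parent_protein"
  )
}

#' @export
print.parent_protein <- function(x, ...) {
  cat(sprintf("<parent_protein> %s: %d aa, absolute numbering %d-%d\n",
              x$id, x$length, x$numbering_offset,
              x$numbering_offset + x$length - 1L))
  invisible(x)
}

#' Absolute residue index of a position within a parent protein
#'
#' @param parent A [parent_protein()].
#' @param pos 1-based position(s) within the stored sequence.
#' @return Absolute residue index (vectorised).
#' @export
parent_residue <- function(parent, pos) {
  stopifnot(inherits(parent, "parent_protein"))
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > parent$length))
    stop("position out of range 1..", parent$length)
  parent$numbering_offset + pos - 1L
}

#' Extract a subregion of a parent protein as a new parent
#'
#' @param parent A [parent_protein()].
#' @param start,end Absolute residue indices (inclusive).
#' @return A `parent_protein` covering the region, numbering preserved.
#' @export
parent_region <- function(parent, start, end) {
  stopifnot(inherits(parent, "parent_protein"))
  i <- as.integer(start) - parent$numbering_offset + 1L
  j <- as.integer(end) - parent$numbering_offset + 1L
  if (i < 1L || j > parent$length || i > j)
    stop("region outside parent: ", start, "-", end)
  parent_protein(parent$id, substr(parent$sequence, i, j), as.integer(start))
}

#' Read parent proteins from a FASTA file
#'
#' Description lines of the form `id/start-end` carry the absolute numbering
#' offset (`start`); a bare `id` gets offset 1.
#'
#' @param file Path to a FASTA file.
#' @return List of [parent_protein()] objects.
#' @export
read_parent_fasta <- function(file) {
  fa <- bio3d::read.fasta(file, rm.dup = FALSE)
  ids <- fa$id
  lapply(seq_along(ids), function(k) {
    seq <- paste(fa$ali[k, fa$ali[k, ] != "-"], collapse = "")
    m <- regmatches(ids[k], regexec("^(.*)/([0-9]+)-([0-9]+)$", ids[k]))[[1]]
    if (length(m) == 4L)
      parent_protein(m[2], seq, as.integer(m[3]))
    else
      parent_protein(ids[k], seq, 1L)
  })
}

#' Write parent proteins or peptide candidates to FASTA
#'
#' Description lines use the `id/start-end` span convention so absolute
#' coordinates survive a round trip.
#'
#' @param x A `parent_protein`, a list of them, or a peptide candidate table
#'   from [enumerate_subpeptides()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(x, file) {
  if (inherits(x, "parent_protein")) x <- list(x)
  if (is.data.frame(x)) {
    ids <- sprintf("%s/%d-%d", x$parent_id, x$parent_start, x$parent_end)
    seqs <- x$sequence
  } else {
    ids <- vapply(x, function(p)
      sprintf("%s/%d-%d", p$id, p$numbering_offset,
              p$numbering_offset + p$length - 1L), character(1))
    seqs <- vapply(x, function(p) p$sequence, character(1))
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(ids))
    writeLines(c(paste0(">", ids[k]), seqs[k]), con)
  invisible(file)
}

#' Locate a motif (with `x` wildcards) in a sequence
#'
#' Scans left to right and reports every occurrence with both the local
#' (1-based within the sequence) and the absolute parent coordinate. The
#' letter `x` in the motif matches any residue.
#'
#' @param sequence One-letter string, or a single-row peptide candidate table.
#' @param motif Motif string; lower- or upper-case `x` is the wildcard.
#' @param numbering_offset Absolute index of sequence position 1 (ignored when
#'   `sequence` is a candidate table, which carries its own span).
#' @return Data frame with columns `pos` (local) and `parent_index`
#'   (absolute); zero rows when there is no match.
#' @examples
#' find_motif("EIVVQDGITLITKEEASGSSVTAEEAKK", "TKEEASG", numbering_offset = 676)
#' @export
find_motif <- function(sequence, motif, numbering_offset = 1L) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    numbering_offset <- sequence$parent_start
    sequence <- sequence$sequence
  }
  if (!nzchar(motif)) stop("motif must be non-empty")
  s <- strsplit(toupper(sequence), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  n <- length(s); w <- length(m)
  hits <- integer(0)
  if (w <= n) {
    wild <- m == "X"
    for (i in seq_len(n - w + 1L)) {
      win <- s[i:(i + w - 1L)]
      if (all(wild | win == m)) hits <- c(hits, i)
    }
  }
  data.frame(pos = hits,
             parent_index = numbering_offset + hits - 1L)
}

#' Longest common contiguous substring of two sequences
#'
#' Dynamic-programming longest common substring; ties are broken by the
#' earliest start in `a`.
#'
#' @param a,b Non-empty strings.
#' @return List with `length` and `substring` (empty string when disjoint).
#' @export
longest_common_overlap <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("both sequences must be non-empty")
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  na <- length(sa); nb <- length(sb)
  prev <- integer(nb)
  best_len <- 0L; best_end_a <- 0L
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_j <- which(sb == sa[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      # strict > keeps the earliest start in a on ties
      if (cur[j] > best_len) {
        best_len <- cur[j]
        best_end_a <- i
      }
    }
    prev <- cur
  }
  if (best_len == 0L) return(list(length = 0L, substring = ""))
  list(length = best_len,
       substring = substr(a, best_end_a - best_len + 1L, best_end_a))
}
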