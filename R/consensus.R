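# Plurality-consensus motif extraction from an aligned peptide library. The
# rule: per column, take the most frequent residue; write it into the motif
# when its count reaches at least `threshold_fraction` of the rows, the
# maximiser is unique, and it is not the gap symbol — otherwise write the
# wildcard x. Substitution-only mutant libraries align columnwise by
# construction; externally aligned (gapped) MSAs are accepted as files.

# Coerce the accepted inputs to an uppercase character matrix of residues.
as_alignment_matrix <- function(msa) {
  if (inherits(msa, "mutant_library")) msa <- msa$members
  if (is.character(msa) && !is.matrix(msa)) {
    widths <- nchar(msa)
    if (!length(msa)) stop("alignment must have at least one row")
    if (length(unique(widths)) != 1L)
      stop("ragged alignment: row widths ", paste(unique(widths),
                                                  collapse = ", "))
    msa <- do.call(rbind, strsplit(toupper(msa), ""))
  }
  if (!is.matrix(msa)) stop("unsupported alignment input")
  toupper(msa)
}

#' Plurality consensus of an alignment
#'
#' @param msa Character vector of equal-length sequences, a character matrix
#'   (rows = sequences), or a [generate_mutants()] library. Gaps as `-`.
#' @param threshold_fraction Minimum fraction of rows the top residue must
#'   reach (default 0.5, i.e. at least half); comparison is `>=`.
#' @return Object of class `consensus_motif`: `motif` (string with `x` at
#'   non-conserved columns), and `profile`, a data frame per column with
#'   `position`, `consensus_residue`, `count`, `n`, `conserved`.
#' @examples
#' consensus_from_alignment(c("ACDE", "ACDF", "ACEG", "ACEG"))$motif
#' @export
consensus_from_alignment <- function(msa, threshold_fraction = 0.5) {
  m <- as_alignment_matrix(msa)
  n <- nrow(m)
  cols <- lapply(seq_len(ncol(m)), function(j) {
    counts <- sort(table(m[, j]), decreasing = TRUE)
    top <- names(counts)[1]
    top_count <- counts[[1]]
    unique_max <- sum(counts == top_count) == 1L
    conserved <- unique_max && top != "-" &&
      top_count >= threshold_fraction * n
    data.frame(position = j,
               consensus_residue = if (conserved) top else "x",
               count = top_count, n = n, conserved = conserved)
  })
  profile <- do.call(rbind, cols)
  structure(list(motif = paste(profile$consensus_residue, collapse = ""),
                 profile = profile,
                 threshold_fraction = threshold_fraction),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus_motif> %s (%d/%d columns conserved, threshold %g)\n",
              x$motif, sum(x$profile$conserved), nrow(x$profile),
              x$threshold_fraction))
  invisible(x)
}

#' Scan a wildcard motif for conserved runs and submotifs
#'
#' Two views of a consensus motif string: the maximal runs of consecutive
#' conserved (non-`x`) positions, and — when `pattern` is given — all
#' occurrences of a wildcard-tolerant literal pattern. A pattern position
#' matches when it is the wildcard `x` (accepts anything, conserved or not)
#' or when it equals the conserved motif character; a literal pattern residue
#' is never satisfied by a non-conserved motif column.
#'
#' @param motif Motif string (from [consensus_from_alignment()]).
#' @param window_min Minimum run length to report (default 1).
#' @param pattern Optional pattern string with `x` wildcards.
#' @return List: `runs` (data frame `start`, `end`, `length`, `segment`) and
#'   `pattern_hits` (integer start positions; empty when no pattern given or
#'   no match).
#' @examples
#' submotif_scan("EIVVQDGITLxxxxExEAxSGSSVxxExKK", pattern = "ExEAxSGSS")
#' @export
submotif_scan <- function(motif, window_min = 1L, pattern = NULL) {
  chars <- strsplit(motif, "")[[1]]
  conserved <- chars != "x" & chars != "X"
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= window_min)
  runs <- data.frame(start = integer(0), end = integer(0),
                     length = integer(0), segment = character(0))
  if (length(keep))
    runs <- data.frame(start = starts[keep], end = ends[keep],
                       length = r$lengths[keep],
                       segment = substring(motif, starts[keep], ends[keep]))
  hits <- integer(0)
  if (!is.null(pattern)) {
    p <- strsplit(pattern, "")[[1]]
    w <- length(p)
    if (w <= length(chars)) {
      for (i in seq_len(length(chars) - w + 1L)) {
        win <- chars[i:(i + w - 1L)]
        if (all(p == "x" | win == p)) hits <- c(hits, i)
      }
    }
  }
  list(runs = runs, pattern_hits = hits)
}

#' Position frequency matrix of an alignment
#'
#' @param msa As in [consensus_from_alignment()].
#' @param alphabet Symbols to tabulate; defaults to the 20 residues plus any
#'   gap symbol present.
#' @return Row-stochastic matrix (positions x symbols); each row sums to 1.
#' @export
frequency_matrix <- function(msa, alphabet = NULL) {
  m <- as_alignment_matrix(msa)
  if (is.null(alphabet)) {
    alphabet <- aa_alphabet()
    if (any(m == "-")) alphabet <- c(alphabet, "-")
  }
  out <- t(vapply(seq_len(ncol(m)), function(j) {
    counts <- table(factor(m[, j], levels = alphabet))
    as.numeric(counts) / nrow(m)
  }, numeric(length(alphabet))))
  dimnames(out) <- list(seq_len(ncol(m)), alphabet)
  out
}

#' Write a position frequency matrix as TSV
#'
#' Logo-tool-compatible layout: one row per position, one column per symbol.
#'
#' @param freq Matrix from [frequency_matrix()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_frequency_matrix <- function(freq, file) {
  utils::write.table(data.frame(position = rownames(freq), freq,
                                check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a multiple sequence alignment from FASTA or Clustal
#'
#' @param file Path; format inferred from content (`CLUSTAL` header) unless
#'   given.
#' @param format `"auto"`, `"fasta"` or `"clustal"`.
#' @return Character matrix (rows = sequences) with row names.
#' @export
read_msa <- function(file, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
              else "fasta"
  }
  if (format == "fasta") {
    fa <- bio3d::read.fasta(file, rm.dup = FALSE)
    m <- toupper(fa$ali)
    rownames(m) <- fa$id
    return(m)
  }
  # Clustal block format: "name  SEGMENT" lines, blocks separated by blank
  # lines, optional conservation lines (only *:. and spaces) ignored
  lines <- readLines(file)[-1]
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^[[:space:]*:.]+$", lines)]
  m <- regmatches(lines, regexec("^(\\S+)\\s+([A-Za-z-]+)\\s*[0-9]*$",
                                 lines))
  ok <- lengths(m) == 3L
  if (!any(ok)) stop("no sequence lines found in Clustal file")
  nam <- vapply(m[ok], `[`, "", 2)
  seg <- vapply(m[ok], `[`, "", 3)
  seqs <- vapply(unique(nam), function(id)
    paste(seg[nam == id], collapse = ""), character(1))
  out <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(out) <- unique(nam)
  out
}
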