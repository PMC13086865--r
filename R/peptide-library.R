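# Subpeptide enumeration and candidate bookkeeping. A peptide library is a
# plain data.frame (one row per candidate) so it composes with base R and
# writes straight to TSV; columns mirror the candidate report:
# peptide, parent_id, parent_start, parent_end, length, sequence, mass_Da,
# plus optional score / contacts / fraction_pct / occupancy / solubility /
# selected filled in by later stages.

#' Enumerate every contiguous subpeptide of a parent protein
#'
#' Generates all windows with `min_len <= length <= max_len`, ordered by start
#' position then length. For a parent of length L and unbounded `max_len` the
#' library size is `(L - min_len + 1) * (L - min_len + 2) / 2`; e.g. a
#' 120-residue region with `min_len = 21` yields 5050 candidates.
#'
#' @param parent A [parent_protein()].
#' @param min_len Minimum window length (residues).
#' @param max_len Maximum window length; `Inf` for unbounded.
#' @return Data frame with one row per candidate: `peptide` (id
#'   `parent/start-end`), `parent_id`, `parent_start`, `parent_end` (absolute,
#'   inclusive), `length`, `sequence`, `mass_Da`.
#' @examples
#' p <- parent_protein("toy", "EIVVQDGITLITKEEASGSSVTAEEAKK", 676)
#' nrow(enumerate_subpeptides(p, min_len = 27))  # 3 windows
#' @export
enumerate_subpeptides <- function(parent, min_len, max_len = Inf) {
  stopifnot(inherits(parent, "parent_protein"))
  min_len <- as.integer(min_len)
  if (min_len < 1L) stop("min_len must be >= 1")
  if (is.finite(max_len) && max_len < min_len)
    stop("max_len must be >= min_len")
  L <- parent$length
  if (min_len > L) {
    warning("min_len (", min_len, ") exceeds parent length (", L,
            "); returning an empty library")
    return(empty_library())
  }
  top <- if (is.finite(max_len)) min(as.integer(max_len), L) else L
  rows <- do.call(rbind, lapply(seq_len(L - min_len + 1L), function(start) {
    lens <- min_len:min(top, L - start + 1L)
    cbind(start = start, len = lens)
  }))
  start <- rows[, "start"]; len <- rows[, "len"]
  seqs <- substring(parent$sequence, start, start + len - 1L)
  abs_start <- parent$numbering_offset + start - 1L
  abs_end <- abs_start + len - 1L
  data.frame(
    peptide = sprintf("%s/%d-%d", parent$id, abs_start, abs_end),
    parent_id = parent$id,
    parent_start = abs_start,
    parent_end = abs_end,
    length = len,
    sequence = seqs,
    mass_Da = vapply(seqs, average_mass, numeric(1), USE.NAMES = FALSE)
  )
}

empty_library <- function() {
  data.frame(peptide = character(0), parent_id = character(0),
             parent_start = integer(0), parent_end = integer(0),
             length = integer(0), sequence = character(0),
             mass_Da = numeric(0))
}

#' Construct a single peptide candidate from an absolute span
#'
#' @param parent A [parent_protein()].
#' @param start,end Absolute residue indices (inclusive).
#' @return One-row candidate data frame (see [enumerate_subpeptides()]).
#' @export
peptide_from_span <- function(parent, start, end) {
  region <- parent_region(parent, start, end)
  data.frame(
    peptide = sprintf("%s/%d-%d", parent$id, start, end),
    parent_id = parent$id, parent_start = as.integer(start),
    parent_end = as.integer(end), length = region$length,
    sequence = region$sequence, mass_Da = average_mass(region$sequence)
  )
}

#' Map a peptide-local position to the absolute parent residue index
#'
#' The inverse of locating a parent residue inside the peptide:
#' `map_to_parent(pep, pos)` returns `parent_start + pos - 1` and round-trips
#' exactly with `pos = index - parent_start + 1`.
#'
#' @param pep One-row candidate data frame (or any list with `parent_start`
#'   and `length`).
#' @param peptide_pos 1-based position(s) within the peptide.
#' @return Absolute residue index (vectorised).
#' @examples
#' p <- parent_protein("ct", "EIVVQDGITLITKEEASGSSVTAEEAKK", 676)
#' ku3 <- peptide_from_span(p, 676, 703)
#' map_to_parent(ku3, 14)  # 689
#' @export
map_to_parent <- function(pep, peptide_pos) {
  peptide_pos <- as.integer(peptide_pos)
  len <- pep$length[1]
  if (any(peptide_pos < 1L | peptide_pos > len))
    stop("peptide position out of range 1..", len)
  pep$parent_start[1] + peptide_pos - 1L
}

#' Keep candidates at or below a maximum length
#'
#' Boundary is inclusive: a cap of 30 keeps 30-residue peptides.
#'
#' @param library Candidate data frame.
#' @param max_len Maximum length in residues.
#' @return The subset, order preserved.
#' @export
length_cap <- function(library, max_len) {
  library[library$length <= max_len, , drop = FALSE]
}

#' Write a candidate report as TSV
#'
#' Emits whatever annotation columns are present (score, contacts,
#' fraction_pct, occupancy, solubility, selected) alongside the core columns.
#'
#' @param library Candidate data frame.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_candidate_table <- function(library, file) {
  utils::write.table(library, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a candidate report written by [write_candidate_table()]
#' @param file TSV path.
#' @return Candidate data frame.
#' @export
read_candidate_table <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
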