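# Seeded substitution-mutant library generation. Each member differs from the
# reference by 1..max_mutations point substitutions: the mutation count is
# drawn uniformly on that range, positions are sampled without replacement,
# and each substituted residue is drawn uniformly over the 19 alternatives.
# Members are deduplicated, so the library is a set of distinct derivatives.

#' Generate a library of substitution mutants of a reference peptide
#'
#' @param reference One-letter reference sequence.
#' @param n Number of unique mutants to generate.
#' @param max_mutations Maximum substitutions per member (>= 1).
#' @param seed Integer seed; fixed seed gives a byte-identical library.
#' @param p_position Optional per-position weight vector (length
#'   `nchar(reference)`), renormalised internally; positions with weight 0 are
#'   never mutated. Default: uniform.
#' @return Object of class `mutant_library`: list with `reference`, `members`
#'   (character vector of unique sequences), `max_mutations`, `seed`.
#' @examples
#' lib <- generate_mutants("EIVVQDGITLITKEEASGSSVTAEEAKK", n = 100,
#'                         max_mutations = 10, seed = 1)
#' length(lib$members)  # 100
#' @export
generate_mutants <- function(reference, n, max_mutations, seed,
                             p_position = NULL) {
  ref <- aa_chars(reference)
  L <- length(ref)
  n <- as.integer(n)
  max_mutations <- as.integer(max_mutations)
  if (n < 1L) stop("n must be >= 1")
  if (max_mutations < 1L || max_mutations > L)
    stop("max_mutations must be in 1..", L)
  if (is.null(p_position)) p_position <- rep(1, L)
  stopifnot(length(p_position) == L, all(p_position >= 0),
            sum(p_position > 0) >= max_mutations)
  # cap n by the number of reachable distinct sequences (exact for small L)
  mutable <- sum(p_position > 0)
  reachable <- sum(choose(mutable, seq_len(max_mutations)) *
                     19^seq_len(max_mutations))
  if (is.finite(reachable) && n > reachable)
    stop("n (", n, ") exceeds the ", format(reachable),
         " distinct reachable sequences")
  alphabet <- aa_alphabet()
  members <- with_seed(seed, {
    acc <- character(0)
    guard <- 0L
    while (length(acc) < n) {
      batch <- vapply(seq_len(max(n - length(acc), 16L)), function(i) {
        m <- sample.int(max_mutations, 1L)
        pos <- sample.int(L, m, prob = p_position)
        mut <- ref
        for (p in pos)
          mut[p] <- sample(setdiff(alphabet, ref[p]), 1L)
        paste(mut, collapse = "")
      }, character(1))
      acc <- unique(c(acc, batch))
      guard <- guard + 1L
      if (guard > 10000L)
        stop("could not reach ", n, " unique mutants; space too small")
    }
    acc
  })
  structure(list(reference = paste(ref, collapse = ""),
                 members = members[seq_len(n)],
                 max_mutations = max_mutations, seed = as.integer(seed)),
            class = "mutant_library")
}

#' @export
print.mutant_library <- function(x, ...) {
  cat(sprintf(
    "<mutant_library> %d unique derivatives of %s (<= %d substitutions)\n",
    length(x$members), x$reference, x$max_mutations))
  invisible(x)
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b One-letter strings of equal length.
#' @return Count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("sequences differ in length")
  sum(ca != cb)
}
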