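# Pluggable peptide-protein interaction scoring. Scorers live in a registry
# keyed by name; each is a pure function (peptide, target, parameters) ->
# finite numeric score. The shipped "propensity" scorer is a deterministic
# baseline — the mean pairwise residue-contact propensity between the two
# sequences over a documented 20x20 table. It is NOT a trained interaction
# predictor; swap in an external model by registering it under its own name.

.scorer_registry <- new.env(parent = emptyenv())

#' Register an interaction scorer
#'
#' @param name Registry key.
#' @param fun Function `(peptide, target, parameters)` returning one finite
#'   numeric score; must be deterministic in its inputs.
#' @return Invisibly, `name`.
#' @export
register_scorer <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .scorer_registry)
  invisible(name)
}

#' List registered scorer names
#' @return Character vector.
#' @export
list_scorers <- function() sort(ls(.scorer_registry))

get_scorer <- function(name) {
  if (!exists(name, envir = .scorer_registry, inherits = FALSE))
    stop("unknown scorer '", name, "'; registered: ",
         paste(list_scorers(), collapse = ", "))
  get(name, envir = .scorer_registry, inherits = FALSE)
}

#' Residue-contact propensity table of the baseline scorer
#'
#' Symmetric 20x20 matrix; entry (a, b) is
#' `0.04 * h(a) * h(b) - 0.5 * q(a) * q(b)`, where `h` is Kyte-Doolittle
#' hydropathy and `q` the formal side-chain charge at neutral pH (H = +0.5).
#' Hydrophobic-hydrophobic and oppositely charged pairs score positive,
#' like-charged pairs negative. Dimensionless; defined entirely by this
#' formula so any entry can be recomputed by hand.
#'
#' @return Named 20x20 numeric matrix.
#' @export
contact_propensity_matrix <- function() {
  aa <- aa_alphabet()
  h <- .aa_hydropathy[aa]
  q <- .aa_charge[aa]
  m <- 0.04 * outer(h, h) - 0.5 * outer(q, q)
  dimnames(m) <- list(aa, aa)
  m
}

# Baseline: mean propensity over all residue pairs (i in peptide, j in
# target). Separable, so computed from per-sequence mean propensity profiles.
propensity_scorer <- function(peptide, target, parameters = list()) {
  tab <- contact_propensity_matrix()
  pc <- aa_chars(peptide)
  tc <- aa_chars(target)
  mean(tab[pc, tc, drop = FALSE])
}

.onLoad <- function(libname, pkgname) {
  register_scorer("propensity", propensity_scorer)
}

#' Scorer specification
#'
#' Bundles a registry name, free-form parameters and (after
#' [calibrate_scorer()]) the score of the reference sequence used for
#' threshold filtering.
#'
#' @param name Registered scorer name.
#' @param parameters Named list passed through to the scorer.
#' @param reference_score Optional precomputed reference score.
#' @return Object of class `scorer_spec`.
#' @export
scorer_spec <- function(name = "propensity", parameters = list(),
                        reference_score = NA_real_) {
  get_scorer(name)  # fail fast on unknown names
  structure(list(name = name, parameters = parameters,
                 reference_score = reference_score),
            class = "scorer_spec")
}

#' Fill in a scorer's reference score
#'
#' Scores `reference_sequence` against `target_sequence` and stores the result
#' in the spec, defining the acceptance threshold for
#' [filter_by_reference()].
#'
#' @param spec A [scorer_spec()].
#' @param reference_sequence Sequence whose score defines the threshold
#'   (e.g. the full parent region).
#' @param target_sequence Target protein sequence.
#' @return The spec with `reference_score` set.
#' @export
calibrate_scorer <- function(spec, reference_sequence, target_sequence) {
  stopifnot(inherits(spec, "scorer_spec"))
  fun <- get_scorer(spec$name)
  spec$reference_score <- fun(reference_sequence, target_sequence,
                              spec$parameters)
  spec
}

#' Score every candidate in a library against a target sequence
#'
#' @param library Candidate data frame (needs a `sequence` column).
#' @param target_sequence Target protein sequence.
#' @param spec A [scorer_spec()].
#' @return The library with a `score` column added; order preserved.
#' @export
score_peptides <- function(library, target_sequence, spec) {
  stopifnot(inherits(spec, "scorer_spec"))
  if (!nzchar(target_sequence)) stop("target sequence must be non-empty")
  fun <- get_scorer(spec$name)
  scores <- vapply(library$sequence, fun, numeric(1),
                   target = target_sequence, parameters = spec$parameters,
                   USE.NAMES = FALSE)
  if (any(!is.finite(scores))) stop("scorer returned non-finite score(s)")
  library$score <- scores
  library
}

#' Keep candidates that beat a reference score
#'
#' @param library Scored candidate data frame (all scores present).
#' @param reference_score Threshold score, or a calibrated [scorer_spec()].
#' @param mode `"greater"` (strict, the default) or `"greater_equal"`.
#' @return Accepted subset, order preserved; the accepted count is reported
#'   via `message()`.
#' @export
filter_by_reference <- function(library, reference_score,
                                mode = c("greater", "greater_equal")) {
  mode <- match.arg(mode)
  if (inherits(reference_score, "scorer_spec"))
    reference_score <- reference_score$reference_score
  if (is.null(library$score) || anyNA(library$score))
    stop("all candidates must be scored before filtering")
  if (!is.finite(reference_score))
    stop("reference score is not set; calibrate the scorer first")
  keep <- if (mode == "greater") library$score > reference_score
          else library$score >= reference_score
  out <- library[keep, , drop = FALSE]
  message(sprintf("filter_by_reference: %d of %d accepted (score %s %.6g)",
                  nrow(out), nrow(library),
                  if (mode == "greater") ">" else ">=", reference_score))
  out
}
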