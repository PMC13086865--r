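# Config-driven orchestration of the screening funnel:
# enumerate -> score -> reference filter -> length cap -> pose import ->
# cluster -> contact selection -> annotate -> report. Docking is an import
# boundary: the funnel consumes pose ensembles (from files or synthetic
# generators), it never runs a docking engine.

#' Funnel configuration
#'
#' Collects every tunable of [run_funnel()] with the pipeline defaults:
#' windows of 21+ residues, strict reference-score filter, 30-residue length
#' cap, k = 10 pose clusters, 10 Angstrom C-alpha contact cutoff and a
#' strict 50 % contact-fraction threshold.
#'
#' @param parent A [parent_protein()] (or FASTA path readable by
#'   [read_parent_fasta()], first record used).
#' @param target_sequence Target protein sequence the scorer sees.
#' @param min_len,max_len Enumeration window bounds (default 21, unbounded).
#' @param scorer A [scorer_spec()] (default the baseline `"propensity"`).
#' @param reference_sequence Sequence whose score is the acceptance
#'   threshold; default the parent region itself.
#' @param filter_mode `"greater"` or `"greater_equal"`.
#' @param cap Length cap after scoring (default 30; `Inf` disables).
#' @param poses Named list of [pose_ensemble()] objects (or multi-model PDB
#'   paths), keyed by candidate `peptide` id; candidates without poses pass
#'   through unannotated.
#' @param k Clusters per ensemble (default 10).
#' @param contact_cutoff_A,fraction_threshold Contact rule parameters
#'   (default 10 A, 50 %).
#' @param representative Cluster representative for contact reports.
#' @param solubility Apply [solubility_heuristic()] to the report.
#' @param seed Integer seed recorded and used for clustering.
#' @return List of class `funnel_config`.
#' @export
funnel_config <- function(parent, target_sequence, min_len = 21L,
                          max_len = Inf, scorer = scorer_spec("propensity"),
                          reference_sequence = NULL,
                          filter_mode = "greater", cap = 30L,
                          poses = list(), k = 10L, contact_cutoff_A = 10,
                          fraction_threshold = 50,
                          representative = "medoid", solubility = TRUE,
                          seed = 1L) {
  if (is.character(parent)) parent <- read_parent_fasta(parent)[[1]]
  stopifnot(inherits(parent, "parent_protein"),
            nzchar(target_sequence), min_len >= 1,
            contact_cutoff_A > 0, fraction_threshold > 0, k >= 1)
  if (is.null(reference_sequence)) reference_sequence <- parent$sequence
  structure(list(parent = parent, target_sequence = target_sequence,
                 min_len = as.integer(min_len), max_len = max_len,
                 scorer = scorer, reference_sequence = reference_sequence,
                 filter_mode = filter_mode, cap = cap, poses = poses,
                 k = as.integer(k), contact_cutoff_A = contact_cutoff_A,
                 fraction_threshold = fraction_threshold,
                 representative = representative,
                 solubility = isTRUE(solubility), seed = as.integer(seed)),
            class = "funnel_config")
}

#' Read a funnel configuration from a YAML file
#'
#' Scalar fields map 1:1 onto [funnel_config()] arguments; `parent` must be
#' a FASTA path and `poses` a named map of candidate id to multi-model PDB
#' path (loaded lazily by [run_funnel()]).
#'
#' @param file YAML path.
#' @return A `funnel_config`.
#' @export
read_funnel_config <- function(file) {
  y <- yaml::read_yaml(file)
  args <- y
  if (!is.null(y$scorer)) args$scorer <- scorer_spec(y$scorer)
  if (!is.null(y$max_len) && identical(y$max_len, "unbounded"))
    args$max_len <- Inf
  do.call(funnel_config, args)
}

#' Water-solubility heuristic flag
#'
#' A simple rule on sequence composition: a peptide is flagged `"good"` when
#' its fraction of charged residues (D, E, K, R) is at least 0.2 AND its
#' mean Kyte-Doolittle hydropathy is at most 0; otherwise `"poor"`. This is
#' a labelled heuristic on composition, not a structure- or ML-based
#' solubility predictor, and every report column produced from it is named
#' `solubility_heuristic`.
#'
#' @param sequence One-letter string (vectorised).
#' @return `"good"` or `"poor"` per sequence.
#' @examples
#' solubility_heuristic("EEEEE")  # good
#' solubility_heuristic("LLLLL")  # poor
#' @export
solubility_heuristic <- function(sequence) {
  vapply(sequence, function(s) {
    chars <- aa_chars(s)
    charged <- mean(chars %in% c("D", "E", "K", "R"))
    hydropathy <- mean(.aa_hydropathy[chars])
    if (charged >= 0.2 && hydropathy <= 0) "good" else "poor"
  }, character(1), USE.NAMES = FALSE)
}

#' Run the screening funnel
#'
#' Executes enumerate -> score -> reference filter -> length cap ->
#' per-candidate pose clustering and contact selection -> annotation, and
#' returns a candidate report plus per-stage counts and a reproducibility
#' manifest. Stage counts are non-increasing: each stage filters or
#' annotates, never adds.
#'
#' @param config A [funnel_config()].
#' @return List of class `funnel_result`: `report` (data frame with columns
#'   `peptide`, `parent_span`, `sequence`, `mass_Da`, `length`, `score`,
#'   `contacts`, `fraction_pct`, `occupancy`, `solubility_heuristic`,
#'   `selected`), `counts` (named per-stage sizes), `manifest`.
#' @export
run_funnel <- function(config) {
  stopifnot(inherits(config, "funnel_config"))
  counts <- c()
  log_stage <- function(stage, n) {
    counts[[stage]] <<- n
    message(sprintf("[funnel] %-16s %d candidates", stage, n))
  }
  library <- enumerate_subpeptides(config$parent, config$min_len,
                                   config$max_len)
  log_stage("library", nrow(library))
  spec <- calibrate_scorer(config$scorer, config$reference_sequence,
                           config$target_sequence)
  scored <- score_peptides(library, config$target_sequence, spec)
  accepted <- suppressMessages(
    filter_by_reference(scored, spec, mode = config$filter_mode))
  log_stage("score_accepted", nrow(accepted))
  capped <- length_cap(accepted, config$cap)
  log_stage("length_capped", nrow(capped))
  capped$contacts <- rep(NA_integer_, nrow(capped))
  capped$fraction_pct <- rep(NA_real_, nrow(capped))
  capped$occupancy <- rep(NA_integer_, nrow(capped))
  capped$selected <- rep(NA, nrow(capped))
  if (nrow(capped) == 0L) {
    warning("no candidates survive the filters; emitting an empty report")
  }
  for (id in intersect(names(config$poses), capped$peptide)) {
    ens <- config$poses[[id]]
    if (is.character(ens)) ens <- read_ensemble_pdb(ens)
    k <- min(config$k, n_poses(ens))
    clusters <- kmedoids_cluster(ens, k = k, seed = config$seed)
    sel <- select_candidates(ens, clusters,
                             cutoff_A = config$contact_cutoff_A,
                             fraction_threshold = config$fraction_threshold,
                             representative = config$representative)
    row <- capped$peptide == id
    capped$contacts[row] <- sel$contacts
    capped$fraction_pct[row] <- sel$fraction_pct
    capped$occupancy[row] <- sel$occupancy
    capped$selected[row] <- sel$selected && sel$occupancy_above_mean
  }
  log_stage("contact_selected", sum(capped$selected, na.rm = TRUE))
  report <- data.frame(
    peptide = capped$peptide,
    parent_span = sprintf("%d-%d", capped$parent_start, capped$parent_end),
    sequence = capped$sequence,
    mass_Da = round(capped$mass_Da, 2),
    length = capped$length,
    score = capped$score,
    contacts = capped$contacts,
    fraction_pct = capped$fraction_pct,
    occupancy = capped$occupancy,
    solubility_heuristic = if (config$solubility)
      solubility_heuristic(capped$sequence) else "unknown",
    selected = capped$selected
  )
  log_stage("soluble_flagged",
            sum(report$solubility_heuristic == "good" &
                  report$selected %in% TRUE))
  manifest <- list(
    parent = list(id = config$parent$id, length = config$parent$length,
                  numbering_offset = config$parent$numbering_offset),
    scorer = config$scorer$name,
    reference_score = spec$reference_score,
    min_len = config$min_len,
    max_len = if (is.finite(config$max_len)) config$max_len else "unbounded",
    cap = config$cap, k = config$k,
    contact_cutoff_A = config$contact_cutoff_A,
    fraction_threshold = config$fraction_threshold,
    filter_mode = config$filter_mode, seed = config$seed,
    package_version = as.character(utils::packageVersion("pepscreen")))
  structure(list(report = report, counts = unlist(counts),
                 manifest = manifest),
            class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("<funnel_result>\n")
  for (s in names(x$counts))
    cat(sprintf("  %-16s %d\n", s, x$counts[[s]]))
  invisible(x)
}
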