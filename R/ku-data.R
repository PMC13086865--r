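# Bundled reference data: the four Ku80-C-terminal-domain peptides (Ku1-Ku4)
# with their published sequences, spans and reported properties, plus a
# synthetic reconstruction of the 120-residue parent region they come from.

#' Published Ku peptide candidates
#'
#' The four Ku80-Ct-derived candidate peptides with their sequences, absolute
#' spans in Ku80 numbering and reported properties (mass, contacts, contact
#' fraction, cluster occupancy, solubility call). Two printed spans are
#' internally inconsistent with their sequences and are shipped alongside the
#' corrected spans (see the `printed_span` and `note` columns): Ku1 586-707
#' -> 686-707 and Ku4 607-635 -> 607-636. Ku1 was synthesised with its
#' terminal P replaced by G; `synthesized_sequence` and `reported_mass_Da`
#' refer to that variant.
#'
#' @return Data frame, one row per peptide.
#' @examples
#' ku <- ku_peptides()
#' ku$sequence[ku$peptide == "Ku3"]
#' @export
ku_peptides <- function() {
  utils::read.table(
    system.file("extdata", "ku_peptides.tsv", package = "pepscreen",
                mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, fill = TRUE,
    quote = "")
}

#' Synthetic Ku80-Ct parent region
#'
#' The full sequence of the Ku80 C-terminal region (residues 590-709) is not
#' bundled; this builds a synthetic stand-in by embedding the four published
#' peptide sequences at their (corrected) absolute spans — which mutually
#' agree on every overlap — and filling the remaining positions at random
#' under `seed`. All coordinate arithmetic on the embedded spans (e.g.
#' locating TKEEASG at 687-693, or mapping Ku3 position 14 to residue 689)
#' is exact; only the filler residues are synthetic.
#'
#' @param seed Integer seed for the filler residues.
#' @param region Absolute first/last residue (default `c(590, 709)`).
#' @return A [parent_protein()] with id `"Ku80-Ct-synthetic"`.
#' @export
synthetic_ku80ct <- function(seed = 1L, region = c(590L, 709L)) {
  ku <- ku_peptides()
  synthetic_parent_embed(
    data.frame(sequence = ku$sequence, parent_start = ku$parent_start),
    region = region, seed = seed, id = "Ku80-Ct-synthetic")
}
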