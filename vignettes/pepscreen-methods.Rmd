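---
title: "Methods: an in silico funnel for protein-derived inhibitory peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an in silico funnel for protein-derived inhibitory peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

## The screening funnel

`pepscreen` implements the computational side of a structure-based peptide
inhibitor screen. The motivating application is the search for endogenous-like
inhibitors of Endonuclease G (EndoG), a dimeric mitochondrial nuclease whose
sublethal nuclease activity at genomic fragile sites is pro-tumorigenic: the
C-terminal domain of human Ku80 (Ku80-Ct, roughly residues 590–709) resembles
the Drosophila EndoG inhibitor, so candidate peptides are carved out of that
region and evaluated against EndoG. The pipeline, however, is generic: any
parent region and any target sequence can be screened.

The funnel has five computational stages:

1. **Enumeration.** Every contiguous subpeptide of the parent region with at
   least `min_len` residues. For a region of length $L$ and minimum window
   $m$ the library size is $(L-m+1)(L-m+2)/2$; the default configuration
   ($L = 120$, $m = 21$) gives 5050 candidates. Published descriptions of
   such libraries sometimes mix "20 or more" with "more than 20" residues;
   both readings reproduce 5050 (a 119-residue region with $m = 20$
   enumerates the same window family shifted by one), and we anchor the
   default to the printed library size.
2. **Interaction scoring.** A pluggable scorer maps (peptide, target) to a
   dimensionless score; candidates are kept when they beat the score of a
   reference sequence (strictly by default). The shipped `"propensity"`
   scorer is a deterministic baseline — the mean of a documented 20×20
   residue-pair propensity table over all peptide–target residue pairs
   (see below). It is *not* a trained interaction predictor; externally
   trained models plug in through `register_scorer()`.
3. **Length cap.** Synthesis practicality: keep candidates of ≤ 30 residues
   (inclusive boundary).
4. **Docking post-processing.** Docking itself is an import boundary: the
   package consumes pose ensembles (multi-model PDB, or the synthetic
   generator). For each candidate, the $N$ poses are clustered into $k$
   groups by k-medoids on pairwise pose RMSD, and cluster representatives
   are subjected to Cα contact analysis against the receptor. A candidate
   passes when more than 50 % of its residues contact the receptor (Cα–Cα
   distance strictly below 10 Å) and the occupancy of its most populated
   cluster is strictly above the ensemble mean $N/k$.
5. **Annotation.** Mass, a labelled composition-based solubility heuristic,
   and a consolidated report with one row per candidate.

Downstream of the funnel, two analysis modules interrogate a winning
candidate: plurality-consensus motif extraction from substitution mutant
libraries, and geometric descriptor analysis of MD trajectories.

## Models and conventions

### Masses

Peptide masses are **average** (not monoisotopic) masses: the sum of standard
average residue masses plus one water (18.0153 Da) for free, unmodified
termini. This convention reproduces the published integer masses of the Ku
peptides (e.g. 2933 Da for the 28-mer Ku3 and 2253 Da for the
synthesis-variant Ku1 ending in G). Terminal modifications are ignored for
mass purposes.

### Coordinates

All residue coordinates are 1-based and spans are inclusive
("aa 676–703" is 28 residues). A `parent_protein` carries a
`numbering_offset` so that subpeptides report absolute parent coordinates:
position 14 of the peptide spanning 676–703 is parent residue 689. Two of
the four published Ku peptide spans are internally inconsistent with their
own sequences; the bundled fixture records both the printed and the
corrected spans, and all code uses the corrected ones (the corrections are
forced by the sequences themselves and by the published 18-residue
Ku1/Ku3 overlap anchored at residue 686).

### The baseline scorer

Entry $(a, b)$ of the propensity table is
$0.04\,h(a)h(b) - 0.5\,q(a)q(b)$, with $h$ the Kyte–Doolittle hydropathy
and $q$ the formal side-chain charge at neutral pH (His counted +0.5).
Hydrophobic–hydrophobic and oppositely charged pairs score positive,
like-charged pairs negative; the scale factors keep both terms of order
one. The score of a peptide against a target is the mean over all residue
pairs, hence deterministic, finite, and reproducible from the formula by
hand. Because published funnel counts (e.g. 5050 → 356 accepted) depend on
the original trained scorer, they are not reproduction targets for the
baseline; the package reproduces the *rules* (strict thresholding against a
configurable reference sequence), not a particular scorer's acceptances.
The reference sequence is exposed as a parameter rather than hard-wired,
since descriptions differ on whether the threshold object is the full
parent or its C-terminal region alone.

### Pose RMSD and clustering

Pose–pose RMSD is computed **in the common receptor frame without
superposition**: docked poses share the receptor's frame, and what
distinguishes binding modes is where on the receptor they sit, not the
peptide's internal conformation. (Superposed RMSD remains available through
the trajectory tools.) Clustering is PAM k-medoids (greedy build plus
best-improvement swap) on the precomputed distance matrix, delegated to
`cluster::pam`, which is deterministic for a fixed matrix; the seed is
recorded for provenance. The degenerate case $k = N$ is the identity
partition at zero cost. Ties for the most populated cluster resolve to the
lowest cluster id.

### Contact rules

All three selection comparisons are strict, following the wording they come
from: contact when Cα–Cα distance $< 10$ Å, selection when the contact
fraction $> 50\,\%$, occupancy rule when the top cluster holds $> N/k$
poses. Contact fractions are rounded to two decimals before the threshold
comparison, which reproduces the published four-row arithmetic exactly:
(22, 18) → 81.82 %, (26, 22) → 84.62 %, (28, 18) → 64.29 %,
(30, 18) → 60.00 %. Contact reports are computed on the cluster **medoid**
by default — the published analysis does not say which member represents a
cluster — with the lowest-energy member available as an option. When pose
energies are absent, the lowest-energy cluster is undefined and only the
occupancy rules apply.

### Consensus motifs

For an aligned library (substitution-only mutant libraries align columnwise
by construction; gapped MSAs from external aligners are read from FASTA or
Clustal files), a column's consensus residue is its plurality residue,
accepted when its count is **at least half** the rows (`>=`, threshold
configurable), the maximiser is unique, and it is not the gap symbol;
otherwise the column is the wildcard `x`. Ties at the maximum are
conservative (non-conserved): the source rule is silent on ties, and
emitting an arbitrary winner would overstate conservation. Gaps count
toward the denominator but can never be the consensus. This is a raw-count
plurality; alignment-engine consensus tools sometimes weight by a
substitution matrix, so the rule here is documented as an interpretation.
In `submotif_scan()`, a literal pattern residue only matches a conserved
motif character (the pattern's own `x` matches anything); otherwise short
literal patterns would spuriously match inside wildcard stretches.

### Mutant libraries

Each derivative differs from the reference by 1..`max_mutations`
substitutions: the count is uniform on that range (the source states only
the maximum, 10 in the published library of 100 000 derivatives of Ku3),
positions are sampled without replacement — optionally with per-position
weights, zero meaning "never mutate" — and the substitute is uniform over
the 19 alternatives. Members are deduplicated ("derivatives" read as
distinct sequences) and the generator errors when asked for more members
than the reachable sequence space holds. Indels are out of scope in the
generator; externally aligned gapped libraries are still accepted by the
consensus stage.

### MD descriptors

* **COM distance $d$**: Euclidean distance of mass-weighted centroids
  (standard atomic masses; geometric centroid as option).
* **Inter-chain angle $\theta$**: angle at a designated vertex Cα between
  two other designated Cα atoms, from the normalised dot product, clamped
  to $[0°, 180°]$. The convention that the **middle** listed atom is the
  vertex (for the EndoG dimer: chain A residue 214, with arms to A:95 and
  B:95) is a documented choice — listings of three atoms usually leave the
  vertex implicit.
* **Binding state**: bound when $d \le 45$ Å, unbound when $d > 50$ Å,
  intermediate in between. The thresholds are configurable; the explicit
  intermediate band exists because the source quantities ("$d \lessapprox
  45$", "$d > 50$") leave 45–50 Å undefined.
* **$d$–$\theta$ density**: uniform 2-D binning, default 151 × 151, counts
  conserved exactly.
* **Conformational clustering**: quality-threshold/leader clustering of
  frames — superpose all frames on the receptor Cα set first, then
  threshold peptide-backbone RMSD at 20 Å; repeatedly take the frame with
  the largest cutoff-neighbourhood (ties to the lowest frame index) as a
  cluster. Because neighbourhoods only shrink as frames are removed,
  cluster sizes are non-increasing in output order. Whether the original
  analysis aligned frames before peptide RMSD is unstated; receptor-Cα
  alignment is the documented default and can be disabled.
* **Contact lifetimes $\lambda$**: per residue pair between two chain
  groups, the fraction of analysed frames with minimum heavy-atom distance
  strictly below 5 Å; persistent when $\lambda \ge 0.5$. The analysis
  window defaults to the trailing 70 % of frames — mirroring the common
  practice of discarding the equilibration third of each replica — selected
  by fraction rather than absolute time because time-step metadata may be
  absent from coordinate-only trajectories.

Trajectory I/O is multi-model PDB or a plain per-frame coordinate table;
native binary trajectory formats are deliberately out of scope to avoid
engine coupling (converters are expected upstream).

## Synthetic generators: what they emulate and what they do not

The `make_*` generators produce the same containers the analysis stages
consume, with the planted truth returned alongside:

* `make_pose_blobs()` emulates a docked ensemble with cluster structure:
  poses are rigid translations of a Cα peptide template around
  well-separated anchor sites with Gaussian jitter. With zero spread,
  intra-cluster RMSD is exactly 0; with separation ≫ spread, k-medoids
  must recover the plant exactly (adjusted Rand index 1).
* `make_contact_pose()` plants an exact contact count: in-contact residues
  sit 3 Å inside the cutoff, the rest at least 2 Å outside, so the contact
  report is fully determined.
* `make_trajectory()` realises planted binding states (by placing the
  peptide COM at an exact distance from the receptor COM), planted angles
  (by constructing the three anchor atoms), and planted contact lifetimes
  (by toggling a contact residue frame-by-frame; the realised $\lambda$ is
  exact to $1/n_\mathrm{frames}$, measured over the full frame range).
* `synthetic_parent_embed()` reconstructs a parent region from published
  subpeptide spans, pinning every embedded residue and filling the rest
  randomly; overlapping embeddings must agree. The bundled
  `synthetic_ku80ct()` uses the four published Ku peptides, whose overlaps
  are mutually consistent, so all span arithmetic on the embedded residues
  is exact while the filler is synthetic.

These generators are scaffolds, not physics: geometry is minimal (Cα-only
chains, carbon masses), conformations are unphysical, and energies, when
planted, are labels rather than an energy function. Passing tests therefore
demonstrate that the *analysis* stages implement their rules correctly on
inputs with known truth — they do not validate docking accuracy, force
fields, or the biological activity of any candidate, and results on real
ensembles inherit whatever biases the upstream docking or simulation engine
has.

## Numerical choices and degenerate inputs

* Strict (`<`, `>`) versus inclusive (`<=`, `>=`) comparisons follow the
  wording of each rule and are covered by boundary tests: a fraction of
  exactly 50 % is not selected, an occupancy of exactly $N/k$ fails, a
  lifetime of exactly 0.5 is persistent, a mass cap of 30 keeps 30-mers,
  and `greater_equal` filtering keeps the reference itself.
* An enumeration request longer than the parent warns and returns an empty
  library; an empty post-filter funnel emits an empty report with a
  warning, not an error.
* All seeded generators restore the caller's RNG state, so they are pure
  functions of their seed argument.
* PDB round trips are exact to the format's three coordinate decimals.

## Problem sizes

The shipped test-suite and the acceptance script use the study-scale
ensemble where the bookkeeping is anchored (1000 poses, $k = 10$, mean
occupancy 100) and smaller seeded instances elsewhere (hundreds of poses,
mutant libraries of 400–2000 members, trajectories of 20–100 frames) —
sizes at which every planted-truth check is exact and the whole suite runs
in seconds on one CPU.

## Known limitations

* The baseline scorer is a composition heuristic; absolute acceptance
  counts are scorer-dependent and not comparable across scorers.
* The solubility flag is a two-parameter composition rule (charged fraction
  ≥ 0.2 and mean hydropathy ≤ 0), labelled `solubility_heuristic` in every
  output; it is not a structure- or ML-based predictor.
* Substitution-only mutant alignment cannot represent indels; use an
  external aligner and feed the MSA file in.
* Pose clustering assumes a rigid receptor shared by all poses.
* Trajectory parsing targets well-formed multi-model PDB; occupancy/altloc
  subtleties of experimental PDB files are out of scope.
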