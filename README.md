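# pepscreen

In silico screening of protein-derived inhibitory peptides.

`pepscreen` is for structural bioinformaticians who want to mine a parent
protein for peptide inhibitors of a target protein and need the whole
computational funnel — library enumeration, interaction-score filtering,
docking-pose post-processing, motif extraction, and trajectory descriptor
analysis — as tested, reusable R functions rather than a chain of one-off
scripts. The motivating system is the C-terminal domain of human Ku80
(Ku80-Ct, residues ~590–709), mined for peptides that inhibit Endonuclease G
(EndoG) the way the Drosophila inhibitor EndoGI does; every stage is generic
over parent and target.

## What it computes

* **Library**: all contiguous subpeptides of a parent region with
  `min_len <= length <= max_len`, with absolute parent coordinates. For a
  region of length *L* and minimum window *m* the library has
  (L−m+1)(L−m+2)/2 members — 5050 for the default 120-residue region with
  21-residue minimum.
* **Scoring**: a pluggable scorer registry with a deterministic baseline
  (mean pairwise residue propensity over a documented 20×20 table);
  candidates are kept when they beat a reference sequence's score.
* **Pose post-processing**: pairwise pose RMSD in the receptor frame,
  PAM k-medoids clustering with occupancy/energy bookkeeping, and Cα
  contact analysis. A candidate is selected when >50 % of its residues have
  a Cα within 10 Å of a receptor Cα in the representative pose of its top
  cluster, and that cluster's occupancy exceeds the ensemble mean N/k.
* **Consensus motifs**: plurality consensus over an aligned mutant library
  — a column is conserved when its top residue reaches at least half the
  rows — plus wildcard submotif scanning and position frequency matrices.
* **MD descriptors**: centre-of-mass distance *d*, inter-chain angle *θ*
  (vertex = middle designated Cα), bound/intermediate/unbound
  classification (d ≤ 45 Å / 45–50 / > 50), 151×151 d–θ density grids,
  quality-threshold conformational clustering (20 Å backbone-RMSD cutoff),
  and residue-pair contact lifetimes (λ = fraction of analysed frames with
  min heavy-atom distance < 5 Å; persistent when λ ≥ 0.5).
* **Synthetic generators**: seeded pose ensembles, contact plants,
  trajectories and mutant libraries with planted ground truth, standing in
  for the docking/MD engines so the pipeline runs and is testable offline.

See `vignettes/pepscreen-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(pepscreen)

# a synthetic Ku80-Ct parent: the four published Ku peptides embedded at
# their absolute spans, random filler elsewhere
parent <- synthetic_ku80ct(seed = 1)
#> <parent_protein> Ku80-Ct-synthetic: 120 aa, absolute numbering 590-709

nrow(enumerate_subpeptides(parent, min_len = 21))
#> [1] 5050

ku3 <- peptide_from_span(parent, 676, 703)
ku3$sequence                       # "EIVVQDGITLITKEEASGSSVTAEEAKK"
round(ku3$mass_Da)                 # 2933
map_to_parent(ku3, c(6, 14, 27))   # 681 689 702
find_motif(ku3, "TKEEASG")
#>   pos parent_index
#> 1  12          687

# pose ensemble with 10 planted sites, clustered back into 10 groups
blobs <- make_pose_blobs(n_poses = 1000, n_clusters = 10, spread_A = 1,
                         separation_A = 30, seed = 42)
kmedoids_cluster(blobs$ensemble, k = 10, seed = 1)
#> <cluster_set> k = 10, N = 1000 (mean occupancy 100.0)
#> occupancies: 111 95 96 123 89 102 99 89 101 95
#> most populated: 4

# contact analysis of a pose with 18 of 28 residues planted in range
contact_analysis(make_contact_pose(length = 28, planted_contacts = 18))
#> <contact_report> 18 / 28 residues within 10 A (64.29%) -> selected

# consensus over 400 Ku3 derivatives in which positions 14 and 27 are
# protected and everything else mutates freely
mut <- generate_mutants(ku3$sequence, n = 400, max_mutations = 26, seed = 7,
                        p_position = replace(rep(1, 28), c(14, 27), 0))
consensus_from_alignment(mut)
#> <consensus_motif> xxxxxxxxxxxxxExxxxxxxxxxxxKx (2/28 columns conserved, threshold 0.5)
```

The cluster occupancies sum to 1000 with mean 100; the contact report shows
the 64.29 % fraction that makes a 28-mer with 18 contact residues a selected
candidate; and the consensus recovers exactly the two protected positions
(E14, K27 — parent residues 689 and 702) as conserved.

`run_funnel(funnel_config(...))` chains the stages (enumerate → score →
filter → cap → cluster → contact-select → annotate) and returns the
candidate report, per-stage counts and a reproducibility manifest.

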