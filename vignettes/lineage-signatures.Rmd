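---
title: "Detecting lineage-specific evolutionary signatures with lineagescan"
author: "lineagescan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific evolutionary signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagescan)
```

# Scope

`lineagescan` implements five analyses that together characterize what is
evolutionarily special about one clade (the *focal lineage*) against a set
of outgroup species:

1. **LSG scanning** — substitutions fixed in every focal species and absent
   from all outgroups, validated by marginal ancestral-state reconstruction;
2. **SCNE calling** — noncoding elements conserved across most focal
   species but absent (or unconserved) in outgroups, from reference-anchored
   whole-genome alignment blocks;
3. **branch-model selection tests** — GY94 codon-model fits with a
   foreground-specific dN/dS (ω0) versus background (ω1) and whole-tree (ω2)
   ratios, classified into positively selected (PSG), rapidly evolving
   (REG), or not significant (NS);
4. **relative-rate tests** — Tajima's χ²(1) test per sequence pair with an
   outgroup, and a two-cluster Z test between taxon groups;
5. **k-mer genome-size estimation** — `G = K_num / K_depth` from a 17-mer
   depth histogram.

Every analysis has a paired simulator with known ground truth, so the whole
pipeline is testable end to end without any external data.

# Data model

Alignments are `LineageAlignment` objects (a character matrix with an
alphabet tag; codon alignments store one in-frame codon per cell over the
61 sense codons of the universal code). Trees are `ape::phylo`; intervals
are `GenomicRanges::GRanges` (1-based closed internally, converted to/from
BED's 0-based half-open convention only at the I/O boundary); MAF blocks
are `AlignmentBlock` objects whose per-row coordinates are always stored as
forward-strand 0-based starts. The `LineagePartition` fixes the focal /
outgroup split that every scan conditions on; taxa outside the partition
are allowed and, importantly, still inform ancestral-state reconstruction.

# LSG scanning and ancestral validation

A column is a candidate lineage-specific substitution when all focal rows
share one unambiguous state, at least `minOutgroupPresent` (default 2)
outgroup rows align a residue there, and none of them matches the focal
state. Two policies deserve comment:

* **Outgroup polymorphism is allowed.** The definition requires the focal
  state to be absent from the outgroups, not that the outgroups agree among
  themselves. `outgroupMonomorphic = TRUE` tightens this.
* **Gap policy.** A focal gap disqualifies the column outright; outgroup
  gaps merely reduce the effective outgroup count. The default
  `minOutgroupPresent = 2` avoids calls supported by a single outgroup row.

Validation asks where the substitution happened. `ancestralMarginal()`
computes, per internal node and column, the marginal posterior over states
by the inside–outside form of Felsenstein pruning under an equal-rate model
(20-state Poisson for amino acids, Jukes–Cantor for nucleotides) with a
uniform root prior. A hit is *confirmed* when the MAP state of the focal
clade's MRCA equals the focal state while the MAP state of the MRCA's
parent does not — i.e. the change maps onto the focal stem branch. The
equal-rate model is deliberately simple: only MAP states are consumed, and
at the divergences where fixed differences are scannable the argmax is
insensitive to the exchangeability details. MAP ties break toward the
lexicographically smallest symbol so results are deterministic. If the
input tree has no branch lengths they are estimated by least squares
(`phangorn::nnls.tree`) on multiple-hit-corrected p-distances.

```{r lsg}
sim <- simulateTree(nFocal = 4, nOutgroup = 3, branchScale = 0.1, seed = 1)
aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
set.seed(2)
row <- sample(aas, 120, replace = TRUE)
aln <- LineageAlignment(matrix(rep(row, each = 7), nrow = 7,
                        dimnames = list(sim$tree$tip.label, NULL)),
                        "amino_acid")
pl <- plantLsg(aln, sim$partition, nSites = 3, seed = 3)
hits <- scanLsg(pl$alignment, sim$partition)
recon <- ancestralMarginal(pl$alignment, sim$tree, "poisson_aa")
validateLsg(hits, recon, sim$tree, sim$partition)[, -1]
```

# SCNE calling

`computeTracks()` turns each reference-anchored block into per-site arrays:
for every gap-free reference position, the number of focal (and outgroup)
rows aligning a real base, and the mean pairwise identity within each
group. Mean pairwise identity was chosen as the similarity statistic
because it is the simplest per-site score bounded in [0, 1] that reduces to
1 for perfect conservation; "present" means an aligned A/C/G/T, which is
the most literal reading of presence/absence calling on genome alignments.

`callElements()` then takes maximal runs of qualifying sites. The defaults
encode the rule set this workflow is built around: at least
`minPresent = 9` focal species ("more than eight"), elements shorter than
`minLen = 20` bp removed, and strict contiguity (`maxJoinGap = 0`). The
focal similarity threshold (`tauFocal = 0.8`) has no community-standard
value; it is this package's own default, exposed as a parameter and meant
to be reported alongside any element set.

Two outgroup modes exist. `"absent"` (default) requires that *no* outgroup
row aligns a base, the strict absence rule. `"low_similarity"` instead
accepts sites where outgroups align but do not agree among themselves
(similarity ≤ `tauOutgroup = 0.5`); this matches alignments where the
flanks recruit outgroup sequence without the element being conserved. A
caveat discovered in simulation: with only a handful of outgroup rows,
*random* bases agree by chance often enough (e.g. all three of three rows
identical at 1/16 of sites) that strict contiguity fragments real
elements; with `"low_similarity"` mode a small `maxJoinGap` (1–2 bp) is
recommended, at the cost of slightly softer boundaries. Under `"absent"`
mode boundaries are exact to within ~2 bp in our recovery simulations.

`subtractMask()` clips called elements against a CDS mask (BED/GFF) and
re-filters by length, which enforces the "noncoding" part of the
definition.

```{r cne}
part <- LineagePartition(paste0("f", 1:10), paste0("o", 1:3))
sim <- simulateCneRegion(part, regionLen = 600,
                         elements = data.frame(start = 120, len = 35,
                                               mode = "outgroup_absent"),
                         seed = 4)
track <- computeTracks(sim$blocks, part)
callElements(track)
```

The generator plants elements as near-identical focal copies (per-row,
per-site divergence 0.005, i.e. ≈ 99% within-clade identity — typical of
deeply conserved regulatory elements) on a background where every
non-reference row diverges at 0.3 per site. It emulates presence/absence
and conservation structure only: there are no indels within rows, no
alignment error, and the focal species are conditionally independent given
the reference rather than phylogenetically correlated, so passing recovery
tests demonstrates the correctness of the caller's rule set, not robustness
to alignment artifacts in real genome alignments.

# Branch-model selection tests

The GY94 codon model assigns rate `π_j · κ^[transition] · ω^[nonsynonymous]`
to single-nucleotide codon changes, zero otherwise, scaled to one expected
substitution per unit branch length. Likelihoods come from Felsenstein
pruning over the 61 sense codons (C++ core), with gap/ambiguous codons as
missing data. Codon frequencies are F3×4 by default (per-position
nucleotide composition, floored at 1e-6 so the spectral decomposition of
the reversible generator is always defined), or equal, or user-supplied.

`fitM0()` maximizes over (κ, ω, branch-length scale); `fitBranchModel()`
over (κ, ω0, ω1, scale) with the foreground set = focal clade plus its stem
branch. Branch-length *proportions* come from the input species tree; only
a single global scale is re-optimized per gene, which keeps per-gene fits
fast and stable at the cost of assuming the relative branch lengths are
right. Optimization is bounded L-BFGS-B on log-parameters from a
deterministic start grid (κ ∈ {1,2,4} × ω ∈ {0.1,0.5,1.5}; the best two
grid points are polished); the two-ratio fit starts from the M0 optimum
(plus ±4-fold ω0 perturbations), which guarantees the nesting inequality
`lnL_branch ≥ lnL_M0` numerically, not just asymptotically.

`classifySelection()` applies a 1-df likelihood-ratio test of two-ratio vs
one-ratio. PSG requires p < α, ω0 > max(ω1, ω2), and ω0 > 1; REG the same
with ω0 ≤ 1; otherwise NS. Two conventions are package choices: the
question "is ω0 significantly higher than ω1 and ω2?" is operationalized
as the standard nested LRT plus the point-estimate ordering, and ω0 > 1 is
the conventional positive-selection boundary separating PSG from REG. Note that the ordering
condition makes the *classifier* conservative under the null by
construction (about α/2 of null genes are called), so calibration is
checked on the LRT p-value itself.

The simulator draws the root from the equilibrium frequencies and evolves
sites independently with exact `exp(Qt)` transition sampling per branch —
it shares the generator construction with the likelihood code but not the
pruning path, and stop codons are structurally impossible. In our
calibration runs (one fixed 8-taxon tree, 500 codons, 200 null replicates)
the LRT rejection rate at α = 0.05 stays inside the exact binomial band,
and the median ω0 over 20 replicates at 2,000 codons recovers a simulated
ω_fg = 2.0 within 20%.

# Relative-rate tests

`tajimaRRT()` counts, over columns where all three rows are unambiguous,
`m1` (sites unique to lineage 1) and `m2` (unique to lineage 2), and uses
the canonical χ²(1) form `(m1 − m2)² / (m1 + m2)`. Columns where all three
states differ belong to neither count. `m1 + m2 = 0` yields χ² = 0, p = 1,
flagged "no informative sites".

`twoClusterTest()` compares mean cluster-to-outgroup distances. The
standard error comes from a site bootstrap (columns resampled with
replacement, default `nBoot = 1000`, seeded and recorded in the output)
rather than an analytic variance — model-free, and honest about the
between-site dependence actually present in the data resampling unit.
Distances are p-distances by default; the Poisson correction
`d = −ln(1 − p)` is available for amino-acid data and refuses saturated
pairs. Concatenating genes before testing mirrors the common "all
single-copy genes" usage.

# Genome size

`estimateGenomeSize()` applies `G = K_num / K_depth` with `K_num` the total
k-mer count summed over *all* depths (the literal "total number of
k-mers") and `K_depth` the modal depth at or above `minDepth = 5`, ties
broken toward larger depth (heterozygosity shoulders sit below the main
peak). `excludeErrors = TRUE` drops sub-cutoff depths from `K_num`; with an
error spike present the default overestimates G by the spike's share of
`K_num`, which the flag removes.

One numerical fact worth knowing: at integer coverage *c* the Poisson depth
law has a two-point mode (`pmf(c−1) = pmf(c)`), so the empirical argmax
falls on either side in about half of histograms and the estimate carries
an irreducible ±1/(c−1) relative wobble (≈5% at 20×, ≈1.7% at 60×). Means
over replicates, and estimates at higher coverage, are well inside 5%.

```{r gsize}
h <- simulateKmerHistogram(G = 1e6, coverage = 30, seed = 5)
estimateGenomeSize(h)
```

# Problem sizes used in the shipped checks

The shipped acceptance checks run: brute-force oracle comparisons on 2- and
4-leaf trees; 20 seeds × 10 genes × 50 planted substitutions for the LSG
scan; 20 seeds × 3 planted elements for SCNE calling; 200 null replicates
(8 taxa, 500 codons) plus 20 recovery replicates (2,000 codons) for the
selection LRT; 1,000 / 200 equal-rate replicates for the Tajima and
two-cluster sizes; and 20 histograms at each of 20×/30×/60× for genome
size. These sizes were chosen to make Monte-Carlo acceptance bands tight
relative to the properties being asserted while keeping a full run in the
tens of minutes on a laptop core.

# Known limitations

* No indel model anywhere: gaps are treated as missing data, never as
  characters.
* The ancestral-state model is equal-rate; empirical exchangeabilities
  (WAG/LG) would sharpen posteriors but are unnecessary for MAP-based
  validation at these divergences.
* Branch lengths are rescaled, not re-estimated, per gene in the selection
  fits.
* The SCNE caller works block by block; elements spanning block boundaries
  are not stitched.
* Site models and branch-site models (positive selection at a site subset)
  are out of scope; the branch model averages ω over sites.
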