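---
title: "Dissecting long-branch attraction with occupancy-by-pruning grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting long-branch attraction with occupancy-by-pruning grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbagrid)
```

## The problem

Long-branch attraction (LBA) is the systematic error by which fast-evolving
lineages are grouped together regardless of their true relationships.  It is
most damaging where short, ancient internodes meet strong rate heterogeneity
among lineages — the regime of the chelicerate backbone, where the placement
of pseudoscorpions has oscillated between a position next to scorpions
(supported by rare genomic changes) and a position among the fast-evolving
acarine orders (the LBA artifact).  `lbagrid` packages the machinery needed
to dissect such a problem: systematic variation of gene occupancy and taxon
sampling over a grid of supermatrices, gene-wise likelihood signal
($\Delta$GLS), evolutionary-rate binning, sister-group classification,
and, as an independent arbiter, rare-genomic-change analyses (ancestral-state
parsimony and gene-tree/species-tree reconciliation for shared whole-genome
duplications).

Everything is exercisable end to end on synthetic data: the package contains
a forward simulator that generates clade-structured LBA scenarios with known
truth, so every stage of the pipeline is testable without any sequence
download.

## The supermatrix grid

The design layer mirrors a taxon-occupancy sensitivity experiment:

* **Occupancy families** `G1..G6` retain loci whose *gene occupancy* (the
  fraction of the full taxon set represented by at least one unambiguous
  residue) meets thresholds of 80% down to 55%.  `G1` is the densest and
  shortest matrix.  A taxon padded entirely with gaps or `X` does not count
  towards occupancy, so padding can never inflate completeness.
* **Taxon subsets** `T0, T-1, ..., T-k` remove declared basally branching
  subgroups of the focal clade one step at a time, with the step sequence
  declared by the user — detecting "basal" lineages automatically is a
  non-goal.  Occupancy filtering precedes pruning and is *not* re-applied
  afterwards, so a family keeps its locus count along the whole series; loci
  left with fewer than four taxa are flagged untreeable but retained.
* The reference design shipped with the package
  (`chelicerate_design()`, `chelicerate_plan()`) encodes a 132-terminal
  census (117 ingroup + 15 outgroup), a six-step pruning series that ends
  with the 12 exemplars of the most densely sampled focal superfamily, the
  6 x 7 = 42-matrix grid, and the full 189-analysis enumeration (two
  grid-wide methods, site-heterogeneous runs on the densest and largest
  families, and rate-tertile runs on the two mid-occupancy families).

```{r design}
plan <- chelicerate_plan()
plan$n_analyses
table(plan$plan$method)
```

## Evolutionary-rate binning

Loci are binned by mean pairwise sequence identity (MPSI): the mean over all
sequence pairs of the proportion of identical residues among columns where
both sequences carry an unambiguous residue.  High identity indicates slow
evolution, so loci sorted by decreasing MPSI are split into `slow`,
`intermediate` and `fast` tertiles.  Where the published procedure is silent
we fixed the conventions ourselves and treat them as part of the method:
tertile sizes differ by at most one with remainders assigned slow-first, and
MPSI ties break lexicographically by locus id, so the binning is
deterministic.

## The likelihood engine

Gene-wise signal requires per-gene likelihoods under fixed topologies, so the
package carries a self-contained amino-acid engine:

* **Models.** General time-reversible rate matrices
  $Q_{ij} \propto S_{ij}\pi_j$, normalised to one expected substitution
  per unit branch length.  LG, WAG and JTT exchangeabilities and frequencies
  are taken from the installed `phangorn`; the equal-rates Poisson model is
  computed.  Among-site rate variation uses the standard discrete-gamma
  approximation: $k$ equal-probability categories (default 4)
  represented by their means, computed in closed form so they average
  exactly 1.
* **Likelihood.** Felsenstein pruning over site patterns, with per-node
  rescaling of partial likelihoods (required beyond a few dozen taxa) and
  `-` / `X` treated as fully ambiguous states.  Sites of zero likelihood
  (possible only with zero-length branches) are floored at a per-site
  log-likelihood of -745 and flagged, keeping sums finite while surfacing
  the pathology.
* **Branch lengths.** Coordinate-wise bracketed search per branch on
  $[10^{-8}, 20]$.  Each sweep first re-optimises all branches against
  partials cached at the sweep start; if the joint update does not improve
  the log-likelihood the sweep is redone branch-by-branch with fresh
  partials, which is exact coordinate ascent, so the log-likelihood is
  non-decreasing across sweeps.  Sweeps stop when the gain drops below
  1e-4.
* **Model choice.** BIC with $p$ = number of branches (+1 for the gamma
  shape) and $n$ = alignment columns, ties broken by candidate order.
* **Search.** Neighbor joining on Poisson-corrected (20-state) distances
  gives starting trees; hill climbing over nearest-neighbour interchanges
  re-optimises branch lengths for the best candidate and accepts it only if
  it improves the log-likelihood.  Saturated distances (mismatch proportion
  $\ge 19/20$) are capped at 20 and flagged.  Support values come from a
  plain nonparametric site bootstrap (resample columns, re-run NJ + NNI,
  count bipartitions); ultrafast bootstrap and site-heterogeneous mixture
  models are out of scope, and trees from such external analyses are
  consumed as Newick.

The engine is verified against independent oracles rather than against
itself: exhaustive enumeration of interior-state assignments on small trees,
the closed-form 20-state Poisson distance, Chapman–Kolmogorov consistency of
the transition matrices, and quadrature for the discrete-gamma means.

## $\Delta$GLS

For a gene $g$ and two competing placements $T_1, T_2$,
$$\Delta GLS(g) = \ln L(g \mid T_1) - \ln L(g \mid T_2).$$
Each constraint topology is pruned to the taxa present in the gene
(suppressing degree-2 nodes and summing branch lengths), the model is chosen
per gene by BIC, and branch lengths are re-optimised on each pruned
topology — the statistic's standard construction, stated here because it is
easy to get silently wrong.  A gene whose surviving taxa cannot distinguish
the two hypotheses (the pruned topologies share all splits) has
$\Delta GLS = 0$ exactly; genes with fewer than four usable taxa on
either side are skipped and flagged rather than guessed.

## Sister-group classification

`classify_sister()` reproduces the read-off behind occupancy-by-pruning
sensitivity plots.  The tree is rooted on the outgroup (on the first
outgroup leaf, loudly flagged, if the outgroup is not monophyletic — a
situation synthetic data can produce even though curated empirical trees
rarely do).  If the focal leaves are not monophyletic the cell is
"non-monophyletic"; otherwise the sister group is the leaf set of the focal
clade's sibling, named by the unique group covering it, by a composite
"A+B" label when exactly covered by a union of groups, or "other".  Nested
hypotheses are respected downstream: `placement_matches()` lets a sister
assignment to a nested group count towards an enclosing hypothesis.
Supports for absent clades are reported as 0 and flagged "not recovered".

## The synthetic LBA scenario

`lba_scenario()` builds a 24-taxon true tree with the structure of the
chelicerate problem: a focal clade of 8 (three basally branching
short-branch subgroups of two tips plus a fast-evolving derived pair), a
short-branch true sister clade of 4, an unrelated fast-evolving attractor
clade of 4, and 8 outgroup/other tips.  Long lineages are created purely by
multiplying branch lengths (6x on the derived and attractor stems and tips);
rate is therefore the only LBA mechanism — no compositional bias, no
heterotachy, no indels (gaps arise only from taxon dropout).  Loci get
independent mean-1 gamma rate multipliers (shape 1.0), lengths of 150–400
sites, and 25% per-taxon dropout; 300 loci per replicate.

The base branch lengths (0.05 internal, 0.06 short tips) are the package's
own calibration, fixed by pilot simulation so the scenario has the geometry
it is defined to have: the pruned-most variant (focal clade reduced to the
derived pair) sits inside the parsimony-inconsistent Felsenstein zone,
while the fully sampled tree is recoverable.  Without the second property
the scenario could not display a sampling *rescue*; without the first it
could not display the artifact.  The quartet generator
(`felsenstein_zone_quartet()`) exposes the same construction in its minimal
four-taxon form.

Grid-scale experiments (`lba_misplacement_rates()`,
`lba_sensitivity_grid()`) run inference on a reduced representative taxon
set — the complete focal clade plus two tips per peripheral clade — and
simulate directly on the correspondingly pruned true tree, which is
distributionally identical to simulating the full tree and discarding rows
(a marginal of a Markov process on a tree is the process on the restricted
tree).  Inference uses Fitch parsimony, the classic LBA-susceptible method,
so that the grid displays the artifact rather than averaging it away.

What passing these tests shows — and what it does not: the synthetic
scenario demonstrates that the pipeline detects a sampling-dependent
category flip when one exists, with all nuisance features (alignment error,
compositional heterogeneity, paralogy, missing-data structure beyond
uniform dropout) absent.  It calibrates the machinery, not the biology.

## Rare genomic changes

* **Ancestral states.** `fitch_length()` is the standard downpass;
  `acctran()`/`deltran()` resolve among the equally parsimonious
  reconstructions via a minimum-cost (Sankoff) downpass and a preorder
  traceback whose tie-breaks either change away from the parental state as
  early as possible (ACCTRAN) or retain it as long as possible (DELTRAN).
  Both provably attain the Fitch minimum; the test suite checks them
  against exhaustive enumeration of all minimum-length reconstructions.
  Root states resolve by the declared outgroup.  The shipped order-level
  fixture codes the courtship dance (*promenade à deux*), brood care and
  book lungs at order granularity — the courtship dance is coded present
  for the pseudoscorpion tip even though only one superfamily retains it,
  because that is the granularity at which the two equally parsimonious
  scenarios (early gain with a spider loss vs. independent gains in the
  two pedipalp-clasping clades) become checkable.
* **Reconciliation.** `lca_reconcile()` maps each gene-tree node to the
  most recent common ancestor of its species; a node mapping onto the same
  species node as one of its children is a duplication.
  `shared_duplication()` separates duplications shared by a clade (mapped
  at or above the clade's ancestor with both child subtrees represented)
  from lineage-specific in-paralogs.  Gene trees must arrive rooted;
  auto-rooting a reconciliation input would silently change the event map,
  so unrooted input is rejected.
* **Paralog screening.** Two candidate peptides are separate copies only
  when their alignment overlap exceeds 100 residues *and* shows at least
  two substitutions ("multiple substitutions" read literally as $\ge$
  2); near-identical pairs merge as alleles and non-overlapping fragments
  merge as parts of one copy, with the copy number given by connected
  components — invariant to input order.  Motif filtering
  (`motif_filter()`, default `ELEKEF`/`KIWFQN`) retains peptides containing
  every required motif exactly.  Upstream homology search and RNA
  secondary-structure validation are out of scope; the package consumes
  candidate peptides and copy-count tables.

## Numerical and design choices

* Transition matrices come from the symmetric eigendecomposition of the
  reversible rate matrix (entries clipped to $[0,1]$); partial
  likelihoods are rescaled per node when they drop below 1e-80.
* Branch-length search tolerance 1e-9 absolute within a branch, 1e-4
  log-likelihood per sweep across branches, at most 50 sweeps; NNI accepts
  a swap only above a 1e-3 gain.
* All stochastic functions take explicit integer seeds; identical seeds
  give byte-identical locus sets.
* Subgroup labels in the pruning series match case-sensitively after
  whitespace trimming — fuzzy matching would hide registry errors.
* Problem sizes used by the automated checks: the engine oracle runs 200
  random trees of 3–5 leaves at 3 sites; the $\Delta$GLS experiment
  uses 200 loci on a 13-taxon reduction of the scenario; misplacement
  rates use 50 replicates of 300 loci on the representative set; the
  sensitivity grid runs one replicate over 6 occupancy families and the
  4-subset series.  These sizes are the package's chosen desk-scale
  demonstration conditions.

## Known limitations

* One substitution model per alignment: the concatenated fits are not
  per-partition, which is an acknowledged simplification of partitioned
  analyses (per-gene models do apply in $\Delta$GLS, where each gene is
  fitted separately).
* The NNI hill climber is a local search; at desk scale it is verified
  against exhaustive topology enumeration, but it is not a replacement for
  a production tree-search program.
* The simulator omits alignment error, compositional bias, heterotachy and
  indels by design; conclusions about those failure modes are out of reach
  of this package's tests.
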