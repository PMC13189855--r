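---
title: "Quality assessment of protein-RNA complex models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of protein-RNA complex models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
conventions it fixes where the field leaves room, and what its synthetic
experiments do and do not demonstrate.

## The problem

Estimation of model accuracy (EMA) for protein–RNA complexes: given one
structural model of a complex, predict several complementary quality scores
— how native-like the overall fold is, how native-like the protein–RNA
interface is, and how good each individual protein–RNA interface is — with
no access to the native structure at prediction time. The predictions are
used to *rank* candidate models and *select* the best few, so the
evaluation statistics of interest are ranking statistics (ranking loss,
top-k quality, quantile-based selection rates), not just correlations.

## Graph encoding

A model is parsed into a residue-typed atom table (`read_structure()`:
PDB/mmCIF via bio3d; waters, ligands, hydrogens dropped; alternate
locations resolved to the highest occupancy, ties to file order; DNA and
unclassifiable chains rejected; common modified residues mapped to parents
through a configurable alias table, e.g. MSE→MET, PSU→U).

Nodes are residues. An edge joins two residues when their **anchor atoms**
(Cβ, Cα for glycine or when the side chain is missing; C3′ for nucleotides)
are within **14 Å**, or when **any heavy-atom pair is within 6 Å**. The
same 6 Å heavy-atom rule against chains of the opposite polymer type
defines **interface residues**, and a (protein chain, RNA chain) pair with
at least one such contact is an enumerated **interface**. All distance
rules use heavy atoms only: hydrogens are usually absent from predicted
models, and placing them would inject modeling assumptions into a
measurement.

### Node features (66 channels)

The exact per-block composition is a versioned convention of this package
(`feature_layout()`, version `carpqa-layout-1`): amino-acid one-hot (20),
nucleotide one-hot (4), unknown flag (1), polymer indicator (1), interface
indicator (1), center-of-mass geometry (4), annotated secondary structure
8-state (8), annotated relative solvent accessibility (1), φ/ψ sin/cos (4),
predicted 3-state secondary structure (3), predicted RSA (1), predicted
φ/ψ sin/cos (4), η/θ sin/cos (4), base-pair flags (canonical,
non-canonical, paired; 3), RNA element one-hot (stem, hairpin, interior,
multiloop, exterior; 5), validity mask + spare (2). Every angle enters as a
sin/cos pair; undefined torsions encode as (0, 0) with the validity mask
cleared, so no NaN ever reaches the network.

*Annotated* channels come from internal annotators:

* **Secondary structure** — a simplified 8-state DSSP-style assigner. The
  amide hydrogen is rebuilt from backbone geometry and the Kabsch–Sander
  electrostatic energy `E = 0.084·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)·332`
  kcal/mol defines a hydrogen bond at `E < −0.5`; helices (H/G/I) come from
  consecutive 4/3/5-turns, strands (E) and isolated bridges (B) from
  Kabsch–Sander bridge patterns, turns (T) from any n-turn, bends (S) from
  a Cα kink > 70°. Chains under 4 residues are all '-'. This reproduces
  the canonical states without the full DSSP edge-case machinery.
* **Solvent accessibility** — Shrake–Rupley SASA (probe 1.4 Å, 144
  deterministic Fibonacci sphere points per atom; at this sampling,
  doubling the point count moves no residue's RSA by more than ~0.03),
  normalized by Tien et al. theoretical maxima for amino acids and by a
  per-nucleotide maximum computed once from an extended trinucleotide and
  cached, clipped to [0, 1].
* **Base pairs** — geometric detection: complementary bases (A-U, G-C,
  G-U) with purine-N1/pyrimidine-N3 distance ≤ 3.5 Å and base-plane
  normals within 30° are canonical; any other base–base ring-atom contact
  ≤ 3.5 Å is non-canonical. Sequence-adjacent residues of a chain are
  excluded (stacking neighbors are not pairs).
* **RNA elements** — the pair list is reduced to its maximum non-crossing
  subset (Nussinov-style dynamic program over the given candidate pairs)
  and residues are labeled stem / hairpin / interior / multiloop /
  exterior by the branch count of their innermost enclosing pair.
  Pseudoknots are deliberately out of scope: crossing pairs lose.
* **Center-of-mass geometry** — distance and angle from each residue's
  anchor to the mass-weighted center of the complex and of its own chain.
  "Angle to a center of mass" is under-specified without an orientation
  convention; we fix the residue orientation vector as Cα→Cβ (Cα→C for
  glycine) and C3′→C1′ for nucleotides, and measure the angle at the
  anchor against the anchor→COM direction. Degenerate vectors flag the
  angle as 0.

*Predicted* channels come from **provider tables**
(`feature_providers()`): per-protein-residue 3-state secondary structure,
RSA and φ/ψ; per-protein-pair predicted distance and two angles;
per-RNA-pair pairing probability. Providers stand in for external
sequence-based predictors; absent providers zero-fill their channels, so
the package is fully self-contained while remaining pluggable.

### Edge features (12 channels)

Minimum heavy-atom distance, anchor–anchor distance, two orientation
angles (each endpoint's orientation vector against the anchor–anchor
axis — these two channels swap between the two directed arcs of an edge),
predicted intra-protein distance and two angles (provider), annotated RNA
pair flag, predicted RNA pairing probability, inter-chain indicator,
protein–RNA indicator, and one spare channel reserved by the layout.
Distances are squashed to [0, 1) by `d/(d + d₀)` with d₀ at the relevant
cutoff scale; angles scale by 1/180.

## The network

Three components, each followed by learned top-k pooling
(`carp_config()`, `init_carp()`, `carp_forward()`):

1. **GPS-style block**: full multi-head self-attention over all node
   embeddings (every node attends to every node — intentionally the first
   and only all-pairs stage, before any node is dropped) in parallel with
   a GINE-style edge-conditioned neighborhood aggregation; the two
   branches and a residual are summed.
2. **TransformerConv**: attention-weighted message passing along the
   surviving edges, with edge features entering both keys and values.
3. **Edge pruning + TransformerConv**: all arcs not connecting a protein
   node to an RNA node are deleted, then a second TransformerConv runs on
   the pruned graph — an explicit inductive bias toward protein–RNA
   interface structure.

GraphNorm (per-graph feature normalization with learned scale/shift) and
ReLU follow each component. Top-k pooling scores nodes with a learned
vector, keeps the `ceiling(ratio·N)` best, gates survivors by tanh of
their score, and breaks ties by original node index so the forward pass is
deterministic. Three global-attention-pooling heads read the final node
embeddings concatenated with the *raw* interface and polymer indicator
channels: a fold head (3 sigmoid outputs), an interface head (3), and a
per-interface head applied once per enumerated interface with its
attention restricted to that interface's chain-pair nodes (2 outputs
each). If pooling has removed every node of an interface, the
per-interface head falls back to the component's pre-pooling embeddings,
and failing that to the embedded input — logged, and rare at keep-ratios
≥ 0.5.

Our resolution of two points the architecture description leaves open:
the per-interface readout masks attention to the interface's chain pair
(rather than re-weighting all nodes), and indicator concatenation uses the
raw 0/1 indicators. Hidden size, head count, pooling ratios and dropout
are configuration keys; the defaults (hidden 64, 4 heads, ratio 0.8,
dropout 0.1) are sized for CPU use, and the test-suite experiments run an
even smaller configuration (hidden 16, 2 heads, dropout 0.05).

The whole network and its training are implemented on a small
reverse-mode autodiff tape (`R/autograd.R`); every backward rule is
finite-difference-checked in the test suite.

**Combined scores** (`carp_scores()`): CARP-Fold = mean(F⁰,F¹,F²);
CARP-Iface = mean(I⁰,I¹,I²); CARP-Merged = their mean;
CARP-PerIF[i] = mean(P⁰[i],P¹[i]); CARP-PerIF-G[i] = mean(PerIF[i],
CARP-Iface); CARP-RP = the grand mean over all per-interface outputs
(equivalently the mean of the per-interface means, since both channels
are always present together). With zero enumerated interfaces the global
scores are still emitted and the per-interface family is flagged NA.

## Ground-truth metrics

* **bb-lDDT / iLDDT** — superposition-free: the fraction of reference
  backbone atom-pair distances (pairs within 15 Å, different residues; for
  iLDDT, different chains) reproduced within {0.5, 1, 2, 4} Å, averaged
  over thresholds. Backbone = N, Cα, C, O (protein) and P, C3′, C4′, O3′,
  O5′ (RNA).
* **ICS** — F1 between inter-chain residue contact sets at 5 Å.
* **IPS** — Jaccard between interface residue sets (6 Å rule on each
  structure).
* **iRMSD** — interface residues taken from the *reference* (heavy atom
  within 10 Å of an opposite-polymer chain); the backbone atoms of those
  residues are Kabsch-superposed and the RMSD reported.
* **GDT-TS/GDT-HA (approximate)** — one global Kabsch superposition on all
  anchors, then the mean fraction within {1,2,4,8} / {0.5,1,2,4} Å. The
  full GDT search over many superposition seeds is intentionally not
  performed; the value is a lower bound and is flagged `approximate`.

The 5 Å contact and 10 Å interface cutoffs follow common CAPRI-style
conventions and are arguments, not constants. Chain correspondence between
model and reference is by identical chain id and residue number (the CASP
convention); chain-mapping search is out of scope. Metrics with empty
reference support (e.g. iLDDT of a monomer) return NA with a `flagged`
attribute and are masked from training losses — never imputed.

## Training

The multi-task loss is the mean absolute error per score type — three
fold, three interface, and the two per-interface types averaged over their
interfaces first — averaged over the types with at least one valid entry.
iRMSD is unbounded and is never a training target; it drives evaluation
only.

Cross-validation folds are stratified over cluster labels: clan strata are
dealt first, then clanless complexes by sequence cluster, each stratum
shuffled (seeded) and dealt round-robin over folds ordered by current
size, so per-stratum counts differ by at most one. Note the deliberate
consequence: members of one cluster are *distributed across* folds
(stratified representation), so folds are not group-disjoint and
validation scores are optimistic about truly novel complexes. We implement
the strategy as stated and flag the leakage implication here.

`train_carp()` runs Adam (batch size 1, default learning rate 1e-3 to
2e-3), halves the rate on a validation plateau, early-stops on patience,
and keeps the minimum-validation-loss checkpoint per fold; the models from
the fold rotation form the prediction ensemble (`ensemble_predict()`
averages every output channel across members).

## The synthetic decoy generator

`make_toy_complex()` builds an ideal α-helical protein (φ = −57°,
ψ = −47°, standard bond geometry) and a single-stranded A-form-torsion RNA
with full backbone, sugar carbons, and planar idealized base rings (fixed
sugar pucker, implicit chi), rigidly docked along a random seeded
direction **to the packing limit**: the deepest approach keeping all
interatomic distances ≥ 3 Å, with at least three residue pairs within
5 Å. Docking to the packing limit matters: a physical native is a packing
optimum, and only then is the native in principle identifiable from a
decoy ensemble by structure alone.

`decoy_set()` degrades the native along a magnitude ladder (default 5
levels). At level `f` the RNA chain receives a rigid move whose realized
chain RMS displacement is pinned to exactly `f · 8 Å` (a random-axis
rotation up to `f · 30°`, topped up by a solved translation), plus
backbone torsion jitter of `f · 10°` s.d. applied through bond-axis
rotations (bond lengths are preserved exactly). The rigid family emulates
docking decoys; the torsion family emulates refinement/perturbation
decoys; the pinned displacement makes the rung label a controlled dose, in
the spirit of grading decoys by their closeness to the native. Every decoy
is labeled with the full truth bundle.

**What the fixtures do not emulate**: side chains beyond Cβ, realistic
base pairing in the single-stranded RNA, energetics, clash relaxation,
sequence-structure correlation, or the diversity of real docking decoys
whose errors are not a one-parameter family. Passing the synthetic
experiments therefore demonstrates that the pipeline *learns and ranks a
controlled degradation signal end to end* — not that it reaches
state-of-the-art accuracy on real complexes, which requires training at
scale on real decoy sets.

Two empirical properties of this design are worth stating plainly. First,
the truth metrics degrade monotonically *in expectation* along the ladder,
but the within-level spread is substantial because independent noise
sources (rotation axis direction, translation direction, jitter
realization) compound; the rank correlation between the rung label and
iLDDT over a 5×10 ensemble plateaus around −0.7 for the compound ladder
(single-mode ladders reach −0.8 and beyond). Second, identifying the
*native itself* as the top model inside a near-native ensemble demands
prediction precision at the ~0.05 iLDDT scale, which is beyond the
desk-scale models trained here; the trained ensemble recovers the ordering
(positive held-out rank correlation) but does not reliably place the
native in the top decile. Both behaviors are measured, not asserted, in
`tests/testthat/test-acceptance.R`.

## Evaluation statistics

All follow the definitions in the package documentation; the conventions
we fixed:

* argmax/top-k ties break by model id (stable, deterministic);
* zero-variance inputs give all-zero Z-scores;
* Spearman uses average ranks on ties; entry correlations that are NA on
  a degenerate (zero-variance) entry count as 0 after the negative-value
  clipping rule;
* per-interface aggregation weights each (target, interface) entry by
  1/(interfaces in that target) so each *target* carries equal weight —
  "weighted by the number of interfaces ... for equal target
  representation" is self-contradictory read literally, and equal target
  representation requires inverse weighting; a `weighting = "direct"`
  flag provides the literal reading;
* feature sensitivity is operationalized as channel zeroing: the mean
  absolute change of each combined score when one node or edge channel is
  zeroed across the graph.

## Problem sizes and numerical choices

The test suite and acceptance experiments use 12+8-residue complexes
(fixture sweeps go up to ~30 residues), ensembles of 20–50 decoys per
complex, 20-complex training sets, hidden width 16 with 2 attention heads,
and ≤ 25 training epochs — sizes chosen so the full suite runs in minutes
on one CPU while every pathway (featurization, training, ranking) is
exercised. Other numerical conventions: SASA uses 144 deterministic sphere
points (convergence well under 0.05 RSA on doubling); GraphNorm adds 1e-5
to the variance; sigmoid outputs are strictly inside (0, 1); top-k and
argmax ties break by index; all stochastic steps draw from seeded
generators (`withr::with_seed`), so every pipeline stage is bit-for-bit
reproducible given its seed.

## Known limitations

* The 66/12 channel composition is this package's convention (the layout
  is versioned so an alternative can be swapped in).
* GDT is a single-superposition lower bound, not the full search.
* No chain-mapping search: model and reference must share chain labels.
* The internal annotators are simplified stand-ins for the full external
  programs they emulate (DSSP edge cases, RNAView edge geometries,
  pseudoknot-aware element decomposition are out of scope).
* Trained toy models are demonstrations of the learning machinery, not
  transferable scoring functions.
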