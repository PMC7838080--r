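---
title: "Predicting the acyl-acceptor class of BAHD acyltransferases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the acyl-acceptor class of BAHD acyltransferases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bahdscope)
```

## The problem

BAHD acyltransferases transfer acyl groups from CoA thioesters onto an
unusually broad range of acceptor molecules — polyamines such as putrescine,
spermidine and spermine on one side, alcohols such as shikimate on the
other. Family members share two conserved sequence features, the catalytic
HXXXD motif near the middle of the chain and the structural DFGWG motif near
the C terminus, but pairwise identity between functionally similar members
can be far below 30%, so substrate specificity cannot be read off a sequence
alignment. `bahdscope` operationalizes a two-evidence strategy for
predicting the acyl-acceptor *class* of an uncharacterized family member:

1. **Guilt by association.** All-vs-all local alignment, a sequence
   similarity network (SSN) thresholded at a stringent E-value, and
   co-clustering with experimentally characterized enzymes. Connected
   components of an SSN approximate isofunctional families.
2. **Pocket electrostatics.** The acyl-acceptor binding pocket of a
   characterized template is mapped onto the query through a global
   alignment, and the mapped pocket is classified by its formal net charge.
   Acidic pockets accommodate protonated polyamines; basic pockets attract
   anionic shikimate-type acceptors.

A verdict of `polyamine/amine` or `shikimate-type` is issued only when both
lines agree; anything else — an unclustered query, a mixed-label cluster, a
neutral pocket, or a disagreement between the two lines — is reported as
`indeterminate` with both lines of evidence attached.

## Alignment layer and statistics

Pairwise alignment is exact dynamic programming (Needleman–Wunsch and
Smith–Waterman with affine gaps; the DP engine is `Biostrings`), scored with
BLOSUM62, gap existence 11 and extension 1, so that a gap of length $L$
costs $11 + L$. Local raw scores $S$ convert to bit scores and E-values with
the Karlin–Altschul gapped-BLOSUM62 constants $\lambda = 0.267$,
$K = 0.041$:

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'},$$

with $m$, $n$ the full sequence lengths. Two cutoffs matter downstream: the
*family gathering* cutoff $E \le 10^{-25}$ (membership-level similarity) and
the *SSN visualization/clustering* cutoff $E \le 10^{-51.5}$ (isofunctional
resolution). Because the engine is exact rather than a heuristic seeded
search, and applies neither composition-based score adjustment nor
low-complexity masking, E-values are comparable to but not identical with
heuristic search tools; the cutoffs are used unchanged.

**Identity convention.** Percent identity is identical aligned pairs divided
by global-alignment columns *after trimming terminal-overhang columns*
(end-gap runs touching a sequence terminus). This single convention is used
everywhere — redundancy collapse, distance matrices, template selection and
pocket mapping — because published identity figures rarely state their
convention and consistency matters more than matching any one tool.

## Motif gate

`scan_motifs()` reports every HXXXD occurrence (literal H and D anchors,
any three middle residues) and every length-5 window within a configurable
mismatch budget of DFGWG (default 1, because the motif degrades in distant
family members). `X` never satisfies an anchor. `is_bahd_candidate()`
passes a sequence when an HXXXD hit starts inside the central window
(default 25–60% of the chain, where the catalytic His of characterized
members sits — His155 and His169 in the two bundled references) *and* a
DFGWG hit starts in the C-terminal third. Both windows are configurable;
the defaults are declared choices, not fitted values.

## SSN clustering

A cluster is a connected component — the established practice for SSN
analysis — with no community-detection alternative by default. Cluster
indices are assigned by decreasing size, ties broken by the
lexicographically smallest member id, so numbering is reproducible.
Singletons are retained in all exports: an unclustered node carries
prediction meaning. `threshold_sweep()` supports choosing a clustering
cutoff; cluster counts are non-increasing as the cutoff loosens, and
clusters at a looser cutoff are unions of clusters at any stricter one.

## Phylogeny

`identity_distance_matrix()` gives $d = 1 - \text{identity}$ (p-distance)
by default; a Poisson correction $-\ln(\text{identity})$ is available by
flag and capped (default 10) as identity approaches zero. Neighbor joining
is the Saitou–Nei algorithm via `ape::nj()`; negative branch lengths, which
NJ produces on non-additive input, are clamped to zero with the pre-clamp
values kept in an attribute. The Newick writer emits fixed 6-decimal branch
lengths and quotes labels containing metacharacters. The package's NJ is
validated by recovery properties (exact topology and branch lengths on
additive matrices; the unique zero-residual topology among all 105 unrooted
6-taxon topologies) rather than by reproducing any particular published
tree, whose sequence selection is database-version dependent.

## Structures and pockets

PDB files are parsed with `bio3d`; alternate locations resolve to the
highest occupancy (ties: altloc `A`, then blank), ligands are kept by
residue name, waters tagged. Superposition is the closed-form Kabsch
solution (SVD, reflections excluded); `ca_rmsd_by_alignment()` pairs chains
by best global identity, pairs CA atoms at non-gap aligned columns, and
runs one superposition over all pairs with **no outlier rejection** — a
declared convention, since published RMSD figures rarely state their atom
selection, and the reason the package compares such figures with a
tolerance band rather than exactly.

Pocket extraction has two modes. *Ligand mode* takes every residue with a
non-hydrogen atom within a radius (default 4.5 Å, a typical heavy-atom
contact cutoff) of any ligand atom; waters are counted but never enter the
position list. *List mode* takes an explicit residue list verbatim — this
is how the bundled in-text interaction-residue lists are represented, and
the radius rule never overrides it.

**Charge model.** Formal charge at neutral pH with fractional histidine:
Asp/Glu $-1$, Lys/Arg $+1$, His $+0.1$, all else 0. The classifier is
acidic when net $\le -1$, basic when net $\ge +1$, else neutral. The
threshold is a declared operationalization of a qualitative
surface-electrostatics argument — no Poisson–Boltzmann calculation is
attempted — and the bundled pockets sit comfortably inside it: the
9-residue spermidine pocket of AtSHT (two Asp, one His) scores $-1.9$, the
13-residue pocket of AtSDT (two Asp, one Glu) scores $-3.0$, both acidic,
while charge-inverting the acidic positions flips either list to basic.
Water-mediated contacts are recorded as role tags only and never
contribute charge.

`map_pocket_to_query()` carries template pocket positions through a global
alignment; positions lost to gaps are reported as `unresolved`, and the
charge is recomputed on the mapped query residues. Below 20% template
identity the mapping refuses (error class `bahdscope_low_identity`): at
that divergence an alignment-based mapping is not trustworthy.

## The verdict rule

`predict_acceptor()` issues `polyamine/amine` only if the mapped pocket is
acidic, `shikimate-type` only if it is basic, and requires the co-cluster
labels to agree. Design decisions worth making explicit:

* **Both evidence lines are required.** Running with `use_cluster = FALSE`
  or `use_pocket = FALSE` always yields `indeterminate`, with a
  reduced-confidence note naming the class the remaining line leans
  toward. Removing a line can therefore only move verdicts toward
  indeterminate, never flip them.
* **Conflicts are never resolved silently.** A basic-pocket variant built
  on an acidic-pocket scaffold still co-clusters with its polyamine-labeled
  relatives (it is nearly identical in sequence); the package reports the
  conflict as indeterminate rather than letting either line win. This is a
  deliberate resolution of a genuine design tension: a pure
  pocket-electrostatics reading would call such a mutant shikimate-type,
  but single-line verdicts are exactly what the two-evidence design
  guards against.
* **Two classes plus indeterminate.** The electrostatic contrast that
  powers the pocket line is binary (amine vs shikimate-type pockets).
  Donor preference (caffeoyl vs feruloyl vs sinapoyl-CoA) and acylation
  degree (mono/di/tri) are *not* predicted: no computable rule is
  available for either.

## The synthetic generator, and what passing tests mean

Real family data cannot ship with the package, so every stage is exercised
against a generator with known ground truth:

* `make_seed_sequence()` — uniform-random background with HXXXD planted at
  35% and DFGWG at 85% of the length (default 450, a typical family chain
  length).
* `evolve_family()` — independent per-site substitution at a configurable
  rate (default 0.1), motif anchors protected so the gate and the
  divergence dial stay independent; optional indels (geometric length,
  mean 2) outside protected positions. Substitution is uniform over the
  other 19 residues, *not* matrix-weighted: expected identity is then
  analytically simple (binomial), at the cost of realism.
* `make_toy_structure()` — ideal α-helical CA trace (rise 1.5 Å, radius
  2.3 Å, 100°/residue), optional Gaussian noise and random rigid moves.
* `make_pocket_variant()` — minimal D/E↔K/R swaps achieving an exact net
  charge delta (even deltas only; odd deltas are unreachable by design and
  rejected with the reachable range).
* `synthetic_scaffold()` / `reference_bundle()` — deterministic synthetic
  sequences that realize the bundled positional constraints (catalytic
  His, pocket residues at their published residue numbers, CoA-site
  residues, C-terminal DFGWG) on random backgrounds. These are stand-ins,
  clearly tagged `synthetic`; they are *not* the real proteins.

What the synthetic families do **not** emulate: among-site rate variation,
guide-tree (non-star) family topologies, matrix-weighted substitution,
domain architecture, low-complexity regions. Perfect ARI and 100% verdict
accuracy on planted families (substitution rate ≤ 0.15, the benchmark
conditions) therefore demonstrate the *machinery* is correct — thresholds
behave, evidence combines as specified, ground truth is recovered when it
is recoverable — not that real uncharacterized proteins are predicted with
that accuracy. On real data the honest failure mode is `indeterminate`,
which is why indeterminate is a first-class verdict.

Problem sizes used by the shipped analyses and checks: families of 4–8
members at length 450; benchmarks of 2–10 queries per class over 5–10
seeded replicates; 100-replicate oracle suites for alignment scores
(lengths ≤ 8), components (≤ 50 nodes) and NJ recovery (≤ 8 taxa). These
sizes were chosen to make every property checkable by brute-force oracles.

## Numerical choices and degenerate inputs

* Alignment tie-breaking among co-optimal tracebacks follows the DP
  engine's deterministic traceback; optimal scores are unaffected.
* Redundancy collapse below threshold 1.0 is greedy in input order and
  documented as order-dependent; at 1.0 only exact duplicates collapse
  (the default).
* Kabsch requires ≥ 3 non-collinear points; collinearity is detected via
  the second singular value and rejected.
* Zero-identity pairs under the Poisson correction hit the configured cap
  with a warning rather than producing infinities.
* Empty FASTA, empty residue lists, missing ligand codes, and queries
  already present in a graph are all errors with messages naming the
  offending item; motif scans on short sequences return empty hit sets,
  not errors.

## Known limitations

* E-values are exact-DP Karlin–Altschul approximations; counts gathered at
  a cutoff will differ from heuristic search tools and from any particular
  database snapshot. Dataset-scale published figures (sequence counts,
  cluster node counts, tree taxon counts) are database-version dependent
  and are not reproduction targets.
* The charge classifier ignores pocket geometry, burial and pKa shifts;
  it is a formal-charge screen, not an electrostatics calculation.
* Comparisons against published identity/RMSD figures require the user to
  supply the real sequence and coordinate files
  (`reference_structure_checks()`); the package does not redistribute
  database records and validates those figures only when the files are
  provided.
* Homology *modeling* is deliberately replaced by alignment-based pocket
  mapping; below the identity floor the right answer is refusal, not a
  model.
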