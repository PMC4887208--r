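---
title: "Detecting recurrent gene conversion between paralogs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent gene conversion between paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two paralogous genes that duplicated once, deep in a clade's history, should
each form a clean monophyletic group on a gene tree: all the IFIT1-like genes
together, all the IFIT1B-like genes together, each mirroring the species
phylogeny. Recurrent interlocus gene conversion breaks this expectation in a
characteristic, *positional* way: each non-reciprocal conversion event
overwrites one paralog's tract with the other's current sequence, so within
the converted tract the two copies in that species look like very recent
sisters, while outside it they retain their ancient divergence. When many
lineages convert the same region -- in the IFIT1/IFIT1B case the 5'
two-thirds of the gene, up to a shared breakpoint near nucleotide 948 of a
~1.4 kb coding sequence -- trees built from the converted region scramble
orthology, while trees from the non-converted 3' region recover it.

paraclade implements the full chain of evidence for this scenario:

1. **Pairwise dichotomy** (`percent_identity()`, `ng86_ds()`,
   `window_scan()`, `identity_changepoint()`): within a species, the
   paralog pair is far more similar 5' of a boundary than 3' of it, and the
   synonymous substitution rate -- a near-neutral clock -- shows the same
   step, so the dichotomy reflects time since divergence, not selection.
2. **Phylogenetic incongruence** (`scan_single_breakpoint()`): the
   alignment is better explained by two trees, one per side of a
   breakpoint, than by one.
3. **Partitioned trees** (`fit_tree()`, `bootstrap_tree()`): the 3'
   (non-recombining) partition yields monophyletic families; the full
   or 5' alignment does not.
4. **Classification** (`assign_families()`, `call_conversions()`,
   `scan_pseudogene()`, `build_repertoire_table()`): genes are assigned to
   families from the 3' tree, conversion events are called per species from
   5'/3' discordance, and inactivated copies are flagged.

A forward simulator (`simulate_family()`) provides ground-truthed input for
every stage; all quantitative claims in the test suite and the acceptance
script are made against its event log.

## The substitution model and its generative use

All likelihoods and the simulator use HKY85: stationary base frequencies
$\pi = (\pi_A, \pi_C, \pi_G, \pi_T)$ and a transition/transversion rate
ratio $\kappa$, with the rate matrix scaled so one unit of branch length is
one expected substitution per site at stationarity. Closed-form transition
probabilities are used throughout (no matrix exponentials at run time).

The simulator (`evolve_sequence()`) runs the exact continuous-time chain
site by site -- drawing exponential waiting times from the summed site
leave-rates, then a site, then a target nucleotide -- rather than sampling
each site from $P(t)$, because conversion tracts must be edited into a
concrete sequence at the moment the event occurs. Purifying selection is
approximated by *thinning*: a proposed substitution that changes the amino
acid is accepted with probability $\omega \in (0, 1]$, and proposals
creating internal stop codons are rejected outright while the gene is
intact. This codon-thinning scheme is standard when a full codon model is
not needed; at $\omega = 1$ the process is exactly neutral HKY85, which is
what the analytic checks in the test suite exercise (Jukes--Cantor closed
forms at $\kappa = 1$ and equal $\pi$). Pseudogenised copies switch to
$\omega = 1$ and may accumulate stops freely.

## The gene-family evolver

`simulate_family()` walks a rooted species tree. The ancestral gene
duplicates `dup_time` substitutions/site *before* the root, so the paralog
divergence at any tip is $2(\texttt{dup\_time} + \text{root-to-tip depth})$
on the neutral scale. On every branch each surviving gene may be lost
(probability `loss_rate`), pseudogenised (`pseudo_rate`; a 1-nt frameshift
or an engineered premature stop at least 15 codons before the end, followed
by neutral evolution), duplicated again (`dup_rate`), and -- when two or
more loci are present -- hit by Poisson(`conversion_rate`) conversion
events at uniform times, each overwriting the recipient's nucleotides
$[0, 3b)$ with the donor's, where $b$ is `conversion_breakpoint` in codons
(optionally jittered by `jitter_nt`). Deterministic events can be planted
on terminal branches (`plant_conversions`) when a benchmark needs an exact
number of conversions at known recency. Every event is logged; the log plus
`true_gene_tree()` reconstructs the expected topology (conversion edits
sequence, never ancestry).

### Default parameters and their calibration

| parameter | default | rationale |
|---|---|---|
| `gene_length_codons` | 472 (1416 nt) | a single-exon ~1.4 kb coding gene, the IFIT scale |
| `kappa` | 4 | typical mammalian nuclear transition bias |
| `base_freqs` | (0.30, 0.20, 0.20, 0.30) | mild AT richness |
| `omega` | 0.2 | ordinary purifying selection on an intact gene |
| `dup_time` | 0.5 | with tree depth 0.3, total paralog divergence 1.6 |
| `conversion_breakpoint` | codon 316 (nt 948) | the recurrent two-thirds breakpoint; scales as ~67% of other gene lengths |
| `loss_rate`, `pseudo_rate` | 0.02/branch | sporadic lineage-specific loss and inactivation |
| `conversion_rate` | 0.15/branch | recurrent but not saturating conversion |

The pair generator `simulate_conversion_pair()` uses total divergence 1.6
and post-conversion residual 0.08. These two numbers were fixed once, by
calibration against the printed cat IFIT1/IFIT1B panel: with $\omega = 0.2$
thinning, nominal divergence 1.6 realises ~63% nucleotide identity (the 3'
value), residual 0.08 realises ~97% (the 5' value), and the mixture gives
~86% whole-gene. No rate estimates for conversion or loss exist to copy, so
those defaults are chosen for signal visibility at desk scale, not inferred
from data.

Species trees for simulations (`sim_species_tree()`) are pure-birth (Yule)
topologies rescaled to a root depth of 0.3 substitutions/site. A Yule tree
is the standard diversification null for species-level phylogenies; a
single-population coalescent was rejected because its deepest internal
edges shrink toward zero, which makes topology recovery fail for reasons
unrelated to the methods under test. Even under Yule, short internal edges
occasionally arise and bound achievable topology-recovery rates.

### What the simulator does not emulate

No insertions/deletions other than pseudogenising frameshifts (so intact
simulated families align gap-free -- real alignments are harder); no rate
variation across sites or lineages; no codon-usage structure beyond the
stationary base composition; no segregating polymorphism or coalescent
layer; conversion donors and recipients are always in the same genome and
tracts always anchor at the 5' end. Passing the suite therefore shows the
statistics behave as designed under the stated model, not that they are
robust to every artefact of genome-mined data (assembly errors, chimeric
models, alignment curation).

## Alignment

The aligner mirrors protein-guided nucleotide alignment: intact genes are
translated, aligned with BLOSUM62 and affine gaps (open 11, extend 1), and
back-threaded to codons, so gaps between intact genes are always
codon-sized. The multiple aligner is progressive along a neighbour-joining
guide tree of protein p-distances, merging profiles by average-of-pairs
BLOSUM62 scores (gap columns score 0) under the same affine scheme.
Pseudogenes cannot be translated, so they are added afterwards in
nucleotide space against the profile consensus; columns they insert are
flagged (`attr(aln, "col_insert")`) and such 1--2 nt columns are the one
place intact rows can carry non-codon-sized gaps. The translated `X` (from
ambiguous codons) scores 0 against everything. A manually curated external
alignment can replace the whole step (`external =`), since automated
alignment is not a substitute for curation on hard families.

## Pairwise statistics

Identity is computed over columns where neither row is gapped; `N` counts
as a mismatch. Synonymous divergence uses Nei--Gojobori (1986) counting --
per-position synonymous fractions averaged over both sequences, multi-hit
codons averaged over all minimal mutational paths (paths through stops
excluded when avoidable, stop-creating changes counted nonsynonymous) --
with the Jukes--Cantor correction $d_S = -\tfrac34\log(1 - \tfrac43 p_S)$,
flagged saturated when $p_S \ge 3/4$ (reported capped at 3 for display,
never averaged downstream). NG86 was chosen over the original tool's
K-estimator because it is fully specified and testable against an
exhaustive enumeration oracle; its known conservative bias under transition
bias is acceptable because the analysis reads *contrasts* between regions,
not absolute rates. Windows default to 200 nt (the display convention for
these scans) with a 100-nt step -- overlap sharpens localisation; dS within
a window uses the complete codons it contains.

The change point maximises the two-segment Bernoulli likelihood of the
per-column match indicators, ties to the smallest position, with a
`min_segment` guard (300 nt) and significance by shuffling the column
labels (999 permutations by default in the pair scan; the estimator itself
is deterministic).

## Tree inference

`fit_tree()` is plain HKY85 maximum likelihood: empirical base frequencies,
$\kappa$ by 1-D optimisation, Felsenstein pruning over compressed site
patterns with per-node scaling, gaps/N as missing data. The search starts
from neighbour joining on pairwise ML distances and alternates per-branch
Brent optimisation (each branch a 1-D problem against cached inside/outside
partials, tolerance 1e-6) with nearest-neighbour interchanges screened by
re-optimising only the central branch, accepting the first move that gains
more than 1e-4 log units in a deterministic preorder edge order. NNI-only
search (no SPR) is deliberate: at the ≤30-taxon scale of these analyses,
NJ + NNI reaches the same optima in a fraction of the time, and the
breakpoint scan warm-starts every segment fit from the full-alignment tree
anyway. No rate heterogeneity is modelled (the analysis is defined on plain
HKY85). Bootstrap supports resample columns with replacement and count
bipartition recovery over full refits; the pipeline default is B = 100
(B = 1000 restores the classical convention at 10x the cost).

## Breakpoint scan

Candidates lie on a 60-nt (20-codon) grid, codon-rounded, with at least
`min_segment` (300 nt) on each side; finer localisation is the change
point's job. For each candidate, independent trees are fitted to the left
and right segments, warm-started from the full-alignment topology -- which
also guarantees the nesting property that the two-tree likelihood never
falls below the single-tree one. Each model is scored by small-sample AICc
with parameter count = branches + 1 ($\kappa$) per tree (frequencies are
empirical, not counted), n = alignment columns; Akaike weights over
{single-tree} ∪ {candidates} give the model-averaged breakpoint support.
The p-value permutes alignment columns and re-runs the same scan (the
single-tree fit is permutation-invariant and reused), 99 replicates by
default, so the smallest attainable p is 0.01. The permuted statistic is
the best two-tree model's AICc advantage rather than the model-averaged
support itself: the support saturates at exactly 100% once the advantage
exceeds ~60 AICc units (Akaike weights underflow), and a saturated
statistic ties with saturated null replicates, blunting the test; the
AICc advantage is monotone in the support and stays continuous. This column-permutation null
replaces a genetic-algorithm search: it answers the same
discordance-between-regions question with a testable, seedable procedure,
but is not numerically identical to GARD/SBP.

## Classification rules

*Assignment*: a gene takes the family of the smallest bipartition side
containing it and exemplars of exactly one family (run on the 3' tree;
support = that edge's bootstrap). *Monophyly*: a family is monophyletic iff
some bipartition isolates exactly its members -- rooting-free. *Conversion
call* for a within-species pair: grouped together in the 5' tree (smallest
side containing both holds only that species' genes -- the generalisation
that handles 3+ copies), *not* grouped in the 3' tree, and 5' identity
exceeding 3' identity by ≥ 10 points (`min_delta`; separates conversion
from stochastic rate variation in simulations). *Pseudogene*: any indel vs
an intact exemplar whose length is not a multiple of 3, or an in-frame stop
≥ 15 codons before the reference end (shorter truncations are tolerated as
terminal-stop polymorphism); nonsense scanning stops at the first
frameshift, where the frame becomes undefined. *Repertoire*: absence of a
family is "lost" only when the species' assembly is flagged complete,
otherwise "not found". Calls are per species pair; collapsing them into
lineage-independent events is left to the user, since independence across
branches is not identifiable from tip data alone.

## Numerical choices and degenerate inputs

Branch lengths live in [1e-8, 10]; pattern compression is exact (tested
against uncompressed likelihoods); underflow is handled by per-node,
per-pattern scaling. Alignments with fewer than three distinct sequences
return a star tree with a warning. Saturated dS windows are flagged, not
numbers. Candidate grids and windows are codon-rounded, with a warning when
a requested window is not a codon multiple. All stochastic steps
(simulation, bootstrap, permutations) run off explicit seeds; identical
seeds give byte-identical outputs.

## Problem sizes

The shipped analyses and acceptance checks run, per replicate, families of
6--12 species x 2 loci at 1416 nt (clean topology-recovery checks use 8
species at ~5 kb), 100 replicates for pairwise change-point recovery and
false-positive calibration, 99 permutations per breakpoint scan, and
bootstrap B = 100. These sizes were chosen as the smallest at which the
contrasts of interest are unambiguous; every threshold quoted in the tests
refers to these conditions.

## Known limitations

The breakpoint model is single-breakpoint (SBP-style); multiple exchange
tracts in one alignment would be summarised by their dominant boundary.
NG86 dS deflates under strong transition bias (contrast-safe, not
absolute-rate-safe). The conversion caller requires the converted tract to
produce within-species grouping in the 5' tree, so very old conversions --
overwritten by later divergence -- fade from recall, which is a property of
the signal, not just the method. Orientation (which locus donated) is not
inferred. Real-data curation (assembly completeness, manual alignment
fixes) enters only through the external-alignment override and the
assembly-completeness flags.
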