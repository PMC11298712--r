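---
title: "Methods: presequence characterization, design and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presequence characterization, design and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presqkit)
```

`presqkit` implements the in-silico arm of a presequence-dissection
workflow: curate organellar targeting-peptide (TP) datasets, quantify their
physicochemistry, design synthetic TPs and systematic variants, screen a
proteome's N-termini for TP-like sequences, and classify peptides with an
empirically derived targeting rule. This vignette records the models,
parameter choices and numerical conventions behind each stage, and what the
synthetic-data generator does and does not emulate.

## Coordinates and alphabet

Positions are 1-based and inclusive everywhere, with the initiator
methionine at position 1 — so "an arginine at the +2 position" means
residue index 2. Sequences are restricted to the 20 canonical residues;
ambiguity codes are rejected at construction rather than silently scored,
because every downstream quantity (charge, hydrophobicity, matrix score)
would otherwise be computed from an undefined residue.

## TP delineation from alignment overhangs

A presequence is operationally the N-terminal region of a precursor that
homologs of the mature protein do not align to. Manual curation of
pairwise alignments is replaced here by a deterministic rule: for one query
protein with earliest aligned query positions $s_1, \dots, s_k$ over its
homologs,

$$\mathrm{tp\_end} = \mathrm{aggregate}(s_1,\dots,s_k) - 1,$$

with median aggregation by default. The median tolerates a minority of
spurious full-length hits (a homolog that itself carries a presequence
aligns from position 1); `min` is the conservative floor and `max` the
permissive ceiling, and `min ≤ median ≤ max` always holds. For an even
number of homologs a half-integer median is floored — the shorter, more
conservative presequence. `tp_end = 0` means a conserved N-terminus, i.e.
no presequence.

Records with TP length outside the inclusive band 10–150 aa are omitted:
below 10 aa an overhang is indistinguishable from alignment jitter, above
150 aa it more likely reflects a missing homolog than a real presequence.
Length summaries use the sample (n − 1) standard deviation, the convention
for "mean ± s.d." of a measured set.

## Physicochemistry

**Net charge** follows the Henderson–Hasselbalch sum over ionizable groups:
positive groups (N-terminus, K, R, H) contribute
$+1/(1+10^{\mathrm{pH}-\mathrm{p}K_a})$, negative groups (C-terminus, D, E,
C, Y) $-1/(1+10^{\mathrm{p}K_a-\mathrm{pH}})$. Two pKa presets ship:
`"protcalc"` (default; N-term 8.0, C-term 3.1, K 10.0, R 12.0, H 6.5,
D/E 4.4, C 8.5, Y 10.0) and `"emboss"` (N-term 8.6, C-term 3.6, K 10.8,
R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1). Published TP charge values in
this field typically come from web calculators that include the free
termini, but rarely say so; both modes are therefore exposed
(`include_termini`), with termini included by default. For the N-terminal
*domain* of a membrane protein — an internal truncation whose chain
continues — `domain_charge()` includes the free amine but excludes the
carboxylate by default (`include_cterm = FALSE`), again switchable.
Net charge is monotonically non-increasing in pH by construction; the test
suite asserts this over a pH grid.

**Hydrophobicity** uses the Fauchère–Pliska octanol/water scale (the scale
used by the HELIQUEST server), shipped as a named vector; alternative
scales plug in as any complete residue → value map. Mean hydrophobicity is
the arithmetic per-residue mean (dimensionless H units).

**Hydrophobic moment** is the mean-vector form

$$\mu H = \frac{1}{N}\sqrt{\Big(\sum_i H_i\cos\delta(i-1)\Big)^2 +
\Big(\sum_i H_i\sin\delta(i-1)\Big)^2},$$

with δ = 100°/residue, the ideal α-helix twist (configurable, e.g. 160° for
β-strands). It is computed over the full peptide by default; the optional
`window` argument returns the maximum over sliding windows (default use:
18, the HELIQUEST window), because it is often unknowable whether published
values were full-length or windowed. Degenerate cases pin the
implementation down: an 18-residue homopolymer at 100° has μH exactly 0
(the 18 unit vectors tile every multiple of 20° and cancel), a single
residue has μH = |H|, and a uniform phase offset leaves μH unchanged. The
unit tests verify the implementation against an independent brute-force
2-D vector summation on random short peptides.

**Class composition** uses the standard textbook grouping — basic {K, R,
H}, acidic {D, E}, polar uncharged {S, T, N, Q, C, Y}, nonpolar {G, A, V,
L, I, P, F, M, W} — as a configurable map, since published composition
figures rarely print their scheme. Fractions are pooled over residues (not
averaged per sequence), so a union of sets is the residue-weighted average
of its parts.

**Frequency matrices** count residues per position over left-anchored
peptides; position $p$ is normalized by its *coverage* (the number of
sequences of length ≥ p), so ragged sets remain properly normalized. The
TSV export is directly consumable by logo-rendering tools.

## Consensus design and variants

The consensus design links the modal residue at each of the first `length`
(default 24) positions. Ties are resolved by preferring the residue more
frequent over the whole input set, then alphabetically — and are flagged
per position, so a design built on a small helix set can be audited rather
than silently trusted. The design is permutation-invariant in its inputs.

`charge_adjust()` applies explicit (position, residue) substitutions —
the step that brings a basic-rich consensus down toward the endogenous
mean charge. Which positions to substitute is a judgement call on real
data, so the function takes them explicitly and warns when a substituted
position does not hold arginine; `suggest_charge_adjust()` offers a greedy
default (replace arginines in position order, alternating leucine and
serine, keeping the prefix that lands closest to the target charge,
default +2.80 e — the endogenous single-helix mean at pH 7).

All variant generators are substitution-only (no indels; output length ==
input length, asserted as an invariant):

- `arg_series()` — progressively removes arginines (ascending position
  order, replacements recycled from `c("L", "S")` — neutral residues
  matching the charge-adjustment convention) down to 0 R, plus an
  all-R→K swap. R counts are strictly decreasing along the series.
- `arg_scan()` — plants a single arginine at each listed position of an
  arginine-free scaffold; default positions 2, 6, 8, 9, 12, 13, 15, 21.
- `point_mutants()` — singles and (optionally) all combinations, with
  `E2A/E18A`-style labels; `from` residues are checked against the base.

## N-terminal screening

`screen_proteome()` scores the ungapped BLOSUM30 similarity between a
query peptide and the first k = 24 residues of every ORF (initiator Met
included). No gaps and no shifts: the biological question is whether an
N-terminus *as synthesized* resembles the query. ORFs shorter than k are
skipped, not padded — padding would need a gap score the model does not
define. Ranking is dense (equal scores share a rank) with a secondary
lexicographic order on ORF id, making output byte-reproducible. The
shipped NCBI-format BLOSUM30 parser validates symmetry and completeness
and drops the B/Z/X/* columns. Because BLOSUM diagonal entries are maximal
in their rows (asserted against the shipped file), a proteome containing
the query's own source ranks it first.

## The targeting rule

The classifier encodes two experimentally grounded clauses over the
N-terminal window (default 24 aa):

1. **Basic clause** — at least `min_basic` (default 1) basic residues
   (R/K) at window positions outside `flank_excluded_positions` (default
   {1, 2}): position 1 is the initiator methionine, and a single arginine
   at position 2 does not support targeting while positions ≥ 6 all do.
2. **Acidic clause** — at most `max_acidic` (default 0) acidic residues
   (D/E) in the window: with two glutamates a TP-like 24-mer stays
   cytosolic, with one it still stays cytosolic, and only removing both
   confers targeting. The default is deliberately strict and overridable,
   since endogenous TP helices do average a few percent acidic residues
   over their full length.

Histidine is not counted basic (only R and K are demonstrated carriers).
Positions 3–5 are untested experimentally; basic residues there are
counted as supporting and the call's `reasons` flag them, so the
assumption is visible. The classifier is monotone: adding a non-flank
basic residue never flips mitochondrion → cytosol, adding an acidic
residue never flips cytosol → mitochondrion.

The shipped 16-row truth table encodes the reporter constructs the rule
was calibrated against, as feature vectors (window, basic positions,
acidic count) because the full construct sequences are not
machine-readable: one single-helix enzyme N-terminus, the arginine series
(3R/2R/0R and the 3K lysine swap), the eight arginine-scan constructs (the
R13 row doubling as the series' 1R member), and the formin-like N-terminus
with its glutamate mutants (the two single-E mutants share one feature
row; the acid-free double mutant also covers a ribosomal-protein
N-terminus with the same signature). The exact basic positions in
multi-basic rows are representative stand-ins, marked synthetic in the
fixture header; only the counts enter the rule. With default parameters
the classifier reproduces 16/16 outcomes (asserted in the test suite);
degenerate parameters (`min_basic = 0`) collapse to all-mitochondrial
calls and demonstrably lose agreement.

## The synthetic-data generator

`generate_proteome()` emulates the statistical structure the analysis
assumes, not any real genome:

- **Scale** — 4,803 single-exon ORFs by default, the nuclear gene count of
  the monomitochondrial red alga *Cyanidioschyzon merolae*, the archetypal
  minimal-import-system organism; mature-region lengths log-normal
  (meanlog = log 350, sdlog = 0.5 — a typical microbial ORF length scale,
  the package's own choice).
- **Background composition** — class fractions 11.2% basic / 14.0% acidic
  / 22.2% polar uncharged / 52.5% nonpolar, spread uniformly within each
  class; a full 20-residue frequency vector can be supplied instead.
- **Planted TPs** — 14% of ORFs (split evenly mito/chloro, roughly the
  336 mitochondrial / 349 chloroplast candidates a predictor flags in that
  genome) carry a TP whose residues follow the
  presequence-helix profile (17.3/3.6/26.2/52.9), with one annotated
  helix segment of 10–24 aa and a guaranteed basic residue at a non-flank
  position inside it.
- **TP lengths** — the published 59.3 ± 23.4 (mito) and 78.4 ± 17.3
  (chloro) are *post-filter* moments, so lengths are drawn from the parent
  normal whose [10, 150]-truncation has exactly those moments
  (`truncated_normal_parent`, a Nelder–Mead fit of the closed-form
  truncated-normal mean/sd; naive truncation of Normal(59.3, 23.4) would
  inflate the mean by about one residue because the sub-10 tail is cut).
- **Overhangs** — per protein, homolog rows at
  `tp_end + 1 + round(Normal(0, noise_sd))`, floored at 1, with a
  configurable fraction of spurious start-at-1 hits; this reproduces the
  failure mode the median delineation rule exists for.
- **Determinism** — a mandatory integer seed drives one stream; the
  caller's RNG state is saved and restored, and equal seeds give
  byte-identical output.

What it does **not** emulate: positional composition structure within
helices (residues are i.i.d., so consensus designs from synthetic helices
are flatter and less arginine-biased than real logos), amphipathic
periodicity (planted helices have no 100° hydrophobicity phase, so their
μH is near the random-sequence baseline rather than the endogenous
0.288), cleavage-site motifs, homology between ORFs, and predictor score
columns. Tests passing on synthetic data therefore validate the
*machinery* — boundary recovery, filters, composition accounting, design
algebra, screening, classification — not the biological conclusions,
which require the curated sequence sets.

## Problem sizes and tolerances

The test suite exercises: the brute-force moment oracle on 1,000 random
peptides of length ≤ 8 (agreement to 1e-12); screening against an
independent nested-loop scorer on proteomes of ≤ 20 ORFs; exact boundary
recovery on noiseless overhangs and ≥ 95% within-noise recovery at
noise sd 2; planted mito TP length mean within 2 standard errors at
n = 2,000; planted helix composition within ±1 percentage point at
10,000 helices; and an end-to-end pipeline run at 400 ORFs. Class
fractions and frequency-matrix rows must normalize to 1 within 1e-9.
`scripts/acceptance.R` runs the pipeline at the full 4,803-ORF scale.

## Checks requiring external sequences

Some dataset-level numbers can only be reproduced with sequences the
package cannot redistribute; the functions are general, the inputs are the
user's:

- `dataset_summary(dir)` recomputes length statistics, the single-helix
  count and composition, and charge/μH aggregates from a curated
  presequence directory (`presequences.tsv` + `helices.fasta`); the
  acceptance suite runs it automatically when such a directory is placed
  under `inst/extdata/supplement/`.
- `domain_charge()` on receptor sequences compares the cytosol-facing
  N-terminal domains of TOM22 homologues (e.g. residues 1–142 of the human
  protein vs 1–119 of a red-algal one) — retrieve the sequences from
  UniProt and call it directly.
- `screen_proteome()` on a real proteome FASTA reproduces a published
  screen given the query peptide's sequence.

## Known limitations

- The classifier is a deliberately minimal rule for one minimal import
  system; it does not model amphipathicity (shown to be broadly
  permissive), histidine protonation, chloroplast-vs-mitochondrion
  discrimination, or anything a learned predictor would capture.
- Net charge assumes context-free pKa values; no isoelectric-point
  solving or local electrostatic shifts.
- Delineation quality is bounded by the homolog set: paralog-free queries
  give no overhang rows and are reported as such, not guessed.
- Consensus design assumes left-anchored, indel-free helix alignment;
  helices that would need gapped alignment should be pre-aligned upstream.
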