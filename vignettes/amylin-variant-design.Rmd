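---
title: "Aggregation-propensity scanning and de novo design of amylin variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregation-propensity scanning and de novo design of amylin variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylscan)
```

## The problem

Human islet amyloid polypeptide (hIAPP, amylin) is a 37-residue peptide
hormone co-secreted with insulin. Its human form readily assembles into
beta-sheet amyloid fibrils, a hallmark of type-2 diabetes; several other
species carry amylin sequences that barely aggregate at all (rat amylin
differs from human at six positions in the 18–29 segment and is far less
amyloidogenic, and the clinical analogue pramlintide borrows three of its
proline substitutions). This package implements a biomimetic design loop
around that observation:

1. score any peptide's intrinsic aggregation propensity per residue and as a
   single summary number;
2. catalogue, per position, which substitutions occur across a panel of
   species and how often;
3. substitute those naturally occurring variants — singly or in
   combinations — into the human reference, re-score every candidate, and
   rank the designs;
4. profile the physicochemical descriptors (hydropathy, net charge,
   isoelectric point, hydrophobic moment) that co-vary with aggregation.

## The aggregation score

Scoring follows the AGGRESCAN approach. Each residue type carries an
intrinsic aggregation-propensity value (**a3v**), experimentally derived
from in-vivo amyloid-beta deposition. For a sequence of length $n$ the
windowed profile (**a4v**) at position $i$ is

$$ a4v_i = \frac{1}{w}\sum_{j=i-h}^{i+h} a3v_j, \qquad h = (w-1)/2, $$

with the convention that out-of-range neighbours contribute zero — the
peptide is treated as embedded in a propensity-neutral context, so the two
first and last positions are pulled towards zero. The window $w$ is 5 for
sequences up to 75 residues (longer tiers, 7/9/11, exist but are never hit
by amylin-sized inputs). The summary score is the sequence sum normalised to
100 residues,

$$ \mathrm{Na4vSS} = \frac{100}{n}\sum_i a4v_i , $$

with *more negative = less aggregation-prone*. **Hot spots** — candidate
aggregation nuclei — are maximal runs of at least 5 consecutive positions
with $a4v$ strictly above the hot-spot threshold HST $= -0.02$ (the
residue-frequency-weighted mean of the scale), with prolines excluded: a
proline never belongs to a hot spot and terminates a run. Under these
conventions the human reference scores $-5.6$ with two hot spots
(12–18-ish and the 23–28 core), rat amylin scores $-8.8$, and the designed
double substitution V17D+F23R scores $-22.9$ and removes hot spots.

### Provenance and calibration of the shipped scale

The a3v table shipped in this package is a *calibrated reconstruction* of
the published AGGRESCAN scale rather than a verbatim copy. Relative values
for 15 of the 20 residues were transcribed and then validated against an
extensive set of published single-substitution effects on full-length human
amylin; all agree within ±0.1 Na4vSS units. The remaining entries were
pinned by published reference scores themselves: asparagine by three
independent asparagine-substitution scores, proline jointly by the rat
amylin and pramlintide scores (which agree on the same value), and cysteine
and glutamine by anchoring the full-length human reference at its published
value of $-5.6$. Methionine has no such calibration surface and carries the
transcribed value. The same published reference values select the
terminal-window convention: the two published terminal-substitution scores
(positions 1 and 37) both imply a terminal weight of exactly $3/5$, i.e.
the zero-padded window above, rather than a truncated mean (weight
$47/60$) or dropping incomplete windows.

Two practical consequences are worth knowing. First, the homopolymer
closed form is $\mathrm{Na4vSS}(\mathrm{poly\text-}X, n) = 100\,a3v(X)\,
(n-1.2)/n$ for $n \ge 5$ (not exactly $100\,a3v(X)$): the terminal windows
shave $1.2$ residue-equivalents off the sum. Second, a window reaches only
two residues, so substitutions more than 4 positions apart have exactly
additive effects on Na4vSS — the package's tests exploit this locality, and
it explains why the published double-substitution scores equal the sums of
their singles.

The reference set the reconstruction cannot reconcile is small and
internally contradictory (three interior T→I substitutions published with
two different scores; one substitution of nearly identical residues, T36S,
published with a tenfold-too-large effect). The package follows the
self-consistent majority. One downstream consequence: with proline pinned
by the rat/pramlintide scores, six proline substitutions in the catalog
score marginally *below* the reference, so the package counts 54 of 112
single-variant designs (48%) below the human reference and 31 below the
pramlintide threshold of $-6.6$, slightly more than the published 43% and
30. Reproducing those published counts would require a proline value that
contradicts the rat and pramlintide scores themselves; we keep the
assignment that reproduces the larger self-consistent set and report the
computed counts as-is.

## Physicochemical profile

* **GRAVY** is the plain mean of Kyte–Doolittle hydropathy values
  (dimensionless; printed comparisons round half-up to 2 decimals). The
  published per-variant hydropathies identify this scale exactly.
* **Net charge** $Z(\mathrm{pH})$ is a Henderson–Hasselbalch sum over the
  two termini and the ionisable side chains (D, E, C, Y, H, K, R) with
  EMBOSS pKa values (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9,
  E 4.1, C 8.5, Y 10.1); the table is injectable via `charge_model()`.
  Cysteines are treated as free thiols — the scored C-terminal fragments
  contain no cysteine, so no disulfide correction is attempted. $Z$ is
  strictly decreasing in pH. Integer-rounded charge at pH 7 reproduces the
  design rationale for F23R: the native 23–37 fragment is neutral, the
  F23R fragment carries +1. Note that below pH ≈ 4 the C-terminal carboxyl
  protonates under this model and the "fragment is neutral" statement
  no longer holds — claims of neutrality over a 3.0–8.5 pH range are only
  matched by this model from about pH 4 upward.
* **pI** is the unique root of $Z$, found by bisection on $[0, 14]$ to
  $10^{-4}$ pH units.
* **Hydrophobic moment** $\mu_H$ uses the Eisenberg consensus scale:
  magnitude of the vector sum of residue hydrophobicities at successive
  rotations of the periodicity angle (default 100°, i.e. alpha-helical;
  180° probes beta-strands), divided by the length. No published values
  exist for these peptides, so $\mu_H$ is verified purely against an
  independent complex-exponential oracle and its symmetries.

## The variant catalog

`amylin_catalog()` loads the packaged catalog of residue variants observed
across 240 cross-species amylin sequences: 113 distinct per-position
substitutions, 1,640 variant occurrences, of which 1,187 (72.4% at full
precision) fall in the hypervariable 17–31 segment; positions 2, 12 and 16
are strictly conserved. The source table records one occurrence total per
*position*, not per variant, so the loader distributes each position's
total as evenly as possible across its listed variants (deterministically;
earlier-listed variants absorb the remainder). This synthetic allocation is
documented in the fixture itself and leaves every per-position total,
whole-catalog total, region statistic and scan statistic unchanged. The one
nonstandard record (an unresolved residue at position 27, "L27X") is kept
in the totals — they do not reach 1,640 without it — but flagged and never
scored.

`catalog_from_panel()` rebuilds such a catalog from any aligned, gap-free,
equal-length panel (FASTA in, `X` tolerated and flagged). No alignment is
computed here; panels must arrive aligned.

## Scanning and design

`single_scan()` substitutes every scorable catalog variant into the
reference one at a time; `multi_scan(k = 2, 3, ...)` enumerates every
combination of catalog variants at pairwise-distinct positions
(exhaustively — there is no search heuristic, and a configurable
combination budget fails loudly rather than truncating silently). Each
record carries the mutated sequence, Na4vSS, its delta against the
reference, GRAVY, hot-spot count and coverage, a `hotspot_deleted` flag
(strictly fewer hot-spot residues than the reference) and a
`lower`/`higher` class. Classification is *strict* on full-precision
values; rounding is applied only for display, because the published counts
are binary classifications that rounding could corrupt. Tables are sorted
ascending by Na4vSS with deterministic tie-breaks (first substituted
position, then substitute letter), so repeated runs produce byte-identical
reports.

`pearson()` (a guarded wrapper over the sample correlation) reproduces the
published association between aggregation score and hydropathy across the
single-variant designs: $r = 0.87$.

## Synthetic panels

`catalog_config()` + `generate_panel()` emulate the kind of cross-species
panel the catalog was derived from: each member is drawn independently,
each position sampled from that position's substitution distribution with
probability `count/240` (the study's panel size), residual mass going to
the reference residue; conserved positions carry zero mass; the
nonstandard X record keeps its mass so simulated catalogs can reproduce the
full occurrence total. Positions are sampled independently — real
cross-species panels carry phylogenetic covariation between sites, which
this generator deliberately does not model, so recovery tests validate the
catalog machinery, not evolutionary realism. Generation is deterministic
given (seed, config); the sampling algorithm is pinned in the config
metadata.

Test problem sizes: oracle equivalences run on a few hundred random
peptides of length ≤ 40; catalog recovery uses one panel of 240 members
(counts within 3 binomial SD, allowing the ~0.3 expected three-sigma
excursions among 113 variants) and frequency convergence one panel of
10,000 members over a four-variant config (within 3 standard errors). The
full double-substitution scan of the catalog (6,123 candidate pairs) runs
in about a second; triple scans are supported under the combination budget.

## Numerical choices, degenerate inputs, limitations

* Printed comparisons round half away from zero (1 decimal for Na4vSS,
  2 for GRAVY, integers for charge and percentages); internal computation
  is full precision.
* Sequences shorter than the window are still scored (the zero-padding
  convention defines every position); the empty sequence is rejected.
* Sequences containing `X` are loadable in panels but refuse to be scored,
  with the offending position named.
* The "theoretical average rate of aggregation" sometimes quoted alongside
  these descriptors names no algorithm and is not implemented. PASTA
  pairing energies and Zyggregator Z-scores are likewise not computed; the
  scan report can merge externally supplied values of that kind as
  pass-through annotation columns (`variant_annotations()`).
* No indels, no nucleotide sequences, no post-translational chemistry (the
  synthesised peptides' C-terminal amidation and the 2–7 disulfide are not
  modelled), no phylogenetic tree construction, no lipid-interaction or
  aggregation-kinetics modelling.
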