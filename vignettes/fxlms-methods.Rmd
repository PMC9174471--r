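---
title: "Identifying and validating formaldehyde cross-links, with companion quantitative proteomics"
author: "fxlms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and validating formaldehyde cross-links, with companion quantitative proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fxlms)
```

## The problem

Formaldehyde permeates living cells and forms methylene bridges between
spatially proximal, reactive side chains — primarily lysine and arginine,
to a lesser degree asparagine, histidine, aspartate, tyrosine and
glutamine. After in-cell cross-linking, tryptic digestion and LC-MS/MS,
a cross-linked peptide pair appears as a single precursor whose mass is
the sum of the two peptide masses plus the linker: the methylene bridge
adds monoisotopic CH2O − H2O = exactly **12 Da** per bridge (24 Da for a
doubly bridged pair). Because the bridge cleaves during fragmentation,
MS2 spectra contain the ordinary a/b/y ions of both peptides *and* twins
shifted by +12 Da where the fragment retains the linker remnant.

`fxlms` implements the identification of such peptide pairs from MGF
peak lists, their aggregation over replicates into consensus residue-pair
cross-links, and their validation against Cα–Cα distance restraints on
high-resolution structures. The quantitative half of the package covers
the companion analyses such an experiment needs: iBAQ-based subcellular
abundance profiling, median-equalised differential abundance with
volcano calls, presence/absence analysis, Fisher over-representation,
and qPCR quantification by 2^−ΔΔCt.

## Cross-link identification model

**Candidate enumeration.** For a spectrum with precursor charge $z$
(searched only for $z \in 4..7$, where cross-linked pairs concentrate)
the neutral mass is $M = z\,m/z - z\,m_p$. All peptide pairs $(A, B)$
from the search database satisfying

$$\left|\mathrm{ppm}\!\left(M,\; m_A + m_B + 12 n_\ell\right)\right| \le 6,
\qquad n_\ell \in \{1, 2\}$$

are candidates. The database holds the $n_{top}$ most abundant proteins
(default 800, ranked by mean iBAQ when available) plus one reversed decoy
per target, digested by trypsin/P (cleavage after K/R including before
proline) with up to 4 missed cleavages.

**Scoring.** For each candidate, every theoretical ion of both peptides —
series a/b/y, charges $1..z-1$, unshifted and +12 Da-shifted — is matched
against the peak list at 8 ppm; the count of distinct matched theoretical
ions per peptide is the fragment score. Confidence follows two rules
applied to the matched counts $f_A, f_B$ and peptide lengths
$n_A, n_B$:

* **high**: $(f_A + f_B)/(n_A + n_B) > 1.5$ *and* $\min(f_A, f_B) > 18$;
* **intermediate**: $\min(f_A, f_B) > 15$;
* otherwise rejected.

One best hit is kept per spectrum (ties: higher ratio, then higher
minimum fragment count, then lexicographic accession pair).

**Site assignment.** Since the bridge cleaves during fragmentation the
linked residue is usually ambiguous; the default site is the middle
residue (N-terminal of the two central residues for even lengths). When
shifted/unshifted evidence brackets the linker — a shifted $y_k$ places
it within the last $k$ residues, an unshifted $y_k$ outside them, and
symmetrically for b/a ions — the site becomes the middle of the
intersected interval, and the interval is reported. Contradictory
evidence (possible with noise peaks matching by chance) collapses back to
the full peptide. A note records whether a K/R lies in the interval;
residue reactivity never changes scores.

**Replicate consensus.** Hits are aggregated per condition into
residue-pair cross-links. Two hits are the same cross-link when their
site-uncertainty intervals overlap on both peptides (the intervals always
contain the true site, so evidence of the same physical link merges even
when the assigned middle residues differ); the consensus site is the
middle of the running intersection. Peptide-pair granularity is available
via `by_peptide = TRUE`. The per-replicate evidence pattern maps to the
1–7 score (3 high = 1; 2 high = 2; 1 high + ≥1 intermediate = 3;
3 intermediate = 4; 2 intermediate = 5; 1 high = 6; 1 intermediate = 7),
and links with score ≤ 4 are accepted. With more than three replicates
the table generalises by category counts. An intra-protein link whose
supporting peptides overlap in protein coordinates is flagged as a
homo-multimer contact — one molecule cannot contribute the same residue
to both peptides.

**Structure validation.** Protein sequences are mapped to chains by
ungapped sliding alignment (≥ 90% identity over the aligned span by
default); over all chain-copy combinations the minimum Euclidean Cα–Cα
distance is reported, except that homo-multimer links require distinct
chains. The restraint is 30 Å; exactly 30 Å counts as satisfied (the
convention chosen where the strict "<30 / >30" phrasing leaves equality
open).

## Quantitative proteome statistics

* **iBAQ** divides protein intensity by its count of theoretically
  observable tryptic peptides (digestion at 0 missed cleavages, length
  7–30); **relative iBAQ** divides by the per-sample total and sums to 1,
  so per-compartment sums are molar-fraction-like abundances. Pairwise
  condition differences per compartment use two-tailed t-tests with
  Bonferroni correction over the family of tests actually run.
* **Equalise medians**: each sample's log2 intensities are shifted so all
  sample medians equal the grand median of medians (idempotent).
* **Differential abundance**: per-protein two-sample two-tailed t-test on
  normalised log2 values (pooled-variance Student by default — the
  simplest contract consistent with a model-based pipeline; Welch by
  flag), Benjamini–Hochberg adjustment across tested proteins, calls at
  |log2FC| > 0.8 and adjusted p < 0.05. The sign convention is
  first-named condition minus second. No imputation: proteins need ≥ 2
  observations per condition to be tested; proteins observed ≥ 2 times in
  one condition and never in the other are reported as
  condition-specific rather than tested.
* **Over-representation** is a one-sided hypergeometric (Fisher) test per
  gene set with BH adjustment — deliberately generic plumbing, not a
  replication of any web service's combined score.

## qPCR quantification

Technical replicates are averaged on the Ct scale (an Open-Question
choice; averaging linearised values differs negligibly at duplicate
counts). ΔCt subtracts the reference gene (e.g. HPRT1) per sample; the
baseline is the control condition's mean ΔCt, equal to the log2 of the
geometric mean of the control samples' linear ratios — so the control's
geometric-mean fold is exactly 1. Fold = 2^−ΔΔCt. Condition comparisons
are two-tailed t-tests on the ΔΔCt (log2) scale. Primer efficiency is
estimated from a dilution series as $10^{-1/\text{slope}} - 1$ and is
reported but never used to correct fold changes (plain 2^−ΔΔCt is the
contract).

## What the synthetic generators emulate

All benchmarks run on seeded generators that record their ground truth;
one master seed fans out to per-generator child seeds by
`child_seed(seed, stream) = (seed + 1000003·stream) mod (2^31 − 1)`.

* `gen_proteome`: random sequences at natural amino-acid frequencies
  (K+R ≈ 11%, so tryptic peptide lengths are realistic) with a
  nine-compartment localisation map.
* `gen_xl_spectra`: plants cross-links between tryptic peptides
  (length 9–13; sites prefer K/R with probability 0.8), emits precursors
  at pair mass + 12 Da (24 Da for 10% of links) with Gaussian MS1 jitter
  (σ = 2 ppm, capped at 5 ppm so planted peaks stay inside the 6 ppm
  tolerance), singly charged a/b/y ladders at a configurable coverage
  (default 85%) with MS2 jitter capped at 7 ppm, and 5 uniform noise
  peaks per spectrum with intensities below the median true-fragment
  intensity. Each ion is emitted in its single physically consistent
  shift state. Not emulated: isotope envelopes, chromatography,
  neutral losses, multiply charged fragments, intensity structure —
  so passing benchmarks demonstrate the search logic, not robustness to
  every instrument artefact.
* `gen_abundance`: log-normal intensities over 3 conditions × 6
  replicates, 50 of 1000 proteins carrying a ±1.5 log2 effect in the
  second condition, residual σ = 0.3 (log2), 5% values missing
  completely at random — real tables' missingness is abundance-dependent,
  which this deliberately does not model.
* `gen_structure_toy`: per planted pair, two extended Cα traces (3.8 Å
  spacing) positioned so the planted sites sit at the exact requested
  distance, pairs separated by 1000 Å; written as minimal mmCIF in the
  canonical RCSB atom_site column layout.
* `gen_ct`: Ct = gene baseline + planted ΔΔCt + per-sample plate offset
  (shared with the reference gene, so normalisation cancels it) +
  Gaussian noise (σ = 0.2 cycles biological, 0.1 technical).

## Numerical choices and benchmark sizes

* All tolerance boundaries are inclusive (≤); confidence floors are
  strict (>), matching their "greater than" phrasing.
* Middle residue of an even-length interval: the N-terminal one.
* Fixed carbamidomethyl-Cys (+57.021464 Da) applied in both searches;
  variable modifications are off in the cross-link search by default.
* Masses are monoisotopic throughout, stated to six decimals in one
  constants function.
* The recovery benchmark uses 30 proteins / 40 links / 3 replicates
  (120 spectra per run, a few tens of seconds); the differential
  benchmark 1000 proteins × 18 samples. The expected log2FC estimation
  error is a Monte Carlo quantity (a single table's mean absolute error
  fluctuates ~±0.015 around its ≈0.14 expectation), so it is estimated
  over 30 independently generated tables; the null false-call rate over
  20–50 tables. Under a global null BH's per-dataset false-discovery
  proportion is all-or-nothing, so its mean is compared with α plus two
  Monte Carlo standard errors rather than α exactly.
* Degenerate inputs: empty peak lists score zero; spectra outside the
  charge window are skipped, not errors; compartments without mapped
  proteins are excluded from the test family; all-constant qPCR groups
  yield NA p-values.

## Known limitations

* Chain mapping is ungapped and positional over observed residues:
  models with interior unobserved stretches can mis-index downstream
  sites. Complete models (and the toys here) are unaffected.
* Loop/mono-links, open modification searches, MS1 feature detection and
  rescoring are out of scope; the second bridge of a +24 Da pair is not
  localised.
* The over-representation test is plain Fisher/BH — no combined scoring,
  no gene-set database retrieval.
* Large-assembly validation (ribosome-scale) is implemented and
  exercised on planted toys; reproducing published assembly-level tallies
  requires the corresponding deposited cross-link tables and structure
  files as inputs.
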