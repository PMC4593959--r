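---
title: "Methods: envelope fingerprinting and OIE_CARE abundance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope fingerprinting and OIE_CARE abundance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oiecare)
```

## Model and assumptions

`oiecare` identifies intact-proteoform fragments in centroided,
high-resolution HCD spectra. The model makes these assumptions:

- **Centroid data, one peak per isotopic aggregate.** Spectra are
  centroided; each observed peak is taken to be the merged centroid of
  all isotopologues sharing one nucleon-number offset (A+0, A+1, ...).
  Fine isotopic structure (e.g. ¹³C vs ¹⁵N at the same offset) is
  deliberately not resolved, matching Orbitrap product-ion resolution.
- **Known elemental compositions.** Envelopes are computed exactly from
  the ion's elemental composition; no Averagine or other average-residue
  approximation is used anywhere.
- **Positive-mode protonation.** m/z = (M + z·m_p)/z with
  m_p = 1.007276466 Da.
- **Within-envelope abundance coherence.** For a correctly assigned ion,
  experimental peak abundances are proportional to theoretical relative
  abundances, up to multiplicative noise. This is what makes a *clean*
  peak of the same envelope usable as an internal normalization
  reference, and what makes a shared peak's excess attributable to
  co-claiming ions.

## Envelope computation

Each element's isotope distribution (IUPAC/CIAAW 2013 values,
`isotope_table()`) is expressed as a distribution over nucleon-number
offsets; `n` atoms of one element are combined by binary exponentiation
of pairwise convolutions, and elements are convolved together. Each
convolution tracks, per offset, the total probability and the
abundance-weighted mean mass, so aggregate centroid masses are exact
expectations rather than nominal masses.

Numerical choices:

- Intermediate states below **1e-12 of the running maximum** are pruned.
  This threshold is deliberately conservative: with looser pruning
  (1e-10) the accumulated loss for protein-sized compositions reaches
  ~2e-9 and the total-probability invariant (sum within 1e-9 of 1) fails.
  At 1e-12 the invariant holds for every composition tested (up to whole
  intact proteins) with no measurable cost.
- After normalizing the most abundant aggregate to 100, peaks below
  **IPACO** are discarded; the theoretical envelope used for matching is
  exactly the set of peaks the spectrum is required to contain.

Correctness is verified against brute-force isotopologue enumeration
(multinomial expansion over all isotope assignments) for compositions up
to ~60 atoms, with agreement to 1e-9 in probability and 1e-7 Da in
centroid mass.

## Fragment generation

Proteoforms are expanded from per-site PTM annotations as all 2^k on/off
combinations (capped at k_max = 10 sites per protein to keep the
expansion bounded). Product ions: `b_j` is the sum of residues 1..j plus
any PTM deltas on those residues; `y_k` is the last k residues plus
water; `a_j = b_j − CO`. Neutral losses are eligibility-gated by
fragment residue content: water losses (H2O, 2H2O) require at least one
D/E/S/T in the fragment, ammonia losses (NH3, 2NH3) at least one
K/N/Q/R, and the combined H2O−NH3 loss requires both. The double losses
are treated as the same eligibility class as the single loss — losing two
waters needs a donor of the same kind, not two distinct residues; this
is the simplest rule consistent with single-loss gating. Generation is
validated by the b/y complementarity identity
`mass(b_j) + mass(y_{n−j}) = mass(precursor)` over random sequences and
PTM placements.

## Matching (fishing)

An ion is fished only if its 100 % theoretical peak finds an experimental
peak within IPMD (nearest peak in ppm; ties broken toward the smaller
absolute m/z difference, then the lower m/z). Every other above-IPACO
peak is linked the same way. The **reference peak** is the linked peak
with the highest theoretical relative abundance that is *not* an OIP;
experimental relative abundances are normalized as
`exp_rel = exp_abund × TA_r / EA_r`, which forces the reference's IPAD to
exactly 0. If every linked peak is an OIP the reference choice is
degenerate: the engine falls back to the peak with the smallest |IPAD|
under base-peak normalization and flags the match, and such groups are
never partitioned (the normalization itself would be contaminated).

IPAD is defined as the *difference* `exp_rel − theo_rel` in percentage
points, not a ratio: the worked-example values (an OIP 214 points too
abundant, and −2 after resolution) only arise under the difference
definition. Tolerance checks use unrounded values; reports round IPMD and
IPAD to integers and relative abundances to 2 decimals for display.

## OIE_CARE partitioning

For an overlap group with observed abundance `EA_OIP` and claimants
`i = 1..n`:

1. `DEA_i = TA_i × EA_r / TA_r` — the abundance the peak *should* have
   for ion i, projected from i's clean reference peak;
2. `RD = (EA_OIP − Σ DEA) / Σ DEA`;
3. `final_i = DEA_i × (1 + RD)`.

Substituting (2) into (3) gives
`final_i = EA_OIP × DEA_i / Σ DEA` — proportional allocation. The
implementation keeps the three-step form (2n + 1 arithmetic operations
per group) and carries RD at full precision; tests verify both the
algebraic identity and abundance conservation on 1,000 random groups.

Resolution is a **single pass**: groups are detected once from the fished
matches, partitioned independently, and the partitioned abundances are
installed before verdicts are re-evaluated. The fished-ion set is
invariant — resolution can flip verdicts but never adds or removes ions.
A group is only partitioned when at least one claimant's provisional
IPAD is ≥ 0 (`gate_nonneg = TRUE`, the default): a shared peak that is
*below* every claimant's expectation carries no excess to redistribute,
and splitting it would push all claimants further into deficit.

## Parameters and defaults

| Parameter | Default (product) | Rationale |
|---|---|---|
| IPACO | 20 % | Peaks below ~20 % relative abundance of product-ion envelopes sit near the noise floor of intact-protein HCD spectra; requiring them produces spurious rejections. Precursor envelopes use 40 % (fewer, stronger peaks needed). |
| IPMD | 15 ppm | Matches routinely calibrated Orbitrap mass accuracy with margin for merged-centroid displacement of overlapping peaks. |
| IPAD | 50 points | Wide enough for multiplicative abundance noise of weak product ions; precursor matching uses 100. |
| max product charge | 15 | Product ions above 15+ are rare below m/z 2000. |
| PMP minimum | 5 % | A PrSM whose matched b/y ions cover under 5 % of the theoretical ion set is indistinguishable from chance. |
| FDR α | 0.01 | Standard 1 % decoy-estimated FDR; the cutoff is the loosest score threshold with decoy/target ratio strictly below α (a ratio exactly equal to α resolves to the stricter cutoff). |

## Scoring and FDR

Sequence coverage is `min(100, (j + k) × 100 / n)` for the largest
matched b index j and y index k; bond coverage counts distinct cleavage
sites (b_i and y_{n−i} cut the same bond); PMP is the percentage of the
`2(n−1)` theoretical b/y ions matched, with charge states and neutral
losses collapsed. The PTM localization count is the number of
charge-collapsed site-containing ions that exclude at least one
alternative candidate site (all site-containing ions when there is no
alternative). PrSMs are ranked by matching-ion count with bond coverage
(scaled by 1e-4) as tie-break — a deliberately simple, fully documented
substitute for probabilistic scores whose null models are not
re-implemented here. Decoys (reversed or composition-preserving shuffled
sequences, `DECOY_` prefix) drive the FDR filter; calibration is tested
by simulation (empirical FDR within binomial error of α over 200
replicates, and near-zero acceptance under a pure null).

## Synthetic spectra

`simulate_spectrum()` builds a spectrum from a proteoform and a list of
ion labels: honest theoretical envelopes (m/z values are never edited to
force an overlap), greedy merging of peaks that fall within the stated
ppm tolerance of a cluster's abundance-weighted running centroid,
multiplicative log-normal abundance noise parameterized by a coefficient
of variation (`sdlog = sqrt(log(1 + cv²))`, mean-preserving), uniform
m/z jitter in ppm, and uniform-random chemical-noise peaks capped at 5 %
of the strongest signal. The returned ground truth maps every true
isotopic peak to its observed spectrum index and lists every engineered
overlap group, which is what the recovery tests check against
(exact recovery at zero noise; median relative error ≤ 0.15 at cv 0.05
over 100 seeds). The generator saves and restores the global RNG state.

Realism limits: peak shapes, detector saturation, charge-state
deconvolution artifacts and co-isolation chimera are not modeled; noise
is independent across peaks. The generator is a calibration instrument,
not a full instrument model.

## End-to-end example

```{r}
pf <- proteoform("MYG_HORSE", read_proteins(
  system.file("extdata", "MYG_HORSE.fasta", package = "oiecare"))[[1]])
ions <- c("y10-1+", "y20-2+", "y72-7+")
sim <- simulate_spectrum(pf, ions, c(202588.8, 416521.9, 120854.8),
                         noise_cv = 0, ppm_jitter = 0, seed = 1)
db <- generate_fragments(pf, series = "y", max_charge = 7, ipaco = 20)
db <- db[db$label %in% ions, ]
p <- search_params(ipaco = 20, ipmd = 15, ipad = 50)
matches <- fish_spectrum(db, sim$spectrum, p)
vapply(matches, `[[`, "", "verdict")
res <- resolve_spectrum(matches, sim$spectrum, p)
vapply(res$matches, `[[`, "", "verdict")
```

Problem sizes used throughout validation: compositions up to whole
intact proteins (envelopes), 1,000-group and 1,000-claimant partitioning
(exact, < 1 s), 100-seed noisy-recovery sweeps, and a miniature
single-spectrum search pipeline. Dataset-scale statistics (thousands of
PrSMs from raw LC-MS/MS runs) are out of scope for a self-contained
package and are documented as such in the test suite.
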