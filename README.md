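# oiecare

A top-down proteomics fragment-matching engine built around **OIE_CARE**,
a closed-form method for resolving **overlapping isotopic envelopes
(OIEs)** in high-resolution tandem mass spectra of intact proteins.

## The problem

In top-down MS/MS an intact proteoform fragments into large, highly
charged b/y ions. Each ion appears not as one peak but as an isotopic
envelope whose shape is fixed by the ion's elemental composition. Because
hundreds of envelopes crowd into a narrow m/z range, isotopic peaks from
different ions frequently fall within instrument tolerance of each other
and are recorded as a single merged centroid — an **overlapping isotopic
peak (OIP)**. The merged peak's abundance is far too high for every ion
that claims it, so otherwise-correct fragment identifications fail the
abundance test and are discarded.

Matching is performed by isotopic *envelope* fingerprinting. For every
candidate ion the engine computes the exact theoretical envelope from the
elemental composition (isotope-distribution convolution, no Averagine
approximation) and compares it against the spectrum under three
thresholds:

- **IPACO** — isotopic peak abundance cutoff: theoretical peaks below
  this relative abundance (%) are not required to be observed.
- **IPMD** — isotopic peak m/z deviation (ppm) between a theoretical
  peak and the experimental peak linked to it.
- **IPAD** — isotopic peak abundance deviation (percentage points)
  between the experimental relative abundance (normalized via a clean
  *reference* peak of the same envelope) and the theoretical relative
  abundance.

An ion is *matching* only when every above-cutoff peak is linked within
IPMD and every linked peak agrees within IPAD.

## The method

When several fished ions claim the same experimental peak, OIE_CARE
partitions the observed abundance `EA_OIP` among the claimants in closed
form. For claimant *i* with theoretical relative abundance `TA_i`, whose
reference peak has experimental abundance `EA_r` and theoretical relative
abundance `TA_r`:

1. ideal abundance: `DEA_i = TA_i × EA_r / TA_r`
2. relative deviation: `RD = (EA_OIP − Σ DEA) / Σ DEA`
3. final abundance: `final_i = DEA_i × (1 + RD)`

which is exactly a proportional allocation of `EA_OIP` by the ideal
abundances: the partitioned abundances conserve the observed total, and
RD is carried at full precision (the printed 2-decimal value is display
only). Each overlap group costs `2n + 1` arithmetic operations for `n`
claimants. Only groups in which at least one claimant shows an abundance
*excess* (provisional IPAD ≥ 0) are partitioned; deficit-only overlaps
are left untouched.

The surrounding engine provides everything needed to use the method in a
search: exact envelope computation, proteoform expansion from PTM
annotations, a/b/y ion generation with neutral losses, spectrum I/O
(MGF / peak-list TSV / centroided mzML), PrSM scoring (sequence and
bond coverage, percentage of matching peaks, PTM localization counts),
decoy-based FDR filtering, a synthetic-spectrum generator with ground
truth, and a command-line interface (`inst/scripts/oiecare`).

## Worked example

The package ships a fixture with a real overlap: three myoglobin y ions
(y10 1+, y20 2+, y72 7+) collide at m/z 1142.6177, a peak of abundance
480992.3125. Before resolution the shared peak is 214, 15 and 343
percentage points too abundant for the three ions, and two of the three
are non-matching:

```r
library(oiecare)
fixture <- system.file("extdata", "oip_worked_example_match_report.tsv",
                       package = "oiecare")
rep <- read_report(fixture)
rep[, c("ion", "theo_rel", "exp_rel", "ipad", "is_oip", "verdict")]
#>      ion theo_rel exp_rel ipad is_oip      verdict
#> 1 y10-1+    63.64   63.64    0  FALSE non-matching
#> 2 y10-1+    23.01  237.41  214   TRUE non-matching
#> 3 y20-2+   100.00  115.48   15   TRUE     matching
#> 4 y20-2+    67.65   67.65    0  FALSE     matching
#> 5 y72-7+    55.06  397.99  343   TRUE non-matching
#> 6 y72-7+   100.00  100.00    0  FALSE non-matching
```

Partitioning the shared abundance:

```r
res <- resolve_match_report(rep)
res$resolution
#>   group   exp_mz   ea_oip    ion   ta_i     ea_r   ta_r       dea     final
#> 1     1 1142.618 480992.3 y10-1+  23.01 128926.9  63.64  46615.47  42330.62
#> 2     1 1142.618 480992.3 y20-2+ 100.00 281777.1  67.65 416521.90 378235.58
#> 3     1 1142.618 480992.3 y72-7+  55.06 120854.8 100.00  66542.65  60426.11
#>      rd ipad_before ipad_after
#> 1 -0.09         214         -2
#> 2 -0.09          15         -9
#> 3 -0.09         343         -5
```

The summed ideal abundance is 529680.016342, so the observed 480992.3125
is 9.19 % low (RD = −0.09 at 2 decimals); each ion receives its ideal
share scaled down accordingly. After installing the partitioned
abundances the deviations collapse to −2, −9 and −5 percentage points
and all three ions become matching:

```r
res$report[, c("ion", "exp_rel", "ipad", "is_oip", "verdict")]
#>      ion exp_rel ipad is_oip  verdict
#> 1 y10-1+   63.64    0  FALSE matching
#> 2 y10-1+   20.89   -2   TRUE matching
#> 3 y20-2+   90.81   -9   TRUE matching
#> 4 y20-2+   67.65    0  FALSE matching
#> 5 y72-7+   50.00   -5   TRUE matching
#> 6 y72-7+  100.00    0  FALSE matching
```

The same flip can be produced end to end from a spectrum: simulate the
three colliding envelopes with `simulate_spectrum()`, fish them with
`fish_spectrum()` at tolerances IPACO 20 / IPMD 15 / IPAD 50, and resolve
with `resolve_spectrum()` — see `vignette("oiecare-methods")`.

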