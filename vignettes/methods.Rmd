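---
title: "Methods: transcript-to-carbon calibration and the synthetic cruise generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-to-carbon calibration and the synthetic cruise generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinofactor)
```

## The model

Each plankton group's absolute transcript concentration *T*
(10⁹ transcripts L⁻¹) is modeled as a power law in its carbon biomass
*C* (µg C L⁻¹):

$$T = a\,C^{b}, \qquad \log_{10} T = \log_{10} a + b \log_{10} C.$$

Fits are ordinary least squares on the log10 scale, which corresponds to
multiplicative lognormal measurement noise — the natural error model for
quantities assembled from sequencing counts and cell-size power laws,
both of which have errors roughly proportional to their magnitude.

The calibration constant of interest is the **Dino-factor**, the ratio
of the dinoflagellate intercept to the pooled non-dinoflagellate
intercept:

$$F = \frac{a_{\mathrm{dino}}}{a_{\mathrm{other}}},
\qquad
\mathrm{SE}(F) = F\sqrt{
  \left(\frac{\mathrm{SE}(a_{\mathrm{dino}})}{a_{\mathrm{dino}}}\right)^2 +
  \left(\frac{\mathrm{SE}(a_{\mathrm{other}})}{a_{\mathrm{other}}}\right)^2}.$$

Each intercept SE comes from the delta method applied to the fitted
log-intercept: $\mathrm{SE}(a) = \ln(10)\,a\,\mathrm{SE}(\log_{10} a)$.
The quadrature formula assumes the two fits are independent, which holds
here because they are estimated from disjoint sets of points. An
alternative estimator, `dino_factor_offset()`, fits a single ANCOVA
`log10 T ~ log10 C + is_dino` and returns $10^{\hat\beta_{\mathrm{dino}}}$;
it assumes a common slope but uses a pooled residual variance. The two
routes are kept separate and never averaged.

Fits with only two points are reported with their coefficients but with
all standard errors set to `NA`: a two-point OLS line has zero residual
degrees of freedom, so any SE would be meaningless, and every quantity
derived from such a fit (including the Dino-factor SE) inherits the `NA`.

## Input pathways

### Spike-in normalization

A known number of synthetic standard transcripts is added to each sample
before extraction. The normalization factor is

$$\mathrm{factor} =
  \frac{\mathrm{standards\ added}/\mathrm{standards\ retrieved}}
       {\mathrm{volume\ sampled\ (L)}},$$

and a contig's absolute concentration is
`mapped_reads * factor / 1e9` (reported in units of 10⁹ transcripts
L⁻¹). Contigs with fewer than 10 mapped reads are discarded **before**
normalization (`filter_contigs()`); applying the filter after
normalization would make the threshold depend on per-sample recovery,
which varies by orders of magnitude. Two per-group pools are
accumulated: *total* mRNA (all retained contigs) and *functional* mRNA
(contigs carrying a KO functional annotation). Functional is a subset
of total by construction.

### Imaging biomass

Each classified cell image yields a biovolume $V$ (µm³); its carbon
quota is the allometric power law $C_{\mathrm{cell}} = a_{\mathrm{alo}}
V^{b_{\mathrm{alo}}}$ in pg. Defaults are the standard protist
regressions — diatoms $a = 0.288, b = 0.811$; all other protists
$a = 0.216, b = 0.939$ — shipped both as `default_allometric_coefficients()`
and as an overridable TSV in `inst/extdata/`. Sample biomass is the sum
of quotas divided by the analyzed volume, converted pg → µg, so units
are µg C L⁻¹. Samples are binned into 1°-latitude floor bins
(`floor(latitude)`), and bin biomass is the unweighted arithmetic mean
over samples in the bin.

### Co-location

Transcript samples are replicate-averaged first (linear scale by
default; `scale = "log10"` gives the geometric mean for users who
prefer averaging on the fitted scale), then matched to the biomass bin
whose center $(\mathrm{bin} + 0.5)$ is nearest in latitude. A sample at
an exact bin edge is assigned to the bin that contains it under the
floor convention. Samples farther than `max_distance` (default 1.0°)
from every bin center are dropped with a warning, and matched pairs with
a zero on either axis are dropped with a message before taking logs.

## Inference on the matched points

- `compare_models()` fits three families to the same matched points —
  `lm(T ~ C)`, `lm(log10 T ~ log10 C)`, and `nlsLM(T ~ a*C^b)` — and
  ranks them by Gaussian AIC with $k = 3$ parameters each. AICs are
  computed on the response scale each model was actually fit on, with
  no Jacobian back-transformation; this is the convention under which
  the comparison is reported, and it means the cross-scale comparison
  favors whichever scale compresses the residuals, so the ranking should
  be read as "which error model describes these data", not as a formal
  likelihood-ratio statement.
- `ancova_taxa()` fits `lm(log10 T ~ log10 C + taxon)`, reports partial
  F-tests for carbon and taxonomy via `drop1()`, and (optionally)
  Tukey-adjusted pairwise comparisons of adjusted means via `emmeans`.
  Taxa whose pairwise comparisons are all non-significant at `alpha`
  are merged into common groups by connected components.
- `calibrate()` packages the per-pool fits, factors, model comparison,
  and ANCOVA into one report object with `tidy()`/`glance()` tidiers
  and an `autoplot()` method.

## The synthetic cruise generator

The generator exists so the whole pipeline can be tested against a known
truth. It emulates a meridional transect survey:

1. **Biomass field.** Stations are equally spaced in latitude; each
   group's biomass is log-linear in latitude, parameterized by its
   southern-end biomass and an exact endpoint fold-change. True
   transcript concentrations follow $T = aC^b$ exactly.
2. **Cells.** Per station, cell count is Poisson with mean chosen so the
   expected summed carbon matches the target biomass: the mean per-cell
   quota is computed from the closed-form moment of the truncated
   lognormal ESD distribution (spherical cells, ESD truncated to 3–100
   µm, the instrument's detection range).
3. **Transcriptome.** Per sample, the true concentration is perturbed by
   multiplicative lognormal noise $10^{\mathcal N(0,\sigma)}$, converted
   to integer counts through a randomized spike-in recovery and sample
   volume, and split across a per-cruise fixed contig "assembly"
   (Dirichlet weights, per-contig KO flags) by multinomial draws, so
   per-group totals are conserved exactly.

Key defaults (all overridable through `cruise_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_stations`, `n_replicates` | 10, 3 | a realistic transect: enough stations for a regression, triplicate sequencing |
| `lat_min`, `lat_max` | 25, 41 °N | a subtropical-to-transition-zone gradient |
| `intercept_a` | 41.6 (dino), 6.5 (others) | configured truth $F = 41.6/6.5 = 6.4$ exactly |
| `slope_b` | 1.0 | proportional transcripts-per-carbon truth |
| `fold_change` | 8–25 per group | total biomass spans over a decade across the transect |
| `noise_sd_log10` | 0.25 | multiplicative scatter typical of field log-log residuals |
| `spike_added` | 4 × 10⁹ | standard spike dose |
| `recovery_range` | (2 × 10⁻⁵, 2 × 10⁻⁴) | keeps integer library sizes realistic and below integer overflow |
| `volume_range` | (1.5, 2.5) L | typical filtered volumes |
| `ifcb_volume` | 0.5 L | *aggregated* analyzed imaging volume per station (many small triggered volumes pooled), large enough that cell-counting error is subdominant to transcript noise |
| `esd_median`, `esd_sdlog` | per group, 8–20 µm medians | group-typical size spectra within the detection window |
| `n_contigs` | 50 per group | enough contigs that the ≥10-read filter bites only where it should |

What the generator deliberately does **not** emulate: taxonomic
misclassification, chloroplast/mitochondrial read contamination,
inter-station spatial autocorrelation beyond the smooth gradient,
tow-to-tow patchiness, diel transcription cycles, and
detection-efficiency differences between groups. Its purpose is
calibration of the estimator under a known clean truth, not ocean
realism.

Determinism: all randomness flows through `withr::with_seed` with
sub-seeds derived from the config seed (cells and transcriptome use
distinct sub-seeds), so `generate_cruise()` and `run_pipeline()` are
byte-reproducible for a given config, as checksummed in the run
manifest.

## Numerical choices

- Counts are produced with R's `round()` (IEEE half-to-even); for
  counts above ~10⁶ the relative rounding error is below 10⁻⁶, which is
  why the noiseless generator round-trips the configured $a, b$ to
  ~10⁻⁴ rather than to machine precision.
- Totals too large for `rmultinom()` are split by largest-remainder
  apportionment instead, preserving exact conservation.
- The nonlinear fit is seeded from the log-log coefficients and a
  failure to converge is reported as `AIC = Inf` with a warning rather
  than an error, so one fragile family cannot abort the comparison.

## Validation

The test suite checks each stage against independent oracles
(closed-form normal equations, brute-force group-and-average, hand-summed
fixtures) and the full pipeline against the generator's ground truth.
The replicated simulations — 200 cruises for factor recovery, 200
data sets for AIC selection, 1000 for ANCOVA null calibration — are
sized as a compromise between Monte-Carlo error and runtime;
`scripts/acceptance.R` reruns them from a single command-line seed.

## Limitations

- The intercept-ratio SE ignores any covariance between the two fits
  induced by shared binning of the biomass field; with disjoint point
  sets this is exact, but users pooling overlapping data should prefer
  the ANCOVA offset route.
- OLS on log10 biomass treats the carbon axis as error-free. When
  per-station cell counts are small, errors-in-variables attenuate the
  fitted slope and bias the intercept ratio; the generator's aggregated
  imaging volume is chosen so this regime is avoided, but real surveys
  with sparse large cells should check per-bin cell counts.
- The AIC comparison across response scales has no Jacobian correction
  (see above) and should not be over-interpreted when models on
  different scales are close.
- Two-point fits are reported without SEs; downstream factors lose
  their SEs accordingly rather than fabricating an uncertainty.
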