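---
title: "Methods: sediment-core blue-carbon accounting in sedcarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sediment-core blue-carbon accounting in sedcarbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedcarbon)
```

# The problem

Seagrass meadows accumulate organic carbon (C~org~) in their sediments over
centuries. When the habitat is destroyed mechanically — here, by the sweep of
mooring chains that carve unvegetated scars into the meadow — two things
happen to that carbon store: part of the existing deposit is eroded, and the
ongoing accumulation stops. `sedcarbon` quantifies both terms from
slice-resolved sediment cores, and scales them to the seascape with a
buffer-based scar-area analysis. It is aimed at blue-carbon scientists who
collect paired cores from disturbed and undisturbed sediments and need a
reproducible path from slice tables to a loss estimate.

# Core handling

**Depth convention.** Depths are cm below the seafloor, positive downward.
Slices are half-open intervals [top, bottom); a slice value represents the
whole interval.

**Compression correction.** Coring compresses soft sediment; the recovered
column is shorter than the barrel penetration. `decompress_depths()` applies a
uniform linear stretch by `barrel_inserted / recovered`. How the field
correction was distributed over depth is generally unknowable from the two
recorded lengths alone, so the minimal (uniform) model is the only one
implemented, and cores carry a `decompressed` flag so the correction cannot be
applied twice. Dry masses are untouched; dry bulk density (DBD) is re-expressed
per decompressed volume (`dbd_decomp_g_cm3`) so that cumulative mass-depth is
conserved exactly, while the measured laboratory DBD is retained — group
summaries of DBD should use the measured value, which is how the quantity is
conventionally reported.

**DBD from dry mass.** When a slice has a dry mass but no density, DBD is
computed from the cylinder formula using the *measured* (compressed) slice
thickness — the laboratory definition of the quantity.

**Alternate-slice gaps.** Designs that analyze every second slice leave gaps;
`interpolate_gaps()` fills them by linear interpolation at slice mid-depths
with nearest-value extension at the ends. For uniform 1-cm grids this is
equivalent to treating each measured slice as representative of a 2-cm band.
Interpolated slices keep `measured = FALSE`, and interpolation never modifies
a measured value or leaves the measured range.

**Grain sizes.** `classify_grain_sizes()` bins particle mass below 1 mm into
coarse sand (0.5–1 mm), medium sand (0.25–0.5 mm), fine sand (0.125–0.25 mm)
and very fine sand plus mud (< 0.125 mm), renormalized to percentages of the
< 1 mm total.

# The ²¹⁰Pb age model

Excess (unsupported) ²¹⁰Pb is the difference between total ²¹⁰Pb and the
supported activity maintained by in-situ ²²⁶Ra decay. Under constant
atmospheric flux *F* and constant sedimentation rate *s* (the CF:CS model),
the excess activity per unit dry mass declines exponentially with depth:

$$C_{xs}(z) = C_0 \, e^{-\lambda z / s},$$

so ln *C~xs~* is linear in *z* with slope −λ/s. The decay constant defaults to
λ = ln(2)/22.23 yr⁻¹ = 0.031183 yr⁻¹ (the modern evaluated half-life; it is a
function argument everywhere it appears). The fit is in linear depth (cm), not
mass depth, because rates are reported in cm yr⁻¹; a mass-depth variant can be
obtained by fitting user-constructed profiles but is not the default path.

**Supported activity** (`estimate_supported()`) is the error-weighted mean of
²²⁶Ra measurements when present, otherwise the mean of total ²¹⁰Pb over the
deepest plateau (grown upward from the core base while each value stays within
*k*σ of the running mean, *k* = 2 by default). The estimate is invariant to
slice order.

**Mixed layer** (`detect_mixed_layer()`). Surface mixing homogenizes the top
of the profile. The detector returns the deepest depth such that all excess
values above it are mutually indistinguishable (each within *k*σ of their
common mean). The threshold *k* = 2 (≈ 95%) is used for both diagnostics; the
field literature reports outcomes ("not statistically different") rather than
a specific test, so a symmetric 2σ criterion is the natural default.

**Excess horizon** (`detect_excess_horizon()`). The datable record ends where
excess becomes indistinguishable from zero. The horizon is placed at the
*first* sub-detection point (|C~xs~| < *k*σ). The alternative — requiring
every deeper value to be indistinguishable as well — proved non-robust in
simulation: a single 2σ fluctuation at depth drags the horizon into the
noise-dominated zone and biases the fitted rate upward by ~10% under 10%
measurement noise.

**Fitting** (`fit_cfcs()`). Ordinary least squares of ln C~xs~ on mid-depth
over the window strictly between the mixed layer and the horizon, positive
excess only (negative excess values are excluded from the log fit, clipped to
zero in inventories, and counted in diagnostics). `s = −λ/slope`,
`SE(s) = λ·SE(slope)/slope²`. A fit is `ok` when the slope is significantly
negative (p < 0.05); when a mixed layer was excluded the status is `mixed` and
the rate is an upper limit; otherwise `undatable` (flat, rising or
under-determined profiles never yield a rate). The default fit is unweighted;
`weighted = TRUE` applies inverse-variance weights on the log scale with
variances evaluated at the *fitted* activities of a preliminary unweighted
pass — evaluating them at the observations would up-weight upward
fluctuations and reinforce exactly the noise the weights should suppress.

**Window refinement** (`refine_horizon()`, used by `date_core()`). Ending the
window at an *observed* sub-detection value selects the points just above the
cutoff for having fluctuated upward, which flattens the slope. After an
initial fit, the cutoff is re-placed where the fitted exponential crosses the
detection level (*k* × median σ) and the model is refit. In simulations at
the study's noise level this moves the mean rate bias from roughly +10% to
about ±1% and the empirical coverage of the nominal 95% interval to ~0.90.
`date_core()` bundles the full sequence (supported → excess → diagnostics →
fit → refinement → inventory) and is what the pipeline runs per core. A
prophylactic surface exclusion (e.g. the top 2 cm) can be supplied; it narrows
the window but, unlike a detected plateau, does not mark the rate as an upper
limit.

**Inventories and flux.** The excess inventory is the depth integral
Σ C~xs,i~ ρ~i~ Δz~i~ (Bq kg⁻¹ × g cm⁻³ × cm × 10 → Bq m⁻²), with negative
contributions clipped at zero (the unclipped sum is also reported) and σ by
quadrature. At steady state the atmospheric flux balances decay of the
accumulated inventory, `F = λI` — on a noiseless constant-flux profile the
integral closes to F/λ up to first-order discretization error, which the test
suite verifies (halving the slice thickness halves the error). Ages are
`depth / s`, flagged as extrapolated beyond five half-lives.

# Stocks, rates and loss accounting

**Stocks** (`cumulative_stock()`). Per-slice areal densities
(DBD × content/100 × thickness × 10, kg m⁻²) are summed from the surface to a
reference thickness (default 50 cm, a typical recovered core length) on
*decompressed* depths. A slice straddling the reference contributes pro-rata;
longer cores are truncated. Shorter cores are extrapolated by the mean areal
density per cm of their bottom quartile of measured depth — a local estimate
that is exact for profiles near their depth asymptote, where short cores
typically end; a linear-trend alternative is available by flag. Extrapolating
a core shorter than half the reference is refused unless forced.

**Rates** (`accumulation_rate()`). The stock divided by the time to deposit
the reference thickness at the CF:CS rate (constant accretion assumed):
C~org~ in g m⁻² yr⁻¹, CaCO₃ in kg m⁻² yr⁻¹, matching field convention. In the
usual design only one core per site and treatment is dated;
`propagate_rate_to_undated()` lets replicates inherit their group's rate while
keeping their own stocks.

**Group summaries** are descriptive: mean ± SEM (sample SD, n−1 denominator)
over per-core stock totals, never pooled slices. Hierarchical inference
(e.g. mixed models over depth-resolved values) is deliberately out of scope.

**Loss** (`stock_loss()`, `foregone_sequestration()`, `loss_estimate()`). The
eroded component is the difference of meadow and scar mean stocks with SEMs
combined in quadrature; the foregone component is rate × years since
disturbance (default 50 yr, configurable), divided by 1000 to kg m⁻². The
total is their sum, scalable to habitat-wide Mg when a scar area is supplied.

# Scar-area mapping

`scar_area_from_counts()` scales a mean per-mooring scar by the mooring count.
`map_scar_area()` works on a rasterized habitat grid (classes seagrass, bare,
reef; plain-text ESRI ASCII dialect): a bare cell is mooring-induced scar when
its *center* lies within the buffer (default 10 m, the typical swing reach of
a mooring chain) of at least one mooring. The original field workflow used
vector polygon intersection in a GIS; the center-in-buffer raster rule was
chosen because it is dependency-free and exactly checkable against a
brute-force lattice count, at the cost of a discretization error that
vanishes as cells shrink (the tests verify < 1% error at cell = buffer/100,
and convergence to πr² on an all-bare grid). Shared cells are attributed to
the nearest mooring, ties to the lowest id, so per-mooring areas partition
the union with no double counting. Hectares are rounded to 1 decimal and m²
to integers only in the report layer.

# The synthetic-data generator

`simulate_core()` generates cores under the same CF:CS model the analysis
assumes, with known ground truth (`synthetic_truth()`): excess activity
`C_xs(z) = F e^{-λz/s} / (10 s ρ(z))` so the noiseless inventory closes to
F/λ; organic carbon decaying exponentially from a surface value to a depth
asymptote; constant carbonate; grain-class means renormalized to 100%.
Optional surface mixing replaces the top layer by its mass-weighted mean
(conserving the inventory exactly) and optional erosion removes the top of
the profile before depths are re-indexed to zero — the two distinct
disturbance signatures (deep mixing vs. truncation) seen in disturbed
sediments. Activity noise is multiplicative lognormal with mean one
(activities are positive and counting-statistics-like); content noise is
normal truncated at the physical bounds. Reported measurement σ is CV × value.
Output is byte-identical under a fixed seed.

Default conditions describe a carbonate seagrass meadow: flux 38 Bq m⁻² yr⁻¹,
s = 0.25 cm yr⁻¹, supported 5 Bq kg⁻¹, DBD 0.82 g cm⁻³, C~org~ from 4% at the
surface to 1.2% at depth with an 8-cm e-folding scale (giving a 50-cm stock
near 6.7 kg m⁻²), CaCO₃ 84%, 10% activity CV, 5% content CV, 1-cm slices to
40 cm, contents analyzed on alternate slices and ²²⁶Ra on every fourth.
Four presets span the study conditions: `thomson_meadow` (datable),
`stark_meadow` (s = 0.27, supported 10, 15-cm mixed layer — at the default
noise level its post-mixing fit window is only a few slices, so replicates
are at best upper-limit dated and often undatable, a faithful rendering of
how marginal such cores are), `thomson_scar` (30-cm homogenization) and
`stark_scar` (30-cm erosional truncation, which leaves excess
indistinguishable from supported: essentially all replicates are undatable).

What the generator does *not* emulate: depth-varying compaction within the
recovered column (compression is a single uniform factor), time-varying
flux or sedimentation, bioturbation as a diffusive process (mixing is
all-or-none homogenization), spatial autocorrelation between cores, and
non-circular or coalesced scars in the seascape generator. Passing recovery
tests therefore demonstrate correctness of the estimators under the model's
own assumptions, not robustness to violations of them.

`recovery_experiment()` runs replicate cores through the full pipeline and
reports bias, RMSE and 95%-CI coverage for the sedimentation rate, flux,
stock and accumulation rate. The test suite runs 250 replicates of the meadow
configuration (a few seconds) and requires |bias| < 5% and coverage within
[0.85, 0.99]; measured values at the default conditions are ≈ +1% bias and
≈ 0.90 coverage. Problem sizes elsewhere in the suite (40–200 slices,
grids up to 240 × 240 cells) keep the whole run under ten seconds while
leaving discretization errors well below the asserted tolerances.

# The pipeline

`run_pipeline()` orchestrates the study from a single YAML configuration in
which every analysis flag above surfaces with its default: per-core
decompression, DBD filling, gap interpolation, dating (`date_core()`), stocks
for both components; group summaries; per-site and pooled loss estimates
(pooled means are means of site-group means, matching how paired designs are
usually reported); scar accounting from counts and/or a grid; and a
flux-closure check of the mean meadow flux against a reference value. It
records one structured log line per stage per core, continues past undatable
cores, and writes a full-precision JSON report plus rounded human-readable
tables (`write_report()`); re-running the same configuration reproduces the
JSON byte for byte. A thin command-line wrapper with subcommands `run`,
`simulate`, `date`, `stocks`, `loss` and `scars` ships in `inst/cli/`.

# Known limitations

- CF:CS only: no constant-rate-of-supply (CRS) or constant-initial-
  concentration models, and no independent ¹³⁷Cs validation.
- The linear compression correction and the bottom-quartile extrapolation are
  minimal-assumption choices; both are flagged in output so downstream users
  can see where they acted.
- δ¹³C is carried as data (it travels through I/O and summaries) but no
  source-mixing interpretation is attempted.
- The raster scar rule approximates the vector-GIS buffer intersection; with
  20 × 20 m cells at a 10 m buffer the discretization is coarse, and users
  should choose cell sizes well below the buffer radius.
- Uncertainty in stocks is propagated only when slice-level σ are supplied;
  otherwise group SEMs carry the between-core variability.
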