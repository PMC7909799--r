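# seasonwood

Dendroecological reconstruction of past insect defoliation events from
**seasonal** (earlywood/latewood) tree-ring widths.

Late-summer and autumn defoliators — the pine looper *Bupalus piniaria* on
Scots pine is the motivating system — feed after the year's wood is largely
formed. The damage therefore shows up in the ring record with a precise,
two-season signature: **latewood** collapses in the year *after* defoliation
(it is built from current-year photosynthate), and **earlywood** collapses in
the *second* year after (it is built largely from the previous season's
reserves). Total ring width, by contrast, reaches its minimum one to four
years late, which blurs the dating of outbreaks reconstructed from
whole-ring series.

`seasonwood` implements the **pointer-year method (PYM)** built on that
signature, three reference detectors that operate on total ring width, the
statistics for comparing them, and a synthetic-data generator so the whole
pipeline is testable without access to measurement archives.

The core quantity is the relative growth change

```
RGC_t = 100 * R_t / R_(t-1)   (%)
```

computed per tree for earlywood (EW), latewood (LW) or total width. Year *t*
is a defoliation year when, in at least `sync.l` % of trees, the latewood
RGC in year *t*+1 falls by at least `change.l` % **and**, in at least
`sync.e` % of trees, the earlywood RGC in year *t*+2 falls by at least
`change.e` %.

Also included:

* **OUTBREAK-style detector** — sustained (≥ `lng` years), abrupt
  (index ratio ≤ `abrupt`) suppressions of spline-detrended per-tree indices
  below `mean − std·sd`, aggregated over trees.
* **Moving-window method (MWM)** — synchronous strict local minima of
  absolute ring width in a ±`width`-year window.
* **MICA** — fixed-point independent component analysis of the standardized
  ring-width matrix; sustained component lows confirmed against
  site-chronology lows.
* Chronology tools: Tucson (RWL) and seasonal-CSV readers/writers,
  Baillie–Pilcher indexing, frequency-cutoff spline and double detrending,
  leave-one-out screening, EPS/SNR, EPS-reliable spans.
* Grid-search calibration of detector parameters against documented outbreak
  windows; lag-tolerant concordance (contingency tables, Fisher's exact
  test, Benjamini–Yekutieli correction, accuracy/sensitivity/specificity).
* Climate–defoliation linear modelling: bootstrapped response-function
  screening of monthly temperature/precipitation, climate-only vs
  climate-plus-defoliation-dummy models with backward AIC selection,
  bootstrap R²adj comparison, and superposed epoch analysis.
* A seed-reproducible generator of multi-tree seasonal ring-width data with
  known defoliation ground truth, and a thin command-line front end
  (`inst/cli/seasonwood.R`).

## Worked example

Simulate a 20-tree, 100-year stand with defoliation events in 1950 and 1997,
then detect them:

```r
library(seasonwood)

cfg <- synth_config(event_years = c(1950L, 1997L),
                    extra_width_suppression = 0.25, seed = 42L)
sim <- simulate_site(cfg, site_id = "demo")

det <- pym_detect(sim$collection, reference_params("zareche", "pym"))
det
#> <detection_result> demo/pym, span 1915-2014: 1950, 1997
det$support
#>   year frac_latewood frac_earlywood
#> 1 1950          0.70            0.8
#> 2 1997          0.85            0.7
```

Both injected years are recovered with zero lag: in 1951, 70 % of trees show
the latewood decline and in 1952, 80 % the earlywood decline (thresholds
10 % change, 55 % synchrony). The whole-ring reference detector dates the
same outbreaks one year late, as expected from its reliance on the total
ring-width minimum:

```r
out <- outbreak_detect(sim$collection, reference_params("zareche", "outbreak"))
out
#> <detection_result> demo/outbreak, span 1915-2014: 1951, 1998

concordance_report(det, list(outbreak = out))
#>     method A B C  D acc sens spec fisher_p adjusted_p
#> 1 outbreak 2 0 0 98   1    1    1 0.000202   0.000202
```

Within the 0–4-year matching window the two reconstructions agree perfectly
(sensitivity 1), and the agreement is far beyond chance (Fisher p ≈ 2e-4).
Chronology quality of the simulated stand:

```r
eps_snr(lapply(sim$collection$trees, spline_detrend))
#> <chronology_stats> 1915-2014, n = 20: rbar 0.247, EPS 0.868, SNR 6.58
```

## Vignette

`vignettes/seasonwood-methods.Rmd` documents the model assumptions, every
tunable parameter, the synthetic-data design (what it emulates and what it
deliberately does not), and the numerical choices.
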