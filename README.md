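# shearlog

Archival geolocators (GLS loggers) weigh a gram or three, record ambient
light and saltwater immersion for a year, and are the workhorse for tracking
small pelagic seabirds such as Manx shearwaters across their trans-equatorial
annual cycle. `shearlog` is an R package that takes a pipeline from those two
raw sensor streams all the way to ecological inference:

* **Geolocation** — twilight events from a 10-unit light threshold; latitude
  by numerically inverting the sunrise equation
  `cos H0 = (sin a − sin φ sin δ) / (cos φ cos δ)` at a per-track calibrated
  sun elevation angle `a` (candidates −3° to −5°, selected against the known
  colony latitude in summer); longitude from the offset of apparent midday
  from Greenwich, via the equation of time. Rolling 3-day smoothing
  (circular in longitude), fence-inclusive 1.5×IQR outlier removal, equinox
  masking with reported (never imputed) coverage, and mean January position
  as the non-breeding location.
* **Behaviour** — 10-min immersion scores 0–200 (200 three-second wet/dry
  samples per bin): 0 = flight, 200 = rest on water, intermediate =
  foraging. Colony attendance via the ≥ 6 h daytime-dry burrow rule, a
  two-component Gaussian EM mixture over nightly wet-event counts for night
  visits (posterior of the drier component > 0.5), ≥ 3-day dry runs as
  incubation evidence, and day-length-standardised foraging effort.
* **Phenology** — southbound start, northbound start and colony return from
  longitude alone (equinox-proof), by an explicit run-length rule (K = 5 d,
  D = 10°) refined to the movement edge.
* **Environment** — seasonal climate-index means (SOI Oct–Dec; NAO Dec–Mar
  winter / Jun–Aug summer) and the latitude of peak January chlorophyll in
  the Patagonian-shelf box (35–45° S, 59–63° W).
* **Inference** — recursive path analysis over the annual-cycle graph with
  χ²/df, CFI, TLI, RMSEA and SRMR; the SEM Bonferroni rule
  α = 0.05 / k^(1−r̄); random-intercept mixed models with likelihood-ratio
  tests and seeded parametric-bootstrap CIs (lme4); van de Pol & Wright
  within/between subject centring; a skipped-breeding logistic GLM with a
  Firth fallback under separation; and a chick peak-mass validation model
  with burrow as a random effect.
* **Synthetic data** — a forward simulator (tracks, light, behaviour,
  immersion, climate index, chlorophyll fields) with full ground truth, so
  every stage is testable by parameter recovery. The within-individual
  response of wintering latitude to the climate index (−0.30 ° per index
  unit by default) is the headline quantity the pipeline must recover.

See `vignettes/methods.Rmd` for the models, assumptions, and design choices.

## Worked example

```r
library(shearlog)

cfg <- run_config(out_dir = "scratch/demo", seed = 5,
                  sim = list(n_birds = 8, n_years = 4, shading_prob = 0.02),
                  nboot = 100)
res <- run_pipeline(cfg)
res$accounting
#>       stage rows_in rows_excluded rows_out
#> 1 geolocate      32             0       32
#> 2 phenology      32             0       32
#> 3 behaviour      32             0       32

round(unlist(res$centring$within), 3)
#> estimate      ci1      ci2
#>   -0.288   -0.410   -0.150
```

The simulator generated 32 bird-years whose winter latitude follows the
index with a true within-individual slope of −0.30; the pipeline — light →
twilights → calibrated positions → January means → subject-centred mixed
model — recovers −0.29 with a bootstrap CI comfortably covering the truth.
The summary table (`res$summary`) carries one row per bird-year with January
latitude/foraging, August foraging and colony visits (which matched the
simulator's true visit nights exactly in this run), migration dates, the
index and the chlorophyll-peak latitude; `res$path` holds the path-model
coefficients and fit indices for the annual-cycle graph.

Per-stage artifacts are plain CSVs under `out_dir` with JSON manifests
(config and input hashes), so re-runs skip unchanged stages and a deleted
artifact recomputes deterministically.

A thin command-line wrapper is installed at `inst/cli/shearlog.R`:

```sh
Rscript inst/cli/shearlog.R run --config config.json --seed 5 --out-dir out/
```

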