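---
title: "Methods: from raw geolocator records to carry-over inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw geolocator records to carry-over inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

shearlog turns raw archival-logger records from pelagic seabirds — a light
trace and a saltwater-immersion trace per bird-year — into migratory
phenology, non-breeding location, behavioural time budgets, and the
statistical layer that links an ENSO-type climate signal to within-individual
shifts in wintering latitude and their carry-over into the next breeding
season. This vignette explains each model, its assumptions, the tunable
parameters, and the design choices that were genuinely open.

## Threshold geolocation

**Model.** A twilight event is the time the light trace crosses a fixed
intensity threshold (10 logger units by default, the conventional "10 lux"
convention for these devices). Between a sunrise and the following sunset,
day length determines latitude through the sunrise equation

$$\cos H_0 = \frac{\sin a - \sin\varphi \sin\delta}{\cos\varphi \cos\delta},$$

where $H_0$ is half the day length expressed as an hour angle, $\delta$ the
solar declination, $a$ the sun elevation angle assumed at threshold crossing,
and $\varphi$ the latitude solved for numerically (bisection via `uniroot`,
0.01° tolerance). The midpoint of the two twilights, corrected by the
equation of time, gives longitude at 15°/h. Declination and the equation of
time use the closed-form low-precision trigonometric expansions (about 0.01°
in $\delta$); the same solar implementation serves the forward light
simulator, the geolocation inversion, and the night/day definitions of the
immersion module, and a test pins them equal.

**Calibration.** Light sensors differ between devices, so $a$ is selected
per track: candidate angles (default −3° to −5° in 0.5° steps) are scored by
the median absolute deviation of estimated summer latitudes from the known
colony latitude, over a June–July window when the bird is reliably at the
colony. Ties break toward the smaller $|a|$. At least 10 valid summer
estimates are required per candidate.

**Error handling.** Near the equinoxes ($|\sin\delta| < 0.01$) day length is
latitude-independent; the estimate is returned invalid with reason
`equinox-degenerate`, and `mask_equinox()` (default ±15 days) additionally
invalidates estimates near the equinox and *reports* the masked fraction —
nothing is imputed. Positions are smoothed with a centred 3-day rolling mean
over valid estimates only (minimum one valid member), with longitude always
averaged on the circle so the date line and prime meridian are safe. Monthly
positions apply a Tukey fence-inclusive IQR filter (the multiplier is not
dictated by convention in the source workflow; 1.5×IQR with values exactly
at the fences retained was chosen, applied per bird-month) before averaging;
mean January position is the non-breeding foraging-ground location.

**What passing tests show.** On noiseless simulated light the round trip
recovers position to a median of ~0.15° and, at 2-minute sampling, to better
than 0.5° everywhere more than 15 days from an equinox. At the native
10-minute sampling the interpolation of a steep log-light curve adds up to
~1 minute of twilight error, which the near-equinox sensitivity can amplify
to ~1° — real devices behave the same way, which is why the January (not
equinox-adjacent) mean is the inference input.

## Migration phenology

Dates come from longitude alone, which is immune to equinox error. The
original field workflow dated migrations by visual inspection; reproducibility
demands an algorithm, so the package fixes a run-length rule: a southbound
start is the first day of a run of at least K days (default 5) displaced more
than D degrees (default 10) from the colony longitude; the northbound start is
the first sustained displacement from the mid-winter longitude centroid back
toward the colony; the return is the first sustained run within D of the
colony. Because a threshold is necessarily crossed a few days *into* a
migration leg (and, for the return, a few days *before* arrival), each date is
then refined along the monotone displacement ramp to the movement edge, using
a small epsilon (1°, configurable as `eps_lon`). K, D and epsilon are exposed
in the configuration; on noiseless synthetic tracks the rule recovers true
dates within ±1 day, and the acceptance checks require ±3. Incomplete tracks
yield missing dates with a reason, never guesses.

## Behaviour from immersion

Loggers sample wet/dry every 3 s and sum over 10 minutes, so scores run 0–200.
At sea: 0 = dry (flight), 200 = wet (rest/preening), 1–199 = intermediate
(foraging). Colony attendance is inferred separately, because a dry night is
ambiguous between colony attendance and night flight:

* **Daytime burrow rule** — a continuous dry spell of ≥ 6 h lying entirely
  between sunrise and sunset (these birds do not leave the burrow in
  daylight). The boundary is exact: 36 ten-minute bins qualify, 35 do not.
* **Night visits** — per night (sunset to next sunrise), bins with any
  immersion are counted as wet events; a two-component Gaussian mixture is
  fitted to the nightly counts by EM (means initialised at the 25th/75th
  percentiles, equal weights, common initial SD; iterate until the
  log-likelihood gain is below 1e-8, 1000-iteration cap; components ordered
  so the drier mean comes first). A night is a colony visit when its
  posterior probability of the drier component exceeds 0.5. The mixture is
  fitted per bird-season by default (`mixture_scope`); degenerate inputs
  (all counts identical, variance collapse) raise errors rather than
  returning a fit.
* **Incubation** — any completely dry run of ≥ 3 days (432 bins) is evidence
  of a breeding attempt; again the boundary is exact (431 bins is not).

August colony visits count distinct visit nights plus daytime-only burrow days
not adjoining a counted night (a continuous night–day–night stay counts once).
Whether daytime-only stays contribute is an interpretation the source
workflow leaves open; both behaviours are available via
`count_daytime_burrow`, with inclusion the default.

Foraging effort is the intermediate daylight hours at sea divided by day
length at the reference position — the mean January position for non-breeding
effort, the colony for August — so effort is comparable across latitudes.
Proportions above 1 (night foraging spilling into the count) are flagged,
never clipped: they are evidence, not errors. Devices recording at other bin
widths are rejected at read time.

## Environmental covariates

The SOI covariate is the October–December mean (the months that set up
Southwest-Atlantic non-breeding conditions); winter NAO averages
December–March with December assigned to the *following* year's winter;
summer NAO averages June–August. A year missing any required month yields NA
with a reason. The chlorophyll-peak latitude within the Patagonian-shelf box
(35–45° S, 59–63° W; the box's published notation uses non-standard signs
and was interpreted accordingly) is, by default, the latitude maximising the
missing-aware zonal (longitudinal) mean — robust to single-pixel blooms —
with `max-cell` available as an alternative; ties resolve toward the box
centre, and boxes with under 50% coverage return NA.

## Statistical layer

**Path analysis.** The annual-cycle graph (climate index → January latitude →
January foraging; previous-August foraging → January foraging → next-August
foraging → colony visits; southbound → northbound start → return; plus the
tested-but-weak phenology edges) is a recursive system of observed variables,
so maximum-likelihood coefficients equal equation-wise least squares (a
property the tests assert to 1e-8) with information-matrix standard errors
(residual variance RSS/n). Fit is judged against the saturated covariance:
$\chi^2 = (n-1)F_{ML}$, CFI/TLI against the independence baseline,
$\mathrm{RMSEA} = \sqrt{\max(\chi^2-\mathrm{df},0)/(\mathrm{df}(n-1))}$, and
SRMR as the root mean squared standardised residual covariance. Variables are
standardised by default (coefficients on the standardised-β scale), with raw
scale available. Exogenous variances/covariances are free, so the saturated
model has exactly zero chi-square. Complete cases are used per model, with
row counts retained.

**Multiple testing.** The SEM-specific Bonferroni rule is
$\alpha_{\text{per test}} = 0.05 / k^{1-\bar r}$ with $k$ the number of tests
and $\bar r$ the mean absolute correlation among tested variables; the
published typography of this formula is ambiguous and this reading (ordinary
Bonferroni at $\bar r = 0$, no correction at $\bar r = 1$) is the one
implemented. $\bar r$ is an explicit argument, never guessed.

**Mixed models.** Random-intercept models are fitted with lme4 (REML for
estimates); significance of a focal fixed effect comes from a
likelihood-ratio $\chi^2_1$ between ML fits, and confidence intervals from a
seeded parametric bootstrap (percentile 2.5/97.5, default 1000 draws;
identical seeds reproduce identical CIs). Singular random-effect fits are
flagged, not hidden. The subject-centring decomposition splits a covariate
into per-individual means (between effect) and deviations (within effect);
the between-minus-within difference is read off the reparametrised model
`y ~ x + xbar + (1|id)`, whose `xbar` coefficient equals that difference.
The skipped-breeding model is an ordinary logistic GLM; under separation the
fit is flagged and Firth-penalised (Jeffreys-prior score correction)
estimates are reported, since ML diverges. Chick peak mass is validated
against colony visits with burrow as the random effect and the weighing date
as a fixed covariate.

## The synthetic-data generator

The generator's defaults encode the study conditions: a Welsh-island colony
(51.74° N, 5.29° W), a September southbound migration (mean day-of-year 260)
to a Patagonian-shelf wintering position (latitude base −42°, longitude
−56°), a March return (DOY 60–85), and winter latitude responding to an
ENSO-like index as

$$\text{lat}_{ij} = -42 + \beta_w \, \text{index}_j + b_i + \varepsilon_{ij},$$

with the within-individual slope $\beta_w = -0.30$ ° per index unit (a
plausible magnitude for this system), per-bird offsets with SD 0.8°, and
residual SD 0.2°. The index is a monthly AR(1) (coefficient 0.5, innovation
SD 1), whose October–December mean drives both the winter latitude and the
January chlorophyll ridge (peak latitude = −40 + 2.4 × index + noise on a
0.5° grid). Light is a log-scaled saturating function of solar elevation at
the true position, calibrated so 10 units is crossed exactly at the
configured twilight angle (−4° by default) and clipped at 64, like a real
logger; shading events only reduce light. Behaviour is a first-order Markov
chain over flight/forage/rest with separate day and night transition
matrices, overlaid with breeding-season night colony visits (probability
0.35, preceded by a short dusk rafting spell on the water — Poisson mean 1.5
bins — as in real traces, which also keeps the mixture's dry component
non-degenerate) and June incubation stints (two stints of five days);
immersion maps states deterministically (flight/colony 0, rest 200, forage
uniform 1–199).
Each bird-year draws from its own RNG stream derived from (seed, bird, year),
so outputs are bit-identical under re-runs and independent of evaluation
order. All timestamps are UTC and bins align to clock 10-minute boundaries;
the simulator does not avoid equinoxes — masking is the pipeline's job.

**What the simulator does not emulate:** oceanography, wind and prey fields;
device failure modes beyond shading; position drift within the wintering
period; sensor-specific light response curves; behavioural seasonality beyond
the day/night matrices. Passing recovery tests therefore demonstrate that
the algorithms invert the stated forward models correctly — not that real
shearwater data are this clean. On real tracks, calibration error, weather
shading and equinox proximity will widen every error distribution.

## Numerical choices and problem sizes

Latitude inversion uses a 1°-grid sign-change scan followed by `uniroot`
(tolerance 1e-4°), keeping the smaller-|latitude| root if a spurious
near-polar root appears; EM tolerance is 1e-8 on the log-likelihood; the LMM
optimiser is lme4's profiled deviance with variances bounded at zero.
Simulation-based checks run at sizes chosen for precision per compute: 50
bird-years for the geolocation round trip, 500 random triples for the
latitude-inversion oracle, 200 replicates for coverage checks (2-SE edge
coverage of the path model, difference-test coverage of the centring
decomposition) with at least 99 bootstrap draws per replicate, and 500
simulations for the LRT type-I check. These sizes make binomial noise on a
nominal 95% rate about 1.5 percentage points, comfortably resolving the 93%
acceptance floors. Coverage experiments use designs (60 individuals × 6
observations) large enough that the interval's asymptotics hold; at half
that size even the Wald interval undercovers for small-sample reasons
unrelated to the bootstrap.

One genuine limitation of threshold geolocation surfaces as an explicit
invalidity reason: with a non-zero twilight angle and a small solar
declination, two latitudes can share one day length, so the estimate is
returned `ambiguous-latitude` rather than silently choosing a root. Shading
artefacts in the light trace (brief sub-threshold dips in daytime) are
removed by iteratively deleting the tightest below-window interval between
crossings — the dip itself — and flagging the surviving neighbours.

## Known limitations

Latitudes within ~2 weeks of an equinox are unusable (reported, not fixed);
the run-length phenology rule assumes a single winter centroid and will
mis-date double-winter or failed migrations; the mixture classifier needs
visit and at-sea count distributions separated by a few SDs (August at a
breeding colony satisfies this easily); the path model assumes linear,
recursive, complete-case relations among observed variables — no latent
variables, no non-recursive feedback, no imputation. The pipeline analyses
synthetic data shaped like the real archive; colony metadata are always
user-supplied, never hard-coded, because published colony coordinates in
this literature carry inconsistent sign conventions.
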