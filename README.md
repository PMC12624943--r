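# lickometry

Simulation and microstructure analysis of RFID-gated home-cage drinking
logs.

## The problem

Open-source home-cage sipper devices let group-housed rats drink from
shared, RFID-gated spouts: when a tagged rat licks the spout, a
capacitive lickometer counts licks and a stepper-driven peristaltic pump
delivers fluid, one animal at a time, logging one CSV row per drinking
bout (timestamp, device, RFID, lick count, dispensed volume). Such logs
support the full repertoire of ingestive-behaviour analysis — daily
intake normalised to body mass, two-bottle alcohol preference, circadian
structure, and bout/lick microstructure — but the analysis chain has
many small conventions (what counts as a bout, how days and light phases
are binned, how doses are computed) that are easy to get subtly wrong.

`lickometry` provides both halves of the problem for R users:

* a **digital twin** of the device — per-rat stochastic drinking
  behaviour shaped by the light cycle and fluid preference, passed
  through a firmware model (RFID gating, exclusive spout occupancy,
  gamma-rhythm lick trains, step-quantized pump with mechanical noise)
  — with exported ground truth, so every analysis routine can be tested
  by parameter recovery; and
* a **complete analysis library** for the device's bout-level and
  lick-level CSV dialects.

## The model

Bout initiations for rat *i* follow an inhomogeneous Poisson process
with rate λ_dark during the dark phase and λ_light during the light
phase of a configurable light cycle (ZT0 = lights-on). Each bout is
directed at the ethanol spout with probability *p*, carries a lognormal
lick count *N* (analysis keeps bouts with N ≥ 20), and a lick train with
gamma inter-lick intervals (mean 0.15 s ≈ 6.7 Hz). The pump delivers a
fixed number of motor steps per lick; dispensed volume is

    V = steps × uL_per_step × ε / 1000  (mL),  ε ~ per-step noise,

so volume is quantized to the step calibration constant. Key analysis
quantities:

* ethanol dose: `g/kg = V_mL × fraction_v/v × 0.789 g/mL ÷ (mass/1000)`
* preference: `100 × V_ethanol / (V_ethanol + V_water)` (by volume)
* volume per lick: `ΣV / Σlicks` per subject × fluid (pooled)
* lick microstructure: interlick interval, interbout interval, bout
  duration (first-to-last lick), lick frequency `(N−1)/duration`.

## Worked example

```r
library(lickometry)

config   <- experiment_config()            # 10% v/v ethanol vs water, 12:12
registry <- subject_registry(paste0("rat", 1:4), sprintf("RF%06d", 1:4),
                             body_mass_g = c(295, 310, 288, 305))
sim <- simulate_session(default_behaviors(registry$subject_id),
                        config, registry, duration_h = 9 * 24, seed = 1)
sim$session
#> <session_log> 2785 bouts, 235281 licks, 4 subjects, 2 devices
#>   span: 2024-03-01T20:15:11.781 .. 2024-03-10T19:44:32.927

validate_session(sim$session)
#> <session_validation>
#>   exclusivity (device-overlap) violations: 0
#>   unknown RFIDs: 0
#>   bad fields: 0
#>   implausible durations: 0
#>   timestamps sorted: TRUE

bt <- filter_bouts(sim$session, n_days = 9)
head(session_summary(bt)[, c("subject_id", "fluid", "mean_daily_mL",
                             "dark_share_pct", "preference_pct",
                             "mean_daily_g_per_kg")], 4)
#>   subject_id  fluid mean_daily_mL dark_share_pct preference_pct mean_daily_g_per_kg
#> 1       rat1 etoh10     24.726111       80.87672       83.94348            6.613187
#> 2       rat1  water      4.729556       80.13908       83.94348            6.613187
#> 3       rat2 etoh10     27.274778       78.16175       73.67778            6.941871
#> 4       rat2  water      9.744222       70.95145       73.67778            6.941871
```

Rat 1 drinks ~25 mL/day of the ethanol solution (≈6.6 g/kg/day of
ethanol at 295 g body mass), ~81% of it in the dark phase, with an 84%
two-bottle preference — the strongly preferring animal of the default
behaviour table, whose four rats span strong preference to
indifference. `daily_intake()`, `preference()`, `hourly_zt_profile()`,
`phase_totals()`, `bout_stats()`, `bout_range_volumes()` and
`lick_microstructure()` return the corresponding long-format tables.

The same pipeline is scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/lickometry simulate --config inst/extdata/example_config.txt \
    --behaviors inst/extdata/example_behaviors.csv \
    --registry inst/extdata/example_registry.csv \
    --out run1 --seed 1 --duration 216
Rscript inst/cli/lickometry analyze --log run1/bouts.csv \
    --licks run1/licks.csv --registry inst/extdata/example_registry.csv \
    --config inst/extdata/example_config.txt --out run1/metrics
```

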