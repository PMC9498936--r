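# divechaos

Behavioral decoding of marine-mammal dive records through the lens of
nonlinear dynamics. Given only a 1-Hz depth series `x(t)` — often the only
channel a time-depth recorder returns — `divechaos` reconstructs a
behavioral state space by time-delay embedding,

    y(i) = [ x(i), x(i+τ), …, x(i+(m−1)τ) ],

selects the delay `τ` (first minimum of auto-mutual information, with the
autocorrelation zero crossing as cross-check) and the dimension `m`
(false-nearest-neighbor knee at R_T = 3) from the data, and quantifies each
30-minute window of the trajectory by attractor invariants:

* `L` — Euclidean distance from the origin (m): near zero during surface
  rest, large inside deep dive bouts;
* `E_k = ½v²` — kinetic energy of motion along the reconstructed
  trajectory ((m/s)²), an excitation measure;
* `Λ_m` — maximum Lyapunov exponent (1/s), Rosenstein's method;
* `d` — Grassberger–Procaccia correlation dimension;
* the dominant wavelet period (s) of the window.

Windows are decoded into behavioral states by Gaussian-mixture clustering
(AIC-guided component count, diagonal or shared-diagonal covariances, soft
assignments), components are tagged by their mean `L`
(`deep-bout`, `shallow-bout`, `intermediate`, `near-surface-shallow`), and
the labeled windows feed diurnal summaries (3-h percentile tables, day vs
night eCDFs), time budgets, and before/after comparisons.

Because long dive records with ground truth are scarce, the package ships a
semi-Markov dive simulator (`simulate_dive_record()`): four behavioral
states with quasi-periodic dive cycles (17-min deep bouts to 250–600 m,
8.5-min shallow bouts to 30–100 m, near-surface rest and intermediate
activity), diurnally modulated transitions, bounded vertical speeds and
sensor noise — so every stage of the pipeline is testable against known
truth. The intended audience is biologging / movement-ecology researchers
who want continuous, threshold-free behavioral annotation of depth records.

## Worked example

```r
library(divechaos)

sim <- simulate_dive_record(sim_config(), duration = 86400, seed = 61)
res <- run_pipeline(sim$record, tau = 255, m = 3, k_range = 1:4,
                    n_init = 5, seed = 2)

res$manifest$k
#> [1] 4
data.frame(tag = res$budget$tag, fraction = round(res$budget$fraction, 2))
#>                    tag fraction
#> 1         shallow-bout     0.08
#> 2         intermediate     0.27
#> 3 near-surface-shallow     0.46
#> 4            deep-bout     0.19
head(res$features[, c("L_med", "Ek_med", "lyap", "dim", "period_s")], 3)
#>      L_med   Ek_med          lyap      dim period_s
#> 1 505.6789 1.821381  0.0034873874 1.858271 1077.564
#> 2 588.9596 2.597449 -0.0020575395 1.125221 1077.564
#> 3 590.2966 2.638776  0.0007063127 1.015857 1017.085
```

One day of simulated diving decodes into four behavioral clusters. This
record happens to open inside a deep bout: the first three windows sit
`L ≈ 500–590 m` from the origin with kinetic energy well above the
noise floor and a dominant period of ~17 min (1020–1080 s), exactly the
deep-bout cycle the simulator was asked to produce; the Lyapunov and
dimension columns are the noisier, comparative measures. The budget table
says the day split roughly half near the surface and half across
intermediate activity and dive bouts.

The `analysis/` directory stages the same workflow as numbered scripts
(simulate → embedding parameters → window invariants → clustering →
summaries), each writing its tables under `results/`.

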