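# stripeflow

Stripe-formation analysis for crossing pedestrian flows.

When two groups of walkers cross each other at an angle α, the crowd
self-organizes into alternating *stripes* — subsets of one group that the
other group does not penetrate — which travel along the bisector of the
crossing angle (in counterflow, α = 180°, the stripes are the familiar
*lanes*). stripeflow is for researchers in pedestrian dynamics and collective
behavior who want to detect and quantify this pattern in multi-pedestrian 2D
trajectory data (e.g. motion-capture recordings of crossing experiments), or
to benchmark crowd simulations against it.

The package implements two complementary methods:

1. **Edge-cutting algorithm** (trajectory-based, local, dynamic). Each group
   starts as a complete graph of virtual edges. The edge between same-group
   pedestrians P and Q is *cut* by an opposing pedestrian R between frames
   t−1 and t when

   - (i) `PQ · PR > 0` and (ii) `d = PQ · PR < |PQ|²` — the projection of R
     falls strictly between P and Q — at both frames, and
   - (iii) the signed angle β from PQ to PR changes sign:
     `β(t)·β(t−1) < 0`.

   Edges are suppressed at first cut; the times of the first and last cut,
   `T_i` and `T_f`, delimit the crossing, and the connected components of
   the residual graph are the stripes.

2. **Sinusoidal pattern matching** (snapshot-based, global). Positions are
   rotated into the bisector frame (x′ along the bisector) and fitted with
   the 2D sinusoid

   `f(x′, y′) = sin(2π X / λ + ψ)`, with wave coordinate
   `X = x′ sin γ − y′ cos γ`,

   by maximizing the matching score C — the mean of `f` over the crest group
   minus the mean over the trough group (ceiling 2) for the whole crowd, or
   the mean of `f` over one group (ceiling 1). The maximizing parameters are
   the global stripe orientation γ (counterclockwise from the bisector;
   the *bisector hypothesis* predicts γ = 90° at every α), the wavelength λ
   (spacing of consecutive same-group stripes), and the phase ψ.

Around these sit rotating-calipers minimum bounding boxes for per-stripe
orientation, width and aspect-ratio filtering (squeeze detection included),
zero-phase Butterworth gait filtering, crossing-angle estimation from
barycenter displacements, strict trajectory CSV I/O, and a synthetic
crossing-flow generator with known ground truth that makes the entire
pipeline testable end to end.

## Worked example

Simulate a 60° crossing of two 19-person groups with positional noise,
then run both analyses:

```r
library(stripeflow)

cfg <- trial_config(crossing_angle_deg = 60, position_noise_sd_m = 0.05, seed = 42)
sim <- generate_crossing_trial(cfg)
trial <- lowpass_filter_trial(sim$trial)   # remove gait sway (0.5 Hz, order 4)

geometry <- estimate_crossing_geometry(trial)
geometry
#> <stripeflow_geometry>
#>   observed crossing angle alpha: 59.974 deg
#>   bisector theta_B: -0.001 deg from x-axis
#>   left group: g1, right group: g2

timeline <- detect_edge_cuts(trial)
timeline
#> <stripeflow_timeline>
#>   events: 288
#>   T_i = 2.608 s, T_f = 4.783 s (crossing time 2.175 s)

crossing_summary(timeline)$n_stripes
#> g1 g2
#>  5  5

tstar <- select_analysis_time(trial, timeline, geometry)
pts <- points_at_frame(trial, tstar$frame, geometry)
W <- diff(range(vapply(pts, function(m) range(m[, 1]), numeric(2))))
lam0 <- heuristic_wavelength(W, sum(crossing_summary(timeline)$n_stripes))
fit <- fit_sinusoid(pts, lambda_bounds_m = c(0.5, 2) * lam0)
fit
#> <stripeflow_fit> whole_crowd
#>   gamma = 91.885 deg, lambda = 1.9839 m, psi = -83.56 deg
#>   score C = 1.83163 over 38 points

residual_errors(pts, fit)$frac_within_quarter
#> [1] 1
```

Reading the output: the observed crossing angle (59.97°) is computed from
the barycenter displacement of each group, not taken from the setup. The
edge-cutting algorithm finds 288 cuts between `T_i = 2.6 s` and
`T_f = 4.8 s` and leaves each group partitioned into 5 stripes — exactly
the generator's ground truth (`sim$truth`). The sinusoid fitted at the
analysis time recovers the stripe orientation within 2° of the 90°
bisector-normal and the wavelength within 1% of the generating 2 m spacing;
a score of 1.83 out of a possible 2 reflects the injected noise, and every
pedestrian lies within a quarter wavelength of their crest or trough.

`run_pipeline(pipeline_config(sim = cfg))` chains all stages (including
per-group fit time series, per-stripe bounding-box orientations and squeeze
flags) into a single JSON-serializable report; `summarize_by_angle()`
aggregates reports into per-angle medians and quartiles. A command-line
front end with the same stages lives in `inst/cli/stripeflow.R`.

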