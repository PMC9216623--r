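---
title: "Detecting and measuring stripes in crossing pedestrian flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and measuring stripes in crossing pedestrian flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripeflow)
```

## The phenomenon and the two estimators

When two groups of pedestrians walk through each other at a crossing angle
$\alpha$, the crowd spontaneously organizes into alternating stripes:
subsets of one group that the opposing group passes around rather than
through. A stripe behaves as a traveling wave moving along the bisector of
the two walking directions, with pedestrians advancing with the stripe and
shifting laterally within it. The *bisector hypothesis* states that stripes
are oriented perpendicular to the bisector — an orientation of
$\gamma = 90^\circ$ in the bisector frame — at every crossing angle.

stripeflow quantifies the pattern with two estimators that make different
assumptions and use different amounts of data:

* the **edge-cutting algorithm** uses full trajectories and no periodicity
  assumption. Each group starts as a complete graph; the edge between
  same-group pedestrians $P$ and $Q$ is removed the first time an opposing
  pedestrian $R$ crosses it, detected by three conditions evaluated on
  consecutive frames: (i) $\vec{PQ}\cdot\vec{PR} > 0$,
  (ii) $d = \vec{PQ}\cdot\vec{PR} < |\vec{PQ}|^2$, and (iii) a sign change
  of the angle $\beta$ from $\vec{PQ}$ to $\vec{PR}$. Stripes are the
  connected components of the residual graph; the first and last cut times
  $T_i$ and $T_f$ bound the crossing, and $T_f - T_i$ is the crossing time.

* **sinusoidal pattern matching** uses a single snapshot and assumes a
  periodic pattern of parallel, equispaced stripes. In the bisector frame
  the model is $f(x', y') = \sin(2\pi X/\lambda + \psi)$ with wave
  coordinate $X = x'\sin\gamma - y'\cos\gamma$; the fit maximizes the score
  $C$, i.e. the mean of $f$ over the crest group minus the mean over the
  trough group (whole crowd, ceiling 2) or the mean of $f$ over one group
  (ceiling 1). The maximizing $(\gamma, \lambda, \psi)$ are the pattern's
  orientation, wavelength and phase.

The two methods are complementary and cross-validate each other: the
partition from edge-cutting supplies the stripe count used to bound the
wavelength search, and per-stripe bounding-box orientations provide a
periodicity-free check of the fitted $\gamma$.

### Score normalization

The whole-crowd score is implemented as the *sum of the two per-group
means*, $C = \overline{f}_{\text{crest}} - \overline{f}_{\text{trough}}$.
This is the only normalization under which the stated ceiling of 2 is
attained in the ideal case (both groups exactly on crests and troughs
respectively); dividing the signed sum by the total headcount instead would
cap the score at 1 for equal groups. For equal group sizes the two
conventions differ only by a constant factor, so the location of the
maximum — and therefore the fitted parameters — is unchanged.

## What the pipeline computes, stage by stage

1. **Filtering.** Head trajectories oscillate at the step frequency
   (~1 Hz). A forward–backward (zero-phase) Butterworth filter of order 4
   removes the sway. The cutoff is not dictated by the method; the default
   0.5 Hz sits below typical step-induced sway and above trajectory-scale
   dynamics. Internally the filter removes the line through the endpoints of
   each series and pads the remainder by odd reflection before the two
   passes: plain forward–backward filtering starts both passes from zero
   state and leaves slowly decaying transients on series with large offsets
   or trends, which matters at a cutoff this far below the Nyquist
   frequency. A line passes an ideal zero-phase unit-gain filter unchanged,
   so the detrending is transparent.

2. **Crossing geometry.** Each group's direction is the unit vector from
   the barycenter of its initial positions to the barycenter of its final
   positions; "initial" and "final" are averaged over 0.5 s windows
   (configurable) for robustness to single-frame noise. The observed
   $\alpha$ is the angle between the two directions, and the bisector is
   their normalized sum. For near-counterflow the sum is short but its
   *axis* remains well conditioned, which is what orientation estimates
   (defined mod 180°) need; exactly antiparallel directions raise an error
   and require a user-supplied bisector. Groups are labeled left/right by
   the sign of the cross product with the bisector.

3. **Edge cutting.** Conditions (i) and (ii) are required at both frames
   $t-1$ and $t$. This choice ties the $\beta$ sign flip to $R$ crossing
   the *interior* of segment $PQ$, which makes the predicate agree with a
   continuous-time segment-crossing oracle (verified in the tests by 100×
   supersampling). Two remarks: first, conditions (i)+(ii) state
   $0 < \vec{PQ}\cdot\vec{PR} < |\vec{PQ}|^2$, which is symmetric in the
   roles of $P$ and $Q$ (and the $\beta$ sign flip is anchor-independent),
   so no separate $Q$-anchored check is needed; second, an exact
   $\beta(t) = 0$ with (i)–(ii) holding counts as a cut, closing the
   measure-zero grazing case that a strict product test would miss. Edges
   are suppressed permanently at first cut. Stripes are connected
   components of the residual graph — for ideal data the components are
   cliques, but components are the well-defined generalization when
   real-world cuts leave non-clique remnants.

4. **Analysis time.** The periodicity of the joint pattern degrades toward
   the end of the crossing, especially at acute angles. The analysis frame
   $T^*$ maximizes the whole-crowd score over frames in
   $[(T_i+T_f)/2,\; T_f]$, evaluated with a coarse fit on at most 50
   candidate frames; ties go to the earliest frame. The score itself is the
   pattern-quality measure of the method, so reusing it as the selection
   criterion operationalizes "best maintained periodicity" without a second
   ad-hoc metric.

5. **Fitting.** The score at fixed $(\gamma, \lambda)$ is linear in
   $(\cos\psi, \sin\psi)$, so the optimal phase is available in closed form:
   with $S = \sum w \sin(2\pi X/\lambda)$ and $K = \sum w \cos(2\pi
   X/\lambda)$ (weights $w$ carrying the crest/trough sign and per-group
   normalization), the maximum over $\psi$ is $\sqrt{S^2+K^2}$ at
   $\psi^* = \operatorname{atan2}(K, S)$. The optimizer is therefore a
   deterministic coarse grid over $(\gamma, \lambda)$ — $2^\circ$ steps over
   $90^\circ \pm 45^\circ$, 40 log-spaced wavelengths — followed by
   Nelder–Mead refinement from the best cell, with no random restarts. The
   refined score can never fall below the grid best, and profiling out
   $\psi$ exactly dominates any discrete $\psi$ grid. Parameters are
   canonicalized to $\gamma \in [0^\circ, 180^\circ)$,
   $\psi \in (-180^\circ, 180^\circ]$ using the identity
   $f(\gamma, \psi) = f(\gamma - 180^\circ, 180^\circ - \psi)$; the left
   group is assigned to crests so that $\psi$ is reproducible.

   Wavelength bounds guard against over- and under-fitting: with $n$
   stripes (both groups pooled) packed into a crossing region of width $W$
   along the wave direction, consecutive same-group stripes are about
   $2W/n$ apart, and the search is restricted to $[0.5, 2]\times$ that
   heuristic. $W$ defaults to the range of the pedestrians' wave
   coordinates at $T^*$ — one plausible operationalization of "width of the
   crossing region", and configurable. Without a stripe count the fallback
   bounds are 0.5 m to half the crowd extent. Collinear point sets raise an
   "unidentifiable fit" warning, as the wavelength then carries no
   information.

6. **Orientation averages.** Orientations are axial quantities (defined mod
   180°); time averages map every value to the branch nearest 90° before
   averaging, so series straddling the 0°/180° seam do not corrupt the mean.

7. **Per-stripe geometry.** Each stripe's minimum-*area* bounding rectangle
   is computed by rotating calipers over the convex hull (the classical
   objective of that algorithm; minimal width is a different box and is not
   used). Orientation is read along the box's long side, re-expressed
   counterclockwise from the bisector. Stripes are excluded from
   orientation statistics when they have fewer than 3 members or an aspect
   ratio (width/length) of 0.5 or more — a compact blob has no meaningful
   long axis. Ties among equal-area boxes break toward the smallest angle.
   For the width-versus-time (squeezing) analysis the membership is frozen
   at the final partition and evaluated backward and forward in time; a
   stripe is *squeezed* when its width reaches a global minimum strictly
   inside the scaled crossing interval $(0, 1)$ that undercuts both
   endpoint widths by more than 1 cm (configurable).

## The synthetic generator

There is no public repository of crossing-flow motion capture, so the
package ships a generator whose defaults emulate a small-group crossing
study: two groups of 19 walkers sampled at 120 Hz, mean speed 1.3 m/s with
0.05 m/s between-subject SD (drawn once per pedestrian — the simplest model
consistent with a straight-line walking instruction), start boxes 2.5 m
wide separated by 12 m, five stripes per group spaced 2 m apart. Stripes
are *imposed*, not emergent: each group is arranged into rows perpendicular
to the bisector, with the two groups' rows interleaved at half the spacing,
so that opposing walkers pass exactly between consecutive rows. Head sway
is a 0.03 m, 0.9 Hz sinusoid perpendicular to heading (typical head-sway
values, chosen so the Butterworth stage has something real to remove), and
measurement noise is iid Gaussian per coordinate and frame.

Same-stripe walkers share their phase along the bisector exactly when
`stripe_depth_m = 0` (the default). A positive depth staggers members by
±depth/2 along the travel axis, giving stripes a finite width for the
bounding-box and squeezing analyses; `squeeze_factor` contracts that depth
with a Gaussian schedule centered midway between the groups' first contact
and their full overlap — centering at full overlap would place the minimum
at the final edge cut itself, i.e. at scaled time 1, which is not a squeeze
by definition. An optional `lateral_drift_m` adds slow within-stripe
lateral motion; its realistic magnitude is unquantified, so it defaults to
0 and exists for sensitivity checks.

Degenerate controls cover the two extreme crossing outcomes: groups that
sidestep each other without interleaving (zero cuts), and full isolation
(every walker a singleton stripe).

**What passing tests do and do not show.** The generator satisfies the
bisector hypothesis and strict periodicity *by construction*. Recovery
tests therefore validate the estimators — that the pipeline returns
$\gamma$ within a few degrees of 90° and $\lambda$ within a few percent
under realistic noise — not the empirical claim that human crowds form such
stripes. Real data add gait idiosyncrasies, avoidance maneuvers, emergent
(not imposed) stripe membership, non-clique residual components, and
tracking artifacts that the generator deliberately omits.

## Numerical choices and degenerate inputs

* Angles are degrees at every interface and radians internally;
  counterclockwise is positive throughout; coordinates are meters in a
  right-handed frame.
* Interior gaps in a pedestrian's track are rejected at ingestion (no
  imputation); missing frames are tolerated only at the head or tail.
* Heading, and hence the angular deviation $\delta$, is undefined near
  standstill; frames slower than 0.2 m/s are excluded.
* The Gaussian histogram fit $a\exp[-b(x-c)^2]$ uses Levenberg–Marquardt
  from moment-based starts, with a derivative-free least-squares fallback
  for sparse or highly symmetric histograms where the Jacobian degenerates.
* Zero-length edges (coincident pedestrians) raise an error in the cut
  predicate; stripes with fewer than 2 distinct positions yield a flagged
  degenerate (zero-width) bounding box.
* Exactly collinear stripes get a zero-width box with the line's
  orientation, so downstream aspect filtering handles them uniformly.

## Problem sizes

The validation suite runs at deliberately modest scales chosen to exercise
every code path at full fidelity: recovery sweeps use 10 trials per
crossing angle at the study's group size (19 per group, 120 Hz), and
property checks use 10–12 walkers at 60 Hz. All results reported by the
package are computed at run time by these same functions; nothing is
hard-coded.

## Known limitations

* Stripes in the generator are imposed; the package does not model the
  behavioral mechanism (collision avoidance) that produces them, and no
  inferential statistics on real experiments are included.
* The exact Butterworth cutoff used in any given motion-capture study is
  usually unreported; conclusions that depend on frame-level timing of
  individual cuts can shift with the cutoff (exposed in the configuration).
* The pattern-matching model is a single sinusoid: multi-wavelength
  patterns, curved (chevron-like) stripes, and unequal within-group spacing
  violate its assumptions and show up as depressed scores rather than
  better-fitting alternatives.
* Whether per-stripe width should be evaluated on frozen final membership
  (as here) or on the instantaneous partition is a modeling choice; frozen
  membership matches the backward-in-time visualization of completed
  stripes.
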