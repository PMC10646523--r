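---
title: "Inter-system recurrence networks: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-system recurrence networks: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irnet)
```

## The problem

When two systems are observed simultaneously — two interacting people wearing
physiological sensors, two coupled oscillators, two neurons — we often want
to know not only *whether* their dynamics are related but *which one drives
the interaction*. `irnet` implements inter-system recurrence networks (IRN),
a graph-theoretical approach to this question built on recurrence
quantification analysis: the recurrence structure of each system and the
cross-recurrence between them are combined into one composite network whose
asymmetries carry information about the implied coupling direction.

## From trajectories to networks

A system observed through state vectors $\vec y_1,\dots,\vec y_N$ (native
coordinates, or a delay embedding of a scalar series) defines an
**auto-recurrence matrix**

$$R_{ij}(\varepsilon) = \Theta(\varepsilon - \|\vec y_i - \vec y_j\|),$$

with $\Theta$ the Heaviside step ($\Theta(0)=1$, i.e. distances equal to the
threshold recur) and $\|\cdot\|$ the Euclidean norm by default (Chebyshev
optional). Rather than fixing $\varepsilon$ directly, we calibrate it so that
a target fraction of eligible cells recur — the **recurrence rate** (RR).
Auto-recurrence rates are accounted on the strict upper triangle (the line
of identity is trivial self-recurrence); cross-recurrence rates over all
cells. The calibrated threshold is the linear-interpolation quantile of the
eligible distance population, which keeps the realized rate within one cell
of the target.

For two systems $X$ and $Y$ sharing a state space, the **cross-recurrence
matrix** $CR_{ij} = \Theta(\varepsilon^{XY} - \|\vec x_i - \vec y_j\|)$ is
generally asymmetric; its transpose is the cross-recurrence of $Y$ relative
to $X$. The three matrices are assembled into the **inter-system recurrence
matrix** with $R^X$ and $R^Y$ on the diagonal blocks and $CR$ off the
diagonal; subtracting the identity yields the adjacency matrix of an
undirected simple graph on $N_X + N_Y$ vertices. Cross-recurrences should be
rarer than intra-system recurrences, so the default targets satisfy
$RR^{XY} \le RR^X \approx RR^Y$ (5% auto, 3–4% cross).

### Measures

* **cross-degree** $k_v^{XY}$: the number of edges from vertex $v$ to the
  opposite subnetwork;
* **cross-edge density** $\rho^{XY}$: cross-edges over $N_X N_Y$, identical
  to the realized cross recurrence rate;
* **local cross-clustering** $C_v^{XY}$: the probability that two distinct
  cross-neighbours of $v$ are themselves adjacent within the opposite
  system; vertices with cross-degree 0 or 1 contribute 0;
* **global cross-clustering** $C^{XY}$: the mean of the local coefficients
  over *all* vertices of one side, zeros included.

If cross-edges were placed independently of the opposite system's internal
structure, $C^{XY}$ would sit near the closure block's edge density
(discounted by the zero- and one-degree vertices); values far above or below
that reference indicate persistent or anti-persistent correlation between
the two systems' connectivity. The test suite verifies this on random
graphs, where the expectation is exact.

### Direction inference

When $X$ unidirectionally drives $Y$, the driven system's states are partly
a function of the driver's history; states of the clean driver matched by a
common driven-system state tend to be genuine near-recurrences of each
other. The coefficient measured *from the driven side toward the driver*
therefore exceeds its mirror image: $C^{YX} > C^{XY}$ for $X \to Y$.
`classify_direction()` applies the fixed-threshold rule to
$\Delta C = C^{XY} - C^{YX}$: values within $\pm 0.01$ read as
*bidirectional or uncoupled*, $\Delta C < -0.01$ as *X leads*, and
$\Delta C > +0.01$ as *Y leads*.

## Triangle closure: the scale-matching design decision

The local coefficient closes a triangle by testing whether two
cross-neighbours are "adjacent". The obvious convention tests them against
the opposite system's own recurrence matrix, thresholded at that system's
calibrated $\varepsilon$ (`closure = "within"` in `analyze_pair()`). This
convention hides a confound: when one system is driven, its trajectory
fills state space differently and its calibrated threshold can be several
times larger than the other system's (in the oscillator study below,
$\varepsilon^Y \approx 4\,\varepsilon^X$ for the driven side). The two
coefficients are then tested at wildly different resolutions, and the
resolution asymmetry — not the coupling geometry — dominates $\Delta C$, to
the point of inverting the direction reading.

`analyze_pair()` therefore defaults to **scale-matched closure**
(`closure = "scale_matched"`): the triangles of a vertex $v$ are closed at
$v$'s *own* system's calibrated threshold, i.e. X-side triangles test
$\Theta(\varepsilon^X - \|\vec y_i - \vec y_j\|)$. Both coefficients are
then measured at comparable resolution, the confound cancels, and the
$\pm 0.01$ rule keeps its intended semantics. The two conventions coincide
whenever the two calibrated thresholds agree — in particular for symmetric
systems, so graph-level worked examples and all symmetric cases are
unaffected. Graph-level functions (`local_cross_clustering()` on an
`irn_graph`) use the within-system convention, which is the only one
defined when just an adjacency structure is given.

A residual limitation: under *competitive* bidirectional coupling
($+\gamma$, $-\gamma$) the system is not symmetric under relabelling
(relabelling maps antiphase initial conditions to in-phase ones), so
$\Delta C$ on the equal-coupling diagonal is small but not exactly zero,
and the scale-matched closure amplifies this small real asymmetry somewhat
(measured $|\Delta C| \approx 0.02\text{–}0.05$ near the
damping/coupling transition, against $\approx 0.01$ for within closure).

## Validation: coupled damped oscillators

Two linear damped oscillators

$$\ddot X = -\eta_x X + \zeta_x \dot X + \gamma_{yx} Y,\qquad
  \ddot Y = -\eta_y Y + \zeta_y \dot Y + \gamma_{xy} X$$

with $\eta = 0.3$, $\zeta = -0.05$ (decay), antiphase initial positions
$(3, -3)$ and zero initial velocities provide a controlled test bed: the
four canonical scenarios are *uncoupled* ($\gamma_{xy} = \gamma_{yx} = 0$),
*X drives Y* ($+0.05, 0$), *Y drives X* ($0, -0.05$) and *competitive
bidirectional* ($+0.05, -0.05$). The sample grid is $t = 0, 1, \dots, 200$
(201 samples, about 17 oscillation periods; the grid spacing is exposed via
`scenario_params(dt =)`). Integration uses `lsoda` with tolerances $10^{-9}$
— tight enough that the sampled states match the closed-form solution of the
undamped oscillator to $4\times10^{-7}$.

Analysis operates on the standardized native 2-D states $(X, \dot X)$ and
$(Y, \dot Y)$ at recurrence rates 5% (auto) and 3% (cross). Under the
default closure, the uncoupled scenario gives exactly equal coefficients
(forced by mirror symmetry), the unidirectional scenarios give strongly
asymmetric coefficients with the driven side's coefficient toward the
driver largest, and the competitive scenario gives a small difference. The
acceptance suite pins these values against reference results.

```{r scenarios, eval = FALSE}
tr <- simulate_oscillators(scenario_params("x_drives_y"))
analyze_pair(cbind(tr$x, tr$dx), cbind(tr$y, tr$dy),
             rr_auto = 0.05, rr_cross = 0.03)
```

`coupling_sweep()` maps $\Delta C$ over a grid of coupling magnitudes
(canonical signs $+\gamma_{xy}$, $-\gamma_{yx}$). Cells whose oscillations
grow — the coupling overcoming the damping, detected by comparing the
amplitude envelope of the first and last tenth of the samples — are flagged
`diverged` rather than dropped, because the transition region is where
direction reversals genuinely occur: near the stability boundary the phase
difference, not the coupling, can decide the sign of $\Delta C$. Away from
the transition, mirrored unidirectional cells flip the sign of $\Delta C$
as expected.

## Diagonal cross-recurrence profiles

The `dcrp()` profile summarises a square cross-recurrence matrix by the
recurrence rate per diagonal: lag $\ell = i - j$, so recurrent mass at
negative lags means states occurred in $X$ first ($X$ leads). It
corroborates the IRN direction call with a complementary, lag-resolved
view. `dcrp_with_surrogates()` adds a pointwise confidence envelope: the
temporal order of the raw $Y$ series is fully randomized (before
standardization and embedding — the surrogate destroys *all* temporal
structure, which is the sharpest null for lead–lag questions), the
cross-threshold is re-calibrated per surrogate to the same target rate so
that the envelope reflects structure rather than rate, and the min/max over
39 surrogates bounds each lag at a pointwise two-sided $p < .05$ (rank
$1/40$ per tail). Surrogate runs are bit-reproducible under a seed, and the
caller's RNG stream is left untouched.

## Choosing embedding parameters

Scalar series are delay-embedded:
$\vec s_i = (s_i, s_{i+\tau}, \dots, s_{i+(m-1)\tau})$. The embedding lag
$\tau$ is chosen at the first minimum of the average mutual information
(AMI) profile, estimated from an equal-width 2-D histogram with 32 bins per
axis (in nats); 32 bins is a plain, reproducible default for series of a
few thousand samples, and the bin count is exposed. When a profile has no
strict local minimum the global minimum is returned with a warning. A
caveat worth knowing: for strongly periodic signals the profile flattens
into a broad valley around a quarter period and histogram ripples decide
the exact minimum — any lag in the valley is an equally good choice.

The embedding dimension $m$ comes from the classic false-nearest-neighbour
(FNN) criterion with literature-standard tolerances (distance-ratio 10,
attractor-size 2, acceptance threshold 1%). Exact duplicate points (periodic
data whose period divides the sampling) would make the distance ratio
floating-point noise; such neighbours are instead compared directly on the
extra coordinate.

One shared $(\tau, m)$ is used for *all* series of an analysis — cross
recurrence between two trajectories is only defined in a common state
space. The dyadic pipeline's defaults, lag 100 samples and dimension 5 at
1 Hz, embed a window of 400 s of signal per state vector; per-series AMI/FNN
profiles remain available as diagnostics.

## The incident-centred dyadic pipeline

`analyze_cohort()` runs the empirical workflow over a set of two-person,
five-channel recordings (ACC, BVP, EDA, HR, TEMP at heterogeneous native
rates) with an incident timestamp each:

1. **Window**: the 35 minutes before each incident.
2. **Resample to 1 Hz**: mean of the samples within each second for rates
   above 1 Hz, linear interpolation onto second marks below 1 Hz (an
   aligned 1 Hz series passes through unchanged). Missing seconds are
   bridged by linear interpolation up to 5 s; longer sensor gaps remain
   missing and are counted. These rules are deliberately simple; both the
   method and the gap limit are configuration-exposed.
3. **Quality control**: an incident is dropped when two or more of its ten
   series cover less than 25 minutes; every exclusion carries a
   machine-readable reason.
4. **Per-variable IRN**: for each channel, client (X) vs caregiver (Y) at
   recurrence rates 5%/4% with the shared embedding; the tidy result table
   has one row per incident and variable.
5. **Direction frequencies**: percentages of client-leading,
   caregiver-leading and bidirectional/uncoupled calls per variable (the
   `Mean` row averages the variable rows).
6. **Multiplex network**: one vertex per variable; every unordered variable
   pair is linked by a full IRN analysis, with edge weight $|\Delta C|$,
   the direction as edge label, and vertex strength (the weighted degree)
   summarising each variable's participation. By default a pair $(a, b)$
   analyses the client's $a$ against the caregiver's $b$ (cross-person,
   cross-variable); within-person variants are a configuration switch, and
   the choice is recorded on the graph object. GraphML and edge-list
   exports are provided.

All parameters live in one `irn_config()` object, readable from YAML.

## The synthetic fixture generator

No real wearable data ship with the package; `generate_fixture()` stands in
for them and, importantly, carries a configurable *ground truth*. Design:

* **Latent layer**: each channel of the dyad is one coupled
  damped-oscillator pair from the model family above, with the planted
  direction mapped to the canonical coupling signs (client drives:
  $\gamma_{xy} = +0.05$). One model time unit is 10 s of wall time, so the
  35-min window corresponds to the validated 201-sample regime and the
  default embedding covers about one oscillation period. The latent pair is
  propagated *exactly* (matrix exponential), so the planted structure is
  free of integration error; an Euler–Maruyama path with process noise is
  available (`sigma_process`) but defaults off — the latent layer models an
  incident-locked transient stress response, with randomness entering
  through a per-incident random phase and a ±10% frequency jitter shared by
  both dyad members (sharing keeps the uncoupled null mirror-symmetric,
  which is what makes "no coupling" a meaningful ground truth).
* **Observation layer**: per person and channel, a slow sinusoidal drift
  (amplitude 0.5% of signal sd, period 10–30 min) and white measurement
  noise (1% sd), then sampling at Empatica-like native rates (ACC 32 Hz,
  BVP 64 Hz, EDA 4 Hz, HR 1 Hz, TEMP 4 Hz) by interpolation of the 1 Hz
  latent signal — the latent band lies two orders of magnitude below 1 Hz,
  so interpolation is exact for practical purposes and all high-frequency
  content is, as in real sensors, noise.
* **Calibration**: the observation-noise defaults were fixed by a 50-seed
  Monte-Carlo so that the instrument is usable with the fixed ±.01 rule:
  at these defaults the planted driver is recovered in 100% of runs and
  uncoupled dyads produce a unidirectional false call in under 10% of runs
  (the acceptance suite re-measures both). This sensitivity is a property
  of the rule, not the generator: the global cross-clustering coefficient
  is a volatile functional — perturbing a few neighbour sets moves it by
  more than 0.01 — so even modest observation noise (2% rather than 1%)
  pushes the false-positive rate of the fixed threshold towards one in
  three.

What the generator does **not** emulate: real sensor artifacts (motion
spikes, contact loss patterns beyond simple gaps), person-specific and
time-varying dynamics, amplitude nonstationarity beyond the damped
transient, circadian trends, or any physiological meaning of the five
channels beyond their sampling rates. Passing the direction-recovery tests
therefore shows that the estimator chain is sound *in the regime the
generator creates* — near-deterministic transients with weak observation
noise — not that coupling direction is recoverable from arbitrary wearable
data. On real recordings the bidirectional/uncoupled band and the
sensitivity of the ±.01 rule deserve particular caution.

## Numerical conventions and degenerate inputs

* Recurrence: $d \le \varepsilon$ recurs ($\Theta(0) = 1$); thresholds are
  type-7 (linear interpolation) quantiles; auto-RR excludes the line of
  identity, cross-RR uses all cells; the all-equal distance population is
  an error (rate not controllable), as is standardizing a constant series.
* The uncoupled mirror scenario yields *bitwise* equal coefficients — the
  two blocks see identical distance matrices.
* Local coefficients with cross-degree 0 or 1 are exactly 0; global
  averages include them.
* Large recurrence plots switch to sparse matrix algebra for the triangle
  counts; results are identical to the dense path.
* The test suite runs its stochastic checks at deliberately scaled sizes:
  50 + 50 dyads for direction recovery, a 9×9 coupling sweep, 1000 random
  graphs for the triangle-enumeration oracle, and series of a few hundred
  samples for the embedding oracles.

## Known limitations

* The direction semantics of $\Delta C$ are regime-dependent; the
  scale-matched closure removes the threshold-scale confound, but near
  stability transitions reversals still occur (and are genuine properties
  of the trajectories, not estimator artifacts).
* Bidirectional coupling and no coupling are not distinguishable by
  $\Delta C$ alone; the DCRP with surrogates helps (uncoupled pairs stay
  inside the envelope, synchronized pairs break it) but does not fully
  resolve the ambiguity.
* The fixed ±.01 threshold is sharp: per-application calibration (e.g. on
  surrogate pairs) is advisable for noisy data.
* Directed or weighted recurrence-network extensions, and group-level
  statistics over DCRPs, are out of scope.
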