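---
title: "Models and methods: fluorescence-force spectroscopy of telomeric G-quadruplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretforce)
```

This vignette is the package's own account of the models it implements, the
tunable parameters that matter, the numerical choices behind them, and what
the synthetic-data generators do and do not emulate.

## The assay

A telomeric DNA construct of five or six T₂AG₃ repeats is held between a
passivated surface and an optically trapped bead through a ~16.4 µm λ-DNA
tether. A donor/acceptor dye pair across the telomeric segment reports its
compaction as a FRET efficiency `E = I_A/(I_A + I_D)`; a piezo stage moving
at 455 nm/s ramps the tension from about 1 pN to about 28 pN in about
6.5 s and back, while photon counts are recorded every 20 ms (30 ms per
frame in the zero-force TIRF geometry). Folded G-quadruplexes appear as
high-E states; unfolding appears as abrupt or gradual E decreases with
force.

## Zero-force smFRET

Channel counts are corrected as `I_D' = I_D − bg_D`,
`I_A' = I_A − bg_A − α·I_D'` (α is donor→acceptor crosstalk), and frames
with non-positive corrected total intensity are flagged invalid. Background
and crosstalk values are instrument properties and default to zero; real
data need measured values.

Molecules are summarized by the mean of the **first ten valid frames**, the
convention under which zero-force efficiency histograms are built: it
samples every molecule equally and before photobleaching has culled the
population. Molecules with `E_mean` below **0.1** are discarded as
donor-only (missing or inactive acceptor); the zero peak carries no
conformational information, and 0.1 sits well below any folded or unfolded
species in these constructs.

Subpopulation fractions are estimated by expectation–maximisation over the
**weights only** of a Gaussian mixture whose centres and widths are held
fixed. The centres come from single-position mutant constructs, each of
which can fold at only one register and therefore calibrates one
component's peak position (`calibrate_components()`). Widths are taken from
the same calibration when available and default to **σ = 0.05**, the
shot-noise-limited peak width at ~500 detected photons per frame. Freezing
the component shapes is what makes three heavily overlapping subpopulations
(centres 0.66/0.75/0.85 with σ ≈ 0.05) identifiable from ~200 molecules;
letting the centres float would simply re-discover one broad peak. The EM
log-likelihood is asserted to be non-decreasing at every iteration, weight
standard errors come from the observed information of the weight simplex,
and hard maximum-posterior labels are kept alongside the soft weights so
integer event counts can be reported.

## Tether mechanics

The tether is modelled as an extensible Marko–Siggia worm-like chain in
series with a harmonic trap:

$$F = \frac{k_BT}{P}\left[\frac{1}{4(1 - x/L_c + F/K)^2} - \frac14 +
\frac{x}{L_c} - \frac{F}{K}\right], \qquad
x_{\text{wlc}}(F) + F/\kappa = \text{stage}.$$

Defaults: `Lc = 16400` nm (λ-DNA), `P = 50` nm, `K = 1200` pN — standard
λ-DNA elasticity — with `κ = 0.046` pN/nm and a 14.00 → 16.96 µm ramp
chosen so the model reproduces the protocol's printed endpoint (~28 pN,
within the stated 16.8–17.2 µm stage range) and duration (~6.5 s). The
full Marko–Siggia relation is solved numerically everywhere (no high-force
interpolation branch): substituting `u = x/Lc − F/K` makes both
`wlc_extension()` and `force_at_stage()` single one-dimensional root
solves, mutual inverses to 10⁻⁶ relative tolerance. One known discrepancy
is recorded rather than hidden: at 14 µm this model gives ~1 pN, not the
~0.3 pN quoted for the protocol start; downstream kinetics depend on the
loading rate at the forces where ruptures happen (≥ 3 pN), which is
insensitive to the sub-pN start.

Temperature is not part of the protocol record; `kBT = 4.11` pN·nm
(298 K) is assumed throughout.

`loading_schedule()` tabulates force versus time and the instantaneous
loading rate `dF/dt = v / (dx_wlc/dF + 1/κ)` once on an 801-point grid at
construction (monotone Hyman splines); every downstream likelihood
evaluation then costs interpolation only. An `ssdna_model()` freely jointed
chain (0.63 nm/nt, Kuhn length 1.5 nm) is available for the optional
mechanistic post-rupture FRET mode of the simulator.

## Loading-rate conventions

The Dudko–Szabo rupture-force distribution is defined relative to a loading
rate Ḟ. Three conventions are supported, and the choice is the one genuinely
open design decision in this pipeline:

* **instantaneous** — the full force-dependent Ḟ(F) of the compliant
  tether. This is the physically exact hazard for simulation and fitting,
  and it is what `sample_ruptures()` and `fit_ds()` use. It is *not*
  suitable for quoting a distribution mode: because the λ-DNA tether is
  very compliant at low force, Ḟ(F) is tiny near the ramp start and the
  unconditional density acquires a spurious peak there.
* **constant** — any fixed Ḟ, e.g. the mean ramp rate
  (F_max − F_min)/duration ≈ 4.2 pN/s.
* **nominal** (default for `reconstruct_profile()`) — Ḟ = κ·v ≈
  20.9 pN/s, the stiff-tether rate of the trap/stage combination. This is
  the conventional single-number summary of a constant-velocity protocol,
  and it is the convention under which the published kinetic parameter
  triples for these constructs reproduce the published force-cluster peaks
  (≈ 8, 16 and 8 pN) when pushed forward through the ν = 1/2
  distribution. Forward-model consistency with the published
  reconstructions is why it is the default.

Sampling and maximum-likelihood fitting always use the same schedule, so
the estimation problem is internally consistent regardless of the
convention chosen for reporting.

## Dudko–Szabo kinetics

The rate law, with ΔG‡ in units of kBT and `ν = 1/2` as the pipeline
default (2/3 and 1 available for sensitivity checks; ν = 1 reduces exactly
to the Bell rate):

$$k(F) = \frac{1}{\tau_u(0)}\left(1 - \frac{\nu F \Delta x^\ddagger}
{\Delta G^\ddagger k_BT}\right)^{1/\nu - 1}
\exp\left\{\Delta G^\ddagger\left[1 - \left(1 - \frac{\nu F \Delta
x^\ddagger}{\Delta G^\ddagger k_BT}\right)^{1/\nu}\right]\right\}$$

The critical force `F_c = ΔG‡·kBT/(ν·Δx‡)` bounds the domain; for ν = 1/2
the rate falls to zero at F_c, a pathology of the functional form that is
handled by truncating densities at F_c (with the residual survival reported
explicitly) and by constraining fits so that F_c stays above the data (see
below).

**Quadrature.** The cumulative hazard in force,
Λ(F) = ∫ k/Ḟ df, is integrated with a logarithmic-interval-mean rule
(exact when the integrand varies exponentially, which force-dependent
rupture hazards do), and the density mass with the same rule, on a
3001-point grid. Probability conservation, ∫p dF + S(F_max) = 1, holds to
10⁻⁴ across randomized parameter sets and is property-tested; an
independent brute-force oracle (Euler integration of dS/dt = −k(F(t))·S at
10⁻⁴ s steps) agrees with the quadrature to ~10⁻³. The reported mode is
the grid argmax refined by a local parabola.

**Sampling** is inverse-CDF on the tabulated survival curve; draws whose
uniform variate falls below S(F_max) are returned censored.

**Fitting** is maximum likelihood on raw, unbinned rupture forces — cleaner
than least squares on binned histograms, and it lets censored cycles
(no rupture by the end of the ramp, the mechanically "ultrastable"
population) contribute their survival probability instead of being
discarded. Mixtures are fitted jointly over component parameters and
weights (softmax). Each component is parameterised as
`(log Δx‡, log τ₀, log ΔG‡_excess)` with
`ΔG‡ = ν·Δx‡·F_floor/kBT + ΔG‡_excess` and `F_floor` the largest observed
force divided by 0.95: the critical force then exceeds every observation by
construction — the same constraint a penalty would impose, but smooth, so
the optimizer never visits parameter vectors whose density vanishes at a
data point. Optimisation is multi-start (default 20) from
quantile-partitioned, moment-based initialisations (a Bell-like spread sets
Δx‡, the Bell modal-force relation sets τ₀) with jitter; Nelder–Mead
followed by BFGS polish. Standard errors come from the observed information
with the delta method; τ₀'s uncertainty is reported on the log scale, where
its likelihood is approximately quadratic. Components are ordered by modal
force, ties broken by weight.

The three parameters are strongly correlated along a ridge — many
(Δx‡, τ₀, ΔG‡) triples imply nearly the same rupture-force distribution
over the observable force window, and ΔG‡ in particular is weakly
identified whenever F_c sits far above the data (a singular observed
information is reported as such rather than papered over). Recovery should
therefore be judged on Δx‡, log τ₀ and the reconstructed distribution, not
on ΔG‡ alone; the test suite checks a median relative error below 10% on
Δx‡ and below 0.3 on log τ₀ at n = 500 over 20 replicates.

## Pulling-cycle analysis

Cycles are segmented at stage-velocity sign changes, each half monotone in
stage; truncated final halves are flagged and excluded from classification,
as are cycles whose stretch half never reaches 90% of the nominal peak
force (photobleaching mid-cycle looks like this).

**Abrupt transitions** are changes of ≥ 0.3 in the 3-sample running median
completed within ≤ 3 samples (60 ms at 20 ms sampling) and persisting ≥ 5
samples. The rationale: cooperative G-quadruplex rupture is effectively
instantaneous at this sampling rate, while the gradual Type I/II unraveling
spans seconds; running medians (not means) make the detector robust to
single-frame blinks. The event force is read at the sample where E crosses
the midpoint `(E_before + E_after)/2` — on constructed steps the force
error is below one sample spacing (≲ 0.2 pN). When several abrupt events
occur in one half, all are kept but the largest-|ΔE| event defines the
cycle's f_unfold. Refolding forces are taken only from abrupt relax-half
events; gradual relaxations refold continuously and have no single
refolding force.

**Classes** are assigned from the minimum of the 5-sample running-median
efficiency over the stretch half: `complete` below 0.15 (with an abrupt
event), `type_I` in [0.15, 0.30), `type_II` in [0.30, 0.45),
`no_unfolding` at or above 0.45. The thresholds bracket the class anchors
(E ~ 0, ~ 0.2, ~ 0.37) at their midpoints-with-margin; 0.45 separates
Type II from cycles that never left the folded band. A sub-0.15 minimum
without an abrupt event — possible only for pathological traces — is
treated as gradual (type_I). On noiseless archetypes the confusion matrix
is exactly the identity, and at σ_E = 0.03 the class fractions of a
263-cycle ensemble with counts 58/150/55 are recovered within two
percentage points.

## Vectorial folding traces

The baseline is the median of the first 10 frames; a trace that never
leaves the baseline ± 0.1 band was never unwound. The terminal state is the
median of the last 20 frames, which at σ_E = 0.05 has a standard error of
~0.011 — the 0.68 boundary between the 0.73-type (direct 3′ folding) and
0.62-type (5′-GQ) terminal bands therefore sits > 4 SE from either anchor,
and misclassification between those classes stays below 5% in the
property tests. A **pause** is ≥ 10 consecutive frames at intermediate
efficiency (0.2–0.55) that stay within a ± 0.05 band *and* show < 0.02 net
drift; the drift condition is what distinguishes a plateau from a steady
slow climb passing through the band, and guarantees the detector never
fires on a monotone rise of any realistic speed. The **rise duration** is
measured from the first departure out of the baseline band to the first
entry into the terminal band (terminal − 0.05); the generator parameterises
its ramp so that this measurable quantity equals the drawn rise time,
because the published ~0.7 s figure is itself such a measurement.

Folded fractions count molecules inside a folded band (default
[0.6, 0.9]) after donor-only exclusion, with a Wilson interval.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure the analysis relies on:
Poisson photon partitioning at ~500 counts/frame (per-frame E noise
~0.022, matching observed peak widths after 10-frame averaging), constant
backgrounds and donor crosstalk, exponential photobleaching, archetype
E(F) curves interpolated monotonically through printed endpoint anchors
(complete: flat 0.80 until rupture, then an ssDNA baseline declining from
0.10; type_I: 0.75 → 0.25; type_II: 0.68 → 0.37), rupture forces drawn
from the Dudko–Szabo hazard under the exact loading schedule, refolding at
a uniform 1–7 pN (phenomenological — no refolding model is fitted),
cycle-to-cycle archetype switching by a Markov matrix, and sigmoidal
vectorial rises. Cycles that carry a rupture-bearing label draw their
rupture conditional on rupturing within the ramp — a cycle is *labelled*
complete only when the rupture was observed — while unconditional draws
(`condition_on_rupture = FALSE`) exercise the censored-likelihood path.

Not emulated: stage drift, camera artifacts, bead-tracking noise,
acceptor blinking and other photophysics beyond bleaching, and the true
interpolating shape of E(F) between the printed anchors (classification
depends only on the anchor ranges, so no claim rests on the interpolant).
Passing the round-trip tests therefore shows the analysis is correct for
data with the declared structure; it does not certify robustness to
instrument pathologies absent from the generative model.

Problem sizes used by the test suite — 500 ruptures × 20 replicates for
parameter recovery, 263 cycles for classification, 200 molecules × 50
replicates for mixture decomposition, 2000 draws for sampler/quadrature
agreement — are the sizes at which the corresponding statistical
tolerances (10% on Δx‡, 2 percentage points on class fractions, 0.02 bias
on weights) are meaningful for desk-scale validation.

## Known limitations

* The Dudko–Szabo parameter ridge: ΔG‡ is poorly identified whenever the
  data do not approach F_c; report distributions, not bare ΔG‡ values.
* The mixture decomposition assumes the calibrated centres/widths transfer
  from mutant constructs to the mixed construct; a systematic shift
  between constructs would bias the weights.
* The WLC defaults describe a single intact λ-DNA tether; multiple
  tethers or a nicked handle change the loading schedule and must be
  recalibrated (`calibrate_stage_end()`, `calibrate_trap_stiffness()`).
* Classification thresholds are tuned to the five-repeat construct's
  anchor efficiencies; other constructs (or dye geometries) need their own
  bands.
* No hidden-Markov dwell-time analysis, no γ-correction for quantum-yield
  differences, no refolding kinetics model, and no equilibrium
  free-energy reconstruction from stretch/relax asymmetry.
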