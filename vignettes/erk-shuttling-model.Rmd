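---
title: "Modeling ERK phosphorylation, shuttling, and substrate buffering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ERK phosphorylation, shuttling, and substrate buffering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(erkshuttle)
library(dplyr)
```

## The scientific problem

Growth-factor stimulation of fibroblasts produces a puzzle in ERK dynamics:
whole-cell ERK phosphorylation and nuclear translocation of ERK are strongly
transient (they peak early and decay most of the way back), while the kinase
activity of ERK actually available to phosphorylate substrates — measured with
compartment-targeted FRET reporters — shows little or no adaptation, and free
active ERK in the nucleus accumulates slowly, lagging the nuclear-translocation
peak by tens of minutes.  `erkshuttle` implements a compartmental kinetic model
family in which reversible anchoring of active ERK by abundant nuclear (and
possibly cytosolic) substrates reconciles these observations: early after
stimulation most nuclear diphospho ERK is substrate-bound — anchored in the
nucleus, protected from phosphatases, and invisible to activity reporters — and
as the substrate pool becomes phosphorylated, ERK is progressively freed,
dephosphorylated, and exported.  Apparent "adaptation" of phosphorylation and
localization is then a by-product of transient buffering rather than of
negative feedback alone.

## Model structure

The model tracks amounts (fractions of total cellular ERK) in two well-mixed
compartments with nuclear volume fraction `phi_n` (default 0.2, a typical
fibroblast value; fittable):

* **MEK** (cytosolic, total = 1): un-, mono-, and diphosphorylated (`M0`,
  `M1`, `M2`), activated sequentially at per-site rate `a_M * S * (1 - D)`,
  where `S` is the dimensionless input strength of the stimulation protocol
  and `D` a desensitization state driven by free cytosolic diphospho ERK
  (`dD/dt = k_fb * E2c * (1 - D) - k_rec * D`).  This dynamic-feedback form is
  the default because measured MEK phosphorylation peaks *before* ERK
  phosphorylation, which requires delayed adaptation; an instantaneous Hill
  inhibition (`fb_mode = 1`, `v = a_M * S / (1 + (E2c/fb_K)^fb_h)`) is
  available as a configuration option.
* **ERK**: free cytosolic pools `E0c, E1c, E2c` (two-site distributive
  phosphorylation by `M2` with independent site rates `a_E1`, `a_E2`; one
  mono-phospho state — the two mono-phosphoforms are not distinguished), free
  nuclear pools `E0n, E1n, E2n`, substrate-bound diphospho pools `EBc`, `EBn`,
  and phosphorylated substrate `Pc`, `Pn`.  Only free diphospho cytosolic ERK
  is imported by the facilitated route (`k_in`); all free states shuttle
  passively at `k_pass` and are exported at `k_out` irrespective of
  phosphorylation state.  Bound ERK is anchored (no transport) and protected
  from phosphatases.
* **Substrate interaction**: association `k_on * E2 * S_free / phi`
  (amounts divided by the compartment volume fraction to convert to
  concentrations), dissociation `k_off`, catalytic turnover `k_cat` (which
  releases active ERK and produces phosphorylated substrate), and substrate
  dephosphorylation `k_sdp`.  The **buffering strength** of a compartment is
  `B = (S_tot / phi) / K_m` with `K_m = (k_off + k_cat) / k_on`.

Model variants: `control` (no substrate interactions, `S*_tot = 0`),
`importin` (nuclear entry of diphospho ERK is routed through an
importin-bound state released at `k_rel`), `combined` (both), and
`constant_mek` (MEK activity clamped; feedback inert) — used to show that
substrate buffering, not feedback, explains the adaptation of ERK
phosphorylation.

Stimulation protocols are step sequences in `S` plus optional inhibitor
events: U0126 zeroes the ERK-phosphorylation fluxes and okadaic acid zeroes
all ERK- and substrate-dephosphorylation fluxes, both instantaneous and
complete by default (partial inhibition is a protocol option,
`u0126_factor` / `okadaic_factor`).

```{r model-quickstart}
theta <- theta_ref()
tr <- erk_simulate(theta, protocol_step(S = 1, t_end = 75))
autoplot(tr)
```

## Observation models

`erk_observe()` maps a trajectory onto the measured readouts.  Whole-cell
diphospho ERK (immunoblot, mass spectrometry) is the *sum of free and
substrate-bound* pools — the key reason the lysate measurement adapts while
reporter activity does not.  The dual-phospho MEK antibody reads `M2` only.
Nuclear localization is the mean nuclear ERK concentration over the whole-cell
mean, renormalized to its pre-stimulus value.  The FRET activity reporters
equilibrate rapidly with free diphospho ERK in their compartment, so they are
modeled as an affine map (`(rho + e2)/(rho + e2(0))`) of the free diphospho
concentration; the offsets `rho_c`, `rho_n` set the displayed amplitude but
cancel out of every normalized shape statistic used here (decay fractions,
half-decay times, rise times), so their defaults are cosmetic.

The half-decay statistic `t_half()` is the elapsed time after inhibitor
addition at which a readout first crosses halfway between its value just
before inhibition and the pre-stimulus baseline, by linear interpolation
between bracketing samples — the same definition used for the single-cell
imaging data.

```{r observe}
erk_observe(tr, readouts = c("nucloc", "ekar_nuc")) |>
  plot_readouts()
```

## The reference parameter set

The rate constants of the study are not published, so the package carries a
frozen reference set `theta_ref()`, calibrated once (script:
`inst/scripts/derive_theta_ref.R`) by Nelder-Mead on log10 parameters against
the qualitative kinetic features of the measured system, with the nuclear
buffering strength pinned in the nuclear-dominant regime (`B_n = 20`, the
value sufficient to explain the data; `B_c` far below 1): nuclear
localization peaking inside 10 min with strong adaptation; near-complete
adaptation of whole-cell diphospho ERK; an early (3-5 min) cytosolic activity
peak decaying by only about a third; slow (~20 min to 90%) non-adapting rise
of nuclear activity; activity half-decay of about 2 min or less after MEK
inhibition at quasi-steady state; and a roughly 4-fold slower nuclear decay
when inhibition is imposed at 10 min instead.  These waypoints pin the
composite quantities (buffering strengths, exit rates, feedback gain); the
individual rate constants are not claimed to be uniquely identified.

```{r features}
round(kinetic_features(theta), 2)
```

A deliberate consequence of the calibration is a large nuclear substrate pool
(`Sn_tot` = 1.8 total-ERK equivalents, i.e., the dominant nuclear anchors are
more abundant than ERK itself) with slow turnover (`k_cat_n` ~ 0.11/min) and
nearly irreversible substrate phosphorylation (`k_sdp_n` ~ 1e-4/min) — the
"gradual, high-stoichiometry" phosphorylation required for transient
buffering.  The slow substrate-dephosphorylation rate makes the basal
relaxation time long (~7,000 min); the pre-stimulus state is therefore found
by a damped Newton solve (to right-hand-side residual below 1e-10) seeded
with a long integration, rather than by integration alone.

## Synthetic data

`default_designs()` encodes the experiments used for fitting: immunoblot
ppMEK/ppERK timecourses (t = 0-120 min, n = 3, arbitrary units), mass
spectrometry mono- and diphospho ERK (same grid, n = 3), single-cell nuclear
localization (n = 10) and cytosolic/nuclear activity traces (every 2 min over
75 min; n = 8 and 6), and MEK inhibition at quasi-steady state (n = 10 and 9)
— plus the held-out prediction experiments (dose step-up 0.5 to 1 at 30 min;
inhibition at 10 vs 46 min).  Noise is multiplicative lognormal throughout
because all readouts are positive intensities or ratios: blot/MS use CV 20%;
single-cell traces draw per-cell lognormal jitter (CV 15%) on the
amplitude-like parameters (`a_M`, `a_E1`, `a_E2`, `Sn_tot`, `Sc_tot`) plus
5% measurement noise, and each trace is renormalized to its own t = 0 value,
mirroring per-cell normalization of the imaging data.  The measurement-error
magnitudes are declared defaults, not inferred values.  The generator
emulates replicate structure and per-cell variability but not image
segmentation, photobleaching, blot nonlinearity, or between-experiment trend
normalization — so green tests certify the computational pipeline on data
whose generative model is known, not the fidelity of any particular
laboratory's error structure.

```{r generate}
ds <- generate_datasets(theta, seed = 1)
ds |> count(experiment_id, readout) |> head()
```

## Ensemble fitting

The cost is weighted least squares over all datasets,
`J = sum_d w_d sum_i (s_d m_i - y_i)^2 / sigma_i^2`; for arbitrary-unit
readouts the gain `s_d` is profiled out analytically
(`s_d* = sum(y m / sigma^2) / sum(m^2 / sigma^2)`), for self-normalized
readouts `s_d = 1`.  Fitting follows the ensemble philosophy: rather than a
single best fit, collect many parameter sets that fit the data almost equally
well.  `fit_anneal()` runs Metropolis simulated annealing in log10-parameter
space (geometric cooling, factor 0.95/iteration by default);
`ensemble_walk()` then performs a hard-threshold random walk from the
annealed optimum, accepting a proposal iff `J <= J_min * (1 + epsilon)` with
`epsilon = 0.25`, recording every accepted set.  Proposal steps are normal in
log10 space with width 0.03, which yields a 20-50% acceptance rate for the
default 23-parameter fit; the walk aborts if acceptance falls below 1% in its
calibration phase.  Everything is deterministic given a seed.  The desk-scale
default collects 250 accepted sets (a few minutes on one CPU); the full-scale
setting of 10,000 is a flag away but not needed for the packaged analyses.

## Buffering analysis and predictions

`classify_modes()` computes `(B_c, B_n)` for each accepted set and labels the
buffering mode.  The boundary at `B = 1` is a declared convention (buffering
must "exceed unity" to matter), configurable via the `boundary` argument:
nuclear-dominant (`B_c < 1 <= B_n`), cytosolic-dominant, mixed, or unbuffered.
`species_breakdown()` decomposes total ERK into the eight pools (c, cp, cpp,
cs; n, np, npp, ns).  `run_predictions()` simulates the dose step-up and the
inhibition-timing battery for every ensemble member and reports mean ± s.d.
traces plus per-member half-decay times; members whose simulation fails are
dropped and counted, never imputed.

```{r predictions, eval = FALSE}
fit <- fit_anneal(ds, seed = 2, init = theta, n_iter = 200)
ens <- ensemble_walk(ds, seed = 3, start = fit$par, J_min = fit$J_min, n = 250)
autoplot(ens)                     # buffering-strength scatter
run_predictions(ens, prediction_protocols())
```

## Numerical choices

* Stiff integration by `deSolve::lsoda` with a compiled right-hand side,
  relative tolerance 1e-8 and absolute 1e-10; the integration restarts
  exactly at each protocol event (no smoothing).  A pure-R right-hand side
  drives an independent fixed-step RK4 oracle (`erk_simulate_rk4()`), and the
  two paths agree to 1e-6 on the reference trajectory.
* Conservation (total ERK, total MEK, per-compartment substrate) holds to
  1e-7 along trajectories and is asserted in the test suite, together with
  non-negativity and the variant-reduction limits (full equals control at zero
  substrate; the importin variant converges to control as `k_rel` grows).
* All kinetic parameters are sampled in log10 space.  Simulation failures map
  to infinite cost.  Degenerate configurations fail loudly: a zero
  pre-stimulus readout denominator (basal input and passive shuttling both
  zero), `k_on = 0` with a positive substrate pool, a trace that never
  reaches its half-decay level (explicit no-decay result rather than a
  number).

## Design decisions on genuinely open points

* Whether unphosphorylated ERK shuttles at baseline: yes, via `k_pass` — a
  finite pre-stimulus nuclear signal is required for ratio normalization.
* Whether mono-phospho ERK binds substrates: no; binding is restricted to the
  diphospho form.
* Whether feedback acts on MEK phosphorylation or upstream: implemented as
  desensitization of the MEK phosphorylation rate, with the instantaneous
  Hill form as an alternative mode.
* The nuclear-localization denominator is total cellular ERK (whole-cell mean
  concentration), including substrate-bound ERK.
* High- versus low-affinity nuclear substrate extremes are represented by the
  phosphorylated-substrate readout (`sub_n_phos`, the slow high-stoichiometry
  anchor) and the nuclear activity readout (`ekar_nuc`, a fast low-affinity
  reporter at quasi-equilibrium with free ERK).

## Limitations

* The reference parameter set reproduces kinetic *features*; individual rate
  constants are sloppy, and only composite groupings (buffering strengths,
  nuclear exit rate, MEK dephosphorylation) should be interpreted.
* The basal nuclear ERK concentration at `theta_ref()` is close to the
  whole-cell mean, higher than the cytoplasm-dominant localization often seen
  in quiescent cells; normalized readouts are insensitive to this.
* Deterministic, well-mixed compartments: no stochastic single-cell dynamics
  beyond parameter jitter, no spatial gradients, no explicit
  importin/exportin machinery outside the optional first-order release step.
* The mapping from ligand dose to input strength `S` is taken as given
  (half-maximal ~ 0.5); no receptor module is modeled.
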