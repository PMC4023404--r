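# erkshuttle

Compartmental kinetic modeling of ERK phosphorylation, nucleocytoplasmic
shuttling, and substrate buffering, for systems biologists studying how the
measurable states of a MAP kinase — phosphorylation in a lysate, localization
in an image, activity on a FRET reporter — relate to one another over time.

In growth-factor-stimulated fibroblasts, whole-cell ERK phosphorylation and
nuclear translocation are strongly transient, yet the ERK activity actually
available to substrates in the cytosol and nucleus shows little adaptation,
and free nuclear activity accumulates slowly, lagging the translocation peak.
`erkshuttle` implements the model family that reconciles these observations:
a cytosolic MEK/ERK cascade with negative feedback (desensitization state
$D$, $\mathrm{d}D/\mathrm{d}t = k_{fb}\,E2c\,(1-D) - k_{rec}D$), two-site
distributive phosphorylation, shuttling (facilitated import of free
diphospho ERK at $k_{in}$, passive exchange $k_{pass}$, phospho-independent
export $k_{out}$), and reversible anchoring of active ERK by one dominant
substrate per compartment:

$$E2 + S \xrightleftharpoons[k_{off}]{k_{on}} E2{\cdot}S
  \xrightarrow{k_{cat}} E2 + P, \qquad P \xrightarrow{k_{sdp}} S,$$

with bound ERK immobile and protected from phosphatases.  The buffering
strength of a compartment, $B = (S_{tot}/\phi)/K_m$ with
$K_m = (k_{off}+k_{cat})/k_{on}$, is the composite quantity that controls the
kinetics: with nuclear $B_n \approx 20$, early nuclear ERK is mostly bound
(anchored, protected, reporter-invisible) and is freed only as the substrate
pool becomes phosphorylated — so "adaptation" of phosphorylation and
localization is a by-product of transient buffering.

The package simulates the model variants (full, substrate-free control,
importin-release, combined, constant-MEK), maps trajectories onto the seven
experimental readouts with their normalization conventions, generates noisy
replicate datasets from a packaged reference parameter set, fits parameter
ensembles by simulated annealing plus hard-threshold acceptance
($J \le J_{min}(1+\varepsilon)$), and analyzes buffering modes and
inhibition-timing predictions.

## Worked example

```r
library(erkshuttle)

theta <- theta_ref()                  # packaged reference parameter set
round(kinetic_features(theta), 3)
#>   nucloc_peak_t     nucloc_peak    nucloc_adapt    ekar_nuc_t90     ekar_nuc_60
#>           9.500           1.957           0.739          19.500           3.708
#>  ekar_nuc_adapt ekar_cyt_peak_t  ekar_cyt_decay    ppMEK_peak_t    ppERK_peak_t
#>           0.026           2.500           0.235           3.500           9.500
#>     ppERK_adapt     th46_nucloc   th46_ekar_nuc   th46_ekar_cyt     th10_nucloc
#>           0.637           1.606           1.169           0.592           6.805
#>   th10_ekar_nuc th_ratio_nucloc             B_c             B_n
#>           4.875           4.237           0.006          19.997
```

Reading the key numbers: nuclear localization peaks at 9.5 min and sheds 74%
of its rise by 75 min (`nucloc_peak_t`, `nucloc_adapt`), while free nuclear
ERK activity needs 19.5 min to reach 90% of its plateau and barely adapts
(`ekar_nuc_t90`, `ekar_nuc_adapt`) — the kinetic decoupling the model exists
to explain.  After MEK inhibition at quasi-steady state (46 min), nuclear
localization decays with a half-time of 1.6 min (`th46_nucloc`), but
inhibition imposed at 10 min — while most nuclear ERK is still
substrate-bound and protected — decays 4.2-fold slower (`th10_nucloc`,
`th_ratio_nucloc`).  The substrate buffering strengths place the set in the
nuclear-dominant mode (`B_n` near 20, `B_c` far below 1).

A full round trip — generate synthetic data, fit an ensemble, classify
buffering modes, predict the inhibition-timing experiments:

```r
ds  <- generate_datasets(theta, seed = 1)
fit <- fit_anneal(ds, seed = 1001, init = theta, n_iter = 200)
ens <- ensemble_walk(ds, seed = 2001, start = fit$par,
                     J_min = fit$J_min, n = 250)
glance(ens)                           # n, J_min, threshold, acceptance rate
classify_modes(ens) |> dplyr::count(mode)
autoplot(ens)                         # B_c vs B_n scatter
run_predictions(ens, prediction_protocols())
```

A thin command-line wrapper over the same functions lives at
`inst/cli/erkshuttle.R`
(`Rscript erkshuttle.R <simulate|generate|fit|analyze|predict|reproduce> ...`);
every run writes a manifest JSON recording the fully resolved configuration
and seed.

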