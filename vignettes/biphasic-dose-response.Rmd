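---
title: "Biphasic dose-response analysis: models, mechanism, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic dose-response analysis: models, mechanism, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biphasicdr)
```

This vignette is the package's account of its science: the empirical
biphasic model and how it is fitted, the enzyme-modifier mechanism that
explains where the bell shape comes from, what the synthetic-data
generators do and do not emulate, the trajectory-mobility layer, and the
numerical choices that were genuinely open. Nothing here asserts an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The empirical model

γ-Secretase-directed drugs frequently *increase* Aβ 1-40 output at low
doses and suppress it at high doses. The package models the measured
activity $S$ at drug concentration $x$ (molar, $X = \log_{10} x$) as a
rising logistic minus a falling one:

$$S(X) = PA + (MA - PA)\,A(X) - (MA - MI)\,I(X),$$
$$A(X) = \frac{1}{1 + 10^{(\log_{10}EC_{50} - X)p}}, \qquad
  I(X) = \frac{1}{1 + 10^{(\log_{10}IC_{50} - X)q}}.$$

* `PA` — baseline activity at zero drug, in response units (pM of Aβ 1-40
  for the synthetic ELISA, or % of vehicle). The DMSO vehicle
  (`conc_M = 0`) is an *exact* special case returning `PA`: representing it
  as a large negative log-dose would smuggle an arbitrary floor constant
  into every fit.
* `MA` — the plateau activation would reach if no inhibition competed;
  `MA = PA` encodes "no activation".
* `MI` — the residual-activity plateau at saturating drug. A reading in
  which `MI` is instead the inhibition *magnitude* below `MA` exists in the
  literature of bell-shaped fits; `biphasic_params(mi_is_magnitude = TRUE)`
  converts that convention at the door so internals never branch.
* `EC50`, `IC50` — stored as `log10` molar. Dose designs are logarithmic
  and the logistic is symmetric in $X$, so fitting in log space is the
  well-conditioned parameterization.
* `p`, `q` — Hill coefficients (dimensionless, $>0$); values above one are
  the signature of more than one drug molecule participating in the binding
  event.

The decomposition functions `activation_component()` /
`inhibition_component()` draw the two binding events separately (the
blue/red curves of a typical figure); their identity
`S = act - (MA - inh)` is property-tested, as is agreement with an
independently coded brute-force evaluator at $10^{-12}$ relative error.

## 2. Fitting and model selection

`fit_biphasic()` minimizes unweighted least squares on the linear response
scale (plain nonlinear regression — the field's default for these assays)
with `minpack.lm::nls.lm` under box bounds, using an internal
parameterization `(PA, MI, d = MA - MI, ...)` so that every constraint
(`PA, MI, d >= 0`, `0 < p, q <= 10`, midpoints within the observed dose
range ± 2 log units) is a box bound. Bounding the midpoints prevents the
classic plateau/midpoint trade-off on finite designs; bounding the Hill
coefficients at 10 keeps noise-spanning step functions out of the family.

**Multi-start.** The least-squares surface is multimodal (midpoints can
swap roles, plateaus can absorb transitions). `multistart_seeds()` lays the
activation midpoint on a grid across the observed log-range and the
inhibition midpoint at a grid of positive offsets above it, so every seed
respects `EC50 < IC50`; plateau seeds come from the first response, the
maximum, and the last response. The reported fit is the lowest-RSS
candidate; everything is deterministic given data + config.

**Design requirements.** A seven-parameter bell needs data on both flanks:
fits refuse outright below a 2-log dose span or with fewer than 6 distinct
non-zero doses, with guidance toward `select_model()` sub-models.

**Nested model selection.** The family {flat (1), activation-only (4),
inhibition-only (4), biphasic (7)} is compared by small-sample AICc
($k$ counts the residual variance), with ties within 2 units resolved
toward fewer parameters — the biphasic claim must earn its extra
parameters. One calibration subtlety matters: with proportional
(CV) assay noise, *unweighted* AICc is anti-conservative, because residual
variance scales with the signal and the richer model harvests the
high-variance region. For selection purposes the package therefore offers
`fit_config(weighting = "inverse_variance")`, whose weights come from the
pooled-CV noise model ($\mathrm{var}_c \propto \bar y_c^2$) rather than
from raw per-concentration sample variances — with 3 replicates those raw
variances are so noisy that using them directly destroys selection
accuracy. The acceptance analyses run selection under this weighting;
parameter estimation keeps the unweighted default.

**Uncertainty.** `bootstrap_ci()` provides percentile intervals under two
schemes. Within-concentration case resampling is the textbook choice, but
with few replicates per concentration its plug-in cell variances are both
shrunken (factor $(n-1)/n$) and extremely noisy, and measured interval
coverage falls well short of nominal. Pooled residual resampling — relative
residuals re-applied to the fitted curve, matching the proportional noise
model — restores close-to-nominal coverage, so `scheme = "auto"` selects it
whenever any concentration has fewer than 4 replicates. The coverage
property (95% intervals covering the true activation midpoint in 90–99 of
100 simulated assays) is exercised directly in the test suite.

**Censoring.** Rows outside the assay's linear window are *flagged*, never
dropped; `fit_config(censored = )` chooses exclusion (default), inclusion,
or down-weighting. Vehicle rows always participate — they anchor `PA`.

## 3. The two-site modifier mechanism

The mechanistic layer asks *why* the dose-response is bell-shaped. The
scheme is rapid-equilibrium Michaelis–Menten with two drug sites:

* an **activation site** (dissociation constant $K_{act}$, occupancy weight
  $a = (D/K_{act})^{n_{act}}$, allowed on both E and ES) whose only kinetic
  effect is to divide the apparent Michaelis constant by $\alpha$ —
  the kinetic shorthand for a drug that helps open the substrate channel
  and form the enzyme–substrate complex;
* an **inhibition site** on substrate-bound states only (weight
  $b = (D/K_{inh})^{n_{inh}}$), strictly dead-end — uncompetitive
  inhibition, a drug binding next to the substrate.

Summing the six state weights (E: 1, EA: $a$, ES: $s$, ESA: $a\alpha s$,
ESI: $bs$, ESAI: $a\alpha b s$, with $s = S/K_m$) gives

$$\frac{v}{k_{cat}E_0} =
  \frac{s(1+a\alpha)}{1 + a + s(1+a\alpha)(1+b)}.$$

Concerted exponents $n_{act}, n_{inh}$ stand in for sequential microscopic
site constants because dose-response data report only Hill-type steepness.
The closed form collapses to Michaelis–Menten at $D = 0$ and to the
textbook uncompetitive law $v = S/(K_m + S(1 + D/K_{inh}))$ at
$\alpha = 1$; both limits, and agreement with a species-enumeration oracle
at $10^{-10}$, are tested. `apparent_mm()` returns
$V_{max}^{app} = k_{cat}/(1+b)$ and
$K_m^{app} = K_m(1+a)/[(1+a\alpha)(1+b)]$ analytically, with a numeric
`method = "fit"` cross-route.

**Sub-saturating substrate is the point.** At $S \ll K_m$ the velocity is
$\propto s(1+a\alpha)/(1+a)$: activation-site occupancy raises it up to
$\alpha$-fold, and the uncompetitive term only bites at higher doses — a
bell. At $S \gg K_m$ the same algebra leaves $v \approx V_{max}^{app}$,
monotone decreasing: the activation phase is invisible in saturating
assays. `classify_response()` turns this into a testable property
(its four classes are exhaustive; a shape with sign changes but no peak
above both endpoints is assigned the class of its net endpoint change).

**Bridge to the empirical model.** Mechanism-generated curves at
$S = 0.1K_m$ are fitted by `fit_biphasic` with $R^2 > 0.99$, and the
recovered midpoints track the binding constants. The documented bridge grid
is $\alpha \in \{8, 10, 15\}$, $n \in \{1, 2\}$, $K_{act} = 10^{-8}$ M,
$K_{inh} = 10^{-6}$ M, and the 0.5-log agreement window is bounded on both
sides by arithmetic, not by fitting error: at sub-saturating substrate the
apparent IC50 sits at $K_{inh}(1 + 1/(s\alpha))$ (weak-$\alpha$ schemes
push it high — $\alpha = 3$ puts it 0.64 logs above $K_{inh}$), while
strong activation drags the apparent EC50 toward
$K_{act}/\sqrt{\alpha}$ ($\alpha = 30$ puts it 0.56 logs low). Within the
grid both offsets stay below 0.36 logs. Fitted Hill coefficients rise
monotonically with the site stoichiometries.

The scheme deliberately omits what the data cannot identify: no
Notch-vs-APP substrate competition, no processive tripeptide kinetics, no
$k_{cat}$-modulating activation variant (noted as an alternative; the
dose-response shape alone cannot distinguish it from Km modulation at
fixed sub-saturating S).

## 4. Synthetic data: what is and is not emulated

`assay_design()` defaults encode the emulated experiment at desk scale: 12
log-spaced doses from 0.1 nM to 100 µM plus a DMSO vehicle row per
replicate, 3 replicates, 5% proportional (CV) noise, and a 6–125 pM ELISA
linear window producing per-row censor flags. The four-drug truth records
(`four_drug_truth()`) encode only *qualitative* orderings reported for the
real compounds — LY-411,575 lowest EC50/IC50, highest Hill coefficients and
maximal activation; DAPT the opposite pole; semagacestat between;
avagacestat sharing LY's midpoints with lower Hill coefficients; identical
baseline `PA` for all four (one cell batch); inhibition steeper than
activation throughout. The numeric values behind those orderings are the
generator's own choices (PA = 25 pM, MA 60–110 pM, MI = 8 pM, midpoints
spread over 2.7 logs), placed inside the ELISA window and the dose grid so
that a realistic design can actually constrain them.

Not emulated, hence not demonstrated by passing tests: plate and edge
effects, day-to-day batch drift, multi-analyte (Aβ42/38) readouts,
non-Gaussian outliers, and any real cell biology — the generators show that
the *pipeline* recovers known truth under its stated noise model, not that
the model is true of cells.

`simulate_trajectory()` builds one pseudo-Cα per residue on an ideal
α-helical backbone and displaces each residue isotropically per frame with
known per-residue σ (so the expected RMSF is $\sigma\sqrt{3}$), optionally
under a random global rotation+translation per frame. Coordinates are
rounded to 0.001 Å — the PDB fixed-width grid — so written files round-trip
bit-identically.

## 5. Trajectory mobility layer

All analyses run on an atom *selection* (default: Cα atoms), unweighted by
mass. `kabsch_superpose()` is the SVD solution with the determinant
correction (always a proper rotation; near-collinear point sets are
flagged). RMSF and PCA superpose every frame onto an iteratively refined
mean structure: the iteration starts from frame 1 and repeats until the
mean converges (tolerance $10^{-12}$, at most 50 passes — typically 2).
A single refinement pass is the common shortcut, but it leaves a residual
dependence on the input frames' global placement of order $10^{-5}$ Å,
and the invariance contract here (RMSF and PCA eigenvalues unchanged to
$10^{-8}$ Å under a global rigid transform of every frame) requires the
fixed point. Mobility classes are RMSF quartiles (`low` to `highest`, ties
to the lower bin), matching the usual thin-blue-to-thick-red mobility
cartoons. `delta_rmsf()` reports contiguous runs of per-residue RMSF
decrease beyond a threshold (default 0.1 Å) ranked by total decrease —
the quantitative form of "the drug rigidifies these loops".
`salt_bridge_occupancy()` counts a bridge in a frame when any Asp/Glu
carboxylate oxygen (or C-terminal OXT) lies within 4.0 Å (the common
convention) of any Lys NZ / Arg NH1/NH2/NE nitrogen.

Two finite-size facts are worth knowing. First, superposition removes six
rigid degrees of freedom and redistributes variance across residues, so
per-residue RMSF recovery is biased at short chain lengths and wide
amplitude profiles; the recovery checks run at 80 residues with
σ ∈ [0.6, 1.4] Å and 5000 frames, where the residual bias plus sampling
noise stays within the 5% assertion. Second, the 0.001 Å file rounding
floors file-roundtripped RMSF at ~3 × 10⁻⁴ Å, so exact rigid-invariance
checks operate on in-memory ensembles.

## 6. Pipeline, seeds, and problem sizes

`run_simulate()` / `run_fit()` / `run_traj()` tie the stages together over
one `default_config()`; the numbered drivers under `analysis/` are thin
narratives over these functions. Every stochastic stage draws its seed
deterministically from the master seed (`derive_seed`), outputs are CSV/JSON
with `%.10g` formatting and provenance headers (stage, seed, config hash),
and identical master seeds reproduce outputs byte-for-byte — a tested
contract, since silent nondeterminism is the usual way pipelines rot.

Simulation sizes used by the tests and the acceptance script — 1000-draw
oracle comparisons, 200 noisy datasets for recovery, 100 per class for
selection accuracy, 100 datasets × 199 bootstrap resamples for coverage,
5000-frame trajectories for RMSF recovery — were chosen so the whole
suite characterizes every stochastic claim while remaining a desk-scale
run on one CPU.

## 7. Known limitations

* The empirical and mechanistic layers are linked by shape, not identity:
  EC50/IC50 approximate $K_{act}$/$K_{inh}$ only within the documented
  bridge regime, and degrade outside it for the arithmetic reasons above.
* The mechanism is rapid-equilibrium; systems where channel-opening
  *kinetics* (not occupancy) rate-limit would need a different treatment.
* The bootstrap targets replicate noise only; systematic assay error
  (calibration drift, plate effects) is outside both the generator and the
  intervals.
* The trajectory layer reads multi-model PDB and XYZ only, one altloc, no
  compressed MD formats, and its fixtures are Cα-level — salt-bridge
  analysis therefore requires user-supplied side-chain coordinates.
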