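---
title: "Models and methods behind pnatherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pnatherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnatherm)
```

`pnatherm` analyses the binding thermodynamics of peptide nucleic acid
(PNA) homoduplexes. This vignette is the package's own account of the
models it implements, the assumptions they rest on, the tunable
parameters that matter, and the places where the design was genuinely
open and a choice had to be made.

## The nearest-neighbor model

A duplex of length $L$ is decomposed into its $L-1$ overlapping
dinucleotide *stacks*. Because the two strands of a homoduplex are
related by antiparallel Watson–Crick complementarity, the stack read
$X_1X_2$ on one strand is the stack $\mathrm{comp}(X_2)\mathrm{comp}(X_1)$
on the other; the 16 dinucleotides therefore collapse into 10
symmetry-unique classes (four self-equivalent: AT, TA, GC, CG; six
two-member classes, e.g. TT→AA, GT→AC). The binding observable
(enthalpy here; entropy and free energy share the algebra) is modelled
as

$$\Delta\chi \;=\; \sum_{i=1}^{10} j_i\,\Delta\Delta\chi_i
  \;+\; \Delta\chi_{\mathrm{init}} \;+\; B\,\Delta\chi_{\mathrm{T.GC}},$$

with $j_i$ the occurrence count of class $i$, a per-duplex helix
initiation term, and a terminal-GC term that enters only when **both**
terminal base pairs are G·C ($B \in \{0,1\}$ — a single A·T terminus
zeroes it). All quantities are stored *signed* (negative = stabilizing);
published tables print magnitudes ($-\Delta H$), and the conversion
happens only at file boundaries (`read_observations()`,
`write_params()`). This prevents double-negation bugs and is why the
packaged parameter CSV carries a `neg_dH_kcal` column.

Two properties of this parameterization are worth stating because the
tests rely on them: predictions are invariant under replacing a strand
by its antiparallel complement (the design row is identical), and the
model is exactly additive, so removing a terminal base changes the
prediction by the lost stack term plus any change in $B$ times the
terminal-GC term.

The packaged reference parameter set (`pna_nn_params()`) carries 12
terms with standard errors. Its helix-initiation enthalpy is
*negative* — atypical for nucleic acids, where charged backbones
penalize association; PNA's neutral backbone removes that barrier. The
parameter table labels follow the field's convention; one source row
was printed as "T.GG" but is, from context (it multiplies the
two-terminal-G·C indicator), the terminal-GC term, and is stored as
`T.GC`.

For self-complementary duplexes (a strand equal to its own antiparallel
complement; only even lengths qualify) the binding entropy is decreased
by 1.4 cal K⁻¹ mol⁻¹ for the C2 rotational symmetry of the helix. The
decrement applies to entropy *predictions* only — never to the enthalpy
fit — and at most once per prediction (`symmetry_correction()`,
triggered automatically inside `nn_predict()` for entropy parameter
sets).

### Estimation

`nn_fit()` solves the weighted least-squares problem
$\min_\varepsilon \lVert \sigma^{-1}(\chi - S\varepsilon)\rVert^2$ with
$S$ the $N \times 12$ design matrix (stack counts, a constant initiation
column, the terminal-GC indicator) and $\sigma^{-1}$ a diagonal matrix
of reciprocal standard errors (or the identity, for
`weighting = "unweighted"`). The solver works on the SVD of the weighted
design; rank deficiency is detected at a singular-value threshold of
$10^{-10}$ times the largest singular value and reported with the names
of the unidentifiable columns rather than silently dropping them. At
least 12 observations are required; p-values are two-sided t-tests on
$N - 12$ degrees of freedom. Tests cross-check the solver against an
explicit normal-equations solution $(S^\top W S)^{-1} S^\top W \chi$ to
$10^{-10}$ relative.

Zero standard errors occur in real compilations (literature values
reported without errors). Reciprocal weighting cannot consume them, so
they are clamped to a floor — by default the smallest *positive* SE in
the data set, overridable via `se_floor` — with a warning, never
silently.

**Standard errors when the weights are themselves estimates.** The
classical weighted covariance $\hat\sigma^2 (S^\top W S)^{-1}$ treats
the weights as known. When each observation's SE comes from only three
replicates it carries 2 degrees of freedom, and the resulting weights
are so noisy that the classical term SEs become badly anticonservative:
in the package's own simulations (49 sequences, triplicate noise of
1 kcal mol⁻¹), the joint probability that all 12 parameters fall within
3 classical SEs of truth is only ~0.6, against a nominal ~0.97.
`nn_fit(se_type = "hc3")` therefore offers a heteroscedasticity-robust
(HC3 sandwich) covariance, which restores the joint 3-SE coverage to
~0.97 in the same simulations. The default remains `"classical"` — it
is what the weighted normal equations imply, matches the oracle tests,
and is correct when the SEs are well determined — but the Monte-Carlo
recovery tests use `"hc3"`, and analyses weighting by few-replicate SEs
should too.

### Calibration propagation

When computed observables are first calibrated against experiment by an
affine map $\chi_{\mathrm{exp}} = a\,\chi_{\mathrm{com}} + b$
(`fit_calibration()`), fitting the nearest-neighbor model to calibrated
data is — exactly, by linearity of least squares — the same as scaling
every stack and terminal-GC term by $a$ and mapping the initiation term
to $a\,\Delta\chi_{\mathrm{init}} + b$: the intercept is absorbed
entirely by the constant column. `propagate_calibration()` implements
this and flags the result, for two documented reasons: slope
coefficients differ between state variables, so
$\Delta\Delta G = \Delta\Delta H - T\Delta\Delta S$ need not survive
calibration; and the calibrated initiation term may be dominated by the
intercept, i.e. by a metric of computational error rather than any
physical quantity.

## Two-state melting analysis

UV melting curves at 260 nm rise on melting (single strands are
hyperchromic). `normalize_to_alpha()` converts absorbance to the
duplexed fraction $\alpha$ by min-max normalization
($\alpha = 1$: all duplex). The melting temperature is the first
downward crossing of $\alpha = 0.5$, linearly interpolated between the
bracketing grid points (measured curves are typically sampled at 2 K
steps; interpolation rather than nearest-point was chosen because it is
deterministic, grid-independent, and exact on linear segments).

The two-state equilibrium constant for self-complementary strands at
total strand concentration $C_T$ is
$K = \alpha / (2(1-\alpha)^2 C_T)$ — the standard Marky–Breslauer form,
which gives the clean fixed point $K(\alpha{=}0.5) = 1/C_T$; for
non-self-complementary duplexes at equal strand concentrations,
$K = 2\alpha / ((1-\alpha)^2 C_T)$. `vant_hoff_fit()` regresses
$\ln K$ on $1/T$: $\Delta H^\circ = -R \cdot \mathrm{slope}$,
$\Delta S^\circ = R \cdot \mathrm{intercept}$, with
$R = 1.987204$ cal K⁻¹ mol⁻¹, energies in kcal mol⁻¹ and entropies in
cal K⁻¹ mol⁻¹ throughout (the `/1000` in
$\Delta G = \Delta H - T\Delta S/1000$ reconciles the two units). The
analysis assumes $\Delta H$ and $\Delta S$ are temperature-independent
and strictly two-state behaviour.

Only points with $\alpha$ inside a window (default $[0.15, 0.85]$)
enter the regression, because the $\alpha \to K$ transform diverges at
the tails and a measured $\alpha$ of exactly 0 or 1 is uninformative.
The window is configurable; on noise-free synthetic curves the result is
window-independent, which the tests exercise.

### What min-max normalization can and cannot do

Min-max anchoring is exact only when the curve actually reaches both
plateaus. On a finite grid the duplexed fraction at the cold end is
$1 - O(1/\sqrt{K C_T})$, so the recovered $\alpha$ is a slightly
rescaled version of the true one; round-trip tests therefore use grids
wide enough that this rescaling is below $10^{-4}$ and assert the
thermodynamic round trip at 0.1%.

Under noise the picture is sharper: the min and max of a noisy curve are
biased estimators of the plateaus (each is an extreme of ~20 draws), and
in simulations with absorbance noise of 0.005 on a 0.5 absorbance range
this alone biases the fitted $\Delta H$ by about +2.5 kcal mol⁻¹.
`normalize_to_alpha(baseline = "linear")` instead fits straight-line
plateaus through the `n_baseline` (default 4) coldest and hottest
points and normalizes between the fitted lines, which removes the bias
and also handles genuinely sloping baselines. Separately, the ordinary
regression SEs of the van't Hoff line cannot see normalization error at
all — it is shared across points — so `melt_fit(se_method =
"bootstrap")` re-estimates the errors by a parametric bootstrap of the
*entire* pipeline: the noise level is estimated from residuals around a
smoothing spline (inflated by the spline's fitted degrees of freedom),
replicate curves are resampled, renormalized and refitted, and the
spread of the refits is reported. In the package's simulations this
brings the 3-SE coverage of $\Delta H$ from ~0.59 (plain min-max +
regression SEs) to ~0.94; the residual shortfall from the nominal
~0.99 reflects the nonlinearity of the two-stage estimator and is why
the corresponding test asserts coverage above 0.88 rather than a
nominal value. Global sigmoid fitting, which would do better still, is
deliberately out of scope.

## End-point (MM-GBSA) post-processing

The package consumes tables of computed binding enthalpies, entropies or
free energies — it never evaluates generalized Born energies or
quasi-harmonic entropies. Three operations wrap such tables:

* `standard_state_correction(v_box, T)` returns
  $-RT\ln(V^\circ/V_{\mathrm{box}})$ with $V^\circ = 1661\ \text{Å}^3$
  (the volume per molecule at 1 M), the additive shift that references a
  free energy computed in a periodic box to the 1 M standard state. The
  sign convention (larger boxes make binding $\Delta G$ more positive)
  follows the standard-state literature; the magnitude is
  convention-independent and is what the tests pin down.
* `fit_calibration()` / `apply_calibration()` fit and apply the affine
  experimental-vs-computed map by ordinary least squares (unweighted —
  appropriate for a 10-point calibration with comparable errors).
* `benchmark_predictions()` reports the mean absolute difference (taken
  as the error of the prediction), the mean relative error in percent,
  and $R^2$ (squared correlation). Entries with a zero reference are
  excluded from the relative error with a warning.

## Hydrogen-bond melting events

`detect_hbond()` applies the geometric Watson–Crick criterion:
donor–acceptor distance `< 0.325` nm **and**
hydrogen–donor–acceptor angle `< 30°`, both strict inequalities. The
angle is measured at the donor (between the donor→hydrogen and
donor→acceptor vectors); trajectory tools are ambiguous about whether
that angle sits at the donor or at the hydrogen, so
`angle_at = "hydrogen"` is available as a flag.

A base pair (2 bonds for A·T, 3 for G·C) is *fully bonded* at a frame
when all its bonds are formed. A **melting event** is a maximal run of
consecutive frames with at least one bond broken; the continuous
definition is discretized at the trajectory sampling interval, so a
single broken frame is an event of duration `dt`. Events touching the
first or last frame are counted but flagged `censored` (their true
duration is unknown); occurrence curves include them, and the dwell-time
tests exclude them. Two exact bookkeeping identities hold by
construction and are asserted in the tests: melted time plus fully
bonded time partitions the series duration per pair, and the
occurrence-per-nanosecond curve is non-increasing in the duration
threshold.

`percent_bonded()` reports the per-pair mean of `count/max_bonds`,
averaged within groups (by default pair class × pair type — "terminal"
means the first and last pairs, "internal" the 3rd-position pairs in the
reference analyses; both selections are configurable by filtering the
input) and expressed as mean ± SD in percent.

## The synthetic-data generators

The generators emulate the study conditions of the reference data set,
and their defaults *are* those conditions: panels of 49 sequences with
lengths 6–18, triplicate observations with homoscedastic Gaussian noise
of ~1 kcal mol⁻¹ around the packaged ground-truth parameters (an
optional length-proportional noise mode exists because longer duplexes
show larger end-point spread), melting curves sampled at 2 K intervals,
and per-bond two-state Markov chains with open/close probabilities
$1 - e^{-k\,dt}$. All generators take a `seed` and restore the caller's
RNG state.

What they deliberately do **not** emulate: correlated replicate errors,
multi-state melting or aggregation, sloping instrument baselines beyond
the linear option, force-field realism, or correlated bond dynamics
within a pair (bonds open independently). Passing tests therefore
demonstrate the correctness and calibration of the estimators under the
stated models, not the validity of those models for any particular
instrument or force field.

Problem sizes in the test suite were chosen to make Monte-Carlo
conclusions stable while staying comfortably interactive: 200 fit
repetitions for parameter-recovery coverage, 100 melting-curve
repetitions with a 60-replicate bootstrap, and 50 Markov runs of 20–30
ns at `dt = 0.01` ns for the dwell-time comparisons (the analytic
reference there is an exact absorbing-chain calculation on the
broken-bond count, solved as a small linear system).

## Known limitations

* The two anomalous benchmark rows (TGTTACGACT, AGGTAACCAG) cannot be
  reproduced from the published parameter table under any defensible
  stack-equivalence convention; they are flagged in
  `pna_benchmark_data()` and excluded from exact checks rather than
  "fixed".
* The 5-bond group mean of the packaged parameters computes to 9.69,
  while the source table prints 9.72; the averaging scheme behind that
  printed cell is unstated, and the package reports the computed value.
* Only the four canonical bases are supported (no IUPAC ambiguity
  codes), only homoduplexes (no PNA/DNA or PNA/RNA heteroduplexes), and
  no mismatch, dangling-end or salt-correction terms.
* No trajectory-format parsing: hydrogen-bond series enter as CSV counts
  or as coordinate triplets already extracted from a trajectory.
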