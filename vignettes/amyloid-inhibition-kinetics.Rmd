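---
title: "Models and methods: classifying inhibitors of amyloid self-assembly"
author: "amylokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: classifying inhibitors of amyloid self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylokin)
```

# The scientific problem

Amyloid formation by peptides such as IAPP (amylin) proceeds by nucleated
polymerization: new fibrils arise from monomers (primary nucleation),
grow by monomer addition at their ends (elongation), and multiply through
fibril-dependent secondary processes (fragmentation or secondary
nucleation on fibril surfaces). A small molecule that slows aggregation
may act on any of these steps, and the distinction matters: an inhibitor
of primary nucleation delays the appearance of aggregates, while an
elongation inhibitor can increase the concentration of diffusible
oligomers. This package implements the quantitative machinery for
answering *which* step a compound perturbs from ordinary plate-reader
dye-binding (ThT) kinetics, plus the auxiliary biophysical fits used to
characterize binding (Taylor dispersion, SPR, NMR chemical-shift
perturbation, microfluidic particle counting, copelleting).

# The kinetic model

## Moment equations

For fibril number concentration $P$ and fibril mass concentration $M$,
with free monomer $m = m_0 - M$:

$$\frac{dP}{dt} = k_n m^{n_c} + \text{(secondary source)},\qquad
  \frac{dM}{dt} = 2 k_+ m P,$$

where the secondary source is $k_f M$ for fragmentation,
$k_2 m^{n_2} M$ for single-step secondary nucleation, or the saturating
(multistep) form $k_2 M\, m^{n_2} / (1 + (m/K_2)^{n_2})$ with effective
Michaelis constant $K_2$. The factor 2 in the mass flux is the two-ended
elongation convention used throughout the secondary-nucleation
literature. `moment_ode_oracle()` integrates this system numerically
(deSolve/lsoda, default `rtol` 1e-8) and is the package's independent
reference: every closed form below is validated against it in the test
suite, and mass conservation $m + M = m_0$ is checked to $10^{-6} m_0$.

## Normalized and macroscopic rates

The per-process rates evaluated at the initial monomer concentration are
$\nu_n = k_n m_0^{n_c}$, $\nu_+ = k_+ m_0$, and
$\nu_2 = k_2 m_0^{n_2}$ (single-step) or
$\nu_2 = k_2 m_0^{n_2}/(1 + (m_0/K_2)^{n_2})$ (multistep); for
fragmentation the secondary rate is simply $k_f$. Curve shapes are
governed by two macroscopic combinations,

$$\lambda = \sqrt{2\,\nu_+ \nu_n / m_0}, \qquad
  \kappa = \sqrt{2\,\nu_+ \nu_2},$$

the rates of monomer conversion through the primary and secondary
pathways. Because each is a square root of a product, scaling one
microscopic rate by a factor $f$ scales the corresponding macroscopic
rate by $\sqrt f$ — the coupling that the dose-series fits exploit.

## Closed-form curves

Without secondary processes, the moment system has an exact solution
(`oosawa_curve()`):

$$M(t)/m_0 = 1 - \operatorname{sech}^{2/n_c}\!\big(\sqrt{n_c/2}\,\lambda t\big).$$

Exactness is not folklore here: substituting
$m/m_0 = \operatorname{sech}^{2/n_c}(\sqrt{n_c/2}\,\lambda t)$ into the
moment system satisfies it identically, and the suite verifies agreement
with the numerical oracle to well below 1% of plateau over
$n_c \in \{1.5, 2, 3\}$.

With a secondary pathway the package uses a renormalization-style
single-parameter closed form (`rg_curve()`):

$$M(t)/m_0 = 1 - \Big[\,1 + \theta\,\tfrac{\lambda^2}{\kappa^2}
  \big(\cosh(\kappa t) - 1\big)\Big]^{-1/\theta}.$$

Its early-time expansion, $(\lambda/\kappa)^2(\cosh\kappa t - 1)$, is the
exact solution of the linearized moment equations independent of
$\theta$; $\theta$ only controls how monomer depletion shuts the
secondary pathway down late in the reaction. Calibrating against the
oracle gives an approximately linear dependence on the *effective* local
reaction order of the secondary rate law,
$\theta \approx 0.32 + 0.69\, n_{2,\mathrm{eff}}$ (`theta_for()`), where
$n_{2,\mathrm{eff}} = 0$ for fragmentation, $n_2$ for single-step
secondary nucleation, and $n_2/(1+(m_0/K_2)^{n_2})$ for the saturating
multistep form. Two consequences:

* a strongly saturated secondary pathway behaves like $\theta \approx
  0.32$, and with matched $\theta$ the closed-form half-time tracks the
  oracle to about 1% over $\kappa/\lambda \in [5, 500]$ (the acceptance
  suite enforces 5%);
* the default $\theta = 0.323$ used for the inhibitor fits corresponds
  to a saturated multistep secondary process, consistent with the
  mechanism the monomer-series comparison favors.

The form does not reduce to the nucleation-elongation solution as
$\kappa \to 0$; `rg_curve()` therefore refuses $\kappa = 0$ with
$\lambda > 0$ and directs the caller to `oosawa_curve()`. Numerically,
$\cosh(\kappa t) - 1$ is evaluated directly below $\kappa t = 350$ and as
$e^{\kappa t}/2$ in log space above, so extreme arguments never overflow
to `NaN`.

# Global fitting

## Scenario fits for inhibitor dose series

An inhibitor dose series shares $m_0$ across conditions, so only
$(\lambda_j, \kappa_j)$ per condition are observable; products such as
$\nu_+\nu_n$ are identifiable but the individual microscopic constants
are not. `fit_scenario()` therefore parameterizes the global fit by the
reference-condition rates $(\lambda_0, \kappa_0)$ plus one factor $f_j$
per non-reference condition multiplying the *normalized rate* of the
scenario's free process: $\lambda_j = \lambda_0\sqrt{f_j}$ (primary
free), $\kappa_j = \kappa_0\sqrt{f_j}$ (secondary free), or both
(elongation free). This is an exact reparameterization of fitting the
$\nu$'s with one process free and the rest shared. All three scenarios
carry the same parameter count, so AICc comparison reduces to residual
comparison with identical penalties — selection is driven purely by which
coupling pattern matches the data.

Choices a fitter must make, fixed and documented here:

* **Log-space rates.** All rates and factors are fitted as logarithms:
  positivity without penalty terms; standard errors are mapped back by
  the delta method.
* **Multistart.** Sigmoid global fits are multi-modal, so each fit runs
  Levenberg–Marquardt (minpack.lm) from a deterministic Latin-hypercube
  of starts (default 16) over a $\kappa$ box spanning
  $[0.5, 30]/t_{50}$ of the reference condition, with $\lambda$ chosen at
  each start so the closed form reproduces the observed half-time. The
  schedule is a pure function of the seed, so results are reproducible
  bit for bit.
* **Replicates pooled, unweighted.** Residuals are computed on normalized
  curves with every replicate well entering individually; no averaging
  before fitting and no weighting.
* **$n$ for AICc** counts every retained time point in every well.
* **Down-sampling.** Wells are thinned to at most 300 points before
  fitting (speed); pass `downsample = Inf` to disable.
* **$\theta$** is fixed at 0.323 for inhibitor scenario fits and free
  (bounded $[0.05, 3]$) for monomer-series mechanism fits, where the
  data span enough of an $m_0$ range to constrain it.

Fit quality uses the least-squares AICc convention,
$n\ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$, with $\Delta$AICc relative
to the best model.

## Monomer-series mechanism fits

`fit_monomer_series()` discriminates mechanisms by their characteristic
scaling of $\lambda$ and $\kappa$ with $m_0$: shared microscopic
constants, $m_0$ varying per condition. The candidates and their free
parameters: nucleation–elongation ($2 k_+ k_n$, $n_c$: 2 parameters),
fragmentation (+$2k_+k_f$, $\theta$: 4), single-step secondary
nucleation (+$2k_+k_2$, $n_2$, $\theta$: 5), multistep secondary
nucleation (+$K_2$: 6). Reaction orders are fitted directly with box
bounds ($n_c \in [1, 6]$, $n_2 \in [0, 5]$); rate products in logs.

## Direct rate extraction

`extract_macroscopic()` refits each condition independently at the level
of $(\lambda, \kappa)$ and reports asymptotic standard errors from the
local Jacobian — the per-dose "rate versus concentration" view that shows
*which* macroscopic pathway an inhibitor suppresses. Standard errors are
asymptotic covariance errors; no profile or bootstrap intervals are
attempted.

# Plate screening

Preprocessing follows the plate-reader conventions: traces are baselined
by the time-pointwise mean of the plate's blank wells, then each
condition's replicate wells are divided by the maximum over time of
their replicate-mean trace, so every condition's mean trace plateaus at
1 (and the operation is idempotent). Half-times are plateau-relative 50%
crossings with linear interpolation between samples and no smoothing by
default. The activity call combines a fold-change of mean half-times
(compound/control) with a two-sided Mann–Whitney U test on the per-well
half-times: active requires fold-change $\ge 1.25$ or $\le 0.8$ *and*
$p < 10^{-4}$. The exact U distribution is used when both groups have at
most 8 wells, the normal approximation with continuity correction above.
Wells that never cross half their plateau are excluded with their
identities recorded; a group losing all wells yields an explicit
no-call.

One consequence worth knowing: with 3 wells per group the exact
two-sided Mann–Whitney floor is $p = 0.1$, so the $10^{-4}$ threshold
can never be met within a single small plate. Significance at that
threshold requires pooling replicates across repeat experiments
(about 9 wells per group or more); the validation suite therefore
calls activity on 12-well groups, emulating pooled repeats.

End-point intensities are summarized per condition as mean and SEM of
the final 10% time window, flagged when the mean trace still drifts by
more than 0.05 normalized units across that window.

# Auxiliary biophysics

* **Taylor dispersion.** Taylorgrams are fitted with the Gaussian
  dispersion model $I(t) = A/\sqrt{2\pi\sigma^2}\,
  e^{-(t-t_R)^2/2\sigma^2}$ with $\sigma^2 = a^2 t_R / (24 D)$
  (capillary radius $a = 37.5$ µm, $T = 303$ K, $\eta = 0.797$ mPa·s by
  default), then $R_h = k_B T / (6\pi\eta D)$. Note that a pure
  time-origin shift changes the fitted $D$ proportionally to $t_R$
  because the data fix the peak *width*; the suite tests exactly this
  invariant.
* **SPR.** Single traces: biexponential association
  $A_1(1-e^{-k_1 t}) + A_2(1-e^{-k_2 t})$ with plateau $A_1+A_2$; rates
  within 5% of each other are flagged effectively monoexponential rather
  than erroring. Dose series: global two-piece 1:1 Langmuir fit
  (exponential association to $\tau = 60$ s, exponential dissociation
  after) sharing $B_\mathrm{max}$, $k_\mathrm{on}$, $k_\mathrm{off}$,
  with optional pinning of $B_\mathrm{max}$. A fitted
  $K_D$ more than 5× the highest analyte concentration is reported with
  status `KD_above_range` — the regime where plateaus grow linearly with
  concentration and the data do not determine $K_D$; with a pinned
  $B_\mathrm{max}$ the reported $K_D$ is then a convention, not a
  measurement.
* **NMR.** CSPs use the weighted two-shift combination
  $\sqrt{(\Delta\delta_H^2 + (w\,\Delta\delta_N)^2)/2}$ with $w = 0.14$
  by default (configurable; published weightings vary between 0.1 and
  0.2 and the choice rescales but does not reorder residues). Intensity
  ratios $I/I_0$ use raw peak heights, not volumes.
* **Copelleting.** Percent free compound is the fold-change of the
  reference-subtracted, 400-nm-baselined absorbance at the compound's
  $\lambda_\mathrm{max}$ (defaults shipped for the four study compounds);
  the measure is invariant under any common gain applied to all four
  spectra.
* **Extinction coefficient.** The standard composition rule
  $5500\,n_\mathrm{Trp} + 1490\,n_\mathrm{Tyr} + 125\,n_\mathrm{cystine}$
  at 280 nm.
* **Buffer capacity.** Van Slyke
  $\beta = \ln 10\,([H^+] + [OH^-] + \sum_i C_i K_{a,i}[H^+]/([H^+]+K_{a,i})^2)$
  with a temperature-interpolated water ion product. For 160 mM
  ammonium acetate (pKa 9.1) at pH 7.4 and 30 °C this evaluates to about
  7.07 mM. Published figures for this buffer are slightly higher;
  without knowing which pKa values and activity corrections produced
  them the package reports the plain Van Slyke value rather than tuning
  constants to match.

# Capflex spike counting

The spike rule is: a sample is spike-flagged when it exceeds the running
median (window 15 samples) by more than 0.01 normalized units.
Implementation choices: the window is in samples (the convention for
running medians); at the series ends the window shrinks to the available
samples; for an even effective window the lower median is taken, so the
statistic is always an observed value; contiguous flagged samples merge
into one spike, with a single unflagged sample sufficient to separate
two spikes. Plateau levels (free-compound fractions after normalization
to the compound-only control) are medians over the plateau window
(default 30–80 s) with spike-flagged samples masked, which keeps them
unbiased to within 1% across 0–20 spikes per trace.

# The synthetic-data generators

Every pipeline input has a seeded generator with recorded ground truth:
raw ThT plates (`gain × model curve + baseline + noise`, with the gain
drawn once per well at 5% spread to emulate well-to-well variability,
readings every 5 min, 3 blanks), inhibitor dose series in which exactly
one process's normalized rate is scaled per condition, monomer series
generated from one microscopic parameter set across $m_0$, Gaussian
taylorgrams, biexponential and Langmuir sensorgrams, and step-plateau
elugrams with planted single-sample spikes. Noise is additive Gaussian
on the normalized signal, default $\sigma = 0.01$ of plateau (0.002 for
elugrams, 1 RU for SPR). The default kinetic conditions
(`default_kinetics()`: $m_0 = 20$ µM, $\lambda \approx 0.04$ h⁻¹,
$\kappa \approx 2$ h⁻¹, half-time ≈ 4 h, saturated multistep secondary
nucleation with $K_2 = 2$ µM) were chosen once to resemble quiescent
micromolar IAPP assembly at 30 °C and are the conditions under which all
recovery and identifiability statements are validated.

What the generators deliberately do **not** emulate: photobleaching,
evaporation, flocculation or drift artifacts; realistic (non-white,
signal-dependent) instrument noise; well-position effects; fibril
length distributions or oligomer populations; seeded kinetics. Passing
the validation suite therefore demonstrates that the estimators are
correct and well-conditioned under the stated noise model — it does not
certify performance on instrument data with artifacts outside that
model, where visual inspection of residuals remains essential.

# Validation problem sizes

The suite and the acceptance script validate at the following scales,
chosen to exercise the estimators while keeping a full run at a few
minutes on one CPU: an 18-point parameter grid for the
nucleation–elongation/oracle comparison; $\kappa/\lambda \in [5, 500]$
for the secondary closed form; 20 seeded dose-series replicates per
perturbation type (5 conditions × 3 wells, scaling $1 \to 0.1$,
$\sigma = 0.01$) for scenario identifiability; 100 seeded elugrams for
spike recall/false positives; and 100 seeded identical-group plates
(12 wells per group) for the screening false-positive rate.

# Known limitations

* The secondary-process closed form is an approximation; its accuracy
  degrades mildly at $\kappa/\lambda < 5$ and for steep unsaturated
  secondary kinetics ($n_2 \ge 3$) where the matched $\theta$ exceeds 2.
* Scenario fits assume the inhibitor rescales exactly one normalized
  rate per concentration; mixed-mechanism compounds will show as the
  closest single-process pattern with inflated residuals.
* Standard errors are asymptotic; for strongly correlated parameters
  (e.g. $\kappa$ and $\theta$ fitted jointly) they understate
  uncertainty.
* No Bayesian posterior sampling, model averaging, or fitting of raw
  fluorescence with instrument gain parameters.
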