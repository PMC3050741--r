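---
title: "Identifiability-guided reduction of kinetic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifiability-guided reduction of kinetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetred)
```

## The problem

Signalling-pathway models are easy to over-specify: every known interaction
adds species and rate constants, while the measurable quantities remain a
handful of composite readouts sampled a few times with large errors. When
model complexity outstrips the information content of the data, maximum
likelihood estimation returns numbers, but the numbers are meaningless —
whole directions of parameter space leave the fit unchanged. The model is
then *not identifiable* for that data.

`kinetred` implements an iterative workflow for restoring the balance by
*structural* simplification (lumping or removing reactions), rather than by
fixing unidentifiable parameters at arbitrary values:

1. estimate the parameters by delocalized multi-start maximum likelihood;
2. rank the parameters by identifiability with an eigenvalue method on the
   Gauss-Newton Hessian;
3. decide identifiability by the variance of accepted multi-start
   estimates; if some coefficient of variation is too large,
4. simplify the part of the model carrying the least identifiable
   parameter, and repeat.

The simplification itself is deliberately human-in-the-loop: the ranking
points at the part of the model that is too detailed, a modeler rewrites it,
and the workflow consumes the resulting model sequence.

## Model class

Models are mass-action reaction networks
$$\dot x = f(x, p, u(t)), \qquad x(0) = x_0, \qquad y = C\,x,$$
with states $x \in \mathbb{R}^{n_x}$ (concentrations, nM), positive rate
constants $p \in \mathbb{R}^{n_p}$ (min$^{-1}$, or nM$^{-1}$min$^{-1}$ for
bimolecular steps), and a scalar input $u(t)$. Reactions are at most
bimolecular. The input enters by multiplying the rate of flagged reactions —
a stimulus such as a ligand is *not* a state variable; a rectangular pulse
$u(t) = 1$ for $t \le t_\mathrm{off}$, $0$ afterwards, models ligand washed
out of the medium.

Outputs are *linear combinations of states*, not states: in a laboratory,
phospho-forms are measured summed over binding partners (Western blots with
phospho-specific antibodies), dimers summed over phosphorylation states
(native gels), and so on. The distinction between $x$ and $y$ carries all of
the identifiability structure, which is why the package forces an explicit
output map.

Initial conditions are treated as known. Estimating them alongside the rates
would only require extending the parameter vector and giving the sensitivity
system nonzero initial columns; this is an extension point, not a current
feature.

## Synthetic data

`generateDataset()` simulates a reference model on a sampling grid and
attaches standard deviations $\sigma_{ij} = \max(\rho\, y_i(t_j),
\sigma_\mathrm{floor})$ with relative error $\rho$. Two modes exist:

* `noise_free` — observations are the exact simulated outputs and the
  $\sigma_{ij}$ act as weights only. This is the replication mode for
  in-silico identifiability studies: the generating parameters then have
  $\chi^2 = 0$ exactly, and any spread in re-estimated parameters is due to
  the model's degeneracy, not to noise.
* `gaussian` — independent $\mathcal N(0, \sigma_{ij}^2)$ noise is added,
  seeded and reproducible, for power and robustness studies.

The default JAK-STAT design (`defaultJakstatDesign()`) encodes the study
conditions of the worked example: a unit pulse washed out at $t = 7$ min,
four outputs recorded every minute from 0 to 15 min, and $\rho = 20\%$
(typical of quantitative Western blots). The $t = 0$ point is recorded but
excluded from fitting: before stimulation every observable is exactly zero,
so a relative error model gives $\sigma = 0$ there and the weight is
undefined. This leaves $n = 4 \times 15 = 60$ fitted data points — the
number under which the small-sample information criteria of the worked
example reproduce (see below).

What the generator does *not* emulate: blot-to-blot normalization error,
correlated noise within a gel, saturation of the detection chemistry, or
replicate structure. Tests that pass on these synthetic data therefore
demonstrate correctness of the algorithms under the stated error model, not
robustness to real Western-blot pathology.

## Estimation

The objective is the weighted least-squares functional
$$\chi^2(p) = \sum_{i=1}^{n_y} \sum_{j} \left(
  \frac{\tilde y_i(t_j) - y_i(t_j, p)}{\sigma_{ij}} \right)^2$$
over the fitted points; under independent Gaussian noise its minimizer is
the maximum-likelihood estimate. Because gradient-based optimizers are
attracted to local minima, estimation is *delocalized*: Latin Hypercube
sampling places `nStarts` starting points in a log-space box
$p^\mathrm{ref} \cdot 10^{\pm w}$ (default $w = 2$, i.e. four orders of
magnitude) with exactly one point per axis stratum, and an independent
bounded quasi-Newton fit (L-BFGS-B) runs from each. All fitting happens in
$\log_{10} p$: rate constants are positive and span orders of magnitude, so
log space both enforces positivity and makes the box geometry meaningful.

Gradients are analytic, from forward sensitivities: the system
$\dot S = (\partial f/\partial x) S + \partial f/\partial p$ is
co-integrated with the states (both right-hand sides are generated in C from
the reaction structure), and
$\partial \chi^2/\partial \log_{10} p_k = \ln(10)\, p_k \cdot
(-2) \sum_{ij} r_{ij} \sigma_{ij}^{-2} \, \partial y_i(t_j)/\partial p_k$.

Numerical choices that matter:

* **Integrator.** A variable-order, variable-step stiff code (`lsoda`) with
  defaults rtol $10^{-10}$, atol $10^{-12}$ nM. The pulse discontinuity is
  handled by integrating each constant-input segment separately and
  restarting at the washout time — multistep codes lose their order across
  discontinuities.
* **Failed evaluations.** In the far corners of a 12-decade sampling box the
  ODE system can be arbitrarily stiff or explosive. Inside a fit, a failed
  integration returns a large finite penalty, so the line search simply
  rejects the step; a failure at the returned point marks the fit
  unconverged. During fitting the step cap is lowered (5000 steps) so
  hopeless evaluations fail fast.
* **Convergence.** A fit counts as converged only if the optimizer
  terminated normally *and* the box-projected gradient satisfies
  $\lVert g \rVert_\infty \le 10^{-4}$ (log10 space). The floor on
  attainable gradients is set by integration accuracy, not machine
  precision; $10^{-4}$ sits two orders above that floor at the default
  tolerances while still pinning accepted estimates to a relative spread
  far below the identifiability bound used downstream.
* **Reproducibility.** One master seed; every stage (start sampling per
  model, variance analysis per model, noise generation) derives a
  documented substream, so reports are bit-reproducible for a fixed
  configuration.

## Identifiability ranking

At the estimate $\hat p$, the Gaussian-approximation (Gauss-Newton) Hessian
of the objective is
$$H = S^\top W S, \qquad
  S_{(ij),k} = \frac{\partial y_i(t_j)}{\partial p_k}, \qquad
  W = \operatorname{diag}(\sigma_{ij}^{-2}),$$
positive semidefinite by construction and equal to the curvature of
$\chi^2/2$ exactly at a zero-residual optimum. Its eigenvectors are the axes
of the local confidence ellipsoid; an eigenvalue near zero means an
ellipsoid axis of near-infinite length — a direction in parameter space the
data do not constrain.

The ranking loop: eigendecompose $H$ over the free parameters, take the
eigenvector of $\lambda_\min$, fix the parameter with the largest-magnitude
component (degenerate $\lambda_\min$: take the most concentrated of the
minimal eigenvectors; residual ties: lowest declaration index), recompute
$H$ over the remaining parameters, repeat until all are fixed. The fixing
order is the identifiability ranking, least identifiable first. Because the
Gauss-Newton Hessian over a free subset is a principal submatrix of the full
one, the default builder computes $H$ once and subsets it; the ranking
function accepts any builder callback, so exact re-computation schemes plug
in unchanged.

Two deliberate choices: the Hessian defaults to **log10 space** (the space
the estimation runs in, and the only one in which "orders of magnitude"
comparisons across rate constants of different units make sense; the linear
form remains available via `space = "linear"`), and **no eigenvalue cutoff**
is applied — the ranking only orders parameters, the verdict comes from the
variance analysis.

## Variance analysis

The verdict criterion is deliberately concrete: re-estimate from $N$ LHS
starts in a *wide* box $\hat p \cdot 10^{\pm 12}$, keep the converged fits
whose $\chi^2$ is acceptably small — lower-tail probability
$P(\chi^2 \mid \nu) \le 0.1\%$ with $\nu = (\text{fitted points}) - n_p$ —
and compute, per parameter, the mean $\bar p_i$, the sample variance, and
the scale-invariant coefficient of variation $v(p_i) = \sigma(p_i)/\bar
p_i$ of the accepted estimates (on the linear scale; the estimator formulas
are in $p$, not $\log p$). The model is **identifiable** iff every
$v(p_i) \le \bar v$ (default 0.01: all acceptable estimates agree to 1%)
and no parameter is *bound-limited*.

Bound-limitation is the subtle part. If the accepted estimates run into the
sampling box, the box — not the data — limited their spread, and $v$ is only
a *lower* bound on the true coefficient of variation: enough to conclude
non-identifiability, never identifiability. The package flags a parameter as
bound-limited when its accepted estimates approach within 5% of the log-box
width of either edge (configurable via `coverageFraction`). A
range-coverage rule ("estimates span ≥ 95% of the box") was considered and
rejected: for additive compensations — e.g. a duplicated rate where only
$k_a + k_b$ is constrained — estimates can only ever reach the *lower* half
of the box ($k_a \le k_a + k_b$), so full-range coverage never occurs even
though the box is plainly truncating the spread. Edge contact detects both
additive and multiplicative compensation structures.

The workflow examines the coefficients in ranking order (least identifiable
first); the first violation names the simplification target and short-cuts
the decision, exactly mirroring the iteration's step "if $v(p_i) > \bar v$,
go to simplify".

## Model comparison

Between candidate models, goodness of fit is balanced against complexity
with Akaike's criterion specialized to $\chi^2$ estimation, where
$\ln L = C - \chi^2/2$ with a model-independent constant:
$$\mathrm{AIC} = \chi^2 + 2 n_p, \qquad
  \mathrm{AICc} = \mathrm{AIC} + \frac{2 n_p (n_p + 1)}{n - n_p - 1},$$
the latter the Hurvich–Tsai small-sample correction — essential here, since
$n_p$ (10–23) is not small against $n = 60$. AICc differences
$\Delta_k = \mathrm{AICc}_k - \min_j \mathrm{AICc}_j$ and Akaike weights
$w_k = e^{-\Delta_k/2} / \sum_j e^{-\Delta_j/2}$ are computed on *unrounded*
AICc values; tables round for display only. The weights sum to one by
construction and are read as the probability that model $k$ is the best of
the candidate set.

## The JAK-STAT worked example

The fixture family `jakstatFamily("M0")` … `jakstatFamily("M6")` is a
reconstruction of a seven-stage reduction of a truncated early
interferon-γ JAK-STAT model (the first 15 minutes of signalling, before
transcriptional feedback, after the pathway model of Yamada et al. 2003,
*Genes to Cells*): receptor–kinase assembly, IFN binding (input-modulated),
receptor dimerization and activation, STAT1c recruitment and
phosphorylation, SHP2-mediated receptor deactivation, STAT1 dimerization,
and phosphatase (PPX) dephosphorylation routes. The reduction stages remove
the re-association of phosphorylated STAT1c (M1), the pre-catalysis
dissociations of high-affinity complexes (M2), the free receptor and kinase
(pre-associated, M3), the entire PPX module in favour of a first-order dimer
decay (M4), the STAT1c–receptor complex in favour of a catalytic
second-order phosphorylation (M5), and the remaining cytoplasmic
dephosphorylation route (M6). The state/parameter counts run
17/25, 16/23, 16/19, 14/17, 10/12, 9/11, 9/10.

Reconstruction caveats, flagged here because the package's contract is the
*topology*, not a published calibration:

* The published presentation specifies the wiring of the PPX/heterodimer
  subnetwork and the SHP2 catalysis step only partially; the fixture commits
  to the variant that is consistent with every stated parameter name,
  rename (kf5→k5, kf9→k9, kf11→k11, kf24→k24) and count simultaneously.
  In particular the parameter introduced at M4 (`k11new`, first-order
  STAT1cPhos$_2$ → 2 STAT1c) is the dephosphorylation route removed at M6.
* Rate-constant *values* shipped with the fixtures are synthetic
  order-of-magnitude placeholders meant to be overridden
  (`jakstatFamily(v, params = ...)`); initial concentrations use the
  published values where stated (R = JAK = 12 nM, PPX = 50 nM, R_JAK = 12
  nM once pre-associated) and the reference model's literature values
  otherwise (STAT1c = 1000 nM, SHP2 = 100 nM).
* Whether a phospho-STAT1 homodimer counts once or twice in the
  phospho-STAT1 readout is a measurement-model decision; the default
  (`multiplicityWeighted = TRUE`) counts molecules, so a dimer contributes
  2 to y1 and a doubly phosphorylated receptor dimer contributes 2 to the
  activated-JAK readout y2. The unweighted complex-counting variant is one
  flag away.

Every fixture conserves its STAT1 moiety (no synthesis or degradation within
15 minutes); `jakstatStat1Moiety()` exposes the copy-number weights, and the
test suite verifies conservation to $10^{-6}$ relative along simulated
trajectories of all seven variants.

## Problem sizes and test design

The workflow defaults mirror the study conditions (1000 starts for both the
estimation and the variance analysis). The test suite and the acceptance
script exercise the identical code paths at reduced counts chosen as the
package's own regression sizes — 100 starts for recovery, 150 for variance
analyses, toy networks with 2–4 parameters — large enough that the verdicts
are stable across seeds for these well-conditioned problems, small enough to
run in minutes. The oracles are independent of the implementation path:
closed-form exponentials, hand-computed residual sums, finite-difference
gradients/Hessians at tightened integrator tolerances, and the $1 -
e^{-x/2}$ form of the two-degrees-of-freedom $\chi^2$ tail.

One oracle deserves a note: finite-difference *sensitivities* with a
$10^{-6}$ relative step are noise-limited when a parameter's value is small
and the outputs are large — the difference quotient divides an
integration-error-sized numerator by a tiny step. The suite therefore
validates well-scaled problems with the $10^{-6}$ linear-space step, and the
JAK-STAT fixtures with a $10^{-3}$-decade log-space step and a global
sensitivity-scale floor in the denominator.

## Limitations

* Mass action only, at most bimolecular; no compartments, rules or events
  beyond the single pulse input. SBML is export-only.
* Local (at-a-point) identifiability only: verdicts are relative to the
  estimate, the design and the error model. No structural methods, no
  profile likelihoods, no bootstrap.
* The Gauss-Newton curvature neglects second-order residual terms; with
  noisy (non-noise-free) data at a poor fit the eigen-structure can mislead
  the ranking. The variance analysis, not the ranking, carries the verdict
  for exactly this reason.
* Parallel execution across starts is not built in; fits are sequential
  (deterministic by construction). The structure — independent fits indexed
  by start — makes user-side parallelization straightforward.
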