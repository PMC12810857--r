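---
title: "Replicator dynamics of healthcare safety supervision: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator dynamics of healthcare safety supervision: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trigame)
```

## The model

trigame implements an evolutionary game among three bounded-rational
populations involved in healthcare safety-risk supervision:

* the **public/patients**, a share $\delta$ of whom participate in oversight
  (reporting violations, using complaint platforms);
* **medical institutions**, a share $\eta$ of which provide compliant care;
* **government regulators**, a share $\zeta$ of which supervise strictly.

Each population has two pure strategies and adjusts its mix by replicator
dynamics: a strategy's share grows in proportion to its payoff advantage
over the population average. Writing $G_p$, $G_m$, $G_g$ for the pairwise
payoff differences (participate $-$ abstain, comply $-$ defect, strict $-$
lax), the system is

$$
\dot\delta = \delta(1-\delta)\,G_p,\qquad
\dot\eta  = \eta(1-\eta)\,G_m,\qquad
\dot\zeta = \zeta(1-\zeta)\,G_g,
$$

with

$$
\begin{aligned}
G_p &= I_{p1}-I_{p2}+(1-\eta)(1-\zeta)\mu B_p\\
G_m &= -C_{m1}-I_{m2}+C_{m2}+(1-\zeta)C_c+\delta\mu B_m+\zeta\theta V_{m2}\\
G_g &= W+(1-\eta)\bigl(\theta V_{m2}+\delta\mu B_g-I_{g2}\bigr).
\end{aligned}
$$

The 17 parameters are normalized payoff units (each parameter's unit is
scaled to 1; no currency calibration is attempted). The two probability-like
parameters are the exposure rate $\mu$ (chance that public participation
reveals a violation) and the penalty intensity $\theta$, which scales the
medical risk of non-compliance $V_{m2}$ into the fine $\theta V_{m2}$
imposed under strict supervision. Validation enforces $\mu,\theta\in[0,1]$,
nonnegativity, and $C_{m2}<C_{m1}$ (cutting corners must be cheaper than
compliance, otherwise the dilemma being modelled does not arise).

A deliberate reconciliation: the stage-game payoff table as usually printed
deducts the fine $\theta V_{m2}$ from non-compliant institutions even under
*lax* regulation, while the expected-utility equations apply the fine only
under strict supervision and charge the regulatory-capture cost $C_c$ under
lax supervision. The expected-utility equations are self-consistent (their
pairwise differences are exactly the $G$ brackets above) and drive all
dynamics in this package; `payoff_cell(..., reconciled = FALSE)` exposes the
verbatim table cells so the discrepancy stays inspectable rather than
hidden. An analogous printed-form inconsistency in the population-mean
utility of the public is resolved the same way: the mean is always computed
from the weighting identity $\bar H_p=\delta H_{p1}+(1-\delta)H_{p2}$.

## Corner equilibria and stability

Every vertex of $[0,1]^3$ is a fixed point. The Jacobian is derived
analytically from the replicator equations; each off-diagonal entry carries
a factor $x(1-x)$, so corner Jacobians are diagonal and the diagonal
entries — the brackets evaluated at the corner, with a sign flip where the
corresponding component is 1 — are the eigenvalues. Classification follows
Lyapunov's first method: all eigenvalues strictly negative gives an
evolutionarily stable strategy (ESS), any strictly positive eigenvalue
gives instability, and an eigenvalue within `tol` (default $10^{-9}$) of
zero is reported *indeterminate*, because the linearization is inconclusive
on a center manifold. The published eigenvalue table contains two garbled
entries (the compliance eigenvalue at the corners $(0,1,1)$ and $(1,1,1)$);
this package derives all entries from the dynamics and verifies them
against a central-difference oracle in the test suite, which is the
arbiter wherever printed formulas disagree.

```{r}
stability_analysis(baseline_parameters())
```

Two closed-form conditions are commonly quoted for when a single corner is
the ESS:

* **condition 1**: $C_{m2}-C_{m1}-I_{m2}+\theta V_{m2}+\mu B_m<0$ and
  $I_{p2}-I_{p1}<0$, associated with $E_6(1,0,1)$ — everyone participates
  and supervises but institutions defect;
* **condition 2**: $C_{m1}-C_{m2}+I_{m2}-C_c-\mu B_m<0$ and
  $I_{p2}-I_{p1}<0$, associated with $E_8(1,1,1)$ — full participation,
  compliance and strict supervision.

`proposition_check()` evaluates these inequalities exactly as printed.
Two caveats, both verified by tests:

1. Each condition constrains only two eigenvalues; the third
   ($I_{g2}-W-\theta V_{m2}-\mu B_g$ at $E_6$, $-W$ at $E_8$) is reported
   as an auxiliary margin rather than assumed negative.
2. The printed condition-2 margin keeps the capture cost $C_c$, whereas
   the exact compliance eigenvalue at $E_8$ is
   $-(C_{m2}-C_{m1}-I_{m2}+\theta V_{m2}+\mu B_m)$, carrying the fine
   $\theta V_{m2}$ instead. The two expressions differ by
   $C_c-\theta V_{m2}$. Consequently condition 2 is sufficient for $E_8$
   stability only when $\theta V_{m2}\ge C_c$; when $C_c>\theta V_{m2}$
   there is a parameter window (at the reference set: $\mu$ between
   $2/7$ and $23/70$) where condition 2 holds *and yet* every trajectory
   converges to $E_6$, because the compliance eigenvalue at $E_8$ is
   positive. Since the $E_6$ and $E_8$ compliance eigenvalues are exact
   negatives of each other, the two corners are never simultaneously
   stable under these dynamics. Classification therefore always uses the
   exact eigenvalues; the printed inequalities are reported as what they
   are — the quoted conditions — and `threshold_scan(criterion =
   "e8_stability")` locates their boundary (closed form
   $(C_{m1}-C_{m2}+I_{m2}-C_c)/B_m$), while `criterion =
   "attractor_flip"` finds the dynamic boundary.

## Numerical integration

Trajectories are computed with an adaptive Runge–Kutta 4(5) pair
(Dormand–Prince, via deSolve) at `rel_tol = 1e-8`, `abs_tol = 1e-10` —
tight enough that the 1e-3 corner-convergence tolerance used throughout is
solver-independent (halving the tolerances moves the baseline final state
by far less than 1e-6, tested). The analytic flow preserves the cube, so
states are clipped to $[0,1]$ only to remove floating-point overshoot.
The default horizon is 200 time units with 401 stored samples; the phrase
"evolve 200 times" in the source analysis is ambiguous between discrete
iterations and time units, and this package reads it as continuous time
$t\in[0,200]$. Reported "normalized time" is $t/\text{horizon}$; the
default initial state, where none is given, is $(0.5, 0.5, 0.5)$ (the
source figures never state theirs). Threshold-crossing times interpolate
linearly between stored samples.

Basin sampling draws initial states uniformly from $(0.01, 0.99)^3$: the
margin exists because the faces of the cube are invariant (a population
with share exactly 0 or 1 never moves), so corner starts would trivially
tally as their own attractor.

```{r}
basin_sample(baseline_parameters(), n = 10, seed = 1)
```

## Experiments

`sweep_game()` integrates once per grid point and extracts `final_delta`,
`final_eta`, `final_zeta`, the detected `attractor_label`, or
`time_to_eta_0.9`. The last two make the headline comparative statics
reproducible: sweeping $\mu$ over $\{0.2, 0.8\}$ flips the attractor from
$E_6$ to $E_8$, and increasing $\theta$ shortens the time to 90%
compliance without changing the attractor. "System stability" as a surface
height in the source's 3-D figures is not numerically defined there;
`final_eta` and `time_to_eta_0.9` are the two surfaces this package
exposes instead.

The published feature-importance analysis used a gradient-boosting
surrogate with SHAP attributions whose training data and targets are
unstated; it is out of scope here. `sensitivity_indices()` replaces it
with transparent first-order variance-based indices (correlation-ratio
estimator: output variance explained by per-bin means across
equal-probability bins of one input) plus one-at-a-time elasticities of
final $\eta$ around the base point. Defaults: $V_{m2}\in[10,30]$,
$\theta\in[0.2,0.8]$, $\mu\in[0.1,0.9]$, $n=512$ draws. Under these
ranges $\mu$ dominates — it is the only one of the three parameters whose
range crosses the attractor boundary — which reproduces the qualitative
ranking claim ("an importance ordering exists") without reproducing SHAP
magnitudes. Elasticities are local: at the reference set final $\eta$
saturates at 1, so they are 0 there by construction. Fixed seeds make the
whole report bit-identical across runs.

`sample_parameters()` generates valid random parameter sets for property
tests: payoffs uniform on $[1,100]$ (bracketing the reference values),
$\mu,\theta$ on $[0.05,0.95]$, the $C_{m2}<C_{m1}$ constraint enforced by
swapping the pair, and optional rejection on condition 1 or 2.

## Case studies

Three supervision scenarios ship as fixtures (`inst/extdata/cases.toml`):
tuberculosis treatment adherence in Saudi Arabia, COVID-19 vaccination
compliance in Guangdong (China), and antibiotic prescription supervision
in rural Vietnam. Each records observed means $(\delta,\eta,\zeta)$ and
the three scenario parameters $(\mu, V_{m2}, \theta)$. The sources report
*only* those values; the remaining 14 payoff parameters fall back to the
reference set when a case is simulated, and case-level conclusions
inherit that fill-in — a documented limitation, not a calibration.
Observed means are used as initial conditions, never as fitting targets.

```{r}
cmp <- compare_cases(horizon = 100)
cmp
```

The cross-case Pearson correlation of observed $\delta$ vs observed
$\eta$ computed from the three recorded pairs is
`r round(cmp$delta_eta_correlation, 3)` (0.414); a published
value of 0.78 for this comparison cannot be reproduced from the three
printed pairs and presumably rests on unpublished underlying data, so the
package reports the computed value flagged as descriptive ($n=3$).

## What the defaults represent, and what passing tests do not show

The reference parameter set (`baseline_parameters()`) *is* the study
condition for all headline claims: one exposure-rate prose value (0.8)
conflicts with a symbol-list value (0.08) in the source analysis, and 0.8
is adopted because 0.08 contradicts that analysis's own convergence
result (condition 2 fails at 0.08). The generator and fixtures emulate a
world where payoffs are constant in time, populations are well-mixed and
infinitely large, and strategy revision follows deterministic replicator
dynamics. Passing tests therefore certify the mathematics and numerics of
that idealization — not that real supervision systems converge to full
compliance: finite populations, stochastic shocks, time-varying policies
and hierarchical regulators are all outside this model, and the observed
case means enter only as initial conditions.

Problem sizes used by the test suite and the reproduction script — 100
random starts for the convergence check, 500 random parameter sets for
the corner-eigenvalue identity, 200 interior states for the
finite-difference oracle, 50 sets for the attractor/ESS agreement, 512
Monte-Carlo draws for sensitivity — are the package's chosen defaults;
they keep every individual check under a minute on one core while making
the Monte-Carlo estimates stable to well inside the asserted tolerances.

## Known limitations

* Interior (mixed) equilibria are not enumerated; the stability analysis
  is restricted to the eight corners, as in the source analysis.
* The printed behavioral thresholds "$\theta>0.5$" and "$\mu>0.7$" are
  not asymptotic properties of the dynamics under either printed $\mu$
  value; they likely reflect finite-horizon transients from unstated
  initial conditions. The package reports scan outputs instead of
  asserting them.
* The flat-TOML reader supports the subset of TOML used by the package's
  own config and fixture files (sections, scalar and numeric-array
  values, comments); it is not a general TOML parser.
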