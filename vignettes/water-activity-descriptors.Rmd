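---
title: "Predicting water activity from molecular descriptors: models and methods"
author: "watact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting water activity from molecular descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watact)
```

# The model

For a binary aqueous solution of a nonelectrolyte the Norrish model
expresses water activity as

$$a_w = x_w \, e^{k_N x_s^2}, \qquad x_w = 1 - x_s,$$

with a single solute-specific parameter $k_N$. The model assumes a
single solute, no dissociation, and isothermal conditions; temperature
dependence of $k_N$ is not modeled. $k_N = 0$ is the Raoult (ideal)
limit, and for every sugar and polyol in the package's reference set
$k_N < 0$: the solute lowers water activity below the ideal line, and
$a_w$ is then strictly decreasing in $x_s$ on $[0, 1)$.

Given data $(x_{s,i}, a_{w,i})$, $k_N$ is estimated by minimizing the
sum of squared activity residuals

$$\Phi(k_N) = \sum_i \left(a_{w,i}^{exp} - a_{w,i}^{calc}\right)^2,$$

and fit quality is summarized by the mean absolute error
$\varepsilon = \frac1n \sum_i |a_{w,i}^{exp} - a_{w,i}^{calc}|$.
`fitNorrish()` minimizes $\Phi$ itself, in $a_w$ space, by bounded
derivative-free scalar minimization; the linearization
$\ln(a_w/x_w) = k_N x_s^2$ is *not* used for estimation (it reweights
the errors) — it only motivates the default search bracket.

# The descriptors

The structure-based route replaces the data fit with a prediction from
two theoretical descriptors computed on the solute molecule:

* the **information index on atomic composition**
  $I_{AC} = A_{tot}\log_2 A_{tot} - \sum_j A_j \log_2 A_j$, a
  Shannon-type constitutional index over atom-type counts *including
  hydrogen* (glucose, C6H12O6: $24\log_2 24 - 2(6\log_2 6) -
  12\log_2 12 = 36$ exactly); it is zero iff the molecule has a single
  atom type, and bounded above by $A_{tot}\log_2 A_{tot}$;
* the **first Zagreb index** $Z_1 = \sum_i \delta_i^2$, the sum of
  squared vertex degrees of the hydrogen-depleted molecular graph, a
  branching measure that — unlike $I_{AC}$ — separates constitutional
  isomers (glucopyranose 58 vs fructofuranose 60);
* their sum, the **global information index** $G = I_{AC} + Z_1$.

Both components are invariant under vertex relabeling, so no canonical
atom ordering is needed; the test suite asserts this by permuting
vertices, and checks $Z_1$ against a brute-force adjacency-matrix
oracle on random graphs.

## Structure input and its deliberate limits

`parseSmiles()` supports exactly what the chemistry here needs:
uppercase atoms with registered valences (C and O in practice; the
valence registry is extensible at run time), branches, single bonds and
single-digit ring closures. Implicit hydrogens are assigned as standard
valence minus heavy-atom degree. Stereo markers are stripped with a
warning rather than rejected, a deliberate choice: both descriptors are
stereochemistry-blind, and the glucose/fructose distinction the indices
must express comes from ring connectivity (pyranose vs furanose), not
configuration. Aromaticity, charges, isotopes and multiple bonds are
outside the supported subset and are rejected with positional error
messages. The parser is cross-checked in the tests against an
independent SMILES implementation (ChemmineR/Open Babel) on the whole
built-in library.

The built-in solutes use the cyclic hemiacetal forms for the sugars and
open chains for the polyols. This is a reverse-engineering decision:
only the ring forms reproduce the reference Zagreb values (58, 60, 48,
120), and the reference source does not state which anomer/ring form
was fed to its descriptor software. Since $Z_1$ is insensitive to
anomeric configuration, the choice of anomer is immaterial; the ring
size is what matters.

# The QSPR model forms

Five forms link $k_N$ to the descriptors:

| form | expression | p |
|---|---|---|
| `linear2` | $k_N = a_{11} + a_{12} I_{AC} + a_{13} Z_1$ | 3 |
| `power2`  | $k_N = a_{21} I_{AC}^{a_{22}} Z_1^{a_{23}}$ | 3 |
| `linearG` | $k_N = b_{11} + b_{12} G$ | 2 |
| `powerG`  | $k_N = b_{21} G^{b_{22}}$ | 2 |
| `polyG`   | $k_N = b_{31} G + b_{32} G^2$ | 2 |

All are fitted by least squares in original $k_N$ space (never in log
space), minimizing $\Theta = \sum (k_N^{exp} - k_N^{calc})^2$; models
are compared through $\varphi = \Theta/(n-p)$, which penalizes
parameter count. `polyG` has no intercept by construction, so its
predictions pass through $(G, k_N) = (0, 0)$ — a model property, not a
defect: a "solute" with no composition diversity and no bonds should
not perturb water.

Power forms need care with signs: every observed $k_N$ is negative
while the descriptor bases are positive, so the leading coefficient is
left unconstrained and initialized as
$\mathrm{sign}(\overline{k_N}) \cdot e^{\hat\alpha}$ from a log–log
regression of $|k_N|$ on the descriptors, the exponents from the same
regression. The nonlinear refinement is Levenberg–Marquardt with an
analytic Jacobian and tight tolerances (`ftol = ptol = 1e-10`, max 500
iterations); with the fixed initialization rule the fit is fully
deterministic.

## The erythritol inconsistency and the reproduction convention

The package ships the published per-solute reference values (Norrish
constants, molecular properties, descriptor values, and the regression
table for the five forms). While validating `fitQspr()` we found that
**the published regression table cannot be obtained by fitting the
eight published $(k_N, \text{descriptor})$ pairs**: ordinary least
squares on all eight gives, e.g., quadratic-model coefficients
$(-2.02\times10^{-2}, -8.5\times10^{-5})$ with $\Theta = 0.53$ versus
the published $(-2.18\times10^{-2}, -7.52\times10^{-5})$ with
$\Theta = 0.31$ — and the published parameters themselves yield
$\Theta = 0.56$ on those data, worse than the true optimum, which is
impossible for a least-squares solution.

Refitting with **erythritol excluded** reproduces *every* row of the
published table — all five forms, linear and nonlinear, parameters and
$\Theta$ — to the full printed precision, while the published $\varphi$
values equal $\Theta/(8-p)$, i.e. retain the full solute count.
Erythritol's tabulated $k_N = -0.950$ is also the one value that breaks
the otherwise monotone relation between $k_N$ and hydroxyl count
(glycerol, 3 OH, $-0.908$; erythritol, 4 OH, $-0.950$; xylitol, 5 OH,
$-2.221$). We conclude the published regressions were estimated on the
seven other solutes, and adopt that as the reproduction convention:
`fitReferenceModels()` excludes erythritol by default (pass
`exclude = character()` to fit all eight), and
`referenceModelReport()` evaluates $\varphi$ with `varianceN = 8` to
match the published statistic. `fitQspr()` itself always uses the size
of the data it is given. Model *selection* is robust to the
convention: the quadratic G model attains the minimum $\varphi$ under
either denominator and either estimation set, as the test suite
asserts.

# The synthetic data generator

The raw activity measurements behind the reference constants are not
redistributable, so validation uses `generateActivityDataset()`:
`nPoints` mole fractions spaced evenly (optionally log-evenly) over a
stated range, exact Norrish activities for a stated $k_N$, plus
additive homoscedastic Gaussian noise on $a_w$, clipped to $(0, 1]$.
Defaults are the study conditions: per-solute $x_s$ ranges as
published, `noiseSigma = 1e-3` (the magnitude of the published mean
absolute errors, $2.7\times10^{-4}$–$1.35\times10^{-3}$), and
`nPoints = 10` as a typical experimental series length (the true counts
are not published). The generator is seeded locally and leaves the
caller's RNG stream untouched.

What it does *not* emulate: real designs are neither evenly spaced nor
homoscedastic (isopiestic and hygrometer errors grow with
concentration), there may be systematic instrument bias, and replicate
structure is absent. Passing the recovery tests therefore shows the
estimator is correct and well-conditioned under the assumed error
model, not that real-data uncertainties are this small.

Validation problem sizes (chosen to characterize the estimator well
while keeping the suite quick): zero-noise recovery on all eight
solute profiles to $10^{-6}$; 200 noisy replicates per profile at
$\sigma = 10^{-3}$, asserting a pooled median absolute recovery error
below 0.1, per-profile bias below 0.05, and that the fitted
$\varepsilon$ values bracket the published range. The pooled (rather
than per-profile) median is deliberate: for the narrowest design
(erythritol, $x_s \in [0.007, 0.069]$) the delta-method standard error
of $\hat k_N$ at this $\sigma$ is itself close to 0.1, so a per-profile
bound there would test the seed, not the method.

# Numerical choices

* **Norrish minimizer**: `stats::optimize()`
  (golden-section/parabolic), default bracket $[-50, 10]$ — covering
  the observed range $[-6.8, -0.9]$ with wide margin — absolute
  $x$-tolerance $10^{-10}$ (effective accuracy is then machine-limited,
  comfortably below the $10^{-6}$ the tests demand). A minimizer within
  $6\times10^{-5}$ of a bracket end is flagged `atBoundary` with a
  warning; the bracket is user-configurable. The tests check the
  minimizer against a two-stage dense grid search to $10^{-4}$.
* **Linear fits**: `stats::lm()` on the exact design matrices; checked
  against an lm-free grid-refinement oracle to 4 significant figures.
* **Degenerate inputs**: empty molecules, single-point activity
  datasets, $a_w > 1$, $x_s \notin (0,1)$, $n \le p$ fits and
  non-positive power-form bases are all rejected with specific errors
  rather than clipped or coerced; a single-atom-type molecule has
  $I_{AC} = 0$ by the limit of the formula.
* **Model selection ties**: minimal $\varphi$, then smaller $p$, then
  canonical form order — fully deterministic.
* **Presentation rounding**: descriptors are computed and stored at
  full double precision; the two-decimal rounding seen in reports and
  CSV output is applied only at the presentation layer. JSON
  serialization keeps full precision.

# Limitations

* Single-solute binary systems only; no multi-solute mixing rule, no
  electrolytes, no temperature dependence.
* The QSPR fits rest on eight (effectively seven) solutes from one
  chemical family; extrapolation beyond hydroxylated C/O compounds
  (or far outside $G \in [40, 190]$) is unsupported.
* The SMILES subset is intentionally minimal; aromatic systems and
  charged species are out of scope.
* No parameter uncertainty is reported for the QSPR fits (none is
  published for the reference values either); $\varphi$ is the only
  comparison statistic.
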