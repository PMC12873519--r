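---
title: "Methods: leaf length, twig vessel diameter, and hydraulic allometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf length, twig vessel diameter, and hydraulic allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafxylem)
```

## The scientific problem

As a plant grows taller, the water-conducting pathway from root to leaf
lengthens, and Poiseuille resistance accumulates along it. Xylem conduits
counter this by widening tip-to-base: lumen diameter $D$ increases with
distance from the organ tip $L$ approximately as a power law,

$$D \propto L^{b},$$

with $b \approx 0.2$ typical of stems and $b \approx 0.4$ of leaves. Because
the Poiseuille resistance of a cylinder of length $\ell$ and diameter $d$ is
$128\,\mu\,\ell/(\pi d^4)$, even modest widening strongly buffers the
resistance cost of added pathlength. This package provides four coordinated
tool sets for studying the hypothesis that *leaf length* contributes to this
buffering by setting vessel diameters at the petiole base and, downstream,
in the twig:

1. **hydraulics** — a stacked-conduit Poiseuille model with power-law
   widening, plus the resistance-balancing model of terminal-conduit
   diameter versus plant height;
2. **allometry** — log10–log10 OLS scaling regressions among leaf length,
   vessel diameters, wood density and height, with a Welch test for slope
   differences and interaction models for leaf type and site;
3. **phylocomp** — phylogenetic signal statistics and GLS regression under
   white-noise (WN), Brownian-motion (BM) and Ornstein–Uhlenbeck (OU)
   residual covariances, ranked by AICc;
4. **synthdata** — a seeded generator of trait tables and pure-birth
   ultrametric trees with the statistical structure the analysis assumes,
   so every stage is testable without access to any particular field
   data set.

## The hydraulic model

A conduit column is discretized into cylindrical elements of length
`element_length` (default 1 mm) starting at `x_min` (default 1 mm) from the
tip; the diameter of each element is evaluated at its midpoint from
$D(x) = d_{\mathrm{ref}} (x/x_{\mathrm{ref}})^{b}$, and element resistances
$128 \mu \ell / (\pi D^4)$ are summed. The midpoint rule matters: for
$4b > 1$ the continuum integrand diverges at $x = 0$, and midpoint
evaluation keeps the first element finite without special-casing. The
discrete sum converges to the analytic integral

$$R(L) \;=\; \frac{128\,\mu\, x_{\mathrm{ref}}^{4b}}{\pi\, d_{\mathrm{ref}}^{4}}
\cdot \frac{L^{1-4b} - x_{\mathrm{min}}^{1-4b}}{1-4b}$$

to better than 1% once the element length is at most $L/1000$ (asserted in
the test suite). Viscosity and the overall prefactor default to 1, so
resistances are in arbitrary units; all the scientifically meaningful
outputs of this module are *ratios*, which the units cancel out of. The
model treats a single tip-to-base conduit column; the number of conduits
running in parallel rescales conductance multiplicatively and is deliberately
out of scope.

```{r}
stem <- conduit_profile(d_ref = 10, b = 0.2)
leaf <- conduit_profile(d_ref = 10, b = 0.4)
r <- function(cp, L) cumulative_resistance(cp, L)$cumulative_resistance
# growth of cumulative resistance from 100 mm to 1000 mm of path
c(stem = r(stem, 1000)[999] / r(stem, 1000)[99],
  leaf = r(leaf, 1000)[999] / r(leaf, 1000)[99])
```

Stem-like widening ($b = 0.2$) roughly doubles cumulative resistance over
that span, while leaf-like widening ($b = 0.4$) leaves it nearly flat —
resistance in leaves is nearly independent of leaf length. We reproduce this
contrast, and the convergence to the integral, as properties; the absolute
"arbitrary resistance units" of any particular published illustration depend
on an unstated normalization and are not reproduced.

### The resistance-balancing tip-diameter model

Conductance scales as $d^4$, so `conductance_ratio(10, 20)` = 16: a plant
with 20 µm terminal conduits moves sixteen times the water of one with
10 µm conduits, all else equal. If the cumulative resistance left unbuffered
by within-plant widening grows with height as $H^{c}$, and the entire
widening profile scales multiplicatively with the terminal diameter $d$, the
resistance of an individual of height $H$ is $R \propto H^{c}/d^{4}$.
Requiring $R(H, d) = R(h_{\mathrm{ref}}, d_{\mathrm{ref}})$ gives

$$d \;=\; d_{\mathrm{ref}}\,(H/h_{\mathrm{ref}})^{c/4},$$

a power law for terminal twig diameter versus height with exponent $g=c/4$.
`balance_tip_diameter()` solves the balance equation numerically
(deterministic bisection on $\log_{10} d$ over
$[d_{\mathrm{ref}}/100,\,100\,d_{\mathrm{ref}}]$, relative tolerance
$10^{-9}$) and agrees with the closed form; the literal single-column
integral with $b = 0.2$ leaves very little unbuffered resistance
($c \approx 0.05 \times 4$), so $c$ is exposed as an explicit parameter
rather than derived from $b$. With $c = 1.04$ (that is, $g = 0.26$, in the
range of empirical tip-diameter–height slopes reported across angiosperms), a
1 m plant with 10 µm terminal conduits is balanced by 18.2 µm at 10 m and
21.8 µm at 20 m:

```{r}
c(h10 = balance_tip_diameter(1.04, 10), h20 = balance_tip_diameter(1.04, 20))
implied_widening_exponent(c(1, 10), c(10, balance_tip_diameter(1.04, 10)))
```

## The allometric regression suite

All continuous traits are log10-transformed: trait variation spans orders of
magnitude, effects are multiplicative, and the fourth-power
diameter–conductance relation makes proportional (not absolute) changes the
functionally relevant ones. Scaling exponents are estimated by OLS rather
than standardized major axis because the scientific question is how well the
predictor *predicts* the response, which is the OLS loss. `fit_loglog()`
reports the slope and intercept with t-based 95% confidence intervals,
adjusted $R^2$, and the overall F test; records missing either trait are
dropped pairwise with a logged count, and non-positive trait values are a
validation error naming the offending species. No multiple-testing
correction is applied across the standard nine-regression panel; each fit
answers its own question.

`compare_slopes()` tests a difference between two scaling exponents using
the Welch two-sample construction on the slope standard errors,

$$t = \frac{b_1 - b_2}{\sqrt{SE_1^2 + SE_2^2}},\qquad
\nu = \frac{(SE_1^2 + SE_2^2)^2}{SE_1^4/\nu_1 + SE_2^4/\nu_2},$$

with a two-sided p-value from the t distribution on the fractional df
$\nu$. The construction is validated in the tests by inverting
published-style confidence intervals into slope SEs and recovering the
expected fractional df. Note the construction assumes the two fits are
computed from independent samples; applied to two regressions sharing the
same species (as in the pipeline's petiole-vs-twig comparison) it is
conservative, since the two slope estimates are positively correlated.

`fit_with_group()` fits `log10(y) ~ log10(x) * group` and reports partial-F
p-values for the interaction (do the groups share a slope?) and the group
main effect (do they share an intercept?), generalizing cleanly to factors
with more than two levels such as collection sites.

## Phylogenetic comparative analysis

Cross-species regressions assume exchangeable residuals, but closely related
species may resemble each other. The package addresses this in two ways.

**Signal tests.** `phylo_signal()` computes Pagel's $\lambda$ (ML over
$[0,1]$ for the intercept-only model under the
$\lambda$-transformed BM covariance) and Blomberg's $K$. For the $\lambda$
likelihood-ratio test against $\lambda = 0$, the null hypothesis lies on the
boundary of the parameter space, where the usual $\chi^2_1$ reference is
conservative — and at moderate $n$ even the asymptotic 50:50
$\{0\}/\chi^2_1$ boundary mixture remains noticeably conservative. The
default p-value therefore comes from a parametric bootstrap: under
$\lambda = 0$ the LR statistic is pivotal (invariant to the trait's location
and scale), so its null distribution is obtained exactly by simulating
`n_null` iid standard-normal trait vectors on the same tree. This makes the
test calibrated at its nominal level at any sample size, at the cost of
`n_null` extra one-dimensional ML optimizations (cheap: for ultrametric
trees the $\lambda$-profile likelihood is evaluated after a single
eigendecomposition of the BM covariance, because
$C(\lambda) = \lambda C + (1-\lambda) T I$ shares $C$'s eigenvectors).
$K$'s p-value is a tip-label permutation test, seeded and deterministic.

**PGLS.** `gls_fit()` implements
$\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$ with the residual variance
profiled by ML, and reports the Gaussian log-likelihood, AIC and AICc
($k$ = number of coefficients + 1 for the variance; the OU rate and
$\lambda$ are fixed, not estimated, and so not counted). The candidate
covariances are WN (identity — GLS then reproduces OLS coefficients
*exactly*, which is the bridge that makes the OLS and PGLS slope tables
coincide when WN wins), BM ($C_{ij}$ = depth of the most recent common
ancestor), and OU with correlation $e^{-\alpha d_{ij}}$ on the patristic
distance $d_{ij}$, $\alpha = 1$ fixed — the `corMartins` convention, against
which the implementation is cross-checked (both coefficients and
log-likelihoods match `nlme::gls` with `ape` correlation structures to
8 decimals in the test suite). Model ranking uses AICc; the text-book AIC is
also reported. Intercepts are reported on the log10 scale together with
their back-transformed $10^{\mathrm{intercept}}$ values, the form in which
power-law prefactors are usually quoted.

Trees are ingested from Newick via `ape`; multifurcations are resolved
randomly (`resolve_polytomies()`, seeded) with each new internal edge given
$10^{-8}\times$ tree depth and the surplus trimmed from the terminal edges,
so tip depths are preserved exactly while covariance matrices stay
non-singular. Species present in only one of table and tree are dropped from
the phylogenetic stages with a logged count — real supertree workflows
routinely lose a species or two relative to the trait table, and the
reported $n$ makes that visible rather than silent.

## The synthetic-data generator

`generate_traits()` draws $\log_{10} H$ uniformly over the log-transformed
height range (default 0.25–52.5 m) — log-uniform sampling mirrors the
design goal of covering the widest feasible span of the predictor — and
then generates the chain $H \to L \to \{D_{\mathrm{pet}}, WD\}$,
$D_{\mathrm{pet}} \to D_{\mathrm{twig}}$ on the log10 scale with defaults
(slope, intercept, $R^2$): $L\sim H$ (0.482, 0.839, 0.22); $D_{\mathrm{pet}}
\sim L$ (0.396, 0.898, 0.72); $D_{\mathrm{twig}} \sim D_{\mathrm{pet}}$
(0.679, 0.592, 0.65); $WD \sim L$ (−0.271, −0.284, 0.24), values typical of
published cross-species samples. Residual SDs are calibrated by inverting
the $R^2$ of a simple regression,

$$\sigma_\varepsilon = |b|\,\mathrm{sd}(\log_{10}x)\sqrt{1/R^2 - 1},$$

using the realized predictor spread, so refitted regressions match the
target $R^2$ in expectation; `target_r2 = 1` gives exact power laws, a
useful noise-free limit for tests. Under `residual_mode = "brownian"` or
`"ou"` the residual vectors are drawn from the tree's BM or OU correlation
(unit diagonal) scaled to the same marginal variance, giving data with
genuine phylogenetic structure for calibrating the PGLS machinery. Defaults
produce 88 species whose leaf lengths typically span a bit over three
orders of magnitude.

What the generator does *not* emulate: intraspecific replication and
measurement error (each species is one exact record), site or climate
effects (leaf type and site are assigned uniformly at random with no effect
on any trait, which is precisely what makes them useful as negative
controls for the interaction models), non-Gaussian residuals, and
biologically impossible extremes — back-transformed wood densities are
clamped to (0.03, 1.4] g/cm³ even though published compilations occasionally
contain physically implausible values above that. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of the
estimators under the model's own assumptions, not the robustness of the
biological conclusions to violations of those assumptions.

## Numerical and design choices

* **Discretization**: 1 mm elements from 1 mm; midpoint diameters (finite
  at the tip for $4b>1$); convergence asserted at 1000 elements.
* **Root finding**: bisection on $\log_{10} d$, deterministic, tolerance
  $10^{-9}$; failure to bracket is a hard error with diagnostics.
* **Near-singular covariances**: Cholesky with a logged jitter of
  $10^{-10}\,\mathrm{tr}(C)/n$ added once; still-singular matrices are a
  hard error.
* **AICc** = $-2\log L + 2k + 2k(k+1)/(n-k-1)$; ranking uses AICc, AIC is
  reported alongside.
* **Boundary LR test**: parametric bootstrap by default (`n_null = 199`,
  nominal level then attained to within about half a percent); the
  asymptotic boundary mixture is available as an option.
* **Degenerate inputs**: constant traits, trees with duplicate tips,
  missing branch lengths, non-positive traits, and degenerate grouping
  factors all raise errors naming the offending entity.
* **Monte-Carlo problem sizes** used by the test suite: 88-species tables
  for calibration experiments, 200 seeds for CI-coverage and
  model-selection recovery, 2000 simulations for the type-I error checks of
  the slope-difference and $\lambda$ tests.

## Known limitations

The hydraulic module is a single-column Poiseuille idealization: no conduit
furcation or parallel-count architecture, no end-wall or pit resistance, no
embolism. The resistance-balancing exponent $c$ is an input, not a derived
quantity; it summarizes whatever fraction of pathlength resistance stem
widening leaves unbuffered. PGLS fixes the OU rate and the signal test's
$\lambda$ grid to the conventional choices rather than estimating them
jointly with the regression; and the Welch slope comparison treats the two
fits as independent, which is exact for independent samples and
conservative for shared ones.
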