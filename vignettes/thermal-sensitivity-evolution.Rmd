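---
title: "Methods: thermal performance curves and the evolution of thermal sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal performance curves and the evolution of thermal sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermevol)
```

`thermevol` chains two layers of analysis: per-curve nonlinear fitting of
thermal performance curves (TPCs), and phylogenetic comparative methods
applied to the fitted thermal-sensitivity parameters. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## The TPC model

A trait value $B$ (a rate: divisions/day, O$_2$/h, ...) follows the
four-parameter Sharpe–Schoolfield model with high-temperature
deactivation:

$$B(T) \;=\; \frac{B_0\, e^{-\frac{E}{k}\left(\frac{1}{T} -
\frac{1}{T_\mathrm{ref}}\right)}}{1 + \frac{E}{E_D - E}\,
e^{\frac{E_D}{k}\left(\frac{1}{T_\mathrm{pk}} - \frac{1}{T}\right)}},$$

with $k = 8.617\times10^{-5}$ eV K$^{-1}$ (fixed exactly). The numerator
is the Boltzmann–Arrhenius rise; the denominator produces the collapse
past the peak. This parameterisation has its maximum exactly at
$T_\mathrm{pk}$ — a property the unit tests verify numerically. Parameter
meanings and constraints:

- $B_0 > 0$: performance normalised at $T_\mathrm{ref}$. Because the
  denominator is not exactly 1 at $T_\mathrm{ref}$, the raw fitted $B_0$
  is replaced by the model value $B(T_\mathrm{ref})$
  (`renormalize_b0()`) in all reporting.
- $E$ (eV), $0 < E < E_D$: thermal sensitivity of the rise — the central
  quantity of the analysis.
- $T_\mathrm{pk}$ (K): peak temperature, $> T_\mathrm{ref}$.
- $E_D$ (eV): deactivation steepness.
- $T_\mathrm{ref}$: 273.15 K (0 °C) by default, configurable. A reference
  below every plausible peak keeps $B_0$ interpretable across cold- and
  warm-adapted taxa. All file I/O is in °C; everything internal is Kelvin.

Derived quantities: $B_\mathrm{pk} = B(T_\mathrm{pk})$; the operational
niche width $W_\mathrm{op} = T_\mathrm{pk} - T_{0.5}$ where $T_{0.5}$ is
the rising-limb temperature with $B = B_\mathrm{pk}/2$; and
$1/B_\mathrm{pk}$, the minimum generation time when the trait is a
population growth rate. $T_{0.5}$ is found by bracketed root-finding
(`uniroot`) on $[T_\mathrm{pk} - 150\,\mathrm{K}, T_\mathrm{pk}]$ with a
$10^{-6}$ K tolerance; the rising limb is monotone for biologically
plausible parameters, so the root is unique. If the curve never falls to
half peak inside the bracket (pathologically flat rises, $E \lesssim
0.02$ eV), the error is reported rather than a value fabricated. Note a
property relevant to testing: $W_\mathrm{op}$ approaches the closed form
$T_\mathrm{pk} - (1/T_\mathrm{pk} + k\ln 2/E)^{-1}$ only as $E_D \to
\infty$; the gap is first order in $E/E_D$ (via the $(E_D-E)/E_D$ factor
in $B_\mathrm{pk}$) and is still ~1% at $E_D = 100$ eV. The suite
therefore checks monotone convergence in $E_D$ rather than a fixed gap at
a moderate $E_D$.

## Fitting and quality control

Residuals are minimised on $\ln B$ (multiplicative error): rate data span
orders of magnitude, variance grows with the mean, and the $R^2$ gate
then lives on the same scale as the fit. The optimiser is
Levenberg–Marquardt (`minpack.lm::nlsLM`) restarted from a deterministic
grid: $E \in \{0.3, 0.65, 1.2\}$ eV, $T_\mathrm{pk}$ at the observed
maximum $\pm\{3, 0\}$ K, $E_D \in \{2, 4\}$ eV, and $B_0$ seeded from the
measurement nearest $T_\mathrm{ref}$ extrapolated down the Arrhenius
rise. The lowest-SSE start wins, so refits are bit-identical. Internally
the model is parameterised as $(\ln B_0, E, T_\mathrm{pk}, d)$ with
$E_D = E + e^{d}$, which enforces $E < E_D$ throughout optimisation;
box bounds keep $E \le 10$ eV and $T_\mathrm{pk}$ within the observed
range $\pm 10$ K. The optimisation cap on $E$ (10 eV) deliberately
exceeds the 4 eV acceptance cap so that implausibly steep rises surface
as observable rejections rather than optimizer artefacts.

Accepted quantities are filtered per curve from the counts of
measurements below/above the fitted peak (a measurement exactly at the
peak counts as below — deterministic and conservative for the rise-side
rules): $B_0$ and $E$ need ≥ 4 points below; $E$ is also capped at 4 eV;
$W_\mathrm{op}$ needs ≥ 4 below and ≥ 2 above; $T_\mathrm{pk}$ and
$B_\mathrm{pk}$ need ≥ 2 on each side; $E_D$ needs ≥ 4 above. A fit with
$R^2 < 0.5$ is rejected wholesale; the gate is applied before the 4 eV
rule. Standard errors on the analysis scales ($\ln B_0$, $\ln E$,
$T_\mathrm{pk}$, $\ln E_D$, $\ln B_\mathrm{pk}$) come from the
delta method on the inverse-Hessian covariance; $\ln W_\mathrm{op}$,
whose dependence on the parameters runs through a root-finder, uses a
seeded residual bootstrap (default 200 refits). When a species has
several curves, comparative analyses use the highest-$R^2$ fit, ties
broken by measurement count then curve id.

## Comparative methods

All comparative machinery assumes a rooted, ultrametric, relative-time
chronogram (unit root-to-tip height; `normalize_tree_height()` rescales
and resolves polytomies deterministically by label order with zero-length
branches). Analysed variables are the log-transformed parameters (and
$T_\mathrm{pk}$ untransformed), which brings their right-skewed
distributions close to the Gaussian world these models live in.

**Pagel's λ (phylogenetic heritability).** The trait covariance is
$\sigma^2 C_\lambda$ where $C$ is the shared-path matrix and $\lambda$
scales its off-diagonals. λ = 1 recovers Brownian motion; λ = 0,
phylogeny-free variation. The likelihood profiles the root state and rate
analytically and optimises λ on [0, 1]; known measurement variances can
be added to the diagonal, in which case (λ, σ²) are optimised jointly.
The 95% interval is profile-likelihood based. The estimate agrees with an
independent implementation (`phytools::phylosig`) to ~10⁻³ in the tests.

**Disparity-through-time.** Disparity of a tip set is the average squared
pairwise difference (= twice the sample variance). At each internal-node
time, taken chronologically from the root, the tree is cut into the
lineages present just before that node splits (the root slice is the
whole tree, so the curve starts at 1); single-tip lineages contribute
zero — the standard convention, which the source analyses leave implicit.
The mean across lineages is divided by whole-tree disparity, making the
curve exactly invariant to affine trait transformations. The null is
`n_sim` Brownian simulations on the same tree at the ML Brownian rate of
the data (study-scale default 10,000; calibration experiments use 200).
Significance uses the extreme pointwise two-sided rank of the observed
curve among all `n_sim + 1`; because many curves share the most extreme
rank, the p value is an interval $[p_\mathrm{lower}, p_\mathrm{upper}]$
(liberal/conservative tie bounds). Decisions in the package's own
calibration use the liberal bound: with a few hundred simulations the
conservative bound lumps every rank-1 curve together and its rejection
rate collapses toward zero, while the liberal bound is approximately
exact (8% empirical at a nominal 5% in the acceptance suite, inside the
1–9% band expected of the discrete rank distribution). Both bounds are
always reported.

**Ancestral states and the trend regression.** Internal-node states under
Brownian motion are GLS conditional expectations given the tips, with
prediction variances that include root-estimate uncertainty; they match a
dense brute-force GLS oracle and `phytools::fastAnc` in the tests. The
trend model regresses the combined tip + ancestral values on node time
with the full Brownian node-by-node covariance as error structure,
returning the central value $\ln\hat\theta$ (intercept) and a slope. The
covariance of the full node set is singular (the root has zero depth), so
a ridge of $10^{-10}\times$ the mean diagonal is always added; a larger
jitter triggers a warning. An identifiability caveat decided the design
here: on an ultrametric tree every tip sits at the same depth, so a
linear time trend is absorbed by the intercept and is *invisible* in tip
data; Brownian reconstructions, being linear shrinkages of the tips,
cannot restore it. The regression on reconstructed states therefore has
essentially no power against a real trend (it remains calibrated under
the null). For that reason `trend_regression()` accepts externally
supplied ancestral states — reconstructions from a heavy-tailed
evolutionary model, or a simulator's ground truth — and the package's
calibration experiments feed it the simulator's true node states, which
is what makes "slope −0.5 detected in ≥ 90% of replicates" a property of
the regression rather than of an impossible reconstruction.

**Latitude models.** Candidates combine latitude (absolute degrees by
default; cosine-of-radians and low/intermediate/high bins with default
edges 20°/40° are alternatives), trait identity, their sum and their
interaction, each with a species random intercept, fitted by one
profiled-ML routine so AIC is comparable across the whole set; the
phylogenetic variants correlate the species effects by the tree
(cov2cor of the shared-path matrix). Candidates whose non-intercept 95%
Wald CI covers zero are discarded, the lowest AIC survives, and an
intercept-only fallback is flagged when nothing survives — an ML/AIC
rendition of a "drop coefficients crossing zero, then best score"
selection rule originally formulated with Bayesian machinery. Variance
explained is reported as $R^2_m = \mathrm{Var}_f/(\mathrm{Var}_f +
\mathrm{Var}_r + \mathrm{Var}_e)$ and $R^2_c = (\mathrm{Var}_f +
\mathrm{Var}_r)/(\cdot)$, with $\mathrm{Var}_f$ the variance of the
fixed-effect predictions.

**Mantel test.** Pearson correlation of lower triangles with joint
row/column permutation of the second matrix,
$p = (1 + \#\{r_\pi \ge r\})/(n_\mathrm{perm} + 1)$, default 9,999
permutations. Identical matrices give $p = 1/(n_\mathrm{perm}+1)$
exactly.

**Branch rates.** As a display proxy for where evolution accelerates,
each branch gets the squared parent–child state difference per unit
length, min–max normalised; zero-length branches inherit the parent's
value with a warning. This is deliberately a descriptive quantity, not a
fitted rate model.

## The synthetic-data generator

The generator emulates the structure of a microbial TPC study: a
birth–death tree conditioned on the tip count (`ape::rphylo`), rescaled
to unit height; the four parameters evolving independently on their
analysis scales ($\ln B_0$, $\ln E$, $T_\mathrm{pk}$ in K, $\ln E_D$);
measurement tables from the model curve with lognormal noise; and
latitudes drawn by inverting $\ln E = \alpha + \beta\,|lat| + \varepsilon$
(clamped to $|lat| \le 66°$, random hemisphere).

Default conditions, chosen once to mirror a realistic microbial dataset:
root states $B_0 = 0.1$, $E = 0.65$ eV (the canonical rise), $T_\mathrm{pk}
= 298.15$ K, $E_D = 3$ eV; Brownian rates per unit tree height 0.5
($\ln B_0$), 0.2 ($\ln E$, giving a tip spread of $e^{\pm0.45}$ around
0.65 eV, comparable to observed right-skewed $E$ distributions), 25 K²
($T_\mathrm{pk}$, ≈ 5 K SD — gradual, strongly heritable evolution), 0.05
($\ln E_D$). Jumps (Poisson intensity 0.5 per unit branch length, SD 1)
apply to $\ln E$ only by default — bursts of adaptive evolution in
thermal sensitivity, while the other parameters stay diffusive. The trend
mode adds a drift (default −0.5 per unit time) to $\ln E$. Measurement
grids default to 2–46 °C every 4 °C with 5% log-noise. Constraint
violations along a branch ($E \ge E_D$, peak at or below the reference)
are resampled up to 100 times.

What passing tests do *not* show about real data: real TPCs have
unbalanced, ragged temperature grids, assay-specific error structure,
within-species strain variation and shared measurement campaigns; real
trees carry topological and dating error; and real latitude records are
strongly clustered at low/intermediate latitudes. The generator captures
none of these, so green calibration here demonstrates correctness of the
machinery, not robustness to every feature of field data.

## Problem sizes and determinism

Calibration experiments in the test suite use 50–100-tip trees, 20–100
replicates, 200 disparity simulations and 999 Mantel permutations —
sizes at which each experiment finishes in seconds to a couple of minutes
while leaving Monte-Carlo error well inside the asserted bands; the
study-scale defaults (10,000 simulations, 9,999 permutations) remain the
package defaults. Every stochastic routine takes an explicit seed, and
`run_pipeline()` forks one global seed per stage through a stable hash
(`stage_seed`), so a config + seed pair reproduces every output byte for
byte.

## Known limitations

- Only the high-temperature-deactivation Sharpe–Schoolfield variant is
  provided (no low-temperature deactivation, no alternative TPC shapes).
- Heritability is univariate; covariances among TPC parameters are not
  modelled jointly.
- Heavy-tailed (stable/Lévy) evolutionary models are not fitted; jumps
  exist in the simulator, and Brownian machinery stands in for inference,
  with the trend regression accepting external ancestral states where a
  heavy-tailed reconstruction is available.
- The latitude mixed models use ML with Wald intervals; with very few
  species per trait group the CIs are approximate.
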