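---
title: "From reporter-assay dose-response to a screening QSAR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From reporter-assay dose-response to a screening QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bmdqsar)
```

This vignette is the package's own account of the statistics and the design
choices behind each stage. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The measurement model

The pipeline starts from a dual-luciferase transactivation assay: cells
transfected with a receptor construct and a firefly-luciferase (FLuc)
reporter, plus a renilla-luciferase (RLuc) transfection control, are exposed
to a concentration series. `normalize_reporter()` divides each well's
FLuc/RLuc ratio by the mean solvent-control ratio *of the same biological
replicate* — each plate carries its own controls, so plate-to-plate
transfection efficiency cancels; solvent-control wells average to exactly 1
within a replicate. The resulting unit, fold induction over solvent control,
is what every downstream stage consumes.

Cytotoxicity bounds the usable concentration range. A tested concentration
is called cytotoxic when mean viability is below 80% of the untreated
control, or at least 10 below the next smaller tested concentration. The
drop rule is interpreted in absolute percentage points by default; a
relative interpretation (percent of the preceding value) is available via
`drop_rule = "relative"` because the verbal form of such rules is ambiguous
— the default is declared, not asserted as the only reading. Once any
concentration is cytotoxic, all higher ones are treated as cytotoxic (a
prefix rule): concentration-response data above the first toxic dose are
uninterpretable for a transactivation endpoint regardless of their nominal
viability. One caution for users of `highest_noncytotoxic()`: *raising* the
absolute threshold makes the rule stricter and can only lower the returned
cutoff; this is the monotonicity the tests assert.

## Dose-response families and the benchmark dose

All eight candidate median curves share the form

$$\mu(x) = a\,[1 + (c - 1)\,F(x; b, d)]$$

with background $a > 0$ (fold induction at dose zero, near 1 by
construction), maximal fold change $c > 1$, dose scale $b > 0$ and shape
$d > 0$. $F$ rises from 0 to 1; the eight choices (exponential, inverse
exponential, Hill/log-logistic, log-normal, gamma, quadratic exponential,
probit, logit) are documented with their formulas in `?drc_families`. The
probit and logit families are CDFs on the dose axis truncated at zero so
that $F(0) = 0$ holds exactly; the other six depend on dose only through
$x/b$.

The benchmark response is ratio-type: $\mathrm{BMR} = 1.5$ means the
concentration at which the *modelled median* response reaches 1.5 times the
*modelled background* $a$, not the literal solvent-control value — responses
are already fold inductions with $a \approx 1$, and using the modelled
background keeps the definition internal to each candidate. The default of
1.5 follows the common positive-classification threshold for luciferase
reporter systems; with a 30-40-fold dynamic range a 5% change would drown
in replicate variance. `bmd_from_params()` solves
$\mu(x) = \mathrm{BMR}\cdot a$ by bracketed root finding to relative
tolerance 1e-8; the closed-form inversions used per MCMC draw are tested
against it, and it against a brute-force grid.

### Error models, priors, MCMC

Each family is fitted under two error models: additive normal on the
response, and median-preserving log-normal
($\log y \sim N(\log \mu, \sigma)$). The log-normal likelihood retains its
$-\sum \log y$ Jacobian so the two error models are compared on the same
data density. Fitting uses adaptive random-walk Metropolis on
$\theta = (\log a, \log b, \log(c-1), \log d, \log\sigma)$, 20,000
iterations with the first 10,000 discarded as warmup by default (tests and
the acceptance script use 4,000/2,000; at the assay's 7-concentration,
3x3-replicate design the posterior is low-dimensional and well behaved, and
recovery results at the two settings agree). The chain starts at the
posterior mode found by a deterministic Nelder-Mead/BFGS pre-optimization;
the proposal covariance is replaced mid-warmup by the empirical warmup
covariance, and the global scale is tuned to ~23% acceptance. Split-R-hat
is reported per candidate.

Priors are weakly informative normals on the transformed scale:
$\log a \sim N(0, 1)$ (background near one-fold),
$\log(c-1) \sim N(1, 2)$ (maximal induction from a few percent to
hundreds-fold), $\log\sigma$ centred on the pooled within-group standard
deviation, and $\log b$ (and for probit/logit $\log d$) centred on the
geometric mean of the tested doses. Centring the dose-scale parameters on
data-derived quantities makes the whole seeded fit *exactly* equivariant
under rescaling of the concentration axis — multiply all doses by $s$ and
every posterior BMD draw multiplies by $s$ to machine precision, which the
tests verify at the default noise level. (With exactly zero residual noise
the posterior becomes a needle and floating-point non-associativity,
amplified by $1/\sigma^2$, can flip individual Metropolis decisions;
equivariance then holds to ~1e-4 rather than machine precision.)

### Trend gate and model averaging

Before any fitting, a one-sided trend test on biological-replicate means
(technical replicates are nested, not independent) regressed on dose rank
must reject at $\alpha = 0.05$; the specific test is a design choice — rank
regression is robust to the dose spacing — and its type-I error is verified
by simulation. Compounds failing the gate get an empty BMD result rather
than a meaningless estimate.

Averaging weights are posterior model probabilities from a Laplace
approximation to each candidate's marginal likelihood under equal prior
model weights; candidates whose mode-finding or Hessian fails are
down-weighted to zero, never fatal. The averaged BMD posterior is the
weighted mixture of per-candidate BMD draws; draws whose plateau never
reaches the BMR count as infinite, so non-response mass inflates the upper
bound instead of vanishing. BMDL/BMDU default to the 5th/95th mixture
percentiles (the one-sided 95% convention); `quantiles = c(0.025, 0.975)`
gives the equal-tailed alternative, since reasonable readings of "lower and
upper 95% confidence bounds" differ.

## Descriptors

`featurize()` computes four blocks from SMILES exactly as supplied (salt
forms are kept; no neutralization): 166 MACCS keys and radius-3
extended-connectivity fingerprints through the OpenBabel backend (native
4096-bit vectors folded by OR to 2048 bits — the length is a configuration,
not an assertion), a native implementation of topological autocorrelation
descriptors, and a small physicochemical block (TPSA, logP, molar
refractivity, molecular weight, hydrogen-bond counts, fluorine count). The
autocorrelation block follows the Broto-Moreau and Geary definitions on the
heavy-atom graph: for property $w$ and lag $k$,
$\mathrm{ATS}_k = \sum_{d(i,j)=k} w_i w_j$ over unordered pairs, AATS its
per-pair average, ATSC the centred version, and GATS the Geary ratio.
Weights are valence electrons less bonded hydrogens, Gasteiger partial
charges (hydrogen-suppressed, from OpenBabel), polarizability, mass and
atomic number — the latter three with implicit-hydrogen contributions
folded into the heavy atom. Descriptor *values* from different software
lineages differ in such conventions; the pipeline therefore never assumes
numeric agreement with any other implementation, only correctness of the
stated formulas (verified against a hand-computed molecule).

The cleaning cascade drops non-finite columns, then low-variance columns
(variance below 1e-8 or modal value covering >= 95% of rows — thresholds
chosen on the synthetic panel; published pipelines of this kind remove the
large majority of raw features at this step), then greedily prunes
correlated pairs in column order, keeping the earlier member of any pair
with $|r| > 0.9$. First-kept greedy order is a deterministic tie-break; the
surviving set provably contains no offending pair, and cleaning is
idempotent. Standardization z-scores continuous columns on training rows
and leaves binary bits on their 0/1 scale, storing the scaler for
projection of screening compounds.

## Feature selection

The genetic algorithm evolves binary masks with fitness
$-\mathrm{MAPE}_{cv} - \lambda k$: MAPE of back-transformed (uM)
predictions from a 5-fold cross-validated OLS on log-BMD, minus
$\lambda$ per selected feature. $\lambda$ defaults to 0.5 MAPE percentage
points per feature — enough that a feature must explain half a point of
error to pay for itself; it is exposed in `ga_config()`. Folds are
re-randomized for every evaluation through a child seed derived from
(master seed, generation, individual index), so evaluations are
order-independent and a parallel implementation would agree with the serial
one. Initial chromosomes activate each bit with probability 0.05: with
n = 34 training compounds, dense random masks would be rank-deficient from
the start. Elitism (top 3) makes the best-so-far trace non-decreasing,
which is asserted on every run. The stopping rule — best fitness unchanged
for 10 generations, or the generation cap — is a convergence heuristic, not
a claim about any particular dataset. Tournament-3 selection, uniform
crossover at 0.75 and bit-flip mutation at 0.25 are the defaults;
roulette selection, two-point crossover and a Gaussian
(perturb-and-threshold) mutation are available behind the same interface.

On planted problems at the modelling scale (2 true features among 141,
n = 34), an exhaustive search over all 1- and 2-feature masks certifies
that the planted pair is the cross-validation optimum, and the GA finds it
— both checks run in the acceptance suite.

## The linear model and its validation

The final model is plain OLS on $\log(\mathrm{BMD})$ — the natural
logarithm; the base only rescales coefficients. Metrics (R2 as
$1 - SS_{res}/SS_{tot}$, MAE, RMSE) are always computed on the
back-transformed uM scale, and R2 may be negative (y-randomized models
routinely are). The final cross-validation uses a fixed, documented fold
seed, deliberately distinct from the GA's re-randomized internal folds.
y-randomization permutes the response (preserving its multiset), refits and
re-evaluates with the same protocol, 20 times by default; a genuine
structure-activity relationship collapses under it. Ridge regularization is
available in principle behind the same interface but is off by default —
with seven standardized features and n = 34, unpenalized least squares is
the transparent choice.

## Applicability domain

Screening predictions are trusted only inside the conjunction of two
criteria computed on the *selected* descriptors (never the full matrix):
the bounding box (every feature within the closed training min-max range)
and leverage $h = x'(X'X)^{-1}x \le h^* = 3(p+1)/n$. Leverage uses the
standardized selected features without an intercept column; the bounding
box uses the same standardized values, which under affine z-scoring is
equivalent to raw-scale bounds. Whether an intercept belongs in the
leverage design is genuinely open (the $+1$ in $h^*$ hints at one); the
no-intercept choice is recorded in the model artifact, and on centred
training data the centroid has leverage 0 either way. A singular $X'X$
falls back to the pseudo-inverse with a warning rather than aborting a
screen.

## Synthetic data: what it emulates and what it does not

`simulate_dose_response()` inverts the same eight families the engine fits:
background 1, plateau 30-fold by default (the observed dynamic range of
strong agonists in such assays), seven half-log concentrations from 0.1 uM,
3 biological x 3 technical replicates, and normal (additive) or log-normal
(multiplicative, median-preserving) noise at sd 0.15 by default. With zero
noise the curve passes through `bmr * background` exactly at `true_bmd`,
giving every fitting routine an exact oracle. What it does *not* emulate:
plate effects, heteroscedasticity beyond the two error models,
within-plate correlation, pipetting outliers, or cytotoxicity-truncated
plateaus arising mid-experiment — so passing recovery tests demonstrates
correctness of the estimator under its own assumptions, not robustness to
every laboratory artifact.

`simulate_descriptor_matrix()` plants a sparse linear signal
($\beta = (1, -0.8)$ on two standardized columns, intercept $\log 20$ uM,
residual sd 0.05 on the log scale) in a 34 x 141 matrix of mixed
binary/continuous columns, optionally with forced high-correlation pairs.
It reproduces the *dimensions and difficulty* of the real selection problem
(n far below p, mixed feature kinds), not the correlation structure of real
chemistry. `make_pfas_like_series()` builds template SMILES for five
homologous series (carboxylic, sulfonic, their mono-ether analogues, and
fluorotelomer sulfonates) — valid chemistry for exercising the descriptor
and screening stages, not a reproduction of any experimental panel.

## Numerical choices and problem sizes

Root finding to relative tolerance 1e-8 with bracket expansion; weighted
mixture quantiles take the midpoint of adjacent order statistics when a
cumulative weight hits the probability exactly (so a symmetric two-model
mixture has its median midway between them); rank-deficient fold fits in
cross-validation zero the aliased coefficients; degenerate inputs (empty
masks, all-cytotoxic profiles, unparseable SMILES, all-failed candidates)
produce sentinels, warnings or flagged records rather than errors, except
where the input contract is violated outright. The test and acceptance
suites run the MCMC at 4,000/2,000 draws, BMD recovery over 20 seeded
curves, trend-gate calibration over 1,000 null simulations, and the GA at
population 300 for up to 30 generations — sizes at which every stochastic
check is stable across seeds while the whole suite completes in minutes.

## Known limitations

Quantal endpoints, covariates and frequentist model averaging are out of
scope. Descriptor values are backend-specific (OpenBabel conventions here);
a model artifact is only valid with features computed by this package. The
Laplace weight approximation can misweight strongly non-Gaussian
posteriors; WAIC-style weights would be a natural alternative behind
`model_average()`. The screening collision audit flags, but does not
resolve, fingerprint bit collisions — flagged hits warrant substructure
verification before follow-up.
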