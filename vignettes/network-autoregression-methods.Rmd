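---
title: "Methods: network autoregression of national outcomes on cultural and spatial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network autoregression of national outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solnet)
```

## The question and the model

Nation states are not independent observations: they share linguistic and
colonial ancestry, and they sit next to each other. Any claim that a
political or economic outcome "spreads" culturally has to beat the
alternative that it merely patterns on geography (Galton's problem). This
package operationalises the comparison with the linear network
**disturbances** autoregression,

$$ y = X\beta + \varepsilon, \qquad \varepsilon = W\varepsilon + \nu,
   \qquad W = \sum_k \rho_k W_k, \qquad \nu \sim N(0, \sigma^2 I), $$

where $X$ is an intercept column, the $W_k$ are a-priori pairwise weight
matrices (here up to four: socio-linguistic affinity `SoL_aff`, spatial
proximity `S_prox`, language adjacency `L_adj`, border adjacency `S_adj`),
and each $\rho_k$ measures how strongly the residual variation patterns on
matrix $k$. The autocorrelation sits in the disturbance, not the response:
writing $A(\rho) = I - \sum_k \rho_k W_k$, the outcome is multivariate
normal with mean $X\beta$ and covariance $\sigma^2 A^{-1}A^{-\top}$, and at
$\rho = 0$ the model is ordinary least squares. A positive $\rho_k$ means
connected countries move together; a negative one means they move apart
(differentiation).

### Weight matrices

Distances become weights in two ways:

* **Affinities**: pairwise distances $D$ (divergence times in years for the
  socio-linguistic matrix, Haversine great-circle km for the spatial one)
  are mapped through $(\max(D) - D_{ij})/\max(D)$, the linear transform used
  in phylogenetic comparative work. The result lies in $[0, 1]$, has unit
  diagonal, puts exactly one off-diagonal pair at 0, and is invariant to
  rescaling the distances.
* **Row-normalized adjacencies**: binary matrices (shared border; languages
  diverged by fewer than 1000 years, a mutual-intelligibility proxy) with
  each nonzero row divided by its sum. Isolates keep zero rows.

When countries drop out of a time bin, affinity matrices are subset from
the full-sample transform (so affinities stay comparable across bins),
while adjacencies are subset and re-row-normalized. Earth radius is fixed
at the conventional mean 6371 km. Distances within `1e-9` of the adjacency
threshold count as *not* less than it, making the strict inequality
deterministic in floating point.

## Estimation

$\beta$ and $\sigma^2$ are profiled analytically: with $\tilde y = Ay$ and
$\tilde X = AX$, least squares gives $\hat\beta$, the mean squared residual
gives $\hat\sigma^2$, and the concentrated log-likelihood is

$$ \ell(\rho) = -\tfrac{n}{2}\log(2\pi\hat\sigma^2) + \log\det A -
   \tfrac{n}{2}. $$

Only $\rho$ is optimized numerically (Nelder–Mead from a start at 0, a
restart at the first optimum, convergence tolerance `1e-8` on the
log-likelihood; this is verified against a dense grid search to `1e-3` in
the tests). Standard errors come from the inverse numerical Hessian of the
negative full log-likelihood in $(\beta, \sigma^2, \rho)$ at the optimum,
and p-values from two-sided normal z-tests — the degrees of freedom used by
the original tooling in this literature are not standardized, so the normal
approximation is the documented choice.

**The stability domain.** The likelihood is only meaningful where
$A(\rho)$ is invertible in the component connected to $\rho = 0$. The
naive condition $\det A > 0$ is *not* sufficient: with an even number of
sign-flipped eigenvalues the determinant turns positive again in
disconnected islands far from zero, and an unconstrained optimizer will
happily wander there and report spuriously good fits (we observed exactly
this with dense affinity matrices). The package therefore requires the
symmetric part of $A$ to be positive definite — for symmetric weight
matrices this is exactly the contiguous domain around 0, and it implies
$\det A > 0$ in general. A practical consequence: for an affinity matrix
with large row sums the admissible $\rho$ is small (roughly
$1/\lambda_{\max}$), so published autocorrelations fitted by tools without
this restriction can lie outside the domain this package will search.

**BIC.** Model selection uses $\mathrm{BIC} = -2\ell + k\log n$ with $k$
counting the intercept, $\sigma^2$, and one $\rho$ per included matrix
(the null model has $k = 2$). Counting $\sigma^2$ matters only as a
constant across models with equal data, so BIC *gaps* are unaffected, but
it is documented so absolute values are reproducible. Reported Bayes
factors follow the doubling convention $2\,\Delta\mathrm{BIC}$, read
against the Kass–Raftery bands on the $2\log \mathrm{BF}$ scale (0–2 weak,
2–6 positive, 6–10 strong).

## The selection machinery

Per time bin, all $2^4 = 16$ subsets of the four matrices are fitted and
ranked by BIC (ties under `1e-6` broken by parsimony, then label order;
non-converged fits rank last and are flagged). Across bins the package
reports: the per-model frequency table of preferred and second-best
models; per-matrix top-two inclusion counts (a matrix present in both the
preferred and second model of one bin counts twice, so counts are bounded
by twice the bin count); median BIC gaps first-to-second and
first-to-third; single-matrix significance censuses at $\alpha = 0.05$
with a one-sample t-test on the significant $\hat\rho$ (df = count − 1);
and an even/odd robustness fraction — of the bins where a matrix made the
top two, the share with even (1-based) bin index, which should sit near
50% unless findings cluster in adjacent intervals.

Bins with fewer than 3 countries, a constant outcome, or a degenerate fit
are skipped and logged with reasons, and every report carries an explicit
estimable-bin count, so denominators are always visible.

## Outcome panels

* **Polity-style**: the −10..+10 autocracy–democracy score sampled every
  other year, 1898–2012 (58 columns; the special codes −66/−77/−88 for
  interruption/interregnum/transition are not scale values and become
  missing). Change panels subtract consecutive bins and have one fewer
  column (57).
* **Default-style**: yearly default event flags for foreign and domestic
  creditors summed into 5-year bins from 1899. The bin grid is
  config-exposed and may extend past the last event year; a trailing
  all-zero bin is inestimable for the state analysis (constant outcome)
  but still contributes a change bin, which is how a 21-bin state census
  coexists with a 22-bin change census when state tests start from 1904.

## The diffusion simulation study

The bias self-test draws $z_i \sim N(0,1)$ per country and applies one
synchronous step $x_i = z_i + r\,(m_i - z_i)$ with rate $r = 0.2$, where
$m_i$ aggregates the neighbours of $i$; 250 independent traits per network
(1000 in total) are then pushed through the identical 16-model selection
machinery, and per-network inclusion counts and median BIC gaps are
tabulated.

The neighbour aggregate was a genuinely open design point. On binary
row-normalized adjacencies "the average of the immediate neighbours" is
unambiguous, and both candidate readings coincide with the plain neighbour
mean. On valued networks (affinities), dividing the weighted sum by the row
sum dilutes the perturbation of a densely connected node to a few percent
of its noise — measured on the synthetic world, own-network recovery
collapses to chance (2/30 significant single-matrix fits), which
contradicts the selection behaviour this machinery demonstrably has at
scale. The tie-weighted sum $(Wz)_i$ (diagonal zeroed) preserves the tie
scale, coincides exactly with the neighbour mean on the row-normalized
matrices, and yields the expected recovery ordering: the generating
affinity network is the most-included matrix in its own condition, and the
adjacency conditions show the documented bias toward spatial proximity.
The sum is therefore the default, the mean is retained as
`aggregate = "mean"` for sensitivity, and a negative `rate` gives the
repelling (differentiation) variant.

## The synthetic world

Every stage runs without external data on a generated world whose
parameters were chosen once to emulate the statistical shape of the study
sample, then frozen:

* 56 countries, of which 20 are colonial offshoots of 4 colonial-power
  languages — the sample this analysis targets is colony-heavy, and the
  large blocks of very recent splits are what give the socio-linguistic
  affinity its contrast;
* a family-structured ultrametric language tree: deep splits between
  families at 55–100% of a 6000-year depth, shallow random coalescent
  structure within families at 15–45%, colony attachments at 50–400 years
  (a colony sits at twice its split time from its parent, sister colonies
  at the sum of their split times, keeping the matrix tree-additive);
* continent-clustered coordinates (5 region centres, countries scattered
  around them), giving spatial affinities near-0 to near-1 contrast like a
  real country sample, with borders as symmetrized 3-nearest-neighbour
  links;
* outcome generators: an exact sampler of the disturbances model
  ($y = \mu + A^{-1}\nu$, refused outside the stability domain);
  polity-like bounded integer panels whose initial cross-section and rare
  increments are both network-correlated (increments rounded half away
  from zero — symmetric treatment of moves toward autocracy and
  democracy — and clipped to ±10); and default-like panels with Bernoulli
  events per country-bin, assigned to a uniform year within the bin and a
  random creditor stream, so expected totals are
  $n \cdot \text{bins} \cdot \text{rate}$ and counts are conserved under
  re-binning.

What the synthetic world does *not* emulate: serial dependence of default
events, realistic geopolitics, any correlation between the language tree
and geography, or the magnitude of published coefficients. Passing tests
on it demonstrate that the machinery recovers known ground truth of the
model class, not that any particular historical claim is true.

## Problem sizes and determinism

The bundled analyses use 56 countries, 58 biennial polity bins, 22–23
five-year default bins, and 50-replicate diffusion batches in the test and
acceptance runs (250 in `analysis/04_simulation_study.R`); these sizes
keep the full pipeline in the minutes range while preserving every
qualitative contrast the full-scale study shows. All randomness flows from
explicit seeds (the bias study derives one substream per network × rep),
so every table in this package is bit-reproducible; fitting itself is
deterministic given the data.

## Known limitations

* The stability-domain restriction means the package will not reproduce
  autocorrelation point estimates that unrestricted tools report beyond
  the domain boundary; selection results (BIC ranks, censuses) are the
  comparable quantities.
* The z-based p-values ignore estimation error in $\sigma^2$; with n in
  the dozens this is the field's standard approximation, and the type-I
  rate is verified near nominal in the tests.
* ML $\hat\rho$ carries a small negative finite-sample bias (about −0.04
  at n = 100 on sparse networks, measured by the acceptance script);
  censuses and model ranks are insensitive to it.
* Significance censuses across bins of a persistent panel are not
  independent replications — a single unusual cross-section can stay
  "significant" for many consecutive bins. The even/odd robustness
  fraction exists precisely to flag that failure mode.
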