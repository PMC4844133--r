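# solnet

Does political and economic change among nation states pattern on shared
cultural history, or just on geography? Countries are not independent data
points: they inherit institutions and norms along linguistic and colonial
lines, and they border each other. `solnet` implements the network
autoregression toolkit for asking which pairwise structure a national
outcome (an autocracy–democracy score, sovereign default counts) actually
follows, for researchers in cultural evolution, comparative politics and
spatial econometrics.

## The model

The core is the Gaussian linear **network disturbances** model

```
y = Xβ + ε,    ε = Wε + ν,    W = Σ_k ρ_k W_k,    ν ~ N(0, σ² I)
```

with an intercept design and up to four simultaneous weight matrices:

| label     | matrix                             | kind                     |
|-----------|------------------------------------|--------------------------|
| `SoL_aff` | socio-linguistic affiliation       | affinity `(max(D)−D)/max(D)` from divergence years |
| `S_prox`  | spatial proximity                  | affinity from Haversine km |
| `L_adj`   | language adjacency (< 1000 years)  | row-normalized binary    |
| `S_adj`   | shared land border                 | row-normalized binary    |

Each ρ is fitted by maximum likelihood (β, σ² profiled analytically;
ln det(A) Jacobian; optimization restricted to the stability domain around
ρ = 0). On top of the fitter sit exhaustive BIC sweeps over all 16 matrix
subsets per time bin, Bayes factors by the `2·ΔBIC` doubling convention,
top-two inclusion frequencies, single-matrix significance censuses with
one-sample t summaries, even/odd temporal robustness, and a one-shot
trait-diffusion simulation study that audits the machinery for selection
bias. A synthetic-data module (family-structured language trees with
colonial blocks, continent-clustered coordinates, polity-like and
default-like panels with known ground truth) makes every stage runnable
with no external downloads.

## Worked example

Plant a known autocorrelation (ρ = 0.7) on the border network of a
synthetic 56-country world, fit it, and let BIC pick among all 16 models:

```r
library(solnet)
world <- make_synthetic_world(seed = 7)
y <- sample_disturbance_outcome(list(world$weights$S_adj), rho = 0.7,
                                sigma2 = 1, intercept = 2, seed = 99)
fit_disturbance(disturbance_model(y, world$weights["S_adj"]))
#> Network-disturbances fit (n = 56 )
#>   intercept: 1.153  sigma2: 0.9423
#>          rho     se p
#> S_adj 0.7388 0.0738 0
#>   loglik: -83.5319  BIC: 179.14  converged: TRUE

sw <- sweep_bin(y, world$weights)
head(as.data.frame(sw)[c("rank", "model", "bic")], 4)
#>   rank         model      bic
#> 1    1         S_adj 179.1399
#> 2    2  S_adj+S_prox 181.8414
#> 3    3 S_adj+SoL_aff 183.0262
#> 4    4   L_adj+S_adj 183.1565
bayes_factor(sw$bic[sw$rank == 2] - sw$bic[sw$rank == 1])
#> [1] 5.402981
```

The planted matrix is recovered (ρ̂ = 0.74 ± 0.07 against a true 0.7), the
single-matrix model wins the sweep, and the Bayes factor of 5.4 ("positive"
on the 2·log scale) says the runner-up — the same matrix plus a redundant
one — is a clearly worse description.

The full analyses live in `analysis/`: `01_build_weights.R` (matrix
construction), `02_polity_analysis.R` (biennial panels, sweeps, censuses),
`03_default_analysis.R` (5-year default bins from 1899, state tests from
1904), `04_simulation_study.R` (250 diffusion traits per network;
`SOLNET_SIM_REPS` scales it down), and `05_polity_benchmark.R` (optional,
needs the external country-year polity table).

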