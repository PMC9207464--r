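# gatemix

Model-based disease subtyping from two data sources at once: longitudinal
clinical follow-up scores and a high-dimensional panel of genetic markers.

Cohort studies of complex diseases (the motivating case is Parkinson's
disease, with a motor score and a cognitive score recorded at yearly
visits) often hide subtypes that differ in how symptoms progress — and
possibly in their genetic background.  The common practice is to cluster
the clinical trajectories first and test markers against the cluster
labels afterwards, which can never use the genetics to improve the
clustering itself.  `gatemix` fits the integrative alternative: a sparse
**mixture of experts**.

## The model

Patient `i` carries a genotype vector `g_i ∈ {-1,0,1}^L` (additive
coding) and visits at times `t_ij` with `V` clinical scores `y_iv(j)`.
With latent subtype `z_i ∈ {1..K}`:

- **Experts** (outcome models): per subtype and score, a polynomial
  trajectory in time with Gaussian noise,
  `y_iv(j) | z_i = k  ~  N( Σ_p α_vkp (t_ij/s)^p ,  σ_vk² )`.
- **Gate** (subtype probabilities): a multinomial logistic model on the
  markers, `P(z_i = k | g_i) = η_k(g_i; ω) ∝ exp(ω_k0 + ω_kᵀ g_i)`,
  class 1 pinned to zero for identifiability.

Because `L ≫ N`, the gating coefficients carry an ℓ1 (lasso) penalty
`λ Σ_k ‖ω_k‖₁` whose exact zeros select the markers relevant to the
subtyping.  Inference is a classification-EM (or soft EM) algorithm with
the penalty re-chosen by 5-fold cross-validation inside every M step,
multiple random initializations, BIC to pick `K` and `P`, and an
unpenalized refit of the selected coefficients with Wald confidence
intervals.  The reference-pinned penalized multinomial solver is
implemented in C++ (proximal Newton + coordinate descent with strong-rule
screening).

A synthetic-cohort generator reproduces the structure of the published
simulation benchmark for this model family (N = 396 patients, 4 scores,
3 subtypes, 3 visit windows spanning ~11 years, 2657 markers of which 10
drive the gate), so every stage is testable without restricted data.

## Worked example

```r
library(gatemix)

ds  <- simulate_dataset(toy_scenario(seed = 1))   # 90 patients, 40 markers
fit <- fit_mixture(ds$clinical, ds$geno, em_config(K = 3, P = 1, seed = 1))
print(fit)
#> gatemix_fit: K=3, P=1 (cem), 8 iterations
#>   loglik -1946.64, BIC 4122.77 (nu=51), lambda 0.06592, support 13 coefficient(s) on 12 marker(s)

adjusted_rand_index(ds$true_labels, fit$labels)
#> [1] 0.486
selected_markers(fit)
#> [1]  1  2  3  4  7  8 16 20 22 23 34 39
head(subset(fit$debias$wald_ci, marker > 0), 5)
#>   class marker  estimate        se       lower      upper    p_value
#> 3     2      1  2.404770 0.9156036  0.61018695  4.1993532 0.00862854
#> 4     2      2  1.183733 0.6378999 -0.06655123  2.4340166 0.06350041
#> 5     2      7  0.665574 0.4550819 -0.22638655  1.5575346 0.14359419
#> 6     2      8  0.915118 0.4726737 -0.01132240  1.8415585 0.05286206
#> 7     2     16 -1.134066 0.4975859 -2.10933411 -0.1587973 0.02265901
```

Reading the output: the engine converged in 8 CEM iterations at a
cross-validated penalty of 0.066, keeping 13 nonzero gating coefficients
on 12 markers — the toy's four truly active markers (1–4) are all among
them, alongside a handful of false positives, which is normal lasso+CV
behavior at this sample size.  The clustering recovers the simulated
subtypes imperfectly (ARI 0.49; the toy's trajectories overlap by
design).  The `wald_ci` table shows the debiased per-class log-odds of
each selected marker: marker 1's interval excludes zero (each unit of the
additive genotype multiplies the subtype-2 odds by `exp(2.4) ≈ 11`),
while weaker candidates remain inconclusive.

Other entry points: `fit_two_step()` (the cluster-then-associate
baseline), `select_model()` (BIC grid over `K`, `P`), `run_benchmark()`
(replicated method comparison with oracle variants),
`adjust_clinical()` / `encode_genotypes()` / `screen_markers()`
(preprocessing), and a command-line launcher in `inst/cli/gatemix-cli.R`
with verbs `fit`, `two-step`, `select`, `simulate`, `benchmark` driven by
a flat YAML configuration.

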