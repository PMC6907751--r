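# genesupport

Does human genetic evidence predict which drug target–indication pairs
get approved? `genesupport` implements the full analysis chain behind
that question for computational genomics and drug-discovery teams:

* **Trait similarity** over a rooted heading ontology (MeSH-like DAG):
  information content from descendant counts,
  IC(c) = −ln((|desc(c)|+1)/N); Resnik (IC of the most informative
  common ancestor) and Lin similarities, averaged after per-trait
  normalization into a combined similarity S_T ∈ [0, 1], with
  provenance-tracked manual overrides.
* **Gene–trait links** from GWAS-style SNP associations (p ≤ 1e-8) via
  LD expansion (r² ≥ 0.5) through distance (±5 kb), eQTL (p < 1e-6) and
  DHS channels, plus OMIM-style curated links, restricted to
  protein-coding genes, with a high-confidence subset of links in high
  LD (r² ≥ 0.9) with deleterious variants.
* **Evidence scoring**: continuous evidence E_C(g, t) = max similarity
  between indication t and any trait genetically linked to gene g;
  binary evidence E_D = 1{E_C ≥ 0.7}.
* **Pipeline assembly**: drug records to target–indication pairs with
  ordinal phases (0 = Preclinical … 4 = US/EU Approved).
* **Progression analysis**: risk ratios
  (N_ev,x/N_ev,y)/(N_no,x/N_no,y) with at-or-beyond counting, percentile
  bootstrap CIs, and validation-set partitions over two snapshots.
* **Approval model**: Bayesian logistic regression
  y_i ~ Bernoulli(logit⁻¹(α + η_i + x_i′β)) with a conditional
  quadratic evidence term η_i = Σ_j γ_j z_i^j for pairs whose gene has
  an association, priors α ~ N(−2.2, 0.75²) (a ~10% baseline approval
  anchor), β, γ ~ N(0, 2²); WAIC and posterior odds-ratio curves.
* **Synthetic data**: a seeded generator for every input table, so the
  whole analysis runs end to end with known ground truth and no
  proprietary data.

## Worked example

```r
library(genesupport)

# a small synthetic study, end to end
cfg <- sim_config(seed = 3, n_terms = 60, n_genes = 120,
                  n_gwas = 120, n_omim = 80, n_drugs = 400)
art <- run_pipeline(cfg, out_dir = "results/demo",
                    fit_spec = model_spec(chains = 2, warmup = 400,
                                          iter = 500, seed = 3))
art$riskratio
#>                 set from to     rr    ci_low  ci_high   n
#> full_data full_data    1  4 1.6875 0.7895149 2.779751 532
```

Pairs with genetic evidence reached approval 1.69× as often as pairs
without (bootstrap 95% CI 0.79–2.78 at this small simulated size, 532
eligible pairs).

```r
print(art$fit)
#> approval_fit: 1000 draws x 6 parameters
#>              2.5%    50%  97.5%
#> alpha      -1.953 -1.494 -1.002
#> gamma_1[2]  0.541  0.884  1.278
#> gamma_1[3] -0.581 -0.356 -0.141
```

The posterior for the linear evidence coefficient γ₁ is clearly
positive and the quadratic coefficient negative: approval odds rise
with trait–indication similarity and bend at the top of the scale.
`head(art$curve)` gives the odds-ratio-versus-similarity curve — values
below 1 at low similarity mean that an association to a *dissimilar*
trait predicts worse-than-baseline odds.

The numbered scripts under `analysis/` run the same chain as a
narrative workflow (simulate → map genes → score → risk ratios → model
fit), writing tables under `results/synthetic/`.

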