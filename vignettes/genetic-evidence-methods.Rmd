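---
title: "Quantifying genetic evidence for drug target-indication success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genetic evidence for drug target-indication success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Drug targets supported by human genetic evidence — a curated Mendelian
gene–phenotype link, or a genome-wide association mapped to the gene —
have repeatedly been reported to be roughly twice as likely to yield an
approved drug. `genesupport` implements that analysis chain as reusable,
tested components: trait-similarity computation over a heading ontology,
SNP-to-gene mapping, genetic-evidence scoring for target–indication
pairs, phase-progression risk ratios on validation-set partitions, and a
Bayesian logistic regression of approval on continuous evidence.

Because the pipeline databases involved (drug pipelines, full
association catalogs, LD panels) are proprietary or too large to ship,
the package includes a first-class synthetic-data generator that
emulates every input with known generating parameters. All claims the
test suite makes are claims about this synthetic study; see
"What the synthetic data does and does not show" below.

## Trait similarity over the heading ontology

Traits and indications live in a rooted DAG of headings (MeSH-like:
multiple parents allowed). Information content is computed from
descendant counts,

$$\mathrm{IC}(c) = -\ln\frac{|\mathrm{desc}(c)|+1}{N},$$

so the root has IC 0 and leaves are maximal; a node reachable by several
paths is counted once. Resnik similarity is the IC of the most
informative common ancestor (MICA); Lin similarity is
$2\,\mathrm{IC}(\mathrm{MICA})/(\mathrm{IC}(t_1)+\mathrm{IC}(t_2))$.

The combined similarity $S_T$ averages Lin with a per-trait-normalized
Resnik. Normalization is per ordered pair — $\mathrm{Resnik}(t_1,t_2)/
\mathrm{IC}(t_1)$ — and the two orders are averaged. We chose this
(rather than normalizing by each trait's maximum similarity over all
partners) because it makes every non-root term's self-similarity exactly
1 by construction, which the evidence functions rely on. Terms with IC 0
(the root) cannot be normalized; all similarities involving them are
defined as 0, including the root's self-pair, and this is deliberate —
a trait so generic it spans the whole vocabulary carries no evidence.
MICA ties are broken lexicographically for determinism. Natural
logarithms are used throughout; the base cancels in both Lin and
normalized Resnik.

Manually assigned similarities (needed in real vocabularies to connect
diseases to closely related quantitative traits, e.g. osteoporosis and
bone density) are supplied as an override table. Overrides replace the
computed value for their unordered pair, are flagged `manual`, and can
be excluded at evaluation time to quantify how much curation drives the
downstream estimates.

## From SNP associations to gene-trait links

GWAS-style associations are filtered at reported $p \le 10^{-8}$ (the
boundary is kept: values *greater than* $10^{-8}$ are excluded).
Curated OMIM-style links drop provisional, drug-response and somatic
entries. Lead SNPs are LD-expanded at $r^2 \ge 0.5$ (inclusive, matching
the explicit $R^2 \ge 0.9$ convention used for the deleterious subset),
then connected to protein-coding genes through three channels:

* **distance** — the SNP lies within 5000 bp of the gene body, closed
  interval. Whether the window should be measured to the gene body or
  the TSS is not fixed by convention; we use the gene body.
* **eQTL** — any tissue record with nominal $p$ strictly below
  $10^{-6}$ (a $10^{-12}$ cutoff is a supported sensitivity setting).
* **DHS** — a DNase-hypersensitivity/expression correlation passing a
  permutation-p cutoff. Descriptions of this filter in the literature
  are internally inconsistent (a printed permutation p-value of 1.000
  from 1000 replicates); we default to 0.001, the resolution of 1000
  replicates, and expose the cutoff as a parameter rather than guessing
  intent.

Links are deduplicated on (gene, trait, source) with channels
accumulated, and each GWAS link records the maximum $r^2$ between its
lead SNP and any variant predicted HIGH or MODERATE deleterious; the
high-confidence subset keeps links with that $r^2 \ge 0.9$.

## Evidence scoring

For association set $A$, the pair score is
$S((g_1,t_1),(g_2,t_2)) = S_T(t_1,t_2)$ if $g_1=g_2$, else 0.
Continuous evidence $E_C(g,t)$ is the maximum score over $A$; binary
evidence $E_D = \mathbf 1\{E_C \ge 0.7\}$. A preset cutoff of 0.73 is
provided: when the heading vocabulary version changes, the decision
boundary equivalent to the original 0.7 shifts, and 0.73 is the
recalibrated critical value.

A gene with *no* association in $A$ is distinct from one whose best
similarity is 0: the first yields the marker `NA` (no association), the
second yields $E_C = 0$. The approval model's evidence term applies only
to pairs whose gene has some association, so the two must not be
conflated.

The two-by-two analyses additionally require at least 5 associations to
traits similar to the indication. The count runs over all genes by
default (the reading most consistent with its role as an
indication-level eligibility gate); a per-gene reading is available as
an option. Neither reading is asserted as the original intent.

## Pipeline assembly

Drug records carry global status, per-country status, per-indication
events and free-text clinical details. The latest historical phase of a
drug-indication pair follows a precedence: country status for
single-indication or globally-preclinical drugs; otherwise the maximum
phase implied by events matching the indication; clinical details only
as a last resort (the field may describe planned trials). Phase
vocabulary is a configurable mapping table. Unknown phases stay unknown
(`NA`), because different analyses treat them differently: excluded from
risk ratios, retained (if unapproved and inactive) in the approval
model.

Approval is US/EU approval of the drug together with indication-level
approval; when a drug is US/EU-approved for only some of its approved
indications, this over-assigns — a documented limitation inherited from
the structure of country-level approval data. Pairs collapse to one row
per (gene, indication) with the most advanced phase across drugs;
approval forces phase 4.

## Risk ratios and validation sets

For phases $y < x$, the risk ratio is
$(N_{g,x}/N_{g,y})/(N_{g',x}/N_{g',y})$ with at-or-beyond counting
("Phase $x$ or later") in both strata and in-progress pairs included.
Undefined ratios (an empty stratum) raise errors rather than returning
NaN, so sweeps over sparse strata fail loudly. Confidence intervals are
percentile bootstrap over pair-level resampling, 2000 replicates by
default, seeded; resamples with undefined ratios are dropped and
counted, and more than 50% undefined aborts.

Validation sets partition two snapshots: pairs with a known unapproved
phase in the old snapshot form the progression set (outcome: did the
pair advance); pairs absent or unknown-phase in the old snapshot form
the new-pipeline set; the new-genetic set re-scores all pairs using only
associations dated after per-source cut dates (defaults 2013-05-21 for
GWAS, 2013-10-01 for OMIM). Pairs approved at the old snapshot can no
longer advance, so progression is undefined for them and they join no
set.

## The approval model

For pair $i$ with outcome $y_i$ (US/EU approval):

$$y_i \sim \mathrm{Bernoulli}\left(\mathrm{logit}^{-1}(\alpha + \eta_i +
x_i'\beta)\right),\qquad
\eta_i = \begin{cases}\sum_{j=0}^{p}\gamma_j\,z_i^j & \text{gene}_i
\text{ has an association}\\ 0 & \text{otherwise}\end{cases}$$

with $z_i$ the standardized $E_C$, degree $p = 2$ by default (supported
by WAIC), priors $\alpha \sim N(-2.2, 0.75^2)$ — encoding the prior
knowledge that about 10% of Phase I compounds are eventually approved,
$\mathrm{logit}^{-1}(-2.2)=0.0997$ — and
$\beta_j, \gamma_j \sim N(0, 2^2)$. Continuous covariates and $E_C$ are
standardized to mean 0, SD 1. $E_C$ is standardized over associated
pairs only, since those are the only pairs where it enters the linear
predictor (standardizing over all pairs is available as an option).
Categorical covariates are one-hot encoded with the alphabetically first
level as reference and levels under 20 pairs pooled into `other`;
missing continuous covariates are imputed at the standardized mean with
a missingness indicator. Multiple evidence sources (GWAS, OMIM) can
enter the same model as separate $\eta$ blocks, each with its own
existence indicator and $\gamma$ vector; fitting sources jointly or in
separate models are both supported, as the original choice is not
documented.

The model universe keeps settled pairs only: approved pairs plus pairs
out of active development (an active program's outcome is unknown);
unapproved unknown-phase pairs are retained.

Sampling is a pluggable backend behind a contract: posterior draws plus
split-$\hat R \le 1.01$ and effective sample size $\ge 400$ per
parameter. The default backend is JAGS with its GLM samplers, 4 chains,
1000 warmup + 1000 kept draws per chain. With zero rows the posterior
equals the prior and is drawn from it directly. WAIC is computed from
pointwise log-likelihoods as $-2(\mathrm{lppd} - p_{\mathrm{WAIC}})$
with the variance-based effective-parameter term. The
odds-ratio-versus-similarity curve reports the pointwise posterior
median and 95% interval of $e^{\eta(s)}$; the reference (odds ratio 1)
is a pair with no association.

## What the synthetic data emulates — and what it does not

The generator produces a random rooted DAG ontology with cross-links
(so MICA is non-trivial), a gene universe with a protein-coding
fraction, dated association tables straddling the validation cut dates,
LD/eQTL/DHS/consequence side tables including deliberate
filter-violating rows, and drug bundles for two snapshots whose
approvals are sampled from the logistic model above, with $E_C$
computed through the package's own similarity code so the statistical
stages are exercised end to end. Default study conditions: a 120-term
ontology, 300 genes, 250 GWAS + 150 OMIM associations (half post-cut),
900 drugs, baseline $\alpha = -2.2$ (the 10% anchor), moderate effects
$\beta = (-0.3, 0.2)$, quadratic evidence coefficients
$\gamma_{\mathrm{OMIM}} = (0.5, 0.8, -0.3)$-scale, 25% phase progression
between snapshots.

It does **not** emulate realistic population LD structure, real MeSH
topology or depth, correlated indication portfolios, or time-varying
approval rates. Passing tests therefore demonstrate correctness of the
computations and calibration of the statistical machinery under the
stated generating model — not that real drug pipelines show a particular
effect size.

Two details matter when validating recovery end to end. First, the
generator standardizes covariates and $E_C$ empirically, exactly as the
model-fitting code does, so generating coefficients and fitted
coefficients share a scale. Second, excluding active unapproved pairs
selects on the outcome; this is equivalent to case-control subsampling
and biases only the intercept, so end-to-end recovery checks target the
$\gamma$ coefficients, while intercept recovery is checked on the
direct simulation harness where no selection occurs.

## Numerical and design choices

* Threshold semantics, fixed by the quoted conventions where they
  exist: GWAS $p \le 10^{-8}$ kept; eQTL strictly $< 10^{-6}$; LD
  $r^2$ thresholds inclusive; distance window closed; DHS cutoff
  inclusive at 0.001; $E_D$ switches at $E_C \ge$ cutoff.
* Bootstrap: percentile intervals, pair-level resampling; the bootstrap
  variant and replicate count are package policy (2000 default), as the
  original is unspecified beyond "bootstrap 95% CI".
* Problem sizes in the test suite are chosen to give stable checks on
  one CPU: oracle equivalence on 200 random DAGs of up to 12 terms;
  parameter recovery over 20 seeds at $N = 4000$ with 2 chains;
  WAIC degree selection over 20 seeds at $N = 2000$; bootstrap coverage
  over 500 replications of 1000 pairs with 500 resamples each.
* Degenerate inputs: empty association sets give `NA` evidence; empty
  strata raise errors; all-constant design columns are dropped with a
  warning; a zero-variance evidence block falls back to an identity
  standardization.

## Known limitations

The phase-precedence rules are a skeleton of the full (unpublished)
assignment logic; the string-matching details live in a configurable
mapping table rather than code. Approval over-assignment for partially
approved multi-indication drugs is inherited from the data model. The
similarity normalization is one of several defensible readings of
"standardized to have a maximum value of 1 for each trait"; the choice
is documented above and isolated in `combined_similarity()`.
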