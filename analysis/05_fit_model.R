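#!/usr/bin/env Rscript
# Fit the Bayesian logistic regression of approval on continuous genetic
# evidence (conditional quadratic term) and target/indication
# covariates, check the WAIC support for the quadratic degree, and write
# the posterior odds-ratio-versus-similarity curve.

library(genesupport)

out <- "results/synthetic"
cfg <- readRDS(file.path(out, "config.rds"))
genes <- read_tsv_table(file.path(out, "genes.tsv"))
new_pairs <- read_tsv_table(file.path(out, "pairs_new_scored.tsv"))

uni <- select_model_universe(new_pairs)
cat("model universe:", nrow(uni), "settled pairs of", nrow(new_pairs), "\n")

covs <- data.frame(
  dev_time = as.numeric(
    as.Date("2018-01-01") -
      as.Date(genes$first_development_date[match(uni$gene_id,
                                                 genes$gene_id)])) / 365,
  rvis = genes$rvis_percentile[match(uni$gene_id, genes$gene_id)])
design <- build_design(covs, evidence = list(all = as.numeric(uni$e_c)),
                       degree = 2)
spec <- model_spec(chains = 4, warmup = 1000, iter = 1000,
                   seed = cfg$seed %% 100000)
fit <- fit_approval_model(uni$y, design, spec)
print(fit)

w2 <- waic(fit)
d0 <- build_design(covs, evidence = list(all = as.numeric(uni$e_c)),
                   degree = 0)
f0 <- fit_approval_model(uni$y, d0, spec, strict = FALSE)
w0 <- waic(f0)
cat(sprintf("WAIC: quadratic evidence term %.1f vs constant term %.1f\n",
            w2$waic, w0$waic))

curve <- odds_ratio_curve(fit)
write_tsv_table(curve, file.path(out, "odds_ratio_curve.tsv"))
at1 <- curve[curve$similarity == 1, ]
cat(sprintf("posterior odds ratio at similarity 1: %.2f [%.2f, %.2f]\n",
            at1$or_median, at1$or_lo, at1$or_hi))
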