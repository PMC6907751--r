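#!/usr/bin/env Rscript
# Generate the synthetic study inputs: trait ontology, gene universe,
# dated GWAS/OMIM association tables with LD / eQTL / DHS / consequence
# side tables, and drug pipeline records over two snapshots whose
# approvals follow the logistic approval model with known parameters.
# Everything downstream (02-05) reads the tables written here.

library(genesupport)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260101)
graph <- generate_ontology(cfg)
genes <- generate_genes(cfg)
assoc <- generate_associations(cfg, graph, genes)

write_tsv_table(graph$edges, file.path(out, "ontology_edges.tsv"))
write_tsv_table(genes, file.path(out, "genes.tsv"))
for (nm in names(assoc)) {
  write_tsv_table(assoc[[nm]], file.path(out, paste0(nm, ".tsv")))
}
saveRDS(cfg, file.path(out, "config.rds"))

cat("ontology:", length(graph$terms), "terms /", nrow(graph$edges),
    "edges\n")
cat("genes:", nrow(genes), sprintf("(%.0f%% protein coding)\n",
    100 * mean(genes$protein_coding)))
cat("GWAS associations:", nrow(assoc$gwas), " OMIM:", nrow(assoc$omim),
    "\n")
cat("written to", out, "\n")
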