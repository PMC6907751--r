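#!/usr/bin/env Rscript
# Map SNP associations to genes and assemble the association set A:
# genome-wide significance filter (p <= 1e-8), OMIM curation filters,
# LD expansion at r2 >= 0.5, then distance (5 kb), eQTL (p < 1e-6) and
# DHS channels, restricted to protein-coding genes, with the
# deleterious-variant LD annotation used for the high-confidence subset.

library(genesupport)

out <- "results/synthetic"
cfg <- readRDS(file.path(out, "config.rds"))
genes <- read_tsv_table(file.path(out, "genes.tsv"))
genes$protein_coding <- as.logical(genes$protein_coding)
gwas_raw <- read_tsv_table(file.path(out, "gwas.tsv"))
omim_raw <- read_tsv_table(file.path(out, "omim.tsv"))
for (cc in c("provisional", "drug_response", "somatic")) {
  omim_raw[[cc]] <- as.logical(omim_raw[[cc]])
}

gwas <- filter_gwas(gwas_raw)
omim <- filter_omim(omim_raw)
cat("OMIM links kept:", nrow(omim), "of", nrow(omim_raw), "\n")

ld <- ld_expand(gwas$snp_id, read_tsv_table(file.path(out, "ld.tsv")))
snps <- read_tsv_table(file.path(out, "snps.tsv"))
channels <- rbind(
  link_by_distance(ld, snps, genes),
  link_by_eqtl(ld, read_tsv_table(file.path(out, "eqtl.tsv"))),
  link_by_dhs(ld, read_tsv_table(file.path(out, "dhs.tsv"))))
cat("channel links:", nrow(channels), "(",
    paste(names(table(channels$channel)), table(channels$channel)), ")\n")

links <- assemble_association_set(
  channels, gwas, omim, genes, ld_pairs = ld,
  consequences = read_tsv_table(file.path(out, "consequences.tsv")))
write_tsv_table(links, file.path(out, "links.tsv"))

del <- deleterious_subset(links)
cat("association set:", nrow(links), "links;",
    sum(links$source == "GWAS"), "GWAS /", sum(links$source == "OMIM"),
    "OMIM;", sum(del$source == "GWAS"),
    "GWAS links in high LD with a deleterious variant\n")
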