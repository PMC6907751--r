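gwas_fix <- function() {
  data.frame(snp_id = paste0("rs", 1:5), trait_heading = "t",
             p_value = c(1e-9, 1e-8, 5e-8, 1e-7, 0.04),
             date_added = "2015-01-01", stringsAsFactors = FALSE)
}

test_that("GWAS p-value filter keeps the 1e-8 boundary and drops above", {
  kept <- suppressMessages(filter_gwas(gwas_fix()))
  expect_identical(kept$snp_id, c("rs1", "rs2"))
  bad <- gwas_fix(); bad$p_value[1] <- 0
  expect_error(suppressMessages(filter_gwas(bad)), "nonpositive")
  # idempotent
  expect_identical(suppressMessages(filter_gwas(kept)), kept)
})

test_that("curated-link filter removes flagged rows only", {
  om <- data.frame(gene_id = paste0("g", 1:6), trait_heading = "t",
                   date_added = "2010-01-01",
                   provisional = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                   drug_response = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   somatic = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  kept <- filter_omim(om)
  expect_identical(kept$gene_id, c("g4", "g5", "g6"))
  expect_identical(filter_omim(kept), kept)
})

test_that("LD expansion is inclusive at the threshold and adds self-pairs", {
  ld <- data.frame(snp_a = c("rs1", "rs1", "rs2", "rs9"),
                   snp_b = c("p1", "p2", "p3", "p4"),
                   r2 = c(0.5, 0.49, 0.8, 0.99), stringsAsFactors = FALSE)
  out <- ld_expand(c("rs1", "rs2", "rs3"), ld, r2_threshold = 0.5)
  expect_true(all(c("rs1", "rs2", "rs3") %in%
                    out$ld_snp[out$lead_snp == out$ld_snp]))
  expect_true("p1" %in% out$ld_snp[out$lead_snp == "rs1"])   # r2 = 0.5 kept
  expect_false("p2" %in% out$ld_snp[out$lead_snp == "rs1"])  # r2 = 0.49 out
  expect_false("p4" %in% out$ld_snp)                          # not a lead
  # empty table: self-pairs only
  empty <- ld_expand("rs1", ld[0, ])
  expect_identical(empty$ld_snp, "rs1")
  expect_equal(empty$r2, 1)
  # brute-force scan over a random fixture
  set.seed(11)
  ld2 <- data.frame(snp_a = sample(paste0("rs", 1:4), 10, replace = TRUE),
                    snp_b = paste0("q", 1:10), r2 = round(runif(10), 2))
  out2 <- ld_expand(paste0("rs", 1:4), ld2, 0.5)
  manual <- ld2[ld2$r2 >= 0.5, ]
  for (i in seq_len(nrow(manual))) {
    expect_true(any(out2$lead_snp == manual$snp_a[i] &
                      out2$ld_snp == manual$snp_b[i]))
  }
  expect_equal(nrow(out2), nrow(manual) + 4)
})

test_that("distance linking uses a closed 5000 bp window around the gene body", {
  genes <- fixture_genes()
  snps <- data.frame(
    snp_id = c("s_at_edge", "s_past_edge", "s_inside", "s_far"),
    chromosome = "chr1",
    position = c(1000 - 5000, 1000 - 5001, 1500, 30000),
    stringsAsFactors = FALSE)
  ld <- data.frame(lead_snp = snps$snp_id, ld_snp = snps$snp_id, r2 = 1)
  out <- link_by_distance(ld, snps, genes)
  expect_setequal(out$lead_snp[out$gene_id == "g1"],
                  c("s_at_edge", "s_inside"))
  # missing position: skipped with a warning
  snps2 <- snps; snps2$position[3] <- NA
  expect_warning(out2 <- link_by_distance(ld, snps2, genes), "skipped")
  expect_false("s_inside" %in% out2$lead_snp)
  # brute-force interval oracle on a random fixture
  set.seed(5)
  rs <- data.frame(snp_id = paste0("x", 1:30), chromosome = "chr1",
                   position = sample.int(120000, 30))
  ldr <- data.frame(lead_snp = rs$snp_id, ld_snp = rs$snp_id, r2 = 1)
  got <- link_by_distance(ldr, rs, genes)
  for (i in seq_len(nrow(rs))) {
    for (j in which(genes$chromosome == "chr1")) {
      inwin <- rs$position[i] >= genes$start[j] - 5000 &
        rs$position[i] <= genes$end[j] + 5000
      expect_equal(any(got$lead_snp == rs$snp_id[i] &
                         got$gene_id == genes$gene_id[j]), inwin)
    }
  }
})

test_that("eQTL linking is strict below the cutoff; DHS inclusive at it", {
  ld <- data.frame(lead_snp = "rs1", ld_snp = "rs1", r2 = 1)
  eq <- data.frame(snp_id = "rs1", gene_id = c("g1", "g2"),
                   tissue = "liver", p_value = c(9.9e-7, 1e-6))
  out <- link_by_eqtl(ld, eq)
  expect_identical(out$gene_id, "g1")  # 1e-6 boundary excluded
  # stringent sensitivity configuration
  eq2 <- data.frame(snp_id = "rs1", gene_id = c("g1", "g2"),
                    tissue = "blood", p_value = c(1e-13, 1e-9))
  expect_identical(link_by_eqtl(ld, eq2, p_cutoff = 1e-12)$gene_id, "g1")
  dhs <- data.frame(snp_id = "rs1", gene_id = c("g1", "g2"),
                    perm_p = c(0.001, 0.5))
  expect_identical(link_by_dhs(ld, dhs)$gene_id, "g1")  # boundary kept
})

test_that("assembly deduplicates, accumulates channels, drops non-coding", {
  genes <- fixture_genes()
  ch <- data.frame(
    lead_snp = c("rs1", "rs1", "rs2"),
    gene_id = c("g1", "g1", "g3"),
    channel = c("distance", "eqtl", "distance"), stringsAsFactors = FALSE)
  gwas <- data.frame(snp_id = c("rs1", "rs2"), trait_heading = c("ta", "tb"),
                     p_value = 1e-9, date_added = c("2014-02-01", "2015-01-01"),
                     stringsAsFactors = FALSE)
  omim <- data.frame(gene_id = "g2", trait_heading = "tc",
                     date_added = "2001-01-01", stringsAsFactors = FALSE)
  ld <- data.frame(lead_snp = c("rs1", "rs1"), ld_snp = c("rs1", "rs1_mis"),
                   r2 = c(1, 0.93))
  cons <- data.frame(snp_id = c("rs1", "rs1_mis"),
                     severity = c("none", "MODERATE"))
  links <- assemble_association_set(ch, gwas, omim, genes,
                                    ld_pairs = ld, consequences = cons)
  g1 <- links[links$gene_id == "g1", ]
  expect_equal(nrow(g1), 1)                       # deduplicated
  expect_identical(g1$channels, "distance,eqtl")  # channels accumulated
  expect_equal(g1$deleterious_r2, 0.93)           # max r2 to deleterious
  expect_false("g3" %in% links$gene_id)           # non-coding removed
  expect_identical(links$channels[links$source == "OMIM"], "curated")
  # unknown gene ids are a loud error
  ch_bad <- rbind(ch, data.frame(lead_snp = "rs1", gene_id = "gX",
                                 channel = "dhs"))
  expect_error(assemble_association_set(ch_bad, gwas, omim, genes),
               "unknown gene_id.*gX")
})

test_that("deleterious subset is inclusive at 0.9, monotone, OMIM-exempt", {
  links <- data.frame(
    gene_id = paste0("g", 1:5), trait_heading = "t",
    source = c("GWAS", "GWAS", "GWAS", "GWAS", "OMIM"),
    channels = "distance", date_added = "2015-01-01",
    deleterious_r2 = c(0.9, 0.89, 0.95, NA, NA), stringsAsFactors = FALSE)
  out <- deleterious_subset(links)
  expect_setequal(out$gene_id, c("g1", "g3", "g5"))  # boundary kept; OMIM passes
  # monotone shrinkage over a threshold grid, always a subset
  prev <- links
  for (r2 in seq(0, 1, by = 0.1)) {
    cur <- deleterious_subset(links, r2_min = r2)
    expect_true(all(cur$gene_id %in% prev$gene_id))
    prev <- cur
  }
  expect_identical(deleterious_subset(out), out)  # idempotent
})
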