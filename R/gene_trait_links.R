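#' Filter GWAS-style SNP associations on reported p-value
#'
#' Associations with reported p-value greater than 1e-8 are excluded;
#' the boundary value 1e-8 itself is retained.
#'
#' @param associations data.frame with at least `snp_id`, `trait_heading`,
#'   `p_value`.
#' @param p_max maximum retained p-value (default 1e-8).
#' @return The retained rows. The number dropped is reported via
#'   `message()`.
#' @export
filter_gwas <- function(associations, p_max = 1e-8) {
  stopifnot(all(c("snp_id", "trait_heading", "p_value") %in% names(associations)))
  if (any(associations$p_value <= 0)) stop("nonpositive p-value in associations")
  keep <- associations$p_value <= p_max
  message(sum(!keep), " association(s) dropped by p-value filter")
  associations[keep, , drop = FALSE]
}

#' Filter curated gene-trait links
#'
#' Removes provisional associations, drug-response associations and
#' somatic-variant associations from an OMIM-style curated table.
#'
#' @param curated_links data.frame with logical columns `provisional`,
#'   `drug_response`, `somatic`.
#' @return The retained rows.
#' @export
filter_omim <- function(curated_links) {
  stopifnot(all(c("provisional", "drug_response", "somatic") %in%
                  names(curated_links)))
  drop <- curated_links$provisional | curated_links$drug_response |
    curated_links$somatic
  curated_links[!drop, , drop = FALSE]
}

#' LD-expand lead SNPs
#'
#' Augments each lead SNP with every SNP in linkage disequilibrium at
#' r-squared at or above the threshold (inclusive), plus the lead SNP
#' itself as a self-pair with r2 = 1. The LD table is treated as
#' symmetric regardless of storage orientation.
#'
#' @param lead_snps character vector of lead SNP ids.
#' @param ld_table data.frame (snp_a, snp_b, r2).
#' @param r2_threshold inclusion threshold in [0, 1] (default 0.5).
#' @return data.frame (lead_snp, ld_snp, r2).
#' @export
ld_expand <- function(lead_snps, ld_table, r2_threshold = 0.5) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1)
  lead_snps <- unique(as.character(lead_snps))
  out <- data.frame(lead_snp = lead_snps, ld_snp = lead_snps, r2 = 1)
  if (nrow(ld_table) > 0) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld_table)))
    if (any(ld_table$r2 < 0 | ld_table$r2 > 1)) stop("r2 outside [0, 1]")
    sym <- rbind(
      data.frame(lead_snp = ld_table$snp_a, ld_snp = ld_table$snp_b,
                 r2 = ld_table$r2),
      data.frame(lead_snp = ld_table$snp_b, ld_snp = ld_table$snp_a,
                 r2 = ld_table$r2)
    )
    sym <- sym[sym$lead_snp %in% lead_snps & sym$r2 >= r2_threshold, ]
    out <- rbind(out, sym)
  }
  # keep the strongest record per (lead, partner)
  out <- out[order(out$lead_snp, out$ld_snp, -out$r2), ]
  out[!duplicated(out[, c("lead_snp", "ld_snp")]), , drop = FALSE]
}

#' Link SNPs to genes by genomic distance
#'
#' A link is made when an LD SNP lies within `window_bp` of the gene body
#' (closed interval, 1-based inclusive coordinates) on the same
#' chromosome.
#'
#' @param ld_pairs data.frame (lead_snp, ld_snp, r2) from [ld_expand()].
#' @param snps SNP position table (snp_id, chromosome, position); LD SNPs
#'   missing from it are skipped with a warning.
#' @param genes gene table (gene_id, chromosome, start, end, ...).
#' @param window_bp flanking window in base pairs (default 5000).
#' @return data.frame (lead_snp, gene_id, channel = "distance").
#' @export
link_by_distance <- function(ld_pairs, snps, genes, window_bp = 5000) {
  stopifnot(window_bp >= 0)
  pos <- snps[match(ld_pairs$ld_snp, snps$snp_id), c("chromosome", "position")]
  nopos <- is.na(pos$position)
  if (any(nopos)) {
    warning(sum(nopos), " LD SNP(s) without position skipped")
  }
  dat <- cbind(ld_pairs[!nopos, , drop = FALSE], pos[!nopos, , drop = FALSE])
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    gin <- dat$chromosome == genes$chromosome[i] &
      dat$position >= genes$start[i] - window_bp &
      dat$position <= genes$end[i] + window_bp
    if (!any(gin)) return(NULL)
    data.frame(lead_snp = dat$lead_snp[gin], gene_id = genes$gene_id[i])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(lead_snp = character(), gene_id = character())
  }
  out$channel <- rep("distance", nrow(out))
  unique(out)
}

#' Link SNPs to genes through expression QTLs
#'
#' A link is made when any tissue record for the (SNP, gene) pair has
#' nominal p-value strictly below the cutoff.
#'
#' @param ld_pairs data.frame from [ld_expand()].
#' @param eqtl data.frame (snp_id, gene_id, tissue, p_value).
#' @param p_cutoff strict upper bound (default 1e-6; 1e-12 reproduces the
#'   stringent sensitivity variant).
#' @return data.frame (lead_snp, gene_id, channel = "eqtl").
#' @export
link_by_eqtl <- function(ld_pairs, eqtl, p_cutoff = 1e-6) {
  stopifnot(p_cutoff > 0)
  hit <- eqtl[eqtl$p_value < p_cutoff, c("snp_id", "gene_id")]
  m <- merge(ld_pairs[, c("lead_snp", "ld_snp")], hit,
             by.x = "ld_snp", by.y = "snp_id")
  out <- unique(m[, c("lead_snp", "gene_id")])
  out$channel <- rep("eqtl", nrow(out))
  out
}

#' Link SNPs to genes through DNase I hypersensitivity correlation
#'
#' A link is made when the SNP falls in a DHS whose activity is
#' correlated with the gene's expression at a one-sided permutation
#' p-value at or below the cutoff. With 1000 permutation replicates the
#' smallest attainable p-value is 0.001, the default cutoff.
#'
#' @param ld_pairs data.frame from [ld_expand()].
#' @param dhs data.frame (snp_id, gene_id, perm_p).
#' @param perm_p_cutoff inclusive cutoff in (0, 1] (default 0.001).
#' @return data.frame (lead_snp, gene_id, channel = "dhs").
#' @export
link_by_dhs <- function(ld_pairs, dhs, perm_p_cutoff = 0.001) {
  stopifnot(perm_p_cutoff > 0, perm_p_cutoff <= 1)
  hit <- dhs[dhs$perm_p <= perm_p_cutoff, c("snp_id", "gene_id")]
  m <- merge(ld_pairs[, c("lead_snp", "ld_snp")], hit,
             by.x = "ld_snp", by.y = "snp_id")
  out <- unique(m[, c("lead_snp", "gene_id")])
  out$channel <- rep("dhs", nrow(out))
  out
}

#' Assemble the gene-trait association set
#'
#' Combines GWAS channel links (distance, eQTL, DHS) with curated OMIM
#' links into one association set: deduplicated on (gene, trait, source)
#' with channels accumulated, restricted to protein-coding genes, and
#' annotated with `deleterious_r2`, the maximum r2 between any lead SNP
#' supporting the link and an LD partner whose predicted consequence is
#' HIGH or MODERATE.
#'
#' @param gwas_channel_links row-bound output of the `link_by_*`
#'   functions (lead_snp, gene_id, channel).
#' @param gwas filtered association table (snp_id, trait_heading,
#'   date_added, ...).
#' @param omim filtered curated table (gene_id, trait_heading,
#'   date_added, ...).
#' @param genes gene table with `gene_id` and logical `protein_coding`.
#' @param ld_pairs data.frame from [ld_expand()] used for the
#'   deleteriousness annotation.
#' @param consequences data.frame (snp_id, severity) with severity in
#'   HIGH, MODERATE, LOW, MODIFIER, none.
#' @return data.frame of links: gene_id, trait_heading, source, channels
#'   (comma-joined), date_added (earliest supporting date),
#'   deleterious_r2 (NA when no deleterious LD partner).
#' @export
assemble_association_set <- function(gwas_channel_links, gwas, omim, genes,
                                     ld_pairs = NULL, consequences = NULL) {
  all_gene <- unique(c(gwas_channel_links$gene_id, omim$gene_id))
  unknown <- setdiff(all_gene, genes$gene_id)
  if (length(unknown)) {
    stop("link(s) to unknown gene_id: ", paste(unknown, collapse = ", "))
  }
  coding <- genes$gene_id[genes$protein_coding]

  out <- NULL
  if (nrow(gwas_channel_links) > 0) {
    gl <- merge(gwas_channel_links,
                gwas[, c("snp_id", "trait_heading", "date_added")],
                by.x = "lead_snp", by.y = "snp_id")
    del <- .deleterious_r2_by_lead(ld_pairs, consequences)
    gl$del_r2 <- if (is.null(del)) NA_real_ else del[gl$lead_snp]
    sp <- split(gl, paste(gl$gene_id, gl$trait_heading, sep = "\r"))
    out <- do.call(rbind, lapply(sp, function(d) {
      data.frame(
        gene_id = d$gene_id[1], trait_heading = d$trait_heading[1],
        source = "GWAS",
        channels = paste(sort(unique(d$channel)), collapse = ","),
        date_added = min(as.character(d$date_added)),
        deleterious_r2 = if (all(is.na(d$del_r2))) NA_real_
                         else max(d$del_r2, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }))
  }
  if (nrow(omim) > 0) {
    sp <- split(omim, paste(omim$gene_id, omim$trait_heading, sep = "\r"))
    om <- do.call(rbind, lapply(sp, function(d) {
      data.frame(
        gene_id = d$gene_id[1], trait_heading = d$trait_heading[1],
        source = "OMIM", channels = "curated",
        date_added = min(as.character(d$date_added)),
        deleterious_r2 = NA_real_, stringsAsFactors = FALSE
      )
    }))
    out <- rbind(out, om)
  }
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), trait_heading = character(),
                      source = character(), channels = character(),
                      date_added = character(), deleterious_r2 = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[out$gene_id %in% coding, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# max r2 from each lead SNP to any HIGH/MODERATE-consequence LD partner
.deleterious_r2_by_lead <- function(ld_pairs, consequences) {
  if (is.null(ld_pairs) || is.null(consequences)) return(NULL)
  sev <- consequences$snp_id[consequences$severity %in% c("HIGH", "MODERATE")]
  hit <- ld_pairs[ld_pairs$ld_snp %in% sev, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(structure(numeric(0), names = character(0)))
  }
  tapply(hit$r2, hit$lead_snp, max)
}

#' Restrict GWAS links to those tagging deleterious variants
#'
#' Retains GWAS-source links whose lead SNP is in high LD (r2 at or above
#' `r2_min`, inclusive) with a variant predicted HIGH or MODERATE
#' deleterious. Curated OMIM links pass through unchanged.
#'
#' @param links association set from [assemble_association_set()].
#' @param r2_min inclusive LD threshold (default 0.9).
#' @return The retained links.
#' @export
deleterious_subset <- function(links, r2_min = 0.9) {
  stopifnot(r2_min >= 0, r2_min <= 1)
  keep <- links$source != "GWAS" |
    (!is.na(links$deleterious_r2) & links$deleterious_r2 >= r2_min)
  links[keep, , drop = FALSE]
}
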