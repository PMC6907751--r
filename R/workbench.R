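#' Run the end-to-end analysis on simulated or supplied data
#'
#' Orchestrates the stages in dependency order: simulate, similarity,
#' map-genes, score, assemble, partition, riskratio, fit, curve. Every
#' stage writes its table under `out_dir` and is recorded in a manifest
#' (parameters, seeds, file checksums). Stages can be skipped; a stage
#' whose inputs were skipped refuses to run.
#'
#' @param config a [sim_config()]; also carries the master seed.
#' @param out_dir output directory.
#' @param stages character vector of stages to run (default: all, in
#'   order).
#' @param fit_spec a [model_spec()] for the fit stage.
#' @param n_boot bootstrap replicates for the riskratio stage.
#' @param cutoff,min_count evidence-scoring parameters.
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("run_"),
                         stages = c("simulate", "similarity", "map_genes",
                                    "score", "assemble", "partition",
                                    "riskratio", "fit", "curve"),
                         fit_spec = model_spec(chains = 2, warmup = 600,
                                               iter = 700,
                                               seed = config$seed),
                         n_boot = 500, cutoff = 0.7, min_count = 5) {
  all_stages <- c("simulate", "similarity", "map_genes", "score",
                  "assemble", "partition", "riskratio", "fit", "curve")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(
    simulate = character(), similarity = "simulate",
    map_genes = "simulate", score = c("map_genes", "similarity"),
    assemble = "simulate", partition = "assemble",
    riskratio = c("partition", "score"), fit = c("partition", "score"),
    curve = "fit")
  for (s in stages) {
    missing_dep <- setdiff(deps[[s]], stages)
    if (length(missing_dep)) {
      stop("stage '", s, "' requires skipped stage(s): ",
           paste(missing_dep, collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list(); manifest <- list(seed = config$seed, stages = list())
  record <- function(name, params, files) {
    hashes <- lapply(files, function(f) unname(tools::md5sum(f)))
    names(hashes) <- basename(as.character(files))
    manifest$stages[[name]] <<- list(params = params, files = hashes)
  }

  if ("simulate" %in% stages) {
    art$graph <- generate_ontology(config)
    art$genes <- generate_genes(config)
    art$assoc <- generate_associations(config, art$graph, art$genes)
    write_tsv_table(art$graph$edges, file.path(out_dir, "ontology_edges.tsv"))
    write_tsv_table(art$genes, file.path(out_dir, "genes.tsv"))
    for (nm in names(art$assoc)) {
      write_tsv_table(art$assoc[[nm]], file.path(out_dir,
                                                 paste0(nm, ".tsv")))
    }
    record("simulate", list(n_terms = config$n_terms,
                            n_genes = config$n_genes),
           file.path(out_dir, c("ontology_edges.tsv", "genes.tsv")))
  }
  if ("similarity" %in% stages) {
    art$sf <- build_similarity_function(art$graph)
    record("similarity", list(terms = length(art$graph$terms)), character())
  }
  if ("map_genes" %in% stages) {
    gwas <- filter_gwas(art$assoc$gwas)
    omim <- filter_omim(art$assoc$omim)
    ld <- ld_expand(gwas$snp_id, art$assoc$ld, r2_threshold = 0.5)
    ch <- rbind(
      link_by_distance(ld, art$assoc$snps, art$genes),
      link_by_eqtl(ld, art$assoc$eqtl),
      link_by_dhs(ld, art$assoc$dhs))
    art$links <- assemble_association_set(ch, gwas, omim, art$genes,
                                          ld_pairs = ld,
                                          consequences = art$assoc$consequences)
    f <- file.path(out_dir, "links.tsv")
    write_tsv_table(art$links, f)
    record("map_genes", list(r2 = 0.5, eqtl_p = 1e-6, dhs_p = 0.001),
           f)
  }
  if ("assemble" %in% stages) {
    art$pipe <- generate_pipeline(config, art$genes, art$graph, art$links,
                                  art$sf)
    pb_old <- apply_target_exclusions(art$pipe$old, art$genes)
    pb_new <- apply_target_exclusions(art$pipe$new, art$genes)
    art$old_pairs <- collapse_to_pairs(pb_old, "old")
    art$new_pairs <- collapse_to_pairs(pb_new, "new")
    f <- file.path(out_dir, c("pairs_old.tsv", "pairs_new.tsv"))
    write_tsv_table(art$old_pairs, f[1]); write_tsv_table(art$new_pairs, f[2])
    record("assemble", list(n_drugs = config$n_drugs), f)
  }
  if ("score" %in% stages) {
    art$scored <- evidence_scores(art$new_pairs, art$links, art$sf,
                                  cutoff = cutoff, min_count = min_count)
    f <- file.path(out_dir, "evidence.tsv")
    write_tsv_table(art$scored, f)
    record("score", list(cutoff = cutoff, min_count = min_count), f)
  }
  if ("partition" %in% stages) {
    art$partition <- partition_validation_sets(
      art$old_pairs, art$new_pairs, art$links,
      gwas_cut_date = config$gwas_cut_date,
      omim_cut_date = config$omim_cut_date)
    record("partition", list(gwas_cut = config$gwas_cut_date,
                             omim_cut = config$omim_cut_date), character())
  }
  if ("riskratio" %in% stages) {
    sets <- list(full_data = art$partition$full_data)
    rows <- list()
    for (nm in names(sets)) {
      pr <- exclusions_for_twobytwo(sets[[nm]]$pairs)
      sc <- evidence_scores(pr, sets[[nm]]$links, art$sf, cutoff = cutoff,
                            min_count = min_count)
      sc <- sc[sc$eligible == 1L, , drop = FALSE]
      rr <- tryCatch(
        bootstrap_risk_ratio(sc$latest_phase, sc$e_d, from_phase = 1,
                             to_phase = 4, n_boot = n_boot,
                             seed = config$seed),
        error = function(e) NULL)
      if (!is.null(rr)) {
        rows[[nm]] <- data.frame(set = nm, from = 1, to = 4, rr = rr$rr,
                                 ci_low = rr$ci_low, ci_high = rr$ci_high,
                                 n = nrow(sc), stringsAsFactors = FALSE)
      }
    }
    art$riskratio <- do.call(rbind, rows)
    f <- file.path(out_dir, "riskratio.tsv")
    write_tsv_table(art$riskratio, f)
    record("riskratio", list(n_boot = n_boot), f)
  }
  if ("fit" %in% stages) {
    uni <- select_model_universe(art$new_pairs)
    sc <- evidence_scores(uni, art$links, art$sf, cutoff = cutoff,
                          min_count = min_count)
    genes <- art$genes
    covs <- data.frame(
      dev_time = as.numeric(
        as.Date("2018-01-01") -
          as.Date(genes$first_development_date[match(sc$gene_id,
                                                     genes$gene_id)])) / 365,
      rvis = genes$rvis_percentile[match(sc$gene_id, genes$gene_id)])
    design <- build_design(covs, evidence = list(all = sc$e_c),
                           degree = fit_spec$degree)
    art$fit <- fit_approval_model(sc$y, design, fit_spec, strict = FALSE)
    record("fit", list(chains = fit_spec$chains, degree = fit_spec$degree,
                       diagnostics_ok = art$fit$diagnostics_ok),
           character())
  }
  if ("curve" %in% stages) {
    art$curve <- odds_ratio_curve(art$fit)
    f <- file.path(out_dir, "odds_ratio_curve.tsv")
    write_tsv_table(art$curve, f)
    record("curve", list(grid = "0:1:0.01"), f)
  }
  manifest$completed <- stages
  art$manifest <- manifest
  saveRDS_path <- file.path(out_dir, "manifest.json")
  writeLines(.manifest_json(manifest), saveRDS_path)
  invisible(art)
}

# minimal JSON serialization for the manifest (names, numbers, strings)
.manifest_json <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  if (is.list(x)) {
    if (length(x) == 0) return("{}")
    items <- vapply(seq_along(x), function(i) {
      nm <- names(x)[i]
      val <- .manifest_json(x[[i]], indent + 1)
      paste0(pad, "  \"", nm, "\": ", val)
    }, character(1))
    return(paste0("{\n", paste(items, collapse = ",\n"), "\n", pad, "}"))
  }
  if (length(x) == 0) return("[]")
  enc <- function(v) {
    if (is.character(v)) paste0("\"", v, "\"") else format(v)
  }
  if (length(x) == 1) enc(x) else
    paste0("[", paste(vapply(x, enc, character(1)), collapse = ", "), "]")
}
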