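#' Simulation configuration
#'
#' Parameters of the synthetic study: a random trait ontology, a gene
#' universe, dated GWAS/OMIM-style association tables with LD, eQTL, DHS
#' and consequence side tables, and drug pipeline records over two
#' snapshots whose approvals are sampled from the approval model with
#' known parameters. Defaults give a small but fully exercised study:
#' a 120-term ontology, 300 genes, 250 GWAS and 150 OMIM associations
#' straddling the validation cut dates, 900 drugs, and generating model
#' alpha = -2.2 (the 10% baseline approval anchor) with moderate
#' covariate and evidence effects.
#'
#' @param seed integer master seed.
#' @param n_terms,max_children,depth,crosslink_rate ontology shape.
#' @param n_genes,protein_coding_frac gene universe.
#' @param n_gwas,n_omim association counts per source.
#' @param post_cut_frac fraction of associations dated after the cut
#'   dates (exercises the new-genetic partition).
#' @param deleterious_frac fraction of GWAS lead SNPs given a high-LD
#'   deleterious partner.
#' @param n_drugs,indications_per_drug pipeline size.
#' @param phase_marginals probabilities of latest phases 0-3 for
#'   unapproved pairs.
#' @param progress_frac fraction of old-snapshot pairs advanced one
#'   phase in the new snapshot.
#' @param active_frac fraction of drugs still in active development.
#' @param alpha,beta,gamma generating parameters of the approval model;
#'   `gamma` is a named list with one numeric vector (length degree + 1)
#'   per evidence source.
#' @param gwas_cut_date,omim_cut_date ISO dates splitting old from new
#'   associations.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_terms = 120, max_children = 5, depth = 5,
                       crosslink_rate = 0.1,
                       n_genes = 300, protein_coding_frac = 0.9,
                       n_gwas = 250, n_omim = 150, post_cut_frac = 0.5,
                       deleterious_frac = 0.3,
                       n_drugs = 900, indications_per_drug = 2,
                       phase_marginals = c(0.35, 0.3, 0.2, 0.15),
                       progress_frac = 0.25, active_frac = 0.3,
                       alpha = -2.2,
                       beta = c(dev_time = -0.3, rvis = 0.2),
                       gamma = list(GWAS = c(0.3, 0.6, -0.2),
                                    OMIM = c(0.5, 0.8, -0.3)),
                       gwas_cut_date = "2013-05-21",
                       omim_cut_date = "2013-10-01") {
  stopifnot(n_terms >= 2, depth <= n_terms, n_genes > 0,
            all(phase_marginals >= 0), post_cut_frac >= 0,
            post_cut_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a random rooted trait ontology
#'
#' Terms are attached under random parents at bounded depth; with
#' probability `crosslink_rate` a term receives a second parent,
#' producing the multi-parent structure that makes the most informative
#' common ancestor nontrivial. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return An [ontology_graph()].
#' @export
generate_ontology <- function(config) {
  set.seed(config$seed)
  n <- config$n_terms
  terms <- c("ROOT", sprintf("T%03d", seq_len(n - 1)))
  depth <- c(0, rep(NA_integer_, n - 1))
  parent <- character(0); child <- character(0)
  n_child <- integer(n)
  for (i in 2:n) {
    ok <- which(!is.na(depth[1:(i - 1)]) & depth[1:(i - 1)] < config$depth &
                  n_child[1:(i - 1)] < config$max_children)
    if (length(ok) == 0) ok <- 1L
    p <- if (length(ok) == 1) ok else sample(ok, 1)
    parent <- c(parent, terms[p]); child <- c(child, terms[i])
    n_child[p] <- n_child[p] + 1L
    depth[i] <- depth[p] + 1L
    if (stats::runif(1) < config$crosslink_rate && i > 3) {
      # second parent from shallower strata, avoiding cycles
      cand <- which(!is.na(depth[1:(i - 1)]) & depth[1:(i - 1)] < depth[i] &
                      seq_len(i - 1) != p)
      if (length(cand) > 0) {
        p2 <- if (length(cand) == 1) cand else sample(cand, 1)
        parent <- c(parent, terms[p2]); child <- c(child, terms[i])
      }
    }
  }
  ontology_graph(data.frame(parent = parent, child = child,
                            stringsAsFactors = FALSE), root = "ROOT")
}

#' Generate the synthetic gene universe
#'
#' @param config a [sim_config()].
#' @return data.frame (gene_id, chromosome, start, end, protein_coding,
#'   rvis_percentile, first_development_date).
#' @export
generate_genes <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  start <- sort(sample.int(5e7, n)) * 2L
  len <- sample(2000:200000, n, replace = TRUE)
  data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    chromosome = sample(paste0("chr", 1:4), n, replace = TRUE),
    start = start, end = start + len,
    protein_coding = stats::runif(n) < config$protein_coding_frac,
    rvis_percentile = round(stats::runif(n, 0, 100), 2),
    first_development_date = as.character(
      as.Date("1990-01-01") + sample.int(9000, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}

.random_dates <- function(n, post_frac, cut_date, seed_offset = 0) {
  cut <- as.Date(cut_date)
  post <- stats::runif(n) < post_frac
  d <- ifelse(post,
              as.character(cut + sample.int(1800, n, replace = TRUE)),
              as.character(cut - sample.int(3600, n, replace = TRUE)))
  d
}

#' Generate dated association tables and their side tables
#'
#' GWAS-style SNP associations (with LD, SNP position, eQTL, DHS and
#' consequence-severity side tables) and OMIM-style curated gene-trait
#' links. Association dates straddle the configured cut dates so the
#' new-genetic partition is non-empty; a configured fraction of GWAS
#' lead SNPs receive an LD partner with HIGH/MODERATE predicted
#' consequence at r2 of at least 0.9, exercising the deleterious subset.
#' A small number of rows violate each filter (p-value above threshold,
#' flagged OMIM rows, non-protein-coding genes) on purpose.
#'
#' @param config a [sim_config()].
#' @param graph the trait ontology.
#' @param genes the gene table from [generate_genes()].
#' @return List of data.frames: `gwas`, `omim`, `ld`, `snps`, `eqtl`,
#'   `dhs`, `consequences`.
#' @export
generate_associations <- function(config, graph, genes) {
  set.seed(config$seed + 2L)
  terms <- setdiff(graph$terms, graph$root)
  ng <- config$n_gwas
  snp_id <- sprintf("rs%05d", seq_len(ng))
  # 90% pass the genome-wide significance filter
  pass <- stats::runif(ng) < 0.9
  p_value <- ifelse(pass, 10^stats::runif(ng, -30, -8.01),
                    10^stats::runif(ng, -7.9, -2))
  gwas <- data.frame(
    snp_id = snp_id,
    trait_heading = sample(terms, ng, replace = TRUE),
    p_value = p_value,
    date_added = .random_dates(ng, config$post_cut_frac,
                               config$gwas_cut_date),
    study_type = sample(c("case_control", "quantitative", "other"), ng,
                        replace = TRUE, prob = c(0.5, 0.4, 0.1)),
    odds_ratio = round(exp(stats::rnorm(ng, 0.1, 0.2)), 3),
    stringsAsFactors = FALSE
  )
  # SNP positions: most lead SNPs placed near a random gene so the
  # distance channel fires; partners get nearby positions
  near_gene <- sample.int(nrow(genes), ng, replace = TRUE)
  pos <- genes$start[near_gene] +
    sample(-20000:20000, ng, replace = TRUE)
  snps <- data.frame(snp_id = snp_id,
                     chromosome = genes$chromosome[near_gene],
                     position = pmax(1, pos), stringsAsFactors = FALSE)
  # LD partners: 0-3 per lead
  ld <- do.call(rbind, lapply(seq_len(ng), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(snp_a = snp_id[i],
               snp_b = sprintf("%s_ld%d", snp_id[i], seq_len(k)),
               r2 = round(stats::runif(k, 0.2, 1), 3),
               stringsAsFactors = FALSE)
  }))
  partner_pos <- data.frame(
    snp_id = ld$snp_b,
    chromosome = snps$chromosome[match(ld$snp_a, snps$snp_id)],
    position = pmax(1, snps$position[match(ld$snp_a, snps$snp_id)] +
                      sample(-50000:50000, nrow(ld), replace = TRUE)),
    stringsAsFactors = FALSE)
  snps <- rbind(snps, partner_pos)
  # deleterious partners in high LD for a configured fraction of leads
  del_leads <- snp_id[stats::runif(ng) < config$deleterious_frac]
  if (length(del_leads) > 0) {
    del <- data.frame(snp_a = del_leads,
                      snp_b = paste0(del_leads, "_mis"),
                      r2 = round(stats::runif(length(del_leads), 0.9, 1), 3),
                      stringsAsFactors = FALSE)
    ld <- rbind(ld, del)
    snps <- rbind(snps, data.frame(
      snp_id = del$snp_b,
      chromosome = snps$chromosome[match(del$snp_a, snps$snp_id)],
      position = snps$position[match(del$snp_a, snps$snp_id)] + 100L,
      stringsAsFactors = FALSE))
  }
  consequences <- data.frame(
    snp_id = snps$snp_id,
    severity = ifelse(grepl("_mis$", snps$snp_id),
                      sample(c("HIGH", "MODERATE"), nrow(snps), replace = TRUE),
                      sample(c("LOW", "MODIFIER", "none"), nrow(snps),
                             replace = TRUE)),
    stringsAsFactors = FALSE)
  # functional channels on a subset of LD SNPs
  all_snps <- snps$snp_id
  ne <- max(1, round(length(all_snps) * 0.3))
  eqtl <- data.frame(
    snp_id = sample(all_snps, ne, replace = TRUE),
    gene_id = sample(genes$gene_id, ne, replace = TRUE),
    tissue = sample(c("liver", "blood", "brain"), ne, replace = TRUE),
    p_value = 10^stats::runif(ne, -12, -3),
    stringsAsFactors = FALSE)
  nd <- max(1, round(length(all_snps) * 0.15))
  dhs <- data.frame(
    snp_id = sample(all_snps, nd, replace = TRUE),
    gene_id = sample(genes$gene_id, nd, replace = TRUE),
    perm_p = sample(c(0.001, 0.01, 0.1, 0.5), nd, replace = TRUE,
                    prob = c(0.4, 0.2, 0.2, 0.2)),
    stringsAsFactors = FALSE)

  no <- config$n_omim
  omim <- data.frame(
    gene_id = sample(genes$gene_id, no, replace = TRUE),
    trait_heading = sample(terms, no, replace = TRUE),
    date_added = .random_dates(no, config$post_cut_frac,
                               config$omim_cut_date),
    provisional = stats::runif(no) < 0.08,
    drug_response = stats::runif(no) < 0.05,
    somatic = stats::runif(no) < 0.05,
    stringsAsFactors = FALSE)
  list(gwas = gwas, omim = omim, ld = ld, snps = snps, eqtl = eqtl,
       dhs = dhs, consequences = consequences)
}

#' Simulate approval data directly from the model
#'
#' The minimal harness behind parameter-recovery and calibration checks:
#' draws covariates and continuous evidence, standardizes them exactly
#' as [build_design()] will, and samples approvals from the logistic
#' model with the supplied truth.
#'
#' @param n number of pairs.
#' @param alpha intercept.
#' @param beta named numeric vector of covariate coefficients (on the
#'   standardized scale); covariates are drawn standard normal.
#' @param gamma named list of evidence-coefficient vectors per source.
#' @param assoc_rate probability a pair's gene carries an association
#'   per source.
#' @param seed integer seed.
#' @return List: `y`, `covariates` (data.frame), `evidence` (named list
#'   of E_C vectors with NA for no association), `truth`.
#' @export
simulate_approval_data <- function(n, alpha = -2.2,
                                   beta = c(dev_time = -0.3, rvis = 0.2),
                                   gamma = list(GWAS = c(0.3, 0.6, -0.2)),
                                   assoc_rate = 0.5, seed = 1) {
  set.seed(seed)
  d <- length(beta)
  X <- matrix(stats::rnorm(n * d), n, d)
  colnames(X) <- names(beta)
  Xs <- scale(X)
  lin <- alpha + if (d > 0) drop(Xs %*% beta) else 0
  evidence <- list()
  for (src in names(gamma)) {
    has <- stats::runif(n) < assoc_rate
    ec <- rep(NA_real_, n)
    ec[has] <- stats::rbeta(sum(has), 2, 2)
    z <- rep(0, n)
    z[has] <- drop(scale(ec[has]))
    g <- gamma[[src]]
    eta <- has * drop(outer(z, seq_along(g) - 1, `^`) %*% g)
    lin <- lin + eta
    evidence[[src]] <- ec
  }
  y <- stats::rbinom(n, 1, stats::plogis(lin))
  list(y = y, covariates = as.data.frame(X), evidence = evidence,
       truth = list(alpha = alpha, beta = beta, gamma = gamma))
}

#' Generate pipeline drug records for two snapshots
#'
#' Builds target-indication pairs, computes their true continuous
#' evidence through the package's own similarity and evidence code,
#' samples approval from the logistic model with the configured truth,
#' back-fills consistent drug records (approved pairs are phase 4; other
#' phases follow the configured marginals), and advances a configured
#' fraction of pairs between the old and new snapshots.
#'
#' @param config a [sim_config()].
#' @param genes gene table.
#' @param graph trait ontology.
#' @param links assembled association set (see
#'   [assemble_association_set()]).
#' @param sf similarity function from [build_similarity_function()].
#' @return List: `old` and `new` drug bundles (see
#'   [assign_latest_phase()]), `truth` (generating parameters, per-pair
#'   evidence and linear predictor, realized risk ratios by phase).
#' @export
generate_pipeline <- function(config, genes, graph, links, sf) {
  set.seed(config$seed + 3L)
  n_drugs <- config$n_drugs
  coding <- genes[genes$protein_coding, , drop = FALSE]
  terms <- setdiff(graph$terms, graph$root)
  # drugs -> targets and indications; pairs emerge from the join
  drug_id <- sprintf("D%04d", seq_len(n_drugs))
  target <- sample(coding$gene_id, n_drugs, replace = TRUE)
  n_ind <- pmax(1, stats::rpois(n_drugs, config$indications_per_drug - 1) + 1)
  di <- data.frame(
    drug_id = rep(drug_id, n_ind),
    indication_heading = sample(terms, sum(n_ind), replace = TRUE),
    stringsAsFactors = FALSE)
  di <- unique(di)
  pairs <- unique(data.frame(
    gene_id = target[match(di$drug_id, drug_id)],
    indication_heading = di$indication_heading, stringsAsFactors = FALSE))

  # evidence through the real scoring code
  sc <- evidence_scores(pairs, links, sf)
  ec <- sc$e_c
  has <- !is.na(ec)
  z <- rep(0, nrow(pairs))
  if (sum(has) > 1 && stats::sd(ec[has]) > 0) z[has] <- drop(scale(ec[has]))
  g <- config$gamma[[1]]
  if (!is.null(config$gamma[["OMIM"]])) g <- config$gamma[["OMIM"]]
  eta <- has * drop(outer(z, seq_along(g) - 1, `^`) %*% g)
  dev_time <- as.numeric(
    as.Date("2018-01-01") -
      as.Date(genes$first_development_date[match(pairs$gene_id,
                                                 genes$gene_id)])) / 365
  rvis <- genes$rvis_percentile[match(pairs$gene_id, genes$gene_id)]
  covs <- cbind(dev_time = drop(scale(dev_time)), rvis = drop(scale(rvis)))
  lin <- config$alpha + drop(covs %*% config$beta[colnames(covs)]) + eta
  approved <- stats::rbinom(nrow(pairs), 1, stats::plogis(lin))

  # phases: approved pairs are 4; others drawn from the marginals
  ph <- ifelse(approved == 1L, 4L,
               sample(0:3, nrow(pairs), replace = TRUE,
                      prob = config$phase_marginals))
  # old snapshot: de-advance progressed pairs by one phase
  progress <- stats::runif(nrow(pairs)) < config$progress_frac & ph > 0
  ph_old <- ifelse(progress, ph - 1L, ifelse(approved == 1L, 4L, ph))
  appr_old <- as.integer(approved == 1L & !progress)
  ph_old[appr_old == 0L & ph_old == 4L] <- 3L
  # a fraction of pairs are new to the new snapshot
  in_old <- stats::runif(nrow(pairs)) > 0.25

  new_bundle <- .pairs_to_bundle(pairs, ph, approved, config, "new")
  old_bundle <- .pairs_to_bundle(pairs[in_old, , drop = FALSE],
                                 ph_old[in_old], appr_old[in_old], config,
                                 "old")
  truth <- list(alpha = config$alpha, beta = config$beta,
                gamma = config$gamma,
                pairs = cbind(pairs, e_c = ec, eta = eta, lin = lin,
                              approved = approved, phase = ph))
  rr <- tryCatch(
    progression_risk_ratio(ph, sc$e_d, from_phase = 1, to_phase = 4)$rr,
    error = function(e) NA_real_)
  truth$realized_rr_phase1_to_approval <- rr
  list(old = old_bundle, new = new_bundle, truth = truth)
}

# back-fill one drug per pair (plus occasional second drug) into the
# bundle-of-tables layout the assembly module consumes
.pairs_to_bundle <- function(pairs, phase, approved, config, label) {
  n <- nrow(pairs)
  drug_id <- sprintf("%s_D%05d", toupper(label), seq_len(n))
  status <- c("Preclinical", "Phase I", "Phase II", "Phase III", "Approved")
  st <- status[phase + 1L]
  active <- approved == 0L & stats::runif(n) < config$active_frac
  drugs <- data.frame(drug_id = drug_id, global_status = st,
                      active = active, stringsAsFactors = FALSE)
  drug_targets <- data.frame(drug_id = drug_id, gene_id = pairs$gene_id,
                             non_human = FALSE, xmhc = FALSE,
                             stringsAsFactors = FALSE)
  drug_indications <- data.frame(drug_id = drug_id,
                                 indication_heading = pairs$indication_heading,
                                 approved = approved == 1L,
                                 stringsAsFactors = FALSE)
  country <- ifelse(approved == 1L,
                    sample(c("US", "EU"), n, replace = TRUE),
                    sample(c("US", "EU", "JP"), n, replace = TRUE))
  country_status <- data.frame(drug_id = drug_id, country = country,
                               status = st, stringsAsFactors = FALSE)
  # events for a subset (exercises the event precedence path)
  has_event <- stats::runif(n) < 0.4 & phase >= 1
  events <- data.frame(
    drug_id = drug_id[has_event],
    indication_heading = pairs$indication_heading[has_event],
    event_phase = status[pmax(1L, phase[has_event]) + 1L],
    stringsAsFactors = FALSE)
  clinical_details <- data.frame(
    drug_id = character(0), indication_heading = character(0),
    detail = character(0), stringsAsFactors = FALSE)
  list(drugs = drugs, drug_targets = drug_targets,
       drug_indications = drug_indications, country_status = country_status,
       events = events, clinical_details = clinical_details)
}
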