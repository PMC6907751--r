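# Fixture builders and independent brute-force oracles. The oracles use
# plain edge-list traversal (no package internals, no igraph) so that the
# ontology code is checked against a genuinely separate computation.

# diamond DAG: r -> a, r -> b, a -> c, b -> c
diamond_edges <- function() {
  data.frame(parent = c("r", "r", "a", "b"), child = c("a", "b", "c", "c"),
             stringsAsFactors = FALSE)
}

# 7-term tree: r -> (a, b); a -> (c, d); b -> (e, f)
seven_term_edges <- function() {
  data.frame(parent = c("r", "r", "a", "a", "b", "b"),
             child = c("a", "b", "c", "d", "e", "f"),
             stringsAsFactors = FALSE)
}

# brute-force descendant set by repeated edge-list expansion
oracle_descendants <- function(edges, term) {
  out <- character(0); frontier <- term
  repeat {
    nxt <- setdiff(edges$child[edges$parent %in% frontier], c(out, term))
    if (length(nxt) == 0) break
    out <- c(out, nxt); frontier <- nxt
  }
  sort(unique(out))
}

oracle_ancestors <- function(edges, term) {
  out <- term; frontier <- term
  repeat {
    nxt <- setdiff(edges$parent[edges$child %in% frontier], out)
    if (length(nxt) == 0) break
    out <- c(out, nxt); frontier <- nxt
  }
  sort(unique(out))
}

oracle_ic <- function(edges) {
  terms <- sort(unique(c(edges$parent, edges$child)))
  ic <- vapply(terms, function(t) {
    -log((length(oracle_descendants(edges, t)) + 1) / length(terms))
  }, numeric(1))
  ic
}

# exhaustive search over the intersection of ancestor sets
oracle_mica <- function(edges, ic, t1, t2) {
  common <- sort(intersect(oracle_ancestors(edges, t1),
                           oracle_ancestors(edges, t2)))
  common[which.max(ic[common])]
}

oracle_resnik <- function(edges, ic, t1, t2) {
  unname(ic[oracle_mica(edges, ic, t1, t2)])
}

oracle_lin <- function(edges, ic, t1, t2) {
  den <- ic[[t1]] + ic[[t2]]
  if (den == 0) 0 else 2 * oracle_resnik(edges, ic, t1, t2) / den
}

oracle_combined <- function(edges, ic, t1, t2) {
  if (ic[[t1]] == 0 || ic[[t2]] == 0) return(0)
  res <- oracle_resnik(edges, ic, t1, t2)
  min(max((oracle_lin(edges, ic, t1, t2) +
             (res / ic[[t1]] + res / ic[[t2]]) / 2) / 2, 0), 1)
}

# random rooted DAG on <= n_max terms; nodes attach to any predecessor,
# extra forward edges make some nodes multi-parent
random_dag_edges <- function(n_max = 12) {
  n <- sample(3:n_max, 1)
  terms <- c("r", paste0("t", seq_len(n - 1)))
  parent <- terms[vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))]
  edges <- data.frame(parent = parent, child = terms[2:n],
                      stringsAsFactors = FALSE)
  extra <- which(stats::runif(n - 1) < 0.3)
  for (i in extra) {
    node <- i + 1
    if (node <= 3) next
    cand <- setdiff(terms[seq_len(node - 1)], edges$parent[i])
    p2 <- if (length(cand) == 1) cand else sample(cand, 1)
    edges <- rbind(edges, data.frame(parent = p2, child = terms[node]))
  }
  unique(edges)
}

# two-by-two risk-ratio oracle by direct subsetting
oracle_rr <- function(phases, evidence, from, to) {
  a <- sum(evidence == 1 & phases >= to) / sum(evidence == 1 & phases >= from)
  b <- sum(evidence == 0 & phases >= to) / sum(evidence == 0 & phases >= from)
  a / b
}

# drug bundle fixture: three drugs over two genes and two indications
fixture_bundle <- function() {
  list(
    drugs = data.frame(
      drug_id = c("d1", "d2", "d3"),
      global_status = c("Phase II", "Preclinical", "Approved"),
      active = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE),
    drug_targets = data.frame(
      drug_id = c("d1", "d2", "d3"),
      gene_id = c("g1", "g1", "g2"),
      non_human = FALSE, xmhc = FALSE, stringsAsFactors = FALSE),
    drug_indications = data.frame(
      drug_id = c("d1", "d1", "d2", "d3"),
      indication_heading = c("i1", "i2", "i1", "i2"),
      approved = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE),
    country_status = data.frame(
      drug_id = c("d1", "d2", "d3"),
      country = c("US", "US", "EU"),
      status = c("Phase II", "Preclinical", "Approved"),
      stringsAsFactors = FALSE),
    events = data.frame(
      drug_id = "d1", indication_heading = "i2",
      event_phase = "Phase III", stringsAsFactors = FALSE),
    clinical_details = data.frame(
      drug_id = character(0), indication_heading = character(0),
      detail = character(0), stringsAsFactors = FALSE)
  )
}

fixture_genes <- function() {
  data.frame(gene_id = c("g1", "g2", "g3"),
             chromosome = "chr1", start = c(1000, 50000, 90000),
             end = c(2000, 60000, 95000),
             protein_coding = c(TRUE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}
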