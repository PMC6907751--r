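#' Pairwise gene-trait score S
#'
#' S((g1, t1), (g2, t2)) equals the trait similarity S_T(t1, t2) when the
#' two genes are identical and 0 otherwise.
#'
#' @param g1,t1 first gene and trait heading.
#' @param g2,t2 second gene and trait heading.
#' @param sf a [build_similarity_function()] object.
#' @param use_manual forwarded to [trait_similarity()].
#' @return Real in [0, 1].
#' @export
pair_score <- function(g1, t1, g2, t2, sf, use_manual = TRUE) {
  if (g1 != g2) {
    .check_terms(sf$graph, c(t1, t2))
    return(0)
  }
  trait_similarity(sf, t1, t2, use_manual = use_manual)
}

#' Continuous genetic evidence E_C
#'
#' The maximum pairwise score between the query and the association set:
#' the similarity between the query indication and the most similar trait
#' linked to the query gene. Returns `NA` when the gene has no
#' association at all in `A` — distinct from a score of 0 (a gene whose
#' best trait similarity is 0), because the approval model's evidence
#' term applies only to pairs whose gene carries some association.
#'
#' @param gene,trait the query target-indication pair.
#' @param links association set A (data.frame with `gene_id`,
#'   `trait_heading`).
#' @param sf a [build_similarity_function()] object.
#' @param use_manual forwarded to [trait_similarity()].
#' @return Real in [0, 1], or `NA_real_` when the gene is absent from A.
#' @export
continuous_evidence <- function(gene, trait, links, sf, use_manual = TRUE) {
  hit <- links$trait_heading[links$gene_id == gene]
  if (length(hit) == 0) return(NA_real_)
  max(trait_similarity(sf, trait, hit, use_manual = use_manual))
}

#' Binary genetic evidence E_D
#'
#' 1 if and only if E_C is at or above the similarity cutoff (default
#' 0.7; the preset `recalibrated` uses 0.73, the value matching the
#' original 0.7 decision boundary after a vocabulary-version change).
#' A gene with no association scores 0.
#'
#' @inheritParams continuous_evidence
#' @param cutoff similarity critical value in [0, 1], or the string
#'   `"recalibrated"` for 0.73.
#' @return 0 or 1.
#' @export
binary_evidence <- function(gene, trait, links, sf, cutoff = 0.7,
                            use_manual = TRUE) {
  cutoff <- .resolve_cutoff(cutoff)
  ec <- continuous_evidence(gene, trait, links, sf, use_manual = use_manual)
  as.integer(!is.na(ec) && ec >= cutoff)
}

.resolve_cutoff <- function(cutoff) {
  if (identical(cutoff, "recalibrated")) cutoff <- 0.73
  stopifnot(is.numeric(cutoff), cutoff >= 0, cutoff <= 1)
  cutoff
}

#' Eligibility by similar-association count
#'
#' The two-by-two analyses require at least `min_count` reported genetic
#' associations for traits similar to the query indication. By default
#' the count runs over all associations in A whose trait has similarity
#' at or above the cutoff to the indication, across all genes
#' (`per_gene = FALSE`); the alternative reading restricts the count to
#' the query gene's own associations.
#'
#' @inheritParams binary_evidence
#' @param min_count minimum association count (default 5).
#' @param per_gene count only associations of the query gene.
#' @return 0 or 1.
#' @export
eligible_by_association_count <- function(gene, trait, links, sf,
                                          cutoff = 0.7, min_count = 5,
                                          per_gene = FALSE,
                                          use_manual = TRUE) {
  stopifnot(min_count >= 0)
  cutoff <- .resolve_cutoff(cutoff)
  sub <- if (per_gene) links[links$gene_id == gene, , drop = FALSE] else links
  if (nrow(sub) == 0) return(as.integer(min_count == 0))
  sims <- trait_similarity(sf, trait, sub$trait_heading,
                           use_manual = use_manual)
  as.integer(sum(sims >= cutoff) >= min_count)
}

#' Score a table of target-indication pairs against an association set
#'
#' Vectorized driver over [continuous_evidence()] and friends; one row of
#' evidence per input pair.
#'
#' @param pairs data.frame with `gene_id` and `indication_heading`.
#' @param links association set A.
#' @param sf a [build_similarity_function()] object.
#' @param cutoff similarity critical value (default 0.7).
#' @param min_count eligibility association count (default 5).
#' @param per_gene forwarded to [eligible_by_association_count()].
#' @param use_manual forwarded to [trait_similarity()].
#' @return `pairs` with added columns `e_c` (NA = no association), `e_d`,
#'   `n_similar` (associations of the query gene with similarity at or
#'   above the cutoff), and `eligible`.
#' @export
evidence_scores <- function(pairs, links, sf, cutoff = 0.7, min_count = 5,
                            per_gene = FALSE, use_manual = TRUE) {
  cutoff <- .resolve_cutoff(cutoff)
  by_gene <- split(links$trait_heading, links$gene_id)
  # eligibility counts per unique indication (gene-independent by default)
  n <- nrow(pairs)
  e_c <- numeric(n); n_similar <- integer(n); eligible <- integer(n)
  elig_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    g <- pairs$gene_id[i]; t <- pairs$indication_heading[i]
    traits <- by_gene[[g]]
    if (is.null(traits)) {
      e_c[i] <- NA_real_; n_similar[i] <- 0L
    } else {
      sims <- trait_similarity(sf, t, traits, use_manual = use_manual)
      e_c[i] <- max(sims)
      n_similar[i] <- sum(sims >= cutoff)
    }
    key <- if (per_gene) paste(g, t, sep = "\r") else t
    if (is.null(elig_cache[[key]])) {
      elig_cache[[key]] <- eligible_by_association_count(
        g, t, links, sf, cutoff = cutoff, min_count = min_count,
        per_gene = per_gene, use_manual = use_manual)
    }
    eligible[i] <- elig_cache[[key]]
  }
  pairs$e_c <- e_c
  pairs$e_d <- as.integer(!is.na(e_c) & e_c >= cutoff)
  pairs$n_similar <- n_similar
  pairs$eligible <- eligible
  pairs
}
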