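#' Construct a rooted ontology DAG of trait headings
#'
#' Builds the hierarchical vocabulary over which trait-indication
#' similarities are computed. The graph must be a directed acyclic graph
#' with every term reachable from a single root; multiple parents are
#' allowed (as in MeSH, where one heading can sit under several tree
#' positions).
#'
#' @param edges data.frame with columns `parent`, `child` (character),
#'   one row per parent-to-child edge.
#' @param root root term identifier; if `NULL`, the unique term with no
#'   parent is used.
#' @return An object of class `ontology_graph` with elements `terms`,
#'   `edges`, `root`, the underlying `igraph` object, and a precomputed
#'   ancestor list (each term's ancestors include the term itself).
#' @export
ontology_graph <- function(edges, root = NULL) {
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (any(edges$parent == edges$child)) {
    stop("self-edge detected: ", edges$parent[edges$parent == edges$child][1])
  }
  terms <- sort(unique(c(edges$parent, edges$child)))
  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     directed = TRUE,
                                     vertices = terms)
  if (!igraph::is_dag(g)) {
    # name one edge on a cycle for the error message
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    stop("cycle detected involving edge ", ends[1], " -> ", ends[2])
  }
  indeg <- igraph::degree(g, mode = "in")
  if (is.null(root)) {
    cand <- names(indeg)[indeg == 0]
    if (length(cand) != 1L) {
      stop("expected exactly one parentless term, found: ",
           paste(cand, collapse = ", "))
    }
    root <- cand
  }
  if (!root %in% terms) stop("root term not in graph: ", root)
  reach <- igraph::subcomponent(g, root, mode = "out")
  if (length(reach) != length(terms)) {
    missing <- setdiff(terms, names(reach))
    stop("terms not reachable from root: ", paste(missing, collapse = ", "))
  }
  # ancestors of each term, inclusive of the term itself
  anc <- lapply(terms, function(t) {
    sort(names(igraph::subcomponent(g, t, mode = "in")))
  })
  names(anc) <- terms
  structure(
    list(terms = terms, edges = edges[, c("parent", "child")],
         root = root, graph = g, ancestors = anc),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$terms), "terms,", nrow(x$edges),
      "edges, root =", x$root, "\n")
  invisible(x)
}

#' Information content from descendant counts
#'
#' The information content of a heading is minus the log of the fraction
#' of the vocabulary at or below it: IC(c) = -ln((|descendants(c)| + 1) /
#' n_terms), with descendants counted once over the full DAG however many
#' paths reach them. The root has IC 0; leaves are maximal.
#'
#' @param graph an [ontology_graph()].
#' @return Named numeric vector of per-term IC values (natural log units).
#' @export
compute_information_content <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  n <- length(graph$terms)
  ic <- vapply(graph$terms, function(t) {
    # subcomponent includes the term itself, so |desc| + 1 = its size
    below <- length(igraph::subcomponent(graph$graph, t, mode = "out"))
    -log(below / n)
  }, numeric(1))
  ic
}

#' Most informative common ancestor of two headings
#'
#' Ancestor sets include the terms themselves. Ties on IC are broken by
#' lexicographic term identifier so results are deterministic.
#'
#' @param graph an [ontology_graph()].
#' @param ic named IC vector from [compute_information_content()].
#' @param t1,t2 term identifiers.
#' @return The identifier of the common ancestor with maximal IC.
#' @export
most_informative_common_ancestor <- function(graph, ic, t1, t2) {
  .check_terms(graph, c(t1, t2))
  common <- intersect(graph$ancestors[[t1]], graph$ancestors[[t2]])
  # common is never empty: the root is an ancestor of every term
  common <- sort(common)
  common[which.max(ic[common])]
}

.check_terms <- function(graph, ts) {
  bad <- setdiff(ts, graph$terms)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Resnik similarity: IC of the most informative common ancestor
#' @inheritParams most_informative_common_ancestor
#' @return Nonnegative real.
#' @export
resnik_similarity <- function(graph, ic, t1, t2) {
  unname(ic[most_informative_common_ancestor(graph, ic, t1, t2)])
}

#' Lin similarity: 2 IC(MICA) / (IC(t1) + IC(t2))
#'
#' Defined as 0 when IC(t1) + IC(t2) = 0 (both terms are the root).
#' @inheritParams most_informative_common_ancestor
#' @return Real in [0, 1].
#' @export
lin_similarity <- function(graph, ic, t1, t2) {
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) return(0)
  2 * resnik_similarity(graph, ic, t1, t2) / denom
}

#' Combined trait similarity
#'
#' Mean of the Lin similarity and a per-trait-normalized Resnik
#' similarity. Resnik is normalized so each trait's self-similarity is its
#' maximum: for the ordered pair (t1, t2) the normalized value is
#' Resnik(t1, t2) / IC(t1); the two orders are averaged to symmetrize.
#' The result is clipped to [0, 1]. Pairs involving a zero-IC term (the
#' root) score 0, including the root's self-pair, since normalization is
#' undefined there.
#'
#' @inheritParams most_informative_common_ancestor
#' @return Real in [0, 1].
#' @export
combined_similarity <- function(graph, ic, t1, t2) {
  ic1 <- ic[[t1]]; ic2 <- ic[[t2]]
  if (ic1 == 0 || ic2 == 0) return(0)
  res <- resnik_similarity(graph, ic, t1, t2)
  norm_res <- (res / ic1 + res / ic2) / 2
  lin <- 2 * res / (ic1 + ic2)
  min(max((lin + norm_res) / 2, 0), 1)
}

#' Build the trait-similarity function, with manual overrides
#'
#' Wraps an ontology and its IC table into a similarity function S_T.
#' Manually assigned similarities (an override table) replace the computed
#' values for the listed unordered pairs and are flagged `manual`; every
#' other pair is `computed`. Evaluation can exclude the manual entries to
#' quantify how much curation drives downstream results.
#'
#' @param graph an [ontology_graph()].
#' @param manual_overrides optional data.frame with columns `term_a`,
#'   `term_b`, `similarity` (values in [0, 1]).
#' @return Object of class `similarity_function`.
#' @export
build_similarity_function <- function(graph, manual_overrides = NULL) {
  ic <- compute_information_content(graph)
  ov <- NULL
  if (!is.null(manual_overrides) && nrow(manual_overrides) > 0) {
    stopifnot(all(c("term_a", "term_b", "similarity") %in%
                    names(manual_overrides)))
    .check_terms(graph, c(manual_overrides$term_a, manual_overrides$term_b))
    if (any(manual_overrides$similarity < 0 | manual_overrides$similarity > 1)) {
      stop("manual override similarity outside [0, 1]")
    }
    ov <- manual_overrides
    ov$key <- .pair_key(ov$term_a, ov$term_b)
  }
  structure(list(graph = graph, ic = ic, overrides = ov),
            class = "similarity_function")
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Evaluate the trait-similarity function
#'
#' @param sf a [build_similarity_function()] object.
#' @param t1,t2 term identifier vectors (recycled to common length).
#' @param use_manual if `FALSE`, manual overrides are ignored and the
#'   computed value returned for every pair.
#' @return Numeric vector of similarities in [0, 1].
#' @export
trait_similarity <- function(sf, t1, t2, use_manual = TRUE) {
  stopifnot(inherits(sf, "similarity_function"))
  n <- max(length(t1), length(t2))
  t1 <- rep_len(as.character(t1), n)
  t2 <- rep_len(as.character(t2), n)
  .check_terms(sf$graph, unique(c(t1, t2)))
  out <- vapply(seq_len(n), function(i) {
    combined_similarity(sf$graph, sf$ic, t1[i], t2[i])
  }, numeric(1))
  if (use_manual && !is.null(sf$overrides)) {
    m <- match(.pair_key(t1, t2), sf$overrides$key)
    hit <- !is.na(m)
    out[hit] <- sf$overrides$similarity[m[hit]]
  }
  out
}

#' Tabulate all pairwise similarities with provenance
#'
#' @param sf a [build_similarity_function()] object.
#' @param terms terms to tabulate (default: all).
#' @param use_manual include manual overrides (flagged in `provenance`).
#' @return data.frame (term_a, term_b, similarity, provenance) over all
#'   unordered pairs including self-pairs.
#' @export
similarity_table <- function(sf, terms = NULL, use_manual = TRUE) {
  if (is.null(terms)) terms <- sf$graph$terms
  idx <- which(upper.tri(diag(length(terms)), diag = TRUE), arr.ind = TRUE)
  ta <- terms[idx[, "row"]]; tb <- terms[idx[, "col"]]
  sim <- trait_similarity(sf, ta, tb, use_manual = use_manual)
  prov <- rep("computed", length(sim))
  if (use_manual && !is.null(sf$overrides)) {
    prov[.pair_key(ta, tb) %in% sf$overrides$key] <- "manual"
  }
  data.frame(term_a = ta, term_b = tb, similarity = sim,
             provenance = prov, stringsAsFactors = FALSE)
}
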