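#' Read a tab-separated table with required columns
#'
#' All module readers share this dialect: header row, tab separator, no
#' quoting surprises, character columns left as character.
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, required = character()) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("file ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  x
}

#' Write a table in the package's TSV dialect
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ontology edge list (child, parent)
#' @param path TSV with header columns `child`, `parent`.
#' @return data.frame (parent, child) ready for [ontology_graph()].
#' @export
read_ontology_edges <- function(path) {
  x <- read_tsv_table(path, c("child", "parent"))
  x[, c("parent", "child")]
}

#' Derive ontology edges from MeSH-style tree numbers
#'
#' A term's parents are the terms holding a tree number one level above
#' any of its own tree numbers (prefix relationship on dot-separated
#' positions). A term may hold several tree numbers and therefore
#' several parents. Top-level positions are attached to the given root.
#'
#' @param tree_numbers data.frame (term, tree_number), or a TSV path.
#' @param root identifier for the synthetic root term (default "ROOT").
#' @return data.frame (parent, child).
#' @export
edges_from_tree_numbers <- function(tree_numbers, root = "ROOT") {
  if (is.character(tree_numbers)) {
    tree_numbers <- read_tsv_table(tree_numbers, c("term", "tree_number"))
  }
  tn <- tree_numbers
  owner <- structure(tn$term, names = tn$tree_number)
  parent_num <- sub("\\.[^.]+$", "", tn$tree_number)
  top <- parent_num == tn$tree_number
  parent <- ifelse(top, root, unname(owner[parent_num]))
  if (anyNA(parent)) {
    stop("tree number(s) whose parent position has no owner: ",
         paste(tn$tree_number[is.na(parent)], collapse = ", "))
  }
  unique(data.frame(parent = parent, child = tn$term,
                    stringsAsFactors = FALSE))
}

#' Read a manual similarity-override table
#' @param path TSV with columns term_a, term_b, similarity.
#' @return data.frame.
#' @export
read_manual_overrides <- function(path) {
  read_tsv_table(path, c("term_a", "term_b", "similarity"))
}

#' Write a drug bundle to a directory of TSV files
#' @param bundle a drug bundle (see [assign_latest_phase()]).
#' @param dir output directory (created if needed).
#' @return The directory path.
#' @export
write_drug_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    write_tsv_table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' Read a drug bundle from a directory of TSV files
#' @param dir directory holding drugs.tsv, drug_targets.tsv,
#'   drug_indications.tsv, country_status.tsv, events.tsv,
#'   clinical_details.tsv.
#' @return A drug bundle list.
#' @export
read_drug_bundle <- function(dir) {
  req <- list(
    drugs = c("drug_id", "global_status", "active"),
    drug_targets = c("drug_id", "gene_id", "non_human", "xmhc"),
    drug_indications = c("drug_id", "indication_heading", "approved"),
    country_status = c("drug_id", "country", "status"),
    events = c("drug_id", "indication_heading", "event_phase"),
    clinical_details = c("drug_id", "indication_heading", "detail")
  )
  out <- lapply(names(req), function(nm) {
    read_tsv_table(file.path(dir, paste0(nm, ".tsv")), req[[nm]])
  })
  names(out) <- names(req)
  for (lc in c("active")) out$drugs[[lc]] <- as.logical(out$drugs[[lc]])
  out$drug_targets$non_human <- as.logical(out$drug_targets$non_human)
  out$drug_targets$xmhc <- as.logical(out$drug_targets$xmhc)
  out$drug_indications$approved <- as.logical(out$drug_indications$approved)
  out
}
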