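#' Default phase vocabulary
#'
#' Maps development-status strings to ordinal phase codes: 0 Preclinical,
#' 1-3 clinical trial phases, 4 US/EU approved. The mapping is data: pass
#' an extended version to the assembly functions when a source uses other
#' strings.
#'
#' @return Named integer vector.
#' @export
phase_map <- function() {
  c("Preclinical" = 0L, "Phase I" = 1L, "Phase II" = 2L, "Phase III" = 3L,
    "Approved" = 4L, "Registered" = 4L,
    "Phase I Clinical Trial" = 1L, "Phase II Clinical Trial" = 2L,
    "Phase III Clinical Trial" = 3L)
}

.phase_ordinal <- function(x, map = phase_map()) {
  out <- unname(map[as.character(x)])
  as.integer(out)
}

#' Assign a drug-indication pair its latest historical phase
#'
#' Precedence: (1) country-level status when the drug has a single
#' indication or is preclinical globally; (2) the maximum phase implied
#' by dated events matching the indication; (3) clinical-details hints,
#' used only when the other sources say nothing, since that field can
#' describe planned trials. Returns `NA` when no source applies.
#'
#' @param bundle drug-record bundle: a list of data.frames `drugs`
#'   (drug_id, global_status, active), `drug_targets` (drug_id, gene_id,
#'   non_human, xmhc), `drug_indications` (drug_id, indication_heading,
#'   approved), `country_status` (drug_id, country, status), `events`
#'   (drug_id, indication_heading, event_phase), `clinical_details`
#'   (drug_id, indication_heading, detail).
#' @param drug_id,indication the query drug-indication pair.
#' @param map phase vocabulary from [phase_map()].
#' @return Integer phase 0-4 or `NA`; attribute `source` records which
#'   rule fired (`country`, `event`, `clinical_details`).
#' @export
assign_latest_phase <- function(bundle, drug_id, indication,
                                map = phase_map()) {
  di <- bundle$drug_indications
  inds <- di$indication_heading[di$drug_id == drug_id]
  if (!indication %in% inds) {
    stop("indication ", indication, " not listed for drug ", drug_id)
  }
  gs <- bundle$drugs$global_status[bundle$drugs$drug_id == drug_id]
  preclinical <- length(gs) && !is.na(.phase_ordinal(gs[1], map)) &&
    .phase_ordinal(gs[1], map) == 0L

  cs <- bundle$country_status[bundle$country_status$drug_id == drug_id, ,
                              drop = FALSE]
  if ((length(inds) == 1L || preclinical) && nrow(cs) > 0) {
    ph <- .phase_ordinal(cs$status, map)
    if (any(!is.na(ph))) {
      return(structure(max(ph, na.rm = TRUE), source = "country"))
    }
  }
  ev <- bundle$events
  ev <- ev[ev$drug_id == drug_id & ev$indication_heading == indication, ,
           drop = FALSE]
  if (nrow(ev) > 0) {
    ph <- .phase_ordinal(ev$event_phase, map)
    if (any(!is.na(ph))) {
      best <- max(ph, na.rm = TRUE)
      if (best == 4L && nrow(cs) > 0 &&
          !any(.phase_ordinal(cs$status, map) == 4L, na.rm = TRUE)) {
        warning("drug ", drug_id, ": approval event but no approved status; ",
                "higher phase wins")
      }
      return(structure(best, source = "event"))
    }
  }
  cd <- bundle$clinical_details
  cd <- cd[cd$drug_id == drug_id & cd$indication_heading == indication, ,
           drop = FALSE]
  if (nrow(cd) > 0) {
    ph <- .phase_ordinal(cd$detail, map)
    if (any(!is.na(ph))) {
      return(structure(max(ph, na.rm = TRUE), source = "clinical_details"))
    }
  }
  structure(NA_integer_, source = "none")
}

.us_eu <- c("US", "EU")

#' US/EU approval flag for a drug-indication pair
#'
#' 1 when the drug is approved in the US or EU and the indication is
#' among its approved indications. When a drug is US/EU approved for one
#' but not all of its approved indications, this rule knowingly
#' over-assigns, because country-level approval is not indication
#' resolved in the source data.
#'
#' @inheritParams assign_latest_phase
#' @return 0 or 1.
#' @export
approval_flag <- function(bundle, drug_id, indication) {
  cs <- bundle$country_status
  us_eu_appr <- any(cs$drug_id == drug_id & cs$country %in% .us_eu &
                      cs$status == "Approved")
  di <- bundle$drug_indications
  ind_appr <- any(di$drug_id == drug_id &
                    di$indication_heading == indication & di$approved)
  as.integer(us_eu_appr && ind_appr)
}

#' Drop drugs with excluded targets
#'
#' Removes drugs with non-human or extended-MHC targets, and drugs with
#' targets not annotated protein coding; all bundle tables are filtered
#' to the surviving drugs.
#'
#' @inheritParams assign_latest_phase
#' @param genes gene table with `gene_id` and logical `protein_coding`.
#' @return The filtered bundle.
#' @export
apply_target_exclusions <- function(bundle, genes) {
  dt <- bundle$drug_targets
  coding <- genes$gene_id[genes$protein_coding]
  bad <- dt$non_human | dt$xmhc | !(dt$gene_id %in% coding)
  bad_drugs <- unique(dt$drug_id[bad])
  keep <- setdiff(unique(bundle$drugs$drug_id), bad_drugs)
  for (nm in names(bundle)) {
    bundle[[nm]] <- bundle[[nm]][bundle[[nm]]$drug_id %in% keep, ,
                                 drop = FALSE]
  }
  bundle
}

#' Collapse drug records to target-indication pairs
#'
#' One row per (gene target, indication): latest phase is the most
#' advanced phase attained by any contributing drug (unknown phases are
#' ignored unless all are unknown), approval is any US/EU approval, and
#' activity is any drug in active development. An approved pair is always
#' phase 4.
#'
#' @inheritParams assign_latest_phase
#' @param snapshot_label label recorded on every output row.
#' @return data.frame (gene_id, indication_heading, latest_phase,
#'   approved, approved_elsewhere, active, snapshot).
#' @export
collapse_to_pairs <- function(bundle, snapshot_label = "snapshot",
                              map = phase_map()) {
  du <- merge(bundle$drug_targets[, c("drug_id", "gene_id")],
              bundle$drug_indications[, c("drug_id", "indication_heading",
                                          "approved")],
              by = "drug_id")
  if (nrow(du) == 0) {
    return(data.frame(gene_id = character(), indication_heading = character(),
                      latest_phase = integer(), approved = integer(),
                      approved_elsewhere = integer(), active = integer(),
                      snapshot = character(), stringsAsFactors = FALSE))
  }
  cs <- bundle$country_status
  du$phase <- vapply(seq_len(nrow(du)), function(i) {
    as.integer(assign_latest_phase(bundle, du$drug_id[i],
                                   du$indication_heading[i], map))
  }, integer(1))
  du$appr <- vapply(seq_len(nrow(du)), function(i) {
    approval_flag(bundle, du$drug_id[i], du$indication_heading[i])
  }, integer(1))
  # approved somewhere, but not in the US/EU
  du$appr_elsewhere <- vapply(seq_len(nrow(du)), function(i) {
    other <- any(cs$drug_id == du$drug_id[i] & !(cs$country %in% .us_eu) &
                   cs$status == "Approved")
    as.integer(other && du$approved[i] && !du$appr[i])
  }, integer(1))
  act <- bundle$drugs$active[match(du$drug_id, bundle$drugs$drug_id)]
  du$act <- as.integer(act)

  sp <- split(du, paste(du$gene_id, du$indication_heading, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) {
    ph <- if (all(is.na(d$phase))) NA_integer_ else max(d$phase, na.rm = TRUE)
    appr <- as.integer(any(d$appr == 1L))
    if (appr == 1L) ph <- 4L
    data.frame(gene_id = d$gene_id[1],
               indication_heading = d$indication_heading[1],
               latest_phase = ph, approved = appr,
               approved_elsewhere = as.integer(any(d$appr_elsewhere == 1L) &&
                                                 appr == 0L),
               active = as.integer(any(d$act == 1L)),
               snapshot = snapshot_label, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id, out$indication_heading), , drop = FALSE]
}
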