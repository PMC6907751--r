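#' Two-by-two progression counts
#'
#' Counts of target-indication pairs at or beyond each of two phases,
#' split by binary genetic-evidence status ("Phase x or later"
#' semantics; pairs in progress are included).
#'
#' @param phases integer vector of latest phases (0-4).
#' @param evidence binary evidence vector aligned with `phases`.
#' @param from_phase the earlier phase (denominator).
#' @param to_phase the later phase (numerator); must exceed `from_phase`.
#' @return List with `n_ev_to`, `n_ev_from`, `n_no_to`, `n_no_from`.
#' @export
progression_counts <- function(phases, evidence, from_phase, to_phase) {
  stopifnot(length(phases) == length(evidence), to_phase > from_phase)
  if (anyNA(phases)) stop("unknown phases must be excluded before counting")
  ev <- evidence == 1
  list(
    n_ev_to = sum(ev & phases >= to_phase),
    n_ev_from = sum(ev & phases >= from_phase),
    n_no_to = sum(!ev & phases >= to_phase),
    n_no_from = sum(!ev & phases >= from_phase)
  )
}

#' Risk ratio of phase progression by genetic-evidence status
#'
#' The ratio of the probability of reaching `to_phase` or later, given
#' `from_phase` or later, between pairs with and without genetic
#' evidence: (N_ev,to / N_ev,from) / (N_no,to / N_no,from).
#'
#' @inheritParams progression_counts
#' @return List of class `risk_ratio` with `rr` and the counts.
#' @export
progression_risk_ratio <- function(phases, evidence, from_phase, to_phase) {
  ct <- progression_counts(phases, evidence, from_phase, to_phase)
  if (ct$n_ev_from == 0) {
    stop("risk ratio undefined: no pairs at or beyond phase ", from_phase,
         " in the evidence stratum")
  }
  if (ct$n_no_from == 0 || ct$n_no_to == 0) {
    stop("risk ratio undefined: ",
         if (ct$n_no_from == 0) "no pairs at or beyond the from-phase"
         else "no progressions",
         " in the no-evidence stratum")
  }
  rr <- (ct$n_ev_to / ct$n_ev_from) / (ct$n_no_to / ct$n_no_from)
  structure(list(rr = rr, counts = ct, from_phase = from_phase,
                 to_phase = to_phase), class = "risk_ratio")
}

#' @export
print.risk_ratio <- function(x, ...) {
  cat(sprintf("risk ratio %.3f (phase %d -> %d; evidence %d/%d, none %d/%d)\n",
              x$rr, x$from_phase, x$to_phase, x$counts$n_ev_to,
              x$counts$n_ev_from, x$counts$n_no_to, x$counts$n_no_from))
  if (!is.null(x$ci_low)) {
    cat(sprintf("  %d%% bootstrap CI [%.3f, %.3f], %d replicates (%d undefined dropped)\n",
                round(100 * x$level), x$ci_low, x$ci_high, x$n_boot,
                x$n_undefined))
  }
  invisible(x)
}

#' Percentile bootstrap confidence interval for the risk ratio
#'
#' Resamples target-indication pairs with replacement and recomputes the
#' risk ratio on each resample; the interval is the percentile interval
#' of the resampled ratios. Resamples on which the ratio is undefined
#' (an empty stratum) are dropped and counted; more than 50% undefined is
#' an error.
#'
#' @inheritParams progression_counts
#' @param n_boot number of bootstrap resamples (default 2000, minimum 100).
#' @param level interval level (default 0.95).
#' @param seed integer seed; the interval is reproducible bit-exact.
#' @return `risk_ratio` object with `ci_low`, `ci_high`, `n_boot`,
#'   `n_undefined`, `level` added.
#' @export
bootstrap_risk_ratio <- function(phases, evidence, from_phase, to_phase,
                                 n_boot = 2000, level = 0.95, seed = 1) {
  stopifnot(n_boot >= 100, level > 0, level < 1)
  est <- progression_risk_ratio(phases, evidence, from_phase, to_phase)
  n <- length(phases)
  rrs <- rep(NA_real_, n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ct <- progression_counts(phases[idx], evidence[idx], from_phase, to_phase)
    if (ct$n_ev_from > 0 && ct$n_no_from > 0 && ct$n_no_to > 0) {
      rrs[b] <- (ct$n_ev_to / ct$n_ev_from) / (ct$n_no_to / ct$n_no_from)
    }
  }
  ok <- !is.na(rrs)
  if (mean(ok) < 0.5) {
    stop("bootstrap failed: ", sum(!ok), " of ", n_boot,
         " resamples had an undefined risk ratio")
  }
  qs <- stats::quantile(rrs[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  est$ci_low <- qs[1]; est$ci_high <- qs[2]
  est$n_boot <- n_boot; est$n_undefined <- sum(!ok); est$level <- level
  est
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Did each pair progress between snapshots?
#'
#' A pair progressed when its latest phase in the new snapshot exceeds
#' its phase in the old snapshot. Pairs absent from the new snapshot are
#' treated as not progressed (and reported via `message()`).
#'
#' @param old_pairs,new_pairs pair tables from [collapse_to_pairs()].
#' @return `old_pairs` with column `progressed` (0/1) added; rows with
#'   unknown old phase are dropped (progression is undefined for them).
#' @export
progressed_since <- function(old_pairs, new_pairs) {
  old <- old_pairs[!is.na(old_pairs$latest_phase), , drop = FALSE]
  key_old <- paste(old$gene_id, old$indication_heading, sep = "\r")
  key_new <- paste(new_pairs$gene_id, new_pairs$indication_heading,
                   sep = "\r")
  m <- match(key_old, key_new)
  absent <- is.na(m)
  if (any(absent)) {
    message(sum(absent), " pair(s) absent from the new snapshot treated as",
            " not progressed")
  }
  new_phase <- new_pairs$latest_phase[m]
  old$progressed <- as.integer(!absent & !is.na(new_phase) &
                                 new_phase > old$latest_phase)
  old
}

#' Partition pairs and associations into validation sets
#'
#' Reproduces the data-partition scheme used to validate historical
#' claims on data unseen when they were made:
#' * `pipeline_progression` — pairs with a known, unapproved phase in the
#'   old snapshot, with outcome `progressed` (did the pair advance by the
#'   new snapshot);
#' * `new_pipeline` — pairs absent from the old snapshot or with unknown
#'   phase there, scored on the new snapshot;
#' * `new_genetic` — all new-snapshot pairs, but scored only with
#'   associations dated strictly after the per-source cut dates;
#' * `full_data` — all new-snapshot pairs with all associations.
#'
#' @param old_pairs,new_pairs pair tables from [collapse_to_pairs()].
#' @param links association set from [assemble_association_set()].
#' @param gwas_cut_date,omim_cut_date ISO-8601 cut dates for the
#'   new-genetic association subset (defaults: 2013-05-21 and
#'   2013-10-01).
#' @return List with elements `pipeline_progression`, `new_pipeline`,
#'   `new_genetic`, `full_data`; each carries a `pairs` table and a
#'   `links` table. Pipeline-set membership labels are mutually
#'   exclusive.
#' @export
partition_validation_sets <- function(old_pairs, new_pairs, links,
                                      gwas_cut_date = "2013-05-21",
                                      omim_cut_date = "2013-10-01") {
  key_old <- paste(old_pairs$gene_id, old_pairs$indication_heading,
                   sep = "\r")
  key_new <- paste(new_pairs$gene_id, new_pairs$indication_heading,
                   sep = "\r")
  m <- match(key_new, key_old)
  known_old <- !is.na(m) & !is.na(old_pairs$latest_phase[m])

  # approved-at-old pairs cannot advance beyond phase 4; progression is
  # undefined for them and they join no validation set
  old_sub <- old_pairs[!is.na(old_pairs$latest_phase) &
                         old_pairs$approved == 0L, , drop = FALSE]
  prog <- progressed_since(old_sub, new_pairs)
  new_pipe <- new_pairs[!known_old, , drop = FALSE]

  cut <- as.Date(ifelse(links$source == "GWAS", gwas_cut_date,
                        omim_cut_date))
  new_links <- links[as.Date(links$date_added) > cut, , drop = FALSE]

  list(
    pipeline_progression = list(pairs = prog, links = links),
    new_pipeline = list(pairs = new_pipe, links = links),
    new_genetic = list(pairs = new_pairs, links = new_links),
    full_data = list(pairs = new_pairs, links = links)
  )
}

#' Exclusions for the two-by-two analyses
#'
#' Removes pairs with unknown latest phase and pairs whose only
#' approvals lie outside the US and EU.
#'
#' @param pairs pair table from [collapse_to_pairs()].
#' @return The retained pairs.
#' @export
exclusions_for_twobytwo <- function(pairs) {
  keep <- !is.na(pairs$latest_phase) &
    !(pairs$approved_elsewhere == 1L & pairs$approved == 0L)
  pairs[keep, , drop = FALSE]
}
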