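test_that("risk ratio matches direct two-by-two counting", {
  # evidence stratum: 4 of 8 reach approval; none: 2 of 8 -> rr 2
  phases <- c(rep(4, 4), rep(1, 4), rep(4, 2), rep(1, 6))
  ev <- c(rep(1, 8), rep(0, 8))
  rr <- progression_risk_ratio(phases, ev, from_phase = 1, to_phase = 4)
  expect_equal(rr$rr, 2)
  expect_equal(rr$counts$n_ev_to, 4)
  expect_equal(rr$counts$n_no_from, 8)
  # identical progression in both strata: rr = 1
  rr1 <- progression_risk_ratio(c(4, 1, 4, 1), c(1, 1, 0, 0), 1, 4)
  expect_equal(rr1$rr, 1)
  # undefined strata are loud errors naming the stratum
  expect_error(progression_risk_ratio(c(4, 1), c(1, 1), 1, 4),
               "no-evidence stratum")
  expect_error(progression_risk_ratio(c(0, 4), c(1, 0), 1, 4),
               "evidence stratum")
  expect_error(progression_risk_ratio(c(4, NA), c(1, 0), 1, 4), "unknown")
})

test_that("risk ratio equals the brute-force oracle on random fixtures", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(30:120, 1)
    phases <- sample(0:4, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.5)
    for (tr in list(c(0, 1), c(1, 2), c(2, 3), c(1, 4), c(3, 4))) {
      ct <- progression_counts(phases, ev, tr[1], tr[2])
      if (ct$n_ev_from == 0 || ct$n_no_from == 0 || ct$n_no_to == 0) next
      got <- progression_risk_ratio(phases, ev, tr[1], tr[2])$rr
      expect_equal(got, oracle_rr(phases, ev, tr[1], tr[2]))
    }
    # at-or-beyond counts are non-increasing in the phase
    ns <- vapply(0:4, function(x) sum(ev == 1 & phases >= x), numeric(1))
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("bootstrap interval is seeded, degenerate-safe and brackets rr", {
  phases <- c(rep(4, 10), rep(1, 10), rep(4, 5), rep(1, 15))
  ev <- c(rep(1, 20), rep(0, 20))
  b1 <- bootstrap_risk_ratio(phases, ev, 1, 4, n_boot = 300, seed = 17)
  b2 <- bootstrap_risk_ratio(phases, ev, 1, 4, n_boot = 300, seed = 17)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_lte(b1$ci_low, b1$rr)
  expect_gte(b1$ci_high, b1$rr)
  # every pair progresses: the interval collapses to [1, 1]
  deg <- bootstrap_risk_ratio(rep(4, 40), rep(c(1, 0), 20), 1, 4,
                              n_boot = 200, seed = 1)
  expect_equal(c(deg$ci_low, deg$ci_high), c(1, 1))
  expect_error(bootstrap_risk_ratio(phases, ev, 1, 4, n_boot = 50),
               "n_boot")
  # interval narrows as the dataset grows (synthetic scaling ladder)
  widths <- vapply(c(40, 160, 640), function(m) {
    ph <- rep(phases, length.out = m); e <- rep(ev, length.out = m)
    b <- bootstrap_risk_ratio(ph, e, 1, 4, n_boot = 300, seed = 2)
    b$ci_high - b$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("progression between snapshots compares phases pairwise", {
  old <- data.frame(gene_id = c("g1", "g1", "g2", "g2", "g3", "g4"),
                    indication_heading = c("i1", "i2", "i1", "i2", "i1", "i1"),
                    latest_phase = c(2L, 2L, 1L, NA, 3L, 2L),
                    approved = 0L, stringsAsFactors = FALSE)
  new <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    indication_heading = c("i1", "i2", "i1", "i1"),
                    latest_phase = c(3L, 2L, 4L, 2L), stringsAsFactors = FALSE)
  out <- suppressMessages(progressed_since(old, new))
  expect_equal(nrow(out), 5)  # unknown-phase old row dropped
  got <- structure(out$progressed,
                   names = paste(out$gene_id, out$indication_heading))
  expect_equal(got[["g1 i1"]], 1L)  # 2 -> 3
  expect_equal(got[["g1 i2"]], 0L)  # 2 -> 2
  expect_equal(got[["g2 i1"]], 1L)  # 1 -> 4
  expect_equal(got[["g3 i1"]], 0L)  # 3 -> 2 (regression is not progression)
  expect_equal(got[["g4 i1"]], 0L)  # absent from new snapshot
})

test_that("validation-set partition matches the data-split scheme", {
  old <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    indication_heading = "i1",
                    latest_phase = c(2L, NA, 4L, 1L),
                    approved = c(0L, 0L, 1L, 0L), stringsAsFactors = FALSE)
  new <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                    indication_heading = "i1",
                    latest_phase = c(3L, 2L, 4L, 1L, 0L),
                    approved = c(0L, 0L, 1L, 0L, 0L),
                    stringsAsFactors = FALSE)
  links <- data.frame(gene_id = c("g1", "g2"), trait_heading = "t",
                      source = c("GWAS", "OMIM"),
                      date_added = c("2014-01-01", "2012-01-01"),
                      stringsAsFactors = FALSE)
  ps <- suppressMessages(partition_validation_sets(old, new, links))
  # known-phase unapproved old pairs form the progression set
  expect_setequal(ps$pipeline_progression$pairs$gene_id, c("g1", "g4"))
  expect_equal(ps$pipeline_progression$pairs$progressed[
    ps$pipeline_progression$pairs$gene_id == "g1"], 1L)
  # absent-or-unknown-in-old pairs form the new-pipeline set
  expect_setequal(ps$new_pipeline$pairs$gene_id, c("g2", "g5"))
  # progression and new-pipeline membership never overlaps
  expect_length(intersect(ps$pipeline_progression$pairs$gene_id,
                          ps$new_pipeline$pairs$gene_id), 0)
  # new-genetic keeps only associations dated after the per-source cuts
  expect_identical(ps$new_genetic$links$gene_id, "g1")
  expect_equal(nrow(ps$full_data$links), 2)
  expect_equal(nrow(ps$full_data$pairs), 5)
})

test_that("two-by-two exclusions drop unknown phase and non-US/EU-only approvals", {
  pairs <- data.frame(gene_id = paste0("g", 1:10),
                      indication_heading = "i1",
                      latest_phase = c(NA, NA, NA, 1:7),
                      approved = c(rep(0L, 9), 1L),
                      approved_elsewhere = c(0L, 0L, 0L, 1L, rep(0L, 6)),
                      stringsAsFactors = FALSE)
  out <- exclusions_for_twobytwo(pairs)
  expect_equal(nrow(out), 6)  # 3 unknown + 1 foreign-only approval dropped
  expect_false("g4" %in% out$gene_id)
  expect_true("g10" %in% out$gene_id)
  expect_identical(exclusions_for_twobytwo(out), out)
})
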