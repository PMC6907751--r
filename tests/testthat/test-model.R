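test_that("model universe keeps settled pairs only", {
  pairs <- data.frame(
    gene_id = paste0("g", 1:12), indication_heading = "i1",
    latest_phase = c(1:4, NA, NA, 1:4, NA, 2),
    approved = c(0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0),
    active =   c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0, 1),
    stringsAsFactors = FALSE)
  out <- select_model_universe(pairs)
  # active unapproved pairs excluded; approved kept even if active
  expect_setequal(out$gene_id,
                  c("g2", "g4", "g5", "g7", "g8", "g10", "g11"))
  # inactive unknown-phase pair included with y = 0
  expect_equal(out$y[out$gene_id == "g5"], 0)
  expect_identical(out$y, out$approved)
})

test_that("design building standardizes, encodes and imputes as documented", {
  covs <- data.frame(
    dev_time = c(rnorm(48), NA, NA),
    rvis = rnorm(50),
    target_class = rep(c("enzyme", "gpcr"), 25),
    constant = 1,
    stringsAsFactors = FALSE)
  ec <- ifelse(runif(50) < 0.5, runif(50), NA)
  expect_warning(
    des <- build_design(covs, evidence = list(GWAS = ec), degree = 2),
    "all-constant")
  X <- des$X
  expect_equal(mean(X[, "dev_time"]), 0, tolerance = 0.2)
  obs <- !is.na(covs$dev_time)
  expect_equal(mean(X[obs, "dev_time"]), 0, tolerance = 1e-9)
  expect_equal(sd(X[obs, "dev_time"]), 1, tolerance = 1e-9)
  expect_true("dev_time_missing" %in% colnames(X))
  expect_equal(X[49:50, "dev_time"], c(0, 0))    # imputed at the mean
  # one-hot with alphabetical reference: only the gpcr indicator remains
  expect_true("target_class.gpcr" %in% colnames(X))
  expect_false("target_class.enzyme" %in% colnames(X))
  expect_false("constant" %in% colnames(X))
  # evidence block: z standardized over associated pairs, 0 elsewhere
  b <- des$blocks$GWAS
  expect_equal(b$has, as.numeric(!is.na(ec)))
  expect_equal(mean(b$Z[b$has == 1, 2]), 0, tolerance = 1e-9)
  expect_equal(sd(b$Z[b$has == 1, 2]), 1, tolerance = 1e-2)
  expect_true(all(b$Z[b$has == 0, 2] == 0))
  expect_equal(b$Z[, 1], rep(1, 50))              # z^0 column
  expect_equal(b$Z[, 3], b$Z[, 2]^2)
  # rare levels pool into "other"
  covs2 <- data.frame(cl = c(rep("a", 30), rep("b", 15), rep("c", 5)))
  des2 <- build_design(covs2, pool_below = 20)
  expect_setequal(colnames(des2$X), "cl.other")
})

test_that("prior-only fit reproduces the intercept prior and 10% baseline", {
  des <- build_design(data.frame(),
                      evidence = list(GWAS = numeric(0)), degree = 2)
  spec <- model_spec(chains = 4, iter = 4000, seed = 5)
  fit <- fit_approval_model(integer(0), des, spec)
  a <- fit$draws[, "alpha"]
  expect_equal(median(a), -2.2, tolerance = 0.05)
  expect_equal(sd(a), 0.75, tolerance = 0.05)
  # implied baseline approval probability is about 10%
  expect_equal(plogis(-2.2), 0.0997, tolerance = 1e-3)
  expect_lt(abs(median(plogis(a)) - 0.0997), 0.01)
  g <- fit$draws[, "gamma_1[2]"]
  expect_equal(sd(g), 2, tolerance = 0.1)
})

test_that("a fitted model satisfies the diagnostic contract and permutation invariance", {
  sim <- simulate_approval_data(800, seed = 21)
  des <- build_design(sim$covariates, sim$evidence, degree = 2)
  fit <- fit_approval_model(sim$y, des,
                            model_spec(chains = 2, warmup = 1500, iter = 3000,
                                       seed = 21))
  expect_true(fit$diagnostics_ok)
  expect_true(all(fit$diagnostics$rhat <= 1.01, na.rm = TRUE))
  expect_true(all(fit$diagnostics$ess >= 400))
  # permuting rows leaves posterior summaries within sampler noise
  perm <- sample(length(sim$y))
  des2 <- build_design(sim$covariates[perm, , drop = FALSE],
                       lapply(sim$evidence, `[`, perm), degree = 2)
  fit2 <- fit_approval_model(sim$y[perm], des2,
                             model_spec(chains = 2, warmup = 1500, iter = 3000,
                                        seed = 22))
  m1 <- apply(fit$draws, 2, median); m2 <- apply(fit2$draws, 2, median)
  expect_equal(m1, m2, tolerance = 0.15)
})

test_that("WAIC matches an independent recomputation from saved log-likelihoods", {
  sim <- simulate_approval_data(400, seed = 31)
  des <- build_design(sim$covariates, sim$evidence, degree = 2)
  fit <- fit_approval_model(sim$y, des,
                            model_spec(chains = 2, warmup = 400, iter = 500,
                                       seed = 31), strict = FALSE)
  w <- waic(fit)
  # straightforward oracle recomputation from the draws themselves
  dr <- fit$draws
  Xs <- des$X; b <- des$blocks[[1]]
  lin <- sapply(seq_len(nrow(dr)), function(s) {
    eta <- b$has * (dr[s, "gamma_1[1]"] * b$Z[, 1] +
                      dr[s, "gamma_1[2]"] * b$Z[, 2] +
                      dr[s, "gamma_1[3]"] * b$Z[, 3])
    dr[s, "alpha"] + Xs %*% dr[s, paste0("beta[", 1:2, "]")] + eta
  })
  p <- plogis(lin)
  ll <- log(p)
  ll[sim$y == 0, ] <- log(1 - p[sim$y == 0, ])
  lppd <- sum(log(rowMeans(exp(ll))))
  p_waic <- sum(apply(ll, 1, var))
  expect_equal(w$waic, -2 * (lppd - p_waic), tolerance = 1e-6)
  expect_gt(w$se, 0)
  # identical fits give identical WAIC
  fit_b <- fit_approval_model(sim$y, des,
                              model_spec(chains = 2, warmup = 400, iter = 500,
                                         seed = 31), strict = FALSE)
  expect_equal(waic(fit_b)$waic, w$waic, tolerance = 1e-8)
  # too few draws is an error
  small <- fit; small$draws <- small$draws[1:50, ]
  expect_error(waic(small), "100")
})

test_that("odds-ratio curve equals the closed form on degenerate draws", {
  sim <- simulate_approval_data(200, seed = 41)
  des <- build_design(sim$covariates, sim$evidence, degree = 2)
  fit <- fit_approval_model(sim$y, des,
                            model_spec(chains = 2, warmup = 300, iter = 300,
                                       seed = 41), strict = FALSE)
  # single-draw fit: the curve is exp(g0 + g1 z + g2 z^2) exactly
  single <- fit
  single$draws <- fit$draws[1, , drop = FALSE]
  grid <- seq(0, 1, by = 0.1)
  cv <- odds_ratio_curve(single, grid = grid)
  b <- des$blocks[[1]]
  z <- (grid - b$center) / b$scale
  g <- fit$draws[1, paste0("gamma_1[", 1:3, "]")]
  expect_equal(cv$or_median, exp(g[1] + g[2] * z + g[3] * z^2),
               ignore_attr = TRUE)
  expect_equal(cv$or_lo, cv$or_hi, tolerance = 1e-12)
  # zero draws: curve identically 1
  zero <- fit
  zero$draws[, paste0("gamma_1[", 1:3, "]")] <- 0
  cz <- odds_ratio_curve(zero, grid = grid)
  expect_equal(cz$or_median, rep(1, length(grid)))
  expect_equal(cz$or_lo, rep(1, length(grid)))
  # credible band contains the median pointwise on the real fit
  cr <- odds_ratio_curve(fit, grid = grid)
  expect_true(all(cr$or_lo <= cr$or_median & cr$or_median <= cr$or_hi))
  expect_error(odds_ratio_curve(fit, source = "nope"), "unknown evidence")
})
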