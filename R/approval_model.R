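#' Select the modelling universe of target-indication pairs
#'
#' The approval model is fit on pairs whose outcome is settled: pairs
#' that are approved, or whose drugs are all out of active development
#' (a pair still in active development may yet be approved). Unapproved
#' pairs with unknown latest phase are retained — unlike the two-by-two
#' analyses, the model does not need a phase, only the approval outcome.
#'
#' @param pairs pair table from [collapse_to_pairs()].
#' @return The retained pairs with outcome column `y` added.
#' @export
select_model_universe <- function(pairs) {
  keep <- pairs$approved == 1L | pairs$active == 0L
  out <- pairs[keep, , drop = FALSE]
  out$y <- out$approved
  out
}

#' Approval-model specification
#'
#' Priors and sampler settings for the Bayesian logistic regression of
#' approval. The intercept prior N(-2.2, 0.75^2) encodes the prior
#' knowledge that roughly 10% of Phase I compounds are eventually
#' approved (plogis(-2.2) = 0.0997); coefficient priors N(0, 2^2) expect
#' moderate effects.
#'
#' @param degree polynomial degree p of the evidence term (default 2).
#' @param mu_a,sigma_a intercept prior mean and SD.
#' @param sigma_b covariate-coefficient prior SD.
#' @param sigma_g evidence-coefficient prior SD.
#' @param chains number of MCMC chains (default 4).
#' @param warmup,iter adaptation+burn-in and kept iterations per chain.
#' @param seed integer seed for the sampler.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(degree = 2, mu_a = -2.2, sigma_a = 0.75,
                       sigma_b = 2, sigma_g = 2, chains = 4,
                       warmup = 1000, iter = 1000, seed = 1) {
  stopifnot(degree >= 0, sigma_a > 0, sigma_b > 0, sigma_g > 0,
            chains >= 1, warmup >= 0, iter >= 1)
  structure(list(degree = degree, mu_a = mu_a, sigma_a = sigma_a,
                 sigma_b = sigma_b, sigma_g = sigma_g, chains = chains,
                 warmup = warmup, iter = iter, seed = seed),
            class = "model_spec")
}

#' Build the model design from pairs, covariates and evidence
#'
#' One-hot encodes categorical covariates (alphabetically first level as
#' reference, levels carried by fewer than `pool_below` pairs pooled
#' into `other`), standardizes continuous covariates to mean 0 / SD 1,
#' imputes missing continuous values at the standardized mean (0) with a
#' missingness-indicator column, and drops all-constant columns with a
#' warning. Each evidence source becomes a block holding the indicator
#' "the pair's gene has at least one association in A" and the
#' standardized continuous evidence E_C; by default E_C is standardized
#' over the associated pairs only (the only pairs where it enters the
#' linear predictor), `ec_standardize = "all"` uses every pair.
#'
#' @param covariates data.frame of per-pair covariates; character/factor
#'   columns are one-hot encoded, numeric columns standardized.
#' @param evidence named list (one element per source, e.g. `GWAS`,
#'   `OMIM`) of numeric E_C vectors aligned with the rows, `NA` meaning
#'   the gene has no association in that source's set.
#' @param degree polynomial degree of the evidence term.
#' @param ec_standardize `"associated"` (default) or `"all"`.
#' @param pool_below pool factor levels with fewer pairs than this into
#'   `"other"` (default 20).
#' @return List of class `model_design`: `X`, per-column metadata, and
#'   `blocks` (per source: `has`, `Z` basis matrix, `center`, `scale`).
#' @export
build_design <- function(covariates, evidence = list(), degree = 2,
                         ec_standardize = c("associated", "all"),
                         pool_below = 20) {
  ec_standardize <- match.arg(ec_standardize)
  n <- nrow(covariates)
  cols <- list(); centers <- numeric(0); scales <- numeric(0)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      miss <- is.na(v)
      ctr <- mean(v[!miss]); scl <- stats::sd(v[!miss])
      if (is.na(scl) || scl == 0) {
        warning("dropping all-constant column ", nm)
        next
      }
      z <- (v - ctr) / scl
      z[miss] <- 0
      cols[[nm]] <- z
      centers[nm] <- ctr; scales[nm] <- scl
      if (any(miss)) cols[[paste0(nm, "_missing")]] <- as.numeric(miss)
    } else {
      v <- as.character(v)
      tab <- table(v)
      v[v %in% names(tab)[tab < pool_below]] <- "other"
      lev <- sort(unique(v))
      if (length(lev) < 2) {
        warning("dropping all-constant column ", nm)
        next
      }
      for (l in lev[-1]) cols[[paste0(nm, ".", l)]] <- as.numeric(v == l)
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow = n, ncol = 0)
  colnames(X) <- names(cols)

  blocks <- list()
  for (src in names(evidence)) {
    ec <- evidence[[src]]
    stopifnot(length(ec) == n)
    has <- as.numeric(!is.na(ec))
    base <- if (ec_standardize == "associated") ec[has == 1] else
      ifelse(is.na(ec), 0, ec)
    ctr <- mean(base); scl <- stats::sd(base)
    if (is.na(scl) || scl == 0) { ctr <- 0; scl <- 1 }
    z <- ifelse(is.na(ec), 0, (ec - ctr) / scl)
    Z <- outer(z, 0:degree, `^`)  # column j+1 is z^j
    blocks[[src]] <- list(has = has, Z = Z, center = ctr, scale = scl)
  }
  structure(list(X = X, n = n, degree = degree, blocks = blocks),
            class = "model_design")
}

.jags_model_string <- function(d, blocks, degree, spec) {
  eta_terms <- vapply(seq_along(blocks), function(k) {
    sprintf("has_%d[i] * inprod(gamma_%d[1:%d], Z_%d[i,1:%d])",
            k, k, degree + 1, k, degree + 1)
  }, character(1))
  x_term <- if (d > 0) " + inprod(X[i,1:d], beta)" else ""
  eta <- if (length(eta_terms)) paste(" +", paste(eta_terms, collapse = " + "))
         else ""
  gamma_priors <- paste(vapply(seq_along(blocks), function(k) {
    sprintf("  for (j in 1:%d) { gamma_%d[j] ~ dnorm(0, %.10g) }",
            degree + 1, k, 1 / spec$sigma_g^2)
  }, character(1)), collapse = "\n")
  beta_prior <- if (d > 0)
    sprintf("  for (j in 1:d) { beta[j] ~ dnorm(0, %.10g) }",
            1 / spec$sigma_b^2) else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    logit(mu[i]) <- alpha", x_term, eta, "\n",
    "    y[i] ~ dbern(mu[i])\n",
    "  }\n",
    sprintf("  alpha ~ dnorm(%.10g, %.10g)\n", spec$mu_a, 1 / spec$sigma_a^2),
    beta_prior, "\n", gamma_priors, "\n}\n"
  )
}

#' Fit the Bayesian logistic approval model
#'
#' Posterior sampling of the approval model
#' y_i ~ Bernoulli(logit^-1(alpha + eta_i + x_i' beta)), where eta_i is a
#' degree-p polynomial in standardized continuous evidence for pairs
#' whose gene has an association (per source block) and 0 otherwise.
#' Sampling uses JAGS (glm module) behind a pluggable-backend contract:
#' a fit is accepted when split chains give Rhat at most 1.01 and every
#' parameter's effective sample size is at least `min_ess`. With
#' zero-row data the posterior equals the prior and is drawn from it
#' directly.
#'
#' @param y binary outcome vector.
#' @param design a [build_design()] object.
#' @param spec a [model_spec()].
#' @param strict error on diagnostic failure (default `TRUE`); when
#'   `FALSE` the fit is returned with `diagnostics_ok = FALSE`.
#' @param min_ess effective-sample-size floor (default 400).
#' @return Object of class `approval_fit`: `draws` (matrix, one column
#'   per parameter), `diagnostics`, `design`, `y`, `spec`.
#' @export
fit_approval_model <- function(y, design, spec = model_spec(),
                               strict = TRUE, min_ess = 400) {
  stopifnot(inherits(design, "model_design"), all(y %in% 0:1),
            length(y) == design$n)
  d <- ncol(design$X)
  K <- length(design$blocks)
  p1 <- design$degree + 1
  par_names <- c("alpha",
                 if (d > 0) paste0("beta[", seq_len(d), "]"),
                 unlist(lapply(seq_len(K), function(k)
                   paste0("gamma_", k, "[", seq_len(p1), "]"))))

  if (length(y) == 0) {
    # prior-only: the posterior is the prior; draw it exactly
    ndr <- spec$chains * spec$iter
    set.seed(spec$seed)
    draws <- cbind(
      alpha = stats::rnorm(ndr, spec$mu_a, spec$sigma_a),
      if (d > 0) matrix(stats::rnorm(ndr * d, 0, spec$sigma_b), ndr, d),
      if (K > 0) matrix(stats::rnorm(ndr * K * p1, 0, spec$sigma_g), ndr,
                        K * p1)
    )
    colnames(draws) <- par_names
    return(structure(list(draws = draws, diagnostics = NULL,
                          diagnostics_ok = TRUE, design = design, y = y,
                          spec = spec, prior_only = TRUE),
                     class = "approval_fit"))
  }
  if (length(y) < d + 5) stop("need at least d + 5 observations")

  dat <- list(N = length(y), y = as.integer(y))
  if (d > 0) { dat$X <- design$X; dat$d <- d }
  for (k in seq_len(K)) {
    dat[[paste0("has_", k)]] <- design$blocks[[k]]$has
    dat[[paste0("Z_", k)]] <- design$blocks[[k]]$Z
  }
  mstr <- .jags_model_string(d, design$blocks, design$degree, spec)
  rjags::load.module("glm", quiet = TRUE)
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed * 1000L + ch)
  })
  jm <- rjags::jags.model(textConnection(mstr), data = dat, inits = inits,
                          n.chains = spec$chains,
                          n.adapt = max(100, spec$warmup %/% 2),
                          quiet = TRUE)
  update(jm, max(100, spec$warmup - spec$warmup %/% 2), progress.bar = "none")
  monitors <- c("alpha", if (d > 0) "beta",
                if (K > 0) paste0("gamma_", seq_len(K)))
  samp <- rjags::coda.samples(jm, monitors, n.iter = spec$iter,
                              progress.bar = "none")

  draws <- as.matrix(samp)
  # coda drops the [1] index on length-1 vectors; restore canonical names
  lone <- match(c("beta", paste0("gamma_", seq_len(K))), colnames(draws))
  colnames(draws)[stats::na.omit(lone)] <-
    paste0(c("beta", paste0("gamma_", seq_len(K)))[!is.na(lone)], "[1]")
  draws <- draws[, par_names, drop = FALSE]
  diag <- .mcmc_diagnostics(samp, spec$chains)
  ok <- all(diag$rhat <= 1.01, na.rm = TRUE) && all(diag$ess >= min_ess)
  if (strict && !ok) {
    stop("MCMC diagnostics failed: max Rhat = ",
         signif(max(diag$rhat, na.rm = TRUE), 4), ", min ESS = ",
         signif(min(diag$ess), 4))
  }
  structure(list(draws = draws, diagnostics = diag, diagnostics_ok = ok,
                 design = design, y = y, spec = spec, prior_only = FALSE),
            class = "approval_fit")
}

# split-Rhat and effective sample size from a coda mcmc.list
.mcmc_diagnostics <- function(samp, chains) {
  split_list <- do.call(c, lapply(samp, function(ch) {
    n <- nrow(ch); h <- n %/% 2
    list(coda::mcmc(ch[seq_len(h), , drop = FALSE]),
         coda::mcmc(ch[(h + 1):(2 * h), , drop = FALSE]))
  }))
  split_list <- coda::mcmc.list(split_list)
  rhat <- tryCatch(
    coda::gelman.diag(split_list, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(samp[[1]])))
  ess <- coda::effectiveSize(samp)
  list(rhat = rhat, ess = ess)
}

#' @export
print.approval_fit <- function(x, ...) {
  cat("approval_fit:", nrow(x$draws), "draws x", ncol(x$draws),
      "parameters\n")
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  max Rhat %.4f, min ESS %.0f (%s)\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess),
                if (x$diagnostics_ok) "accepted" else "REJECTED"))
  }
  print(round(t(apply(x$draws, 2, stats::quantile,
                      c(0.025, 0.5, 0.975))), 3))
  invisible(x)
}

# N x S matrix of pointwise log-likelihood over posterior draws
.pointwise_loglik <- function(fit) {
  X <- fit$design$X; d <- ncol(X); K <- length(fit$design$blocks)
  p1 <- fit$design$degree + 1
  dr <- fit$draws
  lin <- matrix(dr[, "alpha"], nrow = length(fit$y),
                ncol = nrow(dr), byrow = TRUE)
  if (d > 0) {
    lin <- lin + X %*% t(dr[, paste0("beta[", seq_len(d), "]"), drop = FALSE])
  }
  for (k in seq_len(K)) {
    b <- fit$design$blocks[[k]]
    g <- dr[, paste0("gamma_", k, "[", seq_len(p1), "]"), drop = FALSE]
    lin <- lin + (b$has * b$Z) %*% t(g)
  }
  # log Bernoulli likelihood, numerically stable via plogis on log scale
  yy <- fit$y
  ll <- matrix(0, nrow(lin), ncol(lin))
  ll[yy == 1, ] <- stats::plogis(lin[yy == 1, , drop = FALSE], log.p = TRUE)
  ll[yy == 0, ] <- stats::plogis(-lin[yy == 0, , drop = FALSE], log.p = TRUE)
  ll
}

#' Widely applicable information criterion of a fit
#'
#' WAIC = -2 (lppd - p_waic), with lppd the sum of log pointwise
#' posterior predictive densities and p_waic the sum of pointwise
#' posterior variances of the log-likelihood. The standard error follows
#' from the pointwise contributions. Lower is better.
#'
#' @param fit an [fit_approval_model()] object.
#' @return List with `waic`, `se`, `lppd`, `p_waic`.
#' @export
waic <- function(fit) {
  stopifnot(inherits(fit, "approval_fit"))
  if (nrow(fit$draws) < 100) stop("need at least 100 posterior draws")
  ll <- .pointwise_loglik(fit)
  S <- ncol(ll)
  # log mean exp per row, stable
  mx <- apply(ll, 1, max)
  lppd_i <- mx + log(rowMeans(exp(ll - mx)))
  p_i <- apply(ll, 1, stats::var)
  elpd_i <- lppd_i - p_i
  list(waic = -2 * sum(elpd_i), se = 2 * sqrt(length(elpd_i) * stats::var(elpd_i)),
       lppd = sum(lppd_i), p_waic = sum(p_i))
}

#' Posterior odds-ratio curve over the similarity scale
#'
#' For each similarity value s on the grid, eta(s) is the evidence
#' polynomial evaluated at the standardized similarity z(s) (using the
#' standardization stored in the design); the curve reports the
#' pointwise posterior median and 95% interval of exp(eta(s)), the odds
#' ratio of approval relative to a pair with no genetic association
#' (eta = 0, odds ratio 1).
#'
#' @param fit an [fit_approval_model()] object.
#' @param grid similarity grid in [0, 1] (default 0, 0.01, ..., 1).
#' @param source evidence block name (default: the first block).
#' @param level credible level (default 0.95).
#' @return data.frame (similarity, or_median, or_lo, or_hi, source).
#' @export
odds_ratio_curve <- function(fit, grid = seq(0, 1, by = 0.01),
                             source = NULL, level = 0.95) {
  stopifnot(all(grid >= 0 & grid <= 1))
  blocks <- fit$design$blocks
  if (is.null(source)) source <- names(blocks)[1]
  b <- blocks[[source]]
  if (is.null(b)) stop("unknown evidence source: ", source)
  k <- match(source, names(blocks))
  p1 <- fit$design$degree + 1
  g <- fit$draws[, paste0("gamma_", k, "[", seq_len(p1), "]"), drop = FALSE]
  z <- (grid - b$center) / b$scale
  Z <- outer(z, seq_len(p1) - 1, `^`)
  eta <- Z %*% t(g)                       # grid x draws
  qs <- t(apply(exp(eta), 1, stats::quantile,
                c((1 - level) / 2, 0.5, 1 - (1 - level) / 2), names = FALSE))
  data.frame(similarity = grid, or_median = qs[, 2], or_lo = qs[, 1],
             or_hi = qs[, 3], source = source, stringsAsFactors = FALSE)
}
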