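#' Sampler and prior settings for the hierarchical count models
#'
#' The four models share one specification: a Poisson or negative binomial
#' likelihood with offset `log E_i`, fixed effects `b0..b6` under vague
#' Normal(0, 1000) priors, and optionally the Besag-York-Mollie pair of
#' random effects — an intrinsic CAR field `u` and an iid normal field `v` —
#' whose precisions get Gamma(0.0001, 0.0001) priors. The negative binomial
#' size parameter carries a weakly informative Gamma(0.01, 0.01) prior.
#'
#' @param family `"poisson"` or `"negbin"`.
#' @param spatial logical; add the `u + v` random-effect terms.
#' @param chains number of MCMC chains (>= 2).
#' @param iter iterations per chain, including burn-in.
#' @param burnin discarded iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed; chain c uses `seed + c`.
#' @param prior_beta_var prior variance of the fixed effects.
#' @param prior_tau_shape,prior_tau_rate Gamma prior on both precisions.
#' @param prior_theta_shape,prior_theta_rate Gamma prior on the NB size.
#' @return object of class `bhm_spec`.
#' @export
model_spec <- function(family = c("poisson", "negbin"), spatial = TRUE,
                       chains = 4, iter = 5000, burnin = 2500, thin = 1,
                       seed = 1L,
                       prior_beta_var = 1000,
                       prior_tau_shape = 1e-4, prior_tau_rate = 1e-4,
                       prior_theta_shape = 0.01, prior_theta_rate = 0.01) {
  family <- match.arg(family)
  stopifnot(chains >= 2, iter > burnin, burnin >= 200, thin >= 1)
  structure(list(family = family, spatial = spatial, chains = as.integer(chains),
                 iter = as.integer(iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_beta_var = prior_beta_var,
                 prior_tau_shape = prior_tau_shape,
                 prior_tau_rate = prior_tau_rate,
                 prior_theta_shape = prior_theta_shape,
                 prior_theta_rate = prior_theta_rate),
            class = "bhm_spec")
}

#' Per-observation log-likelihood of the count families
#'
#' Poisson with mean `E * rho`, or negative binomial parameterised so the
#' mean is `lambda = E * rho` and the variance `lambda + lambda^2 / size` —
#' the Poisson is its `size -> Inf` limit.
#'
#' @param Y non-negative integer counts.
#' @param E positive expected counts (offset).
#' @param rho relative risks (positive).
#' @param family `"poisson"` or `"negbin"`.
#' @param size NB size parameter (ignored for Poisson).
#' @return vector of log-densities, one per observation.
#' @export
loglik_count <- function(Y, E, rho, family = c("poisson", "negbin"), size = NULL) {
  family <- match.arg(family)
  if (any(Y < 0) || any(Y != round(Y))) stop("Y must be non-negative integers")
  if (any(E <= 0)) stop("E must be positive")
  lambda <- E * rho
  if (family == "poisson") return(stats::dpois(Y, lambda, log = TRUE))
  if (is.null(size) || size <= 0) stop("negbin needs size > 0")
  stats::dnbinom(Y, size = size, mu = lambda, log = TRUE)
}

#' Fit a Bayesian hierarchical count model to village supply counts
#'
#' Runs the MCMC sampler for the model described in [model_spec()] on the
#' modelled villages (those with `E_i > 0`). The ICAR field uses the queen
#' contiguity graph; its conditional for village i is normal around the
#' neighbour mean with variance `sigma_u^2 / N_i`, and the field is kept
#' identifiable against the intercept by per-iteration recentring (the
#' sum-to-zero constraint) when the graph is island-free. Covariates enter
#' as store count, log(income), and the four land-use fractions; internally
#' they are mean-centred for sampling and the intercept is transformed back,
#' so reported coefficients are on the original scale.
#'
#' @param villages a `village_frame` with `Y`, `E` (from [expected_counts()])
#'   and covariates.
#' @param adj an [build_adjacency()] object matching the frame's village
#'   order; optional for non-spatial models.
#' @param spec a [model_spec()].
#' @return A `bhm_fit` with posterior draws (`$draws`: `beta`, `u`, `v`,
#'   `tau_u`, `tau_v`, `theta`, `rho`), the per-draw log-likelihood matrix,
#'   summary tables, exceedance probabilities `Pr(rho < 1)`, and
#'   convergence diagnostics (split across chains). Non-convergence (R-hat
#'   above 1.1 on a fixed effect) is warned about and flagged, never
#'   silent.
#' @export
fit_bhm <- function(villages, adj = NULL, spec = model_spec()) {
  stopifnot(inherits(villages, "village_frame"), inherits(spec, "bhm_spec"))
  d <- villages$data
  if (is.null(d$Y) || is.null(d$E)) stop("villages need Y and E; run allocation and expected_counts")
  modeled <- if (!is.null(d$modeled)) d$modeled else d$E > 0
  if (spec$spatial && is.null(adj)) adj <- build_adjacency(villages)
  keep <- which(modeled)
  Y <- as.numeric(d$Y[keep])
  if (any(Y != round(Y))) stop("Y must be integer-valued")
  E <- d$E[keep]
  X <- village_design(villages)[keep, , drop = FALSE]
  p <- ncol(X)

  if (spec$spatial) {
    adj_m <- subset_adjacency(adj, keep)
    crs <- adjacency_crs(adj_m)
    non_island <- adj_m$N > 0
    comp_sizes <- table(adj_m$components[non_island])
    icar_rank <- sum(non_island) - length(comp_sizes)
    recenter <- all(non_island)
  } else {
    adj_m <- NULL
    crs <- list(idx = integer(0), ptr = integer(length(Y) + 1))
    icar_rank <- 0L
    recenter <- FALSE
  }

  xbar <- c(0, colMeans(X[, -1, drop = FALSE]))
  Xc <- sweep(X, 2, xbar)

  # start every chain near the aspatial GLM mode (jittered)
  beta_mle <- tryCatch(
    stats::glm.fit(Xc, Y, family = stats::poisson(), offset = log(E))$coefficients,
    error = function(e) c(log(sum(Y) / sum(E) + 1e-10), rep(0, p - 1)))
  beta_mle[!is.finite(beta_mle)] <- 0
  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch)
    beta_init <- beta_mle + stats::rnorm(p, 0, 0.05)
    theta_init <- exp(stats::rnorm(1, log(5), 0.2))
    chains[[ch]] <- bym_mcmc(
      Y, log(E), Xc, crs$idx, crs$ptr, as.numeric(if (spec$spatial) adj_m$N else rep(0, length(Y))),
      spec$spatial, spec$family == "negbin",
      spec$iter, spec$burnin, spec$thin,
      spec$prior_beta_var, spec$prior_tau_shape, spec$prior_tau_rate,
      spec$prior_theta_shape, spec$prior_theta_rate,
      icar_rank, recenter, beta_init, theta_init)
  }

  # transform the intercept back to the uncentred covariate scale
  for (ch in seq_along(chains)) {
    b <- chains[[ch]]$beta
    b[, 1] <- b[, 1] - as.vector(b[, -1, drop = FALSE] %*% xbar[-1])
    chains[[ch]]$beta_orig <- b
  }

  beta_all <- do.call(rbind, lapply(chains, `[[`, "beta_orig"))
  colnames(beta_all) <- colnames(X)
  n_keep <- nrow(chains[[1]]$beta)

  # rho draws: n x S
  rho <- exp(X %*% t(beta_all))
  if (spec$spatial) {
    u_all <- do.call(rbind, lapply(chains, `[[`, "u"))
    v_all <- do.call(rbind, lapply(chains, `[[`, "v"))
    rho <- rho * exp(t(u_all) + t(v_all))
    tau_u_all <- unlist(lapply(chains, `[[`, "tau_u"))
    tau_v_all <- unlist(lapply(chains, `[[`, "tau_v"))
  } else {
    u_all <- v_all <- NULL
    tau_u_all <- tau_v_all <- NULL
  }
  theta_all <- if (spec$family == "negbin") unlist(lapply(chains, `[[`, "theta")) else NULL

  loglik <- loglik_matrix(Y, E, rho, spec$family, theta_all)

  diag_tbl <- bhm_diagnostics(chains, spec, colnames(X))
  converged <- all(diag_tbl$rhat[diag_tbl$group == "fixed"] < 1.1, na.rm = TRUE)
  if (!converged)
    warning("R-hat > 1.1 on at least one fixed effect; inspect $diagnostics")

  fit <- structure(list(
    spec = spec,
    village_id = d$village_id[keep], modeled_index = keep,
    Y = Y, E = E, X = X,
    adjacency = adj_m,
    draws = list(beta = beta_all, u = u_all, v = v_all,
                 tau_u = tau_u_all, tau_v = tau_v_all, theta = theta_all,
                 rho = rho),
    n_chains = spec$chains, n_keep = n_keep,
    loglik = loglik,
    diagnostics = diag_tbl,
    converged = converged,
    accept_beta = mean(vapply(chains, `[[`, numeric(1), "accept_beta"))
  ), class = "bhm_fit")
  fit$summary <- summarize_bhm(fit)
  fit$rho_summary <- summarize_rho(fit)
  fit
}

loglik_matrix <- function(Y, E, rho, family, theta_all) {
  lambda <- E * rho
  if (family == "poisson") {
    matrix(stats::dpois(rep(Y, ncol(rho)), lambda, log = TRUE), nrow = length(Y))
  } else {
    th <- rep(theta_all, each = length(Y))
    matrix(stats::dnbinom(rep(Y, ncol(rho)), size = th, mu = lambda, log = TRUE),
           nrow = length(Y))
  }
}

# split the pooled scalar parameters back into per-chain coda objects and
# compute R-hat / effective sample size
bhm_diagnostics <- function(chains, spec, beta_names) {
  mats <- lapply(chains, function(ch) {
    m <- ch$beta_orig
    colnames(m) <- beta_names
    if (spec$spatial) m <- cbind(m, tau_u = ch$tau_u, tau_v = ch$tau_v)
    if (spec$family == "negbin") m <- cbind(m, theta = as.vector(ch$theta))
    coda::mcmc(m)
  })
  ml <- coda::mcmc.list(mats)
  rhat <- tryCatch(coda::gelman.diag(ml, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, ncol(mats[[1]])))
  ess <- coda::effectiveSize(ml)
  nm <- colnames(mats[[1]])
  data.frame(parameter = nm,
             group = ifelse(nm %in% beta_names, "fixed", "hyper"),
             rhat = as.numeric(rhat), ess = as.numeric(ess),
             row.names = NULL)
}

q_summary <- function(x) {
  c(mean = mean(x), sd = stats::sd(x),
    q025 = unname(stats::quantile(x, 0.025)),
    q50 = unname(stats::quantile(x, 0.5)),
    q975 = unname(stats::quantile(x, 0.975)))
}

summarize_bhm <- function(fit) {
  draws <- fit$draws
  rows <- lapply(colnames(draws$beta), function(nm) {
    data.frame(parameter = nm, t(q_summary(draws$beta[, nm])))
  })
  if (!is.null(draws$tau_u)) {
    rows <- c(rows, list(data.frame(parameter = "tau_u", t(q_summary(draws$tau_u))),
                         data.frame(parameter = "tau_v", t(q_summary(draws$tau_v)))))
  }
  if (!is.null(draws$theta)) {
    rows <- c(rows, list(data.frame(parameter = "theta", t(q_summary(draws$theta)))))
  }
  do.call(rbind, rows)
}

summarize_rho <- function(fit) {
  rho <- fit$draws$rho
  s <- t(apply(rho, 1, q_summary))
  data.frame(village_id = fit$village_id,
             rho_mean = s[, "mean"], rho_sd = s[, "sd"],
             rho_q025 = s[, "q025"], rho_q50 = s[, "q50"], rho_q975 = s[, "q975"],
             pr_under = rowMeans(rho < 1),
             row.names = NULL)
}

#' Posterior exceedance probabilities Pr(rho_i < threshold)
#'
#' Fraction of posterior relative-risk draws below the threshold, per
#' village: the undersupply probability map when `threshold = 1`.
#'
#' @param fit a `bhm_fit`, or a matrix of rho draws (villages x draws).
#' @param threshold positive relative-risk threshold (default 1).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
exceedance <- function(fit, threshold = 1) {
  rho <- if (inherits(fit, "bhm_fit")) fit$draws$rho else fit
  stopifnot(threshold > 0)
  rowMeans(rho < threshold)
}

#' @export
print.bhm_fit <- function(x, ...) {
  cat("bhm_fit:", x$spec$family, if (x$spec$spatial) "spatial" else "non-spatial",
      "model;", length(x$Y), "villages;",
      x$n_chains, "chains x", x$n_keep, "kept draws\n")
  cat(if (x$converged) "converged (all fixed-effect R-hat < 1.1)\n"
      else "NOT converged: R-hat > 1.1 on a fixed effect\n")
  print(x$summary, digits = 3)
  invisible(x)
}

# restrict an adjacency object to a subset of areas (used when villages with
# E = 0 are excluded from the likelihood)
subset_adjacency <- function(adj, keep) {
  if (length(keep) == length(adj$N) && all(keep == seq_along(adj$N))) return(adj)
  a <- adj$a[keep, keep, drop = FALSE]
  adjacency_from_matrix(a, if (!is.null(adj$ids)) adj$ids[keep] else NULL)
}
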