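# Model comparison (DIC, WAIC), predictive error against the raw relative
# risks (MAPE, MSE) and variance-inflation-factor screening of the
# covariates.

#' Deviance information criterion of a fitted model
#'
#' Conditional DIC: `DIC = Dbar + pD` with `D = -2 log-likelihood`, `Dbar`
#' the posterior mean deviance and `pD = Dbar - D(posterior means)`, the
#' plug-in deviance evaluated at the posterior means of all parameters
#' including the random effects.
#'
#' @param fit a `bhm_fit`.
#' @return list with `dic`, `p_dic`, `dbar`, `dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bhm_fit"))
  dev <- -2 * colSums(fit$loglik)
  dbar <- mean(dev)
  beta_hat <- colMeans(fit$draws$beta)
  eta_hat <- drop(fit$X %*% beta_hat)
  if (!is.null(fit$draws$u))
    eta_hat <- eta_hat + colMeans(fit$draws$u) + colMeans(fit$draws$v)
  rho_hat <- exp(eta_hat)
  theta_hat <- if (!is.null(fit$draws$theta)) mean(fit$draws$theta) else NULL
  dhat <- -2 * sum(loglik_count(fit$Y, fit$E, rho_hat, fit$spec$family, theta_hat))
  p_dic <- dbar - dhat
  list(dic = dbar + p_dic, p_dic = p_dic, dbar = dbar, dhat = dhat)
}

#' Watanabe-Akaike information criterion of a fitted model
#'
#' `WAIC = -2 (lppd - pWAIC)` with the log pointwise predictive density
#' `lppd = sum_i log mean_s p(Y_i | draw_s)` and the effective parameter
#' count `pWAIC = sum_i Var_s log p(Y_i | draw_s)`. Observations whose
#' variance term exceeds 0.4 are counted and reported as a reliability
#' warning.
#'
#' @param fit a `bhm_fit`.
#' @return list with `waic`, `p_waic`, `lppd`, `n_high_p` (observations
#'   with pointwise variance > 0.4).
#' @export
waic <- function(fit) {
  stopifnot(inherits(fit, "bhm_fit"))
  ll <- fit$loglik
  S <- ncol(ll)
  mx <- apply(ll, 1, max)
  lppd_i <- mx + log(rowMeans(exp(ll - mx))) # row-wise log-mean-exp
  p_i <- apply(ll, 1, stats::var)
  n_high <- sum(p_i > 0.4)
  if (n_high > 0)
    warning(sprintf("%d observations have pWAIC_i > 0.4; WAIC may be unreliable", n_high))
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd,
       n_high_p = n_high)
}

#' Predictive error of fitted relative risks against the raw ones
#'
#' Computed on the relative-risk scale: with posterior means `rho_hat_i` and
#' raw risks `rho_raw_i = Y_i / E_i`,
#' `MAPE = mean |rho_hat - rho_raw| / rho_raw` over villages with positive
#' raw risk (the number excluded is reported) and
#' `MSE = mean (rho_hat - rho_raw)^2` over all modelled villages. The
#' count-scale analogues (against `Y_i`, using `lambda_hat = E_i rho_hat_i`)
#' are also returned for transparency.
#'
#' @param fit a `bhm_fit`.
#' @param rho_raw raw relative risks aligned with the fit's villages;
#'   defaults to `Y / E` from the fit.
#' @return list with `mape`, `mse`, `n_excluded_mape`, `mape_count`,
#'   `mse_count`.
#' @export
predictive_error <- function(fit, rho_raw = NULL) {
  stopifnot(inherits(fit, "bhm_fit"))
  if (is.null(rho_raw)) rho_raw <- fit$Y / fit$E
  rho_hat <- rowMeans(fit$draws$rho)
  pos <- rho_raw > 0
  if (!any(pos)) stop("all raw relative risks are zero; MAPE undefined")
  mape <- mean(abs(rho_hat[pos] - rho_raw[pos]) / rho_raw[pos])
  mse <- mean((rho_hat - rho_raw)^2)
  lambda_hat <- fit$E * rho_hat
  ypos <- fit$Y > 0
  list(mape = mape, mse = mse, n_excluded_mape = sum(!pos),
       mape_count = mean(abs(lambda_hat[ypos] - fit$Y[ypos]) / fit$Y[ypos]),
       mse_count = mean((lambda_hat - fit$Y)^2))
}

#' Variance inflation factors of the six covariates
#'
#' `VIF_j = 1 / (1 - R_j^2)` from an ordinary least-squares regression of
#' covariate j on the other five plus an intercept, on the model scale
#' (store count, log income, land-use fractions). Values below 10 are the
#' usual no-multicollinearity screen.
#'
#' @param villages a `village_frame`.
#' @return named numeric vector of six VIFs.
#' @export
vif_report <- function(villages) {
  X <- village_design(villages)[, -1, drop = FALSE]
  if (nrow(X) < 8) stop("need at least 8 villages for VIF")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  vif <- vapply(seq_len(ncol(X)), function(j) {
    f <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(f$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  vif
}

#' Side-by-side comparison of fitted models
#'
#' @param fits named list of `bhm_fit` objects.
#' @return data.frame with one row per model: DIC, WAIC, their effective
#'   parameter counts, MAPE and MSE.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    d <- dic(f)
    w <- suppressWarnings(waic(f))
    pe <- predictive_error(f)
    data.frame(model = nm, dic = d$dic, waic = w$waic,
               p_dic = d$p_dic, p_waic = w$p_waic,
               mape = pe$mape, mse = pe$mse)
  })
  do.call(rbind, rows)
}
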