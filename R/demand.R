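# Demand side: expected counts E_i = r * Pop_i with r the overall service
# rate, and the raw relative risk Y_i / E_i.

#' Expected counts and raw relative risks
#'
#' Computes the overall service rate `r = sum(Y) / sum(Pop)` over the
#' modelling set, the expected (demand) counts `E_i = r * Pop_i`, and the
#' raw relative risks `rho_raw_i = Y_i / E_i`. By construction
#' `sum(E) = sum(Y)` on the modelling set, so the E-weighted mean raw RR is
#' exactly one. Villages with zero population get `E_i = 0` and are flagged
#' for exclusion from the model likelihood (the log offset is undefined
#' there); `r` is computed after that exclusion so the identity is
#' preserved.
#'
#' @param villages a `village_frame` whose data has `Y` and `pop`.
#' @return list with `r`, `E`, `rho_raw`, `modeled` (logical inclusion
#'   flags) and `villages`, the frame with `E`, `rho_raw`, `modeled`
#'   columns added.
#' @export
expected_counts <- function(villages) {
  stopifnot(inherits(villages, "village_frame"))
  d <- villages$data
  if (is.null(d$Y)) stop("villages carry no supply counts Y; run the allocation first")
  modeled <- d$pop > 0
  if (!any(modeled)) stop("all village populations are zero")
  r <- sum(d$Y[modeled]) / sum(d$pop[modeled])
  E <- ifelse(modeled, r * d$pop, 0)
  rho_raw <- ifelse(E > 0, d$Y / E, NA_real_)
  d$E <- E
  d$rho_raw <- rho_raw
  d$modeled <- modeled
  villages$data <- d
  list(r = r, E = E, rho_raw = rho_raw, modeled = modeled,
       villages = villages)
}

#' Classify raw relative risks into over-/under-supply
#'
#' @param rho_raw numeric vector of raw relative risks.
#' @return character vector: `"over"` where `rho > 1`, `"under"` where
#'   `rho < 1`, `"par"` at exactly 1.
#' @export
classify_raw <- function(rho_raw) {
  stopifnot(all(is.finite(rho_raw)))
  ifelse(rho_raw > 1, "over", ifelse(rho_raw < 1, "under", "par"))
}
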