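# Closed-form two-state (open/close) exchange kinetics and the EX1/EX2
# limiting regimes.

#' Observed exchange rate of the two-state opening model
#'
#' For the local opening scheme closed <-> open -> exchanged with opening
#' rate `k_op`, closing rate `k_cl` and intrinsic rate `k_int`, the
#' observed uptake rate is k_int*k_op / (k_int + k_op + k_cl).
#'
#' @param k_op,k_cl,k_int non-negative rates (same units)
#' @return observed rate (same units)
#' @export
k_obs <- function(k_op, k_cl, k_int) {
  stopifnot(k_op >= 0, k_cl >= 0, k_int >= 0)
  den <- k_int + k_op + k_cl
  if (den == 0) stop("undefined observed rate: all rates are zero")
  k_int * k_op / den
}

#' Classify the exchange regime
#'
#' EX2 when closing outruns intrinsic exchange (k_cl/k_int above the
#' threshold), EX1 when intrinsic exchange outruns closing, intermediate
#' otherwise. Also reports whether the native-state condition k_cl >> k_op
#' holds at the same threshold.
#'
#' @inheritParams k_obs
#' @param ratio_threshold fold-ratio defining "much larger" (default 10)
#' @return list with `regime` ("EX1", "EX2" or "intermediate") and
#'   `native` (logical)
#' @export
classify_regime <- function(k_op, k_cl, k_int, ratio_threshold = 10) {
  stopifnot(ratio_threshold > 1)
  regime <- if (k_int > 0 && k_cl / k_int >= ratio_threshold) "EX2"
  else if (k_cl > 0 && k_int / k_cl >= ratio_threshold) "EX1"
  else if (k_cl == 0 && k_int > 0) "EX1"
  else if (k_int == 0 && k_cl > 0) "EX2"
  else "intermediate"
  list(regime = regime, native = (k_op == 0) || (k_cl / k_op >= ratio_threshold))
}

#' Protection factor from opening/closing rates
#'
#' P = k_cl / k_op, the EX2-limit protection factor.
#'
#' @param k_op opening rate (> 0 for a finite result)
#' @param k_cl closing rate
#' @return protection factor; `Inf` when `k_op` is zero
#' @export
protection_from_rates <- function(k_op, k_cl) {
  stopifnot(k_op >= 0, k_cl >= 0)
  if (k_op == 0) {
    warning("k_op = 0: infinite protection")
    return(Inf)
  }
  k_cl / k_op
}
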