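# Scoring predicted uptake curves against experimental HDX-MS tables:
# pairing, residuals, per-fragment RMSD, apparent exchange rates, and
# residue-level observed-rate maps.

#' Read an experimental uptake table from CSV
#'
#' Expected columns: fragment_id, time_s, D, and optionally sd, condition.
#' Rows with D outside [0, 1] or non-positive times are rejected.
#'
#' @param path CSV path
#' @param exclude_fragments optional fragment ids to drop (e.g. redundant
#'   or high-uncertainty fragments)
#' @return data.frame of class `hdx_experiment`
#' @export
read_experiment_csv <- function(path, exclude_fragments = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("fragment_id", "time_s", "D") %in% names(d)))
  bad <- d$D < 0 | d$D > 1 | d$time_s <= 0 | !is.finite(d$D)
  if (any(bad))
    stop(sum(bad), " row(s) rejected: D outside [0,1] or time <= 0")
  d$fragment_id <- as.character(d$fragment_id)
  if (!is.null(exclude_fragments))
    d <- d[!d$fragment_id %in% as.character(exclude_fragments), ,
           drop = FALSE]
  class(d) <- c("hdx_experiment", "data.frame")
  d
}

#' Pair predicted and experimental uptake values
#'
#' Joins on fragment id and time (relative time tolerance configurable).
#' Unmatched rows of either table are reported in attributes
#' `unmatched_pred` and `unmatched_exp`.
#'
#' @param pred predicted table from [uptake_table()] (fragment_id, time_s,
#'   D_pred)
#' @param exp experimental table (fragment_id, time_s, D)
#' @param time_tol relative time-matching tolerance (default 0.01)
#' @return data.frame: fragment_id, time_s, D_pred, D_exp, residual
#' @export
pair_predictions <- function(pred, exp, time_tol = 0.01) {
  pred$fragment_id <- as.character(pred$fragment_id)
  exp$fragment_id <- as.character(exp$fragment_id)
  matched_p <- logical(nrow(pred))
  rows <- list()
  matched_e <- logical(nrow(exp))
  for (i in seq_len(nrow(exp))) {
    j <- which(pred$fragment_id == exp$fragment_id[i] &
                 abs(pred$time_s - exp$time_s[i]) <=
                   time_tol * exp$time_s[i])
    if (length(j) > 0) {
      j <- j[1]
      matched_e[i] <- TRUE
      matched_p[j] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        fragment_id = exp$fragment_id[i], time_s = exp$time_s[i],
        D_pred = pred$D_pred[j], D_exp = exp$D[i],
        residual = pred$D_pred[j] - exp$D[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    stop("no overlap between predicted and experimental tables")
  out <- do.call(rbind, rows)
  attr(out, "unmatched_pred") <- pred[!matched_p, , drop = FALSE]
  attr(out, "unmatched_exp") <- exp[!matched_e, , drop = FALSE]
  out
}

#' Per-fragment and global RMSD of paired uptake values
#'
#' @param paired output of [pair_predictions()]
#' @return list: `per_fragment` (data.frame fragment_id, n, rmsd) and
#'   `global` (scalar RMSD over all pairs)
#' @export
fragment_rmsd <- function(paired) {
  per <- lapply(split(paired, paired$fragment_id), function(d)
    data.frame(fragment_id = d$fragment_id[1], n = nrow(d),
               rmsd = sqrt(mean(d$residual^2)), stringsAsFactors = FALSE))
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(per_fragment = per, global = sqrt(mean(paired$residual^2)))
}

#' Apparent exchange rate of an uptake curve
#'
#' Least-squares fit of the single-exponential model
#' D(t) = A (1 - exp(-k t)) with A in (0, 1] and k > 0, initialized
#' deterministically from the half-rise time. A fit whose residual norm
#' exceeds `poor_fit_threshold` (root-mean-square residual in D units) is
#' flagged; curves that carry no usable rise (all-zero or non-convergent)
#' return `converged = FALSE` with absent parameters.
#'
#' @param curve an `hdx_uptake` object, or a list with `times` and `values`
#' @param poor_fit_threshold RMS-residual flag level in D units
#'   (default 0.03)
#' @return list: k_app (1/s), A, rms_residual, converged, poor_fit
#' @export
apparent_rate <- function(curve, poor_fit_threshold = 0.03) {
  t <- curve$times
  D <- curve$values
  ok <- is.finite(t) & is.finite(D) & t > 0
  t <- t[ok]; D <- D[ok]
  fail <- list(k_app = NA_real_, A = NA_real_, rms_residual = NA_real_,
               converged = FALSE, poor_fit = NA)
  if (length(t) < 3) return(fail)
  if (max(D) <= 0 || any(D < 0) || any(D >= 1 + 1e-9)) return(fail)

  # deterministic init: A0 from the plateau, k0 from the half-rise time
  A0 <- min(max(D), 1)
  half <- A0 / 2
  i <- which(D >= half)[1]
  t_half <- if (is.na(i)) max(t) else t[i]
  k0 <- log(2) / t_half

  fit <- tryCatch(
    minpack.lm::nlsLM(D ~ A * (1 - exp(-k * t)),
                      start = list(A = A0, k = k0),
                      lower = c(A = 1e-6, k = 1e-12),
                      upper = c(A = 1, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  p <- stats::coef(fit)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  list(k_app = unname(p["k"]), A = unname(p["A"]), rms_residual = rms,
       converged = TRUE, poor_fit = rms > poor_fit_threshold)
}

#' Residue-level predicted observed rates
#'
#' k_obs(i) = k_int(i) * exp(-lnP(i)), the EX2-limit observed rate of each
#' residue; residues without an exchangeable amide are flagged.
#'
#' @param profile an `hdx_protection`
#' @param rates from [rates_for_structure()]
#' @param chain restrict to one chain (default: chain-averaged profile)
#' @return data.frame: resno, aa, has_amide, lnP, k_int_s, k_obs_s
#' @export
residue_rate_map <- function(profile, rates, chain = NULL) {
  tab <- if (is.null(chain)) profile$residue else {
    d <- profile$by_chain[profile$by_chain$chain == chain, , drop = FALSE]
    d
  }
  kint <- kint_by_resno(rates, tab$resno, chain)
  k_obs <- ifelse(tab$has_amide & !is.na(kint),
                  kint * exp(-tab$mean_lnP), NA_real_)
  data.frame(resno = tab$resno, aa = tab$aa, has_amide = tab$has_amide,
             lnP = tab$mean_lnP, k_int_s = kint, k_obs_s = k_obs,
             stringsAsFactors = FALSE)
}
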