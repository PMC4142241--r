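# Residue- and fragment-level deuterium uptake curves D(t) from protection
# profiles and intrinsic rates:
#   D_i(t)   = 1 - exp(-(k_int_i / P_i) t),   P_i = exp(lnP_i)
#   D_j(t)   = mean over the fragment's exchange-competent amides
# with crystal-only, ensemble-mean-lnP, and per-frame averaging modes.

#' Default experimental time grid
#'
#' The ten manual-mixing time points commonly used in HDX-MS uptake
#' experiments: 30 s, 1, 2, 4, 8, 15, 30 min, 1, 2, 4 h.
#'
#' @return numeric vector of times in seconds
#' @export
hdx_times <- function() {
  c(30, 60, 120, 240, 480, 900, 1800, 3600, 7200, 14400)
}

new_uptake_curve <- function(times, values, provenance, id = NA_character_,
                             uncertainty = NULL) {
  stopifnot(length(times) == length(values))
  structure(list(times = times, values = values, provenance = provenance,
                 id = id, uncertainty = uncertainty),
            class = "hdx_uptake")
}

#' @export
print.hdx_uptake <- function(x, ...) {
  cat(sprintf("hdx_uptake [%s] (%s): %d time points, D in [%.3f, %.3f]\n",
              x$id, x$provenance, length(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.hdx_uptake <- function(x, ..., log_time = TRUE) {
  plot(x$times, x$values, type = "b", log = if (log_time) "x" else "",
       xlab = "time (s)", ylab = "deuterium fraction D(t)",
       ylim = c(0, 1), main = x$id, ...)
  invisible(x)
}

#' Uptake curve of a single residue
#'
#' @param lnP protection factor on the natural-log scale (0 = unprotected)
#' @param k_int intrinsic exchange rate in 1/s
#' @param times time grid in seconds (non-negative)
#' @return an `hdx_uptake` curve
#' @export
residue_uptake <- function(lnP, k_int, times) {
  stopifnot(k_int >= 0, is.finite(lnP))
  if (any(times < 0)) stop("negative times are not allowed")
  D <- 1 - exp(-(k_int / exp(lnP)) * times)
  new_uptake_curve(times, D, provenance = "predicted_crystal",
                   id = "residue")
}

#' Fragment definitions
#'
#' Builds a validated fragment table. When an ensemble is supplied the
#' fragment sequences are filled in (or checked) from the chain topology
#' and the number of exchange-competent amides is computed (residues in the
#' inclusive range that are not proline and not chain-initial).
#'
#' @param df data.frame with columns `id`, `start`, `end`, and optionally
#'   `chain` (NA = average over all chains carrying the range), `sequence`,
#'   `observed_mass`
#' @param ensemble optional `hdx_ensemble` providing the topology
#' @return data.frame of class `hdx_fragments` with added `sequence` and
#'   `n_amides` columns
#' @export
hdx_fragments <- function(df, ensemble = NULL) {
  stopifnot(all(c("id", "start", "end") %in% names(df)))
  if (!"chain" %in% names(df)) df$chain <- NA_character_
  if (!"sequence" %in% names(df)) df$sequence <- NA_character_
  if (!"observed_mass" %in% names(df)) df$observed_mass <- NA_real_
  if (any(df$start > df$end)) stop("fragment start must be <= end")
  if (!is.null(ensemble)) {
    cm <- chain_map(ensemble)
    r1 <- residue_table(ensemble$frames[[1]])
    for (i in seq_len(nrow(df))) {
      ch <- df$chain[i]
      if (is.na(ch)) ch <- cm$chain[1]   # sequence from the first chain
      rc <- r1[r1$chain == ch & r1$resno >= df$start[i] &
                 r1$resno <= df$end[i], , drop = FALSE]
      if (nrow(rc) == 0)
        stop("fragment ", df$id[i], " lies outside chain ", ch)
      seq_i <- paste(aa3to1(rc$resid), collapse = "")
      if (!is.na(df$sequence[i]) && df$sequence[i] != seq_i)
        stop("fragment ", df$id[i], ": declared sequence does not match ",
             "the structure (", df$sequence[i], " vs ", seq_i, ")")
      df$sequence[i] <- seq_i
      first_resno <- min(r1$resno[r1$chain == ch])
      df$n_amides[i] <- sum(rc$resid != "PRO" & rc$resno != first_resno)
    }
  } else if (all(!is.na(df$sequence))) {
    if (any(nchar(df$sequence) != df$end - df$start + 1))
      stop("sequence length must equal end - start + 1")
    df$n_amides <- vapply(seq_len(nrow(df)), function(i) {
      aa <- strsplit(df$sequence[i], "")[[1]]
      sum(aa != "P")  # chain-initial status unknown without topology
    }, numeric(1))
  } else {
    df$n_amides <- NA_real_
  }
  class(df) <- c("hdx_fragments", "data.frame")
  df
}

#' Read a fragment table from CSV
#'
#' Expected columns: id, chain, start, end, and optionally observed_mass
#' and sequence.
#'
#' @param path CSV path
#' @param ensemble optional `hdx_ensemble` used for validation
#' @return an `hdx_fragments` table
#' @export
read_fragments_csv <- function(path, ensemble = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hdx_fragments(df, ensemble = ensemble)
}

#' Per-residue intrinsic rates for a structure
#'
#' Evaluates [k_int_profile()] for every chain of an ensemble, keyed by
#' author residue numbering.
#'
#' @param ensemble an `hdx_ensemble`
#' @param cond an [exchange_conditions()] object
#' @param table an [kint_table()] object
#' @return data.frame: chain, resno, aa, k_int_s (1/s; NA for residue 1 and
#'   prolines)
#' @export
rates_for_structure <- function(ensemble, cond = exchange_conditions(),
                                table = kint_table()) {
  cm <- chain_map(ensemble)
  r1 <- residue_table(ensemble$frames[[1]])
  out <- lapply(seq_len(nrow(cm)), function(i) {
    rc <- r1[r1$chain == cm$chain[i], , drop = FALSE]
    prof <- k_int_profile(cm$sequence[i], cond, table, units = "per_s")
    data.frame(chain = cm$chain[i], resno = rc$resno, aa = prof$aa,
               k_int_s = prof$k_int, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# k_int lookup by resno: chain-specific or averaged over chains
kint_by_resno <- function(rates, resno, chain = NULL) {
  sub <- if (is.null(chain)) rates else rates[rates$chain == chain, ,
                                              drop = FALSE]
  vapply(resno, function(r) {
    v <- sub$k_int_s[sub$resno == r]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}

# residues of a fragment contributing amides, given a protection profile
fragment_amides <- function(fragment, profile, chain = NULL,
                            exclude_n_terminal = 0) {
  tab <- if (is.null(chain)) profile$residue else
    profile$by_chain[profile$by_chain$chain == chain, , drop = FALSE]
  sel <- tab[tab$resno >= fragment$start & tab$resno <= fragment$end &
               tab$has_amide, , drop = FALSE]
  if (exclude_n_terminal > 0) {
    drop <- fragment$start + seq_len(exclude_n_terminal) - 1
    sel <- sel[!sel$resno %in% drop, , drop = FALSE]
  }
  sel
}

#' Fragment-level uptake curve
#'
#' In mode `"mean_lnP"` each residue's deuterium fraction is computed from
#' its ensemble-averaged lnP and the fragment curve is the unweighted mean
#' over the fragment's amides. In mode `"mean_D"` the fragment curve is
#' computed separately for every (frame, chain) from the instantaneous lnP
#' and then averaged with the ensemble weights (and over chains). The two
#' modes agree exactly on single-frame, single-chain input.
#'
#' @param fragment one row of an [hdx_fragments()] table (or a list with
#'   `id`, `start`, `end`, optionally `chain`)
#' @param profile an `hdx_protection` from [average_protection()]
#' @param rates per-residue intrinsic rates from [rates_for_structure()]
#' @param times time grid in seconds
#' @param mode `"mean_lnP"`, `"mean_D"`, or NULL to take the profile's mode
#' @param chain restrict to one chain (default: the fragment's `chain`
#'   field, NA meaning average over chains)
#' @param exclude_n_terminal number of fragment-N-terminal residues to
#'   drop as fast exchangers (default 0: all amides count)
#' @return an `hdx_uptake` curve
#' @export
fragment_uptake <- function(fragment, profile, rates, times = hdx_times(),
                            mode = NULL, chain = NULL,
                            exclude_n_terminal = 0) {
  if (is.null(mode)) mode <- profile$mode
  mode <- match.arg(mode, c("mean_lnP", "mean_D"))
  if (any(times < 0)) stop("negative times are not allowed")
  if (is.null(chain) && !is.null(fragment$chain) && !is.na(fragment$chain))
    chain <- fragment$chain

  sel <- fragment_amides(fragment, profile, chain, exclude_n_terminal)
  if (nrow(sel) == 0)
    stop("fragment ", fragment$id, " has no exchange-competent amides")
  kint <- kint_by_resno(rates, sel$resno, chain)
  ok <- !is.na(kint) & !is.na(sel$mean_lnP)
  if (!any(ok)) stop("no residue of fragment ", fragment$id,
                     " has both lnP and k_int")
  sel <- sel[ok, , drop = FALSE]
  kint <- kint[ok]

  if (mode == "mean_lnP") {
    Dmat <- vapply(seq_len(nrow(sel)), function(i)
      1 - exp(-(kint[i] / exp(sel$mean_lnP[i])) * times), numeric(length(times)))
    D <- rowMeans(matrix(Dmat, nrow = length(times)))
  } else {
    bf <- profile$by_frame
    bf <- bf[bf$resno %in% sel$resno & bf$has_amide, , drop = FALSE]
    if (!is.null(chain)) bf <- bf[bf$chain == chain, , drop = FALSE]
    kmap <- stats::setNames(kint, sel$resno)
    grp <- split(bf, paste(bf$frame, bf$chain))
    acc <- 0; wacc <- 0
    for (d in grp) {
      kk <- kmap[as.character(d$resno)]
      oo <- !is.na(kk)
      if (!any(oo)) next
      Dm <- vapply(which(oo), function(i)
        1 - exp(-(kk[i] / exp(d$lnP[i])) * times), numeric(length(times)))
      Dfc <- rowMeans(matrix(Dm, nrow = length(times)))
      w <- d$weight[1]
      acc <- acc + w * Dfc
      wacc <- wacc + w
    }
    D <- acc / wacc
  }
  prov <- if (profile$n_frames == 1) "predicted_crystal" else
    "predicted_ensemble"
  new_uptake_curve(times, D, provenance = prov,
                   id = as.character(fragment$id))
}

#' Per-frame deuterium fraction of a fragment at one time
#'
#' Evaluates the instantaneous (single-conformation) fragment deuterium
#' fraction D(t*) for every frame of the profile, optionally for a single
#' subunit (chain) rather than the chain average.
#'
#' @inheritParams fragment_uptake
#' @param t_star evaluation time in seconds
#' @return list: `series` (data.frame frame, D), `mean` (ensemble-weighted),
#'   `min`, `max`
#' @export
perframe_uptake_series <- function(fragment, profile, rates, t_star,
                                   chain = NULL, exclude_n_terminal = 0) {
  stopifnot(t_star >= 0)
  if (is.null(chain) && !is.null(fragment$chain) && !is.na(fragment$chain))
    chain <- fragment$chain
  sel <- fragment_amides(fragment, profile, chain, exclude_n_terminal)
  kint <- kint_by_resno(rates, sel$resno, chain)
  kmap <- stats::setNames(kint, sel$resno)

  bf <- profile$by_frame
  bf <- bf[bf$resno %in% sel$resno & bf$has_amide, , drop = FALSE]
  if (!is.null(chain)) bf <- bf[bf$chain == chain, , drop = FALSE]
  frames <- sort(unique(bf$frame))
  D <- vapply(frames, function(f) {
    d <- bf[bf$frame == f, , drop = FALSE]
    # chain-average: mean over amides within chain, then over chains
    perch <- vapply(split(d, d$chain), function(dc) {
      kk <- kmap[as.character(dc$resno)]
      oo <- !is.na(kk)
      if (!any(oo)) return(NA_real_)
      mean(1 - exp(-(kk[oo] / exp(dc$lnP[oo])) * t_star))
    }, numeric(1))
    mean(perch, na.rm = TRUE)
  }, numeric(1))
  w <- profile$weights[frames]
  list(series = data.frame(frame = frames, D = D),
       mean = sum(w * D) / sum(w), min = min(D), max = max(D))
}

#' Uptake table for many fragments
#'
#' @param fragments an [hdx_fragments()] table
#' @param profile an `hdx_protection`
#' @param rates from [rates_for_structure()]
#' @param times time grid in seconds (default [hdx_times()])
#' @param mode averaging mode passed to [fragment_uptake()]
#' @param exclude_n_terminal as in [fragment_uptake()]
#' @return long data.frame: fragment_id, time_s, D_pred, mode
#' @export
uptake_table <- function(fragments, profile, rates, times = hdx_times(),
                         mode = NULL, exclude_n_terminal = 0) {
  if (nrow(fragments) == 0)
    return(data.frame(fragment_id = character(0), time_s = numeric(0),
                      D_pred = numeric(0), mode = character(0)))
  if (is.null(mode)) mode <- profile$mode
  out <- lapply(seq_len(nrow(fragments)), function(i) {
    cur <- fragment_uptake(fragments[i, ], profile, rates, times, mode,
                           exclude_n_terminal = exclude_n_terminal)
    data.frame(fragment_id = as.character(fragments$id[i]), time_s = times,
               D_pred = cur$values, mode = mode, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a predicted uptake table to CSV
#' @param table output of [uptake_table()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_uptake_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
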