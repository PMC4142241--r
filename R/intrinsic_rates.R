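# Intrinsic (unprotected) backbone amide exchange rates as a function of
# sequence context, pH and temperature, evaluated from vendored reference
# tables (poly-DL-alanine reference plus per-side-chain log-factors; see
# inst/extdata/intrinsic_rate_factors.csv for provenance).

#' Exchange conditions
#'
#' @param pH solution pH as read (default 7.9)
#' @param temperature absolute temperature in K (default 298)
#' @param pD_correction if TRUE, the glass-electrode correction
#'   pD = pH + 0.4 is applied before evaluating the rate laws (default
#'   FALSE: the pH value is used as-is)
#' @return object of class `hdx_conditions`
#' @export
exchange_conditions <- function(pH = 7.9, temperature = 298,
                                pD_correction = FALSE) {
  stopifnot(pH > 0, pH < 14, temperature > 0)
  structure(list(pH = pH, temperature = temperature,
                 pD_correction = isTRUE(pD_correction),
                 exchange_direction = "H_to_D"),
            class = "hdx_conditions")
}

.hdx_env <- new.env(parent = emptyenv())

#' Load the intrinsic-rate parameter tables
#'
#' Reads the vendored side-chain factor table and reference constants from
#' `inst/extdata`, or user-supplied replacements in the same format.
#'
#' @param factors_path,constants_path optional paths overriding the
#'   vendored CSV files
#' @return object of class `hdx_rate_table` with elements `factors`
#'   (data.frame keyed by residue code) and `const` (named numeric vector)
#' @export
kint_table <- function(factors_path = NULL, constants_path = NULL) {
  default <- is.null(factors_path) && is.null(constants_path)
  if (default && !is.null(.hdx_env$kint_table)) return(.hdx_env$kint_table)
  if (is.null(factors_path))
    factors_path <- system.file("extdata", "intrinsic_rate_factors.csv",
                                package = "hdxkin", mustWork = TRUE)
  if (is.null(constants_path))
    constants_path <- system.file("extdata", "intrinsic_rate_constants.csv",
                                  package = "hdxkin", mustWork = TRUE)
  fac <- utils::read.csv(factors_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  rownames(fac) <- fac$key
  cst <- utils::read.csv(constants_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  const <- stats::setNames(cst$value, cst$name)
  needed <- c("lg_ka", "lg_kb", "lg_kw", "pKD", "Ea_acid", "Ea_base",
              "Ea_water", "T_ref", "pKa_asp", "pKa_glu", "pKa_his",
              "pKa_cterm", "R_cal")
  if (!all(needed %in% names(const)))
    stop("constants file is missing: ",
         paste(setdiff(needed, names(const)), collapse = ", "))
  out <- structure(list(factors = fac, const = const),
                   class = "hdx_rate_table")
  if (default) .hdx_env$kint_table <- out
  out
}

# Henderson-Hasselbalch blend of protonated/deprotonated log-factors,
# performed on linear-scale factors
blend_log_factor <- function(v_prot, v_deprot, pKa, pD) {
  f_prot <- 1 / (1 + 10^(pD - pKa))
  log10(f_prot * 10^v_prot + (1 - f_prot) * 10^v_deprot)
}

# log10 side-chain factor for one residue code, one column, at given pD
side_factor <- function(aa, col, pD, table) {
  fac <- table$factors
  const <- table$const
  if (aa %in% c("D", "E", "H")) {
    pKa <- switch(aa, D = const[["pKa_asp"]], E = const[["pKa_glu"]],
                  H = const[["pKa_his"]])
    return(blend_log_factor(fac[paste0(aa, "_prot"), col],
                            fac[paste0(aa, "_deprot"), col], pKa, pD))
  }
  if (!aa %in% rownames(fac)) stop("unknown residue code '", aa, "'")
  fac[aa, col]
}

#' Intrinsic exchange rate of one amide
#'
#' Evaluates the acid-, base- and water-catalysed contributions to the
#' intrinsic exchange rate of the backbone amide of `sequence[position]`,
#' with the left (preceding residue) and right (own side chain) log-factors
#' applied multiplicatively, Henderson-Hasselbalch blending for ionizable
#' side chains, terminal-group corrections, and Arrhenius scaling from the
#' reference temperature.
#'
#' @param sequence 1-letter amino-acid string
#' @param position 1-based index of the residue whose amide exchanges
#' @param cond an [exchange_conditions()] object
#' @param table an [kint_table()] object
#' @param units `"per_min"` (default, the unit of the source tables) or
#'   `"per_s"`
#' @param n_terminal whether `sequence[1]` is a true protein N-terminus
#'   carrying an ammonium group (default TRUE); set FALSE when the string
#'   is an internal window of a longer chain
#' @param c_terminal likewise for the C-terminal carboxyl (default TRUE)
#' @return intrinsic rate (scalar)
#' @export
k_int <- function(sequence, position, cond = exchange_conditions(),
                  table = kint_table(), units = c("per_min", "per_s"),
                  n_terminal = TRUE, c_terminal = TRUE) {
  units <- match.arg(units)
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (position < 1 || position > n) stop("position out of range")
  if (position == 1 && n_terminal)
    stop("residue 1 has no exchange-competent amide (protonated N-terminus)")
  if (aa[position] == "P") stop("proline has no amide hydrogen")
  bad <- setdiff(aa, c(LETTERS)) # non-letters
  if (length(bad) > 0) stop("invalid sequence characters")

  const <- table$const
  pD <- cond$pH + if (cond$pD_correction) 0.4 else 0
  Tk <- cond$temperature

  cur <- aa[position]
  prev <- if (position > 1) aa[position - 1] else NA

  FA <- side_factor(cur, "lamA", pD, table)
  FB <- side_factor(cur, "lamB", pD, table)
  if (!is.na(prev)) {
    FA <- FA + side_factor(prev, "rhoA", pD, table)
    FB <- FB + side_factor(prev, "rhoB", pD, table)
  }
  if (position == 2 && n_terminal) {
    FA <- FA + table$factors["NT", "rhoA"]
    FB <- FB + table$factors["NT", "rhoB"]
  }
  if (position == n && c_terminal) {
    FA <- FA + blend_log_factor(table$factors["CT_prot", "lamA"],
                                table$factors["CT_deprot", "lamA"],
                                const[["pKa_cterm"]], pD)
    FB <- FB + blend_log_factor(table$factors["CT_prot", "lamB"],
                                table$factors["CT_deprot", "lamB"],
                                const[["pKa_cterm"]], pD)
  }

  R <- const[["R_cal"]]
  arr <- function(Ea_kcal)
    exp(-Ea_kcal * 1000 / R * (1 / Tk - 1 / const[["T_ref"]]))
  k_acid <- 10^(const[["lg_ka"]] + FA - pD) * arr(const[["Ea_acid"]])
  k_base <- 10^(const[["lg_kb"]] + FB + pD - const[["pKD"]]) *
    arr(const[["Ea_base"]])
  k_water <- 10^(const[["lg_kw"]] + FB) * arr(const[["Ea_water"]])
  k <- k_acid + k_base + k_water
  if (units == "per_s") k / 60 else k
}

#' Intrinsic rates for every residue of a sequence
#'
#' @inheritParams k_int
#' @return data.frame: position, aa, exchanger (FALSE for residue 1 and
#'   prolines), k_int (NA for non-exchangers) in the requested units
#' @export
k_int_profile <- function(sequence, cond = exchange_conditions(),
                          table = kint_table(),
                          units = c("per_min", "per_s"),
                          n_terminal = TRUE, c_terminal = TRUE) {
  units <- match.arg(units)
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  exch <- rep(TRUE, n)
  if (n_terminal) exch[1] <- FALSE
  exch[aa == "P"] <- FALSE
  k <- rep(NA_real_, n)
  for (i in which(exch)) {
    if (i == 1) next  # internal window: no left neighbour available
    k[i] <- k_int(sequence, i, cond, table, units,
                  n_terminal = n_terminal, c_terminal = c_terminal)
  }
  data.frame(position = seq_len(n), aa = aa, exchanger = exch & !is.na(k),
             k_int = k, stringsAsFactors = FALSE)
}
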