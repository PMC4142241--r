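# End-to-end convenience: structure(s) -> protection -> intrinsic rates ->
# fragment uptake table.

#' Predict fragment deuterium uptake from a structure or ensemble
#'
#' Runs the full pipeline: amide hydrogens are built where missing,
#' per-residue protection factors are computed and averaged over frames
#' and chains, intrinsic rates are evaluated for the chain sequences at
#' the given conditions, and fragment uptake curves are assembled.
#'
#' @param x an `hdx_ensemble`, an `hdx_frame`, or a PDB file path
#' @param fragments an [hdx_fragments()] table (or data.frame with id,
#'   start, end)
#' @param params [protection_params()]
#' @param cond [exchange_conditions()]
#' @param times time grid in seconds (default [hdx_times()])
#' @param mode `"mean_lnP"` (default) or `"mean_D"`
#' @param model_policy passed to [read_structure()] when `x` is a path
#' @return list: `uptake` (long table from [uptake_table()]), `profile`
#'   (`hdx_protection`), `rates`, `fragments`, `ensemble`
#' @export
predict_hdx <- function(x, fragments, params = protection_params(),
                        cond = exchange_conditions(), times = hdx_times(),
                        mode = c("mean_lnP", "mean_D"),
                        model_policy = "all") {
  mode <- match.arg(mode)
  ens <- if (inherits(x, "hdx_ensemble")) x
  else if (inherits(x, "hdx_frame")) hdx_ensemble(list(x))
  else read_structure(x, model_policy = model_policy)
  ens <- map_frames(ens, build_amide_hydrogens)
  profile <- average_protection(ens, params, mode = mode)
  rates <- rates_for_structure(ens, cond)
  fragments <- hdx_fragments(as.data.frame(fragments), ensemble = ens)
  up <- uptake_table(fragments, profile, rates, times, mode)
  list(uptake = up, profile = profile, rates = rates,
       fragments = fragments, ensemble = ens)
}
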