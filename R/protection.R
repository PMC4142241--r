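# Phenomenological per-residue protection factors:
#   lnP_i(X) = beta_c * Nc_i(X) + beta_h * Nh_i(X)
# where Nc counts heavy atoms near the amide nitrogen and Nh counts
# hydrogen-bond acceptor oxygens near the amide hydrogen.

#' Protection-factor parameters
#'
#' @param beta_c weight per heavy-atom contact (dimensionless, default 0.35)
#' @param beta_h weight per amide hydrogen bond (dimensionless, default 2.0)
#' @param contact_cutoff heavy-atom/amide-N distance cutoff in Å
#'   (default 6.5, strict `<`)
#' @param hbond_cutoff amide-H/acceptor-O distance cutoff in Å
#'   (default 2.4, strict `<`)
#' @param contact_exclusion half-width of the same-chain residue window
#'   excluded from contact counting (default 1, i.e. residues i-1, i, i+1;
#'   0 excludes residue i only)
#' @param acceptor_policy which oxygens may accept the amide H-bond;
#'   `"protein_oxygen_only"` (default) or `"all_oxygen"` (includes water
#'   oxygens when a frame retains them)
#' @return an object of class `hdx_params`
#' @export
protection_params <- function(beta_c = 0.35, beta_h = 2.0,
                              contact_cutoff = 6.5, hbond_cutoff = 2.4,
                              contact_exclusion = 1L,
                              acceptor_policy = c("protein_oxygen_only",
                                                  "all_oxygen")) {
  stopifnot(beta_c >= 0, beta_h >= 0, contact_cutoff > 0, hbond_cutoff > 0,
            contact_exclusion >= 0)
  structure(list(beta_c = beta_c, beta_h = beta_h,
                 contact_cutoff = contact_cutoff,
                 hbond_cutoff = hbond_cutoff,
                 contact_exclusion = as.integer(contact_exclusion),
                 acceptor_policy = match.arg(acceptor_policy)),
            class = "hdx_params")
}

# displacement-to-distance-squared with optional minimum-image wrapping
# (orthorhombic boxes only)
dist2_to_point <- function(xyz, p, box = NULL) {
  dx <- xyz[, 1] - p[1]; dy <- xyz[, 2] - p[2]; dz <- xyz[, 3] - p[3]
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  dx * dx + dy * dy + dz * dz
}

frame_xyz <- function(frame) as.matrix(frame$atoms[, c("x", "y", "z")])

#' Count heavy-atom contacts of one residue's amide nitrogen
#'
#' Heavy atoms strictly within `contact_cutoff` of the backbone N, across
#' all chains (inter-subunit contacts included), excluding atoms of
#' residues in the same-chain exclusion window around residue i.
#'
#' @param frame an `hdx_frame`
#' @param chain,resno residue identity
#' @param params an [protection_params()] object
#' @return integer contact count (NA when the residue lacks a backbone N)
#' @export
count_contacts <- function(frame, chain, resno, params = protection_params()) {
  a <- frame$atoms
  iN <- atom_index(a, chain, resno, "N")
  if (length(iN) == 0) return(NA_integer_)
  p <- as.numeric(a[iN[1], c("x", "y", "z")])
  cand <- a$is_heavy &
    !(a$chain == chain & abs(a$resno - resno) <= params$contact_exclusion)
  if (!any(cand)) return(0L)
  d2 <- dist2_to_point(frame_xyz(frame)[cand, , drop = FALSE], p, frame$box)
  sum(d2 < params$contact_cutoff^2)
}

acceptor_mask <- function(atoms, params) {
  ok <- atoms$element == "O"
  if (params$acceptor_policy == "protein_oxygen_only")
    ok <- ok & atoms$resid %in% STD_AA3
  ok
}

#' Count hydrogen bonds of one residue's amide hydrogen
#'
#' Acceptor oxygens (per `acceptor_policy`) strictly within `hbond_cutoff`
#' of the amide H, on any chain. A residue without an amide H returns 0.
#'
#' @inheritParams count_contacts
#' @return integer H-bond count
#' @export
count_hbonds <- function(frame, chain, resno, params = protection_params()) {
  a <- frame$atoms
  iH <- atom_index(a, chain, resno, c("H", "HN"))
  if (length(iH) == 0) return(0L)
  p <- as.numeric(a[iH[1], c("x", "y", "z")])
  cand <- acceptor_mask(a, params)
  if (!any(cand)) return(0L)
  d2 <- dist2_to_point(frame_xyz(frame)[cand, , drop = FALSE], p, frame$box)
  sum(d2 < params$hbond_cutoff^2)
}

#' Per-residue protection factors of one frame
#'
#' Computes Nc, Nh and lnP = beta_c*Nc + beta_h*Nh for every residue of the
#' frame. Residues without an exchangeable amide (proline, chain-initial,
#' missing amide H) carry `has_amide = FALSE` and `lnP = NA`.
#'
#' @param frame an `hdx_frame` with amide hydrogens resolved (see
#'   [build_amide_hydrogens()])
#' @param params an [protection_params()] object
#' @return data.frame: chain, resno, resid, aa, has_amide, nc, nh, lnP
#' @export
lnP_frame <- function(frame, params = protection_params()) {
  a <- frame$atoms
  am <- amide_table(frame)
  xyz <- frame_xyz(frame)
  heavy <- which(a$is_heavy)
  acc <- which(acceptor_mask(a, params))
  n <- nrow(am)
  nc <- nh <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(am$i_n[i])) {
      p <- xyz[am$i_n[i], ]
      cand <- heavy[!(a$chain[heavy] == am$chain[i] &
                        abs(a$resno[heavy] - am$resno[i]) <=
                          params$contact_exclusion)]
      nc[i] <- if (length(cand) == 0) 0L else
        sum(dist2_to_point(xyz[cand, , drop = FALSE], p, frame$box) <
              params$contact_cutoff^2)
    }
    if (!is.na(am$i_h[i]) && length(acc) > 0) {
      p <- xyz[am$i_h[i], ]
      nh[i] <- sum(dist2_to_point(xyz[acc, , drop = FALSE], p, frame$box) <
                     params$hbond_cutoff^2)
    } else {
      nh[i] <- 0L
    }
  }
  has_amide <- am$exchanger & !is.na(am$i_h)
  lnP <- ifelse(has_amide, params$beta_c * nc + params$beta_h * nh, NA_real_)
  data.frame(chain = am$chain, resno = am$resno, resid = am$resid,
             aa = aa3to1(am$resid), has_amide = has_amide,
             nc = nc, nh = nh, lnP = lnP, stringsAsFactors = FALSE)
}

weighted_mean_na <- function(x, w) {
  ok <- !is.na(x)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

#' Ensemble-averaged protection profile
#'
#' Computes per-(frame, chain, residue) Nc, Nh and lnP and aggregates them.
#' In mode `"mean_lnP"` the residue-level protection is the weighted mean
#' of lnP over frames (and the unweighted mean over chains); by linearity
#' this equals beta_c*mean(Nc) + beta_h*mean(Nh). Mode `"mean_D"` keeps the
#' same tables but signals downstream uptake calculations to average
#' per-frame deuterium fractions instead of protection factors.
#'
#' @param ensemble an `hdx_ensemble` (amide hydrogens resolved)
#' @param params an [protection_params()] object
#' @param mode `"mean_lnP"` (default) or `"mean_D"`
#' @return object of class `hdx_protection` with elements `by_frame`
#'   (frame, chain, resno, ...), `by_chain` (frame-averaged), `residue`
#'   (frame- and chain-averaged), `mode`, `params`, `weights`
#' @export
average_protection <- function(ensemble, params = protection_params(),
                               mode = c("mean_lnP", "mean_D")) {
  mode <- match.arg(mode)
  frames <- ensemble$frames
  w <- ensemble$weights
  per <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    tab <- lnP_frame(frames[[f]], params)
    tab$frame <- f
    tab$weight <- w[f]
    per[[f]] <- tab
  }
  by_frame <- do.call(rbind, per)

  key <- paste(by_frame$chain, by_frame$resno, sep = "|")
  agg_chain <- lapply(split(by_frame, key), function(d) {
    data.frame(chain = d$chain[1], resno = d$resno[1], resid = d$resid[1],
               aa = d$aa[1], has_amide = all(d$has_amide),
               mean_nc = weighted_mean_na(as.numeric(d$nc), d$weight),
               mean_nh = weighted_mean_na(as.numeric(d$nh), d$weight),
               mean_lnP = weighted_mean_na(d$lnP, d$weight),
               n_frames = nrow(d), stringsAsFactors = FALSE)
  })
  by_chain <- do.call(rbind, agg_chain)
  by_chain <- by_chain[order(by_chain$chain, by_chain$resno), , drop = FALSE]
  rownames(by_chain) <- NULL

  agg_res <- lapply(split(by_chain, by_chain$resno), function(d) {
    data.frame(resno = d$resno[1], aa = d$aa[1],
               has_amide = all(d$has_amide),
               mean_nc = mean(d$mean_nc, na.rm = TRUE),
               mean_nh = mean(d$mean_nh, na.rm = TRUE),
               mean_lnP = if (all(is.na(d$mean_lnP))) NA_real_ else
                 mean(d$mean_lnP, na.rm = TRUE),
               n_chains = nrow(d), stringsAsFactors = FALSE)
  })
  residue <- do.call(rbind, agg_res)
  residue <- residue[order(residue$resno), , drop = FALSE]
  rownames(residue) <- NULL

  structure(list(by_frame = by_frame, by_chain = by_chain, residue = residue,
                 mode = mode, params = params, weights = w,
                 n_frames = length(frames)),
            class = "hdx_protection")
}

#' @export
print.hdx_protection <- function(x, ...) {
  cat(sprintf(paste0("hdx_protection: %d frame(s), %d chain-residues, ",
                     "mode=%s\n"),
              x$n_frames, nrow(x$by_chain), x$mode))
  cat(sprintf("  mean lnP over amides: %.3f\n",
              mean(x$by_chain$mean_lnP, na.rm = TRUE)))
  invisible(x)
}

#' Write a per-residue protection profile to CSV
#'
#' Columns: chain, resseq, aa, mean_Nc, mean_Nh, mean_lnP, n_frames.
#'
#' @param profile an `hdx_protection` object
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_protection_csv <- function(profile, path) {
  d <- profile$by_chain
  out <- data.frame(chain = d$chain, resseq = d$resno, aa = d$aa,
                    mean_Nc = d$mean_nc, mean_Nh = d$mean_nh,
                    mean_lnP = d$mean_lnP, n_frames = d$n_frames)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
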