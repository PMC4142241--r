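# Structural descriptors: Shrake-Rupley solvent-accessible surface area,
# surface buried upon oligomerization, and per-residue RMSF about the
# ensemble-mean structure.

vdw_radii <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.hdx_env$vdw)) return(.hdx_env$vdw)
  if (default)
    path <- system.file("extdata", "vdw_radii.csv", package = "hdxkin",
                        mustWork = TRUE)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- stats::setNames(d$radius, toupper(d$element))
  if (default) .hdx_env$vdw <- out
  out
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA of the heavy atoms of a frame: each atom's sphere of
#' radius r_vdw + probe is sampled with a deterministic quasi-uniform
#' point set; points not buried inside any neighbouring sphere contribute
#' area. Hydrogens are ignored (radii set for heavy atoms only).
#'
#' @param frame an `hdx_frame`
#' @param probe_radius probe radius in Å (default 1.4, water)
#' @param n_points sphere sample points per atom (default 960)
#' @param per `"residue"` (default) or `"atom"`
#' @return data.frame with chain, resno, resid and `sasa` in Å²
#' @export
sasa <- function(frame, probe_radius = 1.4, n_points = 960,
                 per = c("residue", "atom")) {
  per <- match.arg(per)
  a <- frame$atoms[frame$atoms$is_heavy, , drop = FALSE]
  n <- nrow(a)
  if (n == 0) stop("no heavy atoms")
  rad <- vdw_radii()[toupper(a$element)]
  rad[is.na(rad)] <- 1.7
  R <- unname(rad) + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  area <- numeric(n)
  # neighbour lists from one pairwise distance pass
  d2 <- as.matrix(stats::dist(xyz))^2
  maxR <- max(R)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + maxR)^2)
    nb <- nb[nb != i]
    nb <- nb[d2[i, nb] < (R[i] + R[nb])^2]
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(acc)) break
        dx <- p[acc, 1] - xyz[j, 1]
        dy <- p[acc, 2] - xyz[j, 2]
        dz <- p[acc, 3] - xyz[j, 3]
        acc[acc] <- (dx * dx + dy * dy + dz * dz) >= R[j]^2
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    area[i] <- 4 * pi * R[i]^2 * frac
  }
  if (per == "atom") {
    out <- a[, c("chain", "resno", "resid", "elety")]
    out$sasa <- area
    rownames(out) <- NULL
    return(out)
  }
  key <- paste(a$chain, a$resno, sep = "|")
  agg <- lapply(split(seq_len(n), key), function(ix)
    data.frame(chain = a$chain[ix[1]], resno = a$resno[ix[1]],
               resid = a$resid[ix[1]], sasa = sum(area[ix]),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

subset_chain <- function(frame, chain_id) {
  a <- frame$atoms[frame$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0) stop("no such chain: ", chain_id)
  rownames(a) <- NULL
  new_hdx_frame(a, frame_index = frame$frame_index, box = frame$box)
}

#' Surface buried upon oligomerization
#'
#' Per-residue difference SASA(chain alone) - SASA(chain in the oligomer):
#' non-negative (up to quadrature noise) and nonzero at subunit interfaces.
#'
#' @param frame oligomeric `hdx_frame`
#' @param chain_id chain to evaluate
#' @param probe_radius,n_points as in [sasa()]
#' @return data.frame: chain, resno, resid, sasa_monomer, sasa_oligomer,
#'   delta_sasa
#' @export
buried_surface <- function(frame, chain_id, probe_radius = 1.4,
                           n_points = 960) {
  s_olig <- sasa(frame, probe_radius, n_points)
  s_olig <- s_olig[s_olig$chain == chain_id, , drop = FALSE]
  s_mono <- sasa(subset_chain(frame, chain_id), probe_radius, n_points)
  stopifnot(nrow(s_olig) == nrow(s_mono))
  data.frame(chain = s_mono$chain, resno = s_mono$resno,
             resid = s_mono$resid, sasa_monomer = s_mono$sasa,
             sasa_oligomer = s_olig$sasa,
             delta_sasa = s_mono$sasa - s_olig$sasa,
             stringsAsFactors = FALSE)
}

# optimal rotation (Kabsch, via SVD): x %*% R best approximates y
kabsch_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

superpose_onto <- function(xyz, ref) {
  cx <- colMeans(xyz); cr <- colMeans(ref)
  xc <- sweep(xyz, 2, cx)
  rc <- sweep(ref, 2, cr)
  Rm <- kabsch_rotation(xc, rc)
  sweep(xc %*% Rm, 2, cr, "+")
}

#' Per-residue root mean-square fluctuation of an ensemble
#'
#' Frames are rigid-body superposed (closed-form optimal rotation) onto the
#' ensemble-average structure -- computed after one alignment pass onto the
#' first frame -- and the RMS deviation of each selected atom from its mean
#' position is averaged within residues.
#'
#' @param ensemble an `hdx_ensemble` with at least 2 frames
#' @param selection atom-name selection (default backbone heavy atoms)
#' @param superpose superpose frames before measuring (default TRUE)
#' @return data.frame: chain, resno, resid, rmsf (Å)
#' @export
rmsf <- function(ensemble, selection = c("N", "CA", "C", "O"),
                 superpose = TRUE) {
  frames <- ensemble$frames
  if (length(frames) < 2) stop("RMSF is undefined for a single frame")
  a1 <- frames[[1]]$atoms
  sel <- which(a1$elety %in% selection)
  if (length(sel) == 0) stop("empty atom selection")
  get_xyz <- function(fr) as.matrix(fr$atoms[sel, c("x", "y", "z")])
  mats <- lapply(frames, get_xyz)
  if (superpose) {
    mats <- lapply(mats, superpose_onto, ref = mats[[1]])
    mean1 <- Reduce(`+`, mats) / length(mats)
    mats <- lapply(mats, superpose_onto, ref = mean1)
  }
  m <- Reduce(`+`, mats) / length(mats)
  dev2 <- Reduce(`+`, lapply(mats, function(x) rowSums((x - m)^2))) /
    length(mats)
  atom_rmsf <- sqrt(dev2)
  key <- paste(a1$chain[sel], a1$resno[sel], sep = "|")
  agg <- lapply(split(seq_along(sel), key), function(ix)
    data.frame(chain = a1$chain[sel[ix[1]]], resno = a1$resno[sel[ix[1]]],
               resid = a1$resid[sel[ix[1]]],
               rmsf = mean(atom_rmsf[ix]), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}
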