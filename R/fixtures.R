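# Deterministic synthetic-data generators: ideal backbones built from
# internal coordinates, ring oligomers with a controlled interface,
# jittered pseudo-trajectories, and synthetic "experimental" uptake tables
# with known ground truth.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# natural-extension reference frame: place atom d given a-b-c, bond |cd|,
# angle b-c-d (deg) and dihedral a-b-c-d (deg)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

# standard peptide internal coordinates
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_ca_c_o = 120.5, omega = 180)

# backbone (N, CA, C, O) from phi/psi vectors; sequence gives residue names
build_backbone <- function(phi, psi, sequence) {
  n <- length(phi)
  aa <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(length(aa) == n, length(psi) == n)
  aa3 <- stats::setNames(bio3d::aa123(aa), NULL)
  rows <- list()
  N <- c(0, 0, 0)
  CA <- c(.BB$b_n_ca, 0, 0)
  ang <- .BB$a_n_ca_c * pi / 180
  C <- CA + .BB$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Nn <- place_atom(Np, CAp, Cp, .BB$b_c_n, .BB$a_ca_c_n, psi[i - 1])
      CA <- place_atom(CAp, Cp, Nn, .BB$b_n_ca, .BB$a_c_n_ca, .BB$omega)
      C <- place_atom(Cp, Nn, CA, .BB$b_ca_c, .BB$a_n_ca_c, phi[i])
      N <- Nn
    }
    O <- place_atom(N, CA, C, .BB$b_c_o, .BB$a_ca_c_o, psi[i] + 180)
    rows[[i]] <- data.frame(
      elety = c("N", "CA", "C", "O"), resid = aa3[i], chain = "A",
      resno = i,
      x = c(N[1], CA[1], C[1], O[1]),
      y = c(N[2], CA[2], C[2], O[2]),
      z = c(N[3], CA[3], C[3], O[3]),
      element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
    Np <- N; CAp <- CA; Cp <- C
  }
  a <- do.call(rbind, rows)
  a$eleno <- seq_len(nrow(a))
  a$is_heavy <- TRUE
  a <- a[, c("eleno", "elety", "resid", "chain", "resno", "x", "y", "z",
             "element", "is_heavy")]
  new_hdx_frame(a)
}

# rotate/translate helper
transform_atoms <- function(atoms, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]
  atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# align the principal (inertia) axis of the CA trace with z and center
orient_axis_z <- function(frame) {
  a <- frame$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  ca <- xyz[a$elety == "CA", , drop = FALSE]
  v <- svd(ca)$v[, 1]
  # rotation sending v to z
  z <- c(0, 0, 1)
  ax <- cross3(v, z)
  s <- sqrt(sum(ax^2))
  if (s < 1e-9) Rm <- diag(3) else {
    ax <- ax / s
    th <- acos(max(-1, min(1, sum(v * z))))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  a[, c("x", "y", "z")] <- xyz %*% t(Rm)
  new_hdx_frame(a, frame$frame_index, frame$box)
}

min_interchain_dist <- function(frame, ch1, ch2) {
  a <- frame$atoms
  x1 <- as.matrix(a[a$chain == ch1, c("x", "y", "z")])
  x2 <- as.matrix(a[a$chain == ch2, c("x", "y", "z")])
  min(vapply(seq_len(nrow(x1)), function(i)
    min(dist2_to_point(x2, x1[i, ])), numeric(1)))^0.5
}

#' Generate a synthetic structure
#'
#' Deterministic idealized backbones (N, CA, C, O; hydrogens are added
#' downstream by [build_amide_hydrogens()]):
#' * `extended_chain`: beta-strand-like (phi = -120, psi = +120); no amide
#'   hydrogen bonds by construction.
#' * `ideal_helix`: canonical alpha-helix (phi = -57, psi = -47); interior
#'   amides accept the i -> i-4 carbonyl hydrogen bond.
#' * `ring_oligomer`: `n_chains` helix copies in Cn symmetry about z; the
#'   ring radius is shrunk until neighbouring subunits form an interface
#'   (closest heavy-atom approach below `contact_target` Å).
#'
#' @param kind fixture kind
#' @param n_residues residues per chain (>= 2)
#' @param sequence 1-letter sequence (default poly-alanine)
#' @param n_chains chains for `ring_oligomer` (default 6)
#' @param ring_radius fixed ring radius in Å (default: automatic search)
#' @param contact_target desired closest inter-chain approach in Å for the
#'   automatic radius search (default 4.0)
#' @param first_resno author number of the first residue (default 1)
#' @return an `hdx_frame`
#' @export
make_structure <- function(kind = c("extended_chain", "ideal_helix",
                                    "ring_oligomer"),
                           n_residues, sequence = NULL, n_chains = 6,
                           ring_radius = NULL, contact_target = 4.0,
                           first_resno = 1L) {
  kind <- match.arg(kind)
  if (n_residues < 2) stop("need at least 2 residues")
  if (is.null(sequence)) sequence <- strrep("A", n_residues)
  if (nchar(sequence) != n_residues)
    stop("sequence length must equal n_residues")
  phi_psi <- switch(kind,
                    extended_chain = c(-120, 120),
                    c(-57, -47))
  mono <- build_backbone(rep(phi_psi[1], n_residues),
                         rep(phi_psi[2], n_residues), sequence)
  mono$atoms$resno <- mono$atoms$resno + as.integer(first_resno) - 1L
  if (kind != "ring_oligomer") return(mono)

  mono <- orient_axis_z(mono)
  a0 <- mono$atoms
  # shift monomer out along +x, then replicate by rotation about z
  assemble <- function(R0) {
    parts <- lapply(seq_len(n_chains), function(k) {
      th <- 2 * pi * (k - 1) / n_chains
      ak <- transform_atoms(a0, diag(3), t = c(R0, 0, 0))
      ak <- transform_atoms(ak, rot_z(th))
      ak$chain <- LETTERS[k]
      ak
    })
    a <- do.call(rbind, parts)
    a$eleno <- seq_len(nrow(a))
    rownames(a) <- NULL
    new_hdx_frame(a)
  }
  if (!is.null(ring_radius)) return(assemble(ring_radius))
  # automatic radius: shrink until neighbours touch (but do not clash)
  ca <- as.matrix(a0[, c("x", "y", "z")])
  r_extent <- max(sqrt(ca[, 1]^2 + ca[, 2]^2))
  R0 <- 2 * r_extent + 8
  repeat {
    fr <- assemble(R0)
    dmin <- min_interchain_dist(fr, "A", "B")
    if (dmin <= contact_target || R0 <= r_extent) break
    R0 <- R0 - 0.25
  }
  attr(fr, "ring_radius") <- R0
  fr
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# displace every chain radially outward from the z axis
open_ring <- function(frame, displacement) {
  a <- frame$atoms
  for (ch in unique(a$chain)) {
    i <- a$chain == ch
    cxy <- c(mean(a$x[i]), mean(a$y[i]))
    u <- cxy / sqrt(sum(cxy^2))
    a$x[i] <- a$x[i] + displacement * u[1]
    a$y[i] <- a$y[i] + displacement * u[2]
  }
  new_hdx_frame(a, frame$frame_index, frame$box)
}

#' Generate a synthetic ensemble
#'
#' Frames are independent Gaussian coordinate jitters of the base
#' structure (emulating thermal fluctuation about a native state). With
#' `open_fraction > 0`, that fraction of frames (the last ones) is derived
#' from an "open" state in which every chain is displaced radially away
#' from the ring axis, separating the subunit interfaces -- a two-state
#' closed/open mixture.
#'
#' @param base an `hdx_frame`
#' @param n_frames number of frames (>= 1)
#' @param jitter_sigma Gaussian sigma per coordinate in Å (>= 0)
#' @param seed integer seed (fixed seed gives identical output)
#' @param open_fraction fraction of frames in the open state (default 0)
#' @param open_displacement radial chain displacement of the open state in
#'   Å (default 10)
#' @return an `hdx_ensemble`
#' @export
make_ensemble <- function(base, n_frames, jitter_sigma = 0.3, seed = 1,
                          open_fraction = 0, open_displacement = 10) {
  stopifnot(n_frames >= 1, jitter_sigma >= 0,
            open_fraction >= 0, open_fraction <= 1)
  n_open <- round(open_fraction * n_frames)
  opened <- if (n_open > 0) open_ring(base, open_displacement) else NULL
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    src <- if (f > n_frames - n_open) opened else base
    a <- src$atoms
    n <- nrow(a)
    a$x <- a$x + stats::rnorm(n, 0, jitter_sigma)
    a$y <- a$y + stats::rnorm(n, 0, jitter_sigma)
    a$z <- a$z + stats::rnorm(n, 0, jitter_sigma)
    new_hdx_frame(a, frame_index = f, box = base$box)
  }))
  hdx_ensemble(frames)
}

#' Generate a synthetic experimental uptake table with known ground truth
#'
#' Deuterium fractions are computed from planted per-residue lnP and
#' intrinsic rates (single-conformation model), averaged over each
#' fragment's exchange-competent amides, then perturbed with truncated
#' Gaussian noise (clipped to [0, 1]).
#'
#' @param planted data.frame: resno, lnP, k_int_s, and logical `exchanger`
#' @param fragments an [hdx_fragments()]-style table (id, start, end)
#' @param times time grid in seconds (> 0)
#' @param noise_sd Gaussian noise sd in D units (default 0)
#' @param seed integer seed
#' @return list: `table` (fragment_id, time_s, D), `truth` (the planted
#'   inputs and the noiseless table)
#' @export
make_uptake_table <- function(planted, fragments, times = hdx_times(),
                              noise_sd = 0, seed = 1) {
  stopifnot(all(times > 0), noise_sd >= 0,
            all(c("resno", "lnP", "k_int_s", "exchanger") %in%
                  names(planted)))
  clean <- lapply(seq_len(nrow(fragments)), function(i) {
    fr <- fragments[i, ]
    sel <- planted[planted$resno >= fr$start & planted$resno <= fr$end &
                     planted$exchanger, , drop = FALSE]
    if (nrow(sel) == 0) stop("fragment ", fr$id, " has no amides")
    D <- rowMeans(vapply(seq_len(nrow(sel)), function(j)
      1 - exp(-(sel$k_int_s[j] / exp(sel$lnP[j])) * times),
      numeric(length(times))))
    data.frame(fragment_id = as.character(fr$id), time_s = times, D = D,
               stringsAsFactors = FALSE)
  })
  clean <- do.call(rbind, clean)
  noisy <- clean
  if (noise_sd > 0) {
    noisy$D <- with_seed(seed, pmin(1, pmax(0,
      clean$D + stats::rnorm(nrow(clean), 0, noise_sd))))
  }
  class(noisy) <- c("hdx_experiment", "data.frame")
  list(table = noisy,
       truth = list(planted = planted, noiseless = clean,
                    noise_sd = noise_sd, seed = seed))
}
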