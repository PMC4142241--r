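# Independent oracles used to cross-check the implementation. These are
# deliberately written as direct, unoptimized evaluations that share no
# code with the package internals.

# ---- vector geometry ------------------------------------------------------

vangle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

vdihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

atom_xyz <- function(frame, chain, resno, elety) {
  a <- frame$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  as.numeric(a[i[1], c("x", "y", "z")])
}

# ---- brute-force contact / H-bond counts ----------------------------------

# all-pairs counts straight from the definitions; exclusion window `w`
# residues on the same chain for contacts, element-O acceptors for H-bonds
oracle_counts <- function(frame, contact_cutoff = 6.5, hbond_cutoff = 2.4,
                          w = 1) {
  a <- frame$atoms
  res <- unique(a[, c("chain", "resno")])
  out <- NULL
  for (k in seq_len(nrow(res))) {
    ch <- res$chain[k]; rn <- res$resno[k]
    iN <- which(a$chain == ch & a$resno == rn & a$elety == "N")
    iH <- which(a$chain == ch & a$resno == rn & a$elety %in% c("H", "HN"))
    nc <- NA_integer_
    if (length(iN) == 1) {
      p <- as.numeric(a[iN, c("x", "y", "z")])
      nc <- 0L
      for (j in seq_len(nrow(a))) {
        if (!a$is_heavy[j]) next
        if (a$chain[j] == ch && abs(a$resno[j] - rn) <= w) next
        d2 <- (a$x[j] - p[1])^2 + (a$y[j] - p[2])^2 + (a$z[j] - p[3])^2
        if (d2 < contact_cutoff^2) nc <- nc + 1L
      }
    }
    nh <- 0L
    if (length(iH) == 1) {
      p <- as.numeric(a[iH, c("x", "y", "z")])
      for (j in which(a$element == "O")) {
        d2 <- (a$x[j] - p[1])^2 + (a$y[j] - p[2])^2 + (a$z[j] - p[3])^2
        if (d2 < hbond_cutoff^2) nh <- nh + 1L
      }
    }
    out <- rbind(out, data.frame(chain = ch, resno = rn, nc = nc, nh = nh))
  }
  out
}

# vectorized variant for larger random fixtures (still definition-direct)
oracle_counts_fast <- function(frame, contact_cutoff = 6.5,
                               hbond_cutoff = 2.4, w = 1) {
  a <- frame$atoms
  res <- unique(a[, c("chain", "resno")])
  nc <- nh <- rep(NA_real_, nrow(res))
  for (k in seq_len(nrow(res))) {
    ch <- res$chain[k]; rn <- res$resno[k]
    iN <- which(a$chain == ch & a$resno == rn & a$elety == "N")
    iH <- which(a$chain == ch & a$resno == rn & a$elety %in% c("H", "HN"))
    if (length(iN) == 1) {
      d2 <- (a$x - a$x[iN])^2 + (a$y - a$y[iN])^2 + (a$z - a$z[iN])^2
      keep <- a$is_heavy & !(a$chain == ch & abs(a$resno - rn) <= w)
      nc[k] <- sum(keep & d2 < contact_cutoff^2)
    }
    nh[k] <- 0
    if (length(iH) == 1) {
      d2 <- (a$x - a$x[iH])^2 + (a$y - a$y[iH])^2 + (a$z - a$z[iH])^2
      nh[k] <- sum(a$element == "O" & d2 < hbond_cutoff^2)
    }
  }
  data.frame(chain = res$chain, resno = res$resno, nc = nc, nh = nh)
}

# random "protein-like" frame: residues of 4 heavy backbone atoms at
# uniform random positions plus an amide H 1.0 A from each N
random_frame <- function(n_res, seed, n_chains = 2, box_len = NULL) {
  set.seed(seed)
  n_atoms <- n_res * 4
  if (is.null(box_len)) box_len <- max(10, (n_atoms)^(1 / 3) * 4)
  per_chain <- ceiling(n_res / n_chains)
  rows <- list()
  for (r in seq_len(n_res)) {
    ch <- LETTERS[(r - 1) %/% per_chain + 1]
    rn <- (r - 1) %% per_chain + 1
    base <- runif(3, 0, box_len)
    off <- matrix(runif(12, -1.5, 1.5), 4, 3)
    names4 <- c("N", "CA", "C", "O")
    for (t in 1:4) {
      rows[[length(rows) + 1]] <- data.frame(
        eleno = NA_integer_, elety = names4[t], resid = "ALA", chain = ch,
        resno = rn, x = base[1] + off[t, 1], y = base[2] + off[t, 2],
        z = base[3] + off[t, 3],
        element = substr(names4[t], 1, 1), is_heavy = TRUE,
        stringsAsFactors = FALSE)
    }
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    hN <- rows[[length(rows) - 3]]
    rows[[length(rows) + 1]] <- data.frame(
      eleno = NA_integer_, elety = "H", resid = "ALA", chain = ch,
      resno = rn, x = hN$x + u[1], y = hN$y + u[2], z = hN$z + u[3],
      element = "H", is_heavy = FALSE, stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, rows)
  a$eleno <- seq_len(nrow(a))
  hdxkin:::new_hdx_frame(a)
}

# ---- elemental-composition peptide mass -----------------------------------

# residue formulas (C, H, N, O, S) and atomic monoisotopic masses
oracle_mass <- function(sequence) {
  comp <- list(
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  amass <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
             O = 15.9949146196, S = 31.97207100)
  total <- c(0, 0, 0, 0, 0)
  for (aa in strsplit(sequence, "")[[1]]) total <- total + comp[[aa]]
  total <- total + c(0, 2, 0, 1, 0)  # + H2O
  sum(total * amass[c("C", "H", "N", "O", "S")])
}

# ---- independent intrinsic-rate evaluation --------------------------------

# reads the vendored CSVs directly and evaluates the rate law from scratch
oracle_kint <- function(sequence, position, pH, tempK,
                        n_terminal = TRUE, c_terminal = TRUE) {
  fdir <- system.file("extdata", package = "hdxkin")
  fac <- read.csv(file.path(fdir, "intrinsic_rate_factors.csv"),
                  comment.char = "#")
  rownames(fac) <- fac$key
  cst <- read.csv(file.path(fdir, "intrinsic_rate_constants.csv"),
                  comment.char = "#")
  cv <- setNames(cst$value, cst$name)
  aa <- strsplit(sequence, "")[[1]]
  pD <- pH
  getf <- function(code, col) {
    if (code %in% c("D", "E", "H")) {
      pk <- switch(code, D = cv["pKa_asp"], E = cv["pKa_glu"],
                   H = cv["pKa_his"])
      fp <- 1 / (1 + 10^(pD - pk))
      return(log10(fp * 10^fac[paste0(code, "_prot"), col] +
                     (1 - fp) * 10^fac[paste0(code, "_deprot"), col]))
    }
    fac[code, col]
  }
  FA <- getf(aa[position], "lamA") + getf(aa[position - 1], "rhoA")
  FB <- getf(aa[position], "lamB") + getf(aa[position - 1], "rhoB")
  if (position == 2 && n_terminal) {
    FA <- FA + fac["NT", "rhoA"]; FB <- FB + fac["NT", "rhoB"]
  }
  if (position == length(aa) && c_terminal) {
    fp <- 1 / (1 + 10^(pD - cv["pKa_cterm"]))
    FA <- FA + log10(fp * 10^fac["CT_prot", "lamA"] +
                       (1 - fp) * 10^fac["CT_deprot", "lamA"])
    FB <- FB + log10(fp * 10^fac["CT_prot", "lamB"] +
                       (1 - fp) * 10^fac["CT_deprot", "lamB"])
  }
  arr <- function(Ea) exp(-Ea * 1000 / cv[["R_cal"]] *
                            (1 / tempK - 1 / cv[["T_ref"]]))
  10^(cv[["lg_ka"]] + FA - pD) * arr(cv[["Ea_acid"]]) +
    10^(cv[["lg_kb"]] + FB + pD - cv[["pKD"]]) * arr(cv[["Ea_base"]]) +
    10^(cv[["lg_kw"]] + FB) * arr(cv[["Ea_water"]])
}

# ---- two-sphere SASA closed form ------------------------------------------

# exposed area of sphere 1 (expanded radius R1) partially buried by a
# second expanded sphere R2 at centre distance d
oracle_two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1
}
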