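# Uniform topology + coordinate model for single structures and
# multi-frame ensembles, plus backbone amide hydrogen construction.

STD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")

# CHARMM/AMBER residue aliases seen in MD-derived PDB files
AA3_ALIASES <- c(HSD = "HIS", HSE = "HIS", HSP = "HIS", HID = "HIS",
                 HIE = "HIS", HIP = "HIS", CYX = "CYS", CYM = "CYS")

#' One-letter amino-acid code for 3-letter residue names
#' @param aa3 character vector of 3-letter residue names
#' @return character vector of 1-letter codes ("X" if unknown)
#' @keywords internal
aa3to1 <- function(aa3) {
  aa3 <- toupper(aa3)
  alias <- AA3_ALIASES[aa3]
  aa3[!is.na(alias)] <- alias[!is.na(alias)]
  out <- bio3d::aa321(aa3)
  out[is.na(out)] <- "X"
  out
}

new_hdx_frame <- function(atoms, frame_index = 1L, box = NULL) {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, frame_index = as.integer(frame_index),
                 box = box),
            class = "hdx_frame")
}

#' @export
print.hdx_frame <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("hdx_frame: %d atoms, %d residues, chains: %s\n",
              nrow(a), nrow(unique(a[, c("chain", "resno")])),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' @export
print.hdx_ensemble <- function(x, ...) {
  cat(sprintf("hdx_ensemble: %d frame(s)\n", length(x$frames)))
  print(x$frames[[1]])
  invisible(x)
}

#' Construct an ensemble from frames
#'
#' An ensemble is an ordered list of frames sharing one topology (same
#' chains, residue numbers and names), with per-frame weights summing to 1.
#'
#' @param frames list of `hdx_frame` objects
#' @param weights optional per-frame weights (default uniform)
#' @return an `hdx_ensemble`
#' @export
hdx_ensemble <- function(frames, weights = NULL) {
  stopifnot(length(frames) >= 1)
  key <- function(fr) {
    a <- fr$atoms
    r <- unique(a[, c("chain", "resno", "resid")])
    paste(r$chain, r$resno, r$resid, collapse = ";")
  }
  k1 <- key(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(key(frames[[i]]), k1))
      stop("ensemble frames do not share an identical residue topology")
  }
  if (is.null(weights)) weights <- rep(1 / length(frames), length(frames))
  if (length(weights) != length(frames) || any(weights < 0))
    stop("weights must be non-negative, one per frame")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(list(frames = frames, weights = weights), class = "hdx_ensemble")
}

element_from_name <- function(elety, elesy = NULL) {
  n <- length(elety)
  el <- if (is.null(elesy)) rep("", n) else toupper(trimws(elesy))
  el[is.na(el)] <- ""
  fallback <- function(nm) {
    nm <- gsub("[0-9' ]", "", toupper(nm))
    # two-letter elements that occur in protein PDB files
    if (substr(nm, 1, 2) %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "NA"))
      return(substr(nm, 1, 2))
    substr(nm, 1, 1)
  }
  need <- el == ""
  el[need] <- vapply(elety[need], fallback, character(1))
  # hydrogens named 1HB, 2HG etc. start with a digit
  el[grepl("^[0-9]*H", gsub("[0-9' ]", "", toupper(elety)))] <- "H"
  el
}

read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 200L, warn = FALSE), value = TRUE)
  if (length(ln) == 0) return(NULL)
  abc <- suppressWarnings(as.numeric(c(substr(ln[1], 7, 15),
                                       substr(ln[1], 16, 24),
                                       substr(ln[1], 25, 33))))
  if (any(is.na(abc)) || any(abc <= 1)) return(NULL)  # placeholder 1 1 1
  abc
}

#' Read a PDB file into an ensemble
#'
#' Parses ATOM records (protein residues only) of a single- or multi-MODEL
#' PDB file into an [hdx_ensemble()]. Alternate locations are resolved by
#' keeping the highest-occupancy conformer (ties: first encountered).
#' Non-standard (HETATM) amino acids and waters are excluded with a warning.
#' Hydrogens present in the file (e.g. MD snapshots) are retained.
#'
#' @param path path to a PDB file
#' @param model_policy `"first"` (default) reads only the first MODEL;
#'   `"all"` returns one frame per MODEL.
#' @return an `hdx_ensemble`
#' @export
read_structure <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = (model_policy == "all"),
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  resid <- toupper(at$resid)
  alias <- AA3_ALIASES[resid]
  resid[!is.na(alias)] <- alias[!is.na(alias)]
  is_protein <- at$type == "ATOM" & resid %in% STD_AA3
  n_het_aa <- sum(at$type == "HETATM" & resid %in% STD_AA3)
  if (n_het_aa > 0)
    warning(n_het_aa, " HETATM amino-acid atoms excluded (non-standard residues)")
  if (!any(is_protein)) stop("no protein residues found in '", path, "'")

  keep <- which(is_protein)
  at <- at[keep, , drop = FALSE]
  at$resid <- resid[keep]
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"

  # altloc: highest occupancy per (chain, resno, insert, elety); tie -> first
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    id <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(id, -occ, seq_len(nrow(at)))
    dup <- duplicated(id[ord])
    sel <- sort(ord[!dup])
    at <- at[sel, , drop = FALSE]
    keep <- keep[sel]
  }

  elesy <- if ("elesy" %in% names(at)) at$elesy else NULL
  element <- element_from_name(at$elety, elesy)
  atoms0 <- data.frame(eleno = seq_len(nrow(at)), elety = trimws(at$elety),
                       resid = at$resid, chain = at$chain, resno = at$resno,
                       x = at$x, y = at$y, z = at$z,
                       element = element,
                       is_heavy = !(element %in% c("H", "D")),
                       stringsAsFactors = FALSE)
  box <- read_cryst1(path)

  xyz <- pdb$xyz
  nmod <- if (is.matrix(xyz)) nrow(xyz) else 1L
  if (model_policy == "first") nmod <- 1L
  frames <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    a <- atoms0
    if (is.matrix(xyz) && nrow(xyz) > 1) {
      cc <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
      a$x <- cc[, 1]; a$y <- cc[, 2]; a$z <- cc[, 3]
    }
    frames[[m]] <- new_hdx_frame(a, frame_index = m, box = box)
  }
  hdx_ensemble(frames)
}

#' Write one frame to a PDB file
#'
#' @param frame an `hdx_frame`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(frame, path) {
  a <- frame$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

# per-chain residue table in file order (ordered by resno within chain)
residue_table <- function(frame) {
  a <- frame$atoms
  r <- unique(a[, c("chain", "resno", "resid")])
  r <- r[order(r$chain, r$resno), , drop = FALSE]
  rownames(r) <- NULL
  r
}

atom_index <- function(atoms, chain, resno, elety) {
  which(atoms$chain == chain & atoms$resno == resno & atoms$elety %in% elety)
}

#' Per-residue amide bookkeeping
#'
#' Identifies, for every residue of a frame, whether it carries an
#' exchangeable backbone amide (not proline, not chain-initial) and the row
#' indices of its backbone N and amide H atoms (if present).
#'
#' @param frame an `hdx_frame`
#' @return data.frame with chain, resno, resid, exchanger flag, and atom
#'   row indices `i_n`, `i_h` (NA when absent)
#' @export
amide_table <- function(frame) {
  a <- frame$atoms
  r <- residue_table(frame)
  n <- nrow(r)
  i_n <- i_h <- rep(NA_integer_, n)
  first <- !duplicated(r$chain)
  for (i in seq_len(n)) {
    jn <- atom_index(a, r$chain[i], r$resno[i], "N")
    if (length(jn) >= 1) i_n[i] <- jn[1]
    jh <- atom_index(a, r$chain[i], r$resno[i], c("H", "HN"))
    if (length(jh) >= 1) i_h[i] <- jh[1]
  }
  exch <- !first & r$resid != "PRO"
  data.frame(chain = r$chain, resno = r$resno, resid = r$resid,
             exchanger = exch, i_n = i_n, i_h = i_h,
             stringsAsFactors = FALSE)
}

#' Construct missing backbone amide hydrogens
#'
#' Every residue that should carry a backbone amide hydrogen (not proline,
#' not chain-initial) and lacks one gets an H placed 1.01 Å from N, in the
#' plane of the preceding peptide group, anti (trans) to the preceding
#' carbonyl oxygen. Existing hydrogens are never moved; heavy atoms are
#' untouched, so the operation is idempotent. Residues with missing
#' backbone context (N or CA, or preceding C/O, e.g. across a numbering
#' gap) are left without an amide H and a warning names them; they are
#' excluded from exchange sums downstream.
#'
#' @param frame an `hdx_frame`
#' @param nh_length N-H bond length in Å (default 1.01)
#' @return a new `hdx_frame` with hydrogens added
#' @export
build_amide_hydrogens <- function(frame, nh_length = 1.01) {
  a <- frame$atoms
  r <- residue_table(frame)
  first <- !duplicated(r$chain)
  add <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(r))) {
    if (first[i] || r$resid[i] == "PRO") next
    if (length(atom_index(a, r$chain[i], r$resno[i], c("H", "HN"))) > 0) next
    prev_ok <- i > 1 && r$chain[i - 1] == r$chain[i] &&
      r$resno[i - 1] == r$resno[i] - 1L
    iN  <- atom_index(a, r$chain[i], r$resno[i], "N")
    iCA <- atom_index(a, r$chain[i], r$resno[i], "CA")
    iC  <- if (prev_ok) atom_index(a, r$chain[i], r$resno[i - 1], "C") else integer(0)
    iO  <- if (prev_ok) atom_index(a, r$chain[i], r$resno[i - 1], "O") else integer(0)
    if (length(iN) == 0 || length(iCA) == 0 || length(iC) == 0 ||
        length(iO) == 0) {
      skipped <- c(skipped, paste0(r$chain[i], ":", r$resno[i]))
      next
    }
    N <- as.numeric(a[iN[1], c("x", "y", "z")])
    C <- as.numeric(a[iC[1], c("x", "y", "z")])
    O <- as.numeric(a[iO[1], c("x", "y", "z")])
    e1 <- C - N; e1 <- e1 / sqrt(sum(e1^2))          # N -> C(prev)
    w <- O - C;  w <- w / sqrt(sum(w^2))
    p <- w - sum(w * e1) * e1                        # in-plane, O side
    if (sqrt(sum(p^2)) < 1e-6) {                     # degenerate: use CA
      CA <- as.numeric(a[iCA[1], c("x", "y", "z")])
      p <- (CA - N) - sum((CA - N) * e1) * e1
    }
    p <- p / sqrt(sum(p^2))
    th <- 119 * pi / 180                             # C-N-H angle
    d <- cos(th) * e1 - sin(th) * p                  # anti to O across C-N
    H <- N + nh_length * d
    add[[length(add) + 1]] <- data.frame(
      eleno = NA_integer_, elety = "H", resid = r$resid[i],
      chain = r$chain[i], resno = r$resno[i],
      x = H[1], y = H[2], z = H[3], element = "H", is_heavy = FALSE,
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0)
    warning("missing backbone atoms; no amide H built for: ",
            paste(skipped, collapse = ", "))
  if (length(add) > 0) {
    a <- rbind(a, do.call(rbind, add))
    # keep residue grouping: order atoms by chain, resno (stable)
    a <- a[order(a$chain, a$resno), , drop = FALSE]
    a$eleno <- seq_len(nrow(a))
    rownames(a) <- NULL
  }
  new_hdx_frame(a, frame_index = frame$frame_index, box = frame$box)
}

#' Apply an operation to every frame of an ensemble
#' @param ensemble an `hdx_ensemble`
#' @param f function taking and returning an `hdx_frame`
#' @return a new `hdx_ensemble`
#' @export
map_frames <- function(ensemble, f) {
  hdx_ensemble(lapply(ensemble$frames, f), weights = ensemble$weights)
}

#' Chain descriptors of an ensemble
#'
#' One row per chain with residue range, 1-letter sequence, and any gaps in
#' the author residue numbering (reported as "first-last" strings).
#'
#' @param ensemble an `hdx_ensemble` (topology taken from frame 1)
#' @return data.frame: chain, first_resno, last_resno, n_residues, sequence,
#'   gaps
#' @export
chain_map <- function(ensemble) {
  r <- residue_table(ensemble$frames[[1]])
  out <- lapply(split(r, r$chain), function(rc) {
    resno <- rc$resno
    gaps <- character(0)
    d <- diff(resno)
    for (k in which(d > 1)) {
      gaps <- c(gaps, paste0(resno[k] + 1L, "-", resno[k + 1L] - 1L))
    }
    data.frame(chain = rc$chain[1], first_resno = min(resno),
               last_resno = max(resno), n_residues = nrow(rc),
               sequence = paste(aa3to1(rc$resid), collapse = ""),
               gaps = paste(gaps, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
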