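# Peptide fragment assignment by monoisotopic mass: exhaustive subsequence
# search against the protein sequence and validation of fragment tables.

# monoisotopic residue masses (Da), neutral peptide = sum + water
MONO_RESIDUE_MASS <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295)

MONO_WATER <- 18.01056468

#' Monoisotopic mass of a peptide
#'
#' Neutral, unmodified peptide: sum of monoisotopic residue masses plus one
#' water.
#'
#' @param sequence 1-letter amino-acid string (standard residues only)
#' @return mass in Da
#' @export
monoisotopic_mass <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 ||
      nchar(sequence) == 0)
    stop("sequence must be a non-empty string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(MONO_RESIDUE_MASS))
  if (length(bad) > 0)
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  sum(MONO_RESIDUE_MASS[aa]) + MONO_WATER
}

#' Search a protein sequence for peptides matching an observed mass
#'
#' Exhaustive scan of all contiguous subsequences within the length bounds;
#' candidates whose computed monoisotopic mass lies within `tolerance_ppm`
#' of the observed mass are ranked by absolute ppm error (ties broken by
#' length, then start position).
#'
#' @param observed_mass observed neutral monoisotopic mass in Da
#' @param protein_sequence 1-letter string of the whole chain
#' @param tolerance_ppm matching tolerance in parts per million (default 50)
#' @param length_bounds integer vector c(min, max) of candidate peptide
#'   lengths (default c(4, 40))
#' @param numbering_offset author number of the first residue minus 1
#'   (default 0: the first residue is number 1)
#' @return data.frame: start, end, sequence, monoisotopic_mass, error_da,
#'   error_ppm, ordered best first (possibly empty)
#' @export
reassign <- function(observed_mass, protein_sequence, tolerance_ppm = 50,
                     length_bounds = c(4, 40), numbering_offset = 0) {
  stopifnot(observed_mass > 0, tolerance_ppm > 0,
            length(length_bounds) == 2, length_bounds[1] >= 1)
  aa <- strsplit(toupper(protein_sequence), "")[[1]]
  n <- length(aa)
  res_mass <- MONO_RESIDUE_MASS[aa]
  if (any(is.na(res_mass)))
    stop("protein sequence contains non-standard residue codes")
  prefix <- c(0, cumsum(res_mass))
  lens <- seq(length_bounds[1], min(length_bounds[2], n))
  rows <- list()
  for (L in lens) {
    starts <- seq_len(n - L + 1)
    mass <- prefix[starts + L] - prefix[starts] + MONO_WATER
    ppm <- (mass - observed_mass) / observed_mass * 1e6
    hit <- which(abs(ppm) <= tolerance_ppm)
    if (length(hit) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        start = starts[hit] + numbering_offset,
        end = starts[hit] + L - 1 + numbering_offset,
        sequence = vapply(hit, function(h)
          paste(aa[starts[h]:(starts[h] + L - 1)], collapse = ""),
          character(1)),
        monoisotopic_mass = mass[hit],
        error_da = mass[hit] - observed_mass,
        error_ppm = ppm[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0),
                      monoisotopic_mass = numeric(0),
                      error_da = numeric(0), error_ppm = numeric(0)))
  out <- do.call(rbind, rows)
  len <- out$end - out$start
  out <- out[order(abs(out$error_ppm), len, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a fragment table against the protein sequence by mass
#'
#' For every fragment with an observed monoisotopic mass, compares the mass
#' computed from the assigned range with the observation; mismatches beyond
#' the tolerance are re-searched with [reassign()] and reported with their
#' top alternatives.
#'
#' @param fragments an [hdx_fragments()] table (columns start, end,
#'   observed_mass; sequence derived from `protein_sequence`)
#' @param protein_sequence 1-letter string of the whole chain
#' @param tolerance_ppm match tolerance in ppm (default 50)
#' @param numbering_offset author number of the first residue minus 1
#' @param n_alternatives alternatives to report for mismatches (default 3)
#' @return data.frame: id, start, end, observed_mass, computed_mass,
#'   error_ppm, status ("match", "mismatch", "skipped"), best_alternative
#'   ("start-end" of the top re-search hit, "" when none)
#' @export
validate_fragment_table <- function(fragments, protein_sequence,
                                    tolerance_ppm = 50,
                                    numbering_offset = 0,
                                    n_alternatives = 3) {
  aa <- strsplit(toupper(protein_sequence), "")[[1]]
  out <- lapply(seq_len(nrow(fragments)), function(i) {
    fr <- fragments[i, ]
    row <- data.frame(id = as.character(fr$id), start = fr$start,
                      end = fr$end, observed_mass = fr$observed_mass,
                      computed_mass = NA_real_, error_ppm = NA_real_,
                      status = "skipped", best_alternative = "",
                      stringsAsFactors = FALSE)
    if (is.null(fr$observed_mass) || is.na(fr$observed_mass)) return(row)
    i1 <- fr$start - numbering_offset
    i2 <- fr$end - numbering_offset
    if (i1 < 1 || i2 > length(aa)) return(row)
    m <- monoisotopic_mass(paste(aa[i1:i2], collapse = ""))
    row$computed_mass <- m
    row$error_ppm <- (m - fr$observed_mass) / fr$observed_mass * 1e6
    if (abs(row$error_ppm) <= tolerance_ppm) {
      row$status <- "match"
    } else {
      row$status <- "mismatch"
      alt <- reassign(fr$observed_mass, protein_sequence, tolerance_ppm,
                      numbering_offset = numbering_offset)
      if (nrow(alt) > 0) {
        top <- utils::head(alt, n_alternatives)
        row$best_alternative <- paste(
          paste0(top$start, "-", top$end), collapse = ";")
      }
    }
    row
  })
  do.call(rbind, out)
}

#' Read a protein sequence from a FASTA file
#'
#' @param path FASTA path (first record is used)
#' @return 1-letter sequence string
#' @export
read_protein_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readAAStringSet(path)
    if (length(s) == 0) stop("no sequence in '", path, "'")
    return(as.character(s[[1]]))
  }
  ln <- readLines(path, warn = FALSE)
  if (length(ln) == 0 || !startsWith(ln[1], ">"))
    stop("not a FASTA file: '", path, "'")
  stop_at <- which(startsWith(ln, ">"))
  end <- if (length(stop_at) > 1) stop_at[2] - 1 else length(ln)
  paste(toupper(ln[2:end]), collapse = "")
}
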