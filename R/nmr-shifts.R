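## Secondary chemical shifts, solution-vs-solid chemical-shift perturbation
## mapping, and residue-type signal accounting.

#' Chemical-shift table
#'
#' Rows of (residue number, one-letter amino-acid code, atom, shift in ppm),
#' restricted to backbone Ca/Cb carbons. Glycine rows never carry CB; at
#' most one entry per (residue, atom).
#'
#' @param df Data frame with columns `resno`, `aa`, `atom` ("CA"/"CB"),
#'   `shift_ppm`.
#' @return Object of class `shift_table` (a data frame).
#' @export
shift_table <- function(df) {
  need <- c("resno", "aa", "atom", "shift_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$atom %in% c("CA", "CB")))
    stop("atom must be CA or CB")
  if (any(df$aa == "G" & df$atom == "CB"))
    stop("glycine rows cannot carry CB")
  if (anyDuplicated(df[, c("resno", "atom")]))
    stop("duplicate (residue, atom) entries")
  if (any(df$shift_ppm < 0 | df$shift_ppm > 200))
    stop("shift(s) outside the 0-200 ppm sanity band")
  rownames(df) <- NULL
  structure(df[order(df$resno, df$atom), ],
            class = c("shift_table", "data.frame"))
}

#' Read a shift table from TSV
#'
#' Expected columns: `resno`, `aa`, `atom`, `shift_ppm`.
#'
#' @param path TSV file path.
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path) {
  shift_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a simplified NMR-STAR chemical-shift loop
#'
#' Parses an `Atom_chem_shift` loop with (at least) the tags
#' `Comp_index_ID`, `Comp_ID`, `Atom_ID` and `Val`; only CA/CB rows are
#' kept. Three-letter residue codes are converted to one-letter.
#'
#' @param path NMR-STAR (subset) file path.
#' @return A [shift_table()].
#' @export
read_nmr_star <- function(path) {
  lines <- readLines(path)
  tag_idx <- grep("^\\s*_Atom_chem_shift\\.", lines)
  if (!length(tag_idx)) stop("no _Atom_chem_shift loop found in ", path)
  tags <- sub("^\\s*_Atom_chem_shift\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  body <- lines[body_start:length(lines)]
  stop_at <- grep("^\\s*(stop_|loop_|save_)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]
  body <- trimws(body[nzchar(trimws(body))])
  fields <- strsplit(body, "\\s+")
  bad <- which(lengths(fields) != length(tags))
  if (length(bad))
    stop("malformed loop row at data line ", bad[1])
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
  miss <- setdiff(need, tags)
  if (length(miss)) stop("loop lacks tag(s): ", paste(miss, collapse = ", "))
  keep <- m[, "Atom_ID"] %in% c("CA", "CB")
  m <- m[keep, , drop = FALSE]
  shift_table(data.frame(
    resno = as.integer(m[, "Comp_index_ID"]),
    aa = aa321(m[, "Comp_ID"]),
    atom = m[, "Atom_ID"],
    shift_ppm = as.numeric(m[, "Val"])))
}

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

aa321 <- function(x) {
  out <- .aa3[toupper(x)]
  if (anyNA(out)) stop("unknown residue name(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Read a random-coil Ca/Cb reference table
#'
#' Columns `aa` (one-letter), `ca_ppm`, `cb_ppm` (NA for glycine). The
#' bundled default carries standard DSS-referenced literature values for all
#' 20 amino acids.
#'
#' @param path TSV path; default the bundled table.
#' @return Data frame of class `random_coil_table`.
#' @export
read_random_coil_table <- function(path = system.file(
    "extdata", "random_coil_ca_cb.tsv", package = "helifil")) {
  rc <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "ca_ppm", "cb_ppm") %in% names(rc)))
  if (length(setdiff(unname(.aa3), rc$aa)))
    stop("random-coil table must cover all 20 amino acids")
  structure(rc, class = c("random_coil_table", "data.frame"))
}

#' Secondary chemical shifts
#'
#' Per-residue deviations of observed Ca/Cb shifts from random-coil values.
#' By convention `delta = observed - random coil` (positive Ca deviations
#' indicate helical propensity); set `convention = "rc_minus_obs"` to flip
#' the sign. Missing atoms yield NA, never zero.
#'
#' @param obs A [shift_table()].
#' @param rc A [read_random_coil_table()] table.
#' @param convention `"obs_minus_rc"` (default) or `"rc_minus_obs"`.
#' @return Data frame with `resno`, `aa`, `d_ca`, `d_cb`.
#' @export
secondary_shifts <- function(obs, rc,
                             convention = c("obs_minus_rc", "rc_minus_obs")) {
  convention <- match.arg(convention)
  stopifnot(inherits(obs, "shift_table"))
  unknown <- setdiff(obs$aa, rc$aa)
  if (length(unknown))
    stop("residue type(s) absent from random-coil table: ",
         paste(unknown, collapse = ", "))
  resno <- sort(unique(obs$resno))
  rows <- lapply(resno, function(r) {
    sub <- obs[obs$resno == r, ]
    aa <- sub$aa[1]
    ref <- rc[rc$aa == aa, ]
    pick <- function(atom, refv) {
      v <- sub$shift_ppm[sub$atom == atom]
      if (!length(v) || is.na(refv)) return(NA_real_)
      d <- v - refv
      if (convention == "rc_minus_obs") -d else d
    }
    data.frame(resno = r, aa = aa,
               d_ca = pick("CA", ref$ca_ppm),
               d_cb = pick("CB", ref$cb_ppm))
  })
  do.call(rbind, rows)
}

#' Solution-vs-solid chemical-shift perturbation
#'
#' For each residue present in both tables, the sum of absolute per-atom
#' shift differences `|dCA| + |dCB|` (a missing atom in either state simply
#' omits that term); residues at or above `threshold` are flagged. Residues
#' present in only one table are listed as unassessed.
#'
#' @param solution,solid [shift_table()] objects for the two states.
#' @param threshold Flagging threshold in ppm (default 1.2).
#' @param mode `"absolute"` flags `sum >= threshold`; `"from_mean"` flags
#'   `|sum - mean(sum)| >= threshold`.
#' @return List with data frame `perturbation` (`resno`, `aa`, `sum_ppm`,
#'   `n_atoms`, `flag`) and integer vector `unassessed`.
#' @export
state_perturbation <- function(solution, solid, threshold = 1.2,
                               mode = c("absolute", "from_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(solution, "shift_table"), inherits(solid, "shift_table"))
  if (threshold <= 0) stop("`threshold` must be positive")
  key <- function(t) paste(t$resno, t$atom)
  common_res <- intersect(solution$resno, solid$resno)
  unassessed <- sort(union(setdiff(solution$resno, solid$resno),
                           setdiff(solid$resno, common_res)))
  rows <- lapply(sort(common_res), function(r) {
    s1 <- solution[solution$resno == r, ]
    s2 <- solid[solid$resno == r, ]
    atoms <- intersect(s1$atom, s2$atom)
    d <- vapply(atoms, function(at)
      abs(s2$shift_ppm[s2$atom == at] - s1$shift_ppm[s1$atom == at]),
      numeric(1))
    data.frame(resno = r, aa = s1$aa[1], sum_ppm = sum(d),
               n_atoms = length(atoms))
  })
  pert <- do.call(rbind, rows)
  pert$flag <- if (mode == "absolute") pert$sum_ppm >= threshold
               else abs(pert$sum_ppm - mean(pert$sum_ppm)) >= threshold
  list(perturbation = pert, unassessed = unassessed)
}

#' Residue-type signal accounting
#'
#' Compares, per amino-acid type, the number of residues with assigned
#' signals against the number present in the construct sequence, and lists
#' the missing positions — used to localise unobserved (disordered) regions.
#'
#' @param assigned Integer vector of residue numbers with assigned signals.
#' @param sequence One-letter sequence (vector or single string) of the
#'   construct.
#' @param types Amino-acid one-letter codes to account for.
#' @param first_resno Residue number of the first sequence position.
#' @return Data frame with `aa`, `observed`, `expected`, `missing`
#'   (comma-joined positions).
#' @export
signal_accounting <- function(assigned, sequence, types = c("L", "T", "V", "P"),
                              first_resno = 1L) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  resno <- seq_along(sequence) + first_resno - 1L
  outside <- setdiff(assigned, resno)
  if (length(outside))
    stop("assigned residue(s) outside sequence: ",
         paste(outside, collapse = ", "))
  rows <- lapply(types, function(tt) {
    pos <- resno[sequence == tt]
    obs <- intersect(pos, assigned)
    data.frame(aa = tt, observed = length(obs), expected = length(pos),
               missing = paste(setdiff(pos, obs), collapse = ","))
  })
  do.call(rbind, rows)
}
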