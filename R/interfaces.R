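## Inter-subunit contact extraction and death-domain type I/II/III interface
## classification for helical assemblies.

#' Inter-subunit atomic contacts grouped by subunit-index offset
#'
#' All heavy-atom pairs between subunit 0 and subunit k within `cutoff`, for
#' `k = 1 .. max_offset`. The assembly must come from [build_filament()] (its
#' atoms carry a `subunit` column) and contain at least `max_offset + 1`
#' subunits.
#'
#' @param assembly Structure from [build_filament()].
#' @param cutoff Distance cutoff in Angstrom (default 4.0, heavy atom).
#' @param max_offset Largest subunit-index offset examined.
#' @return Data frame with columns `offset`, `resno_i`, `elety_i`, `resid_i`,
#'   `resno_j`, `elety_j`, `resid_j`, `dist`, ordered by offset, residue and
#'   atom.
#' @export
subunit_contacts <- function(assembly, cutoff = 4.0, max_offset = 4L) {
  stopifnot(inherits(assembly, "fil_structure"))
  a <- assembly$atoms
  if (is.null(a$subunit)) stop("assembly atoms carry no `subunit` index; ",
                               "build it with build_filament()")
  subs <- sort(unique(a$subunit))
  if (length(subs) < max_offset + 1L)
    stop("assembly has ", length(subs), " subunits; need >= ", max_offset + 1L)
  if (cutoff <= 0) stop("`cutoff` must be positive")
  base <- a[a$subunit == subs[1], ]
  out <- list()
  for (k in seq_len(max_offset)) {
    other <- a[a$subunit == subs[1] + k, ]
    d2 <- outer(base$x, other$x, `-`)^2 + outer(base$y, other$y, `-`)^2 +
      outer(base$z, other$z, `-`)^2
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      offset = k,
      resno_i = base$resno[hit[, 1]], elety_i = base$elety[hit[, 1]],
      resid_i = base$resid[hit[, 1]],
      resno_j = other$resno[hit[, 2]], elety_j = other$elety[hit[, 2]],
      resid_j = other$resid[hit[, 2]],
      dist = sqrt(d2[hit]))
  }
  if (!length(out))
    return(data.frame(offset = integer(0), resno_i = integer(0),
                      elety_i = character(0), resid_i = character(0),
                      resno_j = integer(0), elety_j = character(0),
                      resid_j = character(0), dist = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$offset, res$resno_i, res$elety_i, res$resno_j, res$elety_j), ,
      drop = FALSE]
}

#' Load interface annotations
#'
#' Reads a JSON list of interface annotations, each with fields `type`
#' ("I"/"II"/"III"), `surface_a` and `surface_b` (residue-number vectors)
#' and `pairs` (list of `[res_a, res_b]` interactions). The curated
#' annotation transcribed for the CARD filament studied here ships with the
#' package.
#'
#' @param path JSON file; default the bundled annotation.
#' @return List of class `interface_annotations`.
#' @export
read_interface_annotations <- function(path = system.file(
    "extdata", "card_interface_annotations.json", package = "helifil")) {
  ann <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ann <- lapply(ann, function(a) {
    if (!all(c("type", "surface_a", "surface_b") %in% names(a)))
      stop("annotation entries need fields type, surface_a, surface_b")
    a$surface_a <- as.numeric(unlist(a$surface_a))
    a$surface_b <- as.numeric(unlist(a$surface_b))
    a$pairs <- lapply(a$pairs, function(p) as.numeric(unlist(p)))
    a
  })
  structure(ann, class = "interface_annotations")
}

jaccard <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0) return(0)
  length(intersect(x, y)) / u
}

#' Classify contact offsets as interface types
#'
#' Each populated subunit-index offset is assigned the annotation whose
#' surface residue sets best overlap the contacting residue sets, scored by
#' the mean Jaccard index of the two sides (both surface orientations are
#' tried; the better one counts). Offsets with no contacts are labelled
#' `"other"` with score 0.
#'
#' @param contacts Output of [subunit_contacts()].
#' @param annotations [read_interface_annotations()] output.
#' @return Data frame with `offset`, `type`, `score`.
#' @export
classify_offsets <- function(contacts, annotations) {
  stopifnot(inherits(annotations, "interface_annotations"))
  offsets <- sort(unique(contacts$offset))
  rows <- lapply(offsets, function(k) {
    cc <- contacts[contacts$offset == k, ]
    res_i <- unique(cc$resno_i); res_j <- unique(cc$resno_j)
    if (!length(res_i)) return(data.frame(offset = k, type = "other", score = 0))
    scores <- vapply(annotations, function(a) {
      fwd <- (jaccard(res_i, a$surface_a) + jaccard(res_j, a$surface_b)) / 2
      rev <- (jaccard(res_i, a$surface_b) + jaccard(res_j, a$surface_a)) / 2
      max(fwd, rev)
    }, numeric(1))
    best <- which.max(scores)
    data.frame(offset = k,
               type = if (scores[best] > 0) annotations[[best]]$type else "other",
               score = scores[best])
  })
  do.call(rbind, rows)
}

# heavy charged-group atoms for salt-bridge candidates
.charged_atoms <- list(
  positive = list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                  HIS = c("ND1", "NE2")),
  negative = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")))

#' Per-type interface report
#'
#' For every annotated residue pair, reports whether an inter-subunit
#' heavy-atom contact within `cutoff` exists (at any offset up to
#' `max_offset`), together with the minimal distance found; also lists
#' salt-bridge candidates (charged-group N/O pairs within
#' `salt_bridge_cutoff`).
#'
#' @param assembly Structure from [build_filament()].
#' @param annotations [read_interface_annotations()] output; residue numbers
#'   must lie within the modelled range of the assembly.
#' @param cutoff Contact cutoff, Angstrom.
#' @param max_offset Largest offset examined.
#' @param salt_bridge_cutoff Charged-group cutoff, Angstrom.
#' @return List with data frames `pairs` (type, res_a, res_b, found,
#'   min_dist, offset) and `salt_bridges` (offset, resno_i, resno_j,
#'   elety_i, elety_j, dist).
#' @export
interface_report <- function(assembly, annotations, cutoff = 4.0,
                             max_offset = 4L, salt_bridge_cutoff = 4.0) {
  stopifnot(inherits(annotations, "interface_annotations"))
  rng <- range(assembly$atoms$resno)
  for (a in annotations) {
    res <- c(a$surface_a, a$surface_b, unlist(a$pairs))
    if (any(res < rng[1] | res > rng[2]))
      stop("annotation type ", a$type, " references residue(s) outside the ",
           "modelled range ", rng[1], "-", rng[2], ": ",
           paste(res[res < rng[1] | res > rng[2]], collapse = ", "))
  }
  contacts <- subunit_contacts(assembly, cutoff = max(cutoff, 10),
                               max_offset = max_offset)
  pair_rows <- list()
  for (a in annotations) {
    for (p in a$pairs) {
      # a pair may be realised in either orientation across the interface
      cand <- contacts[(contacts$resno_i == p[1] & contacts$resno_j == p[2]) |
                       (contacts$resno_i == p[2] & contacts$resno_j == p[1]), ]
      if (nrow(cand)) {
        i <- which.min(cand$dist)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          type = a$type, res_a = p[1], res_b = p[2],
          found = cand$dist[i] <= cutoff, min_dist = cand$dist[i],
          offset = cand$offset[i])
      } else {
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          type = a$type, res_a = p[1], res_b = p[2],
          found = FALSE, min_dist = NA_real_, offset = NA_integer_)
      }
    }
  }
  sb <- contacts[contacts$dist <= salt_bridge_cutoff, ]
  is_charged_pair <- function(resid_i, elety_i, resid_j, elety_j) {
    pos_i <- elety_i %in% .charged_atoms$positive[[resid_i]]
    neg_i <- elety_i %in% .charged_atoms$negative[[resid_i]]
    pos_j <- elety_j %in% .charged_atoms$positive[[resid_j]]
    neg_j <- elety_j %in% .charged_atoms$negative[[resid_j]]
    isTRUE((pos_i && neg_j) || (neg_i && pos_j))
  }
  if (nrow(sb)) {
    keep <- mapply(is_charged_pair, sb$resid_i, sb$elety_i,
                   sb$resid_j, sb$elety_j)
    sb <- sb[keep, c("offset", "resno_i", "elety_i", "resno_j", "elety_j",
                     "dist")]
  } else {
    sb <- data.frame(offset = integer(0), resno_i = integer(0),
                     elety_i = character(0), resno_j = integer(0),
                     elety_j = character(0), dist = numeric(0))
  }
  list(pairs = do.call(rbind, pair_rows), salt_bridges = sb)
}

#' Inter-subunit burial of selected residues
#'
#' Counts, for each requested residue, the inter-subunit heavy-atom contacts
#' it makes (as part of either subunit of a pair) and the offsets involved —
#' the quantitative rationale for interface-disrupting mutations.
#'
#' @param assembly Structure from [build_filament()].
#' @param residues Integer residue numbers.
#' @param cutoff Contact cutoff, Angstrom.
#' @param max_offset Largest offset examined.
#' @return Data frame with `resno`, `n_contacts`, `offsets` (comma-joined).
#' @export
mutation_burial <- function(assembly, residues, cutoff = 4.0,
                            max_offset = 4L) {
  known <- unique(assembly$atoms$resno)
  bad <- setdiff(residues, known)
  if (length(bad))
    stop("residue(s) not in model: ", paste(bad, collapse = ", "))
  contacts <- subunit_contacts(assembly, cutoff, max_offset)
  rows <- lapply(residues, function(r) {
    cc <- contacts[contacts$resno_i == r | contacts$resno_j == r, ]
    data.frame(resno = r, n_contacts = nrow(cc),
               offsets = paste(sort(unique(cc$offset)), collapse = ","))
  })
  do.call(rbind, rows)
}
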