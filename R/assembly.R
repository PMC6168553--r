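## Filament assembly generation from a monomer, radial geometry, and
## rigid-body superposition / RMSD.

#' Atomic structure container
#'
#' A light container for heavy-atom models: a data frame of atoms with
#' columns `eleno` (serial), `elety` (atom name), `resid` (residue name),
#' `chain`, `resno`, `x`, `y`, `z` (Angstrom) and `element`.
#'
#' @param atoms Data frame with at least `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z`; `eleno` and `element` are filled in when missing.
#' @return Object of class `fil_structure`.
#' @export
fil_structure <- function(atoms) {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lack column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[^A-Za-z].*", "", atoms$elety), 1, 1)
  dup <- duplicated(atoms[, c("chain", "resno", "elety")])
  if (any(dup))
    stop("duplicated atom(s): ",
         paste(utils::head(paste(atoms$chain[dup], atoms$resno[dup],
                                 atoms$elety[dup]), 3), collapse = "; "))
  structure(list(atoms = atoms), class = "fil_structure")
}

#' @export
print.fil_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("fil_structure: %d atoms, %d chain(s), residues %d-%d\n",
              nrow(a), length(unique(a$chain)), min(a$resno), max(a$resno)))
  invisible(x)
}

#' Coordinate matrix of (a selection of) a structure
#'
#' @param struct A [fil_structure()].
#' @param elety Atom-name filter (e.g. `"CA"`); NULL keeps all.
#' @param resno Residue-number filter; NULL keeps all.
#' @param chain Chain filter; NULL keeps all.
#' @return Numeric matrix n x 3.
#' @export
coords_of <- function(struct, elety = NULL, resno = NULL, chain = NULL) {
  a <- struct$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  as.matrix(a[keep, c("x", "y", "z")])
}

# Chain identifiers in subunit order: A..Z, a..z, 0..9, then two-character.
chain_ids <- function(n) {
  single <- c(LETTERS, letters, 0:9)
  if (n <= length(single)) return(single[seq_len(n)])
  c(single, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(n)]
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' Build a filament assembly from a monomer
#'
#' Places copies of the monomer at subunits `k_range[1] .. k_range[2]`:
#' subunit k is the monomer rotated about +z by `k * twist` and translated
#' by `k * rise` along +z. One chain per subunit, chain ids assigned in k
#' order; subunit 0 is identical to the input monomer. The monomer must
#' already be positioned with the filament axis along z.
#'
#' @param monomer A [fil_structure()] (single chain recommended).
#' @param sym A [helical_symmetry()].
#' @param k_range Integer vector `c(k_min, k_max)`.
#' @return A multi-chain [fil_structure()] with attribute `subunit` on its
#'   atoms and the symmetry stored in `$symmetry`.
#' @export
build_filament <- function(monomer, sym, k_range = c(0L, 9L)) {
  stopifnot(inherits(monomer, "fil_structure"),
            inherits(sym, "helical_symmetry"))
  ks <- seq.int(k_range[1], k_range[2])
  ids <- chain_ids(length(ks))
  xyz <- as.matrix(monomer$atoms[, c("x", "y", "z")])
  pieces <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    new_xyz <- xyz %*% t(rot_z(k * sym$twist_deg))
    new_xyz[, 3] <- new_xyz[, 3] + k * sym$rise_ang
    a <- monomer$atoms
    a$x <- new_xyz[, 1]; a$y <- new_xyz[, 2]; a$z <- new_xyz[, 3]
    a$chain <- ids[i]
    a$subunit <- k
    a
  })
  atoms <- do.call(rbind, pieces)
  atoms$eleno <- seq_len(nrow(atoms))
  out <- fil_structure(atoms)
  out$symmetry <- sym
  out$k_range <- as.integer(k_range)
  out
}

#' Radial extents of a structure about the z axis
#'
#' @param struct A [fil_structure()] (or bare n x 3 matrix).
#' @param per_residue If TRUE, radii are measured on residue centroids.
#' @return Named numeric vector `c(inner = min radius, outer = max radius)`,
#'   Angstrom.
#' @export
radial_extents <- function(struct, per_residue = FALSE) {
  if (inherits(struct, "fil_structure")) {
    a <- struct$atoms
    if (per_residue) {
      key <- paste(a$chain, a$resno)
      x <- tapply(a$x, key, mean); y <- tapply(a$y, key, mean)
    } else { x <- a$x; y <- a$y }
  } else { x <- struct[, 1]; y <- struct[, 2] }
  if (!length(x)) stop("no atoms")
  r <- sqrt(x^2 + y^2)
  c(inner = min(r), outer = max(r))
}

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Finds the proper rotation (det = +1) and translation minimising the RMSD
#' between two paired coordinate sets, via the SVD of the cross-covariance.
#'
#' @param a,b Numeric n x 3 matrices of paired coordinates (n >= 3); `b` is
#'   moved onto `a`.
#' @return List with `rmsd` (Angstrom), `rotation` (3 x 3), `translation`
#'   (length 3): the fitted copy is `b %*% t(rotation) + translation`.
#' @export
superpose_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3)
    stop("need two equally sized n x 3 coordinate matrices")
  if (nrow(a) < 3) stop("need at least 3 point pairs")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (qr(a0)$rank < 2 || qr(b0)$rank < 2)
    stop("degenerate (collinear) point set: superposition is not unique")
  s <- svd(crossprod(b0, a0))          # 3x3
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- b0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((a0 - fitted)^2)))
  list(rmsd = rmsd, rotation = R,
       translation = as.numeric(ca - cb %*% t(R)))
}

#' RMSD without superposition
#'
#' @param a,b Paired n x 3 coordinate matrices.
#' @return RMSD in the fixed frame, Angstrom.
#' @export
rmsd_fixed_frame <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Pair atoms of two structures by residue number and atom name
#'
#' @param a,b [fil_structure()] objects.
#' @param elety Atom names used for pairing (default Calpha only).
#' @param resno Optional residue-number restriction.
#' @return List with matrices `xyz_a`, `xyz_b` (paired, same order) and
#'   `unpaired` (residue numbers present in only one structure).
#' @export
pair_atoms <- function(a, b, elety = "CA", resno = NULL) {
  sel <- function(s) {
    at <- s$atoms[s$atoms$elety %in% elety, ]
    if (!is.null(resno)) at <- at[at$resno %in% resno, ]
    at[order(at$resno, at$elety), ]
  }
  aa <- sel(a); bb <- sel(b)
  key_a <- paste(aa$resno, aa$elety); key_b <- paste(bb$resno, bb$elety)
  common <- intersect(key_a, key_b)
  list(xyz_a = as.matrix(aa[match(common, key_a), c("x", "y", "z")]),
       xyz_b = as.matrix(bb[match(common, key_b), c("x", "y", "z")]),
       unpaired = union(setdiff(aa$resno, bb$resno),
                        setdiff(bb$resno, aa$resno)))
}
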