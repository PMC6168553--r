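## Format readers and writers: PDB/mmCIF atomic models (through bio3d) and
## MRC image stacks / spectra (minimal reader-writer, modes 0/1/2).

#' Read an atomic structure from PDB or mmCIF
#'
#' ATOM/HETATM records are parsed into a [fil_structure()]; coordinates in
#' Angstrom, insertion codes preserved (appended to `resno` as an attribute
#' column `insert`). Format is auto-detected from the extension (`.cif` =
#' mmCIF, otherwise PDB) unless given.
#'
#' @param path File path.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`.
#' @return A [fil_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  if (format == "pdb") .validate_pdb_lines(path)
  obj <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  a <- obj$atom
  fil_structure(data.frame(
    eleno = a$eleno, elety = a$elety, resid = a$resid, chain = a$chain,
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(a$elety, 1, 1), a$elesy)))
}

# line-numbered sanity check of fixed-column coordinate fields
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    l <- lines[i]
    if (nchar(l) < 54)
      stop("malformed ATOM/HETATM record at line ", i,
           ": truncated before coordinate fields")
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM/HETATM record at line ", i,
           ": unparseable coordinate field")
  }
  invisible(TRUE)
}

#' Write an atomic structure to PDB or mmCIF
#'
#' PDB output refuses assemblies with more than 62 chains (the single
#' character chain-id space); use mmCIF for larger filaments.
#'
#' @param struct A [fil_structure()].
#' @param path Output path; format from extension unless given.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`.
#' @export
write_structure <- function(struct, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  stopifnot(inherits(struct, "fil_structure"))
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  a <- struct$atoms
  if (format == "pdb") {
    if (length(unique(a$chain)) > 62)
      stop("PDB chain ids are single characters: ", length(unique(a$chain)),
           " chains do not fit; write mmCIF instead")
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, eleno = a$eleno,
                     elety = a$elety, chain = a$chain,
                     elesy = a$element)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("data_helifil", "#", "loop_",
                 "_atom_site.group_PDB", "_atom_site.id",
                 "_atom_site.type_symbol", "_atom_site.label_atom_id",
                 "_atom_site.label_comp_id", "_atom_site.label_asym_id",
                 "_atom_site.label_entity_id", "_atom_site.label_seq_id",
                 "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
                 "_atom_site.Cartn_y", "_atom_site.Cartn_z",
                 "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
                 "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
                 "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
                 "_atom_site.auth_atom_id",
                 "_atom_site.pdbx_PDB_model_num"), con)
    writeLines(sprintf(
      "ATOM %d %s %s %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
      a$eleno, a$element, a$elety, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety), con)
    writeLines("#", con)
  }
  invisible(path)
}

## ---- MRC (map/image) format, minimal: modes 0 (int8), 1 (int16),
## 2 (float32); always little-endian ----

#' Read an MRC image stack
#'
#' Supports data modes 0, 1 and 2; the pixel size is taken from the header
#' cell (`cella/mx`), falling back to `pixel_size_ang` when the header
#' carries none.
#'
#' @param path MRC file.
#' @param pixel_size_ang Fallback sampling in Angstrom per pixel.
#' @return An `image_stack` (array rows x cols x sections; section index =
#'   image index).
#' @export
read_image_stack <- function(path, pixel_size_ang = NULL) {
  con <- file(path, "rb"); on.exit(close(con))
  h_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- h_int[1]; ny <- h_int[2]; nz <- h_int[3]; mode <- h_int[4]
  mx <- h_int[8]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode, " (supported: 0, 1, 2)")
  px <- if (mx > 0 && cella[1] > 0) cella[1] / mx else pixel_size_ang
  if (is.null(px)) stop("no pixel size in header; pass `pixel_size_ang`")
  seek(con, 1024)
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(vals) < n) stop("truncated MRC data block in ", path)
  # x fastest in the file; store as [row = y, col = x, section]
  data <- array(0, dim = c(ny, nx, nz))
  for (k in seq_len(nz)) {
    sec <- matrix(vals[((k - 1) * nx * ny + 1):(k * nx * ny)], nx, ny)
    data[, , k] <- t(sec)
  }
  structure(list(data = data, pixel_size_ang = px, box = nx, n_images = nz),
            class = "image_stack")
}

#' Write an image stack (or single image) as MRC mode 2
#'
#' @param stack An `image_stack`, or a bare matrix plus `pixel_size_ang`.
#' @param path Output path.
#' @param pixel_size_ang Sampling, required for bare matrices.
#' @export
write_image_stack <- function(stack, path, pixel_size_ang = NULL) {
  if (is.matrix(stack)) {
    stack <- structure(list(data = array(stack, dim = c(dim(stack), 1L)),
                            pixel_size_ang = pixel_size_ang),
                       class = "image_stack")
  }
  stopifnot(inherits(stack, "image_stack"), !is.null(stack$pixel_size_ang))
  d <- stack$data
  if (length(dim(d)) == 2L) d <- array(d, dim = c(dim(d), 1L))
  ny <- dim(d)[1]; nx <- dim(d)[2]; nz <- dim(d)[3]
  px <- stack$pixel_size_ang
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.integer(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(c(nx * px, ny * px, nz * px), con, size = 4, endian = "little")
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")       # cellb
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(c(min(d), max(d), mean(d)), con, size = 4, endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(4 * (52 - 24)), con)                                # words 25-52
  writeChar("MAP ", con, nchars = 4, eos = NULL)                   # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                 # machst
  writeBin(stats::sd(as.numeric(d)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                   # nlabl
  writeBin(raw(1024 - 224), con)                                   # labels
  for (k in seq_len(nz))
    writeBin(as.numeric(t(d[, , k])), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a power spectrum to MRC (mode 2) or TSV
#'
#' @param ps A [power_spectrum()].
#' @param path Output path; `.tsv` writes a plain table, anything else MRC.
#' @export
write_spectrum <- function(ps, path) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    utils::write.table(ps$data, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    # MRC sampling: store reciprocal sampling as "pixel size" so that
    # cella/mx round-trips it
    write_image_stack(ps$data, path, pixel_size_ang = ps$axial_sampling)
  }
  invisible(path)
}
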