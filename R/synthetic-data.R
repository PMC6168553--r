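## Seeded synthetic-data generators: every input the analysis chain consumes
## can be produced here, reproducibly, with known ground truth.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Additive-noise model for simulated images
#'
#' @param sigma Standard deviation of the additive white Gaussian noise
#'   (image counts); `sigma = 0` disables noise.
#' @param envelope_sigma_ang Optional Gaussian real-space width (Angstrom)
#'   used by spectrum simulators as a B-factor-like reciprocal-space falloff;
#'   `0` means none.
#' @param seed Integer RNG seed; the same seed gives bit-identical output.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, envelope_sigma_ang = 0, seed = 1L) {
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  structure(list(sigma = sigma, envelope_sigma_ang = envelope_sigma_ang,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Build a helical filament model from an asymmetric unit of scatterers
#'
#' Expands point scatterers given in cylindrical coordinates by the helical
#' symmetry: subunit k sits at azimuth `phi + k*twist` and height
#' `z + k*rise`, for `k = 0 .. floor(length/rise) - 1`.
#'
#' @param asym_unit Data frame with columns `r` (radius, Angstrom >= 0),
#'   `phi` (azimuth, degrees) and `z` (axial offset, Angstrom).
#' @param symmetry A [helical_symmetry()] object.
#' @param length_ang Filament length in Angstrom; must be at least one rise.
#' @return List of class `filament_model` with the expanded Cartesian
#'   coordinates (`coords`: columns x, y, z, subunit), the symmetry, the
#'   asymmetric unit and `n_subunits`.
#' @examples
#' au <- data.frame(r = 25, phi = 0, z = 0)
#' fil <- make_filament(au, helical_symmetry(-101.124, 4.848), 155.2)
#' fil$n_subunits  # 32
#' @export
make_filament <- function(asym_unit, symmetry, length_ang) {
  stopifnot(is.data.frame(asym_unit),
            all(c("r", "phi", "z") %in% names(asym_unit)),
            inherits(symmetry, "helical_symmetry"))
  if (any(asym_unit$r < 0)) stop("scatterer radii must be >= 0")
  if (length_ang < symmetry$rise_ang)
    stop("`length_ang` (", length_ang, ") is shorter than one rise (",
         symmetry$rise_ang, ")")
  n_sub <- floor(length_ang / symmetry$rise_ang)
  k <- rep(seq_len(n_sub) - 1L, each = nrow(asym_unit))
  phi <- rep(asym_unit$phi, n_sub) + k * symmetry$twist_deg
  r <- rep(asym_unit$r, n_sub)
  z <- rep(asym_unit$z, n_sub) + k * symmetry$rise_ang
  rad <- phi * pi / 180
  coords <- data.frame(x = r * cos(rad), y = r * sin(rad), z = z, subunit = k)
  structure(list(coords = coords, symmetry = symmetry,
                 asym_unit = asym_unit, length_ang = length_ang,
                 n_subunits = as.integer(n_sub)),
            class = "filament_model")
}

#' Project a filament model into a stack of 2D images
#'
#' Renders each scatterer as an isotropic 2D Gaussian after projection along
#' the viewing axis (y), with the filament axis vertical and centred in the
#' box. Each image in the stack views the filament rotated about its axis by
#' the corresponding entry of `view_offsets_deg` (emulating segments taken at
#' different axial positions of one filament); additive noise is applied
#' last, seeded from the noise model.
#'
#' @param model A [make_filament()] model.
#' @param pixel_size_ang Sampling in Angstrom per pixel (default 1.21).
#' @param box Box side in pixels (square images).
#' @param noise A [noise_model()].
#' @param n_images Number of images in the stack.
#' @param view_offsets_deg Azimuthal offset per image (degrees); recycled or
#'   defaulting to the offsets accumulated by stepping one segment
#'   (`step_ang`) along the filament.
#' @param step_ang Axial step between consecutive views used for the default
#'   `view_offsets_deg` (Angstrom).
#' @param blob_sigma_px Gaussian width of a rendered scatterer in pixels.
#' @return List of class `image_stack`: `data` (array box x box x n_images),
#'   `pixel_size_ang`, plus the generation parameters.
#' @export
project_filament <- function(model, pixel_size_ang = 1.21, box = 420,
                             noise = noise_model(0), n_images = 1L,
                             view_offsets_deg = NULL, step_ang = 70,
                             blob_sigma_px = 2) {
  stopifnot(inherits(model, "filament_model"), inherits(noise, "noise_model"))
  max_r <- max(model$asym_unit$r)
  need <- ceiling((2 * max_r + 8 * blob_sigma_px * pixel_size_ang) /
                    pixel_size_ang)
  if (box < need)
    stop("box of ", box, " px cannot contain the filament; need >= ",
         need, " px at ", pixel_size_ang, " A/px")
  if (is.null(view_offsets_deg)) {
    # views along one filament: stepping by step_ang advances the azimuth by
    # (step/rise)*twist
    sym <- model$symmetry
    view_offsets_deg <- (seq_len(n_images) - 1L) *
      (step_ang / sym$rise_ang) * sym$twist_deg
  }
  view_offsets_deg <- rep_len(view_offsets_deg, n_images)

  px_centre <- box %/% 2 + 1          # matches the FFT origin convention
  xs <- seq_len(box)
  half_len <- (model$length_ang - model$symmetry$rise_ang) / 2
  data <- array(0, dim = c(box, box, n_images))
  co <- model$coords
  for (i in seq_len(n_images)) {
    ang <- (co$subunit * 0 + view_offsets_deg[i]) * pi / 180
    # rotate about z by the view offset, then project along y
    x_rot <- co$x * cos(ang) - co$y * sin(ang)
    px <- px_centre + x_rot / pixel_size_ang
    pz <- px_centre + (co$z - half_len) / pixel_size_ang
    img <- matrix(0, box, box)         # [col x, row z] then transpose later
    for (j in seq_along(px)) {
      ix <- round(px[j]); iz <- round(pz[j])
      lo_x <- max(1, ix - 4 * blob_sigma_px); hi_x <- min(box, ix + 4 * blob_sigma_px)
      lo_z <- max(1, iz - 4 * blob_sigma_px); hi_z <- min(box, iz + 4 * blob_sigma_px)
      if (lo_x > hi_x || lo_z > hi_z) next
      gx <- exp(-((xs[lo_x:hi_x] - px[j])^2) / (2 * blob_sigma_px^2))
      gz <- exp(-((xs[lo_z:hi_z] - pz[j])^2) / (2 * blob_sigma_px^2))
      img[lo_x:hi_x, lo_z:hi_z] <- img[lo_x:hi_x, lo_z:hi_z] + outer(gx, gz)
    }
    data[, , i] <- t(img)              # rows = z (vertical axis), cols = x
  }
  if (noise$sigma > 0) {
    data <- data + with_seed(noise$seed,
      array(stats::rnorm(length(data), 0, noise$sigma), dim = dim(data)))
  }
  structure(list(data = data, pixel_size_ang = pixel_size_ang,
                 box = box, n_images = n_images,
                 view_offsets_deg = view_offsets_deg,
                 blob_sigma_px = blob_sigma_px, noise = noise),
            class = "image_stack")
}

#' Paired solution/solid-state chemical-shift tables with planted changes
#'
#' Builds a solution-state Ca/Cb shift table from per-residue base values and
#' a solid-state table equal to it plus the stated perturbations plus
#' Gaussian noise. Glycines never carry a Cb entry.
#'
#' @param sequence Character vector of one-letter residue codes, or a single
#'   string; residue numbers are `first_resno, first_resno+1, ...`.
#' @param perturbed Named list mapping residue number (as name) to
#'   `c(dCA, dCB)` in ppm, added to the solid-state table.
#' @param noise_sigma Gaussian noise sd (ppm) added to the solid table.
#' @param seed RNG seed.
#' @param first_resno Number of the first residue (default 1).
#' @param base Optional random-coil table as from [read_random_coil_table()];
#'   defaults to the bundled table.
#' @return List with elements `solution` and `solid`, each a shift table
#'   (data frame: resno, aa, atom, shift_ppm).
#' @export
make_shift_tables <- function(sequence, perturbed = list(), noise_sigma = 0,
                              seed = 1L, first_resno = 1L, base = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (is.null(base)) base <- read_random_coil_table()
  if (!all(sequence %in% base$aa))
    stop("unknown residue code(s): ",
         paste(setdiff(sequence, base$aa), collapse = ", "))
  resno <- seq_along(sequence) + first_resno - 1L
  if (length(perturbed)) {
    bad <- setdiff(as.integer(names(perturbed)), resno)
    if (length(bad))
      stop("perturbed residue(s) outside sequence: ",
           paste(bad, collapse = ", "))
  }
  rows <- do.call(rbind, lapply(seq_along(sequence), function(i) {
    aa <- sequence[i]
    b <- base[base$aa == aa, ]
    atoms <- if (aa == "G") "CA" else c("CA", "CB")
    data.frame(resno = resno[i], aa = aa, atom = atoms,
               shift_ppm = c(b$ca_ppm, if (aa != "G") b$cb_ppm))
  }))
  solution <- shift_table(rows)
  solid <- rows
  for (nm in names(perturbed)) {
    d <- perturbed[[nm]]
    sel_ca <- solid$resno == as.integer(nm) & solid$atom == "CA"
    sel_cb <- solid$resno == as.integer(nm) & solid$atom == "CB"
    solid$shift_ppm[sel_ca] <- solid$shift_ppm[sel_ca] + d[1]
    if (any(sel_cb)) solid$shift_ppm[sel_cb] <- solid$shift_ppm[sel_cb] + d[2]
  }
  if (noise_sigma > 0)
    solid$shift_ppm <- solid$shift_ppm +
      with_seed(seed, stats::rnorm(nrow(solid), 0, noise_sigma))
  list(solution = solution, solid = shift_table(solid))
}

#' Synthetic immuno-gold particle annotations
#'
#' Emulates counting gold particles on electron micrographs of filaments: a
#' particle lands off-filament with probability `off_filament_rate`;
#' otherwise it attaches to a random filament, at an end with probability
#' `end_preference` and on the body otherwise.
#'
#' @param n_images Number of micrographs.
#' @param filaments_per_image Filaments per micrograph.
#' @param particles_per_image Gold particles per micrograph.
#' @param end_preference Probability p that an on-filament particle sits at
#'   an end (0..1).
#' @param off_filament_rate Probability a particle is off-filament (0..1).
#' @param seed RNG seed.
#' @return Data frame of class `gold_annotations` with columns `image`,
#'   `particle`, `location` (off/on_body/on_end) and `filament`
#'   (NA when off-filament).
#' @export
make_gold_annotations <- function(n_images, filaments_per_image,
                                  particles_per_image = 10L,
                                  end_preference = 0.9,
                                  off_filament_rate = 0.3, seed = 1L) {
  if (end_preference < 0 || end_preference > 1)
    stop("`end_preference` must be in [0, 1]")
  if (off_filament_rate < 0 || off_filament_rate > 1)
    stop("`off_filament_rate` must be in [0, 1]")
  n <- n_images * particles_per_image
  with_seed(seed, {
    image <- rep(seq_len(n_images), each = particles_per_image)
    particle <- rep(seq_len(particles_per_image), times = n_images)
    off <- stats::runif(n) < off_filament_rate
    at_end <- stats::runif(n) < end_preference
    location <- ifelse(off, "off", ifelse(at_end, "on_end", "on_body"))
    filament <- ifelse(off, NA_integer_,
                       sample.int(filaments_per_image, n, replace = TRUE))
    out <- data.frame(image = image, particle = particle,
                      location = location, filament = filament)
    class(out) <- c("gold_annotations", "data.frame")
    out
  })
}
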