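## Grid refinement of helical symmetry: simulate layer-line spectra from
## candidate (pitch, units-per-turn) pairs and maximise the amplitude
## correlation against an experimental power spectrum.

# signed-order Bessel function of the first kind (integer orders)
besselJ_signed <- function(x, n) {
  if (n >= 0) besselJ(x, n) else (-1)^(-n) * besselJ(x, -n)
}

#' Simulate a helical-diffraction power spectrum
#'
#' Single-radius Cochran-Crick-Vand model: layer line l of a helix with
#' repeat c (u subunits in t turns) sits at axial frequency l/c and carries
#' the Bessel orders allowed by the selection rule `l = t*n + u*m`; its
#' radial amplitude is `sum_n J_n(2*pi*R*r)` over the allowed orders, and
#' the finite filament length broadens every line axially by a
#' `sinc^2((Z - l/c) * length)` profile.
#'
#' @param sym A [helical_symmetry()].
#' @param radius Scattering radius r of the helix, Angstrom.
#' @param length_ang Filament length (sets the axial line width 1/length).
#' @param template A [power_spectrum()] supplying the target sampling and
#'   shape, or NULL with `shape`/`samplings` given explicitly.
#' @param shape,axial_sampling,radial_sampling Used when `template` is NULL.
#' @param n_max Largest |Bessel order| included; default covers every order
#'   whose first maximum falls inside the simulated radial range.
#' @param max_turns Denominator bound when rationalising units-per-turn.
#' @param blob_sigma_ang Gaussian real-space width whose reciprocal-space
#'   envelope multiplies the amplitudes (0 = none); lets the model match
#'   images rendered with a known point spread.
#' @return A [power_spectrum()].
#' @export
simulate_spectrum <- function(sym, radius, length_ang, template = NULL,
                              shape = NULL, axial_sampling = NULL,
                              radial_sampling = NULL, n_max = NULL,
                              max_turns = 50L, blob_sigma_ang = 0) {
  stopifnot(inherits(sym, "helical_symmetry"), radius > 0, length_ang > 0)
  if (!is.null(template)) {
    shape <- dim(template$data)
    axial_sampling <- template$axial_sampling
    radial_sampling <- template$radial_sampling
  }
  stopifnot(!is.null(shape), !is.null(axial_sampling), !is.null(radial_sampling))
  pu <- symmetry_to_pitch_units(sym)
  rr <- rational_units_per_turn(pu$units_per_turn, max_turns)
  u <- rr$u; t <- rr$t
  cc <- u * sym$rise_ang
  nr <- shape[1]; nc <- shape[2]
  orow <- nr %/% 2 + 1; ocol <- nc %/% 2 + 1
  z <- (seq_len(nr) - orow) * axial_sampling
  R <- (seq_len(nc) - ocol) * radial_sampling
  if (is.null(n_max)) n_max <- ceiling(2 * pi * radius * max(abs(R))) + 2L

  width <- 1 / length_ang                   # first sinc zero
  z_max <- max(abs(z))
  l_max <- floor((z_max + 4 * width) * cc)
  out <- matrix(0, nr, nc)
  x <- 2 * pi * abs(R) * radius
  for (l in 0:l_max) {
    ns <- selection_rule_orders(u, t, l, n_max)
    if (!length(ns)) next
    amp <- 0
    for (n in ns) amp <- amp + besselJ_signed(x, n)
    I_l <- amp^2
    if (all(I_l == 0)) next
    for (s in if (l == 0) 0 else c(1, -1)) {
      zl <- s * l / cc
      rows <- which(abs(z - zl) < 4 * width)
      if (!length(rows)) next
      arg <- (z[rows] - zl) * length_ang
      w <- ifelse(arg == 0, 1, (sin(pi * arg) / (pi * arg))^2)
      out[rows, ] <- out[rows, ] + outer(w, I_l)
    }
  }
  if (blob_sigma_ang > 0) {
    env <- exp(-4 * pi^2 * blob_sigma_ang^2 * outer(z^2, R^2, `+`))
    out <- out * env
  }
  power_spectrum(out, axial_sampling, radial_sampling)
}

#' Default correlation mask for power spectra
#'
#' Excludes the equator row and a small origin disc (both dominated by
#' low-frequency background), and optionally limits the axial and radial
#' frequency range.
#'
#' @param ps A [power_spectrum()] giving the geometry.
#' @param origin_radius_px Radius of the excluded origin disc, pixels.
#' @param exclude_equator Logical; drop the equator row.
#' @param z_max,r_max Optional frequency limits (Angstrom^-1).
#' @return Logical matrix, TRUE where pixels enter the correlation.
#' @export
default_correlation_mask <- function(ps, origin_radius_px = 3,
                                     exclude_equator = TRUE,
                                     z_max = Inf, r_max = Inf) {
  nr <- nrow(ps$data); nc <- ncol(ps$data)
  ri <- seq_len(nr) - ps$origin["row"]
  ci <- seq_len(nc) - ps$origin["col"]
  mask <- matrix(TRUE, nr, nc)
  mask[outer(ri^2, ci^2, `+`) <= origin_radius_px^2] <- FALSE
  if (exclude_equator) mask[ps$origin["row"], ] <- FALSE
  z <- axial_frequencies(ps); R <- radial_frequencies(ps)
  mask[abs(z) > z_max, ] <- FALSE
  mask[, abs(R) > r_max] <- FALSE
  mask
}

#' Amplitude correlation of two power spectra
#'
#' Pearson correlation of the square-root amplitudes over a mask; 1 for
#' identical inputs.
#'
#' @param a,b [power_spectrum()] objects of identical shape and sampling.
#' @param mask Logical matrix (default: [default_correlation_mask()] of `a`).
#' @return Correlation in `[-1, 1]`.
#' @export
amplitude_correlation <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "power_spectrum"), inherits(b, "power_spectrum"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("power spectra differ in shape: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (is.null(mask)) mask <- default_correlation_mask(a)
  stats::cor(sqrt(a$data[mask]), sqrt(b$data[mask]))
}

#' Refinement grid specification
#'
#' Inclusive ranges for pitch and units per turn; node counts are
#' `round((max - min)/step) + 1` per axis.
#'
#' @param pitch_min,pitch_max,pitch_step Pitch range, Angstrom.
#' @param upt_min,upt_max,upt_step Units-per-turn range.
#' @return List of class `grid_spec` with `pitch` and `upt` node vectors.
#' @examples
#' g <- grid_spec(17.2, 17.4, 0.02, 3.4, 3.6, 0.02)
#' length(g$pitch) * length(g$upt)  # 121
#' @export
grid_spec <- function(pitch_min, pitch_max, pitch_step,
                      upt_min, upt_max, upt_step) {
  if (pitch_max < pitch_min || upt_max < upt_min)
    stop("grid ranges must have max >= min")
  n_pitch <- round((pitch_max - pitch_min) / pitch_step) + 1L
  n_upt <- round((upt_max - upt_min) / upt_step) + 1L
  structure(list(pitch = pitch_min + (seq_len(n_pitch) - 1L) * pitch_step,
                 upt = upt_min + (seq_len(n_upt) - 1L) * upt_step),
            class = "grid_spec")
}

#' Precompute simulated spectra for every grid node
#'
#' @param grid A [grid_spec()].
#' @param template [power_spectrum()] giving shape and sampling.
#' @param radius,length_ang,handedness,max_turns,blob_sigma_ang Passed to
#'   [simulate_spectrum()].
#' @return List of lists of `power_spectrum` (pitch-major indexing
#'   `[[i_pitch]][[i_upt]]`).
#' @export
simulate_grid_spectra <- function(grid, template, radius, length_ang,
                                  handedness = "left", max_turns = 50L,
                                  blob_sigma_ang = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  lapply(grid$pitch, function(p)
    lapply(grid$upt, function(q)
      simulate_spectrum(pitch_units_to_symmetry(p, q, handedness),
                        radius, length_ang, template = template,
                        max_turns = max_turns,
                        blob_sigma_ang = blob_sigma_ang)))
}

#' Grid refinement of pitch and units per turn
#'
#' Evaluates the amplitude correlation between the experimental spectrum and
#' a simulated spectrum at every (pitch, units-per-turn) node, and returns
#' the maximising node together with the full correlation surface. Ties are
#' broken toward the grid centre.
#'
#' @param experimental A [power_spectrum()].
#' @param grid A [grid_spec()].
#' @param radius,length_ang Model parameters for [simulate_spectrum()].
#' @param handedness Handedness assumed for the candidates.
#' @param mask Correlation mask (default [default_correlation_mask()]).
#' @param sims Optional precomputed spectra from [simulate_grid_spectra()]
#'   (reused across repeated refinements against the same sampling).
#' @param blob_sigma_ang Envelope passed to the simulator.
#' @return List of class `symmetry_grid`: `pitch_ang`, `units_per_turn`
#'   (the argmax), `surface` (matrix n_pitch x n_upt), `grid`.
#' @export
grid_refine <- function(experimental, grid, radius, length_ang,
                        handedness = "left", mask = NULL, sims = NULL,
                        blob_sigma_ang = 0) {
  stopifnot(inherits(experimental, "power_spectrum"),
            inherits(grid, "grid_spec"))
  if (!length(grid$pitch) || !length(grid$upt)) stop("empty grid")
  if (is.null(mask)) mask <- default_correlation_mask(experimental)
  if (is.null(sims))
    sims <- simulate_grid_spectra(grid, experimental, radius, length_ang,
                                  handedness, blob_sigma_ang = blob_sigma_ang)
  np <- length(grid$pitch); nq <- length(grid$upt)
  surface <- matrix(NA_real_, np, nq,
                    dimnames = list(format(grid$pitch), format(grid$upt)))
  for (i in seq_len(np))
    for (j in seq_len(nq))
      surface[i, j] <- amplitude_correlation(experimental, sims[[i]][[j]],
                                             mask)
  best <- which(surface == max(surface), arr.ind = TRUE)
  if (nrow(best) > 1L) {    # ties toward the grid centre
    centre <- c((np + 1) / 2, (nq + 1) / 2)
    d <- (best[, 1] - centre[1])^2 + (best[, 2] - centre[2])^2
    best <- best[which.min(d), , drop = FALSE]
  }
  structure(list(pitch_ang = grid$pitch[best[1, 1]],
                 units_per_turn = grid$upt[best[1, 2]],
                 surface = surface, grid = grid),
            class = "symmetry_grid")
}
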