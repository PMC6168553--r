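## Layer-line indexing of filament power spectra: average spectrum, detect
## layer lines, fit the repeat distance, assign Bessel orders, and solve for
## the helical parameters.

fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr %/% 2 + 1):nr, 1:(nr %/% 2)), c((nc %/% 2 + 1):nc, 1:(nc %/% 2))]
}

#' Power-spectrum container
#'
#' A 2D non-negative array with reciprocal-space sampling. Rows are axial
#' frequency Z (meridian = central column), columns radial frequency R
#' (equator = central row); the origin sits at row/column `n %/% 2 + 1`.
#'
#' @param data Non-negative numeric matrix.
#' @param axial_sampling Angstrom^-1 per row.
#' @param radial_sampling Angstrom^-1 per column.
#' @return Object of class `power_spectrum`.
#' @export
power_spectrum <- function(data, axial_sampling, radial_sampling) {
  stopifnot(is.matrix(data), all(data >= 0),
            axial_sampling > 0, radial_sampling > 0)
  structure(list(data = data,
                 axial_sampling = axial_sampling,
                 radial_sampling = radial_sampling,
                 origin = c(row = nrow(data) %/% 2L + 1L,
                            col = ncol(data) %/% 2L + 1L)),
            class = "power_spectrum")
}

#' Axial frequency of each spectrum row
#' @param ps A [power_spectrum()].
#' @return Numeric vector, Angstrom^-1 (negative below the equator).
#' @export
axial_frequencies <- function(ps) {
  (seq_len(nrow(ps$data)) - ps$origin["row"]) * ps$axial_sampling
}

#' Radial frequency of each spectrum column
#' @param ps A [power_spectrum()].
#' @return Numeric vector, Angstrom^-1 (negative left of the meridian).
#' @export
radial_frequencies <- function(ps) {
  (seq_len(ncol(ps$data)) - ps$origin["col"]) * ps$radial_sampling
}

#' Averaged power spectrum of an image stack
#'
#' Mean of the squared Fourier magnitudes over the stack, origin centred;
#' sampling follows from the pixel size and box.
#'
#' @param stack An `image_stack` (see [project_filament()] /
#'   [read_image_stack()]); filament axis vertical.
#' @return A [power_spectrum()].
#' @export
average_power_spectrum <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack$data
  if (length(dim(d)) == 2L) d <- array(d, dim = c(dim(d), 1L))
  if (dim(d)[3] < 1L) stop("empty image stack")
  acc <- 0
  for (i in seq_len(dim(d)[3]))
    acc <- acc + Mod(stats::fft(d[, , i]))^2
  ps <- fftshift2(acc / dim(d)[3])
  s <- 1 / (stack$pixel_size_ang * dim(d)[1:2])
  power_spectrum(ps, axial_sampling = s[1], radial_sampling = s[2])
}

# Radially integrated power per row; columns closer than
# `exclude_meridian_px` to the meridian are dropped (0 keeps all).
axial_power_profile <- function(ps, exclude_meridian_px = 0L) {
  cols <- abs(seq_len(ncol(ps$data)) - ps$origin["col"]) >= exclude_meridian_px
  rowSums(ps$data[, cols, drop = FALSE])
}

#' Detect layer lines in a power spectrum
#'
#' Computes the radially integrated power per row (meridian columns
#' included, since meridional lines carry their power there), subtracts a
#' running-median local background (which tracks the reciprocal-space
#' envelope), keeps rows whose residual exceeds `min_snr`
#' median-absolute-deviations of the residual, takes local maxima, merges
#' Friedel mates (rows at +Z and -Z) and returns the heights.
#'
#' @param ps A [power_spectrum()].
#' @param min_snr Detection threshold in robust (MAD) units above the local
#'   background.
#' @param max_lines Keep at most this many lines (strongest first), then
#'   sort ascending.
#' @param exclude_meridian_px Columns around the meridian excluded from the
#'   profile; 0 (default) keeps the meridian so that n = 0 lines count.
#' @param background_window Odd window length (rows) of the running-median
#'   background.
#' @return Numeric vector of layer-line heights in Angstrom^-1, ascending
#'   (the equator itself is never reported), with the peak strength of each
#'   line (residual profile value) in attribute `"strength"`.
#' @export
detect_layer_lines <- function(ps, min_snr = 5, max_lines = Inf,
                               exclude_meridian_px = 0L,
                               background_window = NULL) {
  stopifnot(inherits(ps, "power_spectrum"))
  prof <- axial_power_profile(ps, exclude_meridian_px)
  z <- axial_frequencies(ps)
  if (is.null(background_window))
    background_window <- max(9L, 2L * (length(prof) %/% 32L) + 1L)
  prof <- prof - stats::runmed(prof, background_window)
  bg <- stats::median(prof)
  sc <- stats::mad(prof)
  if (sc == 0) sc <- .Machine$double.eps
  above <- prof > bg + min_snr * sc
  # local maxima among above-threshold rows
  n <- length(prof)
  is_peak <- above &
    prof >= c(-Inf, prof[-n]) & prof >= c(prof[-1], -Inf)
  is_peak[abs(z) < ps$axial_sampling / 2] <- FALSE   # drop the equator
  heights <- abs(z[is_peak])
  strengths <- prof[is_peak]
  if (!length(heights)) return(numeric(0))
  # merge Friedel mates: same |Z| within half a row
  o <- order(heights)
  heights <- heights[o]; strengths <- strengths[o]
  keep_h <- c(); keep_s <- c()
  i <- 1
  while (i <= length(heights)) {
    j <- i
    while (j < length(heights) &&
           heights[j + 1] - heights[i] < ps$axial_sampling / 2) j <- j + 1
    keep_h <- c(keep_h, mean(heights[i:j]))
    keep_s <- c(keep_s, max(strengths[i:j]))
    i <- j + 1
  }
  if (is.finite(max_lines) && length(keep_h) > max_lines) {
    sel <- sort(order(keep_s, decreasing = TRUE)[seq_len(max_lines)])
    keep_h <- keep_h[sel]; keep_s <- keep_s[sel]
  }
  o <- order(keep_h)
  structure(keep_h[o], strength = keep_s[o])
}

#' Fit the helical repeat to detected layer-line heights
#'
#' Layer lines of a helix with repeat c sit at heights l/c for integer l.
#' For each candidate index of the lowest line, heights are indexed as
#' `l_i = round(h_i * c)` and c refined by least squares
#' (`1/c = sum(l*h)/sum(l^2)`); the smallest candidate whose worst relative
#' height residual is below `rel_tol` wins, so the shortest consistent repeat
#' is preferred.
#'
#' @param heights Layer-line heights in Angstrom^-1 (>= 2 of them).
#' @param max_l Largest admissible layer-line index.
#' @param rel_tol Worst tolerated relative residual `|h - l/c| / h`.
#' @return List with `c_ang` (repeat, Angstrom), integer vector `l`
#'   (assigned indices, one per input height) and `residual` (worst
#'   relative residual).
#' @export
fit_repeat <- function(heights, max_l = 64L, rel_tol = 0.02) {
  heights <- sort(heights)
  if (length(heights) < 2) stop("need at least two layer-line heights")
  if (any(heights <= 0)) stop("heights must be positive")
  cands <- list()
  for (l1 in seq_len(max_l)) {
    c0 <- l1 / heights[1]
    l <- pmax(1L, as.integer(round(heights * c0)))
    if (any(l > max_l) || anyDuplicated(l)) next
    # least-squares refinement of s = 1/c for model h = l*s
    s <- sum(l * heights) / sum(l^2)
    res <- max(abs(heights - l * s) / heights)
    cands[[length(cands) + 1L]] <- list(c_ang = 1 / s, l = l, residual = res)
  }
  if (!length(cands))
    stop("no consistent layer-line indexing with l <= ", max_l)
  res_all <- vapply(cands, `[[`, numeric(1), "residual")
  exact <- which(res_all < 1e-9)
  if (length(exact)) return(cands[[exact[1]]])   # smallest exact repeat
  ok <- which(res_all < rel_tol)
  if (!length(ok))
    stop("no consistent layer-line indexing with l <= ", max_l,
         " (best residual ", signif(min(res_all), 3), ")")
  cands[[ok[1]]]                                 # smallest acceptable repeat
}

# first maximum abscissa of J_n, found numerically (n = 0 -> 0)
bessel_first_max <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    n <- abs(as.integer(n))
    if (n == 0L) return(0)
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # the first maximum of J_n lies between n and n + 2.5 n^(1/3) + 3
    lo <- max(n * 0.9, 0.5); hi <- n + 2.5 * n^(1/3) + 3
    opt <- stats::optimize(function(x) -besselJ(x, n), c(lo, hi))
    cache[[key]] <- opt$minimum
    opt$minimum
  }
})

#' Assign a Bessel order from the first radial intensity maximum
#'
#' On layer line l the intensity profile follows `J_n(2*pi*R*r)^2` for the
#' allowed order(s) n; the radial position of the first maximum therefore
#' encodes |n|. Returns the |n| <= `n_max` whose first-maximum abscissa best
#' matches `2*pi*r_first_max*radius` (0 for a meridional line).
#'
#' @param r_first_max Radial frequency of the first intensity maximum,
#'   Angstrom^-1.
#' @param radius Scattering radius of the helix, Angstrom.
#' @param n_max Largest order considered.
#' @return List with `n` (order magnitude) and `low_confidence` (TRUE when
#'   the observed maximum lies beyond the prediction for `n_max`, in which
#'   case `n = n_max` is returned as a floor).
#' @export
assign_bessel_order <- function(r_first_max, radius, n_max = 10L) {
  if (radius <= 0) stop("`radius` must be positive")
  if (r_first_max < 0) stop("`r_first_max` must be >= 0")
  x_obs <- 2 * pi * r_first_max * radius
  xs <- vapply(0:n_max, bessel_first_max, numeric(1))
  n <- which.min(abs(xs - x_obs)) - 1L
  low <- n == n_max && x_obs > xs[n_max + 1L]
  list(n = n, low_confidence = low)
}

#' Radial position of the first intensity maximum on a layer line
#'
#' Extracts the row nearest `height`, averages it with its Friedel mate and
#' mirror columns, and returns the radial frequency of the first local
#' maximum away from the meridian.
#'
#' @param ps A [power_spectrum()].
#' @param height Layer-line height, Angstrom^-1.
#' @return Radial frequency in Angstrom^-1 (0 when the profile peaks on the
#'   meridian).
#' @export
layer_line_first_max <- function(ps, height) {
  z <- axial_frequencies(ps)
  rows <- c(which.min(abs(z - height)), which.min(abs(z + height)))
  prof <- colMeans(ps$data[rows, , drop = FALSE])
  r <- radial_frequencies(ps)
  half <- prof[r >= 0]
  mirr <- rev(prof[r <= 0])
  m <- min(length(half), length(mirr))
  sym_prof <- (half[seq_len(m)] + mirr[seq_len(m)]) / 2
  if (length(sym_prof) < 3) return(0)
  # first local maximum from the meridian outward
  for (i in seq_along(sym_prof)) {
    nxt <- if (i < length(sym_prof)) sym_prof[i + 1] else -Inf
    prv <- if (i > 1) sym_prof[i - 1] else -Inf
    if (sym_prof[i] >= nxt && sym_prof[i] >= prv)
      return((i - 1) * ps$radial_sampling)
  }
  0
}

#' Solve helical parameters from indexed layer lines
#'
#' Given the repeat c, the index of the first meridional layer line
#' (Bessel order 0, so `l = u`) and the index of the pitch line (order 1, so
#' `l = t`), the symmetry follows: `rise = c/u`, `pitch = c/t`,
#' `units per turn = u/t`. Handedness cannot be read from a single power
#' spectrum and must be supplied.
#'
#' @param c_ang Repeat distance, Angstrom.
#' @param l_meridional Index of the first meridional line (> `l_pitch`).
#' @param l_pitch Index of the pitch line (>= 1).
#' @param handedness `"left"` (default) or `"right"`.
#' @return List with `symmetry` ([helical_symmetry()]) and `repeat`
#'   (`rational_repeat`: u, t, units_per_turn, c_ang).
#' @examples
#' index_symmetry(155.8, 32, 9)
#' @export
index_symmetry <- function(c_ang, l_meridional, l_pitch,
                           handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  l_meridional <- as.integer(l_meridional); l_pitch <- as.integer(l_pitch)
  if (!(l_meridional > l_pitch) || l_pitch < 1)
    stop("need l_meridional > l_pitch >= 1")
  g <- .gcd(l_meridional, l_pitch)
  if (g > 1L) {
    warning("l_meridional and l_pitch share a factor ", g, "; reducing")
    l_meridional <- l_meridional %/% g
    l_pitch <- l_pitch %/% g
  }
  u <- l_meridional; t <- l_pitch
  rise <- c_ang / u
  upt <- u / t
  sym <- pitch_units_to_symmetry(rise * upt, upt, handedness)
  rep <- structure(list(u = u, t = t, units_per_turn = upt, c_ang = c_ang),
                   class = "rational_repeat")
  list(symmetry = sym, repeat_ = rep, pitch_ang = c_ang / t, rise_ang = rise)
}
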