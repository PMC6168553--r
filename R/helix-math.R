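#' Helical symmetry parameters
#'
#' A helical filament is described by the rotation (`twist_deg`) and axial
#' translation (`rise_ang`) relating subunit k to subunit k+1. Subunit k is
#' placed by rotating the asymmetric unit about +z by `k * twist_deg`
#' (right-hand rule) and translating by `k * rise_ang` along +z, so a
#' left-handed filament carries a negative twist.
#'
#' @param twist_deg Signed rotation per subunit in degrees;
#'   `0 < abs(twist_deg) <= 360`.
#' @param rise_ang Axial translation per subunit in Angstrom; positive.
#' @return An object of class `helical_symmetry` with fields `twist_deg`,
#'   `rise_ang` and the derived `handedness` (`"left"` iff `twist_deg < 0`).
#' @examples
#' helical_symmetry(-101.124, 4.848)
#' @export
helical_symmetry <- function(twist_deg, rise_ang) {
  stopifnot(is.numeric(twist_deg), length(twist_deg) == 1L,
            is.numeric(rise_ang), length(rise_ang) == 1L)
  if (!is.finite(twist_deg) || abs(twist_deg) <= 0 || abs(twist_deg) > 360)
    stop("`twist_deg` must satisfy 0 < |twist| <= 360, got ", twist_deg)
  if (!is.finite(rise_ang) || rise_ang <= 0)
    stop("`rise_ang` must be positive, got ", rise_ang)
  structure(
    list(twist_deg = twist_deg, rise_ang = rise_ang,
         handedness = if (twist_deg < 0) "left" else "right"),
    class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("helical symmetry: twist %.4f deg, rise %.4f A (%s-handed)\n",
              x$twist_deg, x$rise_ang, x$handedness))
  pu <- symmetry_to_pitch_units(x)
  cat(sprintf("  pitch %.4f A, %.4f units per turn\n",
              pu$pitch_ang, pu$units_per_turn))
  invisible(x)
}

#' Convert pitch and units-per-turn to twist/rise
#'
#' The pitch P is the axial distance for one full 360 degree turn of the
#' 1-start helix; with `u/t` subunits per turn, `|twist| = 360 / upt` and
#' `rise = P / upt`.
#'
#' @param pitch_ang Pitch in Angstrom; positive.
#' @param units_per_turn Subunits per helical turn; must exceed 1.
#' @param handedness `"left"` or `"right"`; sets the sign of the twist.
#' @return A [helical_symmetry()] object.
#' @examples
#' pitch_units_to_symmetry(17.26, 3.56, "left")
#' @export
pitch_units_to_symmetry <- function(pitch_ang, units_per_turn,
                                    handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  if (!is.finite(pitch_ang) || pitch_ang <= 0)
    stop("`pitch_ang` must be positive, got ", pitch_ang)
  if (!is.finite(units_per_turn) || units_per_turn <= 1)
    stop("`units_per_turn` must exceed 1, got ", units_per_turn)
  twist <- 360 / units_per_turn
  if (handedness == "left") twist <- -twist
  helical_symmetry(twist, pitch_ang / units_per_turn)
}

#' Convert twist/rise to pitch and units-per-turn
#'
#' Inverse of [pitch_units_to_symmetry()]; round-trips to better than 1e-9
#' relative error.
#'
#' @param sym A [helical_symmetry()] object.
#' @return List with `pitch_ang` and `units_per_turn`.
#' @export
symmetry_to_pitch_units <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  upt <- 360 / abs(sym$twist_deg)
  list(pitch_ang = sym$rise_ang * upt, units_per_turn = upt)
}

#' Best rational approximation u/t to a units-per-turn value
#'
#' Finds the coprime integer pair (u, t) with `t <= max_turns` minimising
#' `|u/t - units_per_turn|`: the filament then repeats exactly after u
#' subunits in t turns. Uses the bounded-denominator continued-fraction
#' (Stern-Brocot) walk, which yields the optimal approximation including
#' semiconvergents; ties in error are broken toward the smaller t.
#'
#' @param units_per_turn Real value > 1.
#' @param max_turns Largest admissible number of turns t (>= 1).
#' @param rise_ang Optional rise in Angstrom; if given, the repeat distance
#'   `c = u * rise` is filled in.
#' @return List of class `rational_repeat` with integers `u`, `t`,
#'   `units_per_turn = u/t`, and `c_ang` (NA unless `rise_ang` supplied).
#' @examples
#' rational_units_per_turn(3.56, 10)   # u = 32, t = 9
#' @export
rational_units_per_turn <- function(units_per_turn, max_turns,
                                    rise_ang = NULL) {
  if (!is.finite(units_per_turn) || units_per_turn <= 1)
    stop("`units_per_turn` must exceed 1, got ", units_per_turn)
  max_turns <- as.integer(max_turns)
  if (is.na(max_turns) || max_turns < 1L) stop("`max_turns` must be >= 1")

  # Stern-Brocot walk bounded by denominator: maintain the two fractions
  # bracketing x and descend toward it, never letting t exceed max_turns.
  x <- units_per_turn
  lo <- c(floor(x), 1)           # p/q below x
  hi <- c(floor(x) + 1, 1)      # p/q above x
  repeat {
    med <- lo + hi                 # mediant
    if (med[2] > max_turns) break
    if (med[1] / med[2] <= x) lo <- med else hi <- med
  }
  # After the full descent lo and hi are the best one-sided approximations
  # with denominator <= max_turns; the optimum is one of the two.
  cand <- rbind(lo, hi)
  err <- abs(cand[, 1] / cand[, 2] - x)
  ord <- order(err, cand[, 2])   # ties toward smaller t
  best <- cand[ord[1L], ]
  g <- .gcd(best[1L], best[2L])
  u <- as.integer(best[1L] / g); t <- as.integer(best[2L] / g)
  structure(
    list(u = u, t = t, units_per_turn = u / t,
         c_ang = if (is.null(rise_ang)) NA_real_ else u * rise_ang),
    class = "rational_repeat")
}

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

#' Helical repeat distance
#'
#' The axial repeat `c = u * rise`, the distance over which the filament
#' structure repeats exactly.
#'
#' @param u Integer subunits per repeat (>= 1).
#' @param rise_ang Rise per subunit in Angstrom (> 0).
#' @return Repeat distance in Angstrom.
#' @examples
#' repeat_distance(32, 4.87)  # 155.8
#' @export
repeat_distance <- function(u, rise_ang) {
  if (u < 1) stop("`u` must be >= 1")
  if (!is.finite(rise_ang) || rise_ang <= 0) stop("`rise_ang` must be positive")
  u * rise_ang
}

#' Segmentation parameters for helical refinement
#'
#' @param segment_length_ang Segment (box) length along the filament, Angstrom.
#' @param step_ang Inter-segment step, Angstrom; `0 < step <= segment length`.
#' @param n_segments Number of segments retained (>= 0).
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(segment_length_ang, step_ang, n_segments) {
  if (!is.finite(step_ang) || step_ang <= 0 || step_ang > segment_length_ang)
    stop("need 0 < step_ang <= segment_length_ang")
  n_segments <- as.integer(n_segments)
  if (is.na(n_segments) || n_segments < 0L) stop("`n_segments` must be >= 0")
  structure(list(segment_length_ang = segment_length_ang,
                 step_ang = step_ang, n_segments = n_segments),
            class = "segmentation_params")
}

#' Asymmetric units contributed by a segmented refinement
#'
#' Each segment contributes the subunits in one inter-segment step,
#' `floor(step / rise)` of them, so that no subunit is counted twice by
#' overlapping segments; the total over the data set is
#' `n_segments * floor(step / rise)`.
#'
#' @param seg A [segmentation_params()] object.
#' @param rise_ang Rise per subunit in Angstrom.
#' @return Integer count of asymmetric units.
#' @examples
#' asymmetric_units(segmentation_params(400, 70, 9661), 4.848)  # 135254
#' @export
asymmetric_units <- function(seg, rise_ang) {
  stopifnot(inherits(seg, "segmentation_params"))
  if (!is.finite(rise_ang) || rise_ang <= 0) stop("`rise_ang` must be positive")
  per_seg <- floor(seg$step_ang / rise_ang)
  if (per_seg == 0)
    warning("step smaller than rise: segments contribute 0 asymmetric units")
  as.integer(seg$n_segments * per_seg)
}

#' Bessel orders allowed on a layer line
#'
#' For a 1-start helix with u subunits in t turns, layer line l carries only
#' Bessel orders n satisfying the selection rule `l = t*n + u*m` for some
#' integer m.
#'
#' @param u,t Coprime integers of the rational repeat.
#' @param l Layer-line index (integer).
#' @param n_max Largest |n| to report.
#' @return Sorted integer vector of allowed orders n with `|n| <= n_max`.
#' @examples
#' selection_rule_orders(32, 9, l = 9, n_max = 5)   # contains 1
#' selection_rule_orders(32, 9, l = 32, n_max = 5)  # contains 0
#' @export
selection_rule_orders <- function(u, t, l, n_max) {
  u <- as.integer(u); t <- as.integer(t); l <- as.integer(l)
  if (.gcd(u, t) != 1L) stop("`u` and `t` must be coprime")
  n <- seq.int(-n_max, n_max)
  n[(l - t * n) %% u == 0L]
}
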