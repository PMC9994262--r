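#' Parametric specification of a half-vesicle curve
#'
#' The shell midline is a left-handed helix of constant pitch `P` whose
#' radius is `r_max` for the cylindrical turns (`t < t_cyl`) and then
#' decreases linearly to zero across the conical cap, reaching the tip after
#' `t_cap = r_max / (P * sin(alpha))` further turns. Monomers are placed on
#' this curve at a fixed arc spacing, with the last `n_omit_tip` points
#' toward the tip omitted (the simple constant-pitch helix breaks down at
#' the very tip).
#'
#' @param r_max Cylinder radius, Angstrom (default 178.4).
#' @param pitch Helical pitch, Angstrom (default 48.8).
#' @param alpha Cone semi-angle of the tip, degrees in (0, 90] (default 25).
#' @param t_cyl Number of cylindrical turns (>= 0, default 5).
#' @param spacing Arc spacing between consecutive monomers, Angstrom
#'   (default 12.07).
#' @param n_omit_tip Number of points nearest the tip to omit (default 4).
#' @param handedness `"left"` (default) or `"right"`.
#' @return An object of class `vesicle_spec`.
#' @examples
#' vesicle_spec()
#' @export
vesicle_spec <- function(r_max = 178.4, pitch = 48.8, alpha = 25, t_cyl = 5,
                         spacing = 12.07, n_omit_tip = 4,
                         handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  stopifnot(is.numeric(r_max), is.numeric(pitch), is.numeric(alpha),
            is.numeric(t_cyl), is.numeric(spacing))
  if (r_max < 0) stop("`r_max` must be non-negative", call. = FALSE)
  if (pitch <= 0) stop("`pitch` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha > 90)
    stop("`alpha` must be in (0, 90] degrees", call. = FALSE)
  if (t_cyl < 0) stop("`t_cyl` must be non-negative", call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  if (n_omit_tip < 0 || n_omit_tip != round(n_omit_tip))
    stop("`n_omit_tip` must be a non-negative integer", call. = FALSE)
  structure(
    list(r_max = r_max, pitch = pitch, alpha = alpha, t_cyl = t_cyl,
         spacing = spacing, n_omit_tip = as.integer(n_omit_tip),
         handedness = handedness),
    class = "vesicle_spec")
}

#' @export
print.vesicle_spec <- function(x, ...) {
  cat("Vesicle half-shell curve specification\n")
  cat(sprintf("  r_max %.4g A, pitch %.4g A, cone angle %.4g deg (%s-handed)\n",
              x$r_max, x$pitch, x$alpha, x$handedness))
  cat(sprintf("  t_cyl %.4g turns + t_cap %.4f turns; spacing %.4g A, omit %d tip points\n",
              x$t_cyl, cap_turns(x), x$spacing, x$n_omit_tip))
  invisible(x)
}

#' Number of helical turns in the conical cap
#'
#' `t_cap = r_max / (P * sin(alpha))`: the number of turns needed for the
#' radius to shrink linearly from `r_max` to zero while the axial advance
#' per turn follows the cone slope.
#'
#' @param spec A [vesicle_spec()].
#' @return Turns in the cap.
#' @examples
#' cap_turns(vesicle_spec()) # 8.650
#' @export
cap_turns <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  sa <- sin(spec$alpha * pi / 180)
  spec$r_max / (spec$pitch * sa)
}

# total parameter domain of the curve, in turns
curve_t_end <- function(spec) spec$t_cyl + cap_turns(spec)

#' Evaluate the parametric half-vesicle curve
#'
#' Piecewise equations with `t` in turns: radius `r(t) = r_max` for
#' `t < t_cyl`, then decreasing linearly to 0 at `t_cyl + t_cap`;
#' `x = r(t) cos(2 pi t)`, `y = -r(t) sin(2 pi t)` (minus sign: left-handed),
#' `z = P t` on the cylinder and `P t_cyl + P cos(alpha) (t - t_cyl)` on the
#' cone. The local helix angle is the in-surface winding angle
#' `atan(P / (2 pi r))` between the helix direction and the circumferential
#' direction; it steepens toward the tip as the radius shrinks.
#'
#' @param t Curve parameter in turns (vectorised); must lie in
#'   `[0, t_cyl + t_cap]`.
#' @param spec A [vesicle_spec()].
#' @return A data.frame with columns `t`, `x`, `y`, `z`, `radius` and
#'   `helix_angle` (degrees).
#' @examples
#' curve_point(c(0, 5), vesicle_spec())
#' @export
curve_point <- function(t, spec) {
  stopifnot(inherits(spec, "vesicle_spec"), is.numeric(t))
  tend <- curve_t_end(spec)
  if (any(t < -1e-12 | t > tend + 1e-12))
    stop(sprintf("`t` must lie in [0, %.6f] turns", tend), call. = FALSE)
  t <- pmin(pmax(t, 0), tend)
  P <- spec$pitch; rmax <- spec$r_max; tcyl <- spec$t_cyl
  tcap <- cap_turns(spec)
  ca <- cos(spec$alpha * pi / 180)
  on_cone <- t >= tcyl
  r <- ifelse(on_cone, rmax * (1 - (t - tcyl) / tcap), rmax)
  r <- pmax(r, 0)
  z <- ifelse(on_cone, P * tcyl + P * ca * (t - tcyl), P * t)
  ysgn <- if (spec$handedness == "left") -1 else 1
  # d(arc)/dt = sqrt((2 pi r)^2 + P^2) on both branches (cone:
  # (P cos a)^2 + (r_max/t_cap)^2 = P^2 since r_max/t_cap = P sin a).
  # helix angle = in-surface winding angle atan(P / (2 pi r)): the angle
  # between the local helix direction and the circumferential direction,
  # measured within the wall surface; continuous at the junction and
  # steepening to 90 deg at the tip.
  speed <- sqrt((2 * pi * r)^2 + P^2)
  data.frame(t = t,
             x = r * cos(2 * pi * t),
             y = ysgn * r * sin(2 * pi * t),
             z = z,
             radius = r,
             helix_angle = asin(pmin(1, P / speed)) * 180 / pi)
}

# curve speed |d position / d t| in Angstrom per turn; vectorised
curve_speed <- function(t, spec) {
  tcyl <- spec$t_cyl
  tcap <- cap_turns(spec)
  r <- ifelse(t >= tcyl, spec$r_max * (1 - (t - tcyl) / tcap), spec$r_max)
  r <- pmax(r, 0)
  sqrt((2 * pi * r)^2 + spec$pitch^2)
}

#' Arc length along the half-vesicle curve
#'
#' Numeric arc length of the 3D curve between parameters `t0` and `t1`
#' (turns), by adaptive quadrature of the curve speed at relative tolerance
#' 1e-9, split at the cylinder/cone junction.
#'
#' @param spec A [vesicle_spec()].
#' @param t0,t1 Interval endpoints in turns, `0 <= t0 <= t1 <= t_cyl + t_cap`.
#' @return Arc length in Angstrom.
#' @examples
#' arc_length(vesicle_spec(), 0, 1) # one cylindrical turn, 1121.98 A
#' @export
arc_length <- function(spec, t0, t1) {
  stopifnot(inherits(spec, "vesicle_spec"),
            is.numeric(t0), length(t0) == 1L, is.numeric(t1), length(t1) == 1L)
  tend <- curve_t_end(spec)
  if (t0 < -1e-12 || t1 > tend + 1e-12)
    stop("interval outside curve domain", call. = FALSE)
  if (t1 < t0) stop("`t1` must be >= `t0`", call. = FALSE)
  if (t1 == t0) return(0)
  breaks <- sort(unique(c(t0, t1, spec$t_cyl[spec$t_cyl > t0 && spec$t_cyl < t1])))
  total <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    # cylinder piece: constant speed, integrate exactly
    if (b <= spec$t_cyl) {
      total <- total + (b - a) * curve_speed(a, spec)
    } else {
      total <- total +
        stats::integrate(curve_speed, a, b, spec = spec,
                         rel.tol = 1e-9, subdivisions = 500L)$value
    }
  }
  total
}

# invert arc length: parameter t at arc position s from t = 0 (bisection to
# 1e-10 turns); s vectorised, monotone increasing
arc_length_invert <- function(spec, s) {
  tend <- curve_t_end(spec)
  total <- arc_length(spec, 0, tend)
  vapply(s, function(si) {
    if (si < -1e-9 || si > total + 1e-6)
      stop("arc position outside curve", call. = FALSE)
    if (si <= 0) return(0)
    lo <- 0; hi <- tend
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (arc_length(spec, 0, mid) < si) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}
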