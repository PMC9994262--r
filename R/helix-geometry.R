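#' Helical symmetry of a shell lattice
#'
#' A helical lattice is equivalently described by its pitch `P` (axial length
#' of one full turn, in Angstrom) together with the number of subunits per
#' turn `ut`, or by the per-subunit rise and twist. For a left-handed helix
#' the twist is negative by convention.
#'
#' @param pitch Helical pitch in Angstrom (> 0).
#' @param units_per_turn Subunits per helical turn (> 0, need not be integer).
#' @param handedness `"left"` (default) or `"right"`.
#' @return An object of class `helical_symmetry` with fields `pitch`,
#'   `units_per_turn`, `handedness`, `rise` (Angstrom) and `twist` (degrees,
#'   negative for left-handed).
#' @examples
#' helical_symmetry(48.8, 92.93) # rise 0.525 A, twist -3.874 deg
#' @export
helical_symmetry <- function(pitch, units_per_turn, handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  stopifnot(is.numeric(pitch), length(pitch) == 1L, is.finite(pitch),
            is.numeric(units_per_turn), length(units_per_turn) == 1L,
            is.finite(units_per_turn))
  if (pitch <= 0) stop("`pitch` must be positive", call. = FALSE)
  if (units_per_turn <= 0) stop("`units_per_turn` must be positive", call. = FALSE)
  sgn <- if (handedness == "left") -1 else 1
  structure(
    list(pitch = pitch, units_per_turn = units_per_turn,
         handedness = handedness,
         rise = pitch / units_per_turn,
         twist = sgn * 360 / units_per_turn),
    class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("Helical symmetry (%s-handed)\n", x$handedness))
  cat(sprintf("  pitch: %.4g A   units/turn: %.6g\n", x$pitch, x$units_per_turn))
  cat(sprintf("  rise:  %.4f A   twist: %.4f deg\n", x$rise, x$twist))
  invisible(x)
}

#' Convert pitch/units-per-turn to rise/twist
#'
#' @inheritParams helical_symmetry
#' @return A list with `rise` (Angstrom) and `twist` (degrees).
#' @seealso [symmetry_from_rise_twist()] for the inverse.
#' @examples
#' symmetry_convert(48.8, 92.93)
#' @export
symmetry_convert <- function(pitch, units_per_turn, handedness = c("left", "right")) {
  s <- helical_symmetry(pitch, units_per_turn, handedness)
  list(rise = s$rise, twist = s$twist)
}

#' Convert rise/twist back to pitch/units-per-turn
#'
#' @param rise Axial rise per subunit in Angstrom (> 0).
#' @param twist Azimuthal rotation per subunit in degrees (non-zero; negative
#'   means left-handed).
#' @return A list with `pitch`, `units_per_turn` and `handedness`.
#' @examples
#' symmetry_from_rise_twist(0.525, -3.874)
#' @export
symmetry_from_rise_twist <- function(rise, twist) {
  stopifnot(is.numeric(rise), length(rise) == 1L, is.numeric(twist),
            length(twist) == 1L)
  if (rise <= 0) stop("`rise` must be positive", call. = FALSE)
  if (twist == 0) stop("`twist` must be non-zero", call. = FALSE)
  ut <- 360 / abs(twist)
  list(pitch = rise * ut, units_per_turn = ut,
       handedness = if (twist < 0) "left" else "right")
}

#' Inter-subunit spacing along a helix
#'
#' The path length per subunit along a helix of radius `r`:
#' `sqrt((2*pi*r)^2 + P^2) / ut`. At the reference geometry of the solved
#' shell (r = 178.4 A, P = 48.8 A, ut = 92.93) this gives the 12.07 A
#' monomer spacing used to place subunits.
#'
#' @param r Helix radius in Angstrom (>= 0); vectorised.
#' @param pitch Pitch in Angstrom (> 0).
#' @param units_per_turn Subunits per turn (> 0).
#' @return Spacing in Angstrom.
#' @examples
#' spacing_on_helix(178.4, 48.8, 92.93)
#' @export
spacing_on_helix <- function(r, pitch, units_per_turn) {
  stopifnot(is.numeric(r), is.numeric(pitch), is.numeric(units_per_turn))
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  if (pitch <= 0 || units_per_turn <= 0)
    stop("`pitch` and `units_per_turn` must be positive", call. = FALSE)
  sqrt((2 * pi * r)^2 + pitch^2) / units_per_turn
}

#' Monomers per turn from a vesicle diameter
#'
#' Converts a measured cylinder diameter into the number of wall monomers
#' per helical turn by proportional scaling against a solved reference
#' polymorph (default 35.6 nm diameter with 92.93 units per turn). With a
#' diameter standard deviation, linear error propagation gives
#' `sd_ut = ut_ref * sd_D / D_ref`. An alternative `"spacing"` mode computes
#' `pi * D / s` from a lateral monomer spacing `s` instead.
#'
#' @param diameter Diameter in nm (> 0); vectorised.
#' @param sd Optional standard deviation of the diameter (nm).
#' @param reference Numeric length-2: reference diameter (nm) and its
#'   units-per-turn.
#' @param mode `"reference"` (proportional scaling, default) or `"spacing"`.
#' @param spacing Lateral spacing in Angstrom, used when `mode = "spacing"`.
#' @return A list with `units` (real), `n` (nearest integer,
#'   half-away-from-zero), and when `sd` is given `sd_units` and `sd_n`.
#' @examples
#' units_from_diameter(55.5, sd = 7.3) # ~145 +/- 19
#' units_from_diameter(87.1, sd = 6.9) # ~227 +/- 18
#' @export
units_from_diameter <- function(diameter, sd = NULL,
                                reference = c(35.6, 92.93),
                                mode = c("reference", "spacing"),
                                spacing = 12.07) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(diameter))
  if (any(diameter <= 0)) stop("`diameter` must be positive", call. = FALSE)
  if (mode == "reference") {
    ut <- reference[2] * diameter / reference[1]
    sd_ut <- if (!is.null(sd)) reference[2] * sd / reference[1]
  } else {
    # diameter nm -> A; circumference / lateral spacing
    ut <- pi * diameter * 10 / spacing
    sd_ut <- if (!is.null(sd)) pi * sd * 10 / spacing
  }
  out <- list(units = ut, n = round_half_away(ut))
  if (!is.null(sd)) {
    out$sd_units <- sd_ut
    out$sd_n <- round_half_away(sd_ut)
  }
  out
}

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Diameter increment per added monomer
#'
#' Adding one monomer to a helical turn lengthens the circumference by the
#' lateral spacing, so the diameter grows by `spacing / pi` (3.8 A for a
#' 12 A spacing). Successive shell polymorphs differ by this increment.
#'
#' @param lateral_spacing Lateral monomer spacing in Angstrom (> 0).
#' @return Diameter increment in Angstrom.
#' @examples
#' diameter_increment(12) # 12/pi = 3.8197
#' @export
diameter_increment <- function(lateral_spacing) {
  stopifnot(is.numeric(lateral_spacing))
  if (any(lateral_spacing <= 0))
    stop("`lateral_spacing` must be positive", call. = FALSE)
  lateral_spacing / pi
}

#' Angle of inter-strand hydrogen bonds to the cylinder axis
#'
#' The beta-hairpin strands run at a tilt angle to the cylinder long axis;
#' backbone hydrogen bonds between laterally packed strands are
#' perpendicular to the strand direction, hence at `90 - |tilt|` degrees to
#' the axis. A -36 deg hairpin tilt puts the bonds at 54 deg, close to the
#' magic angle where hoop and axial wall stresses are equal.
#'
#' @param hairpin_tilt Strand tilt relative to the cylinder axis, degrees
#'   (|tilt| <= 90).
#' @return Angle of the hydrogen bonds to the cylinder axis, degrees.
#' @examples
#' rib_hbond_angle(-36) # 54
#' @export
rib_hbond_angle <- function(hairpin_tilt) {
  stopifnot(is.numeric(hairpin_tilt))
  if (any(abs(hairpin_tilt) > 90))
    stop("|hairpin_tilt| must be <= 90 degrees", call. = FALSE)
  90 - abs(hairpin_tilt)
}

#' The magic angle of a pressurised cylinder
#'
#' `atan(sqrt(2))` in degrees (54.7356): the fibre angle at which transverse
#' (hoop) and longitudinal stresses in a thin-walled cylinder are equal.
#'
#' @return Angle in degrees.
#' @examples
#' magic_angle()
#' @export
magic_angle <- function() atan(sqrt(2)) * 180 / pi

#' Geometric calculus of an external reinforcement helix repeat
#'
#' For an all-alpha-helical reinforcement protein (GvpC-like) of tandem
#' repeats binding along the outside of the shell ribs: the axial span of
#' one repeat (`n_res * rise_per_res`), the outward-scaled lateral monomer
#' spacing at the binding radius, the span of the monomer stretch covered by
#' one repeat, the rotational phase between consecutive repeats on an ideal
#' alpha helix (100 deg per residue, mod 360), and the total number of shell
#' monomers engaged by all repeats.
#'
#' @param n_res Residues per repeat (default 33).
#' @param rise_per_res Axial rise per helical residue, Angstrom (default 1.5).
#' @param inner_spacing Lateral monomer spacing at the inner hairpin radius,
#'   Angstrom (default 12.1).
#' @param r_inner Radius of the inner reference points, Angstrom.
#' @param r_binding Radius of the binding site, Angstrom (>= `r_inner`).
#' @param monomers_per_repeat Shell monomers spanned by one repeat (default 4).
#' @param n_repeats Number of tandem repeats (default 5).
#' @return A list with `repeat_span`, `outer_spacing`, `tetrad_span`
#'   (Angstrom), `repeat_phase` (degrees) and `monomers_bound`.
#' @examples
#' gvpc_geometry(r_inner = 121, r_binding = 127)
#' @export
gvpc_geometry <- function(n_res = 33, rise_per_res = 1.5, inner_spacing = 12.1,
                          r_inner, r_binding, monomers_per_repeat = 4,
                          n_repeats = 5) {
  stopifnot(n_res > 0, rise_per_res > 0, inner_spacing > 0, r_inner > 0,
            monomers_per_repeat > 0, n_repeats > 0)
  if (r_binding < r_inner)
    stop("`r_binding` must be >= `r_inner`", call. = FALSE)
  outer <- inner_spacing * r_binding / r_inner
  list(repeat_span = n_res * rise_per_res,
       outer_spacing = outer,
       tetrad_span = monomers_per_repeat * outer,
       repeat_phase = (100 * n_res) %% 360,
       monomers_bound = n_repeats * monomers_per_repeat)
}
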