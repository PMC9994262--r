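# The four correction rotations applied to placed monomers. Each pivots on
# landmark atoms of the monomer itself:
#  (1) helixangle: whole monomer about the normal of the LS plane through
#      C-alpha 23..49, centred on the midpoint of carbonyl O 28 / O 42;
#      compensates the steepening local helix angle on the cone.
#  (2) monomer_tilt: whole monomer about the normal of the C-beta 24..33
#      plane, centred on carbonyl O 36; tips the monomer over with the cone.
#  (3) beta_tilt: residues 23..49 only, about the C-alpha 23 -> C-alpha 49
#      line; hinges the hairpin flap.
#  (4) nterm_tilt: residues 2..23 only, about the same line; hinges the
#      N-arm/alpha1 block to keep the inter-rib contact closed.

rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c + s * K + (1 - c) * outer(a, a)
}

# least-squares plane through points (rows of xyz); returns unit normal.
# Errors if the points are (near-)collinear so no plane is defined.
fit_plane_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate plane fit: landmark atoms are collinear", call. = FALSE)
  sv$v[, 3]
}

# rotate selected rows of an atom table about (center, axis) by angle_deg
rotate_atoms <- function(atoms, center, axis, angle_deg, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(atoms))
  R <- rotation_about_axis(axis, angle_deg)
  xyz <- as_xyz(atoms)[rows, , drop = FALSE]
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
  atoms$x[rows] <- xyz[, 1]; atoms$y[rows] <- xyz[, 2]
  atoms$z[rows] <- xyz[, 3]
  atoms
}

#' Apply one correction rotation to a monomer
#'
#' Rotation centres and axes are computed from the monomer's own landmark
#' atoms (see Details in [build_half_shell()]); corrections (1) and (2)
#' move the whole monomer rigidly, (3) moves residues 23..49 and (4)
#' residues 2..23 only.
#'
#' @param atoms Atom table of one monomer (must contain the landmarks).
#' @param which One of `"helixangle"`, `"monomer_tilt"`, `"beta_tilt"`,
#'   `"nterm_tilt"`.
#' @param angle Rotation angle in degrees.
#' @return The rotated atom table.
#' @export
apply_correction <- function(atoms,
                             which = c("helixangle", "monomer_tilt",
                                       "beta_tilt", "nterm_tilt"),
                             angle) {
  which <- match.arg(which)
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  if (angle == 0) return(atoms)
  switch(which,
    helixangle = {
      ctr <- template_pivot(atoms)
      ca <- atoms[atoms$atom == "CA" & atoms$resid >= 23 & atoms$resid <= 49, ]
      rotate_atoms(atoms, ctr, fit_plane_normal(as_xyz(ca)), angle)
    },
    monomer_tilt = {
      ctr <- landmark_xyz(atoms, "O", 36L)
      cb <- atoms[atoms$atom == "CB" & atoms$resid >= 24 & atoms$resid <= 33, ]
      rotate_atoms(atoms, ctr, fit_plane_normal(as_xyz(cb)), angle)
    },
    beta_tilt = {
      a23 <- landmark_xyz(atoms, "CA", 23L)
      a49 <- landmark_xyz(atoms, "CA", 49L)
      rows <- which(atoms$resid >= 23 & atoms$resid <= 49)
      rotate_atoms(atoms, a23, a49 - a23, angle, rows)
    },
    nterm_tilt = {
      a23 <- landmark_xyz(atoms, "CA", 23L)
      a49 <- landmark_xyz(atoms, "CA", 49L)
      rows <- which(atoms$resid >= 2 & atoms$resid <= 23)
      rotate_atoms(atoms, a23, a49 - a23, angle, rows)
    })
}

#' Correction schedule over the half-shell curve
#'
#' All four corrections are zero throughout the cylindrical region. On the
#' cone, the three manually tuned parameters ramp linearly from 0 at the
#' cylinder/cone junction to their endpoint value, reached at a fraction
#' `tip_frac` of the way through the cone, and stay constant through the
#' remaining tip region. The helix-angle correction is not a free
#' parameter: it is computed analytically as the difference between the
#' local helix angle and the cylindrical reference angle.
#'
#' @param monomer_tilt,beta_tilt,nterm_tilt Endpoint values in degrees
#'   (defaults 0).
#' @param tip_frac Fraction of the cone (in turns) over which the linear
#'   ramp runs; beyond it values are held constant (default 0.8).
#' @return An object of class `correction_schedule`.
#' @export
correction_schedule <- function(monomer_tilt = 0, beta_tilt = 0,
                                nterm_tilt = 0, tip_frac = 0.8) {
  stopifnot(tip_frac > 0, tip_frac <= 1)
  structure(list(monomer_tilt = monomer_tilt, beta_tilt = beta_tilt,
                 nterm_tilt = nterm_tilt, tip_frac = tip_frac),
            class = "correction_schedule")
}

#' Evaluate a correction schedule
#'
#' @param schedule A [correction_schedule()].
#' @param t Curve parameters in turns (vectorised).
#' @param spec The [vesicle_spec()] defining the cylinder/cone regions.
#' @return A data.frame with columns `helixangle`, `monomer_tilt`,
#'   `beta_tilt`, `nterm_tilt` (degrees).
#' @export
schedule_values <- function(schedule, t, spec) {
  stopifnot(inherits(schedule, "correction_schedule"),
            inherits(spec, "vesicle_spec"))
  tcap <- cap_turns(spec)
  frac <- pmax(0, (t - spec$t_cyl)) / tcap      # 0 on cylinder, 0..1 on cone
  ramp <- pmin(frac / schedule$tip_frac, 1)
  cp <- curve_point(t, spec)
  ref_angle <- asin(spec$pitch / sqrt((2 * pi * spec$r_max)^2 + spec$pitch^2)) *
    180 / pi
  data.frame(
    helixangle = cp$helix_angle - ref_angle,
    monomer_tilt = schedule$monomer_tilt * ramp,
    beta_tilt = schedule$beta_tilt * ramp,
    nterm_tilt = schedule$nterm_tilt * ramp)
}
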