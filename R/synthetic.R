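# Synthetic inputs with known ground truth: a landmark-complete toy
# monomer, noisy sigmoid collapse curves, projection images of cylinders
# and helical lattices, and analytic pore scenes. All generators are
# deterministic under a fixed seed and leave the caller's RNG state alone.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a toy GvpA-like monomer template
#'
#' A backbone-level (C-alpha / C-beta / carbonyl-O pseudo-atom) stand-in
#' for the shell monomer, with the coil-alpha-beta-beta-alpha-coil region
#' layout: N-arm 1-7, helix alpha1 8-22, beta-hairpin 23-49 with the turn
#' at 36, helix alpha2 50-66. It contains every landmark atom the
#' correction rotations reference and is pre-oriented in the builder's
#' canonical frame: local x = outward wall normal, local z = cylinder
#' axis, hairpin long axis tilted `hairpin_tilt` degrees from z, and the
#' placement pivot (midpoint of the O28/O42 carbonyls) at the origin.
#'
#' @param hairpin_tilt Hairpin tilt relative to the cylinder axis, degrees
#'   (default -36).
#' @param jitter Gaussian positional jitter in Angstrom (default 0.05).
#' @param seed RNG seed for the jitter (default 0).
#' @param mass Total monomer mass in Dalton (default 7052, a ~7 kDa shell
#'   protein).
#' @param wall_radius Reference wall radius the template is curved to
#'   conform to, Angstrom (default 178.4; `Inf` for a flat template).
#' @return A [monomer_template()].
#' @examples
#' make_toy_monomer()
#' @export
make_toy_monomer <- function(hairpin_tilt = -36, jitter = 0.05, seed = 0,
                             mass = 7052, wall_radius = 178.4) {
  stopifnot(abs(hairpin_tilt) <= 90, jitter >= 0)
  phi <- hairpin_tilt * pi / 180
  # in-wall-plane basis: h = hairpin long axis (z rotated by tilt about x),
  # g = in-plane perpendicular; xn = wall normal (local x)
  h <- c(0, -sin(phi), cos(phi))
  g <- c(0, cos(phi), sin(phi))
  xn <- c(1, 0, 0)
  rec <- function(resid, atom, pos)
    data.frame(atom = atom, resid = resid, x = pos[1], y = pos[2], z = pos[3])
  rows <- list()
  add <- function(resid, atom, pos) rows[[length(rows) + 1L]] <<-
    rec(resid, atom, pos)
  beta_rise <- 3.5; helix_rise <- 1.5
  # beta1 23..35 along +h at -2.4 g; beta2 37..49 back along -h at +2.4 g
  for (i in 23:35) {
    a <- (i - 23) * beta_rise - 21
    ca <- a * h - 2.4 * g + 0.3 * ((-1)^i) * xn
    add(i, "CA", ca)
    add(i, "CB", ca + 1.5 * ((-1)^i) * xn)
    add(i, "O", a * h - 1.2 * g)
  }
  add(36L, "CA", 23.5 * h)
  add(36L, "CB", 23.5 * h + 1.5 * xn)
  add(36L, "O", 24.7 * h)
  for (i in 37:49) {
    a <- 21 - (i - 37) * beta_rise
    ca <- a * h + 2.4 * g + 0.3 * ((-1)^i) * xn
    add(i, "CA", ca)
    add(i, "CB", ca - 1.5 * ((-1)^i) * xn)
    add(i, "O", a * h + 1.2 * g)
  }
  # alpha1 8..22: bridge helix running along -g from the hairpin base, on
  # the inner (luminal) wall layer -- negative x, clear of alpha2 outside
  for (i in 8:22) {
    th <- (i - 8) * 100 * pi / 180
    ca <- -23 * h + (-2.4 - (22 - i) * helix_rise) * g +
      (-3.7 + 1.0 * cos(th)) * xn + 1.0 * sin(th) * h
    add(i, "CA", ca)
    add(i, "O", ca + 1.2 * g)
  }
  # N-arm 1..7: coil continuing along -g, crossing under the neighbouring
  # hairpins on the luminal side (deepest wall layer)
  for (i in 1:7) {
    ca <- (-23 - 1.5) * h + (-25.4 - (7 - i) * 3.2) * g - 4.5 * xn
    add(i, "CA", ca)
    add(i, "O", ca + 1.2 * g)
  }
  # alpha2 50..66: folds back over the hairpin, offset outward in x
  for (i in 50:66) {
    th <- (i - 50) * 100 * pi / 180
    ca <- ((i - 50) * helix_rise - 13) * h + 3.2 * xn +
      1.0 * cos(th) * g + 1.0 * sin(th) * xn
    add(i, "CA", ca)
    add(i, "O", ca + 1.2 * g)
  }
  atoms <- do.call(rbind, rows)
  # conform the template to the reference wall curvature: a straight
  # feature running along the circumferential direction (local y) would
  # otherwise poke radially outward by ~y^2/(2 r) when placed on the
  # cylinder; bend it inward to second order like the real monomer
  if (is.finite(wall_radius) && wall_radius > 0)
    atoms$x <- atoms$x - atoms$y^2 / (2 * wall_radius)
  if (jitter > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(seed,
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(atoms), sd = jitter), ncol = 3))
  }
  # exact pivot centring (jitter moves it slightly off the origin)
  piv <- (unlist(atoms[atoms$atom == "O" & atoms$resid == 28, c("x", "y", "z")]) +
          unlist(atoms[atoms$atom == "O" & atoms$resid == 42, c("x", "y", "z")])) / 2
  atoms$x <- atoms$x - piv[1]; atoms$y <- atoms$y - piv[2]
  atoms$z <- atoms$z - piv[3]
  atoms$resname <- "ALA"
  atoms$chain <- "A"
  atoms$element <- substr(atoms$atom, 1, 1)
  atoms$occ <- 1
  monomer_template(atoms, mass = mass)
}

#' Simulate collapse-pressure curves
#'
#' Optical density follows the collapse sigmoid
#' `OD = 1 / (1 + exp(k (p - p0)))` on a regular pressure grid (default
#' 0.5 bar steps), plus Gaussian noise, clipped at zero.
#'
#' @param p0 Collapse midpoint in bar.
#' @param k Sigmoid width parameter in 1/bar (> 0).
#' @param noise_sd Gaussian noise standard deviation (default 0.05).
#' @param p_max Upper end of the pressure grid in bar (default 12).
#' @param step Pressure increment in bar (default 0.5).
#' @param n_replicates Number of replicate curves (default 3).
#' @param seed RNG seed (default 0).
#' @return A data.frame with columns `pressure`, `od500`, `replicate`, of
#'   class `collapse_curve`.
#' @export
make_collapse_curve <- function(p0, k, noise_sd = 0.05, p_max = 12,
                                step = 0.5, n_replicates = 3, seed = 0) {
  stopifnot(k > 0, noise_sd >= 0, p_max > 0, step > 0, n_replicates >= 1)
  p <- seq(0, p_max, by = step)
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      od <- 1 / (1 + exp(k * (p - p0))) +
        stats::rnorm(length(p), sd = noise_sd)
      data.frame(pressure = p, od500 = pmax(od, 0), replicate = r)
    }))
  })
  class(out) <- c("collapse_curve", "data.frame")
  out
}

#' Simulated projection image of a hollow cylinder
#'
#' Line-integral projection of a thin cylindrical shell viewed side-on
#' (helix axis along image rows): density piles up at the tangents, so the
#' profile across the tube shows two rim peaks separated by the true
#' diameter.
#'
#' @param diameter Cylinder diameter in Angstrom.
#' @param length Cylinder length in Angstrom.
#' @param pixel Pixel size in Angstrom (default 2).
#' @param blur Gaussian blur sigma in Angstrom (default 3).
#' @param noise_sd Additive Gaussian noise, as a fraction of the peak
#'   intensity (default 0).
#' @param pad Extra image width beyond the diameter, Angstrom (default 60).
#' @param seed RNG seed for the noise (default 0).
#' @return A [projection_image()].
#' @export
make_cylinder_image <- function(diameter, length, pixel = 2, blur = 3,
                                noise_sd = 0, pad = 60, seed = 0) {
  stopifnot(diameter > 0, length > 0, pixel > 0)
  R <- diameter / 2
  ncol <- 2 * ceiling((R + pad) / pixel) + 1
  nrow <- max(3L, ceiling(length / pixel))
  xs <- (seq_len(ncol) - (ncol + 1) / 2) * pixel
  # analytic line integral through an infinitesimally thin shell, sampled
  # by dense uniform points on the circle (deterministic)
  ang <- seq(0, 2 * pi, length.out = 40000L + 1L)[-1L]
  px <- R * cos(ang)
  col_idx <- pmin(pmax(round((px / pixel) + (ncol + 1) / 2), 1), ncol)
  prof <- tabulate(col_idx, nbins = ncol)
  img <- matrix(rep(prof, each = nrow), nrow = nrow, ncol = ncol)
  img <- gauss_blur(img, sigma = blur / pixel)
  if (noise_sd > 0) {
    img <- with_seed(seed,
      img + matrix(stats::rnorm(base::length(img),
                                sd = noise_sd * max(img)),
                   nrow = nrow))
  }
  projection_image(img, pixel, blur = blur)
}

#' Simulated projection image of a helical point lattice
#'
#' Point scatterers at the lattice positions of a helix (pitch `P`, `ut`
#' subunits per turn) projected side-on, with the helix axis along image
#' rows. The power spectrum of such an image shows layer lines; the first
#' sits at an axial frequency of `1/P`.
#'
#' @param pitch Helical pitch in Angstrom.
#' @param units_per_turn Subunits per turn.
#' @param diameter Helix diameter in Angstrom.
#' @param n_turns Number of helical turns in the image (default 10).
#' @param pixel Pixel size in Angstrom (default 2).
#' @param blur Gaussian blur sigma in Angstrom (default 3).
#' @param noise_sd Additive Gaussian noise, fraction of peak (default 0).
#' @param seed RNG seed for the noise (default 0).
#' @return A [projection_image()].
#' @export
make_lattice_image <- function(pitch, units_per_turn, diameter,
                               n_turns = 10, pixel = 2, blur = 3,
                               noise_sd = 0, seed = 0) {
  stopifnot(pitch > 0, units_per_turn > 0, diameter > 0, n_turns > 0)
  R <- diameter / 2
  rise <- pitch / units_per_turn
  n <- floor(n_turns * units_per_turn)
  k <- seq_len(n) - 1
  theta <- -2 * pi * k / units_per_turn
  xproj <- R * cos(theta)        # view along y
  zpos <- k * rise
  nrow <- ceiling(n_turns * pitch / pixel)
  ncol <- 2 * ceiling((R + 30) / pixel) + 1
  img <- matrix(0, nrow, ncol)
  ri <- round(zpos / pixel) + 1
  ci <- round(xproj / pixel + (ncol + 1) / 2)
  ok <- ri >= 1 & ri <= nrow & ci >= 1 & ci <= ncol
  for (i in which(ok)) img[ri[i], ci[i]] <- img[ri[i], ci[i]] + 1
  img <- gauss_blur(img, sigma = blur / pixel)
  if (noise_sd > 0) {
    img <- with_seed(seed,
      img + matrix(stats::rnorm(length(img), sd = noise_sd * max(img)),
                   nrow = nrow))
  }
  projection_image(img, pixel, blur = blur)
}

#' Analytic slit pore scene
#'
#' Two parallel walls of atoms (planes at x = +/- gap/2) with a start and
#' end point on opposite sides along y. The widest path runs midway
#' between the walls, so the analytic bottleneck diameter is
#' `2 * (gap/2 - radius)`.
#'
#' @param gap Centre-to-centre distance between the walls, Angstrom; must
#'   exceed `2 * radius` for a passable slit.
#' @param radius Van der Waals radius of the wall atoms, Angstrom
#'   (default 1.7, carbon).
#' @param extent Half-extent of the walls in y and z, Angstrom (default 8).
#' @param atom_step Wall atom grid spacing, Angstrom (default `radius`).
#' @return A [pore_scene()] with attribute `analytic_bottleneck`.
#' @export
make_slit_scene <- function(gap, radius = 1.7, extent = 8,
                            atom_step = radius) {
  stopifnot(gap > 0, radius > 0, extent > 0)
  if (gap <= 2 * radius)
    stop("impassable slit: gap <= 2 * radius (expected bottleneck <= 0)",
         call. = FALSE)
  # symmetric grid including 0 so an atom sits directly beside the midline
  # path and the analytic bottleneck 2*(gap/2 - radius) is attained exactly
  gv <- seq(-extent, extent, length.out = 2 * ceiling(extent / atom_step) + 1)
  wall <- expand.grid(y = gv, z = gv)
  centers <- rbind(
    cbind(x = -gap / 2, wall[, c("y", "z")]),
    cbind(x = gap / 2, wall[, c("y", "z")]))
  names(centers) <- c("x", "y", "z")
  scene <- pore_scene(
    centers = as.matrix(centers),
    radii = rep(radius, nrow(centers)),
    start = c(0, -extent - 4, 0),
    end = c(0, extent + 4, 0),
    bbox = rbind(c(-gap / 2 - radius / 2, -extent - 5, -extent + radius),
                 c(gap / 2 + radius / 2, extent + 5, extent - radius)))
  attr(scene, "analytic_bottleneck") <- 2 * (gap / 2 - radius)
  scene
}
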