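# Building half and complete vesicle shells: monomer copies are placed at
# fixed arc spacing on the parametric curve, oriented by a local frame,
# corrected per schedule, and the half shell duplicated by the two-fold
# (D1) axis (x) into the complete vesicle.

#' Align the curve phase to a monomer's pivot point
#'
#' The placement curve must pass through the pivot point of the seed
#' monomer (the midpoint of the residue-28 and residue-42 carbonyl
#' oxygens). Only a rotation about z and a shift along z are applied: the
#' returned transform brings the pivot to azimuth 0 and height 0, i.e. onto
#' the curve point at t = 0 radially.
#'
#' @param template A [monomer_template()].
#' @param spec A [vesicle_spec()] (used for reporting the radial mismatch).
#' @return A list with `z_rotation` (degrees), `z_shift` (Angstrom),
#'   `radial_mismatch` (pivot radius minus `r_max`, Angstrom) and
#'   `template` (the transformed template).
#' @export
align_curve_to_pivot <- function(template, spec) {
  stopifnot(inherits(template, "monomer_template"),
            inherits(spec, "vesicle_spec"))
  p <- template_pivot(template)
  rot <- -atan2(p[2], p[1]) * 180 / pi
  if (sqrt(p[1]^2 + p[2]^2) < 1e-9) rot <- 0
  shift <- -p[3]
  out <- rotate_atoms(as.data.frame(template), c(0, 0, 0), c(0, 0, 1), rot)
  out$z <- out$z + shift
  list(z_rotation = rot, z_shift = shift,
       radial_mismatch = sqrt(p[1]^2 + p[2]^2) - spec$r_max,
       template = monomer_template(out, mass = attr(template, "monomer_mass")))
}

#' Placement parameters along the half-shell curve
#'
#' Points are placed at arc positions `0, s, 2s, ...` along the curve; the
#' number that fits is `floor(L / s)` where `L` is the total curve length,
#' and the final `n_omit_tip` points nearest the tip are then omitted (at
#' the stated defaults: floor(10497.8 / 12.07) = 869 points, minus 4, i.e.
#' 865 per half shell).
#'
#' @param spec A [vesicle_spec()].
#' @return A data.frame with columns `index`, `arc` (Angstrom) and `t`
#'   (turns).
#' @examples
#' nrow(generate_placements(vesicle_spec())) # 865
#' @export
generate_placements <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  L <- arc_length(spec, 0, curve_t_end(spec))
  n <- floor(L / spec$spacing + 1e-9)
  if (n < 1) stop("spacing larger than total curve length", call. = FALSE)
  n_keep <- n - spec$n_omit_tip
  if (n_keep < 1)
    stop("all placements omitted by `n_omit_tip`", call. = FALSE)
  arc <- (seq_len(n_keep) - 1) * spec$spacing
  data.frame(index = seq_len(n_keep), arc = arc,
             t = arc_length_invert(spec, arc))
}

#' Local orientation frame on the curve
#'
#' An orthonormal right-handed frame at parameter `t`: local x maps to the
#' outward wall normal (the radial direction, orthogonalised against the
#' tangent on the cone), local z to the "up" direction in the wall plane
#' (roughly the cylinder axis; exactly `tangent x radial`), and local y to
#' the reversed curve tangent, completing the right-handed triad. A
#' template is therefore built with the cylinder axis along its local z.
#' At the tip the radius vanishes; the radial axis is taken from its
#' limiting direction.
#'
#' @param t Curve parameter in turns.
#' @param spec A [vesicle_spec()].
#' @return A list with `R` (3x3 rotation, columns = images of local x, y,
#'   z) and `origin` (curve point).
#' @export
local_frame <- function(t, spec) {
  stopifnot(inherits(spec, "vesicle_spec"), length(t) == 1L)
  cp <- curve_point(t, spec)
  th <- 2 * pi * t
  sgn <- if (spec$handedness == "left") -1 else 1
  tcap <- cap_turns(spec)
  on_cone <- t >= spec$t_cyl
  rprime <- if (on_cone) -spec$r_max / tcap else 0
  dz <- if (on_cone) spec$pitch * cos(spec$alpha * pi / 180) else spec$pitch
  r <- cp$radius
  tangent <- c(rprime * cos(th) - 2 * pi * r * sin(th),
               sgn * (rprime * sin(th) + 2 * pi * r * cos(th)),
               dz)
  w <- tangent / sqrt(sum(tangent^2))
  radial <- c(cos(th), sgn * sin(th), 0)
  u <- radial - sum(radial * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])       # v = w x u, approximately +z
  # columns = images of local x, y, z; proper rotation (x cross y = z)
  list(R = cbind(u, -w, v), origin = c(cp$x, cp$y, cp$z))
}

chain_id <- function(i, prefix = "") {
  vapply(i, function(k) {
    k <- k - 1L
    s <- ""
    repeat {
      s <- paste0(LETTERS[k %% 26L + 1L], s)
      k <- k %/% 26L - 1L
      if (k < 0L) break
    }
    paste0(prefix, s)
  }, character(1))
}

place_monomer <- function(local_atoms, frame, chain) {
  xyz <- as_xyz(local_atoms) %*% t(frame$R)
  xyz <- sweep(xyz, 2, frame$origin, "+")
  out <- set_xyz(local_atoms, xyz)
  out$chain <- chain
  out
}

#' Build a half-shell model
#'
#' Places one copy of the template per placement point of
#' [generate_placements()]. The template is first centred on its pivot
#' (midpoint of the O28/O42 carbonyls); each copy receives the four
#' correction rotations evaluated from the schedule at its `t` (applied in
#' the order helixangle, monomer tilt, beta tilt, N-terminal tilt, in
#' template-local coordinates) and is then mapped rigidly into the local
#' curve frame. Chains are labelled in placement order (A, B, ..., Z, AA,
#' ...).
#'
#' @param template A [monomer_template()], pre-oriented in the canonical
#'   frame (local x = outward wall normal, local z = cylinder axis, pivot
#'   anywhere -- it is centred automatically).
#' @param spec A [vesicle_spec()].
#' @param schedule A [correction_schedule()] (default: all zero).
#' @param instantiate If `TRUE` (default) atom coordinates are computed and
#'   stored; `FALSE` keeps only placements and frames.
#' @return An object of class `shell_model`.
#' @export
build_half_shell <- function(template, spec,
                             schedule = correction_schedule(),
                             instantiate = TRUE) {
  stopifnot(inherits(template, "monomer_template"),
            inherits(spec, "vesicle_spec"),
            inherits(schedule, "correction_schedule"))
  pl <- generate_placements(spec)
  corr <- schedule_values(schedule, pl$t, spec)
  pl <- cbind(pl, corr)
  pl$chain <- chain_id(pl$index)
  # centre template on its pivot so the pivot rides exactly on the curve
  local0 <- as.data.frame(template)
  piv <- template_pivot(local0)
  local0$x <- local0$x - piv[1]; local0$y <- local0$y - piv[2]
  local0$z <- local0$z - piv[3]
  frames <- lapply(pl$t, local_frame, spec = spec)
  model <- structure(
    list(template = local0, spec = spec, schedule = schedule,
         placements = pl, frames = frames, kind = "half", atoms = NULL),
    class = "shell_model")
  if (instantiate) model$atoms <- model_atoms(model)
  model
}

# corrected, placed atom table of placement i (template-local corrections,
# then rigid mapping into the frame)
placed_atoms_one <- function(model, i) {
  pl <- model$placements[i, ]
  atoms <- model$template
  for (w in c("helixangle", "monomer_tilt", "beta_tilt", "nterm_tilt")) {
    ang <- pl[[w]]
    if (!is.null(ang) && is.finite(ang) && ang != 0)
      atoms <- apply_correction(atoms, w, ang)
  }
  place_monomer(atoms, model$frames[[i]], pl$chain)
}

#' Expand a shell model to its full atom table
#'
#' @param model A `shell_model`.
#' @return Atom table with one chain per placed monomer.
#' @export
model_atoms <- function(model) {
  stopifnot(inherits(model, "shell_model"))
  if (!is.null(model$atoms)) return(model$atoms)
  do.call(rbind, lapply(seq_len(nrow(model$placements)),
                        function(i) placed_atoms_one(model, i)))
}

#' @export
print.shell_model <- function(x, ...) {
  cat(sprintf("Shell model (%s): %d monomers\n", x$kind,
              nrow(x$placements)))
  if (!is.null(x$atoms)) cat(sprintf("  %d atoms instantiated\n", nrow(x$atoms)))
  invisible(x)
}

#' Number of placed monomers in a shell model
#' @param model A `shell_model`.
#' @return Integer count.
#' @export
monomer_count <- function(model) {
  stopifnot(inherits(model, "shell_model"))
  nrow(model$placements)
}

#' Duplicate a half shell about the D1 axis
#'
#' The complete vesicle is the half shell plus its copy rotated 180 degrees
#' about the x axis (the two-fold D1 axis). Chains of the copy carry the
#' distinguishing prefix `"b"`. Applying the operation to an
#' already-complete model is an error.
#'
#' @param half A half `shell_model`.
#' @return A complete `shell_model` with twice the monomer count.
#' @export
duplicate_d1 <- function(half) {
  stopifnot(inherits(half, "shell_model"))
  if (half$kind != "half")
    stop("model is not a half shell (already duplicated?)", call. = FALSE)
  D <- diag(c(1, -1, -1))
  frames2 <- lapply(half$frames, function(f)
    list(R = D %*% f$R, origin = as.vector(D %*% f$origin)))
  pl2 <- half$placements
  pl2$chain <- paste0("b", pl2$chain)
  pl2$index <- pl2$index + nrow(half$placements)
  full <- half
  full$kind <- "full"
  full$placements <- rbind(half$placements, pl2)
  full$frames <- c(half$frames, frames2)
  if (!is.null(half$atoms)) {
    a2 <- half$atoms
    xyz <- as_xyz(a2) %*% t(D)
    a2 <- set_xyz(a2, xyz)
    a2$chain <- paste0("b", a2$chain)
    full$atoms <- rbind(half$atoms, a2)
  }
  full
}

#' Expand a monomer by helical symmetry
#'
#' Generates `n` copies by the iterated screw operation (rotation about z
#' by `twist` degrees, translation along z by `rise` Angstrom). With
#' `n_per_rib` set, copies are arranged as consecutive ribs: member `j` of
#' rib `r` uses screw exponent `j + r * ut`, so rib neighbours are offset
#' by one full helical turn (`ut = 360/|twist|` units by default).
#'
#' @param template A [monomer_template()] (used as placed; combine with a
#'   `seed_frame` to position it on a shell).
#' @param rise Rise per subunit, Angstrom.
#' @param twist Twist per subunit, degrees (negative = left-handed).
#' @param n Total number of copies (>= 1).
#' @param n_per_rib Optional monomers per rib (must divide `n`).
#' @param ut Units per turn used for the rib offset (default
#'   `360/abs(twist)`).
#' @param seed_frame Optional frame (list `R`, `origin`) positioning the
#'   seed copy; default identity.
#' @return A `shell_model` of kind `"expand"`.
#' @export
helical_expand <- function(template, rise, twist, n, n_per_rib = NULL,
                           ut = 360 / abs(twist), seed_frame = NULL) {
  stopifnot(inherits(template, "monomer_template"), n >= 1,
            is.numeric(rise), is.numeric(twist), twist != 0)
  if (is.null(seed_frame)) seed_frame <- list(R = diag(3), origin = c(0, 0, 0))
  if (is.null(n_per_rib)) {
    expo <- seq_len(n) - 1
  } else {
    if (n %% n_per_rib != 0)
      stop("`n_per_rib` must divide `n`", call. = FALSE)
    ribs <- n / n_per_rib
    expo <- as.vector(outer(seq_len(n_per_rib) - 1,
                            (seq_len(ribs) - 1) * ut, "+"))
  }
  local0 <- as.data.frame(template)
  frames <- lapply(expo, function(e) {
    th <- e * twist * pi / 180
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    list(R = Rz %*% seed_frame$R,
         origin = as.vector(Rz %*% seed_frame$origin) + c(0, 0, e * rise))
  })
  pl <- data.frame(index = seq_along(expo), arc = NA_real_, t = expo,
                   helixangle = 0, monomer_tilt = 0, beta_tilt = 0,
                   nterm_tilt = 0, chain = chain_id(seq_along(expo)))
  model <- structure(
    list(template = local0, spec = NULL, schedule = NULL, placements = pl,
         frames = frames, kind = "expand", atoms = NULL),
    class = "shell_model")
  model$atoms <- do.call(rbind, lapply(seq_along(expo), function(i)
    place_monomer(local0, frames[[i]], pl$chain[i])))
  model
}

#' Total molecular mass of a shell model
#'
#' @param model A `shell_model`.
#' @param per_monomer Mass of one monomer in Dalton; defaults to the
#'   template's `monomer_mass` attribute or the sum of a per-atom `mass`
#'   column.
#' @return Mass in Dalton.
#' @export
model_mass <- function(model, per_monomer = NULL) {
  stopifnot(inherits(model, "shell_model"))
  if (is.null(per_monomer)) per_monomer <- attr(model$template, "monomer_mass")
  if (is.null(per_monomer) && !is.null(model$template$mass))
    per_monomer <- sum(model$template$mass)
  if (is.null(per_monomer))
    stop("no monomer mass available; supply `per_monomer`", call. = FALSE)
  monomer_count(model) * per_monomer
}

#' Inter-chain steric clash report
#'
#' Finds all atom pairs from different chains closer than `cutoff`, using a
#' spatial grid with cell size `cutoff` (no full pairwise scan). Ordering
#' is deterministic (by atom row indices).
#'
#' @param model A `shell_model` or atom table.
#' @param cutoff Distance cutoff in Angstrom (default 2.0).
#' @param atom_names Atom-name selection (default main-chain heavy atoms
#'   `N`, `CA`, `C`, `O`); `NULL` keeps all atoms.
#' @return data.frame with columns `chain1`, `chain2`, `atom1`, `atom2`,
#'   `resid1`, `resid2`, `distance`.
#' @export
clash_report <- function(model, cutoff = 2.0,
                         atom_names = c("N", "CA", "C", "O")) {
  stopifnot(cutoff > 0)
  atoms <- if (inherits(model, "shell_model")) model_atoms(model) else model
  empty <- data.frame(chain1 = character(), chain2 = character(),
                      atom1 = integer(), atom2 = integer(),
                      resid1 = integer(), resid2 = integer(),
                      distance = numeric())
  if (is.null(atoms) || !nrow(atoms)) return(empty)
  if (!is.null(atom_names)) atoms <- atoms[atoms$atom %in% atom_names, ]
  if (nrow(atoms) < 2L) return(empty)
  xyz <- as_xyz(atoms)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- cell[, 1] + 1e4 * cell[, 2] + 1e8 * cell[, 3]
  idx_by_cell <- split(seq_len(nrow(atoms)), key)
  keymap <- as.numeric(names(idx_by_cell))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx + 1e4 * offs$dy + 1e8 * offs$dz >= 0, ]  # forward half
  hits <- list()
  for (ci in seq_along(idx_by_cell)) {
    k <- keymap[ci]
    ia <- idx_by_cell[[ci]]
    for (oi in seq_len(nrow(offs))) {
      dk <- offs$dx[oi] + 1e4 * offs$dy[oi] + 1e8 * offs$dz[oi]
      jb <- if (dk == 0) ia else idx_by_cell[[as.character(k + dk)]]
      if (is.null(jb)) next
      pr <- expand.grid(i = ia, j = jb)
      pr <- if (dk == 0) pr[pr$i < pr$j, ] else pr
      if (!nrow(pr)) next
      d2 <- rowSums((xyz[pr$i, , drop = FALSE] - xyz[pr$j, , drop = FALSE])^2)
      keep <- d2 < cutoff^2 & atoms$chain[pr$i] != atoms$chain[pr$j]
      if (any(keep))
        hits[[length(hits) + 1L]] <-
          data.frame(i = pr$i[keep], j = pr$j[keep], d = sqrt(d2[keep]))
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  swap <- h$i > h$j
  tmp <- h$i[swap]; h$i[swap] <- h$j[swap]; h$j[swap] <- tmp
  h <- h[order(h$i, h$j), ]
  data.frame(chain1 = atoms$chain[h$i], chain2 = atoms$chain[h$j],
             atom1 = h$i, atom2 = h$j,
             resid1 = atoms$resid[h$i], resid2 = atoms$resid[h$j],
             distance = h$d)
}
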