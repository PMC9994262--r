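# Shell building: placements, frames, half/full models, helical expansion,
# clash detection, mass, structure export.

test_that("placement counts follow the arc-length closed form", {
  spec <- vesicle_spec()
  pl <- generate_placements(spec)
  # floor(L/s) - n_omit_tip with L from the closed-form oracle
  L <- oracle_arc_length(spec, 0, spec$t_cyl + cap_turns(spec))
  expect_identical(nrow(pl), as.integer(floor(L / spec$spacing) - 4))
  expect_identical(nrow(pl), 865L)
  expect_equal(pl$t[1], 0)
  # consecutive arc separations equal the spacing to 1e-6 A
  seps <- vapply(seq_len(20), function(i)
    arc_length(spec, pl$t[i], pl$t[i + 1]), numeric(1))
  expect_equal(seps, rep(spec$spacing, 20), tolerance = 1e-6)
  # same near the tip
  n <- nrow(pl)
  expect_equal(arc_length(spec, pl$t[n - 1], pl$t[n]), spec$spacing,
               tolerance = 1e-6)
  # count scaling across a spec grid matches the oracle
  for (par in list(c(150, 20, 3), c(178.4, 30, 2), c(100, 25, 6))) {
    sp <- vesicle_spec(r_max = par[1], alpha = par[2], t_cyl = par[3],
                       n_omit_tip = 0)
    Lo <- oracle_arc_length(sp, 0, sp$t_cyl + cap_turns(sp))
    expect_identical(nrow(generate_placements(sp)),
                     as.integer(floor(Lo / sp$spacing)))
  }
  # constructed divisibility: one cylindrical turn, s = turn length / 10
  turn <- sqrt((2 * pi * 178.4)^2 + 48.8^2)
  pl10 <- generate_placements(vesicle_spec(t_cyl = 1, spacing = turn / 10,
                                           n_omit_tip = 0, alpha = 89.9))
  expect_gte(nrow(pl10), 10L)
  expect_equal(pl10$t[1:10], (0:9) / 10, tolerance = 1e-8)
  # spacing larger than the curve is an error
  expect_error(generate_placements(vesicle_spec(r_max = 5, t_cyl = 0,
                                                spacing = 500)),
               "spacing")
})

test_that("local frames are orthonormal and helically related", {
  spec <- vesicle_spec()
  for (t in c(0, 0.31, 4.99, 5, 9, 13.6)) {
    f <- local_frame(t, spec)
    expect_equal(crossprod(f$R), diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(det(f$R), 1, tolerance = 1e-12)
  }
  # t = 0: radial axis (local x image) is +x
  f0 <- local_frame(0, spec)
  expect_equal(f0$R[, 1], c(1, 0, 0), tolerance = 1e-12)
  # cylinder: tangent elevation = P / sqrt((2 pi r)^2 + P^2)
  tang <- -f0$R[, 2]               # local y maps to the reversed tangent
  expect_equal(tang[3], 48.8 / sqrt((2 * pi * 178.4)^2 + 48.8^2),
               tolerance = 1e-12)
  # frames at t and t + dt in the cylinder are related by the screw
  # (rotation -360 dt about z, translation P dt)
  dt <- 1 / 92.93
  f1 <- local_frame(0.2, spec); f2 <- local_frame(0.2 + dt, spec)
  th <- -2 * pi * dt
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(f2$R, Rz %*% f1$R, tolerance = 1e-9)
  expect_equal(f2$origin, as.vector(Rz %*% f1$origin) + c(0, 0, 48.8 * dt),
               tolerance = 1e-9)
})

test_that("curve alignment to the pivot is a pure z rotation/shift", {
  spec <- vesicle_spec()
  tpl <- make_toy_monomer()
  # pivot already at the origin radially: identity rotation, zero shift
  al0 <- align_curve_to_pivot(tpl, spec)
  expect_equal(al0$z_rotation, 0)
  expect_equal(al0$z_shift, 0)
  # pivot at azimuth 30 deg -> -30 deg rotation; +5 A in z -> -5 A shift
  moved <- as.data.frame(tpl)
  moved$x <- moved$x + 178.4 * cos(pi / 6) - 0   # translate pivot
  moved$y <- moved$y + 178.4 * sin(pi / 6)
  moved$z <- moved$z + 5
  al <- align_curve_to_pivot(monomer_template(moved), spec)
  expect_equal(al$z_rotation, -30, tolerance = 1e-9)
  expect_equal(al$z_shift, -5, tolerance = 1e-9)
  piv <- gvshell:::template_pivot(al$template)
  expect_equal(piv[2], 0, tolerance = 1e-9)
  expect_equal(piv[3], 0, tolerance = 1e-9)
})

test_that("half shells place rigid copies with pivots on the curve", {
  tpl <- make_toy_monomer()
  spec <- vesicle_spec()
  half <- build_half_shell(tpl, spec, instantiate = FALSE)
  expect_identical(monomer_count(half), 865L)
  expect_identical(half$placements$chain[1:3], c("A", "B", "C"))
  expect_identical(half$placements$chain[27], "AA")
  # single placement is a rigid copy of the template
  single <- vesicle_spec(r_max = 50, t_cyl = 1, spacing = 600, n_omit_tip = 0)
  m1 <- build_half_shell(tpl, single)
  expect_identical(monomer_count(m1), 1L)
  d0 <- oracle_dist(as.data.frame(tpl))
  expect_lt(max(abs(oracle_dist(model_atoms(m1)) - d0)), 1e-9)
  # pivots ride on the curve: check a few placements of the default build
  half5 <- build_half_shell(tpl, spec, instantiate = FALSE)
  for (i in c(1, 100, 500, 865)) {
    atoms <- gvshell:::placed_atoms_one(half5, i)
    piv <- gvshell:::template_pivot(atoms)
    cp <- curve_point(half5$placements$t[i], spec)
    expect_equal(piv, c(cp$x, cp$y, cp$z), tolerance = 1e-6)
    # placement + corrections (whole-monomer ones) stay rigid on the cone
    expect_lt(max(abs(oracle_dist(atoms) - d0)), 1e-6)
  }
})

test_that("D1 duplication doubles the count and is a self-symmetry", {
  tpl <- make_toy_monomer()
  spec <- vesicle_spec()
  half <- build_half_shell(tpl, spec,
                           correction_schedule(monomer_tilt = 15,
                                               beta_tilt = 8,
                                               nterm_tilt = 10))
  full <- duplicate_d1(half)
  expect_identical(monomer_count(full), 1730L)
  expect_error(duplicate_d1(full), "half")
  # 180 deg about x maps the full model onto itself (chains permuted)
  atoms <- model_atoms(full)
  D <- diag(c(1, -1, -1))
  rot <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(D)
  # chain X <-> chain bX pairing
  img_chain <- ifelse(startsWith(atoms$chain, "b"),
                      sub("^b", "", atoms$chain),
                      paste0("b", atoms$chain))
  ord_orig <- order(atoms$chain, atoms$resid, atoms$atom)
  ord_img <- order(img_chain, atoms$resid, atoms$atom)
  rmsd <- sqrt(mean(rowSums((rot[ord_img, ] -
                               as.matrix(atoms[ord_orig, c("x", "y", "z")]))^2)))
  expect_lt(rmsd, 1e-6)
  # single-monomer half: the two pivot midpoints are mirror-equivalent
  single <- vesicle_spec(r_max = 50, t_cyl = 1, spacing = 600, n_omit_tip = 0)
  two <- duplicate_d1(build_half_shell(tpl, single))
  expect_identical(monomer_count(two), 2L)
  a <- model_atoms(two)
  p1 <- gvshell:::template_pivot(a[a$chain == "A", ])
  p2 <- gvshell:::template_pivot(a[a$chain == "bA", ])
  expect_equal(p2, as.vector(D %*% p1), tolerance = 1e-9)
})

test_that("helical expansion matches the cylinder-region builder output", {
  tpl <- make_toy_monomer()
  turn <- sqrt((2 * pi * 178.4)^2 + 48.8^2)
  ut <- 20
  spec <- vesicle_spec(t_cyl = 3, spacing = turn / ut, n_omit_tip = 0)
  half <- build_half_shell(tpl, spec)
  exp15 <- helical_expand(tpl, rise = 48.8 / ut, twist = -360 / ut, n = 40,
                          seed_frame = local_frame(0, spec))
  a1 <- model_atoms(half)
  a2 <- model_atoms(exp15)
  n_at <- nrow(as.data.frame(tpl))
  sel <- seq_len(40 * n_at)          # first 40 placements are cylindrical
  expect_lt(max(abs(as.matrix(a1[sel, c("x", "y", "z")]) -
                      as.matrix(a2[, c("x", "y", "z")]))), 1e-6)
})

test_that("helical expansion: segment layout and screw accumulation", {
  tpl <- make_toy_monomer()
  # n = 1 is the identity placement
  one <- helical_expand(tpl, 0.525, -3.87, n = 1)
  expect_equal(as.matrix(model_atoms(one)[, c("x", "y", "z")]),
               as.matrix(as.data.frame(tpl)[, c("x", "y", "z")]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # 15-subunit wall patch: 3 ribs x 5 monomers at the solved symmetry
  seg <- helical_expand(tpl, 0.525, -3.87, n = 15, n_per_rib = 5)
  expect_identical(monomer_count(seg), 15L)
  expect_identical(seg$placements$chain, LETTERS[1:15])
  # rib neighbours are one full turn apart: ~pitch in z at ~same azimuth
  o1 <- seg$frames[[1]]$origin; o6 <- seg$frames[[6]]$origin
  expect_equal(o6[3] - o1[3], 0.525 * 360 / 3.87, tolerance = 1e-9)
  # screw applied ut = 92.93 times: rotation ~ -360 deg, translation ~ P
  f <- helical_expand(tpl, 48.8 / 92.93, -360 / 92.93, n = 2,
                      n_per_rib = 1, ut = 92.93)
  expect_identical(monomer_count(f), 2L)
  expect_equal(f$frames[[2]]$R, diag(3), tolerance = 1e-9)
  expect_equal(f$frames[[2]]$origin, c(0, 0, 48.8), tolerance = 1e-9)
  expect_error(helical_expand(tpl, 0.5, -3.87, n = 10, n_per_rib = 4),
               "divide")
})

test_that("clash detection agrees with the brute-force scan", {
  # two copies of one atom at cutoff/2 -> exactly one clash
  two <- data.frame(atom = "CA", resid = 1L, resname = "ALA",
                    chain = c("A", "B"), element = "C",
                    x = c(0, 1), y = 0, z = 0, occ = 1)
  rep1 <- clash_report(two, cutoff = 2)
  expect_identical(nrow(rep1), 1L)
  expect_equal(rep1$distance, 1)
  # same chain pairs are not clashes
  two$chain <- "A"
  expect_identical(nrow(clash_report(two, cutoff = 2)), 0L)
  # random two-chain soup vs O(n^2) oracle
  set.seed(7)
  soup <- data.frame(atom = "CA", resid = 1L, resname = "ALA",
                     chain = sample(c("A", "B"), 300, TRUE), element = "C",
                     x = runif(300, 0, 20), y = runif(300, 0, 20),
                     z = runif(300, 0, 20), occ = 1)
  expect_identical(nrow(clash_report(soup, cutoff = 1.5)),
                   oracle_clashes(soup, 1.5))
  # empty input
  expect_identical(nrow(clash_report(data.frame())), 0L)
})

test_that("cylinder lattice is clash-free; the tip region is not", {
  tpl <- make_toy_monomer()
  spec <- vesicle_spec()
  half <- build_half_shell(tpl, spec)
  atoms <- model_atoms(half)
  pl <- half$placements
  # main-chain atoms of cylindrical monomers at 2.0 A: no clashes
  cyl_chains <- pl$chain[pl$t < spec$t_cyl]
  acyl <- atoms[atoms$chain %in% cyl_chains, ]
  expect_identical(nrow(clash_report(acyl, cutoff = 2.0,
                                     atom_names = c("CA", "O"))), 0L)
  expect_identical(oracle_clashes(acyl[acyl$atom %in% c("CA", "O"), ][
    seq(1, sum(acyl$atom %in% c("CA", "O")), by = 3), ], 2.0), 0L)
  # the simple constant-pitch model breaks down at the tip: clashes appear
  tip_chains <- pl$chain[pl$t > spec$t_cyl + 0.8 * cap_turns(spec)]
  atip <- atoms[atoms$chain %in% tip_chains, ]
  expect_gt(nrow(clash_report(atip, cutoff = 2.0,
                              atom_names = c("CA", "O"))), 0L)
})

test_that("model mass scales with the monomer count", {
  tpl <- make_toy_monomer()          # 7052 Da default
  spec <- vesicle_spec()
  half <- build_half_shell(tpl, spec, instantiate = FALSE)
  full <- duplicate_d1(half)
  expect_equal(model_mass(full), 1730 * 7052)
  expect_equal(model_mass(full), 1.22e7, tolerance = 1e-3)
  expect_equal(model_mass(full) / model_mass(half), 2)
  expect_equal(model_mass(half, per_monomer = 1000), 865000)
  tpl_nomass <- make_toy_monomer(mass = NULL)
  m <- build_half_shell(tpl_nomass, spec, instantiate = FALSE)
  expect_error(model_mass(m), "mass")
})

test_that("segment and full-model export round-trip", {
  tpl <- make_toy_monomer()
  seg <- helical_expand(tpl, 0.525, -3.87, n = 15, n_per_rib = 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(seg, pdb)
  back <- read_structure(pdb)
  expect_identical(nrow(back), nrow(model_atoms(seg)))
  expect_setequal(unique(back$chain), LETTERS[1:15])
  expect_equal(back$x, round(model_atoms(seg)$x, 3), tolerance = 1e-9)
  # a full vesicle only fits in mmCIF (1730 multi-letter chains)
  spec_small <- vesicle_spec(r_max = 60, t_cyl = 1, spacing = 40,
                             n_omit_tip = 2)
  full <- duplicate_d1(build_half_shell(tpl, spec_small))
  expect_error(write_structure(full, withr::local_tempfile(fileext = ".pdb")),
               "chain")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_structure(full, cif)
  back2 <- read_structure(cif)
  expect_identical(nrow(back2), nrow(model_atoms(full)))
  expect_equal(back2$y, round(model_atoms(full)$y, 3), tolerance = 1e-9)
})
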