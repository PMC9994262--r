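# Helical-geometry calculus: symmetry conversions, spacing, polymorph
# arithmetic, the parametric curve and its arc length.

test_that("symmetry conversion matches the solved shell and round-trips", {
  # pitch 48.8 A with 92.93 units/turn -> rise 0.525 A, twist -3.874 deg
  s <- symmetry_convert(48.8, 92.93)
  expect_equal(s$rise, 0.525, tolerance = 1e-3)
  expect_equal(s$twist, -3.874, tolerance = 1e-4)
  # one unit per turn degenerates to the pitch itself
  expect_equal(symmetry_convert(48.8, 1), list(rise = 48.8, twist = -360))
  # the wider-polymorph lattice: 49 A pitch, 200.85 units/turn
  s2 <- symmetry_convert(49.0, 200.85)
  expect_equal(s2$rise, 49 / 200.85)
  expect_equal(s2$rise, 0.2440, tolerance = 5e-4)
  expect_equal(s2$twist, -1.7924, tolerance = 1e-4)
  # round trip and handedness
  for (case in list(c(48.8, 92.93), c(49, 200.85), c(10, 7.3))) {
    cv <- symmetry_convert(case[1], case[2])
    back <- symmetry_from_rise_twist(cv$rise, cv$twist)
    expect_equal(back$pitch, case[1], tolerance = 1e-12)
    expect_equal(back$units_per_turn, case[2], tolerance = 1e-12)
    expect_identical(back$handedness, "left")
  }
  expect_equal(helical_symmetry(48.8, 92.93, "right")$twist, 360 / 92.93)
  expect_error(symmetry_convert(-1, 10), "positive")
  expect_error(symmetry_convert(48.8, 0), "positive")
})

test_that("spacing_on_helix reproduces the 12.07 A placement distance", {
  expect_equal(spacing_on_helix(178.4, 48.8, 92.93), 12.07, tolerance = 1e-3)
  # r = 0 degenerates to the rise
  expect_equal(spacing_on_helix(0, 48.8, 92.93), 48.8 / 92.93)
  expect_equal(spacing_on_helix(435, 49.0, 200.85), 13.61, tolerance = 1e-3)
  expect_error(spacing_on_helix(-1, 48.8, 92.93), "non-negative")
  # s * ut equals the helix length of one turn (closed form), 1e-9 relative
  for (r in c(50, 178.4, 435)) {
    s <- spacing_on_helix(r, 48.8, 92.93)
    expect_equal(s * 92.93, sqrt((2 * pi * r)^2 + 48.8^2),
                 tolerance = 1e-9)
  }
})

test_that("units_from_diameter matches the printed polymorph counts", {
  # 55.5 +/- 7.3 nm -> 145 +/- 19 monomers/turn; 87.1 +/- 6.9 -> 227 +/- 18
  u1 <- units_from_diameter(55.5, sd = 7.3)
  expect_equal(u1$units, 144.9, tolerance = 1e-3)
  expect_identical(u1$n, 145)
  expect_identical(u1$sd_n, 19)
  u2 <- units_from_diameter(87.1, sd = 6.9)
  expect_identical(u2$n, 227)
  expect_identical(u2$sd_n, 18)
  # identity at the reference polymorph
  expect_equal(units_from_diameter(35.6)$units, 92.93)
  # linear in diameter
  d <- c(20, 40, 80)
  expect_equal(units_from_diameter(2 * d)$units,
               2 * units_from_diameter(d)$units)
  expect_error(units_from_diameter(0), "positive")
  # spacing mode as documented alternative: pi * D / s
  expect_equal(units_from_diameter(35.6, mode = "spacing",
                                   spacing = 12.07)$units,
               pi * 356 / 12.07)
})

test_that("diameter increment per added monomer is spacing/pi", {
  expect_equal(diameter_increment(12), 3.8197, tolerance = 1e-4)
  expect_equal(diameter_increment(pi), 1)
  expect_equal(diameter_increment(12.07), 3.842, tolerance = 1e-3)
  expect_error(diameter_increment(0), "positive")
})

test_that("hairpin tilt geometry: hydrogen-bond angle and magic angle", {
  expect_equal(rib_hbond_angle(-36), 54)
  expect_equal(rib_hbond_angle(0), 90)
  expect_equal(rib_hbond_angle(-35.26), 54.74)
  expect_error(rib_hbond_angle(95), "90")
  expect_equal(magic_angle(), 54.7356, tolerance = 1e-4)
  expect_equal(tan(magic_angle() * pi / 180)^2, 2, tolerance = 1e-12)
  expect_equal(round(magic_angle(), 1), 54.7)
})

test_that("reinforcement-repeat calculus reproduces the printed spans", {
  g <- gvpc_geometry(r_inner = 121, r_binding = 127)
  expect_equal(g$repeat_span, 49.5)         # 33 x 1.5 A/residue
  expect_equal(g$outer_spacing, 12.7)
  expect_equal(g$tetrad_span, 50.8)         # four monomers at 12.7 A
  expect_equal(g$repeat_phase, 60)          # (100 * 33) mod 360
  expect_equal(g$monomers_bound, 20)        # five repeats x four monomers
  # identity when binding radius equals inner radius
  expect_equal(gvpc_geometry(r_inner = 100, r_binding = 100)$outer_spacing,
               12.1)
  expect_error(gvpc_geometry(r_inner = 10, r_binding = 5), "r_binding")
})

test_that("cap turns follow t_cap = r_max / (P sin alpha)", {
  expect_equal(cap_turns(vesicle_spec()), 8.6502, tolerance = 1e-4)
  # r_max = P at alpha = 90 gives exactly one turn
  expect_equal(cap_turns(vesicle_spec(r_max = 48.8, alpha = 90)), 1)
  expect_equal(cap_turns(vesicle_spec(r_max = 0)), 0)
  expect_error(vesicle_spec(alpha = 0), "alpha")
})

test_that("curve points obey the piecewise equations", {
  spec <- vesicle_spec()
  p0 <- curve_point(0, spec)
  expect_equal(c(p0$x, p0$y, p0$z), c(178.4, 0, 0))
  # integer turns return to azimuth 0; z advances by t_cyl * P
  p5 <- curve_point(5, spec)
  expect_equal(c(p5$x, p5$y, p5$z), c(178.4, 0, 5 * 48.8), tolerance = 1e-9)
  # tip: radius 0, z = P t_cyl + P cos(alpha) t_cap
  tend <- 5 + cap_turns(spec)
  pt <- curve_point(tend, spec)
  expect_equal(pt$radius, 0, tolerance = 1e-9)
  expect_equal(pt$z, 48.8 * 5 + 48.8 * cos(25 * pi / 180) * cap_turns(spec))
  expect_error(curve_point(tend + 1, spec), "turns")
  # left-handed: y < 0 just after t = 0
  expect_lt(curve_point(0.1, spec)$y, 0)
  expect_gt(curve_point(0.1, vesicle_spec(handedness = "right"))$y, 0)
  # radius continuous at the junction, non-increasing beyond it
  ts <- seq(4.9, tend, length.out = 200)
  r <- curve_point(ts, spec)$radius
  expect_true(all(diff(r) <= 1e-12))
  expect_equal(curve_point(5 - 1e-9, spec)$radius,
               curve_point(5 + 1e-9, spec)$radius, tolerance = 1e-6)
  # in-surface helix angle is continuous, steepens monotonically to 90 deg
  ha <- curve_point(ts, spec)$helix_angle
  expect_true(all(diff(ha) >= -1e-12))
  expect_equal(ha[1], atan(48.8 / (2 * pi * 178.4)) * 180 / pi)
  expect_equal(ha[length(ha)], 90, tolerance = 1e-6)
})

test_that("numeric arc length matches the closed-form oracle", {
  spec <- vesicle_spec()
  tend <- spec$t_cyl + cap_turns(spec)
  # one cylindrical turn
  expect_equal(arc_length(spec, 0, 1), sqrt((2 * pi * 178.4)^2 + 48.8^2),
               tolerance = 1e-9)
  expect_equal(arc_length(spec, 0, 1), 1121.96, tolerance = 1e-4)
  expect_identical(arc_length(spec, 2, 2), 0)
  # full half-shell curve against the closed form (<= 1e-6 relative)
  expect_equal(arc_length(spec, 0, tend), oracle_arc_length(spec, 0, tend),
               tolerance = 1e-6)
  expect_equal(arc_length(spec, 0, tend), 10498, tolerance = 1e-4)
  # assorted sub-intervals, both branches
  for (iv in list(c(0, 3), c(4, 7), c(6, 10), c(5, tend), c(13, tend))) {
    expect_equal(arc_length(spec, iv[1], iv[2]),
                 oracle_arc_length(spec, iv[1], iv[2]), tolerance = 1e-6)
  }
  # additivity
  expect_equal(arc_length(spec, 0, 4) + arc_length(spec, 4, 9),
               arc_length(spec, 0, 9), tolerance = 1e-9)
  expect_error(arc_length(spec, 3, 1), ">=")
})
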