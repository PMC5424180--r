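# helper: analyze a synthetic atom table into a hexamer-state-like list
analyze_units <- function(atoms) {
  units <- build_packing_units(atoms)
  ligs <- detect_ligands(atoms, units)
  il <- analyze_interfaces(units, ligs)
  structure(list(atoms = atoms, units = units, interfaces = il,
                 ledger = build_ledger(il)),
            class = "hexamer_state")
}

test_that("ring axis is the oriented best-fit plane normal", {
  # planar hexagon of units; N2D pseudo-atoms offset +z -> axis +z
  mk_ring <- function(n2d_up = TRUE) {
    lapply(0:5, function(k) {
      th <- k * pi / 3
      base <- c(20 * cos(th), 20 * sin(th), 0)
      zoff <- if (n2d_up) 3 else -3
      a <- fixture_atoms(rbind(base + c(0, 0, zoff), base - c(0, 0, zoff),
                               base + c(1, 0, zoff), base + c(1, 1, -zoff)),
                         role = c("N2D", "CTD", "N2D", "CTD"))
      fixture_unit(a, index = k)
    })
  }
  up <- ring_axis(mk_ring(TRUE))
  expect_equal(up$axis, c(0, 0, 1), tolerance = 1e-10)
  down <- ring_axis(mk_ring(FALSE))
  expect_equal(down$axis, c(0, 0, -1), tolerance = 1e-10)
})

test_that("puckered ring axis equals the SVD plane normal", {
  set.seed(31)
  units <- lapply(0:5, function(k) {
    th <- k * pi / 3
    base <- c(25 * cos(th), 25 * sin(th), 2 * cos(2 * th))
    a <- fixture_atoms(rbind(base + c(0, 0, 2), base - c(0, 0, 2),
                             base + rnorm(3)),
                       role = c("N2D", "CTD", "CTD"))
    fixture_unit(a, index = k)
  })
  r <- ring_axis(units)
  cents <- t(vapply(units, function(u) u$centroid, numeric(3)))
  sv <- svd(sweep(cents, 2, colMeans(cents)))
  oracle <- sv$v[, 3]
  if (sum(oracle * r$axis) < 0) oracle <- -oracle
  expect_equal(r$axis, oracle, tolerance = 1e-10)
  expect_error(ring_axis(units[1:5]), "6 packing units")
})

test_that("ledger arithmetic reproduces the printed per-interface values", {
  ifaces <- lapply(0:5, function(k) {
    p <- if (k %in% c(2, 5)) c(24, 76) else c(-12, 65)
    interface_record(k, screw_from_params(p[1], p[2]))
  })
  led <- build_ledger(ifaces)
  expect_equal(led$net_rise_A, 0)
  expect_equal(led$net_twist_deg, 412)
  expect_gt(led$net_twist_deg, 360)
  expect_equal(led$c2_pattern, "CCOCCO")
  expect_true(led$is_c2)
  # ledger totals are exactly the member sums (no hidden recomputation)
  expect_identical(led$net_rise_A,
                   sum(vapply(led$interfaces, function(i) i$screw$rise_A,
                              numeric(1))))
  # the 52-degree twist excess appears as the closure rotation residual
  expect_equal(led$closure_rotation_deg, 52, tolerance = 1e-9)
  expect_equal(led$closure_translation_A, 0, tolerance = 1e-9)
})

test_that("a perfect C6 ring is planar with zero closure residual", {
  asm <- build_screw_assembly(synth_spec(),
                              interface_params = cbind(rep(0, 6), rep(60, 6)))
  st <- analyze_units(asm$atoms)
  expect_equal(st$ledger$net_rise_A, 0, tolerance = 1e-9)
  expect_equal(st$ledger$net_twist_deg, 360, tolerance = 1e-9)
  expect_lt(st$ledger$closure_residual, 1e-6)
  expect_equal(st$ledger$shape_class, "planar")
})

test_that("constructed boat pucker is recovered exactly", {
  h <- 2.4
  asm <- build_screw_assembly(
    synth_spec(pucker = list(shape = "boat", amplitude_A = h)),
    interface_params = cbind(rep(0, 6), rep(60, 6)))
  st <- analyze_units(asm$atoms)
  expect_equal(st$ledger$shape_class, "boat")
  expect_equal(st$ledger$pucker_amplitude_A, h, tolerance = 1e-6)
  # the raw deviations equal the construction offsets
  expect_equal(st$ledger$out_of_plane_A, asm$ground_truth$pucker_z,
               tolerance = 1e-6)

  asm_s <- build_screw_assembly(
    synth_spec(pucker = list(shape = "saddle", amplitude_A = h)),
    interface_params = cbind(rep(0, 6), rep(60, 6)))
  expect_equal(analyze_units(asm_s$atoms)$ledger$shape_class, "saddle")
})

test_that("closure residual vanishes iff rises sum to zero and twists to 360k", {
  set.seed(32)
  for (i in 1:10) {
    rises <- rnorm(5, sd = 8); rises <- c(rises, -sum(rises))
    twists <- runif(5, 30, 90); twists <- c(twists, 360 - sum(twists) %% 360)
    ifaces <- lapply(0:5, function(k)
      interface_record(k, screw_from_params(rises[k + 1], twists[k + 1])))
    expect_lt(build_ledger(ifaces)$closure_residual, 1e-6)
    # perturb one rise: residual appears
    rises2 <- rises; rises2[1] <- rises2[1] + 3
    ifaces2 <- lapply(0:5, function(k)
      interface_record(k, screw_from_params(rises2[k + 1], twists[k + 1])))
    expect_gt(build_ledger(ifaces2)$closure_residual, 1)
  }
})

test_that("rotation inference is zero on identical states", {
  asm <- build_screw_assembly(synth_spec())
  st <- analyze_units(asm$atoms)
  rot <- infer_rotation(st, st)
  expect_equal(rot$subpore_rotation_deg, 0, tolerance = 1e-9)
  expect_equal(rot$direction, "none")
  expect_length(rot$thrusting_units, 0)
  expect_true(all(abs(rot$marker_displacements$total_A) < 1e-9))
})

test_that("a constructed +20 degree sub-pore rotation is recovered exactly", {
  pair <- make_two_state_pair(synth_spec(rotation_step_deg = 20,
                                         marker_thrust_A = 0))
  sa <- analyze_units(pair$state_a$atoms)
  sb <- analyze_units(pair$state_b$atoms)
  rot <- infer_rotation(sa, sb)
  expect_equal(rot$subpore_rotation_deg, 20, tolerance = 1e-3)
  expect_equal(rot$direction, "counterclockwise")
  # antisymmetry under state swap
  back <- infer_rotation(sb, sa)
  expect_equal(back$subpore_rotation_deg, -rot$subpore_rotation_deg,
               tolerance = 1e-6)
})

test_that("the catalytic-step pair recovers rotation, thrust and markers", {
  pair <- make_two_state_pair(synth_spec())   # -60 deg step, 13 A thrust
  sa <- analyze_units(pair$state_a$atoms)
  sb <- analyze_units(pair$state_b$atoms)
  expect_equal(sa$ledger$c2_pattern, pair$ground_truth$pattern_a)
  expect_equal(sb$ledger$c2_pattern, pair$ground_truth$pattern_b)
  rot <- infer_rotation(sa, sb)
  expect_equal(rot$subpore_rotation_deg, pair$ground_truth$rotation_deg,
               tolerance = 1e-3)
  expect_equal(rot$direction, "clockwise")
  expect_equal(rot$thrusting_units, pair$ground_truth$thrusting_units)
  md <- rot$marker_displacements
  thr <- md[md$marker == "pore_e400" & md$unit %in% rot$thrusting_units, ]
  expect_equal(sort(thr$axial_A),
               sort(unname(pair$ground_truth$marker_axial_A)),
               tolerance = 1e-6)
})

test_that("enantiomeric rings rotate the opposite way under the same step", {
  spec_b <- synth_spec()
  spec_t <- synth_spec(pattern = "COOCOO",
                       closed = c(rise_A = -24, twist_deg = 65),
                       open = c(rise_A = 12, twist_deg = 76),
                       enantiomer = TRUE)
  rot_b <- {
    p <- make_two_state_pair(spec_b)
    infer_rotation(analyze_units(p$state_a$atoms),
                   analyze_units(p$state_b$atoms))
  }
  rot_t <- {
    p <- make_two_state_pair(spec_t)
    infer_rotation(analyze_units(p$state_a$atoms),
                   analyze_units(p$state_b$atoms))
  }
  expect_equal(rot_b$direction, "clockwise")
  expect_equal(rot_t$direction, "counterclockwise")
  expect_equal(rot_t$subpore_rotation_deg, -rot_b$subpore_rotation_deg,
               tolerance = 1e-6)
})

test_that("states with unequal closed/open counts are incomparable", {
  a <- analyze_units(build_screw_assembly(synth_spec())$atoms)  # 4 closed
  spec2 <- synth_spec(pattern = "COOCOO",
                      closed = c(rise_A = -24, twist_deg = 65),
                      open = c(rise_A = 12, twist_deg = 76))
  b <- analyze_units(build_screw_assembly(spec2)$atoms)         # 2 closed
  expect_error(infer_rotation(a, b), "incomparable")
})

test_that("self-permutation of a C6 ring gives exactly the slot angle", {
  asm <- build_screw_assembly(synth_spec(),
                              interface_params = cbind(rep(0, 6), rep(60, 6)))
  units <- build_packing_units(asm$atoms)
  pm <- pilt_mode_inference(units)
  expect_equal(pm$subpore_rotation_deg, -60, tolerance = 1e-9)
  expect_lt(pm$alignment_rmsd, 1e-9)
})

test_that("self-permutation direction flips for the enantiomeric ring", {
  pb <- pilt_mode_inference(build_packing_units(
    build_screw_assembly(synth_spec())$atoms))
  spec_t <- synth_spec(pattern = "COOCOO",
                       closed = c(rise_A = -24, twist_deg = 65),
                       open = c(rise_A = 12, twist_deg = 76),
                       enantiomer = TRUE)
  pt <- pilt_mode_inference(build_packing_units(
    build_screw_assembly(spec_t)$atoms))
  expect_equal(pb$direction, "clockwise")
  expect_equal(pt$direction, "counterclockwise")
})

test_that("inverting the viewing axis flips the direction label", {
  pair <- make_two_state_pair(synth_spec(rotation_step_deg = 20,
                                         marker_thrust_A = 0))
  ua <- build_packing_units(pair$state_a$atoms)
  ub <- build_packing_units(pair$state_b$atoms)
  rot <- infer_rotation(ua, ub, correspondence = 0)
  # flip the stored ring orientation on both unit sets
  flip <- function(u) {
    r <- attr(u, "ring"); r$axis <- -r$axis
    attr(u, "ring") <- r
    u
  }
  rot_f <- infer_rotation(flip(ua), flip(ub), correspondence = 0)
  expect_equal(rot_f$subpore_rotation_deg, -rot$subpore_rotation_deg,
               tolerance = 1e-6)
  expect_equal(sort(c(rot$direction, rot_f$direction)),
               c("clockwise", "counterclockwise"))
})
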