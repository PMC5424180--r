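test_that("isolated sphere SASA matches the closed form within 1%", {
  a <- fixture_atoms(rbind(c(0, 0, 0)), elesy = "C")
  area <- sum(sasa(a, probe_radius_A = 1.4, n_sample_points = 960))
  expect_equal(area, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # nitrogen radius table entry
  an <- fixture_atoms(rbind(c(0, 0, 0)), elesy = "N")
  expect_equal(sum(sasa(an, 1.4, 960)), 4 * pi * (1.55 + 1.4)^2,
               tolerance = 0.01)
  expect_error(sasa(fixture_atoms(rbind(c(0, 0, 0)), elesy = "XX")),
               "radius")
  expect_error(sasa(a, n_sample_points = 32), ">= 64")
})

test_that("two overlapping spheres match the spherical-cap oracle", {
  for (d in c(2.0, 3.0, 4.5, 5.5)) {
    at <- fixture_atoms(rbind(c(0, 0, 0), c(d, 0, 0)), elesy = c("C", "O"))
    per <- sasa(at, probe_radius_A = 1.4, n_sample_points = 2000)
    expect_equal(per[1], two_sphere_area(1.7, 1.52, d, 1.4), tolerance = 0.01)
    expect_equal(per[2], two_sphere_area(1.52, 1.7, d, 1.4), tolerance = 0.015)
  }
})

test_that("a fully enclosed atom has zero accessible area", {
  set.seed(21)
  shell_dirs <- matrix(rnorm(3 * 80), 80, 3)
  shell_dirs <- shell_dirs / sqrt(rowSums(shell_dirs^2))
  at <- fixture_atoms(rbind(c(0, 0, 0), shell_dirs * 2.5),
                      elesy = rep("C", 81))
  per <- sasa(at, probe_radius_A = 1.4, n_sample_points = 960)
  expect_equal(per[1], 0)
})

test_that("SASA is deterministic per seed and converges with sampling", {
  asm <- build_screw_assembly(synth_spec(residues_per_domain = 6))
  prot <- asm$atoms[!asm$atoms$het, ]
  s1 <- sasa(prot, n_sample_points = 480, seed = 7)
  s2 <- sasa(prot, n_sample_points = 480, seed = 7)
  expect_identical(s1, s2)
  tot1 <- sum(sasa(prot, n_sample_points = 480, seed = 1))
  tot2 <- sum(sasa(prot, n_sample_points = 960, seed = 1))
  expect_lt(abs(tot1 - tot2) / tot2, 0.005)
})

test_that("BSA is symmetric, non-negative, and zero for distant units", {
  far_a <- fixture_unit(fixture_atoms(matrix(rnorm(24), 8, 3)))
  far_b <- fixture_unit(fixture_atoms(matrix(rnorm(24), 8, 3) + 100))
  expect_equal(buried_surface_area(far_a, far_b, n_sample_points = 240), 0)

  set.seed(22)
  for (i in 1:25) {
    a <- fixture_unit(fixture_atoms(matrix(rnorm(24, sd = 2), 8, 3)))
    b <- fixture_unit(fixture_atoms(matrix(rnorm(24, sd = 2), 8, 3) +
                                      runif(1, 0, 6)))
    ab <- buried_surface_area(a, b, n_sample_points = 240)
    ba <- buried_surface_area(b, a, n_sample_points = 240)
    expect_gte(ab, 0)
    expect_equal(ab, ba, tolerance = 1e-9)
  }
})

test_that("two-atom BSA matches the analytic overlap loss", {
  for (d in c(2.5, 4.0, 5.5)) {
    a <- fixture_unit(fixture_atoms(rbind(c(0, 0, 0)), elesy = "C"))
    b <- fixture_unit(fixture_atoms(rbind(c(d, 0, 0)), elesy = "C"))
    bsa <- buried_surface_area(a, b, n_sample_points = 2000)
    loss <- 2 * (4 * pi * 3.1^2 - two_sphere_area(1.7, 1.7, d, 1.4))
    expect_equal(bsa, loss, tolerance = 0.02 * max(loss, 1))
  }
})

test_that("polar contacts find exactly the engineered pairs", {
  # two glycines 20 A apart: nothing
  g1 <- fixture_atoms(rbind(c(0, 0, 0)), elety = "N", elesy = "N", resid = "GLY")
  g2 <- fixture_atoms(rbind(c(20, 0, 0)), elety = "O", elesy = "O", resid = "GLY")
  expect_equal(nrow(polar_contacts(g1, g2)), 0)

  # one N-O pair at 2.9 A plus a C-C pair at 3.0 A (not polar)
  ua <- fixture_atoms(rbind(c(0, 0, 0), c(0, 5, 0)),
                      elety = c("N", "CB"), elesy = c("N", "C"), resno = c(1, 2))
  ub <- fixture_atoms(rbind(c(2.9, 0, 0), c(3.0, 5, 0)),
                      elety = c("O", "CB"), elesy = c("O", "C"),
                      resno = c(10, 11), chain = "B")
  pc <- polar_contacts(ua, ub)
  expect_equal(nrow(pc), 1)
  expect_equal(pc$distance_A, 2.9, tolerance = 1e-9)
  expect_equal(pc$atom_1, "N"); expect_equal(pc$atom_2, "O")
  both <- polar_contacts(ua, ub, include_nonpolar = TRUE)
  expect_equal(nrow(both), 2)
  expect_setequal(both$type, c("polar", "nonpolar"))
})

test_that("polar contacts agree with an exhaustive pair scan", {
  set.seed(23)
  na <- 30; nb <- 30
  ua <- fixture_atoms(matrix(rnorm(3 * na, sd = 4), na, 3),
                      elety = sample(c("N", "O", "CB"), na, TRUE))
  ua$elesy <- substr(ua$elety, 1, 1)
  ub <- fixture_atoms(matrix(rnorm(3 * nb, sd = 4), nb, 3),
                      elety = sample(c("N", "O", "CB"), nb, TRUE), chain = "B")
  ub$elesy <- substr(ub$elety, 1, 1)
  pc <- polar_contacts(ua, ub)
  # oracle: triple loop over every pair
  count <- 0
  for (i in 1:na) for (j in 1:nb) {
    d <- sqrt(sum((c(ua$x[i], ua$y[i], ua$z[i]) -
                     c(ub$x[j], ub$y[j], ub$z[j]))^2))
    if (d <= 3.5 && ua$elesy[i] %in% c("N", "O") && ub$elesy[j] %in% c("N", "O"))
      count <- count + 1
  }
  expect_equal(nrow(pc), count)
})

test_that("expected-contact validation warns on absences only", {
  pc <- data.frame(resno_1 = 327, resno_2 = 411)
  rule <- contact_rule(named_expectations = list(T327_T411 = c(327, 411)))
  expect_silent(check_expected_contacts(pc, rule))
  rule2 <- contact_rule(named_expectations = list(R455_T411 = c(455, 411)))
  expect_warning(check_expected_contacts(pc, rule2), "R455_T411")
})

test_that("interfaces classify by rise sign with nucleotide labels", {
  closed <- screw_from_params(-12, 65)
  open <- screw_from_params(24, 76)
  adp <- data.frame(ligand_code = "ADP")
  expect_equal(classify_interface(closed, 1600, adp)$label, "closed-ADP")
  expect_equal(classify_interface(open, 800, NULL)$label, "open-APO")
  anp <- data.frame(ligand_code = c("AMP-PNP", "MG"))
  expect_equal(classify_interface(closed, NA, anp)$label, "closed-AMP-PNP")
  # metals/buffer alone leave the interface APO
  fmt <- data.frame(ligand_code = "FMT")
  expect_equal(classify_interface(open, NA, fmt)$nucleotide_label, "APO")
  # near-threshold rises fall back to the BSA criterion with a warning
  border <- screw_from_params(0.2, 60)
  expect_warning(res <- classify_interface(border, 1500, NULL), "BSA")
  expect_equal(res$state, "closed")
})

test_that("classification commutes with unit permutation", {
  asm <- build_screw_assembly(synth_spec())
  units <- build_packing_units(asm$atoms)
  ligs <- detect_ligands(asm$atoms, units)
  il <- analyze_interfaces(units, ligs)
  labels <- vapply(il, `[[`, character(1), "label")
  # pure function of (screw, BSA, ligand): recomputing any interface from
  # its own ingredients reproduces the stored label
  for (k in 1:6) {
    redo <- classify_interface(il[[k]]$screw, il[[k]]$bsa_A2, il[[k]]$ligands)
    expect_equal(redo$label, labels[k])
  }
  expect_equal(paste(substr(labels, 1, 1), collapse = ""),
               tolower(paste(strsplit("CCOCCO", "")[[1]], collapse = "")))
})
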