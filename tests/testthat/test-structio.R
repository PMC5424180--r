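test_that("write/read round trip preserves atoms to PDB precision", {
  asm <- build_screw_assembly(synth_spec(residues_per_domain = 5))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(asm$atoms, tmp)
  back <- read_structure(tmp)
  expect_equal(nrow(back), nrow(asm$atoms))
  expect_equal(sort(unique(back$chain)), LETTERS[1:6])
  ord_a <- order(asm$atoms$chain, asm$atoms$resno, asm$atoms$elety, asm$atoms$het)
  ord_b <- order(back$chain, back$resno, back$elety, back$het)
  expect_equal(atom_xyz(back)[ord_b, ], atom_xyz(asm$atoms)[ord_a, ],
               tolerance = 1e-3)
  expect_equal(sum(back$het), sum(asm$atoms$het))
})

test_that("unreadable and protein-free files give informative errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("", empty)
  expect_error(read_structure(empty), "parse error|no protein")
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("altloc policy keeps the highest-occupancy conformer, ties to A", {
  # hand-built fixture: residue 10 has altlocs A (occ 0.4) and B (occ 0.6);
  # residue 11 has a tie (0.5/0.5) -> altloc A wins; 6 ATOM records total
  lines <- c(
    sprintf("ATOM  %5d  CA %sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1, "A", 10, 1, 0, 0, 0.40, 0),
    sprintf("ATOM  %5d  CA %sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            2, "B", 10, 2, 0, 0, 0.60, 0),
    sprintf("ATOM  %5d  CA %sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            3, "A", 11, 3, 0, 0, 0.50, 0),
    sprintf("ATOM  %5d  CA %sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            4, "B", 11, 4, 0, 0, 0.50, 0),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            5, 12, 5, 0, 0, 1.00, 0),
    "END")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  atoms <- read_structure(tmp)
  expect_equal(nrow(atoms), 3)           # one conformer per site (hand count)
  expect_equal(atoms$x[atoms$resno == 10], 2)   # occupancy 0.6 wins
  expect_equal(atoms$x[atoms$resno == 11], 3)   # tie broken towards A
})

test_that("packing units partition the twelve domains exactly once", {
  asm <- build_screw_assembly(synth_spec())
  units <- build_packing_units(asm$atoms)
  expect_length(units, 6)
  cfg <- domain_config()
  prot <- asm$atoms[!asm$atoms$het, ]
  in_dom <- (prot$resno >= cfg$n2d[1] & prot$resno <= cfg$n2d[2]) |
    (prot$resno >= cfg$ctd[1] & prot$resno <= cfg$ctd[2])
  keys <- function(a) paste(a$chain, a$resno, a$elety)
  unit_keys <- unlist(lapply(units, function(u) keys(u$atoms)))
  expect_equal(sort(unit_keys), sort(keys(prot[in_dom, ])))  # partition
  expect_false(any(duplicated(unit_keys)))
  # each unit pairs an N2D with a different chain's CTD
  for (u in units) expect_true(u$n2d_chain != u$ctd_chain)
  # adjacency: following the cycle 6 steps returns to the start
  adj <- attr(units, "adjacency")
  pos <- 1
  for (i in 1:6) pos <- match(adj[pos], adj[c(2:6, 1)])
  expect_equal(adj[1], adj[(match(adj[1], adj))])
  expect_equal(length(unique(adj)), 6)
})

test_that("reversed adjacency is detected as clockwise winding", {
  asm <- build_screw_assembly(synth_spec())
  fwd <- build_packing_units(asm$atoms)
  expect_equal(attr(fwd, "winding"), 1L)
  rev_adj <- rev(attr(fwd, "adjacency"))
  bwd <- build_packing_units(asm$atoms, adjacency = rev_adj)
  expect_equal(attr(bwd, "winding"), -1L)
  # re-orientation: output units are still ordered counterclockwise
  ring <- attr(bwd, "ring")
  cents <- t(vapply(bwd, function(u) u$centroid, numeric(3)))
  ang <- atan2(cents[, 2] - ring$center[2], cents[, 1] - ring$center[1])
  steps <- diff(c(ang, ang[1]))
  steps <- (steps + pi) %% (2 * pi) - pi
  expect_gt(sum(steps), 0)
})

test_that("missing domain ranges raise an incomplete-domain error", {
  asm <- build_screw_assembly(synth_spec())
  crippled <- asm$atoms[!(asm$atoms$chain == "C" & asm$atoms$resno >= 296), ]
  expect_error(build_packing_units(crippled), "incomplete domains.*chain C.*CTD")
})

test_that("enantiomeric assemblies wind clockwise", {
  asm <- build_screw_assembly(synth_spec(enantiomer = TRUE))
  units <- build_packing_units(asm$atoms)
  expect_equal(attr(units, "winding"), -1L)
})

test_that("ligands are assigned to the interface minimising summed distance", {
  asm <- build_screw_assembly(synth_spec())
  units <- build_packing_units(asm$atoms)
  ligs <- detect_ligands(asm$atoms, units)
  # construction placed ADP at the four closed interfaces (0, 1, 3, 4)
  expect_equal(sort(ligs$interface), c(0, 1, 3, 4))
  expect_true(all(ligs$ligand_code == "ADP"))

  # brute-force oracle: exhaustive unit-pair scoring recomputed from scratch
  for (i in seq_len(nrow(ligs))) {
    g <- asm$atoms[asm$atoms$het & asm$atoms$chain == ligs$chain[i] &
                     asm$atoms$resno == ligs$resno[i], ]
    gx <- atom_xyz(g)
    dmin <- vapply(units, function(u) {
      ux <- atom_xyz(u$atoms)
      min(sqrt(outer(rowSums(gx^2), rowSums(ux^2), "+") - 2 * gx %*% t(ux)))
    }, numeric(1))
    scores <- vapply(1:6, function(k) dmin[k] + dmin[(k %% 6) + 1], numeric(1))
    expect_equal(ligs$interface[i], which.min(scores) - 1L)
  }

  # a ligand far from everything is flagged unassignable
  far <- asm$atoms[1, ]
  far$het <- TRUE; far$resid <- "ADP"; far$chain <- "Z"; far$resno <- 999L
  far$x <- 500; far$y <- 500; far$z <- 500
  ligs2 <- detect_ligands(rbind(asm$atoms, far), units)
  expect_true(is.na(ligs2$interface[ligs2$chain == "Z"]))
})

test_that("deposited assembly operators expand a half-ring to six chains", {
  spec <- synth_spec(residues_per_domain = 6)
  asm <- build_screw_assembly(spec, interface_params = cbind(rep(0, 6), rep(60, 6)))
  half <- asm$atoms[asm$atoms$chain %in% c("A", "B", "C") & !asm$atoms$het, ]
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(half, tmp)
  rem <- c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A, B, C",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000")
  writeLines(c(rem, readLines(tmp)), tmp)
  ex <- expand_assembly(tmp)
  expect_equal(length(unique(ex$chain[!ex$het])), 6)
  expect_equal(attr(ex, "n_operators"), 2)
  # the expanded C6 ring is analyzable end to end
  units <- build_packing_units(ex)
  expect_length(units, 6)
})

test_that("multi-model trajectories are written with MODEL records", {
  asm <- build_screw_assembly(synth_spec(residues_per_domain = 4))
  frames <- list(asm$atoms, asm$atoms)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(frames, tmp)
  lines <- readLines(tmp)
  expect_equal(sum(grepl("^MODEL", lines)), 2)
  expect_equal(sum(grepl("^ENDMDL", lines)), 2)
})
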