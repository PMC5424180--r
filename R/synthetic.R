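# Synthetic assemblies with exact ground truth.
#
# The generator emulates the geometric structure the pipeline assumes: a ring
# of six rigid two-domain packing units related by per-interface screws, a
# C2 pattern of open/closed interfaces (the period-3 arrangement of
# extension motors, or its enantiomer for retraction motors), an m=2 radial
# elongation of the ring that orients the two sub-pores, optional
# out-of-plane pucker, bound-ligand pseudo-atoms at closed interfaces, and
# marker residues standing in for the conserved pore glutamate and the
# catalytic glutamate. Pseudo-residues carry standard backbone atom names so
# every downstream selector works unmodified. No physical realism is
# attempted beyond that geometry.

# fixed local backbone offsets of one pseudo-residue (chiral by construction)
.BACKBONE <- list(N = c(-1.0, 0.4, 0.2), CA = c(0, 0, 0),
                  C = c(1.1, 0.5, -0.3), O = c(1.5, 1.6, -0.5))

#' Specification of a synthetic hexamer
#'
#' The defaults encode the canonical extension-motor geometry: pattern
#' CCOCCO with closed interfaces at -12 Angstrom rise / 65 degree twist and
#' open interfaces at +24 Angstrom / 76 degrees (rises summing to zero so
#' the ring closes), a 30 Angstrom ring radius, a 4 Angstrom two-fold
#' elongation that shapes the two sub-pores, ADP pseudo-ligands at closed
#' interfaces, a one-slot clockwise catalytic step (-60 degrees) and a
#' 13 Angstrom axial marker thrust.
#'
#' @param template_seed integer seed for the pseudo-atom template.
#' @param residues_per_domain residues in each of N2D and CTD (>= 4).
#' @param ring_radius_A ring radius, Angstrom.
#' @param closed,open named `c(rise_A=, twist_deg=)` per interface class.
#' @param pattern cyclic string over C/O, length 6 (e.g. "CCOCCO").
#' @param pucker list(shape=, amplitude_A=): shape one of "planar", "boat",
#'   "saddle", "alternating"; amplitude is the RMS out-of-plane deviation.
#' @param elongation_A amplitude of the two-fold radial modulation.
#' @param ligand_plan `"closed-ADP"` (default), `"none"`, or a named vector
#'   interface index -> residue code.
#' @param rotation_step_deg signed sub-pore rotation of one catalytic step.
#' @param marker_thrust_A axial displacement applied to the pore marker of
#'   thrusting units in the second state of a pair.
#' @param enantiomer mirror the assembly (retraction-motor-like winding).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(template_seed = 1, residues_per_domain = 12,
                       ring_radius_A = 30,
                       closed = c(rise_A = -12, twist_deg = 65),
                       open = c(rise_A = 24, twist_deg = 76),
                       pattern = "CCOCCO",
                       pucker = list(shape = "planar", amplitude_A = 0),
                       elongation_A = 4,
                       ligand_plan = "closed-ADP",
                       rotation_step_deg = -60,
                       marker_thrust_A = 13,
                       enantiomer = FALSE) {
  stopifnot(residues_per_domain >= 4, nchar(pattern) == 6,
            grepl("^[CO]{6}$", pattern))
  structure(list(template_seed = template_seed,
                 residues_per_domain = residues_per_domain,
                 ring_radius_A = ring_radius_A,
                 closed = closed, open = open, pattern = pattern,
                 pucker = pucker, elongation_A = elongation_A,
                 ligand_plan = ligand_plan,
                 rotation_step_deg = rotation_step_deg,
                 marker_thrust_A = marker_thrust_A,
                 enantiomer = enantiomer),
            class = "synth_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

#' Pseudo-atom template packing unit
#'
#' One rigid two-domain unit: an N2D blob of pseudo-residues (numbered from
#' 181) displaced towards the positive axis side, a CTD blob (numbered from
#' 296) below it, and marker residues 395 (catalytic glutamate stand-in) and
#' 400 (pore glutamate stand-in) placed on the pore-facing side. Each
#' residue carries N/CA/C/O backbone atoms with a fixed chiral local
#' geometry; the all-atom centroid is exactly at the origin. Deterministic
#' for a fixed seed; the random blobs are non-planar and chiral.
#'
#' @param spec `synth_spec`.
#' @return atom data.frame (template; chain unset) with a `role` column.
#' @export
make_template_unit <- function(spec = synth_spec()) {
  nres <- spec$residues_per_domain
  # tangentially elongated blobs (sd 7 along the ring direction) so that
  # ring-adjacent units genuinely touch, as packing units do
  base <- .with_seed(spec$template_seed, {
    n2d <- cbind(rnorm(nres, 0, 2.5), rnorm(nres, 0, 7.0), rnorm(nres, 6, 1.5))
    ctd <- cbind(rnorm(nres, 0, 3.0), rnorm(nres, 0, 7.0), rnorm(nres, -6, 2.0))
    list(n2d = n2d, ctd = ctd)
  })
  mk <- function(points, resno0, role, resid = "ALA") {
    rows <- lapply(seq_len(nrow(points)), function(i) {
      at <- names(.BACKBONE)
      off <- t(vapply(.BACKBONE, identity, numeric(3)))
      data.frame(chain = "A", resno = resno0 + i - 1L, insert = "",
                 resid = resid, elety = at, alt = "",
                 elesy = c("N", "C", "C", "O"),
                 x = points[i, 1] + off[, 1], y = points[i, 2] + off[, 2],
                 z = points[i, 3] + off[, 3], o = 1, b = 0, het = FALSE,
                 role = role)
    })
    do.call(rbind, rows)
  }
  n2d <- mk(base$n2d, 181L, "N2D")
  ctd <- mk(base$ctd, 296L, "CTD")
  # markers on the pore-facing (axis-facing) side of the CTD
  markers <- rbind(mk(rbind(c(-6, 0, -3)), 395L, "CTD", "GLU"),
                   mk(rbind(c(-7, 1, -5)), 400L, "CTD", "GLU"))
  tmpl <- rbind(n2d, ctd, markers)
  ctr <- colMeans(cbind(tmpl$x, tmpl$y, tmpl$z))
  tmpl$x <- tmpl$x - ctr[1]; tmpl$y <- tmpl$y - ctr[2]; tmpl$z <- tmpl$z - ctr[3]
  tmpl
}

# named pucker shapes as deviation patterns around the ring, normalised to
# unit RMS so that amplitude_A is the ledger's RMS out-of-plane deviation
.pucker_pattern <- function(shape, amplitude) {
  z <- switch(shape,
              planar = rep(0, 6),
              boat = c(1, 0, -1, -1, 0, 1),
              saddle = cos(2 * pi * 2 * (0:5) / 6),
              alternating = (-1)^(0:5),
              stop("unknown pucker shape: ", shape))
  if (amplitude == 0 || all(z == 0)) return(rep(0, 6))
  amplitude * z / sqrt(mean(z^2))
}

# place template atoms with orientation (rotation about z by ang_deg) and
# translation
.place_unit <- function(tmpl, ang_deg, translation) {
  R <- rotation_about_axis(c(0, 0, 1), ang_deg)
  xyz <- atom_xyz(tmpl) %*% t(R)
  tmpl$x <- xyz[, 1] + translation[1]
  tmpl$y <- xyz[, 2] + translation[2]
  tmpl$z <- xyz[, 3] + translation[3]
  tmpl
}

# chain assignment: unit k donates its N2D to chain k and its CTD to chain
# k+1, so rebuilt packing units equal the construction units exactly
.assign_chains <- function(unit_atoms_list) {
  out <- lapply(seq_along(unit_atoms_list), function(k) {
    a <- unit_atoms_list[[k]]
    a$chain <- ifelse(a$role == "N2D", LETTERS[k],
                      LETTERS[(k %% 6) + 1])
    a
  })
  atoms <- do.call(rbind, out)
  atoms[order(atoms$chain, atoms$resno), ]
}

# pseudo-ligand (3 atoms) at the closest approach of two units
.place_ligand <- function(atoms_u1, atoms_u2, resid, chain, resno) {
  x1 <- atom_xyz(atoms_u1); x2 <- atom_xyz(atoms_u2)
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  mid <- (x1[ij[1], ] + x2[ij[2], ]) / 2
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = c("PA", "PB", "N9"), alt = "",
             elesy = c("P", "P", "N"),
             x = mid[1] + c(0, 0.8, -0.8), y = mid[2] + c(0.8, -0.4, -0.4),
             z = mid[3] + c(0, 0.5, -0.5), o = 1, b = 0, het = TRUE,
             role = "LIG")
}

.pattern_states <- function(pattern)
  ifelse(strsplit(pattern, "")[[1]] == "C", "closed", "open")

# interface params (rise, signed twist) per interface from a pattern
.pattern_params <- function(spec, pattern = spec$pattern) {
  st <- strsplit(pattern, "")[[1]]
  rise <- ifelse(st == "C", spec$closed[["rise_A"]], spec$open[["rise_A"]])
  twist <- ifelse(st == "C", spec$closed[["twist_deg"]], spec$open[["twist_deg"]])
  cbind(rise_A = rise, twist_deg = twist)
}

#' Build an assembly of packing units connected by screws
#'
#' Unit k+1 is unit k advanced by the k-th screw (a rotation about the
#' vertical axis plus a rise along it). With `close_ring`, the parameters
#' must satisfy ring closure (rises summing to zero, twists to a multiple
#' of 360 degrees) or `closure_correction` must be enabled, in which case
#' the residual is distributed equally over the six interfaces and the
#' corrected parameters become the recorded ground truth.
#'
#' @param spec `synth_spec`.
#' @param interface_params 6 x 2 matrix (`rise_A`, `twist_deg`; twist signed,
#'   positive counterclockwise). Default: derived from `spec$pattern`.
#' @param close_ring require/enforce ring closure.
#' @param closure_correction distribute the closure residual equally.
#' @param pucker_z optional length-6 out-of-plane offsets (overrides
#'   `spec$pucker`).
#' @return list of class `synthetic_assembly`: `atoms`, `ground_truth`
#'   (corrected parameters, pattern, pucker offsets, construction units).
#' @export
build_screw_assembly <- function(spec = synth_spec(),
                                 interface_params = NULL,
                                 close_ring = TRUE,
                                 closure_correction = TRUE,
                                 pucker_z = NULL) {
  if (is.null(interface_params)) interface_params <- .pattern_params(spec)
  stopifnot(nrow(interface_params) == 6)
  rise <- interface_params[, 1]; twist <- interface_params[, 2]
  if (close_ring) {
    rise_resid <- sum(rise)
    twist_resid <- sum(twist) - 360 * round(sum(twist) / 360)
    if ((abs(rise_resid) > 1e-9 || abs(twist_resid) > 1e-9)) {
      if (!closure_correction)
        stop("interface parameters do not close the ring (net rise ",
             signif(rise_resid, 4), " A, twist residual ",
             signif(twist_resid, 4), " deg)")
      rise <- rise - rise_resid / 6
      twist <- twist - twist_resid / 6
    }
  }
  if (is.null(pucker_z))
    pucker_z <- .pucker_pattern(spec$pucker$shape, spec$pucker$amplitude_A)
  tmpl <- make_template_unit(spec)
  ang <- cumsum(c(0, twist))[1:6]
  zz <- cumsum(c(0, rise))[1:6]
  units_atoms <- lapply(1:6, function(k) {
    a <- ang[k]
    .place_unit(tmpl, a, c(spec$ring_radius_A * cos(a * pi / 180),
                           spec$ring_radius_A * sin(a * pi / 180),
                           zz[k] + pucker_z[k]))
  })
  atoms <- .assign_chains(units_atoms)
  lig <- .build_ligands(spec, units_atoms)
  atoms <- rbind(atoms, lig)
  if (spec$enantiomer) atoms$y <- -atoms$y
  gt <- list(rise_A = rise, twist_deg = twist, pattern = spec$pattern,
             pucker_z = pucker_z, angles_deg = ang, z_A = zz,
             enantiomer = spec$enantiomer,
             n_atoms = nrow(atoms))
  structure(list(atoms = .as_atoms_keep_role(atoms), ground_truth = gt,
                 units = .construction_units(units_atoms, spec$enantiomer),
                 spec = spec),
            class = "synthetic_assembly")
}

# construction bookkeeping: the packing units exactly as placed
.construction_units <- function(units_atoms, enantiomer = FALSE) {
  lapply(seq_along(units_atoms), function(k) {
    a <- units_atoms[[k]]
    a$chain <- ifelse(a$role == "N2D", LETTERS[k], LETTERS[(k %% 6) + 1])
    if (enantiomer) a$y <- -a$y
    a <- .as_atoms_keep_role(a)
    structure(list(index = k - 1L, n2d_chain = LETTERS[k],
                   ctd_chain = LETTERS[(k %% 6) + 1], atoms = a,
                   centroid = colMeans(atom_xyz(a))),
              class = "packing_unit")
  })
}

.as_atoms_keep_role <- function(atoms) {
  role <- atoms$role
  out <- .as_atoms(atoms)
  out$role <- role
  out
}

.build_ligands <- function(spec, units_atoms, pattern = spec$pattern) {
  plan <- spec$ligand_plan
  if (identical(plan, "none")) return(NULL)
  st <- .pattern_states(pattern)
  rows <- list()
  for (k in 1:6) {
    code <- if (identical(plan, "closed-ADP")) {
      if (st[k] == "closed") "ADP" else NA
    } else plan[as.character(k - 1)]
    if (is.null(code) || is.na(code)) next
    rows[[length(rows) + 1]] <-
      .place_ligand(units_atoms[[k]], units_atoms[[(k %% 6) + 1]],
                    code, LETTERS[k], 700L + k)
  }
  if (length(rows) == 0) NULL else do.call(rbind, rows)
}

# slot-based construction used for two-state pairs: all units share one
# orientation step (60 deg) so that the two states differ only by per-unit
# translations, making the constructed sub-pore rotation exactly
# recoverable after alignment
.slot_assembly <- function(spec, pattern, phi_deg) {
  tmpl <- make_template_unit(spec)
  st <- .pattern_states(pattern)
  rise <- ifelse(st == "closed", spec$closed[["rise_A"]], spec$open[["rise_A"]])
  if (abs(sum(rise)) > 1e-9)
    stop("pattern/rise combination does not close the ring: net rise ",
         signif(sum(rise), 4), " A")
  zz <- cumsum(c(0, rise))[1:6]
  theta <- 60 * (0:5)
  r <- spec$ring_radius_A +
    spec$elongation_A * cos(2 * (theta - phi_deg) * pi / 180)
  units_atoms <- lapply(1:6, function(k) {
    .place_unit(tmpl, theta[k],
                c(r[k] * cos(theta[k] * pi / 180),
                  r[k] * sin(theta[k] * pi / 180), zz[k]))
  })
  list(units_atoms = units_atoms, rise = rise, z = zz, r = r, theta = theta,
       states = st)
}

# interface index (0-based) pair of the antipodal minority interfaces
.minority_axis <- function(pattern) {
  st <- .pattern_states(pattern)
  minority <- names(which.min(table(st)))
  idx <- which(st == minority) - 1
  if (length(idx) != 2 || diff(idx) != 3)
    stop("pattern is not C2 with an antipodal minority pair: ", pattern)
  idx
}

.shift_pattern <- function(pattern, by) {
  s <- strsplit(pattern, "")[[1]]
  paste(s[((0:5 - by) %% 6) + 1], collapse = "")
}

#' Two-state synthetic pair with known sub-pore rotation
#'
#' State A is built on the six angular slots with the spec's pattern; its
#' two-fold elongation axis passes through the antipodal minority
#' interfaces. State B advances the open/closed pattern by
#' `round(rotation_step_deg / 60)` slots and the elongation phase by exactly
#' `rotation_step_deg`, and thrusts the pore-marker residue of the thrusting
#' units (those flanked by one closing and one opening interface) axially
#' by `marker_thrust_A`. The construction guarantees that the global
#' C-alpha alignment between the states is the identity rotation, so the
#' recorded ground truth (sub-pore rotation; marker displacements corrected
#' for the alignment's mean shift) is recovered by the analysis exactly.
#'
#' A `rotation_step_deg` that is not a multiple of 60 leaves the pattern
#' unchanged (a pure pore-axis rotation); a zero step returns two identical
#' states.
#'
#' @param spec `synth_spec`.
#' @return list of class `synthetic_pair`: `state_a`, `state_b` (each with
#'   `atoms`), and `ground_truth` (`rotation_deg`, `thrusting_units`,
#'   `marker_axial_A`, patterns, phases).
#' @export
make_two_state_pair <- function(spec = synth_spec()) {
  step <- spec$rotation_step_deg
  advance <- round(step / 60)
  if (abs(step - 60 * advance) > 1e-9) advance <- 0L
  pat_a <- spec$pattern
  pat_b <- .shift_pattern(pat_a, advance)
  min_a <- .minority_axis(pat_a)
  phi_a <- 60 * min_a[1] + 30
  phi_b <- phi_a + step
  A <- .slot_assembly(spec, pat_a, phi_a)
  B <- .slot_assembly(spec, pat_b, phi_b)

  # thrusting units: both flanking interfaces change state, one closed->open
  sa <- A$states; sb <- B$states
  thrust <- integer(0)
  for (k in 0:5) {
    i1 <- (k - 1) %% 6 + 1; i2 <- k + 1
    if (sa[i1] != sb[i1] && sa[i2] != sb[i2] &&
        ((sa[i1] == "closed" && sb[i1] == "open") ||
         (sa[i2] == "closed" && sb[i2] == "open")))
      thrust <- c(thrust, k)
  }
  if (length(thrust) > 0 && spec$marker_thrust_A != 0) {
    for (k in thrust) {
      sel <- B$units_atoms[[k + 1]]$resno == 400L
      B$units_atoms[[k + 1]]$z[sel] <-
        B$units_atoms[[k + 1]]$z[sel] + spec$marker_thrust_A
    }
  }

  finish <- function(S, pattern) {
    atoms <- .assign_chains(S$units_atoms)
    lig <- .build_ligands(spec, S$units_atoms, pattern)
    atoms <- rbind(atoms, lig)
    if (spec$enantiomer) atoms$y <- -atoms$y
    .as_atoms_keep_role(atoms)
  }
  atoms_a <- finish(A, pat_a)
  atoms_b <- finish(B, pat_b)

  # exact ground truth for the marker displacement as measured after a
  # C-alpha alignment: the alignment rotation is identity by construction
  # and its translation subtracts the mean C-alpha shift
  ca_a <- atoms_a[atoms_a$elety == "CA" & !atoms_a$het, ]
  ca_b <- atoms_b[atoms_b$elety == "CA" & !atoms_b$het, ]
  mean_shift <- colMeans(atom_xyz(ca_b)) - colMeans(atom_xyz(ca_a))
  marker_axial <- if (length(thrust) > 0)
    setNames((B$z[thrust + 1] + spec$marker_thrust_A - A$z[thrust + 1]) -
               mean_shift[3], paste0("unit", thrust))
  else setNames(numeric(0), character(0))

  gt <- list(rotation_deg = if (spec$enantiomer) -step else step,
             pattern_a = pat_a, pattern_b = pat_b,
             phi_a_deg = phi_a, phi_b_deg = phi_b,
             thrusting_units = thrust,
             marker_thrust_A = spec$marker_thrust_A,
             marker_axial_A = marker_axial,
             enantiomer = spec$enantiomer)
  structure(list(state_a = list(atoms = atoms_a,
                                units = .construction_units(A$units_atoms,
                                                            spec$enantiomer)),
                 state_b = list(atoms = atoms_b,
                                units = .construction_units(B$units_atoms,
                                                            spec$enantiomer)),
                 ground_truth = gt, spec = spec),
            class = "synthetic_pair")
}

#' Pseudo-atom pore wall
#'
#' Builds a cage of hetero pseudo-atoms lining one or two cylindrical
#' channels (a figure-8 when two overlapping circles are given): the
#' fixture geometry for pore profiling. Atoms of one circle falling inside
#' another circle are omitted, so only the outer wall remains.
#'
#' @param centers n x 2 matrix of in-plane circle centers.
#' @param radii circle radii (to atom centers), Angstrom.
#' @param z z-levels at which to place rings of atoms.
#' @param spacing_deg angular spacing of wall atoms (default 10).
#' @param element wall atom element (default "C").
#' @return atom data.frame (hetero, residue WAL).
#' @export
synth_pore_wall <- function(centers, radii, z = seq(-6, 6, by = 2),
                            spacing_deg = 10, element = "C") {
  centers <- rbind(centers)
  rows <- list()
  for (ci in seq_len(nrow(centers))) {
    th <- seq(0, 360 - spacing_deg, by = spacing_deg) * pi / 180
    px <- centers[ci, 1] + radii[ci] * cos(th)
    py <- centers[ci, 2] + radii[ci] * sin(th)
    keep <- rep(TRUE, length(px))
    for (cj in seq_len(nrow(centers)))
      if (cj != ci)
        keep <- keep & (px - centers[cj, 1])^2 + (py - centers[cj, 2])^2 >
          radii[cj]^2 * 0.999
    for (zz in z)
      rows[[length(rows) + 1]] <- data.frame(
        chain = "Z", resno = 900L + ci, insert = "", resid = "WAL",
        elety = element, alt = "", elesy = element,
        x = px[keep], y = py[keep], z = zz, o = 1, b = 0, het = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .as_atoms(out)
}
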