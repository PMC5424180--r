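# Ring-level analysis: oriented ring axis, the six-interface closure ledger
# with pucker classification, and signed pore-rotation inference between
# nucleotide states.
#
# Sign convention, used everywhere and printed in report headers: the ring
# axis points towards the N2D face; positive rotation is counterclockwise
# for an observer on the N2D side looking down the axis.

.CONVENTION <- paste("signed angles: positive = counterclockwise viewed from",
                     "the N2D face (ring axis oriented towards the N2Ds)")

# orthonormal in-plane basis completing an axis to a right-handed frame
.ring_basis <- function(n) {
  n <- .unit(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(.cross(n, .cross(ref, n)))   # ref projected into the plane
  e2 <- .cross(n, e1)
  list(e1 = e1, e2 = e2)
}

#' Oriented ring axis of a hexamer
#'
#' Total-least-squares normal of the plane through the six packing-unit
#' centroids, oriented so that the mean N2D centroid lies on its positive
#' side (the viewing convention for all signed angles).
#'
#' @param units list of 6 `packing_unit` objects.
#' @return list with unit vector `axis` and 3-vector `center`.
#' @export
ring_axis <- function(units) {
  if (length(units) != 6) stop("need 6 packing units")
  cents <- t(vapply(units, function(u) u$centroid, numeric(3)))
  center <- colMeans(cents)
  sv <- svd(sweep(cents, 2, center))
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1))
    stop("degenerate ring: unit centroids are collinear")
  n <- sv$v[, 3]
  n2d <- t(vapply(units, function(u) {
    a <- u$atoms[u$atoms$role == "N2D", ]
    colMeans(atom_xyz(a))
  }, numeric(3)))
  if (sum((colMeans(n2d) - center) * n) < 0) n <- -n
  list(axis = .unit(n), center = center)
}

#' Coaxial screw parameters from printed rise/twist values
#'
#' Builds the `screw_parameters` of an idealised interface: a rotation by
#' `twist_deg` about the ring axis (counterclockwise, unless
#' `handedness = -1`) plus a translation of `rise_A` along it. This is how
#' per-interface values quoted in the literature (e.g. -12 A / 65 deg for a
#' closed interface) enter the ring ledger without coordinates.
#'
#' @param rise_A signed rise along the oriented ring axis, Angstrom.
#' @param twist_deg twist magnitude, degrees.
#' @param handedness +1 counterclockwise (default), -1 clockwise.
#' @return `screw_parameters`.
#' @export
screw_from_params <- function(rise_A, twist_deg, handedness = 1) {
  tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), handedness * twist_deg),
                        c(0, 0, rise_A))
  screw_decompose(tf, c(0, 0, 1))
}

#' Minimal interface record
#'
#' Container for one packing-unit junction. Fully populated records come out
#' of [analyze_interfaces()]; parameter-only records (screw but no
#' coordinates) are accepted by [build_ledger()] for desk calculations.
#'
#' @param index interface index 0-5 (interface k joins units k and k+1).
#' @param screw `screw_parameters`.
#' @param state `"closed"`, `"open"`, or `NULL` to derive from the rise sign.
#' @param nucleotide_label nucleotide label (default `"APO"`).
#' @param unit_1,unit_2 flanking `packing_unit`s (optional).
#' @param bsa_A2,contacts optional BSA and contact list.
#' @return object of class `interface_record`.
#' @export
interface_record <- function(index, screw, state = NULL,
                             nucleotide_label = "APO",
                             unit_1 = NULL, unit_2 = NULL,
                             bsa_A2 = NA_real_, contacts = NULL) {
  if (is.null(state)) state <- if (screw$rise_A < 0) "closed" else "open"
  structure(list(index = as.integer(index), unit_1 = unit_1, unit_2 = unit_2,
                 screw = screw, state = state,
                 nucleotide_label = nucleotide_label,
                 label = paste(state, nucleotide_label, sep = "-"),
                 bsa_A2 = bsa_A2, contacts = contacts),
            class = "interface_record")
}

#' Measure and classify all six interfaces of a hexamer
#'
#' For each junction of consecutive packing units (counterclockwise order)
#' this computes the inter-unit screw, optionally buried surface area and
#' polar contacts, attaches any assigned ligand, and classifies the
#' interface open/closed.
#'
#' @param units `packing_units` from [build_packing_units()].
#' @param ligands output of [detect_ligands()] (optional).
#' @param rule [contact_rule()].
#' @param compute_bsa,compute_contacts toggle the more expensive measures.
#' @param n_sample_points,seed passed to [sasa()] for BSA.
#' @return list of 6 `interface_record`s (class `interface_list`) carrying
#'   the ring geometry as attribute `ring`.
#' @export
analyze_interfaces <- function(units, ligands = NULL, rule = contact_rule(),
                               compute_bsa = FALSE, compute_contacts = TRUE,
                               n_sample_points = 240, seed = 0) {
  ring <- attr(units, "ring")
  if (is.null(ring)) ring <- ring_axis(units)
  recs <- lapply(1:6, function(k) {
    u1 <- units[[k]]; u2 <- units[[(k %% 6) + 1]]
    sc <- interface_screw(u1, u2, ring$axis, ring$center)
    bsa <- if (compute_bsa)
      buried_surface_area(u1, u2, n_sample_points = n_sample_points,
                          seed = seed) else NA_real_
    lig <- if (!is.null(ligands) && nrow(ligands) > 0)
      ligands[!is.na(ligands$interface) & ligands$interface == k - 1, ]
    else NULL
    cls <- classify_interface(sc, bsa, lig)
    rec <- interface_record(k - 1L, sc, cls$state, cls$nucleotide_label,
                            unit_1 = u1, unit_2 = u2, bsa_A2 = bsa,
                            contacts = if (compute_contacts)
                              polar_contacts(u1, u2, rule) else NULL)
    rec$ligands <- lig
    rec
  })
  structure(recs, class = "interface_list", ring = ring)
}

# discrete Fourier amplitudes of the six signed out-of-plane deviations;
# m = 1 and 2 return cosine amplitudes, m = 3 the alternating amplitude
.pucker_modes <- function(z) {
  k <- 0:5
  amp <- function(m) {
    a <- sum(z * cos(2 * pi * m * k / 6)) / 3
    b <- sum(z * sin(2 * pi * m * k / 6)) / 3
    c(sqrt(a^2 + b^2), atan2(b, a))
  }
  m1 <- amp(1); m2 <- amp(2)
  a3 <- sum(z * (-1)^k) / 6
  list(A1 = m1[1], phase1 = m1[2], A2 = m2[1], phase2 = m2[2], A3 = abs(a3))
}

# classify the pucker of mean-removed deviations z (ordered around the ring)
.classify_pucker <- function(z, planar_tol = 0.25) {
  rms <- sqrt(mean(z^2))
  if (rms < planar_tol) return(list(class = "planar", amplitude = rms))
  m <- .pucker_modes(z)
  power <- c(boat = m$A1^2 / 2, saddle = m$A2^2 / 2, alternating = m$A3^2)
  dom <- names(which.max(power))
  cls <- switch(dom,
                boat = if (power["saddle"] > 0.5 * power["boat"])
                  "twist-boat" else "boat",
                saddle = "saddle",
                alternating = "other")
  list(class = cls, amplitude = rms, modes = m)
}

#' Ring-closure ledger of a hexamer
#'
#' Accounts for the six inter-unit screws of a hexameric ring: the rises
#' must sum to (near) zero for the ring to close, and any excess of the
#' summed twists over 360 degrees manifests as out-of-plane pucker. With
#' four closed interfaces at -12 A / 65 deg and two open at +24 A / 76 deg
#' -- the canonical extension-motor arrangement -- the net rise is exactly 0
#' and the net twist 412 degrees.
#'
#' The closure residual is the distance from the identity of the composed
#' six-step screw cycle (max of its rotation angle in degrees and its
#' translation norm in Angstrom). Pucker is measured, when coordinates are
#' present, as the signed deviations of the unit centroids along the mean
#' interface-screw axis (the ring's helical symmetry axis), decomposed into
#' discrete Fourier modes: a dominant one-node mode is the boat family, a
#' dominant two-node mode the saddle, alternating deviations and mixtures
#' fall to "other", and rings with RMS deviation under `planar_tol` are
#' planar.
#'
#' @param interfaces list of 6 `interface_record`s (an `interface_list`, or
#'   parameter-only records in cyclic order).
#' @param planar_tol RMS out-of-plane deviation below which the ring is
#'   called planar (Angstrom, default 0.25).
#' @return object of class `ring_ledger`.
#' @export
build_ledger <- function(interfaces, planar_tol = 0.25) {
  if (length(interfaces) != 6) stop("need 6 interfaces in cyclic order")
  idx <- vapply(interfaces, function(i) i$index, integer(1))
  if (!all(sort(idx) == 0:5)) stop("interfaces are not a cyclic 0-5 set")
  interfaces <- interfaces[order(idx)]
  screws <- lapply(interfaces, `[[`, "screw")
  net_rise <- sum(vapply(screws, `[[`, numeric(1), "rise_A"))
  net_twist <- sum(vapply(screws, `[[`, numeric(1), "twist_deg"))
  cyc <- Reduce(function(acc, s) compose_transforms(reconstruct_transform(s), acc),
                screws, init = rigid_transform())
  rot_resid <- .axis_angle(cyc$rotation)$angle * 180 / pi
  trans_resid <- sqrt(sum(cyc$translation^2))
  closure <- max(rot_resid, trans_resid)
  pattern <- paste(vapply(interfaces, function(i)
    if (i$state == "closed") "C" else "O", character(1)), collapse = "")
  is_c2 <- substr(pattern, 1, 3) == substr(pattern, 4, 6)

  have_units <- !any(vapply(interfaces, function(i) is.null(i$unit_1),
                            logical(1)))
  pucker <- list(class = NA_character_, amplitude = NA_real_)
  deviations <- rep(NA_real_, 6)
  if (have_units) {
    units <- lapply(interfaces, `[[`, "unit_1")
    cents <- t(vapply(units, function(u) u$centroid, numeric(3)))
    # reference normal: mean screw rotation axis (helical symmetry axis);
    # unlike the centroid-plane normal it is not tilted by the pucker itself
    axes <- t(vapply(screws, `[[`, numeric(3), "axis_direction"))
    n_ref <- .unit(colMeans(axes))
    deviations <- as.numeric(sweep(cents, 2, colMeans(cents)) %*% n_ref)
    pucker <- .classify_pucker(deviations, planar_tol)
  }
  structure(list(interfaces = interfaces,
                 net_rise_A = net_rise,
                 net_twist_deg = net_twist,
                 closure_residual = closure,
                 closure_rotation_deg = rot_resid,
                 closure_translation_A = trans_resid,
                 pucker_amplitude_A = pucker$amplitude,
                 shape_class = pucker$class,
                 out_of_plane_A = deviations,
                 c2_pattern = pattern,
                 is_c2 = is_c2,
                 convention = .CONVENTION),
            class = "ring_ledger")
}

#' @export
print.ring_ledger <- function(x, ...) {
  cat("ring ledger (", x$convention, ")\n", sep = "")
  cat(sprintf("  pattern %s%s | net rise %.2f A | net twist %.1f deg\n",
              x$c2_pattern, if (x$is_c2) " (C2)" else "",
              x$net_rise_A, x$net_twist_deg))
  cat(sprintf("  closure residual %.3g (rot %.3g deg, trans %.3g A)\n",
              x$closure_residual, x$closure_rotation_deg,
              x$closure_translation_A))
  if (!is.na(x$pucker_amplitude_A))
    cat(sprintf("  pucker: %s, amplitude %.2f A (RMS out-of-plane)\n",
                x$shape_class, x$pucker_amplitude_A))
  for (i in x$interfaces)
    cat(sprintf("  interface %d: %-14s rise %+7.2f A  twist %6.2f deg\n",
                i$index, i$label, i$screw$rise_A, i$screw$twist_deg))
  invisible(x)
}

# in-plane polar coordinates of unit centroids about the ring
.unit_polar <- function(units, ring) {
  b <- .ring_basis(ring$axis)
  cents <- t(vapply(units, function(u) u$centroid, numeric(3)))
  v <- sweep(cents, 2, ring$center)
  x <- v %*% b$e1; y <- v %*% b$e2
  list(theta = atan2(y, x), r = sqrt(x^2 + y^2), basis = b)
}

# phase (radians, mod pi) and amplitude (Angstrom) of the two-fold radial
# modulation of the unit centroids: the orientation of the elongated pore /
# sub-pore axis, undefined (amplitude ~ 0) for non-elongated rings
.subpore_axis_phase <- function(units, ring) {
  p <- .unit_polar(units, ring)
  rho <- p$r - mean(p$r)
  a <- sum(rho * cos(2 * p$theta)) / 3
  b <- sum(rho * sin(2 * p$theta)) / 3
  list(phase = 0.5 * atan2(b, a), amplitude = sqrt(a^2 + b^2))
}

.wrap_deg <- function(x, half = 180) ((x + half) %% (2 * half)) - half

#' Signed sub-pore rotation between two hexamer states
#'
#' Aligns state B onto state A over all matched C-alpha atoms (under a chain
#' correspondence that is searched over the six cyclic shifts when not
#' given), then measures the signed in-plane rotation of the sub-pore axis
#' about the oriented ring axis. When explicit sub-pore centers (e.g. from
#' [subpore_detect()]) are supplied for both states, the mean signed angular
#' displacement of matched centers is used; otherwise the two-fold phase of
#' the unit-centroid radii -- the orientation of the elongated pore --
#' serves as the sub-pore axis.
#'
#' Also reports the thrusting packing units (units both of whose flanking
#' interfaces change state, at least one closed-to-open: the units the
#' catalytic step pushes along the axis) and the displacement of configured
#' marker residues.
#'
#' @param state_a,state_b `hexamer_state` objects from [analyze_hexamer()],
#'   or bare `packing_units`.
#' @param correspondence integer cyclic shift s (unit k of A corresponds to
#'   unit k+s of B), or `NULL` to search by interface-pattern match then
#'   RMSD.
#' @param subpores_a,subpores_b optional matrices of sub-pore centers
#'   (rows are points) for the explicit-center path.
#' @param markers named integer vector of marker residues (default from the
#'   units' domain config).
#' @return object of class `rotation_inference` with
#'   `subpore_rotation_deg` (positive = counterclockwise viewed from the
#'   N2D face), `direction`, `thrusting_units`, `marker_displacements`,
#'   and the alignment diagnostics.
#' @export
infer_rotation <- function(state_a, state_b, correspondence = NULL,
                           subpores_a = NULL, subpores_b = NULL,
                           markers = NULL) {
  ua <- if (inherits(state_a, "hexamer_state")) state_a$units else state_a
  ub <- if (inherits(state_b, "hexamer_state")) state_b$units else state_b
  ia <- if (inherits(state_a, "hexamer_state")) state_a$interfaces else NULL
  ib <- if (inherits(state_b, "hexamer_state")) state_b$interfaces else NULL
  ring <- attr(ua, "ring"); if (is.null(ring)) ring <- ring_axis(ua)
  if (is.null(markers)) {
    cfg <- attr(ua, "config")
    markers <- if (!is.null(cfg)) cfg$markers else integer(0)
  }

  states_of <- function(il) if (is.null(il)) NULL else
    vapply(il, `[[`, character(1), "state")
  sa <- states_of(ia); sb <- states_of(ib)
  if (!is.null(sa) && !is.null(sb) &&
      sum(sa == "closed") != sum(sb == "closed"))
    stop("states are incomparable: unequal closed/open counts (",
         sum(sa == "closed"), " vs ", sum(sb == "closed"),
         " closed interfaces) under every cyclic correspondence")

  # when the two states share chain labels, the physical correspondence is
  # the label-preserving shift (the same chains before and after the step);
  # only label-free comparisons fall back to the pattern/RMSD search
  if (is.null(correspondence)) {
    ca <- vapply(ua, `[[`, character(1), "n2d_chain")
    cb <- vapply(ub, `[[`, character(1), "n2d_chain")
    for (s in 0:5)
      if (all(cb[(0:5 + s) %% 6 + 1] == ca)) { correspondence <- s; break }
  }
  shifts <- if (is.null(correspondence)) 0:5 else as.integer(correspondence)
  score_shift <- function(s) {
    mism <- if (!is.null(sa) && !is.null(sb))
      sum(sa != sb[(0:5 + s) %% 6 + 1]) else 0
    m <- .stack_matched(ua, ub, s)
    fit <- kabsch_superpose(m$b, m$a)
    c(mism, fit$rmsd)
  }
  sc <- vapply(shifts, score_shift, numeric(2))
  if (!is.null(sa) && !is.null(sb) && is.null(correspondence) &&
      min(sc[1, ]) == 6)
    stop("states are incomparable: no cyclic correspondence matches the ",
         "open/closed patterns")
  best <- shifts[order(sc[1, ], sc[2, ])[1]]

  m <- .stack_matched(ua, ub, best)
  fit <- kabsch_superpose(m$b, m$a)   # maps B onto A

  # sub-pore axis angle in both states, measured in A's ring frame
  if (!is.null(subpores_a) && !is.null(subpores_b)) {
    pa <- rbind(subpores_a); pb <- apply_transform(fit$transform, rbind(subpores_b))
    b <- .ring_basis(ring$axis)
    ang_of <- function(p) {
      v <- sweep(p, 2, ring$center)
      atan2(v %*% b$e2, v %*% b$e1) * 180 / pi
    }
    aa <- ang_of(pa); ab <- ang_of(pb)
    d <- vapply(seq_along(aa), function(i)
      .wrap_deg(ab[which.min(abs(.wrap_deg(ab - aa[i])))] - aa[i]),
      numeric(1))
    rot <- mean(d)
  } else {
    ub_aligned <- .transform_units(ub, fit$transform)
    phi_a <- .subpore_axis_phase(ua, ring)
    phi_b <- .subpore_axis_phase(ub_aligned, ring)
    if (min(phi_a$amplitude, phi_b$amplitude) >= 0.3) {
      rot <- .wrap_deg((phi_b$phase - phi_a$phase) * 180 / pi, half = 90)
    } else {
      # ring not measurably elongated: no sub-pore axis to track; fall back
      # to the mean signed angular displacement of matched unit centroids
      pa <- .unit_polar(ua, ring)
      pb <- .unit_polar(ub_aligned[(0:5 + best) %% 6 + 1], ring)
      rot <- mean(.wrap_deg((pb$theta - pa$theta) * 180 / pi))
    }
  }

  thrust <- integer(0)
  if (!is.null(sa) && !is.null(sb)) {
    sb_c <- sb[(0:5 + best) %% 6 + 1]
    for (k in 0:5) {
      i1 <- (k - 1) %% 6 + 1; i2 <- k + 1  # flanking interfaces k-1 and k
      ch1 <- sa[i1] != sb_c[i1]; ch2 <- sa[i2] != sb_c[i2]
      opening <- (sa[i1] == "closed" && sb_c[i1] == "open") ||
        (sa[i2] == "closed" && sb_c[i2] == "open")
      if (ch1 && ch2 && opening) thrust <- c(thrust, k)
    }
  }

  md <- .marker_displacements(ua, ub, best, fit$transform, ring, markers)

  structure(list(subpore_rotation_deg = rot,
                 direction = if (abs(rot) < 0.5) "none"
                 else if (rot > 0) "counterclockwise" else "clockwise",
                 correspondence_shift = best,
                 alignment_rmsd = fit$rmsd,
                 thrusting_units = thrust,
                 marker_displacements = md,
                 convention = .CONVENTION),
            class = "rotation_inference")
}

# stacked matched C-alpha coordinates of two unit lists under cyclic shift s
.stack_matched <- function(ua, ub, s) {
  ms <- lapply(1:6, function(k) .matched_ca(ua[[k]], ub[[(k - 1 + s) %% 6 + 1]]))
  list(a = do.call(rbind, lapply(ms, `[[`, "a")),
       b = do.call(rbind, lapply(ms, `[[`, "b")))
}

.transform_units <- function(units, tf) {
  out <- lapply(units, function(u) {
    xyz <- apply_transform(tf, atom_xyz(u$atoms))
    u$atoms$x <- xyz[, 1]; u$atoms$y <- xyz[, 2]; u$atoms$z <- xyz[, 3]
    u$centroid <- colMeans(xyz)
    u
  })
  attributes(out) <- attributes(units)
  out
}

# per-unit marker C-alpha displacements (total / axial / tangential) of B
# (aligned onto A) relative to A
.marker_displacements <- function(ua, ub, s, tf, ring, markers) {
  if (length(markers) == 0)
    return(data.frame(marker = character(), unit = integer(),
                      total_A = numeric(), axial_A = numeric(),
                      tangential_A = numeric()))
  rows <- list()
  for (mi in seq_along(markers)) {
    resno <- markers[[mi]]
    for (k in 1:6) {
      aa <- ua[[k]]$atoms
      ba <- ub[[(k - 1 + s) %% 6 + 1]]$atoms
      pa <- aa[aa$elety == "CA" & aa$resno == resno & !aa$het, ]
      pb <- ba[ba$elety == "CA" & ba$resno == resno & !ba$het, ]
      if (nrow(pa) != 1 || nrow(pb) != 1) next
      d <- as.numeric(apply_transform(tf, atom_xyz(pb))) - as.numeric(atom_xyz(pa))
      ax <- sum(d * ring$axis)
      tot <- sqrt(sum(d^2))
      rows[[length(rows) + 1]] <-
        data.frame(marker = names(markers)[mi], unit = k - 1L,
                   total_A = tot, axial_A = ax,
                   tangential_A = sqrt(max(0, tot^2 - ax^2)))
    }
  }
  if (length(rows) == 0)
    return(data.frame(marker = character(), unit = integer(),
                      total_A = numeric(), axial_A = numeric(),
                      tangential_A = numeric()))
  do.call(rbind, rows)
}

#' @export
print.rotation_inference <- function(x, ...) {
  cat("rotation inference (", x$convention, ")\n", sep = "")
  cat(sprintf("  sub-pore rotation %+.2f deg (%s); shift %d; alignment RMSD %.3f A\n",
              x$subpore_rotation_deg, x$direction, x$correspondence_shift,
              x$alignment_rmsd))
  if (length(x$thrusting_units) > 0)
    cat("  thrusting units:", paste(x$thrusting_units, collapse = ", "), "\n")
  if (nrow(x$marker_displacements) > 0) {
    cat("  marker displacements (A):\n")
    print(x$marker_displacements, row.names = FALSE)
  }
  invisible(x)
}

#' One-catalytic-step inference by self-permutation
#'
#' Retraction-motor hexamers (PilT-like, two closed / four open interfaces)
#' are compared against their own copy cyclically permuted by one packing
#' unit along the chain-winding sense -- the standard device for modelling
#' one catalytic step when only a single nucleotide state is available. The
#' reported rotation is the signed ring-axis component of the optimal
#' alignment rotation mapping the permuted copy onto the original; for a
#' perfectly C6-symmetric ring this is exactly the 60-degree slot angle with
#' zero residual deformation. Enantiomeric open/closed arrangements (the
#' retraction motors) traverse their winding in the opposite spatial sense
#' and therefore yield the opposite rotation direction from extension-motor
#' rings under the same step.
#'
#' @param state `hexamer_state` or `packing_units`.
#' @param step number of packing units to advance (default 1).
#' @param markers named marker residues (default: the units' config markers).
#' @return `rotation_inference`; marker displacements are per unit.
#' @export
pilt_mode_inference <- function(state, step = 1, markers = NULL) {
  units <- if (inherits(state, "hexamer_state")) state$units else state
  ring <- attr(units, "ring"); if (is.null(ring)) ring <- ring_axis(units)
  winding <- attr(units, "winding"); if (is.null(winding)) winding <- 1L
  if (is.null(markers)) {
    cfg <- attr(units, "config")
    markers <- if (!is.null(cfg)) cfg$markers else integer(0)
  }
  s <- (step * winding) %% 6
  m <- .stack_matched(units, units, s)
  fit <- kabsch_superpose(m$b, m$a)
  rot <- .angle_about_axis(fit$transform$rotation, ring$axis)
  md <- .marker_displacements(units, units, s, fit$transform, ring, markers)
  structure(list(subpore_rotation_deg = rot,
                 direction = if (abs(rot) < 0.5) "none"
                 else if (rot > 0) "counterclockwise" else "clockwise",
                 correspondence_shift = s,
                 alignment_rmsd = fit$rmsd,
                 thrusting_units = integer(0),
                 marker_displacements = md,
                 convention = .CONVENTION),
            class = "rotation_inference")
}
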