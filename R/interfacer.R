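# Interface quantification: solvent accessibility, buried surface area,
# polar contacts, and the open/closed classification with nucleotide labels.

# united-atom van der Waals radii by element (Angstrom); values follow the
# widely used Chothia-style table shared with the pore module
.VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
          SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
          MG = 1.73, ZN = 1.39, MN = 1.61, FE = 1.52, "NA" = 2.27, K = 2.75,
          CA = 2.31)

#' Van der Waals radius lookup
#' @param element character vector of element symbols.
#' @return numeric radii, Angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  el[el == "" | is.na(el)] <- "C"
  r <- .VDW[el]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  unname(r)
}

# deterministic quasi-uniform sphere points: Fibonacci spiral, rotated by a
# seed-derived random rotation so different seeds give different samplings
.sphere_points <- function(n, seed = 0) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  ax <- .unit(rnorm(3)); angle <- runif(1, 0, 360)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  pts %*% t(rotation_about_axis(ax, angle))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible areas by spherical sampling: each atom's expanded
#' sphere (vdW radius + probe) is covered with a deterministic quasi-uniform
#' point set and the fraction of points not buried inside any neighbour's
#' expanded sphere is converted to area.
#'
#' @param atoms atom data.frame (heavy atoms; waters should be excluded
#'   upstream).
#' @param probe_radius_A probe radius, Angstrom (default 1.4, a water).
#' @param n_sample_points points per sphere (>= 64; default 960).
#' @param seed integer controlling the sampling orientation; results are
#'   deterministic for a fixed seed.
#' @return numeric vector of per-atom areas (Angstrom^2); total SASA is its
#'   sum.
#' @export
sasa <- function(atoms, probe_radius_A = 1.4, n_sample_points = 960, seed = 0) {
  if (n_sample_points < 64) stop("n_sample_points must be >= 64")
  n <- nrow(atoms)
  if (n == 0) return(numeric(0))
  r <- vdw_radius(atoms$elesy) + probe_radius_A
  xyz <- atom_xyz(atoms)
  pts <- .sphere_points(n_sample_points, seed)
  areas <- numeric(n)
  # neighbour lists from one distance matrix; fine at hexamer scale
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (length(nb) == 0) { areas[i] <- 4 * pi * r[i]^2; next }
    p <- sweep(pts * r[i], 2, -xyz[i, ])   # sample points on sphere i
    free <- rep(TRUE, n_sample_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 > r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(free) / n_sample_points
  }
  areas
}

#' Buried surface area between two packing units
#'
#' BSA = SASA(a) + SASA(b) - SASA(a united with b): the solvent-accessible
#' area occluded by forming the contact. Waters are excluded; metals and
#' nucleotides are excluded from this protein-protein measure (they are
#' handled by ligand assignment).
#'
#' @param unit_a,unit_b `packing_unit` objects or atom data.frames.
#' @param probe_radius_A,n_sample_points,seed as in [sasa()].
#' @return buried surface area, Angstrom^2 (non-negative, symmetric).
#' @export
buried_surface_area <- function(unit_a, unit_b, probe_radius_A = 1.4,
                                n_sample_points = 960, seed = 0) {
  ga <- if (inherits(unit_a, "packing_unit")) unit_a$atoms else unit_a
  gb <- if (inherits(unit_b, "packing_unit")) unit_b$atoms else unit_b
  ga <- ga[!ga$het & ga$resid != "HOH", ]
  gb <- gb[!gb$het & gb$resid != "HOH", ]
  sa <- sum(sasa(ga, probe_radius_A, n_sample_points, seed))
  sb <- sum(sasa(gb, probe_radius_A, n_sample_points, seed))
  sab <- sum(sasa(rbind(ga, gb), probe_radius_A, n_sample_points, seed))
  max(0, sa + sb - sab)
}

#' Contact rule for interface analysis
#'
#' Cutoffs for polar and heavy-atom contacts, plus an optional list of named
#' expected contacts used purely for validation (a warning is raised when an
#' expected contact is absent; expectations never influence classification).
#' Each expectation is `c(resno_1, resno_2)` giving residue numbers on
#' packing unit 1 and 2 of a closed interface. The defaults encode the
#' landmark closed-interface contacts of PilB-family motors (T327-T411
#' backbone pairing, R455-T411, and the arginine sensors around the ASP box).
#'
#' @param polar_cutoff_A N/O-N/O distance cutoff (default 3.5 A).
#' @param heavy_cutoff_A heavy-atom cutoff for nonpolar contacts and ligand
#'   assignment (default 4.0 A).
#' @param named_expectations named list of `c(resno_1, resno_2)` pairs.
#' @return object of class `contact_rule`.
#' @export
contact_rule <- function(polar_cutoff_A = 3.5, heavy_cutoff_A = 4.0,
                         named_expectations = list(
                           T327_T411 = c(327, 411),
                           R455_T411 = c(455, 411),
                           E357_R271 = c(357, 271),
                           E357_R257 = c(357, 257),
                           H420_T411 = c(420, 411))) {
  stopifnot(polar_cutoff_A > 0, heavy_cutoff_A > 0)
  structure(list(polar_cutoff_A = polar_cutoff_A,
                 heavy_cutoff_A = heavy_cutoff_A,
                 named_expectations = named_expectations),
            class = "contact_rule")
}

#' Polar contacts across a packing-unit junction
#'
#' Enumerates all nitrogen/oxygen atom pairs across the interface within the
#' polar cutoff; optionally also other heavy-atom pairs within the heavy
#' cutoff, typed `nonpolar`.
#'
#' @param unit_a,unit_b `packing_unit` objects or atom data.frames.
#' @param rule [contact_rule()].
#' @param include_nonpolar also list non-N/O heavy-atom contacts.
#' @param dedup_residues keep only the shortest contact per residue pair.
#' @return data.frame: residue/atom identifiers on both sides, `distance_A`,
#'   `type`.
#' @export
polar_contacts <- function(unit_a, unit_b, rule = contact_rule(),
                           include_nonpolar = FALSE, dedup_residues = FALSE) {
  ga <- if (inherits(unit_a, "packing_unit")) unit_a$atoms else unit_a
  gb <- if (inherits(unit_b, "packing_unit")) unit_b$atoms else unit_b
  ga <- ga[!ga$het & ga$elesy != "H", ]
  gb <- gb[!gb$het & gb$elesy != "H", ]
  empty <- data.frame(resno_1 = integer(), resid_1 = character(),
                      atom_1 = character(), resno_2 = integer(),
                      resid_2 = character(), atom_2 = character(),
                      distance_A = numeric(), type = character())
  if (nrow(ga) == 0 || nrow(gb) == 0) return(empty)
  xa <- atom_xyz(ga); xb <- atom_xyz(gb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  cut <- max(rule$polar_cutoff_A, if (include_nonpolar) rule$heavy_cutoff_A else 0)
  hit <- which(d2 <= cut^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  dist <- sqrt(pmax(0, d2[hit]))
  polar <- ga$elesy[i] %in% c("N", "O") & gb$elesy[j] %in% c("N", "O")
  keep <- (polar & dist <= rule$polar_cutoff_A) |
    (include_nonpolar & !polar & dist <= rule$heavy_cutoff_A)
  if (!any(keep)) return(empty)
  out <- data.frame(resno_1 = ga$resno[i], resid_1 = ga$resid[i],
                    atom_1 = ga$elety[i],
                    resno_2 = gb$resno[j], resid_2 = gb$resid[j],
                    atom_2 = gb$elety[j],
                    distance_A = dist,
                    type = ifelse(polar, "polar", "nonpolar"))[keep, ]
  out <- out[order(out$distance_A), ]
  if (dedup_residues) {
    k <- paste(out$resno_1, out$resno_2)
    out <- out[!duplicated(k), ]
  }
  rownames(out) <- NULL
  out
}

#' Check named expected contacts
#'
#' Validation-only check: warns about any expectation of `rule` absent from a
#' contact list. Expectations never feed back into classification.
#'
#' @param contacts output of [polar_contacts()].
#' @param rule [contact_rule()].
#' @return named logical vector of expectations met, invisibly warns on
#'   absences.
#' @export
check_expected_contacts <- function(contacts, rule = contact_rule()) {
  found <- vapply(rule$named_expectations, function(p)
    any(contacts$resno_1 == p[1] & contacts$resno_2 == p[2]), logical(1))
  if (any(!found))
    warning("expected contacts absent: ",
            paste(names(found)[!found], collapse = ", "))
  invisible(found)
}

#' Classify a packing-unit interface as open or closed
#'
#' The decision is made on the screw rise: closed interfaces carry a
#' negative rise (they wrap down around the nucleotide), open interfaces a
#' positive one. The two populations are separated by tens of Angstroms in
#' these motors, so the rise sign is the robust discriminant; buried surface
#' area is consulted only to break ties when the rise falls within `epsilon`
#' of the threshold (with a warning).
#'
#' @param screw `screw_parameters` for the interface (computed about the
#'   oriented ring axis).
#' @param bsa_A2 buried surface area (optional unless tie-breaking).
#' @param ligand one row of [detect_ligands()] output assigned to this
#'   interface, or `NULL`.
#' @param rise_threshold_A classification threshold on rise (default 0).
#' @param epsilon_A ambiguity band around the threshold (default 1).
#' @param bsa_floor_A2 closed-interface BSA floor for tie-breaks
#'   (default 1000).
#' @return list with `state` ("closed"/"open"), `nucleotide_label`
#'   ("ADP", "AMP-PNP", "APO", or "other") and composite `label`
#'   such as "closed-ADP".
#' @export
classify_interface <- function(screw, bsa_A2 = NA, ligand = NULL,
                               rise_threshold_A = 0, epsilon_A = 1,
                               bsa_floor_A2 = 1000) {
  rise <- screw$rise_A
  if (abs(rise - rise_threshold_A) < epsilon_A && !is.na(bsa_A2)) {
    warning("rise within ", epsilon_A, " A of threshold; state decided by BSA")
    state <- if (bsa_A2 >= bsa_floor_A2) "closed" else "open"
  } else {
    state <- if (rise < rise_threshold_A) "closed" else "open"
  }
  nuc <- "APO"
  if (!is.null(ligand) && nrow(ligand) > 0) {
    lab <- ligand$ligand_code
    pick <- intersect(c("AMP-PNP", "ATP", "ATP-gamma-S", "ADP", "other"), lab)
    nuc <- if (length(pick) > 0) pick[1] else "APO"
  }
  list(state = state, nucleotide_label = nuc,
       label = paste(state, nuc, sep = "-"))
}
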