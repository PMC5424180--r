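# Two-state morphing: Cartesian linear interpolation after global alignment,
# and per-residue displacement decomposition along/about the ring axis.

# match rows of two atom tables by (mapped chain, resno, insert, atom name)
.match_atoms <- function(atoms_a, atoms_b, chain_map = NULL) {
  bchain <- atoms_b$chain
  if (!is.null(chain_map)) {
    mapped <- chain_map[bchain]
    bchain <- ifelse(is.na(mapped), bchain, mapped)
  }
  ka <- paste(atoms_a$chain, atoms_a$resno, atoms_a$insert, atoms_a$elety)
  kb <- paste(bchain, atoms_b$resno, atoms_b$insert, atoms_b$elety)
  common <- intersect(ka, kb)
  list(a = match(common, ka), b = match(common, kb),
       n_unmatched = (nrow(atoms_a) - length(common)) +
         (nrow(atoms_b) - length(common)))
}

# global C-alpha alignment of b onto a over matched atoms
.global_alignment <- function(atoms_a, atoms_b, m) {
  ca <- atoms_a$elety[m$a] == "CA" & !atoms_a$het[m$a]
  if (sum(ca) < 3) stop("fewer than 3 matched C-alpha atoms for alignment")
  kabsch_superpose(atom_xyz(atoms_b)[m$b[ca], , drop = FALSE],
                   atom_xyz(atoms_a)[m$a[ca], , drop = FALSE])
}

#' Interpolated trajectory between two states
#'
#' Linear Cartesian interpolation between matched atoms of two states of the
#' same assembly, after a global alignment of state B onto state A over all
#' matched C-alpha atoms (so the trajectory shows internal motion, not
#' whole-body drift). Endpoints are the input states exactly; intermediate
#' frames accept the usual bond-geometry distortion of Cartesian morphs.
#'
#' @param atoms_a,atoms_b atom data.frames of the two states.
#' @param chain_map named character vector mapping chains of B to chains of
#'   A (identity when `NULL`).
#' @param n_frames number of frames including both endpoints (>= 2,
#'   default 21).
#' @param align superpose B onto A first (default TRUE).
#' @return list of `n_frames` atom data.frames on the matched topology
#'   (class `trajectory`); unmatched atoms are dropped with a warning.
#' @export
interpolate_states <- function(atoms_a, atoms_b, chain_map = NULL,
                               n_frames = 21, align = TRUE) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  m <- .match_atoms(atoms_a, atoms_b, chain_map)
  if (m$n_unmatched > 0)
    warning(m$n_unmatched, " unmatched atoms excluded from the morph")
  if (length(m$a) < 3) stop("fewer than 3 matched atoms")
  xa <- atom_xyz(atoms_a)[m$a, , drop = FALSE]
  xb <- atom_xyz(atoms_b)[m$b, , drop = FALSE]
  if (align) xb <- apply_transform(.global_alignment(atoms_a, atoms_b, m)$transform, xb)
  topo <- atoms_a[m$a, ]
  frames <- lapply(seq_len(n_frames), function(i) {
    w <- (i - 1) / (n_frames - 1)
    xyz <- (1 - w) * xa + w * xb
    topo$x <- xyz[, 1]; topo$y <- xyz[, 2]; topo$z <- xyz[, 3]
    topo
  })
  structure(frames, class = "trajectory", n_frames = n_frames)
}

#' Displacement of one residue between two states
#'
#' C-alpha displacement of a residue from state A to state B (aligned onto A
#' over all matched C-alphas), decomposed along the oriented ring axis
#' ("towards the viewer" on the N2D face is positive axial) and
#' perpendicular to it.
#'
#' @param atoms_a,atoms_b atom data.frames.
#' @param chain chain id of the residue (in state A's labelling).
#' @param resno residue number.
#' @param axis oriented ring axis (unit vector).
#' @param chain_map,align as in [interpolate_states()].
#' @param atom atom name to track (default `"CA"`).
#' @return named numeric: `total_A`, `axial_A`, `tangential_A`.
#' @export
residue_displacement <- function(atoms_a, atoms_b, chain, resno, axis,
                                 chain_map = NULL, align = TRUE,
                                 atom = "CA") {
  m <- .match_atoms(atoms_a, atoms_b, chain_map)
  sel <- atoms_a$chain[m$a] == chain & atoms_a$resno[m$a] == resno &
    atoms_a$elety[m$a] == atom
  if (sum(sel) != 1)
    stop("residue ", chain, ":", resno, " ", atom,
         " not uniquely matched between states")
  xb <- atom_xyz(atoms_b)[m$b, , drop = FALSE]
  if (align) xb <- apply_transform(.global_alignment(atoms_a, atoms_b, m)$transform, xb)
  d <- as.numeric(xb[sel, ] - atom_xyz(atoms_a)[m$a[sel], ])
  n <- .unit(axis)
  ax <- sum(d * n)
  tot <- sqrt(sum(d^2))
  c(total_A = tot, axial_A = ax,
    tangential_A = sqrt(max(0, tot^2 - ax^2)))
}
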