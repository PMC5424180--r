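# Independent oracles used across the suite. These deliberately do not share
# code paths with the package implementation they check.

# Horn quaternion superposition: rotation from the largest eigenvalue of the
# 4x4 key matrix; RMSD from the eigenvalue itself
quaternion_superpose <- function(moving, fixed) {
  mc <- colMeans(moving); fc <- colMeans(fixed)
  P <- sweep(moving, 2, mc); Q <- sweep(fixed, 2, fc)
  S <- crossprod(P, Q)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]; lambda <- e$values[1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
                2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
                2 * (x * z + w * y), 2 * (y * z - w * x),
                w^2 - x^2 - y^2 + z^2), 3, 3)
  rmsd <- sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lambda)) / nrow(P))
  list(rotation = R, rmsd = rmsd)
}

# analytic accessible area of sphere 1 (radius R1) partly occluded by a
# neighbouring sphere (radius R2) at center distance d: spherical-cap formula
two_sphere_area <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  full <- 4 * pi * R1^2
  if (d >= R1 + R2) return(full)
  if (d <= abs(R1 - R2)) return(if (R1 > R2) full else 0)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  full - 2 * pi * R1 * h
}

# dense-grid oracle for the largest empty in-slice sphere: scan a 3D slice
# plane on a grid and maximise the clearance to all vdW surfaces
grid_pore_radius <- function(xyz, radii, z0, grid = 0.25, extent = 20) {
  g <- seq(-extent, extent, by = grid)
  best <- -Inf
  for (gy in g) {
    d2 <- outer(g, xyz[, 1], "-")^2 +
      matrix((gy - xyz[, 2])^2 + (z0 - xyz[, 3])^2,
             length(g), nrow(xyz), byrow = TRUE)
    cl <- apply(sweep(sqrt(d2), 2, radii), 1, min)
    best <- max(best, max(cl))
  }
  best
}

# minimal atom table builder for hand fixtures
fixture_atoms <- function(xyz, elety = "CA", elesy = "C", chain = "A",
                          resno = seq_len(nrow(xyz)), resid = "ALA",
                          het = FALSE, role = NULL) {
  xyz <- rbind(xyz)
  df <- data.frame(chain = chain, resno = resno, insert = "", resid = resid,
                   elety = elety, alt = "", elesy = elesy,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   o = 1, b = 0, het = het)
  if (!is.null(role)) df$role <- role
  df
}

# wrap a bare atom table as a packing unit
fixture_unit <- function(atoms, index = 0L, n2d = "A", ctd = "B") {
  if (is.null(atoms$role)) atoms$role <- "N2D"
  structure(list(index = index, n2d_chain = n2d, ctd_chain = ctd,
                 atoms = atoms,
                 centroid = colMeans(cbind(atoms$x, atoms$y, atoms$z))),
            class = "packing_unit")
}

random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_about_axis(ax, runif(1, 0, 360))
}
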