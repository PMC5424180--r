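# Central-channel profiling: per-slice maximal inscribed sphere radii along
# the ring axis, and detection of the two sub-pores of elongated C2 rings.
#
# Radii are reported against van der Waals surfaces (shared radius table
# with the interface module); center-to-atom-center distances are emitted
# alongside since the literature does not always state its basis.

# project atoms into the (e1, e2, n) frame of an axis through `center`
.axis_frame <- function(atoms, axis, center) {
  b <- .ring_basis(axis)
  v <- sweep(atom_xyz(atoms), 2, center)
  list(u = as.numeric(v %*% b$e1), v = as.numeric(v %*% b$e2),
       w = as.numeric(v %*% .unit(axis)), basis = b,
       r = vdw_radius(atoms$elesy))
}

# fraction of 12 angular bins occupied by atoms around a point (are we
# actually inside a channel, or off the end of the molecule?)
.angular_coverage <- function(u, v, cx, cy) {
  if (length(u) == 0) return(0)
  ang <- atan2(v - cy, u - cx)
  length(unique(floor((ang + pi) / (2 * pi) * 12) %% 12)) / 12
}

#' Pore radius profile along the ring axis
#'
#' At each axial position the largest sphere centered in the slice plane
#' that touches no van der Waals surface is found by local search of the
#' in-slice center (started from the axis and from the previous slice's
#' center). Slices where the channel is not enclosed by atoms (angular
#' coverage below `min_coverage`) are flagged open and excluded from the
#' min/max summary.
#'
#' @param atoms atom data.frame (the assembly; waters excluded internally).
#' @param axis oriented ring axis.
#' @param center point on the axis.
#' @param step_A axial slice spacing (default 1).
#' @param search_radius_A maximal in-plane distance of the pore center from
#'   the axis (default 25).
#' @param min_coverage angular coverage needed to call a slice enclosed.
#' @return data.frame of class `pore_profile` with columns `z`, `radius_A`
#'   (vdW-surface based), `radius_center_A` (to atom centers), `cx`, `cy`
#'   (in-plane center), `coverage`, `enclosed`; attributes
#'   `min_diameter_A`, `max_diameter_A`, `lining_residues`.
#' @export
pore_profile <- function(atoms, axis, center, step_A = 1,
                         search_radius_A = 25, min_coverage = 0.75) {
  stopifnot(step_A > 0)
  atoms <- atoms[atoms$resid != "HOH", ]
  f <- .axis_frame(atoms, axis, center)
  zs <- seq(min(f$w), max(f$w), by = step_A)
  prev <- c(0, 0)
  rows <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    z0 <- zs[i]
    clear <- function(p) {
      if (sqrt(sum(p^2)) > search_radius_A) return(-1e6)
      min(sqrt((f$u - p[1])^2 + (f$v - p[2])^2 + (f$w - z0)^2) - f$r)
    }
    best <- NULL
    for (start in list(prev, c(0, 0))) {
      o <- optim(start, function(p) -clear(p), method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8))
      if (is.null(best) || o$value < best$value) best <- o
    }
    cx <- best$par[1]; cy <- best$par[2]
    rad <- -best$value
    prev <- c(cx, cy)
    slab <- abs(f$w - z0) <= max(6, 2 * step_A)
    cov <- .angular_coverage(f$u[slab], f$v[slab], cx, cy)
    rc <- min(sqrt((f$u - cx)^2 + (f$v - cy)^2 + (f$w - z0)^2))
    rows[[i]] <- data.frame(z = z0, radius_A = max(0, rad),
                            radius_center_A = rc, cx = cx, cy = cy,
                            coverage = cov,
                            enclosed = cov >= min_coverage & rad > 0)
  }
  out <- do.call(rbind, rows)
  encl <- out[out$enclosed, ]
  lining <- NULL
  if (nrow(encl) > 0) {
    hit <- logical(nrow(atoms))
    for (i in seq_len(nrow(encl))) {
      d <- sqrt((f$u - encl$cx[i])^2 + (f$v - encl$cy[i])^2 +
                  (f$w - encl$z[i])^2) - f$r
      hit <- hit | d <= encl$radius_A[i] + 1.0
    }
    lining <- unique(atoms[hit & !atoms$het, c("chain", "resno", "resid")])
  }
  structure(out, class = c("pore_profile", "data.frame"),
            min_diameter_A = if (nrow(encl) > 0) 2 * min(encl$radius_A) else NA,
            max_diameter_A = if (nrow(encl) > 0) 2 * max(encl$radius_A) else NA,
            lining_residues = lining)
}

# union-find (roots are attached to roots, so chains stay shallow)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Detect the sub-pores of an elongated channel
#'
#' Projects the atoms of an axial slab onto the ring plane, computes the 2D
#' clearance field (distance to the nearest projected vdW circle) on a
#' grid, and finds up to two clearance maxima separated by a saddle: two
#' maxima count as distinct sub-pores when the best path connecting them
#' dips below `saddle_frac` of the smaller maximum. A C6-symmetric ring
#' yields a single centered pore.
#'
#' @param atoms atom data.frame.
#' @param axis,center ring axis and center.
#' @param slab axial bounds `c(lo, hi)` relative to `center` (default: full
#'   atom range).
#' @param grid_A grid resolution (default 0.5).
#' @param saddle_frac saddle criterion (default 0.8).
#' @param min_radius_A ignore maxima smaller than this (default 2).
#' @return data.frame: one row per sub-pore with in-plane center (`cx`,
#'   `cy`), 3D center (`x`, `y`, `z`), `diameter_A` (vdW-surface based) and
#'   `diameter_center_A`, ordered by decreasing diameter.
#' @export
subpore_detect <- function(atoms, axis, center, slab = NULL, grid_A = 0.5,
                           saddle_frac = 0.8, min_radius_A = 2) {
  atoms <- atoms[atoms$resid != "HOH", ]
  f <- .axis_frame(atoms, axis, center)
  if (is.null(slab)) slab <- range(f$w)
  sel <- f$w >= slab[1] & f$w <= slab[2]
  if (!any(sel)) stop("no atoms in the requested slab")
  u <- f$u[sel]; v <- f$v[sel]; r <- f$r[sel]
  gx <- seq(min(u) - 2, max(u) + 2, by = grid_A)
  gy <- seq(min(v) - 2, max(v) + 2, by = grid_A)
  nu <- length(gx); nv <- length(gy)
  clear <- matrix(Inf, nu, nv)
  for (i in seq_along(u)) {
    du2 <- (gx - u[i])^2
    dv2 <- (gy - v[i])^2
    clear <- pmin(clear, sqrt(outer(du2, dv2, "+")) - r[i])
  }
  # watershed-by-descending-value: component founders are local maxima;
  # the level at which a component merges into a higher one is the saddle
  ord <- order(clear, decreasing = TRUE)
  ord <- ord[clear[ord] > 0]
  parent <- integer(nu * nv)
  peak_val <- numeric(nu * nv)
  death <- rep(NA_real_, nu * nv)     # indexed by founder cell
  founders <- integer(0)
  active <- logical(nu * nv)
  nbr_off <- as.integer(c(-1, 1, -nu, nu, -nu - 1, -nu + 1, nu - 1, nu + 1))
  for (idx in ord) {
    ix <- (idx - 1) %% nu + 1
    nb <- idx + nbr_off
    ok <- nb >= 1 & nb <= nu * nv
    # exclude wrap-around across matrix columns
    nbx <- (nb - 1) %% nu + 1
    ok <- ok & abs(nbx - ix) <= 1
    nb <- nb[ok]
    nb <- nb[active[nb]]
    active[idx] <- TRUE
    parent[idx] <- idx
    if (length(nb) == 0) {
      peak_val[idx] <- clear[idx]
      founders <- c(founders, idx)
      next
    }
    roots <- unique(vapply(nb, function(j) .uf_find(parent, j), integer(1)))
    # attach to the highest-peak root; lower roots die at this level
    main <- roots[which.max(peak_val[roots])]
    parent[idx] <- main
    for (rt in roots) if (rt != main) {
      parent[rt] <- main
      if (is.na(death[rt])) death[rt] <- clear[idx]
    }
  }
  if (length(founders) == 0)
    return(data.frame(cx = numeric(), cy = numeric(), x = numeric(),
                      y = numeric(), z = numeric(), diameter_A = numeric(),
                      diameter_center_A = numeric()))
  fv <- clear[founders]
  keep <- founders[fv >= min_radius_A]
  fv <- clear[keep]
  keep <- keep[order(fv, decreasing = TRUE)]
  pores <- keep[1]
  for (cand in keep[-1]) {
    if (length(pores) >= 2) break
    d <- death[cand]
    if (!is.na(d) && d < saddle_frac * clear[cand]) pores <- c(pores, cand)
  }
  zmid <- mean(slab)
  rows <- lapply(pores, function(idx) {
    ix <- (idx - 1) %% nu + 1; iy <- (idx - 1) %/% nu + 1
    cx <- gx[ix]; cy <- gy[iy]
    cov <- .angular_coverage(u, v, cx, cy)
    if (cov < 0.75) return(NULL)
    p3 <- center + cx * f$basis$e1 + cy * f$basis$e2 + zmid * .unit(axis)
    data.frame(cx = cx, cy = cy, x = p3[1], y = p3[2], z = p3[3],
               diameter_A = 2 * clear[idx],
               diameter_center_A = 2 * min(sqrt((u - cx)^2 + (v - cy)^2)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(cx = numeric(), cy = numeric(), x = numeric(),
                      y = numeric(), z = numeric(), diameter_A = numeric(),
                      diameter_center_A = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
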