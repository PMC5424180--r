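# Structure input/output and packing-unit assembly.
#
# Atoms travel through the package as a plain data.frame with columns
#   chain, resno, insert, resid, elety, alt, elesy, x, y, z, o, b, het
# (author residue numbering as deposited; `het` flags HETATM records).
# bio3d does the PDB/mmCIF parsing and PDB writing; this module only applies
# the altloc policy, carves domains, and does the packing-unit bookkeeping.

.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "alt",
                "elesy", "x", "y", "z", "o", "b", "het")

.as_atoms <- function(df) {
  for (col in .ATOM_COLS) if (is.null(df[[col]])) df[[col]] <- NA
  df$chain <- ifelse(is.na(df$chain), " ", as.character(df$chain))
  df$insert <- ifelse(is.na(df$insert), "", as.character(df$insert))
  df$alt <- ifelse(is.na(df$alt), "", as.character(df$alt))
  df$o <- ifelse(is.na(df$o), 1, df$o)
  df$b <- ifelse(is.na(df$b), 0, df$b)
  df$het <- as.logical(df$het)
  rownames(df) <- NULL
  df[, .ATOM_COLS]
}

.atoms_from_bio3d <- function(pdb) {
  a <- pdb$atom
  a$het <- a$type == "HETATM"
  .as_atoms(a)
}

#' Coordinate matrix of an atom table
#' @param atoms atom data.frame.
#' @return n x 3 numeric matrix.
#' @export
atom_xyz <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

# Altloc policy: keep the highest-occupancy conformer of each
# (chain, residue, atom) site; ties broken towards altloc 'A' (alphabetical).
.apply_altloc_policy <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "|")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(key[ord]), ]
  atoms[order(atoms$het, atoms$chain, atoms$resno), ]
}

#' Read a macromolecular structure
#'
#' Reads a PDB or mmCIF file into the package's atom table, applying the
#' altloc policy (highest occupancy kept, ties towards 'A'). Hetero records
#' are retained and flagged with `het = TRUE`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return atom data.frame (see package docs for columns).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("parse error reading ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  atoms <- .apply_altloc_policy(.atoms_from_bio3d(pdb))
  if (!any(!atoms$het)) stop("no protein chains in ", path)
  attr(atoms, "source") <- path
  atoms
}

#' Write an atom table as a PDB file
#' @param atoms atom data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(atom_xyz(atoms))),
                   type = ifelse(atoms$het, "HETATM", "ATOM"),
                   resno = atoms$resno,
                   resid = atoms$resid,
                   elety = atoms$elety,
                   chain = ifelse(atoms$chain == " ", NA, atoms$chain),
                   insert = ifelse(atoms$insert == "", NA, atoms$insert),
                   alt = ifelse(atoms$alt == "", NA, atoms$alt),
                   o = atoms$o, b = atoms$b, elesy = atoms$elesy)
  invisible(path)
}

#' Write a multi-model PDB trajectory
#' @param frames list of atom data.frames sharing one topology.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(frames)) {
    write_structure(frames[[i]], tmp)
    lines <- readLines(tmp)
    lines <- lines[!grepl("^END", lines)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Expand a deposited assembly using its crystallographic operators
#'
#' Applies the REMARK 350 biological-assembly operators of a PDB file (via
#' bio3d) and returns the expanded assembly with the most chains. Structures
#' whose hexamer lives in the crystal packing (three chains per asymmetric
#' unit) are expanded to six chains this way; files without operators are
#' returned as read, so such inputs must be pre-expanded upstream.
#'
#' @param path PDB file path.
#' @return atom data.frame, with the applied operator count in
#'   attribute `n_operators`.
#' @export
expand_assembly <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("parse error reading ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  units <- tryCatch(suppressWarnings(bio3d::biounit(pdb)),
                    error = function(e) NULL)
  if (is.null(units) || length(units) == 0) {
    atoms <- .apply_altloc_policy(.atoms_from_bio3d(pdb))
    attr(atoms, "n_operators") <- 1L
    return(atoms)
  }
  nch <- vapply(units, function(u) length(unique(u$atom$chain)), integer(1))
  best <- units[[which.max(nch)]]
  atoms <- .apply_altloc_policy(.atoms_from_bio3d(best))
  attr(atoms, "n_operators") <- max(nch) / length(unique(pdb$atom$chain))
  atoms
}

#' Domain configuration for a two-domain motor ATPase chain
#'
#' Residue intervals (author numbering, inclusive) for the second N-terminal
#' domain (N2D), the C-terminal domain (CTD) and the flexible linker joining
#' them, plus named marker residues tracked by the displacement analysis.
#' Defaults describe Geobacter metallireducens PilB: N2D 181-288, linker
#' 289-295, CTD 296-568, with the conserved pore residue E400 and the
#' catalytic glutamate E395 as markers. For PilT-family chains supply the
#' equivalents (e.g. E222, and N260 at the midpoint of the pore-loop-3
#' extension).
#'
#' @param n2d,ctd,linker inclusive residue intervals `c(first, last)`.
#' @param markers named integer vector of marker residue numbers.
#' @return object of class `domain_config`.
#' @export
domain_config <- function(n2d = c(181, 288), ctd = c(296, 568),
                          linker = c(289, 295),
                          markers = c(pore_e400 = 400, catalytic_glu = 395)) {
  stopifnot(length(n2d) == 2, length(ctd) == 2, length(linker) == 2)
  iv <- list(n2d = n2d, linker = linker, ctd = ctd)
  for (v in iv) if (v[1] > v[2]) stop("interval reversed: ", v[1], "-", v[2])
  if (!(n2d[2] < linker[1] && linker[2] < ctd[1]))
    stop("intervals must be disjoint and ordered n2d < linker < ctd")
  structure(list(n2d = as.integer(n2d), ctd = as.integer(ctd),
                 linker = as.integer(linker), markers = markers),
            class = "domain_config")
}

.in_range <- function(x, range) x >= range[1] & x <= range[2]

# contact-based adjacency inference: the ring-adjacent partner of chain c is
# the chain whose CTD C-alphas lie closest to c's N2D C-alphas
.infer_adjacency <- function(atoms, config, chains) {
  ca <- atoms[!atoms$het & atoms$elety == "CA", ]
  score <- function(c1, c2) {
    a <- ca[ca$chain == c1 & .in_range(ca$resno, config$n2d), ]
    b <- ca[ca$chain == c2 & .in_range(ca$resno, config$ctd), ]
    if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
    d2 <- outer(rowSums(atom_xyz(a)^2), rowSums(atom_xyz(b)^2), "+") -
      2 * atom_xyz(a) %*% t(atom_xyz(b))
    mean(sort(sqrt(pmax(d2, 0)))[seq_len(min(25, length(d2)))])
  }
  nxt <- vapply(chains, function(c1) {
    others <- setdiff(chains, c1)
    others[which.min(vapply(others, function(c2) score(c1, c2), numeric(1)))]
  }, character(1))
  cycle <- chains[1]
  for (i in seq_len(length(chains) - 1)) {
    nx <- nxt[[cycle[length(cycle)]]]
    if (nx %in% cycle) stop("chain adjacency does not form a single cycle")
    cycle <- c(cycle, nx)
  }
  if (nxt[[cycle[length(cycle)]]] != cycle[1])
    stop("chain adjacency does not close into a cycle")
  cycle
}

#' Assemble the six packing units of a hexamer
#'
#' Packing unit k is the N2D of chain `adjacency[k]` together with the CTD of
#' chain `adjacency[k+1]` (cyclic): the rigid "bead" of the
#' beads-on-a-string description of these hexamers. Units are returned
#' ordered counterclockwise about the ring axis as seen from the N2D face;
#' if the supplied adjacency cycle runs clockwise the output is re-oriented
#' and the `winding` attribute records `-1`.
#'
#' @param atoms atom data.frame of a six-chain assembly.
#' @param config [domain_config()].
#' @param adjacency ordered chain cycle (character vector of 6), or `NULL`
#'   to infer it from N2D/CTD contacts.
#' @return list of 6 `packing_unit` objects with attributes `adjacency`,
#'   `winding` (+1 counterclockwise handoff, -1 clockwise), `linker_atoms`
#'   and `ring` (axis + center).
#' @export
build_packing_units <- function(atoms, config = domain_config(),
                                adjacency = NULL) {
  prot <- atoms[!atoms$het, ]
  chains <- unique(prot$chain)
  if (length(chains) != 6)
    stop("need six protein chains, found ", length(chains),
         " (expand the assembly first)")
  missing <- lapply(chains, function(c) {
    res <- prot$resno[prot$chain == c]
    c(if (!any(.in_range(res, config$n2d))) "N2D" else NULL,
      if (!any(.in_range(res, config$ctd))) "CTD" else NULL)
  })
  bad <- lengths(missing) > 0
  if (any(bad))
    stop("incomplete domains: ",
         paste(sprintf("chain %s lacks %s", chains[bad],
                       vapply(missing[bad], paste, "", collapse = "+")),
               collapse = "; "))
  if (is.null(adjacency)) adjacency <- .infer_adjacency(atoms, config, chains)
  if (!setequal(adjacency, chains) || length(adjacency) != 6)
    stop("adjacency must be a cyclic permutation of the six chain ids")

  unit_of <- function(k) {
    cn <- adjacency[k]
    cc <- adjacency[(k %% 6) + 1]
    n2d <- prot[prot$chain == cn & .in_range(prot$resno, config$n2d), ]
    ctd <- prot[prot$chain == cc & .in_range(prot$resno, config$ctd), ]
    n2d$role <- "N2D"; ctd$role <- "CTD"
    a <- rbind(n2d, ctd)
    structure(list(index = k - 1L, n2d_chain = cn, ctd_chain = cc, atoms = a,
                   centroid = colMeans(atom_xyz(a))),
              class = "packing_unit")
  }
  units <- lapply(1:6, unit_of)

  ring <- ring_axis(units)
  # angular positions about the oriented axis
  ang <- vapply(units, function(u) {
    v <- u$centroid - ring$center
    b <- .ring_basis(ring$axis)
    atan2(sum(v * b$e2), sum(v * b$e1))
  }, numeric(1))
  # winding of the adjacency handoff: sign of the summed signed angular steps
  d <- diff(ang[c(1:6, 1)])
  d <- (d + pi) %% (2 * pi) - pi
  winding <- ifelse(sum(d) > 0, 1L, -1L)
  order_ccw <- order(((ang - ang[1]) %% (2 * pi)))
  units <- units[order_ccw]
  for (k in 1:6) units[[k]]$index <- k - 1L
  linker <- prot[.in_range(prot$resno, config$linker), ]
  structure(units, class = "packing_units",
            adjacency = adjacency, winding = winding,
            linker_atoms = linker, ring = ring, config = config)
}

# nucleotide / ligand residue-name vocabulary
.NUCLEOTIDES <- c(ADP = "ADP", ANP = "AMP-PNP", ATP = "ATP", AGS = "ATP-gamma-S",
                  ADX = "ADP")
.METALS <- c("MG", "ZN", "MN", "CA", "NA", "K")
.BUFFER <- c("FMT", "GOL", "EDO", "PEG", "MPD", "SO4", "PO4", "ACT", "CL")

#' Locate bound ligands and assign them to interfaces
#'
#' Groups hetero records (waters excluded) into ligand sites and assigns each
#' site to the packing-unit junction whose two flanking units both lie within
#' the heavy-atom contact cutoff, choosing among candidate pairs by the
#' smallest summed minimum distance. Interface k joins units k and k+1
#' (cyclic, counterclockwise order).
#'
#' @param atoms atom data.frame.
#' @param units `packing_units` from [build_packing_units()].
#' @param heavy_cutoff_A heavy-atom contact cutoff, Angstrom (default 4).
#' @return data.frame with one row per ligand site: `ligand_code`, `resid`,
#'   `chain`, `resno`, `n_atoms`, `occupancy`, `interface` (0-5 or `NA` when
#'   unassignable) and the two flanking minimum distances.
#' @export
detect_ligands <- function(atoms, units, heavy_cutoff_A = 4.0) {
  het <- atoms[atoms$het & atoms$resid != "HOH", ]
  if (nrow(het) == 0)
    return(data.frame(ligand_code = character(), resid = character(),
                      chain = character(), resno = integer(),
                      n_atoms = integer(), occupancy = numeric(),
                      interface = integer(), d_unit1 = numeric(),
                      d_unit2 = numeric()))
  key <- paste(het$chain, het$resno, het$resid)
  groups <- split(het, factor(key, levels = unique(key)))
  uxyz <- lapply(units, function(u) atom_xyz(u$atoms))
  rows <- lapply(groups, function(g) {
    g_xyz <- atom_xyz(g)
    dmin <- vapply(uxyz, function(x) {
      d2 <- outer(rowSums(g_xyz^2), rowSums(x^2), "+") - 2 * g_xyz %*% t(x)
      sqrt(max(0, min(d2)))
    }, numeric(1))
    pair_score <- vapply(1:6, function(k) dmin[k] + dmin[(k %% 6) + 1],
                         numeric(1))
    feasible <- vapply(1:6, function(k)
      dmin[k] <= heavy_cutoff_A && dmin[(k %% 6) + 1] <= heavy_cutoff_A,
      logical(1))
    iface <- if (any(feasible)) {
      cand <- which(feasible)
      cand[which.min(pair_score[cand])] - 1L
    } else NA_integer_
    code <- if (g$resid[1] %in% names(.NUCLEOTIDES)) .NUCLEOTIDES[[g$resid[1]]]
    else if (g$resid[1] %in% .METALS) g$resid[1]
    else if (g$resid[1] %in% .BUFFER) g$resid[1]
    else "other"
    data.frame(ligand_code = code, resid = g$resid[1], chain = g$chain[1],
               resno = g$resno[1], n_atoms = nrow(g),
               occupancy = mean(g$o), interface = iface,
               d_unit1 = if (is.na(iface)) NA_real_ else dmin[iface + 1],
               d_unit2 = if (is.na(iface)) NA_real_ else dmin[(iface + 1) %% 6 + 1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.packing_unit <- function(x, ...) {
  cat(sprintf("packing unit %d: N2D(chain %s) + CTD(chain %s), %d atoms\n",
              x$index, x$n2d_chain, x$ctd_chain, nrow(x$atoms)))
  invisible(x)
}

#' @export
print.packing_units <- function(x, ...) {
  cat("hexamer of 6 packing units; adjacency ",
      paste(attr(x, "adjacency"), collapse = "->"),
      sprintf(" (winding %+d)\n", attr(x, "winding")))
  for (u in x) print(u)
  invisible(x)
}
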