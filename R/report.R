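# Orchestration and report assembly: the high-level entry points that a
# shell wrapper (inst/scripts/hexscrew-cli.R) exposes as `analyze`,
# `compare` and `synth` subcommands.

.PKG_VERSION <- function()
  as.character(utils::packageVersion("hexscrew"))

#' Full geometric analysis of one hexamer
#'
#' Runs the whole single-state pipeline: packing-unit assembly, ligand
#' detection, per-interface screws/BSA/contacts with open/closed
#' classification, the ring-closure ledger with pucker, and (optionally)
#' the pore profile and sub-pore detection.
#'
#' @param input path to a PDB/mmCIF file, or an atom data.frame.
#' @param config [domain_config()].
#' @param adjacency chain cycle or `NULL` to infer.
#' @param expand apply deposited assembly operators when reading from a
#'   file with fewer than six chains.
#' @param compute_bsa compute buried surface areas (slower; default FALSE).
#' @param pore run pore profiling (default TRUE).
#' @param rule [contact_rule()].
#' @param seed seed for area sampling.
#' @return object of class `hexamer_state`: `atoms`, `units`, `ligands`,
#'   `interfaces`, `ledger`, `pore`, `subpores`, `meta`.
#' @export
analyze_hexamer <- function(input, config = domain_config(),
                            adjacency = NULL, expand = TRUE,
                            compute_bsa = FALSE, pore = TRUE,
                            rule = contact_rule(), seed = 0) {
  atoms <- if (is.character(input)) {
    a <- read_structure(input)
    if (length(unique(a$chain[!a$het])) < 6 && expand) expand_assembly(input)
    else a
  } else input
  units <- build_packing_units(atoms, config, adjacency)
  ring <- attr(units, "ring")
  ligands <- detect_ligands(atoms, units)
  interfaces <- analyze_interfaces(units, ligands, rule,
                                   compute_bsa = compute_bsa, seed = seed)
  ledger <- build_ledger(interfaces)
  prof <- subp <- NULL
  if (pore) {
    prof <- pore_profile(atoms[!atoms$het, ], ring$axis, ring$center)
    encl <- prof[prof$enclosed, ]
    slab <- if (nrow(encl) > 0)
      range(encl$z) + c(-3, 3) else NULL
    subp <- subpore_detect(atoms[!atoms$het, ], ring$axis, ring$center,
                           slab = slab)
  }
  structure(list(atoms = atoms, units = units, ligands = ligands,
                 interfaces = interfaces, ledger = ledger,
                 pore = prof, subpores = subp,
                 meta = list(version = .PKG_VERSION(), seed = seed,
                             adjacency = attr(units, "adjacency"),
                             winding = attr(units, "winding"),
                             convention = .CONVENTION,
                             source = attr(atoms, "source"))),
            class = "hexamer_state")
}

#' @export
print.hexamer_state <- function(x, ...) {
  cat("hexamer state (", x$meta$convention, ")\n", sep = "")
  print(x$ledger)
  if (!is.null(x$pore))
    cat(sprintf("  pore: min diameter %.1f A, max %.1f A; %d sub-pore(s)\n",
                attr(x$pore, "min_diameter_A"), attr(x$pore, "max_diameter_A"),
                if (is.null(x$subpores)) 0L else nrow(x$subpores)))
  invisible(x)
}

#' Compare two hexamer states
#'
#' Rotation inference plus an interpolated trajectory between two analyzed
#' states (sub-pore centers from the pore module are used when both states
#' have them, otherwise the elongation-phase fallback).
#'
#' @param state_a,state_b `hexamer_state` objects.
#' @param correspondence cyclic shift or `NULL` to search.
#' @param n_frames trajectory frames (default 21).
#' @return list of class `two_state_comparison`: `rotation`
#'   (a `rotation_inference`), `trajectory`, `displacements` (all marker
#'   residues).
#' @export
compare_hexamers <- function(state_a, state_b, correspondence = NULL,
                             n_frames = 21) {
  sp_a <- if (!is.null(state_a$subpores) && nrow(state_a$subpores) == 2)
    as.matrix(state_a$subpores[, c("x", "y", "z")]) else NULL
  sp_b <- if (!is.null(state_b$subpores) && nrow(state_b$subpores) == 2)
    as.matrix(state_b$subpores[, c("x", "y", "z")]) else NULL
  rot <- infer_rotation(state_a, state_b, correspondence,
                        subpores_a = sp_a, subpores_b = sp_b)
  traj <- interpolate_states(state_a$atoms, state_b$atoms,
                             n_frames = n_frames)
  structure(list(rotation = rot, trajectory = traj,
                 displacements = rot$marker_displacements,
                 meta = list(version = .PKG_VERSION(),
                             convention = .CONVENTION)),
            class = "two_state_comparison")
}

#' Write analysis reports to files
#'
#' Writes the machine-readable outputs of [analyze_hexamer()]: a JSON
#' manifest (units, ligands, ledger, sub-pores, metadata including seed and
#' the sign convention), a per-interface TSV, and the pore-profile TSV.
#'
#' @param state `hexamer_state`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_report <- function(state, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iface_df <- do.call(rbind, lapply(state$interfaces, function(i)
    data.frame(index = i$index, label = i$label, state = i$state,
               nucleotide = i$nucleotide_label, bsa_A2 = i$bsa_A2,
               twist_deg = i$screw$twist_deg,
               twist_signed_deg = i$screw$twist_signed_deg,
               rise_A = i$screw$rise_A,
               local_rise_A = i$screw$local_rise_A,
               axis_x = i$screw$axis_direction[1],
               axis_y = i$screw$axis_direction[2],
               axis_z = i$screw$axis_direction[3],
               n_contacts = if (is.null(i$contacts)) NA_integer_
               else nrow(i$contacts))))
  tsv <- file.path(dir, "interfaces.tsv")
  write.table(iface_df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    meta = state$meta,
    ledger = list(net_rise_A = state$ledger$net_rise_A,
                  net_twist_deg = state$ledger$net_twist_deg,
                  closure_residual = state$ledger$closure_residual,
                  pucker_amplitude_A = state$ledger$pucker_amplitude_A,
                  shape_class = state$ledger$shape_class,
                  c2_pattern = state$ledger$c2_pattern),
    interfaces = iface_df,
    units = lapply(state$units, function(u)
      list(index = u$index, n2d_chain = u$n2d_chain,
           ctd_chain = u$ctd_chain, n_atoms = nrow(u$atoms))),
    ligands = state$ligands,
    subpores = state$subpores,
    pore = if (!is.null(state$pore))
      list(min_diameter_A = attr(state$pore, "min_diameter_A"),
           max_diameter_A = attr(state$pore, "max_diameter_A")))
  js <- file.path(dir, "report.json")
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  pp <- NULL
  if (!is.null(state$pore)) {
    pp <- file.path(dir, "pore_profile.tsv")
    write.table(as.data.frame(state$pore), pp, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(json = js, interfaces = tsv, pore = pp))
}

#' Write a synthetic fixture to disk
#'
#' Builds a synthetic hexamer from a [synth_spec()] and writes the PDB file
#' plus a JSON ground-truth sidecar. Deterministic: the same spec yields
#' byte-identical output.
#'
#' @param spec `synth_spec`.
#' @param dir output directory.
#' @param name basename for the files (default "synthetic_hexamer").
#' @return named vector of file paths, invisibly.
#' @export
write_synthetic_hexamer <- function(spec = synth_spec(), dir,
                                    name = "synthetic_hexamer") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asm <- build_screw_assembly(spec)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  write_structure(asm$atoms, pdb)
  side <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(c(asm$ground_truth,
                         list(spec = unclass(spec))), side,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(pdb = pdb, ground_truth = side))
}

#' Per-chain C-alpha RMSD between two hexamers under a residue map
#'
#' Cross-protein comparison (e.g. against a related secretion-system
#' ATPase) requires an explicit residue correspondence; given one, this
#' superposes each mapped chain pair and reports the C-alpha RMSD per chain
#' and over the whole assembly.
#'
#' @param atoms_a,atoms_b atom data.frames.
#' @param residue_map data.frame with columns `resno_a`, `resno_b`.
#' @param chain_map named vector mapping chains of B to chains of A
#'   (identity if `NULL`).
#' @return list with `per_chain` (named RMSDs) and `overall`.
#' @export
rmsd_per_chain <- function(atoms_a, atoms_b, residue_map, chain_map = NULL) {
  ca_a <- atoms_a[atoms_a$elety == "CA" & !atoms_a$het, ]
  ca_b <- atoms_b[atoms_b$elety == "CA" & !atoms_b$het, ]
  if (!is.null(chain_map)) {
    mapped <- chain_map[ca_b$chain]
    ca_b$chain <- ifelse(is.na(mapped), ca_b$chain, mapped)
  }
  chains <- intersect(unique(ca_a$chain), unique(ca_b$chain))
  per <- sapply(chains, function(ch) {
    a <- ca_a[ca_a$chain == ch, ]; b <- ca_b[ca_b$chain == ch, ]
    ia <- match(residue_map$resno_a, a$resno)
    ib <- match(residue_map$resno_b, b$resno)
    ok <- !is.na(ia) & !is.na(ib)
    if (sum(ok) < 3) return(NA_real_)
    kabsch_superpose(atom_xyz(b)[ib[ok], ], atom_xyz(a)[ia[ok], ])$rmsd
  })
  # whole-assembly superposition over all mapped pairs
  all_a <- list(); all_b <- list()
  for (ch in chains) {
    a <- ca_a[ca_a$chain == ch, ]; b <- ca_b[ca_b$chain == ch, ]
    ia <- match(residue_map$resno_a, a$resno)
    ib <- match(residue_map$resno_b, b$resno)
    ok <- !is.na(ia) & !is.na(ib)
    all_a[[ch]] <- atom_xyz(a)[ia[ok], , drop = FALSE]
    all_b[[ch]] <- atom_xyz(b)[ib[ok], , drop = FALSE]
  }
  overall <- kabsch_superpose(do.call(rbind, all_b),
                              do.call(rbind, all_a))$rmsd
  list(per_chain = per, overall = overall)
}
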