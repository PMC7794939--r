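# PDB reading/writing sits on bio3d; this file adds the validation layer
# (line-level format checks, residue-key invariants, model consistency) and
# the conversion into pharmflow's protein/molecule/trajectory types.

# covalent radii (Angstrom) for distance-based bond perception of HETATM ligands
COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
               S = 1.05, CL = 1.02, BR = 1.20, I = 1.39)

# coordinate fields of ATOM/HETATM records must parse as numbers
check_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")
  for (ln in which(rec)) {
    line <- lines[ln]
    if (nchar(line) < 54)
      stop("malformed ATOM/HETATM record at line ", ln, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                         substr(line, 39, 46),
                                         substr(line, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM/HETATM record at line ", ln, ": bad coordinates")
  }
  invisible(TRUE)
}

bio3d_to_atoms <- function(at) {
  el <- at$elesy
  if (is.null(el) || all(is.na(el) | el == "")) {
    # fall back to first letter(s) of the atom name
    el <- sub("^[0-9]*", "", at$elety)
    el <- ifelse(substr(el, 1, 2) %in% c("CL", "Cl", "BR", "Br"),
                 substr(el, 1, 2), substr(el, 1, 1))
  }
  data.frame(type = at$type,
             chain = ifelse(is.na(at$chain), "A", at$chain),
             resno = at$resno,
             insert = ifelse(is.na(at$insert), "", at$insert),
             resname = at$resid,
             name = at$elety,
             element = toupper(el),
             x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

# bonds between heavy/any atoms whose distance is below 1.25 * sum of
# covalent radii (all single order; PDB carries no bond orders)
infer_bonds <- function(elements, coords) {
  n <- length(elements)
  if (n < 2L) return(NULL)
  el <- toupper(elements)
  r <- COV_RADII[el]
  r[is.na(r)] <- 0.77
  out <- list()
  for (i in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(coords[(i + 1L):n, , drop = FALSE]) - coords[i, ])^2))
    hit <- which(d < 1.25 * (r[i] + r[(i + 1L):n]) & d > 0.4)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(i = i, j = i + hit, order = "1",
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

#' Read a protein structure (and optionally a bound ligand) from a PDB file
#'
#' @param path PDB file.
#' @param ligand_resname optional HETATM residue name; matching atoms are
#'   extracted as a bound `molecule` (bonds inferred from interatomic
#'   distances, all single order) instead of being kept in the protein.
#' @return with `ligand_resname = NULL`, a `protein`; otherwise a list
#'   `list(protein, ligand)`.
#' @details Waters (HOH/WAT) are flagged via [is_water()]. Alternate
#'   locations other than 'A'/blank are dropped; occupancy and B-factor are
#'   ignored. Hydrogens are preserved when present. Malformed ATOM/HETATM
#'   records raise an error naming the offending line.
#' @export
read_pdb <- function(path, ligand_resname = NULL) {
  check_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)
  atoms <- bio3d_to_atoms(pdb$atom)
  lig <- NULL
  if (!is.null(ligand_resname)) {
    m <- atoms$resname == toupper(ligand_resname)
    if (!any(m)) stop("no atoms with residue name '", ligand_resname, "' in ", path)
    lig_at <- atoms[m, , drop = FALSE]
    coords <- unname(as.matrix(lig_at[, c("x", "y", "z")]))
    lig <- molecule(ligand_resname, lig_at$element, coords,
                    infer_bonds(lig_at$element, coords))
    atoms <- atoms[!m, , drop = FALSE]
  }
  prot <- protein_structure(atoms)
  if (is.null(lig)) prot else list(protein = prot, ligand = lig)
}

# assemble per-atom vectors for bio3d::write.pdb from a protein + optional ligand
complex_atom_table <- function(protein, ligand = NULL, ligand_resname = "LIG",
                               ligand_resno = 900L) {
  at <- protein$atoms
  tab <- data.frame(type = at$type, chain = at$chain, resno = at$resno,
                    insert = at$insert, resname = at$resname, name = at$name,
                    element = at$element, x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  if (!is.null(ligand)) {
    xyz <- conformer_coords(ligand, 1L)
    el <- ligand$atoms$element
    tab <- rbind(tab, data.frame(
      type = "HETATM", chain = "Z", resno = ligand_resno, insert = "",
      resname = toupper(ligand_resname),
      name = paste0(toupper(el), seq_along(el)),
      element = toupper(el), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE))
  }
  tab
}

write_pdb_tab <- function(tab, file) {
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(as.matrix(tab[, c("x", "y", "z")]))),
                   type = tab$type, resno = tab$resno, resid = tab$resname,
                   insert = ifelse(tab$insert == "", NA, tab$insert),
                   chain = tab$chain, eleno = seq_len(nrow(tab)),
                   elety = tab$name, elesy = tab$element)
}

#' Write a protein (and optionally a posed ligand) to a PDB file
#'
#' @param protein a `protein`.
#' @param path output file.
#' @param ligand optional `molecule` in the receptor frame, written as
#'   HETATM records with residue name `ligand_resname` on chain Z.
#' @param ligand_resname residue name for the ligand records.
#' @return invisibly, the path.
#' @export
write_pdb <- function(protein, path, ligand = NULL, ligand_resname = "LIG") {
  write_pdb_tab(complex_atom_table(protein, ligand, ligand_resname), path)
  invisible(path)
}

# counts ATOM/HETATM lines per MODEL block; errors name the offending model
scan_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(NULL)
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
  counts <- mapply(function(s, e)
    sum(substr(lines[s:e], 1, 6) %in% c("ATOM  ", "HETATM")), starts, ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop("model ", bad, " has ", counts[bad], " atoms; model 1 has ", counts[1])
  }
  length(starts)
}

#' Read a multi-model PDB trajectory of a protein-ligand complex
#'
#' @param path multi-model PDB file (MODEL/ENDMDL records), frames ordered by
#'   MODEL number. The first model defines the topology.
#' @param ligand_resname residue name identifying the ligand HETATM group.
#' @param frame_interval optional time between frames in ns.
#' @return a `trajectory` with protein atoms first, ligand atoms last.
#' @details Every model must carry the same atom count; a mismatch raises an
#'   error naming the offending model. Ligand bonds are inferred from
#'   first-frame distances.
#' @export
read_trajectory <- function(path, ligand_resname = "LIG", frame_interval = NULL) {
  lines <- readLines(path, warn = FALSE)
  check_pdb_lines(lines)
  nmod <- scan_models(lines)
  if (is.null(nmod) || nmod < 2L)
    stop("trajectory file must contain at least 2 MODEL records")
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  atoms <- bio3d_to_atoms(pdb$atom)
  m <- atoms$resname == toupper(ligand_resname)
  if (!any(m)) stop("no ligand atoms with residue name '", ligand_resname, "'")
  xyz <- pdb$xyz  # nframes x 3N, model-1 order
  ord <- c(which(!m), which(m))
  frames <- lapply(seq_len(nrow(xyz)), function(k) {
    f <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    f[ord, , drop = FALSE]
  })
  lig_at <- atoms[m, , drop = FALSE]
  coords0 <- frames[[1]][nrow(atoms) - sum(m) + seq_len(sum(m)), , drop = FALSE]
  lig <- molecule(ligand_resname, lig_at$element, coords0,
                  infer_bonds(lig_at$element, coords0))
  prot <- protein_structure(atoms[!m, , drop = FALSE])
  prot <- set_protein_coords(prot, frames[[1]][seq_len(sum(!m)), , drop = FALSE])
  trajectory(prot, lig, frames, frame_interval = frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param ligand_resname residue name for the ligand records.
#' @return invisibly, the path.
#' @export
write_trajectory <- function(traj, path, ligand_resname = "LIG") {
  tab <- complex_atom_table(traj$protein, traj$ligand, ligand_resname)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (k in seq_len(n_frames(traj))) {
    f <- traj$frames[[k]]
    tab$x <- f[, 1]; tab$y <- f[, 2]; tab$z <- f[, 3]
    write_pdb_tab(tab, tmp)
    body <- readLines(tmp, warn = FALSE)
    body <- body[substr(body, 1, 6) %in% c("ATOM  ", "HETATM", "TER   ")]
    writeLines(c(sprintf("MODEL     %4d", k), body, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}
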