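#' Construct a protein structure
#'
#' Flat atom-table representation of a (prepared) protein, including
#' crystallographic waters and any other HETATM groups. Coordinates are in
#' Angstrom; occupancy/B-factor are not carried.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resname`,
#'   `name` (atom name), `element`, `x`, `y`, `z`, and optionally `type`
#'   ("ATOM"/"HETATM", defaults to "ATOM").
#'
#' @return object of class `"protein"`: list with `atoms` (the validated
#'   table) plus a `key` column (chain/resno/insert residue key).
#'
#' @details Invariants enforced: each residue key (chain, residue number,
#'   insertion code) maps to exactly one residue name, and every water
#'   residue (HOH/WAT) contains exactly one oxygen atom.
#' @export
protein_structure <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resname", "name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("protein atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resname <- toupper(as.character(atoms$resname))
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  atoms$key <- paste0(atoms$chain, atoms$resno, atoms$insert)

  # one residue name per key
  tab <- unique(atoms[, c("key", "resname")])
  if (anyDuplicated(tab$key)) {
    bad <- tab$key[duplicated(tab$key)][1]
    stop("duplicate residue key '", bad, "' with conflicting residue names")
  }
  # every water has exactly one oxygen
  wat <- atoms[atoms$resname %in% c("HOH", "WAT"), , drop = FALSE]
  if (nrow(wat)) {
    n_o <- tapply(toupper(wat$element) == "O", wat$key, sum)
    if (any(n_o != 1L))
      stop("water residue '", names(n_o)[n_o != 1L][1], "' must contain exactly one oxygen")
  }
  structure(list(atoms = atoms), class = "protein")
}

#' @export
print.protein <- function(x, ...) {
  cat("<protein>", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$key)), "residues,",
      length(unique(x$atoms$key[is_water(x)])), "waters\n")
  invisible(x)
}

#' Water mask over protein atoms
#' @param protein a `protein`.
#' @return logical vector over atoms, TRUE for atoms in HOH/WAT residues.
#' @export
is_water <- function(protein) protein$atoms$resname %in% c("HOH", "WAT")

#' Protein coordinates as a matrix
#' @param protein a `protein`.
#' @return n x 3 coordinate matrix (Angstrom).
#' @export
protein_coords <- function(protein)
  unname(as.matrix(protein$atoms[, c("x", "y", "z")]))

#' Replace protein coordinates
#' @param protein a `protein`.
#' @param coords n x 3 matrix over the same atoms.
#' @return the modified protein.
#' @export
set_protein_coords <- function(protein, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(protein$atoms) || ncol(coords) != 3L)
    stop("coordinate matrix must be ", nrow(protein$atoms), " x 3")
  protein$atoms$x <- coords[, 1]; protein$atoms$y <- coords[, 2]; protein$atoms$z <- coords[, 3]
  protein
}

#' Residue/atom selector
#'
#' Names one residue (and optionally one atom within it) of a protein
#' structure, e.g. the backbone nitrogen of Ala51 on chain A.
#'
#' @param chain chain identifier.
#' @param resno residue number.
#' @param resname optional residue-name check (e.g. "ALA").
#' @param atom optional atom name (e.g. "N").
#' @param insert insertion code (default "").
#' @return object of class `"residue_selector"`.
#' @export
residue_selector <- function(chain, resno, resname = NULL, atom = NULL, insert = "") {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 resname = if (!is.null(resname)) toupper(resname) else NULL,
                 atom = atom, insert = insert),
            class = "residue_selector")
}

#' @export
print.residue_selector <- function(x, ...) {
  cat("<selector>", paste0(x$chain, x$resno, x$insert),
      if (!is.null(x$resname)) x$resname else "",
      if (!is.null(x$atom)) paste0("/", x$atom) else "", "\n")
  invisible(x)
}

#' Resolve a selector against a protein structure
#'
#' @param protein a `protein`.
#' @param sel a `residue_selector`.
#' @return integer vector of atom-row indices: all atoms of the residue, or
#'   the single named atom if the selector carries an atom name.
#' @details Errors unless the selector resolves to exactly one residue (and,
#'   with an atom name, exactly one atom).
#' @export
resolve_selector <- function(protein, sel) {
  stopifnot(inherits(sel, "residue_selector"))
  key <- paste0(sel$chain, sel$resno, sel$insert)
  idx <- which(protein$atoms$key == key)
  if (!length(idx))
    stop("selector ", key, " matches no residue")
  if (!is.null(sel$resname) && protein$atoms$resname[idx[1]] != sel$resname)
    stop("selector ", key, " expected residue ", sel$resname,
         " but found ", protein$atoms$resname[idx[1]])
  if (!is.null(sel$atom)) {
    idx <- idx[protein$atoms$name[idx] == sel$atom]
    if (length(idx) != 1L)
      stop("selector ", key, "/", sel$atom, " resolves to ", length(idx),
           " atoms (need exactly 1)")
  }
  idx
}

selector_label <- function(sel) {
  paste0(if (!is.null(sel$resname)) sel$resname else "", sel$chain, sel$resno, sel$insert,
         if (!is.null(sel$atom)) paste0(":", sel$atom) else "")
}
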