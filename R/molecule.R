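#' Construct a small-molecule object
#'
#' The universal small-molecule carrier used throughout pharmflow: a named
#' atom list (element, formal charge), an explicit bond list, and one or more
#' conformers (coordinate sets in Angstrom over the same atoms).
#'
#' @param name molecule name (non-empty string).
#' @param elements character vector of element symbols (e.g. "C", "N", "Cl").
#' @param coords numeric n x 3 matrix of coordinates in Angstrom, or a list of
#'   such matrices (multiple conformers over the same atoms).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (one of "1", "2", "3", "ar"). May have zero rows.
#' @param charges integer vector of formal charges, recycled to the atom count.
#'
#' @return an object of class `"molecule"`: a list with elements `name`,
#'   `atoms` (data.frame: element, charge), `bonds`, and `conformers`
#'   (list of n x 3 matrices).
#'
#' @details Invariants enforced: bond indices reference existing atoms, no
#'   self-bonds, no duplicate bonds (undirected), every conformer has exactly
#'   one coordinate triple per atom, and at least one heavy (non-hydrogen)
#'   atom is present.
#'
#' @examples
#' co <- molecule("carbonyl", c("C", "O"),
#'                rbind(c(0, 0, 0), c(1.23, 0, 0)),
#'                data.frame(i = 1, j = 2, order = "2"))
#' n_atoms(co)
#' @export
molecule <- function(name, elements, coords, bonds = NULL, charges = 0L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("molecule name must be a non-empty string")
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("molecule must have at least one atom")
  if (!any(toupper(elements) != "H")) stop("molecule must have at least one heavy atom")

  if (is.matrix(coords)) coords <- list(coords)
  conformers <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 3L)
      stop("each conformer must be an n x 3 coordinate matrix (n = ", n, ")")
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  if (length(conformers) < 1L) stop("molecule needs at least one conformer")

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = character(0),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.character(bonds$order), stringsAsFactors = FALSE)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond indices reference non-existent atoms")
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (!all(bonds$order %in% c("1", "2", "3", "ar")))
      stop("bond order must be one of '1','2','3','ar'")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
  }

  charges <- rep_len(as.integer(charges), n)
  structure(list(
    name = name,
    atoms = data.frame(element = elements, charge = charges, stringsAsFactors = FALSE),
    bonds = bonds,
    conformers = conformers
  ), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$name, "\n")
  cat("  atoms:", nrow(x$atoms), "(", sum(heavy_atoms(x)), "heavy )",
      " bonds:", nrow(x$bonds), " conformers:", length(x$conformers), "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @return integer atom count (including hydrogens).
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Logical mask of heavy (non-hydrogen) atoms
#' @param mol a `molecule`.
#' @return logical vector over atoms, TRUE for non-hydrogen.
#' @export
heavy_atoms <- function(mol) toupper(mol$atoms$element) != "H"

HALOGENS <- c("F", "CL", "BR", "I")

is_halogen <- function(elements) toupper(elements) %in% HALOGENS

#' Coordinates of one conformer
#' @param mol a `molecule`.
#' @param conformer conformer index (default 1).
#' @return n x 3 coordinate matrix (Angstrom).
#' @export
conformer_coords <- function(mol, conformer = 1L) {
  if (conformer < 1L || conformer > length(mol$conformers))
    stop("molecule '", mol$name, "' has no conformer ", conformer)
  mol$conformers[[conformer]]
}

#' Replace the coordinates of a molecule (single conformer)
#' @param mol a `molecule`.
#' @param coords n x 3 matrix.
#' @param conformer index of the conformer to replace.
#' @return the modified molecule.
#' @export
set_coords <- function(mol, coords, conformer = 1L) {
  coords <- as.matrix(coords)
  if (nrow(coords) != n_atoms(mol) || ncol(coords) != 3L)
    stop("coordinate matrix must be ", n_atoms(mol), " x 3")
  dimnames(coords) <- NULL
  mol$conformers[[conformer]] <- coords
  mol
}

# adjacency list over bonds (list of integer vectors, one per atom)
bond_neighbors <- function(mol) {
  nb <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# apolar heavy atoms: C, S or halogen with no bonded N or O
apolar_atoms <- function(mol) {
  el <- toupper(mol$atoms$element)
  nb <- bond_neighbors(mol)
  vapply(seq_len(n_atoms(mol)), function(i) {
    if (!(el[i] %in% c("C", "S") || el[i] %in% HALOGENS)) return(FALSE)
    !any(el[nb[[i]]] %in% c("N", "O"))
  }, logical(1))
}

# same connectivity: same elements in order and identical undirected bond set
same_connectivity <- function(a, b) {
  if (n_atoms(a) != n_atoms(b)) return(FALSE)
  if (!identical(toupper(a$atoms$element), toupper(b$atoms$element))) return(FALSE)
  key <- function(m) {
    if (nrow(m$bonds) == 0L) return(character(0))
    sort(paste(pmin(m$bonds$i, m$bonds$j), pmax(m$bonds$i, m$bonds$j), m$bonds$order))
  }
  identical(key(a), key(b))
}
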