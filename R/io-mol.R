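# Small-molecule I/O: SDF (V2000) written natively, read through ChemmineR;
# SMILES and MOL2 converted to SDF by OpenBabel (ChemmineOB) first.

CHG_TO_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `-1` = 5L, `-2` = 6L, `-3` = 7L)
CODE_TO_CHG <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

ORDER_TO_SDF <- c(`1` = 1L, `2` = 2L, `3` = 3L, ar = 4L)
SDF_TO_ORDER <- c(`1` = "1", `2` = "2", `3` = "3", `4` = "ar")

molecule_to_sdf <- function(mol, conformer = 1L) {
  xyz <- conformer_coords(mol, conformer)
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  lines <- c(mol$name, "  pharmflow", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  code <- CHG_TO_CODE[as.character(pmax(pmin(chg, 3L), -3L))]
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                            xyz[, 1], xyz[, 2], xyz[, 3], el, code))
  if (nb > 0)
    lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                              ORDER_TO_SDF[mol$bonds$order]))
  ichg <- which(chg != 0L)
  if (length(ichg)) {
    for (grp in split(ichg, ceiling(seq_along(ichg) / 8)))
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, chg[grp]), collapse = "")))
  }
  c(lines, "M  END", "$$$$")
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols a `molecule` or list of molecules.
#' @param path output file.
#' @param all_conformers if TRUE, each conformer of a molecule is written as a
#'   consecutive record under the same name (the multi-conformer convention
#'   that [read_molecules()] can merge back).
#' @return invisibly, the path.
#' @export
write_molecules <- function(mols, path, all_conformers = FALSE) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  out <- unlist(lapply(mols, function(m) {
    ks <- if (all_conformers) seq_along(m$conformers) else 1L
    unlist(lapply(ks, function(k) molecule_to_sdf(m, k)))
  }))
  writeLines(out, path)
  invisible(path)
}

chemmine_to_molecule <- function(sdf, fallback_name = "mol") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  xyz <- unname(ab[, 1:3, drop = FALSE])
  # atom-block charge code is the 2nd numeric field after the coordinates
  chg <- if (ncol(ab) >= 5) CODE_TO_CHG[as.character(ab[, 5])] else rep(0L, length(el))
  chg[is.na(chg)] <- 0L
  bonds <- NULL
  if (!is.null(bb) && nrow(bb) > 0)
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = SDF_TO_ORDER[as.character(bb[, 3])],
                        stringsAsFactors = FALSE)
  nm <- ChemmineR::sdfid(sdf)
  if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- fallback_name
  molecule(nm, el, xyz, bonds, chg)
}

# minimal V2000 fallback for records ChemmineR rejects (e.g. single-atom or
# zero-bond molecules such as bare waters/ions)
parse_v2000 <- function(chunk, fallback_name = "mol") {
  name <- trimws(chunk[1])
  if (!nzchar(name)) name <- fallback_name
  na <- as.integer(substr(chunk[4], 1, 3))
  nb <- as.integer(substr(chunk[4], 4, 6))
  if (is.na(na) || na < 1L) stop("bad counts line")
  at <- chunk[4L + seq_len(na)]
  xyz <- cbind(as.numeric(substr(at, 1, 10)), as.numeric(substr(at, 11, 20)),
               as.numeric(substr(at, 21, 30)))
  el <- trimws(substr(at, 32, 34))
  chg <- CODE_TO_CHG[trimws(substr(at, 37, 39))]
  chg[is.na(chg)] <- 0L
  bonds <- NULL
  if (!is.na(nb) && nb > 0L) {
    bl <- chunk[4L + na + seq_len(nb)]
    bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                        j = as.integer(substr(bl, 4, 6)),
                        order = SDF_TO_ORDER[trimws(substr(bl, 7, 9))],
                        stringsAsFactors = FALSE)
  }
  for (ln in grep("^M  CHG", chunk, value = TRUE)) {
    n <- as.integer(substr(ln, 7, 9))
    for (q in seq_len(n)) {
      off <- 10 + (q - 1) * 8
      chg[as.integer(substr(ln, off, off + 3))] <-
        as.integer(substr(ln, off + 4, off + 7))
    }
  }
  molecule(name, el, xyz, bonds, chg)
}

merge_conformer_runs <- function(mols) {
  if (length(mols) < 2L) return(mols)
  out <- list(mols[[1]])
  for (m in mols[-1]) {
    last <- out[[length(out)]]
    if (identical(m$name, last$name) && same_connectivity(m, last)) {
      last$conformers <- c(last$conformers, m$conformers)
      out[[length(out)]] <- last
    } else out[[length(out) + 1L]] <- m
  }
  out
}

#' Read small molecules from SDF, MOL2 or SMILES files
#'
#' @param path input file.
#' @param format one of "sdf", "mol2", "smiles" (default guessed from the
#'   file extension). MOL2 and SMILES input is converted through OpenBabel
#'   (ChemmineOB) and therefore arrives with Kekule bond orders.
#' @param strict if TRUE an unparsable record is an error; otherwise it is
#'   skipped with a warning reporting the skip count.
#' @param merge_conformers if TRUE, consecutive SDF records with the same
#'   name and identical connectivity are merged into one multi-conformer
#'   molecule.
#' @return list of `molecule` objects, in record order.
#' @export
read_molecules <- function(path, format = NULL, strict = FALSE,
                           merge_conformers = FALSE) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", mol = "sdf", mol2 = "mol2",
                     smi = "smiles", smiles = "smiles", "sdf")
  }
  format <- match.arg(tolower(format), c("sdf", "mol2", "smiles"))
  sdf_path <- path
  if (format != "sdf") {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("reading ", format, " requires the ChemmineOB package")
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    conv <- ChemmineOB::convertFormat(toupper(if (format == "smiles") "SMI" else "MOL2"),
                                      "SDF", txt)
    sdf_path <- tempfile(fileext = ".sdf")
    on.exit(unlink(sdf_path))
    writeLines(conv, sdf_path)
  }
  set <- suppressWarnings(ChemmineR::read.SDFset(sdf_path))
  valid <- ChemmineR::validSDF(set)
  lines <- readLines(sdf_path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  n_bad <- 0L
  mols <- list()
  for (k in seq_along(set)) {
    m <- tryCatch({
      if (valid[k]) chemmine_to_molecule(set[[k]], fallback_name = paste0("mol", k))
      else parse_v2000(lines[starts[k]:ends[k]], fallback_name = paste0("mol", k))
    }, error = function(e) e)
    if (inherits(m, "error")) n_bad <- n_bad + 1L else mols[[length(mols) + 1L]] <- m
  }
  if (n_bad > 0) {
    msg <- paste0(n_bad, " unparsable record(s) in ", path)
    if (strict) stop(msg) else warning(msg, " skipped")
  }
  if (merge_conformers) mols <- merge_conformer_runs(mols)
  mols
}

#' Parse a single SMILES string into a molecule
#'
#' Convenience wrapper over OpenBabel: 2D coordinates are generated, bond
#' orders arrive Kekulized, hydrogens stay implicit.
#'
#' @param smiles SMILES string.
#' @param name molecule name.
#' @return a `molecule`.
#' @export
smiles_to_molecule <- function(smiles, name = smiles) {
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  writeLines(smiles, tmp)
  mol <- read_molecules(tmp, format = "smiles", strict = TRUE)[[1]]
  mol$name <- name
  mol
}

#' Read docking poses from an SDF file
#'
#' @param path SDF file of poses in the receptor coordinate frame.
#' @param method_label docking-method label attached to every pose.
#' @param ... passed to [read_molecules()].
#' @return list of `pose` objects, in record order.
#' @export
read_poses <- function(path, method_label, ...) {
  mols <- read_molecules(path, ...)
  lapply(mols, pose, method = method_label)
}
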