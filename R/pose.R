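#' Construct a docking pose
#'
#' A pose is a single-conformer molecule whose coordinates are interpreted in
#' the receptor frame, tagged with the docking method that produced it.
#'
#' @param mol a `molecule`; if it has several conformers, `conformer` selects
#'   the one fixed into the pose.
#' @param method non-empty method label (e.g. "goldscore").
#' @param score optional docking score.
#' @param conformer conformer index to freeze (default 1).
#' @return object of class `"pose"`: list(molecule, method, score).
#' @export
pose <- function(mol, method, score = NULL, conformer = 1L) {
  stopifnot(inherits(mol, "molecule"))
  if (!is.character(method) || length(method) != 1L || !nzchar(method))
    stop("pose method label must be a non-empty string")
  mol$conformers <- mol$conformers[conformer]
  structure(list(molecule = mol, method = method, score = score), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("<pose>", x$molecule$name, "by", x$method,
      if (!is.null(x$score)) paste0("(score ", signif(x$score, 4), ")") else "", "\n")
  invisible(x)
}

pose_coords <- function(p) conformer_coords(p$molecule, 1L)

#' Construct a trajectory of a protein-ligand complex
#'
#' @param protein topology `protein` (frame-0 coordinates).
#' @param ligand topology `molecule` (frame-0 coordinates, receptor frame).
#' @param frames list of full-complex coordinate matrices, each
#'   (n_protein + n_ligand) x 3, protein atoms first, in frame order.
#' @param frame_interval optional time between frames in ns.
#' @return object of class `"trajectory"`.
#' @details At least two frames are required and every frame must carry one
#'   coordinate triple per topology atom.
#' @export
trajectory <- function(protein, ligand, frames, frame_interval = NULL) {
  stopifnot(inherits(protein, "protein"), inherits(ligand, "molecule"))
  n_top <- nrow(protein$atoms) + n_atoms(ligand)
  if (length(frames) < 2L) stop("a trajectory needs at least 2 frames")
  for (k in seq_along(frames)) {
    f <- as.matrix(frames[[k]])
    if (nrow(f) != n_top || ncol(f) != 3L)
      stop("frame ", k, " has ", nrow(f), " atoms; topology has ", n_top)
    frames[[k]] <- unname(f)
  }
  structure(list(protein = protein, ligand = ligand, frames = frames,
                 frame_interval = frame_interval,
                 protein_idx = seq_len(nrow(protein$atoms)),
                 ligand_idx = nrow(protein$atoms) + seq_len(n_atoms(ligand))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$frames), "frames,",
      nrow(x$protein$atoms), "protein atoms +", n_atoms(x$ligand), "ligand atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

# protein and ligand objects with frame-k coordinates substituted
frame_complex <- function(traj, k) {
  f <- traj$frames[[k]]
  list(protein = set_protein_coords(traj$protein, f[traj$protein_idx, , drop = FALSE]),
       ligand = set_coords(traj$ligand, f[traj$ligand_idx, , drop = FALSE]))
}
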