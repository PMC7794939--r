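# Synthetic-fixture generators: a toy pocket/ligand complex with planted
# interactions, libraries with planted match sizes, pose ensembles realizing
# a prescribed RMSD matrix, and trajectories with planted per-frame
# interaction presence. All geometry is constructed, not energy-minimized;
# planted quantities are exact by construction so every analysis stage can
# be tested against ground truth.

hexagon <- function(center, radius = 1.39, z = center[3], start = 0) {
  ang <- start + (0:5) * pi / 3
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang), z)
}

unit2 <- function(v) v / sqrt(sum(v^2))

#' Toy receptor-ligand reference complex with planted interactions
#'
#' Builds a minimal binding pocket (11 residues incl. one water) around a
#' 24-atom ligand, realizing by construction the canonical serine-hydrolase
#' recognition motif this package targets: two backbone-amide donors
#' (Ala51/Met123 analogues) H-bonded to two ligand carbonyls, an arginine
#' side-chain donor (Arg57 analogue), a structural water bridging a fourth
#' ligand acceptor to Glu53/His272 analogues, four apolar clusters packing
#' the ligand's two rings, chlorine and aliphatic pair, and a tyrosine ring
#' face-to-face with one ligand ring. Model building on this complex yields
#' 4 HBA + 4 HYD features with a 5-mandatory/3-optional split.
#'
#' @param seed accepted for interface uniformity; the geometry is fixed and
#'   fully deterministic.
#' @return list: `protein`, `ligand` (posed in the receptor frame),
#'   `structural_water` (selector), `water_partners` (selectors),
#'   `hbond_partners` (selectors for the three direct H-bond residues), and
#'   `truth` (planted interaction inventory).
#' @export
make_reference_complex <- function(seed = 1L) {
  ringA <- hexagon(c(0, 0, 0))
  ringB <- hexagon(c(11.78, 0, 0), start = pi)
  lig_xyz <- rbind(
    ringA,                                  # 1-6
    c(2.89, 0, 0),                          # 7  C7 (carbonyl C)
    c(2.89, 1.23, 0),                       # 8  O1 -> A51 backbone N
    c(4.39, 0, 0),                          # 9  C8 linker
    c(5.89, 0, 0),                          # 10 C9 (carbonyl C)
    c(5.89, -1.23, 0),                      # 11 O2 -> M123 backbone N
    c(7.39, 0, 0),                          # 12 C10 (carbonyl C)
    c(7.39, 1.23, 0),                       # 13 O3 -> R57 NH1
    c(8.89, 0, 0),                          # 14 C11 (carbonyl C)
    c(8.89, -1.23, 0),                      # 15 O4 -> structural water
    ringB,                                  # 16-21
    c(14.91, 0, 0),                         # 22 Cl on ring B para position
    c(-2.89, 0, 0),                         # 23 C12 aliphatic
    c(-3.99, 1.02, 0))                      # 24 C13 aliphatic
  elements <- c(rep("C", 6), "C", "O", "C", "C", "O", "C", "O", "C", "O",
                rep("C", 6), "Cl", "C", "C")
  bonds <- rbind(
    data.frame(i = 1:6, j = c(2:6, 1), order = "ar"),
    data.frame(i = c(1, 7, 7, 9, 10, 10, 12, 12, 14, 14),
               j = c(7, 8, 9, 10, 11, 12, 13, 14, 15, 16),
               order = c("1", "2", "1", "1", "2", "1", "2", "1", "2", "1")),
    data.frame(i = 16:21, j = c(17:21, 16), order = "ar"),
    data.frame(i = c(19, 4, 23), j = c(22, 23, 24), order = "1"))
  ligand <- molecule("refmimic", elements, lig_xyz, bonds)

  rows <- list()
  res <- function(resname, resno, names, elements, coords) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = if (resname %in% c("HOH")) "HETATM" else "ATOM",
      chain = "A", resno = resno, insert = "", resname = resname,
      name = names, element = elements,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
  }
  res("ALA", 51, c("N", "CA", "C", "O", "CB"), c("N", "C", "C", "O", "C"),
      rbind(c(2.89, 4.13, 0), c(4.15, 4.93, 0), c(5.65, 4.93, 0),
            c(6.25, 6.00, 0), c(3.35, 6.13, 0.4)))
  res("GLU", 53, c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
      c("N", "C", "C", "O", "C", "C", "C", "O", "O"),
      rbind(c(3.6, -10.4, 0), c(4.8, -11.1, 0), c(4.4, -12.55, 0),
            c(3.3, -13.1, 0), c(5.2, -9.7, 0), c(6.0, -8.5, 0),
            c(6.666, -7.412, 0), c(7.266, -6.312, 0), c(5.416, -7.312, 0)))
  res("ARG", 57, c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
      c("N", "C", "C", "O", "C", "C", "C", "N", "C", "N", "N"),
      rbind(c(4.6, 11.9, 0), c(5.6, 10.9, 0), c(7.0, 11.4, 0), c(7.6, 12.5, 0),
            c(5.0, 9.6, 0), c(6.0, 8.6, 0), c(6.59, 7.35, 0), c(7.49, 6.45, 0),
            c(7.99, 5.25, 0), c(7.39, 4.13, 0), c(9.19, 5.75, 0)))
  res("MET", 123, c("N", "CA", "C", "O", "CB"), c("N", "C", "C", "O", "C"),
      rbind(c(5.89, -4.13, 0), c(4.63, -4.93, 0), c(3.13, -4.93, 0),
            c(3.13, -6.16, 0), c(4.9, -4.2, 1.2)))
  res("ILE", 179, c("N", "CA", "C", "O", "CB", "CD1", "CG2"),
      c("N", "C", "C", "O", "C", "C", "C"),
      rbind(c(1.2, -1.5, 6.5), c(0.3, -0.5, 7.2), c(0.9, 0.9, 7.6),
            c(2.1, 1.2, 7.8), c(0.2, 0.3, 5.3),
            c(0, 0, 3.6),              # packs ring A from above
            c(-3.44, 0.51, -3.6)))     # packs the aliphatic cluster from below
  tyr_ring <- hexagon(c(11.78, 0, 3.5), start = pi)
  res("TYR", 194, c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
                    "CZ", "OH"),
      c("N", "C", "C", "O", "C", "C", "C", "C", "C", "C", "C", "O"),
      rbind(c(7.0, 0.5, 5.6), c(8.39, 0, 5.6), c(9.2, -0.9, 6.4),
            c(9.2, -0.9, 7.63), c(9.59, 0, 4.7),
            tyr_ring[1, , drop = FALSE],      # CG
            tyr_ring[2, , drop = FALSE],      # CD1
            tyr_ring[6, , drop = FALSE],      # CD2
            tyr_ring[3, , drop = FALSE],      # CE1
            tyr_ring[5, , drop = FALSE],      # CE2
            tyr_ring[4, , drop = FALSE],      # CZ
            c(14.27, 0, 4.1)))
  res("LEU", 205, c("N", "CA", "C", "O", "CD1"), c("N", "C", "C", "O", "C"),
      rbind(c(14.91, 3.0, 6.0), c(16.1, 3.7, 6.0), c(17.6, 3.7, 6.0),
            c(18.2, 4.75, 6.1), c(16.5, 0, 2.8)))    # packs the chlorine
  res("LEU", 213, c("N", "CA", "C", "O", "CD1", "CD2"),
      c("N", "C", "C", "O", "C", "C"),
      rbind(c(0, 1.5, -6.5), c(-0.9, 0.8, -7.3), c(-2.3, 1.2, -7.5),
            c(-2.6, 2.4, -7.6),
            c(0, 0, -3.6),             # packs ring A from below
            c(14.91, 0, -3.8)))        # packs the chlorine from below
  res("LEU", 241, c("N", "CA", "C", "O", "CD1", "CD2"),
      c("N", "C", "C", "O", "C", "C"),
      rbind(c(-1.0, 3.5, 6.3), c(-2.2, 4.2, 6.3), c(-3.7, 4.2, 6.3),
            c(-4.2, 5.3, 6.4),
            c(0, 2.0, 3.2),            # packs ring A edge
            c(-3.44, 0.51, 3.6)))      # packs the aliphatic cluster
  # histidine imidazole, NE2 vertex pointing at the water
  w <- c(8.89, -4.03, 0)
  ctr <- c(11.8, -7.0, 0)
  u <- unit2(w[1:2] - ctr[1:2])
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  pent <- t(vapply(c(0, 72, 144, 216, 288) * pi / 180,
                   function(a) c(ctr[1:2] + 1.17 * rot(u, a), 0), numeric(3)))
  res("HIS", 272, c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
      c("N", "C", "C", "O", "C", "C", "N", "C", "C", "N"),
      rbind(c(14.7, -10.0, 0), c(13.3, -10.3, 0), c(13.0, -11.8, 0),
            c(12.4, -12.87, 0), c(12.19, -9.64, 0),
            pent[3, , drop = FALSE],   # CG
            pent[4, , drop = FALSE],   # ND1
            pent[2, , drop = FALSE],   # CD2
            pent[5, , drop = FALSE],   # CE1
            pent[1, , drop = FALSE]))  # NE2 (2.99 A from the water O)
  res("HOH", 300, "O", "O", matrix(w, 1, 3))

  protein <- protein_structure(do.call(rbind, rows))
  list(
    protein = protein,
    ligand = ligand,
    structural_water = residue_selector("A", 300, "HOH"),
    water_partners = list(residue_selector("A", 53, "GLU"),
                          residue_selector("A", 272, "HIS")),
    hbond_partners = list(residue_selector("A", 51, "ALA", atom = "N"),
                          residue_selector("A", 57, "ARG"),
                          residue_selector("A", 123, "MET", atom = "N")),
    truth = list(
      n_hbonds = 4L,
      hbond_residues = c("A51", "A57", "A123"),
      hydrophobic_residues = c("A179", "A194", "A205", "A213", "A241"),
      pi_stack_residues = "A194",
      n_hba_features = 4L, n_hyd_features = 4L, n_mandatory = 5L))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c_ <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
           2 * (b * c_ + a * d), a^2 - b^2 + c_^2 - d^2, 2 * (c_ * d - a * b),
           2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 - b^2 - c_^2 + d^2),
         3, 3, byrow = TRUE)
}

# fragment molecule realizing the given model features at their centers:
# a C=O pair per HBA (O on the center), a C-C pair per HYD (centered)
star_molecule <- function(name, model, feature_ids, jitter = 0, tail = FALSE) {
  f <- model$features
  pocket <- colMeans(as.matrix(f[, c("x", "y", "z")]))
  atoms <- list(); elements <- character(0); bonds <- list()
  for (id in sort(feature_ids)) {
    q <- which(f$id == id)
    ctr <- c(f$x[q], f$y[q], f$z[q]) + stats::rnorm(3, 0, jitter / sqrt(3))
    n0 <- length(elements)
    if (f$kind[q] == "HBA") {
      u <- unit2(pocket - ctr + c(0, 0, 1e-3))
      atoms <- c(atoms, list(ctr, ctr + 1.23 * u))
      elements <- c(elements, "O", "C")
      bonds[[length(bonds) + 1L]] <- data.frame(i = n0 + 2L, j = n0 + 1L, order = "2")
    } else {
      v <- unit2(c(0.3, 0.7, 0.648))
      atoms <- c(atoms, list(ctr + 0.75 * v, ctr - 0.75 * v))
      elements <- c(elements, "C", "C")
      bonds[[length(bonds) + 1L]] <- data.frame(i = n0 + 1L, j = n0 + 2L, order = "1")
    }
  }
  if (tail) {
    n0 <- length(elements)
    tx <- seq(-6.5, -12, length.out = 6)
    for (k in seq_along(tx))
      atoms <- c(atoms, list(c(tx[k], 0.3 * (k %% 2), 0)))
    elements <- c(elements, rep("C", 6))
    bonds[[length(bonds) + 1L]] <- data.frame(i = n0 + 1:5, j = n0 + 2:6, order = "1")
  }
  molecule(name, elements, do.call(rbind, atoms), do.call(rbind, bonds))
}

#' Library of molecules with planted pharmacophore match sizes
#'
#' Each molecule is a set of chemical fragments (carbonyl C=O for acceptor
#' features, apolar C-C pairs for hydrophobic features) placed at the
#' centers of a chosen subset of model features - always including all
#' mandatory ones for sizes >= the mandatory count - then moved to a random
#' rigid frame. Alignment-mode matching must recover exactly the planted
#' match size.
#'
#' @param model a `pharmacophore_model`.
#' @param sizes integer vector of planted match sizes, one per molecule;
#'   sizes below the mandatory count plant that many mandatory features only
#'   (such molecules can never satisfy the model).
#' @param seed RNG seed; fixes all outputs.
#' @param jitter per-fragment placement noise (Angstrom, well inside the
#'   tolerance radii).
#' @return list: `molecules` (random-frame, single conformer each) and
#'   `truth` (data.frame: name, planted size).
#' @export
make_library <- function(model, sizes, seed = 1L, jitter = 0.2) {
  set.seed(seed)
  f <- model$features
  mand <- f$id[f$mandatory]
  opt <- f$id[!f$mandatory]
  mols <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    ids <- if (k >= length(mand)) {
      c(mand, if (k > length(mand)) sample(opt, k - length(mand)) else integer(0))
    } else sample(mand, k)
    m <- star_molecule(sprintf("lib%04d", i), model, ids, jitter = jitter)
    xyz <- conformer_coords(m, 1L)
    R <- random_rotation()
    t_ <- stats::rnorm(3, 0, 10)
    m <- set_coords(m, sweep(xyz %*% t(R), 2, t_, `+`))
    mols[[i]] <- m
  }
  list(molecules = mols,
       truth = data.frame(name = vapply(mols, `[[`, character(1), "name"),
                          size = as.integer(sizes), stringsAsFactors = FALSE))
}

#' Pose ensemble realizing a prescribed pairwise RMSD matrix
#'
#' Realizes the target matrix by pure translations of the input pose: the
#' in-place RMSD between two translated copies of the same conformer equals
#' the translation distance exactly, so any Euclidean-embeddable target
#' matrix is realized to numerical precision. Translation vectors come from
#' classical multidimensional scaling of the target with a short stress
#' refinement.
#'
#' @param mol a `molecule` (conformer 1 is the pose geometry).
#' @param methods character vector of method labels (defines the ensemble
#'   size).
#' @param target symmetric nonnegative matrix of desired pairwise RMSDs.
#' @param tol maximum allowed deviation from the target (Angstrom).
#' @return list: `poses` (named by method), `achieved` (realized matrix),
#'   `offsets` (the translation vectors).
#' @export
make_pose_ensemble <- function(mol, methods, target, tol = 0.05) {
  n <- length(methods)
  target <- as.matrix(target)
  stopifnot(nrow(target) == n, ncol(target) == n)
  if (all(target == 0)) {
    pts <- matrix(0, n, 3)
  } else {
    pts <- suppressWarnings(stats::cmdscale(stats::as.dist(target), k = min(3, n - 1)))
    if (ncol(pts) < 3) pts <- cbind(pts, matrix(0, n, 3 - ncol(pts)))
    # stress majorization to polish the embedding
    for (it in seq_len(500)) {
      d <- as.matrix(stats::dist(pts))
      if (max(abs(d - target)) < tol / 5) break
      new <- pts
      for (i in seq_len(n)) {
        acc <- c(0, 0, 0)
        for (j in seq_len(n)[-i]) {
          dij <- d[i, j]
          acc <- acc + if (dij > 1e-12)
            pts[j, ] + target[i, j] * (pts[i, ] - pts[j, ]) / dij else pts[j, ]
        }
        new[i, ] <- acc / (n - 1)
      }
      pts <- new
    }
  }
  achieved <- as.matrix(stats::dist(pts))
  if (max(abs(achieved - target)) > tol)
    warning("target RMSD matrix not Euclidean-embeddable within ", tol, " A")
  xyz <- conformer_coords(mol, 1L)
  poses <- lapply(seq_len(n), function(i)
    pose(set_coords(mol, sweep(xyz, 2, pts[i, ], `+`)), methods[i]))
  names(poses) <- methods
  dimnames(achieved) <- list(methods, methods)
  list(poses = poses, achieved = achieved, offsets = pts)
}

#' Trajectory with planted interaction occupancy and ligand jitter
#'
#' Starting from a posed complex, generates frames in which each named
#' interaction is present in an exact, planted fraction of frames: in
#' "present" frames the partner atom (or water oxygen) is re-placed at the
#' native H-bond distance from the (jittered) ligand atom, in "absent"
#' frames at 0.3 Angstrom beyond the H-bond cutoff, so occupancy recovery is
#' exact and never boundary-flaky. Ligand heavy atoms get isotropic Gaussian
#' jitter (frames 2..N) plus an optional constant drift translation.
#'
#' @param protein,ligand the complex (ligand posed in the receptor frame).
#' @param interactions list of interaction specifications as in
#'   [hbond_occupancy()]; direct entries need `partner` selectors carrying an
#'   atom name.
#' @param occupancy named fractions in \code{[0,1]}, one per interaction key.
#' @param n_frames number of frames (>= 2).
#' @param jitter per-coordinate ligand jitter sigma (Angstrom).
#' @param drift magnitude of a constant ligand translation applied from
#'   frame 2 on (Angstrom).
#' @param criteria an [interaction_criteria()] (sets the cutoff geometry).
#' @param seed RNG seed.
#' @param water_swap if TRUE a second, distant water is added and the two
#'   waters exchange positions in the second half of the trajectory (for
#'   exercising water-tracking modes).
#' @return list: `trajectory` and `truth` (exact planted occupancies, jitter,
#'   drift).
#' @export
make_trajectory <- function(protein, ligand, interactions, occupancy,
                            n_frames = 50L, jitter = 0.08, drift = 0,
                            criteria = interaction_criteria(), seed = 1L,
                            water_swap = FALSE) {
  set.seed(seed)
  stopifnot(n_frames >= 2L)
  keys <- vapply(interactions, `[[`, character(1), "key")
  stopifnot(all(keys %in% names(occupancy)))
  if (water_swap) {
    wrow <- protein$atoms[is_water(protein), , drop = FALSE][1, , drop = FALSE]
    wrow$resno <- wrow$resno + 1L
    wrow$x <- wrow$x + 6
    protein <- protein_structure(rbind(protein$atoms[, names(wrow)], wrow))
  }
  n_p <- nrow(protein$atoms)
  base_p <- protein_coords(protein)
  base_l <- conformer_coords(ligand, 1L)
  heavy <- heavy_atoms(ligand)

  # resolve the partner atom (or water O) and its approach direction once
  plan <- lapply(interactions, function(x) {
    if (!is.null(x$water)) {
      widx <- resolve_selector(protein, x$water)
      wo <- widx[toupper(protein$atoms$element[widx]) == "O"]
      li <- x$lig_atoms[1]
      list(kind = "water", atom = wo, li = li,
           u = unit2(base_p[wo, ] - base_l[li, ]),
           d_on = sqrt(sum((base_p[wo, ] - base_l[li, ])^2)))
    } else {
      idx <- resolve_selector(protein, x$partner)
      idx <- idx[toupper(protein$atoms$element[idx]) %in% c("N", "O")]
      li <- x$lig_atoms[1]
      d <- sqrt(colSums((t(base_p[idx, , drop = FALSE]) - base_l[li, ])^2))
      ai <- idx[which.min(d)]
      list(kind = "direct", atom = ai, li = li,
           u = unit2(base_p[ai, ] - base_l[li, ]), d_on = min(d))
    }
  })
  d_off <- criteria$hbond_dist + 0.3
  present <- lapply(keys, function(k) {
    n_on <- round(occupancy[[k]] * n_frames)
    on <- logical(n_frames)
    if (n_on >= 1L) {
      on[1] <- TRUE
      if (n_on > 1L) on[sample(2:n_frames, n_on - 1L)] <- TRUE
    }
    on
  })
  names(present) <- keys

  drift_vec <- if (drift > 0) drift * unit2(stats::rnorm(3)) else c(0, 0, 0)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    p <- base_p
    l <- base_l
    if (k > 1L) {
      l[heavy, ] <- l[heavy, ] + matrix(stats::rnorm(sum(heavy) * 3, 0, jitter),
                                        ncol = 3) +
        matrix(drift_vec, sum(heavy), 3, byrow = TRUE)
    }
    for (q in seq_along(plan)) {
      pl <- plan[[q]]
      d_target <- if (present[[q]][k]) pl$d_on else d_off
      p[pl$atom, ] <- l[pl$li, ] + d_target * pl$u
    }
    if (water_swap && k > n_frames / 2) {
      wo_all <- which(is_water(protein) & toupper(protein$atoms$element) == "O")
      if (length(wo_all) >= 2L) {
        tmp <- p[wo_all[1], ]; p[wo_all[1], ] <- p[wo_all[2], ]; p[wo_all[2], ] <- tmp
      }
    }
    frames[[k]] <- rbind(p, l)
  }
  truth_occ <- vapply(present, mean, numeric(1))
  list(trajectory = trajectory(protein, ligand, frames),
       truth = list(occupancy = truth_occ, jitter = jitter, drift = drift))
}

#' Complete synthetic screening campaign with planted funnel counts
#'
#' Assembles everything [run_pipeline()] consumes - model, library, poses
#' from several mock docking methods, trajectories - with each compound
#' assigned a fate: screened out (too few planted features), dropped by the
#' interaction filter (one method's pose loses a required H-bond), dropped
#' by pose consensus (one method swings an inert tail by > 2 Angstrom),
#' dropped by the MD filter (planted occupancy below threshold), or
#' surviving every stage.
#'
#' @param seed RNG seed.
#' @param n_screen_out,n_filter_fail,n_consensus_fail,n_md_fail,n_survive
#'   compounds per fate.
#' @param methods mock docking-method labels.
#' @param n_frames trajectory length for the MD stage.
#' @return list with `complex`, `model`, `library`, `poses` (method ->
#'   compound -> pose), `trajectories`, `traj_interactions`, `filter_spec`,
#'   `md_spec`, and `truth` (expected funnel counts and per-compound fates).
#' @export
make_campaign <- function(seed = 1L, n_screen_out = 2L, n_filter_fail = 2L,
                          n_consensus_fail = 2L, n_md_fail = 2L, n_survive = 2L,
                          methods = c("dockA", "dockB", "dockC"),
                          n_frames = 20L) {
  set.seed(seed)
  cplx <- make_reference_complex(seed)
  model <- build_receptor_model(cplx$protein, cplx$ligand,
                                structural_waters = list(cplx$structural_water))
  f <- model$features
  mand <- f$id[f$mandatory]
  opt <- f$id[!f$mandatory]
  fates <- c(rep("screen_out", n_screen_out), rep("filter_fail", n_filter_fail),
             rep("consensus_fail", n_consensus_fail), rep("md_fail", n_md_fail),
             rep("survive", n_survive))
  n_cmp <- length(fates)
  names(fates) <- sprintf("cmp%03d", seq_len(n_cmp))

  lib <- list(); poses <- lapply(methods, function(m) list()); names(poses) <- methods
  a51_n <- resolve_selector(cplx$protein, residue_selector("A", 51, atom = "N"))
  for (i in seq_len(n_cmp)) {
    nm <- names(fates)[i]
    k <- if (fates[i] == "screen_out") 6L else sample(7:8, 1L)
    ids <- c(mand, sample(opt, k - length(mand)))
    planted <- star_molecule(nm, model, ids, jitter = 0.15, tail = TRUE)
    # library copy in a random frame (screening must re-align it)
    xyz <- conformer_coords(planted, 1L)
    libm <- set_coords(planted, sweep(xyz %*% t(random_rotation()), 2,
                                      stats::rnorm(3, 0, 8), `+`))
    lib[[i]] <- libm
    for (mi in seq_along(methods)) {
      pxyz <- conformer_coords(planted, 1L)
      shift <- stats::rnorm(3); shift <- 0.15 * shift / sqrt(sum(shift^2))
      pxyz <- sweep(pxyz, 2, shift, `+`)
      if (fates[i] == "filter_fail" && mi == 1L) {
        # push the A51-bound carbonyl 1.2 A away from its donor
        o1 <- which.min(sqrt(colSums((t(pxyz) -
          unlist(cplx$protein$atoms[a51_n, c("x", "y", "z")]))^2)))
        frag <- which(sqrt(colSums((t(pxyz) - pxyz[o1, ])^2)) < 1.6)
        dir <- unit2(pxyz[o1, ] -
          unlist(cplx$protein$atoms[a51_n, c("x", "y", "z")], use.names = FALSE))
        pxyz[frag, ] <- sweep(pxyz[frag, , drop = FALSE], 2, 1.2 * dir, `+`)
      }
      if (fates[i] == "consensus_fail" && mi == 1L) {
        tail_idx <- (n_atoms(planted) - 5L):n_atoms(planted)
        pxyz[tail_idx, 3] <- pxyz[tail_idx, 3] + 4
      }
      poses[[mi]][[nm]] <- pose(set_coords(planted, pxyz), methods[mi])
    }
  }

  traj_interactions <- list(
    list(key = "A51", lig_atoms = NA, partner = residue_selector("A", 51, atom = "N")),
    list(key = "M123", lig_atoms = NA, partner = residue_selector("A", 123, atom = "N")),
    list(key = "R57", lig_atoms = NA, partner = residue_selector("A", 57, atom = "NH1")),
    list(key = "water", lig_atoms = NA, water = cplx$structural_water,
         partners = cplx$water_partners))
  trajectories <- list()
  for (nm in names(fates)[fates %in% c("md_fail", "survive")]) {
    p0 <- poses[[1]][[nm]]
    lig <- p0$molecule
    lxyz <- conformer_coords(lig, 1L)
    # the ligand atom serving each interaction = nearest acceptor O (or any atom)
    ints <- lapply(traj_interactions, function(x) {
      tgt <- if (!is.null(x$water)) {
        widx <- resolve_selector(cplx$protein, x$water)
        unlist(cplx$protein$atoms[widx[1], c("x", "y", "z")], use.names = FALSE)
      } else {
        ai <- resolve_selector(cplx$protein, x$partner)
        unlist(cplx$protein$atoms[ai[1], c("x", "y", "z")], use.names = FALSE)
      }
      ox <- which(toupper(lig$atoms$element) == "O")
      x$lig_atoms <- ox[which.min(sqrt(colSums((t(lxyz[ox, , drop = FALSE]) - tgt)^2)))]
      x
    })
    occ <- if (fates[nm] == "md_fail")
      c(A51 = 0.9, M123 = 0.4, R57 = 0.6, water = 0.9)
    else c(A51 = 0.9, M123 = 0.4, R57 = 0.95, water = 0.9)
    tr <- make_trajectory(cplx$protein, lig, ints, occ, n_frames = n_frames,
                          jitter = 0.08, seed = seed + match(nm, names(fates)))
    trajectories[[nm]] <- list(trajectory = tr$trajectory, interactions = ints,
                               truth = tr$truth)
  }

  filter_spec <- pose_filter_spec(
    hbond_partners = cplx$hbond_partners,
    water = list(water = cplx$structural_water, partners = cplx$water_partners),
    min_hydrophobic = 2L)
  md_spec <- md_filter_spec(required = c("R57", "water"),
                            any_of = c("A51", "M123"))
  expected <- list(
    screened = n_cmp - n_screen_out,
    filter_intersection = n_cmp - n_screen_out - n_filter_fail,
    consensus = n_cmp - n_screen_out - n_filter_fail - n_consensus_fail,
    md = n_survive)
  list(complex = cplx, model = model, library = lib, poses = poses,
       trajectories = trajectories, traj_interactions = traj_interactions,
       filter_spec = filter_spec, md_spec = md_spec,
       truth = list(fates = fates, expected = expected))
}
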