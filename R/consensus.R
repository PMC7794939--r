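# Pose RMSD (in-place, docking convention), self-docking validation,
# complete-linkage pose-consensus clustering.

#' Heavy-atom RMSD between two poses of the same molecule
#'
#' In-place (no-fit) RMSD in the docking convention: the coordinates are
#' compared as supplied, with no superposition. With `symmetry = TRUE` the
#' minimum over the molecule's graph automorphisms (element-colored,
#' bond-order-colored, enumerated by VF2) is returned, so topologically
#' equivalent atoms - e.g. the two arms of a para-disubstituted ring - do not
#' inflate the value.
#'
#' @param a,b `pose`s (or single-conformer `molecule`s) with identical
#'   connectivity.
#' @param symmetry use symmetry correction (default TRUE).
#' @param max_automorphisms cap on the automorphisms examined.
#' @param automorphisms optional precomputed automorphism list (as returned
#'   by the internal enumerator), for repeated RMSDs on the same molecule.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, symmetry = TRUE, max_automorphisms = 1e4,
                      automorphisms = NULL) {
  ma <- if (inherits(a, "pose")) a$molecule else a
  mb <- if (inherits(b, "pose")) b$molecule else b
  if (!same_connectivity(ma, mb))
    stop("poses have different connectivity; RMSD undefined")
  heavy <- which(heavy_atoms(ma))
  xa <- conformer_coords(ma, 1L)
  xb <- conformer_coords(mb, 1L)
  rmsd_perm <- function(perm)
    sqrt(mean(rowSums((xa[heavy, , drop = FALSE] -
                         xb[perm, , drop = FALSE])^2)))
  best <- rmsd_perm(heavy)
  if (symmetry) {
    perms <- if (!is.null(automorphisms)) automorphisms
      else molecule_automorphisms(ma, max_automorphisms)
    for (p in perms) {
      v <- rmsd_perm(p[heavy])
      if (v < best) best <- v
    }
  }
  best
}

# element- and bond-order-respecting graph automorphisms (list of index maps)
molecule_automorphisms <- function(mol, cap = 1e4) {
  g <- mol_graph(mol)
  vcol <- as.integer(factor(toupper(mol$atoms$element)))
  ecol <- if (nrow(mol$bonds))
    as.integer(factor(mol$bonds$order, levels = c("1", "2", "3", "ar"))) else NULL
  iso <- igraph::isomorphisms(g, g, method = "vf2",
                              vertex.color1 = vcol, vertex.color2 = vcol,
                              edge.color1 = ecol, edge.color2 = ecol)
  if (length(iso) > cap) iso <- iso[seq_len(cap)]
  lapply(iso, as.integer)
}

#' Self-docking validation report
#'
#' Compares the pose of a co-crystallized ligand predicted by each docking
#' method with its experimental disposition and flags the methods whose RMSD
#' is below the acceptance threshold (strictly; the conventional bound is
#' 2.0 Angstrom).
#'
#' @param predicted either a named numeric vector of precomputed RMSD values
#'   (method -> Angstrom), or a named list of `pose`s to be compared against
#'   `reference` with [pose_rmsd()].
#' @param reference the crystallographic `pose` (required when `predicted`
#'   holds poses).
#' @param threshold acceptance threshold in Angstrom (default 2.0).
#' @param ... passed to [pose_rmsd()].
#' @return list of class `"selfdock_report"`: `table` (method, rmsd, pass,
#'   sorted by RMSD ascending), `n_pass`, `threshold`.
#' @export
selfdock_validate <- function(predicted, reference = NULL, threshold = 2.0, ...) {
  if (is.numeric(predicted)) {
    rmsd <- predicted
    if (is.null(names(rmsd))) names(rmsd) <- paste0("method", seq_along(rmsd))
  } else {
    if (is.null(reference)) stop("reference pose required when poses are supplied")
    rmsd <- vapply(predicted, function(p) pose_rmsd(reference, p, ...), numeric(1))
  }
  tab <- data.frame(method = names(rmsd), rmsd = unname(rmsd),
                    pass = unname(rmsd) < threshold, stringsAsFactors = FALSE)
  tab <- tab[order(tab$rmsd, tab$method), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, n_pass = sum(tab$pass), threshold = threshold),
            class = "selfdock_report")
}

#' @export
print.selfdock_report <- function(x, ...) {
  cat("<selfdock_report>", x$n_pass, "of", nrow(x$table),
      "methods below", x$threshold, "A\n")
  print(x$table)
  invisible(x)
}

#' Published MAGL self-docking RMSD values
#'
#' The self-docking RMSD (Angstrom) of 13 docking methods re-docking the
#' co-crystallized piperazinyl-pyrrolidine inhibitor into the human MAGL
#' crystal structure (PDB 5ZUN), as printed in the study this workflow
#' re-implements. Used as the standard input for the self-docking threshold
#' check.
#'
#' @return named numeric vector (13 methods).
#' @export
magl_selfdock_rmsd <- function() {
  c("Autodock 4.2" = 1.5, "Dock6" = 0.5, "Fred" = 3.8, "Glamdock" = 1.3,
    "Glide SP" = 0.6, "Glide XP" = 1.5, "Gold ASP" = 1.4,
    "Gold Chemscore" = 3.1, "Gold Goldscore" = 0.6, "Gold PLP" = 0.7,
    "Plants" = 3.2, "rDock" = 1.6, "Vina" = 9.4)
}

#' Agglomerative complete-linkage clustering of an RMSD matrix
#'
#' Clusters pose labels by repeatedly merging the pair of clusters with the
#' smallest complete-linkage (maximum member-pair) distance, stopping when
#' that distance reaches the threshold. Equal merge distances are resolved by
#' the lexicographically smallest label pair, so the partition is
#' deterministic.
#'
#' @param matrix symmetric nonnegative RMSD matrix (Angstrom) with zero
#'   diagonal; dimnames supply the labels.
#' @param threshold clustering threshold in Angstrom.
#' @return list of class `"consensus_result"`: `clusters` (list of label
#'   vectors partitioning the labels), `threshold`, and `full_consensus`
#'   (TRUE iff a single cluster remains, equivalently iff every off-diagonal
#'   value is below the threshold).
#' @export
complete_linkage <- function(matrix, threshold) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8))
    stop("RMSD matrix must be symmetric")
  if (any(diag(m) != 0)) stop("RMSD matrix must have a zero diagonal")
  if (any(m < 0)) stop("RMSD values must be nonnegative")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  clusters <- lapply(seq_len(nrow(m)), function(i) i)
  repeat {
    if (length(clusters) < 2L) break
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- max(m[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    if (best$d >= threshold) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  out <- lapply(clusters, function(idx) sort(labels[idx]))
  out <- out[order(vapply(out, `[`, character(1), 1))]
  structure(list(clusters = out, threshold = threshold,
                 full_consensus = length(out) == 1L),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>", length(x$clusters), "cluster(s) at",
      x$threshold, "A;", if (x$full_consensus) "FULL consensus" else "no full consensus", "\n")
  for (cl in x$clusters) cat(" ", paste(cl, collapse = ", "), "\n")
  invisible(x)
}

#' Full pose consensus across docking methods
#'
#' @param poses named list (method -> `pose`) of the top pose of one
#'   compound from each docking method (at least two).
#' @param threshold consensus threshold in Angstrom (default 2.0).
#' @param ... passed to [pose_rmsd()].
#' @return list: `full_consensus` (TRUE iff every reciprocal pairwise RMSD is
#'   strictly below the threshold), `rmsd` (the labeled matrix), `clustering`
#'   (the [complete_linkage()] result at the same threshold).
#' @export
full_consensus <- function(poses, threshold = 2.0, ...) {
  if (length(poses) < 2L) stop("need poses from at least two methods")
  n <- length(poses)
  labs <- names(poses)
  if (is.null(labs)) labs <- vapply(poses, `[[`, character(1), "method")
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  dots <- list(...)
  if (!isFALSE(dots$symmetry) && is.null(dots$automorphisms)) {
    ma <- if (inherits(poses[[1]], "pose")) poses[[1]]$molecule else poses[[1]]
    dots$automorphisms <- molecule_automorphisms(
      ma, if (is.null(dots$max_automorphisms)) 1e4 else dots$max_automorphisms)
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- do.call(
        pose_rmsd, c(list(poses[[i]], poses[[j]]), dots))
    }
  }
  cl <- complete_linkage(m, threshold)
  list(full_consensus = all(m[upper.tri(m)] < threshold), rmsd = m,
       clustering = cl)
}
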