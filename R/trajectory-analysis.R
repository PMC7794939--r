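# MD-trajectory analytics: ligand/water RMSD series, per-interaction
# occupancy, and the occupancy/drift acceptance filter.

superpose_frame <- function(traj, k) {
  f <- traj$frames[[k]]
  ca <- which(traj$protein$atoms$name == "CA")
  if (!length(ca)) return(f)
  ref <- traj$frames[[1]]
  tf <- kabsch_transform(f[ca, , drop = FALSE], ref[ca, , drop = FALSE])
  apply_transform(tf, f)
}

#' Ligand RMSD time series over a trajectory
#'
#' Per-frame heavy-atom RMSD of the ligand against its frame-1 coordinates,
#' optionally after least-squares superposition of the protein alpha-carbons
#' (the default: harmless on trajectories run with restrained alpha-carbons,
#' necessary on unrestrained ones).
#'
#' @param traj a `trajectory` (at least 2 frames).
#' @param superpose_on "protein-CA" (default) or "none".
#' @return list: `series` (per-frame RMSD, Angstrom; first entry 0), `mean`,
#'   `max`.
#' @export
ligand_rmsd_series <- function(traj, superpose_on = c("protein-CA", "none")) {
  superpose_on <- match.arg(superpose_on)
  if (n_frames(traj) < 2L) stop("trajectory has fewer than 2 frames")
  heavy <- which(heavy_atoms(traj$ligand))
  lidx <- traj$ligand_idx[heavy]
  ref <- traj$frames[[1]][lidx, , drop = FALSE]
  series <- vapply(seq_len(n_frames(traj)), function(k) {
    f <- if (superpose_on == "protein-CA") superpose_frame(traj, k) else traj$frames[[k]]
    sqrt(mean(rowSums((f[lidx, , drop = FALSE] - ref)^2)))
  }, numeric(1))
  list(series = series, mean = mean(series), max = max(series))
}

#' Water RMSD time series
#'
#' Tracks the displacement of a (structural) water oxygen from its frame-1
#' site. `tracking = "identity"` follows the same water molecule;
#' `tracking = "nearest"` follows whichever water oxygen is nearest to the
#' frame-1 site in each frame (for engines that exchange waters).
#'
#' @param traj a `trajectory`.
#' @param water `residue_selector` resolving to a water at frame 1.
#' @param tracking "identity" (default) or "nearest".
#' @param superpose_on "protein-CA" (default) or "none".
#' @return list: `series` (per-frame displacement, Angstrom), `mean`, `max`.
#' @export
water_rmsd_series <- function(traj, water, tracking = c("identity", "nearest"),
                              superpose_on = c("protein-CA", "none")) {
  tracking <- match.arg(tracking)
  superpose_on <- match.arg(superpose_on)
  widx <- resolve_selector(traj$protein, water)
  wo <- widx[toupper(traj$protein$atoms$element[widx]) == "O"]
  all_wo <- which(is_water(traj$protein) &
                    toupper(traj$protein$atoms$element) == "O")
  site <- traj$frames[[1]][traj$protein_idx[wo], ]
  series <- vapply(seq_len(n_frames(traj)), function(k) {
    f <- if (superpose_on == "protein-CA") superpose_frame(traj, k) else traj$frames[[k]]
    if (tracking == "identity") {
      sqrt(sum((f[traj$protein_idx[wo], ] - site)^2))
    } else {
      d <- sqrt(colSums((t(f[traj$protein_idx[all_wo], , drop = FALSE]) - site)^2))
      min(d)
    }
  }, numeric(1))
  list(series = series, mean = mean(series), max = max(series))
}

#' Per-interaction occupancy over a trajectory
#'
#' Evaluates the named interactions in every frame with the same geometric
#' machinery used for static poses and reports the fraction of frames in
#' which each holds. A direct H-bond interaction is specified as
#' `list(key =, lig_atoms =, partner = residue_selector)` and holds when any
#' named ligand atom is within the H-bond distance of a polar (N/O) atom of
#' the partner (of the named atom, if the selector carries one). A water
#' bridge is specified as `list(key =, water = selector, partners = list of
#' selectors)` and holds when [detect_water_bridge()] finds it.
#'
#' @param traj a `trajectory`.
#' @param interactions list of interaction specifications (see Details).
#' @param criteria an [interaction_criteria()].
#' @param water optional `residue_selector` of the structural water whose
#'   RMSD should be reported alongside.
#' @return list of class `"occupancy_report"`: `occupancy` (named fractions),
#'   `tracks` (named list of per-frame logical vectors), `n_frames`,
#'   `ligand_rmsd_mean`, `water_rmsd_mean` (NA without `water`).
#' @export
hbond_occupancy <- function(traj, interactions, criteria = interaction_criteria(),
                            water = NULL) {
  keys <- vapply(interactions, function(x) x$key, character(1))
  if (anyDuplicated(keys)) stop("interaction keys must be unique")
  # resolve selectors and ligand polar atoms once on the topology (feature
  # kinds and source atoms are conformer-independent)
  feats0 <- perceive_features(traj$ligand, 1L)
  lig_polar <- unique(unlist(feats0$atoms[feats0$kind %in% c("HBA", "HBD")]))
  resolved <- lapply(interactions, function(x) {
    if (!is.null(x$water)) {
      widx <- resolve_selector(traj$protein, x$water)
      if (!all(is_water(traj$protein)[widx]))
        stop("selector ", selector_label(x$water), " does not resolve to a water")
      x$water_o <- widx[toupper(traj$protein$atoms$element[widx]) == "O"]
      x$partner_idx <- lapply(x$partners, function(sel) {
        idx <- resolve_selector(traj$protein, sel)
        idx[toupper(traj$protein$atoms$element[idx]) %in% c("N", "O")]
      })
      x
    } else {
      idx <- resolve_selector(traj$protein, x$partner)
      idx <- idx[toupper(traj$protein$atoms$element[idx]) %in% c("N", "O")]
      if (!length(idx))
        stop("partner ", selector_label(x$partner), " has no polar atoms")
      x$prot_idx <- idx
      x
    }
  })
  nf <- n_frames(traj)
  tracks <- lapply(resolved, function(x) logical(nf))
  names(tracks) <- keys
  np <- length(traj$protein_idx)
  for (k in seq_len(nf)) {
    f <- traj$frames[[k]]
    p_xyz <- f[seq_len(np), , drop = FALSE]
    lig_xyz <- f[traj$ligand_idx, , drop = FALSE]
    for (q in seq_along(resolved)) {
      x <- resolved[[q]]
      present <- if (!is.null(x$water)) {
        # same geometry as detect_water_bridge, on precomputed atom sets
        w <- p_xyz[x$water_o, ]
        lig_arm <- length(lig_polar) &&
          min(sqrt(colSums((t(lig_xyz[lig_polar, , drop = FALSE]) - w)^2))) <=
            criteria$hbond_dist
        arm_ok <- any(vapply(x$partner_idx, function(idx)
          length(idx) > 0 &&
            min(sqrt(colSums((t(p_xyz[idx, , drop = FALSE]) - w)^2))) <=
              criteria$hbond_dist, logical(1)))
        isTRUE(lig_arm && arm_ok)
      } else {
        pxyz <- p_xyz[x$prot_idx, , drop = FALSE]
        any(vapply(x$lig_atoms, function(li)
          min(sqrt(colSums((t(pxyz) - lig_xyz[li, ])^2))) <= criteria$hbond_dist,
          logical(1)))
      }
      tracks[[q]][k] <- present
    }
  }
  lr <- ligand_rmsd_series(traj)
  wr <- if (!is.null(water)) water_rmsd_series(traj, water)$mean else NA_real_
  occ <- vapply(tracks, mean, numeric(1))
  structure(list(occupancy = occ, tracks = tracks, n_frames = nf,
                 ligand_rmsd_mean = lr$mean, ligand_rmsd_series = lr$series,
                 water_rmsd_mean = wr),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat("<occupancy_report>", x$n_frames, "frames; mean ligand RMSD",
      sprintf("%.2f", x$ligand_rmsd_mean), "A\n")
  print(round(x$occupancy, 3))
  invisible(x)
}

#' Acceptance criteria for the MD-trajectory filter
#'
#' @param max_mean_rmsd mean ligand RMSD must be strictly below this
#'   (Angstrom, default 2.0).
#' @param theta occupancy threshold; required occupancies must be strictly
#'   above it (default 0.70).
#' @param required keys whose occupancy must each exceed `theta`.
#' @param any_of keys of which at least one must exceed `theta` (e.g. the
#'   two oxyanion-hole amides).
#' @return list of class `"md_filter_spec"`.
#' @export
md_filter_spec <- function(max_mean_rmsd = 2.0, theta = 0.70,
                           required = character(0), any_of = character(0)) {
  stopifnot(theta > 0, theta < 1)
  structure(list(max_mean_rmsd = max_mean_rmsd, theta = theta,
                 required = required, any_of = any_of),
            class = "md_filter_spec")
}

#' Apply the MD acceptance filter to an occupancy report
#'
#' Passes when the mean ligand RMSD is strictly below the bound and every
#' required interaction (plus at least one of the `any_of` set) is
#' maintained for strictly more than the occupancy threshold.
#'
#' @param report an `occupancy_report` (must contain all keys the spec
#'   names).
#' @param spec an [md_filter_spec()].
#' @return list(pass = logical, reasons = character vector of failures).
#' @export
md_filter <- function(report, spec) {
  stopifnot(inherits(spec, "md_filter_spec"))
  need <- unique(c(spec$required, spec$any_of))
  miss <- setdiff(need, names(report$occupancy))
  if (length(miss))
    stop("report lacks interaction(s): ", paste(miss, collapse = ", "))
  reasons <- character(0)
  if (!(report$ligand_rmsd_mean < spec$max_mean_rmsd))
    reasons <- c(reasons, sprintf("mean ligand RMSD %.2f A (need < %.2f)",
                                  report$ligand_rmsd_mean, spec$max_mean_rmsd))
  for (key in spec$required) {
    if (!(report$occupancy[[key]] > spec$theta))
      reasons <- c(reasons, sprintf("occupancy(%s) = %.2f (need > %.2f)",
                                    key, report$occupancy[[key]], spec$theta))
  }
  if (length(spec$any_of) &&
      !any(report$occupancy[spec$any_of] > spec$theta))
    reasons <- c(reasons, sprintf("none of {%s} above %.2f",
                                  paste(spec$any_of, collapse = ", "), spec$theta))
  list(pass = length(reasons) == 0L, reasons = reasons)
}
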