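# Feature matching: in-place sphere matching of a pose against a model
# (exact maximum-cardinality assignment via depth-first search; model feature
# counts are small by construction) and alignment-mode matching of free
# conformers (mandatory-correspondence enumeration + Kabsch superposition).

# least-squares rigid transform mapping point set P onto Q (Kabsch)
kabsch_transform <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- t(sweep(P, 2, pc)) %*% sweep(Q, 2, qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.vector(qc - R %*% pc))
}

apply_transform <- function(tf, X) {
  sweep(as.matrix(X) %*% t(tf$R), 2, tf$t, `+`)
}

# matchable ligand points for model-feature kinds; HYD accepts both ligand
# HYD and ARO features, deduplicated by position so a ring counts once
matchable_points <- function(feats) {
  if (!nrow(feats))
    return(data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  hba <- feats[feats$kind == "HBA", c("kind", "x", "y", "z")]
  hbd <- feats[feats$kind == "HBD", c("kind", "x", "y", "z")]
  hyd <- feats[feats$kind %in% c("HYD", "ARO"), c("kind", "x", "y", "z")]
  if (nrow(hyd)) {
    hyd$kind <- "HYD"
    hyd <- hyd[!duplicated(round(as.matrix(hyd[, c("x", "y", "z")]), 6)), ]
  }
  out <- rbind(hba, hbd, hyd)
  rownames(out) <- NULL
  out
}

# exact maximum-cardinality, minimum-cost one-to-one assignment of model
# features to candidate points; candidates[[q]] = data.frame(point, dist)
assign_features <- function(n_feat, candidates) {
  best <- list(count = -1L, cost = Inf, sel = integer(0))
  sel <- integer(n_feat)
  recurse <- function(q, count, cost) {
    if (q > n_feat) {
      if (count > best$count ||
          (count == best$count && cost < best$cost - 1e-12)) {
        best <<- list(count = count, cost = cost, sel = sel[seq_len(n_feat)])
      }
      return(invisible(NULL))
    }
    if (count + (n_feat - q + 1L) < best$count) return(invisible(NULL))
    cand <- candidates[[q]]
    if (nrow(cand)) {
      for (r in seq_len(nrow(cand))) {
        p <- cand$point[r]
        if (p %in% sel[seq_len(q - 1L)]) next
        sel[q] <<- p
        recurse(q + 1L, count + 1L, cost + cand$dist[r])
      }
    }
    sel[q] <<- 0L
    recurse(q + 1L, count, cost)
  }
  recurse(1L, 0L, 0)
  best
}

match_result <- function(model, sel, points, ev_clash, transform = NULL) {
  f <- model$features
  matched <- which(sel > 0L)
  dists <- if (length(matched)) sqrt(rowSums(
    (as.matrix(f[matched, c("x", "y", "z")]) -
       as.matrix(points[sel[matched], c("x", "y", "z")]))^2)) else numeric(0)
  assignment <- data.frame(id = f$id[matched], kind = f$kind[matched],
                           point = sel[matched], distance = dists)
  structure(list(
    matched_ids = f$id[matched],
    assignment = assignment,
    n_matched = length(matched),
    mandatory_satisfied = all(f$id[f$mandatory] %in% f$id[matched]),
    ev_clash = ev_clash,
    rms = if (length(dists)) sqrt(mean(dists^2)) else NA_real_,
    transform = transform), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result>", x$n_matched, "features matched;",
      "mandatory", if (x$mandatory_satisfied) "satisfied" else "NOT satisfied;",
      if (x$ev_clash) "EXCLUDED-VOLUME CLASH" else "no EV clash", "\n")
  invisible(x)
}

ev_clash_check <- function(model, heavy_xyz) {
  ev <- model$excluded_volumes
  if (!nrow(ev)) return(FALSE)
  for (q in seq_len(nrow(ev))) {
    d2 <- colSums((t(heavy_xyz) - c(ev$x[q], ev$y[q], ev$z[q]))^2)
    if (any(d2 < ev$radius[q]^2 - 1e-12)) return(TRUE)
  }
  FALSE
}

#' Match a docking pose against a pharmacophore model in place
#'
#' Finds the maximum-cardinality one-to-one assignment of the pose's
#' perceived feature points to kind-compatible model features, where a pair
#' is feasible when the point lies within the feature's tolerance sphere.
#' The pose coordinates are never moved. Cardinality ties are broken by the
#' minimal sum of center distances, then by feature-id order, so the result
#' is deterministic.
#'
#' @param model a `pharmacophore_model`.
#' @param pose a `pose` (or posed `molecule`) in the model's frame.
#' @param check_ev if TRUE (default) any ligand heavy atom strictly inside an
#'   excluded-volume sphere sets `ev_clash`.
#' @return a `match_result`: matched ids, assignment table, `n_matched`,
#'   `mandatory_satisfied`, `ev_clash`, and the RMS of matched center
#'   distances.
#' @export
match_pose <- function(model, pose, check_ev = TRUE) {
  mol <- if (inherits(pose, "pose")) pose$molecule else pose
  feats <- perceive_features(mol, 1L)
  points <- matchable_points(feats)
  f <- model$features
  candidates <- lapply(seq_len(nrow(f)), function(q) {
    ok <- which(points$kind == f$kind[q])
    if (!length(ok)) return(data.frame(point = integer(0), dist = numeric(0)))
    d <- sqrt(colSums((t(as.matrix(points[ok, c("x", "y", "z")])) -
                         c(f$x[q], f$y[q], f$z[q]))^2))
    keep <- d <= f$radius[q]
    data.frame(point = ok[keep], dist = d[keep])
  })
  best <- assign_features(nrow(f), candidates)
  ev <- if (check_ev)
    ev_clash_check(model, conformer_coords(mol, 1L)[heavy_atoms(mol), , drop = FALSE])
  else FALSE
  match_result(model, best$sel, points, ev)
}

#' Screen a multi-conformer molecule against a model by rigid alignment
#'
#' For every conformer, candidate correspondences between the mandatory model
#' features and kind-compatible ligand feature points are enumerated, pruned
#' by pairwise-distance compatibility (a pair of model features and a pair of
#' ligand points are compatible when the two inter-center distances differ by
#' at most the sum of the two tolerance radii). Each surviving correspondence
#' is realized by least-squares rigid superposition of the matched points
#' onto the model centers; the placed conformer is then extended greedily to
#' optional features (nearest unused compatible point within tolerance) and
#' tested against the excluded volumes. Placements that clash with an
#' excluded volume are discarded.
#'
#' @param model a `pharmacophore_model`.
#' @param mol a `molecule` with one or more conformers.
#' @param max_correspondences combinatorial cap; when exceeded a warning is
#'   emitted and the best result found so far is returned.
#' @return the best `match_result` over all conformers, maximizing
#'   (`mandatory_satisfied`, `n_matched`, -RMS). Its `transform` element
#'   holds the rigid placement (`R`, `t`) and `conformer` the index used;
#'   `placed_coords` carries the aligned conformer coordinates.
#' @export
match_conformers <- function(model, mol, max_correspondences = 1e5) {
  f <- model$features
  mand <- which(f$mandatory)
  empty <- match_result(model, integer(nrow(f)),
                        data.frame(kind = character(0), x = numeric(0),
                                   y = numeric(0), z = numeric(0)), FALSE)
  best <- NULL
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    key_a <- c(a$mandatory_satisfied, a$n_matched, -ifelse(is.na(a$rms), Inf, a$rms))
    key_b <- c(b$mandatory_satisfied, b$n_matched, -ifelse(is.na(b$rms), Inf, b$rms))
    for (i in 1:3) {
      if (key_a[i] > key_b[i] + 1e-12) return(TRUE)
      if (key_a[i] < key_b[i] - 1e-12) return(FALSE)
    }
    FALSE
  }
  n_corr <- 0L
  capped <- FALSE
  mand_pos <- as.matrix(f[mand, c("x", "y", "z")])
  d_model <- as.matrix(dist(mand_pos))
  rsum <- outer(f$radius[mand], f$radius[mand], `+`)

  for (ci in seq_along(mol$conformers)) {
    feats <- perceive_features(mol, ci)
    points <- matchable_points(feats)
    if (!nrow(points)) next
    pmat <- as.matrix(points[, c("x", "y", "z")])
    d_lig <- as.matrix(dist(pmat))
    cand_by_feat <- lapply(mand, function(q) which(points$kind == f$kind[q]))
    if (any(!lengths(cand_by_feat))) next

    sel <- integer(length(mand))
    recurse <- function(q) {
      if (capped) return(invisible(NULL))
      if (q > length(mand)) {
        n_corr <<- n_corr + 1L
        if (n_corr > max_correspondences) { capped <<- TRUE; return(invisible(NULL)) }
        res <- realize_correspondence(model, mol, ci, points, pmat, mand, sel)
        if (!is.null(res) && better(res, best)) best <<- res
        return(invisible(NULL))
      }
      for (p in cand_by_feat[[q]]) {
        if (p %in% sel[seq_len(q - 1L)]) next
        ok <- TRUE
        for (r in seq_len(q - 1L)) {
          if (abs(d_model[r, q] - d_lig[sel[r], p]) > rsum[r, q]) { ok <- FALSE; break }
        }
        if (!ok) next
        sel[q] <<- p
        recurse(q + 1L)
        if (capped) return(invisible(NULL))
      }
      sel[q] <<- 0L
    }
    recurse(1L)
    if (capped) break
  }
  if (capped)
    warning("correspondence cap (", format(max_correspondences, scientific = FALSE),
            ") exceeded; returning best result so far")
  if (is.null(best)) empty else best
}

# place the conformer by the mandatory correspondence, extend greedily to
# optional features, test excluded volumes; NULL if the placement clashes
realize_correspondence <- function(model, mol, ci, points, pmat, mand, sel) {
  f <- model$features
  tf <- kabsch_transform(pmat[sel, , drop = FALSE],
                         as.matrix(f[mand, c("x", "y", "z")]))
  placed_pts <- apply_transform(tf, pmat)
  full_sel <- integer(nrow(f))
  used <- logical(nrow(points))
  for (k in seq_along(mand)) {
    q <- mand[k]
    d <- sqrt(sum((placed_pts[sel[k], ] - c(f$x[q], f$y[q], f$z[q]))^2))
    if (d <= f$radius[q]) { full_sel[q] <- sel[k]; used[sel[k]] <- TRUE }
  }
  for (q in which(!f$mandatory)) {
    ok <- which(points$kind == f$kind[q] & !used)
    if (!length(ok)) next
    d <- sqrt(colSums((t(placed_pts[ok, , drop = FALSE]) -
                         c(f$x[q], f$y[q], f$z[q]))^2))
    r <- which.min(d)
    if (d[r] <= f$radius[q]) { full_sel[q] <- ok[r]; used[ok[r]] <- TRUE }
  }
  placed_coords <- apply_transform(tf, conformer_coords(mol, ci))
  if (ev_clash_check(model, placed_coords[heavy_atoms(mol), , drop = FALSE]))
    return(NULL)
  placed_points <- points
  placed_points$x <- placed_pts[, 1]; placed_points$y <- placed_pts[, 2]
  placed_points$z <- placed_pts[, 3]
  res <- match_result(model, full_sel, placed_points, FALSE, transform = tf)
  res$conformer <- ci
  res$placed_coords <- placed_coords
  res
}

#' Screen a library of molecules against a pharmacophore model
#'
#' Runs [match_conformers()] on every molecule and ranks the hits by the
#' number of matched features (descending; ties broken by name). A molecule
#' is a hit when all mandatory features are matched, no excluded volume is
#' violated, and at least `min_features` features are matched.
#'
#' @param model a `pharmacophore_model`.
#' @param molecules list of `molecule`s.
#' @param min_features minimum matched-feature count for a hit; must be at
#'   least the number of mandatory features (the default).
#' @param ... passed to [match_conformers()].
#' @return list with `hits` (data.frame: name, n_matched, rms, in rank
#'   order), `results` (named list of `match_result`s for all molecules) and
#'   `levels` (data.frame: per matched-feature level `k`, the exact count
#'   `n_exact` and the cumulative count `n_at_least` of hits).
#' @export
screen_library <- function(model, molecules, min_features = NULL, ...) {
  n_mand <- sum(model$features$mandatory)
  if (is.null(min_features)) min_features <- n_mand
  if (min_features < n_mand)
    stop("min_features (", min_features, ") must be >= the number of mandatory features (",
         n_mand, ")")
  results <- lapply(molecules, function(m) match_conformers(model, m, ...))
  names(results) <- vapply(molecules, function(m) m$name, character(1))
  ok <- vapply(results, function(r)
    r$mandatory_satisfied && !r$ev_clash && r$n_matched >= min_features, logical(1))
  nm <- vapply(results, function(r) r$n_matched, integer(1))
  hits <- data.frame(name = names(results)[ok], n_matched = nm[ok],
                     rms = vapply(results[ok], function(r) r$rms, numeric(1)),
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$n_matched, hits$name), , drop = FALSE]
  rownames(hits) <- NULL
  ks <- seq(min_features, nrow(model$features))
  levels <- data.frame(k = ks,
                       n_exact = vapply(ks, function(k) sum(hits$n_matched == k), integer(1)),
                       n_at_least = vapply(ks, function(k) sum(hits$n_matched >= k), integer(1)))
  list(hits = hits, results = results, levels = levels)
}
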