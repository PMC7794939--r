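# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by exhaustive enumeration or via base-R/stats machinery,
# never by calling the implementation path they check.

# exhaustive best assignment of model features to candidate points:
# enumerates every injective (feature -> point or unassigned) combination,
# maximizing count then minimizing summed distance
oracle_best_assignment <- function(model, points) {
  f <- model$features
  n <- nrow(f)
  cand <- lapply(seq_len(n), function(q) {
    ok <- which(points$kind == f$kind[q])
    if (!length(ok)) return(list(p = integer(0), d = numeric(0)))
    d <- unname(sqrt(colSums((t(as.matrix(points[ok, c("x", "y", "z")])) -
                                c(f$x[q], f$y[q], f$z[q]))^2)))
    keep <- d <= f$radius[q]
    list(p = ok[keep], d = d[keep])
  })
  best <- list(count = -1L, cost = Inf)
  enum <- function(q, used, count, cost) {
    if (q > n) {
      if (count > best$count ||
          (count == best$count && cost < best$cost - 1e-12))
        best <<- list(count = count, cost = cost)
      return(invisible(NULL))
    }
    enum(q + 1L, used, count, cost)  # leave feature q unassigned
    for (r in seq_along(cand[[q]]$p)) {
      p <- cand[[q]]$p[r]
      if (!(p %in% used))
        enum(q + 1L, c(used, p), count + 1L, cost + cand[[q]]$d[r])
    }
  }
  enum(1L, integer(0), 0L, 0)
  best
}

# complete-linkage partition at a strict threshold via stats::hclust
oracle_complete_linkage <- function(m, threshold) {
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  hc <- stats::hclust(stats::as.dist(m), method = "complete")
  grp <- stats::cutree(hc, h = threshold - 1e-9)
  unname(split(labels, grp))
}

# canonical form of a partition (sorted list of sorted member vectors)
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, character(1), 1))]
}

# all element- and adjacency-preserving atom permutations (tiny molecules)
oracle_automorphisms <- function(mol) {
  n <- n_atoms(mol)
  el <- toupper(mol$atoms$element)
  adj <- matrix("", n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[i, j] <- adj[j, i] <- mol$bonds$order[k]
  }
  perms <- list()
  assign_next <- function(map) {
    q <- length(map) + 1L
    if (q > n) { perms[[length(perms) + 1L]] <<- map; return(invisible(NULL)) }
    for (p in seq_len(n)) {
      if (p %in% map || el[p] != el[q]) next
      ok <- TRUE
      for (r in seq_len(q - 1L)) {
        if (adj[r, q] != adj[map[r], p]) { ok <- FALSE; break }
      }
      if (ok) assign_next(c(map, p))
    }
  }
  assign_next(integer(0))
  perms
}

rmsd_under_perm <- function(xa, xb, perm, heavy) {
  sqrt(mean(rowSums((xa[heavy, , drop = FALSE] -
                       xb[perm[heavy], , drop = FALSE])^2)))
}

# random symmetric nonnegative matrix with zero diagonal (generic distances)
random_rmsd_matrix <- function(n, scale = 4) {
  m <- matrix(0, n, n)
  v <- stats::runif(n * (n - 1) / 2, 0.05, scale)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# tiny rigid-body helpers for constructing test poses
rotate_about_z <- function(xyz, angle, center = c(0, 0, 0)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center, `+`)
}

translate_mol <- function(mol, v) {
  set_coords(mol, sweep(conformer_coords(mol, 1L), 2, v, `+`))
}
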