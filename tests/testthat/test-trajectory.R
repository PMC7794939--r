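ref_interactions <- function(cx) {
  list(
    list(key = "A51", lig_atoms = 8L,
         partner = residue_selector("A", 51, atom = "N")),
    list(key = "M123", lig_atoms = 11L,
         partner = residue_selector("A", 123, atom = "N")),
    list(key = "R57", lig_atoms = 13L,
         partner = residue_selector("A", 57, atom = "NH1")),
    list(key = "water", lig_atoms = 15L, water = cx$structural_water,
         partners = cx$water_partners))
}

static_traj <- function(cx, n = 5, ligand_shift = NULL) {
  base <- rbind(protein_coords(cx$protein), conformer_coords(cx$ligand))
  frames <- lapply(seq_len(n), function(k) base)
  if (!is.null(ligand_shift)) {
    lidx <- nrow(protein_coords(cx$protein)) + seq_len(n_atoms(cx$ligand))
    for (k in 2:n) frames[[k]][lidx, ] <-
        sweep(frames[[k]][lidx, ], 2, ligand_shift, `+`)
  }
  trajectory(cx$protein, cx$ligand, frames)
}

test_that("ligand RMSD series: identical frames are zero, translation is exact", {
  cx <- make_reference_complex()
  still <- ligand_rmsd_series(static_traj(cx))
  expect_equal(still$series, rep(0, 5))
  expect_equal(still$mean, 0)

  moved <- ligand_rmsd_series(static_traj(cx, ligand_shift = c(1, 0, 0)),
                              superpose_on = "none")
  expect_equal(moved$series, c(0, rep(1, 4)), tolerance = 1e-12)
  # with restrained-CA-style frames the superposed result is identical
  moved_ca <- ligand_rmsd_series(static_traj(cx, ligand_shift = c(1, 0, 0)))
  expect_equal(moved_ca$series, moved$series, tolerance = 1e-9)
})

test_that("planted Gaussian jitter gives the closed-form mean squared RMSD", {
  cx <- make_reference_complex()
  sigma <- 0.25
  tr <- make_trajectory(cx$protein, cx$ligand, ref_interactions(cx),
                        occupancy = c(A51 = 1, M123 = 1, R57 = 1, water = 1),
                        n_frames = 200, jitter = sigma, seed = 21)
  s <- ligand_rmsd_series(tr$trajectory, superpose_on = "none")$series[-1]
  # E[RMSD^2] = 3 sigma^2 for isotropic per-coordinate jitter
  se <- stats::sd(s^2) / sqrt(length(s))
  expect_lt(abs(mean(s^2) - 3 * sigma^2), 3 * se)
})

test_that("water tracking: identity vs nearest agree without exchange, differ with it", {
  cx <- make_reference_complex()
  ints <- ref_interactions(cx)
  occ <- c(A51 = 1, M123 = 1, R57 = 1, water = 1)
  no_swap <- make_trajectory(cx$protein, cx$ligand, ints, occ,
                             n_frames = 20, jitter = 0.05, seed = 3)
  wi <- water_rmsd_series(no_swap$trajectory, cx$structural_water, "identity")
  wn <- water_rmsd_series(no_swap$trajectory, cx$structural_water, "nearest")
  expect_equal(wi$series, wn$series, tolerance = 1e-9)

  swapped <- make_trajectory(cx$protein, cx$ligand, ints, occ,
                             n_frames = 20, jitter = 0.05, seed = 3,
                             water_swap = TRUE)
  wi2 <- water_rmsd_series(swapped$trajectory, cx$structural_water, "identity")
  wn2 <- water_rmsd_series(swapped$trajectory, cx$structural_water, "nearest")
  expect_gt(wi2$mean, wn2$mean)   # identity follows the departed water
  expect_lt(wn2$mean, 1)
})

test_that("planted per-frame displacement gives an exact mean water RMSD", {
  cx <- make_reference_complex()
  widx <- resolve_selector(cx$protein, cx$structural_water)
  base <- rbind(protein_coords(cx$protein), conformer_coords(cx$ligand))
  frames <- lapply(1:10, function(k) {
    f <- base
    if (k > 1) f[widx, 1] <- f[widx, 1] + 0.5
    f
  })
  tr <- trajectory(cx$protein, cx$ligand, frames)
  w <- water_rmsd_series(tr, cx$structural_water)
  expect_equal(w$series, c(0, rep(0.5, 9)), tolerance = 1e-9)
  expect_equal(w$mean, 0.45, tolerance = 1e-9)
})

test_that("occupancy is recovered exactly for planted fractions", {
  cx <- make_reference_complex()
  ints <- ref_interactions(cx)
  occ <- c(A51 = 0.85, M123 = 0.7, R57 = 1.0, water = 0.85)
  tr <- make_trajectory(cx$protein, cx$ligand, ints, occ,
                        n_frames = 200, jitter = 0.08, seed = 8)
  rep_ <- hbond_occupancy(tr$trajectory, ints, water = cx$structural_water)
  expect_equal(rep_$occupancy[["A51"]], 0.85)
  expect_equal(rep_$occupancy[["M123"]], 0.70)
  expect_equal(rep_$occupancy[["R57"]], 1.0)
  expect_equal(rep_$occupancy[["water"]], 0.85)
  expect_equal(rep_$occupancy, tr$truth$occupancy)
  expect_equal(rep_$n_frames, 200L)
  # 7-of-10 counting sanity
  tr2 <- make_trajectory(cx$protein, cx$ligand, ints,
                         c(A51 = 0.7, M123 = 1, R57 = 1, water = 1),
                         n_frames = 10, jitter = 0.02, seed = 2)
  r2 <- hbond_occupancy(tr2$trajectory, ints)
  expect_equal(r2$occupancy[["A51"]], 0.7)
})

test_that("occupancy equals a brute-force frame loop on randomized geometry", {
  cx <- make_reference_complex()
  ints <- ref_interactions(cx)[c(1, 3)]   # two direct H-bonds
  set.seed(55)
  n <- 30
  base <- rbind(protein_coords(cx$protein), conformer_coords(cx$ligand))
  a51 <- resolve_selector(cx$protein, residue_selector("A", 51, atom = "N"))
  r57 <- resolve_selector(cx$protein, residue_selector("A", 57, atom = "NH1"))
  frames <- lapply(1:n, function(k) {
    f <- base
    f[a51, 2] <- f[a51, 2] + runif(1, -1.5, 1.5)
    f[r57, 2] <- f[r57, 2] + runif(1, -1.5, 1.5)
    f
  })
  tr <- trajectory(cx$protein, cx$ligand, frames)
  rep_ <- hbond_occupancy(tr, ints)
  lidx <- nrow(protein_coords(cx$protein))
  brute_a51 <- mean(vapply(frames, function(f)
    sqrt(sum((f[a51, ] - f[lidx + 8, ])^2)) <= 3.5, logical(1)))
  brute_r57 <- mean(vapply(frames, function(f)
    sqrt(sum((f[r57, ] - f[lidx + 13, ])^2)) <= 3.5, logical(1)))
  expect_equal(rep_$occupancy[["A51"]], brute_a51)
  expect_equal(rep_$occupancy[["R57"]], brute_r57)
  # occupancy is invariant to frame-order permutation
  perm <- sample(n)
  trp <- trajectory(cx$protein, cx$ligand, c(frames[1], frames[perm[perm != 1]]))
  repp <- hbond_occupancy(trp, ints)
  expect_equal(sort(repp$tracks[["A51"]]), sort(rep_$tracks[["A51"]]))
})

test_that("MD filter: the strong-binder occupancy profile passes", {
  report <- structure(list(
    occupancy = c(R57 = 0.98, water = 0.94, A51 = 0.82, M123 = 0.30),
    n_frames = 200L, ligand_rmsd_mean = 1.2, water_rmsd_mean = 0.5),
    class = "occupancy_report")
  spec <- md_filter_spec(required = c("R57", "water"),
                         any_of = c("A51", "M123"))
  v <- md_filter(report, spec)
  expect_true(v$pass)
  expect_length(v$reasons, 0L)
})

test_that("MD filter boundaries are strict and reasons are named", {
  spec <- md_filter_spec(required = c("R57", "water"),
                         any_of = c("A51", "M123"))
  drifted <- structure(list(
    occupancy = c(R57 = 1, water = 1, A51 = 1, M123 = 1),
    ligand_rmsd_mean = 2.5), class = "occupancy_report")
  v1 <- md_filter(drifted, spec)
  expect_false(v1$pass)
  expect_true(any(grepl("RMSD", v1$reasons)))

  boundary <- structure(list(
    occupancy = c(R57 = 0.70, water = 0.94, A51 = 0.82, M123 = 0.30),
    ligand_rmsd_mean = 1.2), class = "occupancy_report")
  v2 <- md_filter(boundary, spec)
  expect_false(v2$pass)                     # "more than 70%" is strict
  expect_true(any(grepl("R57", v2$reasons)))

  rmsd_edge <- structure(list(
    occupancy = c(R57 = 0.98, water = 0.94, A51 = 0.82, M123 = 0.30),
    ligand_rmsd_mean = 2.0), class = "occupancy_report")
  expect_false(md_filter(rmsd_edge, spec)$pass)   # "< 2.0 A" is strict

  missing_key <- structure(list(occupancy = c(R57 = 1), ligand_rmsd_mean = 1),
                           class = "occupancy_report")
  expect_error(md_filter(missing_key, spec), "lacks")
})

test_that("MD filter is monotone in occupancy and drift", {
  spec <- md_filter_spec(required = c("R57", "water"),
                         any_of = c("A51", "M123"))
  set.seed(19)
  for (rep_ in 1:50) {
    occ <- c(R57 = runif(1), water = runif(1), A51 = runif(1), M123 = runif(1))
    rmsd <- runif(1, 0, 3)
    base <- structure(list(occupancy = occ, ligand_rmsd_mean = rmsd),
                      class = "occupancy_report")
    improved <- structure(list(occupancy = pmin(occ + runif(4, 0, 0.2), 1),
                               ligand_rmsd_mean = rmsd * runif(1, 0.5, 1)),
                          class = "occupancy_report")
    if (md_filter(base, spec)$pass) expect_true(md_filter(improved, spec)$pass)
  }
})
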