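ref_model <- function() {
  cx <- make_reference_complex()
  list(cx = cx,
       model = build_receptor_model(cx$protein, cx$ligand,
                                    structural_waters = list(cx$structural_water)))
}

test_that("model constructor and JSON dialect round trip", {
  feats <- data.frame(id = 1:2, kind = c("HBA", "HYD"),
                      x = c(0, 3), y = 0, z = 0, radius = 1.5,
                      mandatory = c(TRUE, FALSE))
  ev <- data.frame(x = 5, y = 0, z = 0, radius = 1.2)
  m <- pharmacophore_model(feats, ev, frame_note = "toy")
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  back <- read_model(f)
  expect_equal(back$features, m$features)
  expect_equal(back$excluded_volumes, m$excluded_volumes)
  expect_equal(back$frame_note, "toy")

  expect_error(pharmacophore_model(transform(feats, mandatory = FALSE)),
               "mandatory")
  expect_error(pharmacophore_model(transform(feats, radius = 0)), "radii")
  expect_error(pharmacophore_model(transform(feats, id = c(1, 1))), "unique")
})

test_that("receptor-based model reproduces the 4 HBA + 4 HYD / 5-mandatory topology", {
  rm_ <- ref_model()
  f <- rm_$model$features
  expect_equal(sum(f$kind == "HBA"), 4L)
  expect_equal(sum(f$kind == "HYD"), 4L)
  expect_equal(sum(f$mandatory), 5L)
  expect_true(all(f$mandatory[f$kind == "HBA"]))
  # the mandatory HYD is the best-contacted one (the stacked ring site)
  expect_equal(f$id[f$kind == "HYD" & f$mandatory], 5L)
  # explicit override is honored
  m2 <- build_receptor_model(rm_$cx$protein, rm_$cx$ligand,
                             structural_waters = list(rm_$cx$structural_water),
                             config = model_config(mandatory = c(1L, 2L)))
  expect_equal(m2$features$id[m2$features$mandatory], c(1L, 2L))
})

test_that("a ligand far from the pocket gives an empty-model error", {
  cx <- make_reference_complex()
  far <- translate_mol(cx$ligand, c(0, 0, 20))
  expect_error(
    build_receptor_model(cx$protein, far,
                         structural_waters = list(cx$structural_water)),
    "empty model|no protein-ligand interactions")
})

test_that("excluded-volume set equals a brute-force shell scan", {
  rm_ <- ref_model()
  cx <- rm_$cx
  lig_heavy <- conformer_coords(cx$ligand)[heavy_atoms(cx$ligand), ]
  pxyz <- protein_coords(cx$protein)
  at <- cx$protein$atoms
  in_shell <- vapply(seq_len(nrow(at)), function(i)
    toupper(at$element[i]) != "H" &&
      min(sqrt(colSums((t(lig_heavy) - pxyz[i, ])^2))) <= 6.0, logical(1))
  # H-bond partner atoms: the three donors and the water oxygen
  partners <- c(resolve_selector(cx$protein, residue_selector("A", 51, atom = "N")),
                resolve_selector(cx$protein, residue_selector("A", 123, atom = "N")),
                resolve_selector(cx$protein, residue_selector("A", 57, atom = "NH1")),
                resolve_selector(cx$protein, cx$structural_water))
  expect_equal(nrow(rm_$model$excluded_volumes),
               length(setdiff(which(in_shell), partners)))
})

test_that("in-place matching: exact placement, displacement, and EV clash", {
  rm_ <- ref_model()
  model <- rm_$model
  res <- match_pose(model, rm_$cx$ligand)
  expect_equal(res$n_matched, 8L)
  expect_true(res$mandatory_satisfied)
  expect_false(res$ev_clash)
  expect_equal(res$rms, 0)

  # displace the whole ligand just beyond one tolerance radius along +y:
  # feature spheres are 1.5 A, so a 1.6 A shift must lose features
  shifted <- translate_mol(rm_$cx$ligand, c(0, 1.6, 0))
  res2 <- match_pose(model, shifted)
  expect_lt(res2$n_matched, 8L)
  expect_false(res2$mandatory_satisfied)

  # a ligand atom pushed into the receptor wall trips the EV flag
  into_wall <- translate_mol(rm_$cx$ligand, c(0, 0, 3.0))
  res3 <- match_pose(model, into_wall)
  expect_true(res3$ev_clash)
})

test_that("match_pose equals exhaustive assignment enumeration on random cases", {
  rm_ <- ref_model()
  model <- rm_$model
  set.seed(42)
  for (rep_ in 1:50) {
    lib <- make_library(model, sizes = sample(5:8, 1), seed = rep_, jitter = 0.4)
    m <- lib$molecules[[1]]
    # random in-pocket perturbation of the planted frame: re-plant the star
    # near the model and jitter strongly so assignments become ambiguous
    planted <- pharmflow:::star_molecule("probe", model, model$features$id,
                                         jitter = runif(1, 0.5, 1.6))
    res <- match_pose(model, planted, check_ev = FALSE)
    oracle <- oracle_best_assignment(
      model, pharmflow:::matchable_points(perceive_features(planted)))
    expect_equal(res$n_matched, oracle$count)
    if (res$n_matched > 0)
      expect_equal(sum(res$assignment$distance), oracle$cost, tolerance = 1e-9)
  }
})

test_that("alignment-mode matching is invariant to the ligand frame", {
  rm_ <- ref_model()
  model <- rm_$model
  xyz <- conformer_coords(rm_$cx$ligand)
  rot <- rotate_about_z(xyz, 1.1, center = c(30, -20, 5))
  moved <- set_coords(rm_$cx$ligand, sweep(rot, 2, c(15, 40, -3), `+`))
  res <- match_conformers(model, moved)
  expect_equal(res$n_matched, 8L)
  expect_true(res$mandatory_satisfied)
  expect_lt(res$rms, 0.1)
})

test_that("a molecule without acceptors cannot satisfy the mandatory set", {
  rm_ <- ref_model()
  m <- molecule("apolar", c("C", "C", "C"),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.3, 0)),
                data.frame(i = c(1, 2), j = c(2, 3), order = "1"))
  res <- match_conformers(rm_$model, m)
  expect_false(res$mandatory_satisfied)
})

test_that("planted match sizes k in 5..8 are recovered for 20 fixture molecules", {
  rm_ <- ref_model()
  sizes <- rep(5:8, each = 5)
  lib <- make_library(rm_$model, sizes = sizes, seed = 99)
  got <- vapply(lib$molecules, function(m)
    match_conformers(rm_$model, m)$n_matched, integer(1))
  expect_equal(got, sizes)
})

test_that("screening a planted 100-molecule library reproduces level counts", {
  rm_ <- ref_model()
  sizes <- c(rep(8, 10), rep(7, 20), rep(6, 30), rep(5, 40))
  lib <- make_library(rm_$model, sizes = sizes, seed = 5)
  sc <- screen_library(rm_$model, lib$molecules, min_features = 5)
  lv <- sc$levels
  expect_equal(lv$n_at_least[lv$k == 8], 10L)
  expect_equal(lv$n_at_least[lv$k == 7], 30L)
  expect_equal(lv$n_at_least[lv$k == 6], 60L)
  expect_equal(lv$n_at_least[lv$k == 5], 100L)
  # cumulativity: hits at level k+1 are a subset of hits at level k
  expect_true(all(diff(lv$n_at_least) <= 0))
  # ranking is by n_matched descending with name tie-break
  expect_true(all(diff(sc$hits$n_matched) <= 0))
})

test_that("screening an empty library yields an empty hit list", {
  rm_ <- ref_model()
  sc <- screen_library(rm_$model, list())
  expect_equal(nrow(sc$hits), 0L)
  expect_true(all(sc$levels$n_at_least == 0L))
})

test_that("min_features below the mandatory count is rejected", {
  rm_ <- ref_model()
  expect_error(screen_library(rm_$model, list(), min_features = 3),
               "mandatory")
})

test_that("joint rigid motion of query and molecule leaves the match unchanged", {
  rm_ <- ref_model()
  model <- rm_$model
  lib <- make_library(model, sizes = 7, seed = 12)
  planted <- pharmflow:::star_molecule("p", model,
                                       model$features$id[c(1:5, 7)], jitter = 0.2)
  base <- match_pose(model, planted, check_ev = FALSE)

  shift <- c(3, -7, 11)
  model2 <- model
  model2$features$x <- model$features$x + shift[1]
  model2$features$y <- model$features$y + shift[2]
  model2$features$z <- model$features$z + shift[3]
  moved <- translate_mol(planted, shift)
  res <- match_pose(model2, moved, check_ev = FALSE)
  expect_equal(res$n_matched, base$n_matched)
  expect_equal(res$rms, base$rms, tolerance = 1e-9)
})

test_that("the correspondence cap degrades gracefully with a warning", {
  rm_ <- ref_model()
  lib <- make_library(rm_$model, sizes = 8, seed = 2)
  expect_warning(res <- match_conformers(rm_$model, lib$molecules[[1]],
                                         max_correspondences = 1),
                 "cap")
  expect_s3_class(res, "match_result")
})
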