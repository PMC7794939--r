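toy_protein <- function(n_pos = c(0, 2.9, 0)) {
  protein_structure(data.frame(
    chain = "A", resno = 1, insert = "", resname = "GLY",
    name = c("N", "CA"), element = c("N", "C"),
    x = c(n_pos[1], n_pos[1] + 1.2), y = c(n_pos[2], n_pos[2] + 0.9),
    z = c(n_pos[3], n_pos[3])))
}

carbonyl_at <- function(o_pos) {
  molecule("probe", c("C", "O"),
           rbind(o_pos + c(0, -1.23, 0), o_pos),
           data.frame(i = 1, j = 2, order = "2"))
}

test_that("H-bond detection honors the distance cutoff", {
  crit <- interaction_criteria()
  near <- detect_interactions(toy_protein(), carbonyl_at(c(0, 0, 0)), crit)
  expect_equal(sum(vapply(near$records, function(r) r$type == "HBOND",
                          logical(1))), 1L)
  expect_equal(near$records[[1]]$distance, 2.9, tolerance = 1e-9)

  far <- detect_interactions(toy_protein(c(0, 3.6, 0)),
                             carbonyl_at(c(0, 0, 0)), crit)
  expect_equal(length(far$records), 0L)
})

test_that("loosening the cutoff never removes a detected interaction", {
  cx <- make_reference_complex()
  tight <- detect_interactions(cx$protein, cx$ligand,
                               interaction_criteria(hbond_dist = 3.0,
                                                    hydrophobic_dist = 4.0))
  loose <- detect_interactions(cx$protein, cx$ligand,
                               interaction_criteria(hbond_dist = 3.8,
                                                    hydrophobic_dist = 5.0))
  key <- function(det) paste(det$table$type, det$table$key)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("the reference complex shows its planted interaction inventory", {
  cx <- make_reference_complex()
  det <- detect_interactions(cx$protein, cx$ligand)
  tab <- det$table
  hb <- tab[tab$type == "HBOND", ]
  expect_equal(sort(hb$key), c("A123", "A51", "A57"))
  expect_true(all(hb$distance <= 3.5))
  hyd <- tab[tab$type == "HYDROPHOBIC", ]
  expect_true(all(c("A179", "A194", "A205", "A213", "A241") %in% hyd$key))
  expect_gte(nrow(hyd), 4L)
  expect_equal(tab$key[tab$type == "PI_STACK"], "A194")
})

test_that("detection is invariant under rigid motion of the whole complex", {
  cx <- make_reference_complex()
  det1 <- detect_interactions(cx$protein, cx$ligand)
  rot <- function(xyz) rotate_about_z(xyz, 0.7, center = c(5, 5, 5)) +
    matrix(c(10, -4, 2), nrow(xyz), 3, byrow = TRUE)
  prot2 <- set_protein_coords(cx$protein, rot(protein_coords(cx$protein)))
  lig2 <- set_coords(cx$ligand, rot(conformer_coords(cx$ligand)))
  det2 <- detect_interactions(prot2, lig2)
  expect_equal(det1$table$type, det2$table$type)
  expect_equal(det1$table$key, det2$table$key)
  expect_equal(det1$table$distance, det2$table$distance, tolerance = 1e-6)
})

test_that("water bridge: planted geometry found, absent geometry rejected", {
  cx <- make_reference_complex()
  wb <- detect_water_bridge(cx$protein, cx$ligand, cx$structural_water,
                            cx$water_partners)
  expect_false(is.null(wb))
  expect_setequal(wb$partners, c("GLUA53", "HISA272"))
  expect_lte(wb$distance, 3.5)

  # move the water 5 A away: no bridge
  prot2 <- cx$protein
  widx <- resolve_selector(prot2, cx$structural_water)
  prot2$atoms$y[widx] <- prot2$atoms$y[widx] - 5
  expect_null(detect_water_bridge(prot2, cx$ligand, cx$structural_water,
                                  cx$water_partners))

  # a non-water selector errors
  expect_error(detect_water_bridge(cx$protein, cx$ligand,
                                   residue_selector("A", 51),
                                   cx$water_partners),
               "not resolve to a water")
})

test_that("water-bridge predicate equals a brute-force distance check", {
  cx <- make_reference_complex()
  crit <- interaction_criteria()
  widx <- resolve_selector(cx$protein, cx$structural_water)
  set.seed(7)
  for (rep_ in 1:40) {
    prot <- cx$protein
    prot$atoms$x[widx] <- prot$atoms$x[widx] + runif(1, -3, 3)
    prot$atoms$y[widx] <- prot$atoms$y[widx] + runif(1, -3, 3)
    got <- !is.null(detect_water_bridge(prot, cx$ligand, cx$structural_water,
                                        cx$water_partners, crit))
    w <- unlist(prot$atoms[widx, c("x", "y", "z")], use.names = FALSE)
    feats <- perceive_features(cx$ligand)
    lp <- unique(unlist(feats$atoms[feats$kind %in% c("HBA", "HBD")]))
    lig_arm <- min(sqrt(colSums((t(conformer_coords(cx$ligand)[lp, , drop = FALSE]) -
                                   w)^2))) <= crit$hbond_dist
    arm_ok <- FALSE
    for (sel in cx$water_partners) {
      idx <- resolve_selector(prot, sel)
      idx <- idx[toupper(prot$atoms$element[idx]) %in% c("N", "O")]
      d <- sqrt(colSums((t(as.matrix(prot$atoms[idx, c("x", "y", "z")])) - w)^2))
      if (min(d) <= crit$hbond_dist) arm_ok <- TRUE
    }
    expect_equal(got, lig_arm && arm_ok)
  }
})

test_that("pose filter passes the reference pose and names what breaks", {
  cx <- make_reference_complex()
  model <- build_receptor_model(cx$protein, cx$ligand,
                                structural_waters = list(cx$structural_water))
  spec <- pose_filter_spec(
    hbond_partners = cx$hbond_partners,
    water = list(water = cx$structural_water, partners = cx$water_partners))
  ref <- filter_pose(cx$protein, pose(cx$ligand, "xtal"), spec, model)
  expect_true(ref$pass)
  expect_length(ref$reasons, 0L)

  # push the R57-bound carbonyl oxygen out of H-bond range
  lig2 <- cx$ligand
  xyz <- conformer_coords(lig2)
  xyz[13, 2] <- xyz[13, 2] - 1.2   # O3 away from the Arg donor
  lig2 <- set_coords(lig2, xyz)
  broken <- filter_pose(cx$protein, pose(lig2, "xtal"), spec, model)
  expect_false(broken$pass)
  expect_true(any(grepl("57", broken$reasons)))

  # deleting the water breaks exactly the water-bridge requirement
  keep <- !is_water(cx$protein)
  dry <- protein_structure(cx$protein$atoms[keep,
    c("type", "chain", "resno", "insert", "resname", "name", "element", "x", "y", "z")])
  spec_dry <- pose_filter_spec(
    hbond_partners = cx$hbond_partners,
    water = list(water = cx$structural_water, partners = cx$water_partners))
  expect_error(filter_pose(dry, pose(cx$ligand, "x"), spec_dry, model),
               "matches no residue")
})

test_that("filter verdicts agree with an independent composition on perturbed poses", {
  cx <- make_reference_complex()
  model <- build_receptor_model(cx$protein, cx$ligand,
                                structural_waters = list(cx$structural_water))
  spec <- pose_filter_spec(
    hbond_partners = cx$hbond_partners,
    water = list(water = cx$structural_water, partners = cx$water_partners))
  crit <- interaction_criteria()
  hyd_model <- model
  hyd_model$features <- model$features[model$features$kind == "HYD", ]
  hyd_model$features$mandatory <- c(TRUE, FALSE, FALSE, FALSE)

  set.seed(31)
  n_checked <- 0L
  for (rep_ in 1:100) {
    shift <- stats::rnorm(3, 0, 0.6)
    p <- pose(translate_mol(cx$ligand, shift), "perturbed")
    got <- filter_pose(cx$protein, p, spec, model, crit)

    det <- detect_interactions(cx$protein, p, crit)
    keys <- vapply(det$records, function(r)
      if (r$type == "HBOND") r$key else "", character(1))
    want_hb <- all(c("A51", "A57", "A123") %in% keys)
    want_wb <- !is.null(detect_water_bridge(cx$protein, p, cx$structural_water,
                                            cx$water_partners, crit))
    n_hyd <- match_pose(hyd_model, p, check_ev = FALSE)$n_matched
    expect_equal(got$pass, want_hb && want_wb && n_hyd >= 2L)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 100L)
})

test_that("method intersection behaves like a set fold", {
  expect_equal(intersect_by_method(list(m1 = c("a", "b"), m2 = c("b", "c"))), "b")
  expect_equal(intersect_by_method(list(m1 = c("b", "a"))), c("a", "b"))
  expect_error(intersect_by_method(list()), "at least one")
  set.seed(13)
  for (rep_ in 1:20) {
    sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
    names(sets) <- paste0("m", 1:4)
    folded <- sort(Reduce(intersect, sets[sample(4)]))
    expect_equal(intersect_by_method(sets), folded)
  }
})
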