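# Geometric protein-ligand interaction detection. All criteria are
# heavy-atom based so un-protonated structures work; the donor-angle term is
# applied only when an explicit hydrogen is present.

#' Geometric criteria for interaction detection
#'
#' @param hbond_dist max heavy-atom donor-acceptor distance in Angstrom.
#' @param hbond_angle min donor-H...acceptor angle in degrees (used only when
#'   the donor hydrogen is present in the structure).
#' @param hydrophobic_dist max apolar-apolar heavy-atom distance in Angstrom.
#' @param pistack_dist max aromatic ring centroid-centroid distance.
#' @param pistack_angle max interplanar angle in degrees for face-to-face
#'   pi-stacking.
#' @return list of class `"interaction_criteria"`.
#' @export
interaction_criteria <- function(hbond_dist = 3.5, hbond_angle = 120,
                                 hydrophobic_dist = 4.5,
                                 pistack_dist = 4.5, pistack_angle = 30) {
  stopifnot(hbond_dist > 0, hydrophobic_dist > 0, pistack_dist > 0,
            hbond_angle > 0, hbond_angle < 180,
            pistack_angle > 0, pistack_angle < 180)
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 hydrophobic_dist = hydrophobic_dist,
                 pistack_dist = pistack_dist, pistack_angle = pistack_angle),
            class = "interaction_criteria")
}

# protein heavy atom is apolar if C/S/halogen with no N/O within bonding range
protein_apolar <- function(protein) {
  at <- protein$atoms
  el <- toupper(at$element)
  xyz <- protein_coords(protein)
  no_idx <- which(el %in% c("N", "O"))
  cand <- el %in% c("C", "S") | el %in% HALOGENS
  out <- logical(nrow(at))
  for (i in which(cand)) {
    if (length(no_idx)) {
      d2 <- colSums((t(xyz[no_idx, , drop = FALSE]) - xyz[i, ])^2)
      if (any(d2 < 1.8^2)) next
    }
    out[i] <- TRUE
  }
  out
}

SIDECHAIN_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

interaction_record <- function(type, key, resname, lig_atoms, prot_atoms,
                               distance, angle = NA_real_, n_contacts = NA_integer_,
                               extra = NULL) {
  rec <- list(type = type, key = key, resname = resname,
              lig_atoms = lig_atoms, prot_atoms = prot_atoms,
              distance = distance, angle = angle, n_contacts = n_contacts)
  c(rec, extra)
}

records_table <- function(records) {
  if (!length(records))
    return(data.frame(type = character(0), key = character(0),
                      resname = character(0), lig_atoms = character(0),
                      prot_atoms = character(0), distance = numeric(0),
                      angle = numeric(0), n_contacts = integer(0)))
  do.call(rbind, lapply(records, function(r)
    data.frame(type = r$type, key = r$key, resname = r$resname,
               lig_atoms = paste(r$lig_atoms, collapse = "+"),
               prot_atoms = paste(r$prot_atoms, collapse = "+"),
               distance = r$distance, angle = r$angle,
               n_contacts = r$n_contacts, stringsAsFactors = FALSE)))
}

#' Detect protein-ligand interactions for a docking pose
#'
#' Finds hydrogen bonds, per-residue hydrophobic contacts, and face-to-face
#' pi-stacking between a pose and a protein, using purely geometric criteria.
#' Water residues are not listed as direct H-bond partners; water-mediated
#' contacts are the business of [detect_water_bridge()].
#'
#' @param protein a `protein`.
#' @param pose a `pose` (or a `molecule` posed in the receptor frame).
#' @param criteria an [interaction_criteria()] object.
#' @return list with `records` (list of interaction records, sorted by type
#'   then residue) and `table` (a flat data.frame view).
#' @details H-bonds require a ligand N/O and a protein N/O within
#'   `hbond_dist` with chemically possible donor/acceptor roles: protein N
#'   (backbone or side chain) and hydroxyl O (Ser/Thr/Tyr) count as donors,
#'   protein O (and His ring N) as acceptors; ligand roles come from feature
#'   perception. Hydrophobic contacts are aggregated per residue. A ligand
#'   centroid further than 50 Angstrom from the protein centroid triggers a
#'   frame-mismatch warning.
#' @export
detect_interactions <- function(protein, pose, criteria = interaction_criteria()) {
  mol <- if (inherits(pose, "pose")) pose$molecule else pose
  lig_xyz <- conformer_coords(mol, 1L)
  prot_xyz <- protein_coords(protein)
  at <- protein$atoms
  el_p <- toupper(at$element)
  el_l <- toupper(mol$atoms$element)
  wat <- is_water(protein)

  if (sqrt(sum((colMeans(lig_xyz) - colMeans(prot_xyz))^2)) > 50)
    warning("ligand centroid is > 50 A from the protein centroid; frame mismatch?")

  feats <- perceive_features(mol, 1L)
  lig_acc <- unique(unlist(feats$atoms[feats$kind == "HBA"]))
  lig_don <- unique(unlist(feats$atoms[feats$kind == "HBD"]))

  prot_donor <- (el_p == "N" |
                   (el_p == "O" & at$name %in% c("OG", "OG1", "OH"))) & !wat
  prot_acc <- (el_p == "O" | (el_p == "N" & at$name %in% c("ND1", "NE2"))) & !wat

  nb <- bond_neighbors(mol)
  records <- list()

  # --- hydrogen bonds -------------------------------------------------------
  lig_polar <- sort(unique(c(lig_acc, lig_don)))
  for (li in lig_polar) {
    cand <- which((prot_donor & (li %in% lig_acc)) |
                    (prot_acc & (li %in% lig_don)))
    if (!length(cand)) next
    d <- sqrt(colSums((t(prot_xyz[cand, , drop = FALSE]) - lig_xyz[li, ])^2))
    for (q in which(d <= criteria$hbond_dist)) {
      pi_ <- cand[q]
      ang <- NA_real_
      if (li %in% lig_don && !(li %in% lig_acc)) {
        # ligand is the donor: apply the angle test if its H is explicit
        h_nb <- nb[[li]][el_l[nb[[li]]] == "H"]
        if (length(h_nb)) {
          ang <- max(vapply(h_nb, function(h)
            vec_angle(lig_xyz[li, ] - lig_xyz[h, ], prot_xyz[pi_, ] - lig_xyz[h, ]),
            numeric(1)))
          if (ang < criteria$hbond_angle) next
        }
      }
      records[[length(records) + 1L]] <- interaction_record(
        "HBOND", at$key[pi_], at$resname[pi_], li, at$name[pi_], d[q], angle = ang,
        extra = list(lig_atom = li, prot_idx = pi_))
    }
  }

  # --- hydrophobic contacts, aggregated per residue -------------------------
  lig_apolar <- which(apolar_atoms(mol) & el_l != "H")
  p_apolar <- which(protein_apolar(protein))
  if (length(lig_apolar) && length(p_apolar)) {
    hits <- list()
    for (li in lig_apolar) {
      d <- sqrt(colSums((t(prot_xyz[p_apolar, , drop = FALSE]) - lig_xyz[li, ])^2))
      ok <- which(d <= criteria$hydrophobic_dist)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(li = li, pi = p_apolar[ok], d = d[ok])
    }
    if (length(hits)) {
      hits <- do.call(rbind, hits)
      for (key in sort(unique(at$key[hits$pi]))) {
        sub <- hits[at$key[hits$pi] == key, , drop = FALSE]
        records[[length(records) + 1L]] <- interaction_record(
          "HYDROPHOBIC", key, at$resname[sub$pi[1]],
          sort(unique(sub$li)), sort(unique(at$name[sub$pi])),
          min(sub$d), n_contacts = nrow(sub))
      }
    }
  }

  # --- face-to-face pi-stacking ---------------------------------------------
  lig_rings <- feats[feats$kind == "ARO", , drop = FALSE]
  if (nrow(lig_rings)) {
    for (key in unique(at$key[at$resname %in% names(SIDECHAIN_RINGS)])) {
      ridx <- which(at$key == key)
      ring_defs <- SIDECHAIN_RINGS[[at$resname[ridx[1]]]]
      for (def in ring_defs) {
        sel <- ridx[at$name[ridx] %in% def]
        if (length(sel) < 5L) next
        ctr <- colMeans(prot_xyz[sel, , drop = FALSE])
        nrm <- ring_normal(prot_xyz[sel, , drop = FALSE])
        for (q in seq_len(nrow(lig_rings))) {
          lctr <- c(lig_rings$x[q], lig_rings$y[q], lig_rings$z[q])
          lnrm <- c(lig_rings$dx[q], lig_rings$dy[q], lig_rings$dz[q])
          dd <- sqrt(sum((ctr - lctr)^2))
          aa <- vec_angle(nrm, lnrm)
          aa <- min(aa, 180 - aa)
          if (dd <= criteria$pistack_dist && aa <= criteria$pistack_angle)
            records[[length(records) + 1L]] <- interaction_record(
              "PI_STACK", key, at$resname[ridx[1]],
              lig_rings$atoms[[q]], sort(at$name[sel]), dd, angle = aa)
        }
      }
    }
  }

  ord <- order(vapply(records, function(r)
    paste(match(r$type, c("HBOND", "WATER_BRIDGE", "HYDROPHOBIC", "PI_STACK")),
          r$key), character(1)))
  records <- records[ord]
  list(records = records, table = records_table(records))
}

vec_angle <- function(a, b) {
  cosv <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Detect a water-bridged hydrogen bond
#'
#' Tests whether the ligand is H-bonded to a named water molecule that is
#' itself H-bonded to at least one of the named partner residues (the
#' structural-water network motif).
#'
#' @param protein a `protein`.
#' @param pose a `pose` (or posed `molecule`).
#' @param water `residue_selector` resolving to one water molecule.
#' @param partners list of `residue_selector`s for the polar partners the
#'   water may bridge to (any N/O atom of the selected residue counts).
#' @param criteria an [interaction_criteria()].
#' @return an interaction record (type `WATER_BRIDGE`) listing which partners
#'   are bridged, or `NULL` when no bridge is present.
#' @export
detect_water_bridge <- function(protein, pose, water, partners,
                                criteria = interaction_criteria()) {
  mol <- if (inherits(pose, "pose")) pose$molecule else pose
  widx <- resolve_selector(protein, water)
  if (!all(is_water(protein)[widx]))
    stop("selector ", selector_label(water), " does not resolve to a water")
  wo <- widx[toupper(protein$atoms$element[widx]) == "O"]
  w_pos <- unlist(protein$atoms[wo, c("x", "y", "z")])

  feats <- perceive_features(mol, 1L)
  lig_polar <- unique(unlist(feats$atoms[feats$kind %in% c("HBA", "HBD")]))
  if (!length(lig_polar)) return(NULL)
  lig_xyz <- conformer_coords(mol, 1L)
  d_lig <- sqrt(colSums((t(lig_xyz[lig_polar, , drop = FALSE]) - w_pos)^2))
  if (min(d_lig) > criteria$hbond_dist) return(NULL)

  prot_xyz <- protein_coords(protein)
  bridged <- list()
  for (sel in partners) {
    idx <- resolve_selector(protein, sel)
    idx <- idx[toupper(protein$atoms$element[idx]) %in% c("N", "O")]
    if (!length(idx)) next
    d <- sqrt(colSums((t(prot_xyz[idx, , drop = FALSE]) - w_pos)^2))
    if (min(d) <= criteria$hbond_dist)
      bridged[[length(bridged) + 1L]] <- list(label = selector_label(sel),
                                              distance = min(d))
  }
  if (!length(bridged)) return(NULL)
  interaction_record(
    "WATER_BRIDGE", protein$atoms$key[wo], "HOH",
    lig_polar[which.min(d_lig)], "O", min(d_lig),
    extra = list(partners = vapply(bridged, `[[`, character(1), "label"),
                 partner_distances = vapply(bridged, `[[`, numeric(1), "distance")))
}

#' Specification for the interaction-based pose filter
#'
#' @param hbond_partners list of `residue_selector`s that must each receive
#'   at least one direct H-bond from the ligand.
#' @param water optional `list(water = selector, partners = list of
#'   selectors)`: the pose must additionally show the water-bridged H-bond.
#' @param min_hydrophobic minimum number of hydrophobic model features the
#'   pose must occupy in place (default 2 of the model's 4).
#' @return list of class `"pose_filter_spec"`.
#' @export
pose_filter_spec <- function(hbond_partners, water = NULL, min_hydrophobic = 2L) {
  structure(list(hbond_partners = hbond_partners, water = water,
                 min_hydrophobic = as.integer(min_hydrophobic)),
            class = "pose_filter_spec")
}

#' Interaction-based filtering of a docking pose
#'
#' A pose passes when every required residue receives a direct H-bond, the
#' structural-water bridge (if specified) is present, and at least
#' `min_hydrophobic` of the model's hydrophobic features are occupied by the
#' pose in place (sphere match, coordinates untouched).
#'
#' @param protein a `protein`.
#' @param pose a `pose`.
#' @param spec a [pose_filter_spec()].
#' @param model a `pharmacophore_model` supplying the hydrophobic features.
#' @param criteria an [interaction_criteria()].
#' @return list(pass = logical, reasons = character vector of failed
#'   requirements, n_hydrophobic = integer, interactions = detection output).
#' @export
filter_pose <- function(protein, pose, spec, model,
                        criteria = interaction_criteria()) {
  stopifnot(inherits(spec, "pose_filter_spec"))
  det <- detect_interactions(protein, pose, criteria)
  reasons <- character(0)

  hb_keys <- vapply(det$records, function(r)
    if (r$type == "HBOND") r$key else NA_character_, character(1))
  for (sel in spec$hbond_partners) {
    key <- paste0(sel$chain, sel$resno, sel$insert)
    hit <- which(!is.na(hb_keys) & hb_keys == key)
    if (!is.null(sel$atom) && length(hit))
      hit <- hit[vapply(det$records[hit], function(r)
        sel$atom %in% r$prot_atoms, logical(1))]
    if (!length(hit)) reasons <- c(reasons, selector_label(sel))
  }

  if (!is.null(spec$water)) {
    wb <- detect_water_bridge(protein, pose, spec$water$water,
                              spec$water$partners, criteria)
    if (is.null(wb)) reasons <- c(reasons, "structural-water bridge")
  }

  hyd_model <- model
  hyd_model$features <- model$features[model$features$kind == "HYD", , drop = FALSE]
  n_hyd <- 0L
  if (nrow(hyd_model$features)) {
    hyd_model$features$mandatory <- FALSE
    hyd_model$features$mandatory[1] <- TRUE  # keep >=1 mandatory invariant
    mres <- match_pose(hyd_model, pose, check_ev = FALSE)
    n_hyd <- mres$n_matched
  }
  if (n_hyd < spec$min_hydrophobic)
    reasons <- c(reasons, sprintf("hydrophobic features %d/%d",
                                  n_hyd, spec$min_hydrophobic))

  list(pass = length(reasons) == 0L, reasons = reasons,
       n_hydrophobic = n_hyd, interactions = det)
}

#' Intersect per-method pose-filter survivors
#'
#' @param results named list: docking method -> character vector of compound
#'   ids that passed the filter under that method.
#' @return character vector of ids passing under every method.
#' @export
intersect_by_method <- function(results) {
  if (!length(results)) stop("need at least one method")
  sort(Reduce(intersect, lapply(results, unique)))
}
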