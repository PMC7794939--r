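# The pharmacophore model: typed tolerance spheres with mandatory/optional
# flags plus excluded-volume spheres, serialized as a documented JSON dialect.

#' Construct a pharmacophore model
#'
#' @param features data.frame with columns `id` (unique integers), `kind`
#'   ("HBA", "HBD" or "HYD"; HYD spheres also accept aromatic-ring centroids),
#'   `x`, `y`, `z` (center, Angstrom), `radius` (tolerance, > 0) and
#'   `mandatory` (logical; at least one feature must be mandatory).
#' @param excluded_volumes data.frame with columns `x`, `y`, `z`, `radius`
#'   (may have zero rows).
#' @param frame_note free-text receptor-frame identifier.
#' @return object of class `"pharmacophore_model"`.
#' @export
pharmacophore_model <- function(features, excluded_volumes = NULL, frame_note = "") {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("id", "kind", "x", "y", "z", "radius", "mandatory")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("model features lack columns: ", paste(miss, collapse = ", "))
  features$id <- as.integer(features$id)
  if (anyDuplicated(features$id)) stop("model feature ids must be unique")
  if (!all(features$kind %in% c("HBA", "HBD", "HYD")))
    stop("feature kind must be HBA, HBD or HYD")
  if (any(features$radius <= 0)) stop("tolerance radii must be > 0")
  if (!any(features$mandatory)) stop("model needs at least one mandatory feature")
  features <- features[order(features$id), , drop = FALSE]
  rownames(features) <- NULL
  if (is.null(excluded_volumes) || nrow(as.data.frame(excluded_volumes)) == 0L) {
    excluded_volumes <- data.frame(x = numeric(0), y = numeric(0),
                                   z = numeric(0), radius = numeric(0))
  } else {
    excluded_volumes <- as.data.frame(excluded_volumes)[, c("x", "y", "z", "radius")]
    if (any(excluded_volumes$radius <= 0)) stop("excluded-volume radii must be > 0")
  }
  structure(list(features = features, excluded_volumes = excluded_volumes,
                 frame_note = frame_note),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  k <- table(x$features$kind)
  cat("<pharmacophore_model>", nrow(x$features), "features (",
      paste(names(k), as.integer(k), collapse = ", "), "),",
      sum(x$features$mandatory), "mandatory,",
      nrow(x$excluded_volumes), "excluded volumes\n")
  invisible(x)
}

#' Write a pharmacophore model to JSON
#'
#' Dialect: `{"features": [{"id", "kind", "center": [x,y,z], "radius",
#' "mandatory"}], "excluded_volumes": [{"center": [x,y,z], "radius"}],
#' "meta": {"frame_note"}}`.
#'
#' @param model a `pharmacophore_model`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_model <- function(model, path) {
  f <- model$features
  obj <- list(
    features = lapply(seq_len(nrow(f)), function(q) list(
      id = f$id[q], kind = f$kind[q],
      center = c(f$x[q], f$y[q], f$z[q]),
      radius = f$radius[q], mandatory = f$mandatory[q])),
    excluded_volumes = lapply(seq_len(nrow(model$excluded_volumes)), function(q) list(
      center = unlist(model$excluded_volumes[q, c("x", "y", "z")], use.names = FALSE),
      radius = model$excluded_volumes$radius[q])),
    meta = list(frame_note = model$frame_note))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pharmacophore model from JSON
#' @param path JSON file in the dialect written by [write_model()].
#' @return a `pharmacophore_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- do.call(rbind, lapply(obj$features, function(q)
    data.frame(id = q$id, kind = q$kind, x = q$center[[1]], y = q$center[[2]],
               z = q$center[[3]], radius = q$radius, mandatory = q$mandatory,
               stringsAsFactors = FALSE)))
  evs <- if (length(obj$excluded_volumes))
    do.call(rbind, lapply(obj$excluded_volumes, function(q)
      data.frame(x = q$center[[1]], y = q$center[[2]], z = q$center[[3]],
                 radius = q$radius))) else NULL
  pharmacophore_model(feats, evs,
                      frame_note = if (!is.null(obj$meta$frame_note)) obj$meta$frame_note else "")
}

#' Configuration for receptor-based model building
#'
#' @param hba_radius tolerance radius (Angstrom) of H-bond acceptor features.
#' @param hyd_radius tolerance radius of hydrophobic features.
#' @param ev_radius excluded-volume sphere radius.
#' @param ev_shell protein heavy atoms within this distance of any ligand
#'   heavy atom become excluded volumes.
#' @param min_apolar_contacts minimum protein apolar heavy atoms within the
#'   hydrophobic cutoff for a ligand hydrophobic site to become a feature.
#' @param criteria [interaction_criteria()] used for H-bond detection.
#' @param mandatory optional explicit integer vector of mandatory feature
#'   ids, overriding the default rule (all HBA plus the best-contacted HYD).
#' @return list of class `"model_config"`.
#' @export
model_config <- function(hba_radius = 1.5, hyd_radius = 1.5, ev_radius = 1.2,
                         ev_shell = 6.0, min_apolar_contacts = 2L,
                         criteria = interaction_criteria(), mandatory = NULL) {
  structure(list(hba_radius = hba_radius, hyd_radius = hyd_radius,
                 ev_radius = ev_radius, ev_shell = ev_shell,
                 min_apolar_contacts = as.integer(min_apolar_contacts),
                 criteria = criteria, mandatory = mandatory),
            class = "model_config")
}

#' Build a receptor-based pharmacophore model from a complex
#'
#' Derives typed feature spheres from the interactions a bound ligand makes:
#' one HBA feature per ligand acceptor that is H-bonded to a protein donor or
#' to a listed structural water, and one HYD feature per ligand
#' hydrophobic/aromatic site with enough protein apolar atoms nearby. Feature
#' centers sit at the ligand feature positions. Every protein heavy atom
#' within `ev_shell` of any ligand heavy atom becomes an excluded volume,
#' except atoms that are H-bond partners of a feature.
#'
#' By default all HBA features plus the HYD feature with the most protein
#' contacts are mandatory and the remaining HYD features optional; pass
#' `config$mandatory` to override.
#'
#' @param protein a `protein`.
#' @param ligand a `molecule` posed in the receptor frame.
#' @param structural_waters list of `residue_selector`s naming conserved
#'   waters whose H-bonds to the ligand should be represented as features.
#' @param config a [model_config()].
#' @return a `pharmacophore_model`.
#' @export
build_receptor_model <- function(protein, ligand, structural_waters = list(),
                                 config = model_config()) {
  feats <- perceive_features(ligand, 1L)
  lig_xyz <- conformer_coords(ligand, 1L)
  prot_xyz <- protein_coords(protein)
  at <- protein$atoms
  det <- detect_interactions(protein, ligand, config$criteria)

  # ligand acceptor atoms that are H-bonded (record role: ligand acceptor)
  acc_feats <- feats[feats$kind == "HBA", , drop = FALSE]
  partner_idx <- integer(0)
  hba_rows <- list()
  if (nrow(acc_feats)) {
    wat_o <- integer(0)
    for (sel in structural_waters) {
      widx <- resolve_selector(protein, sel)
      wat_o <- c(wat_o, widx[toupper(at$element[widx]) == "O"])
    }
    for (q in seq_len(nrow(acc_feats))) {
      ai <- acc_feats$atoms[[q]][1]
      hb <- Filter(function(r) r$type == "HBOND" && r$lig_atom == ai, det$records)
      bonded <- length(hb) > 0L
      if (length(hb)) partner_idx <- c(partner_idx, vapply(hb, `[[`, integer(1), "prot_idx"))
      if (length(wat_o)) {
        d <- sqrt(colSums((t(prot_xyz[wat_o, , drop = FALSE]) -
                             lig_xyz[ai, ])^2))
        if (any(d <= config$criteria$hbond_dist)) {
          bonded <- TRUE
          partner_idx <- c(partner_idx, wat_o[d <= config$criteria$hbond_dist])
        }
      }
      if (bonded)
        hba_rows[[length(hba_rows) + 1L]] <- data.frame(
          kind = "HBA", x = acc_feats$x[q], y = acc_feats$y[q], z = acc_feats$z[q],
          radius = config$hba_radius, contacts = NA_integer_)
    }
  }

  # ligand hydrophobic sites backed by enough protein apolar atoms
  hyd_feats <- feats[feats$kind %in% c("HYD", "ARO"), , drop = FALSE]
  hyd_rows <- list()
  if (nrow(hyd_feats)) {
    pos <- feature_positions(hyd_feats)
    keep <- !duplicated(round(pos, 6))
    hyd_feats <- hyd_feats[keep, , drop = FALSE]
    pos <- pos[keep, , drop = FALSE]
    p_apolar <- which(protein_apolar(protein))
    for (q in seq_len(nrow(hyd_feats))) {
      n_contact <- if (length(p_apolar))
        sum(sqrt(colSums((t(prot_xyz[p_apolar, , drop = FALSE]) - pos[q, ])^2)) <=
              config$criteria$hydrophobic_dist) else 0L
      if (n_contact >= config$min_apolar_contacts)
        hyd_rows[[length(hyd_rows) + 1L]] <- data.frame(
          kind = "HYD", x = pos[q, 1], y = pos[q, 2], z = pos[q, 3],
          radius = config$hyd_radius, contacts = n_contact)
    }
  }

  if (!length(hba_rows) && !length(hyd_rows))
    stop("no protein-ligand interactions detected; cannot build an empty model")

  hba <- if (length(hba_rows)) do.call(rbind, hba_rows) else NULL
  hyd <- if (length(hyd_rows)) do.call(rbind, hyd_rows) else NULL
  if (!is.null(hyd)) hyd <- hyd[order(-hyd$contacts), , drop = FALSE]
  tab <- rbind(hba, hyd)
  tab$id <- seq_len(nrow(tab))
  tab$mandatory <- FALSE
  if (!is.null(config$mandatory)) {
    tab$mandatory <- tab$id %in% config$mandatory
  } else {
    tab$mandatory[tab$kind == "HBA"] <- TRUE
    if (!is.null(hyd)) tab$mandatory[tab$id == tab$id[tab$kind == "HYD"][1]] <- TRUE
  }

  # excluded volumes: in-shell protein heavy atoms, minus H-bond partners
  heavy_p <- toupper(at$element) != "H"
  lig_heavy <- lig_xyz[heavy_atoms(ligand), , drop = FALSE]
  in_shell <- vapply(seq_len(nrow(at)), function(i) {
    if (!heavy_p[i]) return(FALSE)
    min(sqrt(colSums((t(lig_heavy) - prot_xyz[i, ])^2))) <= config$ev_shell
  }, logical(1))
  ev_idx <- setdiff(which(in_shell), unique(partner_idx))
  evs <- if (length(ev_idx))
    data.frame(x = at$x[ev_idx], y = at$y[ev_idx], z = at$z[ev_idx],
               radius = config$ev_radius) else NULL

  pharmacophore_model(tab[, c("id", "kind", "x", "y", "z", "radius", "mandatory")],
                      evs, frame_note = "receptor frame of the source complex")
}
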