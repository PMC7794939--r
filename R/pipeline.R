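# End-to-end virtual-screening cascade: pharmacophore screen -> per-method
# interaction filter -> intersection -> pose consensus -> MD filter, with a
# per-compound dossier recording every decision.

#' Run the full virtual-screening cascade
#'
#' Stages are executed in workflow order: (1) alignment-mode pharmacophore
#' screening of the library, (2) in-place interaction filtering of each
#' surviving compound's top pose under every docking method, (3)
#' intersection of the per-method survivor sets, (4) full pose-consensus
#' across methods (all reciprocal RMSDs strictly below the threshold), and
#' (5), when trajectories are supplied, the MD occupancy/drift filter.
#' Missing stage inputs skip the stage with an explicit flag in the report,
#' never silently.
#'
#' @param model a `pharmacophore_model`.
#' @param library list of `molecule`s to screen.
#' @param poses named list: method -> named list (compound name -> `pose` or
#'   list of poses, of which the first is used).
#' @param protein the receptor `protein` (frame of the poses).
#' @param filter_spec a [pose_filter_spec()].
#' @param min_features minimum matched features for a screening hit
#'   (default 7, the usual "all but one" cut on an 8-feature model).
#' @param consensus_threshold pose-consensus RMSD threshold (Angstrom).
#' @param trajectories optional named list (compound ->
#'   `list(trajectory, interactions)`) for the MD stage.
#' @param md_spec an [md_filter_spec()] (required with trajectories).
#' @param criteria an [interaction_criteria()].
#' @param rmsd_symmetry symmetry-aware consensus RMSD (default TRUE).
#' @param seed recorded in the report for provenance (the cascade itself is
#'   deterministic given its inputs).
#' @return list of class `"funnel_report"`: `stages` (data.frame of
#'   input/output counts), `survivors` (per stage), `levels` (screening
#'   level counts), `per_method` (filter pass counts), `dossier`
#'   (per-compound decisions with reasons), `skipped` (stage names),
#'   `seed`.
#' @export
run_pipeline <- function(model, library, poses, protein, filter_spec,
                         min_features = 7L, consensus_threshold = 2.0,
                         trajectories = NULL, md_spec = NULL,
                         criteria = interaction_criteria(),
                         rmsd_symmetry = TRUE, seed = NULL) {
  dossier <- list()
  stages <- list()
  skipped <- character(0)
  note <- function(cmp, stage, decision, detail = "") {
    dossier[[cmp]][[stage]] <<- list(decision = decision, detail = detail)
  }

  # stage 1: pharmacophore screening
  scr <- screen_library(model, library, min_features = min_features)
  screened <- scr$hits$name
  for (m in library) {
    r <- scr$results[[m$name]]
    note(m$name, "screen",
         m$name %in% screened,
         sprintf("%d/%d features matched%s", r$n_matched, nrow(model$features),
                 if (r$ev_clash) ", excluded-volume clash" else ""))
  }
  stages[["screen"]] <- c(n_in = length(library), n_out = length(screened))

  # stage 2: per-method interaction filter
  per_method <- list()
  if (length(poses)) {
    for (meth in names(poses)) {
      passing <- character(0)
      for (cmp in screened) {
        p <- poses[[meth]][[cmp]]
        if (is.null(p)) {
          note(cmp, paste0("filter:", meth), FALSE, "no pose supplied")
          next
        }
        if (is.list(p) && !inherits(p, "pose")) p <- p[[1]]
        fr <- filter_pose(protein, p, filter_spec, model, criteria)
        note(cmp, paste0("filter:", meth), fr$pass,
             paste(fr$reasons, collapse = "; "))
        if (fr$pass) passing <- c(passing, cmp)
      }
      per_method[[meth]] <- passing
    }
    intersected <- intersect_by_method(per_method)
    for (cmp in screened)
      note(cmp, "intersection", cmp %in% intersected, "")
    stages[["pose_filter"]] <- c(n_in = length(screened), n_out = length(intersected))
  } else {
    skipped <- c(skipped, "pose_filter", "consensus")
    intersected <- screened
  }

  # stage 3: pose consensus
  if (length(poses) >= 2L) {
    consensus_ok <- character(0)
    for (cmp in intersected) {
      pl <- lapply(poses, function(mp) {
        p <- mp[[cmp]]
        if (is.list(p) && !inherits(p, "pose")) p[[1]] else p
      })
      pl <- pl[!vapply(pl, is.null, logical(1))]
      fc <- full_consensus(pl, threshold = consensus_threshold,
                           symmetry = rmsd_symmetry)
      note(cmp, "consensus", fc$full_consensus,
           sprintf("max reciprocal RMSD %.2f A", max(fc$rmsd)))
      if (fc$full_consensus) consensus_ok <- c(consensus_ok, cmp)
    }
    stages[["consensus"]] <- c(n_in = length(intersected),
                               n_out = length(consensus_ok))
  } else {
    if (length(poses) == 1L) skipped <- c(skipped, "consensus")
    consensus_ok <- intersected
  }

  # stage 4: MD filter
  if (!is.null(trajectories)) {
    if (is.null(md_spec)) stop("md_spec required when trajectories are supplied")
    md_ok <- character(0)
    for (cmp in consensus_ok) {
      tr <- trajectories[[cmp]]
      if (is.null(tr)) {
        note(cmp, "md", FALSE, "no trajectory supplied")
        next
      }
      rep_ <- hbond_occupancy(tr$trajectory, tr$interactions, criteria)
      verdict <- md_filter(rep_, md_spec)
      note(cmp, "md", verdict$pass, paste(verdict$reasons, collapse = "; "))
      if (verdict$pass) md_ok <- c(md_ok, cmp)
    }
    stages[["md"]] <- c(n_in = length(consensus_ok), n_out = length(md_ok))
  } else {
    skipped <- c(skipped, "md")
    md_ok <- consensus_ok
  }

  stage_tab <- data.frame(stage = names(stages),
                          n_in = vapply(stages, `[`, numeric(1), 1),
                          n_out = vapply(stages, `[`, numeric(1), 2),
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(stages = stage_tab,
                 survivors = list(screen = screened,
                                  pose_filter = sort(intersected),
                                  consensus = sort(consensus_ok),
                                  md = sort(md_ok)),
                 levels = scr$levels,
                 per_method = lapply(per_method, sort),
                 dossier = dossier, skipped = skipped, seed = seed),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(x$stages, row.names = FALSE)
  if (length(x$skipped)) cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  cat("  final survivors:", if (length(x$survivors$md))
    paste(x$survivors$md, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a funnel report to JSON
#' @param report a `funnel_report`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_funnel <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

mols_to_apset <- function(mols) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_molecules(mols, tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  suppressWarnings(ChemmineR::sdf2ap(sdfs))
}

#' Two-dimensional similarity novelty check
#'
#' Scores every candidate against a reference set by Tanimoto similarity of
#' atom-pair descriptors computed on the 2D structures (bond topology only),
#' scaled to 0-100 (100 = identical descriptor set). A candidate is "novel"
#' when its best reference score does not exceed the bound.
#'
#' @param candidates list of `molecule`s to assess.
#' @param references non-empty list of reference `molecule`s (e.g. known
#'   inhibitors of the target class).
#' @param bound novelty bound on the 0-100 scale (default 80).
#' @return data.frame: `name`, `max_score` (0-100), `closest_reference`,
#'   `novel`; unparsable candidates get `NA` scores and `error = TRUE`.
#' @export
novelty_check <- function(candidates, references, bound = 80) {
  if (!length(references)) stop("need at least one reference molecule")
  if (inherits(candidates, "molecule")) candidates <- list(candidates)
  if (inherits(references, "molecule")) references <- list(references)
  ref_ap <- mols_to_apset(references)
  ref_names <- vapply(references, `[[`, character(1), "name")
  out <- lapply(candidates, function(m) {
    row <- tryCatch({
      ap <- mols_to_apset(list(m))
      sims <- vapply(ChemmineR::cid(ref_ap), function(rid)
        ChemmineR::cmp.similarity(ap[[1]], ref_ap[[rid]]), numeric(1))
      score <- round(100 * as.numeric(sims))
      best <- which.max(score)
      data.frame(name = m$name, max_score = score[best],
                 closest_reference = ref_names[best],
                 novel = score[best] <= bound, error = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(name = m$name, max_score = NA_real_,
                 closest_reference = NA_character_, novel = NA,
                 error = TRUE, stringsAsFactors = FALSE))
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
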