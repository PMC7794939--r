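# Ligand pharmacophore feature perception: explicit, versioned typing rules
# (documented in the package vignette) rather than a proprietary rule base.

mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  g
}

# smallest ring through each bond (size <= 8), deduplicated by member set
find_rings <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(list())
  g <- mol_graph(mol)
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j)$vpath[[1]])
    if (length(sp) == 0L || length(sp) > 8L) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = "-")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- ring }
  }
  rings
}

bond_order_between <- function(mol, i, j) {
  hit <- (mol$bonds$i == i & mol$bonds$j == j) | (mol$bonds$i == j & mol$bonds$j == i)
  if (!any(hit)) NA_character_ else mol$bonds$order[which(hit)[1]]
}

# aromatic: every ring atom is C/N/O/S and either carries a double/"ar" bond
# to a ring neighbour or is an N/O/S lone-pair donor (all ring bonds single);
# geometric fallback for order-less input (e.g. PDB): planar ring of
# conjugated-range bond lengths
ring_is_aromatic <- function(mol, ring, xyz) {
  el <- toupper(mol$atoms$element[ring])
  if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
  if (!(length(ring) %in% c(5L, 6L))) return(FALSE)
  nxt <- c(ring[-1], ring[1])
  orders <- mapply(function(i, j) bond_order_between(mol, i, j), ring, nxt)
  ok_atom <- vapply(seq_along(ring), function(q) {
    inc <- orders[c(q, if (q == 1L) length(ring) else q - 1L)]
    if (any(inc %in% c("2", "ar"))) return(TRUE)
    el[q] %in% c("N", "O", "S") && all(inc == "1")
  }, logical(1))
  if (all(ok_atom) && any(orders %in% c("2", "ar"))) return(TRUE)
  # geometric fallback
  pts <- xyz[ring, , drop = FALSE]
  lens <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  if (any(lens < 1.30 | lens > 1.46)) return(FALSE)
  ctr <- colMeans(pts)
  dev <- svd(sweep(pts, 2, ctr))$d[3] / sqrt(nrow(pts))
  dev < 0.10
}

ring_normal <- function(pts) {
  v <- svd(sweep(pts, 2, colMeans(pts)))$v[, 3]
  v / sqrt(sum(v^2))
}

STD_VALENCE <- c(N = 3, O = 2, S = 2, C = 4)

# implicit hydrogen count by valence (Kekule orders give exact results;
# "ar" counts 1.5 per bond)
implicit_h <- function(mol) {
  el <- toupper(mol$atoms$element)
  ord_num <- c(`1` = 1, `2` = 2, `3` = 3, ar = 1.5)
  deg <- numeric(n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    w <- ord_num[mol$bonds$order[k]]
    deg[mol$bonds$i[k]] <- deg[mol$bonds$i[k]] + w
    deg[mol$bonds$j[k]] <- deg[mol$bonds$j[k]] + w
  }
  val <- STD_VALENCE[el]
  h <- pmax(0, round(val + mol$atoms$charge - deg))
  h[is.na(val)] <- 0
  h
}

feature_row <- function(kind, pos, atoms, dir = NULL) {
  data.frame(kind = kind, x = pos[1], y = pos[2], z = pos[3],
             atoms = I(list(sort(atoms))),
             dx = if (is.null(dir)) NA_real_ else dir[1],
             dy = if (is.null(dir)) NA_real_ else dir[2],
             dz = if (is.null(dir)) NA_real_ else dir[3],
             stringsAsFactors = FALSE)
}

#' Perceive pharmacophore feature points on a molecule conformer
#'
#' Detects hydrogen-bond acceptors (HBA), donors (HBD), aromatic rings (ARO)
#' and hydrophobic centroids (HYD) using an explicit rule table:
#' \itemize{
#'   \item HBA: N or O with a free lone pair - positively charged N, amide N,
#'     aniline N, pyrrole-type aromatic N, and aromatic O/S ring members are
#'     excluded; carbonyl, sulfonyl/sulfonamide, ether, hydroxyl O and
#'     pyridine-type N are included.
#'   \item HBD: N or O bearing at least one hydrogen (explicit, or implicit
#'     by standard valence).
#'   \item ARO: centroid of each aromatic ring (smallest set of smallest
#'     rings), with the unit ring normal as direction.
#'   \item HYD: (a) each aromatic ring centroid (so a model hydrophobic
#'     sphere can sit on a ring), (b) the centroid of each maximal connected
#'     set of two or more non-ring apolar heavy atoms (C/S/halogen with no
#'     bonded N or O), (c) each halogen bonded to carbon.
#' }
#'
#' @param mol a `molecule`.
#' @param conformer conformer index supplying the geometry.
#' @return a data.frame of class `"features"` with columns `kind`, `x`, `y`,
#'   `z`, `atoms` (list of source-atom indices) and `dx`, `dy`, `dz`
#'   (optional unit direction: acceptor lone-pair axis or ring normal).
#' @details Perception is deterministic: the feature order depends only on
#'   atom order. Kind and source atoms are conformer-independent; only the
#'   positions change between conformers.
#' @export
perceive_features <- function(mol, conformer = 1L) {
  xyz <- conformer_coords(mol, conformer)
  el <- toupper(mol$atoms$element)
  nb <- bond_neighbors(mol)
  rings <- find_rings(mol)
  arom <- vapply(rings, function(r) ring_is_aromatic(mol, r, xyz), logical(1))
  arom_rings <- rings[arom]
  in_ring <- rep(FALSE, n_atoms(mol))
  for (r in rings) in_ring[r] <- TRUE
  in_arom <- rep(FALSE, n_atoms(mol))
  for (r in arom_rings) in_arom[r] <- TRUE
  impl_h <- implicit_h(mol)
  chg <- mol$atoms$charge

  lone_pair_dir <- function(i) {
    heavy_nb <- nb[[i]][el[nb[[i]]] != "H"]
    if (!length(heavy_nb)) return(NULL)
    v <- xyz[i, ] - colMeans(xyz[heavy_nb, , drop = FALSE])
    n <- sqrt(sum(v^2))
    if (n < 1e-8) NULL else v / n
  }

  is_amide_n <- function(i) {
    any(vapply(nb[[i]], function(c_) {
      el[c_] == "C" && any(vapply(nb[[c_]], function(o_) {
        el[o_] %in% c("O", "S") && identical(bond_order_between(mol, c_, o_), "2")
      }, logical(1)))
    }, logical(1)))
  }

  feats <- list()
  for (i in seq_len(n_atoms(mol))) {
    if (!(el[i] %in% c("N", "O"))) next
    acceptor <- FALSE
    if (el[i] == "O") {
      acceptor <- chg[i] <= 0L && !in_arom[i]
    } else {
      acceptor <- chg[i] <= 0L && !is_amide_n(i)
      if (acceptor && in_arom[i]) {
        # pyridine-type only: an in-ring double/"ar" bond signals the sp2 lone pair
        ring_nb <- intersect(nb[[i]], which(in_arom))
        ords <- vapply(ring_nb, function(j) bond_order_between(mol, i, j), character(1))
        acceptor <- any(ords %in% c("2", "ar")) && length(nb[[i]]) + impl_h[i] <= 2
      }
      if (acceptor && !in_arom[i]) {
        # aniline-type: N attached to an aromatic ring atom
        if (any(in_arom[nb[[i]]])) acceptor <- FALSE
      }
    }
    if (acceptor)
      feats[[length(feats) + 1L]] <- feature_row("HBA", xyz[i, ], i, lone_pair_dir(i))

    n_h <- impl_h[i] + sum(el[nb[[i]]] == "H")
    if (n_h >= 1L) {
      h_nb <- nb[[i]][el[nb[[i]]] == "H"]
      dir <- if (length(h_nb)) {
        v <- xyz[h_nb[1], ] - xyz[i, ]; v / sqrt(sum(v^2))
      } else lone_pair_dir(i)
      feats[[length(feats) + 1L]] <- feature_row("HBD", xyz[i, ], i, dir)
    }
  }

  for (r in arom_rings) {
    pts <- xyz[r, , drop = FALSE]
    feats[[length(feats) + 1L]] <- feature_row("ARO", colMeans(pts), r, ring_normal(pts))
    feats[[length(feats) + 1L]] <- feature_row("HYD", colMeans(pts), r)
  }

  apolar <- apolar_atoms(mol)
  cand <- which(apolar & !in_ring & el != "H")
  if (length(cand) >= 2L) {
    sub <- igraph::induced_subgraph(mol_graph(mol), cand)
    comp <- igraph::components(sub)
    for (cid in seq_len(comp$no)) {
      members <- cand[comp$membership == cid]
      if (length(members) >= 2L)
        feats[[length(feats) + 1L]] <- feature_row(
          "HYD", colMeans(xyz[members, , drop = FALSE]), members)
    }
  }
  for (i in which(is_halogen(el))) {
    if (any(el[nb[[i]]] == "C"))
      feats[[length(feats) + 1L]] <- feature_row("HYD", xyz[i, ], i)
  }

  if (!length(feats)) {
    out <- data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), atoms = I(list()), dx = numeric(0),
                      dy = numeric(0), dz = numeric(0))
  } else {
    out <- do.call(rbind, feats)
    kind_rank <- match(out$kind, c("HBA", "HBD", "ARO", "HYD"))
    first_atom <- vapply(out$atoms, min, numeric(1))
    out <- out[order(kind_rank, first_atom), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("features", "data.frame")
  out
}

#' Count perceived features by kind
#' @param mol a `molecule`.
#' @param conformer conformer index.
#' @return named integer vector over the kinds present (HBA, HBD, ARO, HYD).
#' @export
feature_counts <- function(mol, conformer = 1L) {
  f <- perceive_features(mol, conformer)
  if (!nrow(f)) return(integer(0))
  tab <- table(f$kind)
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

feature_positions <- function(feats) unname(as.matrix(feats[, c("x", "y", "z")]))
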