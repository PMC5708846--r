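#' @name ifp
#' @title Protein-ligand interaction fingerprints
#'
#' @description
#' An interaction fingerprint (IFP) encodes, for every pocket residue, the
#' presence or absence of eight interaction types with the bound ligand:
#' hydrophobic, H-bond donor, H-bond acceptor, weak H-bond donor, weak
#' H-bond acceptor, ionic positive, ionic negative and aromatic. Donor /
#' acceptor bits name the residue's role; the ionic bits name the LIGAND's
#' charge sign (`ionic_negative` = anionic ligand group contacting a
#' cationic residue). All geometry is heavy-atom based.
NULL

ifp_types <- c("hydrophobic", "Hbond_donor", "Hbond_acceptor",
               "weakHbond_donor", "weakHbond_acceptor",
               "ionic_positive", "ionic_negative", "aromatic")

#' Default geometric criteria for fingerprint bits
#'
#' Thresholds (Angstrom / degrees) follow published ranges for
#' presence/absence fingerprints: hydrophobic apolar-pair distance 4.5;
#' H-bond heavy-atom distance 3.5 with a donor-antecedent angle >= 120
#' degrees when an antecedent is identifiable (distance-only otherwise);
#' weak H-bond 3.8; ionic 4.0; aromatic ring-centroid distance 4.5 with an
#' interplanar angle <= 30 (face-to-face) or >= 60 degrees (edge-to-face),
#' pooled into a single bit.
#'
#' @param hydrophobic,hbond,weak_hbond,ionic,aromatic_centroid Distance
#'   thresholds in Angstrom.
#' @param hbond_angle Minimum donor-antecedent-acceptor angle in degrees.
#' @param aromatic_face,aromatic_edge Interplanar angle limits in degrees.
#' @return A named list of thresholds.
#' @export
ifp_criteria <- function(hydrophobic = 4.5, hbond = 3.5, hbond_angle = 120,
                         weak_hbond = 3.8, ionic = 4.0,
                         aromatic_centroid = 4.5, aromatic_face = 30,
                         aromatic_edge = 60) {
  list(hydrophobic = hydrophobic, hbond = hbond, hbond_angle = hbond_angle,
       weak_hbond = weak_hbond, ionic = ionic,
       aromatic_centroid = aromatic_centroid,
       aromatic_face = aromatic_face, aromatic_edge = aromatic_edge)
}

# ---- atom role tables ------------------------------------------------------

# Side-chain functional atoms of the standard residues. When a residue is
# represented coarsely (a single non-backbone pseudo-atom), that atom
# inherits the whole profile of its residue type.
residue_roles <- list(
  SER = list(donor = "OG", acceptor = "OG"),
  THR = list(donor = "OG1", acceptor = "OG1"),
  TYR = list(donor = "OH", acceptor = "OH",
             ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  ASN = list(donor = "ND2", acceptor = "OD1"),
  GLN = list(donor = "NE2", acceptor = "OE1"),
  HIS = list(donor = c("ND1", "NE2"), acceptor = c("ND1", "NE2"),
             ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  LYS = list(donor = "NZ", positive = "NZ"),
  ARG = list(donor = c("NE", "NH1", "NH2"), positive = c("NH1", "NH2")),
  ASP = list(acceptor = c("OD1", "OD2"), negative = c("OD1", "OD2")),
  GLU = list(acceptor = c("OE1", "OE2"), negative = c("OE1", "OE2")),
  TRP = list(donor = "NE1",
             ring = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
                      "CZ3", "CH2")),
  CYS = list(donor = "SG"),
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
)

# Per-atom role flags for the receptor atoms of one residue.
receptor_residue_roles <- function(atoms) {
  res_name <- atoms$res_name[1]
  prof <- residue_roles[[res_name]] %||% list()
  side <- !is_backbone_atom(atoms$atom)
  coarse <- sum(side) == 1 && !atoms$atom[side][1] %in%
    unlist(prof[c("donor", "acceptor", "positive", "negative", "ring")])
  in_set <- function(key) {
    if (coarse && !is.null(prof[[key]])) return(side)
    atoms$atom %in% (prof[[key]] %||% character())
  }
  ring_atoms <- if (coarse && !is.null(prof$ring)) atoms$atom[side] else {
    intersect(prof$ring %||% character(), atoms$atom)
  }
  list(
    # apolar carbon/sulfur: C or S atoms that carry no polar role
    hydrophobic = atoms$element %in% c("C", "S") &
      !(in_set("donor") | in_set("acceptor") |
          in_set("positive") | in_set("negative")),
    donor = in_set("donor"), acceptor = in_set("acceptor"),
    weak_donor = atoms$atom == "CA" | atoms$atom %in% ring_atoms,
    positive = in_set("positive"), negative = in_set("negative"),
    ring = ring_atoms
  )
}

# Ligand atom roles from elements, explicit formal charges and declared
# aromatic rings. Carbons are hydrophobic; ring carbons are additionally
# weak-H-bond donors; N is donor+acceptor, O acceptor; charges from the
# complex's ligand_charges annotation.
ligand_roles <- function(complex) {
  lig <- complex$ligand
  q <- rep(0, nrow(lig))
  if (length(complex$ligand_charges) > 0) {
    q <- ifelse(lig$atom %in% names(complex$ligand_charges),
                complex$ligand_charges[lig$atom], 0)
    q[is.na(q)] <- 0
  }
  ring_names <- unlist(complex$ligand_rings)
  list(
    hydrophobic = lig$element %in% c("C", "S") & q == 0,
    donor = lig$element == "N" & q >= 0,
    acceptor = (lig$element == "O" & q <= 0) | (lig$element == "N" & q <= 0),
    weak_donor = lig$element == "C" & lig$atom %in% ring_names,
    positive = q > 0, negative = q < 0,
    rings = complex$ligand_rings
  )
}

ring_geometry <- function(coords) {
  centroid <- colMeans(coords)
  s <- svd(sweep(coords, 2, centroid))
  list(centroid = centroid, normal = s$v[, 3])
}

interplanar_angle <- function(n1, n2) {
  ang <- acos(pmin(1, abs(sum(n1 * n2)) /
                     (sqrt(sum(n1^2)) * sqrt(sum(n2^2))))) * 180 / pi
  ang
}

# Donor quality check: distance plus (when an antecedent heavy atom is
# covalently attached, i.e. within 1.9 A in the same residue) an
# antecedent-donor-acceptor angle of at least `min_angle` degrees.
donor_ok <- function(d_xyz, a_xyz, res_xyz, max_dist, min_angle) {
  dd <- sqrt(sum((d_xyz - a_xyz)^2))
  if (dd > max_dist) return(FALSE)
  if (is.null(res_xyz) || nrow(res_xyz) == 0) return(TRUE)
  dv <- sqrt(rowSums(sweep(res_xyz, 2, d_xyz)^2))
  ante <- res_xyz[dv > 1e-6 & dv <= 1.9, , drop = FALSE]
  if (nrow(ante) == 0) return(TRUE)
  v1 <- sweep(ante, 2, d_xyz)          # donor -> antecedent
  v2 <- a_xyz - d_xyz                  # donor -> acceptor
  cosang <- (v1 %*% v2) / (sqrt(rowSums(v1^2)) * sqrt(sum(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  any(ang >= min_angle)
}

#' Compute the interaction fingerprint of a complex
#'
#' For each pocket residue the eight interaction bits are set when the
#' corresponding geometric criterion is met by at least one residue-atom /
#' ligand-atom pair (or ring pair for the aromatic bit). See [ifp] for the
#' bit semantics and [ifp_criteria()] for the thresholds.
#'
#' @param complex A [pf_complex()].
#' @param pocket A [define_pocket()] result; every pocket residue must be
#'   present in the complex.
#' @param criteria Thresholds from [ifp_criteria()].
#' @return An `ifp` object: logical matrix (residues x 8 types) with the
#'   pocket residue ids as row names.
#' @export
compute_ifp <- function(complex, pocket, criteria = ifp_criteria()) {
  rec <- complex$receptor[complex$receptor$element != "H", ]
  lig <- complex$ligand[complex$ligand$element != "H", ]
  lr <- ligand_roles(complex)
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  lig_ring_geo <- purrr::map(lr$rings, function(nm) {
    idx <- match(nm, lig$atom)
    if (anyNA(idx) || length(idx) < 3) return(NULL)
    ring_geometry(lxyz[idx, , drop = FALSE])
  })
  lig_ring_geo <- purrr::compact(lig_ring_geo)

  bits <- matrix(FALSE, nrow(pocket$residues), 8,
                 dimnames = list(pocket$residues$res_id, ifp_types))
  for (i in seq_len(nrow(pocket$residues))) {
    r <- pocket$residues[i, ]
    at <- rec[rec$chain == r$chain & rec$res_num == r$res_num &
                rec$ins == r$ins, ]
    if (nrow(at) == 0) {
      abort_pf(paste0("pocket residue ", r$res_id, " absent from complex"),
               "correspondence_error")
    }
    roles <- receptor_residue_roles(at)
    rxyz <- as.matrix(at[, c("x", "y", "z")])
    d <- cross_dist(rxyz, lxyz)

    hit <- function(res_mask, lig_mask, cut) {
      any(d[res_mask, lig_mask, drop = FALSE] <= cut)
    }
    bits[i, "hydrophobic"] <-
      hit(roles$hydrophobic, lr$hydrophobic, criteria$hydrophobic)
    # residue donates to a ligand acceptor
    don <- which(roles$donor); acc <- which(lr$acceptor)
    for (di in don) {
      for (ai in acc) {
        if (donor_ok(rxyz[di, ], lxyz[ai, ], rxyz,
                     criteria$hbond, criteria$hbond_angle)) {
          bits[i, "Hbond_donor"] <- TRUE; break
        }
      }
      if (bits[i, "Hbond_donor"]) break
    }
    # ligand donates to a residue acceptor (distance-only on the coarse
    # ligand side unless covalent neighbours are present)
    lacc <- which(roles$acceptor); ldon <- which(lr$donor)
    for (di in ldon) {
      for (ai in lacc) {
        if (donor_ok(lxyz[di, ], rxyz[ai, ], lxyz,
                     criteria$hbond, criteria$hbond_angle)) {
          bits[i, "Hbond_acceptor"] <- TRUE; break
        }
      }
      if (bits[i, "Hbond_acceptor"]) break
    }
    bits[i, "weakHbond_donor"] <-
      hit(roles$weak_donor, lr$acceptor, criteria$weak_hbond)
    bits[i, "weakHbond_acceptor"] <-
      hit(roles$acceptor, lr$weak_donor, criteria$weak_hbond)
    bits[i, "ionic_positive"] <- hit(roles$negative, lr$positive, criteria$ionic)
    bits[i, "ionic_negative"] <- hit(roles$positive, lr$negative, criteria$ionic)
    if (length(roles$ring) >= 3 && length(lig_ring_geo) > 0) {
      rg <- ring_geometry(rxyz[at$atom %in% roles$ring, , drop = FALSE])
      for (lg in lig_ring_geo) {
        cd <- sqrt(sum((rg$centroid - lg$centroid)^2))
        ang <- interplanar_angle(rg$normal, lg$normal)
        if (cd <= criteria$aromatic_centroid &&
            (ang <= criteria$aromatic_face || ang >= criteria$aromatic_edge)) {
          bits[i, "aromatic"] <- TRUE; break
        }
      }
    }
  }
  structure(bits, class = c("ifp", class(bits)))
}

#' Flatten a fingerprint to one boolean vector
#'
#' Residue-major then interaction-type order; length is always
#' `8 * n_residues`.
#'
#' @param ifp An `ifp` object (plain logical vectors pass through).
#' @return Logical vector.
#' @export
ifp_flatten <- function(ifp) {
  if (is.matrix(ifp)) {
    v <- as.logical(t(unclass(ifp)))
    names(v) <- paste(rep(rownames(ifp), each = ncol(ifp)),
                      rep(colnames(ifp), nrow(ifp)), sep = ":")
    return(v)
  }
  as.logical(ifp)
}

check_comparable <- function(a, b) {
  if (is.matrix(a) && is.matrix(b) && !identical(rownames(a), rownames(b))) {
    abort_pf("fingerprints computed over different residue lists",
             "correspondence_error")
  }
}

#' Jaccard distance between two boolean vectors
#'
#' `d_J = (C_TF + C_FT) / (C_TT + C_TF + C_FT)` where `C_ij` counts
#' positions with `u[k] = i` and `v[k] = j`. A distance of 0 means
#' identical fingerprints; two fingerprints with disjoint support are at
#' distance 1. When both vectors are all-FALSE the ratio is 0/0 and the
#' distance is defined as 0 (identical absence of contacts).
#'
#' @param u,v Logical vectors of equal length, or comparable `ifp`
#'   objects.
#' @return A `jaccard_result` list: `d_j`, `c_tt`, `c_tf`, `c_ft`.
#' @export
jaccard_distance <- function(u, v) {
  check_comparable(u, v)
  u <- ifp_flatten(u); v <- ifp_flatten(v)
  if (length(u) != length(v)) {
    abort_pf(paste0("fingerprint lengths differ: ", length(u), " vs ",
                    length(v)), "dimension_error")
  }
  if (length(u) < 1) abort_pf("empty fingerprint", "dimension_error")
  c_tt <- sum(u & v); c_tf <- sum(u & !v); c_ft <- sum(!u & v)
  denom <- c_tt + c_tf + c_ft
  d <- if (denom == 0) 0 else (c_tf + c_ft) / denom
  structure(list(d_j = d, c_tt = c_tt, c_tf = c_tf, c_ft = c_ft),
            class = "jaccard_result")
}

#' Pairwise Jaccard distance matrix
#'
#' @param ifps Named list of comparable fingerprints.
#' @return A symmetric numeric matrix.
#' @export
jaccard_matrix <- function(ifps) {
  n <- length(ifps)
  ids <- names(ifps) %||% paste0("m", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      m[i, j] <- m[j, i] <- jaccard_distance(ifps[[i]], ifps[[j]])$d_j
    }
  }
  m
}

#' Cluster fingerprints by Jaccard distance
#'
#' Agglomerative clustering (average linkage by default) on the pairwise
#' Jaccard matrix, cut flat at `cutoff`: two fingerprints whose merge
#' height reaches the cutoff are considered "sufficiently different" and
#' end up in different clusters. Lower the cutoff when the cluster count
#' at the default is inconveniently large.
#'
#' @param ifps Named list of >= 2 comparable fingerprints.
#' @param cutoff Flat-cut height (default 0.6).
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An `ifp_clusters` object: `tree` (hclust), `cutoff`, and a
#'   `clusters` tibble (`model`, `cluster`).
#' @export
cluster_ifps <- function(ifps, cutoff = 0.6, linkage = "average") {
  if (length(ifps) < 2) abort_pf("need at least two fingerprints to cluster",
                                 "dimension_error")
  m <- jaccard_matrix(ifps)
  tree <- stats::hclust(stats::as.dist(m), method = linkage)
  grp <- stats::cutree(tree, h = cutoff - 1e-9)
  structure(list(
    tree = tree, cutoff = cutoff, distances = m,
    clusters = tibble::tibble(model = names(grp), cluster = unname(grp))),
    class = "ifp_clusters")
}

#' @export
print.ifp_clusters <- function(x, ...) {
  cat("<ifp_clusters> ", nrow(x$clusters), " models in ",
      max(x$clusters$cluster), " clusters at cutoff ", x$cutoff, "\n",
      sep = "")
  invisible(x)
}

#' Export an IFP dendrogram as Newick
#'
#' Branch lengths encode the Jaccard merge heights.
#'
#' @param clusters An `ifp_clusters` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
export_dendrogram <- function(clusters, path = NULL) {
  phy <- ape::as.phylo(clusters$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Pick the best-scoring representative of each cluster
#'
#' Within each cluster the member with the highest combined score is the
#' representative; ties break deterministically by model id ascending.
#'
#' @param clusters An `ifp_clusters` object.
#' @param ranking Named numeric vector of combined scores (higher is
#'   better) covering every clustered model.
#' @return Tibble (`cluster`, `representative`, `score`).
#' @export
select_representatives <- function(clusters, ranking) {
  cl <- clusters$clusters
  missing <- setdiff(cl$model, names(ranking))
  if (length(missing) > 0) {
    abort_pf(paste0("no score for model(s): ", paste(missing, collapse = ", ")),
             "ranking_error")
  }
  cl |>
    dplyr::mutate(score = unname(ranking[.data$model])) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$model, .by_group = TRUE) |>
    dplyr::summarise(representative = dplyr::first(.data$model),
                     score = dplyr::first(.data$score), .groups = "drop")
}

#' Write fingerprints to CSV
#'
#' One row per model; columns are `residue:type` 0/1 bits in residue-major
#' order.
#'
#' @param ifps Named list of comparable `ifp` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ifp_csv <- function(ifps, path) {
  rows <- purrr::map(ifps, function(f) as.integer(ifp_flatten(f)))
  df <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(df) <- names(ifp_flatten(ifps[[1]]))
  df <- dplyr::bind_cols(tibble::tibble(model = names(ifps)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read fingerprints from CSV written by [write_ifp_csv()]
#'
#' @param path CSV path.
#' @return Named list of logical vectors (flattened fingerprints).
#' @export
read_ifp_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- df$model
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  out <- purrr::map(seq_len(nrow(m)), function(i) {
    v <- m[i, ]; names(v) <- colnames(m); v
  })
  names(out) <- ids
  out
}
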