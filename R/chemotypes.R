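#' @name chemotypes
#' @title Chemotype clustering and racemic library preparation
#'
#' @description
#' Small-molecule libraries are handled as ChemmineR `SDFset` objects
#' (read from SDF). Chemotypes are defined by complete-linkage
#' agglomerative clustering on `1 - Tanimoto` over 2D pharmacophore
#' point-pair fingerprints (feature type pair x binned topological
#' distance), cut flat at a pharmacophore cutoff of 0.5 by default.
NULL

need_chemmine <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort_pf("the ChemmineR package is required for molecule handling",
             "dependency_error")
  }
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort_pf("the igraph package is required for molecule handling",
             "dependency_error")
  }
}

#' Read molecules from an SDF file
#'
#' @param path SDF (V2000) file path.
#' @return A ChemmineR `SDFset` with unique compound ids (the molecule
#'   names from the SDF header, made unique).
#' @export
read_molecules <- function(path) {
  need_chemmine()
  sdf <- ChemmineR::read.SDFset(path)
  ids <- make.unique(ChemmineR::sdfid(sdf), sep = "_")
  ChemmineR::cid(sdf) <- ids
  sdf
}

# Molecule graph pieces: element vector, formal charges, bond data frame,
# igraph object over heavy atoms.
mol_graph <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  bb <- ChemmineR::bondblock(sdf_mol)
  elem <- gsub("_\\d+$", "", rownames(ab))
  charge <- if ("C6" %in% colnames(ab)) {
    # V2000 charge code: 0 none, 1 = +3 ... 3 = +1, 5 = -1 ... 7 = -3
    code <- ab[, "C6"]
    ifelse(code == 0, 0, 4 - code)
  } else rep(0, nrow(ab))
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]),
                      stereo = if (ncol(bb) >= 4) as.integer(bb[, 4]) else 0L)
  heavy <- which(elem != "H")
  keep <- bonds$a1 %in% heavy & bonds$a2 %in% heavy
  g <- igraph::graph_from_data_frame(
    bonds[keep, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = heavy))
  list(elem = elem, charge = charge, bonds = bonds, heavy = heavy, graph = g,
       parity = if ("C7" %in% colnames(ab)) ab[, "C7"] else rep(0, nrow(ab)))
}

# Pharmacophore feature typing from the 2D graph: donor (N, or O bonded to
# exactly one heavy atom), acceptor (N/O with non-positive charge),
# aromatic (atoms of ChemmineR-perceived aromatic rings), hydrophobe
# (carbon with no hetero neighbour), cation/anion (formal charge).
pharmacophore_types <- function(sdf_mol, mg = mol_graph(sdf_mol)) {
  elem <- mg$elem; n <- length(elem)
  deg_heavy <- rep(0L, n)
  nbr_hetero <- rep(FALSE, n)
  for (k in seq_len(nrow(mg$bonds))) {
    a <- mg$bonds$a1[k]; b <- mg$bonds$a2[k]
    if (elem[a] != "H" && elem[b] != "H") {
      deg_heavy[a] <- deg_heavy[a] + 1L
      deg_heavy[b] <- deg_heavy[b] + 1L
      if (elem[b] %in% c("N", "O", "S")) nbr_hetero[a] <- TRUE
      if (elem[a] %in% c("N", "O", "S")) nbr_hetero[b] <- TRUE
    }
  }
  arom <- rep(FALSE, n)
  ring_idx <- tryCatch(
    ChemmineR::rings(sdf_mol, type = "ring", arom = TRUE),
    error = function(e) NULL)
  if (!is.null(ring_idx) && length(ring_idx$AROMATIC) > 0) {
    ar <- unlist(ring_idx$RINGS[ring_idx$AROMATIC])
    arom[as.integer(gsub("\\D", "", ar))] <- TRUE
  }
  types <- list(
    D = (elem == "N" & mg$charge >= 0) |
      (elem == "O" & deg_heavy == 1 & mg$charge == 0),
    A = elem %in% c("N", "O") & mg$charge <= 0,
    R = arom,
    H = elem == "C" & !nbr_hetero & !arom,
    P = mg$charge > 0,
    M = mg$charge < 0
  )
  purrr::map(types, ~ which(.x & elem != "H"))
}

#' 2D pharmacophore point-pair fingerprint
#'
#' Every pair of pharmacophore features (donor D, acceptor A, aromatic R,
#' hydrophobe H, cation P, anion M) at topological (bond-count) distance
#' `d` sets the bit `"T1T2:b"` where `b = min(d, 10)`. The fingerprint is
#' the set of bits present.
#'
#' @param sdf_mol A single `SDF` molecule (e.g. `sdfset[[i]]`).
#' @return Character vector of bits (sorted, unique).
#' @export
pharmacophore_fingerprint <- function(sdf_mol) {
  need_chemmine()
  mg <- mol_graph(sdf_mol)
  if (length(mg$heavy) == 0) {
    abort_pf("molecule has no heavy atoms", "molecule_error")
  }
  feats <- pharmacophore_types(sdf_mol, mg)
  dmat <- igraph::distances(mg$graph)
  vid <- as.integer(igraph::V(mg$graph)$name)
  bits <- character()
  tn <- names(feats)
  for (i in seq_along(feats)) {
    for (j in i:length(feats)) {
      ai <- feats[[i]]; aj <- feats[[j]]
      if (length(ai) == 0 || length(aj) == 0) next
      di <- match(ai, vid); dj <- match(aj, vid)
      d <- dmat[di, dj, drop = FALSE]
      d <- d[is.finite(d) & d > 0]
      if (length(d) == 0) next
      bits <- c(bits, paste0(tn[i], tn[j], ":", pmin(d, 10)))
    }
  }
  sort(unique(bits))
}

tanimoto_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Cluster a library into chemotypes
#'
#' Complete-linkage agglomerative clustering on `1 - Tanimoto` over
#' pharmacophore point-pair fingerprints, cut flat at `cutoff`. Labels are
#' stable under input order: molecules are processed in canonical
#' (ascending id) order and clusters are numbered by their first member.
#'
#' @param library An `SDFset` (see [read_molecules()]).
#' @param cutoff Flat-cut distance (default 0.5, the pharmacophore
#'   cutoff).
#' @param linkage Linkage method (default `"complete"`).
#' @return Tibble (`id`, `chemotype`) with labels `"C1"`, `"C2"`, ...
#' @export
cluster_chemotypes <- function(library, cutoff = 0.5, linkage = "complete") {
  need_chemmine()
  ids <- ChemmineR::cid(library)
  ord <- order(ids)
  fps <- purrr::map(ord, function(i) {
    fp <- tryCatch(pharmacophore_fingerprint(library[[i]]),
                   error = function(e) NULL)
    if (is.null(fp) || length(fp) == 0) {
      abort_pf(paste0("molecule '", ids[i], "' has no pharmacophore features"),
               "molecule_error")
    }
    fp
  })
  n <- length(fps)
  if (n == 1) {
    return(tibble::tibble(id = ids[ord], chemotype = "C1"))
  }
  m <- matrix(0, n, n, dimnames = list(ids[ord], ids[ord]))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      m[i, j] <- m[j, i] <- 1 - tanimoto_sets(fps[[i]], fps[[j]])
    }
  }
  tree <- stats::hclust(stats::as.dist(m), method = linkage)
  grp <- stats::cutree(tree, h = cutoff - 1e-9)
  # renumber clusters by first (canonical-order) member
  first <- tapply(seq_len(n), grp, min)
  relabel <- match(grp, names(sort(first)))
  tibble::tibble(id = ids[ord], chemotype = paste0("C", relabel))
}

# ---- racemic library preparation ------------------------------------------

# Candidate stereocentres: carbons with >= 3 heavy neighbours whose
# neighbour branches (components of the graph minus the centre) are
# pairwise distinct by a canonical multiset signature. "Unassigned" means
# no atom parity and no wedge/hash bond from the centre.
stereocentres <- function(sdf_mol, mg = mol_graph(sdf_mol)) {
  elem <- mg$elem
  adj <- vector("list", length(elem))
  for (k in seq_len(nrow(mg$bonds))) {
    a <- mg$bonds$a1[k]; b <- mg$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  branch_sig <- function(centre, start) {
    seen <- c(centre); frontier <- start; depth <- 0; parts <- character()
    while (length(frontier) > 0 && depth < 12) {
      seen <- c(seen, frontier)
      parts <- c(parts,
                 paste0(depth, ":", paste(sort(elem[frontier]), collapse = "")))
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      depth <- depth + 1
    }
    paste(parts, collapse = "|")
  }
  out <- integer()
  for (a in which(elem == "C")) {
    nb <- adj[[a]]
    nb_heavy <- nb[elem[nb] != "H"]
    n_h <- (length(nb) - length(nb_heavy)) + max(0, 4 - length(nb))
    bonds_a <- mg$bonds[mg$bonds$a1 == a | mg$bonds$a2 == a, ]
    if (any(bonds_a$order > 1)) next
    # a carbon with two or more hydrogens can never be a stereocentre
    if (length(nb_heavy) < 3 || n_h > 1) next
    sigs <- vapply(nb_heavy, function(s) branch_sig(a, s), character(1))
    if (length(nb_heavy) == 3) sigs <- c(sigs, "implicit-H")
    if (anyDuplicated(sigs) == 0) out <- c(out, a)
  }
  assigned <- mg$parity != 0
  wedge <- mg$bonds$a1[mg$bonds$stereo %in% c(1L, 6L)]
  unassigned <- setdiff(out, c(which(assigned), wedge))
  list(all = out, unassigned = unassigned)
}

#' Prepare a racemic screening library
#'
#' Removes exact duplicates (atom-pair descriptor identity), then expands
#' every molecule with unassigned stereocentres into all explicit
#' stereoisomers (parity set on the centre), leaving assigned centres
#' untouched and generating no tautomers. Molecules with more than
#' `max_centres` unassigned centres are passed through unexpanded with a
#' warning and flagged in the result.
#'
#' @param library An `SDFset`.
#' @param max_centres Enumeration cap (default 5, i.e. at most 32 isomers
#'   per molecule).
#' @return A list: `library` (expanded `SDFset`, ids suffixed `_S<k>` for
#'   enumerated isomers), `table` (tibble `id`, `parent`, `n_centres`,
#'   `overflow`).
#' @export
prepare_racemic_library <- function(library, max_centres = 5) {
  need_chemmine()
  ap <- ChemmineR::sdf2ap(library)
  dup <- ChemmineR::cmp.duplicated(ap)
  library <- library[!dup]
  ids <- ChemmineR::cid(library)
  out_sdfs <- list(); rows <- list()
  for (i in seq_along(ids)) {
    mol <- library[[i]]
    mg <- mol_graph(mol)
    sc <- stereocentres(mol, mg)
    m <- length(sc$unassigned)
    if (m == 0) {
      out_sdfs[[length(out_sdfs) + 1]] <- mol
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = ids[i], parent = ids[i], n_centres = 0L, overflow = FALSE)
      next
    }
    if (m > max_centres) {
      warning("molecule '", ids[i], "' has ", m,
              " unassigned stereocentres (cap ", max_centres,
              "); passed through unexpanded")
      out_sdfs[[length(out_sdfs) + 1]] <- mol
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = ids[i], parent = ids[i], n_centres = as.integer(m),
        overflow = TRUE)
      next
    }
    combos <- as.matrix(expand.grid(rep(list(c(1L, 2L)), m)))
    for (k in seq_len(nrow(combos))) {
      iso <- mol
      ab <- ChemmineR::atomblock(iso)
      ab[sc$unassigned, "C7"] <- combos[k, ]
      iso@atomblock <- ab
      out_sdfs[[length(out_sdfs) + 1]] <- iso
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = paste0(ids[i], "_S", k), parent = ids[i],
        n_centres = as.integer(m), overflow = FALSE)
    }
  }
  tab <- dplyr::bind_rows(rows)
  expanded <- methods::new("SDFset", SDF = out_sdfs,
                           ID = tab$id)
  list(library = expanded, table = tab)
}

#' Write an SDFset to file
#'
#' @param library An `SDFset`.
#' @param path Output SDF path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(library, path) {
  need_chemmine()
  ChemmineR::write.SDF(library, path, cid = TRUE)
  invisible(path)
}
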