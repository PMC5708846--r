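#' @name synthetic_fixtures
#' @title Deterministic toy receptors, ligands and screening tables
#'
#' @description
#' Generators for a coarse-grained seven-transmembrane receptor with a
#' posed pseudo-ligand, a matching topology annotation and
#' Ballesteros-Weinstein anchor map, and labelled screening score tables
#' with controllable class separation. Every generator is a pure function
#' of its spec and seed, so fixtures are regenerated bit-identically at
#' test time and never stored.
NULL

#' Toy receptor specification
#'
#' Seven idealised alpha-helices (2.3 Angstrom helix radius, 1.5 rise,
#' 100 degrees per residue) stand on a ring; residues carry a C-alpha and
#' one side-chain pseudo-atom displaced toward the bundle axis. Short
#' loops connect the helices; ECL2 carries the conserved cysteine. A
#' 12-atom pseudo-ligand (aromatic ring, charged and polar contact atoms)
#' is posed in the orthosteric pocket with its polar atoms ~1.3 Angstrom
#' from matched pocket side chains, so the default 1.5 Angstrom pocket
#' cutoff captures the lining residues.
#'
#' @param residues_per_helix Residues per TM helix (default 14).
#' @param ring_radius Helix-centre ring radius in Angstrom (default 9.5).
#' @param helix_radius Alpha-helix radius in Angstrom (default 2.3).
#' @param rise Rise per residue in Angstrom (default 1.5).
#' @param seed Integer seed.
#' @return A `toy_receptor_spec` list.
#' @export
toy_receptor_spec <- function(residues_per_helix = 14, ring_radius = 9.5,
                              helix_radius = 2.3, rise = 1.5, seed = 1) {
  structure(list(residues_per_helix = residues_per_helix,
                 ring_radius = ring_radius, helix_radius = helix_radius,
                 rise = rise, seed = seed),
            class = "toy_receptor_spec")
}

# Residue-name cycle; polar and apolar types interleaved.
toy_res_cycle <- c("LEU", "SER", "ALA", "ASP", "PHE", "ASN", "VAL",
                   "ARG", "THR", "ILE", "TYR", "GLY", "MET", "GLN")

# Names given to the inward-facing contact residue of each helix TM2-TM7,
# chosen to exercise every fingerprint chemistry.
toy_contact_names <- c(TM2 = "ASP", TM3 = "SER", TM4 = "LEU",
                       TM5 = "ARG", TM6 = "ASN", TM7 = "PHE")

#' Generate a toy receptor-ligand complex
#'
#' @param spec A [toy_receptor_spec()].
#' @return A list: `complex` ([pf_complex()]), `topology`
#'   ([pf_topology()]), `bw_map` (named character vector of the seven
#'   anchors), `planted_pocket` (the generated pocket C-alpha geometry).
#' @export
make_toy_complex <- function(spec = toy_receptor_spec()) {
  if (2 * spec$helix_radius >=
      2 * spec$ring_radius * sin(pi / 7)) {
    abort_pf("helix spacing too small: adjacent helices overlap", "spec_error")
  }
  n <- spec$residues_per_helix
  z_top <- (n - 1) * spec$rise
  segs <- list(); atoms <- list(); res_counter <- 0L
  add_res <- function(res_name, xyz_ca, xyz_sc = NULL) {
    res_counter <<- res_counter + 1L
    rows <- tibble::tibble(atom = "CA", element = "C", res_name = res_name,
                           chain = "A", res_num = res_counter, ins = "",
                           x = xyz_ca[1], y = xyz_ca[2], z = xyz_ca[3],
                           occ = 1, altloc = "")
    if (!is.null(xyz_sc)) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        atom = "SC", element = if (res_name %in% c("ASP", "GLU", "SER",
                                                   "THR", "ASN", "GLN",
                                                   "TYR")) "O" else
          if (res_name %in% c("ARG", "LYS", "HIS")) "N" else "C",
        res_name = res_name, chain = "A", res_num = res_counter, ins = "",
        x = xyz_sc[1], y = xyz_sc[2], z = xyz_sc[3], occ = 1, altloc = ""))
    }
    atoms[[length(atoms) + 1]] <<- rows
    res_counter
  }
  seg_push <- function(label, first, last) {
    segs[[length(segs) + 1]] <<- tibble::tibble(label = label, start = first,
                                                end = last)
  }
  helix_centre <- function(h) {
    a <- 2 * pi * (h - 1) / 7
    c(spec$ring_radius * cos(a), spec$ring_radius * sin(a))
  }
  build_helix <- function(h, going_up) {
    ctr <- helix_centre(h)
    first <- res_counter + 1L
    for (i in seq_len(n)) {
      t <- (i - 1) * 100 * pi / 180
      z <- if (going_up) (i - 1) * spec$rise else z_top - (i - 1) * spec$rise
      ca <- c(ctr[1] + spec$helix_radius * cos(t),
              ctr[2] + spec$helix_radius * sin(t), z)
      inward <- -ca[1:2] / sqrt(sum(ca[1:2]^2))
      sc <- c(ca[1:2] + 1.5 * inward, z)
      nm <- toy_res_cycle[(res_counter %% length(toy_res_cycle)) + 1]
      add_res(nm, ca, sc)
    }
    seg_push(paste0("TM", h), first, res_counter)
  }
  build_loop <- function(label, from_h, to_h, n_res, top) {
    z <- if (top) z_top + 2.5 else -2.5
    c1 <- helix_centre(from_h); c2 <- helix_centre(to_h)
    first <- res_counter + 1L
    for (i in seq_len(n_res)) {
      w <- i / (n_res + 1)
      p <- (1 - w) * c1 + w * c2
      p <- p * 1.15  # bow loops slightly outward
      nm <- if (label == "ECL2" && i == 3) "CYS" else "GLY"
      add_res(nm, c(p, z), NULL)
    }
    seg_push(label, first, res_counter)
    if (label == "ECL2") first + 2L else NA_integer_
  }
  # N-terminus (2 residues), then TM1..TM7 with connecting loops.
  first <- res_counter + 1L
  nt <- helix_centre(1)
  add_res("GLY", c(nt * 1.3, z_top + 4)); add_res("SER", c(nt * 1.25, z_top + 3))
  seg_push("NTERM", first, res_counter)
  build_helix(1, going_up = FALSE)
  build_loop("ICL1", 1, 2, 3, top = FALSE)
  build_helix(2, going_up = TRUE)
  build_loop("ECL1", 2, 3, 3, top = TRUE)
  build_helix(3, going_up = FALSE)
  build_loop("ICL2", 3, 4, 3, top = FALSE)
  build_helix(4, going_up = TRUE)
  cys <- build_loop("ECL2", 4, 5, 6, top = TRUE)
  build_helix(5, going_up = FALSE)
  build_loop("ICL3", 5, 6, 3, top = FALSE)
  build_helix(6, going_up = TRUE)
  build_loop("ECL3", 6, 7, 3, top = TRUE)
  build_helix(7, going_up = FALSE)
  receptor <- dplyr::bind_rows(atoms)
  seg_tbl <- dplyr::bind_rows(segs)
  topology <- pf_topology(seg_tbl, ecl2_cysteine = cys, chain = "A")

  # Rename the inward-most top residue of TM2-TM7 to a fixed contact type
  # and pose one matched ligand atom 1.3 A inward of its side chain.
  lig_rows <- list(); charges <- numeric()
  for (h in 2:7) {
    seg <- seg_tbl[seg_tbl$label == paste0("TM", h), ]
    cand <- receptor[receptor$res_num >= seg$start &
                       receptor$res_num <= seg$end &
                       receptor$atom == "SC" &
                       receptor$z > z_top - 5, ]
    cand$r <- sqrt(cand$x^2 + cand$y^2)
    pick <- cand[which.min(cand$r), ]
    nm <- toy_contact_names[[paste0("TM", h)]]
    sel <- receptor$res_num == pick$res_num
    receptor$res_name[sel] <- nm
    receptor$element[sel & receptor$atom == "SC"] <-
      if (nm %in% c("ASP", "SER", "ASN")) "O" else
        if (nm == "ARG") "N" else "C"
    inward <- -c(pick$x, pick$y) / sqrt(pick$x^2 + pick$y^2)
    pos <- c(pick$x + 1.3 * inward[1], pick$y + 1.3 * inward[2], pick$z)
    lig <- switch(nm,
      ASP = list(atom = "N1", element = "N", q = 1),
      ARG = list(atom = "O1", element = "O", q = -1),
      SER = list(atom = "O2", element = "O", q = 0),
      ASN = list(atom = "O3", element = "O", q = 0),
      list(atom = paste0("C", h), element = "C", q = 0))
    lig_rows[[length(lig_rows) + 1]] <- tibble::tibble(
      atom = lig$atom, element = lig$element, res_name = "LIG", chain = "L",
      res_num = 1L, ins = "", x = pos[1], y = pos[2], z = pos[3],
      occ = 1, altloc = "")
    if (lig$q != 0) charges[lig$atom] <- lig$q
  }
  # aromatic ring at the pocket centre
  ring_z <- z_top - 3
  ring <- purrr::map_dfr(1:6, function(i) {
    a <- 2 * pi * (i - 1) / 6
    tibble::tibble(atom = paste0("CR", i), element = "C", res_name = "LIG",
                   chain = "L", res_num = 1L, ins = "",
                   x = 1.25 * cos(a), y = 1.25 * sin(a), z = ring_z,
                   occ = 1, altloc = "")
  })
  ligand <- dplyr::bind_rows(c(lig_rows, list(ring)))
  cplx <- pf_complex(receptor, ligand,
                     metadata = paste0("toy 7TM receptor (seed ", spec$seed, ")"),
                     ligand_rings = list(paste0("CR", 1:6)),
                     ligand_charges = charges)
  bw <- character()
  for (h in 1:7) {
    seg <- seg_tbl[seg_tbl$label == paste0("TM", h), ]
    ca <- receptor[receptor$atom == "CA" & receptor$res_num >= seg$start &
                     receptor$res_num <= seg$end, ]
    target_z <- z_top - 7  # anchors sit below the pocket, ~1/3 down
    anchor <- ca$res_num[which.min(abs(ca$z - target_z))]
    bw[bw_anchor_positions[h]] <- paste0("A:", anchor)
  }
  pocket <- define_pocket(cplx, cutoff = 1.5)
  list(complex = cplx, topology = topology, bw_map = bw,
       planted_pocket = pocket)
}

#' Apply a seeded random perturbation to a residue region
#'
#' Each named residue is displaced rigidly (all its atoms share one
#' random direction and a random amount in `[0, magnitude]`), so no atom
#' moves farther than `magnitude`; all other atoms are bit-identical to
#' the input. Set `collective = FALSE` for independent per-atom
#' displacements.
#'
#' @param complex A [pf_complex()].
#' @param region Character vector of residue ids (`chain:resnum`).
#' @param magnitude Maximum displacement in Angstrom.
#' @param seed Integer seed.
#' @param collective Move residues as rigid units (default `TRUE`).
#' @return A perturbed [pf_complex()].
#' @export
perturb_complex <- function(complex, region, magnitude, seed = 1,
                            collective = TRUE) {
  stopifnot(magnitude >= 0)
  ids <- receptor_residues(complex)
  unknown <- setdiff(region, ids)
  if (length(unknown) > 0) {
    abort_pf(paste0("unknown residue(s) in region: ",
                    paste(unknown, collapse = ", ")), "id_error")
  }
  at <- complex$receptor
  rid <- res_id(at$chain, at$res_num, at$ins)
  sel <- rid %in% region
  k <- sum(sel)
  if (k > 0 && magnitude > 0) {
    grp <- if (collective) match(rid[sel], unique(rid[sel])) else seq_len(k)
    ng <- max(grp)
    disp <- with_seed(seed, {
      dir <- matrix(stats::rnorm(3 * ng), ng, 3)
      dir <- dir / sqrt(rowSums(dir^2))
      (dir * stats::runif(ng, 0, magnitude))[grp, , drop = FALSE]
    })
    at$x[sel] <- at$x[sel] + disp[, 1]
    at$y[sel] <- at$y[sel] + disp[, 2]
    at$z[sel] <- at$z[sel] + disp[, 3]
  }
  out <- complex
  out$receptor <- at
  out
}

#' Screening-table specification
#'
#' Defaults emulate the scale and structure of the GPCR ligand library /
#' decoy database screens: 100 known ligands (50 agonists, 50 inhibitors)
#' matched with 39 decoys each, three docking repeats per compound, and
#' class-conditional Gaussian scores on a lower-is-better (docking energy)
#' scale. `active_mean` below `decoy_mean` yields positive expected
#' NSQ_AUC; the gap is the enrichment control.
#'
#' @param n_agonists,n_inhibitors,n_decoys Class sizes.
#' @param n_repeats Docking repeats per compound (default 3).
#' @param agonist_mean,inhibitor_mean,decoy_mean Class score means
#'   (kcal/mol-like arbitrary units).
#' @param score_sd Common score standard deviation.
#' @param n_chemotypes Number of chemotype clusters among actives.
#' @param seed Integer seed.
#' @return A `screen_spec` list.
#' @export
screen_spec <- function(n_agonists = 50, n_inhibitors = 50, n_decoys = 3900,
                        n_repeats = 3, agonist_mean = -29,
                        inhibitor_mean = -29, decoy_mean = -25,
                        score_sd = 2.5, n_chemotypes = 5, seed = 1) {
  if (n_agonists < 0 || n_inhibitors < 0 || n_decoys < 0) {
    abort_pf("class counts must be non-negative", "spec_error")
  }
  if (n_repeats < 1) abort_pf("need at least one repeat", "spec_error")
  structure(list(n_agonists = n_agonists, n_inhibitors = n_inhibitors,
                 n_decoys = n_decoys, n_repeats = n_repeats,
                 agonist_mean = agonist_mean, inhibitor_mean = inhibitor_mean,
                 decoy_mean = decoy_mean, score_sd = score_sd,
                 n_chemotypes = n_chemotypes, seed = seed),
            class = "screen_spec")
}

#' Generate a labelled screening score table
#'
#' @param spec A [screen_spec()].
#' @return A [screen_table()] tibble with `id`, `role`, `pharmacology`,
#'   `chemotype` and `score_1..score_k` columns.
#' @export
make_screen_table <- function(spec = screen_spec()) {
  n_act <- spec$n_agonists + spec$n_inhibitors
  n <- n_act + spec$n_decoys
  if (n == 0) abort_pf("empty screen spec", "spec_error")
  with_seed(spec$seed, {
    role <- c(rep("active", n_act), rep("decoy", spec$n_decoys))
    pharm <- c(rep("agonist", spec$n_agonists),
               rep("inhibitor", spec$n_inhibitors),
               rep("none", spec$n_decoys))
    chem <- rep(NA_character_, n)
    if (n_act > 0 && spec$n_chemotypes > 0) {
      w <- 2^-(seq_len(spec$n_chemotypes))  # few large, many small clusters
      chem[seq_len(n_act)] <- sample(paste0("C", seq_len(spec$n_chemotypes)),
                                     n_act, replace = TRUE, prob = w / sum(w))
    }
    mu <- c(rep(spec$agonist_mean, spec$n_agonists),
            rep(spec$inhibitor_mean, spec$n_inhibitors),
            rep(spec$decoy_mean, spec$n_decoys))
    sc <- matrix(stats::rnorm(n * spec$n_repeats, mean = mu, sd = spec$score_sd),
                 nrow = n)
    colnames(sc) <- paste0("score_", seq_len(spec$n_repeats))
    screen_table(dplyr::bind_cols(
      tibble::tibble(id = sprintf("CPD%06d", seq_len(n)), role = role,
                     pharmacology = pharm, chemotype = chem),
      tibble::as_tibble(sc)))
  })
}
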