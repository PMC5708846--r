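#' Toy stage backends for the LDM workflow
#'
#' Deterministic, self-contained stand-ins for the heavy sampling,
#' docking and fold-scoring stages so the orchestrator runs end-to-end on
#' coarse-grained fixtures. They are simple geometric models in their own
#' right, not re-implementations of any production engine:
#'
#' * `init_relax` - small seeded jitter of the mobile (non-static) region,
#'   giving each replica a distinct start.
#' * `backbone_sample` - seeded random displacement of the mobile region's
#'   atoms (per-residue collective moves of C-alpha + side-chain
#'   pseudo-atom).
#' * `sidechain_sample` - seeded jitter of side-chain pseudo-atoms only.
#' * `rebuild_and_minimize` - restores the static region to its reference
#'   coordinates and relieves hard clashes with a few steepest-descent
#'   steps on a soft-sphere potential.
#' * `dock` - rigid-ligand search over a small translation grid, scored by
#'   clash penalty minus polar-contact reward (lower is better). Receptor
#'   atoms outside `refine_radius` of the ligand are never moved.
#' * `fold_score` - squared deviation of consecutive C-alpha distances
#'   from the ideal 3.8 Angstrom plus a soft-sphere clash term (lower is
#'   better).
#'
#' The dock score can be anchored to a reference complex: when
#' `reference` is supplied, every receptor side-chain / ligand heavy-atom
#' pair within `contact_range` of each other in the reference defines a
#' distance restraint, and the reward is a Gaussian well around each
#' reference distance. The toy dock score is then optimised exactly at
#' the reference (planted) pocket geometry, which is what makes
#' planted-optimum recovery experiments meaningful. Without a reference
#' the reward falls back to generic chemistry (polar-polar and
#' apolar-apolar contacts at `contact_distance`).
#'
#' @param reference Optional [pf_complex()] whose contact geometry
#'   anchors the dock reward.
#' @param mobile_amplitude Backbone sampling amplitude per move, Angstrom
#'   (default 0.15).
#' @param move_fraction Fraction of mobile residues displaced per
#'   backbone move (default 0.15); small low-dimensional moves keep the
#'   per-round best-of-directories selection effective.
#' @param sidechain_amplitude Side-chain jitter amplitude, Angstrom
#'   (default 0.1).
#' @param contact_distance Ideal contact distance of the generic dock
#'   reward, matching the fixture's planted contact geometry (default
#'   1.3 Angstrom).
#' @param contact_range Residues whose reference side-chain / ligand
#'   minimum distance is within this range are restrained (default 4
#'   Angstrom).
#' @param grid_step,grid_extent Translation grid of the rigid dock search
#'   (default 0.25 Angstrom steps out to +/- 0.5).
#' @return A named list of backend functions satisfying the stage
#'   contract of [run_ldm()].
#' @export
toy_backends <- function(reference = NULL, mobile_amplitude = 0.15,
                         move_fraction = 0.15, sidechain_amplitude = 0.1,
                         contact_distance = 1.3, contact_range = 4,
                         grid_step = 0.25, grid_extent = 0.5) {
  contact_map <- NULL
  if (!is.null(reference)) {
    # residues whose side chain touches the ligand in the reference are
    # restrained against the full ligand distance profile, which pins
    # their position uniquely (multilateration) instead of leaving a
    # degenerate sphere per single restraint
    rec <- reference$receptor
    sc <- which(rec$atom == "SC")
    d <- cross_dist(as.matrix(rec[sc, c("x", "y", "z")]),
                    as.matrix(reference$ligand[, c("x", "y", "z")]))
    near <- which(apply(d, 1, min) <= contact_range)
    idx <- as.matrix(expand.grid(i = near, j = seq_len(ncol(d))))
    contact_map <- list(
      rec_key = res_id(rec$chain, rec$res_num, rec$ins)[sc][idx[, 1]],
      lig_atom = reference$ligand$atom[idx[, 2]],
      d_ref = d[idx])
  }
  # Collective per-residue moves: every atom of a residue shares one
  # displacement, so selection acting on side-chain contacts also
  # constrains the backbone.
  jitter_region <- function(complex, sel, amp, seed, collective = TRUE) {
    at <- complex$receptor
    k <- sum(sel)
    if (k == 0 || amp == 0) return(complex)
    rid <- res_id(at$chain, at$res_num, at$ins)[sel]
    grp <- if (collective) match(rid, unique(rid)) else seq_len(k)
    ng <- max(grp)
    disp <- with_seed(seed, {
      dir <- matrix(stats::rnorm(3 * ng), ng, 3)
      (dir / sqrt(rowSums(dir^2)) * stats::runif(ng, 0, amp))[grp, , drop = FALSE]
    })
    at$x[sel] <- at$x[sel] + disp[, 1]
    at$y[sel] <- at$y[sel] + disp[, 2]
    at$z[sel] <- at$z[sel] + disp[, 3]
    complex$receptor <- at
    complex
  }
  mobile_mask <- function(complex, static_region = attr(complex, "static_region")) {
    ids <- res_id(complex$receptor$chain, complex$receptor$res_num,
                  complex$receptor$ins)
    !(ids %in% (static_region %||% character()))
  }
  soft_sphere_relief <- function(complex, n_steps = 3, hard = 1.0) {
    at <- complex$receptor
    xyz <- as.matrix(at[, c("x", "y", "z")])
    for (s in seq_len(n_steps)) {
      d <- cross_dist(xyz, xyz)
      diag(d) <- Inf
      clash <- which(d < hard, arr.ind = TRUE)
      clash <- clash[clash[, 1] < clash[, 2], , drop = FALSE]
      if (nrow(clash) == 0) break
      for (k in seq_len(nrow(clash))) {
        i <- clash[k, 1]; j <- clash[k, 2]
        v <- xyz[j, ] - xyz[i, ]
        nv <- sqrt(sum(v^2))
        if (nv < 1e-9) next
        push <- 0.5 * (hard - nv) * v / nv
        xyz[i, ] <- xyz[i, ] - push
        xyz[j, ] <- xyz[j, ] + push
      }
    }
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    complex$receptor <- at
    complex
  }
  dock_score_fn <- function(rec, lig, lig_xyz) {
    rxyz <- as.matrix(rec[, c("x", "y", "z")])
    d <- cross_dist(rxyz, lig_xyz)
    clash <- sum(pmax(0, 0.9 - d)^2) * 10
    if (!is.null(contact_map)) {
      sc <- which(rec$atom == "SC")
      ri <- match(contact_map$rec_key,
                  res_id(rec$chain, rec$res_num, rec$ins)[sc])
      li <- match(contact_map$lig_atom, lig$atom)
      dc <- d[sc[ri] + (li - 1) * nrow(d)]
      reward <- sum(exp(-((dc - contact_map$d_ref) / 0.6)^2), na.rm = TRUE)
    } else {
      lig_polar <- lig$element %in% c("N", "O")
      rec_polar <- rec$atom == "SC" & rec$element %in% c("N", "O")
      rec_apolar <- rec$atom == "SC" & rec$element == "C"
      gauss <- function(x) exp(-((x - contact_distance) / 0.4)^2)
      reward <- sum(gauss(d[rec_polar, lig_polar, drop = FALSE])) +
        0.5 * sum(gauss(d[rec_apolar, !lig_polar, drop = FALSE]))
    }
    clash - reward
  }
  list(
    init_relax = function(complex, seed) {
      jitter_region(complex, mobile_mask(complex), 0.05, seed)
    },
    backbone_sample = function(complex, seed, receptor_only = FALSE) {
      # collective displacement of a random subset of mobile residues:
      # low-dimensional moves give the round's best-of-directories
      # selection something to act on
      sel <- mobile_mask(complex)
      rid <- res_id(complex$receptor$chain, complex$receptor$res_num,
                    complex$receptor$ins)
      mob <- unique(rid[sel])
      pick <- with_seed(seed, sample(mob, max(1, round(move_fraction *
                                                         length(mob)))))
      jitter_region(complex, sel & rid %in% pick, mobile_amplitude,
                    seed + 7L)
    },
    sidechain_sample = function(complex, seed) {
      sel <- mobile_mask(complex) & complex$receptor$atom == "SC"
      jitter_region(complex, sel, sidechain_amplitude, seed)
    },
    rebuild_and_minimize = function(complex, static_region) {
      complex <- soft_sphere_relief(complex)
      ref <- attr(complex, "static_reference")
      if (!is.null(ref) && length(static_region) > 0) {
        ids <- res_id(complex$receptor$chain, complex$receptor$res_num,
                      complex$receptor$ins)
        sel <- ids %in% static_region
        complex$receptor[sel, c("x", "y", "z")] <- ref[sel, c("x", "y", "z")]
      }
      complex
    },
    dock = function(complex, pocket, refine_radius, seed) {
      lig <- complex$ligand
      lxyz <- as.matrix(lig[, c("x", "y", "z")])
      steps <- seq(-grid_extent, grid_extent, by = grid_step)
      grid <- as.matrix(expand.grid(dx = steps, dy = steps, dz = steps))
      best <- NULL; best_score <- Inf
      for (g in seq_len(nrow(grid))) {
        cand <- sweep(lxyz, 2, grid[g, ], "+")
        s <- dock_score_fn(complex$receptor, lig, cand)
        if (s < best_score) { best_score <- s; best <- cand }
      }
      complex$ligand$x <- best[, 1]
      complex$ligand$y <- best[, 2]
      complex$ligand$z <- best[, 3]
      list(complex = complex, dock_score = best_score)
    },
    fold_score = function(complex) {
      ca <- complex$receptor[complex$receptor$atom == "CA", ]
      ca <- dplyr::arrange(ca, .data$chain, .data$res_num, .data$ins)
      xyz <- as.matrix(ca[, c("x", "y", "z")])
      consec <- diff(ca$res_num) == 1
      dd <- sqrt(rowSums(diff(xyz)^2))
      bond <- sum((dd[consec] - 3.8)^2)
      d <- cross_dist(xyz, xyz); diag(d) <- Inf
      clash <- sum(pmax(0, 2.5 - d)^2) / 2
      bond + clash
    }
  )
}
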