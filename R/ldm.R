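#' LDM run configuration
#'
#' Controls the replica / round / directory hierarchy of the iterative
#' ligand-directed refinement and its two selection filters. The default
#' counts give a capacity of `16 x 20 = 320` output models; they are
#' artifact defaults meant to be tuned per study, and the test suites run
#' far smaller configurations.
#'
#' @param n_replicas Independent restarts (default 16).
#' @param n_rounds Refinement iterations per replica (default 20).
#' @param n_directories Parallel sampling chains per round (default 8).
#' @param pocket_rmsd_cutoff Pocket C-alpha RMSD filter in Angstrom
#'   (default 1.0).
#' @param polar_conservation_fraction Minimum conserved fraction of
#'   reference polar pocket residues (default 0.8).
#' @param polar_tolerance Displacement tolerance (Angstrom) under which a
#'   polar side-chain group counts as conserved (default 1.5).
#' @param refine_radius Docking refinement radius around the ligand in
#'   Angstrom (default 2.0).
#' @param pocket_cutoff Pocket definition cutoff in Angstrom (default
#'   1.5).
#' @param master_seed Integer seed; every per-directory seed derives from
#'   `(master_seed, replica, round, directory)` so results are independent
#'   of execution order.
#' @return An `ldm_config` list.
#' @export
ldm_config <- function(n_replicas = 16, n_rounds = 20, n_directories = 8,
                       pocket_rmsd_cutoff = 1.0,
                       polar_conservation_fraction = 0.8,
                       polar_tolerance = 1.5, refine_radius = 2.0,
                       pocket_cutoff = 1.5, master_seed = 1) {
  stopifnot(n_replicas >= 1, n_rounds >= 1, n_directories >= 1,
            pocket_rmsd_cutoff > 0, polar_conservation_fraction > 0,
            polar_conservation_fraction <= 1, refine_radius > 0)
  structure(list(n_replicas = as.integer(n_replicas),
                 n_rounds = as.integer(n_rounds),
                 n_directories = as.integer(n_directories),
                 pocket_rmsd_cutoff = pocket_rmsd_cutoff,
                 polar_conservation_fraction = polar_conservation_fraction,
                 polar_tolerance = polar_tolerance,
                 refine_radius = refine_radius,
                 pocket_cutoff = pocket_cutoff,
                 master_seed = as.integer(master_seed)),
            class = "ldm_config")
}

#' Read an LDM configuration from JSON
#'
#' @param path JSON file whose keys match the [ldm_config()] arguments.
#' @return An `ldm_config`.
#' @export
read_ldm_config <- function(path) {
  j <- jsonlite::fromJSON(path)
  do.call(ldm_config, j[intersect(names(j), names(formals(ldm_config)))])
}

#' Keep candidates whose pocket stayed near the reference
#'
#' Retains every candidate whose pocket C-alpha RMSD to the reference
#' (after least-squares superposition) is at most `cutoff`.
#'
#' @param candidates List of [pf_complex()]es.
#' @param reference The round's starting [pf_complex()].
#' @param cutoff RMSD cutoff in Angstrom.
#' @param pocket A `binding_pocket` fixing the residue list.
#' @return The surviving sublist, with an `rmsd` attribute.
#' @export
pocket_distance_filter <- function(candidates, reference, cutoff, pocket) {
  if (length(candidates) == 0) return(candidates)
  ref <- extract_pocket(reference, pocket)
  rmsd <- purrr::map_dbl(candidates, function(cc) {
    superimpose_pockets(ref, extract_pocket(cc, pocket))$rmsd
  })
  out <- candidates[rmsd <= cutoff]
  attr(out, "rmsd") <- rmsd
  out
}

# Polar side-chain group centroid per polar pocket residue.
polar_group_centroids <- function(complex, pocket) {
  res <- pocket$residues[pocket$residues$polar, ]
  if (nrow(res) == 0) return(NULL)
  at <- complex$receptor[!is_backbone_atom(complex$receptor$atom), ]
  m <- matrix(NA_real_, nrow(res), 3, dimnames = list(res$res_id, NULL))
  for (i in seq_len(nrow(res))) {
    sel <- at$chain == res$chain[i] & at$res_num == res$res_num[i] &
      at$ins == res$ins[i]
    if (any(sel)) m[i, ] <- colMeans(as.matrix(at[sel, c("x", "y", "z")]))
  }
  m
}

#' Keep candidates that conserve the reference's polar pocket residues
#'
#' A polar residue is conserved when its side-chain polar-group centroid
#' stays within `tolerance` of the reference position after pocket
#' superposition; a candidate survives when the conserved fraction is at
#' least `fraction`. A reference without polar pocket residues passes all
#' candidates with a warning.
#'
#' @param candidates List of [pf_complex()]es.
#' @param reference Reference [pf_complex()].
#' @param fraction Minimum conserved fraction in `(0, 1]`.
#' @param pocket A `binding_pocket` (its `polar` mask defines the
#'   reference polar residues).
#' @param tolerance Conservation tolerance in Angstrom (default 1.5).
#' @return The surviving sublist, with a `conservation` attribute.
#' @export
polar_conservation_filter <- function(candidates, reference, fraction, pocket,
                                      tolerance = 1.5) {
  if (length(candidates) == 0) return(candidates)
  ref_cent <- polar_group_centroids(reference, pocket)
  if (is.null(ref_cent) || all(is.na(ref_cent))) {
    warning("reference pocket has no polar residues; filter passes all")
    attr(candidates, "conservation") <- rep(1, length(candidates))
    return(candidates)
  }
  ref_pocket <- extract_pocket(reference, pocket)
  cons <- purrr::map_dbl(candidates, function(cc) {
    # superimpose candidate pocket onto reference, then carry the same
    # rigid transform to the candidate's polar group centroids
    tg <- extract_pocket(cc, pocket)
    cm <- colMeans(tg$ca_coords); cr <- colMeans(ref_pocket$ca_coords)
    s <- svd(crossprod(sweep(tg$ca_coords, 2, cm),
                       sweep(ref_pocket$ca_coords, 2, cr)))
    rot <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
    cand_cent <- polar_group_centroids(cc, pocket)
    moved <- sweep(sweep(cand_cent, 2, cm) %*% rot, 2, cr, "+")
    d <- sqrt(rowSums((moved - ref_cent)^2))
    mean(d <= tolerance, na.rm = TRUE)
  })
  out <- candidates[cons >= fraction]
  attr(out, "conservation") <- cons
  out
}

#' Equal-weight normalised combined ranking of LDM models
#'
#' Dock and fold scores are each min-max normalised over the model set
#' and oriented so 1 is most favourable; the combined score is their
#' equal-weight mean. A zero-range score contributes 0.5 for every model.
#' Models are sorted by descending combined score with deterministic ties
#' (dock score, replica, round).
#'
#' @param models Tibble with `dock_score` and `fold_score` columns (lower
#'   favourable for both).
#' @return The tibble with `norm_dock`, `norm_fold` and `combined_score`,
#'   sorted.
#' @export
combined_rank <- function(models) {
  if (nrow(models) == 0) return(models)
  if (anyNA(models$dock_score) || anyNA(models$fold_score)) {
    abort_pf("model(s) with missing dock or fold score", "ranking_error")
  }
  norm <- function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) rep(0.5, length(x)) else (max(x) - x) / rng
  }
  models$norm_dock <- norm(models$dock_score)
  models$norm_fold <- norm(models$fold_score)
  models$combined_score <- 0.5 * models$norm_dock + 0.5 * models$norm_fold
  dplyr::arrange(models, dplyr::desc(.data$combined_score),
                 .data$dock_score, .data$replica, .data$round)
}

#' Take the top-k ranked models and assign LDM names
#'
#' @param models A ranked model tibble (see [combined_rank()]).
#' @param k Number of models to keep (default 25). When fewer are
#'   available all are returned with a warning.
#' @return The first `k` rows with a `model_id` column `"LDM 000"` ...
#' @export
top_k <- function(models, k = 25) {
  if (k > nrow(models)) {
    warning("requested top ", k, " of ", nrow(models), " models")
    k <- nrow(models)
  }
  out <- models[seq_len(k), ]
  out$model_id <- sprintf("LDM %03d", seq_len(k) - 1)
  dplyr::relocate(out, "model_id")
}

#' Run the iterative ligand-directed modeling workflow
#'
#' Per replica, the start system is relaxed and minimally sampled into a
#' distinct starting point; each round then runs `n_directories`
#' independent chains of backbone sampling, the pocket-distance filter,
#' side-chain sampling, the polar-conservation filter, static-region
#' rebuild/minimisation and docking. The best-docking survivor of the
#' round is extracted, fold-scored, recorded as that round's model and
#' becomes the next round's input; all other complexes are discarded. The
#' first round samples the receptor alone; later rounds sample the
#' receptor-ligand complex. After all rounds the collected models are
#' ranked by the equal-weight normalised dock+fold score. A round whose
#' directories are all filtered out yields no model and the replica
#' continues from its previous complex; a backend failure aborts the
#' replica with a diagnostic and the run continues.
#'
#' @param start A [pf_complex()] (loops already trimmed, or supply
#'   `topology` to trim here).
#' @param config An [ldm_config()].
#' @param backends A [toy_backends()]-shaped backend list.
#' @param topology Optional [pf_topology()]; when given, loops are
#'   trimmed and the static region is derived via [partition_regions()]
#'   with `bw_map`.
#' @param bw_map Ballesteros-Weinstein anchor map (required with
#'   `topology`).
#' @return An `ldm_run` object: `models` (ranked tibble), `complexes`
#'   (named list of output [pf_complex()]es), `provenance` (one row per
#'   directory), `config`, `pocket`.
#' @export
run_ldm <- function(start, config = ldm_config(), backends = toy_backends(),
                    topology = NULL, bw_map = NULL) {
  required <- c("init_relax", "backbone_sample", "sidechain_sample",
                "rebuild_and_minimize", "dock", "fold_score")
  missing <- setdiff(required, names(backends))
  if (length(missing) > 0) {
    abort_pf(paste0("backend contract incomplete; missing: ",
                    paste(missing, collapse = ", ")), "config_error")
  }
  static_region <- character()
  if (!is.null(topology)) {
    start <- trim_loops(start, topology)
    if (is.null(bw_map)) abort_pf("topology given without bw_map",
                                  "config_error")
    static_region <- partition_regions(start, topology, bw_map)$cytoplasmic
  }
  pocket <- define_pocket(start, cutoff = config$pocket_cutoff)
  # static-region identity and reference coordinates travel with the
  # complex so backends can honour the rigid-cytoplasm contract
  attr(start, "static_region") <- static_region
  attr(start, "static_reference") <- start$receptor
  models <- list(); complexes <- list(); prov <- list()
  for (replica in seq_len(config$n_replicas)) {
    current <- tryCatch(
      backends$init_relax(start, derive_seed(config$master_seed, replica)),
      error = function(e) {
        message("replica ", replica, " aborted in init_relax: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(current)) next
    aborted <- FALSE
    for (round in seq_len(config$n_rounds)) {
      if (aborted) break
      round_results <- purrr::map(seq_len(config$n_directories), function(d) {
        seed <- derive_seed(config$master_seed, replica, round, d)
        tryCatch({
          # round 1 samples the receptor alone; the ligand rejoins at dock
          sys <- current
          cand <- backends$backbone_sample(sys, seed,
                                           receptor_only = round == 1)
          keep1 <- length(pocket_distance_filter(
            list(cand), current, config$pocket_rmsd_cutoff, pocket)) == 1
          if (!keep1) {
            return(list(status = "filtered_rmsd", seed = seed))
          }
          cand <- backends$sidechain_sample(cand, seed + 1L)
          keep2 <- length(polar_conservation_filter(
            list(cand), current, config$polar_conservation_fraction, pocket,
            config$polar_tolerance)) == 1
          if (!keep2) {
            return(list(status = "filtered_polar", seed = seed))
          }
          cand <- backends$rebuild_and_minimize(cand, static_region)
          dock <- backends$dock(cand, pocket, config$refine_radius, seed + 2L)
          list(status = "docked", seed = seed, complex = dock$complex,
               dock_score = dock$dock_score)
        }, error = function(e) list(status = "backend_error",
                                    message = conditionMessage(e)))
      })
      statuses <- purrr::map_chr(round_results, "status")
      if (any(statuses == "backend_error")) {
        message("replica ", replica, " aborted in round ", round, ": ",
                round_results[[which(statuses == "backend_error")[1]]]$message)
        aborted <- TRUE
      }
      docked <- which(statuses == "docked")
      extracted_dir <- NA_integer_
      if (!aborted && length(docked) > 0) {
        scores <- purrr::map_dbl(round_results[docked], "dock_score")
        best <- docked[which.min(scores)]
        extracted_dir <- best
        current <- round_results[[best]]$complex
        fold <- tryCatch(backends$fold_score(current), error = function(e) {
          message("replica ", replica, " aborted in fold_score: ",
                  conditionMessage(e))
          NULL
        })
        if (is.null(fold)) {
          aborted <- TRUE
        } else {
          key <- sprintf("r%02d_round%02d", replica, round)
          models[[key]] <- tibble::tibble(
            model = key, replica = replica, round = round,
            dock_score = round_results[[best]]$dock_score, fold_score = fold)
          complexes[[key]] <- current
        }
      }
      prov[[length(prov) + 1]] <- tibble::tibble(
        replica = replica, round = round,
        directory = seq_len(config$n_directories),
        status = statuses,
        dock_score = purrr::map_dbl(round_results, ~ .x$dock_score %||% NA_real_),
        extracted = seq_len(config$n_directories) == extracted_dir)
    }
  }
  models <- if (length(models) > 0) dplyr::bind_rows(models) else
    tibble::tibble(model = character(), replica = integer(),
                   round = integer(), dock_score = numeric(),
                   fold_score = numeric())
  ranked <- combined_rank(models)
  structure(list(models = ranked, complexes = complexes,
                 provenance = dplyr::bind_rows(prov), config = config,
                 pocket = pocket, static_region = static_region),
            class = "ldm_run")
}

#' @export
print.ldm_run <- function(x, ...) {
  cat("<ldm_run> ", nrow(x$models), " models from ",
      x$config$n_replicas, " replica(s) x ", x$config$n_rounds,
      " round(s)\n", sep = "")
  invisible(x)
}

#' @rdname run_ldm
#' @param x An `ldm_run`.
#' @param ... Unused.
#' @export
tidy.ldm_run <- function(x, ...) x$models

#' @rdname run_ldm
#' @export
glance.ldm_run <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$models),
    capacity = x$config$n_replicas * x$config$n_rounds,
    n_filtered_rmsd = sum(x$provenance$status == "filtered_rmsd"),
    n_filtered_polar = sum(x$provenance$status == "filtered_polar"),
    best_dock = if (nrow(x$models)) min(x$models$dock_score) else NA_real_,
    best_combined = if (nrow(x$models)) max(x$models$combined_score) else NA_real_)
}

#' Write LDM run outputs
#'
#' Emits the ranked model complexes as PDB files, the ranking CSV and a
#' JSON-lines provenance log into a directory.
#'
#' @param run An `ldm_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ldm_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$models, file.path(dir, "ranking.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "provenance.jsonl"), "w")
  for (i in seq_len(nrow(run$provenance))) {
    writeLines(jsonlite::toJSON(as.list(run$provenance[i, ]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  close(con)
  for (nm in names(run$complexes)) {
    write_complex(run$complexes[[nm]], file.path(dir, paste0(nm, ".pdb")))
  }
  invisible(dir)
}
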