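small_cfg <- function(...) {
  args <- list(n_replicas = 2, n_rounds = 3, n_directories = 3,
               master_seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(ldm_config, args)
}

test_that("combined ranking normalises each score and breaks ties deterministically", {
  m <- tibble::tibble(model = c("a", "b"), replica = 1:2, round = 1L,
                      dock_score = c(-40, -30), fold_score = c(80, 100))
  r <- combined_rank(m)
  expect_equal(r$combined_score, c(1, 0))
  expect_equal(r$model, c("a", "b"))
  # single model: both ranges zero -> 0.5
  r1 <- combined_rank(m[1, ])
  expect_equal(r1$combined_score, 0.5)
  # identical scores -> deterministic order by replica
  m2 <- tibble::tibble(model = c("x", "y"), replica = c(2L, 1L), round = 1L,
                       dock_score = -10, fold_score = 5)
  expect_equal(combined_rank(m2)$model, c("y", "x"))
  expect_error(combined_rank(dplyr::mutate(m, fold_score = NA_real_)),
               class = "ranking_error")
})

test_that("top_k renames models LDM 000.. and warns when short", {
  m <- combined_rank(tibble::tibble(
    model = paste0("m", 1:30), replica = 1L, round = 1:30,
    dock_score = -(1:30), fold_score = 1:30))
  t25 <- top_k(m, 25)
  expect_equal(t25$model_id[1], "LDM 000")
  expect_equal(t25$model_id[25], "LDM 024")
  expect_warning(t5 <- top_k(m[1:3, ], 25))
  expect_equal(nrow(t5), 3)
  expect_equal(top_k(m, 1)$model, m$model[1])
})

test_that("pocket distance filter keeps near pockets and drops far ones", {
  toy <- get_toy()
  pocket <- toy$planted_pocket
  same <- toy$complex
  near <- perturb_complex(toy$complex, pocket$residues$res_id, 0.5, seed = 3)
  far <- perturb_complex(toy$complex, pocket$residues$res_id, 6, seed = 4)
  rmsd_far <- superimpose_pockets(pocket, extract_pocket(far, pocket))$rmsd
  expect_gt(rmsd_far, 1)
  kept <- pocket_distance_filter(list(same, near, far), toy$complex,
                                 cutoff = 1.0, pocket = pocket)
  expect_length(kept, 2)
  # RMSD of a 0.5 A perturbation is bounded by the max displacement
  expect_lte(attr(kept, "rmsd")[2], 0.5)
  # identical candidate retained at any cutoff; everything kept at Inf
  expect_length(pocket_distance_filter(list(same), toy$complex, 1e-9, pocket), 1)
  expect_length(pocket_distance_filter(list(same, near, far), toy$complex,
                                       Inf, pocket), 3)
  expect_length(pocket_distance_filter(list(), toy$complex, 1, pocket), 0)
})

test_that("polar conservation filter counts conserved polar groups", {
  toy <- get_toy()
  pocket <- toy$planted_pocket
  n_polar <- sum(pocket$residues$polar)
  expect_gte(n_polar, 3)
  polar_ids <- pocket$residues$res_id[pocket$residues$polar]
  # identical candidate: conservation 1
  kept <- polar_conservation_filter(list(toy$complex), toy$complex, 1.0,
                                    pocket)
  expect_length(kept, 1)
  expect_equal(attr(kept, "conservation"), 1)
  # displace one polar side chain far: conservation (n-1)/n
  one <- polar_ids[1]
  moved <- toy$complex
  sel <- with(moved$receptor,
              paste0(chain, ":", res_num) == one & atom == "SC")
  moved$receptor$x[sel] <- moved$receptor$x[sel] + 8
  frac_keep <- (n_polar - 1) / n_polar
  kept2 <- polar_conservation_filter(list(moved), toy$complex,
                                     frac_keep - 1e-6, pocket)
  expect_length(kept2, 1)
  kept3 <- polar_conservation_filter(list(moved), toy$complex,
                                     frac_keep + 1e-6, pocket)
  expect_length(kept3, 0)
  # no polar residues in reference -> pass-through with warning
  apolar <- pocket
  apolar$residues$polar <- FALSE
  expect_warning(
    kept4 <- polar_conservation_filter(list(moved), toy$complex, 0.8, apolar),
    regexp = "no polar")
  expect_length(kept4, 1)
})

test_that("orchestrator yields exactly replicas x rounds models when nothing fails", {
  toy <- get_toy()
  run <- run_ldm(toy$complex, small_cfg(), toy_backends(reference = toy$complex),
                 topology = toy$topology, bw_map = toy$bw_map)
  expect_equal(nrow(run$models), 2 * 3)
  expect_lte(nrow(run$models), run$config$n_replicas * run$config$n_rounds)
  # each round's extracted model has the minimum dock score among the
  # round's docked survivors (read back from the provenance log)
  prov <- run$provenance
  for (key in unique(paste(prov$replica, prov$round))) {
    rows <- prov[paste(prov$replica, prov$round) == key, ]
    docked <- rows[rows$status == "docked", ]
    if (nrow(docked) == 0) next
    expect_equal(docked$dock_score[docked$extracted],
                 min(docked$dock_score))
  }
  # recorded model scores agree with provenance
  for (i in seq_len(nrow(run$models))) {
    m <- run$models[i, ]
    rows <- prov[prov$replica == m$replica & prov$round == m$round, ]
    expect_equal(m$dock_score, min(rows$dock_score[rows$status == "docked"]))
  }
})

test_that("orchestrator output is bit-identical for identical seeds", {
  toy <- get_toy()
  be <- toy_backends(reference = toy$complex)
  r1 <- run_ldm(toy$complex, small_cfg(), be, topology = toy$topology,
                bw_map = toy$bw_map)
  r2 <- run_ldm(toy$complex, small_cfg(), be, topology = toy$topology,
                bw_map = toy$bw_map)
  expect_identical(r1$models, r2$models)
  expect_identical(r1$complexes, r2$complexes)
  r3 <- run_ldm(toy$complex, small_cfg(master_seed = 12), be,
                topology = toy$topology, bw_map = toy$bw_map)
  expect_false(identical(r1$models$dock_score, r3$models$dock_score))
})

test_that("a fully filtered round yields no model and the replica continues", {
  toy <- get_toy()
  # a sampler that always moves every mobile residue, against an
  # unreachable RMSD cutoff, filters every directory of every round
  run <- suppressWarnings(run_ldm(
    toy$complex, small_cfg(pocket_rmsd_cutoff = 1e-9),
    toy_backends(reference = toy$complex, move_fraction = 1),
    topology = toy$topology, bw_map = toy$bw_map))
  expect_equal(nrow(run$models), 0)
  expect_true(all(run$provenance$status == "filtered_rmsd"))
  # a backend error aborts the replica but not the run
  bad <- toy_backends(reference = toy$complex)
  bad$fold_score <- function(complex) stop("boom")
  expect_message(
    run2 <- run_ldm(toy$complex, small_cfg(), bad, topology = toy$topology,
                    bw_map = toy$bw_map),
    regexp = "boom")
})

test_that("static cytoplasmic residues never move under toy backends", {
  toy <- get_toy()
  part <- partition_regions(trim_loops(toy$complex, toy$topology),
                            toy$topology, toy$bw_map)
  run <- run_ldm(toy$complex, small_cfg(), toy_backends(reference = toy$complex),
                 topology = toy$topology, bw_map = toy$bw_map)
  start <- trim_loops(toy$complex, toy$topology)$receptor
  ids0 <- with(start, paste0(chain, ":", res_num))
  static_sel <- ids0 %in% part$cytoplasmic
  for (cplx in run$complexes) {
    at <- cplx$receptor
    expect_identical(as.matrix(at[static_sel, c("x", "y", "z")]),
                     as.matrix(start[static_sel, c("x", "y", "z")]))
  }
})

test_that("toy LDM refinement recovers a planted pocket geometry", {
  toy <- get_toy()
  part <- partition_regions(toy$complex, toy$topology, toy$bw_map)
  planted <- toy$planted_pocket
  be <- toy_backends(reference = toy$complex)
  improved <- 0
  for (s in 1:3) {
    pert <- perturb_complex(toy$complex, part$extracellular, 1.0,
                            seed = 100 + s)
    init <- superimpose_pockets(planted, extract_pocket(pert, planted))$rmsd
    cfg <- ldm_config(n_replicas = 1, n_rounds = 8, n_directories = 8,
                      master_seed = s)
    run <- run_ldm(pert, cfg, be, topology = toy$topology,
                   bw_map = toy$bw_map)
    fin <- superimpose_pockets(
      planted, extract_pocket(run$complexes[[run$models$model[1]]],
                              planted))$rmsd
    improved <- improved + (fin < init)
  }
  expect_gte(improved, 2)
})
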