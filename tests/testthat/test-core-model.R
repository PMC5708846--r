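test_that("read_complex separates receptor and ligand and round-trips", {
  toy <- get_toy()
  path <- tempfile(fileext = ".pdb")
  write_complex(toy$complex, path)
  back <- read_complex(path, "LIG")
  expect_equal(length(receptor_residues(back)),
               length(receptor_residues(toy$complex)))
  expect_equal(nrow(back$ligand), nrow(toy$complex$ligand))
  expect_equal(as.matrix(back$ligand[, c("x", "y", "z")]),
               as.matrix(toy$complex$ligand[, c("x", "y", "z")]),
               tolerance = 1e-3)
  # second write is byte-identical (fixed 3-decimal formatting)
  path2 <- tempfile(fileext = ".pdb")
  write_complex(toy$complex, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "HETATM    4  O1  LIG L   9       0.000   3.000   0.000  1.00  0.00           O",
    "END")
  cplx <- read_complex(pdb, "LIG")
  cb <- cplx$receptor[cplx$receptor$atom == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 1.0)  # occupancy 0.6 conformer A wins
  # equal occupancy: alphabetical altloc wins
  pdb_tie <- sub("0.60", "0.40", pdb)
  cb_tie <- read_complex(pdb_tie, "LIG")$receptor
  expect_equal(cb_tie$x[cb_tie$atom == "CB"], 1.0)
  # higher-occupancy B conformer beats A
  pdb_b <- sub("0.60", "0.30", pdb)
  pdb_b <- sub("0.40", "0.70", pdb_b)
  cb_b <- read_complex(pdb_b, "LIG")$receptor
  expect_equal(cb_b$x[cb_b$atom == "CB"], 2.0)
})

test_that("ligand selector errors on zero and multiple matches", {
  toy <- get_toy()
  path <- tempfile(fileext = ".pdb")
  write_complex(toy$complex, path)
  expect_error(read_complex(path, "XYZ"), class = "selector_error")
  lines <- readLines(path)
  het <- grep("^HETATM", lines, value = TRUE)
  extra <- sub("LIG L   1", "LIG L   2", het[1])
  writeLines(append(lines, extra, after = length(lines) - 1), path)
  # the deliberately duplicated serial makes bio3d warn on read
  expect_error(suppressWarnings(read_complex(path, "LIG")),
               class = "selector_error")
})

test_that("pocket membership is inclusive at the boundary and monotone in cutoff", {
  # nearest side-chain atoms at exactly 1.0 / 1.4 / 1.6 A from the seed
  rec <- dplyr::bind_rows(
    atom_row("CA", "C", "ALA", 1, 0, 10, 0),
    atom_row("CB", "C", "ALA", 1, 0, 1.0, 0),
    atom_row("CA", "C", "SER", 2, 5, 10, 0),
    atom_row("OG", "O", "SER", 2, 0, -1.4, 0),
    atom_row("CA", "C", "LEU", 3, 10, 10, 0),
    atom_row("CD1", "C", "LEU", 3, 1.6, 0, 0))
  cplx <- pf_complex(rec, simple_ligand(0, 0, 0))
  p <- define_pocket(cplx, cutoff = 1.5)
  expect_setequal(p$residues$res_num, c(1, 2))
  # inclusive boundary: exactly at the cutoff is in
  p16 <- define_pocket(cplx, cutoff = 1.6)
  expect_setequal(p16$residues$res_num, c(1, 2, 3))
  # monotone: pocket(c1) subset of pocket(c2) for c1 <= c2
  cuts <- c(0.5, 1.0, 1.4, 1.45, 1.6, 2, 5, 12)
  prev <- character()
  for (ct in cuts) {
    ids <- tryCatch(define_pocket(cplx, cutoff = ct)$residues$res_id,
                    pocketforge_error = function(e) character())
    expect_true(all(prev %in% ids))
    prev <- ids
  }
  expect_error(define_pocket(cplx, cutoff = 0), class = "empty_pocket_error")
  expect_error(define_pocket(cplx, cutoff = 0.2), class = "empty_pocket_error")
})

test_that("polar mask follows the residue-type table", {
  toy <- get_toy()
  p <- toy$planted_pocket
  expect_equal(p$residues$polar,
               p$residues$res_name %in% c("SER", "THR", "TYR", "ASN", "GLN",
                                          "HIS", "LYS", "ARG", "ASP", "GLU",
                                          "TRP", "CYS"))
})

test_that("region partition follows the anchor and sequence-direction rule", {
  # TM2 runs residues 40-70 with its extracellular end at 70 (even helix,
  # intracellular->extracellular); anchor 2.51 = residue 52
  res <- 1:105
  rec <- dplyr::bind_rows(lapply(res, function(i) {
    atom_row("CA", "C", "ALA", i, i, 0, 0)
  }))
  cplx <- pf_complex(rec, simple_ligand())
  segs <- tibble::tibble(
    label = c("TM1", "ICL1", "TM2", "ECL1", "TM3", "ICL2", "TM4", "ECL2",
              "TM5", "ICL3", "TM6", "ECL3", "TM7"),
    start = c(1, 36, 40, 71, 73, 79, 81, 86, 92, 95, 97, 100, 102),
    end = c(35, 39, 70, 72, 78, 80, 85, 91, 94, 96, 99, 101, 105))
  topo <- pf_topology(segs, ecl2_cysteine = 88)
  bw <- c("1.48" = "A:20", "2.51" = "A:52", "3.38" = "A:75",
          "4.51" = "A:83", "5.50" = "A:93", "6.43" = "A:98",
          "7.45" = "A:103")
  part <- partition_regions(cplx, topo, bw)
  expect_true(all(paste0("A:", 53:70) %in% part$extracellular))
  expect_true(all(paste0("A:", 40:52) %in% part$cytoplasmic))
  # all of TM1 cytoplasmic regardless of its anchor
  expect_true(all(paste0("A:", 1:35) %in% part$cytoplasmic))
  # disjoint and jointly exhaustive
  expect_length(intersect(part$extracellular, part$cytoplasmic), 0)
  expect_setequal(c(part$extracellular, part$cytoplasmic),
                  receptor_residues(cplx))
  # odd helix TM3 (73-78, extracellular end at its start): above anchor 75
  expect_true(all(paste0("A:", 73:74) %in% part$extracellular))
  expect_true(all(paste0("A:", 75:78) %in% part$cytoplasmic))
  # loops: ECLs extracellular, ICLs cytoplasmic
  expect_true(all(paste0("A:", 71:72) %in% part$extracellular))
  expect_true(all(paste0("A:", 36:39) %in% part$cytoplasmic))
  expect_error(partition_regions(cplx, topo, bw[names(bw) != "5.50"]),
               regexp = "5.50", class = "mapping_error")
})

test_that("loop trimming keeps ECL2-distal including the conserved cysteine", {
  res <- 160:200
  rec <- dplyr::bind_rows(lapply(res, function(i) {
    atom_row("CA", "C", if (i == 176) "CYS" else "ALA", i, i, 0, 0)
  }))
  cplx <- pf_complex(rec, simple_ligand())
  segs <- tibble::tibble(label = c("TM4", "ECL2", "TM5"),
                         start = c(160, 170, 186), end = c(169, 185, 200))
  topo <- pf_topology(segs, ecl2_cysteine = 176)
  tr <- trim_loops(cplx, topo)
  kept <- unique(tr$receptor$res_num)
  expect_false(any(170:175 %in% kept))
  expect_true(all(176:185 %in% kept))
  expect_true(all(c(160:169, 186:200) %in% kept))
  # idempotent
  tr2 <- trim_loops(tr, topo)
  expect_identical(tr$receptor, tr2$receptor)
  # no loops annotated -> identity
  segs_tm <- tibble::tibble(label = c("TM4", "TM5"),
                            start = c(160, 186), end = c(185, 200))
  topo_tm <- pf_topology(segs_tm, ecl2_cysteine = 176)
  expect_identical(trim_loops(cplx, topo_tm)$receptor, cplx$receptor)
  # unlabeled residue -> annotation error
  segs_gap <- tibble::tibble(label = c("TM4", "ECL2", "TM5"),
                             start = c(160, 170, 186), end = c(169, 185, 190))
  expect_error(trim_loops(cplx, pf_topology(segs_gap, 176)),
               class = "annotation_error")
})

test_that("superposition removes rigid motion and matches the quaternion oracle", {
  set.seed(42)
  m <- matrix(rnorm(25 * 3, sd = 5), 25, 3)
  ref <- pocket_with_coords(m)
  # pure translation -> RMSD 0
  tr <- pocket_with_coords(sweep(m, 2, c(5, 0, 0), "+"))
  expect_equal(superimpose_pockets(ref, tr)$rmsd, 0, tolerance = 1e-10)
  # one CA displaced: RMSD equals the quaternion oracle exactly
  m2 <- m; m2[7, ] <- m2[7, ] + c(1, 0, 0)
  tg <- pocket_with_coords(m2)
  fit <- superimpose_pockets(ref, tg)
  expect_equal(fit$rmsd, quaternion_rmsd(m2, m), tolerance = 1e-9)
  # the re-fit correction keeps it at or below sqrt(1/25)
  expect_lte(fit$rmsd, sqrt(1 / 25) + 1e-12)
  # invariance under random rigid transforms of the target
  for (s in 1:5) {
    tg_r <- pocket_with_coords(random_rigid_transform(m2, seed = s))
    expect_equal(superimpose_pockets(ref, tg_r)$rmsd, fit$rmsd,
                 tolerance = 1e-8)
  }
  # mismatched residue lists -> correspondence error
  bad <- pocket_with_coords(m[1:24, , drop = FALSE])
  expect_error(superimpose_pockets(ref, bad), class = "correspondence_error")
})
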