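# pocketforge

Ligand-directed refinement of GPCR binding pockets, with the full
evaluation stack used to judge refined pockets.

## The problem

G protein-coupled receptors (GPCRs) are the largest family of drug
targets, but their experimentally determined structures are mostly
inactive, inhibitor-bound conformations. Because even small
conformational differences make an inhibitor-bound pocket preferentially
retrieve inhibitors in virtual screening (and vice versa for agonists),
structure-based discovery of agonists is starved of suitable templates.
Ligand-directed modeling (LDM) addresses this: starting from one
available structure and a *single* known ligand of the desired
pharmacology, it iteratively samples the receptor's extracellular region,
filters the sampled pockets for integrity, docks the ligand, and carries
the best-scoring complex forward — converging on a low-energy pocket
conformation shaped around that ligand.

`pocketforge` implements the complete workflow and its analytics as a
tested R package:

* **Structural substrate** — PDB I/O, binding-pocket definition (any
  residue heavy atom within a cutoff of a seed, default 1.5 Å), the
  extracellular/cytoplasmic partition of the helix bundle anchored at
  Ballesteros–Weinstein positions 1.48, 2.51, 3.38, 4.51, 5.50, 6.43,
  7.45, loop trimming that keeps only ECL2 distal of its conserved
  cysteine, and least-squares pocket superposition with Cα RMSD.
* **Interaction fingerprints (IFPs)** — per pocket residue, eight boolean
  contact types (hydrophobic, H-bond donor/acceptor, weak H-bond
  donor/acceptor, ionic ±, aromatic), compared with the Jaccard distance

  `d_J = (C_TF + C_FT) / (C_TT + C_TF + C_FT)`

  and clustered (average linkage, flat cut at 0.6 by default) with
  Newick dendrogram export and best-scoring cluster representatives.
* **Pocket PCA** — covariance PCA over superimposed pocket Cα
  coordinates, variance-explained axis labels ("PC1 (50%)"), optional
  colouring by Jaccard distance to a reference complex.
* **Virtual-screening metrics** — best-of-repeats score aggregation,
  recovery (actives vs decoys) and selectivity (agonists vs inhibitors)
  ROC curves, the normalised square-root AUC
  `NSQ_AUC = 100·(A_sq − 1/3)/(2/3)` with `A_sq = ∫ TPR d√FPR`
  (random = 0, perfect = 100, worst = −50), chemotype enrichment factors
  at 1/5/10% of the library, pharmacophore chemotype clustering
  (Tanimoto on 2D point-pair fingerprints, complete linkage, 0.5 cutoff),
  and racemic library preparation (duplicate removal + enumeration of
  unassigned stereocentres).
* **The LDM orchestrator** — replicas × rounds × directories, the
  pocket-RMSD and polar-conservation selection filters, per-round
  best-dock extraction, fold scoring, and the equal-weight min–max
  normalised dock+fold ranking, with every heavy stage behind a
  pluggable backend contract. Deterministic toy backends and synthetic
  7-TM fixtures are included, so the whole pipeline runs end-to-end with
  no external engine.

## Worked example

```r
library(pocketforge)

toy <- make_toy_complex()                      # 7-TM receptor + ligand
part <- partition_regions(toy$complex, toy$topology, toy$bw_map)
pocket <- define_pocket(toy$complex, cutoff = 1.5)

run <- run_ldm(
  perturb_complex(toy$complex, part$extracellular, 1.0, seed = 101),
  ldm_config(n_replicas = 2, n_rounds = 5, n_directories = 8,
             master_seed = 1),
  toy_backends(reference = toy$complex),
  topology = toy$topology, bw_map = toy$bw_map)
glance(run)
#> # A tibble: 1 × 6
#>   n_models capacity n_filtered_rmsd n_filtered_polar best_dock best_combined
#>      <int>    <int>           <int>            <int>     <dbl>         <dbl>
#> 1       10       10               0                0     -116.             1
```

Ten models from 2 replicas × 5 rounds (the maximum: no round failed its
filters), ranked by the combined normalised dock+fold score; `best_dock`
is the toy docking energy of the best complex (lower is better). Scoring
a screen:

```r
tab <- best_of_repeats(make_screen_table(screen_spec(seed = 1)))
nsq_auc(roc_recovery(tab))
#> [1] 68.46986
```

A positive NSQ_AUC (0 = random, 100 = perfect) reflecting the
synthetic actives' more favourable score distribution; `autoplot()` on
the ROC object draws the curve, and `enrichment_factors(tab)` reports
per-chemotype EF1/EF5/EF10.

## Command line

A thin wrapper in `inst/cli/pocketforge` exposes the same functions:

```sh
pocketforge fixtures --seed 1 --out fixtures/
pocketforge ldm-run --config run.json --complex fixtures/toy_complex.pdb \
    --ligand LIG --topology fixtures/topology.json \
    --bw fixtures/bw_map.json --out out/
pocketforge ifp --complex out/r01_round01.pdb --ligand LIG --out ifp.csv
pocketforge vs --scores fixtures/screen.csv --mode recovery --out vs.json
```

Every invocation writes a `manifest.json` with input/output hashes.

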