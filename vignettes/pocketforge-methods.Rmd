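---
title: "Ligand-directed pocket refinement: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-directed pocket refinement: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketforge)
```

`pocketforge` refines a GPCR orthosteric binding pocket around a single
known ligand and evaluates the result the way a virtual-screening
benchmark would: interaction fingerprints, pocket-conformation PCA, and
ROC-based screening metrics. This vignette is the package's account of
the underlying models, the parameters that matter, and the places where
the design was genuinely open.

## The refinement model

The receptor is split into two regions. Seven anchor residues at
Ballesteros–Weinstein positions 1.48, 2.51, 3.38, 4.51, 5.50, 6.43 and
7.45 sit roughly a third of the way down each helix, below the
orthosteric pocket. Everything extracellular of an anchor on TM2–TM7
(plus the extracellular loops) is mobile; the anchors themselves,
everything below them, and the whole of TM1 form the static cytoplasmic
region that preserves the seven-helix fold during sampling. The
direction "extracellular of" is resolved from canonical class-A membrane
topology: even-numbered helices run intracellular→extracellular in
sequence, odd-numbered ones the reverse. The annotation itself is
user-supplied (JSON segment table + BW map); the package never infers
helix boundaries from coordinates.

Flexible loops expand the conformational search space without improving
docking, and can occlude the pocket, so all loops and termini are
deleted before refinement — except the segment of ECL2 downstream of its
conserved cysteine (ECL2-distal), which lines the pocket in most class-A
structures. The cysteine itself is retained: it forms the disulfide to
TM3 and removing it would leave the retained segment unanchored. Whether
that residue survives trimming was an open point; retention is this
package's documented choice, and `trim_loops()` is idempotent either
way.

The iterative engine (`run_ldm()`) runs `n_replicas` independent
restarts; each replica is relaxed and minimally sampled into a distinct
starting point, then iterates `n_rounds` rounds. A round launches
`n_directories` independent chains of

1. backbone sampling of the mobile region,
2. a pocket-distance filter: pocket Cα RMSD to the round's starting
   system ≤ `pocket_rmsd_cutoff` (default 1.0 Å),
3. side-chain sampling of the pocket,
4. a polar-conservation filter: at least `polar_conservation_fraction`
   (default 0.8) of the reference's polar pocket residues keep their
   side-chain polar-group centroid within `polar_tolerance` (default
   1.5 Å) after pocket superposition,
5. static-region rebuild and minimisation,
6. docking of the single refinement ligand, refining only the 2 Å zone
   around it.

The best-docking survivor is extracted, fold-scored, recorded as the
round's model, and seeds the next round; everything else is discarded.
The first round samples the receptor alone, all later rounds the
complex. A fully filtered round yields no model and the replica carries
its previous complex forward; a backend error aborts that replica with a
diagnostic while the run continues. The two filters are what make the
search incremental: they bound how far any accepted conformation may
drift from the previous one.

Polar "conservation" has no standard operational definition; here a
polar residue counts as conserved when its side-chain polar-group
centroid stays within the tolerance of its reference position after
superposition on the pocket Cα atoms.

After all rounds, each model's dock and fold scores are min–max
normalised over the model set, oriented so 1 is most favourable, and
combined with equal weights; a zero-range score contributes 0.5
everywhere, and ties break deterministically by (dock score, replica,
round). `top_k()` names the leading models `LDM 000 …`. Replica, round
and directory seeds all derive arithmetically from `(master_seed,
replica, round, directory)`, so results are independent of execution
order and bit-reproducible.

The default configuration (16 replicas × 20 rounds × 8 directories,
capacity 320 models) reflects the scale such refinements are run at;
the test suites use 1–2 replicas, 2–15 rounds and 3–12 directories so
the whole suite completes in minutes on one CPU.

## Backends and the toy implementations

Production deployments of this workflow delegate sampling, rebuilding,
docking and fold scoring to heavyweight external engines. Those stages
are behind a six-function contract (`init_relax`, `backbone_sample`,
`sidechain_sample`, `rebuild_and_minimize`, `dock`, `fold_score`), each
a pure function of its inputs and seed. The package ships deterministic
toy implementations (`toy_backends()`) that are simple geometric models
in their own right:

* Sampling moves are *per-residue collective*: a randomly chosen subset
  (`move_fraction`, default 0.15) of mobile residues each receives one
  rigid displacement of at most `mobile_amplitude` (default 0.15 Å)
  applied to all its atoms. Collectivity matters: if Cα and side-chain
  pseudo-atoms moved independently, no contact-based score could ever
  constrain the backbone. Low-dimensional moves keep the per-round
  best-of-directories selection informative — a move touching every
  residue at once averages away its own signal.
* The toy dock is a rigid-ligand search over a small translation grid.
  Its score is a clash penalty minus a contact reward. With a
  `reference` complex supplied, every residue whose side chain lies
  within `contact_range` (default 4 Å) of the ligand is restrained
  against its full reference ligand-distance profile by Gaussian wells
  (σ = 0.6 Å); distances to several non-collinear ligand atoms pin each
  side chain's position (multilateration), so the score's optimum *is*
  the reference pocket geometry. A single nearest-contact reward was
  tried first and leaves the pocket shape degenerate — any arrangement
  preserving pairwise contact distances scores equally — which defeats
  planted-optimum experiments. Without a reference the reward falls back
  to generic chemistry (polar–polar and apolar–apolar contacts at the
  fixture's planted 1.3 Å contact distance).
* The toy fold score penalises deviations of consecutive Cα distances
  from the ideal 3.8 Å plus soft-sphere clashes.

These are explicitly not re-implementations of any production engine;
they exist so that orchestration, filtering, scoring and ranking are
testable end-to-end.

## Synthetic fixtures and what they do (not) show

`make_toy_complex()` builds an idealised seven-helix bundle (2.3 Å helix
radius, 1.5 Å rise, 100°/residue, helices on a 9.5 Å ring) with one Cα
and one side-chain pseudo-atom per residue, short connecting loops, an
ECL2 with its conserved cysteine, a consistent topology annotation and
BW anchor map, and a 12-atom pseudo-ligand posed in the pocket. The
inward-facing top residue of each of TM2–TM7 is assigned a fixed
chemistry (ASP, SER, LEU, ARG, ASN, PHE) and receives a matched ligand
atom 1.3 Å from its side-chain pseudo-atom, so the default 1.5 Å pocket
cutoff captures the lining residues and every fingerprint chemistry
(ionic both ways, H-bonds, hydrophobic) is exercised; an aromatic
six-carbon ring sits at the pocket centre. Coordinates are emitted at
PDB's three decimals, so regeneration is hash-stable.

`perturb_complex()` displaces named residues rigidly (direction and
magnitude seeded, bounded by `magnitude`), which keeps the Cα–side-chain
geometry intact — the property that makes recovery experiments
meaningful, see above. `make_screen_table()` draws class-conditional
Gaussian docking scores (three repeats) for 50 agonists, 50 inhibitors
and 3,900 matched decoys by default — the ~39:1 decoy ratio of public
GPCR ligand/decoy collections — with actives centred 4 score units below
(more favourable than) decoys at σ = 2.5, giving screens in the
NSQ_AUC ≈ 60–70 range typical of well-performing pockets; chemotype
labels follow a geometric size distribution (few large, many small
clusters).

Passing tests on these fixtures demonstrate the machinery — geometry,
filters, ranking, metrics — not biology: coarse pseudo-atoms cannot
validate all-atom interaction geometry, the toy dock cannot validate a
docking force field, and synthetic score tables cannot validate a real
screen's enrichment.

## Interaction fingerprints

Eight boolean types per pocket residue, heavy-atom geometry only, all
thresholds configurable via `ifp_criteria()`: hydrophobic (apolar C/S
pair ≤ 4.5 Å), H-bond donor/acceptor (donor heavy atom to acceptor
≤ 3.5 Å, with a donor-antecedent angle ≥ 120° when a covalently bonded
antecedent is identifiable, distance-only otherwise), weak H-bond
(Cα/aromatic-C donor ≤ 3.8 Å), ionic (opposite formal charges ≤ 4.0 Å),
aromatic (ring-centroid distance ≤ 4.5 Å with interplanar angle ≤ 30° or
≥ 60°; face and edge geometries pool into one bit). Donor/acceptor bits
name the residue's role; ionic bits name the *ligand's* charge sign
(`ionic_negative` = anionic ligand group at a cationic residue) — the
convention is documented because fingerprint diagrams in the literature
often leave it implicit. Receptor charges come from a fixed residue
table (Asp/Glu −, Lys/Arg +), ligand charges from the input record; no
pKa model is applied.

Fingerprints over the same residue list are compared with the Jaccard
distance; both-empty vectors are defined to be at distance 0 (identical
absence of contacts — the 0/0 case resolved by identity semantics).
Clustering is agglomerative with average linkage (the common choice for
fingerprint dendrograms; configurable) on the pairwise Jaccard matrix,
cut flat at 0.6: merges strictly below the cutoff stay together, so two
fingerprints at exactly the cutoff distance land in different clusters.
When the cluster count at 0.6 is impractically large, passing a smaller
cutoff is the intended remedy. Representatives are each cluster's
highest combined-score member, ties broken by ascending model id.

## Pocket PCA

Covariance PCA (no per-feature scaling — the features are like-for-like
Cα coordinates in Å) on the flattened, superimposed pockets. Explained
fractions annotate the axis labels ("PC1 (50%)"). PCA signs are
arbitrary, so each loading vector is sign-fixed to make its
largest-magnitude element positive, which keeps regression tests and
plots stable. An all-identical input set has zero total variance; scores
and explained fractions are then reported as 0 with a `zero_variance`
flag rather than NaN. All structures passed by the caller are pooled
into one decomposition (models and any reference structures alike);
projecting references onto model-only axes would be a different, equally
defensible choice, and pooling was chosen for symmetry and simplicity.

## Virtual-screening metrics

Docking scores follow the energy convention (lower = better; a flag
flips it). Each compound keeps the best of its repeats; ranking ties
break by compound id so ROC curves and enrichment factors are
deterministic. Recovery ROC ranks actives against decoys; selectivity
ROC drops decoys and ranks one pharmacology against the other, raising a
class error when a class is absent (a screen with no agonists has no
selectivity). The NSQ_AUC integrates TPR against √FPR (trapezoid rule)
and normalises so random = 0 and perfect = 100:

\[ \mathrm{NSQ\_AUC} = 100 \cdot \frac{A_{sq} - 1/3}{1 - 1/3}, \qquad
   A_{sq} = \int_0^1 \mathrm{TPR}\, d\sqrt{\mathrm{FPR}} \]

since the diagonal has \(\int_0^1 x\, d\sqrt{x} = 1/3\) and the worst
ranking (all actives last) scores −50. The √FPR weighting is the point:
it amplifies early recovery, where a prospective screen actually picks
compounds. The same property makes the metric sensitive to systematic
early/late placement: an "evenly interleaved" null must place its
actives at the centre of each block (their random-expectation
positions); putting them at block starts biases NSQ_AUC to +0.8 even
though the plain AUC barely moves.

Enrichment factors use `n_top = ceiling(f·N)` (so even tiny libraries
get a non-empty top fraction) and `EF = (recovered/n_top)/(n_cluster/N)`,
bounded by 1/f; the union of all compounds always has EF = 1 exactly,
which the tests assert as a calibration identity. Empty clusters report
`EF = NA` with a flag instead of erroring.

Chemotypes are complete-linkage clusters (tight clusters match the
intuitive meaning of a chemotype; configurable) at a 0.5 cutoff on
1 − Tanimoto over 2D pharmacophore point-pair fingerprints: feature
pairs (donor, acceptor, aromatic, hydrophobe, cation, anion) × the
topological bond-count distance, capped at 10. Labels are assigned in
canonical id order, so they are stable under input permutation.

Racemic preparation removes exact duplicates (atom-pair descriptor
identity), then enumerates unassigned stereocentres — tetrahedral
carbons with four topologically distinct branches and neither a parity
code nor a wedge bond — into explicit stereoisomers, capped at 2⁵ = 32
per molecule (beyond the cap the molecule passes through unexpanded,
flagged, with a warning). Assigned centres are untouched and no
tautomers are generated. Ionisation states are taken from the input as
written. Stereocentre perception here is deliberately topological and
conservative; ring stereochemistry and stereogenic double bonds are out
of scope.

## Numerical choices and degenerate inputs

* Pocket membership is boundary-inclusive (d ≤ cutoff) for reproducible
  ties; `define_pocket` is monotone in the cutoff.
* The pocket seed is the bound ligand's heavy atoms (or a user-supplied
  coordinate box); the grid-based pocket-envelope construction of
  commercial pocket finders has no published geometry to reproduce.
* Alternate locations: highest occupancy wins, ties alphabetically by
  altloc id. Residue numbering follows the input file verbatim.
* Superposition is SVD-based least squares with a determinant guard
  against reflections; RMSD is computed post-fit.
* Zero-range scores normalise to 0.5; single models rank at 0.5.
* Dendrogram flat cuts group merges strictly below the cutoff.

## Known limitations

Water-mediated contacts are not modelled in the fingerprints. The
H-bond angle term degrades to distance-only on coarse fixtures (no
antecedent). Real-engine backends (molecular-dynamics relaxation,
production docking) are out of scope by design; the backend contract is
the extension point. Benchmarks against deposited X-ray structures and
public ligand/decoy libraries are supported through the same readers but
are not part of the test suite, which is fully synthetic.
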