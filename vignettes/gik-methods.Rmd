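---
title: "Methods: receptor-G protein interface analysis with gik"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor-G protein interface analysis with gik}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gik)
```

## What the package models

Class A G protein-coupled receptors (GPCRs) signal by recruiting a
heterotrimeric G protein; the C-terminal α5 helix of the Gα subunit inserts
into the intracellular cavity of the receptor, and the identity and
orientation of that helix largely decide whether a receptor couples Gs, Gi
or Gq. `gik` implements the structural-analysis pipeline used to build and
validate a docking model of a promiscuously coupling receptor (the
cannabinoid CB1 receptor engaging Gs, whose native partner is Gi):

1. **Restraint selection** — derive a minimal set of residue-pair docking
   restraints from conservation arguments rather than from any single
   template structure.
2. **Ensemble validation** — given multi-replicate molecular-dynamics
   trajectories of the docked complex, quantify the stability and geometry
   of the interface: conformational clustering of the α5-helix position,
   contact and hydrogen-bond occupancies, per-residue contact counts,
   TM2–TM6 opening, and block-averaged RMSD statistics.

Everything operates on generic residue numbering so analyses transfer
across receptors and Gα subfamilies: Ballesteros–Weinstein (BW) labels for
the receptor (`3.54`, `34.51` for the second intracellular loop, `8.51` for
helix 8) and common Gα numbering (CGN) for the G protein (`H5.20` is
position 20 of the α5 helix; the long form `G.H5.20` is accepted on input
and emitted short).

## The restraint-selection funnel

`select_restraints()` composes three stages, each of which only narrows the
previous survivor set (a monotone funnel):

1. `h5_conserved_positions()` — α5 (H5) positions whose alignment column is
   a single amino-acid type across all Gα subfamily sequences. On the
   packaged alignment this yields seven positions (H5.01, H5.03, H5.07,
   H5.08, H5.13, H5.20, H5.25).
2. `shared_interface_positions()` — of those, positions that touch the
   receptor (heavy-atom contact at the cutoff) in at least one member of
   **both** a Gi-bound and a Gs-bound complex set; a stricter
   "majority-of-set" membership criterion is available. Four positions
   survive on the demo sets.
3. A per-position consistency filter — the position must contact *some*
   receptor position in at least `conservation_min` (default 0.77) of the
   complexes of each family set. The default threshold reuses the value at
   which the class A receptor–Gs contact-pair matrix is considered
   conserved. Positions with only sporadic structural involvement (H5.08,
   H5.13 in the demo sets) fall out of this same filter; no special-case
   exclusion list exists. Two positions survive.

Survivors are paired with their *modal* receptor partner — the most
frequent partner label pooled over both sets, ties resolved by label order
— and mapped through the numbering maps of the docking target onto author
residue numbers, emitted with a restraint radius (`max_distance`, default
5.0 Å, a typical attraction-restraint radius). An empty survivor set is a
first-class outcome (`status = "no restraints derivable"`) that still
reports per-stage counts.

The docking engine itself is out of scope. The published weighted-score
convention under which the docked model pool was ranked
(E = 0.40 E_rep − 0.40 E_att + 600 E_elect + 1.00 E_dars) is recorded as
metadata in `cluspro_weighted_score()`, which applies those weights to
user-supplied component energies.

## Contacts, hydrogen bonds and occupancies

Three contact criteria, with defaults chosen from common practice because
analysis cutoffs of this kind are rarely printed in papers; every report
echoes the cutoff used:

* **heavy_atom** — two residues are in contact when their closest
  non-hydrogen atom pair is within 4.5 Å.
* **polar** — side-chain N/O/S pair within 4.0 Å, no angle term. This is a
  salt-bridge-like "engagement" criterion, intended for charge-pair
  stability percentages, not strict hydrogen bonding.
* **hbond** — donor–acceptor distance ≤ 3.0 Å *and* the D–H···A angle
  within 20° of linear (the defaults of the trajectory-analysis tool
  conventionally used for hydrogen-bond occupancy). Structures without
  explicit hydrogens get an explicit error directing them to the
  heavy-atom-only `polar` fallback.

The contact search is vectorized with a conservative bounding-box
prefilter; a brute-force double loop over atoms is kept in the test suite
as an oracle, and the two must agree exactly on every instance up to 100
residues.

`occupancy_map()` applies the ensemble's equilibration discard first
(fraction of leading frames per replicate; 0.5 for trajectories read from
files, matching the exclusion of the first half of each production run),
counts per-frame presence of each residue pair, and reports
`occupancy = frames_present / frames_total` exactly. Only pairs at or above
`min_occupancy` (default 0.05, the display threshold used for interface
hydrogen-bond maps) are returned, sorted by descending occupancy with
deterministic tie-breaks.

## Helix geometry and the TM2–TM6 opening

`helix_axis()` takes ordered Cα coordinates, returns the principal
component of the centered coordinates as a unit axis sign-fixed from the
N- to the C-terminal half, the centroid origin, the extent along the axis,
and the XZ/XY plane projections. The membrane frame is assumed to be the
input frame with +z the membrane normal (OPM convention); projections
follow the input axes and are documented as such rather than re-derived.
`orientation_compare()` reduces a target-vs-reference comparison to an
(angle, origin-offset) pair; descriptors must first be computed in a common
receptor-aligned frame. The published comparison of helix orientations is
visual; the angle/offset pair is this package's quantitative
operationalization of it.

`tm_distance()` is the Cα–Cα distance between two generic labels; the
TM2–TM6 opening uses positions 6.33 and 2.39 and scales with the outward
TM6 movement that distinguishes Gs- from Gi-coupled receptor
conformations.

## Clustering and block statistics

`cluster_frames()` implements GROMOS neighbor-count clustering: on the
pairwise frame-RMSD graph at `rmsd_cutoff` (default 1.5 Å), repeatedly take
the frame with the most neighbors as a cluster center (medoid), assign and
remove its neighborhood, and continue until all frames are assigned. Ties
always resolve to the lowest frame index, so results are deterministic.
Because the pipeline clusters the *position* of the α5 helix after the
receptors are already in a common frame, the default metric is positional
RMSD without superposition — fitting the helix selection onto itself would
erase exactly the signal being clustered. `superpose = TRUE` switches to
pairwise Kabsch-fitted RMSD for shape clustering. Populations are reported
over all clusters (fractions sum to 1) and `representative()` returns the
medoid frame.

`block_stats()` estimates the uncertainty of correlated RMSD series by
block averaging: non-overlapping blocks of `block_size` frames (50 frames =
50 ns at the default 1 ns sampling; trailing partial blocks are dropped and
reported), block means per replicate give the replicate mean and SEM, and
across replicates each replicate mean is one independent observation, so
the ensemble SEM is the sample (n−1) standard deviation of replicate means
divided by √R. With the published twelve replicate means both the n and
n−1 conventions round to the same printed SEM; the n−1 choice follows from
treating replicates as independent observations.

## The synthetic-data generator

Real cryo-EM structures and microsecond trajectory ensembles are neither
redistributable nor recomputable at desk scale, so every input is emulated
by generators with planted ground truth; the analysis operations are then
validated by recovering what was planted.

* `make_helix()` — ideal α-helix (rise 1.5 Å, twist 100°/residue, Cα radius
  2.3 Å) with a minimal N/CA/C backbone and one CB side-chain pseudo-atom.
* `make_complex()` — a 7-helix receptor bundle on a 16 Å circle (TM
  segments with author numbering that follows the CB1 convention, e.g.
  3.54 → 218, 6.33 → 341, 34.51 → 222), an ICL2 and an H8 segment, and a
  docked Gα α5-like helix (H5.01–H5.26 → 369–394) with a small Ras-domain
  stub (S1/S3 positions → 41/217) underneath. Planted contacts are realized
  geometrically: a pseudo side-chain atom of the Gα residue is placed at
  the exact criterion distance (3.0 Å heavy-atom, 2.8 Å polar/hydrogen
  bond) from the receptor residue, in the direction that maximizes
  clearance from all other receptor atoms; if no direction clears 4.8 Å, or
  a residue would need more than six planted partners, generation fails
  with an explicit infeasible-geometry error naming the pair. The realized
  contact set is verified to equal the planted set before the complex is
  returned.
* `make_ensemble()` — frames drawn i.i.d. from a basin mixture. Defaults
  are the study conditions: 12 replicates × 625 frames at 1 ns, three
  basins holding 47% / 15.5% / 14.9% of frames (the published cluster
  populations used as planted truth), the remainder diffuse (per-frame
  uniform displacement and rotation so it cannot form a coherent cluster),
  and isotropic Gaussian coordinate noise of 0.5 Å — the simplest model
  consistent with RMSD fluctuations that are thermal rather than
  rearrangements. Basin transforms are rigid (rotation about the mobile
  group's own axis plus displacement) applied to the Gα subunit by default,
  or to a named receptor segment (e.g. TM6 for opening scenarios). Planted
  contacts are re-realized per frame from independent Bernoulli draws of
  their presence probability; realization atoms (and the synthetic
  polar/hydrogen-bond acceptor atoms) are placed exactly, so the planted
  occupancy equals the Bernoulli fraction and is not eroded by noise at a
  strict criterion. Generated ensembles carry `discard_fraction = 0`
  because frames are stationary by construction; file-read ensembles
  default to 0.5. One RNG stream per scenario, seeded explicitly, saved and
  restored so generators never perturb the session RNG.
* `make_alignment()` — Gα subfamily alignments over the 26 H5 columns with
  exactly the requested invariant columns.
* `demo_complex_sets()` — six Gs-bound and six Gi-bound toy complexes whose
  planted interface statistics emulate the structural record: H5.20/H5.25
  in consistent contact in both families (modal partners 3.54/6.33),
  H5.08/H5.13 sporadic, and six pairs conserved in ≥ 77% of the Gs set, of
  which the demo model complex preserves five. The sixth conserved pair
  (5.68–H5.24) is a package choice: the published analysis names the five
  preserved pairs but not the missing sixth.

What the generator does **not** emulate: real side-chain packing and
rotamer exchange, correlated (non-isotropic) fluctuations, slow
equilibration (frames are stationary), water-mediated and aromatic
interactions, and sequence-structure coupling. Passing the planted-truth
tests therefore demonstrates that the estimators are correct and unbiased
under the stated noise model, not that any particular biological complex
is stable.

## Numbering annotation

`annotate()` transfers generic labels to a chain by global affine-gap
alignment (BLOSUM62, gap open/extend 10/0.5 — conventional defaults) of the
chain sequence against a reference sequence whose positions carry label
anchors. Labels transfer only across aligned (non-gap) columns, the result
must be a bijection, and alignment identity below 0.9 raises a
wrong-protein error. Annotation is invariant to author renumbering since
only the sequence enters the alignment. The packaged reference tables are
**synthetic stand-ins** (their filenames say so): offline snapshots of the
real numbering databases are not redistributable here, so the tables are
generated sequences whose anchors honour the published conventions
(e.g. a Gαs-like chain numbered so H5.20 falls on residue 388 and H5.25 on
393; a CB1-like receptor with 3.54 on 218 and 6.33 on 341). Supplying a
real GPCRdb/CGN table in the same four-column TSV format swaps in real
annotations without code changes.

## Numerical choices and problem sizes

* Contact decisions compare squared distances to a squared cutoff;
  equality at the boundary counts as contact. Planted geometries avoid
  measure-zero knife edges except where a test exercises them on purpose.
* Clustering at full study scale (7,500 frames) builds the 7,500² neighbor
  matrix in row blocks (~2×10⁷ doubles at a time) to bound memory near
  250 MB.
* The validation loops use 20 seeded ensembles at the full 12 × 625 study
  geometry (the package's chosen problem size for stochastic recovery:
  three-basin population recovery to a mean absolute error below 0.02, and
  Bernoulli contact occupancy within three binomial standard deviations).
* Degenerate inputs are contracts, not crashes: single-frame clustering is
  one cluster of one, an empty selection is an empty result, an
  all-different alignment yields zero conserved columns, and a threshold
  outside (0, 1] is a precondition error.

## Known limitations

* The hydrogen-bond detector requires explicit hydrogens; there is no
  donor-inference for heavy-atom-only structures beyond the `polar`
  fallback (by design — silent donor guessing is a common source of
  irreproducible occupancy tables).
* `orientation_compare()` presumes its inputs share a receptor-aligned
  frame; it does not superpose for you.
* Binary trajectory formats are supported only through the in-memory
  adapter contract (arrays or lists of frames); the native text carrier is
  multi-model PDB.
* The alt-loc policy (keep highest occupancy) and water stripping are
  fixed at read time; occupancy-weighted ensembles are out of scope.
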