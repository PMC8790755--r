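---
title: "Attributing voxel-based protein-ligand scorers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing voxel-based protein-ligand scorers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

3D convolutional networks that score protein-ligand complexes -- affinity
regressors, docking-pose classifiers, clash detectors -- consume a voxelized
image of the binding site and emit one number. They perform well, but a
single scalar gives no hint of *why*: whether the network noticed the
hydrogen bond that a chemist would point to, or merely a shortcut feature of
the training set. `voxattrib` answers this with Integrated Gradients (IG)
attributions over the input voxels, plus a set of quantitative reciprocity
analyses that test whether both partners of an interaction are credited in
their complementary channels.

## Input representation

A complex is voxelized into a cubic grid of 24 voxels per side at 1.0 Å
spacing, centered on the ligand's heavy-atom geometric center, with 16
channels: 8 pharmacophore properties (hydrophobic, aromatic, hydrogen-bond
donor, hydrogen-bond acceptor, positive ionizable, negative ionizable,
metal, occupancy/excluded volume) for the protein block and the same 8 for
the ligand. Every atom carrying a property paints the kernel

\[ n(r) = 1 - \exp\bigl(-(r_{vdw}/r)^{12}\bigr) \]

into the corresponding channels, evaluated at each voxel center within a
5 Å cutoff and aggregated per voxel by **maximum**, so values stay in
[0, 1] (at the atom center \(n = 1\); at \(r = r_{vdw}\),
\(n = 1 - e^{-1} \approx 0.632\)). Max aggregation rather than summation
keeps the [0, 1] invariant testable and makes channel values interpretable
as "how occupied is this voxel by the property". The box follows the
ligand, so the featurization is translation-equivariant by construction.

Pharmacophore typing is deterministic and rule-based: connectivity rules
for ligands read from SDF records (aromatic = order-4 bonds; donors from
explicit or implied polar hydrogens; carboxylate/phosphate/sulfonate
oxygens negative-ionizable; amine/guanidinium nitrogens positive-ionizable),
residue/atom-name rules for proteins (Phe/Tyr/Trp/His side-chain rings
aromatic, backbone N/O polar, Asp/Glu carboxylates negative, Lys/Arg
positive, aliphatic C/S hydrophobic). Only heavy atoms reach the occupancy
channels; polar hydrogens are kept as records solely to confirm donor flags
on their parent. Waters and organic HETATM groups are dropped on reading;
single-atom metal ions are kept so the metal channel stays meaningful.

## Scorers

The package trains three compact 3D CNNs on synthetic data (below): a
**clash detector** (clashed vs. regular pose), a **pose classifier** (good
vs. bad rigid decoys by RMSD) and an optional **affinity regressor** on a
pKd-like 2-12 scale derived from engineered contact counts. The shared
architecture is three 3x3x3 convolutions with stride 2 and 16 -> 32 -> 64
-> 64 feature maps (stride-2 convolution plays the role of pooling at an
eighth of the cost of conv-then-pool), ReLU activations, then a dense head
on the *flattened* conv features: one 32-unit ReLU layer and a linear
scalar output. Classifiers are trained on the logistic loss of the logit;
attribution always targets the pre-sigmoid logit, since sigmoid extremes
are exactly where plain gradients saturate.

The dense head is deliberately fully connected rather than a global
average pool. We evaluated a GAP head first: it classifies equally well,
but because every spatial position shares one output path, its gradients
-- and therefore IG attributions -- smear across the whole box.
Per-position dense weights keep attributions spatially resolved. We also
prototyped detection-style heads (a shared per-position detector with
hard or soft max pooling over positions, alone and in a staged hybrid
with a dense branch): on the synthetic task none matched the dense head's
accuracy while improving attribution localization, so the package ships
the single dense-head architecture for all three tasks; see the
limitations section for what this implies for the reciprocity analysis.

Training: Adam (lr 1e-3), batch 16, at most 30 epochs, a fixed
seed-determined 80/20 train/validation split, early stopping when
validation loss stops improving by at least 5% relative (patience 3), and
the best-validation parameters are kept. Everything is seeded: two runs
with the same data, config and seed give identical parameters and metrics
in single-threaded execution. Checkpoints are single-file JSON embedding a
channel-scheme + geometry fingerprint; scoring or attributing a grid whose
fingerprint mismatches is refused rather than silently misinterpreted.

## Integrated Gradients

For input \(x\), baseline \(x'\) and scorer \(F\),

\[ \mathrm{IG}_i = (x_i - x'_i) \int_0^1
   \frac{\partial F\bigl(x' + \alpha (x - x')\bigr)}{\partial x_i}
   \, d\alpha , \]

approximated with a **midpoint Riemann sum** over 100 steps by default. The
baseline is the all-zero grid (an empty box); alternative baselines are
accepted but flagged as non-default. The completeness identity
\(\sum_i \mathrm{IG}_i = F(x) - F(x')\) is the built-in quadrature
diagnostic: every attribution records its completeness gap, computed from
two extra forward passes, and the test suite requires the gap at 100 steps
to stay within 1% of \(|F(x) - F(x')|\) and to be non-increasing as steps
double. For a linear scorer the midpoint rule is exact for any number of
steps (the integrand is linear in \(\alpha\)), which gives an
analytically-checkable base case: \(\mathrm{IG}_i = w_i x_i\) with gap 0.
Attribution signs are preserved end to end (positive pushes the prediction
up); thresholds for display are the consumer's concern.

Summaries follow the voxel-to-region and voxel-to-atom conventions: per
channel, the top voxel is the argmax of |attribution| (ties broken by
lowest linear index, channel-major then x, y, z -- determinism beats
arbitrariness), with its in-bounds Chebyshev-radius-1 neighborhood (26
neighbors in the interior, 7 at a corner); the channels owning the 5
globally largest |attributions| form the display selection. For atom
mapping, each nonzero voxel of a channel is assigned to the nearest atom
among that channel's entity+property carriers, atoms accumulate absolute
attributions, and the per-entity top atom is the score argmax. A channel
top voxel with no property-matched atom within 3 Å is reported unassigned
rather than force-mapped. The neighborhood radius and the nearest-atom
rule are this package's choices; the source analyses they emulate do not
pin them down.

## Synthetic complexes

All training and analysis can run with no external data. A synthetic
complex is a spherical-shell pocket of pseudo-residue atoms (default 160
atoms at radius 8-11 Å) around a connected random-walk heavy-atom ligand
(default 12 atoms, 1.5 Å steps, 1.4 Å minimum separation), with a stated
fraction (default 0.6) of flagged ligand atoms given a complementary
protein partner at 2.6-3.4 Å (donor-acceptor, aromatic-aromatic,
hydrophobic-hydrophobic) -- hydrogen-bond-like geometry without hydrogens.
Crystal-like poses keep every protein-ligand heavy-atom distance at or
above 2.4 Å.

Pose manipulations are rigid-body only: **clashed poses** translate the
ligand along a random direction into the pocket wall until the minimum
contact falls below the 1.5 Å clash threshold (the achieved contact is
sampled in 0.6-1.45 Å for variety); **perturbed poses** apply a random
rotation+translation whose magnitude is bisected until the achieved RMSD
is within 5% of target (0.05 Å absolute for small targets); **rotations**
are uniform (quaternion-sampled) about the ligand center, applied jointly
to protein and ligand. RMSD is computed over heavy atoms without
re-superposition, matching docking practice. Pose classes use the
community docking-success convention: good ≤ 2 Å, bad ≥ 4 Å, the (2, 4)
band excluded as ambiguous; the 1.5 Å clash threshold is well below any
physical contact distance. Because clashed poses (contact < 1.5 Å) and
crystal-like poses (≥ 2.4 Å) are disjoint by construction, the clash task
is learnable at desk scale, as the source task was at corpus scale.

What the generator does **not** emulate: real pockets are not spherical
shells, ligands have torsional flexibility and realistic valence
chemistry, decoys come from docking rather than rigid jitter, and label
noise is absent. Passing tests therefore demonstrate that the attribution
machinery and analyses behave correctly on structured, learnable inputs --
not that any particular real model has learned real chemistry.

## Reciprocity analyses

For a set of complexes, the distance study voxelizes, attributes, and for
each of the five complementary channel pairs (protein/ligand hydrophobic,
aromatic, protein acceptor/ligand donor, protein donor/ligand acceptor,
occupancy/occupancy) records the Euclidean distance between the two
per-channel top voxels and the summed |attribution| in them. The random
baseline draws, per complex and pair, one voxel per channel uniformly
among voxels whose **feature** value exceeds 0.75 (evaluated on the
voxelized input, not the attribution -- the gate guarantees an atom is
nearby) and records their distance. Per pair we report the two-sided
Mann-Whitney U test of distances against baseline and the Pearson
correlation between magnitude and distance. The Mann-Whitney p-value uses
exhaustive enumeration of group assignments over midranks when
min(n, m) ≤ 8 (exact even under ties) and the normal approximation with
tie and continuity corrections otherwise. Pairs are reported without
multiplicity correction, matching per-combination reporting conventions.
On the desk-scale clash detector the occupancy-pair distances are strongly
stochastically smaller than the random baseline (the Mann-Whitney test is
the headline assertion); full sub-3 Å co-localization of both channels is
a corpus-scale phenomenon this analog only partially reproduces -- see
the limitations section.

The consistency study generates variants of one complex (rotations, or
0.5 Å-RMSD pose perturbations -- "slight" is not quantified by the source
analyses, so 0.5 Å is this package's choice), attributes each, takes the
top atom per entity, and compares the modal atom count to the expectation
under uniform random atom choice (estimated by seeded simulation). Top
atoms are taken per entity, not per channel.

## Numerical and degenerate-input choices

* Argmax ties anywhere resolve to the lowest linear index.
* An identically-zero channel makes a pair distance undefined: the complex
  is excluded from that pair's distribution with a warning, never coerced
  to 0.
* A classifier that predicts no positives reports precision as NA
  (undefined), never 0.
* Training on single-class labels or mismatched lengths errors early;
  divergence (non-finite loss) errors with the config echoed.
* Degenerate generator parameters (a ligand that cannot fit the cavity)
  raise generation errors rather than looping forever.
* Cube files store lengths in Bohr (1 Å = 1.8897259886 Bohr) with values
  written z-fastest at 7 significant digits, so write-then-read
  round-trips to at least 6 significant figures.
* PDB reading takes the first model and first alternate location;
  multi-model semantics are out of scope.

## Problem sizes and runtime

The desk-scale study sizes are: 500 base complexes (hence 1000 grids) per
classifier training, 100 fresh clashed complexes for the reciprocity
study, 100-step IG throughout. On one CPU core a full classifier training
takes a few minutes and the 100-complex study a few more; unit tests run
the same code paths at 8-12 voxel grid sizes, where the conv stack still
halves cleanly, in seconds. These sizes are the package's chosen study
conditions, mirroring a corpus-scale analysis at a size a laptop
reproduces comfortably.

## Known limitations

* The scorers are deliberately small; they demonstrate the attribution
  machinery, not state-of-the-art scoring. Corpus-scale results (affinity
  correlations on curated crystal-structure databases, real-complex case
  studies) are out of reach by design and are not claimed.
* Attribution reciprocity on the clash task is partial at desk scale. The
  ligand-occupancy top voxel reliably sits within a few Angstrom of the
  clash, and the occupancy-pair distances are far below the random
  baseline, but the protein-occupancy top voxel often lands on displaced
  pocket-wall density instead of the contact itself, so the median pair
  distance stays above the sub-3 Å level seen in corpus-scale studies.
  The cause is a property of the synthetic study design: clashed poses are
  made by rigidly translating the ligand into a uniform spherical wall, so
  the wall's displacement relative to the ligand-centered box is exactly
  as discriminative as the local overlap, and a loss-optimal classifier
  uses both. Real corpora break this symmetry through pocket diversity.
  We verified this with per-branch gradient decompositions and with
  detection-head architectures whose gradients are confined to local
  evidence; those heads localize but cap at ~0.93 accuracy because the
  1 Å grid and the saturating kernel make mild clashes (contact
  1.3-1.45 Å) and tight crystal contacts (2.4-2.7 Å) locally ambiguous.
* Ligand aromaticity relies on SDF order-4 bonds; kekulized rings without
  aromatic bond types are typed as alternating single/double.
* Protein typing is name-based; exotic residues fall back to element
  rules (and unknown elements to heavy-only with a warning).
* The voxelizer has no partial-charge channels and no rotation-augmented
  multi-pose featurization.
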