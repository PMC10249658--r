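---
title: "Locating Mg2+ ions in RNA structures with voxmg: models and methods"
author: "voxmg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating Mg2+ ions in RNA structures with voxmg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Magnesium ions neutralize the phosphodiester backbone of RNA (one negative
elementary charge per nucleotide) and are essential to folding and
function, yet they are hard to place experimentally: in electron density
Mg2+ is nearly indistinguishable from water and Na+ except at high
resolution, and many deposited structures miss ions outright. `voxmg`
implements a structure-based predictor: given an RNA 3D structure it
returns a ranked list of candidate Mg2+ binding sites, together with
interpretation tools (gradient saliency projected onto atoms, radial
contact distributions) and a geometric classifier of inner-sphere binding
motifs.

## The model

**Featurization.** For every nucleotide, a 24 x 24 x 24 A cubic box is
centred on the residue's heavy-atom centroid and discretized at a
configurable spacing (1.0 A by default; `grid_config()`). Two channels
describe the local environment:

* *volume occupancy* — for each voxel centre, the maximum over atoms of
  `1 - exp(-(r_vdw / d)^12)`, a soft indicator of atomic volume that is 1
  at the atom centre and decays steeply past the van der Waals radius.
  Max-aggregation keeps the channel in [0, 1].
* *partial charge* — the sum over atoms of the atom's partial charge
  smeared by a Gaussian of one voxel width. This channel is additive and
  unbounded by design.

Waters and ions are never featurized: the model must not see the answer.
Partial charges come from a shipped per-atom table
(`default_charge_table()`) in which hydrogen charges are folded into their
parent heavy atoms so that every standard nucleotide sums to exactly -1 e.
The table is an AMBER-style construction of this package (the upstream
tooling choice of charge scheme is not reproducible from the published
description); any table with the same columns can be supplied instead.

**Network.** A residual 3D regression CNN maps the two-channel image to a
per-voxel ion probability `p(i, j, k)`: an input 3x3x3 convolution, `n_blocks`
residual blocks (two 3x3x3 convolutions plus an identity shortcut each),
and a single-channel output convolution under a sigmoid. Stride is 1
everywhere, so any grid size is accepted and the output matches the input
shape. Activations are leaky ReLU (slope 0.1): with plain ReLU the
network can die into the constant-zero predictor on these sparse targets.
Convolutions are computed in compiled code (im2col plus BLAS); training
uses Adam with backpropagation written in the package, which is also what
makes exact input gradients available for saliency.

**Targets and loss.** Training labels are Gaussian bumps
(`sigma = 1.5` A, half the 3 A hit radius) around known ion positions.
Binding voxels are a tiny fraction of each grid, so the loss weights every
voxel by `1 + pos_weight * label` (`pos_weight = 30` by default); both a
weighted MSE and a weighted binomial cross-entropy (`loss = "bce"`) are
available. Cross-entropy pushes confident predictions closer to
saturation and is what the end-to-end tests use; MSE is the default for
the regression reading of the probability grid.

**Site extraction.** Per-nucleotide probability grids overlap; they are
assembled onto a global voxel lattice where each voxel takes the *mean*
over covering boxes (the mean avoids double counting mass in the ranking
score). Voxels above `threshold = 0.5` are clustered with DBSCAN
(`eps = 2` A, `min_samples = 4` — calibrated so a single sigma = 1.5 A
Gaussian blob forms one cluster on a 1 A lattice). Within a cluster,
representative points are found by probability-weighted k-means with
seeded k-means++ initialization, using `k = max(1, floor(diameter / 6 A))`
so an elongated high-probability channel can yield several sites. Each
representative is scored by the summed probability of its k-means
partition, and sites are ranked by score with lexicographic coordinate
tie-breaks for reproducibility.

When a coarser lattice is used, the DBSCAN parameters must be recalibrated
to the voxel density: on the 1.5 A lattice used by the package's
end-to-end experiment, `eps = 2.25` (face and edge neighbours) and
`min_samples = 3` are the equivalents of the 1 A defaults. This is a
lattice-geometry calculation, not a tuning knob: a supra-threshold blob
holds about `(1/spacing)^3` times as many voxels as on the unit lattice.

**Evaluation.** A predicted site is a hit when it lies within 3 A of an
experimentally observed ion; matching is greedy nearest-first and
one-to-one. TPR is hits over experimental sites, PPV hits over predicted
sites; the two are antagonistic except for a perfect predictor. Top-n
curves pool the n best-ranked predictions per structure; success-rate
curves sweep the distance cutoff; `kfold()` provides seeded balanced
partitions for cross-validation.

**Saliency.** The prediction score of a site is the summed probability
over voxels within 3 A of it. Saliency is the absolute gradient of that
score with respect to each input channel, optionally SmoothGrad-averaged
over noisy input copies (25 samples, noise 10% of the channel range by
default). Voxel saliency is projected onto atoms by trilinear
interpolation at the atom position. Radial profiles histogram
centre-to-atom distances per atom class (phosphate oxygens O_ph, ribose
and bridging oxygens O_r, base oxygens and nitrogens split by
purine/pyrimidine — six classes), weighted by 1 or by atom saliency, in
0.25 A bins over 0-8 A, each curve normalized to maximum 1. The
`ablate_coordinators()` operation supports the perturbation experiment:
delete the inner-sphere atoms and compare predictions before and after.

**Motifs.** Inner-sphere coordinating atoms are RNA O/N heavy atoms
within 2.6 A of a site — a cutoff that clears the ~2.3 A inner-sphere
contact peak while excluding the ~4.3 A water-mediated outer shell;
waters inside the cutoff are counted separately. For a pair of
coordinating phosphate oxygens, the *ring size* is the atom count (ion
included) of the minimal cycle through the backbone bond graph: 10 for
consecutive phosphates, 16 for phosphates separated by one residue, 4 for
the two oxygens of a single phosphate. Classification applies rules in
priority order — phosphate pyramid (three O_ph from distinct phosphates
with a 10- or 16-ring among them), 16-ring, 10-ring, magnesium clamp,
Y-clamp, G-phosphate, U-phosphate, single-atom, unclassified — so every
shell receives exactly one label. Two reconstructions deserve note. A
literal reading of the rule order would classify every Y-clamp as a
magnesium clamp (its phosphate-oxygen pair also bridges without a short
backbone ring); the clamp rule therefore additionally requires the
*absence* of an inner pyrimidine base oxygen. And the clamp/Y-clamp
geometric signatures themselves (distinct-phosphate O_ph pair with no
backbone ring of 16 or fewer atoms; plus a pyrimidine O_b) are
operationalizations of verbal descriptions, documented here as such.
Outer-sphere (water-mediated) motifs are out of scope by design. Motif
abundance divides each label's count by the number of sites with at least
one inner-sphere RNA atom.

## The synthetic generator

Real curated corpora cannot ship with the package, so `gen_config()` /
`make_corpus()` emulate the study conditions with seeded synthetic
fixtures: idealized single-strand chains built from a rigid
all-heavy-atom nucleotide template propagated along a helical screw
(twist 32.7 degrees, rise 2.81 A, optimized once so the O3'-P linkage is
1.60 A and residues do not clash), with planted Mg2+ sites realizing a
requested motif exactly:

* the coordinating phosphate oxygen is re-pointed along the P-to-ion
  direction so the Mg-O distance equals `inner_distance` (2.1 A, the
  canonical inner-sphere bond length, inside the ~2.3 A contact peak);
* the 16-member ring bends the chain rigidly at the intervening phosphate
  to bring the two anchor phosphates into range;
* clamp- and base-contact motifs place a rigid single-nucleotide fragment
  on a second chain, with the ion direction searched for steric
  clearance;
* the shell is optionally completed to octahedral six-coordination with
  water oxygens (parsed and counted downstream, never featurized);
* Gaussian coordinate noise (0.15 A default) is added to atoms, never to
  the recorded ground truth, and all coordinates are written at PDB
  precision.

Defaults are 50 structures of 6 nt, 20% decoys without a site, and a
motif mix dominated by the 10-member ring, 16-member ring and magnesium
clamp with smaller fractions of pyramid, base-contact, Y-clamp and
single-atom sites. What the generator does *not* emulate — duplexes and
tertiary folds, sequence-dependent geometry, crystallographic noise,
outer-sphere-only sites, competing ions — bounds what the closed-loop
tests can show: they demonstrate that the pipeline's machinery (geometry,
featurization, learning, extraction, scoring, classification) is
self-consistent and recovers planted signal, not that the shipped
defaults reach any particular accuracy on real PDB structures. Users with
curated data train on it through the same interfaces (see the `train`
subcommand).

## Problem sizes and numerical choices

The package's own end-to-end experiment (also the heaviest test) uses the
50-structure default corpus, a 4:1 train/held-out split from `kfold`, a
1.5 A lattice and a 2-block, 8-channel network trained for 18 epochs with
Adam at learning rate 1e-3 (minutes on one CPU core); it recovers planted
sites with TPR and PPV well above the 0.8/0.5 property thresholds.
Degenerate inputs are handled explicitly: an empty field yields an empty
site list (not an error), a zero-prediction evaluation leaves PPV
undefined (`NA`) rather than 0/0, residues missing from the charge table
degrade to charge 0 and radius 1.5 A with a warning, and chain breaks
(O3'-P beyond 2.25 A, the covalent sanity bound with its tolerance
factor) leave the bond graph disconnected, which the ring
classifier treats as "no ring". All stochastic stages (sequence draws,
noise, shuffling, initialization, k-means++ seeding, fold assignment)
derive from explicit integer seeds, and every stage is bitwise
reproducible under a fixed seed.

## Known limitations

* The network is trained per use case; no pretrained weights ship with
  the package, and published benchmark numbers on curated PDB corpora are
  not reproducible without that external data.
* Greedy nearest-first matching can in principle fall below the maximum
  bipartite matching cardinality on adversarial geometries where one
  prediction blocks two true sites; on well-separated sites (the regime
  of the 3 A cutoff) it is exact, which the tests verify against a
  brute-force oracle.
* The occupancy kernel saturates to exactly 1.0 in double precision below
  about 1.3 A, so strict monotonicity holds only outside the saturated
  core.
* Charge-channel values depend on the shipped charge table; swapping
  tables changes the input scale and warrants retraining.
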