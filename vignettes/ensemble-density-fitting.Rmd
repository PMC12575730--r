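---
title: "Ensemble-based density-guided refinement: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-based density-guided refinement: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the protocol

A cryo-EM map of a protein in a new functional state often cannot be
modelled by refining the one known experimental structure: flexible
fitting is a local optimisation, and a large conformational change —
a helix that kinks, helices that repack, a domain that reorients — can
leave it stranded partway. `ensemblefit` implements the ensemble
alternative: generate or import many candidate conformations, discard
the misfolded ones, cluster the rest, refine one representative per
cluster into the density, and choose the final model by a score that
rewards both map fit and stereochemical quality.

The pipeline stages and their contracts are described in the README;
this vignette records the underlying models, the parameters that
matter, and the design decisions taken where the design was genuinely
open.

## Density model

A model is turned into a density by spreading each heavy atom as an
isotropic Gaussian, amplitude 1 by default (an `atomic_number` mode
exists but Pearson correlation is scale-invariant, so uniform weights
are the simplest adequate choice), truncated at 4σ (< 0.04% of mass).
The default width σ = 1.5 Å corresponds to a ~3.5 Å map under the
FWHM ≈ resolution heuristic `sigma_from_resolution()`; it is
configurable because simulated-map conventions differ between tools.
Maps are held float64 internally and written as MRC2014 mode-2 float32;
on reading, axis order is normalised to (x, y, z) and the origin is
reconstructed from the ORIGIN record or, failing that, from
nstart × voxel. Non-orthogonal cells are rejected rather than silently
mishandled.

The target map is blurred by a 1 Å Gaussian before fitting, treating
the stated width as a standard deviation (tools differ on whether a
"blur width" is an SD or a B-factor-like parameter; the SD reading is
documented here as the package's convention and the blur is separable,
so it is exact to the sampled kernel).

## Geometry scoring and the −100 filter

External statistical-potential scores (e.g. GOAP program output) are
read from CSV and scaled by sequence length; the keep rule is
`scaled ≤ threshold` with the boundary kept, since models "above" the
threshold are the ones discarded. The −100 default is a round,
admittedly arbitrary number; it is exposed in `filter_config()`.

When no external table is given, an internal fallback scorer provides
the same interface: `scaled = −(base − w_clash·clashscore −
w_bond·msd_bond)` with base 125, w_clash 0.02, and w_bond 8 per Å².
The two ingredients are a heavy-atom clash score (MolProbity-style
overlaps ≥ 0.4 Å per 1000 atoms, excluding pairs within a residue or
within bonded-graph distance 3) and the mean squared deviation of
standard-connectivity bond lengths from ideal values. The weights were
calibrated once against the synthetic suite so that models with sound
stereochemistry — including copies carrying the generator's default
0.5 Å coordinate noise — score at −110 or below, while
coordinate-scrambled decoys score in the thousands; the two
populations do not overlap, so the standard −100 cutoff applies
unchanged. The fallback is labelled `internal_fallback` everywhere and
mixing it with external scores in one run is an error: scores are only
comparable within one source.

## Clustering

Two routes mirror two use cases. With a known alternative-state
structure, every model is Kabsch-superposed onto it and k-means
(k-means++ seeding, Lloyd iterations, 10 restarts, best inertia kept)
runs on the flattened Cα coordinates; representatives are the models
nearest each centroid, ties to the lowest index. Without any known
structure, the pairwise internal-distance RMSD matrix — symmetric,
hollow, and exactly rigid-invariant — feeds PAM k-medoids, whose
medoids are the representatives. k defaults to 20, a practical
compute budget rather than an estimate of the true number of states;
no automatic selection of k is attempted.

## Rigid-body fitting

The fit maximises mean-subtracted Pearson correlation between the
simulated model map and the target, over a quaternion-parameterised
rotation about the model centroid plus a translation, by Nelder–Mead
from multiple starts (the identity pose plus seeded perturbations
within 30°/5 Å by default). Keeping the identity start guarantees the
returned correlation never drops below the input pose's. The method is
a local refiner for roughly pre-posed models — cluster representatives
aligned to a known state — not a global FFT search. Whether the
"standard" map correlation is mean-subtracted differs between tools;
mean-subtracted is the default here and the raw inner-product variant
is available in `cc_config()`.

## The refiner

The refiner replaces a full MD engine with damped steepest descent
under restraints, which keeps the selection logic — the part this
package exists for — testable at desk scale; an import path
(`read_trajectory()` on multi-model PDB) accepts trajectories produced
by real MD engines.

**Restraints.** Bonds from standard residue connectivity (backbone,
CB, peptide bonds; distance-heuristic bonds for nonstandard atoms),
angles from bonded triples, torsions from bonded quadruples. Bond
references are ideal lengths, so noisy starting coordinates relax to
sound stereochemistry; angle and torsion references are measured from
the start model, because those degrees of freedom legitimately encode
conformation (a hinge lives partly in a backbone angle) and must not
be erased by the restraints. The torsion term is weak (k = 100 vs
2000 per Å² for bonds) and exists to give the chain the torsional
rigidity a real backbone has — without it the model bends almost
freely and refinement behaviour is unphysical. No secondary-structure
restraints are applied, deliberately: the refinement must be able to
change conformation. Angle and torsion forces taper smoothly to zero
near collinear geometry, where their gradients diverge.

**Bias force.** The default bias is k times the analytic gradient of
the Pearson correlation between the simulated and target maps. Its
stationary point is the generating structure itself, which gives the
refiner a true fixed point: refining a model into its own map moves it
< 0.1 Å. The simpler point-sampling force (k times the local map
gradient at each atom, `bias_mode = "map_gradient"`,
`density_bias_force()`) is also provided, but it pulls every atom
toward the nearest density ridge and therefore contracts dense
structures — measured at ~2.3 Å of drift on a helix refined into its
own map — so it is not the default.

**Schedule.** The bias applies every 2 steps. The force constant
starts at 5000 (in the restraint energy scale; chosen so the initial
bias displacement per application is a few 10⁻³ Å, a small fraction of
the 0.05 Å per-step trust region, leaving the adaptive schedule in
control) and grows ×1.05 every 10 applications — adaptive force
scaling. A run ends either at the step budget or as soon as any
atom's raw per-step displacement exceeds 0.5 Å, the observable
consequence of forces growing too large for stable integration; the
termination reason is recorded. Each run is preceded by 200 bias-free
clipped-descent steps, the minimisation/equilibration phase of any MD
workflow, exempt from the termination criterion.

**The step budget as a study condition.** The default budget
(`max_steps = 1200`, roughly three times the relaxation time of a
well-posed start) is deliberately finite. On a smooth synthetic
landscape an unbounded local optimiser will eventually complete even a
large conformational transition from the wrong starting state; real
refinement protocols are bounded by simulation time and by automatic
termination, and it is within that bounded regime that the choice of
starting structure — the thing the ensemble approach supplies —
determines the outcome. The budget is long enough that a well-posed
start converges and relaxes fully, and short enough that a
wrong-state start lands mid-transition. Users studying exhaustive
refinement can raise it.

## Selection

Per trajectory, frames are scored by map correlation and scaled
geometry score; the compound score is the sum of the min-max-normalised
correlation and the min-max-normalised *magnitude* of the geometry
score, so better geometry (more negative score) increases it. The
normalisation is per-trajectory by default; the global variant pools
extrema across all trajectories of a run. Geometry scores must be
negative — taking |x| of a positive score would invert the ranking, so
the package fails loudly rather than guessing. Trajectory choice is by
highest mean correlation over stored frames (stride-dependent, which
is documented because sampling density is a protocol choice), ties to
the lexicographically smallest label; frame choice by highest compound
score, ties to the earliest frame. RMSD to a ground-truth structure,
when available, is reported for validation but is never a selection
criterion.

## The synthetic benchmark

`make_toy_system()` builds the two-state scenario the pipeline assumes:
a 40-residue poly-alanine α-helix (backbone + CB; ideal φ/ψ = −57/−47,
~100°/residue twist, 1.5 Å rise) as the known state; the same helix
hinged 40° at residue 20 as the target state; a target map simulated
from the target state at 1 Å voxels with σ = 1.5 Å and blurred by
1 Å; and an ensemble of 200 models, 20% sampled around the target
state, all with isotropic 0.5 Å per-atom Gaussian noise — a stand-in
for the conformational spread of an AI-generated ensemble. The hinge
rotation pivots on the backbone N of the first rotated residue, which
preserves every bond length exactly while changing only the hinge
angles. Optional coordinate-scrambled decoys exercise the filter.

What the generator does *not* emulate: realistic map noise (CTF,
solvent, B-factor falloff), per-residue confidence structure,
side-chain packing, oligomers, or internal-coordinate (as opposed to
Cartesian) model noise. Passing tests on this suite therefore
demonstrates the correctness of the pipeline's logic and the
qualitative starting-point phenomenology, not performance on
experimental maps.

Problem sizes used by the shipped tests and the acceptance script:
the full 200-model, 40-residue system for the end-to-end comparison
(about seven minutes on one CPU), 100 models for the filter check,
and 16-24-residue systems for orchestration and determinism checks.

## Numerical choices and degenerate inputs

Superposition uses Kabsch via SVD with the determinant sign
correction; near-collinear point sets are rejected. Trilinear map
interpolation provides values and analytic gradients; the gradient is
piecewise constant per cell, so forces at exact grid nodes are
one-sided — the bias examples in the tests place features at cell
centres where symmetry holds. Min-max normalisation of a constant
series returns zeros with a warning. Constant maps correlate as 0
with a warning. All tie-breaks are deterministic (lowest index,
smallest label, earliest frame), and every stochastic stage takes an
explicit seed, making whole-pipeline runs bitwise reproducible.

## Known limitations

- The refiner is a minimiser, not thermal dynamics: it cannot cross
  energy barriers, and its trajectories are monotone descents rather
  than samples from an ensemble.
- The internal fallback geometry score is a stereochemistry screen,
  not a statistical potential; it separates folded models from
  scrambled ones but cannot rank subtle misfolds the way an
  orientation-dependent potential can. External score tables are the
  intended production route.
- The clash score approximates MolProbity counting with heavy atoms
  only (no hydrogen placement, no rotamer or Ramachandran analysis).
- Rigid fitting is local; models must be roughly posed (the pipeline's
  alignment stage does this when a known state exists).
- Only orthogonal-cell MRC maps and PDB/mmCIF structures are read;
  compressed MD trajectory formats are out of scope — convert to
  multi-model PDB for import.
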