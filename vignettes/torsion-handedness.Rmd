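---
title: "Classifying DNA handedness from backbone torsion angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying DNA handedness from backbone torsion angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Left-handed G-quadruplexes (LHG4) are a recently characterized class of
four-stranded DNA whose jagged, Z-DNA-like phosphate backbone distinguishes
them from the canonical right-handed parallel quadruplexes (RHG4). Because
helical handedness is a property of the backbone's progression through
space, it should be readable directly from the backbone dihedral angles of
individual nucleotides. `g4hand` implements that reading: it computes the
six backbone torsions α (O3′(i−1)–P–O5′–C5′), β (P–O5′–C5′–C4′), γ, δ, ε, ζ
and the glycosidic angle χ from PDB coordinates, builds a labelled
per-nucleotide feature table (0 = left-handed origin, 1 = right-handed), and
trains small, human-readable decision trees that expose *which* angles carry
the handedness signal.

## The classifier

The tree is ID3-style: each internal node tests one angle against a
threshold θ ∈ [0, 360]. Candidate thresholds are midpoints between
consecutive distinct sorted feature values; the node chosen maximizes the
information gain

E(S) − |S_L|/|S| · E(S_L) − |S_R|/|S| · E(S_R),

where E(S) = −Σᵢ pᵢ log₂ pᵢ is the Shannon entropy of the class proportions
(0·log₂0 ≡ 0, so a pure node has entropy 0 and an evenly mixed two-class
node entropy 1). Ties are broken by the fixed feature order
(α, β, γ, δ, ε, ζ, χ), then by the smaller threshold, making training fully
deterministic. Growth stops at pure nodes or when no split has positive
gain.

Model size is then controlled by minimal cost-complexity ("weakest link")
pruning with misclassification-rate impurity: internal nodes whose
effective complexity g(t) = (R(t) − R(T_t)) / (|leaves(T_t)| − 1) is at or
below the complexity parameter are collapsed, weakest first, until every
remaining subtree earns its keep. The working value of the complexity
parameter is 0.04; 0 disables pruning, ∞ collapses the tree to a single
majority leaf. An alternative early stop on the entropy drop
(`grow_tree(min_gain = )`) is available, but cost-complexity pruning is the
default because it is parameterized by a single reproducible number.
Prediction routes left on `value ≤ θ`; leaf ties predict the left-handed
class. The two-threshold closed-form rule the pruned trees converge to —
left-handed iff α < 252° and β > 150° — ships as `rule_classifier()`.

## Validation protocol

`repeated_holdout()` repeats a uniform random 70/30 split (test size
`ceiling(0.3 N)`, so 213 samples split 149/64), trains and prunes on the
training part, and scores accuracy on the held-out part; iteration *i* runs
under seed `base_seed + i`, so every report is reproducible bit for bit.
`transfer_experiment()` additionally mixes k duplex (Z-/B-DNA) samples into
the quadruplex training set and scores the same tree both on the quadruplex
test split and on all duplex samples *not* drawn into training — the
latter choice avoids evaluating on trained-on duplex samples at the cost of
a slightly shrinking evaluation pool as k grows. `single_angle_assessment()`
reruns the protocol with the tree restricted to one angle at a time under
identical seeds, making the seven mean accuracies directly comparable.
`first_split_statistics()` summarizes which angle the pruned trees choose at
the root and at what average threshold.

## Angle conventions and numerical choices

* All angles live on [0, 360), cis = 0, trans = 180; that is the convention
  the thresholds of interest (252°, 300°, 325°) are quoted in. Wrapping is
  plain `x %% 360`.
* Angles are treated as **linear** features on that interval, both in the
  trees and in PCA. A circular treatment would change the methodology being
  reproduced; the shipped class distributions keep their mass far from the
  0/360 seam, so the linearization is benign there.
* The dihedral uses the atan2 triple-product form and rejects quadruples
  whose cross-product norms fall below 1e-8 (real structures never approach
  this). Reversing the atom order of a quadruple leaves the signed torsion
  unchanged; mirror reflection negates it — the geometric root of the
  handedness signal, asserted in the test suite.
* α and β are reported only through a geometrically established 5′ linkage
  (O3′–P distance < 2 Å), and ε/ζ only with a 3′ linkage; terminal residues
  therefore carry missing values and are dropped by the completeness filter
  in `build_dataset()` — no imputation, matching a feature table whose
  per-nucleotide rows are complete 7-vectors.
* Residue connectivity is inferred from O3′–P distances, never from residue
  numbering; alternate locations resolve to the highest occupancy (ties to
  altloc A); only one model of a multi-model file is used (model 1 by
  default). Modified bases (bromo-cytosine, inosine, 2-aminoadenine) map to
  their parent base for the χ quadruple (O4′–C1′–N9–C4 for purines,
  O4′–C1′–N1–C2 for pyrimidines).
* PCA centres but never scales (all features share one unit, degrees), uses
  the SVD, and fixes each component's sign so its largest-magnitude loading
  is positive.

## Which nucleotides enter the dataset

Only tetrad guanines of the quadruplex structures belong in the feature
table; loop and overhang nucleotides are excluded. Tetrad membership is
**manifest-driven**: `inst/extdata/table1_manifest.yaml` lists, per
structure, the structural class and an explicit residue selection (or
`all-complete` for duplexes). The shipped G4 residue lists are reconstructed
from the published sequences with 1-based chain-A numbering — the original
study does not enumerate its selections — and are expected to be edited to
match deposited chain IDs and author numbering before use on real files.
One structure contains both a left- and a right-handed component and
appears twice with disjoint residue lists.

## The synthetic generator

`sample_dataset(default_torsion_spec(), seed)` draws labelled profiles from
per-class wrapped-normal mixtures (a normal draw reduced mod 360). The
shipped parameters encode the documented class features: LHG4 guanosine α
centred at 180° with sd 12.5° (≈95% of mass in 150–200°), RHG4 α at 300°
with sd 18° (mass in 250–325°), a bimodal LHG4 ε/ζ tied to the first vs
second guanosine of each tract (subpopulations alternate deterministically,
mirroring the repeating tract structure), Z-DNA generated at dinucleotide
granularity with syn guanosines (χ ≈ 60°) alternating with anti cytidines
(χ ≈ 240°, α ≈ 180°), and a broad B-DNA α around 300° (sd 25°). Angles with
no documented range receive canonical, deliberately broad backbone values
so they cannot drive classification by construction; each such value is
marked "filled" in the YAML. Default class sizes are the curated-set counts
125/88/76/175.

What the generator does *not* emulate: within-class covariance between
angles (draws are independent per angle), sequence context, crystallographic
noise or resolution effects, and the long tails real torsion distributions
can have. Passing tests on synthetic data therefore demonstrate that the
pipeline's machinery is correct and that the documented class geometry is
recoverable by it — not that real deposited structures will reproduce any
particular accuracy. The real-structure path (`cmd_extract()` over PDB
files plus the manifest) exists precisely so that the same downstream code
runs on deposited coordinates when they are available.

`make_fixture_structure()` builds small, geometrically exact PDB chains
from internal coordinates (fixed bond lengths/angles, caller-chosen
torsions placed by the NeRF construction), giving the torsion stack a
ground truth that is exact to machine precision in memory and to the 0.001 Å
PDB column resolution on disk.

## Problem sizes used by the shipped tests

The test suite and acceptance checks run the generator at the curated-set
sizes (213 quadruplex, 251 duplex samples) and at 200 samples/class for the
root-split stability checks, with 10–50 holdout iterations and 15–50 seeds
per property — sizes chosen so the whole suite completes in a few minutes
on one core while keeping Monte-Carlo error well inside the asserted
margins. The protocol default of 1000 iterations remains the package
default for real analyses.

## Known limitations

* Tetrad selection is curated, not computed; a hydrogen-bond-geometry
  tetrad detector is out of scope.
* PDB is the only input dialect (every curated entry is available as PDB);
  mmCIF is a non-goal.
* Circular statistics are deliberately not used (see above).
* The duplex evaluation set in the transfer experiment excludes trained-on
  samples; a variant that scores all duplex samples would report slightly
  higher numbers at large k.
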