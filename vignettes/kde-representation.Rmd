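---
title: "KDE-binned internal-coordinate representations for molecular energy prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KDE-binned internal-coordinate representations for molecular energy prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molkde)
```

## The model

molkde builds an explainable, fixed-length feature vector for a small
organic molecule (atom types C, H, N, O) from its 3D geometry, and
regresses DFT-level energies on it. The representation has six blocks:

1. **Atom counts**, one slot per element, weighted by 100. The weighting is
   deliberate: the number of atoms of each element is by far the largest
   contributor to a molecular electronic energy, and the factor of 100 makes
   that dominance visible to distance-based learners (the RBF kernel)
   without any feature standardisation.
2. **Bond-length features.** Every perceived bond is classified by the
   element pair it joins (e.g. CC, CH). Over a training set, the pooled
   lengths of each class are smoothed with a Gaussian kernel density
   estimate; every local *maximum* of the KDE becomes one feature slot, and
   the flanking local *minima* become the assignment boundaries. A molecule
   is encoded by counting how many of its bonds fall into each maximum's
   interval.
3. **Angle features** — the same construction over all bonded triples,
   classified with connectivity-annotated tokens (C3, C4, ...) because the
   angle at an sp2 carbon and at an sp3 carbon are chemically different
   populations.
4. **Dihedral features** — the same construction over all bonded
   quadruples, element-level tokens, absolute torsion in [0°, 180°]. The
   absolute value makes the representation achiral: enantiomeric torsions
   land in the same bin, and a KDE over signed values would split every
   peak in two.
5. **Hydrogen-bond features.** Every hydrogen covalently bound to N or O
   is a donor hydrogen; every other N/O atom is a candidate acceptor. A
   contact with H⋯acceptor distance between 1.3 and 2.6 Å is recorded in
   one of the four classes OH–O, OH–N, NH–O, NH–N and binned like bonds.
   The window is interpreted as a hydrogen-to-acceptor distance: a
   heavy-atom–to–heavy-atom separation of 1.3 Å is physically impossible,
   so the range only makes sense measured from the hydrogen.
6. **NH_x counts** — the number of nitrogens carrying exactly x hydrogens
   (primary, secondary, tertiary amine environments).

Because every entry is a count attached to a nameable chemical feature,
linear-model coefficients are directly readable as kcal/mol per
occurrence — this is what makes the representation explainable.

### The worked example

For the idealized staggered ethanol fixture (`make_ethanol()`; C–C 1.52 Å,
C–O 1.43 Å, O–H 0.96 Å, C–H 1.09 Å, tetrahedral angles):

```{r ethanol}
eth <- perceive_bonds(make_ethanol())
table(enumerate_bond_obs(eth)$class_label)
table(enumerate_angle_obs(eth, "element")$class_label)
nrow(enumerate_dihedral_obs(eth))
nrow(detect_hbond_obs(eth))
```

One CC, five CH, one CO, one HO bond; angle counts 5/4/2/1/1 (labels are
canonical with element order C < H < N < O, so the angle usually written
OCH prints as HCO and COH keeps its central oxygen in the middle); twelve
dihedrals; no intramolecular hydrogen bond.

## Pipeline stages and their parameters

**Bond perception.** Bonds are perceived from geometry: atoms i and j are
bonded when their distance is below `scale × (r_cov(i) + r_cov(j))` with
single-bond covalent radii H 0.31, C 0.76, N 0.71, O 0.66 Å and
`scale = 1.15`. This reproduces standard organic connectivity for
near-equilibrium geometries, is deterministic, and the same bond
definition feeds both feature extraction and the long-bond cleaning
filter (we see no reason to maintain two bond definitions).

**Curation.** Six filters, applied in a fixed order so every removal has
exactly one reason: imaginary lowest frequency (the geometry is not a
minimum); any element outside C/H/N/O; any bond longer than 1.6 Å
(strained outliers too rare to learn); nitrogens with four neighbours
(zwitterions); three-coordinate carbons whose neighbours are all H(1),
O(2) or N(3) — an incomplete carbon octet; and four-coordinate carbons
with a bond angle above 160°. The 160° default is our choice: wide enough
that no ordinary sp3 centre (angles ≲ 120°) is touched, tight enough to
catch near-planar or near-linear distortions; it is configurable.

**Splitting.** Molecules are grouped by molecular formula and split group
by group: singleton formulas go to neither set (their energy scale has no
counterpart to learn from), pairs send one molecule to each side, larger
groups are split at the test fraction (default 0.33) with a
`ceiling(f·n)` test count capped at n−1, so both sides are always
non-empty. The ceiling makes the aggregate test share land slightly above
the nominal fraction, which is the intended behaviour.

**KDE binning.** Bandwidths default to `0.07 × sd` of the pooled class
sample (the factor convention of the usual Gaussian-KDE toolkits), for all
four families; the bond and angle factors are the published working
values and the dihedral/H-bond factors mirror them since those two are
not pinned. The density is evaluated on a 2048-point grid padded three
bandwidths beyond the sample range; maxima localisation error on that
grid is far below any chemically meaningful length or angle scale. Two
numerical guards matter: maxima in regions whose density is below 1e-9 of
the global maximum are ignored (the FFT-based density wiggles at machine
scale in effectively-zero valleys), and the outermost interval bounds are
±∞, so a distorted or force-field geometry can never produce an
unassignable observation — out-of-range values are absorbed by the edge
bins. Interval membership uses the half-open convention (lower, upper];
ties at a boundary have measure zero and the choice is unobservable in
practice. A class with a single distinct value yields exactly one
all-covering bin. Classes present in a molecule but absent from the
dictionary are dropped into a coverage report rather than raising — this
is required for extrapolation to larger molecules than the training set
contains.

**Augmentation.** A distorted replica moves every atom independently by
exactly δ along one coordinate axis, sign and axis uniform (we read the
per-atom interpretation of the published procedure, and sample the sign
too so the distortion neighbourhood is symmetric). Replicas keep the
original's target energies: the point is to teach the model that the
neighbourhood of a PES minimum maps to the minimum's energy, so
force-field-quality geometries remain usable inputs. The working δ is
0.01 Å, and `c(0.01, 0.05)` is the published two-replicate compromise.
The distortion constant quantifies representation movement:
C = (1/N) Σ_j ‖X_j − D_j‖₁. We do not divide by the feature count: the
published constants (3.49–36.23 over ~760 features) are only reproducible
in order of magnitude without that normalisation, so the per-feature
variant is left as an option. Atom-count slots are excluded by default —
they are exactly distortion-invariant, so including them changes nothing.

**Regressors.** Four families behind one interface:

* **KRR** (authored here; the solve is `(K + αI) w = y` with
  K the RBF kernel `exp(−‖x−x′‖²/2σ²)`). α defaults to 1e-11, the
  published best value — its role is purely to regularise the solve, and
  exact duplicate feature rows (common with replicas) need a larger α.
  When σ is not given, it is set to 100 × the median pairwise training
  distance: energies are smooth, near-additive functions of the counts,
  so kernels approaching the linear-kernel limit generalise much better
  here than the bare median heuristic, consistent with the published
  observation that small widths did not help. For interpolation-style
  use, pass σ near the median distance explicitly.
* **NN**: a two-hidden-layer ReLU perceptron with linear output, MSE
  loss, batch size 64, uniform (Glorot) hidden initialisation and a
  zero-initialised output layer, trained with Adam (SGD and RMSprop are
  available) under cosine learning-rate decay. Inputs and targets are
  standardised internally for optimisation only; predictions return on
  the original scale. The published architecture pins the layer count,
  loss, batch size and init family but not the widths or schedule, so
  width 64 and the decay schedule are our engineering defaults.
* **MLR**: the L2-regularised least-squares objective solved exactly by
  SVD (stable when features outnumber molecules or are collinear; the
  intercept is unpenalised via centring). An exact solve replaces the
  original's stochastic gradient fit of the same objective — the optimum
  is the optimum, and determinism is worth more than fidelity to an
  optimiser.
* **RFR**: random forests via ranger, with all features per split and
  full-sample bagging as the best published setting.

All stochastic components funnel through explicit integer seeds; two runs
with the same configuration are bit-identical, including the dictionary
JSON on disk.

## What the synthetic data does and does not show

`make_toy_dataset()` draws jittered copies of eight idealized CHNO
templates, perceives bonds, builds a dictionary, and assigns energies
that are *exactly linear* in the encoded counts plus Gaussian noise
(default 1 kcal/mol, the scale of chemical accuracy); atom-slot
coefficients are drawn negative and larger so the energy hierarchy
resembles real atomisation energies. One ammonia singleton and a
two-water pair are always included so all three split rules fire. This
emulates the *mechanics* of real data — multiple stoichiometry groups,
multimodal coordinate distributions under jitter, H-bonded and
H-bond-free molecules — but not its chemistry: real DFT energies are not
exactly linear in the counts, real conformational distributions are far
broader than Gaussian jitter, and the template library spans eight
formulas rather than hundreds. Passing tests therefore certify the
machinery (enumeration, binning, encoding, splitting, augmentation,
training) and the recoverability of a known signal, not chemical accuracy
on real databases — the published headline errors require the deposited
~57k-molecule DFT dataset, which is outside this package's test surface.

For coefficient-recovery claims the template set is rank-limited (every
noise-free copy of a template encodes identically), so exact-recovery
tests use `make_count_fixture()`: Poisson count features with a known
coefficient vector whose magnitudes are bounded away from zero, making
relative error well defined per term.

Problem sizes used in the shipped tests — a shared 80-molecule toy set,
500 × 20 count fixtures, 10⁴ molecules for the split-share check — were
chosen so the full suite exercises every rule (including the binomial
regime of the split) while staying comfortable on one CPU.

## Known limitations

* Bond perception is a radius-sum rule: it will mis-perceive strongly
  compressed or stretched geometries (by design, those are what the
  long-bond filter removes).
* No ring perception, aromaticity, formal charges or stereochemistry;
  enantiomers encode identically (intended), diastereotopic environments
  are not distinguished beyond connectivity tokens.
* The QC-log reader extracts exactly three quantities (last SCF energy,
  last thermal free energy, lowest frequency) from the common log
  dialect; it is not a general parser.
* Energies are modelled per molecule with no atomic decomposition;
  extrapolation beyond the training size range relies on the dictionary's
  edge bins and dropped-class reporting rather than on size-consistent
  physics.
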