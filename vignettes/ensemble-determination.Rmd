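---
title: "Determining RNA dynamic ensembles from residual dipolar couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining RNA dynamic ensembles from residual dipolar couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcens)
```

## The problem

Flexible RNAs such as two-helix bulge junctions do not adopt one structure
in solution: they interconvert among many conformations, and observables
like NMR residual dipolar couplings (RDCs) report averages over that
ensemble. `rdcens` determines an atomic-resolution ensemble by *selection*:
given a large library of candidate conformers (from structure prediction,
molecular dynamics, or this package's synthetic generator), it picks the
small sub-ensemble whose *averaged* predicted RDCs best reproduce the
measured ones, and then characterises that ensemble structurally.

## The observable and its prediction

An RDC for a bonded atom pair with unit internuclear vector $u$ is the
quadratic form

$$D = D_{max}\, u^{\mathsf T} S\, u,$$

where $S$ is the Saupe order matrix — a symmetric, traceless
$3\times 3$ matrix describing the molecule's partial alignment in the
medium — and $D_{max}$ is the dipolar interaction constant of the pair
type (`bond_constants()`: C–H at an effective 1.104 Å bond, N–H at
1.041 Å; only the ratio between pair types matters downstream because
per-construct scale factors absorb overall magnitude).

Two routes to $S$ are provided:

* **Steric prediction** (`steric_tensor()`): partial alignment in a
  crowding medium is modelled by obstruction-weighted orientational
  averaging. For each of ~5,000 near-uniform directions $u$ (a
  deterministic Fibonacci grid), the accessible fraction between planar
  barriers spaced $d$ apart is $f(u) = \max(0, 1 - \ell(u)/d)$, with
  $\ell(u)$ the molecule's heavy-atom extent along $u$ (`wall`) or its
  largest extent perpendicular to $u$ (`rod`, mimicking phage-rod media).
  Then $S = \langle f\,(3uu^{\mathsf T} - I)/2\rangle / \langle f\rangle$.
  The barrier spacing is derived from the medium concentration as
  $d = 15/\sqrt{c}$ Å, which puts the typical phage concentration of
  0.022 g/mL at roughly 100 Å. The spacing constant only sets the overall
  magnitude of $S$, which the per-construct scale factors absorb; the
  *orientational* content of the tensor is what matters.
* **SVD fitting** (`fit_svd_tensor()`): with five or more measured RDCs on
  a rigid fragment, the five independent Saupe elements are the least
  squares solution of the standard direction-cosine design matrix,
  computed by singular-value decomposition (the design condition number is
  reported). This is the classical order-tensor analysis used to
  characterise helices without ensemble modelling.

## Sample-and-select

`sas_select()` minimises the mean squared misfit between ensemble-averaged
predictions and measurements over $N$-member subsets of the library:

$$\chi^2/N_{rec} = \frac{1}{N_{rec}}\sum_j \sum_i
\left(L_j\,\bar D^{calc}_{i,j} - D^{exp}_{i,j}\right)^2,$$

where $\bar D^{calc}$ is the unweighted (equiprobable) mean over the $N$
selected conformers and $L_j$ is a per-construct scale factor accounting
for different alignment magnitudes of the experimental constructs
(elongated variants, different medium concentrations). $L_j$ has a closed
form — $L_j = \sum_i D^{exp} D^{calc} / \sum_i (D^{calc})^2$ — and is by
default refit at every cost evaluation, since it is part of the objective.
The reported `chi2` is the residual sum of squares, so
`rmsd_hz = sqrt(chi2 / N_records)` holds exactly and matches the "RDC
RMSD" convention used throughout.

The optimisation is a simulated-annealing Metropolis chain: start from $N$
distinct uniform draws, propose swapping one member for a non-member,
accept with probability $\min(1, e^{-\Delta/T})$, report the best ensemble
ever visited. Defaults: starting temperature 100, cooling factor 0.9,
$5\times 10^5$ steps, temperature floor $10^{-12}$.

**Cooling cadence.** Applying the 0.9 factor at every proposal step
quenches the chain to an effectively greedy search within a few hundred
steps; on easy noise-free recovery problems such a quench finds the global
optimum in only about one run in ten, landing in single-swap local minima
otherwise. The default therefore spreads the same temperature ladder
(start to floor) uniformly over the whole run, which makes independent
seeds converge to the same cost and recovers generating ensembles
reliably. `cool_every = 1` restores the literal per-step quench for users
who want it.

**Move set and restarts.** Proposals swap one member for a non-member;
one quarter of them (configurable) exchange two members at once, which
crosses cost barriers that no single swap can. `restarts` runs several
independent anneals per selection and returns the best ensemble — on
noise-free recovery problems single-swap-only chains stall in local minima
on a sizeable fraction of instances, while pair moves plus a handful of
restarts recover the generating cost reliably.

**Duplicates.** Members of one ensemble are distinct library conformers; a
conformer's weight is effectively refined by the pooling protocol
(`pool_runs()`), which concatenates many independent runs (e.g.
$20 \times 100 = 2000$) for distribution analyses, where duplicates across
runs are counted.

`size_scan()` repeats the selection over a ladder of ensemble sizes and
flags the plateau where the mean RMSD stops improving by more than a
tolerance (default 0.2 Hz) — the standard way to choose $N$.

## Cross-validation

Two hold-out schemes test for over-fitting:

* `crossval_random()`: 10% of the records held out uniformly, selection on
  the rest, held-out RMSD computed with the training-fit scale factors
  (the constructs remain represented in training); averaged over 10
  repeats.
* `crossval_media()`: each construct's whole dataset left out in turn.
  Because the alignment magnitude of an unseen construct is not
  identifiable, one free scale is fit post hoc on the held-out construct
  and the relative pattern is scored. The alternative — fixing the scale
  at 1 — would conflate alignment-magnitude mismatch with structural
  misfit.

An over-fitted selection shows held-out RMSDs clearly above training
RMSDs; the package's acceptance checks verify this signature on pure-noise
data.

## Ensemble analytics

* **Torsions and pucker** (`compute_torsions()`, `classify_pucker()`):
  IUPAC backbone dihedrals, glycosidic $\chi$, and the ribose
  pseudorotation phase $P$ and amplitude $\nu_{max}$ from the five
  endocyclic torsions. C2'-endo (South) is $P \in [90°, 270°)$, otherwise
  C3'-endo; amplitudes under 10° are ambiguous. When ring atoms are
  missing, a $\delta$-based fallback (C2'-endo iff
  $100° < \delta < 200°$) is used and flagged.
* **Chemical-shift pucker map** (`shift_to_c2endo()`): the C1' shift is
  mapped linearly between 86 ppm (100% C2'-endo) and 94 ppm (100%
  C3'-endo), clamped to [0, 100] by default.
* **Inter-helical Euler angles** (`interhelical_euler()`): idealized
  A-form references are superposed (all heavy atoms, least squares) onto
  the configured base pairs of each helix; the upper helix's rotation
  *expressed in the lower-helix frame*, $R = R_{lower}^{\mathsf T}
  R_{upper}$, is decomposed in ZYZ convention. This frame-relative form is
  exactly invariant under global rigid motion. The reported
  $\alpha_h, \gamma_h$ carry inverted signs so that a positive twist
  $\alpha_h + \gamma_h$ means over-twisting; $|\beta_h|$ is the bend. Near
  the $\beta_h = 0$ gimbal only the twist is defined, and it is then
  attributed entirely to $\alpha_h$. Bend categories split at 45° and 70°
  (linear / intermediate / kinked), with boundary values assigned to the
  less-bent class.
* **Stacking and flipping** (`detect_stacking()`, `detect_coaxial()`,
  `detect_extra_helical()`): two bases stack when their ring centroids are
  within 4.5 Å, plane normals within 30° (unsigned), and lateral centroid
  offset within 2.5 Å — a standard geometric criterion; all three
  thresholds are arguments. A junction is coaxial when any configured
  cross-junction residue pair stacks. A bulge residue is extra-helical
  when it stacks with no base of either closing pair; published flip
  assignments made by visual inspection may differ from this geometric
  rule, so flip *counts* should be compared with that caveat.
* **Cooperativity** (`cooperativity()`): from per-conformer flip flags,
  each nucleotide's independent flip-out probability is estimated among
  conformers whose other bulge nucleotides are flipped in; the observed
  all-out fraction is compared with the independence product via
  $\Delta G = -RT \ln(P_{obs}/P_{indep})$ at 298 K. Negative values mean
  favourable cooperativity; magnitudes are what is usually quoted.
* **Ensemble distance** (`ensemble_distance()`): for each member of A the
  best-matching member of B is found by superposition RMSD; the root mean
  square of those minima is taken in both directions and the smaller value
  returned — a lower bound on how much two ensembles differ.

## The idealized A-form template

The duplex builder repeats a rigid nucleotide template by the helical
screw symmetry, the classical fiber-model construction. Twist
(32.7°/bp) and rise (2.81 Å/bp) are the fiber A-RNA values and are
realised exactly (they are recovered to machine precision from the
generated C1' coordinates). The remaining template geometry is a stylized
parameterization kept in one editable table (`aform_parameters()`):
C1' ring radius 6.2 Å, cross-pair C1'–C1' span 10.4 Å, a 50° glycosidic
swing off the cross-pair chord (purines get a calibrated extra 17° so that
purine and pyrimidine ring centroids share one azimuth, which keeps
mixed-sequence stacks within the stacking criterion), sugar rings built at
explicit pseudorotation phases (18° North, 162° South), and backbone
torsions tuned so the intra-strand O3'–P distance equals the bonded
1.6 Å. The atom-level template of fiber diffraction work is not
reproduced: groove dimensions and some backbone rotamers are deliberately
stylized, which is acceptable here because (i) RDC prediction depends on
bond-vector orientations and global shape, both realistic at this level,
(ii) the per-construct scale factors absorb residual shape-scale
differences, and (iii) every geometric analysis in the package is tested
against this same template's known properties.

In-silico elongation (`elongate_in_silico()`) appends idealized pairs
coaxially to a terminus, anchored by superposing a reference pair step on
the two outermost base pairs; both slot directions are tried and the
better fit kept, and a superposition RMSD above 2 Å is rejected as "not a
paired region". This mimics the experimentally elongated constructs whose
alignment differs mainly through shape.

## The synthetic generator

`generate_library()` emulates the system this pipeline targets: two
idealized A-form helices joined by a 1–7 nt bulge. Defaults (the study
conditions for all tests and acceptance checks):

* a TAR-like construct — 4-bp helices, 3-nt pyrimidine bulge (UCU);
* a bimodal bend-magnitude mixture: a narrow stacked mode
  (15° ± 8°, weight 0.45) and a broad kinked mode (75° ± 20°, weight
  0.55), the classic two-state picture of bulge junctions; twist jitter
  15°; bend direction uniform;
* bulge C2'-endo probability 0.5 per residue (unpaired pyrimidines sample
  both puckers roughly evenly);
* extra-helical flip probability coupled to coaxiality: 0.9 when the
  sampled bend is linear (< 45°), 0.35 otherwise — flipping out makes room
  for helix stacking;
* 2 Hz Gaussian coupling noise in `simulate_rdc_dataset()`, the typical
  experimental uncertainty, with per-construct alignment tensors and scale
  factors standing in for experimental elongation.

Numerical choices worth knowing:

* The hinge of the bend sits on the strand-2 backbone — the strand that
  runs uninterrupted across the junction — so bending opens the helices
  like a book instead of folding one body through the other; bent
  junctions additionally open by $2\sin(\beta/2)$ Å along the upper axis.
* Bulge nucleotides detour around the junction on an outward arc, fanned
  azimuthally; flipped-out residues sit at 13 Å from the axis, flipped-in
  at 10 Å. The bulge backbone is placed analytically with a heavy-atom
  clash check (1.5 Å tolerance) rather than by fragment assembly: the
  downstream mathematics needs plausible, not physical, geometry.
* Bend and pucker draws are made once per conformer and kept across clash
  retries, so rejection sampling cannot bias their distributions (this is
  verified by a Kolmogorov–Smirnov test against the specified mixture at
  n = 2000 and by pucker-population recovery to ±0.03).
* The bend mixture is truncated at 115°: beyond that the two helix bodies
  of this construct self-collide at any bend direction. The truncation
  removes well under 1% of the default mixture's mass.
* Flip geometry is schematic: the extra-helical *flags* returned as truth
  are exact, but geometric re-detection of flipped-in middle residues is
  conservative, since an intra-helical 3-nt bulge cannot have all members
  stacking on the closing pairs.

What passing tests on this generator do **not** show: real conformer
libraries contain correlated, physically relaxed geometries, sequence
dependent stacking, and non-canonical pairing that the generator does not
model, and real RDC errors are not exactly Gaussian. The generator
validates the *machinery* (prediction, selection, cross-validation,
analytics) under known truth, not force-field realism.

## Problem sizes and runtimes

The shipped tests and the acceptance script run desk-scale versions of
every experiment: 200-conformer libraries with 4-member truths and
3 constructs × 40 records for recovery (10 repeats), $2\times 10^5$
annealing steps per selection, 2000-conformer libraries for distribution
checks, and 8,000-orientation grids against 22,500-orientation brute-force
references for the steric model. These sizes were chosen so the full suite
completes in minutes on one CPU while keeping every statistical margin
(binomial ±0.03 bands, KS at α = 0.01) meaningful.

## Known limitations

* The steric obstruction model is a planar/rod approximation with a
  calibrated spacing constant; it reproduces shape-driven alignment
  orientation well but absolute magnitudes only up to the per-construct
  scale factor.
* Energies are metadata: the package filters on them
  (`filter_library()`) but never computes them.
* No Bayesian or maximum-entropy reweighting of the selected ensemble;
  selection is hard (equiprobable members), as in the sample-and-select
  tradition.
* The configuration format for the command line is YAML.

## A worked miniature

```{r example, eval = FALSE}
model <- junction_model(seed = 7)
lib <- generate_library(model, 200)
set.seed(1)
members <- sort(sample.int(200, 4))
tensors <- rdcens:::random_tensors(3)
truth <- simulated_truth(members, tensors, noise_sd = 2)
ds <- simulate_rdc_dataset(lib, truth, seed = 2)
mat <- precompute_matrix(lib, ds, mode = "fixed-tensor", tensors = tensors)
res <- sas_select(mat, ds, sas_config(ensemble_size = 4, seed = 3))
res$rmsd_hz  # ~2 Hz: the noise floor
crossval_random(mat, ds, sas_config(ensemble_size = 4, seed = 3))
```
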