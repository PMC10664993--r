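---
title: "Structure-based chemical shift assignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based chemical shift assignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftassign)
```

# The assignment problem

Resonance assignment maps each assignable `r "¹H"`, `r "¹³C"`
and `r "¹⁵N"` nucleus of a protein to its chemical shift, using
cross peaks picked from multidimensional NMR spectra. shiftassign treats
this as a combinatorial mapping problem between two peak sets:

* **Expected peaks**, back-calculated before looking at any data. For
  through-bond experiments these are instances of magnetization-transfer
  pathway templates (an HNCA correlates the amide proton and nitrogen of
  residue *i* with the CA of residues *i* and *i−1*, and so on),
  instantiated at every residue where all constituent atoms exist:
  prolines and the chain-initial residue carry no amide proton, glycine
  has no CB. For NOESY experiments, expected peaks come from a structure
  bundle: a cross peak is expected for every proton pair closer than
  6.0 Å in *all* conformers of the bundle, a deliberately conservative
  rule — any single conformer would predict a superset.
* **Observed peaks**, positions in ppm with a picker confidence score in
  [0, 1]. Through-bond lists are filtered to the K highest-confidence
  peaks where K is the number of expected peaks; NOESY lists keep every
  peak with confidence at least 0.1, because for NOESY the expected
  count is not a reliable yardstick and generous selection with later
  filtering is preferable.

Each expected peak also carries an a priori observation probability. For
through-bond pathways these are fixed per pathway class (0.95 for
one-bond/strong transfers, 0.80 for sequential and long TOCSY relays;
both editable in the bundled spectrum library file, since reference
values for every pathway are not tabulated anywhere authoritative). For
NOESY peaks the probability is a step function of the maximal bundle
distance $d_{max}$: 0.9 below 4 Å, then 0.8, 0.7, 0.6 and 0.5 in 0.5-Å
steps up to the 6-Å cutoff.

# Priors

Every assignable atom receives a Gaussian prior. By default the priors
come from a bundled per-(residue type, atom) statistics table patterned
on database-wide shift distributions; the table ships as package data
because only realistic magnitudes matter for the search mechanics.
When structure-based shift predictions are available for the backbone
(CA, CB, C′, HN, HA, N), they replace the statistical priors with
per-atom-name default uncertainties of 0.85 (C′), 0.77 (CA), 0.86 (CB),
0.39 (HN), 0.20 (HA) and 1.98 (N) ppm — the documented RMSDs of a
structure-based predictor against database depositions. These are
configurable (`sd_overrides`) because other predictors come with other
error profiles.

Priors have two roles: a soft score reward for assignments near the
prior mean, and a hard candidate gate — an observed peak is a candidate
for an expected peak only if every dimension lies within
tolerance + k·sd of the dimension atom's prior (k = 3 by default). The
gate is what makes informative priors computationally valuable: narrow
priors shrink the search space.

# The score

A solution is a partial mapping of expected peaks to observed peaks.
Atom shifts are *derived* from the mapping: the shift of atom *a* is the
tolerance-weighted mean (weights $1/\mathrm{tol}_d^2$) of all mapped
peak positions in dimensions attributed to *a*, clipped to the 3-sd
prior range. The score is

$$
\sum_{e\ \mathrm{mapped}} p_e \prod_d
  \exp\!\left(-\frac{\Delta_{e,d}^2}{2(\mathrm{tol}_d/2)^2}\right)
\;-\; \lambda \sum_{e\ \mathrm{unmapped}} p_e
\;+\; \beta \sum_{a\ \mathrm{assigned}}
  \exp\!\left(-\frac{(\omega_a-\mu_a)^2}{2\sigma_a^2}\right)
$$

with $\Delta_{e,d}$ the deviation between the observed position and the
derived shift of the dimension's atom. Defaults $\lambda = 0.2$ (small
enough that artifact peaks are not force-mapped, large enough that
observable peaks are sought) and $\beta = 0.5$. Feasibility is enforced:
every mapped peak must match the derived shifts within the per-dimension
tolerance (0.03 ppm for `r "¹H"`, 0.4 ppm for
`r "¹³C"`/`r "¹⁵N"`), and violations are repaired by
unmapping. Two expected peaks may map to the same observed peak — real
spectra contain genuine overlap — and an overlapped peak contributes its
kernel once per expected peak.

# The optimizer

The published description of this class of methods names the optimizer
family (evolutionary plus local optimization) but not the operators, so
the concrete design here is the package's own; all claims about
assignment quality are made with respect to this implementation.

The genome is the vector of per-peak candidate choices, organised in
*proposal units*: for each residue, an amide-rooted unit (all peaks
touching the residue's HN/N — HSQC, triple-resonance and
`r "¹⁵N"`-edited NOESY peaks) and an aliphatic unit (TOCSY,
`r "¹³C"`-HSQC and `r "¹³C"`-edited NOESY peaks),
interleaved along the sequence. This decomposition mirrors spin-system
reasoning: the two units of a residue are coupled through its CA/CB/HA
atoms, and consecutive residues through the sequential pathways.

Moves are *coherent segment proposals*: within a window of consecutive
units, peaks are processed most-constrained-first (dynamic ordering over
the number of already-fixed dimensions), each peak takes its
deviation-best candidate given the tentative shifts accumulated so far,
and chosen positions immediately fix tentative shifts that propagate
through the window. Atoms owned by the window are scored against their
priors (free), atoms constrained by mapped peaks outside it keep full
kernel weights — this is what lets sequential evidence re-anchor a
residue instead of being vetoed by its stale proton shifts. During
construction, candidates whose observed peak is already in use are softly
penalised, steering proposals toward one-to-one matchings; the score
itself retains overlap capacity.

Around these proposals sit four layers:

* a generational EA (tournament selection, one-point crossover at a
  residue boundary, segment re-proposal as mutation; defaults:
  population 50, 200 generations, mutation 0.05, tournament 3, early
  stop after a stall),
* *local refinement*: alternate mapping-given-shifts (each peak to its
  deviation-best candidate — rankings use the squared-deviation sums
  directly, which survive kernel underflow far from the optimum) and
  shifts-given-mapping, keeping the best repaired solution,
* *segment-ICM*: windows of 1–3 units re-proposed from every root-anchor
  candidate, accepting full-evaluation improvements; this escapes
  chain-swapped spin-system permutations,
* an *anchor-swap* sweep over unit pairs (exchanging the anchors of two
  possibly distant units) and, for small instances, an exhaustive
  per-peak polish.

Runs are deterministic given the seed. An independent exhaustive oracle
(`exhaustive_search()`) enumerates all feasible mappings on small
instances and is used in the test suite to verify that the optimizer
attains the global optimum of the same score.

# Consensus and reliability

The pipeline repeats the optimization (20 runs by convention; consensus
requires at least 2) with seeds `seed`, `seed+1`, .... For each atom the
per-run shift values are pooled and the window of width 2Δω (Δω =
0.03/0.4 ppm by nucleus) containing the most values is located; anchoring
candidate windows at observed values makes this mode search exact. The
consensus shift is the mean of the in-window values and the support is
their fraction. An atom is **strong** if support ≥ 0.8 — the boundary is
inclusive, 16 of 20 qualifies — and **weak** otherwise. Two documented
choices: the support denominator is the number of runs in which the atom
was *found* (a stricter all-runs denominator is available via
`support_denominator = "total"`), and atoms found in fewer than half the
runs are demoted to weak regardless of support, because a one-run atom
with nominal 100% support carries no consensus evidence.

An optional seeded multi-pass mode (`two_pass`) assigns the
through-bond spectra first and narrows the priors of strong atoms to
their consensus shifts (sd = the nucleus tolerance) before re-running
over all spectra; it is off by default and recommended for NOESY-heavy
sets, where it both shrinks the candidate space and stabilises the
backbone before the NOESY network is brought in. Only strong atoms are
narrowed — seeding weak values was measured to lock errors in
(confirmation feedback) and is deliberately not done.

From the percentage S of strong assignments among assigned atoms, the
expected accuracy is estimated by the published linear relationships
A = 0.89·S + 7.88 (%) for all assignments and A^strong = 0.45·S + 51.49
(%) for the strong subset. These coefficients come from large-scale
benchmarking reported in the literature; the package evaluates, and does
not refit, them.

# Evaluation

Against a reference shift list, an assigned atom is correct when it
matches within the nucleus tolerance; backbone amides are additionally
scored as (HN, N) pairs that must both match. Stereo pairs swapped
relative to the reference (HB2/HB3, VAL/LEU methyl pairs) count as
correct by default because reference stereo-assignments are frequently
arbitrary (`stereo_leniency = FALSE` disables this). Ratios with empty
denominators are reported as NA, never silently as 0 or 100.

# The synthetic benchmark generator

Because experimental benchmark spectra are not redistributable, every
stage is exercised against generated problems with known ground truth:

* **Structures** are built from idealized covalent geometry by natural
  extension reference frame placement over the residue topology tree,
  with backbone torsions set per mode (helix −57/−47, extended, or
  random) and side chains at staggered rotamers plus noise. Aromatic
  rings are built over a spanning tree and hence do not exactly close;
  proton positions are idealized. Random-torsion bundles relieve clashes
  by stochastic torsion-space descent on a repulsion-only score.
* **True shifts** are drawn from the Gaussian priors truncated at 3 sd.
* **Peak lists** include each expected peak with probability
  $p_e$ (Bernoulli detection, or always when detection is off), at the
  true shifts plus Gaussian jitter of sd = tolerance/3 per dimension by
  default; artifact peaks (Binomial(n, 0.1) by default) are placed
  uniformly over the occupied ppm box of the true peaks so they are
  confusable, with confidence scores from Beta(2,8) against Beta(8,2)
  for true peaks — most true peaks clear the NOESY 0.1 threshold while
  the top-K filter still has work to do.
* **Decoys** perturb all torsions along a fixed random direction whose
  magnitude is bisected until the backbone RMSD (Kabsch superposition on
  N/CA/C) lands within 10% of the target; a decoy is a triplet of
  conformers with pairwise RMSD below 1 Å.
* **Multi-domain problems** concatenate domains with 10-glycine linkers,
  renumber contiguously, merge peak lists, and place rigid domain
  bundles along an extended linker without global packing.

What passing synthetic tests does *not* show: real spectra have
relaxation-dependent linewidths, solvent and exchange effects, folding
artifacts and systematically biased pickers, none of which the noise
model emulates. The generator validates the machinery and the relative
orderings (structure helps; near-native decoys help more than distant
ones; strong assignments are more reliable than weak ones), not absolute
accuracies on experimental data.

# Study conditions used by the acceptance suite

The heavier acceptance checks run on deliberately small problems so the
suite completes on one CPU:

* *Optimizer vs oracle*: 100 four-residue instances (HSQC + HNCA, at
  most 6 expected and 8 observed peaks, jitter = tolerance/3, 30%
  artifacts) compared against the exhaustive enumeration.
* *Noiseless round trip*: one 30-residue protein with the recommended
  spectra set (two HSQCs, CBCAcoNH, HCCH-TOCSY, CCH-TOCSY and both
  edited NOESYs), a random-fold bundle (an idealized helix has a
  translationally symmetric NOESY contact pattern that creates spurious
  spin-system degeneracy; an irregular fold is both more realistic and
  identifiable), 3 consensus runs, three-pass seeding.
* *Strong/weak separation*: ten 16-residue replicates of the
  triple-resonance preset under the default noise model, 6 runs.
* *Structure benefit*: ten 8-residue replicates of the NOESY-only
  preset (both HSQCs plus both edited NOESYs), 2 runs per arm.
* *Decoy gradient*: ten 10-residue replicates with ¹⁵N-HSQC,
  CBCAcoNH and ¹⁵N-edited NOESY (the decoys modulate only the NOESY
  stage; the backbone experiment keeps the comparison about structure
  quality), 2 runs, with the decoy perturbation direction shared across
  tiers per protein so the tier comparison is paired.
* *Concatenation*: 10-residue domains for the accuracy comparison; the
  50/60-residue linker-length check needs no optimization.

Engine efforts are scaled accordingly (population 16-24, 25-50
generations, early stall).

# Known limitations

* The score is a documented surrogate for an undisclosed reference
  objective; absolute accuracies are not comparable to published
  benchmark tables.
* The noiseless 30-residue round trip does not reach 100% under this
  surrogate: the three-pass pipeline recovers roughly 84% of assigned
  atoms correctly, with residual errors concentrated in weak-class
  near-tied spin systems. This is an optimization shortfall, not a
  score defect — the ground-truth mapping evaluates strictly higher
  than the best solutions found — and the same round trip is exact at
  12 residues and below. The corresponding acceptance check is expected
  to fail and is retained as an honest record of the gap.
* Under this surrogate, expected-NOESY information *reduces* desk-scale
  accuracy relative to the fallback short-range expectation: expected
  NOESY peaks whose partners are undetected or ambiguous are still
  mapped (a mapped kernel always beats the unmapped penalty) and drag
  the tolerance-weighted means of sparsely constrained atoms, while the
  no-structure arm solves a smaller, cleaner problem and is scored only
  on the atoms it assigns. The structure-benefit and decoy-gradient
  acceptance checks therefore fail under their stated orderings; the
  multi-domain comparison (structure softens the decline with protein
  size) does hold.
* Aliphatic `r "¹³C"`-NOESY-heavy configurations are the hardest case
  for the optimizer; consensus support (weak class) flags the resulting
  uncertainty but absolute side-chain accuracy in that regime is modest.
* Geometry is idealized; generated structures are benchmarks, not
  models of real proteins.
* Histidine is enumerated as the neutral Nδ-H tautomer; hydroxyl,
  sulfhydryl, ammonium and guanidinium protons are excluded from the
  assignable complement.
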