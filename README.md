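# shiftassign

Automated, structure-informed assignment of protein NMR chemical shifts
from picked peak lists — for spectroscopists and methods developers who
want a fully scriptable, reproducible assignment engine in R, together
with a ground-truthed synthetic benchmark generator that makes every
stage testable without measuring a single spectrum.

## What it does

Resonance assignment is cast as a combinatorial mapping between two peak
sets. **Expected peaks** are back-calculated before looking at data:
through-bond experiments (HSQC, HNCA, CBCA(CO)NH, HCCH-TOCSY, ...) from
magnetization-transfer pathway templates instantiated at each residue,
and NOESY experiments from a 3D structure bundle — a cross peak is
expected for every proton pair closer than 6.0 Å in *all* conformers,
with a tiered observation probability (0.9 below 4 Å, then 0.8, 0.7,
0.6, 0.5 in 0.5-Å steps). **Observed peaks** are positions with picker
confidence scores; through-bond lists keep the top-K peaks by
confidence (K = number of expected peaks), NOESY lists keep everything
with confidence ≥ 0.1.

Expected peaks are mapped onto observed peaks by a seeded evolutionary
optimization with residue-block (spin-system) proposals and local
refinement, under Gaussian shift priors (database-style statistics, or
structure-based predictions for the backbone). The objective for a
partial mapping with derived atom shifts ω is

    Σ_mapped  p_e · Π_d exp(−Δ²_{e,d} / (2 (tol_d/2)²))
  − λ · Σ_unmapped p_e
  + β · Σ_assigned exp(−(ω_a − μ_a)² / (2 σ_a²))

with per-dimension tolerances 0.03 ppm (¹H) and 0.4 ppm (¹³C/¹⁵N).
Repeating the optimization R times (20 by convention) and pooling the
per-atom values yields a consensus: an atom is **strong** when at least
80% of its values fall in a window of ± the nucleus tolerance, else
**weak**. From the strong percentage S, the expected accuracy follows
the published linear estimators A = 0.89·S + 7.88 (%) and
A_strong = 0.45·S + 51.49 (%).

The synthetic module generates complete benchmark problems: idealized
structures (helix/extended/random; multi-conformer bundles), true shifts
drawn from the priors (magnetically equivalent protons share one
resonance), noisy peak lists with detection losses and confusable
artifact peaks, decoy bundles bisected to a target backbone RMSD, and
multi-domain concatenations with 10-glycine linkers.

## A worked example

```r
library(shiftassign)

# a complete synthetic problem: 12 residues, triple-resonance spectra,
# noiseless (full detection, no jitter, no artifacts)
prob <- synthetic_problem(12, spectra = dataset_preset("triple"),
                          noise = noise_model(position_jitter = 0,
                                              detection = FALSE,
                                              artifact_rate = 0),
                          seed = 11)

res <- assign_shifts(prob$sequence, prob$peaks,
                     reference = prob$reference, runs = 3,
                     params = engine_params(seed = 5, generations = 50,
                                            population_size = 20))
res
#> <shift_assignment> 3 runs, 55 atoms assigned (54 strong)
#>   S = 98.18%  estimated A = 95.26%  A_strong = 95.67%
#> Assignment evaluation (percent):
#>   Correct (strong) 100.00  Completeness (strong)  37.50  Strong  98.18
#>   Correct (weak)     0.00  Correct (all)         98.18
```

Fifty-four of 55 assigned atoms were found consistently across the runs
(S = 98.2%) and every one of them matches the ground truth
(`Correct (strong) = 100`). The single atom on which the runs disagreed
was demoted to weak — and it is indeed the one wrong assignment, which
is exactly the reliability separation the strong/weak classification is
for. From S alone, the estimator predicts 95.3% expected overall
accuracy. Completeness is modest simply because backbone spectra touch
only part of the proton network. `tidy(res)` returns the consensus
shift table, `glance(res)` the one-row summary, and
`autoplot(res$consensus)` the per-residue support display.

File-based workflows use XEASY/Sparky peak lists, FASTA or numbered
sequences, multi-MODEL PDB bundles, prot-style or NMR-STAR shift tables,
and a flat `key = value` config (`assign_from_config("run.cfg")`); a
thin CLI (`exec/shiftassign`) wraps the same functions with
`assign`, `expect`, `simulate`, `perturb` and `evaluate` subcommands.

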