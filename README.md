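# reaxplore

Guided discovery of chemical reaction pathways by **imposed activation** of a
single internal coordinate.

## The problem

Predicting how a given set of reactants can react — without assuming the
products or the mechanism — is one of the hard open problems of computational
chemistry. Brute-force dynamics cannot bridge the ~15 orders of magnitude
between bond vibrations (fs) and reaction half-lives (seconds or more), and
exhaustive coordinate driving over all atom pairs scales quadratically with
system size. `reaxplore` implements a guided middle road for computational
chemists who know *which bond (or angle) is labile* but not *what happens
when it breaks*: constrain that one activating coordinate q‡ at
out-of-equilibrium values, let biased dynamics explore every conformation the
activated species can adopt, and push each of them over the hill with relaxed
scans.

## The method

The workflow has four steps, repeated over a grid of activation values q‡ᵢ:

1. Optimize the reactants, measure the equilibrium value q‡₀ of the
   user-chosen activating coordinate (a distance, bending angle, or torsion),
   and build a reference conformer ensemble at q‡₀.
2. Run a conformer search with q‡ held at q‡ᵢ > q‡₀: molecular dynamics
   augmented with a history-dependent bias
   V(x) = Σᵢ k·exp(−α·Δᵢ²),
   where Δᵢ is the minimized (Kabsch) RMSD to the i-th stored snapshot — the
   bias repels the system from everywhere it has already been, so orthogonal
   conformational space fills in fast. Snapshots are optimized under the
   constraint and pruned to distinct *activated conformers* by joint RMSD /
   energy / rotational-constant thresholds plus an energy window.
3. From every activated conformer, scan q‡ forward to the maximal value q‡_N
   (toward products) and backward to q‡₀ (back to a reactant conformation),
   each step a constrained minimization warm-started from the last. Stitching
   both legs gives a full reactant→product trajectory.
4. Convert the trajectory's energy minima to canonical SMILES (Open Babel);
   consecutive minima with different strings are a reaction event whose
   transition-structure guess is the highest-energy frame between them. Over
   all trajectories, each reaction's barrier is estimated as
   ΔE‡ = E(best TS guess) − E(most stable reactant conformer).

The energy engine is pluggable: anything that returns an energy and gradient
for a 3-D structure. The package ships a pairwise-Morse toy reactive force
field plus brute-force grid oracles (watershed saddle search on dense 2-D
grids), so the *entire* pipeline runs and is verified end-to-end without any
external software; `external_engine_backend()` drives a real semi-empirical
engine through exchange files when you have one.

## Worked example

A collinear exchange toy reaction F–Cl + Br → F + Cl–Br on the built-in Morse
surface, with the F–Cl distance as activating coordinate. The fixture carries
its own grid-oracle saddle, so the workflow's estimate can be checked against
an independent brute-force answer:

```r
library(reaxplore)

sys <- make_collinear_exchange(asymmetry = 0.2, oracle_n = 80)
sprintf("oracle saddle: %.2f kcal/mol above the reactant well", sys$barrier_kcal)
#> "oracle saddle: 64.48 kcal/mol above the reactant well"

cfg <- run_config(sys$geometry, sys$coordinate, sys$backend,
                  multiplicity = 2L, stretch_factors = c(1.2, 1.35, 1.5),
                  budget = 12L, seed = 42L)
report <- run_iacta(cfg)
print(report)
#> <run report: 1 reactions from 12 trajectories (13.9 s)>
#>   reactant_smiles product_smiles count dE_act_kcal dE_rxn_kcal
#> 1        [Br].FCl       [F].ClBr    12    64.09572   -18.64511
```

Reading the output: the table has one row per discovered reaction, keyed by
canonical reactant/product SMILES (fragments dot-joined). All 12 trajectories
found the halogen exchange; its estimated activation energy (64.1 kcal/mol)
agrees with the independent grid-oracle saddle (64.5 kcal/mol) to well under
1 kcal/mol, and the reaction energy (−18.6 kcal/mol) reflects the
deliberately deeper product well of this asymmetric fixture. With
`outdir = ...` the run also writes `reactions.csv`/`reactions.json`, the best
transition-structure guess per reaction as XYZ, the equilibrium ensemble, and
`report.json`.

A command-line wrapper with the same knobs lives in
`inst/scripts/reaxplore-run.R` (atom indices are 1-based; run with
`--help` for details).

## Scope and limits

The toy force field supports bond breaking/forming but makes no quantitative
claim about real chemistry; transition-structure guesses are trajectory
maxima, not verified saddle points (no NEB/IRC); SMILES carry constitution
only, not stereochemistry. See the methods vignette
(`vignettes/reaction-discovery.Rmd`) for the model assumptions, parameter
choices, and numerical details.
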