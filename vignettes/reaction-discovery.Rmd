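---
title: "Reaction discovery by imposed activation: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction discovery by imposed activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reaxplore)
```

## The model

`reaxplore` searches for reaction pathways by *imposing* chemical activation:
one internal coordinate q‡ — a bond distance, bending angle, or torsion that
the user believes initiates the chemistry — is constrained at values between
the reactant equilibrium q‡₀ and a maximal value q‡_N, while all orthogonal
degrees of freedom are sampled and relaxed freely. The activated species at a
stretched q‡ᵢ is highly reactive; which product it falls into depends almost
entirely on its conformation. The workflow therefore alternates two engines:

* **Constrained metadynamics** explores the conformations of the activated
  species. Molecular dynamics (velocity Verlet, Berendsen thermostat) run on
  the backend potential plus a history-dependent bias
  V(x) = Σᵢ k·exp(−α·Δᵢ²), where Δᵢ is the minimized all-atom RMSD between
  the current structure and the i-th stored snapshot. Each deposited kernel
  makes revisiting a known conformation cost ~k, so the simulation is pushed
  into new territory; the activating coordinate itself is held near q‡ᵢ by a
  stiff harmonic restraint.
* **Relaxed scans** drive each distinct activated conformer along q‡: forward
  to q‡_N (toward products) and backward to q‡₀ (back to a reactant
  conformation). Each scan frame is a constrained local minimum warm-started
  from the previous frame, so the stitched trajectory is a connected,
  energy-tagged reactant→product path.

Post-processing is purely geometric and graph-based: trajectory energy minima
are re-optimized without constraints, converted to molecular graphs by a
covalent-radius bond rule (bond iff d ≤ 1.2·(r_cov(A)+r_cov(B))), and
canonicalized to SMILES with Open Babel. A change of SMILES between
consecutive minima is a reaction event; the transition-structure guess is the
highest-energy frame strictly between the two minima. Aggregating events over
all trajectories gives, per reaction, an occurrence count, the lowest-energy
transition-structure guess, and the estimated activation energy
ΔE‡ = E(best TS) − E(most stable conformer of the equilibrium ensemble).

Two modeling assumptions are worth making explicit. First, ΔE‡ is a
*trajectory-maximum* estimate: it upper-bounds the barrier along the
discovered path but is not a verified first-order saddle (no eigenvector
following, NEB, or IRC — those belong to a refinement stage outside this
package's scope). Second, using one global reactant reference means barriers
of different reactions are directly comparable, at the cost of including the
conformer-selection energy in each estimate.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `stretch_factors` | 1.1, 1.2, 1.3, 1.5 | × q‡₀ | activation grid spanning mild to strong activation of a bond |
| `qmax_factor` | 2.5 | × q‡₀ | beyond ~2.5× a typical bond is fully broken on any reasonable potential |
| `scan_step` | 0.1 Å / 5° | — | resolves barrier tops to ≲ step²·curvature/8 without wasting minimizations |
| `k_per_atom` | 0.002 | Hartree/atom | kernel height; scaling with N keeps the per-mode push roughly size-independent |
| `alpha` | 0.8 | Å⁻² | kernel width ~1 Å in RMSD space: wide enough to merge vibrational noise, narrow enough to separate conformers |
| `snapshot_interval` | 25 | fs | a few vibrational periods between kernels, so deposits are decorrelated |
| `temperature` | 300 | K | room-temperature sampling of the orthogonal space |
| `timestep` | 0.5 | fs | stable for the stiff toy Morse bonds (periods ≳ 25 fs) |
| `tau` (Berendsen) | 50 | fs | weak coupling; fast enough to absorb bias-injected heat |
| `md_time_per_atom` | 0.05 | ps/atom | total metadynamics time grows linearly with system size, as larger systems have proportionally more conformational space; the equilibrium (step 1) search runs 2×, the per-q‡ᵢ searches are deliberately shorter |
| `md_restraint_k` | 10 | Hartree/Å² | against thermal forces a soft spring would let q‡ drift; 10 keeps fluctuations ≤ 0.05 Å at 300 K |
| `rmsd_thr`, `energy_thr`, `rotconst_rel_thr` | 0.125 Å, 0.05 kcal/mol, 1% | — | conformer-duplicate rule: all three must agree; standard conformer-ensemble practice |
| `ewin` | 35 | kcal/mol | activated conformers more than ~35 kcal/mol above the best are not competitive starting points at ordinary temperatures |
| `budget` | 100 | trajectories | hard cap; trajectories are embarrassingly parallel and seeded individually |

All defaults are surfaced in `run_config()` and echoed into `report.json`.

## Numerical choices

**Constrained minimization.** Engine-agnostic constraint handling cannot rely
on an engine's native constraint input, so constraints are enforced in the
optimizer itself. A plain stiff harmonic restraint was rejected: at a
penalized minimum the residual is |F|/k, so a restraint soft enough to keep
L-BFGS well-conditioned (k ≈ 1 Hartree/Å²) leaves ~0.1 Å error on a stretched
Morse bond, while a restraint stiff enough for 0.01 Å wrecks the line search.
Instead the working objective is an augmented Lagrangian (multiplier updates
between L-BFGS-B descents, stiffness escalated tenfold whenever the residual
stalls), followed by exact Newton projection of the constrained coordinate
onto its target along the coordinate Jacobian. Convergence is declared on the
gradient component *orthogonal* to the constraint Jacobians
(`gtol` = 5·10⁻⁴ Hartree/Å, common semi-empirical practice), and constraints
end up satisfied to machine precision — which is what lets a relaxed scan of
a Morse diatomic reproduce the closed-form profile to 10⁻⁶ Hartree. The
reported energy is always the pure backend energy.

**Coordinate Jacobians** (d q/d x) are central finite differences of the
measurement function (h = 10⁻⁵ Å); on these smooth coordinates that is
accurate to ~10⁻⁹ and avoids hand-maintained angle/dihedral derivative code.
Dihedral differences are wrapped to (−180°, 180°] everywhere.

**RMSD and its gradient.** Superposition uses the Kabsch algorithm
(all atoms, unweighted, fixed atom order — snapshots track atom identity, so
permutation matching would be wrong; a heavy-atom-only flag exists). The bias
gradient uses the envelope theorem: with the rotation optimal,
∂RMSD/∂xᵢ = (x′ᵢ − R y′ᵢ)/(N·RMSD) on centered coordinates. The RMSD gradient
is singular at Δ = 0; below 10⁻⁶ Å a zero gradient is returned, consistent
with the kernel chain rule k·e^{−αΔ²}·(−2αΔ) vanishing there.

**Rotational constants** come from the eigenvalues of the standard-mass
inertia tensor; a principal moment below 10⁻⁸ amu·Å² (linear molecule) is
reported as an `Inf` sentinel and excluded from duplicate comparisons.

**Non-converged scan frames** are kept and flagged rather than aborted:
dropping whole trajectories would bias discovery against exactly the strained
regions where convergence is hardest. Rows of the reaction table whose best
TS frame is flagged are marked `approximate`.

**Pruning order.** Snapshots are re-optimized under the constraint *before*
duplicate comparison (structures fresh off thermostatted MD are all
"distinct" at any sensible RMSD threshold). Within a duplicate class the
lowest-energy member wins; exact energy ties keep the earlier-indexed
snapshot, making pruning deterministic and order-independent up to duplicate
classes.

**Determinism.** Every stochastic step derives its seed from the master seed
and the (activation index, conformer index) pair, below 2³¹. Two runs with
the same configuration write byte-identical reaction tables, and trajectories
can be farmed out process-parallel without changing results.

**Degenerate inputs** fail loudly: coincident atoms in an angle/dihedral
definition, mismatched element sequences in superposition, a declared XYZ
atom count that disagrees with the file, and Morse evaluation on an element
pair without parameters are all explicit errors, never NaN.

## The synthetic test systems and what they do (not) show

The package must be testable end-to-end without an external engine, so the
`synthetic` module provides systems whose answers are known by brute force:

* `make_collinear_exchange()` builds A–B + C → A + B–C on a pairwise-Morse
  surface. A sum of purely attractive Morse terms has *no* exchange barrier
  (the doubly-bonded central structure is a well), so the A···C pair carries
  a Morse term with a large equilibrium distance that is strongly repulsive
  over the reactive region — still exactly the pairwise-Morse functional
  form, but now with two wells and one saddle. A and C are distinct elements
  so the exchange is visible in SMILES.
* `grid_saddle_oracle()` finds that saddle independently of all optimizer and
  dynamics code: dense-grid evaluation of the closed-form collinear energy,
  watershed flooding in ascending energy order (the merge energy of the two
  basins is the lowest maximum over all grid paths), Newton polish on the
  analytic surface with a Hessian-signature check, and a mandatory 2×
  refinement agreement of 0.1 kcal/mol. Base resolution 160² (refined 320²)
  resolves the toy saddles to ≪ 0.1 kcal/mol in a few seconds.
* `make_torsion_chain()` is a 4-atom chain whose 1–4 Morse term carves two
  mirror-image torsional wells — the minimal system on which biased sampling
  demonstrably escapes a well that plain low-temperature MD cannot leave.
* `muller_brown()` is the standard 2-D optimizer testbed (three minima, two
  saddles). The frozen-coordinate check of the constrained optimizer is run
  on the collinear system against a dense 1-D grid instead, since freezing a
  Cartesian axis is not expressible as an internal-coordinate constraint.

The acceptance workflow runs the three exchange systems (symmetric, and
product wells deepened by 20% and 40%) at 12 trajectories each over
activation factors {1.2, 1.35, 1.5}; the full-pipeline barrier estimates land
within 1 kcal/mol of the grid-oracle saddles, and the reaction tables contain
exactly the exchange reaction.

What passing these tests shows: every stage of the machinery — constrained
optimization, biased sampling, pruning, scanning, stitching, SMILES-based
event detection, aggregation arithmetic — is individually and jointly
correct against independent references. What it does not show: anything
quantitative about real chemistry. The toy surfaces are 3–4 atoms with clean
single saddles; real systems have soft modes, competing channels, flat
ion-pair regions, and engine-specific convergence behavior. In particular,
discovery completeness (does the sampling find *all* low-barrier channels?)
is only meaningfully testable with a real engine on real molecules.

## Open design decisions, as resolved here

* **All-atom vs heavy-atom RMSD** for bias and pruning: all-atom by default
  (hydrogen motion distinguishes genuinely different conformers such as
  mirror gauche wells), with `heavy_only` available.
* **Pruning before or after re-optimization:** after; raw MD snapshots are
  never compared directly.
* **Which minima to compare for reaction detection:** consecutive trajectory
  minima, not endpoints-only — multi-step cascades then appear as chains of
  events rather than one lumped transformation.
* **Ion handling in SMILES:** total charge is distributed by a valence-rule
  pass (electronegativity-ordered for anions, over-coordination-ordered for
  cations). When the heuristic cannot place the full charge, a deterministic
  charge-annotated formula string is used and the fallback is logged. This
  keeps charged species comparable without a full formal-charge model.
* **Metal complexes:** `drop_metals` deletes d-block atoms before graph
  construction, preventing spurious bond-change events around a metal center
  whose coordination sphere fluctuates; the metal set is configurable.
* **Tautomer/protonation-state enumeration** is intentionally not automated;
  alternative protonation states are separate runs.

## Known limitations

Transition-structure guesses are not verified saddle points. The bias kernel
buffer is capped (default 100 kernels; sampling continues but stops learning
beyond the cap). The restraint-based constraint can, on very flat surfaces,
admit slow drift orthogonal to q‡ during MD. Bond perception is a fixed
radius rule with no bond orders; SMILES therefore track constitution only.
The external-engine adapter assumes a file-based, subprocess-callable engine
and parses a simple text gradient format; engine-version differences in
energetics are outside the package's control and should be recorded with run
artifacts (`report.json` echoes the resolved configuration for exactly this
reason).
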