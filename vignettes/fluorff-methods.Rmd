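---
title: "Models and methods in fluorff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fluorff}
  %\VignetteEncoding{UTF-8}
---

`fluorff` is a pipeline for benchmarking a class-I molecular-mechanics
force field against a reference potential, retuning its bonded parameters,
and scoring the result energetically (relative conformer energies),
geometrically (superposition RMSD) and in terms of sampling (conformer
populations and population-averaged NMR observables). This vignette
documents the models, the tunable parameters, the numerical choices, and
the design decisions that were genuinely open.

## The energy model

The potential is the standard class-I (AMBER-type) form: harmonic bonds
$K_b (r - r_\mathrm{eq})^2$ and angles
$K_\theta (\theta - \theta_\mathrm{eq})^2$, a cosine torsion series
$\tfrac{V_n}{2}\left[1 + \cos(n\phi - \gamma_n)\right]$, 12-6
Lennard-Jones and Coulomb terms over all non-excluded intramolecular
pairs. Conventions that the printed functional form leaves open were fixed
as follows:

* **Torsion amplitude.** The torsion term carries the conventional factor
  $V_n/2$; GAFF-style parameter sets assume it, so amplitudes read from
  such sets keep their meaning.
* **Nonbonded combination and scaling.** Lorentz–Berthelot combination
  (arithmetic-mean $\sigma$, geometric-mean $\epsilon$); atoms one or two
  bonds apart are excluded; atoms three bonds apart (1-4 pairs) are scaled
  by 0.5 (LJ) and $1/1.2$ (Coulomb) — the AMBER defaults.
* **Units.** kJ/mol, Å, radians internally and degrees at every
  user-facing torsion interface; charges in e with the Coulomb prefactor
  $k_e = 1389.3546$ kJ mol⁻¹ Å e⁻²; $k_B = 8.3144621 \times 10^{-3}$
  kJ mol⁻¹ K⁻¹. Masses are in amu, which makes the internal MD time unit
  $\sqrt{\text{amu}\,\text{Å}^2/(\text{kJ/mol})} \approx 100$ fs; time
  steps are supplied in fs and converted.
* **No cutoffs.** The targets are small gas-phase molecules, so all
  intramolecular nonbonded pairs are summed exactly. Periodic boundary
  conditions, PME and solvent boxes are out of scope.
* **Torsion range.** Signed IUPAC torsions in $[-180°, 180°)$, with the
  anti boundary reported as $-180$. Collinear central bonds raise a
  degenerate-geometry error rather than returning an arbitrary angle.

Forces are fully analytic (including the torsion inner-atom terms) and are
validated against central finite differences in the test suite.
`minimize_conformation` wraps L-BFGS-B on the analytic gradient and
enforces a force max-norm tolerance (default $10^{-4}$ kJ/mol/Å),
restarting the optimizer up to five times before returning the best
iterate with a warning.

## RESP charge fitting

Charges are fit to electrostatic potentials sampled on shells around the
molecule. The multiconformational fit stacks one block of rows
$A_{mi} = k_e/|r_m - x_i|$ per conformation into a single least-squares
system. Each restrained stage minimizes

$$\lVert A q - b \rVert^2 + a \sum_{j \in \text{varying}}
\left(\sqrt{q_j^2 + b^2} - b\right)$$

subject to an exact total-charge constraint and within-group equality
constraints, solved by iteratively reweighted least squares on the KKT
system (the hyperbolic penalty is majorized by its tangent quadratic, so
the objective is non-increasing across reweighting iterations;
convergence when $\max|\Delta q| < 10^{-6}$ e, 200-iteration cap).

Design choices where the protocol is conventionally under-specified:

* The fit operates on the *Coulomb-normalized* system ($A$ and $b$ divided
  by $k_e$), so the design matrix is $O(1)$ and the restraint scales
  $a = 0.01$ (stage 1) and $0.001$ (stage 2) are dimensionally consistent
  with charges in e, comparable to conventional RESP restraint strengths.
* The hyperbolic width is $b = 0.1$ e (the standard choice).
* Stage 2 refits only the declared symmetry-equivalent atoms, equal within
  each group, with every other atom frozen at its stage-1 charge — the
  standard two-stage protocol.

Fitted charges carry two caveats demonstrated by the tests: recovery of
generating charges is exact only as the restraint vanishes or the grid
becomes dense (the restraint bias scales like $a/M$ for $M$ grid rows),
and buried atoms in larger molecules are genuinely ill-determined by
ESP data, so their restrained charges can deviate visibly from the
generating values. Both are properties of RESP itself, not artifacts.

## Samplers

`hmc_chain` is standard hybrid Monte Carlo: full momentum refresh from the
Maxwell distribution, `n_leapfrog` velocity-Verlet steps, Metropolis test
on the total-energy change. `nmcmc_run` nests it: the inner chain advances
the cheap potential at $T_\mathrm{low}$, and every `switch_period` moves
the current inner state $x'$ is proposed against the last accepted outer
state $x$ with acceptance

$$\min\left\{1, \exp\left(-\frac{U_\mathrm{high}(x') -
U_\mathrm{high}(x)}{k_B T_\mathrm{target}} + \frac{U_\mathrm{low}(x') -
U_\mathrm{low}(x)}{k_B T_\mathrm{low}}\right)\right\},$$

and on rejection the inner chain is reset to $x$. The reset is what makes
the promoted ensemble exactly follow
$\exp(-U_\mathrm{high}/k_B T_\mathrm{target})$: the inner chain then
behaves as a reversible proposal mechanism with ratio
$\pi_\mathrm{low}(x')/\pi_\mathrm{low}(x)$. The two-temperature correction
above is the natural generalization of the equal-temperature nested rule
to a boosted inner chain; at $T_\mathrm{low} = T_\mathrm{target}$ and
identical potentials it cancels exactly, which the tests assert as an
identity. Correctness is checked two ways: moment agreement with analytic
canonical variances on harmonic wells, and histogram total-variation
agreement with an independent random-walk Metropolis chain on a double
well.

Sampler defaults mirror a realistic small-molecule setup — 100 leapfrog
steps of 1 fs, $T_\mathrm{low} = 350$ K against a 300 K target,
$2.5\times 10^4$ sweeps — but all scales are settings, and the packaged
benchmark runs far smaller (below). All randomness flows through the
`seed` field, making every run bit-reproducible.

## The reparametrization objective

Bonded parameters are retuned by minimizing $X_U + \Theta$ with

$$X_U = \frac{\sum_i \omega_i\,(U_i^\mathrm{ref} - U_i^\mathrm{MM} -
\bar\Delta)^2}{\mathrm{Var}(U^\mathrm{ref})}, \qquad
\Theta = \alpha \sum_m \frac{(p_m - p_m^0)^2}{\gamma_m^2}.$$

$\bar\Delta$ is the $\omega$-weighted mean of
$U^\mathrm{ref} - U^\mathrm{MM}$, which makes $X_U$ exactly invariant to
constant shifts of either energy column; $\mathrm{Var}(U^\mathrm{ref})$ is
the unweighted population variance of the reference energies. Open choices
and their resolutions:

* **$\alpha$.** Set to $1/N_p$ (the number of optimizable parameters), so
  the prior term is an average rather than a sum and does not grow with
  parameter count; configurable.
* **Weights $\omega_i$.** Uniform by default; `training_set()` accepts any
  weight vector so alternative (e.g. non-Boltzmann reweighting) schemes
  can be plugged in.
* **Prior widths $\gamma_m$.** Per-type defaults chosen as "a sizable but
  physical excursion": 400 kJ/mol/Å² (bond $K$), 0.05 Å ($r_\mathrm{eq}$),
  100 kJ/mol/rad² (angle $K$), 0.1 rad ($\theta_\mathrm{eq}$), 8 kJ/mol
  (torsion $V$), $\pi/2$ (phases). All overridable per fit.
* **Phases.** Excluded from the mask by default; when enabled they are
  wrapped into $[0, 2\pi)$ and a warning is raised if a final phase leaves
  $\{0, \pi\}$, since such phases break the energetic equivalence of
  mirror-image conformers.

Numerically, the optimizer works in prior-scaled coordinates
$(p - p^0)/\gamma_m$ (so all directions are $O(1)$), bounds force
constants at zero, and uses L-BFGS-B with numerical gradients of the
closed-form objective: internal coordinates of the training conformations
and the fixed nonbonded energies are precomputed once, after which each
objective evaluation is a few small matrix products. Relative-objective
tolerance $10^{-8}$.

Identifiability matters for interpreting recovery tests: torsion
amplitudes of several dihedrals sharing one central bond and multiplicity
are linearly degenerate (only their sum is determined), so exact
per-parameter recovery is asserted on a bare 5-atom chain where every
central bond carries a single torsion.

## Conformers, populations, observables

Rotamer labels use the half-open 120° intervals with g+ centered at 60°,
t at 180° and g− at −60°; input angles are wrapped into $[-120°, 240°)$,
so the three preimages exactly partition the circle (e.g. both 240° and
−120° label g−). Conformer keys are `chi phi (psi)` for monofluoro
species, `chi phi1 phi2 (psi)` for difluoro, `chi (psi)` for trifluoro.
Because the difluoro key admits two printed orderings, keys are
canonicalized to the lexicographic minimum of the pair, which merges
symmetric assignments; any fixed deterministic tie-break would do, and
this one needs no extra state.

Boltzmann populations are $p_i \propto \exp(-\Delta G_i / RT)$; the
minimum free energy is subtracted first, so adding a constant to all
entries is exactly neutral and overflow is impossible. SAEP compares two
population tables over the *union* of their keys with zero fill — needed
because a model may sample conformers the reference never visits — and is
bounded by 2. Superposition RMSD removes centroids and solves the optimal
rotation by SVD with the determinant-corrected sign, so reflections are
excluded and chirality is preserved. The intramolecular-hydrogen-bond flag
uses a donor-H–acceptor distance threshold, default 2.5 Å, configurable
since no universal geometric criterion exists.

J-coupling comparison follows the sign conventions of the packaged
13-coupling table: experimental magnitudes are signless, so model-vs-
experiment statistics compare $|J_\mathrm{calc}|$ with the experimental
magnitude whenever any record's sign is undetermined, while
model-vs-model comparisons are signed. The magnitude convention is not a
guess: the test suite shows it reproduces every published summary
statistic of the table to the printed two decimals.

## What the synthetic data does and does not emulate

The generator stands in for the expensive reference machinery so that
every stage has checkable ground truth:

* **Toy molecules** (`make_toy_molecule`) reproduce the *connectivity
  pattern* of γ-fluorohydrins — hydroxyl head, carbon backbone, F
  substituents, three role torsions — with generic but physically ordered
  parameters. They are not chemically accurate fluorohydrins; bond
  lengths, charges and LJ parameters are plausible class-I values, nothing
  more.
* **The surrogate reference** perturbs the base force field's constants
  smoothly (fixed $U(-1,1)$ draws per term, scaled) and adds a cubic
  bond-stretch term. The cubic term is deliberately *outside* the class-I
  functional form, so retuning faces the same structural limitation a real
  force field faces against an ab initio surface: the tuned parameters
  improve $X_U$ but cannot drive it to zero. This yields the qualitative
  base-worse-than-tuned ordering without claiming the reference physics.
* **Dihedral trajectories** draw conformer keys from declared weights and
  role torsions from von Mises wells at (60°, 180°, −60°). The
  concentration default $\kappa = 16$ keeps the mass a torsion places
  outside its 120° assignment window at about $3\times 10^{-5}$, so
  realized key frequencies converge to the weights at the binomial rate
  with negligible leakage bias even at $10^5$ frames. Frames are built by
  rigid rotations about the role bonds (processed outermost-first so all
  rotation axes can be precomputed); everything else about the geometry is
  frozen, unlike a physical trajectory.
* **ESP grids** are exact point-charge potentials on shells at 1.4–2.0
  times the van der Waals radii — no quantum electron density, so RESP
  recovery tests probe the fitting machinery, not charge physics.

Consequently, passing tests demonstrate the *correctness of the
machinery* — samplers target what they claim, the optimizer recovers
recoverable parameters, the metrics compute their definitions — but say
nothing about how well any real force field reproduces any real quantum
reference. Published numbers that require external DFT or neural-network
potentials (acceptance-rate magnitudes on real molecules, real ΔΔE/SAEP
distributions, minimized-geometry RMSD tables) are out of scope by
construction; only their procedures are implemented.

## Benchmark problem sizes

`run_benchmark` chains every stage on the toy system. Its defaults — 800
nested-sampler sweeps of 12 leapfrog steps, a 120/240 train/test split,
400-move population chains, 400-point ESP grids — are chosen so a full
run takes well under a minute on one CPU while every stage still has
enough data to exhibit its expected behavior (hMC acceptance near 1,
switch acceptance well above 0, tuned test-set $X_U$ below the base
value). A production-scale study would raise these by two to three orders
of magnitude; nothing in the code depends on the scale.

## Known limitations

* Gas-phase intramolecular energetics only: no solvent, no periodic
  systems, no long-range electrostatics machinery.
* The reparametrization optimizer is a local quasi-Newton method with a
  prior anchored at the starting parameters; like any such scheme its
  solution depends on the initial guess.
* RESP charges for buried atoms are ill-conditioned by nature; the
  restraint resolves the degeneracy but biases those charges toward zero.
* `ensemble_average_j` requires a coupling value for every populated
  conformer and fails loudly otherwise; it does not extrapolate.
* The samplers are plain R loops over closure calls — ample for the toy
  systems and 1-D analytic checks they serve, but not tuned for large
  molecules.
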