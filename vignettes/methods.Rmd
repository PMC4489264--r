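---
title: "Methods: the elastic-network model, mutation scoring and ensemble sampling in cgnma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the elastic-network model, mutation scoring and ensemble sampling in cgnma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgnma)
```

# The model and its assumptions

`cgnma` performs normal mode analysis (NMA) on a coarse-grained elastic
network: one node per residue at the CA position, pairwise Hookean springs
at the equilibrium distances, uniform masses. The harmonic approximation
is taken around the input structure, which is assumed to be a (near-)
equilibrium conformation; the analysis says nothing about barrier
crossings or unfolding, only about the curvature of the energy landscape
at the minimum.

Two spring laws are provided. The anisotropic network model (`"anm"`)
connects every node pair within a distance cutoff with the same constant
and is deliberately blind to sequence — it serves as the package's
negative control, since structurally identical wild type and mutant then
produce bit-identical Hessians and every mutation scores exactly neutral.
The sequence-aware law (`"encom_like"`, the default) keeps the cutoff
term, adds a stiff spring between sequence-consecutive residues, and adds
a contact term in which every heavy-atom pair of two residues contributes
an interaction-matrix weight times a linear contact-surface ramp. Because
the atom census of each residue enters this term, replacing a side chain
changes spring constants — and therefore eigenvalues, entropies and
b-factors — without moving a single node.

The contact ramp `s(d) = clamp((R_p + R_q + t − d)/t, 0, 1)` with
`t = 1.4` Å (a water-probe-like tolerance) is this package's smooth,
monotone surrogate for an exact surface-in-contact calculation. It
preserves the model family — short-ranged, saturating, larger for bulkier
residues in contact — while remaining a two-line formula that the test
suite can check against direct evaluation. The van der Waals radii are
per element (C 1.70, N 1.55, O 1.52, S 1.80 Å).

Spring units are arbitrary relative energies. All downstream quantities
(vibrational entropy, ΔΔS_vib, b-factors) are therefore in relative units;
this is deliberate, because the stability predictor rescales the entropic
term by a fitted coefficient anyway, and only eigenvalue *ratios* enter
entropy differences.

# Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `anm_cutoff` | 18 | Å | customary ANM cutoff; also gates the uniform term of the sequence-aware law |
| `base_spring` | 1 | energy/Å² | uniform-term constant; sets the overall energy scale |
| `covalent_spring` | 100 | energy/Å² | sequence-consecutive residues; two orders stiffer than non-bonded, mirroring the separation between covalent and contact interactions |
| `contact_scale` | 1 | — | multiplier on the surface-contact term; 0 disables sequence awareness |
| `contact_tol` | 1.4 | Å | ramp width of `s(d)` |
| interaction matrix | all ones | — | 8×8 over atom classes; neutral default so that the surface geometry alone drives the weights. Users may sharpen it (e.g. reward polar–polar contacts) via CSV |
| `alpha`, `beta` | −1.12, 0.38 | — / kcal·mol⁻¹ scale | published bootstrap-median coefficients for the entropy + enthalpy combination; refit with `calibrate()` |
| `max_rmsd`, `min_rmsd` | 2, 0.5 | Å | ensemble distortion bound and pairwise spacing |
| `cap` | 350 | conformers | hard ensemble limit; enforced by coarsening the grid |

The 8 atom classes (aliphatic C, aromatic C, carbonyl/carboxyl C, amide N,
charged/ring N, neutral O, carboxylate O, S) ship as an editable CSV;
lookup falls back from (residue, atom) to (\*, atom) to an element
default, so a user table only needs to list exceptions.

# Mutation scoring

Mutations are addressed in author (PDB) numbering with insertion codes,
in a compact grammar (`"A:10-12:ALL"`). The default mutant builder is a
*sequence swap*: backbone and CA stay fixed and the side chain is replaced
by the canonical heavy-atom census of the target residue, placed at 1.5 Å
spacing along the CA→CB direction (ideal tetrahedral CB when absent, a
neighbour-midpoint fallback on bare CA traces). What matters to the score
is the atom census entering the contact weights, not realistic rotamers;
the quality caveat is the same as for any template-based mutant model —
a mutation that in reality disrupts the fold is outside the harmonic
model's reach. A full modelling program can be plugged in through
`external_command` mode, and failures of that command skip the mutation
with a warning rather than aborting the batch.

`ΔΔS_vib = S(mut) − S(wt)` with `S = −½Σ ln λ` over non-trivial modes;
physical prefactors are dropped because they cancel in the difference.
The combined predictor `ΔΔG = α·ΔΔS_vib + β·ΔΔG_B` consumes the external
enthalpic term from CSV — it is never computed internally. `calibrate()`
reproduces the coefficient-fitting procedure: bootstrap resampling of the
(ΔΔG_A, ΔΔG_B, ΔΔG_exp) table, a no-intercept least-squares fit per
sample (minimizing RMSE), medians over samples, and RMSE summaries for
all rows and for the stabilizing/destabilizing subsets split at
0.5 kcal/mol. The printed spread is the bootstrap standard deviation of
the RMSE. A rank-deficient bootstrap sample is redrawn; a globally
collinear table (e.g. an all-zero enthalpic column) cannot be fixed by
resampling, so the deficient column is dropped and its coefficient
reported as `NA` while the other is still estimated.

Flexibility output is the per-residue difference of predicted b-factors,
in raw relative units (no per-structure normalization — profiles from one
job share a single network scale, so raw differences are comparable
within the job). The colour scale is `min(max|δ|, 3·sd(|δ|))` over all
mutations of the job; when the standard deviation degenerates to zero
with nonzero differences, the rule is undefined and the maximum is used.
Colours are comparable only within one job, by construction.

# Ensemble generation

Because eigenvectors are orthonormal, displacing along modes with
amplitudes `a_k` gives RMSD `√(Σa_k²/N)` from the input *exactly*, so the
user's RMSD constraints translate into amplitude space with no further
geometry. The sampler builds a per-mode grid `0, ±δ, ±2δ, …` with
`δ = min_rmsd·√N` up to `max_rmsd·√N`, takes the Cartesian product over
the selected modes, and removes tuples whose implied RMSD exceeds the
maximum. The δ-lattice is this package's documented choice for "uniform
and exhaustive": it covers the ball evenly, and since all coordinates are
multiples of δ, no two tuples are closer than δ — the pairwise minimum-
RMSD constraint holds by construction (a greedy post-filter that keeps
lexicographically smaller tuples guards any future non-lattice grid; on
the lattice it is provably a no-op and skipped).

When the grid exceeds the 350-conformer cap, δ grows geometrically by a
factor 1.2 and the grid is rebuilt until it fits; the factor is a
compromise between termination speed and overshooting the coarsening
(about 5 iterations per decade of excess). The final spacing is reported
as `effective_min_rmsd`.

RMSD is computed over CA nodes in the shared input frame with no
superposition: rigid-body modes are excluded from sampling, every
conformer lives in the input frame, and the modes themselves are defined
on the nodes, so neither alignment nor all-atom RMSD is meaningful here.

The visualization ordering is the multi-start greedy heuristic for the
path-minimization problem (which is NP-hard in general): from every
start, hop to the nearest unvisited conformer; keep the cheapest completed
path; ties break to the lower start index then the lower candidate index,
making the output deterministic. Per-mode trajectories displace along one
eigenvector by `a·sin(2πt/n)` so the movie loops smoothly; by default the
first 20 internal modes are written.

# Synthetic fixtures: what they emulate and what they do not

All tests and examples run on generated structures:

* `make_helix(n)` — an ideal α-helix CA trace (rise 1.5 Å, 100°/residue,
  radius 2.3 Å; consecutive CA ≈ 3.8 Å) with deterministic side-chain
  stubs: the canonical heavy-atom names of each residue placed at 1.5 Å
  spacing along a fixed direction tilted 60° toward the helix axis. The
  tilt makes stubs pack against the next turn, as real side chains do —
  with purely radial stubs every side-chain atom would sit outside
  contact range of its neighbours and the contact term could not see the
  sequence at all.
* `make_dumbbell()` — two mirror-image compact domains on the arms of a
  70° hinge with a 3-D zigzag backbone. The zigzag avoids the spurious
  zero modes any straight or planar linker produces in a central-force
  network, and the bent geometry makes the slowest internal mode the
  hinge-opening motion that separates the domains (squared overlap with
  the inter-domain separation direction above 0.5 under both spring
  laws). The palindromic sequence makes the two halves exact mirrors, so
  b-factors must come out mirror-equal.
* `make_line(n)` — a collinear chain, kept as a *degenerate* fixture: its
  Hessian has more than six null directions, exercising the diagnostic
  warning.
* `make_ddg_table()` — calibration rows drawn from the generating model
  `ΔΔG_exp = α·ΔΔG_A + β·ΔΔG_B + ε`.

Fixtures are bit-reproducible from their arguments and touch the RNG
stream only where noise is part of the definition (the calibration table,
which seeds locally and restores the stream). They emulate the geometry
and contact topology of folded proteins, not their energetics: there are
no realistic rotamers, no solvent, no secondary-structure mix, and the
stub side chains are straight pseudo-chains. Passing tests therefore
demonstrate the *mathematical* properties of the implementation
(invariances, closed forms, constraint satisfaction, recovery of known
coefficients) and the qualitative physics (termini are floppy, bulky
replacements rigidify, hinges dominate the slow spectrum) — they do not
certify predictive accuracy on experimental mutation datasets, which
requires external structures and an external enthalpic predictor.

# Numerical choices

* **Trivial-mode threshold**: an eigenvalue is trivial when
  `λ < 10⁻⁸·max(λ)`. The relative form is scale-free (spring units are
  arbitrary). A count other than six triggers a warning naming the likely
  cause (disconnected network, collinear geometry).
* **Degenerate eigenvalues**: the eigenvector basis inside a degenerate
  subspace is solver-dependent, so tests only assert basis-invariant
  quantities (entropies, b-factors, overlap sums over full bases).
* **Finite-difference oracle**: the analytic Hessian is validated against
  central second differences of the potential (step 10⁻⁴ Å, agreement to
  10⁻⁵) on every fixture; the oracle shares no code with the assembly.
* **Altloc / models**: first MODEL only; alternate locations resolved to
  highest occupancy, first label on ties. Selenomethionine is folded back
  to MET; other non-standard residues are dropped with a warning; both
  conventions are stated package policy, not facts about any upstream
  service.
* **Calibration rank handling**: per-sample redraw up to 100 attempts,
  then fall back to the reduced design; the redraw count is reported.
* **Greedy ordering tie-breaks**: lower start index, then lower candidate
  index — byte-identical output across runs.

Problem sizes used throughout the documentation and test suite — a
20-residue helix (3N = 60) and a 41-residue dumbbell (3N = 123), with
1 000 bootstrap samples and 300-row tables for calibration checks — were
chosen as the smallest systems on which every property of interest
(six rigid modes, hinge spectra, cap enforcement, coefficient recovery
within ±0.1) is cleanly expressed.

# Known limitations

* The sequence-aware spring law is a configurable model *family*; its
  default constants are neutral choices, not fitted values, so absolute
  ΔΔS magnitudes should be interpreted relatively and, for stability
  work, recalibrated against data via `calibrate()`.
* The covalent term is a single nearest-neighbour spring; there are no
  angle or dihedral terms. This keeps the analytic/numeric Hessian
  equivalence exact but underestimates backbone stiffness anisotropy.
* Sequence-swap mutants keep the backbone fixed; mutations whose effect
  is mediated by backbone rearrangement are outside the model.
* Ensemble conformers are linear mode displacements and therefore break
  bond geometry at large amplitudes; an external rebuilding tool can be
  attached through the same command hook as the external mutant builder,
  and the geometric conformers are always emitted as generated.
* The trajectory ordering is a heuristic; it matches the exhaustive
  optimum on all enumerable cases in the test suite but carries no
  optimality guarantee at 350 conformers.
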