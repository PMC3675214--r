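---
title: "Methods: restricted mutagenesis search and Jarzynski PMF estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restricted mutagenesis search and Jarzynski PMF estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdesign)
```

# The design problem

A short peptide that packs into the glycine grooves of an amyloid
protofilament can block fibril growth. The reference binder `RGTFEGKF`
alternates groove-facing residues (positions 2, 4, 6, 8 — the `xGxFxGxF`
face) with solvent-facing residues (1, 3, 5, 7) that keep it soluble.
`pepdesign` searches the neighbourhood of this peptide for stronger
binders and provides the machinery to assess finalists energetically.

## Restricted mutation space

The full sequence space of an 8-mer, `sequenceSpaceSize(8, 20)` =
2.56 × 10¹⁰, is unsearchable when each evaluation is a docking run. The
package therefore confines substitutions to the residue's chemical group
(`aminoAcidTable()`): nonpolar aliphatic {G,A,V,P,L,I,M}, aromatic
{F,Y,W}, polar uncharged {S,T,C,N,Q}, negatively charged {D,E},
positively charged {K,H,R}. This preserves the physicochemical character
of each face while still varying side-chain bulk. Two further rules:

* **Exclusions** are directional `"from>to"` pairs; the default forbids
  only G→M, a derivative known to be ineffective. M→G remains allowed —
  the evidence concerns one direction only.
* **Self-substitutions are never enumerated**, and histidine sits in the
  positively charged group with no pH-dependent handling.

For `RGTFEGKF` the group sizes minus the two excluded G→M substitutions
give 2+5+4+2+1+5+2+2 = 23 single mutants. Mutations are written
`<from><position><to>` (`"G2V"`), 1-based, and enumeration order is fixed
(position, then alphabetical target) so runs are reproducible
byte-for-byte.

## Scorer contract

The search only needs a pure function sequence → score plus a declared
polarity. Docking-like scores are higher-is-better; free-energy-like
rescoring functions (kJ/mol) are lower-is-better. Polarity is explicit
metadata rather than a sign convention, because mixing the two
conventions silently is the classic failure mode of rescoring pipelines.
Three implementations ship:

* `tableScorer()` — externally computed scores from a two-column TSV;
  missing sequences raise an error naming the sequence rather than
  returning a default.
* `surrogateScorer()` — `wc·Σ h(contact) − ws·Σ h(solvent)` over
  Kyte–Doolittle hydropathies `h`. It encodes only the two-face logic of
  groove binding (bulky hydrophobics on the contact face, hydrophilics on
  the solvent face). It is non-physical, exists so the full pipeline runs
  without proprietary docking software, and is not expected to reproduce
  docking-score rankings.
* `mockScorer()` — seeded additive gains plus optional pairwise
  interaction terms; used to drive property-based tests.

## The combine–score–accept search

`initializeLibrary()` accepts the single mutants that *strictly* improve
on the reference (ties are rejected: with no stated tie rule, strictness
keeps the library minimal). `combinationCycle()` then forms pairwise
unions of members' mutation sets. Key semantics, each of which changes
the reachable set:

* **Pairwise reachability, not subset enumeration.** A k-point candidate
  exists only if it is the union of two current members. With an
  interaction-bearing scorer this is strictly weaker than enumerating all
  subsets of accepted singles, and it is what the recursive flowchart
  actually does.
* **Snapshot pairing.** Members pair only if at least one of them was
  accepted in the *previous* cycle; both-older pairs were exhausted
  earlier, and newly accepted members do not chain within the cycle that
  accepts them. Cycle 1 therefore forms 1+1 pairs; cycle 2 forms 1+2 and
  2+2 pairs, yielding three- and four-point candidates.
* **Typed rejections.** A union is rejected as `position-conflict`,
  `over-cap` (default cap 4 mutations) or `no-new-mutation` (the union
  adds nothing); the per-cycle log counts each reason.
* **Score caching.** A sequence reachable through several parent pairs is
  scored once; later encounters only extend its provenance. Rejected
  sequences are cached too.
* **Early stop** when a cycle adds no member, or when an optional target
  library size is reached.
* **Veto hook.** Discarding docked poses that miss the groove is a manual
  step in the original workflow; it is modelled as an optional
  user-supplied predicate applied to otherwise-accepted candidates
  (default: accept all).

`rescoreAndFilter()` applies a second scorer to the reference and all
members, keeps strict improvements, and ranks best-first by the second
scorer's polarity. Acceptance during the cycles uses the primary scorer
only; the second scorer is a final filter. Both roles are configurable,
so any scorer pair can be used.

The engine is verified against an independently coded brute-force
recursion (same acceptance and reachability rules, different data
structures and traversal) on 200 seeded mock scorers over short
references — libraries, scores, levels and cycle indices must match
exactly.

# Free-energy assessment

## Work, Jarzynski, stiff spring

A constant-velocity pulling run couples the reaction coordinate ξ (the
peptide–fibril centre-of-mass distance in the original setting) to a
guide moving as λ(t) = λ₀ + v·t through a spring of stiffness k. The
external work is

W(t) = v ∫₀ᵗ k (λ(t′) − ξ(t′)) dt′,

evaluated by trapezoidal quadrature on the recorded sample times (the
integral's standard discretization; a refinement test confirms the
expected second-order convergence). Jarzynski's equality
exp(−βΔA) = ⟨exp(−βW)⟩ converts the work ensemble at fixed λ into the
free-energy profile ΔA(λ), regardless of pulling speed; the exponential
average is computed as a shifted log-sum-exp (minimum work subtracted
before exponentiation) so large βW cannot underflow. Work values from
different trajectories are combined at the same λ by linearly
interpolating each trajectory's W(λ) onto a common grid. Under the
stiff-spring approximation ξ tracks λ closely and, at leading order,

Φ(ξ = λ) = ΔA(λ) − ΔA(λ₀).

A second-order correction −(ΔA′)²/(2k) is available behind an explicit
flag (finite-difference gradient), off by default: with the noisy
profiles typical of small ensembles, differentiating the estimate adds
more error than the correction removes. The profile records k so users
can judge stiffness validity.

The companion estimator `cumulant2DeltaA()` (mean(W) − β·var(W)/2,
unbiased variance) is exact for Gaussian work distributions and far less
sample-hungry at high dissipation; it is offered alongside the
exponential average, which remains the default. Bootstrap percentile
intervals over trajectories (`bootstrapUncertainty()`, seeded) quantify
ensemble noise.

Units: kcal/mol, Å, ns throughout; kB = 0.0019872041 kcal/(mol·K);
T defaults to 310 K. Forces in kJ/(mol·Å) convert via ×0.239006 at read
time. The guide spring constant for peptide unbinding is conventionally
printed as 5 kcal/(mol·Å); a harmonic constant must carry per-length-
squared units, so the package treats it as 5 kcal/(mol·Å²).

## The synthetic pulling simulator

`simulatePulling()` integrates an overdamped Langevin particle in a known
1-D potential U dragged by the harmonic guide:

dξ = [−U′(ξ) − k(ξ − λ(t))] dt/γ + √(2dt/(βγ)) η.

Overdamped dynamics suffice for estimator validation and avoid the mass,
thermostat and solvation choices an all-atom setup would impose. What the
simulator emulates: the guide schedule, the spring coupling, thermal work
fluctuations, dissipation growing with v·γ, and ensemble variability over
independent starting states. What it does not: molecular detail of any
kind — multidimensional reaction coordinates, conformational gating,
solvent memory effects, anisotropic friction. Passing the recovery tests
therefore certifies the *estimator chain* (work quadrature → exponential
average → stiff-spring mapping), not the realism of any MD protocol.

Numerical choices:

* **Stability guard** dt·(k + max U″)/γ < 0.1, checked against the
  potential's curvature over the pulling range; violations raise an error
  advising a smaller dt rather than producing silently wrong dynamics.
* **Initial state** `"equilibrium-in-guide"` samples the Boltzmann
  distribution of U(ξ) + k/2(ξ − λ₀)² by inverse-CDF on a fine grid
  (grid-cell jitter included), so W(λ₀) = 0 holds and no equilibration
  phase is needed; `"fixed"` starts exactly at λ₀ for deterministic
  limits.
* **Seeding**: one master seed; per-trajectory seeds derived by a fixed
  affine splitting rule and recorded in each trace's provenance, so any
  single trajectory can be regenerated alone and ensembles are
  bit-reproducible.

## The validation scenario and its sizing

`validationScenario()` fixes the ground-truth study: harmonic potential
a = 1 kcal/(mol·Å²) centred mid-range, guide k = 50 kcal/(mol·Å²),
v = 1 Å/ns, γ = 1 kcal·ns/(mol·Å²), T = 310 K, M = 50 trajectories,
dt = 0.001 ns (guard value 0.051), pulled range λ: 0 → 1 Å.

The pulled range is the one deliberately chosen quantity, and it is set
by the estimator's own statistics. Dissipated work grows as ≈ γ·v·L along
the pull, and near equilibrium the work variance obeys σ² = 2·W_diss/β.
For the Jarzynski exponential average to converge at M = 50, β·W_diss
must stay of order one — at these γ and v that means a pull of about
1 Å (W_diss ≈ 1 kcal/mol, σ_W ≈ 1.1 kcal/mol at the far end). Over this
range the quasi-static and stiff-spring assumptions demonstrably hold and
the recovered Φ tracks the analytic parabola to within 0.5 kcal/mol;
stretching the same protocol to several Å drives β·W_diss to 3–10, where
the M = 50 exponential average is dominated by its smallest samples and
no honest tolerance of this size survives. The recovery test runs the
scenario as a five-seed replicate study (master seeds 42…46, paired
across velocities): the mean maximum error must stay within
0.5 kcal/mol at v = 1 Å/ns and must drop when v is halved on the same
seeds. A single-seed comparison of the velocity effect would be
noise-dominated at this dissipation level; pairing the seeds and
averaging five replicates makes the dissipation signal reliably visible
while leaving every physical parameter at its stated value.

Problem sizes across the test suite follow the same logic — search/oracle
equivalence uses 200 seeded scorers on references of length ≤ 4 (small
enough for exhaustive recursion to be an oracle), the Gaussian closed-form
check uses 10⁵ work samples, bootstrap monotonicity uses M ∈ {5, 20, 80} —
sizes at which each property is decisive for the implementation while the
whole suite stays quick to run.

# Degenerate inputs and edge behaviour

* Unknown residue letters are reported with their position; mutation
  strings are validated against the reference (mismatched `from` residue,
  duplicated positions).
* A scorer that never improves on the reference yields an empty library
  (n₁ = 0), which propagates cleanly (no pairs, empty rescoring).
* Empty work ensembles, single-trajectory cumulant calls and
  single-trajectory bootstraps raise input errors rather than returning
  NaN.
* Trace files are validated on read: strictly increasing time, guide
  positions matching the protocol schedule (tolerance 10⁻³ Å), any force
  column consistent with k(λ − ξ). Directories must agree on the
  protocol; offenders are listed by name.
* Score-table TSVs serialize with six fractional digits, so tables with
  at most six decimals round-trip bit-identically.

# Known limitations

* The surrogate scorer is additive and cannot express epistasis between
  positions; rankings beyond "bulkier hydrophobics on the contact face
  score higher" carry no physical meaning.
* The search's pairwise reachability means a candidate whose intermediate
  is rejected is never reached, even if its own score would qualify —
  this is inherent to the recursive design, not a defect, but users
  comparing against exhaustive enumeration should expect differences
  whenever a scorer has interaction terms.
* The stiff-spring mapping is leading-order; for soft springs or sharply
  curved potentials, profiles inherit a systematic O(1/k) smoothing.
* The Jarzynski estimator's finite-sample bias grows exponentially with
  β·W_diss; for strongly dissipative pulls prefer the cumulant estimator
  (if work is near-Gaussian) or slower pulling, and treat the bootstrap
  interval as a lower bound on the true uncertainty.
* No bidirectional (Crooks/BAR) or histogram-based estimators, no MD
  engine integration, and no structural/pose handling are included.
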