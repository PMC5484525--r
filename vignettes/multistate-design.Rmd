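---
title: "Multi-state design: model, parameters, and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state design: model, parameters, and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdesign)
```

## The design problem

Proteins populate conformational ensembles, yet classical computational
design optimizes a sequence for one fixed backbone (single-state design,
SSD). When the design target is an ensemble — or when positive and
negative design goals must be traded off — the sequence has to be a
compromise that satisfies several states at once (multi-state design,
MSD). `msdesign` implements the canonical architecture for this problem:
a population-based *sequence optimizer* that never looks inside the
scoring, and a pluggable *evaluator* that scores one sequence in one
state, joined only by a *fitness function* over the per-state scores.

The evaluator contract is deliberately minimal: `score(state, sequence)`
must be finite, lower-is-better, and deterministic for identical inputs.
Determinism is what makes the parallel evaluation contract trivial — the
score table of an ensemble against a sequence batch is computed cell by
cell in a fixed (state, sequence) order, so any worker count yields a
bit-identical table, and reproducibility reduces to fixing the optimizer
seed.

## Fitness functions

Two fitness modes are provided, both minimized:

* **mean**: the arithmetic mean of the per-state total scores. This is the
  consensus fitness used for ensemble (multi-specificity) design.
* **pos_neg**: `dscore_plus - w * dscore_minus`, where each `dscore` is
  the score difference between the candidate and a reference sequence,
  averaged over the states of its side. The reference is typically the
  optimal single-state design; for the reference itself the fitness is 0
  for any `w`.

The weight `w` has no default on purpose. Its natural scale depends on the
score units of the evaluator and on how aggressively the negative state
should be penalized; any default would silently encode a design goal. The
averaging of multi-state sides before differencing is the package's
generalization of the one-state-per-side formulation; it keeps the two
sides on the same scale regardless of how many states each contains.

## The genetic algorithm

`ga_config()` defaults encode the published multi-state protocol
constants:

| parameter | default | meaning |
|---|---|---|
| `population_size` | 210 | seed + 209 single-point mutants in generation 1 |
| `replaced_fraction` | 1/2 | the worst half is replaced each generation |
| `mutation_probability` | 0.5 | offspring by point mutation vs recombination |
| `generations_max` | 600 | hard cap |
| `convergence_window` | 50 | generations without improvement that stop the run |
| `convergence_tolerance` | 1e-6 | minimum improvement of the best fitness |

Where the protocol is silent, the package makes the simplest defensible
choice and exposes it:

* **Parent selection** is uniform over the surviving (best) half. The
  replacement rule is specified by the protocol; selection pressure
  already enters through survival, so no additional fitness-proportional
  bias is layered on top.
* **Recombination** is single-point crossover of two distinct surviving
  parents at a uniformly random cut. One-position shells fall back to
  mutation (there is no cut point).
* **Mutation** introduces exactly one substitution, drawn uniformly from
  the non-current letters of the shell alphabet — matching the
  initialization, which is defined in terms of single point mutants.
* **Survivor fitness is cached**, not recomputed: the evaluator contract
  is deterministic, so re-scoring survivors could only waste evaluations.
  (For a stochastic evaluator this choice would matter; the contract
  forbids that case.)
* **Duplicates are permitted** within a population; uniqueness is not
  enforced.
* Convergence means: the best fitness improved by less than
  `convergence_tolerance` over `convergence_window` consecutive
  generations. Both knobs are exposed; `convergence_window = Inf` forces
  exactly `generations_max` generations.

Ties in the fitness sort are broken by stable order (insertion order), so
replacement of "the worst half" is deterministic.

## The single-state baseline

`run_ssd_mc()` is a generic simulated-annealing Metropolis walk over
single-point mutations with a geometric cooling schedule, returning the
best sequence *visited* (not the last accepted one). It plays the role a
Monte-Carlo packing protocol plays in SSD benchmarks, but it is **not** a
rotamer-level packer: it operates on sequences through the same evaluator
interface as the GA. Comparisons between `run_msd()` and `run_ssd_mc()`
therefore isolate the single-state/multi-state axis from the scoring
model, which is shared.

Defaults (`steps = 10000`, `t_initial = 2`, `t_final = 0.02`, in score
units) are sized for the synthetic landscapes, whose score differences per
mutation are of order 1: the initial temperature accepts most moves, the
final temperature is effectively greedy. A zero temperature is allowed and
degenerates to accepting only non-worsening proposals.

## Recovery metrics

`nsr` is the fraction of design positions with the native residue; `nssr`
additionally counts residues whose BLOSUM62 score against the native
residue is strictly positive. The BLOSUM62 table is embedded in the
package source (the canonical NCBI values; the test suite cross-checks the
embedded copy against the one distributed with Biostrings). Because every
diagonal entry of BLOSUM62 is positive, `nsr <= nssr` always holds; the
per-amino-acid recovery profile, weighted by native residue counts,
reconstructs the set-level `nssr` exactly — both facts are asserted as
properties in the tests.

Sequences are restricted to the 20 standard residues. Non-standard codes
(B, J, O, U, X, Z) are rejected at validation time rather than scored 0:
design operates over the standard alphabet, and silently scoring an
unknown residue would mask upstream errors. All metrics are fractions
internally; percentages appear only in formatted output.

## Synthetic landscapes: what they emulate, and what they do not

`generate_landscape_ensemble()` builds, for each state `l`, an additive
table `h_l(position, residue)` (plus optional pairwise couplings shared
across states). Construction:

1. A base table is drawn i.i.d. normal (`base_sd = 1`), and the planted
   native residue's entry is lowered to `min(others) - margin` at every
   position (`margin = 1` score unit per position).
2. Each state adds zero-mean Gaussian noise of standard deviation
   `divergence` to every entry. The noise is **recentered to sum to zero
   across states per entry**, so the mean table equals the base table
   exactly and the planted native is the *exact* optimum of the mean
   score for every divergence — no rejection sampling needed in the
   additive case. With couplings enabled, optimality is re-certified by
   enumeration and, if violated, restored by uniformly lowering the
   native additive entries (bounded retries, then an error advising
   smaller divergence or coupling density).

This reproduces the qualitative regime that motivates multi-state design:
individual states have private optima that drift away from the consensus
as `divergence` grows (for `divergence = 0` all states are identical and
every per-state optimum is the native), while the consensus optimum never
moves. The default alphabet subset for reduced alphabets always contains
alanine (so all-alanine seeding works) and BLOSUM62-similar pairs such as
A/S and D/E (so `nssr` remains informative between non-identical
residues).

What the landscapes do **not** emulate: the energy *distributions* of real
proteins, rotamer-level frustration, backbone relaxation, or any
correlation structure between states beyond the shared base table. A
passing benchmark on these landscapes therefore demonstrates that the
optimizers and the comparison calculus behave as specified — it does not
predict recovery rates on physical energy functions.

The brute-force oracle enumerates all `A^L` sequences (bound `1e6`,
refusing beyond it) and breaks exact ties lexicographically, leftmost
position most significant — the same tie order used when reporting
optima, so oracle comparisons are deterministic.

## The benchmark harness

`synthetic_benchmark()` mirrors the published benchmark layout: 16
"proteins", 20 conformations each, partitioned in order into four
disjoint ensembles of five. `run_synthetic_benchmark()` then runs, from a
common all-alanine seed, repeated annealing designs per conformation
(SSD) and one GA per ensemble (MSD), and assembles:

* best-so-far SSD curves over the number of runs (score monotone
  non-increasing by construction; the recovery curve is computed from the
  *same* selected sequences),
* generation-wise MSD curves over the top-k sequences (k = 5 by default,
  matching the per-ensemble protocol; runs that converge early are padded
  by carrying their converged state forward before averaging),
* the per-protein summary table with a grand-average row,
* the per-protein ensemble ranking by top-k `nssr` (ties by ensemble id)
  and the cross-protein ES groups, with 1.5-IQR boxplot statistics
  emitted **both** per ensemble and per sequence (the granularity of such
  box plots is genuinely ambiguous, so both are reported),
* a two-sided paired Wilcoxon signed-rank test on the per-protein `nssr`
  values (exact null for up to 25 untied non-zero pairs via
  `stats::wilcox.test`; all-zero differences yield a flagged degenerate
  result with p = 1). The test suite validates the exact p against full
  enumeration of the signed-rank null.

Default harness sizes — 3 annealing runs of 800 steps per conformation,
GA capped at 150 generations with a 30-generation window — are the
package's chosen benchmark conditions for landscapes of L = 6, A = 5,
divergence 1: the annealing baseline reliably reaches each state's
optimum basin at these settings, and the GA converges well inside the
cap, so both methods are compared at convergence rather than mid-run.

## Structure input

For structure states, `read_structure()` (backed by bio3d) normalizes PDB
ATOM/HETATM records, selects one model of multi-model files and resolves
alternate locations to the highest-occupancy copy (first on ties).
`detect_design_shell()` is a distance-based stand-in for protocol-level
shell autodetection: residues with any heavy atom within 6 Å of any
ligand heavy atom become design positions, within 8 Å repack positions,
unioned across conformations with design overriding repack. The cutoffs
are package defaults, exposed as arguments, and are not derived from any
packing algorithm. The contact-surrogate evaluator (C-beta contact pairs
within 8 Å, C-alpha burial counts within 10 Å, user-supplied pair and
burial potentials) exists so structure ensembles can be scored
deterministically end-to-end; it makes no claim of compatibility with
physics-based energy units.

## Degenerate inputs and numerical conventions

* Empty sequence sets, empty score columns, and empty run lists raise
  errors rather than returning NaN.
* Position-misaligned sequences are rejected everywhere; the package
  never aligns sequences (same-shell alignment is by construction).
* `best_of_runs()` and the fitness sort break ties toward the earliest
  entry; the enumeration oracle breaks ties lexicographically.
* Amino acids absent from a native sequence get `NA` (not 0) in the
  residue recovery profile — an undefined denominator is not a zero
  recovery.
* All derived RNG seeds are kept within 32-bit integer range.

## Known limitations

* No rotamers, no backbone flexibility, no catalytic-constraint scoring:
  the evaluator interface accepts any external scorer that honors the
  determinism contract, but none of the physics is reimplemented here.
* The annealing baseline's temperature defaults are tuned to the
  synthetic landscapes' score scale; other evaluators will need their own
  schedule.
* Whether the original multi-state protocol re-evaluates survivor
  fitness, or enforces population uniqueness, is unspecified; this
  implementation caches and permits duplicates, and documents both
  choices above.
* Parallel evaluation uses forked workers (`parallel::mclapply`) and so
  degrades gracefully to serial execution on platforms without fork.
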