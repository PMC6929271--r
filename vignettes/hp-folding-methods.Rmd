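---
title: "Ground-state search in the 2D HP model with full-state-space Q-learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ground-state search in the 2D HP model with full-state-space Q-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpfold)
```

## The model

The hydrophobic-polar (HP) lattice model reduces a protein to a string over
\{H, P\}: hydrophobic residues (H) drive folding, polar ones (P) are inert.
A conformation places the chain on the 2D square lattice as a self-avoiding
walk — integer coordinates, consecutive residues at unit distance, no two
residues on one cell. Its energy counts hydrophobic *topological contacts*:

$$E \;=\; \sum_{i<j} W_{ij}, \qquad
W_{ij} = \begin{cases}-1 & \text{residues } i,j \text{ both H},\; |i-j|\ge 2,\;
\text{unit lattice distance}\\ 0 & \text{otherwise,}\end{cases}$$

and the native structure is taken to be a global minimizer of $E$. Finding
that minimizer is NP-hard in general, which makes the model a standard
testbed for global-optimization heuristics. `hpfold` implements one such
heuristic — tabular Q-learning over the *full* state space of fold prefixes —
together with the baselines needed to evaluate it (a compressed-state
learner, a myopic greedy folder) and an exact enumeration oracle that makes
every claim checkable on benchmark-sized chains.

Energy is computed mechanically from coordinates, so it is defined even for
overlapping (illegal) chains; that totality matters below, because one of
the two training criteria deliberately allows overlaps during learning.
All reporting of "lowest energy achieved", however, counts only legal
conformations.

## The full state space

Growing a fold is a sequential decision process: residue 1 sits at the
origin, and each subsequent residue is placed by one of $b$ actions. The
*full* state space assigns one state to every action history — a perfect
$b$-ary tree with

$$S(n, b) = \frac{b^n - 1}{b - 1}$$

states for an $n$-residue chain, numbered breadth-first from the root
$s_1$. Taking action $l$ in the depth-$i$ state with ordinal $k$ leads to

$$T\!\left(s_{\frac{b^{i-1}-1}{b-1}+k},\, a_l\right) =
s_{\frac{b^i-1}{b-1} + b(k-1) + l},$$

a bijection onto the next depth block: every state encodes exactly one
partial fold, so the process is Markov by construction. The package keeps
this arithmetic exact: `full_state_count()` uses digit-vector integer
arithmetic (exact for any $n \le 64$, far beyond what is ever trained), and
the training loop indexes states as 64-bit integers, which is exact up to
$n = 33$ for $b = 3$ and $n = 26$ for $b = 4$ — comfortably past the longest
benchmark chain ($n = 21$).

Two action sets are supported. With four actions (L, U, R, D as fixed
lattice directions) every walk is expressible. With three actions the tree
is smaller, but the geometric meaning matters: if L/U/R were *fixed*
directions the chain could never step in $-y$, restricting it to partially
directed walks. Restricted exact enumeration shows such walks miss the true
minimum on 12 of the 16 benchmark sequences (for example $-10$ versus the
known $-12$ on the 21-mer HHHHHPHHPHHHHPPHHHHHH), while the benchmark
results the method is expected to reproduce attain all 16. The three
actions must therefore be *relative* moves — turn-left / straight /
turn-right with respect to the previous bond, with the first bond's
reference direction $+x$ — and that is the package default
(`state_mode = "full3"`, `action_geometry = "relative3"`). An `absolute3`
mode is kept for fidelity experiments on the restricted geometry.

Only visited states are materialized: the Q table is a sparse hash from
state index to action values, with unset entries reading exactly 0. A dense
table is impossible at $n = 21$ ($\approx 5.2\times10^9$ states for $b=3$),
but the number of *visited* states is bounded by episodes × chain length
and stays modest in practice.

The *partial* state space is the comparison method: $1 + 4(n-1)$ states
identified by (residue index, last absolute action). Distinct histories
alias to the same state, the process loses the Markov property, and — as the
benchmark harness reproduces — the learner solves short chains but cannot
converge stably on longer ones.

## Rewards: rigid and flexible criteria

Both criteria reward the *absolute value* of the final energy, $|E|$, at the
terminal step, turning energy minimization into return maximization.
They differ in how an *invalid* action — one that would place a residue on
an occupied cell, detected with a $(2n-1)\times(2n-1)$ occupancy ("check")
grid centred on residue 1 — is handled before the terminal step:

* **Rigid**: the invalid action is rejected and another is selected, so
  every completed episode is a legal self-avoiding walk; the per-step reward
  is 0 until the terminal $|E|$. If no valid action exists (a dead end),
  the episode terminates with no terminal bonus; dead ends are counted and
  reported.
* **Flexible**: the placement is allowed, with reward $-10$; the fold
  continues through the overlap, and the terminal step still earns $|E|$
  (computed mechanically on the overlapping coordinates). Only legal test
  folds count toward "minimum achieved" bookkeeping.

Learning is standard one-step Q-learning with $\epsilon$-greedy behaviour,

$$Q(s,a) \leftarrow Q(s,a) + \alpha\left(r + \gamma \max_{a'} Q(s',a') -
Q(s,a)\right),$$

with the bootstrap term dropped at terminal transitions (terminal states
have no successors in the episodic process). Defaults are the study
protocol: $\alpha = 0.01$, $\epsilon = 0.5$, $\gamma = 0.9$, 5 million
episodes sampled every 10,000. Because rewards are bounded, $|Q|$ is
bounded by $\max(10(n-1), \max|E|)/(1-\gamma)$; the trainer reports the
realized maximum and the tests assert the bound.

The empirical contrast the package reproduces: the rigid criterion
converges to the known minima on all benchmark sequences, whereas the
flexible criterion stalls on chains of 13+ residues. The mechanism is
visible in the Q table — under the flexible criterion, states reached
through overlaps acquire nonzero (even positive, via the terminal bonus)
values and keep attracting the argmax, while under the rigid criterion
those states are simply never entered and their values stay at the neutral
default 0.

## Protocol choices the text leaves open

Three details of the reference protocol are not pinned down by its
description, and the package had to fix them. Each choice is a documented
option, with the default selected on internal evidence:

* **What a periodic "sample" is.** If each sample were a frozen greedy
  ($\epsilon = 0$) probe of the learned policy, a converged learner would
  hit the minimum on essentially *every* late sample; the reference
  hit-counts for converged full-state runs are instead ~5–13 per 100 late
  samples, which is only consistent with sampling the $\epsilon$-greedy
  *training* episodes themselves. Default `test_policy = "sample"` records
  the sampled training episode's energy; `"greedy"` (frozen rollouts) is
  available, and the final structure decoding always uses the greedy policy
  regardless. Measured here, post-convergence training-episode hit rates
  are 14–30% on 7–10-mers, in line with those reported counts.
* **How the rigid criterion rejects invalid actions.** The rule as stated
  re-selects until a valid action occurs; the default
  (`invalid_action = "reselect"`) implements exactly that — fresh
  $\epsilon$-greedy redraws over the full action set, with a safety fallback
  to one uniform draw among valid actions after 32 rejections (reachable
  only when every maximizer is blocked at small $\epsilon$). The
  alternative `"mask"` restricts selection to valid actions up front; it is
  equivalent in the exploration branch but greedier when the learned best
  action is blocked, and measurably accelerates convergence.
* **Tie-breaking among equal Q values.** Unspecified; the default is a
  uniform seeded draw among maximizers, which avoids the directional bias a
  fixed preference order would imprint on early exploration.
  `tie_break = "first"` reproduces the deterministic-argmax behaviour of
  naive implementations.

With these defaults, the convergence protocol (5 seeded runs, samples every
10,000 episodes) first samples the exact minimum after a mean of roughly
20,000–80,000 episodes on the 7-mer benchmark sequence and 90,000–180,000
on the 10-mer, depending on the master seed — the same order as, though on
the 7-mer somewhat slower than, the reference averages of 30,000 and
210,000. No single resolution of the open details reproduces both averages
simultaneously; the package keeps the text-faithful resolution rather than
one tuned to the reported numbers, and `convergence_experiment()` exposes
the whole protocol so the sensitivity is easy to re-measure.

## The exact oracle

`enumerate_min_energy()` is a depth-first search over all self-avoiding
walks of the chain with two independently switchable accelerations:

* **Symmetry reduction**: the first step is fixed to $+x$ and the first
  turn, if any, to $+y$. Any walk that leaves the axis has a trivial
  stabilizer in the 8-element lattice point group, so this enumerates
  exactly one representative per congruence class (straight walks, fixed by
  the axis reflection, are also counted once). `optimum_count` is
  therefore a count of symmetry *classes*, stated as such to avoid the
  8-fold ambiguity.
* **Branch-and-bound pruning**: a branch is cut when the running energy
  minus an optimistic bound on the remaining contacts cannot reach the
  incumbent. The bound is admissible and cheap: every not-yet-placed H can
  gain at most 2 contacts (3 for the chain's last residue), because a chain
  residue has at most that many non-bond neighbours.

Correctness does not rest on either device: the tests require bit-identical
minima with both switched off (up to $n = 12$), and a deliberately naive
secondary oracle — pure R, enumerating all $4^{n-1}$ move strings with the
package's own `decode_moves()`/`energy()` — must agree on minima *and* on
symmetry-class counts at small $n$. With both accelerations the full
16-sequence benchmark, including the 20–21-mers, verifies in under a second
per sequence on one CPU; a `node_cap` turns overruns into a flagged
truncated result rather than a silent wrong answer.

## Baselines

The greedy baseline places residues sequentially, choosing uniformly among
the valid moves that create the most new H–H contacts. Each attempt is
independent — the method has no memory, so it finds deep minima only by
luck and cannot converge; its hit counts come from repeating attempts and
reading the tail of the series, mirroring the learners' curve bookkeeping.
The rule itself is the canonical myopic heuristic for HP folding; the
reference describes its greedy comparator only behaviourally (independent
episodes, no convergence), and this rule reproduces that behaviour.

## Reproducibility machinery

Every stochastic component draws from R's RNG. The native training loop
consumes exactly two uniforms per placement step (an explore check, then an
index draw — even when one candidate remains), and the pure-R reference
runner `run_episode()`/`train_reference()` mirrors that pattern, so the two
implementations produce bitwise-identical learning curves and Q tables
under the same seed — a test enforces this for both criteria and both
invalid-action rules. Benchmark cells derive child seeds from a master
seed by a counter scheme (`derive_seed()`), making rounds independent but
the whole report a pure function of one integer.

## Problem sizes and runtime

The tests and the acceptance protocol run at desk scale on one CPU:
500,000-episode budgets for the 7-mer convergence statistic, 1 million for
the 10-mer (about 40 s for both five-run sets), full 5-million-episode
rounds for the rigid-versus-flexible contrast on the 13-mer (about 35 s for
six runs), and sub-second exact enumeration for all 16 benchmark
sequences. The full study protocol — 16 sequences × 4 methods × 5 rounds ×
5 million episodes — is exposed as `benchmark_preset("paper")` and is a
deliberate long-running job (hours), not part of the default checks.

## What the synthetic generator does and does not emulate

`generate_fixtures()` draws i.i.d. H/P strings with a chosen hydrophobic
fraction. That matches the benchmark sequences' alphabet and length range
and is sufficient for the package's property tests (oracle bounds,
reproducibility, legality invariants), but real proteins are not i.i.d.:
hydrophobicity clusters along natural sequences, and the benchmark's
Uniref-derived entries carry such structure. Passing the property tests
therefore says nothing about biological realism of folds — only about the
correctness of the optimizer and oracle on HP instances.

## Known limitations

* Exact enumeration beyond $n \approx 25$ grows impractical despite
  pruning; the oracle is a verification tool for benchmark-sized chains,
  not a general solver.
* Full-state training at $n$ much beyond 21 is memory-bound through the
  visited-state hash (and index-bound at $n > 33$); the partial state space
  or function approximation would be needed, and the latter is out of
  scope.
* The flexible criterion's terminal energy on overlapping chains follows
  the mechanical contact count; other conventions (e.g. scoring only the
  legal prefix) are conceivable but would change the reward landscape.
* Reported convergence episode counts are stochastic with heavy right
  tails; five-run means on the 10-mer vary by a factor of ~2 across master
  seeds at the protocol's sampling resolution.
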