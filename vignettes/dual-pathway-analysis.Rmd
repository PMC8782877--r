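---
title: "Dual structural and parametric analysis of signaling pathway models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual structural and parametric analysis of signaling pathway models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrisig)
```

# Motivation

Signaling pathways such as the DNA-damage-response network around ATM, p53
and NF-κB can be described at two levels. A classical Petri net captures the
*structure* of the pathway — which species participate in which elementary
reactions — with no kinetic information at all; an ODE model captures the
*dynamics*, at the cost of needing a full set of kinetic parameters.
`petrisig` implements the analysis toolchain for both levels, because the
two answer different questions: invariant-based significance analysis finds
elementary processes that carry many steady-state subprocesses of the net,
while sensitivity analysis finds kinetic parameters whose perturbation most
changes the simulated transient response. A process can matter structurally
but not kinetically and vice versa, which is precisely what makes running
both worthwhile.

# The Petri net model and its invariants

A classical place/transition net is a weighted bipartite directed graph:
places (species) and transitions (reactions) connected by arcs with positive
integer weights, plus a marking assigning tokens to places. Its incidence
matrix $A \in \mathbb{Z}^{n \times m}$ has one row per place and one column
per transition; $a_{ij}$ is the net token change of place $i$ when
transition $j$ fires.

A **t-invariant** is a vector $x \in \mathbb{N}^m$, $x \neq 0$, with
$A x = 0$; its support $s(x) = \{t_j : x_j > 0\}$ is the set of reactions
involved. Firing each $t_j \in s(x)$ exactly $x_j$ times returns the net to
its starting marking, so t-invariants formalize "subprocesses that leave the
system state unchanged". **p-invariants** ($y A = 0$) are the dual notion:
weighted token counts conserved by every firing. All analyses use the
*minimal* invariants: gcd-normalized and with supports forming an antichain.

## The elimination engine

`minimalTInvariants()` runs a Farkas-style (Fourier–Motzkin) elimination on
the table $[A^\top \mid I_m]$: the place columns are annihilated one at a
time by combining row pairs of opposite sign (each combination immediately
divided by its gcd), discarding rows still nonzero in the processed column,
and pruning rows whose identity-part support strictly contains another
row's after every step. The surviving identity parts are exactly the
minimal semi-positive solutions.

Numerical choices:

* **Exact integers.** The engine never touches floating-point fractions;
  entries live on R doubles, which represent integers exactly up to
  $2^{53}$, and a guard aborts (rather than silently losing exactness) if
  any intermediate entry exceeds $2^{49}$. With gcd reduction after every
  combination, nets of the size this package targets stay orders of
  magnitude below the guard.
* **Elimination order.** The place column with the fewest nonzero rows is
  processed first. This is purely a performance heuristic; the result is
  order-independent, and the test suite checks set equality under random
  place permutations.
* **Canonical output.** Invariants are gcd-normalized and sorted
  lexicographically by support, so results are reproducible across runs
  and platforms.
* **Correctness oracle.** `bruteForceTInvariants()` enumerates all
  bounded-entry solutions directly from the definition (guarded at
  $m \cdot (\text{bound}+1)^m \le 10^7$) and is compared with the engine on
  hundreds of seeded random nets in the tests. The default bound of 3 is
  sufficient for the generated test nets, whose arcs all have weight 1.

Degenerate inputs: a transition with no arcs has an all-zero incidence
column, so the unit vector on it is a (mathematically forced) minimal
t-invariant; nets whose flows cannot close simply yield fewer invariants,
and an empty invariant set is a valid result meaning "not covered".

## Significance, knockout, subsets

With $s$ the total number of minimal t-invariants and $f$ the number of
supports containing a transition, its significance is $S = f \cdot 100 / s$
[%]. Percentages are rounded half-up to two decimals, matching the
convention of published significance tables (base R `round()` would round
half-even). Coverage — every transition in at least one support — is a
prerequisite: transitions outside every invariant get $S = 0$ and make the
report misleading, which is why `isCovered()` is exposed and checked.

Knockout of a transition set removes every invariant whose support meets
the set; $E = (tinv_b - tinv_a) \cdot 100 / tinv_b$ [%] measures the
excluded fraction. Knockout is implemented as support *filtering* rather
than re-running the engine on the reduced net: for minimal invariants the
two coincide (an invariant avoiding the knocked columns is minimal in the
reduced net iff it is minimal in the full net), and filtering is linear in
the number of invariants. The identity is nevertheless verified against
the recompute route on hundreds of random nets, because it is the kind of
shortcut that deserves a standing regression test.

The subset search has two modes because "a significant set of transitions"
has two readings. In *joint-containment* mode an Apriori-style level-wise
expansion finds all maximal sets whose joint frequency in the supports
reaches the threshold θ (default 0.8, i.e. the set occurs in more than 80%
of all modeled subprocesses). In *union-knockout* mode a greedy forward
selection grows a set maximizing the knockout exclusion per added
transition — appropriate when the members cover complementary groups of
subprocesses and no single set passes the joint threshold. Both modes are
exposed since published significant subsets typically include transitions
whose individual frequencies are below 80%, which no joint-containment set
can contain; such sets are only reachable through the knockout reading.
The search accepts plain support lists as well as invariant sets, since a
support family under study need not itself be an antichain.

# Translation motifs

The motif builders encode the standard recipes for translating ODE rate
terms into net fragments. Three are worth explaining:

* **Catalyst pools.** Classical nets have a single arc type, so an enzyme
  or catalyst appearing as a pre-place is consumed by its transition. To
  return catalysts to circulation, `addCatalyzedConversion(withPool=TRUE)`
  adds a pool-source transition feeding the catalyst place. The
  alternative — bidirectional (read-arc-like) arcs — was rejected because
  it leaves the pool transition outside every invariant and breaks
  coverage.
* **Output transitions.** Degradations have no post-places. They are what
  closes synthesis→conversion chains into t-invariants; the test suite
  checks that removing the degradation from such a chain breaks coverage.
* **Inhibition drains.** Weakened (not blocked) inhibition is modeled by a
  transition consuming the inhibitor together with the pre-places of the
  inhibited reaction. Complete inhibition is the job of knockout analysis,
  not of the net structure.

`buildP53Fragment()` assembles the fragment for the nuclear p53 activation
balance: places `p53n`, `p53pn`, `ATMan`, `CHK2pn`, `WIP1n`, `MDM2pn`; one
transition per rate term plus the p53 synthesis source and four pools. One
design point was genuinely open: whether the Mdm2-mediated degradation
consumes `MDM2pn` or reads it. The fragment consumes it and feeds `MDM2pn`
from a pool source, consistent with the pool convention above. A
consequence is that knocking out *only* the mediated-degradation transition
leaves its dedicated pool source outside every surviving support; the
meaningful knockout unit is the branch (degradation plus its pool), which
the tests use.

# The reduced ODE fixture

`reducedFixtureModel()` is a closed six-species model around the nuclear
phospho-p53 balance:

$$\frac{d\,p53_{pn}}{dt} = \left(pa_1 + pa_2\frac{ATM_{an}}{ATM_{an}+pm_1} +
pa_3\frac{CHK2_{pn}}{CHK2_{pn}+pm_2}\right) p53_n
- pc_1\, p53_{pn}\, WIP1_n - (pd_4 + pd_5\, MDM2_{pn}^2)\, p53_{pn}$$

`p53n` carries the synthesis source, the mirrored activation/inactivation
terms and first-order degradation; the four driver species follow
first-order production/decay, with `ATMan` and `CHK2pn` production gated by
the ionizing-radiation input. Choices and caveats:

* **Parameters are package defaults, not published estimates.** They were
  chosen once for hour-scale kinetics (decay rates 0.5–1.2 h⁻¹), low
  resting damage signals (ATMan ≈ 0.017, CHK2pn ≈ 0.02 in arbitrary
  concentration units, mirroring homeostasis with low Chk2/ATM/p53p
  levels) and an O(1) resting p53 pool. Species units are arbitrary
  concentration units; no unit system is implied.
* **Initial state = resting steady state, computed analytically.** The
  drivers are linear, and at resting driver levels the (p53n, p53pn) pair
  is linear too, so the no-input equilibrium is available in closed form.
  Starting there makes the 24 h equilibration phase a *verification* (the
  solver must stay put within
  $\lVert \dot x\rVert_\infty < 10^{-6}\lVert x\rVert_\infty + 10^{-9}$)
  rather than a hunt for an equilibrium, which is also the biologically
  sensible reading: a cell enters the experiment in homeostasis.
* **IR input.** The protocol specifies a total dose; the input is a
  rectangular dose-rate pulse of amplitude dose/duration over the 1 h
  stimulation phase.
* **Solver contract.** `deSolve::ode` (lsoda, stiff-capable, adaptive)
  with rtol $10^{-6}$, atol $10^{-9}$; species are clamped at zero during
  RHS evaluation and in returned trajectories. A convergence test checks
  that halving the tolerances changes the fixture trajectory by well under
  0.1%.
* The TNF input is declared but unused by the fixture: the reduced model
  contains no NF-κB arm. It exists so protocol handling is exercised
  end-to-end and models with a TNF-dependent term drop in unchanged.

`settlingTime()` reports when a trajectory permanently enters a ±band
(default 5%) around its final value, measured from the end of the
stimulation phase. Two conventions matter: when the final value is ~0 the
band falls back to the post-stimulation amplitude (so exponential decay
gives the closed form $t^* = \ln(1/\text{band})/p$, which the tests
verify), and a trajectory only counts as settled if the in-band tail covers
at least 10% of the analysis window — otherwise an oscillation that ends
near a sampled extremum would spuriously "settle" at its last crossing.

# OAT sensitivity analysis

Each analyzed parameter is perturbed one at a time, uniformly within ±δ
(default 30%) of its nominal value, `nRuns` times (default 1000; desk-scale
work and the tests use 40–200), with the full three-phase protocol
re-simulated per draw. The published method specifies the sampling scheme
and the averaging but not the index formula, so the index is a pluggable
strategy with two implementations:

* `"l1"` (default): mean over runs of
  $\int |v_r(t) - \bar v(t)|\,dt \,/\, (\int |\bar v(t)|\,dt + \varepsilon)$
  over the stimulation and recovery phases, $\bar v$ the nominal
  trajectory;
* `"dispersion"`: time-averaged inter-run standard deviation normalized by
  the mean nominal level.

Per-variable index columns are max-normalized to $[0,1]$ before the
combined index is formed as the arithmetic row mean. Raw indices of
variables with different scales would make that mean meaningless, which is
why normalization precedes averaging; ranking ties break by parameter id.

**Sampling design.** Draws are keyed on (seed, parameter id, run index), so
any single draw is reproducible in isolation and the whole analysis is
bit-for-bit deterministic. Across the `nRuns` runs of one parameter the
draws are *stratified*: run $r$ falls uniformly within the $r$-th of
`nRuns` equal sub-intervals of the ±δ band. The ensemble remains uniform
over the band, while the Monte Carlo error of the averaged index shrinks
like $n^{-3/2}$ instead of $n^{-1/2}$ — at 40 runs the index of the linear
benchmark below is stable to ~$10^{-3}$, where independent draws would
leave noise comparable to the effects being ranked.

**Benchmark.** On $\dot x = a - bx$ started at steady state, both
trajectories sit at their (perturbed) steady states across the analysis
window, so the expected indices have closed forms:
$E|u| = \delta/2$ for $a$ and $E\left|\frac{u}{1+u}\right|$ for $b$
(quadrature over $u \sim U(-\delta, \delta)$). The classical log-derivative
steady-state sensitivities $|\partial x^*/\partial \log a|$ and
$|\partial x^*/\partial \log b|$ are exactly tied ($x^* = a/b$ gives $a/b$
for both), so they cannot discriminate; the expected-index ordering —
$b$ above $a$, because a relative change in $b$ moves the level by
$|u/(1+u)|$ which averages slightly above $|u|$ — is the discriminating
analytic oracle the acceptance tests use. Failed integrations are discarded
and counted; more than 10% failures abort the analysis (an invented but
necessary policy — silent discard without a cap would bias indices).

**What the fixture does and does not show.** Passing tests demonstrate the
machinery — exact invariants, correct index arithmetic, reproducibility,
agreement with closed forms — on models whose answers are analytically
known. They do not validate any biological claim about the full-scale
pathway: the published 61-equation, 135-parameter model is not reprinted in
the sources available here, so its trajectories, full parameter rankings
and the published net's 541-invariant statistics are out of reach unless
the user supplies the supplementary model files (see the README). The
generated random nets are cycle/chain compositions, structurally far
simpler than real pathway nets; they are chosen because their invariant
sets are provable, not because they mimic pathway topology.

# Problem sizes

The test suite and the acceptance script run at desk scale by design:
random nets at ≤ 8 places × 8 transitions (where brute-force enumeration is
exact and fast), 200 nets per oracle comparison, 40–200 OAT runs per
parameter, and benchmark protocols of a few simulated hours rather than the
full 265 h protocol (which the fixture still runs in well under a second).
These sizes are the package's own testing choices; all engines accept
larger inputs.

# Known limitations

* Reachability, liveness, boundedness, timed/colored/continuous nets and
  MCT/cluster decompositions are out of scope.
* The `.spped` reader covers the discrete place/transition dialect only,
  best-effort, read-only; the Holmes `.project` format is undocumented and
  not parsed.
* The greedy union-knockout search is a heuristic; it is not claimed to
  reproduce any specific published subset-selection algorithm.
* Catalyst-pool translation inflates invariant counts relative to a
  read-arc formalism; significance values are therefore convention-dependent
  and comparable only within one translation convention.
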