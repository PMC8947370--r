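---
title: "Order-based partial information decomposition: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-based partial information decomposition: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blackwellpid)
```

## The decomposition

Given discrete sources $X_1,\dots,X_n$ and a target $Y$ with joint
distribution $P$, the partial information decomposition splits the total
mutual information $I(Y; X_1,\dots,X_n)$ into interpretable parts. This
package defines the two primitive parts by direct analogy with
intersection and union of sets. Fix an ordering relation $Q \sqsubseteq X$
("$Q$ is at most as informative about $Y$ as $X$"). Then

$$I_\cap = \max_Q I(Q;Y) \ \text{ s.t. } \ Q \sqsubseteq X_i \ \forall i,
\qquad
I_\cup = \min_Q I(Q;Y) \ \text{ s.t. } \ X_i \sqsubseteq Q \ \forall i.$$

Unique information, synergy and excluded information are derived
arithmetically: $U_i = I(Y;X_i) - I_\cap$,
$S = I(Y;X_{1..n}) - I_\cup$, $E_i = I_\cup - I(Y;X_i)$. Redundancy and
union information are *independent* measures here: no inclusion–exclusion
identity is imposed, and `iep_residual()` reports the (possibly nonzero,
either-signed) discrepancy $I(Y;X_1)+I(Y;X_2)-I_\cap-I_\cup$ for two
sources.

The package instantiates $\sqsubseteq$ with the **Blackwell order**:
$B \prec_Y C$ iff $P_{B|Y} = \kappa\, P_{C|Y}$ for some stochastic channel
$\kappa$, i.e. the signal $B$ can be simulated by garbling $C$.
Blackwell's theorem gives this order its operational meaning: $B \prec_Y
C$ exactly when no utility-maximization problem about $Y$ is solved
strictly better with $B$ than with $C$. `value_of_information()` and
`blackwell_falsifier()` expose this reading directly: the falsifier
samples random utility games and can *refute* a claimed dominance (one
game where $B$ earns more), but never certify it — certification is the
job of the feasibility test in `is_blackwell_leq()`.

Two stronger orders are implemented for the baseline measures:
conditional independence $Q - X_i - Y$ (`is_ci_leq()`, behind
`redundancy_gh()`) and the deterministic-function order $Q = f(X_i)$
(`is_deterministic_leq()`, behind `redundancy_det()`). The strength chain
deterministic $\Rightarrow$ conditional independence $\Rightarrow$
Blackwell $\Rightarrow$ $I(B;Y) \le I(C;Y)$ yields the measure ordering
$I_\cap^{\lhd} \le I_\cap^{GH} \le I_\cap^{\prec} \le I_\cap^{MMI}$,
which the test suite checks on random joints.

## Computing redundancy: vertex enumeration

Parameterize the optimizer $Q$ by one channel $\kappa_i(q \mid x_i)$ per
source. The constraints are linear: each $\kappa_i$ is column-stochastic,
and all sources must induce the same conditional
$P(q\mid y)=\sum_{x_i}\kappa_i(q|x_i)P(x_i|y)$. The feasible set is a
convex polytope and $I(Q;Y)$ is convex in the stacked channel entries, so
the maximum sits at a vertex. `build_polytope()` assembles the
H-representation and `polytope_vertices()` enumerates vertices:

1. reduce the equality system by SVD to a particular solution plus an
   orthonormal null-space basis (dimension $k$);
2. de-duplicate the projected nonnegativity constraints up to positive
   scaling;
3. treat every subset of $k$ independent active constraints as a basic
   point, keep the feasible ones, and de-duplicate coordinates.

A cardinality of $|Q| = \sum_i |X_i| - n + 1$ is always sufficient for
the optimum (`q_cardinality_bound()`). An optional `q_cap` below the
bound turns the result into a certified *lower* bound, flagged as such in
the diagnostics and never silently substituted. A guard refuses
enumerations beyond `max_bases` active-set combinations
(`pid_vertex_overflow`) instead of stalling; the benchmark gates all
enumerate in milliseconds because their degenerate conditionals collapse
the polytope (for the three-source overlap gate, for example, the
consistency constraints force the channels to be constant on the blocks
of the shared bit, so even the full-cardinality run is small).

Arithmetic is double precision throughout. The benchmark gate tables are
dyadic rationals, which binary floating point represents exactly, and the
SVD/elimination steps on such inputs are stable at the $10^{-9}$
tolerances used for rank decisions, feasibility and vertex
de-duplication. The enumeration-order tie-break among equal-objective
vertices is deterministic; optimizers need not be unique and the returned
$Q$ is one witness.

The returned `pid_result` is a checkable certificate: the value is
recomputable from the optimizer's $(Q, Y)$ joint, the per-source channels
reproduce the same $P(q|y)$ (cross-source residual in the diagnostics,
asserted $\le 10^{-7}$), and the tests verify $Q \prec_Y X_i$ with the
independent feasibility test.

`redundancy_gh()` reuses the same machinery with variables
$\kappa(q \mid x_1..x_n, y)$ on the support cells and linear Markov
constraints ($P(q|x_i,y)$ independent of $y$). No sufficient cardinality
bound is known for this program, so the default reuses the Blackwell
bound and results are reported as certified at the chosen cardinality —
a deliberate, documented choice rather than a claim of global optimality.

## Computing union information: a certified convex program

The union optimization over dominating variables $Q$ is equivalent to a
convex minimization over joint distributions
$\tilde P(x_1,\dots,x_n,y)$ whose pairwise marginals
$\tilde P(x_i, y)$ are pinned to the observed ones:
minimize $I(Y;\tilde X_1..\tilde X_n)$. Since $P(y)$ is fixed by the
constraints, the objective is (a constant minus) the conditional entropy
$H(Y|\tilde X)$, concave in $\tilde P$ — the program is convex.

`union_blackwell()` solves it with a log-barrier damped-Newton
path-following method in the null-space parametrization:

- **Support reduction.** Cells with a zero pinned marginal are forced to
  zero and eliminated, keeping the gradient finite.
- **Initialization.** The conditional-independence coupling
  $P(y)\prod_i P(x_i|y)$ is used as the starting point: it always
  satisfies the marginal constraints and is strictly positive on exactly
  the free support, which an interior-point method requires (the observed
  joint, though feasible, may sit on the boundary).
- **Certificate.** At any feasible $p$, a dual estimate $\nu$ gives
  $s = \nabla f - A^\top\nu$ and the bound
  $\mathrm{gap} \le s\cdot p - \sum_j \min(0, s_j)\,u_j$, where
  $u_j \le 1$ bounds each cell by its smallest pinned marginal. $\nu$ is
  fitted by least squares on the inactive cells (several activity
  thresholds are tried and the best certified bound kept). The default
  tolerance is a duality gap of $10^{-8}$ bits; if the solver cannot
  certify it, it raises `pid_solver_not_converged` with the achieved gap
  rather than returning silently.

The returned coupling is itself a certificate: `union_feasibility_check()`
verifies the pinned marginals, and the tests verify that the coupled
joint source Blackwell-dominates every individual source.

## Baselines and the common part

`common_part()` computes the maximal random variable that is a
deterministic function of every source: supported joint source outcomes
are linked whenever they share a coordinate value, and the connected
components of this graph are the blocks. Maximality holds because any
common function must be constant on each component, and the component
labeling itself is a common function; the tests confirm it against an
exhaustive search over labelings on small alphabets. Blocks are numbered
by their lexicographically smallest member for reproducibility.
`gacs_korner()` is the entropy of the block distribution, and
`redundancy_det()` evaluates $I(\text{blocks}; Y)$ directly — the maximal
common function dominates every deterministic-order-feasible $Q$, so no
search is needed. On full-support source couplings the common part is a
single block and both quantities vanish, however correlated the sources:
this is the known discontinuity of these measures, not an artifact.

## Continuity diagnostic

Blackwell redundancy can be discontinuous in the joint distribution when
the conditionals $P(y|x_i)$ are rank-deficient relative to $|Y|$ (the
geometric mechanism is the discontinuity of intersections of
low-dimensional subspaces). `continuity_condition()` reports the
numerical rank (relative singular-value threshold $10^{-9}$) of each
$P_{Y|X_i}$ and whether at least $n-1$ of them equal $|Y|$ — a
*sufficient* condition for local continuity, automatically met for binary
targets. When unmet the report says "continuity not guaranteed"; it
never claims discontinuity.

## Fixtures, random joints, and what the tests show

`make_gate()` generates the benchmark distributions in exact dyadic
arithmetic: the two-source AND, SUM, UNQ (target copies one source) and
COPY (target copies both) gates with i.i.d. uniform binary sources, their
three-source AND/SUM analogues, and the overlap gate (four i.i.d. bits
$A,B,C,D$; sources $(A,B), (A,C), (A,D)$; target their joint outcome).
For the two-source gates a `correlation` parameter $\rho$ couples the
sources with $P(X_1{=}X_2)=(1+\rho)/2$ while keeping uniform marginals —
a one-parameter family chosen for the symbolic table rows; the symbolic
expectations in the tests are evaluated at the same $\rho$.

`random_joint()` draws seeded Dirichlet(1) tables, optionally sparsified.
The property suites run on two-source joints with binary sources and
targets of up to three outcomes (50 seeded draws per property), with
three-source spot checks on a smaller set — sizes at which the polytopes
enumerate in milliseconds and the whole suite runs in well under a
minute. These fixtures emulate generic small discrete systems; they do
not emulate features of real data such as large alphabets, sampling noise
(all inputs are exact distributions, not estimates), or continuous
marginals. Passing tests therefore certify the algebra and the
optimizers' correctness on small exact inputs, not estimator behavior on
empirical data.

## Known limitations

- Vertex enumeration is exponential in the polytope dimension; large
  alphabets or many sources exceed the `max_bases` guard. Relaxation or
  cutting-plane schemes are out of scope.
- The conditional-independence measure is only certified at its chosen
  cardinality (no known sufficient bound).
- Estimation from finite samples, continuous/Gaussian variables, and
  multivariate lattice refinements of the decomposition are out of scope.
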