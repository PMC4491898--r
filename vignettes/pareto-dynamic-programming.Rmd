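---
title: "Exact Pareto fronts in algebraic dynamic programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Pareto fronts in algebraic dynamic programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretodp)
```

## The model

A combinatorial optimization problem evaluates a search space $X$ of
candidates by an objective $\psi = \varphi \circ \sigma$: a scoring
function $\sigma$ per candidate and a choice function $\varphi$ over the
multiset of scores.  With two scoring functions $\sigma_1, \sigma_2$
over totally ordered carriers, this package computes the **Pareto
front**

$$\mathrm{pf}(S) = \{(a,b) \in S \mid \nexists\,(a',b') \in S
  \text{ dominating } (a,b)\},$$

where $(a',b') \succ (a,b)$ iff it is strictly better in one dimension
and not worse in the other, with "better" fixed per dimension by an
orientation (`order_spec`).  Two classical alternatives are also
provided for comparison and cross-validation: the weighted-additive
combination $\lambda\sigma_1 + (1-\lambda)\sigma_2$ and the
lexicographic combination.

The engine is a miniature algebraic dynamic programming (ADP)
framework: a *tree grammar* generates the candidate terms whose yield
is the input sequence (or sequence pair), an *evaluation algebra*
interprets each term symbol as a scoring function and supplies the
choice function, and tabulated evaluation applies the choice at every
(nonterminal, subword) cell.  The central correctness fact is that the
Pareto choice preserves Bellman's principle whenever both component
algebras optimize a total order with strictly monotone scoring
functions; the package treats this as an *executable* theorem — the
test suite compares every DP front against the brute-force front of the
fully enumerated, doubly scored search space on hundreds of seeded
instances.

## Assumptions that matter

* **Strict monotonicity.** Each $k$-ary scoring function must strictly
  increase in every subproblem argument.  This cannot be checked by the
  engine in general; `check_monotone()` spot-checks it by sampling and
  perturbation, and all shipped algebras (energy, expected accuracy,
  Sankoff SIM/PROB) pass by construction (they add constants or
  non-negative terms).
* **Total orders per dimension.** Minimization is expressed by
  orientation in comparisons, never by negating stored scores, so
  reported values keep their natural scale (free energies stay
  negative).
* **Exact comparisons.** Scores are compared exactly by default.  An
  absolute tolerance $\varepsilon$ can be set in `order_spec(eps =)`
  for probability-valued scores; it is an explicit opt-in, every test
  in this package runs at $\varepsilon = 0$.

## The front operators and their niches

`pf_sort` sorts lexicographically and extracts in one pass
($O(N\log N)$).  `pf_isort` is a Pareto-flavoured insertion sort
(worst case $O(N^2)$) that shrinks the list while sorting.  `pf_lex`
is the one-pass $O(N)$ extractor whose *precondition* is a
lexicographically sorted input; the precondition is verified only in
debug mode, because an unconditional check would forfeit the $O(N)$
claim in production — on unsorted input it returns garbage, by
contract.  `pf_smooth` adds two repair rules to the linear pass and
degrades gracefully ($O(N^2)$ worst case, identical to `pf_lex` with
zero repairs on sorted input).  `pf_nosort` never sorts at all.
`pareto_merge` joins two sorted fronts in linear time with a
`dropWhile`-style elimination.  All operators count oriented scalar
comparisons, which is what `bench_pf()` reports — wall-clock time is
printed but never asserted.

One rule interleaving was left open by the published rewrite system for
the smooth operator: when the incoming pair is out of order *and*
dominates the last kept element, either the out-of-order rules or the
plain drop/keep rules could fire.  This implementation gives the
out-of-order (repair) rules priority and widens their guard from
"strictly greater in the first dimension" to "greater or equal with
domination", which also subsumes duplicate elimination; on sorted input
neither rule can fire, so the equivalence with `pf_lex` is unaffected
(and is asserted by instrumentation).

Duplicate score pairs are removed on construction everywhere: a front
is a set, and two pairs equal in one dimension cannot coexist in a
front anyway (one dominates).  Consequently co-optimal *candidates*
with equal score pairs are represented by one witness each — the first
one encountered; candidate multiplicity is observable through the
enumeration and counting algebras, not through fronts.

## Evaluation strategies

A grammar production is evaluated by three operators: *extend* applies
a scoring function to the cartesian product of subproblem answer lists,
*combine* joins alternative lists, *select* applies the choice.

* **standard**: plain cartesian products and concatenation; select is
  any front operator except `pf_lex` (intermediate lists are unsorted —
  requesting `pf_lex` here is a configuration error).
* **sorted**: every intermediate list is kept lexicographically
  sorted, so select can be the linear `pf_lex`.
* **Pareto-eager**: combine *is* the linear Pareto merge, extension
  folds its monotone sub-lists with the merge, and select degenerates
  to the identity — every intermediate list is already a front (debug
  mode asserts this and that select would remove nothing).

All strategies provably compute the same fronts; the suite asserts this
set equality per instance, and (in debug mode) the intermediate-list
invariants per cell.

## The two applications

**Folding (energy vs expected accuracy).**  The folding grammar is an
unambiguous Nussinov-style decomposition-by-first-position with a
dedicated `stk` symbol for a pair immediately enclosing another pair,
so the energy algebra can score stacking algebraically: each admissible
pair contributes `e_pair` (default −1), each stack additionally
`e_stack` (default −1).  This is deliberately *not* a
nearest-neighbour parameter model: the Pareto machinery is
model-agnostic, and the simplified model keeps the enumeration oracle
exact and fast.  Pairing rule (Watson–Crick + GU) and the minimum loop
size (`minloop`, default 3, meaning a pair $(i,j)$ requires
$j - i > 3$) are configurable; lonely-pair avoidance is an optional
grammar variant, off by default, because it complicates the oracle
without touching the Pareto logic.  The accuracy objective is the plain
sum of base-pair probabilities of the chosen pairs — the published MEA
objective family also weights unpaired positions; that term is omitted
here and the objective is labelled accordingly.  Pair probabilities
come from a generic inside–outside pass over the same grammar with
Boltzmann weights $e^{-\beta E}$ ($\beta = 1$ by default, in model
units), computed entirely in log space so long inputs cannot overflow;
the pass is verified against exhaustive enumeration to $10^{-9}$.

**Sankoff (similarity vs consensus pairing).**  The two-track grammar
consumes alignment columns (match, insert, delete) and forms consensus
pairs between two match columns, with the inner region decomposed
recursively.  The published production rules were not printed in the
available text; the grammar here is reconstructed from the signature
and the recurrences and validated by a *cross-implementation oracle*:
an independent, non-algebraic implementation of the recurrences
(`sankoff_reference_front`) that shares no code with the engine or the
optimized operators.  The similarity algebra scores matches via
$\sigma$ (1/0 by default), gaps via $\gamma$ (−3), and — in the
**corrected** variant — the two columns closed by a consensus pair via
$\sigma$ as well.  The **schnattinger** variant reproduces the
historical scoring in which paired columns earn no similarity credit;
on two identical sequences this anti-correlation inflates the front to
a ladder with one rung per omissible base pair, which the package
demonstrates on a 9-nt hairpin (front size 4 = 3 pairs + 1, confirmed
by the reference recurrences; the corrected variant returns a singleton
on the same input).  Consensus pairs are restricted to match columns
(both sequences contribute a position, which the $\Psi$ lookups
require) and respect `minloop` on both sequences — the recurrences as
published state no loop constraint, so it is configurable and defaults
to the folding value 3.  $\Psi$ matrices default to the partition-based
probabilities; an indicator mode ($\Psi = 1$ for admissible pairs)
makes all scores small integers for exact discrete tests.  Positions,
not characters, index $\Psi$: terminal symbols therefore carry
(character, position) pairs, which resolves the notational ambiguity of
writing $\Psi(a, c)$ over column characters.

## Synthetic data

`generate_sequences()` draws i.i.d. residues with a configurable GC
content (default 0.5, G/C and A/U equiprobable within their class) and
uniform lengths; `(spec, seed)` determines the output byte-for-byte.
It emulates the *content* statistics of random RNA, not the homology
structure, covariation or length distribution of curated families — a
green acceptance run therefore establishes algorithmic exactness
(DP = enumeration) and the distributional facts proved for random
inputs (harmonic-law front sizes), but says nothing about biological
datasets.  The front-size screening utility (`front_size_report`) is
exercised on identical versus shuffled pairs for the same reason: the
direction of the effect (homology ⇒ small front) is testable
synthetically, its magnitude on real families is not.

## Numerical and scale choices

* Acceptance sweeps run 200 seeded instances per class.  Instance
  lengths are drawn below their admissible bounds — folding 6–12 nt of
  the 12-nt bound, Sankoff 2–5 nt of the 6-nt bound — purely to keep
  the full sweep within its time budget on one CPU; the strategy ×
  operator grid is standard × {sort, isort, smooth, nosort} plus the
  sorted and eager strategies with their defining linear `pf_lex`.
  Cross-variant agreement for the remaining (redundant) combinations is
  covered in the module tests at smaller scale.
* The $\lambda$-grid subsumption check accepts that at the endpoints
  ($\lambda \in \{0, 1\}$) the weighted objective ties dominated
  candidates with front members; the assertion is therefore that the
  optimal weighted *value* matches the front and that at least one
  weighted-optimal pair lies on the front.
* For the folding subsumption check the weighted product is formed from
  the negated-energy (maximizing) algebra, since the weighted sum
  requires both components to optimize in the same direction; reported
  fronts keep energies on their natural (minimize) scale.
* The anti-correlation worst case is checked at 9+9 nt against the
  independent recurrence implementation, not against full enumeration,
  which is infeasible there (the candidate space exceeds $10^6$ terms);
  enumeration and recurrences are shown equal on all pairs up to 4+4.
* Guards: `fold_pareto` refuses inputs beyond 200 nt and
  `sankoff_pareto` beyond 40 nt per side by default (the DPs are
  $O(n^3)$ and $O(n^2m^2)$ cells with quadratic front work); both
  bounds are parameters, not hard limits.

## Known limitations

* Pure-R evaluation loop: the engine favours clarity and testability
  over raw speed; realistic-scale folding (hundreds of nt) works but is
  slow compared to compiled DP frameworks.  The front operators
  themselves are compiled.
* Two objectives only; higher-dimensional Pareto optimization needs
  different data structures and is out of scope.
* The energy model is the simplified pair/stack model described above;
  absolute energies are not comparable to thermodynamic predictions.
* Grammars are built in code; there is no grammar DSL, table-design
  optimization, or yield-size analysis.
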