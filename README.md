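# paretodp

Multi-objective dynamic programming with exact Pareto fronts, built on a
small algebraic dynamic-programming (ADP) engine, with two worked RNA
applications.

## The problem

Many sequence-analysis problems optimize a search space of exponentially
many candidates under *two* competing criteria — free energy versus
expected accuracy in RNA folding, or sequence similarity versus
base-pairing strength in joint alignment-and-folding.  The usual fixes
(a weighted sum `λσ₁ + (1−λ)σ₂`, or a lexicographic primary/secondary
order) force an a-priori balance between the objectives.  The
alternative computed here is the **Pareto front**: the set of all score
pairs `(σ₁(x), σ₂(x))` not *dominated* by any other candidate, where
`(a,b) ≻ (a′,b′)` iff one coordinate is strictly better and the other
not worse.

The key fact making this a dynamic program rather than a brute-force
enumeration is that the Pareto product of two well-behaved scoring
algebras preserves Bellman's principle of optimality: taking the front
at every subproblem cell loses no element of the final front.  This
package makes that statement executable — every DP front is tested
against the brute-force front of the fully enumerated search space.

## What is in the package

* **Pareto-set kernels** (Rcpp): domination, five front operators
  (`pf_sort`, `pf_isort`, `pf_lex`, `pf_smooth`, `pf_nosort`), a
  linear-time Pareto merge of sorted fronts, all instrumented with
  hardware-independent comparison counts, plus the harmonic-number
  expectation `H(N) = Σ 1/i` for the front size of `N` random pairs.
* **ADP engine**: tree grammars over one or two input tracks,
  evaluation algebras, tabulated evaluation, full search-space
  enumeration, and the algebra products `*lex`, `*+λ` and `*Par` — the
  last with three evaluation strategies (standard, sorted, Pareto-eager).
* **Applications**: `fold_pareto()` (energy versus expected accuracy on
  a simplified, configurable folding model with a Boltzmann
  inside–outside pass for pair probabilities) and `sankoff_pareto()`
  (joint pairwise alignment and consensus folding under similarity
  versus pairing algebras, with the corrected and the historical
  anti-correlated similarity variants).
* **CLI + simulation**: `pdp_cli()` / `inst/cli/paretodp` with
  subcommands `fold`, `sankoff`, `bench-pf`, `simulate-front-size`,
  `generate`; a seeded synthetic-sequence generator supplies all inputs.

## A worked example

```r
library(paretodp)

fold_pareto("GGGAAACCC")$table
#>  energy      mea structure
#>      -5 1.985371 (((...)))
```

One front element: the hairpin with three stacked pairs, energy −5
(3 pairs at −1 plus 2 stacks at −1) and accumulated pair probability
1.99 — for this sequence the two objectives agree on a single best
structure, so the front is a singleton.  When the objectives disagree
the front spreads out; each row is optimal for *some* trade-off:

```r
fold_pareto("GCUUAACGG")$table
#>  energy       mea structure
#>      -3 0.7841128 ..((...))
#>      -2 0.8934376 .(.(...))
```

The stacked helix is energetically better; the split pair accumulates
more ensemble probability.  Anti-correlated objectives produce the
extreme case:

```r
inp <- sankoff_input("GGGAAACCC", "GGGAAACCC", psi = "indicator")
sankoff_pareto(inp, sankoff_params(variant = "schnattinger"))$table
#>  sim prob alignment_x alignment_y consensus
#>    3    6   GGGAAACCC   GGGAAACCC (((...)))
#>    5    4   GGGAAACCC   GGGAAACCC ((.....))
#>    7    2   GGGAAACCC   GGGAAACCC (.......)
#>    9    0   GGGAAACCC   GGGAAACCC .........
```

Aligning a sequence against itself under the historical similarity
score — which gives paired columns no similarity credit — produces a
worst-case ladder: each omitted base pair buys similarity score at the
cost of pairing score.  The corrected variant
(`sankoff_params(variant = "corrected")`) collapses the same instance
to a single front element `(9, 6)`: no gaps, no mismatches, maximal
pairing.

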