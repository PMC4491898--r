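# The miniature ADP engine: grammars, evaluation, algebra products and
# the three Pareto evaluation strategies.

lemma_grammar <- function() {
  adp_grammar("lemma", tracks = 1L, axiom = "W", rules = list(
    adp_rule("X", "x1"), adp_rule("X", "x2"),
    adp_rule("Y", "y1"), adp_rule("Y", "y2"),
    adp_rule("W", "f", list(nt_arg("X"), nt_arg("Y")))),
    nt_order = c("X", "Y", "W"))
}

lemma_algebras <- function() {
  mk <- function(vals) adp_algebra("num", fns = c(
    list(f = function(x, y) x + y),
    lapply(vals, function(v) function() v)), adp_choice("max"),
    direction = "max")
  list(A = mk(list(x1 = 4, x2 = 3, y1 = 3, y2 = 1)),
       B = mk(list(x1 = 1, x2 = 2, y1 = 3, y2 = 4)))
}

test_that("the binary-extension production is cleaned up by pf", {
  g <- lemma_grammar()
  ab <- lemma_algebras()
  expected <- rbind(c(7, 4), c(6, 5), c(4, 6))
  for (cb in applicable_combos()) {
    p <- product_pareto(ab$A, ab$B, strategy = cb[1], pf_variant = cb[2])
    r <- evaluate(g, p, "", debug = TRUE)
    expect_true(front_setequal(r$value, expected),
                label = paste(cb, collapse = "/"))
  }
})

test_that("enumeration: yields equal input, no duplicate candidates, counts match", {
  set.seed(50)
  for (rep in 1:10) {
    inst <- make_toy_instance(rep + 500)
    cands <- enumerate_candidates(inst$grammar, inst$input)
    expect_gt(length(cands), 0)
    keys <- vapply(cands, function(cc) paste(deparse(cc), collapse = ""),
                   character(1))
    expect_equal(anyDuplicated(keys), 0L)
    cnt <- evaluate(inst$grammar, count_algebra(), inst$input)$value
    expect_equal(cnt, length(cands))
  }
  # yields on a string-consuming grammar
  model <- fold_model()
  g <- fold_grammar(model)
  for (s in c("GAAAC", "GGGAAACCC")) {
    cands <- enumerate_candidates(g, s)
    expect_true(all(vapply(cands, candidate_yield, character(1)) == s))
    expect_equal(fold_count(s, model), length(cands))
  }
  expect_error(enumerate_candidates(g, "GGGAAACCCGGGAAACCC", limit = 5),
               "cell_limit")
})

test_that("evaluate equals choice over the scored enumeration (Eq.-16 route)", {
  set.seed(51)
  for (rep in 1:10) {
    inst <- make_toy_instance(rep + 900)
    cands <- enumerate_candidates(inst$grammar, inst$input)
    sa <- vapply(cands, function(cc) apply_algebra(inst$A, cc), numeric(1))
    v <- evaluate(inst$grammar, inst$A, inst$input)$value
    expect_true(all(v == max(sa)) && length(v) >= 1)
  }
})

test_that("Theorem 3.3 executable: DP Pareto front equals enumerated front", {
  set.seed(52)
  for (rep in 1:25) {
    inst <- make_toy_instance(rep + 100)
    p <- product_pareto(inst$A, inst$B)
    ref <- enum_front(inst$grammar, inst$input, p)
    for (cb in applicable_combos()) {
      r <- evaluate(inst$grammar, p, inst$input, strategy = cb[1],
                    pf_variant = cb[2])
      expect_true(front_setequal(r$value, ref),
                  label = paste("toy", rep, cb[1], cb[2]))
    }
  }
})

test_that("witnesses re-score exactly to their front coordinates", {
  set.seed(53)
  for (rep in 1:8) {
    inst <- make_toy_instance(rep + 300)
    p <- product_pareto(inst$A, inst$B)
    for (st in c("standard", "sorted", "eager")) {
      r <- evaluate(inst$grammar, p, inst$input, strategy = st,
                    witness = TRUE)
      rescored <- do.call(rbind, lapply(r$witnesses, function(w)
        apply_algebra(p, w)))
      expect_equal(rescored, unname(r$value))
    }
  }
})

test_that("lexicographic product: optimum, then B's choice among co-optima", {
  g <- lemma_grammar()
  ab <- lemma_algebras()
  r <- evaluate(g, product_lex(ab$A, ab$B), "")
  expect_equal(unname(r$value), rbind(c(7, 4)))
  # phi_B = identity keeps all B-values of A-optimal candidates
  Ball <- ab$B; Ball$choice <- adp_choice("all")
  # all four candidates are A-co-optimal (A constants all equal)
  mkA <- adp_algebra("A2", fns = c(list(f = function(x, y) x + y),
    lapply(list(x1 = 2, x2 = 2, y1 = 1, y2 = 1), function(v) function() v)),
    adp_choice("max"), direction = "max")
  r2 <- evaluate(g, product_lex(mkA, Ball), "")
  expect_equal(unname(r2$value[, 1]), rep(3, 4))
  expect_setequal(r2$value[, 2], c(4, 5, 5, 6))
  # on enumerated spaces, equals the lexicographic maximum
  set.seed(54)
  for (rep in 1:8) {
    inst <- make_toy_instance(rep + 700)
    p <- product_lex(inst$A, inst$B)
    es <- enum_scores(inst$grammar, inst$input, p)
    o <- lex_order(es$scores, p$orders)
    r <- evaluate(inst$grammar, p, inst$input)
    expect_equal(unname(r$value[1, ]), unname(es$scores[o[1], ]))
  }
})

test_that("weighted-additive product: endpoints and domain errors", {
  g <- lemma_grammar()
  ab <- lemma_algebras()
  expect_equal(unname(evaluate(g, product_add_lambda(ab$A, ab$B, 1), "")$value),
               rbind(c(7, 4)))
  expect_equal(unname(evaluate(g, product_add_lambda(ab$A, ab$B, 0), "")$value),
               rbind(c(4, 6)))
  expect_error(product_add_lambda(ab$A, ab$B, 1.2), "lambda")
  Bmin <- ab$B; Bmin$direction <- "min"
  expect_error(product_add_lambda(ab$A, Bmin, 0.5), "same direction")
})

test_that("Theorem 3.1: *+lambda and *lex optima are recoverable from the front", {
  set.seed(55)
  for (rep in 1:10) {
    inst <- make_toy_instance(rep + 1100)
    p <- product_pareto(inst$A, inst$B)
    front <- evaluate(inst$grammar, p, inst$input)$value
    for (lam in seq(0, 1, by = 0.25)) {
      r <- evaluate(inst$grammar, product_add_lambda(inst$A, inst$B, lam),
                    inst$input)$value
      w <- lam * front[, 1] + (1 - lam) * front[, 2]
      best <- max(lam * r[, 1] + (1 - lam) * r[, 2])
      expect_equal(max(w), best)
      # and at least one weighted-optimal pair is a member of the front
      # (at the endpoints, ties may include dominated co-optima)
      expect_true(any(apply(r, 1, function(p)
        any(front[, 1] == p[1] & front[, 2] == p[2]))))
    }
    rl <- evaluate(inst$grammar, product_lex(inst$A, inst$B), inst$input)$value
    o <- lex_order(front, p$orders)
    expect_equal(unname(front[o[1], ]), unname(rl[1, ]))
  }
})

test_that("pf_lex under the standard strategy is a configuration error", {
  ab <- lemma_algebras()
  expect_error(product_pareto(ab$A, ab$B, strategy = "standard",
                              pf_variant = "lex"), "standard strategy")
  p <- product_pareto(ab$A, ab$B)
  expect_error(evaluate(lemma_grammar(), p, "", strategy = "standard",
                        pf_variant = "lex"), "standard strategy")
})

test_that("singleton search space gives a singleton front", {
  g <- adp_grammar("one", tracks = 1L, axiom = "S",
                   rules = list(adp_rule("S", "h")))
  A <- adp_algebra("a", list(h = function() 2), adp_choice("max"),
                   direction = "max")
  B <- adp_algebra("b", list(h = function() 5), adp_choice("min"),
                   direction = "min")
  r <- evaluate(g, product_pareto(A, B), "")
  expect_equal(unname(r$value), rbind(c(2, 5)))
})

test_that("strategy operator triples behave per their contracts", {
  set.seed(57)
  o <- order_spec()
  X <- pf_sort(rand_pairs(8))$pairs
  Y <- pf_sort(rand_pairs(5))$pairs
  f <- function(x, y) x + y   # componentwise on 2-col matrices
  std <- strategy_ops("standard", o)
  ext <- std$extend(f, X, Y)
  expect_equal(nrow(ext), nrow(X) * nrow(Y))
  grid <- cbind(rep(X[, 1], times = nrow(Y)) + rep(Y[, 1], each = nrow(X)),
                rep(X[, 2], times = nrow(Y)) + rep(Y[, 2], each = nrow(X)))
  srt_rows <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  expect_equal(srt_rows(ext), srt_rows(grid), ignore_attr = TRUE)
  srt <- strategy_ops("sorted", o)
  exts <- srt$extend(f, X, Y)
  expect_identical(lex_order(exts, o), seq_len(nrow(exts)))
  expect_equal(srt$select(exts), pf_lex(exts, o)$pairs, ignore_attr = TRUE)
  egr <- strategy_ops("eager", o)
  exte <- egr$extend(f, X, Y)
  # eager extension is already a Pareto front and select removes nothing
  expect_true(front_setequal(exte, brute_force_front(grid)))
  expect_equal(egr$select(exte), exte, ignore_attr = TRUE)
  cmb <- egr$combine(X, Y)
  expect_true(front_setequal(cmb, brute_force_front(rbind(X, Y))))
})

test_that("Eq.-18 distribution: pf(X u Y) = pf(pf(X) u pf(Y))", {
  set.seed(56)
  for (rep in 1:15) {
    X <- rand_pairs(40, integer = TRUE, M = 9L)
    Y <- rand_pairs(40, integer = TRUE, M = 9L)
    lhs <- brute_force_front(rbind(X, Y))
    rhs <- brute_force_front(rbind(brute_force_front(X)$pairs,
                                   brute_force_front(Y)$pairs))
    expect_true(front_setequal(lhs, rhs))
  }
})

test_that("check_monotone flags violations and passes additive algebras", {
  g <- lemma_grammar()
  sig <- grammar_signature(g)
  bad <- adp_algebra("bad", fns = c(
    list(f = function(x, y) pmin(x, 5) + y),
    lapply(list(x1 = 1, x2 = 2, y1 = 1, y2 = 2), function(v) function() v)),
    adp_choice("max"), direction = "max")
  rep_bad <- check_monotone(bad, sig, n_samples = 60, seed = 2)
  expect_false(attr(rep_bad, "ok"))
  expect_gt(sum(rep_bad$violations[rep_bad$symbol == "f" &
                                     rep_bad$argument == 1]), 0)
  good <- adp_algebra("good", fns = c(
    list(f = function(x, y) x + y + 3.7)),
    adp_choice("max"), direction = "max")
  rep_good <- check_monotone(good, sig["f"], n_samples = 60, seed = 2)
  expect_true(attr(rep_good, "ok"))
  # the Sankoff similarity algebra is strictly monotone
  rep_sim <- check_monotone(sim_algebra(sankoff_params()),
                            grammar_signature(sankoff_grammar()),
                            n_samples = 40, seed = 3)
  expect_true(attr(rep_sim, "ok"))
})

test_that("grammar validation catches structural errors", {
  expect_error(adp_grammar("g", 1L, "S", list(
    adp_rule("S", "f", list(nt_arg("T"))))), "undefined nonterminal")
  expect_error(adp_grammar("g", 1L, "S", list(
    adp_rule("S", "h"), adp_rule("U", "h"))), "unreachable")
  g <- lemma_grammar()
  A <- adp_algebra("partial", list(f = function(x, y) x + y),
                   adp_choice("max"), direction = "max")
  expect_error(evaluate(g, A, ""), "no function for symbol")
})
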