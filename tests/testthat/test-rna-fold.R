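# Bi-objective RNA folding: grammar, counting, partition function and
# the energy/accuracy Pareto front.

structure_ok <- function(pairs, s, model) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  if (nrow(pairs) == 0L) return(TRUE)
  pos <- c(pairs[, 1], pairs[, 2])
  ok <- all(pairs[, 1] < pairs[, 2]) && anyDuplicated(pos) == 0L &&
    all(pairs[, 2] - pairs[, 1] > model$minloop) &&
    all(paste0(ch[pairs[, 1]], ch[pairs[, 2]]) %in% model$pairing)
  # non-crossing
  if (ok && nrow(pairs) > 1L) {
    for (r in seq_len(nrow(pairs) - 1L)) for (q in (r + 1L):nrow(pairs)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]; k <- pairs[q, 1]; l <- pairs[q, 2]
      if (i < k && k < j && j < l) ok <- FALSE
    }
  }
  ok
}

test_that("sequence validation and normalization", {
  expect_equal(rna_seq("gattaca")$residues, "GAUUACA")
  expect_error(rna_seq("ACGX"), "invalid residue")
  expect_error(fold_pareto(""), "empty")
})

test_that("the folding grammar generates exactly the admissible structures", {
  model <- fold_model()
  expect_equal(fold_count("AAAA", model), 1)    # no admissible pair
  expect_equal(fold_count("GAAAC", model), 2)   # open chain + (1,5)
  g <- fold_grammar(model)
  set.seed(60)
  for (rep in 1:6) {
    s <- rand_string(sample(8:12, 1))
    cands <- enumerate_candidates(g, s)
    expect_equal(fold_count(s, model), length(cands))
    dbs <- character(length(cands))
    for (ci in seq_along(cands)) {
      expect_equal(candidate_yield(cands[[ci]]), s)
      prs <- structure_pairs(cands[[ci]])
      expect_true(structure_ok(prs, s, model))
      dbs[ci] <- dot_bracket(prs, nchar(s))
    }
    # unambiguous: one candidate per structure
    expect_equal(anyDuplicated(dbs), 0L)
  }
})

test_that("lonely-pair avoidance restricts to helices of length >= 2", {
  model <- fold_model(avoid_lonely = TRUE)
  base <- fold_model()
  g <- fold_grammar(model)
  set.seed(61)
  for (rep in 1:4) {
    s <- rand_string(10)
    keep <- enumerate_candidates(g, s)
    all_cands <- enumerate_candidates(fold_grammar(base), s)
    helix_ok <- function(prs) {
      if (nrow(prs) == 0L) return(TRUE)
      key <- paste(prs[, 1], prs[, 2])
      stacked <- function(i, j) paste(i + 1, j - 1) %in% key ||
        paste(i - 1, j + 1) %in% key
      all(mapply(stacked, prs[, 1], prs[, 2]))
    }
    expected <- sum(vapply(all_cands, function(cc)
      helix_ok(structure_pairs(cc)), logical(1)))
    expect_equal(length(keep), expected)
    expect_true(all(vapply(keep, function(cc)
      helix_ok(structure_pairs(cc)), logical(1))))
  }
})

test_that("pair probabilities match exhaustive enumeration", {
  model <- fold_model()
  expect_true(all(partition_pairprobs("AAAA", model) == 0))
  # two equiprobable structures in the beta -> 0 limit
  psi <- partition_pairprobs("GAAAC", fold_model(beta = 1e-12))
  expect_equal(psi[1, 5], 0.5, tolerance = 1e-9)
  g <- fold_grammar(model)
  set.seed(62)
  for (rep in 1:5) {
    s <- rand_string(10)
    cands <- enumerate_candidates(g, s)
    E <- vapply(cands, function(cc)
      apply_algebra(energy_algebra(model), cc), numeric(1))
    w <- exp(-model$beta * E)
    n <- nchar(s)
    ref <- matrix(0, n, n)
    for (ci in seq_along(cands)) {
      prs <- structure_pairs(cands[[ci]])
      if (nrow(prs)) for (r in seq_len(nrow(prs)))
        ref[prs[r, 1], prs[r, 2]] <- ref[prs[r, 1], prs[r, 2]] + w[ci]
    }
    ref <- ref / sum(w)
    psi <- partition_pairprobs(s, model)
    expect_lt(max(abs(psi - ref)), 1e-9)
    expect_true(all(rowSums(psi + t(psi)) <= 1 + 1e-12))
  }
})

test_that("energy and accuracy algebras score structures as documented", {
  model <- fold_model()
  g <- fold_grammar(model)
  cands <- enumerate_candidates(g, "GAAAC")
  dbs <- vapply(cands, function(cc)
    dot_bracket(structure_pairs(cc), 5), character(1))
  open <- cands[[which(dbs == ".....")]]
  paired <- cands[[which(dbs == "(...)")]]
  psi <- partition_pairprobs("GAAAC", model)
  expect_equal(apply_algebra(energy_algebra(model), open), 0)
  expect_equal(apply_algebra(mea_algebra(psi), open), 0)
  expect_equal(apply_algebra(energy_algebra(model), paired), model$e_pair)
  expect_equal(apply_algebra(mea_algebra(psi), paired), psi[1, 5])
  # single-objective DP optima equal exhaustive optima
  set.seed(63)
  for (rep in 1:4) {
    s <- rand_string(12)
    cands <- enumerate_candidates(g, s)
    E <- vapply(cands, function(cc)
      apply_algebra(energy_algebra(model), cc), numeric(1))
    expect_equal(unique(evaluate(g, energy_algebra(model), s)$value), min(E))
    psi <- partition_pairprobs(s, model)
    M <- vapply(cands, function(cc)
      apply_algebra(mea_algebra(psi), cc), numeric(1))
    expect_equal(unique(evaluate(g, mea_algebra(psi), s)$value), max(M))
  }
})

test_that("both folding algebras pass the monotonicity spot-check", {
  model <- fold_model()
  sig <- grammar_signature(fold_grammar(model))
  expect_true(attr(check_monotone(energy_algebra(model), sig,
                                  n_samples = 40, seed = 5), "ok"))
  psi <- matrix(runif(400), 20, 20)
  expect_true(attr(check_monotone(mea_algebra(psi), sig,
                                  n_samples = 40, seed = 5), "ok"))
})

test_that("fold_pareto: trivial front, oracle equality, witness consistency", {
  model <- fold_model()
  r <- fold_pareto("AAAA", model)
  expect_equal(unname(r$front$pairs), rbind(c(0, 0)))
  expect_equal(r$table$structure, "....")
  set.seed(64)
  for (rep in 1:5) {
    s <- rand_string(sample(8:12, 1))
    psi <- partition_pairprobs(s, model)
    prod <- product_pareto(energy_algebra(model), mea_algebra(psi))
    ref <- enum_front(fold_grammar(model), s, prod)
    for (cb in applicable_combos()[c(1, 4, 5, 9)]) {
      rr <- fold_pareto(s, model, strategy = cb[1], pf_variant = cb[2],
                        psi = psi)
      expect_true(front_setequal(rr$front, ref))
      # witnesses re-score to their coordinates
      resc <- do.call(rbind, lapply(rr$witnesses, function(w)
        apply_algebra(prod, w)))
      expect_equal(resc, unname(rr$front$pairs))
    }
    # front size bounded by the number of distinct energy values
    es <- enum_scores(fold_grammar(model), s, prod)
    expect_lte(length(ref), length(unique(es$scores[, 1])))
  }
})

test_that("orientation flip: maximizing -energy yields the mirrored front", {
  model <- fold_model()
  set.seed(65)
  s <- rand_string(11)
  psi <- partition_pairprobs(s, model)
  r1 <- fold_pareto(s, model, psi = psi)
  neg <- adp_algebra("negenergy", fns = list(
    nil = function() 0,
    unp = function(t, x) x,
    split = function(x, y) x + y,
    pr = function(t1, x, t2) x - model$e_pair,
    stk = function(t1, x, t2) x - model$e_pair - model$e_stack),
    choice = adp_choice("max"), carrier = "numeric", direction = "max")
  p2 <- product_pareto(neg, mea_algebra(psi))
  r2 <- evaluate(fold_grammar(model), p2, s)
  flipped <- cbind(-r2$value[, 1], r2$value[, 2])
  expect_true(front_setequal(r1$front$pairs, flipped))
})

test_that("fold_pareto refuses over-long input", {
  expect_error(fold_pareto(strrep("A", 30), max_len = 20), "max_len")
})
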