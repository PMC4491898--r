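# Pareto-set mathematics: domination, the front operators, the linear
# merge and the harmonic law.

paper_set <- rbind(c(7, 4), c(5, 5), c(6, 5), c(4, 6))
paper_front <- rbind(c(7, 4), c(6, 5), c(4, 6))

test_that("dominates implements strict-in-one, not-worse-in-other", {
  expect_true(dominates(c(6, 5), c(5, 5)))
  expect_false(dominates(c(5, 5), c(6, 5)))
  expect_false(dominates(c(2, 3), c(3, 2)))
  expect_false(dominates(c(3, 2), c(2, 3)))
  expect_false(dominates(c(4, 7), c(4, 7)))
  # orientation: under min/min the smaller pair dominates
  o <- order_spec("min", "min")
  expect_true(dominates(c(5, 5), c(6, 5), o))
  expect_false(dominates(c(6, 5), c(5, 5), o))
  # mixed orientation, e.g. energy (min) vs accuracy (max)
  o2 <- order_spec("min", "max")
  expect_true(dominates(c(-3, 0.5), c(-2, 0.5), o2))
  expect_error(dominates(c(Inf, 1), c(0, 0)), "finite")
})

test_that("brute-force front oracle satisfies the defining properties", {
  f <- brute_force_front(paper_set)
  expect_true(front_setequal(f, paper_front))
  expect_equal(length(brute_force_front(matrix(numeric(0), ncol = 2))), 0L)
  set.seed(41)
  for (rep in 1:20) {
    X <- rand_pairs(sample(c(1, 3, 17, 80), 1),
                    integer = sample(c(TRUE, FALSE), 1))
    orders <- sample(all_order_specs(), 1)[[1]]
    f <- brute_force_front(X, orders)
    # pf(X) subset of X
    expect_true(all(apply(f$pairs, 1, function(p)
      any(X[, 1] == p[1] & X[, 2] == p[2]))))
    # empty iff input empty
    expect_gt(length(f), 0L)
    # idempotency
    expect_true(front_setequal(brute_force_front(f$pairs, orders), f))
    # no element dominates another, no duplicates
    expect_silent(validate_front(f))
  }
})

test_that("intersection property: pf(X & Y) contains pf(X) & pf(Y)", {
  set.seed(42)
  for (rep in 1:10) {
    pool <- rand_pairs(40, integer = TRUE, M = 8L)
    X <- pool[sample.int(40, 25), , drop = FALSE]
    Y <- pool[sample.int(40, 25), , drop = FALSE]
    key <- function(m) paste(m[, 1], m[, 2])
    XiY <- X[key(X) %in% key(Y), , drop = FALSE]
    lhs <- key(brute_force_front(XiY)$pairs)
    rhs <- intersect(key(brute_force_front(X)$pairs),
                     key(brute_force_front(Y)$pairs))
    expect_true(all(rhs %in% lhs))
  }
})

test_that("all five operators agree with the oracle on the worked set", {
  for (v in pf_variants()) {
    input <- if (v == "lex") paper_set[order(-paper_set[, 1]), ] else paper_set
    expect_true(front_setequal(pf(input, variant = v), paper_front),
                label = v)
  }
  # sorted variants return the exact sorted order
  expect_equal(pf_isort(paper_set)$pairs, paper_front,
               ignore_attr = TRUE)
  expect_equal(pf_sort(paper_set)$pairs, paper_front, ignore_attr = TRUE)
  expect_equal(pf_smooth(paper_set)$pairs, paper_front, ignore_attr = TRUE)
})

test_that("operators equal the oracle on random inputs in all orientations", {
  set.seed(43)
  for (rep in 1:12) {
    n <- sample(c(1, 2, 10, 200, 1000), 1)
    X <- rand_pairs(n, integer = rep %% 2 == 0, M = 12L)
    orders <- sample(all_order_specs(), 1)[[1]]
    ref <- brute_force_front(X, orders)
    for (v in c("sort", "isort", "smooth", "nosort")) {
      f <- pf(X, orders, variant = v)
      expect_true(front_setequal(f, ref), label = paste(v, "rep", rep))
      if (v != "nosort") {
        # Observation 2: strictly decreasing in A, increasing in B
        expect_true(f$sorted)
        expect_silent(validate_front(f))
      }
    }
    Xs <- X[lex_order(X, orders), , drop = FALSE]
    expect_true(front_setequal(pf_lex(Xs, orders, check = TRUE), ref))
  }
})

test_that("pf_lex precondition is a contract checked only in debug mode", {
  bad <- rbind(c(1, 5), c(7, 4))   # increasing in A: not sorted
  expect_error(pf_lex(bad, check = TRUE), "sorted")
  expect_silent(pf_lex(bad, check = FALSE))  # garbage in, no diagnosis
})

test_that("pf_smooth equals pf_lex on sorted input with zero repairs", {
  set.seed(44)
  for (rep in 1:8) {
    X <- rand_pairs(50)
    Xs <- X[lex_order(X), , drop = FALSE]
    fs <- pf_smooth(Xs)
    fl <- pf_lex(Xs)
    expect_equal(fs$pairs, fl$pairs, ignore_attr = TRUE)
    expect_identical(attr(fs, "repairs"), 0)
    # identical comparison trace on sorted input
    expect_lte(attr(fs, "comparisons"), 2 * attr(fl, "comparisons") + 2)
  }
  expect_gt(attr(pf_smooth(rbind(c(1, 1), c(2, 2))), "repairs"), 0)
})

test_that("worst-case front size on integer grids is M (Observation 3)", {
  set.seed(45)
  M <- 50L
  for (rep in 1:5) {
    X <- rand_pairs(500, integer = TRUE, M = M)
    expect_lte(length(pf_sort(X)), M)
  }
  i <- sample.int(M)
  adversarial <- cbind(as.numeric(i), as.numeric(M - i))
  for (v in c("sort", "isort", "smooth", "nosort"))
    expect_equal(length(pf(adversarial, variant = v)), M)
})

test_that("pareto_merge matches pf of the union, linearly", {
  o <- order_spec()
  e <- pareto_front(matrix(numeric(0), ncol = 2), o, sorted = TRUE)
  y <- pf_sort(rbind(c(1, 2), c(3, 1)))
  expect_equal(pareto_merge(e, y)$pairs, y$pairs, ignore_attr = TRUE)
  expect_equal(pareto_merge(y, e)$pairs, y$pairs, ignore_attr = TRUE)
  m <- pareto_merge(pareto_front(rbind(c(7, 4), c(4, 6)), o, sorted = TRUE),
                    pareto_front(rbind(c(6, 5), c(3, 7)), o, sorted = TRUE))
  expect_equal(m$pairs, rbind(c(7, 4), c(6, 5), c(4, 6), c(3, 7)),
               ignore_attr = TRUE)
  set.seed(46)
  for (rep in 1:10) {
    A <- pf_sort(rand_pairs(sample(c(1, 10, 300), 1)))
    B <- pf_sort(rand_pairs(sample(c(1, 10, 300), 1)))
    C <- pf_sort(rand_pairs(sample(c(1, 10, 300), 1)))
    u <- brute_force_front(rbind(A$pairs, B$pairs))
    ab <- pareto_merge(A, B, check = TRUE)
    expect_true(front_setequal(ab, u))
    # commutativity and associativity (Observation 1)
    expect_equal(pareto_merge(B, A)$pairs, ab$pairs, ignore_attr = TRUE)
    lhs <- pareto_merge(ab, C)
    rhs <- pareto_merge(A, pareto_merge(B, C))
    expect_equal(lhs$pairs, rhs$pairs, ignore_attr = TRUE)
    expect_true(front_setequal(
      lhs, brute_force_front(rbind(A$pairs, B$pairs, C$pairs))))
    # linear comparison count
    expect_lte(attr(ab, "comparisons"), 8 * (length(A) + length(B)) + 8)
  }
  expect_error(pareto_merge(pareto_front(rbind(c(1, 1), c(2, 2)), o,
                                         sorted = TRUE), y, check = TRUE),
               "sorted Pareto list")
})

test_that("harmonic numbers", {
  expect_identical(harmonic(1), 1)
  expect_identical(harmonic(2), 1.5)
  expect_equal(harmonic(100), sum(1 / (1:100)))
  expect_equal(harmonic(100), 5.18737751763962, tolerance = 1e-12)
  # H(N) ~ ln N + Euler-Mascheroni for large N
  expect_equal(harmonic(1e5), log(1e5) + 0.5772156649, tolerance = 1e-5)
  expect_error(harmonic(0), "N")
})

test_that("strictly monotone unary extension preserves the Pareto property", {
  set.seed(47)
  for (rep in 1:50) {
    f <- pf_sort(rand_pairs(30))
    a <- runif(2, 0.2, 3); b <- runif(2, -2, 2)
    mapped <- cbind(a[1] * f$pairs[, 1] + b[1],
                    exp(a[2] * f$pairs[, 2] + b[2]))  # both strictly increasing
    expect_equal(length(brute_force_front(mapped)), length(f))
  }
  # the binary counter-example: componentwise + does not preserve it
  X <- rbind(c(4, 1), c(3, 2)); Y <- rbind(c(3, 3), c(1, 4))
  ext <- cbind(rep(X[, 1], each = 2) + Y[, 1], rep(X[, 2], each = 2) + Y[, 2])
  expect_true(front_setequal(rbind(ext), paper_set))
  expect_true(dominates(c(6, 5), c(5, 5)))
  expect_true(front_setequal(brute_force_front(ext), paper_front))
})

test_that("comparison tolerance eps treats near-ties as equal", {
  o <- order_spec(eps = 1e-6)
  expect_false(dominates(c(1 + 1e-9, 1), c(1, 1), o))
  expect_true(dominates(c(1 + 1e-3, 1), c(1, 1), o))
  X <- rbind(c(1, 1), c(1 + 1e-9, 1))
  expect_equal(length(brute_force_front(X, o)), 1L)  # duplicates under eps
})

test_that("TSV serialization round-trips a front", {
  f <- pf_sort(paper_set)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_front_tsv(f, path, labels = c("s1", "s2", "s3"),
                  header_lines = "cfg: test")
  lines <- readLines(path)
  expect_match(lines[1], "^# cfg")
  df <- read.delim(path, comment.char = "#")
  expect_equal(df$score_a, f$pairs[, 1])
  expect_equal(df$score_b, f$pairs[, 2])
  expect_equal(df$candidate, c("s1", "s2", "s3"))
})
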