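# Shared generators and oracles for the test suite.  All randomness is
# seed-parameterized; suites fix their seeds.

ACGU <- c("A", "C", "G", "U")

rand_pairs <- function(n, integer = FALSE, M = 10L) {
  if (integer) cbind(sample.int(M, n, replace = TRUE),
                     sample.int(M, n, replace = TRUE)) + 0
  else matrix(runif(2 * n), ncol = 2)
}

rand_string <- function(len) paste(sample(ACGU, len, replace = TRUE),
                                   collapse = "")

all_order_specs <- function() list(
  order_spec("max", "max"), order_spec("max", "min"),
  order_spec("min", "max"), order_spec("min", "min"))

# strategy x pf-variant combinations admissible for the Pareto product
applicable_combos <- function() list(
  c("standard", "sort"), c("standard", "isort"), c("standard", "smooth"),
  c("standard", "nosort"),
  c("sorted", "lex"), c("sorted", "sort"), c("sorted", "isort"),
  c("sorted", "smooth"),
  c("eager", "lex"))

# ---- toy instances ----------------------------------------------------------
# The example production W -> f(X, Y) | g(Z) | h with constant answer
# alternatives: f is the hard binary case of Pareto set extension, g a
# strictly monotone unary map, h a constant.

make_toy_instance <- function(seed) {
  set.seed(seed)
  nx <- sample(2:4, 1); ny <- sample(2:4, 1); nz <- sample(1:3, 1)
  consts_a <- as.numeric(sample.int(10, nx + ny + nz + 1, replace = TRUE))
  consts_b <- as.numeric(sample.int(10, nx + ny + nz + 1, replace = TRUE))
  gshift_a <- runif(1, 0.5, 3); gshift_b <- runif(1, 0.5, 3)
  nms <- c(paste0("x", seq_len(nx)), paste0("y", seq_len(ny)),
           paste0("z", seq_len(nz)), "h")
  mk_fns <- function(consts, gshift) {
    fns <- list(f = function(x, y) x + y,
                g = function(x) x + gshift)
    for (i in seq_along(nms)) {
      local({
        v <- consts[i]
        fns[[nms[i]]] <<- function() v
      })
    }
    fns
  }
  A <- adp_algebra("A", mk_fns(consts_a, gshift_a), adp_choice("max"),
                   direction = "max")
  B <- adp_algebra("B", mk_fns(consts_b, gshift_b), adp_choice("max"),
                   direction = "max")
  rules <- c(
    lapply(paste0("x", seq_len(nx)), function(s) adp_rule("X", s)),
    lapply(paste0("y", seq_len(ny)), function(s) adp_rule("Y", s)),
    lapply(paste0("z", seq_len(nz)), function(s) adp_rule("Z", s)),
    list(adp_rule("W", "f", list(nt_arg("X"), nt_arg("Y"))),
         adp_rule("W", "g", list(nt_arg("Z"))),
         adp_rule("W", "h")))
  g <- adp_grammar("toy", tracks = 1L, axiom = "W", rules = rules,
                   nt_order = c("X", "Y", "Z", "W"))
  list(grammar = g, A = A, B = B, input = "")
}

# score every enumerated candidate under a pair algebra
enum_scores <- function(grammar, input, pair_algebra, limit = 100000) {
  cands <- enumerate_candidates(grammar, input, limit = limit)
  list(candidates = cands,
       scores = do.call(rbind, lapply(cands, function(cc)
         apply_algebra(pair_algebra, cc))))
}

# Pareto front of the fully enumerated, doubly-scored search space
enum_front <- function(grammar, input, pair_algebra, limit = 100000) {
  es <- enum_scores(grammar, input, pair_algebra, limit)
  brute_force_front(es$scores, pair_algebra$orders)
}

# ---- folding instances ------------------------------------------------------

make_fold_instance <- function(seed, min_len = 6L, max_len = 12L) {
  set.seed(seed)
  len <- sample(min_len:max_len, 1)
  s <- rand_string(len)
  model <- fold_model()
  psi <- partition_pairprobs(s, model)
  list(seq = s, model = model, psi = psi,
       product = product_pareto(energy_algebra(model), mea_algebra(psi)))
}

# number of consensus Pair symbols in a Sankoff candidate term
count_pair_syms <- function(term) {
  n <- 0L
  rec <- function(x) {
    if (inherits(x, "adp_term")) return(invisible())
    if (x$sym == "Pair") n <<- n + 1L
    for (a in x$args) if (!inherits(a, "adp_term")) rec(a)
  }
  rec(term)
  n
}

# ---- Sankoff instances ------------------------------------------------------

make_sankoff_instance <- function(seed, min_len = 2L, max_len = 5L,
                                  psi = "indicator",
                                  variant = c("corrected", "schnattinger")) {
  set.seed(seed)
  variant <- if (length(variant) > 1L) sample(variant, 1) else variant
  x <- rand_string(sample(min_len:max_len, 1))
  y <- rand_string(sample(min_len:max_len, 1))
  params <- sankoff_params(variant = variant)
  inp <- sankoff_input(x, y, psi = psi)
  list(input = inp, params = params,
       product = product_pareto(sim_algebra(params), prob_algebra(inp)))
}
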