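#' Choice (objective) functions
#'
#' A choice function maps the multiset of candidate scores of a
#' subproblem to the answers that survive.  Selective choices
#' (max, min, Pareto front, lexicographic, weighted sum, `all`)
#' return indices into the value list so that candidate witnesses can
#' follow their scores; reducing choices (`sum`, used by counting
#' algebras) collapse the list to an aggregate.
#'
#' @param kind one of `"max"`, `"min"`, `"all"`, `"sum"`.
#' @return an `adp_choice` object.
#' @export
adp_choice <- function(kind = c("max", "min", "all", "sum")) {
  kind <- match.arg(kind)
  selective <- kind != "sum"
  structure(list(kind = kind, selective = selective, params = list()),
            class = "adp_choice")
}

.choice_pf <- function(orders, variant = "nosort", check = FALSE) {
  structure(list(kind = "pf", selective = TRUE,
                 params = list(orders = orders, variant = variant,
                               check = check)),
            class = "adp_choice")
}

.choice_lex <- function(orders, b_kind = "opt") {
  structure(list(kind = "lex", selective = TRUE,
                 params = list(orders = orders, b_kind = b_kind)),
            class = "adp_choice")
}

.choice_wsum <- function(lambda, direction) {
  structure(list(kind = "wsum", selective = TRUE,
                 params = list(lambda = lambda, direction = direction)),
            class = "adp_choice")
}

# returns kept indices for selective choices given the value container
.choice_select <- function(choice, vals) {
  switch(choice$kind,
    all = seq_len(.val_len(vals)),
    max = which(vals == max(vals)),
    min = which(vals == min(vals)),
    pf = {
      p <- choice$params
      .pf_idx(vals, p$orders, p$variant, p$check)
    },
    lex = {
      orders <- choice$params$orders
      a <- .sign_a(orders) * vals[, 1]
      ia <- which(a == max(a))
      if (identical(choice$params$b_kind, "all")) ia
      else {
        b <- .sign_b(orders) * vals[, 2]
        ia[b[ia] == max(b[ia])]
      }
    },
    wsum = {
      p <- choice$params
      w <- p$lambda * vals[, 1] + (1 - p$lambda) * vals[, 2]
      if (p$direction == "max") which(w == max(w)) else which(w == min(w))
    },
    stop("choice kind ", choice$kind, " is not selective"))
}

.choice_reduce <- function(choice, vals) {
  switch(choice$kind,
         sum = sum(vals),
         stop("choice kind ", choice$kind, " is not reducing"))
}

.val_len <- function(vals) {
  if (is.matrix(vals)) nrow(vals) else length(vals)
}

# Pareto-front kept indices (into the original row order)
.pf_idx <- function(m, orders, variant, check = FALSE) {
  sa <- .sign_a(orders); sb <- .sign_b(orders); eps <- orders$eps
  switch(variant,
    sort = {
      o <- lex_order(m, orders)
      res <- cpp_pf_lex(m[o, , drop = FALSE], sa, sb, eps, FALSE)
      o[res$idx + 1L]
    },
    isort = cpp_pf_isort(m, sa, sb, eps)$idx + 1L,
    lex = cpp_pf_lex(m, sa, sb, eps, check)$idx + 1L,
    smooth = cpp_pf_smooth(m, sa, sb, eps)$idx + 1L,
    nosort = cpp_pf_nosort(m, sa, sb, eps)$idx + 1L,
    stop("unknown pf variant: ", variant))
}

#' Evaluation algebra
#'
#' An interpretation of a grammar's signature: one scoring function per
#' symbol plus a choice function.  Scoring functions receive subproblem
#' answers and terminal values in the argument order of the grammar
#' rule.  For the `"numeric"` carrier, functions must be vectorized
#' over their subproblem arguments (terminal arguments arrive as single
#' `adp_term` objects and behave like constants under recycling); this
#' is what makes the tabulated evaluation fast.
#'
#' @param name algebra name.
#' @param fns named list of scoring functions, one per signature symbol.
#' @param choice an `adp_choice` (or one made by the product
#'   constructors).
#' @param carrier `"numeric"` (scores are numbers), `"pair"`
#'   (two-dimensional scores as 2-column matrices).
#' @param direction `"max"`, `"min"` or `NULL`; the total-order
#'   orientation when the choice optimizes.  Used by the product
#'   constructors to orient the Pareto front.
#' @return an object of class `adp_algebra`.
#' @export
adp_algebra <- function(name, fns, choice,
                        carrier = c("numeric", "pair"),
                        direction = NULL) {
  carrier <- match.arg(carrier)
  if (!inherits(fns, c("adp_fn_any", "adp_fn_pair")))
    stopifnot(is.list(fns), !is.null(names(fns)),
              all(vapply(fns, is.function, logical(1))))
  stopifnot(inherits(choice, "adp_choice"))
  structure(list(name = name, fns = fns, choice = choice,
                 carrier = carrier, direction = direction),
            class = "adp_algebra")
}

#' @export
print.adp_algebra <- function(x, ...) {
  cat(sprintf("<adp_algebra '%s': carrier %s, choice %s%s>\n",
              x$name, x$carrier, x$choice$kind,
              if (!is.null(x$direction)) paste0(", ", x$direction) else ""))
  invisible(x)
}

#' Score one candidate term under an algebra
#'
#' Interprets a candidate (as returned by [enumerate_candidates()] or
#' as an evaluation witness) bottom-up.  This is the non-tabulated
#' route used by the enumeration oracle and by witness re-scoring.
#'
#' @param algebra an [adp_algebra()].
#' @param term a candidate term.
#' @return a carrier value (number or length-2 score pair).
#' @export
apply_algebra <- function(algebra, term) {
  rec <- function(t) {
    args <- lapply(t$args, function(a) {
      if (inherits(a, "adp_term")) a else rec(a)
    })
    f <- algebra$fns[[t$sym]]
    if (is.null(f)) stop("algebra has no function for symbol ", t$sym)
    if (algebra$carrier == "pair") {
      args <- lapply(args, function(a) {
        if (inherits(a, "adp_term")) a else matrix(a, ncol = 2)
      })
      as.numeric(do.call(f, args))
    } else {
      do.call(f, args)
    }
  }
  rec(term)
}

#' The counting algebra
#'
#' Determines the size of the search space: every symbol multiplies the
#' counts of its subproblem arguments and the choice function sums.
#'
#' @return an [adp_algebra()] with a summing choice.
#' @export
count_algebra <- function() {
  count_fn <- function(...) {
    args <- Filter(Negate(function(a) inherits(a, "adp_term")), list(...))
    Reduce(`*`, args, 1)
  }
  adp_algebra("count", fns = .symbol_fn_table(count_fn),
              choice = adp_choice("sum"), carrier = "numeric")
}

# a "table" that serves the same function for every symbol
.symbol_fn_table <- function(fn) {
  structure(list(), class = c("adp_fn_any", "list"), fn = fn)
}

#' @export
`[[.adp_fn_any` <- function(x, i) attr(x, "fn")

#' Spot-check strict monotonicity of an algebra's scoring functions
#'
#' When the choice function maximizes or minimizes over a total order,
#' Bellman's principle requires every scoring function to be strictly
#' monotone in each subproblem argument.  This samples random argument
#' tuples, perturbs one subproblem argument upward and checks that the
#' score strictly increases (strict monotonicity with respect to the
#' carrier's numeric order, which is the required direction for both
#' maximizing and minimizing choices).
#'
#' @param algebra a numeric-carrier [adp_algebra()].
#' @param signature a [grammar_signature()] naming the symbols and
#'   their argument kinds.
#' @param n_samples samples per (symbol, argument) combination.
#' @param seed RNG seed.
#' @param term_sampler `function(width)` producing a random `adp_term`
#'   for a terminal argument; the default draws RNA characters and
#'   positions 1..20 (override when scoring functions index external
#'   matrices).
#' @return a data frame (symbol, argument, samples, violations); the
#'   attribute `ok` is `TRUE` when no violations were found.
#' @export
check_monotone <- function(algebra, signature, n_samples = 50, seed = 1,
                           term_sampler = NULL) {
  stopifnot(algebra$carrier == "numeric")
  if (is.null(term_sampler)) {
    term_sampler <- function(width) {
      mk <- function() list(char = sample(c("A", "C", "G", "U"), 1),
                            pos = sample.int(20L, 1))
      if (length(width) == 1L) {
        structure(mk(), class = "adp_term")
      } else {
        a <- mk(); b <- mk()
        structure(list(xchar = if (width[1]) a$char else NA,
                       xpos = if (width[1]) a$pos else NA,
                       ychar = if (width[2]) b$char else NA,
                       ypos = if (width[2]) b$pos else NA),
                  class = "adp_term")
      }
    }
  }
  rows <- list()
  .with_seed(seed, {
    for (sym in names(signature)) {
      kinds <- signature[[sym]]$kinds
      nt_pos <- which(kinds == "nt")
      if (length(nt_pos) == 0L) next
      f <- algebra$fns[[sym]]
      for (p in nt_pos) {
        viol <- 0L
        for (s in seq_len(n_samples)) {
          args <- vector("list", length(kinds))
          for (q in seq_along(kinds)) {
            args[[q]] <- if (kinds[q] == "nt") runif(1, -10, 10)
                         else term_sampler(signature[[sym]]$widths[[q]])
          }
          base <- do.call(f, args)
          args[[p]] <- args[[p]] + runif(1, 0.1, 2)
          up <- do.call(f, args)
          if (!(up > base)) viol <- viol + 1L
        }
        rows[[length(rows) + 1L]] <-
          data.frame(symbol = sym, argument = p, samples = n_samples,
                     violations = viol)
      }
    }
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(symbol = character(0), argument = integer(0),
                         samples = integer(0), violations = integer(0))
  attr(out, "ok") <- all(out$violations == 0L)
  out
}

# evaluate an expression with a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
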