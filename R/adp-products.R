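# Algebra products: the pairwise scoring functions are shared (each
# symbol scores independently in both coordinates); the products differ
# only in their objective.

.pair_fn_table <- function(A, B) {
  structure(list(), class = c("adp_fn_pair", "list"), A = A, B = B)
}

#' @export
`[[.adp_fn_pair` <- function(x, i) {
  fa <- attr(x, "A")$fns[[i]]
  fb <- attr(x, "B")$fns[[i]]
  if (is.null(fa) || is.null(fb)) return(NULL)
  function(...) {
    args <- list(...)
    aargs <- lapply(args, function(a) if (is.matrix(a)) a[, 1] else a)
    bargs <- lapply(args, function(a) if (is.matrix(a)) a[, 2] else a)
    cbind(do.call(fa, aargs), do.call(fb, bargs))
  }
}

.require_direction <- function(x, who) {
  if (is.null(x$direction) || !(x$direction %in% c("max", "min")))
    stop(who, ": algebra '", x$name,
         "' must maximize or minimize over a total order")
}

#' Pareto product of two evaluation algebras
#'
#' Combines two algebras that each optimize a total order into a
#' bi-objective algebra whose choice function is the Pareto front
#' operator.  The product preserves Bellman's principle provided the
#' component scoring functions are strictly monotone (spot-check with
#' [check_monotone()]), so [evaluate()] returns the exact Pareto front
#' of the candidate space.
#'
#' @param A,B component [adp_algebra()]s with `direction` set.
#' @param strategy default evaluation strategy for this product.
#' @param pf_variant default Pareto-front operator; `"lex"` is a
#'   configuration error under the standard strategy because
#'   intermediate lists come out unsorted there.
#' @param eps comparison tolerance forwarded to the front's
#'   [order_spec()].
#' @return a pair-carrier `adp_algebra` whose `orders` field gives the
#'   front orientation.
#' @export
product_pareto <- function(A, B, strategy = c("standard", "sorted", "eager"),
                           pf_variant = NULL, eps = 0) {
  strategy <- match.arg(strategy)
  .require_direction(A, "product_pareto")
  .require_direction(B, "product_pareto")
  orders <- order_spec(A$direction, B$direction, eps = eps)
  if (is.null(pf_variant))
    pf_variant <- if (strategy == "standard") "nosort" else "lex"
  pf_variant <- match.arg(pf_variant, pf_variants())
  if (strategy == "standard" && pf_variant == "lex")
    stop("pf_lex requires sorted intermediate lists; ",
         "it cannot be used under the standard strategy")
  out <- adp_algebra(paste0(A$name, " *Par ", B$name),
                     fns = .pair_fn_table(A, B),
                     choice = .choice_pf(orders, pf_variant),
                     carrier = "pair")
  out$orders <- orders
  out$strategy <- strategy
  out$pf_variant <- pf_variant
  out
}

#' Lexicographic product of two evaluation algebras
#'
#' The objective optimizes the first coordinate under `A`'s order and
#' applies `B`'s choice to the second coordinates of the co-optimal
#' candidates: the optimum among the co-optimal, or all their B-values
#' when `B`'s choice is the identity (`adp_choice("all")`).
#'
#' @inheritParams product_pareto
#' @return a pair-carrier `adp_algebra`.
#' @export
product_lex <- function(A, B) {
  .require_direction(A, "product_lex")
  b_all <- identical(B$choice$kind, "all")
  if (!b_all) .require_direction(B, "product_lex")
  orders <- order_spec(A$direction, if (b_all) "max" else B$direction)
  out <- adp_algebra(paste0(A$name, " *lex ", B$name),
                     fns = .pair_fn_table(A, B),
                     choice = .choice_lex(orders, if (b_all) "all" else "opt"),
                     carrier = "pair")
  out$orders <- orders
  out
}

#' Parametrized additive product of two evaluation algebras
#'
#' Optimizes the weighted score `lambda * a + (1 - lambda) * b`; both
#' algebras must optimize numbers in the same direction.  The answer
#' carries the full `(a, b)` pair for reporting.
#'
#' @inheritParams product_pareto
#' @param lambda weight in `[0, 1]`; 1 recovers `A`'s optimum, 0
#'   recovers `B`'s.
#' @return a pair-carrier `adp_algebra`.
#' @export
product_add_lambda <- function(A, B, lambda) {
  .require_direction(A, "product_add_lambda")
  .require_direction(B, "product_add_lambda")
  if (!identical(A$direction, B$direction))
    stop("product_add_lambda: both algebras must optimize in the same direction")
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  out <- adp_algebra(sprintf("%s *+%g %s", A$name, lambda, B$name),
                     fns = .pair_fn_table(A, B),
                     choice = .choice_wsum(lambda, A$direction),
                     carrier = "pair")
  out$orders <- order_spec(A$direction, B$direction)
  out
}

#' The (select, combine, extend) operator triple of a strategy
#'
#' Exposes the per-production operators used internally by
#' [evaluate()], acting on plain n x 2 score-pair matrices: `extend(f,
#' X, Y, ...)` applies a scoring function to the cartesian product of
#' answer lists, `combine(x, y)` joins answer lists of alternative
#' productions, and `select(x)` applies the choice.  Under the standard
#' strategy lists are unordered; under the sorted strategy every
#' operator returns lexicographically sorted lists; under the eager
#' strategy every operator returns sorted Pareto fronts and `select` is
#' the identity.
#'
#' @param strategy `"standard"`, `"sorted"` or `"eager"`.
#' @param orders an [order_spec()].
#' @param pf_variant Pareto-front operator for `select`.
#' @return list of functions `extend`, `combine`, `select`.
#' @export
strategy_ops <- function(strategy = c("standard", "sorted", "eager"),
                         orders = order_spec(), pf_variant = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(pf_variant))
    pf_variant <- if (strategy == "standard") "nosort" else "lex"
  if (strategy == "standard" && pf_variant == "lex")
    stop("pf_lex cannot be used under the standard strategy")
  as_sl <- function(m) .sl_new(.as_pair_matrix(m))
  extend <- function(f, ...) {
    lists <- lapply(list(...), .as_pair_matrix)
    lens <- vapply(lists, nrow, integer(1))
    total <- prod(lens)
    if (total == 0L) return(matrix(numeric(0), ncol = 2))
    idx <- vector("list", length(lists))
    before <- 1L
    for (r in seq_along(lists)) {
      idx[[r]] <- rep(rep.int(seq_len(lens[r]), rep.int(before, lens[r])),
                      length.out = total)
      before <- before * lens[r]
    }
    args <- lapply(seq_along(lists), function(r)
      lists[[r]][idx[[r]], , drop = FALSE])
    val <- do.call(f, args)
    if (!is.matrix(val)) val <- matrix(val, ncol = 2)
    s <- .sl_new(val)
    if (strategy == "sorted") s <- .sl_sort(s, orders)
    if (strategy == "eager") s <- .sl_fold_chunks(s, lens[1L], orders)
    s$val
  }
  combine <- function(x, y) {
    sx <- as_sl(x); sy <- as_sl(y)
    out <- switch(strategy,
                  standard = .sl_concat(list(sx, sy)),
                  sorted = .sl_sort(.sl_concat(list(sx, sy)), orders),
                  eager = .sl_pmerge(sx, sy, orders))
    out$val
  }
  select <- function(x) {
    s <- as_sl(x)
    out <- switch(strategy,
                  standard = .sl_pf(s, orders, pf_variant),
                  sorted = .sl_pf(s, orders, pf_variant),
                  eager = s)
    out$val
  }
  list(extend = extend, combine = combine, select = select)
}
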