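#' Pareto-front operators
#'
#' Five implementations of the Pareto front operator on two-dimensional
#' score pairs, differing in input assumptions and cost profile:
#'
#' \describe{
#'   \item{`sort`}{sort lexicographically (O(N log N)), then one linear
#'     extraction pass.  Sorted output.}
#'   \item{`isort`}{Pareto-flavoured insertion sort: dominated elements
#'     are eliminated already during sorting.  Worst case O(N^2),
#'     expected O(N log N).  Sorted output.}
#'   \item{`lex`}{single O(N) pass; \emph{requires} input sorted in
#'     decreasing lexicographic order.  The precondition is checked only
#'     when `check = TRUE` (debug mode); in production the pass stays
#'     linear and unsorted input yields garbage.}
#'   \item{`smooth`}{the linear pass extended by two repair rules for
#'     out-of-order elements; identical to `lex` (and performs zero
#'     repairs) on sorted input, O(N^2) worst case otherwise.  Sorted
#'     output.}
#'   \item{`nosort`}{never sorts; consumes and produces unsorted lists.
#'     O(N^2) worst case.}
#' }
#'
#' All variants return the same set as [brute_force_front()].  The
#' returned front carries attributes `comparisons` (count of oriented
#' scalar comparisons, a hardware-independent cost measure) and, for
#' `smooth`, `repairs` (number of out-of-order rule firings).
#'
#' @param pairs n x 2 matrix of score pairs (rows may be unsorted,
#'   duplicated or dominated except where a variant requires otherwise).
#' @param orders an [order_spec()].
#' @param variant which operator to use.
#' @param check logical; verify preconditions / input invariants
#'   (debug mode).
#' @return a [pareto_front()]; sorted for all variants except `nosort`.
#' @examples
#' m <- rbind(c(5, 5), c(7, 4), c(4, 6), c(6, 5))
#' pf(m, variant = "isort")$pairs  # [(7,4),(6,5),(4,6)]
#' @export
pf <- function(pairs, orders = order_spec(),
               variant = c("sort", "isort", "lex", "smooth", "nosort"),
               check = FALSE) {
  variant <- match.arg(variant)
  switch(variant,
         sort = pf_sort(pairs, orders),
         isort = pf_isort(pairs, orders),
         lex = pf_lex(pairs, orders, check = check),
         smooth = pf_smooth(pairs, orders),
         nosort = pf_nosort(pairs, orders))
}

#' All Pareto-front operator names
#' @return character vector of the five variant names.
#' @export
pf_variants <- function() c("sort", "isort", "lex", "smooth", "nosort")

.pf_result <- function(m, res, orders, sorted) {
  out <- pareto_front(m[res$idx + 1L, , drop = FALSE], orders, sorted = sorted)
  attr(out, "comparisons") <- res$comparisons
  if (!is.null(res$repairs)) attr(out, "repairs") <- res$repairs
  out
}

#' Lexicographic sort order of score pairs
#'
#' Index permutation sorting rows of `pairs` in decreasing
#' lexicographic order under the oriented `(>_A, >_B)`.
#' @param pairs n x 2 matrix.
#' @param orders an [order_spec()].
#' @return integer permutation.
#' @export
lex_order <- function(pairs, orders = order_spec()) {
  m <- .as_pair_matrix(pairs)
  order(.sign_a(orders) * m[, 1], .sign_b(orders) * m[, 2],
        decreasing = TRUE, method = "radix")
}

#' @rdname pf
#' @export
pf_sort <- function(pairs, orders = order_spec()) {
  m <- .as_pair_matrix(pairs)
  o <- lex_order(m, orders)
  ms <- m[o, , drop = FALSE]
  res <- cpp_pf_lex(ms, .sign_a(orders), .sign_b(orders), orders$eps, FALSE)
  .pf_result(ms, res, orders, sorted = TRUE)
}

#' @rdname pf
#' @export
pf_isort <- function(pairs, orders = order_spec()) {
  m <- .as_pair_matrix(pairs)
  res <- cpp_pf_isort(m, .sign_a(orders), .sign_b(orders), orders$eps)
  .pf_result(m, res, orders, sorted = TRUE)
}

#' @rdname pf
#' @export
pf_lex <- function(pairs, orders = order_spec(), check = FALSE) {
  m <- .as_pair_matrix(pairs)
  res <- cpp_pf_lex(m, .sign_a(orders), .sign_b(orders), orders$eps,
                    isTRUE(check))
  .pf_result(m, res, orders, sorted = TRUE)
}

#' @rdname pf
#' @export
pf_smooth <- function(pairs, orders = order_spec()) {
  m <- .as_pair_matrix(pairs)
  res <- cpp_pf_smooth(m, .sign_a(orders), .sign_b(orders), orders$eps)
  .pf_result(m, res, orders, sorted = TRUE)
}

#' @rdname pf
#' @export
pf_nosort <- function(pairs, orders = order_spec()) {
  m <- .as_pair_matrix(pairs)
  res <- cpp_pf_nosort(m, .sign_a(orders), .sign_b(orders), orders$eps)
  .pf_result(m, res, orders, sorted = FALSE)
}

#' Linear-time Pareto merge
#'
#' Merges two \emph{sorted} Pareto fronts into the Pareto front of their
#' union (`x \\/p y = pf(x U y)`), walking both lists once with a
#' `dropWhile`-style elimination of elements beaten in the second
#' dimension; the comparison count stays linear in `|x| + |y|`.
#' Commutative and associative.
#'
#' @param x,y sorted [pareto_front()] objects over the same orders.
#' @param check logical; verify that both inputs satisfy the sorted
#'   Pareto-list invariant (debug mode).
#' @return a sorted [pareto_front()] with a `comparisons` attribute.
#' @export
pareto_merge <- function(x, y, check = FALSE) {
  stopifnot(inherits(x, "pareto_front"), inherits(y, "pareto_front"))
  orders <- x$orders
  res <- cpp_pareto_merge(x$pairs, y$pairs, .sign_a(orders), .sign_b(orders),
                          orders$eps, isTRUE(check))
  pick <- ifelse(res$src == 1L, res$idx + 1L, -(res$idx + 1L))
  m <- matrix(0, nrow = length(pick), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  if (length(pick)) {
    from_x <- res$src == 1L
    m[from_x, ] <- x$pairs[res$idx[from_x] + 1L, , drop = FALSE]
    m[!from_x, ] <- y$pairs[res$idx[!from_x] + 1L, , drop = FALSE]
  }
  out <- pareto_front(m, orders, sorted = TRUE)
  attr(out, "comparisons") <- res$comparisons
  out
}
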