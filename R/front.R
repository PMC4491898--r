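#' Orientation of the two score dimensions
#'
#' Fixes the total orders used by domination.  Minimization is handled by
#' orientation of the comparisons, not by negating stored scores, so
#' reported values keep their natural scale (e.g. free energies stay
#' negative while being minimized).
#'
#' @param dir_a,dir_b `"max"` or `"min"` for dimensions A and B.
#' @param eps absolute comparison tolerance; differences with
#'   `|delta| <= eps` count as ties.  Default 0 (exact comparison).
#' @return An object of class `order_spec`.
#' @examples
#' order_spec("min", "max")  # e.g. free energy vs expected accuracy
#' @export
order_spec <- function(dir_a = "max", dir_b = "max", eps = 0) {
  dir_a <- match.arg(dir_a, c("max", "min"))
  dir_b <- match.arg(dir_b, c("max", "min"))
  stopifnot(is.numeric(eps), length(eps) == 1L, eps >= 0, is.finite(eps))
  structure(list(dir_a = dir_a, dir_b = dir_b, eps = eps),
            class = "order_spec")
}

#' @export
print.order_spec <- function(x, ...) {
  cat(sprintf("<order_spec A:%s B:%s eps=%g>\n", x$dir_a, x$dir_b, x$eps))
  invisible(x)
}

.sign_a <- function(orders) if (orders$dir_a == "max") 1 else -1
.sign_b <- function(orders) if (orders$dir_b == "max") 1 else -1

.as_pair_matrix <- function(pairs) {
  if (is.null(pairs)) return(matrix(numeric(0), ncol = 2,
                                    dimnames = list(NULL, c("a", "b"))))
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (is.numeric(pairs) && is.null(dim(pairs))) {
    stopifnot(length(pairs) == 2L)
    pairs <- matrix(pairs, ncol = 2)
  }
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  storage.mode(pairs) <- "double"
  if (nrow(pairs) && any(!is.finite(pairs)))
    stop("score pairs must be finite")
  colnames(pairs) <- c("a", "b")
  pairs
}

#' Construct a Pareto front object
#'
#' A duplicate-free set of two-dimensional score pairs containing no
#' dominated element, stored as a matrix.  A sorted front is strictly
#' decreasing in dimension A and (consequently) strictly increasing in
#' dimension B under the chosen orders.  The constructor trusts its
#' input; use [brute_force_front()] or [pf()] to build fronts from raw
#' pair collections, and [validate_front()] to check the invariant.
#'
#' @param pairs n x 2 numeric matrix of score pairs.
#' @param orders an [order_spec()].
#' @param sorted logical; does `pairs` carry the sorted-list invariant?
#' @return An object of class `pareto_front`.
#' @export
pareto_front <- function(pairs, orders = order_spec(), sorted = FALSE) {
  structure(list(pairs = .as_pair_matrix(pairs), orders = orders,
                 sorted = isTRUE(sorted)),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("Pareto front: %d element(s) (A:%s, B:%s, %s)\n",
              nrow(x$pairs), x$orders$dir_a, x$orders$dir_b,
              if (x$sorted) "sorted" else "unsorted"))
  print(x$pairs)
  invisible(x)
}

#' @export
length.pareto_front <- function(x) nrow(x$pairs)

#' @export
as.data.frame.pareto_front <- function(x, ...) {
  data.frame(score_a = x$pairs[, 1], score_b = x$pairs[, 2])
}

#' Check the Pareto-front invariant
#'
#' Verifies that no element dominates another, that there are no
#' duplicates, and (for sorted fronts) that the list is strictly
#' decreasing in A and strictly increasing in B.
#'
#' @param x a [pareto_front()].
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_front <- function(x) {
  stopifnot(inherits(x, "pareto_front"))
  m <- x$pairs
  if (nrow(m) > 1L) {
    ref <- brute_force_front(m, x$orders)
    if (nrow(ref$pairs) != nrow(m))
      stop("front contains dominated or duplicate elements")
    if (x$sorted &&
        !cpp_is_sorted_front(m, .sign_a(x$orders), .sign_b(x$orders),
                             x$orders$eps))
      stop("front is flagged sorted but violates the sorted-list invariant")
  }
  invisible(TRUE)
}

#' Domination between two score pairs
#'
#' `p` dominates `q` iff it is strictly better in one dimension and not
#' worse in the other, under the total orders fixed by `orders`.
#'
#' @param p,q numeric length-2 score pairs.
#' @param orders an [order_spec()].
#' @return logical.
#' @examples
#' dominates(c(6, 5), c(5, 5))          # TRUE
#' dominates(c(2, 3), c(3, 2))          # FALSE (incomparable)
#' dominates(c(4, 7), c(4, 7))          # FALSE (no strict improvement)
#' @export
dominates <- function(p, q, orders = order_spec()) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 2L, length(q) == 2L)
  if (any(!is.finite(p)) || any(!is.finite(q)))
    stop("score pairs must be finite")
  sa <- .sign_a(orders); sb <- .sign_b(orders); eps <- orders$eps
  da <- sa * (p[1] - q[1]); db <- sb * (p[2] - q[2])
  ga <- da > eps; gea <- da >= -eps
  gb <- db > eps; geb <- db >= -eps
  (ga && geb) || (gea && gb)
}

#' Brute-force Pareto front (test oracle)
#'
#' Direct all-pairs implementation of the definition of the Pareto
#' front: an element is kept iff no other element dominates it.
#' Quadratic, vectorized per element, independent of the optimized
#' operators in [pf()] -- this is the reference oracle the whole test
#' suite compares against.  Duplicates are removed (first occurrence
#' kept); output order follows input order.
#'
#' @param pairs n x 2 matrix (or anything [pareto_front()] accepts).
#' @param orders an [order_spec()].
#' @return an unsorted [pareto_front()].
#' @examples
#' m <- rbind(c(7, 4), c(5, 5), c(6, 5), c(4, 6))
#' as.data.frame(brute_force_front(m))  # (5,5) is dominated by (6,5)
#' @export
brute_force_front <- function(pairs, orders = order_spec()) {
  m <- .as_pair_matrix(pairs)
  n <- nrow(m)
  if (n == 0L) return(pareto_front(m, orders, sorted = FALSE))
  sa <- .sign_a(orders); sb <- .sign_b(orders); eps <- orders$eps
  a <- sa * m[, 1]; b <- sb * m[, 2]
  keep <- logical(n)
  for (i in seq_len(n)) {
    da <- a - a[i]; db <- b - b[i]
    dominated <- any((da > eps & db >= -eps) | (da >= -eps & db > eps))
    dup <- FALSE
    if (!dominated && i > 1L) {
      j <- seq_len(i - 1L)
      dup <- any(abs(da[j]) <= eps & abs(db[j]) <= eps)
    }
    keep[i] <- !dominated && !dup
  }
  pareto_front(m[keep, , drop = FALSE], orders, sorted = FALSE)
}

#' Harmonic number: expected Pareto-front size
#'
#' For N pairs with i.i.d. continuous coordinates the expected front
#' size is the harmonic number `H(N) = sum_{i=1..N} 1/i`.
#'
#' @param N positive integer.
#' @return `H(N)` as a double.
#' @examples
#' harmonic(2)    # 1.5
#' harmonic(100)  # about 5.187
#' @export
harmonic <- function(N) {
  stopifnot(is.numeric(N), length(N) == 1L, is.finite(N), N >= 1)
  sum(1 / seq_len(as.integer(N)))
}

#' Write a Pareto front to TSV
#'
#' One row per front element, header line, UTF-8, '.' decimal separator.
#'
#' @param x a [pareto_front()].
#' @param path output file path.
#' @param labels optional character vector of candidate labels (one per
#'   front element), written as a third column.
#' @param header_lines optional character vector of `#`-prefixed
#'   comment lines (e.g. the run configuration) written before the header.
#' @return `path`, invisibly.
#' @export
write_front_tsv <- function(x, path, labels = NULL, header_lines = NULL) {
  stopifnot(inherits(x, "pareto_front"))
  df <- as.data.frame(x)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(df))
    df$candidate <- labels
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              dec = ".")
  invisible(path)
}
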