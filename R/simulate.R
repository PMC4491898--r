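#' Monte-Carlo check of the harmonic front-size law
#'
#' Draws `replicates` sets of `N` i.i.d. continuous-uniform score
#' pairs, computes each Pareto front size, and compares the mean
#' against the harmonic-law expectation `H(N)` (see [harmonic()]).
#'
#' @param N points per replicate.
#' @param replicates number of replicates.
#' @param seed RNG seed.
#' @return list with `N`, `replicates`, `mean`, `se` (standard error),
#'   `harmonic` and `z` (standardized deviation from `H(N)`).
#' @export
simulate_front_size <- function(N, replicates = 2000L, seed = 1L) {
  stopifnot(N >= 1, replicates >= 1)
  sizes <- .with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      m <- matrix(runif(2L * N), ncol = 2)
      length(.pf_idx(m, order_spec(), "sort"))
    }, integer(1))
  })
  mu <- mean(sizes)
  se <- if (replicates > 1L) sd(sizes) / sqrt(replicates) else NA_real_
  h <- harmonic(N)
  list(N = as.integer(N), replicates = as.integer(replicates),
       mean = mu, se = se, harmonic = h,
       z = if (is.na(se) || se == 0) NA_real_ else (mu - h) / se)
}

.bench_input <- function(distribution, size) {
  switch(distribution,
    random = matrix(runif(2L * size), ncol = 2),
    sorted = {
      m <- matrix(runif(2L * size), ncol = 2)
      m[lex_order(m, order_spec()), , drop = FALSE]
    },
    anticorrelated = {
      # adversarial integer grid: every element is Pareto-optimal
      i <- sample.int(size)
      cbind(as.numeric(i), as.numeric(size - i))
    },
    stop("unknown distribution: ", distribution))
}

#' Comparative operation counts of the Pareto-front operators
#'
#' Runs the five front operators (and the linear merge) on seeded
#' random, pre-sorted and anti-correlated adversarial inputs, reporting
#' element-comparison counts (hardware independent) and wall time
#' (informational only).  `pf_lex` is only run on the sorted inputs,
#' where its precondition holds.  Before timing, all applicable
#' variants are checked to return set-equal fronts.
#'
#' @param sizes integer vector of input sizes.
#' @param distributions subset of `c("random", "sorted",
#'   "anticorrelated")`.
#' @param seed RNG seed.
#' @return data frame (size, distribution, variant, comparisons,
#'   front_size, seconds).
#' @export
bench_pf <- function(sizes = c(100L, 1000L, 10000L),
                     distributions = c("random", "sorted", "anticorrelated"),
                     seed = 1L) {
  distributions <- match.arg(distributions, several.ok = TRUE)
  orders <- order_spec()
  rows <- list()
  .with_seed(seed, {
    for (size in sizes) for (dist in distributions) {
      m <- .bench_input(dist, size)
      variants <- c("sort", "isort", "smooth", "nosort",
                    if (dist == "sorted") "lex")
      ref <- NULL
      for (v in variants) {
        t0 <- proc.time()[["elapsed"]]
        f <- pf(m, orders, variant = v)
        el <- proc.time()[["elapsed"]] - t0
        if (is.null(ref)) ref <- f
        else if (!front_setequal(ref, f))
          stop(sprintf("pf variants disagree (size %d, %s, %s)",
                       size, dist, v))
        rows[[length(rows) + 1L]] <-
          data.frame(size = size, distribution = dist, variant = v,
                     comparisons = attr(f, "comparisons"),
                     front_size = length(f), seconds = el)
      }
      # linear merge of the fronts of the two input halves
      h <- seq_len(nrow(m) %/% 2)
      f1 <- pf_sort(m[h, , drop = FALSE], orders)
      f2 <- pf_sort(m[-h, , drop = FALSE], orders)
      t0 <- proc.time()[["elapsed"]]
      fm <- pareto_merge(f1, f2)
      el <- proc.time()[["elapsed"]] - t0
      if (!front_setequal(fm, ref))
        stop("pareto_merge disagrees with the direct front")
      rows[[length(rows) + 1L]] <-
        data.frame(size = size, distribution = dist, variant = "merge",
                   comparisons = attr(fm, "comparisons"),
                   front_size = length(fm), seconds = el)
    }
  })
  do.call(rbind, rows)
}
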