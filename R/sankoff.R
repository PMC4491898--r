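#' Parameters for the Sankoff similarity algebra
#'
#' @param gamma gap penalty for insertions and deletions (negative;
#'   default -3).
#' @param match,mismatch column similarity scores: `match` when the two
#'   aligned residues are equal, `mismatch` otherwise (defaults 1 / 0;
#'   both non-negative).
#' @param variant `"corrected"` scores base-paired columns for sequence
#'   similarity like any other aligned column (a proper similarity
#'   score); `"schnattinger"` reproduces the historical variant in
#'   which paired columns contribute nothing to the similarity score --
#'   the source of anti-correlation between the two objectives and of
#'   worst-case Pareto fronts on identical sequences.
#' @param minloop minimal separation of consensus pair partners in each
#'   sequence (`close - open > minloop`).
#' @return an object of class `sankoff_params`.
#' @export
sankoff_params <- function(gamma = -3, match = 1, mismatch = 0,
                           variant = c("corrected", "schnattinger"),
                           minloop = 3L) {
  variant <- match.arg(variant)
  stopifnot(gamma < 0, match >= 0, mismatch >= 0)
  structure(list(gamma = gamma, match = match, mismatch = mismatch,
                 variant = variant, minloop = as.integer(minloop)),
            class = "sankoff_params")
}

#' Sankoff problem input
#'
#' Bundles the two sequences with their base-pair probability matrices.
#' `psi = "partition"` computes each matrix with
#' [partition_pairprobs()] under the folding model; `psi = "indicator"`
#' uses 1 for every admissible pair (model pairing rule + minloop) and
#' 0 otherwise, which makes all scores small integers -- convenient for
#' exact discrete tests.
#'
#' @param x,y [rna_seq()] objects or character strings.
#' @param psi `"partition"` or `"indicator"`.
#' @param model the [fold_model()] used for pairing rule, minloop and
#'   (in partition mode) Boltzmann weights.
#' @return an object of class `sankoff_input`.
#' @export
sankoff_input <- function(x, y, psi = c("partition", "indicator"),
                          model = fold_model()) {
  psi <- match.arg(psi)
  x <- .as_rna(x); y <- .as_rna(y)
  mk <- function(s) {
    n <- nchar(s$residues)
    if (psi == "partition") return(partition_pairprobs(s, model))
    ch <- if (n) strsplit(s$residues, "")[[1]] else character(0)
    m <- matrix(0, n, n)
    if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (j - i > model$minloop && .can_pair(model, ch[i], ch[j]))
        m[i, j] <- 1
    m
  }
  structure(list(x = x, y = y, psi_x = mk(x), psi_y = mk(y),
                 psi_mode = psi, model = model),
            class = "sankoff_input")
}

#' Tree grammar for the Sankoff problem
#'
#' Two-track grammar over the signature `nil`, `NoStr`, `Split`,
#' `Pair`, `Ins`, `Del`, `Match`.  Alignment columns are terminals
#' consuming one residue from one or both tracks; consensus pairs
#' (`Pair`) consume a match column on each side and require both sides
#' to respect the minimum loop size.  Candidates decompose uniquely by
#' their first column.
#'
#' @param params a [sankoff_params()].
#' @return an [adp_grammar()].
#' @export
sankoff_grammar <- function(params = sankoff_params()) {
  minloop <- params$minloop
  pair_guard <- function(terms, spans, input) {
    o <- terms[[1]]; c <- terms[[3]]
    (c$xpos - o$xpos > minloop) && (c$ypos - o$ypos > minloop)
  }
  rules <- list(
    adp_rule("C", "Ins", list(t_arg(c(0L, 1L)))),
    adp_rule("C", "Del", list(t_arg(c(1L, 0L)))),
    adp_rule("C", "Match", list(t_arg(c(1L, 1L)))),
    adp_rule("P", "Pair",
             list(t_arg(c(1L, 1L)), nt_arg("A"), t_arg(c(1L, 1L))),
             pair_guard),
    adp_rule("A", "nil"),
    adp_rule("A", "NoStr", list(nt_arg("C"), nt_arg("A"))),
    adp_rule("A", "Split", list(nt_arg("P"), nt_arg("A"))))
  adp_grammar("sankoff", tracks = 2L, axiom = "A", rules = rules,
              nt_order = c("C", "P", "A"))
}

.sigma <- function(params, a, b) {
  if (identical(a, b)) params$match else params$mismatch
}

#' Similarity and base-pairing algebras for the Sankoff problem
#'
#' `sim_algebra` scores sequence similarity: matches/mismatches via
#' sigma, insertions and deletions via the gap penalty gamma, and --
#' in the corrected variant -- the two columns closed by a consensus
#' pair via sigma as well (the schnattinger variant leaves paired
#' columns unscored).  `prob_algebra` accumulates the base-pair
#' probabilities of the consensus pairs in both sequences.  Both
#' maximize.
#'
#' @param params a [sankoff_params()].
#' @param input a [sankoff_input()] providing the probability matrices.
#' @return an [adp_algebra()].
#' @export
sim_algebra <- function(params = sankoff_params()) {
  sig <- function(t) .sigma(params, t$xchar, t$ychar)
  pair_fn <- if (params$variant == "corrected") {
    function(c1, x, c2) x + sig(c1) + sig(c2)
  } else {
    function(c1, x, c2) x
  }
  adp_algebra(paste0("SIM-", params$variant), fns = list(
    nil = function() 0,
    NoStr = function(x, y) x + y,
    Split = function(x, y) x + y,
    Pair = pair_fn,
    Ins = function(t) params$gamma,
    Del = function(t) params$gamma,
    Match = function(t) sig(t)),
    choice = adp_choice("max"), carrier = "numeric", direction = "max")
}

#' @rdname sim_algebra
#' @export
prob_algebra <- function(input) {
  stopifnot(inherits(input, "sankoff_input"))
  px <- input$psi_x; py <- input$psi_y
  adp_algebra("PROB", fns = list(
    nil = function() 0,
    NoStr = function(x, y) x + y,
    Split = function(x, y) x + y,
    Pair = function(c1, x, c2)
      x + px[c1$xpos, c2$xpos] + py[c1$ypos, c2$ypos],
    Ins = function(t) 0,
    Del = function(t) 0,
    Match = function(t) 0),
    choice = adp_choice("max"), carrier = "numeric", direction = "max")
}

# decode a Sankoff witness term into columns and consensus pairs
.sankoff_decode <- function(term) {
  cols <- list()
  pairs <- list()
  rec <- function(x) {
    if (x$sym == "nil") return(invisible())
    if (x$sym == "NoStr") {
      col <- x$args[[1]]            # C node: Ins/Del/Match
      t <- col$args[[1]]
      cols[[length(cols) + 1L]] <<-
        list(type = tolower(col$sym), xpos = t$xpos, ypos = t$ypos)
      rec(x$args[[2]])
      return(invisible())
    }
    if (x$sym == "Split") {
      rec(x$args[[1]])
      rec(x$args[[2]])
      return(invisible())
    }
    if (x$sym == "Pair") {
      t1 <- x$args[[1]]; t2 <- x$args[[3]]
      cols[[length(cols) + 1L]] <<-
        list(type = "match", xpos = t1$xpos, ypos = t1$ypos)
      open <- length(cols)
      rec(x$args[[2]])
      cols[[length(cols) + 1L]] <<-
        list(type = "match", xpos = t2$xpos, ypos = t2$ypos)
      pairs[[length(pairs) + 1L]] <<- c(open, length(cols))
      return(invisible())
    }
    stop("unexpected symbol in Sankoff candidate: ", x$sym)
  }
  rec(term)
  list(cols = cols, pairs = pairs)
}

.sankoff_alignment <- function(term, x, y) {
  d <- .sankoff_decode(term)
  xs <- strsplit(x$residues, "")[[1]]
  ys <- strsplit(y$residues, "")[[1]]
  ax <- ay <- character(length(d$cols))
  for (ci in seq_along(d$cols)) {
    col <- d$cols[[ci]]
    ax[ci] <- if (is.na(col$xpos)) "-" else xs[col$xpos]
    ay[ci] <- if (is.na(col$ypos)) "-" else ys[col$ypos]
  }
  cons <- rep(".", length(d$cols))
  for (p in d$pairs) {
    cons[p[1]] <- "("
    cons[p[2]] <- ")"
  }
  list(x = paste(ax, collapse = ""), y = paste(ay, collapse = ""),
       consensus = paste(cons, collapse = ""))
}

#' Joint alignment and consensus folding under the Pareto product
#'
#' Solves the Sankoff problem for a sequence pair under `SIM *Par
#' PROB`: the exact Pareto front between sequence similarity and
#' accumulated consensus base-pair probability, with one witness
#' alignment-plus-structure per front element.
#'
#' @param input a [sankoff_input()].
#' @param params a [sankoff_params()].
#' @param strategy,pf_variant forwarded to [product_pareto()].
#' @param max_len refuse sequences longer than this on either side
#'   (the DP has O(n^2 m^2) cells).
#' @param witness keep witness candidates.
#' @return an object of class `sankoff_result` with `$front`, `$table`
#'   (sim, prob, alignment rows and consensus line) and the inputs.
#' @export
sankoff_pareto <- function(input, params = sankoff_params(),
                           strategy = "standard", pf_variant = NULL,
                           max_len = 40L, witness = TRUE) {
  stopifnot(inherits(input, "sankoff_input"))
  nx <- nchar(input$x$residues); ny <- nchar(input$y$residues)
  if (nx > max_len || ny > max_len)
    stop(sprintf(paste0("sequence lengths (%d, %d) exceed max_len = %d; ",
                        "the Sankoff DP has O(n^2 m^2) cells -- shorten the ",
                        "input or raise max_len explicitly"),
                 nx, ny, max_len))
  grammar <- sankoff_grammar(params)
  prod <- product_pareto(sim_algebra(params), prob_algebra(input),
                         strategy = strategy, pf_variant = pf_variant)
  res <- evaluate(grammar, prod, list(input$x, input$y), witness = witness)
  tbl <- data.frame(sim = res$value[, 1], prob = res$value[, 2])
  if (witness && length(res$witnesses)) {
    al <- lapply(res$witnesses, .sankoff_alignment, x = input$x, y = input$y)
    tbl$alignment_x <- vapply(al, `[[`, character(1), "x")
    tbl$alignment_y <- vapply(al, `[[`, character(1), "y")
    tbl$consensus <- vapply(al, `[[`, character(1), "consensus")
  }
  structure(list(input = input, params = params, front = res$front,
                 table = tbl, witnesses = res$witnesses,
                 strategy = res$strategy, pf_variant = res$pf_variant),
            class = "sankoff_result")
}

#' @export
print.sankoff_result <- function(x, ...) {
  cat(sprintf("Sankoff Pareto front of '%s' vs '%s' (%s variant): %d element(s)\n",
              x$input$x$id, x$input$y$id, x$params$variant, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Direct-recurrence reference for the Sankoff Pareto front
#'
#' An independent, non-algebraic implementation of the joint
#' alignment-and-folding recurrences with a Pareto-maximizing choice at
#' every cell, using the brute-force front oracle.  It shares no code
#' path with the grammar engine or the optimized front operators and
#' serves as the cross-implementation oracle in the test suite.
#'
#' @param input a [sankoff_input()].
#' @param params a [sankoff_params()].
#' @return the Pareto front as an unsorted n x 2 matrix (sim, prob).
#' @export
sankoff_reference_front <- function(input, params = sankoff_params()) {
  x <- strsplit(input$x$residues, "")[[1]]
  y <- strsplit(input$y$residues, "")[[1]]
  px <- input$psi_x; py <- input$psi_y
  nx <- length(x); ny <- length(y)
  gam <- params$gamma; ml <- params$minloop
  sig <- function(a, b) if (a == b) params$match else params$mismatch
  corrected <- params$variant == "corrected"
  orders <- order_spec("max", "max")
  key <- function(i, j, k, l)
    ((i * (nx + 1) + j) * (ny + 1) + k) * (ny + 1) + l + 1
  S <- vector("list", (nx + 1)^2 * (ny + 1)^2)
  # S(i,j,k,l): front over x_(i..j], y_(k..l]; filled by increasing width
  for (w in 0:(nx + ny)) {
    for (wx in max(0, w - ny):min(nx, w)) {
      wy <- w - wx
      for (i in 0:(nx - wx)) for (k in 0:(ny - wy)) {
        j <- i + wx; l <- k + wy
        if (wx == 0 && wy == 0) {
          S[[key(i, j, k, l)]] <- matrix(c(0, 0), ncol = 2)
          next
        }
        if (wx == 0) {                       # only insertions remain
          S[[key(i, j, k, l)]] <- matrix(c(gam * wy, 0), ncol = 2)
          next
        }
        if (wy == 0) {                       # only deletions remain
          S[[key(i, j, k, l)]] <- matrix(c(gam * wx, 0), ncol = 2)
          next
        }
        parts <- list(
          sweep(S[[key(i, j - 1, k, l)]], 2, c(gam, 0), "+"),
          sweep(S[[key(i, j, k, l - 1)]], 2, c(gam, 0), "+"),
          sweep(S[[key(i, j - 1, k, l - 1)]], 2,
                c(sig(x[j], y[l]), 0), "+"))
        # last columns close a consensus pair (x_h, x_j) / (y_q, y_l)
        for (h in (i + 1):j) for (q in (k + 1):l) {
          if (j - h <= ml || l - q <= ml) next
          outer_f <- S[[key(i, h - 1, k, q - 1)]]
          inner_f <- S[[key(h, j - 1, q, l - 1)]]
          d_sim <- if (corrected) sig(x[h], y[q]) + sig(x[j], y[l]) else 0
          d_prob <- px[h, j] + py[q, l]
          comb <- cbind(
            rep(outer_f[, 1], each = nrow(inner_f)) + inner_f[, 1] + d_sim,
            rep(outer_f[, 2], each = nrow(inner_f)) + inner_f[, 2] + d_prob)
          parts[[length(parts) + 1L]] <- comb
        }
        S[[key(i, j, k, l)]] <-
          brute_force_front(do.call(rbind, parts), orders)$pairs
      }
    }
  }
  S[[key(0, nx, 0, ny)]]
}

#' Pareto-front sizes over a collection of sequence pairs
#'
#' Screening utility: a small front indicates strongly correlated
#' similarity and structure signals (e.g. homologous pairs), a large
#' front anti-correlation.  Reports one row per input pair and group
#' means when groups are declared.
#'
#' @param pairs list of `list(x = , y = )` sequence pairs.
#' @param params a [sankoff_params()].
#' @param psi,model forwarded to [sankoff_input()].
#' @param groups optional character vector, one group label per pair.
#' @param max_len forwarded to [sankoff_pareto()].
#' @return data frame (id_x, id_y, n, front_size, group) with a
#'   `summary` attribute of group means.
#' @export
front_size_report <- function(pairs, params = sankoff_params(),
                              psi = "indicator", model = fold_model(),
                              groups = NULL, max_len = 40L) {
  stopifnot(is.list(pairs))
  if (!is.null(groups)) stopifnot(length(groups) == length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    inp <- sankoff_input(p$x, p$y, psi = psi, model = model)
    res <- sankoff_pareto(inp, params, max_len = max_len, witness = FALSE)
    data.frame(id_x = inp$x$id, id_y = inp$y$id,
               n = nchar(inp$x$residues) + nchar(inp$y$residues),
               front_size = nrow(res$table),
               group = if (is.null(groups)) NA_character_ else groups[i])
  })
  out <- do.call(rbind, rows)
  if (!is.null(groups)) {
    attr(out, "summary") <-
      aggregate(front_size ~ group, data = out, FUN = mean)
  }
  out
}
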