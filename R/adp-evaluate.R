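# Tabulated evaluation of a tree grammar under an evaluation algebra.
#
# Answer lists ("scored lists") are pairs of a value container (numeric
# vector or 2-column matrix) and an optional parallel list of candidate
# witnesses.  The three Pareto evaluation strategies differ only in the
# (#, combine, extend) operators applied to these lists:
#   standard: extend = plain cartesian application, combine = append,
#             # = the configured pf variant;
#   sorted:   extend/combine keep lists lexicographically sorted,
#             # = pf on the sorted list (pf_lex by default);
#   eager:    extend folds monotone chunks with the linear Pareto
#             merge, combine = Pareto merge, # = identity.

.sl_new <- function(val, wit = NULL) list(val = val, wit = wit)

.sl_len <- function(s) {
  if (is.null(s)) 0L else .val_len(s$val)
}

.sl_take <- function(s, idx) {
  val <- if (is.matrix(s$val)) s$val[idx, , drop = FALSE] else s$val[idx]
  .sl_new(val, if (!is.null(s$wit)) s$wit[idx])
}

.sl_concat <- function(parts) {
  if (length(parts) == 1L) return(parts[[1L]])
  vals <- lapply(parts, `[[`, "val")
  val <- if (is.matrix(vals[[1L]])) do.call(rbind, vals) else unlist(vals)
  wit <- NULL
  if (!is.null(parts[[1L]]$wit))
    wit <- do.call(c, lapply(parts, `[[`, "wit"))
  .sl_new(val, wit)
}

.sl_sort <- function(s, orders) {
  if (.sl_len(s) <= 1L) return(s)
  .sl_take(s, lex_order(s$val, orders))
}

.sl_pf <- function(s, orders, variant, check = FALSE) {
  if (.sl_len(s) <= 1L) return(s)
  .sl_take(s, .pf_idx(s$val, orders, variant, check))
}

# linear Pareto merge of two sorted-front scored lists
.sl_pmerge <- function(s1, s2, orders, check = FALSE) {
  if (.sl_len(s1) == 0L) return(s2)
  if (.sl_len(s2) == 0L) return(s1)
  res <- cpp_pareto_merge(s1$val, s2$val, .sign_a(orders), .sign_b(orders),
                          orders$eps, check)
  nout <- length(res$src)
  val <- matrix(0, nrow = nout, ncol = 2)
  from1 <- res$src == 1L
  val[from1, ] <- s1$val[res$idx[from1] + 1L, , drop = FALSE]
  val[!from1, ] <- s2$val[res$idx[!from1] + 1L, , drop = FALSE]
  wit <- NULL
  if (!is.null(s1$wit)) {
    wit <- vector("list", nout)
    wit[from1] <- s1$wit[res$idx[from1] + 1L]
    wit[!from1] <- s2$wit[res$idx[!from1] + 1L]
  }
  .sl_new(val, wit)
}

# fold consecutive chunks of a scored list with the Pareto merge; each
# chunk is sorted by construction (monotone image of a sorted front)
.sl_fold_chunks <- function(s, chunk, orders, check = FALSE) {
  n <- .sl_len(s)
  if (n <= chunk) return(s)
  acc <- .sl_take(s, seq_len(chunk))
  at <- chunk
  while (at < n) {
    hi <- min(at + chunk, n)
    acc <- .sl_pmerge(acc, .sl_take(s, (at + 1L):hi), orders, check)
    at <- hi
  }
  acc
}

# static per-rule information resolved once per evaluation
.preprocess_rules <- function(grammar) {
  lapply(grammar$rules, function(r) {
    kinds <- vapply(r$args, `[[`, character(1), "kind")
    nt_pos <- which(kinds == "nt")
    list(id = r$id, nt = r$nt, sym = r$sym, k = length(r$args),
         kinds = kinds, nt_pos = nt_pos, n_nt = length(nt_pos),
         nt_names = vapply(seq_along(r$args), function(ai)
           if (kinds[ai] == "nt") r$args[[ai]]$name else NA_character_,
           character(1)),
         widths = lapply(r$args, function(a)
           if (a$kind == "term") a$width else NULL),
         guard = r$guard, args = r$args)
  })
}

# relative splits as an integer matrix (one row per split)
.rule_splits_mat <- function(rule, widths, tracks) {
  rel <- .rule_splits_rel(rule, widths, tracks)
  if (length(rel) == 0L) return(NULL)
  if (length(rule$args) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  do.call(rbind, lapply(rel, function(sp) unlist(sp, use.names = FALSE)))
}

# pre-built terminal values, indexed by position
.term_caches <- function(input, tracks) {
  if (tracks == 1L) {
    chars <- input$tracks[[1]]
    list(single = lapply(seq_along(chars), function(p)
      structure(list(char = chars[p], pos = p), class = "adp_term")))
  } else {
    xs <- input$tracks[[1]]; ys <- input$tracks[[2]]
    nx <- length(xs); ny <- length(ys)
    mc <- vector("list", nx * ny)
    if (nx && ny) for (i in seq_len(nx)) for (j in seq_len(ny))
      mc[[(i - 1L) * ny + j]] <-
        structure(list(xchar = xs[i], xpos = i, ychar = ys[j], ypos = j),
                  class = "adp_term")
    dc <- lapply(seq_len(nx), function(i)
      structure(list(xchar = xs[i], xpos = i, ychar = NA_character_,
                     ypos = NA_integer_), class = "adp_term"))
    ic <- lapply(seq_len(ny), function(j)
      structure(list(xchar = NA_character_, xpos = NA_integer_,
                     ychar = ys[j], ypos = j), class = "adp_term"))
    list(mc = mc, dc = dc, ic = ic, ny = ny)
  }
}

# cartesian extension of subproblem answer lists through one rule at
# one split (flat span vector, subproblem cells already fetched);
# returns NULL when the rule's guard rejects the split
.extend <- function(pr, sp, input, tcache, f, pair, subs, strategy,
                    orders, witness, debug, tracks) {
  k <- pr$k
  step <- 2L * tracks
  terms <- vector("list", k)
  sub_pos <- pr$nt_pos
  for (ai in seq_len(k)) {
    if (pr$kinds[ai] == "term") {
      base <- (ai - 1L) * step
      if (tracks == 1L) {
        terms[[ai]] <- tcache$single[[sp[base + 1L] + 1L]]
      } else {
        w <- pr$widths[[ai]]
        terms[[ai]] <- if (w[1] == 1L && w[2] == 1L) {
          tcache$mc[[sp[base + 1L] * tcache$ny + sp[base + 3L] + 1L]]
        } else if (w[1] == 1L) {
          tcache$dc[[sp[base + 1L] + 1L]]
        } else {
          tcache$ic[[sp[base + 3L] + 1L]]
        }
      }
    }
  }
  if (!is.null(pr$guard)) {
    spans <- lapply(seq_len(k), function(ai)
      sp[((ai - 1L) * step + 1L):(ai * step)])
    if (!isTRUE(pr$guard(terms, spans, input))) return(NULL)
  }
  nsub <- pr$n_nt
  if (nsub == 0L) {
    val <- do.call(f, terms)
    if (pair) val <- matrix(val, ncol = 2) else val <- as.numeric(val)
    wit <- NULL
    if (witness)
      wit <- rep(list(list(sym = pr$sym, args = terms)), .val_len(val))
    out <- .sl_new(val, wit)
    # constant answers: sorted strategy sorts them, eager takes their front
    if (strategy == "sorted") out <- .sl_sort(out, orders)
    if (strategy == "eager") out <- .sl_pf(out, orders, "sort")
    return(out)
  }
  lens <- vapply(subs, .sl_len, integer(1))
  total <- prod(lens)
  # index grids, first subproblem argument varying fastest
  idx <- vector("list", nsub)
  before <- 1L
  for (r in seq_len(nsub)) {
    idx[[r]] <- rep(rep.int(seq_len(lens[r]), rep.int(before, lens[r])),
                    length.out = total)
    before <- before * lens[r]
  }
  args <- terms
  for (r in seq_len(nsub)) {
    v <- subs[[r]]$val
    args[[sub_pos[r]]] <- if (is.matrix(v)) v[idx[[r]], , drop = FALSE]
                          else v[idx[[r]]]
  }
  val <- do.call(f, args)
  if (pair) {
    if (!is.matrix(val)) val <- matrix(val, ncol = 2)
  } else {
    val <- as.numeric(val)
  }
  if (.val_len(val) != total)
    stop("scoring function for symbol ", pr$sym,
         " is not properly vectorized")
  wit <- NULL
  if (witness) {
    wit <- vector("list", total)
    for (t in seq_len(total)) {
      wargs <- terms
      for (r in seq_len(nsub))
        wargs[[sub_pos[r]]] <- subs[[r]]$wit[[idx[[r]][t]]]
      wit[[t]] <- list(sym = pr$sym, args = wargs)
    }
  }
  out <- .sl_new(val, wit)
  if (strategy == "sorted") {
    out <- .sl_sort(out, orders)
  } else if (strategy == "eager") {
    out <- .sl_fold_chunks(out, lens[1L], orders, check = debug)
  }
  out
}

.sorted_lex_ok <- function(m, orders) {
  if (nrow(m) <= 1L) return(TRUE)
  identical(lex_order(m, orders), seq_len(nrow(m)))
}

#' Evaluate a grammar under an algebra by tabulated dynamic programming
#'
#' Computes the algebra's answer for the full input: the choice
#' function applied to the evaluation of every candidate in the search
#' space, memoized per (nonterminal, subword) cell.  Equal to scoring
#' the fully enumerated search space and applying the choice once --
#' provided the algebra satisfies Bellman's principle.
#'
#' @param grammar an [adp_grammar()].
#' @param algebra an [adp_algebra()] or a product algebra
#'   ([product_pareto()], [product_lex()], [product_add_lambda()]).
#' @param input a character string (one-track grammars) or a list of
#'   two strings / [rna_seq()] objects (two-track grammars).
#' @param strategy evaluation strategy for Pareto products:
#'   `"standard"`, `"sorted"` or `"eager"`.  Ignored (forced to
#'   standard combination) for non-Pareto choices.
#' @param pf_variant Pareto-front operator used at choice points.
#'   `"lex"` requires sorted intermediate lists and is therefore
#'   rejected under the standard strategy.  Defaults: `"nosort"`
#'   (standard), `"lex"` (sorted/eager).
#' @param witness keep one candidate term per surviving answer.
#' @param debug enable invariant instrumentation: sortedness /
#'   Pareto-list checks on intermediate lists and pf precondition
#'   checks.
#' @param cell_limit abort when any cell holds more answers than this
#'   (guards full enumerations).
#' @param keep_tables return the dynamic-programming tables.
#' @return an `adp_result` list with elements `value` (vector, 2-column
#'   matrix, or scalar, per the choice), `front` (a [pareto_front()],
#'   Pareto products only), `witnesses`, `strategy`, `pf_variant`.
#' @export
evaluate <- function(grammar, algebra, input, strategy = NULL,
                     pf_variant = NULL, witness = FALSE, debug = FALSE,
                     cell_limit = Inf, keep_tables = FALSE) {
  stopifnot(inherits(grammar, "adp_grammar"), inherits(algebra, "adp_algebra"))
  if (is.null(strategy))
    strategy <- if (!is.null(algebra$strategy)) algebra$strategy else "standard"
  strategy <- match.arg(strategy, c("standard", "sorted", "eager"))
  if (is.null(pf_variant) && !is.null(algebra$pf_variant) &&
      identical(strategy, algebra$strategy))
    pf_variant <- algebra$pf_variant
  choice <- algebra$choice
  is_pf <- choice$kind == "pf"
  if (!is_pf) {
    strategy <- "standard"
    pf_variant <- NULL
  } else {
    if (is.null(pf_variant))
      pf_variant <- if (strategy == "standard") "nosort" else "lex"
    pf_variant <- match.arg(pf_variant, pf_variants())
    if (strategy == "standard" && pf_variant == "lex")
      stop("pf_lex requires sorted intermediate lists; ",
           "it cannot be used under the standard strategy")
  }
  orders <- if (is_pf) choice$params$orders else NULL
  input <- .adp_input(input, grammar$tracks)
  n <- input$n
  tab_len <- if (grammar$tracks == 1L) (n[1] + 1L)^2
             else (n[1] + 1L)^2 * (n[2] + 1L)^2
  tab <- lapply(setNames(grammar$nt_order, grammar$nt_order),
                function(nt) vector("list", tab_len))
  occ <- lapply(tab, function(x) logical(tab_len))
  spans <- .spans_by_width(n)
  witness_engine <- witness && (is_pf || choice$selective)
  pair <- algebra$carrier == "pair"
  syms <- unique(vapply(grammar$rules, `[[`, character(1), "sym"))
  fns <- setNames(lapply(syms, function(s) {
    f <- algebra$fns[[s]]
    if (is.null(f)) stop("algebra has no function for symbol ", s)
    f
  }), syms)
  tracks <- grammar$tracks
  pre_all <- .preprocess_rules(grammar)
  pre_by_nt <- split(pre_all,
                     factor(vapply(pre_all, `[[`, character(1), "nt"),
                            levels = grammar$nt_order))
  tcache <- .term_caches(input, tracks)
  # per-rule split matrices, cached by width index
  nw <- if (tracks == 1L) n[1] + 1L else (n[1] + 1L) * (n[2] + 1L)
  smat_cache <- lapply(pre_all, function(x) vector("list", nw))
  smat_done <- lapply(pre_all, function(x) logical(nw))
  rules_src <- grammar$rules
  for (span in spans) {
    id <- .span_id(span, n)
    if (tracks == 1L) {
      wkey <- span[2] - span[1] + 1L
      off <- rep(c(span[1], span[1]), 64L)
    } else {
      wkey <- (span[2] - span[1]) * (n[2] + 1L) + (span[4] - span[3]) + 1L
      off <- rep(c(span[1], span[1], span[3], span[3]), 64L)
    }
    for (nt in grammar$nt_order) {
      parts <- list()
      for (pr in pre_by_nt[[nt]]) {
        rid <- pr$id
        if (!smat_done[[rid]][wkey]) {
          widths <- if (tracks == 1L) span[2] - span[1]
                    else c(span[2] - span[1], span[4] - span[3])
          sm_new <- .rule_splits_mat(rules_src[[rid]], widths, tracks)
          if (!is.null(sm_new)) smat_cache[[rid]][[wkey]] <- sm_new
          smat_done[[rid]][wkey] <- TRUE
        }
        sm <- smat_cache[[rid]][[wkey]]
        if (is.null(sm)) next
        nc <- ncol(sm)
        f <- fns[[pr$sym]]
        sma <- if (nc > 0L) sm + rep(off[seq_len(nc)], each = nrow(sm))
               else sm
        n_nt <- pr$n_nt
        nt_pos <- pr$nt_pos
        step <- 2L * tracks
        # vectorized subcell ids and occupancy filter over all splits
        rows <- seq_len(nrow(sma))
        sidm <- NULL
        if (n_nt > 0L) {
          sidm <- matrix(0L, nrow(sma), n_nt)
          alive <- rep(TRUE, nrow(sma))
          for (r2 in seq_len(n_nt)) {
            base <- (nt_pos[r2] - 1L) * step
            sidm[, r2] <- if (tracks == 1L) {
              sma[, base + 1L] * (n[1] + 1L) + sma[, base + 2L] + 1L
            } else {
              ((sma[, base + 1L] * (n[1] + 1L) + sma[, base + 2L]) *
                 (n[2] + 1L) + sma[, base + 3L]) * (n[2] + 1L) +
                sma[, base + 4L] + 1L
            }
            alive <- alive & occ[[pr$nt_names[nt_pos[r2]]]][sidm[, r2]]
          }
          rows <- which(alive)
        }
        for (si in rows) {
          sp <- sma[si, ]
          subs <- NULL
          if (n_nt > 0L) {
            subs <- vector("list", n_nt)
            for (r2 in seq_len(n_nt))
              subs[[r2]] <- tab[[pr$nt_names[nt_pos[r2]]]][[sidm[si, r2]]]
          }
          s <- .extend(pr, sp, input, tcache, f, pair, subs, strategy,
                       orders, witness_engine, debug, tracks)
          if (.sl_len(s) > 0L) parts[[length(parts) + 1L]] <- s
        }
      }
      if (length(parts) == 0L) next
      if (strategy == "eager") {
        cell <- Reduce(function(a, b) .sl_pmerge(a, b, orders, check = debug),
                       parts)
        # the select step is the identity; in debug mode verify that it
        # would remove nothing
        if (debug) {
          stopifnot(cpp_is_sorted_front(cell$val, .sign_a(orders),
                                        .sign_b(orders), orders$eps))
          stopifnot(length(.pf_idx(cell$val, orders, "sort")) ==
                      nrow(cell$val))
        }
      } else if (strategy == "sorted") {
        cell <- .sl_sort(.sl_concat(parts), orders)
        if (debug) stopifnot(.sorted_lex_ok(cell$val, orders))
        cell <- .sl_pf(cell, orders, pf_variant, check = debug)
      } else {
        cell <- .sl_concat(parts)
        if (is_pf) {
          cell <- .sl_pf(cell, orders, pf_variant, check = debug)
        } else if (choice$selective) {
          cell <- .sl_take(cell, .choice_select(choice, cell$val))
        } else {
          cell <- .sl_new(.choice_reduce(choice, cell$val), NULL)
        }
      }
      if (.sl_len(cell) > cell_limit)
        stop("cell size ", .sl_len(cell), " exceeds cell_limit (",
             cell_limit, ")")
      tab[[nt]][[id]] <- cell
      occ[[nt]][id] <- TRUE
    }
  }
  full <- if (grammar$tracks == 1L) c(0L, n[1]) else c(0L, n[1], 0L, n[2])
  root <- tab[[grammar$axiom]][[.span_id(full, n)]]
  if (is.null(root)) root <- .sl_new(if (algebra$carrier == "pair")
    matrix(numeric(0), ncol = 2) else numeric(0), if (witness_engine) list())
  front <- NULL
  if (is_pf) {
    sorted <- !(strategy == "standard" && pf_variant == "nosort")
    front <- pareto_front(root$val, orders, sorted = sorted)
  }
  structure(list(value = root$val, front = front, witnesses = root$wit,
                 grammar = grammar$name, algebra = algebra$name,
                 strategy = strategy, pf_variant = pf_variant,
                 tables = if (keep_tables) tab else NULL),
            class = "adp_result")
}

#' @export
print.adp_result <- function(x, ...) {
  cat(sprintf("<adp_result: %s(%s), strategy %s%s>\n", x$grammar, x$algebra,
              x$strategy,
              if (!is.null(x$pf_variant)) paste0("/", x$pf_variant) else ""))
  if (!is.null(x$front)) print(x$front) else print(x$value)
  invisible(x)
}

#' Enumerate the search space
#'
#' Produces every candidate term whose yield equals the input -- the
#' full enumeration route used by the test oracles.  Exponential;
#' guarded by `limit`.
#'
#' @param grammar an [adp_grammar()].
#' @param input as in [evaluate()].
#' @param limit maximum candidate count per cell before aborting.
#' @return list of candidate terms.
#' @export
enumerate_candidates <- function(grammar, input, limit = 100000) {
  unit <- adp_algebra("enumerate",
                      fns = .symbol_fn_table(function(...) {
                        args <- Filter(is.numeric, list(...))
                        if (length(args) == 0L) 0 else Reduce(`+`, args) * 0
                      }),
                      choice = adp_choice("all"), carrier = "numeric")
  res <- evaluate(grammar, unit, input, witness = TRUE, cell_limit = limit)
  res$witnesses
}

#' Yield of a candidate term
#'
#' Concatenates the terminal characters of a candidate in left-to-right
#' order, per track.
#'
#' @param term a candidate term.
#' @param tracks 1 or 2.
#' @return character vector of length `tracks`.
#' @export
candidate_yield <- function(term, tracks = 1L) {
  acc <- vector("list", tracks)
  for (t in seq_len(tracks)) acc[[t]] <- character(0)
  rec <- function(x) {
    if (inherits(x, "adp_term")) {
      if (tracks == 1L) {
        if (!is.na(x$pos)) acc[[1]][[length(acc[[1]]) + 1L]] <<- x$char
      } else {
        if (!is.na(x$xpos)) acc[[1]][[length(acc[[1]]) + 1L]] <<- x$xchar
        if (!is.na(x$ypos)) acc[[2]][[length(acc[[2]]) + 1L]] <<- x$ychar
      }
      return(invisible())
    }
    for (a in x$args) rec(a)
  }
  rec(term)
  vapply(acc, paste, character(1), collapse = "")
}
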