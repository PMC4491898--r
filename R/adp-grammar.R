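#' Grammar argument specifications
#'
#' Building blocks for [adp_rule()]: `nt_arg(name)` declares a
#' subproblem argument (a nonterminal), `t_arg(width)` a terminal
#' argument consuming a fixed number of characters per track (0 or 1;
#' e.g. `c(1, 0)` is a deletion column in a two-track grammar).
#'
#' @param name nonterminal name.
#' @param width integer vector, one entry per track, each 0 or 1.
#' @return an argument specification used by [adp_rule()].
#' @export
nt_arg <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(kind = "nt", name = name), class = "adp_arg")
}

#' @rdname nt_arg
#' @export
t_arg <- function(width = 1L) {
  width <- as.integer(width)
  stopifnot(all(width %in% 0:1), any(width == 1L))
  structure(list(kind = "term", width = width), class = "adp_arg")
}

#' Grammar production rule
#'
#' One alternative `nt -> sym(args...)` of a regular tree grammar.  The
#' optional guard restricts admissible rule applications; it receives
#' the terminal values (a list parallel to `args`, `NULL` at
#' subproblem positions), the argument spans, and the input object, and
#' must return a single logical.
#'
#' @param nt name of the left-hand side nonterminal.
#' @param sym signature symbol name.
#' @param args list of [nt_arg()] / [t_arg()] specifications.
#' @param guard `NULL` or `function(terms, spans, input)`.
#' @return an `adp_rule` object.
#' @export
adp_rule <- function(nt, sym, args = list(), guard = NULL) {
  stopifnot(is.character(nt), is.character(sym),
            all(vapply(args, inherits, logical(1), "adp_arg")),
            is.null(guard) || is.function(guard))
  structure(list(nt = nt, sym = sym, args = args, guard = guard),
            class = "adp_rule")
}

#' Regular tree grammar over one or two input tracks
#'
#' The search-space generator of the ADP engine: candidates are terms
#' over the signature implied by the rules, whose yield equals the
#' input (sub)word.  Subwords are 0-based half-open `(i, j)` index
#' pairs, one pair per track, so the empty subword is `i == j`.
#'
#' Within a span, nonterminals are evaluated in the order given by
#' `nt_order` (default: order of first appearance in `rules`); a rule
#' may only consume same-span results of nonterminals evaluated
#' \emph{earlier} in that order.
#'
#' @param name grammar name (used in printing and the CLI registry).
#' @param tracks 1 or 2.
#' @param axiom name of the axiom nonterminal.
#' @param rules list of [adp_rule()].
#' @param nt_order optional character vector ordering the nonterminals.
#' @return an object of class `adp_grammar`.
#' @export
adp_grammar <- function(name, tracks, axiom, rules, nt_order = NULL) {
  stopifnot(tracks %in% 1:2, length(rules) > 0L,
            all(vapply(rules, inherits, logical(1), "adp_rule")))
  nts <- unique(vapply(rules, function(r) r$nt, character(1)))
  if (is.null(nt_order)) nt_order <- nts
  stopifnot(setequal(nt_order, nts), axiom %in% nts)
  for (r in rules) {
    for (a in r$args) {
      if (a$kind == "nt" && !(a$name %in% nts))
        stop(sprintf("rule %s -> %s refers to undefined nonterminal %s",
                     r$nt, r$sym, a$name))
      if (a$kind == "term" && length(a$width) != tracks)
        stop(sprintf("terminal width in rule %s -> %s must have %d entries",
                     r$nt, r$sym, tracks))
    }
  }
  # reachability from the axiom
  reach <- axiom
  repeat {
    new <- unique(unlist(lapply(rules, function(r) {
      if (!(r$nt %in% reach)) return(NULL)
      vapply(Filter(function(a) a$kind == "nt", r$args),
             function(a) a$name, character(1))
    })))
    grown <- union(reach, new)
    if (length(grown) == length(reach)) break
    reach <- grown
  }
  if (!setequal(reach, nts))
    stop("unreachable nonterminal(s): ",
         paste(setdiff(nts, reach), collapse = ", "))
  for (i in seq_along(rules)) rules[[i]]$id <- i
  by_nt <- split(rules, factor(vapply(rules, function(r) r$nt, character(1)),
                               levels = nt_order))
  structure(list(name = name, tracks = tracks, axiom = axiom,
                 rules = rules, by_nt = by_nt, nt_order = nt_order),
            class = "adp_grammar")
}

#' @export
print.adp_grammar <- function(x, ...) {
  cat(sprintf("<adp_grammar '%s': %d track(s), axiom %s, %d rules over {%s}>\n",
              x$name, x$tracks, x$axiom, length(x$rules),
              paste(x$nt_order, collapse = ", ")))
  invisible(x)
}

#' Signature implied by a grammar
#'
#' @param grammar an [adp_grammar()].
#' @return named list: for each symbol, a list with `kinds`
#'   (`"nt"`/`"term"` per argument) and `widths` (terminal widths).
#' @export
grammar_signature <- function(grammar) {
  sig <- list()
  for (r in grammar$rules) {
    kinds <- vapply(r$args, function(a) a$kind, character(1))
    widths <- lapply(r$args, function(a) if (a$kind == "term") a$width else NULL)
    if (is.null(sig[[r$sym]])) {
      sig[[r$sym]] <- list(kinds = kinds, widths = widths)
    } else if (!identical(sig[[r$sym]]$kinds, kinds)) {
      stop(sprintf("symbol %s used with inconsistent argument kinds", r$sym))
    }
  }
  sig
}

# ---- input handling ---------------------------------------------------------

.adp_input <- function(x, tracks) {
  as_chars <- function(s) {
    if (inherits(s, "rna_seq")) s <- s$residues
    stopifnot(is.character(s), length(s) == 1L)
    if (nchar(s) == 0L) character(0) else strsplit(s, "")[[1]]
  }
  if (tracks == 1L) {
    tr <- list(as_chars(x))
  } else {
    stopifnot(is.list(x), length(x) == 2L)
    tr <- lapply(x, as_chars)
  }
  structure(list(tracks = tr, n = vapply(tr, length, integer(1))),
            class = "adp_input")
}

# span: integer vector c(i, j) or c(i, j, k, l), 0-based half-open
.span_id <- function(span, n) {
  if (length(span) == 2L) {
    span[1] * (n[1] + 1L) + span[2] + 1L
  } else {
    ((span[1] * (n[1] + 1L) + span[2]) * (n[2] + 1L) + span[3]) *
      (n[2] + 1L) + span[4] + 1L
  }
}

.span_widths <- function(span) {
  if (length(span) == 2L) span[2] - span[1]
  else c(span[2] - span[1], span[4] - span[3])
}

# all spans in order of increasing total width
.spans_by_width <- function(n) {
  out <- list()
  if (length(n) == 1L) {
    for (w in 0:n[1])
      for (i in 0:(n[1] - w))
        out[[length(out) + 1L]] <- c(i, i + w)
  } else {
    for (w in 0:(n[1] + n[2]))
      for (wx in max(0L, w - n[2]):min(n[1], w)) {
        wy <- w - wx
        for (i in 0:(n[1] - wx))
          for (k in 0:(n[2] - wy))
            out[[length(out) + 1L]] <- c(i, i + wx, k, k + wy)
      }
  }
  out
}

# compositions of total width W over args with fixed (non-NA) widths
.compositions <- function(fixed, W) {
  k <- length(fixed)
  if (k == 0L) return(if (W == 0L) list(integer(0)) else list())
  rest <- function(pos, left) {
    if (pos > k) {
      if (left == 0L) return(list(integer(0))) else return(list())
    }
    if (!is.na(fixed[pos])) {
      if (fixed[pos] > left) return(list())
      tails <- rest(pos + 1L, left - fixed[pos])
      return(lapply(tails, function(t) c(fixed[pos], t)))
    }
    out <- list()
    for (w in 0:left) {
      tails <- rest(pos + 1L, left - w)
      out <- c(out, lapply(tails, function(t) c(w, t)))
    }
    out
  }
  rest(1L, W)
}

# relative (zero-based) argument spans for a rule at given widths;
# pure in (rule, widths), so results are cached per evaluation
.rule_splits_rel <- function(rule, widths, tracks) {
  k <- length(rule$args)
  if (k == 0L) {
    if (all(widths == 0L)) return(list(list()))
    return(list())
  }
  per_track <- vector("list", tracks)
  for (t in seq_len(tracks)) {
    fixed <- vapply(rule$args, function(a)
      if (a$kind == "term") a$width[t] else NA_integer_, integer(1))
    per_track[[t]] <- .compositions(fixed, widths[t])
    if (length(per_track[[t]]) == 0L) return(list())
  }
  out <- list()
  if (tracks == 1L) {
    for (ws in per_track[[1]]) {
      pos <- 0L
      spans <- vector("list", k)
      for (ai in seq_len(k)) {
        spans[[ai]] <- c(pos, pos + ws[ai])
        pos <- pos + ws[ai]
      }
      out[[length(out) + 1L]] <- spans
    }
  } else {
    for (wx in per_track[[1]]) for (wy in per_track[[2]]) {
      px <- 0L; py <- 0L
      spans <- vector("list", k)
      for (ai in seq_len(k)) {
        spans[[ai]] <- c(px, px + wx[ai], py, py + wy[ai])
        px <- px + wx[ai]; py <- py + wy[ai]
      }
      out[[length(out) + 1L]] <- spans
    }
  }
  out
}

# split cache for one evaluation run
.split_cache <- function() new.env(parent = emptyenv(), hash = TRUE)

# enumerate argument spans for a rule at a span (absolute coordinates)
.rule_splits <- function(rule, span, tracks, cache = NULL, rule_id = NULL) {
  widths <- if (tracks == 1L) span[2] - span[1]
            else c(span[2] - span[1], span[4] - span[3])
  rel <- NULL
  key <- NULL
  if (!is.null(cache)) {
    key <- paste0(rule_id, ":", paste(widths, collapse = ","))
    rel <- cache[[key]]
  }
  if (is.null(rel)) {
    rel <- .rule_splits_rel(rule, widths, tracks)
    if (!is.null(cache)) cache[[key]] <- rel
  }
  if (length(rel) == 0L) return(rel)
  off <- if (tracks == 1L) c(span[1], span[1])
         else c(span[1], span[1], span[3], span[3])
  lapply(rel, function(spans) lapply(spans, function(s) s + off))
}

# terminal value: characters and 1-based positions per track (NA where
# the terminal consumes nothing on a track)
.term_value <- function(arg, span, input) {
  tr <- input$tracks
  if (length(span) == 2L) {
    if (arg$width[1] == 1L) {
      structure(list(char = tr[[1]][span[1] + 1L], pos = span[1] + 1L),
                class = "adp_term")
    } else {
      structure(list(char = NA_character_, pos = NA_integer_),
                class = "adp_term")
    }
  } else {
    xc <- NA_character_; xp <- NA_integer_
    yc <- NA_character_; yp <- NA_integer_
    if (arg$width[1] == 1L) { xc <- tr[[1]][span[1] + 1L]; xp <- span[1] + 1L }
    if (arg$width[2] == 1L) { yc <- tr[[2]][span[3] + 1L]; yp <- span[3] + 1L }
    structure(list(xchar = xc, xpos = xp, ychar = yc, ypos = yp),
              class = "adp_term")
  }
}
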