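# Inside-outside over a tree grammar in log space.
#
# Works for any additive numeric scoring whose Boltzmann weight
# factorizes over the rule application: the weight of applying a rule
# is exp(logw(sym, terms)) times the weights of the subproblem
# derivations.  Accumulation is in log space throughout, so deep
# recursions cannot overflow.

.logaddexp <- function(x, y) {
  if (x == -Inf) return(y)
  if (y == -Inf) return(x)
  m <- max(x, y)
  m + log1p(exp(-abs(x - y)))
}

# inside[nt][span] = log sum of Boltzmann weights of all derivations
.pf_inside <- function(grammar, logw, input, cache = .split_cache()) {
  n <- input$n
  tab_len <- if (grammar$tracks == 1L) (n[1] + 1L)^2
             else (n[1] + 1L)^2 * (n[2] + 1L)^2
  ins <- lapply(setNames(grammar$nt_order, grammar$nt_order),
                function(nt) rep(-Inf, tab_len))
  spans <- .spans_by_width(n)
  for (span in spans) {
    id <- .span_id(span, n)
    for (nt in grammar$nt_order) {
      acc <- -Inf
      for (r in grammar$by_nt[[nt]]) {
        for (sp in .rule_splits(r, span, grammar$tracks, cache, r$id)) {
          terms <- vector("list", length(r$args))
          lw <- 0
          ok <- TRUE
          for (ai in seq_along(r$args)) {
            a <- r$args[[ai]]
            if (a$kind == "term") {
              terms[[ai]] <- .term_value(a, sp[[ai]], input)
            } else {
              v <- ins[[a$name]][.span_id(sp[[ai]], n)]
              if (v == -Inf) { ok <- FALSE; break }
              lw <- lw + v
            }
          }
          if (!ok) next
          if (!is.null(r$guard) && !isTRUE(r$guard(terms, sp, input))) next
          acc <- .logaddexp(acc, lw + logw(r$sym, terms))
        }
      }
      ins[[nt]][id] <- acc
    }
  }
  list(inside = ins, spans = spans)
}

# outside[nt][span] = log sum of weights of contexts of nt at span
.pf_outside <- function(grammar, logw, input, ins, spans,
                        cache = .split_cache()) {
  n <- input$n
  out <- lapply(ins, function(v) rep(-Inf, length(v)))
  full <- if (grammar$tracks == 1L) c(0L, n[1]) else c(0L, n[1], 0L, n[2])
  out[[grammar$axiom]][.span_id(full, n)] <- 0
  for (span in rev(spans)) {
    id <- .span_id(span, n)
    # same-span dependencies run opposite to the inside order
    for (nt in rev(grammar$nt_order)) {
      o <- out[[nt]][id]
      if (o == -Inf) next
      for (r in grammar$by_nt[[nt]]) {
        for (sp in .rule_splits(r, span, grammar$tracks, cache, r$id)) {
          terms <- vector("list", length(r$args))
          sub_ids <- integer(0); sub_pos <- integer(0)
          lws <- numeric(0)
          ok <- TRUE
          for (ai in seq_along(r$args)) {
            a <- r$args[[ai]]
            if (a$kind == "term") {
              terms[[ai]] <- .term_value(a, sp[[ai]], input)
            } else {
              sid <- .span_id(sp[[ai]], n)
              v <- ins[[a$name]][sid]
              if (v == -Inf) { ok <- FALSE; break }
              sub_ids <- c(sub_ids, sid)
              sub_pos <- c(sub_pos, ai)
              lws <- c(lws, v)
            }
          }
          if (!ok || length(sub_ids) == 0L) next
          if (!is.null(r$guard) && !isTRUE(r$guard(terms, sp, input))) next
          base <- o + logw(r$sym, terms)
          tot <- sum(lws)
          for (ri in seq_along(sub_ids)) {
            name <- r$args[[sub_pos[ri]]]$name
            contrib <- base + (tot - lws[ri])
            out[[name]][sub_ids[ri]] <-
              .logaddexp(out[[name]][sub_ids[ri]], contrib)
          }
        }
      }
    }
  }
  out
}

#' Base-pair probability matrix from the Boltzmann ensemble
#'
#' Computes `Psi[i, j] = P[(i, j) paired]` over the folding space of
#' the sequence, weighting each structure `S` by `exp(-beta * E(S))`
#' with the model's simplified energy.  Implemented as a generic
#' inside-outside pass over the folding grammar, entirely in log space.
#' Stored in the upper triangle (`i < j`); non-admissible pairs are 0.
#'
#' @param seq an [rna_seq()] or character string.
#' @param model a [fold_model()].
#' @param max_len refuse longer sequences (the pass is cubic).
#' @return an n x n matrix with entries in `[0, 1]`,
#'   `sum(Psi[i, ]) <= 1` for every `i`.
#' @export
partition_pairprobs <- function(seq, model = fold_model(), max_len = 150L) {
  seq <- .as_rna(seq)
  n <- nchar(seq$residues)
  if (n > max_len)
    stop(sprintf("sequence length %d exceeds max_len = %d", n, max_len))
  psi <- matrix(0, n, n)
  if (n == 0L) return(psi)
  grammar <- fold_grammar(model)
  beta <- model$beta
  contrib <- c(nil = 0, unp = 0, split = 0, pr = model$e_pair,
               stk = model$e_pair + model$e_stack)
  logw <- function(sym, terms) -beta * contrib[[sym]]
  input <- .adp_input(seq$residues, 1L)
  i_res <- .pf_inside(grammar, logw, input)
  ins <- i_res$inside
  out <- .pf_outside(grammar, logw, input, ins, i_res$spans)
  logZ <- ins[[grammar$axiom]][.span_id(c(0L, n), input$n)]
  # every application of pr/stk at a P-span (i, j) realizes the pair
  # (i + 1, j) in 1-based coordinates
  for (r in grammar$rules) {
    if (!(r$sym %in% c("pr", "stk"))) next
    for (span in i_res$spans) {
      w <- span[2] - span[1]
      if (w < 2L) next
      o <- out[[r$nt]][.span_id(span, input$n)]
      if (o == -Inf) next
      for (sp in .rule_splits(r, span, 1L)) {
        terms <- list(.term_value(r$args[[1]], sp[[1]], input), NULL,
                      .term_value(r$args[[3]], sp[[3]], input))
        if (!is.null(r$guard) && !isTRUE(r$guard(terms, sp, input))) next
        v <- ins[[r$args[[2]]$name]][.span_id(sp[[2]], input$n)]
        if (v == -Inf) next
        i1 <- span[1] + 1L; j1 <- span[2]
        psi[i1, j1] <- psi[i1, j1] +
          exp(o + logw(r$sym, terms) + v - logZ)
      }
    }
  }
  psi
}
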