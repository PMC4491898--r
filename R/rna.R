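#' RNA sequence
#'
#' A validated single RNA sequence: case-folded to upper case, `T`
#' normalized to `U`, alphabet restricted to `A`, `C`, `G`, `U`.
#'
#' @param residues character string of residues.
#' @param id sequence identifier.
#' @return an object of class `rna_seq`.
#' @examples
#' rna_seq("gattaca", "toy")$residues  # "GAUUACA"
#' @export
rna_seq <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L,
            is.character(id), length(id) == 1L)
  r <- chartr("tT", "uU", residues)
  r <- toupper(r)
  bad <- regmatches(r, regexpr("[^ACGU]", r))
  if (length(bad) && nzchar(bad))
    stop(sprintf("invalid residue '%s' in sequence '%s'", bad, id))
  structure(list(id = id, residues = r), class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf(">%s\n%s\n", x$id, x$residues))
  invisible(x)
}

#' Simplified folding model
#'
#' A deliberately small, configurable energy model for secondary
#' structures: each admissible base pair contributes `e_pair`, each
#' stacked pair (a pair immediately enclosing another pair) an
#' additional `e_stack`; there is no nearest-neighbour parameter table.
#' The same model drives the Boltzmann ensemble used for base-pair
#' probabilities via the inverse temperature proxy `beta`.
#'
#' @param pairing admissible base pairs (default Watson-Crick + GU).
#' @param minloop minimal number of positions between the two partners
#'   of a pair: a pair `(i, j)` requires `j - i > minloop`.
#' @param e_pair,e_stack energy contributions (model units; negative =
#'   stabilizing).
#' @param beta Boltzmann scale (> 0) weighting structures by
#'   `exp(-beta * E)`.
#' @param avoid_lonely if `TRUE`, the grammar only generates helices of
#'   at least two stacked pairs.
#' @return an object of class `fold_model`.
#' @export
fold_model <- function(pairing = c("AU", "UA", "CG", "GC", "GU", "UG"),
                       minloop = 3L, e_pair = -1, e_stack = -1, beta = 1,
                       avoid_lonely = FALSE) {
  minloop <- as.integer(minloop)
  stopifnot(minloop >= 0L, is.finite(e_pair), is.finite(e_stack), beta > 0)
  structure(list(pairing = pairing, minloop = minloop, e_pair = e_pair,
                 e_stack = e_stack, beta = beta,
                 avoid_lonely = isTRUE(avoid_lonely)),
            class = "fold_model")
}

.can_pair <- function(model, x, y) paste0(x, y) %in% model$pairing

#' Folding tree grammar
#'
#' An unambiguous Nussinov-style grammar whose candidates are exactly
#' the non-crossing secondary structures respecting the model's pairing
#' rule and minimum loop size.  Every structure decomposes uniquely by
#' what happens at its first position (`nil` / unpaired / paired);
#' pairs immediately enclosing another pair use the dedicated `stk`
#' symbol so that stacking energies are scored algebraically.
#'
#' Signature: `nil()`, `unp(base, S)`, `split(P, S)`, `pr(base, S,
#' base)`, `stk(base, P, base)`.
#'
#' @param model a [fold_model()].
#' @return an [adp_grammar()].
#' @export
fold_grammar <- function(model = fold_model()) {
  pair_guard <- function(terms, spans, input) {
    o <- terms[[1]]; c <- terms[[3]]
    .can_pair(model, o$char, c$char) && (c$pos - o$pos > model$minloop)
  }
  nonempty_rest <- function(terms, spans, input) {
    spans[[2]][2] > spans[[2]][1]
  }
  if (!model$avoid_lonely) {
    rules <- list(
      adp_rule("P", "pr", list(t_arg(), nt_arg("N"), t_arg()), pair_guard),
      adp_rule("P", "stk", list(t_arg(), nt_arg("P"), t_arg()), pair_guard),
      adp_rule("N", "nil"),
      adp_rule("N", "unp", list(t_arg(), nt_arg("S"))),
      adp_rule("N", "split", list(nt_arg("P"), nt_arg("S")), nonempty_rest),
      adp_rule("S", "nil"),
      adp_rule("S", "unp", list(t_arg(), nt_arg("S"))),
      adp_rule("S", "split", list(nt_arg("P"), nt_arg("S"))))
    adp_grammar("fold", tracks = 1L, axiom = "S", rules = rules,
                nt_order = c("P", "N", "S"))
  } else {
    rules <- list(
      adp_rule("P", "pr", list(t_arg(), nt_arg("N"), t_arg()), pair_guard),
      adp_rule("P", "stk", list(t_arg(), nt_arg("P"), t_arg()), pair_guard),
      adp_rule("H", "stk", list(t_arg(), nt_arg("P"), t_arg()), pair_guard),
      adp_rule("N", "nil"),
      adp_rule("N", "unp", list(t_arg(), nt_arg("S"))),
      adp_rule("N", "split", list(nt_arg("H"), nt_arg("S")), nonempty_rest),
      adp_rule("S", "nil"),
      adp_rule("S", "unp", list(t_arg(), nt_arg("S"))),
      adp_rule("S", "split", list(nt_arg("H"), nt_arg("S"))))
    adp_grammar("fold_nolonely", tracks = 1L, axiom = "S", rules = rules,
                nt_order = c("P", "H", "N", "S"))
  }
}

#' Free-energy and expected-accuracy algebras for folding
#'
#' `energy_algebra` sums the model's per-pair and per-stack
#' contributions and minimizes; `mea_algebra` sums the base-pair
#' probabilities of the chosen pairs and maximizes.  (The latter is a
#' plain pair-probability sum without an unpaired-accuracy term.)  Both
#' are strictly monotone, as [check_monotone()] confirms.
#'
#' @param model a [fold_model()].
#' @param psi base-pair probability matrix from
#'   [partition_pairprobs()] for the sequence being folded.
#' @return an [adp_algebra()].
#' @export
energy_algebra <- function(model = fold_model()) {
  adp_algebra("energy", fns = list(
    nil = function() 0,
    unp = function(t, x) x,
    split = function(x, y) x + y,
    pr = function(t1, x, t2) x + model$e_pair,
    stk = function(t1, x, t2) x + model$e_pair + model$e_stack),
    choice = adp_choice("min"), carrier = "numeric", direction = "min")
}

#' @rdname energy_algebra
#' @export
mea_algebra <- function(psi) {
  stopifnot(is.matrix(psi))
  adp_algebra("mea", fns = list(
    nil = function() 0,
    unp = function(t, x) x,
    split = function(x, y) x + y,
    pr = function(t1, x, t2) {
      if (t1$pos > nrow(psi) || t2$pos > ncol(psi))
        stop("pair probability matrix does not match the sequence length")
      x + psi[t1$pos, t2$pos]
    },
    stk = function(t1, x, t2) {
      if (t1$pos > nrow(psi) || t2$pos > ncol(psi))
        stop("pair probability matrix does not match the sequence length")
      x + psi[t1$pos, t2$pos]
    }),
    choice = adp_choice("max"), carrier = "numeric", direction = "max")
}

#' Size of the folding space
#'
#' Evaluates the counting algebra: the number of admissible secondary
#' structures of the sequence.
#'
#' @param seq an [rna_seq()] or character string.
#' @param model a [fold_model()].
#' @return a count (double).
#' @export
fold_count <- function(seq, model = fold_model()) {
  evaluate(fold_grammar(model), count_algebra(), .as_rna(seq)$residues)$value
}

.as_rna <- function(seq) {
  if (inherits(seq, "rna_seq")) seq else rna_seq(seq)
}

#' Pairs and dot-bracket string of a folding candidate
#'
#' @param term a candidate term from the folding grammar.
#' @return `structure_pairs`: integer matrix with columns `i`, `j`
#'   (1-based, `i < j`); `dot_bracket`: the usual parenthesis string.
#' @export
structure_pairs <- function(term) {
  acc <- list()
  rec <- function(x) {
    if (inherits(x, "adp_term")) return(invisible())
    if (x$sym %in% c("pr", "stk"))
      acc[[length(acc) + 1L]] <<- c(x$args[[1]]$pos, x$args[[3]]$pos)
    for (a in x$args) if (!inherits(a, "adp_term")) rec(a)
  }
  rec(term)
  if (length(acc) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, acc)
  colnames(m) <- c("i", "j")
  m[order(m[, 1]), , drop = FALSE]
}

#' @rdname structure_pairs
#' @param pairs a pair matrix as returned by `structure_pairs`.
#' @param n sequence length.
#' @export
dot_bracket <- function(pairs, n) {
  s <- rep(".", n)
  if (nrow(pairs)) {
    s[pairs[, 1]] <- "("
    s[pairs[, 2]] <- ")"
  }
  paste(s, collapse = "")
}

#' Bi-objective folding: free energy versus expected accuracy
#'
#' Folds one sequence under the Pareto product of the energy algebra
#' (minimized) and the expected-accuracy algebra (maximized), returning
#' the exact Pareto front of the folding space with one witness
#' structure per front element.
#'
#' @param seq an [rna_seq()] or character string.
#' @param model a [fold_model()].
#' @param strategy,pf_variant forwarded to [product_pareto()].
#' @param psi optional precomputed [partition_pairprobs()] matrix.
#' @param max_len refuse longer sequences (cubic DP with quadratic
#'   front work; the default keeps runtimes interactive).
#' @param witness keep witness structures (default `TRUE`).
#' @return an object of class `fold_result`: a data frame-like summary
#'   (`$table` with columns energy, mea, structure), the
#'   [pareto_front()] in `$front`, and the inputs used.
#' @export
fold_pareto <- function(seq, model = fold_model(), strategy = "standard",
                        pf_variant = NULL, psi = NULL, max_len = 200L,
                        witness = TRUE) {
  seq <- .as_rna(seq)
  n <- nchar(seq$residues)
  if (n == 0L) stop("cannot fold an empty sequence")
  if (n > max_len)
    stop(sprintf("sequence '%s' has length %d > max_len = %d", seq$id, n,
                 max_len))
  if (is.null(psi)) psi <- partition_pairprobs(seq, model)
  grammar <- fold_grammar(model)
  prod <- product_pareto(energy_algebra(model), mea_algebra(psi),
                         strategy = strategy, pf_variant = pf_variant)
  res <- evaluate(grammar, prod, seq$residues, witness = witness)
  structures <- NULL
  if (witness)
    structures <- vapply(res$witnesses, function(w)
      dot_bracket(structure_pairs(w), n), character(1))
  tbl <- data.frame(energy = res$value[, 1], mea = res$value[, 2])
  if (!is.null(structures)) tbl$structure <- structures
  structure(list(seq = seq, model = model, front = res$front, table = tbl,
                 witnesses = res$witnesses, psi = psi,
                 strategy = res$strategy, pf_variant = res$pf_variant),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("Pareto folding of '%s' (%d nt): %d front element(s)\n",
              x$seq$id, nchar(x$seq$residues), nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
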