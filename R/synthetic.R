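#' Specification for the synthetic sequence generator
#'
#' The generator stands in for external sequence datasets: given a
#' spec and its seed it deterministically produces random RNA
#' sequences with a chosen GC content.
#'
#' @param n_sequences number of sequences.
#' @param length either one integer (fixed length) or `c(min, max)`
#'   (uniform lengths).
#' @param gc target GC content in `[0, 1]`; G and C (resp. A and U)
#'   are drawn with equal probability within their class.
#' @param seed RNG seed; `(spec, seed)` fully determines the output.
#' @param prefix id prefix.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences = 10L, length = c(20L, 40L), gc = 0.5,
                           seed = 1L, prefix = "synth") {
  length <- as.integer(length)
  if (base::length(length) == 1L) length <- c(length, length)
  stopifnot(base::length(length) == 2L, length[1] >= 1L,
            length[2] >= length[1], gc >= 0, gc <= 1, n_sequences >= 1L)
  structure(list(n_sequences = as.integer(n_sequences), length = length,
                 gc = gc, seed = as.integer(seed), prefix = prefix),
            class = "synthetic_spec")
}

#' Generate seeded random RNA sequences
#'
#' @param spec a [synthetic_spec()].
#' @return list of [rna_seq()] objects.
#' @examples
#' s <- generate_sequences(synthetic_spec(2, 10, seed = 42))
#' s[[1]]$residues
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
             G = spec$gc / 2, U = (1 - spec$gc) / 2)
  .with_seed(spec$seed, {
    lens <- spec$length[1] - 1L +
      sample.int(spec$length[2] - spec$length[1] + 1L, spec$n_sequences,
                 replace = TRUE)
    lapply(seq_len(spec$n_sequences), function(i) {
      r <- paste(sample(names(probs), lens[i], replace = TRUE, prob = probs),
                 collapse = "")
      rna_seq(r, sprintf("%s_%03d", spec$prefix, i))
    })
  })
}
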