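#' Read RNA sequences from a FASTA file
#'
#' Records are case-folded, `T` is accepted and stored as `U`, and the
#' alphabet is validated; a malformed record is reported with its
#' index.  An empty file yields an empty list.
#'
#' @param path FASTA file path.
#' @return list of [rna_seq()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .input_error("no such file: ", path)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    .input_error("malformed FASTA file '", path, "': ",
                                 conditionMessage(e)))
  out <- vector("list", length(set))
  nms <- names(set)
  for (i in seq_along(set)) {
    id <- sub("\\s.*$", "", nms[i])
    if (!nzchar(id)) id <- sprintf("record_%d", i)
    out[[i]] <- tryCatch(rna_seq(as.character(set[[i]]), id),
                         error = function(e)
                           .input_error(sprintf("record %d of '%s': %s", i,
                                                path, conditionMessage(e))))
  }
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs list of [rna_seq()] objects.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- vapply(seqs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.input_error <- function(...) {
  stop(structure(class = c("pdp_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.usage_error <- function(...) {
  stop(structure(class = c("pdp_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Set equality of two pair collections
#'
#' Compares two score-pair collections as sets (exact componentwise
#' equality, order-insensitive).
#'
#' @param x,y [pareto_front()] objects or n x 2 matrices.
#' @return logical.
#' @export
front_setequal <- function(x, y) {
  as_m <- function(z) if (inherits(z, "pareto_front")) z$pairs
                      else .as_pair_matrix(z)
  mx <- as_m(x); my <- as_m(y)
  if (nrow(mx) != nrow(my)) return(FALSE)
  if (nrow(mx) == 0L) return(TRUE)
  ox <- order(mx[, 1], mx[, 2]); oy <- order(my[, 1], my[, 2])
  isTRUE(all.equal(mx[ox, , drop = FALSE], my[oy, , drop = FALSE],
                   tolerance = 0, check.attributes = FALSE))
}
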