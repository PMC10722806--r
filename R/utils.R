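# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a per-stage seed from a master seed, kept inside 32-bit range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector of sequences.
#' @return Reverse-complemented sequences (N preserved).
#' @export
revcomp <- function(x) {
  as.character(cpp_revcomp(x))
}
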