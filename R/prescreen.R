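#' Pre-screen reads against the starting database
#'
#' Optional recruitment step that shrinks the read set before the EM
#' iteration: a read passes when it shares at least `min_shared` canonical
#' k-mers (lexicographic minimum of a k-mer and its reverse complement) with
#' any database representative.  If either mate of a pair passes, both mates
#' are retained, since the EM treats pairs as units.  Input order is
#' preserved and the operation is idempotent.
#'
#' @param reads Read data frame as returned by [read_fastq_pair()] (or
#'   [read_fastq()] for unpaired input).
#' @param db A `starting_db` object from [build_reference_db()], or a named
#'   character vector of reference sequences.
#' @param k k-mer size; must not exceed the shortest read length.
#' @param min_shared Minimum number of shared canonical k-mers.
#' @return The subset of `reads` that passes the screen.
#' @export
prescreen_reads <- function(reads, db, k = 21L, min_shared = 1L) {
  refs <- db_sequences(db)
  if (!length(refs)) stop("empty reference database")
  if (!nrow(reads)) return(reads)
  if (k > min(nchar(reads$bases)))
    stop("k = ", k, " exceeds the shortest read length")
  shared <- cpp_prescreen(cpp_encode(reads$bases), cpp_encode(refs), k)
  pass <- shared >= min_shared
  if (!is.null(reads$pair)) {
    # pair rescue: either mate passing retains both
    pass_pairs <- unique(reads$pair[pass])
    pass <- reads$pair %in% pass_pairs
  }
  reads[pass, , drop = FALSE]
}

db_sequences <- function(db) {
  if (inherits(db, "starting_db"))
    stats::setNames(db$representatives$sequence, db$representatives$id)
  else if (is.data.frame(db)) stats::setNames(db$sequence, db$id)
  else db
}
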