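#' Resolve IUPAC ambiguity codes to concrete bases
#'
#' Every non-ACGT symbol is replaced deterministically by the alphabetically
#' first compatible concrete base: R->A, Y->C, S->C, W->A, K->G, M->A, B->C,
#' D->A, H->A, V->A, N->A.
#'
#' @param sequence Character vector of nucleotide sequences (IUPAC alphabet).
#' @return Character vector over `{A, C, G, T}`.
#' @export
resolve_ambiguity <- function(sequence) {
  sequence <- toupper(sequence)
  bad <- grepl(sprintf("[^%s]", IUPAC_CODES), sequence)
  if (any(bad))
    stop("symbol outside the IUPAC nucleotide alphabet in sequence ",
         which(bad)[1L])
  chartr("RYSWKMBDHVN", "ACCAGACAAAA", sequence)
}

#' Global-alignment identity between two sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' gap -2; identity is the number of identical columns divided by the total
#' number of alignment columns.  This is the shared identity definition used
#' both for reference clustering and for merging reconstructed clusters.
#'
#' @param a,b Nucleotide sequences (character scalars, ambiguity-free).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- cpp_nw_align(cpp_encode(a)[[1]], cpp_encode(b)[[1]])
  aln$identity
}

#' Build a starting reference database
#'
#' Filters, clusters and ambiguity-resolves an arbitrary FASTA of candidate
#' gene sequences into the starting database for the EM iteration.
#' Sequences shorter than `min_length` are dropped; the rest are resolved to
#' concrete bases and greedily clustered CD-HIT-style: sorted by length
#' descending (ties by id ascending), each sequence joins the first existing
#' representative whose global-alignment identity exceeds
#' `cluster_identity`, otherwise it founds a new cluster.
#'
#' @param seqs A data frame as returned by [read_fasta()], a named character
#'   vector of sequences, or a FASTA path.
#' @param min_length Minimum sequence length (nt) to retain.
#' @param cluster_identity Identity threshold above which a sequence joins an
#'   existing cluster.
#' @return An object of class `starting_db`: list with `representatives`
#'   (data frame `id`, `sequence`), `cluster_map` (named character, member id
#'   -> representative id), `min_length`, `cluster_identity`.
#' @export
build_reference_db <- function(seqs, min_length = 150L,
                               cluster_identity = 0.97) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fasta(seqs)
  if (!is.data.frame(seqs))
    seqs <- data.frame(id = names(seqs), sequence = unname(seqs),
                       stringsAsFactors = FALSE)
  if (!nrow(seqs)) stop("no input sequences")
  seqs$sequence <- resolve_ambiguity(seqs$sequence)
  keep <- nchar(seqs$sequence) >= min_length
  seqs <- seqs[keep, , drop = FALSE]
  if (!nrow(seqs))
    stop("empty database: all sequences shorter than min_length = ",
         min_length)
  ord <- order(-nchar(seqs$sequence), seqs$id, method = "radix")
  seqs <- seqs[ord, , drop = FALSE]
  rep_id <- character(0)
  rep_seq <- character(0)
  cluster_map <- character(0)
  for (i in seq_len(nrow(seqs))) {
    assigned <- NA_integer_
    for (j in seq_along(rep_seq)) {
      if (pairwise_identity(seqs$sequence[i], rep_seq[j]) > cluster_identity) {
        assigned <- j
        break
      }
    }
    if (is.na(assigned)) {
      rep_id <- c(rep_id, seqs$id[i])
      rep_seq <- c(rep_seq, seqs$sequence[i])
      cluster_map[seqs$id[i]] <- seqs$id[i]
    } else {
      cluster_map[seqs$id[i]] <- rep_id[assigned]
    }
  }
  structure(list(representatives = data.frame(id = rep_id, sequence = rep_seq,
                                              stringsAsFactors = FALSE),
                 cluster_map = cluster_map,
                 min_length = as.integer(min_length),
                 cluster_identity = cluster_identity),
            class = "starting_db")
}

#' @export
print.starting_db <- function(x, ...) {
  cat("Starting reference database\n")
  cat(sprintf("  %d representatives from %d input sequences\n",
              nrow(x$representatives), length(x$cluster_map)))
  cat(sprintf("  min length %d nt, cluster identity > %.2f\n",
              x$min_length, x$cluster_identity))
  invisible(x)
}

#' Write a starting database to disk
#'
#' Emits the representatives as FASTA and the member-to-representative map as
#' a two-column TSV.
#'
#' @param db A `starting_db` object.
#' @param fasta_path,map_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_reference_db <- function(db, fasta_path, map_path = NULL) {
  write_fasta(db$representatives, fasta_path)
  if (!is.null(map_path)) {
    utils::write.table(
      data.frame(member = names(db$cluster_map),
                 representative = unname(db$cluster_map)),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
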