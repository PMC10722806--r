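#' Per-sample cluster abundance counts
#'
#' Counts, for every sample and cluster, the reads whose primary alignment
#' is to that cluster.  Input can be a fitted [gscem()] object, a SAM path
#' written by [write_gscem_outputs()], or an alignment data frame with
#' `read_id`, `gsc_id` and `primary` columns.  Sample tags are parsed from
#' the read ids (`"<sample_tag>:<serial>"`); unaligned reads contribute
#' nothing.
#'
#' @param x Fit, SAM path, or alignment data frame.
#' @param samples Optional character vector fixing the sample (row) order;
#'   samples without alignments get zero rows.
#' @param gsc_ids Optional character vector fixing the cluster (column)
#'   order.
#' @param fractional If `TRUE` and `x` is a fit, spread each read's weight
#'   over all its alignments by posterior instead of hard primary counting.
#' @return Count matrix, samples as rows, clusters as columns.
#' @export
count_abundance <- function(x, samples = NULL, gsc_ids = NULL,
                            fractional = FALSE) {
  if (inherits(x, "gscem")) {
    a <- x$alignments
    a$read_id <- paste0(a$read_id, "/", a$mate)
    if (is.null(gsc_ids)) gsc_ids <- x$gscs$id
    w <- if (fractional) a$posterior else as.numeric(a$primary)
  } else {
    if (is.character(x) && length(x) == 1L) x <- read_sam(x)$alignments
    a <- x
    if (fractional)
      stop("fractional counting requires a fitted gscem object")
    w <- as.numeric(a$primary)
  }
  tag <- parse_sample_tag(a$read_id)
  if (anyNA(tag[w > 0]))
    stop("read id without parseable sample tag: ",
         a$read_id[w > 0 & is.na(tag)][1L])
  if (is.null(samples)) samples <- sort(unique(stats::na.omit(tag)))
  if (is.null(gsc_ids)) gsc_ids <- sort(unique(a$gsc_id))
  A <- matrix(0, nrow = length(samples), ncol = length(gsc_ids),
              dimnames = list(samples, gsc_ids))
  keep <- w > 0 & !is.na(tag)
  if (any(keep)) {
    agg <- stats::aggregate(w[keep],
                            list(sample = tag[keep], gsc = a$gsc_id[keep]),
                            sum)
    A[cbind(match(agg$sample, samples), match(agg$gsc, gsc_ids))] <- agg$x
  }
  A
}

#' Depth- and length-corrected abundance normalization
#'
#' Applies the cross-sample normalization
#' `N[s, i] = A[s, i] * (r_max / r_s) * (l_max / l_i)`, where `r_s` is the
#' number of input clean reads of sample `s`, `r_max` its maximum over
#' samples, `l_i` the length of gene (cluster) `i` and `l_max` the maximum
#' gene length.  For the deepest sample and the longest gene the matrix is
#' returned unchanged.
#'
#' @param A Count matrix, samples as rows, clusters as columns.
#' @param reads_per_sample Named numeric vector of input read counts per
#'   sample (individual reads, not pairs).
#' @param gene_lengths Named numeric vector of cluster lengths (nt).
#' @return The normalized matrix `N`, same dimensions as `A`.
#' @export
normalize_abundance <- function(A, reads_per_sample, gene_lengths) {
  if (is.table(reads_per_sample)) {
    reads_per_sample <- stats::setNames(as.numeric(reads_per_sample),
                                        names(reads_per_sample))
  }
  r_s <- reads_per_sample[rownames(A)]
  l_i <- gene_lengths[colnames(A)]
  if (anyNA(r_s)) stop("missing read counts for sample: ",
                       rownames(A)[is.na(r_s)][1L])
  if (anyNA(l_i)) stop("missing length for cluster: ",
                       colnames(A)[is.na(l_i)][1L])
  if (any(r_s <= 0)) stop("read counts must be positive")
  if (any(l_i <= 0)) stop("gene lengths must be positive")
  sweep(sweep(A, 1, max(r_s) / r_s, `*`), 2, max(l_i) / l_i, `*`)
}
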