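#' @export
print.gscem <- function(x, ...) {
  cat("EM gene-sequence-cluster reconstruction\n")
  cat(sprintf("  %d reads (%d units) -> %d GSCs in %d iterations, logLik %.2f\n",
              x$n_reads, x$n_units, nrow(x$gscs), nrow(x$history), x$logLik))
  ab <- sort(x$gscs$norm_prior, decreasing = TRUE)
  cat("  length-normalized abundances:",
      paste(sprintf("%.3f", utils::head(ab, 8)), collapse = " "),
      if (length(ab) > 8) "...\n" else "\n")
  invisible(x)
}

#' Summarize a fitted reconstruction
#'
#' @param object A `gscem` fit.
#' @param ... Unused.
#' @return A list with the per-cluster table and the iteration history,
#'   printed as a compact report.
#' @export
summary.gscem <- function(object, ...) {
  out <- list(gscs = object$gscs[, c("id", "length", "prior", "norm_prior",
                                     "origin", "source_id")],
              history = object$history, logLik = object$logLik,
              n_reads = object$n_reads)
  class(out) <- "summary.gscem"
  out
}

#' @export
print.summary.gscem <- function(x, ...) {
  cat("Gene sequence clusters:\n")
  print(x$gscs, row.names = FALSE, digits = 4)
  cat("\nIteration history:\n")
  print(x$history, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Mixing proportions of a fitted reconstruction
#'
#' @param object A `gscem` fit.
#' @param normalized If `TRUE` (default) return the length-normalized
#'   relative abundances `(pi_i / l_i) / sum_k (pi_k / l_k)`; otherwise the
#'   raw mixing priors `pi`.
#' @param ... Unused.
#' @return Named numeric vector over cluster ids.
#' @export
coef.gscem <- function(object, normalized = TRUE, ...) {
  stats::setNames(if (normalized) object$gscs$norm_prior
                  else object$gscs$prior, object$gscs$id)
}

#' @export
logLik.gscem <- function(object, ...) {
  structure(object$logLik, df = nrow(object$gscs), class = "logLik")
}

#' Diagnostic plots for a fitted reconstruction
#'
#' Two base-graphics panels: the observed-data log-likelihood trace over
#' iterations and the final length-normalized cluster abundances.
#'
#' @param x A `gscem` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gscem <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$iteration, x$history$loglik, type = "b",
                 xlab = "iteration", ylab = "log-likelihood",
                 main = "EM trace", ...)
  graphics::barplot(sort(x$gscs$norm_prior, decreasing = TRUE),
                    names.arg = x$gscs$id[order(-x$gscs$norm_prior)],
                    las = 2, ylab = "relative abundance",
                    main = "final GSCs")
  invisible(x)
}

#' Write the standard output files of a fit
#'
#' Materializes the reconstruction: `gscs.fasta` (headers carry prior,
#' length-normalized prior, length and origin), `relative_abundance.tsv`,
#' `final.sam` (last-iteration alignments; the max-posterior alignment per
#' read is flagged primary) and `iterations.tsv`.
#'
#' @param fit A `gscem` fit.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gscem_outputs <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- fit$gscs
  write_fasta(data.frame(
    id = g$id,
    description = sprintf("prior=%.6g norm_prior=%.6g length=%d origin=%s",
                          g$prior, g$norm_prior, g$length, g$origin),
    sequence = g$consensus), file.path(dir, "gscs.fasta"))
  utils::write.table(g[, c("id", "length", "prior", "norm_prior", "origin",
                           "source_id")],
                     file.path(dir, "relative_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$history, file.path(dir, "iterations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_alignment(sam_records(fit), stats::setNames(g$consensus, g$id),
                  file.path(dir, "final.sam"))
  invisible(dir)
}

# turn the fit's alignment table into write_alignment() records
sam_records <- function(fit) {
  a <- fit$alignments
  info <- fit$read_info
  bases <- info$bases[a$read]
  quals <- info$quals[a$read]
  minus <- a$strand == "-"
  seq_out <- bases
  seq_out[minus] <- revcomp(bases[minus])
  qual_out <- vapply(seq_along(quals), function(i) {
    q <- quals[[i]]
    if (minus[i]) q <- rev(q)
    rawToChar(as.raw(q + 33L))
  }, character(1))
  data.frame(read_id = paste0(a$read_id, "/", a$mate),
             gsc_id = a$gsc_id, ref_start = a$ref_start, strand = a$strand,
             cigar = a$cigar, nm = a$nm, seq = seq_out, qual = qual_out,
             primary = a$primary, stringsAsFactors = FALSE)
}
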