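#' Simulate a set of gene templates at controlled divergence
#'
#' Draws one random ancestor sequence and derives each template by
#' substituting bases at a fraction `divergence` of positions chosen
#' uniformly (each substituted to a uniformly chosen different base), so that
#' every template's identity to the ancestor is `1 - divergence` exactly.
#' Bit-reproducible given `seed`.
#'
#' @param n Number of templates.
#' @param length Template length (nt).
#' @param divergence Fraction of positions substituted per template, in
#'   `[0, 0.75]`.
#' @param seed Integer RNG seed.
#' @param prefix Template id prefix.
#' @return Data frame with columns `id`, `description`, `sequence`.
#' @export
simulate_templates <- function(n, length, divergence = 0.1, seed = 1L,
                               prefix = "tpl") {
  if (n < 1L) stop("n must be >= 1")
  if (divergence < 0 || divergence > 0.75)
    stop("divergence must lie in [0, 0.75]")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    anc <- sample(bases, length, replace = TRUE)
    n_sub <- as.integer(round(divergence * length))
    seqs <- vapply(seq_len(n), function(i) {
      s <- anc
      if (n_sub > 0L) {
        pos <- sample.int(length, n_sub)
        for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
      }
      paste(s, collapse = "")
    }, character(1))
    data.frame(id = sprintf("%s_%02d", prefix, seq_len(n)),
               description = sprintf("divergence=%g", divergence),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Simulate paired-end reads from templates
#'
#' Fragments are drawn per pair: template index from `abundances`, fragment
#' start uniform, insert length normal (rounded, clamped into
#' `[read_len, template length]`).  Mate 1 is the fragment 5' end, mate 2 the
#' reverse complement of its 3' end.  Each base is substituted independently
#' with probability `error_rate`; all quality characters encode `qual`.
#' Read ids follow the `"<sample_tag>:<serial>"` convention carrying the
#' sample tag.
#'
#' @param templates Data frame (`id`, `sequence`) or named character vector.
#' @param abundances Relative abundances, one per template (normalized
#'   internally).
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (nt).
#' @param insert_mean,insert_sd Insert-size distribution (nt).
#' @param error_rate Per-base substitution probability.
#' @param qual Constant Phred quality assigned to every base.
#' @param seed Integer RNG seed.
#' @param sample_tag Sample tag carried in read ids.
#' @return List with `reads` (data frame as in [read_fastq_pair()]) and
#'   `truth` (per-pair provenance: `id`, `template`, `start`, `insert`).
#' @export
simulate_reads <- function(templates, abundances, n_pairs,
                           read_len = 150L, insert_mean = 300L,
                           insert_sd = 30L, error_rate = 0, qual = 40L,
                           seed = 1L, sample_tag = "S1") {
  tpl <- db_sequences(templates)
  if (length(abundances) != length(tpl))
    stop("abundances must match templates")
  if (read_len > min(nchar(tpl)))
    stop("read_len exceeds the shortest template")
  if (grepl(":", sample_tag, fixed = TRUE))
    stop("sample_tag must not contain ':'")
  p <- abundances / sum(abundances)
  with_seed(seed, {
    tidx <- sample.int(length(tpl), n_pairs, replace = TRUE, prob = p)
    L <- nchar(tpl)[tidx]
    ins <- pmin(L, pmax(read_len, as.integer(round(
      stats::rnorm(n_pairs, insert_mean, insert_sd)))))
    start <- as.integer(floor(stats::runif(n_pairs) * (L - ins + 1))) + 1L
    m1 <- substr(tpl[tidx], start, start + read_len - 1L)
    m2 <- revcomp(substr(tpl[tidx], start + ins - read_len, start + ins - 1L))
    if (error_rate > 0) {
      m1 <- inject_errors(m1, error_rate)
      m2 <- inject_errors(m2, error_rate)
    }
    ids <- sprintf("%s:%06d", sample_tag, seq_len(n_pairs))
    qv <- rep.int(as.integer(qual), read_len)
    quals <- rep(list(qv), n_pairs)
    reads <- data.frame(
      id = c(ids, ids), mate = rep(c(1L, 2L), each = n_pairs),
      sample_tag = sample_tag, bases = c(m1, m2),
      quals = I(c(quals, quals)), pair = c(seq_len(n_pairs), seq_len(n_pairs)),
      stringsAsFactors = FALSE)
    truth <- data.frame(id = ids, template = names(tpl)[tidx],
                        start = start, insert = ins,
                        sample_tag = sample_tag, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

inject_errors <- function(seqs, error_rate) {
  bases <- c("A", "C", "G", "T")
  nerr <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(s), nerr[i])
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a layered community design
#'
#' Emulates a sediment-core style design: `n_layers` depth layers, each with
#' `replicates` samples, over a shared template set.  Each template follows a
#' monotone log-linear abundance trend across layers (`"up"`, `"down"` or
#' `"flat"`, spanning a factor `fold` from first to last layer); per-layer
#' vectors are normalized to sum 1.  Paired-end reads are simulated per
#' sample with seeds derived from the single top-level `seed`.  The truth
#' surface includes the per-sample template abundances, an environmental
#' table (depth plus two depth-covarying factors) and a star phylogeny over
#' the templates with branch lengths equal to the simulated divergence.
#'
#' @param n_templates,template_length,divergence Template set parameters,
#'   passed to [simulate_templates()].
#' @param n_layers Number of depth layers.
#' @param replicates Samples per layer.
#' @param trend Character vector of per-template trends (recycled), each one
#'   of `"up"`, `"down"`, `"flat"`.
#' @param fold Abundance fold change from first to last layer for monotone
#'   trends.
#' @param n_pairs Read pairs per sample.
#' @param read_len,insert_mean,insert_sd,error_rate,qual Read-simulation
#'   parameters, see [simulate_reads()].
#' @param seed Integer master seed; all per-sample seeds derive from it.
#' @return List with `templates`, `abundance` (truth matrix, samples x
#'   templates), `design` (sample, layer, replicate, depth), `reads`
#'   (combined read data frame), `truth`, `env` (environmental table) and
#'   `tree` (star phylogeny over templates).
#' @export
simulate_layered_design <- function(n_templates = 5L, n_layers = 4L,
                                    replicates = 1L,
                                    trend = c("up", "down", "flat"),
                                    fold = 10, template_length = 1000L,
                                    divergence = 0.1, n_pairs = 1000L,
                                    read_len = 150L, insert_mean = 300L,
                                    insert_sd = 30L, error_rate = 0,
                                    qual = 40L, seed = 1L) {
  if (!all(trend %in% c("up", "down", "flat")))
    stop("trend entries must be 'up', 'down' or 'flat'")
  trend <- rep_len(trend, n_templates)
  templates <- simulate_templates(n_templates, template_length, divergence,
                                  seed = derive_seed(seed, 0L))
  grad <- if (n_layers > 1L) (seq_len(n_layers) - 1L) / (n_layers - 1L) else 0
  w <- sapply(seq_len(n_templates), function(t) switch(trend[t],
    up = fold^grad, down = fold^rev(grad), flat = rep(1, n_layers)))
  w <- matrix(w, nrow = n_layers)
  layer_ab <- w / rowSums(w)
  colnames(layer_ab) <- templates$id

  samples <- expand.grid(replicate = seq_len(replicates),
                         layer = seq_len(n_layers))[, 2:1]
  samples$sample <- sprintf("L%d_R%d", samples$layer, samples$replicate)
  depth_step <- 6
  samples$depth_cm <- (samples$layer - 0.5) * depth_step

  reads <- vector("list", nrow(samples))
  truth <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sim <- simulate_reads(templates, layer_ab[samples$layer[i], ], n_pairs,
                          read_len, insert_mean, insert_sd, error_rate, qual,
                          seed = derive_seed(seed, i),
                          sample_tag = samples$sample[i])
    reads[[i]] <- sim$reads
    truth[[i]] <- sim$truth
  }
  ab <- layer_ab[samples$layer, , drop = FALSE]
  rownames(ab) <- samples$sample

  env <- with_seed(derive_seed(seed, 999L), data.frame(
    sample = samples$sample,
    depth_cm = samples$depth_cm,
    methane_uM = 5 * exp(samples$depth_cm / 8) *
      exp(stats::rnorm(nrow(samples), 0, 0.05)),
    sulfate_mM = pmax(0.5, 28 - samples$depth_cm +
      stats::rnorm(nrow(samples), 0, 0.5)),
    stringsAsFactors = FALSE))

  tree <- parse_newick(paste0("(", paste(sprintf("%s:%g", templates$id,
                                                 divergence),
                                         collapse = ","), ");"))
  list(templates = templates, abundance = ab,
       design = samples[, c("sample", "layer", "replicate", "depth_cm")],
       reads = do.call(rbind, reads), truth = do.call(rbind, truth),
       env = env, tree = tree)
}

#' Write a simulated layered design to disk
#'
#' Materializes the fixture for the pipeline: per-sample FASTQ pairs (gzip),
#' the template FASTA, the truth and design TSVs, the environmental table,
#' the template star tree (newick) and a reads manifest
#' (`sample`, `r1`, `r2`).
#'
#' @param sim Result of [simulate_layered_design()].
#' @param dir Output directory (created if missing).
#' @return Path of the reads manifest, invisibly.
#' @export
write_sim_design <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$templates, file.path(dir, "templates.fasta"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$env, file.path(dir, "env.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_abundance_tsv(sim$abundance, file.path(dir, "abundance_truth.tsv"))
  ape::write.tree(sim$tree, file.path(dir, "templates.nwk"))
  man <- data.frame(sample = character(0), r1 = character(0),
                    r2 = character(0))
  for (s in unique(sim$reads$sample_tag)) {
    r1 <- file.path(dir, paste0(s, "_R1.fastq.gz"))
    r2 <- file.path(dir, paste0(s, "_R2.fastq.gz"))
    sub <- sim$reads[sim$reads$sample_tag == s, ]
    write_fastq(sub[sub$mate == 1L, ], r1)
    write_fastq(sub[sub$mate == 2L, ], r2)
    man <- rbind(man, data.frame(sample = s, r1 = r1, r2 = r2))
  }
  man_path <- file.path(dir, "reads_manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man_path)
}
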