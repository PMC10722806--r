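#' Configuration for the EM reconstruction
#'
#' Bundles every tunable of [gscem()].  The defaults are the method's
#' standard settings: at most 40 iterations, a split when the fraction of
#' variant positions exceeds 0.04 (a position being a variant when its
#' second-largest base probability exceeds 0.1), a merge when two cluster
#' consensuses exceed 0.97 global identity, pruning below mean depth 3, and
#' Phred+33 qualities.  Both split and merge thresholds are strict
#' inequalities.
#'
#' @param max_iters Maximum number of EM iterations (`-n`).
#' @param threads Thread count (`-a`); only 1 is used, kept for interface
#'   compatibility.
#' @param snp_fraction Variant-position fraction above which a cluster is
#'   split (`-p`).
#' @param variant_fraction Second-base probability above which a position
#'   counts as a variant (`-v`).
#' @param join_identity Consensus identity above which two clusters are
#'   merged (`-j`).
#' @param min_depth Mean posterior-weighted depth below which a cluster is
#'   pruned (`-c`); 0 disables pruning.
#' @param phred_offset Phred encoding offset of the input reads (33 or 64).
#' @param seed Optional integer seed recorded in the fit (the EM itself is
#'   deterministic).
#' @param max_error_rate Maximum edit distance per read length for an
#'   alignment to be retained during read recruitment.
#' @param alpha Pseudocount added to every base count in the M step.
#' @param gap_factor Fixed per-column likelihood factor for inserted or
#'   deleted alignment columns.
#' @param init_prob Probability placed on the reference base when a cluster's
#'   base-probability matrix is initialized (the remainder is spread over the
#'   other three bases).
#' @param seed_k k-mer size used to seed candidate read-to-cluster
#'   alignments.
#' @param band Half-width of the banded semi-global alignment around the
#'   seeded diagonal.
#' @return A list of class `gscem_config`.
#' @export
gscem_config <- function(max_iters = 40L, threads = 1L, snp_fraction = 0.04,
                         variant_fraction = 0.1, join_identity = 0.97,
                         min_depth = 3, phred_offset = 33L, seed = NULL,
                         max_error_rate = 0.15, alpha = 0.1,
                         gap_factor = 1e-3, init_prob = 0.97,
                         seed_k = 15L, band = 15L) {
  cfg <- list(max_iters = as.integer(max_iters), threads = as.integer(threads),
              snp_fraction = snp_fraction,
              variant_fraction = variant_fraction,
              join_identity = join_identity, min_depth = min_depth,
              phred_offset = as.integer(phred_offset), seed = seed,
              max_error_rate = max_error_rate, alpha = alpha,
              gap_factor = gap_factor, init_prob = init_prob,
              seed_k = as.integer(seed_k), band = as.integer(band))
  if (cfg$max_iters < 1L) stop("max_iters must be >= 1")
  for (f in c("snp_fraction", "variant_fraction", "join_identity"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop(f, " must lie in (0, 1)")
  if (cfg$min_depth < 0) stop("min_depth must be >= 0")
  if (!cfg$phred_offset %in% c(33L, 64L)) stop("phred_offset must be 33 or 64")
  class(cfg) <- "gscem_config"
  cfg
}

# construct one gene sequence cluster
gsc_new <- function(id, consensus, probs = NULL, prior = 1,
                    origin = "db", source_id = id, init_prob = 0.97,
                    fresh = FALSE) {
  L <- nchar(consensus)
  if (is.null(probs)) {
    idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(idx)) stop("consensus must be ambiguity-free: ", id)
    probs <- matrix((1 - init_prob) / 3, nrow = L, ncol = 4)
    probs[cbind(seq_len(L), idx)] <- init_prob
  }
  list(id = id, consensus = consensus, probs = probs, prior = prior,
       origin = origin, source_id = source_id, fresh = fresh)
}

consensus_from_probs <- function(probs) {
  # argmax per row; ties broken alphabetically (A < C < G < T)
  paste(c("A", "C", "G", "T")[max.col(probs, ties.method = "first")],
        collapse = "")
}

#' Map reads against the current cluster consensuses
#'
#' For every (read, cluster) pair sharing at least one canonical
#' `seed_k`-mer, computes the best banded semi-global alignment (the read
#' fully consumed, reference ends free; match +1, mismatch -1, gap -2) on
#' both strands, normalized into reference orientation.  All alignments with
#' edit distance at most `max_error_rate` times the read length are
#' retained, so multi-mapping reads keep every qualifying candidate.
#'
#' @param reads Read data frame ([read_fastq_pair()] layout).
#' @param gscs List of cluster objects, or a named character vector of
#'   reference sequences.
#' @param config A [gscem_config()].
#' @return Data frame with columns `read` (row index into `reads`), `gsc`
#'   (cluster index), `gsc_id`, `strand`, `ref_start` (0-based), `cigar`
#'   (extended `=XID` alphabet), `nm`, `score`, `alen`.
#' @export
map_reads <- function(reads, gscs, config = gscem_config()) {
  if (!is.list(gscs[[1]])) {
    ids <- names(gscs)
    gscs <- lapply(seq_along(gscs), function(i)
      gsc_new(ids[i], unname(gscs[i]), init_prob = config$init_prob))
  }
  if (!length(gscs)) stop("no clusters to map against")
  cons <- vapply(gscs, `[[`, character(1), "consensus")
  aln <- cpp_map_reads(cpp_encode(reads$bases), cpp_encode(cons),
                       config$seed_k, config$band, config$max_error_rate)
  aln <- as.data.frame(aln, stringsAsFactors = FALSE)
  aln$gsc_id <- vapply(gscs, `[[`, character(1), "id")[aln$gsc]
  aln
}

#' Likelihood of one read given one cluster
#'
#' Reference-quality scalar implementation of the read model used by the EM:
#' over aligned columns the probability is
#' `sum_x probs[t, x] * M(obs | x, q)` with `M = 1 - eps` on agreement and
#' `eps / 3` otherwise, `eps = 10^(-q/10)`; every inserted or deleted column
#' contributes the fixed factor `gap_factor`.  The batch C++ path used inside
#' [gscem()] implements the same model; the two are cross-checked in the
#' test-suite.
#'
#' @param bases Read bases as stored (original orientation).
#' @param quals Integer Phred qualities.
#' @param gsc A cluster object (needs `probs`).
#' @param aln One row of a [map_reads()] data frame for this read/cluster.
#' @param gap_factor Per-gap-column likelihood factor.
#' @return The likelihood, a probability in (0, 1].
#' @export
read_likelihood <- function(bases, quals, gsc, aln, gap_factor = 1e-3) {
  if (aln$strand == "-") {
    bases <- revcomp(bases)
    quals <- rev(quals)
  }
  b <- strsplit(bases, "")[[1]]
  ops <- cigar_ops(aln$cigar)
  rpos <- 1L; tpos <- aln$ref_start + 1L
  ll <- 0
  for (j in seq_along(ops$op)) {
    op <- ops$op[j]; len <- ops$len[j]
    if (op %in% c("M", "=", "X")) {
      for (t in seq_len(len)) {
        obs <- match(b[rpos], c("A", "C", "G", "T"))
        if (!is.na(obs)) {
          eps <- min(10^(-quals[rpos] / 10), 0.75)
          m <- rep(eps / 3, 4); m[obs] <- 1 - eps
          ll <- ll + log(sum(gsc$probs[tpos, ] * m))
        }
        rpos <- rpos + 1L; tpos <- tpos + 1L
      }
    } else if (op == "I") {
      ll <- ll + len * log(gap_factor); rpos <- rpos + len
    } else if (op == "D") {
      ll <- ll + len * log(gap_factor); tpos <- tpos + len
    } else stop("unsupported CIGAR op: ", op)
  }
  exp(ll)
}

# ---------------------------------------------------------------------------
# read units: a pair is one unit over the clusters where BOTH mates align
# (mate likelihoods multiplied); pairs without any shared cluster, and
# unpaired reads, contribute each aligned mate as its own unit.

build_units <- function(aln, reads, n_gscs) {
  if (!nrow(aln)) {
    return(list(keep = logical(0), eidx = integer(0), uvec = numeric(0),
                gvec = integer(0), n_units = 0L))
  }
  pid <- if (!is.null(reads$pair)) reads$pair[aln$read] else rep(NA_real_, nrow(aln))
  mate <- if (!is.null(reads$mate)) reads$mate[aln$read] else rep(1L, nrow(aln))
  key <- (as.numeric(pid) - 1) * n_gscs + aln$gsc
  k1 <- unique(key[mate == 1L & !is.na(key)])
  k2 <- unique(key[mate == 2L & !is.na(key)])
  shared_keys <- intersect(k1, k2)
  is_both <- !is.na(key) & key %in% shared_keys
  pair_shared <- unique(pid[is_both])
  in_shared_pair <- !is.na(pid) & pid %in% pair_shared
  keep <- !in_shared_pair | is_both
  # entry and unit keys: positive for pair entries, negative for lone mates
  ekey <- ifelse(in_shared_pair & is_both, key,
                 -((as.numeric(aln$read) - 1) * n_gscs + aln$gsc))
  ukey <- ifelse(in_shared_pair & is_both, as.numeric(pid),
                 -as.numeric(aln$read))
  ekey <- ekey[keep]; ukey <- ukey[keep]
  eu <- unique(ekey)
  eidx <- match(ekey, eu)
  first <- match(eu, ekey)
  uvec <- ukey[first]
  gvec <- aln$gsc[keep][first]
  list(keep = keep, eidx = eidx, uvec = uvec, gvec = gvec,
       n_units = length(unique(uvec)),
       unit_of_entry = match(uvec, unique(uvec)))
}

#' Posterior read-unit assignment (E step)
#'
#' Computes `z(u, i) = pi_i P(u|i) / sum_k pi_k P(u|k)` over the clusters a
#' unit maps to, in log space.  Units whose total mass underflows to zero
#' are excluded.
#'
#' @param loglik Log-likelihood per (unit, cluster) entry.
#' @param unit Integer unit index per entry.
#' @param gsc Integer cluster index per entry.
#' @param pi Mixing priors (summing to 1).
#' @return List with `z` (posterior per entry), `unit_loglik` (observed-data
#'   log-likelihood contribution per unit) and `loglik` (their sum).
#' @export
e_step <- function(loglik, unit, gsc, pi) {
  if (abs(sum(pi) - 1) > 1e-6) stop("priors must sum to 1")
  lp <- log(pi)[gsc] + loglik
  idx <- split(seq_along(lp), unit)
  z <- numeric(length(lp))
  ull <- numeric(length(idx))
  for (j in seq_along(idx)) {
    ix <- idx[[j]]
    m <- max(lp[ix])
    if (!is.finite(m)) { z[ix] <- 0; ull[j] <- NA_real_; next }
    e <- exp(lp[ix] - m)
    s <- sum(e)
    z[ix] <- e / s
    ull[j] <- m + log(s)
  }
  list(z = z, unit_loglik = ull, loglik = sum(ull, na.rm = TRUE))
}

#' Re-estimate priors, base probabilities and consensuses (M step)
#'
#' Priors become the mean posterior mass per assigned unit.  Base
#' probabilities are posterior-weighted, quality-damped base counts with
#' pseudocount `alpha`; positions whose posterior-weighted depth falls below
#' 1 keep their previous row.  Consensuses are re-derived by per-row argmax
#' with alphabetic tie-breaking.
#'
#' @param reads Read data frame.
#' @param alignments Alignment data frame from [map_reads()].
#' @param weights Posterior weight per alignment row (its unit's `z` for the
#'   aligned cluster; 0 for rows excluded from units).
#' @param unit_z Data frame with columns `gsc` and `z`, one row per
#'   (unit, cluster) entry, used for the prior update.
#' @param gscs Current cluster list.
#' @param config A [gscem_config()].
#' @return The updated cluster list, with per-cluster posterior depth in
#'   attribute `"depth"`.
#' @export
m_step <- function(reads, alignments, weights, unit_z, gscs,
                   config = gscem_config()) {
  K <- length(gscs)
  n_units <- sum(unit_z$z)
  mass <- vapply(seq_len(K), function(i) sum(unit_z$z[unit_z$gsc == i]),
                 numeric(1))
  pi_new <- if (n_units > 0) mass / sum(mass) else rep(1 / K, K)
  res <- cpp_mstep(cpp_encode(reads$bases), reads$quals,
                   alignments$read, alignments$gsc, alignments$strand,
                   alignments$ref_start, alignments$cigar, weights,
                   lapply(gscs, `[[`, "probs"),
                   alpha = config$alpha, depth_keep = 1.0)
  for (i in seq_len(K)) {
    gscs[[i]]$probs <- res$probs[[i]]
    gscs[[i]]$consensus <- consensus_from_probs(res$probs[[i]])
    gscs[[i]]$prior <- pi_new[i]
  }
  attr(gscs, "depth") <- res$depth
  gscs
}

#' Split clusters carrying an excess of variant positions
#'
#' A position is a variant when its second-largest base probability exceeds
#' `variant_fraction`; when the fraction of variant positions in a cluster
#' exceeds `snp_fraction` (strictly), one new cluster is split out carrying
#' the minor allele at every variant position — the strongest composite
#' variant haplotype.  When read-level `evidence` is supplied the minor
#' haplotype is phased by linkage: reads carrying the minor allele at the
#' strongest variant position (the anchor) vote, by posterior weight, for
#' the base at every other variant position, which avoids chimeric
#' major/minor mosaics in balanced mixtures.  Without evidence the
#' second-most-probable base is substituted position by position.  The new
#' prior is the parent prior times the mean minor-base probability over
#' variant positions; the parent prior is reduced by the same amount.  At
#' most one split per cluster per iteration.
#'
#' @param gscs Cluster list.
#' @param config A [gscem_config()].
#' @param evidence Optional read-linkage evidence: a list with `reads_enc`
#'   (encoded reads), `aln` (current alignment table) and `w` (posterior
#'   weight per alignment row), as assembled inside [gscem()].
#' @return List with `gscs` (possibly extended) and `n_splits`.
#' @export
split_gscs <- function(gscs, config = gscem_config(), evidence = NULL) {
  v <- config$variant_fraction; p <- config$snp_fraction
  next_id <- max(c(0L, suppressWarnings(as.integer(
    sub("^GSC_", "", grep("^GSC_[0-9]+$",
                          vapply(gscs, `[[`, character(1), "id"),
                          value = TRUE)))))) + 1L
  new_gscs <- list()
  for (i in seq_along(gscs)) {
    pr <- gscs[[i]]$probs
    o1 <- max.col(pr, ties.method = "first")
    L <- nrow(pr)
    tmp <- pr
    tmp[cbind(seq_len(L), o1)] <- -Inf
    o2 <- max.col(tmp, ties.method = "first")
    second <- pr[cbind(seq_len(L), o2)]
    variant <- second > v
    if (sum(variant) / L > p) {
      vi <- which(variant)
      minor <- o2
      if (!is.null(evidence)) {
        # phase the minor haplotype by read linkage, anchored at the
        # strongest variant position
        anchor_idx <- which.max(second[vi])
        rows <- which(evidence$aln$gsc == i & evidence$w > 0)
        if (length(rows)) {
          phased <- cpp_phase_minor(
            evidence$reads_enc, evidence$aln$read[rows],
            evidence$aln$strand[rows], evidence$aln$ref_start[rows],
            evidence$aln$cigar[rows], evidence$w[rows],
            vi - 1L, o1[vi] - 1L, o2[vi] - 1L, anchor_idx - 1L, L) + 1L
          minor[vi] <- phased
        }
      }
      cons <- strsplit(gscs[[i]]$consensus, "")[[1]]
      cons[vi] <- c("A", "C", "G", "T")[minor[vi]]
      child_probs <- pr
      # concentrate the child on its phased haplotype at variant positions
      child_probs[vi, ] <- (1 - config$init_prob) / 3
      child_probs[cbind(vi, minor[vi])] <- config$init_prob
      take <- gscs[[i]]$prior * mean(second[variant])
      child <- gsc_new(sprintf("GSC_%d", next_id),
                       paste(cons, collapse = ""), probs = child_probs,
                       prior = take, origin = "split",
                       source_id = gscs[[i]]$id, fresh = TRUE)
      next_id <- next_id + 1L
      gscs[[i]]$prior <- gscs[[i]]$prior - take
      new_gscs <- c(new_gscs, list(child))
    }
  }
  list(gscs = c(gscs, new_gscs), n_splits = length(new_gscs))
}

#' Merge clusters whose consensuses exceed the join identity
#'
#' Cluster pairs are scanned in descending-prior order; whenever the global
#' alignment identity of two consensuses exceeds `join_identity` (strictly),
#' they are merged: the survivor is the higher-prior cluster (ties to the
#' lexicographically smaller id), its prior becomes the sum, and its base
#' probabilities become the prior-weighted average over aligned columns.
#' Scanning repeats until no pair exceeds the threshold.
#'
#' @param gscs Cluster list.
#' @param config A [gscem_config()].
#' @return List with `gscs` and `n_merges`.
#' @export
merge_gscs <- function(gscs, config = gscem_config()) {
  j_thr <- config$join_identity
  n_merges <- 0L
  repeat {
    K <- length(gscs)
    if (K < 2L) break
    pi <- vapply(gscs, `[[`, numeric(1), "prior")
    ids <- vapply(gscs, `[[`, character(1), "id")
    ord <- order(-pi, ids, method = "radix")
    merged <- FALSE
    for (a in seq_len(K - 1L)) {
      for (b in (a + 1L):K) {
        ia <- ord[a]; ib <- ord[b]
        # a freshly split child is exempt until its parent's consensus has
        # been re-estimated once; otherwise it would be folded straight back
        # into the still-mixed parent
        if (isTRUE(gscs[[ia]]$fresh) || isTRUE(gscs[[ib]]$fresh)) next
        aln <- cpp_nw_align(cpp_encode(gscs[[ia]]$consensus)[[1]],
                            cpp_encode(gscs[[ib]]$consensus)[[1]])
        if (aln$identity > j_thr) {
          # survivor = higher prior; ord already ranks by (-prior, id)
          surv <- ia; gone <- ib
          wa <- gscs[[surv]]$prior; wb <- gscs[[gone]]$prior
          if (wa + wb > 0) {
            acol <- aln$acol + 1L; bcol <- aln$bcol + 1L
            both <- aln$acol >= 0L & aln$bcol >= 0L
            pr <- gscs[[surv]]$probs
            pr[acol[both], ] <- (wa * pr[acol[both], , drop = FALSE] +
              wb * gscs[[gone]]$probs[bcol[both], , drop = FALSE]) / (wa + wb)
            gscs[[surv]]$probs <- pr
            gscs[[surv]]$consensus <- consensus_from_probs(pr)
          }
          gscs[[surv]]$prior <- wa + wb
          gscs[[gone]] <- NULL
          n_merges <- n_merges + 1L
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  list(gscs = gscs, n_merges = n_merges)
}

#' Prune clusters below the minimum mean depth
#'
#' Removes clusters whose mean posterior-weighted depth (assigned read bases
#' per consensus position) falls below `min_depth`, then renormalizes the
#' priors.  `min_depth = 0` disables pruning.  Clusters freshly created by a
#' split in the same iteration are exempt until they have been mapped once.
#'
#' @param gscs Cluster list.
#' @param mean_depth Numeric vector of mean posterior-weighted depth per
#'   cluster.
#' @param config A [gscem_config()].
#' @return List with `gscs` and `n_pruned`.
#' @export
prune_gscs <- function(gscs, mean_depth, config = gscem_config()) {
  if (config$min_depth <= 0)
    return(list(gscs = gscs, n_pruned = 0L))
  fresh <- vapply(gscs, function(g) isTRUE(g$fresh), logical(1))
  drop <- mean_depth < config$min_depth & !fresh
  if (all(drop))
    stop("all clusters pruned at min_depth = ", config$min_depth,
         " (max mean depth ", signif(max(mean_depth), 3),
         "); no cluster is supported by the reads")
  gscs <- gscs[!drop]
  pi <- vapply(gscs, `[[`, numeric(1), "prior")
  for (i in seq_along(gscs)) gscs[[i]]$prior <- pi[i] / sum(pi)
  list(gscs = gscs, n_pruned = sum(drop))
}

# ---------------------------------------------------------------------------

#' Reconstruct gene sequence clusters from reads by EM
#'
#' The central fitting function.  Starting from one cluster per reference
#' representative (uniform priors, base probabilities concentrated on the
#' reference base), it iterates: map reads to the current consensuses,
#' E step (posterior read-unit assignment), M step (priors, base
#' probabilities, consensuses), variant-driven splitting, identity-driven
#' merging, and depth-based pruning, for at most `config$max_iters`
#' iterations, stopping early once an iteration changes no consensus base,
#' performs no split/merge/prune, and moves no prior by more than 1e-8.
#' The procedure is deterministic for given reads and references.
#'
#' @param reads A read data frame from [read_fastq_pair()], or a list/vector
#'   of length 2 with mate-1 and mate-2 FASTQ paths.
#' @param db A `starting_db` from [build_reference_db()], a named character
#'   vector of reference sequences (used as representatives as-is), or a
#'   FASTA path (clustered with default settings first).
#' @param config A [gscem_config()].
#' @param verbose Print one line per iteration.
#' @return An object of class `gscem`; see [summary.gscem()].  Key parts:
#'   `gscs` (data frame: id, length, prior, norm_prior, origin, source_id,
#'   consensus), `alignments` (final-iteration alignments with posterior
#'   weights and primary flags), `history` (per-iteration log: clusters,
#'   splits, merges, prunes, log-likelihood), `logLik`.
#' @examples
#' tpl <- simulate_templates(2, 400, divergence = 0.12, seed = 7)
#' sim <- simulate_reads(tpl, c(0.7, 0.3), 300, read_len = 100, seed = 7)
#' db <- build_reference_db(tpl, min_length = 100)
#' fit <- gscem(sim$reads, db)
#' fit
#' coef(fit)
#' @export
gscem <- function(reads, db, config = gscem_config(), verbose = FALSE) {
  if (!is.data.frame(reads)) {
    if (length(reads) != 2L)
      stop("reads must be a read data frame or two FASTQ paths")
    reads <- read_fastq_pair(reads[[1]], reads[[2]],
                             phred_offset = config$phred_offset)
  }
  if (!nrow(reads)) stop("no reads")
  if (is.character(db) && length(db) == 1L && file.exists(db))
    db <- build_reference_db(db)
  refs <- db_sequences(db)
  if (!length(refs)) stop("empty reference database")
  if (is.null(names(refs))) stop("reference sequences must be named")
  refs[] <- resolve_ambiguity(refs)
  gscs <- lapply(seq_along(refs), function(i)
    gsc_new(sprintf("GSC_%d", i), unname(refs[i]),
            prior = 1 / length(refs), origin = "db",
            source_id = names(refs)[i], init_prob = config$init_prob))

  enc_reads <- cpp_encode(reads$bases)
  aln_cache <- new.env(parent = emptyenv())
  map_all <- function(gscs) {
    cons <- vapply(gscs, `[[`, character(1), "consensus")
    out <- vector("list", length(gscs))
    todo <- which(!vapply(cons, exists, logical(1), envir = aln_cache))
    if (length(todo)) {
      fresh <- cpp_map_reads(enc_reads, cpp_encode(cons[todo]),
                             config$seed_k, config$band,
                             config$max_error_rate)
      fresh <- as.data.frame(fresh, stringsAsFactors = FALSE)
      for (j in seq_along(todo)) {
        sub <- fresh[fresh$gsc == j, , drop = FALSE]
        sub$gsc <- NULL
        assign(cons[todo[j]], sub, envir = aln_cache)
      }
    }
    for (i in seq_along(gscs)) {
      sub <- get(cons[i], envir = aln_cache)
      if (nrow(sub)) sub$gsc <- i
      else sub$gsc <- integer(0)
      out[[i]] <- sub
    }
    aln <- do.call(rbind, out)
    rownames(aln) <- NULL
    aln$gsc_id <- vapply(gscs, `[[`, character(1), "id")[aln$gsc]
    aln[order(aln$read, aln$gsc), , drop = FALSE]
  }

  history <- data.frame()
  pi_prev <- vapply(gscs, `[[`, numeric(1), "prior")
  aln <- NULL; units <- NULL; est <- NULL; stale <- TRUE

  for (iter in seq_len(config$max_iters)) {
    aln <- map_all(gscs)
    units <- build_units(aln, reads, length(gscs))
    ll <- cpp_loglik(enc_reads, reads$quals, aln$read[units$keep],
                     aln$gsc[units$keep], aln$strand[units$keep],
                     aln$ref_start[units$keep], aln$cigar[units$keep],
                     lapply(gscs, `[[`, "probs"),
                     gap_factor = config$gap_factor)
    entry_ll <- as.vector(rowsum(ll, units$eidx))
    pi <- vapply(gscs, `[[`, numeric(1), "prior")
    est <- e_step(entry_ll, units$unit_of_entry, units$gvec, pi)
    w <- numeric(nrow(aln))
    w[units$keep] <- est$z[units$eidx]
    unit_z <- data.frame(gsc = units$gvec, z = est$z)
    cons_before <- vapply(gscs, `[[`, character(1), "consensus")
    gscs <- m_step(reads, aln, w, unit_z, gscs, config)
    mean_depth <- vapply(seq_along(gscs), function(i) {
      rows <- aln$gsc == i
      sum(w[rows] * aln$alen[rows]) / nrow(gscs[[i]]$probs)
    }, numeric(1))
    cons_changed <- any(vapply(gscs, `[[`, character(1), "consensus")
                        != cons_before)
    sp <- split_gscs(gscs, config,
                     evidence = list(reads_enc = enc_reads, aln = aln, w = w))
    mean_depth <- c(mean_depth, rep(Inf, sp$n_splits))
    mg <- merge_gscs(sp$gscs, config)
    keep_idx <- match(vapply(mg$gscs, `[[`, character(1), "id"),
                      vapply(sp$gscs, `[[`, character(1), "id"))
    mean_depth <- mean_depth[keep_idx]
    pr <- prune_gscs(mg$gscs, mean_depth, config)
    gscs <- pr$gscs
    # renormalize priors after structural edits
    pi_now <- vapply(gscs, `[[`, numeric(1), "prior")
    for (i in seq_along(gscs)) {
      gscs[[i]]$prior <- pi_now[i] / sum(pi_now)
      gscs[[i]]$fresh <- FALSE
    }
    pi_now <- pi_now / sum(pi_now)
    structural <- sp$n_splits + mg$n_merges + pr$n_pruned > 0L
    pi_delta <- if (length(pi_now) == length(pi_prev))
      max(abs(pi_now - pi_prev)) else Inf
    history <- rbind(history, data.frame(
      iteration = iter, n_gscs = length(gscs), n_splits = sp$n_splits,
      n_merges = mg$n_merges, n_pruned = pr$n_pruned,
      loglik = est$loglik, pi_delta = pi_delta))
    if (verbose)
      message(sprintf(
        "iter %d: %d GSCs, %d splits, %d merges, %d pruned, logL %.3f",
        iter, length(gscs), sp$n_splits, mg$n_merges, pr$n_pruned,
        est$loglik))
    pi_prev <- pi_now
    stale <- structural || cons_changed
    if (!structural && !cons_changed && pi_delta < 1e-8) break
  }

  if (stale) {
    # final mapping and posteriors against the converged cluster set
    aln <- map_all(gscs)
    units <- build_units(aln, reads, length(gscs))
    ll <- cpp_loglik(enc_reads, reads$quals, aln$read[units$keep],
                     aln$gsc[units$keep], aln$strand[units$keep],
                     aln$ref_start[units$keep], aln$cigar[units$keep],
                     lapply(gscs, `[[`, "probs"),
                     gap_factor = config$gap_factor)
    entry_ll <- as.vector(rowsum(ll, units$eidx))
    est <- e_step(entry_ll, units$unit_of_entry, units$gvec,
                  vapply(gscs, `[[`, numeric(1), "prior"))
  }
  w <- numeric(nrow(aln))
  w[units$keep] <- est$z[units$eidx]

  ids <- vapply(gscs, `[[`, character(1), "id")
  lens <- vapply(gscs, function(g) nchar(g$consensus), integer(1))
  pi <- vapply(gscs, `[[`, numeric(1), "prior")
  norm <- (pi / lens) / sum(pi / lens)
  gsc_df <- data.frame(
    id = ids, length = lens, prior = pi, norm_prior = norm,
    origin = vapply(gscs, `[[`, character(1), "origin"),
    source_id = vapply(gscs, `[[`, character(1), "source_id"),
    consensus = vapply(gscs, `[[`, character(1), "consensus"),
    stringsAsFactors = FALSE)

  aln_out <- aln
  aln_out$posterior <- w
  aln_out$read_id <- reads$id[aln$read]
  aln_out$sample_tag <- reads$sample_tag[aln$read]
  aln_out$mate <- if (!is.null(reads$mate)) reads$mate[aln$read] else 1L
  # primary flag: per read, the max-posterior alignment
  # (ties to the lexicographically smaller cluster id)
  ord <- order(aln_out$read, -aln_out$posterior, aln_out$gsc_id,
               method = "radix")
  primary <- logical(nrow(aln_out))
  primary[ord[!duplicated(aln_out$read[ord])]] <- TRUE
  aln_out$primary <- primary

  fit <- structure(list(
    gscs = gsc_df, probs = lapply(gscs, `[[`, "probs"),
    alignments = aln_out, history = history, logLik = est$loglik,
    n_units = units$n_units, config = config,
    reads_per_sample = table(reads$sample_tag),
    n_reads = nrow(reads),
    read_info = reads[, intersect(c("id", "mate", "sample_tag", "bases",
                                    "quals"), names(reads))]),
    class = "gscem")
  fit
}
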