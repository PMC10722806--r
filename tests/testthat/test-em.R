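degenerate_gsc <- function(seq, id = "GSC_1", prior = 1) {
  g <- gscem:::gsc_new(id, seq, prior = prior, init_prob = 1)
  g$probs[g$probs < 1] <- 0          # probability 1 on the consensus base
  g
}

test_that("the read likelihood matches its closed forms", {
  g <- degenerate_gsc("AC")
  aln <- data.frame(strand = "+", ref_start = 0L, cigar = "2=",
                    stringsAsFactors = FALSE)
  # perfect 2-bp read at q30: (1 - 1e-3)^2
  expect_equal(read_likelihood("AC", c(30L, 30L), g, aln), 0.999^2,
               tolerance = 1e-12)
  # one mismatch: 0.999 * (0.001 / 3)
  aln$cigar <- "1=1X"
  expect_equal(read_likelihood("AT", c(30L, 30L), g, aln),
               0.999 * (0.001 / 3), tolerance = 1e-12)
  # uniform rows: 0.25^L regardless of the read
  gu <- g; gu$probs[] <- 0.25
  aln$cigar <- "2="
  expect_equal(read_likelihood("GG", c(30L, 30L), gu, aln), 0.25^2,
               tolerance = 1e-12)
  # each gap column contributes the fixed factor
  aln$cigar <- "1=1D1="
  g3 <- degenerate_gsc("AGC")
  expect_equal(read_likelihood("AC", c(30L, 30L), g3, aln),
               0.999^2 * 1e-3, tolerance = 1e-12)
})

test_that("the scalar R likelihood and the batch C++ path agree", {
  set.seed(41)
  tpl <- simulate_templates(2, 300, divergence = 0.1, seed = 41)
  sim <- simulate_reads(tpl, c(0.6, 0.4), 40, read_len = 80,
                        error_rate = 0.01, seed = 42)
  gscs <- lapply(seq_len(2), function(i)
    gscem:::gsc_new(sprintf("GSC_%d", i), tpl$sequence[i], prior = 0.5))
  aln <- map_reads(sim$reads, gscs, gscem_config())
  ll_cpp <- gscem:::cpp_loglik(gscem:::cpp_encode(sim$reads$bases),
                               sim$reads$quals, aln$read, aln$gsc,
                               aln$strand, aln$ref_start, aln$cigar,
                               lapply(gscs, `[[`, "probs"))
  for (r in sample(nrow(aln), 10)) {
    ll_r <- read_likelihood(sim$reads$bases[aln$read[r]],
                            sim$reads$quals[[aln$read[r]]],
                            gscs[[aln$gsc[r]]], aln[r, ])
    expect_equal(ll_cpp[r], log(ll_r), tolerance = 1e-9)
  }
})

test_that("posterior assignment follows priors and likelihoods", {
  # equal likelihoods, equal priors
  z <- e_step(c(-10, -10), c(1L, 1L), c(1L, 2L), c(0.5, 0.5))
  expect_equal(z$z, c(0.5, 0.5))
  # equal likelihoods, skewed priors
  z2 <- e_step(c(-10, -10), c(1L, 1L), c(1L, 2L), c(0.9, 0.1))
  expect_equal(z2$z, c(0.9, 0.1))
  # perfect 100-bp q30 match vs one mismatch, computed two independent ways
  l1 <- 100 * log(0.999)
  l2 <- 99 * log(0.999) + log(0.001 / 3)
  z3 <- e_step(c(l1, l2), c(1L, 1L), c(1L, 2L), c(0.5, 0.5))
  direct <- 0.999^100 / (0.999^100 + 0.999^99 * (0.001 / 3))
  expect_equal(z3$z[1], direct, tolerance = 1e-12)
  # observed-data log-likelihood accumulates over units
  expect_equal(z3$loglik, log(0.5 * exp(l1) + 0.5 * exp(l2)),
               tolerance = 1e-9)
})

test_that("the M step updates priors, base probabilities and consensus", {
  cfg <- gscem_config()
  g1 <- gscem:::gsc_new("GSC_1", "AA", prior = 0.5)
  g2 <- gscem:::gsc_new("GSC_2", "CC", prior = 0.5)
  reads <- make_reads(c("AA", "AA", "CC"), qual = 30L)
  aln <- data.frame(read = 1:3, gsc = c(1L, 1L, 2L), strand = "+",
                    ref_start = 0L, cigar = "2=", alen = 2L,
                    stringsAsFactors = FALSE)
  unit_z <- data.frame(gsc = c(1L, 1L, 2L), z = 1)
  out <- m_step(reads, aln, weights = c(1, 1, 1), unit_z,
                list(g1, g2), cfg)
  expect_equal(vapply(out, `[[`, numeric(1), "prior"), c(2 / 3, 1 / 3),
               tolerance = 1e-12)

  # a position covered only by q30 'G' reads with total weight 10 -> G
  g <- gscem:::gsc_new("GSC_1", "AT", prior = 1)
  readsG <- make_reads(rep("G", 10), qual = 30L)
  alnG <- data.frame(read = 1:10, gsc = 1L, strand = "+", ref_start = 0L,
                     cigar = "1=", alen = 1L, stringsAsFactors = FALSE)
  outG <- m_step(readsG, alnG, weights = rep(1, 10),
                 data.frame(gsc = rep(1L, 10), z = 1), list(g), cfg)
  expect_equal(substr(outG[[1]]$consensus, 1, 1), "G")
  # the uncovered position keeps its previous probability row
  expect_equal(outG[[1]]$probs[2, ], g$probs[2, ])
  expect_equal(substr(outG[[1]]$consensus, 2, 2), "T")
  # every row remains a probability distribution
  expect_equal(rowSums(outG[[1]]$probs), rep(1, 2), tolerance = 1e-9)
})

test_that("splitting requires the variant fraction strictly above threshold", {
  cfg <- gscem_config()      # p = 0.04, v = 0.1
  L <- 100
  make_probs <- function(n_var) {
    pr <- matrix(c(0.97, 0.01, 0.01, 0.01), L, 4, byrow = TRUE)
    if (n_var > 0)
      pr[seq_len(n_var), ] <- rep(c(0.8, 0.14, 0.03, 0.03), each = n_var)
    pr
  }
  base <- paste(rep("A", L), collapse = "")
  g <- gscem:::gsc_new("GSC_1", base, probs = make_probs(5), prior = 1)
  out <- split_gscs(list(g), cfg)
  expect_equal(out$n_splits, 1L)
  expect_equal(length(out$gscs), 2L)
  child <- out$gscs[[2]]
  # second-most-probable base substituted at every variant position
  expect_equal(substr(child$consensus, 1, 5), "CCCCC")
  expect_equal(substr(child$consensus, 6, 10), "AAAAA")
  expect_equal(child$origin, "split")
  expect_equal(child$source_id, "GSC_1")
  # prior mass conserved: child gets parent_pi * mean minor probability
  expect_equal(child$prior, 0.14, tolerance = 1e-12)
  expect_equal(out$gscs[[1]]$prior + child$prior, 1, tolerance = 1e-12)

  # exactly 4 variants in 100 positions (0.04, not > 0.04): no split
  g4 <- gscem:::gsc_new("GSC_1", base, probs = make_probs(4), prior = 1)
  expect_equal(split_gscs(list(g4), cfg)$n_splits, 0L)

  # second-largest probability 0.09 < 0.1 is not a variant position
  pr <- matrix(c(0.85, 0.09, 0.04, 0.02), L, 4, byrow = TRUE)
  g5 <- gscem:::gsc_new("GSC_1", base, probs = pr, prior = 1)
  expect_equal(split_gscs(list(g5), cfg)$n_splits, 0L)
})

test_that("merging requires identity strictly above the join threshold", {
  cfg <- gscem_config()      # j = 0.97
  set.seed(43)
  a <- random_seq(100)
  b <- mutate_seq(a, 3)      # identity exactly 0.97
  expect_equal(pairwise_identity(a, b), 0.97)
  g1 <- gscem:::gsc_new("GSC_1", a, prior = 0.6)
  g2 <- gscem:::gsc_new("GSC_2", b, prior = 0.4)
  expect_equal(merge_gscs(list(g1, g2), cfg)$n_merges, 0L)

  # identical consensuses merge and pool the priors
  g3 <- gscem:::gsc_new("GSC_3", a, prior = 0.3)
  g4 <- gscem:::gsc_new("GSC_4", a, prior = 0.2)
  m <- merge_gscs(list(g3, g4), cfg)
  expect_equal(m$n_merges, 1L)
  expect_equal(m$gscs[[1]]$prior, 0.5)
  expect_equal(m$gscs[[1]]$id, "GSC_3")   # higher prior survives

  # 300-nt pair with 6 mismatches: identity 0.98 > 0.97, verified by the
  # independent DP oracle, must merge
  set.seed(44)
  x <- random_seq(300)
  y <- mutate_seq(x, 6)
  expect_equal(bs_global(x, y)$identity, 0.98, tolerance = 1e-12)
  gm <- merge_gscs(list(gscem:::gsc_new("GSC_1", x, prior = 0.5),
                        gscem:::gsc_new("GSC_2", y, prior = 0.5)), cfg)
  expect_equal(gm$n_merges, 1L)
})

test_that("merging is order-independent when components are unambiguous", {
  set.seed(45)
  a <- random_seq(200)
  b <- mutate_seq(a, 2)          # 0.99 identity with a
  c3 <- mutate_seq(a, 80)        # far from both
  mk <- function(ids, seqs, pis)
    lapply(seq_along(ids), function(i)
      gscem:::gsc_new(ids[i], seqs[i], prior = pis[i]))
  cfg <- gscem_config()
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    gl <- mk(c("GSC_1", "GSC_2", "GSC_3")[perm],
             c(a, b, c3)[perm], c(0.5, 0.3, 0.2)[perm])
    out <- merge_gscs(gl, cfg)
    expect_equal(length(out$gscs), 2L)
    expect_equal(sum(vapply(out$gscs, `[[`, numeric(1), "prior")), 1)
  }
})

test_that("pruning removes unsupported clusters and renormalizes", {
  cfg <- gscem_config()      # c = 3
  g1 <- gscem:::gsc_new("GSC_1", "ACGT", prior = 0.7)
  g2 <- gscem:::gsc_new("GSC_2", "TTTT", prior = 0.3)
  out <- prune_gscs(list(g1, g2), mean_depth = c(10, 0), cfg)
  expect_equal(length(out$gscs), 1L)
  expect_equal(out$gscs[[1]]$id, "GSC_1")
  expect_equal(out$gscs[[1]]$prior, 1)
  # c = 0 disables pruning
  cfg0 <- gscem_config(min_depth = 0)
  expect_equal(length(prune_gscs(list(g1, g2), c(10, 0), cfg0)$gscs), 2L)
  expect_error(prune_gscs(list(g1, g2), c(0.1, 0.2), cfg), "pruned")
})

test_that("a single-template mixture collapses to one exact cluster", {
  tpl <- simulate_templates(1, 500, divergence = 0, seed = 46)
  sim <- simulate_reads(tpl, 1, 600, read_len = 120, seed = 47)
  fit <- gscem(sim$reads, stats::setNames(tpl$sequence, tpl$id))
  expect_equal(nrow(fit$gscs), 1L)
  expect_equal(fit$gscs$consensus, tpl$sequence)
  expect_equal(fit$gscs$prior, 1)
  expect_equal(fit$gscs$norm_prior, 1)
  # every aligned read has exactly one primary alignment
  expect_equal(sum(fit$alignments$primary),
               length(unique(fit$alignments$read)))
})

test_that("the fit is bit-reproducible on identical input", {
  tpl <- simulate_templates(3, 400, divergence = 0.12, seed = 48)
  sim <- simulate_reads(tpl, c(0.5, 0.3, 0.2), 400, read_len = 100,
                        error_rate = 0.005, seed = 49)
  db <- build_reference_db(tpl, min_length = 150)
  f1 <- gscem(sim$reads, db)
  f2 <- gscem(sim$reads, db)
  expect_identical(f1$gscs, f2$gscs)
  expect_identical(f1$alignments, f2$alignments)
  expect_identical(f1$history, f2$history)
})

test_that("abundance recovery is accurate over replicated noisy mixtures", {
  # scaled-down replicate study: 5 templates >= 10% divergence, Dirichlet
  # abundances, 1% base errors
  set.seed(50)
  maes <- vapply(1:4, function(rep) {
    tpl <- simulate_templates(5, 500, divergence = 0.1, seed = 50 + rep)
    ab <- stats::rgamma(5, 2); ab <- ab / sum(ab)
    sim <- simulate_reads(tpl, ab, 1500, read_len = 120, error_rate = 0.01,
                          seed = 150 + rep)
    fit <- gscem(sim$reads, build_reference_db(tpl, min_length = 150))
    # attribute every cluster to its nearest template by identity
    g <- fit$gscs
    src <- vapply(g$consensus, function(cs)
      tpl$id[which.max(vapply(tpl$sequence, pairwise_identity, numeric(1),
                              a = cs))], character(1))
    est <- vapply(tpl$id, function(t) sum(g$norm_prior[src == t]),
                  numeric(1))
    mean(abs(est - ab))
  }, numeric(1))
  expect_lte(mean(maes), 0.03)
})

test_that("priors stay normalized through split, merge and prune", {
  set.seed(51)
  a <- random_seq(200)
  gl <- list(gscem:::gsc_new("GSC_1", a, prior = 0.5),
             gscem:::gsc_new("GSC_2", mutate_seq(a, 2), prior = 0.3),
             gscem:::gsc_new("GSC_3", mutate_seq(a, 90), prior = 0.2))
  pr <- matrix(c(0.7, 0.24, 0.03, 0.03), 200, 4, byrow = TRUE)
  gl[[3]]$probs <- pr
  cfg <- gscem_config()
  sp <- split_gscs(gl, cfg)
  expect_equal(sum(vapply(sp$gscs, `[[`, numeric(1), "prior")), 1,
               tolerance = 1e-9)
  mg <- merge_gscs(sp$gscs, cfg)
  expect_equal(sum(vapply(mg$gscs, `[[`, numeric(1), "prior")), 1,
               tolerance = 1e-9)
  pu <- prune_gscs(mg$gscs, rep(10, length(mg$gscs)), cfg)
  expect_equal(sum(vapply(pu$gscs, `[[`, numeric(1), "prior")), 1,
               tolerance = 1e-9)
})
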