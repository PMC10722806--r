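test_that("taxonomic Hill numbers match their closed forms", {
  expect_equal(hill_taxonomic(c(0.5, 0.5), 0), 2)
  expect_equal(hill_taxonomic(c(0.5, 0.5), 1), 2)
  expect_equal(hill_taxonomic(c(0.5, 0.5), 2), 2)
  expect_equal(hill_taxonomic(c(0.75, 0.25), 2), 1.6, tolerance = 1e-12)
  expect_equal(hill_taxonomic(c(0.75, 0.25), 1),
               exp(-(0.75 * log(0.75) + 0.25 * log(0.25))),
               tolerance = 1e-12)
  # q = 1 agrees with the q -> 1 limit of the general formula
  p <- c(0.5, 0.3, 0.15, 0.05)
  lim <- mean(c(hill_taxonomic(p, 1 - 1e-6), hill_taxonomic(p, 1 + 1e-6)))
  expect_equal(hill_taxonomic(p, 1), lim, tolerance = 1e-6)
  # q = 0 is richness, zeros excluded
  expect_equal(hill_taxonomic(c(0.2, 0.8, 0), 0), 2)
  expect_error(hill_taxonomic(c(0, 0), 1), "all-zero")
})

test_that("qD at q = 2 equals inverse Simpson on random vectors", {
  for (s in 1:20) {
    p <- random_abundance(letters[1:6], s)
    expect_equal(hill_taxonomic(p, 2), 1 / sum((p / sum(p))^2),
                 tolerance = 1e-12)
  }
})

test_that("phylogenetic Hill numbers reduce correctly", {
  # q = 0 gives Faith's PD (all tips present)
  tr <- parse_newick("((A:1,B:2):0.5,(C:1.5,D:1):2);")
  p <- c(A = 0.4, B = 0.3, C = 0.2, D = 0.1)
  expect_equal(hill_phylogenetic(tr, p, 0), sum(tr$edge.length))
  # star tree with unit branches: qPD equals qD for all q
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  u <- c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)
  for (q in c(0, 1, 2)) expect_equal(hill_phylogenetic(star, u, q), 4)
  for (q in c(0, 1, 2))
    expect_equal(hill_phylogenetic(star, p, q), hill_taxonomic(p, q),
                 tolerance = 1e-12)
  # two-tip tree, hand evaluation: Tbar = 1, qPD = 1/(0.75^2 + 0.25^2)
  two <- parse_newick("(A:1,B:1);")
  expect_equal(hill_phylogenetic(two, c(A = 0.75, B = 0.25), 2), 1.6,
               tolerance = 1e-12)
  expect_error(hill_phylogenetic(two, c(A = 0.5, Z = 0.5), 1), "absent")
})

test_that("diversity profiles are non-increasing in q", {
  qs <- c(0, 0.5, 1, 1.5, 2, 3)
  for (s in 1:100) {
    tr <- random_tree(6, seed = s)
    p <- random_abundance(tr$tip.label, s + 1000)
    qd <- vapply(qs, function(q) hill_taxonomic(p, q), numeric(1))
    qpd <- vapply(qs, function(q) hill_phylogenetic(tr, p, q), numeric(1))
    expect_true(all(diff(qd) <= 1e-9))
    expect_true(all(diff(qpd) <= 1e-9))
    expect_gte(qd[1], 1)
  }
})

test_that("weighted UniFrac matches the brute-force branch oracle", {
  expect_equal(weighted_unifrac(parse_newick("(A:1,B:1);"),
                                c(A = 1, B = 0), c(A = 0, B = 1),
                                normalized = FALSE), 2)
  expect_equal(weighted_unifrac(parse_newick("(A:1,B:1);"),
                                c(A = 1, B = 0), c(A = 0, B = 1)), 1)
  for (s in 1:100) {
    tr <- random_tree(8, seed = s)
    pA <- random_abundance(tr$tip.label, s + 2000)
    pB <- random_abundance(tr$tip.label, s + 3000)
    expect_equal(weighted_unifrac(tr, pA, pB),
                 oracle_wunifrac(tr, pA, pB), tolerance = 1e-12)
    expect_equal(weighted_unifrac(tr, pA, pB, normalized = FALSE),
                 oracle_wunifrac(tr, pA, pB, normalized = FALSE),
                 tolerance = 1e-12)
    # identical communities are at distance zero
    expect_equal(weighted_unifrac(tr, pA, pA), 0)
    # doubling branch lengths doubles the raw form, fixes the normalized
    tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
    expect_equal(weighted_unifrac(tr2, pA, pB, normalized = FALSE),
                 2 * weighted_unifrac(tr, pA, pB, normalized = FALSE),
                 tolerance = 1e-12)
    expect_equal(weighted_unifrac(tr2, pA, pB),
                 weighted_unifrac(tr, pA, pB), tolerance = 1e-12)
  }
})

test_that("weighted UniFrac agrees with the phyloseq implementation", {
  skip_if_not_installed("phyloseq")
  for (s in 1:5) {
    tr <- random_tree(10, seed = s + 100)
    A <- rbind(S1 = random_abundance(tr$tip.label, s + 4000),
               S2 = random_abundance(tr$tip.label, s + 5000))
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(A, taxa_are_rows = FALSE), phyloseq::phy_tree(tr))
    for (norm in c(TRUE, FALSE))
      expect_equal(weighted_unifrac(tr, A[1, ], A[2, ], normalized = norm),
                   as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                                normalized = norm)),
                   tolerance = 1e-9)
  }
})

test_that("the UniFrac matrix is consistent with pairwise calls", {
  tr <- random_tree(6, seed = 7)
  A <- rbind(S1 = random_abundance(tr$tip.label, 1),
             S2 = random_abundance(tr$tip.label, 2),
             S3 = random_abundance(tr$tip.label, 3))
  D <- unifrac_matrix(tr, A)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_equal(D["S1", "S3"], weighted_unifrac(tr, A[1, ], A[3, ]))
  # identical samples give a zero matrix
  D0 <- unifrac_matrix(tr, A[c(1, 1), ])
  expect_true(all(D0 == 0))
  # permuting samples permutes rows and columns identically
  Dp <- unifrac_matrix(tr, A[c(3, 1, 2), ])
  expect_equal(Dp, D[c(3, 1, 2), c(3, 1, 2)])
})

test_that("MNTD matches the all-pairs patristic oracle and picante", {
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(mntd(star, c("A", "C", "D")), 2)
  expect_equal(mntd(parse_newick("(A:1,B:3);"), c("A", "B")), 4)
  expect_error(mntd(star, "A"), "at least two")
  for (s in 1:100) {
    tr <- random_tree(10, seed = s + 200)
    tips <- sample(tr$tip.label, sample(3:10, 1))
    expect_equal(mntd(tr, tips), oracle_mntd(tr, tips), tolerance = 1e-12)
  }
  skip_if_not_installed("picante")
  tr <- random_tree(12, seed = 999)
  p <- random_abundance(tr$tip.label, 998)
  comm <- matrix(p, 1, dimnames = list("s", names(p)))
  expect_equal(mntd(tr, names(p)),
               picante::mntd(comm > 0, stats::cophenetic(tr)),
               tolerance = 1e-9)
  expect_equal(mntd(tr, p, abundance_weighted = TRUE),
               picante::mntd(comm, stats::cophenetic(tr),
                             abundance.weighted = TRUE),
               tolerance = 1e-9)
})
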