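test_that("template simulation hits the requested divergence exactly", {
  tpl0 <- simulate_templates(3, 800, divergence = 0, seed = 81)
  expect_equal(length(unique(tpl0$sequence)), 1L)

  tpl <- simulate_templates(2, 1000, divergence = 0.10, seed = 82)
  # identity to the shared ancestor is 0.90 exactly by construction;
  # recover the ancestor as the zero-divergence draw under the same seed
  anc <- simulate_templates(1, 1000, divergence = 0, seed = 82)$sequence
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(ham(tpl$sequence[1], anc), 100L)
  expect_equal(ham(tpl$sequence[2], anc), 100L)
  # template-template divergence lies between the one- and two-step bounds
  d12 <- ham(tpl$sequence[1], tpl$sequence[2]) / 1000
  expect_gte(d12, 0.10)
  expect_lte(d12, 0.20)

  expect_identical(simulate_templates(4, 500, 0.2, seed = 83),
                   simulate_templates(4, 500, 0.2, seed = 83))
  expect_error(simulate_templates(2, 100, divergence = 0.9, seed = 1),
               "divergence")
})

test_that("read simulation respects abundances, structure and determinism", {
  tpl <- simulate_templates(2, 600, divergence = 0.1, seed = 84)
  sim <- simulate_reads(tpl, c(0.7, 0.3), 10000, read_len = 100, seed = 85)
  # error-free mate-1 reads are exact template substrings
  i <- which(sim$reads$mate == 1L)[1:50]
  for (r in i) {
    t_idx <- match(sim$truth$template[sim$reads$pair[r]], tpl$id)
    expect_true(grepl(sim$reads$bases[r], tpl$sequence[t_idx], fixed = TRUE))
  }
  # mate 2 is the reverse complement of a template substring
  r2 <- which(sim$reads$mate == 2L)[1]
  t_idx <- match(sim$truth$template[sim$reads$pair[r2]], tpl$id)
  expect_true(grepl(gscem::revcomp(sim$reads$bases[r2]), tpl$sequence[t_idx],
                    fixed = TRUE))
  # realized template-1 fraction within 3 binomial SDs of 0.7
  frac <- mean(sim$truth$template == "tpl_01")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
  # provenance covers every emitted pair
  expect_setequal(sim$truth$id, unique(sim$reads$id))

  # byte-identical FASTQ under a fixed seed
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  s1 <- simulate_reads(tpl, c(0.5, 0.5), 100, read_len = 80, seed = 86)
  s2 <- simulate_reads(tpl, c(0.5, 0.5), 100, read_len = 80, seed = 86)
  write_fastq(s1$reads[s1$reads$mate == 1L, ], f1)
  write_fastq(s2$reads[s2$reads$mate == 1L, ], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_reads(tpl, c(0.5, 0.5), 10, read_len = 700, seed = 1),
               "read_len")
})

test_that("the empirical base error rate matches the nominal rate", {
  tpl <- simulate_templates(1, 500, divergence = 0, seed = 87)
  rate <- 0.01
  sim <- simulate_reads(tpl, 1, 1000, read_len = 120, error_rate = rate,
                        seed = 88)
  m1 <- sim$reads[sim$reads$mate == 1L, ]
  n_err <- 0; n_base <- 0
  for (r in seq_len(nrow(m1))) {
    start <- sim$truth$start[m1$pair[r]]
    truth_seg <- substr(tpl$sequence, start, start + 119)
    n_err <- n_err + sum(strsplit(m1$bases[r], "")[[1]] !=
                           strsplit(truth_seg, "")[[1]])
    n_base <- n_base + 120
  }
  expect_gte(n_base, 1e5)
  expect_lt(abs(n_err / n_base - rate), 3 * sqrt(rate * (1 - rate) / n_base))
})

test_that("layered designs follow the requested abundance gradients", {
  flat <- simulate_layered_design(n_templates = 3, n_layers = 4,
                                  trend = "flat", n_pairs = 10,
                                  template_length = 300, seed = 89)
  expect_true(all(apply(flat$abundance, 2, function(x) diff(range(x)) == 0)))

  sim <- simulate_layered_design(n_templates = 2, n_layers = 4,
                                 trend = c("up", "down"), n_pairs = 10,
                                 template_length = 300, seed = 90)
  expect_equal(cor(sim$abundance[, 1], 1:4, method = "spearman"), 1)
  expect_equal(cor(sim$abundance[, 2], 1:4, method = "spearman"), -1)
  expect_equal(unname(rowSums(sim$abundance)), rep(1, 4), tolerance = 1e-9)

  # weighted UniFrac between adjacent layers is monotone along the gradient
  grad <- simulate_layered_design(n_templates = 4, n_layers = 4,
                                  trend = c("up", "down"), fold = 30,
                                  n_pairs = 10, template_length = 300,
                                  seed = 91)
  d1 <- weighted_unifrac(grad$tree, grad$abundance[1, ], grad$abundance[2, ])
  d13 <- weighted_unifrac(grad$tree, grad$abundance[1, ], grad$abundance[3, ])
  d14 <- weighted_unifrac(grad$tree, grad$abundance[1, ], grad$abundance[4, ])
  expect_lt(d1, d13)
  expect_lt(d13, d14)
  expect_error(simulate_layered_design(trend = "sideways", seed = 1),
               "trend")
})
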