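test_that("binary entropy has the expected shape and endpoints", {
  expect_equal(binary_entropy(0.5), 1.0)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  p <- c(0.01, 0.1, 0.25, 0.4)
  expect_equal(binary_entropy(p), binary_entropy(1 - p))
  expect_error(binary_entropy(-0.1), "0, 1")
  expect_error(binary_entropy(1.1), "0, 1")
})

test_that("the per-base error term reproduces the published 3-dp values", {
  expect_equal(round(error_entropy_per_base(0.0030), 3), 0.047)
  expect_equal(round(error_entropy_per_base(0.0010), 3), 0.018)
  expect_equal(error_entropy_per_base(0), 0)
})

test_that("Poisson entropy matches a long-truncation series oracle", {
  # independent oracle: direct pmf summation over a much longer range
  oracle <- function(lam, kmax = 2000) {
    pk <- dpois(0:kmax, lam)
    pk <- pk[pk > 0]
    -sum(pk * log2(pk))
  }
  expect_equal(poisson_entropy(0), 0)
  for (lam in c(0.2, 0.4, 0.5, 0.8, 2, 10, 100))
    expect_equal(poisson_entropy(lam), oracle(lam), tolerance = 1e-9)
  expect_lt(poisson_entropy(0.2), poisson_entropy(0.4))
  expect_lt(poisson_entropy(0.4), poisson_entropy(0.8))
  expect_error(poisson_entropy(-1), ">= 0")
})

test_that("LZ genome bits are deterministic and sane", {
  g <- strrep("A", 10000)
  b <- lz_genome_bits(g)
  expect_lt(b, 2 * 10000) # repetitive input compresses far below 2 bits/base
  expect_identical(b, lz_genome_bits(g))
  gu <- simulate_genome(100000, seed = 4)
  rate <- lz_genome_bits(gu) / 100000
  expect_gt(rate, 1.8) # incompressible 4-letter text
  expect_lt(rate, 2.4)
  expect_error(lz_genome_bits(""), "non-empty")
})

test_that("the three-term estimate is additive and monotone in N", {
  g <- simulate_genome(20000, seed = 6)
  e <- estimate_read_set_entropy(g, N = 2000, L = 100, p = 0)
  expect_equal(e$error_bits, 0)
  expect_equal(e$total_bits, e$lz_genome_bits + e$sampling_bits + e$error_bits)
  expect_true(all(unlist(e$per_base) >= 0))
  e2 <- estimate_read_set_entropy(g, N = 4000, L = 100, p = 0)
  expect_gt(e2$sampling_bits, e$sampling_bits)
  ep <- estimate_read_set_entropy(g, N = 2000, L = 100, p = 0.01)
  expect_equal(ep$total_bits - e$total_bits, ep$error_bits)
  expect_error(estimate_read_set_entropy(g, N = 0, L = 100), "N must")
  expect_error(estimate_read_set_entropy(g, N = 10, L = 30000), "L must")
})

test_that("on error-free high-coverage data the estimate lower-bounds the codec", {
  # 40x coverage, typical of bacterial resequencing experiments
  glen <- 60000
  L <- 101
  N <- round(40 * glen / L)
  g <- simulate_genome(glen, seed = 14)
  rs <- sample_reads(g, simulation_spec(N, L, 0, 0, seed = 15))
  achieved <- container_stats(compress_reads(rs))$bits_per_base
  est <- estimate_read_set_entropy(g, N, L, 0)$per_base[["total"]]
  expect_gt(achieved, est)
  expect_lt(achieved, 2.0)
})
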