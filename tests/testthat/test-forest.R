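test_that("seeded suffix-prefix overlap matches exhaustive expectations", {
  # enumerated by hand over all window positions
  expect_equal(suffix_prefix_overlap("AACGT", "CGTTT", K = 2, eps = 0), 3L)
  expect_equal(suffix_prefix_overlap("ACGT", "ACGT", K = 1, eps = 0), 4L)
  expect_equal(suffix_prefix_overlap("ACGTT", "AGTTC", K = 2, eps = 1), 4L)
  expect_true(is.na(suffix_prefix_overlap("AAAAA", "CCCCC", K = 2, eps = 0)))
  expect_error(suffix_prefix_overlap("ACGT", "ACGT", K = 5), "K must")
  expect_error(suffix_prefix_overlap("ACGT", "ACG", K = 2), "equal length")
})

test_that("default overlap length is floor(L/5), floored at 1", {
  expect_equal(default_overlap_k(100), 20L)
  expect_equal(default_overlap_k(101), 20L)
  expect_equal(default_overlap_k(3), 1L)
  expect_error(default_overlap_k(0), "positive")
})

test_that("the greedy builder reproduces the worked 5-read cycle forest", {
  f <- build_read_forest(c("ACGT", "CGTA", "GTAC", "TACG", "ACGG"),
                         K = 2, eps = 0)
  expect_equal(total_weight(f), 5L)
  expect_equal(f$nodes$weight, rep(1L, 5))
  # 4-cycle ACGT -> TACG -> GTAC -> CGTA -> ACGT, plus ACGG under TACG
  expect_equal(f$nodes$parent, c(4L, 1L, 2L, 3L, 4L))
})

test_that("degenerate inputs: single read, duplicates, empty set", {
  f <- build_read_forest("ACGTACGT", K = 2, eps = 0)
  expect_equal(total_weight(f), 8L)
  expect_true(is.na(f$nodes$parent))

  f <- build_read_forest(c("ACGT", "ACGT", "ACGT"), K = 2, eps = 0)
  expect_equal(nrow(f$nodes), 1L)
  expect_equal(f$nodes$fwd_mult, 3L)
  expect_equal(total_weight(f), 4L)

  f <- build_read_forest(character(0))
  expect_equal(nrow(f$nodes), 0L)
  expect_equal(total_weight(f), 0L)
})

test_that("children search reassigns an earlier root to a better parent", {
  # "CGTA" enters first as a root (weight 4); "ACGT" then enters and its
  # children search finds CGTA with overlap 3, so pi(CGTA) is reset.
  f <- build_read_forest(c("CGTA", "ACGT"), K = 2, eps = 0)
  expect_equal(f$nodes$seq, c("CGTA", "ACGT"))
  expect_equal(f$nodes$parent, c(2L, NA_integer_))
  expect_equal(f$nodes$weight, c(1L, 4L))

  # same forest via incremental insertion
  f1 <- build_read_forest("CGTA", K = 2, eps = 0)
  f2 <- forest_insert(f1, "ACGT")
  expect_equal(f2$nodes$parent, c(2L, NA_integer_))
  expect_equal(total_weight(f2), 5L)
})

test_that("every committed edge satisfies the seed rule", {
  set.seed(101)
  for (eps in c(0L, 2L)) {
    g <- simulate_genome(3000, seed = 7 + eps)
    rs <- sample_reads(g, simulation_spec(300, 50, 0.01, 0, seed = 8 + eps))
    K <- default_overlap_k(50)
    f <- build_read_forest(rs, K = K, eps = eps)
    nd <- f$nodes
    for (i in which(!is.na(nd$parent))) {
      u <- nd$seq[nd$parent[i]]
      v <- nd$seq[i]
      l <- 50L - nd$weight[i]
      expect_gte(l, K)
      # seed window: last K overlap positions exact
      expect_equal(substring(v, l - K + 1, l), substring(u, 50 - K + 1, 50))
      mm <- sum(strsplit(substring(v, 1, l - K), "")[[1]] !=
                strsplit(substring(u, 50 - l + 1, 50 - K), "")[[1]])
      expect_lte(mm, eps)
    }
  }
})

test_that("total weight is invariant under input read order (eps = 0)", {
  set.seed(55)
  for (rep in 1:10) {
    g <- simulate_genome(800, seed = rep)
    rs <- sample_reads(g, simulation_spec(120, 25, 0, 0, seed = 50 + rep))
    K <- default_overlap_k(25)
    w0 <- total_weight(build_read_forest(rs, K = K, eps = 0))
    for (perm in 1:3) {
      w <- total_weight(build_read_forest(sample(rs$reads), K = K, eps = 0))
      expect_identical(w, w0)
    }
  }
})

test_that("each connected component has exactly one cycle or one root", {
  set.seed(77)
  for (rep in 1:8) {
    g <- simulate_genome(600, seed = rep)
    rs <- sample_reads(g, simulation_spec(150, 20, 0.02, 0.3, seed = rep))
    f <- build_read_forest(rs, K = 4, eps = 2, strand_correct = TRUE)
    nd <- f$nodes
    n <- nrow(nd)
    # union-find over undirected parent edges
    comp <- seq_len(n)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (i in which(!is.na(nd$parent))) {
      a <- find(i); b <- find(nd$parent[i])
      if (a != b) comp[a] <- b
    }
    for (i in seq_len(n)) comp[i] <- find(i)
    # a component with a NIL-root has no cycle and vice versa
    for (cid in unique(comp)) {
      nil_roots <- sum(is.na(nd$parent[comp == cid]))
      expect_true(nil_roots %in% c(0L, 1L))
    }
    # decompose view: one anchor (cycle contig or NIL-root contig) per component
    cg <- decompose_forest(f)
    n_anchor <- sum(vapply(cg, function(x) x$is_cycle || is.na(x$parent_contig),
                           logical(1)))
    expect_equal(n_anchor, length(unique(comp)))
  }
})

test_that("strand correction commits the longer-overlap orientation", {
  # "ACCGGTAC" overlaps nothing forward, but its reverse complement
  # "GTACCGGT" has a 4-base prefix overlap with the suffix of "AAAAGTAC"
  f <- build_read_forest(c("AAAAGTAC", "ACCGGTAC"), K = 3, eps = 0,
                         strand_correct = TRUE)
  expect_equal(f$nodes$seq[2], "GTACCGGT")
  expect_equal(f$nodes$parent[2], 1L)
  expect_equal(f$nodes$weight[2], 4L)
  expect_equal(f$nodes$rev_mult[2], 1L)
  # without strand correction it stays a root in input orientation
  f0 <- build_read_forest(c("AAAAGTAC", "ACCGGTAC"), K = 3, eps = 0)
  expect_equal(f0$nodes$seq[2], "ACCGGTAC")
  expect_true(is.na(f0$nodes$parent[2]))
  # reverse-complement duplicates collapse only under strand correction
  fd <- build_read_forest(c("AAAAGTAC", revcomp("AAAAGTAC")), K = 3,
                          strand_correct = TRUE)
  expect_equal(nrow(fd$nodes), 1L)
  expect_equal(fd$nodes$fwd_mult + fd$nodes$rev_mult, 2L)
  fd0 <- build_read_forest(c("AAAAGTAC", revcomp("AAAAGTAC")), K = 3)
  expect_equal(nrow(fd0$nodes), 2L)
})
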