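# Build the test's multi-alignment for candidate c against reference d with
# a given set of reads, mirroring candidate_pair_pvalue()'s construction.
build_test_ma <- function(read_seqs, c_seq, d_seq) {
  al <- lapply(c(read_seqs, c_seq), align_pair, target = d_seq)
  multi_alignment(al[seq_along(read_seqs)], reference = al[[length(al)]])
}

test_that("variant positions count disagreeing columns, gaps included", {
  d <- "ACGTACGTACGTACGTACGT"
  # one substitution and a 2-nt deletion -> 3 variant columns
  c1 <- paste0(substr(d, 1, 4), "T", substr(d, 6, 14), substr(d, 17, 20))
  A <- build_test_ma(c(d, d), c1, d)
  expect_equal(length(variant_positions(A)), 3L)
  # a 1-nt insertion -> one insertion column
  c2 <- paste0(substr(d, 1, 10), "A", substr(d, 11, 20))
  A2 <- build_test_ma(c(d, d), c2, d)
  V2 <- variant_positions(A2)
  expect_equal(length(V2), 1L)
  expect_equal(A2$target_row[V2], "-")
  # without a reference row the accessor refuses
  A3 <- multi_alignment(list(align_pair(d, d)))
  expect_error(variant_positions(A3), "reference")
})

test_that("error probabilities follow the Phred convention with clamping", {
  d <- "ACGTACGTAC"
  c1 <- paste0("ACGTT", substr(d, 6, 10))   # substitution at position 5
  reads <- flat_reads(c(d, c1), q = 40)
  A <- build_test_ma(reads$seq, c1, d)
  V <- variant_positions(A)
  p <- read_error_probabilities(rep(40L, 10L), A, 1L, V)
  expect_equal(p, 1e-4 / 3)
  # raw convention: undivided
  p_raw <- read_error_probabilities(rep(40L, 10L), A, 1L, V,
                                    test_params(p_convention = "raw"))
  expect_equal(p_raw, 1e-4)
  # Phred 0 (raw probability 1) clamps at the cap; the specific-base
  # convention then sits below it at 1/3
  p0 <- read_error_probabilities(rep(0L, 10L), A, 1L, V,
                                 test_params(p_convention = "raw"))
  expect_equal(p0, 0.5)
  expect_equal(read_error_probabilities(rep(0L, 10L), A, 1L, V), 1 / 3)
  # a deletion variant at a read-gap cell uses the minimum flanking quality
  c2 <- paste0(substr(d, 1, 4), substr(d, 6, 10))  # deletes position 5
  al <- lapply(c(c2, c2), align_pair, target = d)
  A2 <- multi_alignment(al[1], reference = al[[2]])
  V2 <- variant_positions(A2)
  qual <- c(10L, 10L, 10L, 7L, 9L, 10L, 10L, 10L, 10L)
  p2 <- read_error_probabilities(qual, A2, 1L, V2)
  expect_equal(p2, 10^(-min(7, 9) / 10))
})

test_that("the weighted support statistic is the product of inverse p_i", {
  mk <- function(s, p) structure(list(s = as.integer(s), log_p = log(p),
                                      n = length(s)), class = "support_profile")
  expect_equal(weighted_support(mk(c(0, 0, 0), c(.1, .1, .1)))$t, 1)
  expect_equal(weighted_support(mk(c(1, 1, 0), c(.01, .1, .2)))$t, 1000)
  expect_equal(weighted_support(mk(1, .5))$t, 2)
})

test_that("the tail bound reproduces the closed form and its branches", {
  mk <- function(s, p) structure(list(s = as.integer(s), log_p = log(p),
                                      n = length(s)), class = "support_profile")
  # worked case: p = (0.1, 0.1), both supporting
  tb <- tail_bound(mk(c(1, 1), c(.1, .1)))
  expect_equal(tb$t_prime, 2)
  expect_equal(tb$mu, 0.2)
  expect_equal(tb$delta, 10)
  expect_equal(tb$p_value, exp(0.2 * (10 - 11 * log(11))), tolerance = 1e-12)
  # observed support at or below expectation: insignificance default 0.5
  tb2 <- tail_bound(mk(c(0, 0, 0), c(.3, .3, .3)))
  expect_equal(tb2$p_value, 0.5)
  # shifted delta convention applies the bound at t' itself
  tb3 <- tail_bound(mk(c(1, 1), c(.1, .1)),
                    test_params(delta_convention = "shifted"))
  expect_equal(tb3$delta, 9)
  expect_gt(tb3$p_value, tb$p_value)
})

test_that("lowering a supporting read's p_i never weakens the bound", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    p <- runif(n, 0.02, 0.5)
    s <- as.integer(runif(n) < 0.5)
    s[1L] <- 1L
    p[2L] <- 1e-4  # fixed smallest p, so max_k(-log p_k) does not move
    base <- tail_bound(structure(list(s = s, log_p = log(p), n = n),
                                 class = "support_profile"))
    p2 <- p
    p2[1L] <- p[1L] / 2
    better <- tail_bound(structure(list(s = s, log_p = log(p2), n = n),
                                   class = "support_profile"))
    expect_lte(better$p_value, base$p_value + 1e-12)
  }
})

test_that("the bound dominates a Monte-Carlo estimate of the tail", {
  set.seed(52)
  for (rep in 1:15) {
    n <- sample(2:10, 1)
    p <- runif(n, 0.05, 0.5)
    s <- as.integer(runif(n) < p)  # a draw under the null
    if (sum(s) == 0) s[sample(n, 1)] <- 1L
    prof <- structure(list(s = s, log_p = log(p), n = n),
                      class = "support_profile")
    tb <- tail_bound(prof)
    if (tb$p_value == 0.5) next
    emp <- mc_tail_probability(log(p), tb$t_prime, n_draws = 2e5)
    expect_gte(tb$p_value, emp)
  }
})

test_that("the cached fast test path equals the multi-alignment route", {
  set.seed(54)
  for (rep in 1:12) {
    d <- rand_seq(120)
    # candidate with a random mix of substitutions and small indels
    v <- strsplit(d, "")[[1L]]
    at <- sort(sample(10:110, sample(1:3, 1)))
    for (a in at) v[a] <- sample(setdiff(c("A", "C", "G", "T"), v[a]), 1)
    if (runif(1) < 0.5) v <- v[-sample(20:100, 1)]
    if (runif(1) < 0.5) v <- append(v, sample(c("A", "C", "G", "T"), 1),
                                    after = sample(20:100, 1))
    # occasionally differ at the very ends (insertion junction 0 / L)
    if (runif(1) < 0.3) v <- c(sample(c("A", "C", "G", "T"), 1), v)
    if (runif(1) < 0.3) v <- c(v, sample(c("A", "C", "G", "T"), 1))
    c1 <- paste(v, collapse = "")
    if (c1 == d) next
    # noisy reads from both candidates with varying qualities
    seqs <- vapply(1:12, function(i) {
      s <- strsplit(if (i <= 6) c1 else d, "")[[1L]]
      k <- sample(0:2, 1)
      if (k) {
        p <- sample(length(s), k)
        s[p] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      }
      paste(s, collapse = "")
    }, "")
    reads <- ccs_reads(sprintf("r%d", 1:12), seqs,
                       lapply(nchar(seqs), function(n)
                         sample(5:45, n, replace = TRUE)))
    slow <- candidate_pair_pvalue(c1, d, reads[1:6], reads[7:12])
    cache <- new.env()
    fast <- isoresolve:::.fast_pair_pvalue(c1, d, reads,
                                           test_params(), align_scoring(),
                                           cache = cache)
    expect_equal(fast$n_variants, slow$n_variants)
    expect_equal(fast$p_value, slow$p_value, tolerance = 1e-12)
    expect_equal(fast$t_prime, slow$t_prime, tolerance = 1e-12)
    # cached second evaluation is identical
    fast2 <- isoresolve:::.fast_pair_pvalue(c1, d, reads,
                                            test_params(), align_scoring(),
                                            cache = cache)
    expect_identical(fast, fast2)
  }
})

test_that("candidate pairs with too many variants are skipped as significant", {
  d <- rand_seq(60)
  s <- strsplit(d, "")[[1L]]
  at <- seq(3, 57, by = 5)  # 11 substitutions
  s[at] <- vapply(s[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  c1 <- paste(s, collapse = "")
  res <- candidate_pair_pvalue(c1, d, flat_reads(c1, ids = "a"),
                               flat_reads(d, ids = "b"))
  expect_true(res$skipped)
  expect_equal(res$p_value, 0)
  expect_gt(res$n_variants, 10L)
})

test_that("a one-nucleotide variant at depth 5 against depth 300 is significant", {
  set.seed(53)
  d <- rand_seq(200)
  c1 <- d
  substr(c1, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(d, 100, 100))[1L]
  reads_c <- flat_reads(rep(c1, 5), q = 40, ids = paste0("c", 1:5))
  reads_d <- flat_reads(rep(d, 300), q = 40, ids = paste0("d", 1:300))
  res <- candidate_pair_pvalue(c1, d, reads_c, reads_d)
  expect_lt(res$p_value, 1e-6)
  # a single weakly supporting, low-quality read is far from the threshold
  reads_c1 <- flat_reads(c1, q = 1, ids = "w")
  reads_d2 <- flat_reads(rep(d, 50), q = 40, ids = paste0("e", 1:50))
  res2 <- candidate_pair_pvalue(c1, d, reads_c1, reads_d2)
  expect_gt(res2$p_value, 0.01)
})
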