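test_that("greedy assignment follows the most-covered-candidate rule", {
  # single candidate takes everything
  reads <- flat_reads(c("ACGT", "ACTT", "AAAA"))
  a1 <- assign_reads(reads, c(c1 = "ACGT"))
  expect_equal(a1$candidate_id, rep("c1", 3))
  # r1, r2 closest only to c1; r3 equidistant; r4 closest only to c2:
  # round one picks c1 (covers three reads), then c2 takes r4
  c1 <- "AAAAAAAA"; c2 <- "TTTTTTTT"
  r <- flat_reads(c("AAAAAAAT", "AAAAAATT", "AAAATTTT", "TTTTTTTA"),
                  ids = c("r1", "r2", "r3", "r4"))
  a2 <- assign_reads(r, c(c1 = c1, c2 = c2))
  expect_equal(a2$candidate_id, c("c1", "c1", "c1", "c2"))
  expect_equal(a2$edit_distance, c(1L, 2L, 4L, 1L))
  # disjoint pairs resolve independently of pick order
  r3 <- flat_reads(c("AAAAAAAT", "AAAAAAAT", "TTTTTTTA", "TTTTTTTA"))
  a3 <- assign_reads(r3, c(c1 = c1, c2 = c2))
  expect_equal(a3$candidate_id, c("c1", "c1", "c2", "c2"))
  # no candidates with reads present is an error
  expect_error(assign_reads(reads, character()), "no candidates")
})

test_that("a testing round assigns each candidate its least significant p-value", {
  # a singleton candidate set cannot be tested and is kept with p = 0
  reads <- flat_reads(rep("ACGTACGT", 5))
  cand <- data.frame(candidate_id = "c1", sequence = "ACGTACGT",
                     stringsAsFactors = FALSE)
  tr <- test_round(cand, assign_reads(reads, cand), reads)
  expect_equal(tr$p_value, 0)
  # a mutually well-supported 1-substitution pair: both significant
  set.seed(61)
  t1 <- rand_seq(150)
  t2 <- t1; substr(t2, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                                          substr(t1, 75, 75))[1L]
  reads2 <- flat_reads(c(rep(t1, 50), rep(t2, 50)), q = 20)
  cand2 <- data.frame(candidate_id = c("a", "b"), sequence = c(t1, t2),
                      stringsAsFactors = FALSE)
  tr2 <- test_round(cand2, assign_reads(reads2, cand2), reads2)
  expect_true(all(tr2$p_value <= 0.01))
  # a spurious candidate backed by one low-quality read next to a deep one
  reads3 <- c(flat_reads(rep(t1, 100), q = 20, ids = paste0("d", 1:100)),
              flat_reads(t2, q = 3, ids = "weak"))
  tr3 <- test_round(cand2, assign_reads(reads3, cand2), reads3)
  expect_gt(tr3$p_value[tr3$candidate_id == "b"], 0.01)
  expect_lt(tr3$p_value[tr3$candidate_id == "a"], 0.01)
})

test_that("filtering removes at most tau candidates per round, worst first", {
  set.seed(62)
  t1 <- rand_seq(150)
  mutate1 <- function(s, at) {
    v <- strsplit(s, "")[[1L]]
    v[at] <- sample(setdiff(c("A", "C", "G", "T"), v[at]), 1)
    paste(v, collapse = "")
  }
  spur <- vapply(c(30, 80, 130), function(at) mutate1(t1, at), "")
  reads <- flat_reads(rep(t1, 60), q = 20)
  cand <- data.frame(candidate_id = c("real", "s1", "s2", "s3"),
                     sequence = c(t1, spur), stringsAsFactors = FALSE)
  res <- filter_candidates(reads, cand, alpha = 0.01, tau = 1)
  expect_equal(res$transcripts$sequence, t1)
  expect_equal(res$rounds, 4L)                  # three removal rounds + final
  expect_equal(lengths(res$removed), rep(1L, 3L))
  # with tau = 10 all three go in one round
  res2 <- filter_candidates(reads, cand, alpha = 0.01, tau = 10)
  expect_equal(res2$rounds, 2L)
  # all-significant input passes through in a single round
  t2 <- rand_seq(150)
  reads3 <- flat_reads(c(rep(t1, 40), rep(t2, 40)), q = 20)
  cand3 <- data.frame(candidate_id = c("a", "b"), sequence = c(t1, t2),
                      stringsAsFactors = FALSE)
  res3 <- filter_candidates(reads3, cand3)
  expect_equal(res3$rounds, 1L)
  expect_setequal(res3$transcripts$sequence, c(t1, t2))
})

test_that("the driver recovers error-free transcripts exactly", {
  set.seed(63)
  truth <- replicate(4, rand_seq(150))
  reads <- flat_reads(rep(truth, each = 50), q = 30)
  fit <- isoresolve(reads)
  expect_setequal(fit$transcripts$sequence, truth)
  expect_equal(recall_precision(fit, truth), c(recall = 1, precision = 1))
  expect_equal(sum(fit$transcripts$support), 200L)
  # a single read is reported as itself (nothing to test against)
  fit1 <- isoresolve(flat_reads("ACGTACGTACGT"))
  expect_equal(fit1$transcripts$sequence, "ACGTACGTACGT")
})

test_that("assignments cover every read exactly once and sequences never change", {
  set.seed(64)
  sim <- simulate_family("TSPY", n_copies = 3, patterns = "copies_only",
                         abundance = "equal", depth = 10, seed = 99)
  fit <- isoresolve(sim$reads)
  expect_setequal(fit$assignments$read_id, sim$reads$id)
  expect_false(anyDuplicated(fit$assignments$read_id) > 0)
  expect_true(all(fit$transcripts$sequence %in% fit$candidates$sequence))
  r <- residuals(fit)
  expect_equal(length(r), length(sim$reads))
  expect_true(all(r >= 0))
})
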