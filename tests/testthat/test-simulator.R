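test_that("gene-copy simulation respects the mutation model", {
  root <- make_root_exons(c(100L, 120L, 80L), seed = 1)
  expect_equal(nchar(root), c(100L, 120L, 80L))
  # zero mutation rate: all copies identical to the root
  cp0 <- simulate_copies(root, 5, 0, seed = 2)
  expect_true(all(vapply(cp0, identical, NA, y = root)))
  # a single copy is just the root
  expect_equal(simulate_copies(root, 1, 0.05, seed = 3), list(root))
  # substitution counts concentrate around rate * length (binomial law)
  L <- sum(nchar(root))
  rate <- 0.02
  subs <- unlist(lapply(1:20, function(s) {
    cp <- simulate_copies(root, 2, rate, seed = s)
    edit_distance(paste(cp[[1]], collapse = ""), paste(cp[[2]], collapse = ""))
  }))
  expect_lt(abs(mean(subs) - rate * L), 3 * sqrt(rate * L) / sqrt(20) + 1)
  # copies never change exon lengths (substitution-only model)
  cp <- simulate_copies(root, 4, 0.05, seed = 9)
  for (c in cp) expect_equal(nchar(c), nchar(root))
})

test_that("isoforms concatenate included exons and collapse duplicates", {
  root <- make_root_exons(c(60L, 50L, 40L), seed = 4)
  # full inclusion on one copy reproduces the concatenated root
  tr <- simulate_isoforms(list(root), list(c(TRUE, TRUE, TRUE)),
                          abundance_values = 8)
  expect_equal(tr$sequence, paste(root, collapse = ""))
  # identical copies with the same pattern collapse to one truth transcript
  tr2 <- simulate_isoforms(list(root, root), list(c(TRUE, TRUE, TRUE)),
                           abundance_values = c(4, 8))
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$abundance, 12)
  # patterns must keep at least one exon and reference real exons
  expect_error(simulate_isoforms(list(root), list(logical(3))), "exon")
  expect_error(simulate_isoforms(list(root), list(c(1L, 5L))), "missing exon")
})

test_that("the 30-isoform design spans relative abundances of ~0.1% to ~15%", {
  rng <- sapply(1:10, function(s) {
    sim <- simulate_family("TSPY", n_copies = 6, mutation_rate = 0.05,
                           depth = 1, seed = s)
    expect_equal(nrow(sim$truth), 30L)
    expect_true(all(sim$truth$abundance %in% cumsum(2^(1:8)) |
                      sim$truth$abundance %in% 2^(1:8) |
                      sim$truth$abundance >= 2))
    range(sim$truth$rel_abundance)
  })
  # the draw from {2^i, i=1..8} over 30 isoforms puts the rarest isoform
  # near 0.1% and the most abundant near 15% of the pool
  expect_gt(median(rng[1, ]), 0.0004)
  expect_lt(median(rng[1, ]), 0.003)
  expect_gt(median(rng[2, ]), 0.07)
  expect_lt(median(rng[2, ]), 0.25)
})

test_that("read simulation reproduces origins, rates and qualities", {
  root <- make_root_exons(c(120L, 120L), seed = 5)
  truth <- simulate_isoforms(list(root), list(c(TRUE, TRUE), c(TRUE, FALSE)),
                             abundance_values = c(3, 1))
  # error rate 0: reads equal their origin transcripts, qualities at the cap
  r0 <- simulate_ccs_reads(truth, 50, 0, seed = 6)
  org <- attr(r0, "origins")
  expect_equal(r0$seq,
               truth$sequence[match(org$transcript_id, truth$transcript_id)])
  expect_true(all(unlist(r0$qual) == 60L))
  # realized mean per-read error fraction within 20% of the configured rate
  truth1 <- truth[1L, ]
  rr <- simulate_ccs_reads(truth1, 1000, 0.005, seed = 7)
  frac <- edit_distance(truth1$sequence, rr$seq) / nchar(truth1$sequence)
  expect_lt(abs(mean(frac) - 0.005) / 0.005, 0.2)
  # origin frequencies converge to the relative abundances
  big <- simulate_ccs_reads(truth, 10000, 0, seed = 8)
  freq <- table(attr(big, "origins")$transcript_id)[truth$transcript_id]
  chi <- stats::chisq.test(as.vector(freq), p = truth$rel_abundance)
  expect_gt(chi$p.value, 1e-4)
  # identical seeds give byte-identical reads and truth tables
  a <- simulate_family("TSPY", depth = 2, seed = 123)
  b <- simulate_family("TSPY", depth = 2, seed = 123)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("exact-match recall and precision use the stated conventions", {
  truth <- c("AAAA", "CCCC", "GGGG", "TTTT")
  expect_equal(recall_precision(truth, truth), c(recall = 1, precision = 1))
  expect_equal(recall_precision(c(truth[1:3], "ACGT"), truth),
               c(recall = 0.75, precision = 0.75))
  expect_equal(recall_precision(character(), truth),
               c(recall = 0, precision = 1))
})

test_that("a zero-noise simulation collapses the pipeline to deduplication", {
  sim <- simulate_family("TSPY", n_copies = 4, patterns = "copies_only",
                         abundance = "equal", mutation_rate = 0.02,
                         depth = 8, error_rate = 0, seed = 11)
  fit <- isoresolve(sim$reads)
  expect_setequal(fit$transcripts$sequence, sim$truth$sequence)
})
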