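test_that("edit distance handles the elementary cases", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "ACTT"), 1L)
  expect_equal(edit_distance("AAA", ""), 3L)
  expect_equal(edit_distance("ACGT", "ACTT"), edit_distance("ACTT", "ACGT"))
})

test_that("edit distance matches a quadratic DP oracle on random strings", {
  set.seed(101)
  for (i in 1:80) {
    a <- rand_seq(sample(1:50, 1))
    b <- rand_seq(sample(0:50, 1))
    expect_equal(edit_distance(a, b), dp_edit_distance(a, b))
  }
  # multi-word regime (> 64 nt patterns)
  for (i in 1:10) {
    a <- rand_seq(sample(100:300, 1))
    b <- rand_seq(sample(100:300, 1))
    expect_equal(edit_distance(a, b), as.integer(adist(a, b)))
  }
})

test_that("align_pair is a valid global alignment and exact under unit costs", {
  al <- align_pair("ACT", "ACGT", align_scoring_unit())
  expect_equal(al$target_row, "ACGT")
  expect_equal(gsub("-", "", al$query_row), "ACT")
  expect_equal(al$edit_distance, 1L)
  set.seed(7)
  for (i in 1:40) {
    a <- rand_seq(sample(1:50, 1)); b <- rand_seq(sample(1:50, 1))
    al <- align_pair(a, b, align_scoring_unit())
    # rows recover the originals; no double-gap columns
    q <- strsplit(al$query_row, "")[[1L]]; t <- strsplit(al$target_row, "")[[1L]]
    expect_equal(length(q), length(t))
    expect_false(any(q == "-" & t == "-"))
    expect_equal(paste(q[q != "-"], collapse = ""), a)
    expect_equal(paste(t[t != "-"], collapse = ""), b)
    expect_equal(al$edit_distance, edit_distance(a, b))
    # affine default scoring still recovers the strings
    al2 <- align_pair(a, b)
    expect_equal(gsub("-", "", al2$query_row), a)
    expect_equal(gsub("-", "", al2$target_row), b)
  }
})

test_that("multi-alignment anchors target columns and shares insertion columns", {
  # identical reads: no gap columns, all cells match
  al <- lapply(rep("ACGTAC", 3), align_pair, target = "ACGTAC")
  A <- multi_alignment(al)
  expect_equal(ncol(A$mat), 6L)
  expect_true(all(ma_annotate(A)$states == 1L))
  # one read with a 1-nt insertion: exactly one extra column, gap elsewhere
  al2 <- lapply(c("ACGTAC", "ACGTTAC"), align_pair, target = "ACGTAC")
  A2 <- multi_alignment(al2)
  expect_equal(ncol(A2$mat), 7L)
  expect_equal(sum(A2$mat == "-"), 1L)
  # counts: reads ACGT, ACTT, ACGT on target ACGT -> column 3 split G2/T1
  al3 <- lapply(c("ACGT", "ACTT", "ACGT"), align_pair, target = "ACGT")
  A3 <- multi_alignment(al3)
  cons3 <- ma_consensus(A3)
  expect_equal(unname(cons3$counts["G", 3L]), 2)
  expect_equal(unname(cons3$counts["T", 3L]), 1)
  # insertions at the same junction share columns, left-aligned; the longer
  # insertion alone pays for the extra column
  al4 <- lapply(c("ACGTAC", "ACGTTAC"), align_pair, target = "ACGAC")
  A4 <- multi_alignment(al4)
  expect_equal(ncol(A4$mat), 7L)
  expect_equal(paste(A4$mat[1L, A4$mat[1L, ] != "-"], collapse = ""), "ACGTAC")
  expect_equal(sum(A4$mat[1L, ] == "-"), 1L)
  # mixed targets are rejected
  expect_error(multi_alignment(list(align_pair("ACGT", "ACGT"),
                                    align_pair("ACGT", "ACTT"))),
               "identical target")
})

test_that("rows spell their original sequences after gap removal", {
  set.seed(21)
  target <- rand_seq(60)
  queries <- replicate(8, {
    s <- strsplit(target, "")[[1L]]
    i <- sample(60, 3)
    s[i[1L]] <- sample(c("A", "C", "G", "T"), 1)
    paste(s[-i[2L]], collapse = "")
  })
  A <- multi_alignment(lapply(queries, align_pair, target = target))
  for (i in seq_along(queries)) {
    row <- A$mat[i, ]
    expect_equal(paste(row[row != "-"], collapse = ""), queries[i])
    expect_equal(sum(row != "-"), nchar(queries[i]))
  }
})

test_that("consensus takes the per-column majority and flags ties", {
  al <- lapply(c(rep("ACGT", 5), "ACTT"), align_pair, target = "ACGT")
  cons <- ma_consensus(multi_alignment(al))
  expect_equal(cons$sequence, "ACGT")
  expect_false(any(cons$tie))
  al2 <- lapply(c("AC", "AG"), align_pair, target = "AC")
  cons2 <- ma_consensus(multi_alignment(al2))
  expect_true(cons2$tie[2L])
})

test_that("cell states and state-specific support follow the definitions", {
  al <- lapply(c(rep("ACGT", 5), "ACTT"), align_pair, target = "ACGT")
  A <- multi_alignment(al)
  st <- ma_annotate(A)
  # the lone substitution cell has support n_3^sub / n^sub = 1/1
  expect_equal(st$states[6L, 3L], 2L)
  expect_equal(st$support[6L, 3L], 1)
  # all-identical rows: every cell match with uniform support
  al2 <- lapply(rep("ACGTA", 4), align_pair, target = "ACGTA")
  st2 <- ma_annotate(multi_alignment(al2))
  expect_true(all(st2$states == 1L))
  expect_true(all(abs(st2$support - 1 / 5) < 1e-12))
  # two substitution cells in different columns split the support 1/2 each
  al3 <- lapply(c(rep("ACGTACGTAC", 8), "AGGTACGTAC", "ACGTACCTAC"),
                align_pair, target = "ACGTACGTAC")
  st3 <- ma_annotate(multi_alignment(al3))
  expect_equal(st3$support[9L, 2L], 0.5)
  expect_equal(st3$support[10L, 7L], 0.5)
  # support per state sums to one over the columns, for each present state
  csc <- st3$column_state_counts
  tot <- st3$total_state_counts
  for (t in which(tot > 0)) expect_equal(unname(sum(csc[t, ]) / tot[t]), 1)
})
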