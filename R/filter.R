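#' Greedy assignment of reads to candidate transcripts
#'
#' Every read is assigned to exactly one of its closest (minimum edit
#' distance) candidates. Because a read can have several closest candidates,
#' assignment is resolved greedily: repeatedly select the candidate that is a
#' closest neighbor of the most unassigned reads, bind those reads to it,
#' remove both from consideration, and repeat until all reads are bound.
#' Ties between candidates covering equally many reads are broken by the
#' lexicographically smallest candidate sequence (determinism). Candidates
#' chosen by no read simply receive no reads.
#'
#' @param reads a [ccs_reads] object.
#' @param candidates named character vector of candidate sequences (names are
#'   candidate ids), or a candidate data frame with columns `candidate_id`
#'   and `sequence`.
#' @return A data frame (`read_id`, `candidate_id`, `edit_distance`), one row
#'   per read.
#' @export
assign_reads <- function(reads, candidates) {
  if (is.data.frame(candidates)) {
    cand <- candidates$sequence
    names(cand) <- candidates$candidate_id
  } else cand <- candidates
  if (length(cand) == 0L) {
    if (length(reads) > 0L) stop("no candidates to assign reads to")
    return(data.frame(read_id = character(), candidate_id = character(),
                      edit_distance = integer(), stringsAsFactors = FALSE))
  }
  u <- unique(reads$seq)
  f <- match(reads$seq, u)
  mm <- c_min_distances(u, unname(cand))
  # per-read closest candidate index sets
  near <- mm$which[f]
  mind <- mm$min[f]
  n <- length(reads)
  assigned <- rep(NA_character_, n)
  active_reads <- rep(TRUE, n)
  active_cand <- rep(TRUE, length(cand))
  while (any(active_reads)) {
    cnt <- integer(length(cand))
    for (i in which(active_reads)) {
      live <- near[[i]][active_cand[near[[i]]]]
      cnt[live] <- cnt[live] + 1L
    }
    best <- which(cnt == max(cnt) & active_cand)
    if (length(best) > 1L) best <- best[order(cand[best])][1L]
    take <- vapply(seq_len(n), function(i)
      active_reads[i] && best %in% near[[i]], NA)
    assigned[take] <- names(cand)[best]
    active_reads[take] <- FALSE
    active_cand[best] <- FALSE
    if (!any(active_cand) && any(active_reads))
      stop("internal error: reads left without candidates") # unreachable
  }
  data.frame(read_id = reads$id, candidate_id = assigned,
             edit_distance = mind, stringsAsFactors = FALSE)
}

#' One statistical testing round over all candidates
#'
#' For each candidate c_i, tests the null hypothesis that its assigned reads
#' originated from each of c_i's closest-neighbor candidates c_j in turn
#' ([candidate_pair_pvalue()] on the pooled reads of the pair, with c_j as
#' the reference), and records p_i, the least significant (largest) of those
#' p-values. A candidate with no neighbor to test against (a singleton
#' candidate set) gets p_i = 0 and is kept.
#'
#' @param candidates candidate data frame (`candidate_id`, `sequence`).
#' @param assignment data frame from [assign_reads()].
#' @param reads the original (uncorrected) [ccs_reads].
#' @param params a [test_params()] object.
#' @param scoring an [align_scoring()] object.
#' @param cache optional environment used to reuse read-to-candidate
#'   alignments across rounds (alignments are deterministic; p-values are
#'   still recomputed from scratch every round).
#' @return A data frame (`candidate_id`, `p_value`, `n_assigned`,
#'   `n_variants`) of class `"filter_round"`.
#' @export
test_round <- function(candidates, assignment, reads,
                       params = test_params(), scoring = align_scoring(),
                       cache = NULL) {
  k <- nrow(candidates)
  pv <- numeric(k)
  nv <- rep(NA_integer_, k)
  n_assigned <- integer(k)
  idx_by_cand <- split(seq_along(reads$id),
                       factor(assignment$candidate_id,
                              levels = candidates$candidate_id))
  n_assigned <- lengths(idx_by_cand)
  if (k > 1L) {
    D <- c_pairwise_distances(candidates$sequence)
    for (i in seq_len(k)) {
      d_i <- D[i, -i]
      nbrs <- setdiff(which(D[i, ] == min(d_i)), i)
      p_best <- 0
      nv_i <- NA_integer_
      for (j in nbrs) {
        pool_i <- idx_by_cand[[i]]
        pool_j <- idx_by_cand[[j]]
        if (length(pool_i) + length(pool_j) == 0L) { p_best <- max(p_best, 0.5); next }
        res <- .fast_pair_pvalue(candidates$sequence[i],
                                 candidates$sequence[j],
                                 reads[c(pool_i, pool_j)],
                                 params, scoring, cache = cache,
                                 d_id = candidates$candidate_id[j])
        if (res$p_value >= p_best) { p_best <- res$p_value; nv_i <- res$n_variants }
      }
      pv[i] <- p_best
      nv[i] <- nv_i
    }
  }
  out <- data.frame(candidate_id = candidates$candidate_id, p_value = pv,
                    n_assigned = as.integer(n_assigned), n_variants = nv,
                    stringsAsFactors = FALSE)
  class(out) <- c("filter_round", class(out))
  out
}

#' Iterative statistical filtering of candidate transcripts
#'
#' Alternates read assignment and statistical testing: in each round the
#' original reads are re-assigned to the surviving candidates
#' ([assign_reads()]), every candidate receives its least significant
#' pairwise p-value ([test_round()]), and the candidates with p above
#' `alpha` are removed - at most `tau` of them per round, those with the
#' highest p-values first. The loop stops when no candidate's p-value
#' exceeds `alpha`. P-values are recomputed from scratch every round
#' against the fresh assignment; nothing is cached across rounds.
#'
#' @param reads the original (uncorrected) [ccs_reads].
#' @param candidates candidate data frame from [cluster_correct()] (columns
#'   `candidate_id`, `sequence`), or a named character vector.
#' @param alpha significance threshold; default 0.01.
#' @param tau maximum number of candidates removed per round; default 10.
#' @param params a [test_params()] object.
#' @param scoring an [align_scoring()] object.
#' @param trace if `TRUE`, log per-round summaries to stderr.
#' @return A list of class `"filter_result"` with `transcripts` (surviving
#'   candidates with `support` and `p_value`), `assignments` (final read
#'   assignment), `rounds`, and `removed` (list of candidate ids removed per
#'   round).
#' @export
filter_candidates <- function(reads, candidates, alpha = 0.01, tau = 10L,
                              params = test_params(),
                              scoring = align_scoring(), trace = FALSE) {
  stopifnot(alpha > 0, alpha < 1, tau >= 1)
  if (!is.data.frame(candidates))
    candidates <- data.frame(candidate_id = names(candidates),
                             sequence = unname(candidates),
                             stringsAsFactors = FALSE)
  if (anyDuplicated(candidates$sequence))
    stop("candidate sequences must be distinct")
  removed <- list()
  rounds <- 0L
  cache <- new.env(parent = emptyenv())
  repeat {
    rounds <- rounds + 1L
    asn <- assign_reads(reads, candidates)
    tst <- test_round(candidates, asn, reads, params, scoring, cache = cache)
    bad <- which(tst$p_value > alpha)
    if (trace)
      message(sprintf("filter round %d: %d candidates, %d above alpha",
                      rounds, nrow(candidates), length(bad)))
    if (length(bad) == 0L) break
    ord <- bad[order(-tst$p_value[bad], candidates$sequence[bad])]
    drop <- ord[seq_len(min(tau, length(ord)))]
    removed[[rounds]] <- candidates$candidate_id[drop]
    candidates <- candidates[-drop, , drop = FALSE]
    if (nrow(candidates) == 0L) {
      asn <- asn[0L, ]
      tst <- tst[0L, ]
      break
    }
  }
  transcripts <- data.frame(
    transcript_id = candidates$candidate_id,
    sequence = candidates$sequence,
    support = if (nrow(candidates)) tst$n_assigned[match(candidates$candidate_id, tst$candidate_id)] else integer(),
    p_value = if (nrow(candidates)) tst$p_value[match(candidates$candidate_id, tst$candidate_id)] else numeric(),
    stringsAsFactors = FALSE)
  names(asn)[names(asn) == "candidate_id"] <- "transcript_id"
  structure(list(transcripts = transcripts, assignments = asn,
                 rounds = rounds, removed = removed),
            class = "filter_result")
}
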