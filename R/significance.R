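#' Test parameters for the candidate significance test
#'
#' @param max_variants candidate pairs with more variant positions than this
#'   are not statistically evaluated (their p-value would be nearly 0); such
#'   pairs are marked `skipped` with p-value 0, i.e. treated as significant.
#'   Default 10.
#' @param p_floor,p_cap clamp for per-position error probabilities; the
#'   Bernoulli-mean interpretation requires probabilities strictly below 1.
#' @param p_convention how Phred scores map to the probability that an error
#'   produced the specific character the tested candidate carries:
#'   `"specific"` (default) divides the substitution error probability by 3
#'   (three possible wrong bases) and leaves insertion/deletion probabilities
#'   undivided; `"raw"` uses the undivided probability everywhere.
#' @param delta_convention `"printed"` (default) uses delta = t'/mu in the
#'   Chernoff-type bound; `"shifted"` uses delta = t'/mu - 1, which applies
#'   the bound exactly at t' rather than at t' + mu.
#' @return A list of class `"test_params"`.
#' @export
test_params <- function(max_variants = 10L, p_floor = 1e-7, p_cap = 0.5,
                        p_convention = c("specific", "raw"),
                        delta_convention = c("printed", "shifted")) {
  structure(list(max_variants = as.integer(max_variants),
                 p_floor = p_floor, p_cap = p_cap,
                 p_convention = match.arg(p_convention),
                 delta_convention = match.arg(delta_convention)),
            class = "test_params")
}

#' Variant positions between the reference row and the target
#'
#' The columns of the multi-alignment matrix where the reference row (the
#' candidate c under test) and the target (the candidate d acting as
#' reference sequence) disagree; gap characters count as disagreement.
#'
#' @param A a [multi_alignment()] built with a `reference` alignment.
#' @return Ordered integer vector of column indices (empty iff c equals d).
#' @export
variant_positions <- function(A) {
  stopifnot(inherits(A, "multi_alignment"))
  if (is.na(A$ref_row)) stop("multi-alignment has no reference row")
  which(A$mat[A$ref_row, ] != A$target_row)
}

# Variant type per column of V, judged from the reference row vs the target
# row: insertion where the target has a gap, deletion where the candidate
# has a gap, substitution otherwise.
.variant_types <- function(A, V) {
  rr <- A$mat[A$ref_row, V]
  tr <- A$target_row[V]
  ifelse(tr == "-", "insertion", ifelse(rr == "-", "deletion", "substitution"))
}

#' Per-read error probabilities at the variant positions
#'
#' For read row `i` of the matrix and each variant column j in `V`, the
#' probability p_ij that the character the read shows at j arose by a
#' sequencing error, derived from the read's Phred score at the base
#' occupying the column. For a column where the read has a gap, the quality
#' is taken as the minimum of the two flanking read bases. Substitution
#' variants use (10^(-q/10))/3 under the `"specific"` convention (the error
#' must produce the specific base the candidate carries); insertion and
#' deletion variants use 10^(-q/10) undivided. Values are clamped to
#' `[p_floor, p_cap]`.
#'
#' @param qual integer vector of the read's Phred scores.
#' @param A a [multi_alignment()] with a reference row.
#' @param row row index of the read in `A`.
#' @param V variant columns, from [variant_positions()].
#' @param params a [test_params()] object.
#' @return Numeric vector of p_ij, one per column of `V`.
#' @export
read_error_probabilities <- function(qual, A, row, V,
                                     params = test_params()) {
  if (length(V) == 0L) stop("V must be non-empty")
  bi <- A$base_index[row, ]
  nc <- length(bi)
  # nearest non-gap base on each side, for quality at read-gap cells
  lastb <- cummax(ifelse(is.na(bi), 0L, bi))
  nextb <- rev(-cummax(rev(ifelse(is.na(bi), -.Machine$integer.max, -bi))))
  q <- numeric(length(V))
  for (k in seq_along(V)) {
    j <- V[k]
    if (!is.na(bi[j])) {
      q[k] <- qual[bi[j]]
    } else {
      cand <- c(if (lastb[j] > 0L) qual[lastb[j]],
                if (nextb[j] <= length(qual)) qual[nextb[j]])
      q[k] <- if (length(cand)) min(cand) else 0
    }
  }
  p <- 10^(-q / 10)
  types <- .variant_types(A, V)
  if (params$p_convention == "specific")
    p[types == "substitution"] <- p[types == "substitution"] / 3
  pmin(pmax(p, params$p_floor), params$p_cap)
}

#' Support profile of the reads for a set of variant positions
#'
#' For every read aligned in the matrix, the support indicator s_i (1 iff
#' the read shows the candidate's characters at every variant column; reads
#' whose alignment does not span all of V are forced to 0) and the
#' per-read error probability p_i = prod_j p_ij, kept on the log scale.
#'
#' @param reads the [ccs_reads] whose rows appear in `A` (in row order,
#'   via `row_of`).
#' @param A a [multi_alignment()] with a reference row.
#' @param V variant columns.
#' @param row_of integer vector: matrix row index of each read.
#' @param params a [test_params()] object.
#' @return A list of class `"support_profile"` with `s` (0/1 integer vector),
#'   `log_p` (per-read log p_i), and `n`.
#' @export
support_profile <- function(reads, A, V, row_of = seq_along(reads$id),
                            params = test_params()) {
  stopifnot(inherits(A, "multi_alignment"))
  n <- length(reads$id)
  s <- integer(n)
  log_p <- numeric(n)
  ref_chars <- A$mat[A$ref_row, V]
  for (i in seq_len(n)) {
    r <- row_of[i]
    bi <- A$base_index[r, ]
    nz <- which(!is.na(bi))
    spans <- length(nz) > 0L && min(V) >= min(nz) && max(V) <= max(nz)
    s[i] <- as.integer(spans && all(A$mat[r, V] == ref_chars))
    log_p[i] <- sum(log(read_error_probabilities(reads$qual[[i]], A, r, V,
                                                 params)))
  }
  structure(list(s = s, log_p = log_p, n = n), class = "support_profile")
}

#' Weighted support statistic
#'
#' T = prod over supporting reads (s_i = 1) of 1/p_i; the empty product is 1.
#' Reads with higher base quality (smaller p_i) contribute more evidence, and
#' p_i shrinks with the number of linked variant positions, so fewer reads
#' are needed to support a candidate that differs at many positions or is
#' covered by high-quality reads.
#'
#' @param profile a [support_profile()].
#' @return A list with `t` (the statistic; may overflow to `Inf` for very
#'   strong support) and `log_t` (always finite), of class
#'   `"weighted_support"`.
#' @export
weighted_support <- function(profile) {
  log_t <- sum(-profile$log_p[profile$s == 1L])
  structure(list(t = exp(log_t), log_t = log_t), class = "weighted_support")
}

#' Chernoff-type upper bound on the support statistic's tail
#'
#' Transforms T to the normalized log statistic
#' T' = log T / max_k(-log p_k), a weighted sum of independent Bernoulli
#' variables with coefficients in (0,1], and applies the closed-form bound
#' P(T >= t) = P(T' >= t') < (e^delta / (1+delta)^(1+delta))^mu with
#' mu = E(T') and delta = t'/mu. When t' <= mu the observed support is below
#' its expectation under the null hypothesis (all variant support arises
#' from sequencing error); such values are insignificant and the returned
#' p-value defaults to 0.5. All computation is in log space; the logarithm
#' base cancels in t' and mu.
#'
#' @param profile a [support_profile()].
#' @param params a [test_params()] object (for the delta convention).
#' @return A list of class `"test_result"`: `t`, `log_t`, `t_prime`, `mu`,
#'   `delta`, `p_value`, `skipped` (always `FALSE` here), `n_variants`
#'   (`NA`; filled by [candidate_pair_pvalue()]).
#' @export
tail_bound <- function(profile, params = test_params()) {
  ws <- weighted_support(profile)
  M <- max(-profile$log_p)
  if (M <= 0) {
    return(structure(list(t = ws$t, log_t = ws$log_t, t_prime = NA_real_,
                          mu = NA_real_, delta = NA_real_, p_value = 0.5,
                          skipped = FALSE, n_variants = NA_integer_),
                     class = "test_result"))
  }
  t_prime <- ws$log_t / M
  p_i <- exp(profile$log_p)
  mu <- sum(p_i * (-profile$log_p)) / M
  delta <- switch(params$delta_convention,
                  printed = t_prime / mu,
                  shifted = t_prime / mu - 1)
  if (t_prime <= mu || delta <= 0) {
    pv <- 0.5
  } else {
    pv <- exp(mu * (delta - (1 + delta) * log1p(delta)))
    pv <- min(max(pv, 0), 1)
  }
  structure(list(t = ws$t, log_t = ws$log_t, t_prime = t_prime, mu = mu,
                 delta = delta, p_value = pv, skipped = FALSE,
                 n_variants = NA_integer_),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("test_result: p = %.4g (t' = %.3g, mu = %.3g%s)\n",
              x$p_value, x$t_prime, x$mu,
              if (isTRUE(x$skipped)) ", skipped: too many variants" else ""))
  invisible(x)
}

#' Significance of one candidate against a neighboring candidate
#'
#' Tests the null hypothesis that the reads assigned to candidates c and d
#' all originated from d, i.e. that c is not a real transcript. The pooled
#' reads and c are aligned to d (which acts as the error-free reference in
#' the test), the multi-alignment matrix is built, the variant positions V
#' where c and d disagree are read off, and the weighted-support tail bound
#' is evaluated. Pairs with more than `params$max_variants` variant
#' positions are not evaluated: their p-value would be nearly 0, so they are
#' returned as `skipped` with p-value 0.
#'
#' Validity rests on the test's stated assumptions: d is error-free, errors
#' at different positions and in different reads are independent, and at
#' positions where c and d agree they are not both wrong. None of these are
#' (or can be) asserted at runtime.
#'
#' @param c_seq,d_seq the two candidate sequences (distinct).
#' @param reads_c,reads_d [ccs_reads] assigned to c and d (either may be
#'   empty, not both).
#' @param params a [test_params()] object.
#' @param scoring an [align_scoring()] object for the alignments to d.
#' @return A `"test_result"` (see [tail_bound()]) with `n_variants` set.
#' @export
candidate_pair_pvalue <- function(c_seq, d_seq, reads_c, reads_d,
                                  params = test_params(),
                                  scoring = align_scoring()) {
  if (identical(c_seq, d_seq)) stop("c and d must be distinct")
  reads <- c(reads_c, reads_d)
  if (length(reads) == 0L) stop("no reads to test")
  u <- unique(reads$seq)
  f <- match(reads$seq, u)
  al <- align_to_target(c(u, c_seq), d_seq, scoring)
  A <- multi_alignment(al[seq_along(u)], reference = al[[length(al)]],
                       weights = as.numeric(tabulate(f, length(u))))
  V <- variant_positions(A)
  if (length(V) > params$max_variants) {
    return(structure(list(t = NA_real_, log_t = NA_real_, t_prime = NA_real_,
                          mu = NA_real_, delta = NA_real_, p_value = 0,
                          skipped = TRUE, n_variants = length(V)),
                     class = "test_result"))
  }
  prof <- support_profile(reads, A, V, row_of = f, params = params)
  res <- tail_bound(prof, params)
  res$n_variants <- length(V)
  res
}
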