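#' Levenshtein edit distance between DNA strings
#'
#' Unit-cost edit distance (substitution, insertion, deletion each cost 1),
#' computed with a bit-parallel algorithm in C. Vectorized over pairs; if one
#' argument has length 1 it is recycled against the other.
#'
#' @param x,y character vectors of sequences over A/C/G/T.
#' @return Integer vector of distances.
#' @examples
#' edit_distance("ACGT", "ACTT") # 1
#' @export
edit_distance <- function(x, y) {
  c_edit_distance(as.character(x), as.character(y))
}

#' Alignment scoring parameters
#'
#' The default scoring (match +2, mismatch -2, gap open -3, gap extend -1,
#' end-to-end global) mirrors common practice for aligning CCS reads within a
#' gene family. `align_scoring_unit()` gives the unit-cost configuration under
#' which the optimal alignment score equals minus the Levenshtein distance.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores; gap costs are
#'   negative, and a gap of length L costs `gap_open + L * gap_extend`.
#' @return A list of class `"align_scoring"`.
#' @export
align_scoring <- function(match = 2L, mismatch = -2L, gap_open = -3L,
                          gap_extend = -1L) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' @rdname align_scoring
#' @export
align_scoring_unit <- function() align_scoring(0L, -1L, 0L, -1L)

#' Global pairwise alignment of two sequences
#'
#' End-to-end (Needleman-Wunsch/Gotoh) alignment with affine gap penalties.
#' Ties in the traceback are broken deterministically (diagonal, then gap in
#' the query, then gap in the target), so identical inputs always yield the
#' identical alignment.
#'
#' @param query,target sequences over A/C/G/T (non-empty).
#' @param scoring an [align_scoring()] object.
#' @return A list of class `"pairwise_alignment"` with elements `query_row`
#'   and `target_row` (equal-length gapped strings over \{A,C,G,T,-\}),
#'   `score`, and `edit_distance` (the column-wise mismatch plus gap count of
#'   this alignment).
#' @export
align_pair <- function(query, target, scoring = align_scoring()) {
  res <- c_align_affine(as.character(query), as.character(target),
                        scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)[[1L]]
  q <- strsplit(res$query_row, "", fixed = TRUE)[[1L]]
  t <- strsplit(res$target_row, "", fixed = TRUE)[[1L]]
  res$edit_distance <- sum(q != t)
  class(res) <- "pairwise_alignment"
  res
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %d columns, score %d, edit distance %d\n",
              nchar(x$query_row), x$score, x$edit_distance))
  invisible(x)
}

# Align many queries to one common target; returns a bare list of
# (query_row, target_row, score) lists. Internal hot path.
align_to_target <- function(queries, target, scoring = align_scoring()) {
  c_align_affine(as.character(queries), as.character(target),
                 scoring$match, scoring$mismatch,
                 scoring$gap_open, scoring$gap_extend)
}

#' Multi-alignment matrix over a common target
#'
#' Builds the multi-alignment matrix from pairwise alignments that all share
#' the same target. The target's positions anchor the matrix columns, in
#' order; between consecutive target positions, insertion columns are created
#' so that every inserted base occupies a cell. Insertions from different
#' rows at the same junction share columns left-aligned, with extra columns
#' only for the longest insertion, which makes the construction deterministic
#' and independent of row order. After gap removal every row spells its
#' original sequence.
#'
#' @param alignments list of [align_pair()] results (or bare
#'   `query_row`/`target_row` lists) against the identical target.
#' @param reference optional: an alignment of a reference sequence (e.g. a
#'   candidate transcript) to the same target; stored as an extra flagged row
#'   that does not contribute to consensus or support counts.
#' @param weights optional non-negative numeric vector, one per alignment;
#'   rows represent that many identical reads in consensus/support counts.
#' @param row_ids optional character ids for the rows.
#' @return An object of class `"multi_alignment"`: a list with `mat`
#'   (character matrix, one aligned row per alignment, `"-"` for gaps),
#'   `base_index` (integer matrix mapping cells to 1-based positions in the
#'   original row sequence, `NA` at gaps), `target` (ungapped target string),
#'   `target_row` (character vector of the target spread over the matrix
#'   columns), `is_target_col` (logical), `weights`, and `ref_row` (row index
#'   of the reference row or `NA`).
#' @export
multi_alignment <- function(alignments, reference = NULL, weights = NULL,
                            row_ids = NULL) {
  if (!is.null(reference)) alignments <- c(alignments, list(reference))
  n <- length(alignments)
  if (n == 0L) stop("no alignments")
  qs <- lapply(alignments, function(a) strsplit(a$query_row, "", fixed = TRUE)[[1L]])
  ts <- lapply(alignments, function(a) strsplit(a$target_row, "", fixed = TRUE)[[1L]])
  targets <- vapply(ts, function(t) paste(t[t != "-"], collapse = ""), "")
  if (length(unique(targets)) != 1L)
    stop("alignments do not share an identical target")
  target <- targets[1L]
  L <- nchar(target)

  # per-alignment insertion runs: junction j in 0..L means "after target pos j"
  per <- lapply(seq_len(n), function(i) {
    t <- ts[[i]]
    g <- t == "-"
    tpos <- cumsum(!g)
    junc <- tpos[g]                      # one junction per gap cell
    off <- if (any(g)) sequence(rle(junc)$lengths) else integer()
    list(g = g, tpos = tpos, junc = junc, off = off)
  })
  maxins <- integer(L + 1L)              # index j+1 = junction j
  for (p in per) if (length(p$junc)) {
    tb <- tapply(p$off, p$junc, max)
    j <- as.integer(names(tb)) + 1L
    maxins[j] <- pmax(maxins[j], as.integer(tb))
  }
  cs <- cumsum(maxins)                   # cs[p] = ins cols at junctions 0..p-1
  cs0 <- c(0L, cs)
  target_col <- seq_len(L) + cs[seq_len(L)]
  ncol <- L + cs[L + 1L]

  mat <- matrix("-", nrow = n, ncol = ncol)
  bidx <- matrix(NA_integer_, nrow = n, ncol = ncol)
  for (i in seq_len(n)) {
    p <- per[[i]]
    q <- qs[[i]]
    qpos <- cumsum(q != "-")
    cols <- integer(length(q))
    cols[!p$g] <- target_col[p$tpos[!p$g]]
    if (length(p$junc))
      cols[p$g] <- p$junc + cs0[p$junc + 1L] + p$off
    mat[i, cols] <- q
    nb <- q != "-"
    bidx[i, cols[nb]] <- qpos[nb]
  }
  trow <- rep("-", ncol)
  trow[target_col] <- strsplit(target, "", fixed = TRUE)[[1L]]

  ref_row <- if (is.null(reference)) NA_integer_ else n
  w <- rep(1, n)
  if (!is.null(weights)) {
    if (length(weights) != n - !is.na(ref_row))
      stop("weights length must match the number of read alignments")
    w[seq_along(weights)] <- weights
  }
  if (!is.na(ref_row)) w[ref_row] <- 0
  if (is.null(row_ids)) row_ids <- as.character(seq_len(n))
  structure(list(mat = mat, base_index = bidx, target = target,
                 target_row = trow,
                 is_target_col = seq_len(ncol) %in% target_col,
                 weights = w, ref_row = ref_row, row_ids = row_ids),
            class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat(sprintf("multi_alignment: %d rows x %d columns (target %d nt%s)\n",
              nrow(x$mat), ncol(x$mat), nchar(x$target),
              if (!is.na(x$ref_row)) ", with reference row" else ""))
  invisible(x)
}

#' Column-wise consensus of a multi-alignment matrix
#'
#' The consensus character of a column is its most frequent character,
#' counting the gap character and weighting rows by their multiplicities. A
#' column whose most frequent character is not unique has an undefined
#' consensus: it is flagged in `tie` and never corrected; for bookkeeping the
#' lexicographically smallest of the tied characters is recorded. Columns
#' whose consensus is the gap character contribute nothing to the ungapped
#' consensus string.
#'
#' @param A a [multi_alignment()] object.
#' @return A list of class `"ma_consensus"` with `chars` (per-column
#'   consensus character), `tie` (logical), `counts` (5 x ncol weighted
#'   character counts), and `sequence` (the ungapped consensus string).
#' @export
ma_consensus <- function(A) {
  stopifnot(inherits(A, "multi_alignment"))
  syms <- c("A", "C", "G", "T", "-")
  counts <- matrix(0, nrow = 5L, ncol = ncol(A$mat), dimnames = list(syms, NULL))
  for (k in seq_along(syms))
    counts[k, ] <- colSums((A$mat == syms[k]) * A$weights)
  top <- apply(counts, 2L, max)
  tie <- colSums(counts == rep(top, each = 5L)) > 1L
  chars <- syms[apply(counts, 2L, which.max)]  # ties: first = lexicographic (A<C<G<T<-)
  structure(list(chars = chars, tie = tie, counts = counts,
                 sequence = paste(chars[chars != "-"], collapse = "")),
            class = "ma_consensus")
}

#' Cell states and state-specific support of a multi-alignment matrix
#'
#' Classifies every cell with respect to the column consensus: a cell is a
#' `match` if it equals the consensus character of its column, an `insertion`
#' if it is a base where the consensus is a gap, a `deletion` if it is a gap
#' where the consensus is a base, and a `substitution` otherwise. The support
#' of a cell in state t and column j is n_j^t / n^t, where n_j^t counts cells
#' of state t in column j and n^t counts cells of state t in the whole matrix
#' (rows weighted by multiplicity; the reference row, if any, is excluded).
#' State-specific support makes the correction step more conservative for
#' frequent error types: indels, which dominate CCS errors, need more column
#' support than substitutions to survive.
#'
#' @param A a [multi_alignment()] object.
#' @param cons a [ma_consensus()] object (computed from `A` if omitted).
#' @return A list of class `"ma_states"` with `states` (integer matrix; 1 =
#'   match, 2 = substitution, 3 = insertion, 4 = deletion), `support`
#'   (numeric matrix of per-cell supports), `column_state_counts` (4 x ncol),
#'   and `total_state_counts` (length 4).
#' @export
ma_annotate <- function(A, cons = ma_consensus(A)) {
  stopifnot(inherits(A, "multi_alignment"))
  m <- A$mat
  nr <- nrow(m); nc <- ncol(m)
  consm <- matrix(cons$chars, nrow = nr, ncol = nc, byrow = TRUE)
  states <- matrix(2L, nrow = nr, ncol = nc)   # default: substitution
  states[m == consm] <- 1L                     # match
  states[m != consm & consm == "-"] <- 3L      # insertion
  states[m == "-" & consm != "-"] <- 4L        # deletion
  csc <- matrix(0, nrow = 4L, ncol = nc,
                dimnames = list(c("match", "substitution", "insertion",
                                  "deletion"), NULL))
  for (t in 1:4) csc[t, ] <- colSums((states == t) * A$weights)
  tot <- rowSums(csc)
  support <- matrix(0, nrow = nr, ncol = nc)
  for (t in 1:4) {
    if (tot[t] == 0) next
    sel <- states == t
    support[sel] <- (rep(csc[t, ], each = nr) / tot[t])[sel]
  }
  structure(list(states = states, support = support,
                 column_state_counts = csc, total_state_counts = tot),
            class = "ma_states")
}
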