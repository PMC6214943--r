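#' One round of partial error correction within a cluster
#'
#' Aligns every member string to the cluster center, builds the
#' multi-alignment matrix, and partially corrects each member: the member's
#' variant cells (cells whose state is substitution, insertion, or deletion
#' with respect to the column consensus) are ranked by support, and only the
#' ceiling(k/2) cells of lowest support (k = number of variant cells in that
#' member) are corrected to the most frequent character of their column - and
#' only where that character is unique; ties leave the cell untouched.
#' Correcting only half of the variant positions, and never at tied columns,
#' is what keeps genuine variants shared by half the cluster from being
#' erased.
#'
#' Support ties among a member's variant cells are broken by ascending column
#' index.
#'
#' @param members character vector of working strings (the cluster).
#' @param center the center string; must be one of `members`.
#' @param scoring an [align_scoring()] object used for the row alignments.
#' @return Character vector of corrected strings, parallel to `members`.
#' @export
correct_cluster_once <- function(members, center, scoring = align_scoring()) {
  if (length(members) < 1L) stop("empty cluster")
  if (!center %in% members) stop("center must be a member of the cluster")
  u <- unique(members)
  f <- match(members, u)
  wt <- tabulate(f, length(u))
  corrected_u <- .correct_unique(u, wt, center, scoring)
  corrected_u[f]
}

# Correction at the level of unique strings (weights = multiplicities).
.correct_unique <- function(u, wt, center, scoring) {
  if (length(u) == 1L) return(u)
  al <- align_to_target(u, center, scoring)
  A <- multi_alignment(al, weights = wt)
  cons <- ma_consensus(A)
  st <- ma_annotate(A, cons)
  out <- character(length(u))
  for (i in seq_along(u)) {
    row <- A$mat[i, ]
    vc <- which(st$states[i, ] != 1L)
    if (length(vc)) {
      k <- ceiling(length(vc) / 2)
      sel <- vc[order(st$support[i, vc], vc)][seq_len(k)]
      sel <- sel[!cons$tie[sel]]      # no unique majority -> no correction
      row[sel] <- cons$chars[sel]
    }
    out[i] <- paste(row[row != "-"], collapse = "")
  }
  out
}

#' Iterative clustering and error correction of CCS reads
#'
#' The correction loop: partition the working strings into center-anchored
#' clusters ([partition_strings()]), partially correct every non-converged
#' cluster toward its consensus ([correct_cluster_once()]), and repeat until
#' every cluster has converged (all its strings identical). Three safeguards
#' bound the loop:
#'
#' * a member's correction is undone if it increased the member's edit
#'   distance to its center relative to the previous round;
#' * if the multiset of working strings returns to a state already seen, the
#'   loop is in a cycle and stops;
#' * if a full round changes nothing (corrections blocked by majority ties),
#'   the loop has stalled and stops.
#'
#' The centers of the final clusters, deduplicated by sequence, are the
#' candidate transcripts handed to the statistical filtering stage.
#'
#' @param reads a [ccs_reads] object (or character vector of sequences).
#' @param max_rounds safety cap on partition/correction rounds; if reached,
#'   a warning is issued and the current centers are returned.
#' @param scoring an [align_scoring()] object.
#' @param trace if `TRUE`, log a per-round summary to stderr.
#' @return A list of class `"cluster_correct"` with `candidates` (data frame
#'   `candidate_id`, `sequence`, `source_cluster_size`), `final_strings`
#'   (named per-read working strings), `rounds`, `converged` (logical: all
#'   clusters converged, as opposed to stopping on a cycle/stall), and
#'   `partition` (the final [partition_strings()] result).
#' @export
cluster_correct <- function(reads, max_rounds = 20L, scoring = align_scoring(),
                            trace = FALSE) {
  if (is.character(reads)) reads <- ccs_reads(paste0("r", seq_along(reads)),
                                              reads,
                                              lapply(nchar(reads), function(n) rep(30L, n)))
  stopifnot(inherits(reads, "ccs_reads"))
  ids <- reads$id
  cur <- reads$seq
  n <- length(cur)
  prev_cdist <- rep(Inf, n)
  names(prev_cdist) <- ids
  seen <- character()
  rounds <- 0L
  status <- "converged"
  repeat {
    part <- partition_strings(cur, ids)
    conv <- vapply(part, function(cl) {
      length(unique(cur[match(cl$members, ids)])) == 1L
    }, NA)
    if (all(conv)) break
    if (rounds >= max_rounds) {
      status <- "max_rounds"
      warning(sprintf("correction stopped after %d rounds without full convergence",
                      max_rounds))
      break
    }
    key <- paste(sort(cur), collapse = "\r")
    if (key %in% seen) { status <- "cycle"; break }
    seen <- c(seen, key)
    rounds <- rounds + 1L
    changed <- FALSE
    for (ci in which(!conv)) {
      cl <- part[[ci]]
      mem <- match(cl$members, ids)
      center <- cl$center_seq
      old <- cur[mem]
      new <- correct_cluster_once(old, center, scoring)
      newd <- c_edit_distance(center, new)
      undo <- newd > prev_cdist[mem]
      new[undo] <- old[undo]
      newd[undo] <- c_edit_distance(center, old[undo])
      if (any(new != old)) changed <- TRUE
      cur[mem] <- new
      prev_cdist[mem] <- newd
    }
    if (trace)
      message(sprintf("round %d: %d clusters, %d converged, strings changed: %s",
                      rounds, length(part), sum(conv), changed))
    if (!changed) { status <- "stalled"; break }
  }
  centers <- vapply(part, `[[`, "", "center_seq")
  sizes <- vapply(part, function(cl) length(cl$members), 0L)
  keep <- !duplicated(centers)
  cand <- data.frame(candidate_id = paste0("cand_", seq_len(sum(keep))),
                     sequence = centers[keep],
                     source_cluster_size =
                       as.integer(tapply(sizes, centers, sum)[centers[keep]]),
                     stringsAsFactors = FALSE)
  names(cur) <- ids
  structure(list(candidates = cand, final_strings = cur, rounds = rounds,
                 converged = status == "converged", status = status,
                 partition = part),
            class = "cluster_correct")
}

#' @export
print.cluster_correct <- function(x, ...) {
  cat(sprintf("cluster_correct: %d candidate transcripts from %d reads (%d rounds, %s)\n",
              nrow(x$candidates), length(x$final_strings), x$rounds, x$status))
  invisible(x)
}
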