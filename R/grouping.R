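#' Are two transcripts isoform-compatible (indels only)?
#'
#' Two transcripts of the same gene copy differ only by exon
#' presence/absence: their optimal alignment contains large insertions or
#' deletions (missing exons) but no substitutions. This predicate aligns the
#' pair with mismatches penalized so heavily (-1000) that any
#' substitution-free co-linear alignment dominates, and with gap opens
#' expensive relative to extensions so that indels consolidate into few long
#' runs instead of fragmenting around chance character identities. It then
#' requires the alignment to have no mismatched column, no gap run shorter
#' than `min_indel_length` (end gaps included), and at least
#' `min_indel_length` matched columns - isoforms of one copy share exons, so
#' a pair aligned only by skipping each other entirely is not compatible.
#' Identical sequences are vacuously compatible.
#'
#' @param u,v transcript sequences (non-empty).
#' @param min_indel_length minimum length of any indel run, in nt; the
#'   default 20 is far below any real exon but well above sequencing-error
#'   indels.
#' @return `TRUE` or `FALSE`.
#' @export
indel_only_compatible <- function(u, v, min_indel_length = 20L) {
  stopifnot(nchar(u) > 0L, nchar(v) > 0L)
  if (u == v) return(TRUE)
  al <- align_pair(u, v, align_scoring(match = 1L, mismatch = -1000L,
                                       gap_open = -50L, gap_extend = 0L))
  q <- strsplit(al$query_row, "", fixed = TRUE)[[1L]]
  t <- strsplit(al$target_row, "", fixed = TRUE)[[1L]]
  aligned <- q != "-" & t != "-"
  if (any(aligned & q != t)) return(FALSE)
  if (sum(aligned) < min_indel_length) return(FALSE)
  gap <- !aligned
  if (!any(gap)) return(TRUE)   # cannot happen for u != v, kept for safety
  runs <- rle(gap)
  all(runs$lengths[runs$values] >= min_indel_length)
}

#' Group transcripts into putative gene copies
#'
#' Builds the compatibility graph (vertices = transcripts, edges = pairs
#' that differ only by large indels, per [indel_only_compatible()]), takes
#' its maximal cliques as the groups, and finds by exhaustive search the
#' minimum number of maximal cliques whose union covers all transcripts.
#' That minimum is the best estimate of the number of gene copies in the
#' family. A transcript can belong to several groups - this happens when an
#' exon carrying the variant that separates two copies is skipped, so the
#' transcript cannot be attributed to either copy.
#'
#' Ties between covers of minimal size are broken by preferring covers made
#' of larger cliques, then by the lexicographic order of member ids.
#'
#' @param transcripts named character vector of transcript sequences (or a
#'   transcripts data frame, or an [isoresolve] fit). At most 64 transcripts
#'   (exhaustive search guard).
#' @param min_indel_length see [indel_only_compatible()].
#' @return A list of class `"group_cover"` with `n_groups`, `groups` (list
#'   of transcript-id vectors: the cliques of one minimum cover),
#'   `all_cliques` (every maximal clique), `membership` (data frame
#'   `transcript_id`, `group`), and `min_indel_length`.
#' @export
minimum_group_cover <- function(transcripts, min_indel_length = 20L) {
  if (inherits(transcripts, "isoresolve")) transcripts <- transcripts$transcripts
  if (is.data.frame(transcripts)) {
    seqs <- transcripts$sequence
    names(seqs) <- transcripts$transcript_id
    transcripts <- seqs
  }
  n <- length(transcripts)
  if (n == 0L)
    return(structure(list(n_groups = 0L, groups = list(),
                          all_cliques = list(),
                          membership = data.frame(transcript_id = character(),
                                                  group = integer()),
                          min_indel_length = min_indel_length),
                     class = "group_cover"))
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("t%d", seq_len(n))
  if (n > 64L)
    stop("more than 64 transcripts; exhaustive group search is guarded - ",
         "split the input or raise the guard deliberately")
  ids <- names(transcripts)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    adj[i, j] <- adj[j, i] <-
      indel_only_compatible(transcripts[i], transcripts[j], min_indel_length)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- lapply(igraph::max_cliques(g), function(v) sort(as.integer(v)))
  cliques <- cliques[order(-lengths(cliques),
                           vapply(cliques, function(cl)
                             paste(ids[cl], collapse = ","), ""))]
  k <- length(cliques)
  masks <- lapply(cliques, function(cl) seq_len(n) %in% cl)
  best <- NULL
  for (size in seq_len(k)) {
    combos <- utils::combn(k, size, simplify = FALSE)
    covering <- Filter(function(cb)
      all(Reduce(`|`, masks[cb])), combos)
    if (length(covering)) {
      # cliques are pre-sorted large-first then lexicographic, so the first
      # covering combination in combn order realizes the tie-break
      best <- covering[[1L]]
      break
    }
  }
  groups <- lapply(cliques[best], function(cl) ids[cl])
  membership <- do.call(rbind, lapply(seq_along(groups), function(gi)
    data.frame(transcript_id = groups[[gi]], group = gi,
               stringsAsFactors = FALSE)))
  structure(list(n_groups = length(best), groups = groups,
                 all_cliques = lapply(cliques, function(cl) ids[cl]),
                 membership = membership,
                 min_indel_length = min_indel_length),
            class = "group_cover")
}

#' @export
print.group_cover <- function(x, ...) {
  cat(sprintf("group_cover: %d group(s) over %d transcript(s) (min indel %d nt)\n",
              x$n_groups, length(unique(x$membership$transcript_id)),
              x$min_indel_length))
  invisible(x)
}
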