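#' Nearest-neighbor graph of a multiset of strings
#'
#' Directed graph on the strings: an edge runs from x to y (y != x) exactly
#' when y is at minimal edit distance from x among all other strings.
#' Identical duplicate strings are distinct vertices at distance 0, so every
#' duplicated string points to (all of) its twins and nothing else.
#'
#' @param strings character vector of sequences (a multiset; duplicates kept).
#' @param ids optional character ids, one per string.
#' @return A list of class `"nn_graph"` with `ids`, `strings`, `edges` (data
#'   frame `from`, `to`, `dist`) and `min_distance` (per-vertex distance to
#'   its closest neighbors; `NA` for a singleton input).
#' @export
nearest_neighbor_graph <- function(strings, ids = NULL) {
  n <- length(strings)
  if (n < 1L) stop("need at least one string")
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  meta <- .collapse_strings(strings, ids)
  from <- to <- character(0)
  dist <- integer(0)
  mind <- rep(NA_integer_, n)
  names(mind) <- ids
  for (ui in seq_along(meta$u)) {
    members <- meta$members[[ui]]
    if (length(members) > 1L) {
      # duplicates: closest neighbor is a twin at distance 0
      for (v in members) {
        tw <- setdiff(members, v)
        from <- c(from, rep(ids[v], length(tw)))
        to <- c(to, ids[tw])
        dist <- c(dist, rep(0L, length(tw)))
      }
      mind[members] <- 0L
    } else if (length(meta$u) > 1L) {
      d <- meta$D[ui, -ui]
      md <- min(d)
      tgt <- setdiff(which(meta$D[ui, ] == md), ui)
      tgt_reads <- unlist(meta$members[tgt], use.names = FALSE)
      from <- c(from, rep(ids[members], length(tgt_reads)))
      to <- c(to, ids[tgt_reads])
      dist <- c(dist, rep(md, length(tgt_reads)))
      mind[members] <- md
    }
  }
  structure(list(ids = ids, strings = strings,
                 edges = data.frame(from = from, to = to, dist = dist,
                                    stringsAsFactors = FALSE),
                 min_distance = mind),
            class = "nn_graph")
}

# Collapse a multiset to unique strings with multiplicities; pairwise
# distances among unique strings are only needed where a singleton is
# involved (a duplicated string's nearest neighbor is its twin).
.collapse_strings <- function(strings, ids, need_all = FALSE) {
  u <- unique(strings)
  f <- match(strings, u)
  members <- split(seq_along(strings), f)   # names "1".."k"
  members <- members[order(as.integer(names(members)))]
  wt <- lengths(members)
  D <- NULL
  if (length(u) > 1L) D <- c_pairwise_distances(u)
  list(u = u, f = f, members = members, wt = wt, D = D)
}

#' Partition strings into center-anchored clusters
#'
#' Iterative partitioning on the nearest-neighbor graph: repeatedly pick the
#' vertex that the largest number of vertices can reach (by directed paths),
#' cut out the cluster of all vertices that reach it (the picked vertex is
#' the cluster center), remove it from the graph, and repeat on the residual
#' graph. The resulting clusters partition the input, and each string has at
#' least one of its closest neighbors (from the round in which it was still
#' present) inside its cluster.
#'
#' Ties for the maximal reachability count are broken in favor of the vertex
#' whose string is most abundant in the multiset, then by the
#' lexicographically smallest read id, which makes the partition
#' deterministic.
#'
#' @inheritParams nearest_neighbor_graph
#' @return A list of clusters, each a list with `center` (read id),
#'   `center_seq`, and `members` (read ids, center included).
#' @export
partition_strings <- function(strings, ids = NULL) {
  n <- length(strings)
  if (n < 1L) stop("need at least one string")
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  meta <- .collapse_strings(strings, ids)
  k <- length(meta$u)
  rep_id <- unname(vapply(meta$members, function(m) min(ids[m]), ""))
  if (k == 1L)
    return(list(list(center = rep_id[1L], center_seq = meta$u[1L],
                     members = ids)))
  # meta-level NN edges: only singleton strings point at other vertices
  el <- NULL
  for (ui in seq_len(k)) {
    if (meta$wt[ui] > 1L) next
    d <- meta$D[ui, -ui]
    md <- min(d)
    tgt <- setdiff(which(meta$D[ui, ] == md), ui)
    el <- rbind(el, cbind(ui, tgt))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(el)) matrix(integer(), ncol = 2L) else el, directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
  igraph::V(g)$orig <- seq_len(k)

  clusters <- list()
  wt <- meta$wt
  repeat {
    nv <- igraph::vcount(g)
    if (nv == 0L) break
    orig <- igraph::V(g)$orig
    reach <- vapply(seq_len(nv), function(v) {
      anc <- as.integer(igraph::subcomponent(g, v, mode = "in"))
      sum(wt[orig[anc]])
    }, 0)
    best <- which(reach == max(reach))
    if (length(best) > 1L) {
      bw <- wt[orig[best]]
      best <- best[bw == max(bw)]
      if (length(best) > 1L)
        best <- best[order(rep_id[orig[best]])][1L]
    }
    best <- best[1L]
    anc <- as.integer(igraph::subcomponent(g, best, mode = "in"))
    mem_u <- orig[anc]
    members <- ids[sort(unlist(meta$members[mem_u], use.names = FALSE))]
    clusters[[length(clusters) + 1L]] <-
      list(center = rep_id[orig[best]],
           center_seq = meta$u[orig[best]],
           members = members)
    g <- igraph::delete_vertices(g, anc)
  }
  clusters
}
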