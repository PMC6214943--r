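# Independent oracles used to cross-check the implementation.

# Quadratic dynamic-programming Levenshtein distance, written independently
# of the package's bit-parallel kernel.
dp_edit_distance <- function(a, b) {
  m <- nchar(a); n <- nchar(b)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (av[i] != bv[j]))
    }
    prev <- cur
  }
  prev[n + 1L]
}

# Brute-force transitive closure (Floyd-Warshall on booleans).
closure_oracle <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) for (i in seq_len(n)) if (reach[i, k])
    reach[i, ] <- reach[i, ] | reach[k, ]
  reach
}

# Independent re-implementation of the partitioning rule at the read level:
# full distance matrix (via dp oracle through adist), nearest-neighbor edge
# set, reachability by transitive closure, greedy extraction with the same
# tie-break (string multiplicity, then smallest id).
partition_oracle <- function(strings, ids = paste0("s", seq_along(strings))) {
  n <- length(strings)
  if (n == 1L) return(list(list(center = ids, members = ids)))
  D <- adist(strings)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    adj[i, which(D[i, ] == min(d))] <- TRUE
    adj[i, i] <- FALSE
  }
  mult <- table(strings)
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    idx <- which(alive)
    reach <- closure_oracle(adj[idx, idx, drop = FALSE])
    cnt <- colSums(reach)
    best <- which(cnt == max(cnt))
    if (length(best) > 1L) {
      w <- as.integer(mult[strings[idx[best]]])
      best <- best[w == max(w)]
      if (length(best) > 1L) best <- best[order(ids[idx[best]])][1L]
    }
    best <- best[1L]
    mem <- idx[reach[, best]]
    clusters[[length(clusters) + 1L]] <-
      list(center = min(ids[idx[best]]), members = sort(ids[mem]))
    alive[mem] <- FALSE
  }
  clusters
}

# Exhaustive minimum cover of vertices by maximal cliques: enumerate all
# subsets of the maximal-clique list (bitmask over at most ~15 cliques).
cover_oracle <- function(adj) {
  n <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- lapply(igraph::max_cliques(g), as.integer)
  k <- length(cl)
  best <- Inf
  for (mask in seq_len(2^k) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    if (length(sel) >= best) next
    if (length(unique(unlist(cl[sel]))) == n) best <- length(sel)
  }
  best
}

# Random DNA string helper.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Reads at a constant Phred score.
flat_reads <- function(seqs, q = 30L, ids = paste0("r", seq_along(seqs))) {
  ccs_reads(ids, seqs, lapply(nchar(seqs), function(n) rep(as.integer(q), n)))
}

# Monte-Carlo estimate of P(T' >= t') for a support profile: draw
# independent Bernoulli(p_i) supports and compare the weighted log support.
mc_tail_probability <- function(log_p, t_prime, n_draws = 1e6) {
  p <- exp(log_p)
  n <- length(p)
  M <- max(-log_p)
  draws <- matrix(runif(n * n_draws) < p, nrow = n)
  tp <- colSums(draws * (-log_p)) / M
  mean(tp >= t_prime - 1e-12)
}
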