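# Fast path for the candidate significance test.
#
# The multi-alignment matrix is anchored on the target's positions, and
# insertion columns at a junction are shared left-aligned, so any row's
# characters at the variant columns can be read off that row's own pairwise
# alignment to the target without materializing the matrix. This lets
# test_round() cache one preprocessed alignment per (read string, target
# candidate) pair and reuse it across filtering rounds; the result is
# numerically identical to the matrix route in candidate_pair_pvalue()
# (asserted in the test suite).

# Preprocess a gapped query/target alignment pair for per-position lookups.
.prep_row <- function(q_row, t_row) {
  qs <- strsplit(q_row, "", fixed = TRUE)[[1L]]
  ts <- strsplit(t_row, "", fixed = TRUE)[[1L]]
  nong <- ts != "-"
  tpos <- cumsum(nong)
  qpos <- cumsum(qs != "-")
  rowchar_t <- qs[nong]                     # query char over target positions
  bidx_t <- ifelse(rowchar_t == "-", NA_integer_, qpos[nong])
  left_t <- qpos[nong]                      # read bases consumed through pos p
  ins_chars <- list(); ins_bidx <- list()
  if (any(!nong)) {
    g <- which(!nong)
    j <- tpos[g]                            # junction (0 = before target pos 1)
    ins_chars <- split(qs[g], j)
    ins_bidx <- split(qpos[g], j)
  }
  # aligned span of the query in junction-aware coordinates: target
  # position p has key 2p, insertion junction j has key 2j + 1, so column
  # order in the multi-alignment matrix is preserved
  nz <- which(qs != "-")
  key_of <- function(i) 2L * tpos[i] + as.integer(!nong[i])
  list(rowchar_t = rowchar_t, bidx_t = bidx_t, left_t = left_t,
       ins_chars = ins_chars, ins_bidx = ins_bidx,
       first_key = if (length(nz)) key_of(nz[1L]) else 0L,
       last_key = if (length(nz)) key_of(nz[length(nz)]) else -1L,
       n_bases = if (length(qs)) qpos[length(qpos)] else 0L)
}

# Variant-position spec of candidate c against target d, from c's alignment:
# one entry per disagreeing target position (substitution/deletion) and per
# inserted base of c (insertion), with the character c carries there.
.vspec_from_prep <- function(prep_c, d_chars) {
  kind <- character(); tpos <- integer(); junction <- integer()
  offset <- integer(); char <- character()
  mism <- which(prep_c$rowchar_t != d_chars)
  for (p in mism) {
    ch <- prep_c$rowchar_t[p]
    kind <- c(kind, if (ch == "-") "deletion" else "substitution")
    tpos <- c(tpos, p); junction <- c(junction, NA_integer_)
    offset <- c(offset, NA_integer_); char <- c(char, ch)
  }
  for (jc in names(prep_c$ins_chars)) {
    chs <- prep_c$ins_chars[[jc]]
    for (o in seq_along(chs)) {
      kind <- c(kind, "insertion")
      tpos <- c(tpos, NA_integer_); junction <- c(junction, as.integer(jc))
      offset <- c(offset, o); char <- c(char, chs[o])
    }
  }
  list(kind = kind, tpos = tpos, junction = junction, offset = offset,
       char = char, n = length(kind))
}

# Support indicator and log error probability of one read for a vspec.
.eval_read_fast <- function(prep, qual, vs, params) {
  n <- vs$n
  chars <- character(n)
  q <- numeric(n)
  covered <- logical(n)
  for (k in seq_len(n)) {
    if (vs$kind[k] != "insertion") {
      p <- vs$tpos[k]
      ch <- prep$rowchar_t[p]
      if (ch != "-") {
        qv <- qual[prep$bidx_t[p]]
      } else {
        lb <- prep$left_t[p]
        rb <- lb + 1L
        cand <- c(if (lb >= 1L) qual[lb], if (rb <= prep$n_bases) qual[rb])
        qv <- if (length(cand)) min(cand) else 0
      }
      covered[k] <- 2L * p >= prep$first_key && 2L * p <= prep$last_key
    } else {
      j <- vs$junction[k]; o <- vs$offset[k]
      jc <- as.character(j)
      ins <- prep$ins_chars[[jc]]
      len <- length(ins)
      if (o <= len) {
        ch <- ins[o]
        qv <- qual[prep$ins_bidx[[jc]][o]]
      } else {
        ch <- "-"
        lb <- (if (j >= 1L) prep$left_t[j] else 0L) + len
        rb <- lb + 1L
        cand <- c(if (lb >= 1L) qual[lb], if (rb <= prep$n_bases) qual[rb])
        qv <- if (length(cand)) min(cand) else 0
      }
      covered[k] <- 2L * j + 1L >= prep$first_key &&
                    2L * j + 1L <= prep$last_key
    }
    chars[k] <- ch
    q[k] <- qv
  }
  p <- 10^(-q / 10)
  if (params$p_convention == "specific") {
    sub <- vs$kind == "substitution"
    p[sub] <- p[sub] / 3
  }
  p <- pmin(pmax(p, params$p_floor), params$p_cap)
  list(s = as.integer(all(covered) && all(chars == vs$char)),
       log_p = sum(log(p)))
}

# Fetch (or compute and cache) preprocessed alignments of `strings` to the
# target candidate `d_id`/`d_seq`. `cache` is an environment or NULL.
.prep_aligned <- function(strings, d_id, d_seq, scoring, cache = NULL) {
  sub <- NULL
  if (!is.null(cache)) {
    if (is.null(cache[[d_id]])) cache[[d_id]] <- new.env(parent = emptyenv())
    sub <- cache[[d_id]]
  }
  out <- vector("list", length(strings))
  need <- logical(length(strings))
  for (i in seq_along(strings)) {
    hit <- if (!is.null(sub)) sub[[strings[i]]] else NULL
    if (is.null(hit)) need[i] <- TRUE else out[[i]] <- hit
  }
  if (any(need)) {
    al <- align_to_target(strings[need], d_seq, scoring)
    preps <- lapply(al, function(a) .prep_row(a$query_row, a$target_row))
    out[need] <- preps
    if (!is.null(sub)) for (k in seq_along(preps))
      assign(strings[need][k], preps[[k]], envir = sub)
  }
  out
}

# Fast equivalent of candidate_pair_pvalue(); same contract and result.
.fast_pair_pvalue <- function(c_seq, d_seq, reads, params, scoring,
                              cache = NULL, d_id = d_seq) {
  u <- unique(reads$seq)
  f <- match(reads$seq, u)
  preps <- .prep_aligned(c(u, c_seq), d_id, d_seq, scoring, cache)
  prep_c <- preps[[length(preps)]]
  d_chars <- strsplit(d_seq, "", fixed = TRUE)[[1L]]
  vs <- .vspec_from_prep(prep_c, d_chars)
  if (vs$n > params$max_variants) {
    return(structure(list(t = NA_real_, log_t = NA_real_, t_prime = NA_real_,
                          mu = NA_real_, delta = NA_real_, p_value = 0,
                          skipped = TRUE, n_variants = vs$n),
                     class = "test_result"))
  }
  n <- length(reads$id)
  s <- integer(n); log_p <- numeric(n)
  for (i in seq_len(n)) {
    ev <- .eval_read_fast(preps[[f[i]]], reads$qual[[i]], vs, params)
    s[i] <- ev$s
    log_p[i] <- ev$log_p
  }
  prof <- structure(list(s = s, log_p = log_p, n = n),
                    class = "support_profile")
  res <- tail_bound(prof, params)
  res$n_variants <- vs$n
  res
}
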