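#' Built-in gene-family simulation profiles
#'
#' Three profiles spanning the spectrum of length, exon number and CCS error
#' rate characteristic of Y-chromosome ampliconic gene families: a short
#' 914 nt / 6 exon family sequenced at 0.5% error ("TSPY"-like), a mid-size
#' 2668 nt / 6 exon family at 2.6% ("HSFY"-like), and a long, exon-rich
#' 5904 nt / 28 exon family at 6.1% ("DAZ"-like). Longer transcripts get
#' fewer polymerase passes, hence the higher error rates.
#'
#' @param name one of `"TSPY"`, `"HSFY"`, `"DAZ"`.
#' @return A list with `name`, `exon_lengths`, `error_rate`, and
#'   `median_passes`.
#' @export
family_profile <- function(name = c("TSPY", "HSFY", "DAZ")) {
  name <- match.arg(name)
  switch(name,
    TSPY = list(name = "TSPY", exon_lengths = c(153L, 152L, 152L, 152L, 152L, 153L),
                error_rate = 0.005, median_passes = 18),
    HSFY = list(name = "HSFY", exon_lengths = c(445L, 445L, 445L, 445L, 444L, 444L),
                error_rate = 0.026, median_passes = 16),
    DAZ  = list(name = "DAZ", exon_lengths = c(rep(211L, 24L), rep(210L, 4L)),
                error_rate = 0.061, median_passes = 2))
}

#' Random root gene as a list of exon sequences
#'
#' @param exon_lengths integer vector of exon lengths (or a
#'   [family_profile()]).
#' @param seed integer seed; the caller's RNG state is restored.
#' @return Character vector of exon sequences.
#' @export
make_root_exons <- function(exon_lengths, seed = NULL) {
  if (is.list(exon_lengths)) exon_lengths <- exon_lengths$exon_lengths
  with_seed(seed, vapply(exon_lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""))
}

#' Simulate duplicate gene copies from a root gene
#'
#' Copy 1 is the root itself; each subsequent copy is derived from a
#' uniformly chosen earlier copy by independent per-base substitutions at
#' `mutation_rate`, emulating the duplication history of an ampliconic gene
#' family. (Only substitution mutation is modeled; gene conversion and other
#' processes shaping real duplicate copies are not.)
#'
#' @param root_exons character vector of exon sequences.
#' @param n_copies number of copies (>= 1).
#' @param mutation_rate per-base substitution probability in \[0, 0.1\].
#' @param seed integer seed; the caller's RNG state is restored.
#' @return A list of length `n_copies`, each a character vector of exon
#'   sequences.
#' @export
simulate_copies <- function(root_exons, n_copies, mutation_rate, seed = NULL) {
  stopifnot(n_copies >= 1, mutation_rate >= 0, mutation_rate <= 0.1)
  with_seed(seed, {
    copies <- vector("list", n_copies)
    copies[[1L]] <- root_exons
    if (n_copies > 1L) for (i in 2:n_copies) {
      src <- copies[[sample.int(i - 1L, 1L)]]
      copies[[i]] <- vapply(src, .mutate_seq, "", rate = mutation_rate,
                            USE.NAMES = FALSE)
    }
    copies
  })
}

.mutate_seq <- function(seq, rate) {
  if (rate == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(bases, b), 1L), "", USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

#' Default exon-skipping isoform patterns
#'
#' The full-inclusion pattern plus one single-internal-exon skip per internal
#' exon, the dominant isoform structure of targeted multigene-family data.
#'
#' @param n_exons number of exons.
#' @param n_patterns optionally truncate to the first `n_patterns` patterns.
#' @return A list of logical inclusion vectors.
#' @export
default_isoform_patterns <- function(n_exons, n_patterns = NULL) {
  pats <- list(rep(TRUE, n_exons))
  if (n_exons > 2L) for (e in 2:(n_exons - 1L)) {
    p <- rep(TRUE, n_exons); p[e] <- FALSE
    pats[[length(pats) + 1L]] <- p
  }
  if (!is.null(n_patterns)) pats <- pats[seq_len(min(n_patterns, length(pats)))]
  pats
}

#' Simulate isoforms and assemble the truth set
#'
#' Applies each exon-inclusion pattern to each gene copy: a transcript is the
#' concatenation of the included exons of its copy. Transcripts with
#' identical sequences (copies identical over the included exons) are
#' collapsed into one truth entry, with their abundances summed. Absolute
#' abundances are assigned by a seeded shuffle of `abundance_values` across
#' the (copy, pattern) combinations.
#'
#' @param copies list of copies from [simulate_copies()].
#' @param patterns list of logical (or index) exon-inclusion vectors; every
#'   pattern must include at least one exon.
#' @param abundance_values abundances for the copy-pattern combinations:
#'   either a vector recycled/sampled to the number of combinations, or
#'   `NULL` to draw from \{2^i, i = 1..8\}.
#' @param seed integer seed; the caller's RNG state is restored.
#' @return A data frame (`transcript_id`, `sequence`, `abundance`,
#'   `rel_abundance`) - the truth set skeleton.
#' @export
simulate_isoforms <- function(copies, patterns = NULL,
                              abundance_values = NULL, seed = NULL) {
  n_exons <- length(copies[[1L]])
  if (is.null(patterns)) patterns <- default_isoform_patterns(n_exons)
  patterns <- lapply(patterns, function(p) {
    if (is.logical(p)) which(p) else as.integer(p)
  })
  if (any(lengths(patterns) == 0L)) stop("every pattern must include an exon")
  if (any(unlist(patterns) > n_exons)) stop("pattern references a missing exon")
  combos <- expand.grid(copy = seq_along(copies),
                        pattern = seq_along(patterns))
  seqs <- vapply(seq_len(nrow(combos)), function(i) {
    cp <- copies[[combos$copy[i]]]
    paste(cp[patterns[[combos$pattern[i]]]], collapse = "")
  }, "")
  ab <- with_seed(seed, {
    if (is.null(abundance_values))
      sample(2^(1:8), length(seqs), replace = TRUE)
    else if (length(abundance_values) == length(seqs))
      abundance_values[sample.int(length(abundance_values))]
    else rep_len(abundance_values, length(seqs))
  })
  agg <- tapply(ab, factor(seqs, levels = unique(seqs)), sum)
  out <- data.frame(transcript_id = sprintf("truth_%d", seq_along(agg)),
                    sequence = names(agg),
                    abundance = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out$rel_abundance <- out$abundance / sum(out$abundance)
  rownames(out) <- NULL
  out
}

#' Simulate CCS reads from a truth set
#'
#' Draws read origins from the truth set's relative abundances and corrupts
#' each read with sequencing errors. Per-read variability in CCS quality
#' (fewer passes on longer templates give noisier reads) is modeled by a
#' lognormal multiplier on the per-base error rate (sdlog `sigma`, meanlog
#' `-sigma^2/2` so the mean rate is unbiased); errors are substitutions,
#' insertions and deletions in the ratio `error_mix`. Every base of a read is
#' emitted with the Phred score corresponding to the per-base error
#' probability actually used for that read, capped at `q_cap`.
#'
#' @param truth truth-set data frame from [simulate_isoforms()] (columns
#'   `transcript_id`, `sequence`, and `abundance` or `rel_abundance`).
#' @param n_reads total number of reads (>= 1).
#' @param error_rate mean per-base total error rate (e.g. 0.005, 0.026,
#'   0.061), or a [family_profile()].
#' @param seed integer seed; the caller's RNG state is restored.
#' @param error_mix substitution:insertion:deletion weights; default 1:1:1.
#' @param sigma sdlog of the per-read lognormal rate multiplier.
#' @param q_cap maximum emitted Phred score (used verbatim when
#'   `error_rate = 0`).
#' @param median_passes median of the cosmetic per-read pass-count draw.
#' @return A [ccs_reads] object with attribute `origins`: a data frame
#'   (`read_id`, `transcript_id`) recording each read's true origin.
#' @export
simulate_ccs_reads <- function(truth, n_reads, error_rate, seed = NULL,
                               error_mix = c(1, 1, 1), sigma = 0.5,
                               q_cap = 60L, median_passes = NULL) {
  stopifnot(n_reads >= 1)
  if (is.list(error_rate) && !is.null(error_rate$error_rate)) {
    median_passes <- median_passes %||% error_rate$median_passes
    error_rate <- error_rate$error_rate
  }
  rel <- truth$rel_abundance %||% (truth$abundance / sum(truth$abundance))
  with_seed(seed, {
    origin <- sample(nrow(truth), n_reads, replace = TRUE, prob = rel)
    rate_i <- if (error_rate > 0)
      pmin(error_rate * rlnorm(n_reads, meanlog = -sigma^2 / 2, sdlog = sigma), 0.4)
    else rep(0, n_reads)
    mix <- error_mix / sum(error_mix)
    ids <- sprintf("read_%d", seq_len(n_reads))
    seqs <- character(n_reads)
    quals <- vector("list", n_reads)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n_reads)) {
      tmpl <- strsplit(truth$sequence[origin[i]], "", fixed = TRUE)[[1L]]
      q <- if (rate_i[i] > 0) min(as.integer(round(-10 * log10(rate_i[i]))), q_cap)
           else q_cap
      pieces <- tmpl
      err <- which(runif(length(tmpl)) < rate_i[i])
      if (length(err)) {
        type <- sample(3L, length(err), replace = TRUE, prob = mix)
        sub <- err[type == 1L]
        if (length(sub))
          pieces[sub] <- vapply(tmpl[sub], function(b)
            sample(setdiff(bases, b), 1L), "", USE.NAMES = FALSE)
        ins <- err[type == 2L]
        if (length(ins))
          pieces[ins] <- paste0(pieces[ins],
                                sample(bases, length(ins), replace = TRUE))
        del <- err[type == 3L]
        if (length(del)) pieces[del] <- ""
      }
      seqs[i] <- paste(pieces, collapse = "")
      if (nchar(seqs[i]) == 0L) seqs[i] <- paste(sample(bases, 1L)) # degenerate
      quals[[i]] <- rep(q, nchar(seqs[i]))
    }
    passes <- if (!is.null(median_passes))
      pmax(1L, as.integer(round(rlnorm(n_reads, log(median_passes), 0.3))))
    else rep(NA_integer_, n_reads)
    reads <- ccs_reads(ids, seqs, quals, num_passes = passes)
    attr(reads, "origins") <- data.frame(
      read_id = ids, transcript_id = truth$transcript_id[origin],
      stringsAsFactors = FALSE)
    reads
  })
}

#' One-stop family simulation
#'
#' Generates a complete synthetic data set for one gene family: a random
#' root gene, duplicate copies, exon-skipping isoforms with assigned
#' abundances, and CCS-like reads, all reproducible under one seed.
#'
#' @param profile a profile name (see [family_profile()]) or profile list.
#' @param n_copies number of gene copies.
#' @param mutation_rate per-base substitution rate between copies.
#' @param patterns isoform patterns (`NULL` for the defaults;
#'   `"copies_only"` for one full-length transcript per copy).
#' @param abundance `"random"` (draw from \{2^i, i = 1..8\}) or `"equal"`.
#' @param depth mean per-transcript read depth; `n_reads` (total) overrides.
#' @param n_reads total number of reads.
#' @param error_rate per-base error rate (defaults to the profile's rate).
#' @param seed integer seed driving all stages.
#' @return A list with `truth` (data frame), `reads` ([ccs_reads]),
#'   `origins` (data frame), and `config`.
#' @export
simulate_family <- function(profile = "TSPY", n_copies = 6,
                            mutation_rate = 0.01, patterns = NULL,
                            abundance = c("random", "equal"),
                            depth = 20, n_reads = NULL, error_rate = NULL,
                            seed = 1) {
  if (is.character(profile)) profile <- family_profile(profile)
  abundance <- match.arg(abundance)
  error_rate <- error_rate %||% profile$error_rate
  n_exons <- length(profile$exon_lengths)
  if (identical(patterns, "copies_only")) patterns <- list(rep(TRUE, n_exons))
  root <- make_root_exons(profile, seed = seed)
  copies <- simulate_copies(root, n_copies, mutation_rate, seed = seed + 1L)
  n_combo <- n_copies * length(patterns %||% default_isoform_patterns(n_exons))
  ab_values <- if (abundance == "equal") rep(1, n_combo) else NULL
  truth <- simulate_isoforms(copies, patterns, ab_values, seed = seed + 2L)
  if (is.null(n_reads)) n_reads <- max(1L, round(depth * nrow(truth)))
  reads <- simulate_ccs_reads(truth, n_reads, error_rate, seed = seed + 3L,
                              median_passes = profile$median_passes)
  list(truth = truth, reads = reads, origins = attr(reads, "origins"),
       config = list(profile = profile$name, n_copies = n_copies,
                     mutation_rate = mutation_rate,
                     abundance = abundance, n_reads = n_reads,
                     error_rate = error_rate, seed = seed))
}

#' Exact-match recall and precision of predicted transcripts
#'
#' A truth transcript is recalled if some prediction matches its sequence
#' exactly (end to end, no tolerance); a prediction is correct if it exactly
#' matches some truth transcript. Recall of an empty truth set and precision
#' of an empty prediction set are both defined as 1.
#'
#' @param predicted character vector of predicted sequences (or an
#'   [isoresolve] fit, or a transcripts data frame).
#' @param truth the truth set data frame (column `sequence`) or a character
#'   vector of true sequences.
#' @return Named numeric vector `c(recall = , precision = )`.
#' @export
recall_precision <- function(predicted, truth) {
  if (inherits(predicted, "isoresolve")) predicted <- predicted$transcripts
  if (is.data.frame(predicted)) predicted <- predicted$sequence
  if (is.data.frame(truth)) truth <- truth$sequence
  truth <- unique(truth)
  predicted <- unique(predicted)
  recall <- if (length(truth) == 0L) 1 else mean(truth %in% predicted)
  precision <- if (length(predicted) == 0L) 1 else mean(predicted %in% truth)
  c(recall = recall, precision = precision)
}
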