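#' Reconstruct transcripts from full-length CCS reads
#'
#' The top-level driver: derives the set of distinct transcript sequences
#' present in a family of full-length CCS reads. Two stages run in order:
#'
#' 1. **Clustering/correction** ([cluster_correct()]): reads are iteratively
#'    partitioned into nearest-neighbor clusters and partially corrected
#'    toward each cluster's consensus until all clusters converge; the
#'    distinct converged centers become candidate transcripts.
#' 2. **Statistical filtering** ([filter_candidates()]): the original
#'    (uncorrected) reads are assigned to candidates and candidates without
#'    sufficient quality-weighted read support are removed iteratively,
#'    using a Chernoff-type tail bound on the weighted support statistic.
#'
#' The pipeline is fully deterministic: the same input reads (in the same
#' order) produce byte-identical output, and no randomness is used anywhere.
#'
#' @param reads a [ccs_reads] object, or the path to a Phred+33 FASTQ file.
#' @param alpha significance threshold for candidate removal (default 0.01).
#' @param tau maximum candidates removed per filtering round (default 10).
#' @param max_variants variant-position cutoff of the statistical test
#'   (default 10; see [test_params()]).
#' @param max_rounds cap on correction rounds (default 20).
#' @param params a [test_params()] object (overrides `max_variants`).
#' @param scoring an [align_scoring()] object used for all row alignments.
#' @param trace if `TRUE`, log per-round summaries to stderr.
#' @return An object of class `"isoresolve"`: a list with
#'   \describe{
#'     \item{transcripts}{data frame `transcript_id`, `sequence`, `support`
#'       (assigned reads), `p_value` (least significant pairwise value).}
#'     \item{assignments}{data frame `read_id`, `transcript_id`,
#'       `edit_distance`.}
#'     \item{candidates}{the candidate data frame from the correction stage.}
#'     \item{correction, filter}{stage diagnostics (rounds, removals).}
#'     \item{params, n_reads, call}{run metadata.}
#'   }
#' @examples
#' reads <- simulate_family("TSPY", n_copies = 2, mutation_rate = 0.01,
#'                          depth = 10, error_rate = 0, seed = 1)
#' fit <- isoresolve(reads$reads)
#' fit
#' coef(fit)$support
#' @export
isoresolve <- function(reads, alpha = 0.01, tau = 10L, max_variants = 10L,
                       max_rounds = 20L, params = NULL,
                       scoring = align_scoring(), trace = FALSE) {
  cl <- match.call()
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_ccs_fastq(reads)
  stopifnot(inherits(reads, "ccs_reads"))
  if (length(reads) < 1L) stop("need at least one read")
  if (is.null(params)) params <- test_params(max_variants = max_variants)
  corr <- cluster_correct(reads, max_rounds = max_rounds, scoring = scoring,
                          trace = trace)
  filt <- filter_candidates(reads, corr$candidates, alpha = alpha, tau = tau,
                            params = params, scoring = scoring, trace = trace)
  tx <- filt$transcripts
  ord <- order(-tx$support, tx$sequence)
  tx <- tx[ord, , drop = FALSE]
  tx$transcript_id <- sprintf("transcript_%d", seq_len(nrow(tx)))
  rownames(tx) <- NULL
  rename <- c(stats::setNames(tx$transcript_id,
                              filt$transcripts$transcript_id[ord]))
  asn <- filt$assignments
  asn$transcript_id <- unname(rename[asn$transcript_id])
  structure(list(transcripts = tx, assignments = asn,
                 candidates = corr$candidates,
                 correction = list(rounds = corr$rounds,
                                   status = corr$status,
                                   n_candidates = nrow(corr$candidates)),
                 filter = list(rounds = filt$rounds, removed = filt$removed),
                 params = c(list(alpha = alpha, tau = as.integer(tau),
                                 max_rounds = as.integer(max_rounds)),
                            unclass(params), unclass(scoring)),
                 n_reads = length(reads), call = cl),
            class = "isoresolve")
}

#' @export
print.isoresolve <- function(x, ...) {
  cat(sprintf("isoresolve fit: %d transcript(s) from %d reads\n",
              nrow(x$transcripts), x$n_reads))
  cat(sprintf("  correction: %d candidate(s) in %d round(s) [%s]\n",
              x$correction$n_candidates, x$correction$rounds,
              x$correction$status))
  cat(sprintf("  filtering: %d round(s), %d candidate(s) removed (alpha = %g, tau = %d)\n",
              x$filter$rounds, length(unlist(x$filter$removed)),
              x$params$alpha, x$params$tau))
  invisible(x)
}

#' @method summary isoresolve
#' @export
summary.isoresolve <- function(object, ...) {
  tx <- object$transcripts
  out <- data.frame(transcript_id = tx$transcript_id,
                    length = nchar(tx$sequence),
                    support = tx$support,
                    p_value = tx$p_value)
  structure(list(table = out, n_reads = object$n_reads,
                 params = object$params), class = "summary.isoresolve")
}

#' @export
print.summary.isoresolve <- function(x, ...) {
  cat(sprintf("Transcripts reconstructed from %d CCS reads:\n\n", x$n_reads))
  print(x$table, row.names = FALSE)
  cat(sprintf("\nalpha = %g, tau = %d, variant cutoff = %d\n",
              x$params$alpha, x$params$tau, x$params$max_variants))
  invisible(x)
}

#' Extract the fitted transcripts
#'
#' The "coefficients" of the fit: the reconstructed transcript sequences with
#' their read support and significance values.
#'
#' @param object an [isoresolve] fit.
#' @param ... unused.
#' @return The transcript data frame (`transcript_id`, `sequence`,
#'   `support`, `p_value`).
#' @method coef isoresolve
#' @export
coef.isoresolve <- function(object, ...) object$transcripts

#' Per-read residual edit distances
#'
#' The edit distance of each read to its assigned transcript; the analogue of
#' residuals for this model, reflecting the read's uncorrected errors (plus
#' any true variation not represented by a surviving transcript).
#'
#' @param object an [isoresolve] fit.
#' @param ... unused.
#' @return Named integer vector, one element per read.
#' @method residuals isoresolve
#' @export
residuals.isoresolve <- function(object, ...) {
  stats::setNames(object$assignments$edit_distance, object$assignments$read_id)
}

#' @export
fitted.isoresolve <- function(object, ...) {
  seqs <- stats::setNames(object$transcripts$sequence,
                          object$transcripts$transcript_id)
  stats::setNames(unname(seqs[object$assignments$transcript_id]),
                  object$assignments$read_id)
}

#' Assign new reads to the fitted transcripts
#'
#' Greedy closest-neighbor assignment of new reads to the transcripts of an
#' existing fit (the same rule used internally during filtering).
#'
#' @param object an [isoresolve] fit.
#' @param newreads a [ccs_reads] object (defaults to re-assigning nothing).
#' @param ... unused.
#' @return A data frame `read_id`, `transcript_id`, `edit_distance`.
#' @export
predict.isoresolve <- function(object, newreads, ...) {
  if (missing(newreads)) return(object$assignments)
  cand <- stats::setNames(object$transcripts$sequence,
                          object$transcripts$transcript_id)
  out <- assign_reads(newreads, cand)
  names(out)[names(out) == "candidate_id"] <- "transcript_id"
  out
}

#' Simulate CCS reads from a fitted set of transcripts
#'
#' Draws reads from the fitted transcripts with abundances proportional to
#' their observed read support, through the same error model as
#' [simulate_ccs_reads()]. Useful for parametric-bootstrap style checks of
#' the pipeline on its own output.
#'
#' @param object an [isoresolve] fit.
#' @param nsim number of read sets to simulate.
#' @param seed integer seed (the caller's RNG state is restored afterwards).
#' @param n_reads reads per simulated set; defaults to the fitted read count.
#' @param error_rate per-base error rate; default the short-family CCS rate
#'   0.005.
#' @param ... passed to [simulate_ccs_reads()].
#' @return A list of `nsim` elements, each the result of
#'   [simulate_ccs_reads()] (a `ccs_reads` object with an `origins`
#'   attribute).
#' @export
simulate.isoresolve <- function(object, nsim = 1, seed = NULL,
                                n_reads = object$n_reads,
                                error_rate = 0.005, ...) {
  tx <- object$transcripts
  if (nrow(tx) == 0L) stop("fit has no transcripts")
  truth <- data.frame(transcript_id = tx$transcript_id,
                      sequence = tx$sequence,
                      abundance = pmax(tx$support, 1),
                      stringsAsFactors = FALSE)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_ccs_reads(truth, n_reads = n_reads, error_rate = error_rate,
                       seed = NULL, ...)))
}

#' Plot read support against significance
#'
#' One point per transcript: read support (log scale) against the
#' significance value from the final filtering round, with the removal
#' threshold alpha drawn as a reference line.
#'
#' @param x an [isoresolve] fit.
#' @param ... passed to [graphics::plot()].
#' @method plot isoresolve
#' @export
plot.isoresolve <- function(x, ...) {
  tx <- x$transcripts
  if (nrow(tx) == 0L) {
    plot(1, type = "n", xlab = "read support", ylab = "p-value",
         main = "no transcripts retained")
    return(invisible(x))
  }
  pv <- pmax(tx$p_value, 1e-300)
  plot(tx$support, pv, log = "xy",
       xlab = "read support (assigned reads)",
       ylab = "significance value (tail bound)",
       main = "Transcript support vs significance", pch = 19, ...)
  abline(h = x$params$alpha, lty = 2)
  text(tx$support, pv, labels = tx$transcript_id, pos = 3, cex = 0.7)
  invisible(x)
}
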