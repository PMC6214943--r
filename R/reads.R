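#' Full-length CCS reads with per-base qualities
#'
#' Container for a set of full-length, non-chimeric circular consensus (CCS)
#' reads from one gene family, as produced by upstream Iso-Seq preprocessing.
#' Each read carries its sequence over \{A,C,G,T\} and a vector of per-base
#' Phred quality scores of the same length.
#'
#' @param id character vector of read identifiers (unique).
#' @param seq character vector of read sequences (uppercase A/C/G/T).
#' @param qual list of integer vectors of Phred scores, one per read, each the
#'   same length as its sequence.
#' @param num_passes optional integer vector of CCS pass counts.
#' @return An object of class `"ccs_reads"`: a list with elements `id`, `seq`,
#'   `qual` and `num_passes`.
#' @examples
#' ccs_reads("r1", "ACGT", list(c(40L, 40L, 40L, 40L)))
#' @export
ccs_reads <- function(id, seq, qual, num_passes = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (anyDuplicated(id)) stop("read ids must be unique")
  if (length(seq) != length(id)) stop("id and seq lengths differ")
  if (length(qual) != length(id)) stop("id and qual lengths differ")
  qual <- lapply(qual, as.integer)
  nc <- nchar(seq)
  if (any(nc == 0L)) stop("empty read sequence")
  ql <- lengths(qual)
  if (any(ql != nc)) {
    bad <- which(ql != nc)[1L]
    stop(sprintf("read '%s': sequence length %d != quality length %d",
                 id[bad], nc[bad], ql[bad]))
  }
  if (any(grepl("[^ACGT]", seq)))
    stop("sequences must contain only A, C, G, T (see read_ccs_fastq() for ambiguity handling)")
  if (any(unlist(qual, use.names = FALSE) < 0L)) stop("negative Phred score")
  structure(list(id = id, seq = seq, qual = qual,
                 num_passes = if (is.null(num_passes)) rep(NA_integer_, length(id))
                              else as.integer(num_passes)),
            class = "ccs_reads")
}

#' @export
length.ccs_reads <- function(x) length(x$id)

#' @export
`[.ccs_reads` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(id = x$id[i], seq = x$seq[i], qual = x$qual[i],
                 num_passes = x$num_passes[i]),
            class = "ccs_reads")
}

#' @export
print.ccs_reads <- function(x, ...) {
  cat(sprintf("ccs_reads: %d reads, lengths %d-%d nt, median Phred %.0f\n",
              length(x), if (length(x)) min(nchar(x$seq)) else 0L,
              if (length(x)) max(nchar(x$seq)) else 0L,
              if (length(x)) stats::median(unlist(x$qual, use.names = FALSE)) else NA))
  invisible(x)
}

#' @export
c.ccs_reads <- function(...) {
  parts <- list(...)
  ccs_reads(unlist(lapply(parts, `[[`, "id")),
            unlist(lapply(parts, `[[`, "seq")),
            do.call(c, lapply(parts, `[[`, "qual")),
            unlist(lapply(parts, `[[`, "num_passes")))
}

#' Read full-length CCS reads from a FASTQ file
#'
#' Loads a Phred+33 FASTQ file into a [ccs_reads] object, decoding quality
#' characters to integer Phred scores. Phred+33 is the only accepted encoding
#' (the modern CCS standard). Reads containing ambiguity codes (e.g. `N`) are
#' dropped with a warning by default; with `ambiguous = "mask"` each ambiguous
#' base is replaced by `A` with a Phred score of 1 (error probability about
#' 0.75, i.e. effectively uninformative at that position).
#'
#' @param path path to an existing FASTQ file.
#' @param ambiguous how to treat reads with non-ACGT characters: `"drop"`
#'   (default) or `"mask"`.
#' @return A [ccs_reads] object; records appear in file order. An empty file
#'   yields a zero-length object.
#' @export
read_ccs_fastq <- function(path, ambiguous = c("drop", "mask")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("no such file: ", path)
  # structural pre-scan: names the first broken record, if any (Biostrings
  # accepts some malformed records silently)
  rec <- .locate_bad_fastq_record(path)
  if (!is.na(rec$index))
    stop(sprintf("malformed FASTQ record %d ('%s') in %s: %s",
                 rec$index, rec$id, path, rec$reason))
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    list(ids = sub("\\s.*$", "", names(set)),
         seqs = as.character(set),
         qchar = as.character(S4Vectors::mcols(set)$qualities))
  }, error = function(e) {
    stop(sprintf("malformed FASTQ file %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(parsed$ids) == 0L)
    return(ccs_reads(character(), character(), list()))
  ids <- parsed$ids
  seqs <- parsed$seqs
  quals <- lapply(parsed$qchar, function(q) utf8ToInt(q) - 33L)
  seqs <- toupper(seqs)
  amb <- grepl("[^ACGT]", seqs)
  if (any(amb)) {
    if (ambiguous == "drop") {
      warning(sprintf("dropping %d read(s) with ambiguous bases: %s",
                      sum(amb), paste(head(ids[amb], 5L), collapse = ", ")))
      ids <- ids[!amb]; seqs <- seqs[!amb]; quals <- quals[!amb]
    } else {
      for (i in which(amb)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        hit <- !ch %in% c("A", "C", "G", "T")
        ch[hit] <- "A"
        quals[[i]][hit] <- 1L
        seqs[i] <- paste(ch, collapse = "")
      }
    }
  }
  ccs_reads(ids, seqs, quals)
}

# Scan a FASTQ file line-wise to name the first structurally broken record.
.locate_bad_fastq_record <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  n <- length(lines)
  i <- 1L; rec <- 0L
  while (i <= n) {
    rec <- rec + 1L
    if (!startsWith(lines[i], "@"))
      return(list(index = rec, id = lines[i], reason = "record does not start with '@'"))
    id <- sub("^@", "", sub("\\s.*$", "", lines[i]))
    if (i + 3L > n)
      return(list(index = rec, id = id, reason = "truncated record"))
    if (!startsWith(lines[i + 2L], "+"))
      return(list(index = rec, id = id, reason = "missing '+' separator"))
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      return(list(index = rec, id = id,
                  reason = "sequence/quality length mismatch"))
    i <- i + 4L
  }
  list(index = NA_integer_, id = NA_character_, reason = NA_character_)
}

#' Write a set of reads as Phred+33 FASTQ
#'
#' Inverse of [read_ccs_fastq()]; round-tripping preserves sequences and
#' qualities exactly.
#'
#' @param reads a [ccs_reads] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ccs_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "ccs_reads"))
  qstr <- vapply(reads$qual, function(q) intToUtf8(pmin(q, 93L) + 33L), "")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qstr), con, sep = "\n")
  invisible(path)
}

#' Write predicted transcripts to FASTA
#'
#' One record per transcript; the header carries the transcript id, the number
#' of supporting reads, and the significance value, as
#' `id support=<n> pval=<p>`. Transcript sequences must be pairwise distinct
#' (deduplication happens upstream, in the correction stage).
#'
#' @param transcripts a data frame with columns `transcript_id`, `sequence`,
#'   `support`, `p_value` (as returned by [coef.isoresolve()]), or an
#'   [isoresolve] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  if (inherits(transcripts, "isoresolve")) transcripts <- transcripts$transcripts
  stopifnot(is.data.frame(transcripts))
  if (anyDuplicated(transcripts$sequence))
    stop("duplicate transcript sequences; deduplicate before writing")
  if (nrow(transcripts) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(transcripts$sequence)
  names(set) <- sprintf("%s support=%d pval=%g",
                        transcripts$transcript_id,
                        as.integer(transcripts$support),
                        transcripts$p_value)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read transcripts from a FASTA file
#'
#' @param path FASTA file path.
#' @return A named character vector of sequences (names are the first
#'   whitespace-separated token of each header).
#' @export
read_transcripts_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write the per-run report tables
#'
#' Writes two tab-separated tables: the read assignment
#' (`read_id`, `transcript_id`, `edit_distance`) and the transcript summary
#' (`transcript_id`, `support`, `p_value`), plus a JSON echo of the run
#' configuration. All coordinates in reports are 0-based, half-open.
#'
#' @param assignments data frame with columns `read_id`, `transcript_id`,
#'   `edit_distance`; every read id must appear exactly once.
#' @param transcripts data frame with columns `transcript_id`, `support`,
#'   `p_value`.
#' @param dir output directory (created if missing).
#' @param config optional named list echoed to `config.json`.
#' @return The directory path, invisibly.
#' @export
write_run_report <- function(assignments, transcripts, dir, config = NULL) {
  if (anyDuplicated(assignments$read_id))
    stop("a read id appears in more than one assignment")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(assignments[, c("read_id", "transcript_id", "edit_distance")],
              file.path(dir, "read_assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(transcripts[, c("transcript_id", "support", "p_value")],
              file.path(dir, "transcripts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(config, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
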