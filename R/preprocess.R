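#' Clip the 3' sequencing adapter from footprint reads
#'
#' Truncates each read at the leftmost exact occurrence of the adapter
#' (default `CTGTAGGCACCATCAAT`, the standard Ribo-seq linker). With 26--34 nt
#' inserts on longer sequencing reads the adapter must be present, so reads
#' lacking it — and reads whose insert is empty — are discarded and counted.
#' Quality strings are truncated in register. Exact matching only; the
#' operation is idempotent on its own output.
#'
#' @param reads tibble with `read_id`, `seq`, `qual` (see [read_fastq()]).
#' @param adapter non-empty adapter sequence.
#' @param require_adapter discard reads with no adapter occurrence (default).
#'   With `require_adapter = FALSE` adapter-less reads pass through unchanged
#'   (for input that may already be clipped), which makes the operation
#'   idempotent.
#' @return the clipped read tibble; discarded counts via [stage_stats()].
#' @export
clip_adapter <- function(reads, adapter = "CTGTAGGCACCATCAAT",
                         require_adapter = TRUE) {
  if (!is.character(adapter) || length(adapter) != 1L || nchar(adapter) == 0) {
    abort("adapter must be a non-empty sequence")
  }
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("malformed FASTQ record: sequence and quality lengths differ")
  }
  pos <- regexpr(adapter, reads$seq, fixed = TRUE)
  keep <- if (require_adapter) pos > 1L else pos != 1L
  out <- reads[keep, , drop = FALSE]
  p <- as.integer(pos[keep])
  clipme <- p > 0L
  out$seq[clipme] <- substr(out$seq[clipme], 1L, p[clipme] - 1L)
  out$qual[clipme] <- substr(out$qual[clipme], 1L, p[clipme] - 1L)
  out <- as_tibble(out)
  attr(out, "ribopause_stats") <- attr(reads, "ribopause_stats")
  add_stage_stats(out, "clip_adapter", nrow(reads), nrow(out),
                  nrow(reads) - nrow(out))
}

#' Trim the first 5' base of each read
#'
#' Removes the first nucleotide and its quality so reads start on the second
#' base (a library-construction artifact of untemplated addition during
#' reverse transcription). Reads shorter than 2 nt are discarded and counted.
#'
#' @param reads tibble with `read_id`, `seq`, `qual`.
#' @return trimmed read tibble; counts via [stage_stats()].
#' @export
trim_first_base <- function(reads) {
  keep <- nchar(reads$seq) >= 2L
  out <- reads[keep, , drop = FALSE]
  out$seq <- substring(out$seq, 2L)
  out$qual <- substring(out$qual, 2L)
  out <- as_tibble(out)
  attr(out, "ribopause_stats") <- attr(reads, "ribopause_stats")
  add_stage_stats(out, "trim_first_base", nrow(reads), nrow(out),
                  nrow(reads) - nrow(out))
}

#' Retain reads or alignments within a length window
#'
#' Applies the inclusive length filter (default 29--33 nt, the lengths
#' showing clean ribosome-footprint periodicity). Works on footprint
#' alignment tibbles (uses the `length` column) or on read tibbles (uses
#' `nchar(seq)`).
#'
#' @param x alignment or read tibble.
#' @param lo,hi inclusive bounds, `lo <= hi`.
#' @return the filtered tibble; retention counts via [stage_stats()].
#' @export
filter_lengths <- function(x, lo = 29L, hi = 33L) {
  if (lo > hi) abort("lo must be <= hi")
  len <- if ("length" %in% names(x)) x$length else nchar(x$seq)
  out <- as_tibble(x[len >= lo & len <= hi, , drop = FALSE])
  attr(out, "ribopause_stats") <- attr(x, "ribopause_stats")
  add_stage_stats(out, sprintf("filter_lengths_%s_%s", format(lo), format(hi)),
                  nrow(x), nrow(out), nrow(x) - nrow(out))
}

#' Ingest transcript-space footprint alignments
#'
#' Reads alignments from TSV (`read_id`, `transcript_id`, `five_prime_pos`,
#' `length`) or transcript-space BAM (primary alignments only, so
#' multi-mapped reads are counted once), validates every record against the
#' transcriptome (known transcript; `five_prime_pos >= 0`;
#' `five_prime_pos + length` within the transcript; length in 26--34 nt),
#' and drops reads on the exclusion list (e.g. rRNA hits identified
#' elsewhere). Invalid records are rejected with a warning.
#'
#' @param path alignment file.
#' @param transcriptome transcriptome tibble.
#' @param format `"tsv"` or `"bam"` (BAM requires the Rsamtools package).
#' @param exclusion_list character vector of read ids to drop.
#' @return a validated footprint tibble; rejection counts via [stage_stats()].
#' @export
ingest_alignments <- function(path, transcriptome, format = c("tsv", "bam"),
                              exclusion_list = character()) {
  format <- match.arg(format)
  raw <- if (format == "tsv") {
    read_footprints(path)
  } else {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      abort("BAM ingestion requires the Rsamtools package")
    }
    prm <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isUnmappedQuery = FALSE),
      what = c("qname", "rname", "pos", "qwidth"))
    b <- Rsamtools::scanBam(path, param = prm)[[1]]
    tibble(read_id = b$qname,
           transcript_id = as.character(b$rname),
           five_prime_pos = b$pos - 1L,  # BAM is 1-based
           length = b$qwidth)
  }
  n_in <- nrow(raw)
  excl <- raw$read_id %in% exclusion_list
  x <- raw[!excl, , drop = FALSE]
  tx_len <- setNames(nchar(transcriptome$sequence), transcriptome$transcript_id)
  known <- x$transcript_id %in% names(tx_len)
  ok <- known & x$five_prime_pos >= 0L & x$length >= 26L & x$length <= 34L
  ok[known] <- ok[known] &
    (x$five_prime_pos[known] + x$length[known] <=
       unname(tx_len[x$transcript_id[known]]))
  if (any(!ok)) {
    warn(sprintf("%d alignment record(s) rejected (unknown transcript, out-of-bounds coordinates, or length outside 26-34)",
                 sum(!ok)))
  }
  out <- as_tibble(x[ok, , drop = FALSE])
  out <- add_stage_stats(out, "exclusion_list", n_in, n_in - sum(excl), sum(excl))
  add_stage_stats(out, "ingest_validation", n_in - sum(excl), nrow(out),
                  sum(!ok))
}
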