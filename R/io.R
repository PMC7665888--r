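#' Read and write pipeline interchange files
#'
#' All tabular intermediates are plain TSV; transcript sequences travel as
#' FASTA plus a CDS table (`transcript_id`, `gene_id`, `cds_start`, `cds_end`;
#' 0-based, half-open, transcript coordinates).
#'
#' @param transcriptome transcriptome tibble (see [simulate_transcriptome()]).
#' @param fasta_path,cds_path output paths.
#' @return `write_transcriptome()` returns its input invisibly;
#'   `read_transcriptome()` returns a transcriptome tibble.
#' @name transcriptome_io
NULL

#' @rdname transcriptome_io
#' @export
write_transcriptome <- function(transcriptome, fasta_path, cds_path) {
  seqs <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(seqs) <- transcriptome$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(
    dplyr::select(transcriptome, "transcript_id", "gene_id",
                  "cds_start", "cds_end"),
    cds_path)
  invisible(transcriptome)
}

#' @rdname transcriptome_io
#' @export
read_transcriptome <- function(fasta_path, cds_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  cds <- readr::read_tsv(cds_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           transcript_id = "c", gene_id = "c",
                           cds_start = "i", cds_end = "i"))
  seq_tbl <- tibble(transcript_id = names(seqs),
                    sequence = as.character(seqs))
  out <- dplyr::inner_join(cds, seq_tbl, by = "transcript_id")
  if (nrow(out) != nrow(cds)) {
    warn("some CDS-table transcripts are missing from the FASTA")
  }
  bad <- out$cds_end > nchar(out$sequence) | out$cds_start < 0 |
    (out$cds_end - out$cds_start) %% 3L != 0L
  if (any(bad)) abort("CDS table inconsistent with sequences")
  dplyr::mutate(out, n_codons = (cds_end - cds_start) %/% 3L) |>
    dplyr::select("transcript_id", "gene_id", "sequence",
                  "cds_start", "cds_end", "n_codons")
}

#' @param footprints footprint tibble (`read_id`, `transcript_id`,
#'   `five_prime_pos`, `length`).
#' @param path file path.
#' @name footprint_io
#' @return `write_footprints()` its input invisibly; `read_footprints()` a
#'   footprint tibble.
NULL

#' @rdname footprint_io
#' @export
write_footprints <- function(footprints, path) {
  readr::write_tsv(
    dplyr::select(footprints, "read_id", "transcript_id",
                  "five_prime_pos", "length"),
    path)
  invisible(footprints)
}

#' @rdname footprint_io
#' @export
read_footprints <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    read_id = "c", transcript_id = "c",
                    five_prime_pos = "i", length = "i"))
}

#' FASTQ input and output as tibbles
#'
#' Reads are represented as a tibble with `read_id`, `seq`, `qual`
#' (Phred+33). Parsing and writing go through Biostrings.
#'
#' @param path FASTQ path.
#' @param reads read tibble.
#' @return `read_fastq()` a read tibble; `write_fastq()` its input invisibly.
#' @name fastq_io
NULL

#' @rdname fastq_io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  tibble(read_id = names(x),
         seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
}

#' @rdname fastq_io
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(reads)
}
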