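#' Calibrate per-read-length A-site offsets from the start-codon metagene
#'
#' For each read length L, collects the distance d = cds_start -
#' five_prime_pos over reads whose 5' end lies upstream of the annotated
#' start codon with a plausible in-read P-site (1 <= d <= L - 4). Initiating
#' ribosomes hold the start codon in the P-site, so the modal d is the
#' P-site offset; the A-site offset is that mode + 3 nt (one codon
#' downstream, standard 80S geometry). Ties in the mode break toward the
#' smaller offset. Lengths with fewer than `min_support` qualifying reads
#' fall back, with a warning, to the modal offset pooled across lengths.
#'
#' @param footprints footprint tibble.
#' @param transcriptome transcriptome tibble.
#' @param min_support minimum reads per length for a length-specific mode.
#' @return tibble: `length`, `p_offset`, `a_offset`, `support`, `method`
#'   (`"per_length"` or `"global_fallback"`), one row per observed length.
#' @export
calibrate_offsets <- function(footprints, transcriptome, min_support = 50L) {
  d_tbl <- footprints |>
    dplyr::inner_join(dplyr::select(transcriptome, "transcript_id", "cds_start"),
                      by = "transcript_id") |>
    dplyr::mutate(d = .data$cds_start - .data$five_prime_pos) |>
    dplyr::filter(.data$d >= 1L, .data$d <= .data$length - 4L)
  if (nrow(d_tbl) == 0L) abort("no reads overlap annotated start codons")

  modal <- function(d) {
    tab <- table(d)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)  # tie-break toward the smaller offset
  }
  global_mode <- modal(d_tbl$d)

  lens <- sort(unique(footprints$length))
  out <- purrr::map(lens, function(L) {
    d <- d_tbl$d[d_tbl$length == L]
    if (length(d) >= min_support) {
      tibble(length = L, p_offset = modal(d), support = length(d),
             method = "per_length")
    } else {
      tibble(length = L, p_offset = global_mode, support = length(d),
             method = "global_fallback")
    }
  }) |> dplyr::bind_rows()
  if (any(out$method == "global_fallback")) {
    warn(sprintf("insufficient start-codon support for length(s) %s; using the global modal offset",
                 paste(out$length[out$method == "global_fallback"], collapse = ", ")))
  }
  dplyr::mutate(out, a_offset = .data$p_offset + 3L) |>
    dplyr::select("length", "p_offset", "a_offset", "support", "method")
}

#' Assign each footprint's A-site nucleotide and codon
#'
#' The A-site nucleotide is `five_prime_pos + a_offset(length)`; the codon
#' index is `(a_site_nt - cds_start) %/% 3` when the nucleotide lies inside
#' the CDS (`in_cds = TRUE`), and reads whose A-site lands in a UTR are
#' flagged `in_cds = FALSE` (a value, not an error; they are excluded from
#' all codon statistics downstream).
#'
#' @param footprints footprint tibble; every `length` must appear in
#'   `offsets`.
#' @param offsets offset table from [calibrate_offsets()] (or any tibble with
#'   `length`, `a_offset`).
#' @param transcriptome transcriptome tibble.
#' @return the footprint tibble with `a_site_nt`, `codon_index`, `in_cds`
#'   columns appended (any extra input columns, e.g. `sample`, pass through).
#' @export
assign_asite <- function(footprints, offsets, transcriptome) {
  missing_len <- setdiff(unique(footprints$length), offsets$length)
  if (length(missing_len) > 0) {
    abort(sprintf("no A-site offset for read length(s) %s",
                  paste(missing_len, collapse = ", ")))
  }
  footprints |>
    dplyr::inner_join(dplyr::select(offsets, "length", "a_offset"),
                      by = "length") |>
    dplyr::inner_join(dplyr::select(transcriptome, "transcript_id",
                                    "cds_start", "cds_end"),
                      by = "transcript_id") |>
    dplyr::mutate(
      a_site_nt = .data$five_prime_pos + .data$a_offset,
      in_cds = .data$a_site_nt >= .data$cds_start &
        .data$a_site_nt < .data$cds_end,
      codon_index = dplyr::if_else(
        .data$in_cds,
        (.data$a_site_nt - .data$cds_start) %/% 3L,
        NA_integer_)) |>
    dplyr::select(-"a_offset", -"cds_start", -"cds_end")
}

#' Tally A-site codon counts per transcript
#'
#' Builds the sparse per-transcript, per-codon-position A-site count table
#' o(t, i) from assigned footprints. Reads whose A-site lies outside the CDS
#' are excluded and counted (conservation: assigned + outside-CDS = input).
#' If a `sample` column is present, counts are tallied per sample.
#'
#' @param assigned output of [assign_asite()].
#' @return sparse count tibble: `transcript_id`, (`sample`,) `codon_index`,
#'   `count`; the number of excluded outside-CDS reads is available as
#'   `attr(x, "outside_cds")` and via [stage_stats()].
#' @export
count_asite_codons <- function(assigned) {
  grp <- intersect(c("sample", "transcript_id", "codon_index"), names(assigned))
  inside <- dplyr::filter(assigned, .data$in_cds)
  out <- inside |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), name = "count") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)))
  attr(out, "outside_cds") <- nrow(assigned) - nrow(inside)
  add_stage_stats(out, "asite_in_cds", nrow(assigned), nrow(inside),
                  nrow(assigned) - nrow(inside))
}
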