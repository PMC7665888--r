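#' Uniform expected A-site counts per codon position
#'
#' Under the null of footprints spread uniformly across the coding part of a
#' transcript, every codon position of transcript t expects
#' e(t, i) = total_reads(t) / n_codons(t). Computed over the analysis window
#' (see [codon_occupancy()] for the window convention); with the default
#' window of the full CDS this is the textbook uniform expectation.
#'
#' @param counts sparse count tibble from [count_asite_codons()].
#' @param transcriptome transcriptome tibble.
#' @return tibble `transcript_id`, `codon_index`, `observed`, `expected`
#'   (dense over CDS positions; `sum(expected) == sum(observed)` per
#'   transcript).
#' @export
expected_counts <- function(counts, transcriptome) {
  dense_window_counts(counts, transcriptome, exclude_start = 0L,
                      exclude_end = 0L) |>
    dplyr::select("transcript_id", "codon_index", "observed", "expected")
}

# Dense per-position observed counts plus the uniform expectation, restricted
# to the analysis window [exclude_start, n_codons - 1 - exclude_end].
dense_window_counts <- function(counts, transcriptome, exclude_start,
                                exclude_end, sample_col = NULL) {
  inst <- codon_instances(transcriptome) |>
    dplyr::left_join(dplyr::select(transcriptome, "transcript_id", "n_codons"),
                     by = "transcript_id") |>
    dplyr::filter(.data$codon_index >= exclude_start,
                  .data$codon_index <= .data$n_codons - 1L - exclude_end)
  if (!is.null(sample_col)) {
    inst <- tidyr::crossing(sample = sample_col, inst)
  }
  by_cols <- c(if (!is.null(sample_col)) "sample", "transcript_id", "codon_index")
  dense <- inst |>
    dplyr::left_join(dplyr::select(counts, dplyr::all_of(c(by_cols, "count"))),
                     by = by_cols) |>
    dplyr::mutate(observed = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::select(-"count")
  grp <- c(if (!is.null(sample_col)) "sample", "transcript_id")
  dense |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(expected = sum(.data$observed) / dplyr::n()) |>
    dplyr::ungroup()
}

#' Genome-wide observed/expected codon occupancy
#'
#' The central descriptive statistic of codon-specific pausing: for each
#' sense-codon identity c, observed reads O_c are summed A-site counts over
#' every instance of c, expected reads E_c sum the per-transcript uniform
#' expectation over the same instances, and the occupancy ratio is
#' R_c = O_c / E_c. A ratio of 1 means average dwell; a codon decoded slowly
#' (e.g. AGA under arginine-tRNA deficiency) shows R_c > 1.
#'
#' For `site = "P"` or `"E"` the grouping identity is the codon one or two
#' positions upstream of the A-site index, i.e. the codon actually occupying
#' that ribosomal site for the same reads.
#'
#' The first and last CDS codons are excluded by default: initiation and
#' termination geometry, not elongation dwell, dominates them. Expected
#' counts are computed per transcript over the same window, so
#' sum(O) = sum(E) exactly per library.
#'
#' @param counts sparse count tibble from [count_asite_codons()]; a `sample`
#'   column, if present, yields per-sample (per-replicate) ratios.
#' @param transcriptome transcriptome tibble.
#' @param site ribosomal site whose codon identity is interrogated.
#' @param exclude_start,exclude_end CDS codons trimmed from each end.
#' @return a tibble of class `"occupancy_tbl"`: (`sample`,) `codon`,
#'   `observed`, `expected`, `ratio` over the 61 sense codons (ratio `NA`
#'   where a codon has no instances).
#' @export
codon_occupancy <- function(counts, transcriptome, site = c("A", "P", "E"),
                            exclude_start = 1L, exclude_end = 1L) {
  site <- match.arg(site)
  shift <- c(A = 0L, P = 1L, E = 2L)[[site]]
  samples <- if ("sample" %in% names(counts)) sort(unique(counts$sample))
  dense <- dense_window_counts(counts, transcriptome, exclude_start,
                               exclude_end, sample_col = samples)
  if (shift > 0L) {
    # identity of the codon sitting in the P/E site for a read with this
    # A-site index: look upstream within the same transcript
    inst_all <- codon_instances(transcriptome) |>
      dplyr::mutate(codon_index = .data$codon_index + shift) |>
      dplyr::select("transcript_id", "codon_index", site_codon = "codon")
    dense <- dense |>
      dplyr::select(-"codon") |>
      dplyr::inner_join(inst_all, by = c("transcript_id", "codon_index")) |>
      dplyr::rename(codon = "site_codon")
  }
  grp <- c(if (!is.null(samples)) "sample", "codon")
  occ <- dense |>
    dplyr::filter(.data$codon %in% sense_codons()) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(observed = sum(.data$observed),
                     expected = sum(.data$expected), .groups = "drop")
  full <- tidyr::expand_grid(
    sample = if (is.null(samples)) NA_character_ else samples,
    codon = sense_codons())
  if (is.null(samples)) full$sample <- NULL
  occ <- full |>
    dplyr::left_join(occ, by = grp) |>
    dplyr::mutate(
      observed = dplyr::coalesce(.data$observed, 0),
      expected = dplyr::coalesce(.data$expected, 0),
      ratio = dplyr::if_else(.data$expected > 0,
                             .data$observed / .data$expected, NA_real_))
  class(occ) <- c("occupancy_tbl", class(occ))
  attr(occ, "site") <- site
  occ
}

#' Aggregate occupancy ratios across replicate libraries
#'
#' @param occ an `"occupancy_tbl"` with a `sample` column.
#' @return tibble `codon`, `mean_ratio`, `sem`, `n` (SEM across libraries,
#'   the biological-replicate spread shown on occupancy bar plots).
#' @export
summarize_occupancy <- function(occ) {
  if (!"sample" %in% names(occ)) abort("per-sample occupancy table required")
  occ |>
    dplyr::group_by(.data$codon) |>
    dplyr::summarise(
      mean_ratio = mean(.data$ratio, na.rm = TRUE),
      sem = sd(.data$ratio, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$ratio))),
      n = sum(!is.na(.data$ratio)),
      .groups = "drop")
}

#' Standardize occupancy ratios to per-codon z-scores
#'
#' z_c = (R_c - mean(R)) / sd(R) over the defined ratios — a presentation
#' statistic that makes a single elevated codon stand out against the other
#' 60. Requires at least 3 defined ratios; if the ratios are constant all z
#' are 0.
#'
#' @param occ an occupancy table (a `ratio` column; grouped by `sample` if
#'   present).
#' @return the table with a `z` column appended.
#' @export
occupancy_zscores <- function(occ) {
  grp <- intersect("sample", names(occ))
  out <- occ |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(z = {
      r <- .data$ratio
      if (sum(!is.na(r)) < 3L) abort("need >= 3 defined occupancy ratios")
      s <- sd(r, na.rm = TRUE)
      if (is.na(s) || s == 0) rep(0, length(r))
      else (r - mean(r, na.rm = TRUE)) / s
    }) |>
    dplyr::ungroup()
  class(out) <- unique(c("occupancy_tbl", class(out)))
  out
}
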