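#' Threshold transcripts on read density across all samples
#'
#' A transcript enters the pause analysis only if its in-CDS A-site read
#' density (total reads / CDS codons) reaches `min_density` in every sample
#' — the standard 0.5 reads/codon cutoff applied jointly across libraries,
#' so a pause call never rests on a transcript that is poorly covered in any
#' replicate.
#'
#' @param counts sparse count tibble with a `sample` column covering all
#'   libraries (a table without `sample` is treated as one library).
#' @param transcriptome transcriptome tibble (the transcript universe).
#' @param min_density inclusive reads/codon threshold.
#' @return character vector of retained transcript ids.
#' @export
threshold_transcripts <- function(counts, transcriptome, min_density = 0.5) {
  if (!"sample" %in% names(counts)) counts$sample <- "library_1"
  samples <- unique(counts$sample)
  dens <- counts |>
    dplyr::group_by(.data$sample, .data$transcript_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    tidyr::complete(sample = samples,
                    transcript_id = transcriptome$transcript_id,
                    fill = list(total = 0L)) |>
    dplyr::left_join(dplyr::select(transcriptome, "transcript_id", "n_codons"),
                     by = "transcript_id") |>
    dplyr::mutate(density = .data$total / .data$n_codons)
  dens |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(keep = all(.data$density >= min_density), .groups = "drop") |>
    dplyr::filter(.data$keep) |>
    dplyr::pull("transcript_id") |>
    sort()
}

#' Per-codon pause scores and z-scores
#'
#' For each transcript the analysis window is its CDS minus `trim` codons at
#' each end (initiation ramp and termination are not elongation pauses).
#' With o(t, i) the A-site count at window position i, mu_t and sigma_t the
#' window mean and standard deviation:
#' \deqn{s(t,i) = o(t,i) / \mu_t, \qquad z(t,i) = (o(t,i) - \mu_t)/\sigma_t.}
#' Both are dimensionless and invariant under scaling all counts — a pause
#' is a spike against the transcript's own background, not high coverage.
#' Transcripts with sigma_t = 0 (perfectly uniform coverage) cannot harbour
#' a pause and are skipped with a message.
#'
#' @param counts sparse count tibble (optionally with `sample`).
#' @param transcriptome transcriptome tibble.
#' @param transcripts transcripts to score (default: all in `counts`);
#'   normally the output of [threshold_transcripts()].
#' @param trim codons excluded at each CDS end (default 5).
#' @return tibble: (`sample`,) `transcript_id`, `gene_id`, `codon_index`,
#'   `codon`, `count`, `score`, `z` — dense over each window.
#' @export
pause_scores <- function(counts, transcriptome, transcripts = NULL, trim = 5L) {
  samples <- if ("sample" %in% names(counts)) sort(unique(counts$sample))
  if (is.null(transcripts)) transcripts <- unique(counts$transcript_id)
  txset <- transcriptome[transcriptome$transcript_id %in% transcripts, ,
                         drop = FALSE]
  if (nrow(txset) == 0L) abort("no transcripts to score")
  dense <- dense_window_counts(counts, txset, exclude_start = trim,
                               exclude_end = trim, sample_col = samples)
  grp <- c(if (!is.null(samples)) "sample", "transcript_id")
  scored <- dense |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(mu = mean(.data$observed), sigma = sd(.data$observed)) |>
    dplyr::ungroup()
  n_skip <- scored |>
    dplyr::distinct(dplyr::across(dplyr::all_of(grp)), .data$sigma) |>
    dplyr::filter(.data$sigma == 0 | is.na(.data$sigma)) |>
    nrow()
  if (n_skip > 0) {
    inform(sprintf("%d transcript-library combination(s) skipped: uniform or empty coverage cannot pause",
                   n_skip))
  }
  scored |>
    dplyr::filter(.data$sigma > 0) |>
    dplyr::mutate(score = .data$observed / .data$mu,
                  z = (.data$observed - .data$mu) / .data$sigma) |>
    dplyr::select(dplyr::all_of(c(if (!is.null(samples)) "sample",
                                  "transcript_id", "gene_id", "codon_index",
                                  "codon")),
                  count = "observed", "score", "z")
}

#' Call pause genes per replicate and form the consensus set
#'
#' A gene is called in a replicate if any of its sites (optionally
#' restricted to one codon identity, e.g. AGA) reaches `z >= z_min`
#' (inclusive). The consensus set contains genes called in at least
#' `min_replicates` replicates — the "detected in at least two biological
#' replicates" rule.
#'
#' @param scores pause-score tibble from [pause_scores()] with a `sample`
#'   column identifying replicates.
#' @param z_min inclusive z threshold (default 10).
#' @param codon codon identity restriction (default `"AGA"`; `NULL` = any).
#' @param min_replicates minimum replicates for the consensus (default 2).
#' @return list of class `"pause_calls"`: `$sites` (qualifying sites),
#'   `$by_replicate` (tibble `sample`, `gene_id`), `$sets` (named list of
#'   per-replicate gene-id vectors), `$consensus` (character vector),
#'   `$params`.
#' @export
call_pause_genes <- function(scores, z_min = 10, codon = "AGA",
                             min_replicates = 2L) {
  if (z_min <= 0 || min_replicates < 1L) abort("thresholds must be positive")
  if (!"sample" %in% names(scores)) scores$sample <- "library_1"
  sites <- scores |>
    dplyr::filter(.data$z >= z_min,
                  if (is.null(codon)) TRUE else .data$codon == !!codon)
  by_rep <- sites |>
    dplyr::distinct(.data$sample, .data$gene_id) |>
    dplyr::arrange(.data$sample, .data$gene_id)
  sets <- split(by_rep$gene_id, by_rep$sample)
  # replicates with zero calls still contribute an (empty) set
  for (s in setdiff(unique(scores$sample), names(sets))) sets[[s]] <- character()
  sets <- sets[sort(names(sets))]
  consensus <- by_rep |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n >= min_replicates) |>
    dplyr::pull("gene_id") |>
    sort()
  structure(list(sites = sites, by_replicate = by_rep, sets = sets,
                 consensus = consensus,
                 params = list(z_min = z_min, codon = codon,
                               min_replicates = as.integer(min_replicates))),
            class = "pause_calls")
}

#' @export
print.pause_calls <- function(x, ...) {
  cat(sprintf("<pause_calls> z >= %g, codon %s\n", x$params$z_min,
              x$params$codon %||% "any"))
  for (s in names(x$sets)) {
    cat(sprintf("  %s: %d gene(s)\n", s, length(x$sets[[s]])))
  }
  cat(sprintf("  consensus (>= %d replicates): %d gene(s)\n",
              x$params$min_replicates, length(x$consensus)))
  invisible(x)
}

#' Intersect pause-gene sets across replicates or genotypes
#'
#' Reports, for every pair of sets, the shared count and the shared
#' fractions |A∩B|/|A| and |A∩B|/|B| (NA for empty sets), plus the full
#' Venn partition when exactly three sets are given — the replicate-overlap
#' summary behind the observation that roughly half of pausing genes are
#' shared between libraries when pausing is stochastic.
#'
#' @param sets named list (length >= 2) of gene-id character vectors.
#' @return list: `$pairwise` tibble (`set_a`, `set_b`, `n_a`, `n_b`,
#'   `shared`, `frac_a`, `frac_b`), `$venn` tibble (`region`, `size`; 3-set
#'   case only, else `NULL`), `$mean_shared_fraction` (mean of all pairwise
#'   fractions).
#' @export
intersect_pause_sets <- function(sets) {
  if (length(sets) < 2L) abort("need at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  prs <- utils::combn(names(sets), 2L)
  pairwise <- purrr::map(seq_len(ncol(prs)), function(j) {
    a <- sets[[prs[1, j]]]; b <- sets[[prs[2, j]]]
    sh <- length(intersect(a, b))
    tibble(set_a = prs[1, j], set_b = prs[2, j],
           n_a = length(a), n_b = length(b), shared = sh,
           frac_a = if (length(a) > 0) sh / length(a) else NA_real_,
           frac_b = if (length(b) > 0) sh / length(b) else NA_real_)
  }) |> dplyr::bind_rows()
  venn <- NULL
  if (length(sets) == 3L) {
    nm <- names(sets)
    memb <- tibble(gene_id = unique(unlist(sets)))
    for (s in nm) memb[[s]] <- memb$gene_id %in% sets[[s]]
    venn <- memb |>
      dplyr::count(dplyr::across(dplyr::all_of(nm)), name = "size") |>
      dplyr::mutate(region = apply(
        dplyr::pick(dplyr::all_of(nm)), 1L,
        function(r) paste(nm[as.logical(r)], collapse = "&"))) |>
      dplyr::select("region", "size")
  }
  list(pairwise = pairwise, venn = venn,
       mean_shared_fraction = mean(c(pairwise$frac_a, pairwise$frac_b),
                                   na.rm = TRUE))
}

#' Correlate gene-level pause scores with expression effect sizes
#'
#' The gene pause statistic follows the published recipe: within each
#' replicate, a transcript's pause score is its maximum per-codon score and
#' a gene's score is the average over its transcripts; these per-replicate
#' gene scores are then summed across replicates, and the sums are
#' rank-correlated (Spearman, average-rank ties) with the expression effect
#' sizes (beta, natural-log-scale fold changes from a differential-expression
#' model). Only genes present in both tables enter.
#'
#' @param scores pause-score tibble from [pause_scores()] (with `sample`).
#' @param effects tibble `gene_id`, `beta` (a `q_value` column, if present,
#'   passes through to the paired table).
#' @return list of class `"pause_cor"`: `rho`, `p_value`, `n`, `method`,
#'   and `$data` (the paired gene table).
#' @export
correlate_pause_with_expression <- function(scores, effects) {
  if (!"sample" %in% names(scores)) scores$sample <- "library_1"
  gene_stat <- scores |>
    dplyr::group_by(.data$sample, .data$gene_id, .data$transcript_id) |>
    dplyr::summarise(tx_score = max(.data$score), .groups = "drop") |>
    dplyr::group_by(.data$sample, .data$gene_id) |>
    dplyr::summarise(rep_score = mean(.data$tx_score), .groups = "drop") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(pause_score = sum(.data$rep_score), .groups = "drop")
  paired <- dplyr::inner_join(gene_stat, effects, by = "gene_id")
  if (nrow(paired) < 3L) abort("need at least 3 paired genes")
  st <- spearman_test(paired$pause_score, paired$beta)
  structure(c(st, list(data = paired)), class = "pause_cor")
}

#' @export
print.pause_cor <- function(x, ...) {
  cat(sprintf("<pause_cor> Spearman rho = %.4f, p = %.4g (n = %d genes, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}
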