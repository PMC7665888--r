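#' Gene-filter configuration for TE analysis
#'
#' Histone mRNAs are not polyadenylated and distort footprint/RNA coupling,
#' so genes whose names start with the (case-sensitive) prefix `"Hist"` are
#' removed, alongside any explicit exclusion list. A 5'TOP gene list can be
#' attached for [top_gene_report()].
#'
#' @param histone_prefix exact, case-sensitive gene-name prefix to drop.
#' @param exclude extra gene ids to drop.
#' @param top_genes gene ids with known 5'TOP motifs.
#' @return list of class `"gene_filters"`.
#' @export
gene_filters <- function(histone_prefix = "Hist", exclude = character(),
                         top_genes = character()) {
  structure(list(histone_prefix = histone_prefix,
                 exclude = exclude, top_genes = top_genes),
            class = "gene_filters")
}

#' Build the matched footprint/RNA count table for TE analysis
#'
#' Footprint counts per gene are reads whose assigned A-site lies in the CDS
#' (per sample); RNA counts come from the gene-level RNA-seq table. Both
#' assays pass through the same gene filter (histone prefix + exclusion
#' list), and genes detected in only one assay are excluded with a message.
#'
#' @param assigned assigned footprints ([assign_asite()]) with a `sample`
#'   column.
#' @param rna_counts tibble `gene_id`, `sample`, `count`.
#' @param transcriptome transcriptome tibble (transcript-to-gene map).
#' @param filters a [gene_filters()].
#' @return tibble `gene_id`, `sample`, `footprint`, `rna` — dense over
#'   retained genes x samples present in either assay (missing counts are 0
#'   once a gene is detected in both assays).
#' @export
count_for_te <- function(assigned, rna_counts, transcriptome,
                         filters = gene_filters()) {
  if (!"sample" %in% names(assigned)) assigned$sample <- "library_1"
  fp <- assigned |>
    dplyr::filter(.data$in_cds) |>
    dplyr::inner_join(dplyr::select(transcriptome, "transcript_id", "gene_id"),
                      by = "transcript_id") |>
    dplyr::count(.data$gene_id, .data$sample, name = "footprint")
  rna <- rna_counts |>
    dplyr::group_by(.data$gene_id, .data$sample) |>
    dplyr::summarise(rna = sum(.data$count), .groups = "drop")

  drop_filtered <- function(g) {
    g[!startsWith(g, filters$histone_prefix) & !(g %in% filters$exclude)]
  }
  fp_genes <- drop_filtered(unique(fp$gene_id))
  rna_genes <- drop_filtered(unique(rna$gene_id))
  common <- intersect(fp_genes, rna_genes)
  lost <- setdiff(union(fp_genes, rna_genes), common)
  if (length(lost) > 0) {
    inform(sprintf("%d gene(s) present in only one assay excluded from TE",
                   length(lost)))
  }
  samples <- sort(union(unique(fp$sample), unique(rna$sample)))
  tidyr::crossing(gene_id = sort(common), sample = samples) |>
    dplyr::left_join(fp, by = c("gene_id", "sample")) |>
    dplyr::left_join(rna, by = c("gene_id", "sample")) |>
    dplyr::mutate(footprint = dplyr::coalesce(.data$footprint, 0L),
                  rna = dplyr::coalesce(as.integer(.data$rna), 0L))
}

# DESeq-style median-of-ratios size factors for one assay's count matrix
# (genes x samples, long format). Genes with a zero anywhere drop out of the
# geometric-mean reference.
median_of_ratios <- function(counts_long, value_col) {
  wide <- counts_long |>
    dplyr::select(dplyr::all_of(c("gene_id", "sample", value_col))) |>
    tidyr::pivot_wider(names_from = "sample",
                       values_from = dplyr::all_of(value_col))
  m <- as.matrix(wide[, -1, drop = FALSE])
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) abort("no gene has positive counts in every sample; cannot normalize")
  logg <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2L, function(col) {
    median(exp(log(col) - logg))
  })
  sf / exp(mean(log(sf)))  # geometric-mean centred
}

#' Differential translational-efficiency test
#'
#' Per-assay library-size normalization by median-of-ratios, then per gene
#' and sample
#' \deqn{\log_2 TE = \log_2\frac{FP + 0.5}{s^{FP}} - \log_2\frac{RNA + 0.5}{s^{RNA}}}
#' (pseudocount 0.5 stabilizes zeros), followed by a per-gene Welch t-test
#' of log2 TE between the two conditions and Benjamini-Hochberg correction
#' across genes. Genes with zero TE variance in both groups get an undefined
#' (NA) p-value. This deliberately simple test answers "did TE change";
#' count-model (DESeq2-style GLM) parity is not attempted.
#'
#' @param te_counts table from [count_for_te()].
#' @param conditions named character vector mapping sample -> condition
#'   (exactly two condition levels; the first sorted level is the
#'   reference). Each condition needs >= 2 samples.
#' @param pseudocount added to both counts before logs.
#' @return tibble of class `"te_fit"`: `gene_id`, `log2_te_ref`,
#'   `log2_te_alt`, `delta_log2_te` (alt - ref), `statistic`, `df`,
#'   `p_value`, `q_value`. Condition labels and size factors are attached
#'   as attributes.
#' @export
differential_te <- function(te_counts, conditions, pseudocount = 0.5) {
  samples <- sort(unique(te_counts$sample))
  if (!all(samples %in% names(conditions))) {
    abort("every sample needs a condition label")
  }
  cond <- conditions[samples]
  lev <- sort(unique(cond))
  if (length(lev) != 2L) abort("exactly two conditions required")
  if (any(table(cond) < 2L)) abort("need >= 2 samples per condition")

  sf_fp <- median_of_ratios(te_counts, "footprint")
  sf_rna <- median_of_ratios(te_counts, "rna")
  lt <- te_counts |>
    dplyr::mutate(
      log2_te = log2((.data$footprint + pseudocount) / sf_fp[.data$sample]) -
        log2((.data$rna + pseudocount) / sf_rna[.data$sample]),
      condition = unname(cond[.data$sample]))

  wide <- lt |>
    dplyr::select("gene_id", "sample", "log2_te") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "log2_te")
  m <- as.matrix(wide[, -1, drop = FALSE])
  g1 <- colnames(m) %in% samples[cond == lev[1]]
  w <- welch_rows(m[, g1, drop = FALSE], m[, !g1, drop = FALSE])

  ref_mean <- rowMeans(m[, g1, drop = FALSE])
  alt_mean <- rowMeans(m[, !g1, drop = FALSE])
  out <- tibble(
    gene_id = wide$gene_id,
    log2_te_ref = ref_mean,
    log2_te_alt = alt_mean,
    delta_log2_te = alt_mean - ref_mean,
    statistic = w$t, df = w$df, p_value = w$p,
    q_value = p.adjust(w$p, method = "BH"))
  class(out) <- c("te_fit", class(out))
  attr(out, "conditions") <- c(ref = lev[1], alt = lev[2])
  attr(out, "size_factors") <- list(footprint = sf_fp, rna = sf_rna)
  out
}

# Row-wise Welch t-tests: x, y matrices with genes as rows.
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  t[zero] <- NA_real_; df[zero] <- NA_real_; p[zero] <- NA_real_
  list(t = t, df = df, p = p)
}

#' Remove footprints with a target codon near the A-site
#'
#' Drops every read for which any codon within `window` codons of its
#' assigned A-site codon (clipped at the CDS boundaries) matches the target
#' identity — the AGA-filtered re-analysis that asks whether TE changes
#' survive removal of pause-associated footprints. Reads whose A-site lies
#' outside the CDS have no A-site codon and are retained.
#'
#' @param assigned assigned footprints ([assign_asite()]).
#' @param transcriptome transcriptome tibble.
#' @param codon target identity (default `"AGA"`).
#' @param window codons to each side of the A-site (default 1; 0 = A-site
#'   only).
#' @return the filtered tibble; removal counts via [stage_stats()].
#' @export
filter_codon_asite_reads <- function(assigned, transcriptome, codon = "AGA",
                                     window = 1L) {
  if (window < 0L) abort("window must be >= 0")
  targets <- codon_instances(transcriptome) |>
    dplyr::filter(.data$codon == !!codon) |>
    dplyr::select("transcript_id", target_index = "codon_index")
  hit <- assigned |>
    dplyr::filter(.data$in_cds) |>
    dplyr::select("read_id", "transcript_id", "codon_index") |>
    dplyr::inner_join(targets, by = "transcript_id",
                      relationship = "many-to-many") |>
    dplyr::filter(abs(.data$codon_index - .data$target_index) <= window) |>
    dplyr::distinct(.data$read_id, .data$transcript_id)
  drop <- paste(assigned$read_id, assigned$transcript_id) %in%
    paste(hit$read_id, hit$transcript_id)
  out <- as_tibble(assigned[!drop, , drop = FALSE])
  attr(out, "ribopause_stats") <- attr(assigned, "ribopause_stats")
  add_stage_stats(out, sprintf("filter_%s_asite_w%d", codon, window),
                  nrow(assigned), nrow(out), sum(drop))
}

#' Report TE results for a 5'TOP gene list
#'
#' Restricts a TE fit to the listed genes (those detected in the table) and
#' counts how many show altered TE at `q <= q_threshold` — the readout used
#' to ask whether mTORC1-driven translation of TOP mRNAs changed.
#'
#' @param te_fit a [differential_te()] result.
#' @param top_genes non-empty character vector of 5'TOP gene ids.
#' @param q_threshold BH-adjusted significance cutoff.
#' @return list: `$table` (TE rows of detected TOP genes), `$n_detected`,
#'   `$n_altered`, `$q_threshold`.
#' @export
top_gene_report <- function(te_fit, top_genes, q_threshold = 0.05) {
  if (length(top_genes) == 0) abort("top_genes must be non-empty")
  sub <- dplyr::filter(te_fit, .data$gene_id %in% top_genes)
  list(table = sub,
       n_detected = nrow(sub),
       n_altered = sum(sub$q_value <= q_threshold, na.rm = TRUE),
       q_threshold = q_threshold)
}
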