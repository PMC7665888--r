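#' Minimal differential-expression test on RNA-seq counts
#'
#' A deliberately small gene-level test used to exercise synthetic data:
#' median-of-ratios size factors, log2 of normalized counts (+0.5), Welch
#' t-test between conditions, BH correction. The reported `beta` is on the
#' natural-log scale, matching the effect sizes exported by transcript-
#' abundance DE tools. For real data, supply an externally computed effects
#' table instead.
#'
#' @param rna_counts tibble `gene_id`, `sample`, `count`.
#' @param conditions named vector sample -> condition (two levels).
#' @return tibble `gene_id`, `beta`, `p_value`, `q_value`.
#' @export
differential_expression <- function(rna_counts, conditions) {
  samples <- sort(unique(rna_counts$sample))
  cond <- conditions[samples]
  lev <- sort(unique(cond))
  if (length(lev) != 2L) abort("exactly two conditions required")
  wide <- rna_counts |>
    dplyr::group_by(.data$gene_id, .data$sample) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  sf <- median_of_ratios(
    tidyr::pivot_longer(wide, -"gene_id", names_to = "sample",
                        values_to = "count"), "count")
  lm2 <- log2(sweep(m + 0.5, 2L, sf[colnames(m)], "/"))
  g1 <- colnames(m) %in% samples[cond == lev[1]]
  w <- welch_rows(lm2[, g1, drop = FALSE], lm2[, !g1, drop = FALSE])
  delta_log2 <- rowMeans(lm2[, !g1, drop = FALSE]) -
    rowMeans(lm2[, g1, drop = FALSE])
  tibble(gene_id = wide$gene_id,
         beta = delta_log2 * log(2),
         p_value = w$p,
         q_value = p.adjust(w$p, method = "BH"))
}

#' Default pipeline run configuration
#'
#' A fully specified profile holding the standard analysis parameters: the
#' Ribo-seq linker adapter, 29--33 nt length retention, pause z >= 10 with
#' 0.5 reads/codon density in all samples and >= 2 replicates for the
#' consensus, AGA +/-1-codon A-site read filtering, and histone-prefix
#' removal for TE.
#'
#' @param outdir output directory for all stage artifacts.
#' @param seed base seed for the synthetic run.
#' @param ... overrides for `simulate` (passed to [sim_config()]).
#' @return nested configuration list (YAML-serializable).
#' @export
default_run_config <- function(outdir = "ribopause_run", seed = 1L, ...) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = list(...),
    preprocess = list(adapter = "CTGTAGGCACCATCAAT", min_len = 29L,
                      max_len = 33L),
    asite = list(min_support = 50L),
    occupancy = list(site = "A", exclude_start = 1L, exclude_end = 1L),
    pause = list(min_density = 0.5, trim = 5L, z_min = 10, codon = "AGA",
                 min_replicates = 2L),
    te = list(filter_codon = "AGA", window = 1L, histone_prefix = "Hist",
              q_threshold = 0.05, top_genes = character())
  )
}

#' Validate a run configuration
#'
#' Checks every stage's preconditions up front and reports all violations at
#' once rather than failing on the first.
#'
#' @param config a configuration list (see [default_run_config()]).
#' @return character vector of violations; `character(0)` means ok.
#' @export
validate_config <- function(config) {
  v <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  need(is.character(config$outdir %||% NULL) && length(config$outdir) == 1L,
       "outdir must be a single path")
  need(is.numeric(config$seed %||% NULL) && length(config$seed) == 1L &&
         config$seed == round(config$seed), "seed must be an integer")
  sim_err <- tryCatch({
    do.call(sim_config, c(config$simulate %||% list(),
                          list(seed = as.integer(config$seed %||% 1L))))
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(sim_err)) v <- c(v, paste0("simulate: ", sim_err))
  pp <- config$preprocess %||% list()
  need(nchar(pp$adapter %||% "x") > 0, "preprocess: adapter must be non-empty")
  need((pp$min_len %||% 29L) <= (pp$max_len %||% 33L),
       "preprocess: min_len must be <= max_len")
  need((config$asite$min_support %||% 50L) >= 1,
       "asite: min_support must be >= 1")
  oc <- config$occupancy %||% list()
  need((oc$site %||% "A") %in% c("A", "P", "E"),
       "occupancy: site must be A, P or E")
  need((oc$exclude_start %||% 1L) >= 0 && (oc$exclude_end %||% 1L) >= 0,
       "occupancy: codon exclusions must be >= 0")
  pz <- config$pause %||% list()
  need((pz$z_min %||% 10) > 0, "pause: z_min must be > 0")
  need((pz$min_density %||% 0.5) >= 0, "pause: min_density must be >= 0")
  need((pz$trim %||% 5L) >= 0, "pause: trim must be >= 0")
  need((pz$min_replicates %||% 2L) >= 1, "pause: min_replicates must be >= 1")
  te <- config$te %||% list()
  need((te$window %||% 1L) >= 0, "te: window must be >= 0")
  need((te$q_threshold %||% 0.05) > 0 && (te$q_threshold %||% 0.05) <= 1,
       "te: q_threshold must lie in (0, 1]")
  v
}

#' Run the synthetic pause-analysis pipeline end to end
#'
#' Executes simulate -> preprocess -> asite -> occupancy -> pause -> te in
#' dependency order, writing every intermediate as TSV/FASTA under
#' `config$outdir`. Any subset of stages can be re-run from the serialized
#' intermediates of a previous run via `stages`; identical config + seed
#' give byte-identical outputs.
#'
#' @param config configuration list (see [default_run_config()]);
#'   validated before any compute.
#' @param stages stages to execute (default: all).
#' @return a `"run_report"` list: per-stage record counts, occupancy /
#'   pause / TE summaries, package version and config hash.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "asite",
                                    "occupancy", "pause", "te")) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    abort(paste0("invalid configuration:\n", paste("-", viol, collapse = "\n")))
  }
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out, paste0(...))
  cfg <- do.call(sim_config, c(config$simulate %||% list(),
                               list(seed = as.integer(config$seed))))
  report <- list(package_version = as.character(utils::packageVersion("ribopause")),
                 config_hash = rlang::hash(config), stages = list())
  log_line <- function(...) inform(sprintf(...))

  samples_grid <- tidyr::expand_grid(
    condition = c("control", "mutant"),
    replicate = seq_len(cfg$n_replicates_per_condition)) |>
    dplyr::mutate(sample = paste0(.data$condition, "_", .data$replicate))

  ## -- simulate ------------------------------------------------------------
  if ("simulate" %in% stages) {
    tx <- simulate_transcriptome(cfg)
    write_transcriptome(tx, pth("transcriptome.fa"), pth("cds_table.tsv"))
    effects <- simulate_gene_effects(tx, cfg)
    readr::write_tsv(effects, pth("true_effects.tsv"))
    truth_all <- list()
    for (j in seq_len(nrow(samples_grid))) {
      s <- samples_grid[j, ]
      lib <- simulate_footprints(tx, cfg, replicate = s$replicate,
                                 condition = s$condition, effects = effects)
      write_footprints(lib$footprints, pth("footprints_raw_", s$sample, ".tsv"))
      truth_all[[s$sample]] <- dplyr::mutate(lib$paused_sites, sample = s$sample)
      log_line("simulate: %s, %d footprints, %d implanted pauses",
               s$sample, nrow(lib$footprints), nrow(lib$paused_sites))
    }
    readr::write_tsv(dplyr::bind_rows(truth_all), pth("true_paused_sites.tsv"))
    rna <- simulate_rna_counts(tx, cfg, effects)
    readr::write_tsv(rna, pth("rna_counts.tsv"))
    report$stages$simulate <- list(
      n_genes = nrow(tx), reads_per_library = cfg$reads_per_library)
  }
  tx <- read_transcriptome(pth("transcriptome.fa"), pth("cds_table.tsv"))
  rna <- readr::read_tsv(pth("rna_counts.tsv"), show_col_types = FALSE)

  ## -- preprocess ----------------------------------------------------------
  if ("preprocess" %in% stages) {
    pp <- config$preprocess
    stats <- list()
    for (s in samples_grid$sample) {
      fp <- ingest_alignments(pth("footprints_raw_", s, ".tsv"), tx)
      fp <- filter_lengths(fp, pp$min_len %||% 29L, pp$max_len %||% 33L)
      write_footprints(fp, pth("footprints_", s, ".tsv"))
      stats[[s]] <- dplyr::mutate(stage_stats(fp), sample = s)
      log_line("preprocess: %s, retained %d reads", s, nrow(fp))
    }
    stats <- dplyr::bind_rows(stats)
    readr::write_tsv(stats, pth("preprocess_stats.tsv"))
    report$stages$preprocess <- stats
  }

  ## -- asite ---------------------------------------------------------------
  if ("asite" %in% stages) {
    all_counts <- list(); all_offsets <- list(); outside <- integer()
    for (s in samples_grid$sample) {
      fp <- read_footprints(pth("footprints_", s, ".tsv"))
      off <- calibrate_offsets(fp, tx,
                               min_support = config$asite$min_support %||% 50L)
      asg <- assign_asite(fp, off, tx)
      cnt <- count_asite_codons(dplyr::mutate(asg, sample = s))
      all_offsets[[s]] <- dplyr::mutate(off, sample = s)
      all_counts[[s]] <- cnt
      outside[s] <- attr(cnt, "outside_cds")
      log_line("asite: %s, %d in-CDS A-site reads (%d outside CDS)",
               s, sum(cnt$count), attr(cnt, "outside_cds"))
    }
    readr::write_tsv(dplyr::bind_rows(all_offsets), pth("offsets.tsv"))
    readr::write_tsv(dplyr::bind_rows(all_counts), pth("codon_counts.tsv"))
    report$stages$asite <- list(outside_cds = outside)
  }
  counts <- readr::read_tsv(pth("codon_counts.tsv"), show_col_types = FALSE)

  ## -- occupancy -----------------------------------------------------------
  if ("occupancy" %in% stages) {
    oc <- config$occupancy
    occ <- codon_occupancy(counts, tx, site = oc$site %||% "A",
                           exclude_start = oc$exclude_start %||% 1L,
                           exclude_end = oc$exclude_end %||% 1L)
    readr::write_tsv(occ, pth("occupancy.tsv"))
    mut_occ <- occ[grepl("^mutant", occ$sample), ]
    occ_sum <- summarize_occupancy(mut_occ)
    readr::write_tsv(occ_sum, pth("occupancy_summary_mutant.tsv"))
    pc <- occ_sum$mean_ratio[occ_sum$codon == cfg$pause_codon]
    report$stages$occupancy <- list(
      mutant_pause_codon_ratio = pc,
      mutant_max_other = max(occ_sum$mean_ratio[occ_sum$codon != cfg$pause_codon],
                             na.rm = TRUE))
    log_line("occupancy: mutant %s ratio %.2f", cfg$pause_codon, pc)
  }

  ## -- pause ---------------------------------------------------------------
  if ("pause" %in% stages) {
    pz <- config$pause
    analyzed <- threshold_transcripts(counts, tx,
                                      min_density = pz$min_density %||% 0.5)
    mut_counts <- counts[grepl("^mutant", counts$sample), ]
    scores <- pause_scores(mut_counts, tx, transcripts = analyzed,
                           trim = pz$trim %||% 5L)
    readr::write_tsv(scores, pth("pause_scores.tsv"))
    calls <- call_pause_genes(scores, z_min = pz$z_min %||% 10,
                              codon = pz$codon %||% "AGA",
                              min_replicates = pz$min_replicates %||% 2L)
    readr::write_tsv(calls$by_replicate, pth("pause_genes_by_replicate.tsv"))
    readr::write_tsv(tibble(gene_id = calls$consensus),
                     pth("pause_genes_consensus.tsv"))
    ov <- intersect_pause_sets(calls$sets)
    readr::write_tsv(ov$pairwise, pth("pause_overlap.tsv"))
    effects_path <- config$pause$effects_table %||% NULL
    eff <- if (!is.null(effects_path)) {
      readr::read_tsv(effects_path, show_col_types = FALSE)
    } else {
      conditions <- setNames(samples_grid$condition, samples_grid$sample)
      differential_expression(rna, conditions)
    }
    cor_res <- correlate_pause_with_expression(scores, eff)
    report$stages$pause <- list(
      n_analyzed_transcripts = length(analyzed),
      n_called_per_replicate = vapply(calls$sets, length, integer(1)),
      n_consensus = length(calls$consensus),
      mean_shared_fraction = ov$mean_shared_fraction,
      spearman_rho = cor_res$rho, spearman_p = cor_res$p_value)
    log_line("pause: %d analyzed transcripts, consensus %d genes, mean shared fraction %.2f",
             length(analyzed), length(calls$consensus), ov$mean_shared_fraction)
  }

  ## -- te ------------------------------------------------------------------
  if ("te" %in% stages) {
    tecfg <- config$te
    conditions <- setNames(samples_grid$condition, samples_grid$sample)
    offsets <- readr::read_tsv(pth("offsets.tsv"), show_col_types = FALSE)
    asg_all <- purrr::map(samples_grid$sample, function(s) {
      fp <- read_footprints(pth("footprints_", s, ".tsv"))
      off <- offsets[offsets$sample == s, ]
      dplyr::mutate(assign_asite(fp, off, tx), sample = s)
    }) |> dplyr::bind_rows()
    filt <- gene_filters(histone_prefix = tecfg$histone_prefix %||% "Hist",
                         top_genes = tecfg$top_genes %||% character())
    tec <- count_for_te(asg_all, rna, tx, filt)
    readr::write_tsv(tec, pth("te_counts.tsv"))
    fit <- differential_te(tec, conditions)
    readr::write_tsv(fit, pth("te_results.tsv"))
    asg_f <- filter_codon_asite_reads(asg_all, tx,
                                      codon = tecfg$filter_codon %||% "AGA",
                                      window = tecfg$window %||% 1L)
    tec_f <- count_for_te(asg_f, rna, tx, filt)
    fit_f <- differential_te(tec_f, conditions)
    readr::write_tsv(fit_f, pth("te_results_codon_filtered.tsv"))
    n_sig <- function(f) sum(f$q_value <= (tecfg$q_threshold %||% 0.05),
                             na.rm = TRUE)
    report$stages$te <- list(
      n_genes = nrow(fit), n_altered = n_sig(fit),
      n_altered_codon_filtered = n_sig(fit_f),
      reads_removed_by_codon_filter = nrow(asg_all) - nrow(asg_f))
    if (length(filt$top_genes) > 0) {
      top <- top_gene_report(fit, filt$top_genes, tecfg$q_threshold %||% 0.05)
      readr::write_tsv(top$table, pth("te_top_genes.tsv"))
      report$stages$te$top_detected <- top$n_detected
      report$stages$te$top_altered <- top$n_altered
    }
    log_line("te: %d genes, %d altered (%d after %s filtering)",
             nrow(fit), n_sig(fit), n_sig(fit_f), tecfg$filter_codon %||% "AGA")
  }

  class(report) <- "run_report"
  yaml::write_yaml(report_to_yaml(report), pth("run_report.yaml"))
  report
}

report_to_yaml <- function(report) {
  rapply(unclass(report), how = "replace", f = function(x) {
    if (inherits(x, "data.frame")) as.list(x) else x
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> ribopause %s, config %s\n",
              x$package_version, x$config_hash))
  for (s in names(x$stages)) cat("  stage:", s, "\n")
  if (!is.null(x$stages$pause)) {
    cat(sprintf("  pause: consensus %d genes, mean shared fraction %.2f\n",
                x$stages$pause$n_consensus, x$stages$pause$mean_shared_fraction))
  }
  if (!is.null(x$stages$te)) {
    cat(sprintf("  te: %d genes, %d altered (%d after codon filtering)\n",
                x$stages$te$n_genes, x$stages$te$n_altered,
                x$stages$te$n_altered_codon_filtered))
  }
  invisible(x)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys as in [default_run_config()].
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(outdir = cfg$outdir %||% "ribopause_run",
                             seed = cfg$seed %||% 1L)
  utils::modifyList(base, cfg)
}
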