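#' Generate a synthetic coding transcriptome
#'
#' Builds one transcript per gene: a 5'UTR, an ATG start codon, a CDS body of
#' sense codons drawn i.i.d. from `codon_usage`, a stop codon, and a 3'UTR.
#' By construction no stop codon occurs inside the CDS body. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `sequence`, `cds_start`, `cds_end` (0-based, half-open, transcript
#'   coordinates) and `n_codons` (CDS codons including start and stop).
#' @export
simulate_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "transcriptome"))
  sense <- names(config$codon_usage)
  bases <- c("A", "C", "G", "T")
  body_len <- sample(seq(config$cds_length_range[1], config$cds_length_range[2]),
                     config$n_genes, replace = TRUE)
  rows <- purrr::map(seq_len(config$n_genes), function(i) {
    utr5 <- paste(sample(bases, config$utr5_length, replace = TRUE), collapse = "")
    utr3 <- paste(sample(bases, config$utr3_length, replace = TRUE), collapse = "")
    body <- paste(sample(sense, body_len[i], replace = TRUE,
                         prob = config$codon_usage), collapse = "")
    stopc <- sample(stop_codons(), 1L)
    cds <- paste0("ATG", body, stopc)
    tibble(
      transcript_id = sprintf("tx%04d", i),
      gene_id = sprintf("gene%04d", i),
      sequence = paste0(utr5, cds, utr3),
      cds_start = config$utr5_length,
      cds_end = config$utr5_length + nchar(cds),
      n_codons = body_len[i] + 2L
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate per-gene expression and translational-efficiency effects
#'
#' Draws the ground-truth effect table shared by the footprint and RNA-seq
#' simulators: a log-uniform base mean per gene, a transcriptional log2
#' shift (`de_log2`, nonzero for `de_fraction` of genes, sign random) and a
#' TE log2 shift (`te_log2`, nonzero for `te_shift_fraction` of genes)
#' applied in the mutant condition. Deterministic given `config$seed`.
#'
#' @param transcriptome output of [simulate_transcriptome()].
#' @param config a [sim_config()].
#' @return tibble: `gene_id`, `base_mean`, `de_log2`, `te_log2`.
#' @export
simulate_gene_effects <- function(transcriptome, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "effects"))
  genes <- transcriptome$gene_id
  n <- length(genes)
  base_mean <- exp(runif(n, log(config$rna_mean_range[1]),
                         log(config$rna_mean_range[2])))
  de <- rep(0, n)
  n_de <- round(config$de_fraction * n)
  if (n_de > 0) {
    idx <- sample.int(n, n_de)
    de[idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$de_effect
  }
  te <- rep(0, n)
  n_te <- round(config$te_shift_fraction * n)
  if (n_te > 0) {
    idx <- sample.int(n, n_te)
    te[idx] <- sample(c(-1, 1), n_te, replace = TRUE) * config$te_effect
  }
  tibble(gene_id = genes, base_mean = base_mean, de_log2 = de, te_log2 = te)
}

# Long table of codon instances for a transcriptome: one row per CDS codon.
codon_instances <- function(transcriptome) {
  cds <- substring(transcriptome$sequence, transcriptome$cds_start + 1L,
                   transcriptome$cds_end)
  codons <- lapply(cds, codon_vector)
  tibble(
    transcript_id = rep(transcriptome$transcript_id, lengths(codons)),
    gene_id = rep(transcriptome$gene_id, lengths(codons)),
    codon_index = unlist(lapply(lengths(codons), function(n) seq_len(n) - 1L)),
    codon = unlist(codons)
  )
}

#' Simulate one ribosome-footprint library
#'
#' Draws `reads_per_library` footprints for one biological replicate of one
#' condition. Elongation A-sites are placed multinomially over codon
#' instances (excluding the start codon, only ever decoded with the start in
#' the P-site, and the stop codon) with weight
#' abundance x dwell_weight; in the mutant condition each gene independently
#' receives a pause at one uniformly chosen instance of the pause codon with
#' probability `pause_gene_fraction`, multiplying that instance's weight by
#' `pause_multiplier`. A fraction `init_fraction` of reads are initiation
#' footprints (A-site on codon 1). Read lengths follow
#' `read_length_distribution` and the 5' position is the A-site nucleotide
#' minus the length's true offset.
#'
#' Genes selected for pausing but lacking the pause codon in their CDS body
#' are skipped with a message and counted in the result.
#'
#' @param transcriptome output of [simulate_transcriptome()].
#' @param config a [sim_config()].
#' @param replicate integer replicate id.
#' @param condition `"control"` or `"mutant"`.
#' @param effects optional effect table from [simulate_gene_effects()];
#'   recomputed deterministically from `config` when omitted.
#' @return a list of class `"fp_library"`:
#'   \describe{
#'     \item{footprints}{tibble `read_id`, `transcript_id`, `five_prime_pos`,
#'       `length` — one row per footprint.}
#'     \item{truth}{tibble of ground-truth A-site draws: `transcript_id`,
#'       `gene_id`, `codon_index`, `codon`, `count`, `is_init`.}
#'     \item{paused_sites}{tibble `gene_id`, `transcript_id`, `replicate`,
#'       `condition`, `codon_index` of implanted pauses.}
#'     \item{offsets}{tibble `length`, `a_offset` — the generator's truth.}
#'     \item{n_pause_skipped}{genes selected for pausing without a pause-codon
#'       instance.}
#'   }
#' @export
simulate_footprints <- function(transcriptome, config, replicate = 1L,
                                condition = c("control", "mutant"),
                                effects = NULL) {
  validate_sim_config(config)
  condition <- match.arg(condition)
  if (is.null(effects)) effects <- simulate_gene_effects(transcriptome, config)
  set.seed(derive_seed(config$seed, "footprints", replicate, condition))

  inst <- codon_instances(transcriptome) |>
    dplyr::left_join(
      dplyr::select(transcriptome, "transcript_id", "cds_start", "n_codons"),
      by = "transcript_id")
  # elongation positions: codons 1 .. n_codons-2 (excludes start + stop)
  elo <- inst |>
    dplyr::filter(.data$codon_index >= 1L,
                  .data$codon_index <= .data$n_codons - 2L)
  mut <- condition == "mutant"
  elo$weight <- unname(config$dwell_weights[elo$codon])

  paused <- tibble(gene_id = character(), transcript_id = character(),
                   replicate = integer(), condition = character(),
                   codon_index = integer())
  n_skipped <- 0L
  if (mut && config$pause_gene_fraction > 0) {
    genes <- transcriptome$gene_id
    hit <- genes[runif(length(genes)) < config$pause_gene_fraction]
    if (length(hit) > 0) {
      cand <- which(elo$gene_id %in% hit & elo$codon == config$pause_codon)
      if (length(cand) > 0) {
        pick <- vapply(split(cand, elo$gene_id[cand]), function(ix) {
          if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
        }, integer(1))
        elo$weight[pick] <- elo$weight[pick] * config$pause_multiplier
        paused <- tibble(
          gene_id = elo$gene_id[pick],
          transcript_id = elo$transcript_id[pick],
          replicate = as.integer(replicate),
          condition = condition,
          codon_index = elo$codon_index[pick])
      }
      n_skipped <- length(setdiff(hit, elo$gene_id[elo$codon == config$pause_codon]))
      if (n_skipped > 0) {
        inform(sprintf(
          "%d gene(s) selected for pausing carry no %s codon; no pause implanted",
          n_skipped, config$pause_codon))
      }
    }
  }

  abundance <- effects$base_mean *
    2^(effects$de_log2 * mut) * 2^(effects$te_log2 * mut)
  names(abundance) <- effects$gene_id
  elo$weight <- elo$weight * unname(abundance[elo$gene_id])

  # initiation component: start codon in the P-site, A-site on codon 1
  f <- config$init_fraction
  draws <- elo |> dplyr::mutate(is_init = FALSE)
  if (f > 0) {
    init <- elo |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::summarise(
        gene_id = dplyr::first(.data$gene_id),
        codon_index = 1L,
        codon = .data$codon[.data$codon_index == 1L][1],
        cds_start = dplyr::first(.data$cds_start),
        n_codons = dplyr::first(.data$n_codons),
        weight = sum(.data$weight) * f / (1 - f),
        .groups = "drop") |>
      dplyr::mutate(is_init = TRUE)
    draws <- dplyr::bind_rows(draws, init)
  }

  counts <- as.integer(rmultinom(1L, config$reads_per_library,
                                 draws$weight / sum(draws$weight)))
  truth <- draws |>
    dplyr::mutate(count = counts) |>
    dplyr::select("transcript_id", "gene_id", "codon_index", "codon",
                  "count", "is_init", "cds_start")

  hit <- truth[truth$count > 0L, ]
  idx <- rep.int(seq_len(nrow(hit)), hit$count)
  n_reads <- length(idx)
  lens <- as.integer(names(config$read_length_distribution))
  read_len <- sample(lens, n_reads, replace = TRUE,
                     prob = config$read_length_distribution)
  a_nt <- hit$cds_start[idx] + 3L * hit$codon_index[idx]
  fp <- tibble(
    read_id = sprintf("r%07d", seq_len(n_reads)),
    transcript_id = hit$transcript_id[idx],
    five_prime_pos = a_nt - unname(config$true_offsets[as.character(read_len)]),
    length = read_len
  )
  structure(list(
    footprints = fp,
    truth = dplyr::select(truth, -"cds_start"),
    paused_sites = paused,
    offsets = tibble(length = lens,
                     a_offset = as.integer(unname(config$true_offsets))),
    n_pause_skipped = n_skipped,
    replicate = as.integer(replicate),
    condition = condition
  ), class = "fp_library")
}

#' @export
print.fp_library <- function(x, ...) {
  cat(sprintf("<fp_library> %s replicate %d: %d footprints, %d implanted pause site(s)\n",
              x$condition, x$replicate, nrow(x$footprints), nrow(x$paused_sites)))
  invisible(x)
}

#' Simulate a matched RNA-seq count table
#'
#' Negative-binomial gene-level counts for all replicates of both conditions,
#' with mean `base_mean * 2^de_log2` in the mutant. TE shifts do not touch
#' RNA counts (they act on footprint abundance only), which is precisely what
#' makes them translational. `rna_dispersion = 0` gives the Poisson limit.
#'
#' @inheritParams simulate_footprints
#' @return tibble: `gene_id`, `sample` (e.g. `"mutant_2"`), `condition`,
#'   `replicate`, `count`. Deterministic given `config$seed`.
#' @export
simulate_rna_counts <- function(transcriptome, config, effects = NULL) {
  validate_sim_config(config)
  if (config$rna_dispersion < 0) abort("rna_dispersion must be >= 0")
  if (is.null(effects)) effects <- simulate_gene_effects(transcriptome, config)
  set.seed(derive_seed(config$seed, "rna"))
  n <- nrow(effects)
  grid <- tidyr::expand_grid(
    condition = c("control", "mutant"),
    replicate = seq_len(config$n_replicates_per_condition))
  out <- purrr::pmap(grid, function(condition, replicate) {
    mu <- effects$base_mean * 2^(effects$de_log2 * (condition == "mutant"))
    cnt <- if (config$rna_dispersion == 0) {
      rpois(n, mu)
    } else {
      rnbinom(n, mu = mu, size = 1 / config$rna_dispersion)
    }
    tibble(gene_id = effects$gene_id,
           sample = paste0(condition, "_", replicate),
           condition = condition,
           replicate = as.integer(replicate),
           count = as.integer(cnt))
  })
  dplyr::bind_rows(out)
}
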