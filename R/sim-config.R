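#' Simulation configuration for the synthetic Ribo-seq generator
#'
#' Bundles every knob of the synthetic-data module: transcriptome geometry,
#' the codon dwell-time model with stochastic pause implantation, footprint
#' library composition, and the matched RNA-seq negative-binomial model.
#'
#' The elongation model assigns each codon instance a dwell weight
#' \eqn{w_c}; A-site positions are drawn multinomially with those weights.
#' In the `mutant` condition each gene independently (per replicate) acquires
#' a pause with probability `pause_gene_fraction` at one uniformly chosen
#' instance of `pause_codon`, whose weight is multiplied by
#' `pause_multiplier`. This emulates stochastic ribosome stalling at AGA
#' codons when the decoding arginine tRNA pool is limiting.
#'
#' A small fraction of reads (`init_fraction`) are initiation footprints with
#' the start codon in the ribosomal P-site (A-site on codon 1). Real
#' start-codon metagenes carry exactly this peak, and the per-read-length
#' A-site offset calibration relies on it.
#'
#' @param n_genes number of genes (one transcript per gene).
#' @param cds_length_range integer c(min, max): CDS body length in codons,
#'   excluding the start and stop codons.
#' @param codon_usage named probability vector over the 61 sense codons
#'   (must sum to 1); default uniform.
#' @param dwell_weights named positive vector over the 61 sense codons:
#'   relative A-site dwell time per codon identity; default all 1.
#' @param pause_codon codon identity receiving stochastic pauses ("AGA").
#' @param pause_multiplier dwell multiplier k applied at a paused instance.
#' @param pause_gene_fraction probability p that a gene carries a pause in a
#'   given mutant replicate.
#' @param reads_per_library footprints per simulated library (exact total).
#' @param read_length_distribution named probability vector over footprint
#'   lengths 26--34 nt (must sum to 1).
#' @param true_offsets named integer vector: A-site offset (nt from the read
#'   5' end) per read length 26--34.
#' @param init_fraction expected fraction of initiation footprints.
#' @param utr5_length,utr3_length UTR lengths in nt.
#' @param n_replicates_per_condition biological replicates per condition.
#' @param rna_mean_range c(min, max) for per-gene RNA-seq base means
#'   (log-uniformly drawn).
#' @param rna_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0, or 0 for the Poisson limit.
#' @param de_fraction,de_effect fraction of genes with a transcriptional
#'   shift in the mutant and its log2 magnitude (sign random per gene).
#' @param te_shift_fraction,te_effect fraction of genes with a translational
#'   efficiency shift in the mutant and its log2 magnitude (sign random).
#' @param seed base integer seed; every library stream is derived from it.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 100L,
                       cds_length_range = c(150L, 300L),
                       codon_usage = NULL,
                       dwell_weights = NULL,
                       pause_codon = "AGA",
                       pause_multiplier = 50,
                       pause_gene_fraction = 0.5,
                       reads_per_library = 2e5,
                       read_length_distribution = NULL,
                       true_offsets = NULL,
                       init_fraction = 0.02,
                       utr5_length = 30L,
                       utr3_length = 30L,
                       n_replicates_per_condition = 3L,
                       rna_mean_range = c(50, 500),
                       rna_dispersion = 0.02,
                       de_fraction = 0.1,
                       de_effect = 1,
                       te_shift_fraction = 0.1,
                       te_effect = 1,
                       seed = 1L) {
  sense <- sense_codons()
  if (is.null(codon_usage)) {
    codon_usage <- setNames(rep(1 / length(sense), length(sense)), sense)
  }
  if (is.null(dwell_weights)) {
    dwell_weights <- setNames(rep(1, length(sense)), sense)
  }
  lens <- 26:34
  if (is.null(read_length_distribution)) {
    read_length_distribution <- setNames(
      c(0.01, 0.02, 0.05, 0.18, 0.22, 0.24, 0.17, 0.08, 0.03), lens)
  }
  if (is.null(true_offsets)) {
    true_offsets <- setNames(c(12L, 13L, 14L, 15L, 15L, 16L, 16L, 17L, 17L), lens)
  }
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    cds_length_range = as.integer(cds_length_range),
    codon_usage = codon_usage,
    dwell_weights = dwell_weights,
    pause_codon = pause_codon,
    pause_multiplier = pause_multiplier,
    pause_gene_fraction = pause_gene_fraction,
    reads_per_library = as.integer(reads_per_library),
    read_length_distribution = read_length_distribution,
    true_offsets = true_offsets,
    init_fraction = init_fraction,
    utr5_length = as.integer(utr5_length),
    utr3_length = as.integer(utr3_length),
    n_replicates_per_condition = as.integer(n_replicates_per_condition),
    rna_mean_range = rna_mean_range,
    rna_dispersion = rna_dispersion,
    de_fraction = de_fraction,
    de_effect = de_effect,
    te_shift_fraction = te_shift_fraction,
    te_effect = te_effect,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  sense <- sense_codons()
  stopifnot(is.list(cfg))
  if (cfg$n_genes < 1L) abort("n_genes must be >= 1")
  if (length(cfg$cds_length_range) != 2L ||
      cfg$cds_length_range[1] > cfg$cds_length_range[2]) {
    abort("cds_length_range must be c(min, max) with min <= max")
  }
  if (cfg$cds_length_range[1] < 1L) abort("CDS body must have >= 1 codon")
  if (!setequal(names(cfg$codon_usage), sense)) {
    abort("codon_usage must be named over the 61 sense codons")
  }
  if (abs(sum(cfg$codon_usage) - 1) > 1e-9) abort("codon_usage must sum to 1")
  if (any(cfg$codon_usage < 0)) abort("codon_usage must be non-negative")
  if (!setequal(names(cfg$dwell_weights), sense)) {
    abort("dwell_weights must be named over the 61 sense codons")
  }
  if (any(cfg$dwell_weights <= 0)) abort("all dwell_weights must be > 0")
  if (!(cfg$pause_codon %in% sense)) abort("pause_codon must be a sense codon")
  if (cfg$pause_multiplier <= 0) abort("pause_multiplier must be > 0")
  if (cfg$pause_gene_fraction < 0 || cfg$pause_gene_fraction > 1) {
    abort("pause_gene_fraction must lie in [0, 1]")
  }
  if (cfg$reads_per_library < 0L) abort("reads_per_library must be >= 0")
  if (!identical(sort(as.integer(names(cfg$read_length_distribution))), 26:34)) {
    abort("read_length_distribution must be named over lengths 26..34")
  }
  if (abs(sum(cfg$read_length_distribution) - 1) > 1e-9) {
    abort("read_length_distribution must sum to 1")
  }
  if (!identical(sort(as.integer(names(cfg$true_offsets))), 26:34)) {
    abort("true_offsets must be named over lengths 26..34")
  }
  lens <- as.integer(names(cfg$true_offsets))
  if (any(cfg$true_offsets <= 0 | cfg$true_offsets >= lens)) {
    abort("each A-site offset must satisfy 0 < offset < read length")
  }
  if (cfg$init_fraction < 0 || cfg$init_fraction >= 1) {
    abort("init_fraction must lie in [0, 1)")
  }
  if (cfg$rna_dispersion < 0) abort("rna_dispersion must be >= 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1 ||
      cfg$te_shift_fraction < 0 || cfg$te_shift_fraction > 1) {
    abort("de_fraction and te_shift_fraction must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d, CDS body %d-%d codons, %d reads/library\n",
              x$n_genes, x$cds_length_range[1], x$cds_length_range[2],
              x$reads_per_library))
  cat(sprintf("  pause: %s x%g, per-gene probability %.2f (mutant condition)\n",
              x$pause_codon, x$pause_multiplier, x$pause_gene_fraction))
  cat(sprintf("  RNA: NB mean %g-%g, dispersion %g; DE %g @ %g log2; TE %g @ %g log2\n",
              x$rna_mean_range[1], x$rna_mean_range[2], x$rna_dispersion,
              x$de_fraction, x$de_effect, x$te_shift_fraction, x$te_effect))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
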