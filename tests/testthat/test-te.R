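make_te_fixture <- function(seed = 2, n_genes = 40, te_effect = 1,
                            te_fraction = 0.1, reads = 5e4) {
  cfg <- sim_config(n_genes = n_genes, cds_length_range = c(80, 150),
                    reads_per_library = reads, pause_gene_fraction = 0,
                    de_fraction = 0, te_shift_fraction = te_fraction,
                    te_effect = te_effect, n_replicates_per_condition = 3,
                    seed = seed)
  tx <- simulate_transcriptome(cfg)
  eff <- simulate_gene_effects(tx, cfg)
  asg <- purrr::pmap(expand.grid(rep = 1:3, cond = c("control", "mutant"),
                                 stringsAsFactors = FALSE),
                     function(rep, cond) {
                       lib <- simulate_footprints(tx, cfg, rep, cond, eff)
                       dplyr::mutate(
                         assign_asite(lib$footprints, lib$offsets, tx),
                         sample = paste0(cond, "_", rep))
                     }) |> dplyr::bind_rows()
  rna <- simulate_rna_counts(tx, cfg, eff)
  conditions <- setNames(rna$condition[!duplicated(rna$sample)],
                         rna$sample[!duplicated(rna$sample)])
  list(cfg = cfg, tx = tx, eff = eff, asg = asg, rna = rna,
       conditions = conditions)
}

test_that("histone-prefix and exclusion filtering is exact and case-sensitive", {
  tx <- make_tx(rep(paste(rep("GAA", 20), collapse = ""), 3),
                gene_ids = c("Hist1h1a", "Actb", "history"))
  offs <- tibble::tibble(length = 30L, a_offset = 15L)
  fp <- tibble::tibble(read_id = sprintf("r%d", 1:6),
                       transcript_id = rep(tx$transcript_id, 2),
                       five_prime_pos = 30L, length = 30L)
  asg <- dplyr::mutate(assign_asite(fp, offs, tx), sample = "s1")
  rna <- tibble::tibble(gene_id = rep(tx$gene_id, 1), sample = "s1",
                        count = 10L)
  tec <- quiet(count_for_te(asg, rna, tx, gene_filters()))
  # "Hist" prefix removed; "history" (lower case) retained: exact match only
  expect_setequal(unique(tec$gene_id), c("Actb", "history"))
  tec2 <- quiet(count_for_te(asg, rna, tx,
                             gene_filters(exclude = "history")))
  expect_setequal(unique(tec2$gene_id), "Actb")
  # genes in one assay only are dropped with a message
  expect_message(
    count_for_te(asg, rna[rna$gene_id != "Actb", ], tx, gene_filters()),
    "only one assay")
})

test_that("footprint TE counts equal a brute-force in-CDS tally", {
  fx <- make_te_fixture(seed = 4, n_genes = 10, reads = 5e3)
  tec <- count_for_te(fx$asg, fx$rna, fx$tx, gene_filters())
  tally <- fx$asg |>
    dplyr::filter(in_cds) |>
    dplyr::inner_join(dplyr::select(fx$tx, transcript_id, gene_id),
                      by = "transcript_id")
  set.seed(1)
  for (i in sample.int(nrow(tec), 25)) {
    expect_equal(tec$footprint[i],
                 sum(tally$gene_id == tec$gene_id[i] &
                       tally$sample == tec$sample[i]))
  }
})

test_that("differential TE recovers simulated shifts and cancels scaling", {
  fx <- make_te_fixture(seed = 6, n_genes = 60, reads = 1e5)
  tec <- count_for_te(fx$asg, fx$rna, fx$tx, gene_filters())
  fit <- differential_te(tec, fx$conditions)
  j <- dplyr::inner_join(fit, fx$eff, by = "gene_id")
  shifted <- j[j$te_log2 != 0, ]
  expect_gt(nrow(shifted), 2)
  expect_lt(max(abs(shifted$delta_log2_te - shifted$te_log2)), 0.35)
  expect_lt(abs(mean(j$delta_log2_te[j$te_log2 == 0])), 0.1)

  # multiplying every footprint library by a constant is absorbed by the
  # size factors: delta log2 TE unchanged
  tec_scaled <- dplyr::mutate(tec, footprint = footprint * 7L)
  fit_scaled <- differential_te(tec_scaled, fx$conditions)
  # invariance is exact up to the unscaled pseudocount (0.5 on counts ~100+)
  expect_equal(fit_scaled$delta_log2_te, fit$delta_log2_te, tolerance = 1e-2)

  # identically scaled footprint and RNA counts between conditions -> no TE
  base <- tidyr::crossing(gene_id = sprintf("g%02d", 1:20),
                          sample = names(fx$conditions)) |>
    dplyr::mutate(
      base_n = 100L + (as.integer(factor(gene_id)) %% 7L) * 10L,
      footprint = base_n * ifelse(grepl("mutant", sample), 3L, 1L),
      rna = footprint) |>
    dplyr::select(gene_id, sample, footprint, rna)
  fit0 <- differential_te(base, fx$conditions)
  expect_true(all(abs(fit0$delta_log2_te) < 1e-9))
})

test_that("Welch statistics and BH q-values match independent references", {
  set.seed(8)
  x <- matrix(rnorm(30), nrow = 5)  # 5 genes x 6 samples
  g1 <- x[, 1:3, drop = FALSE]; g2 <- x[, 4:6, drop = FALSE]
  w <- ribopause:::welch_rows(g1, g2)
  for (i in 1:5) {
    tt <- stats::t.test(g2[i, ], g1[i, ])
    expect_equal(w$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df[i], unname(tt$parameter), tolerance = 1e-12)
    expect_equal(w$p[i], tt$p.value, tolerance = 1e-12)
  }
  p <- c(0.01, 0.4, 0.03, 0.002, 0.9, 0.2, 0.05, 0.6, 0.001, 0.07)
  expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
})

test_that("codon-window read filtering removes exactly the windowed reads", {
  # AGA at codon 5 of a 12-codon CDS; reads with A-site codons 3..8
  body <- paste(c(rep("GCT", 4), "AGA", rep("GCT", 5)), collapse = "")
  tx <- make_tx(body)
  offs <- tibble::tibble(length = 30L, a_offset = 15L)
  fp <- tibble::tibble(read_id = sprintf("c%d", 3:8),
                       transcript_id = "tx0001",
                       five_prime_pos = tx$cds_start + 3L * (3:8) - 15L,
                       length = 30L)
  asg <- assign_asite(fp, offs, tx)
  kept <- filter_codon_asite_reads(asg, tx, codon = "AGA", window = 1L)
  expect_setequal(kept$read_id, c("c3", "c7", "c8"))
  st <- stage_stats(kept)
  expect_equal(st$input, st$retained + st$discarded)
  # window 0 removes only the direct A-site hit
  kept0 <- filter_codon_asite_reads(asg, tx, codon = "AGA", window = 0L)
  expect_setequal(kept0$read_id, paste0("c", c(3, 4, 6, 7, 8)))
  # a transcript without the codon is untouched
  tx2 <- make_tx(paste(rep("GCT", 12), collapse = ""))
  asg2 <- assign_asite(dplyr::mutate(fp, transcript_id = "tx0001"), offs, tx2)
  expect_equal(nrow(filter_codon_asite_reads(asg2, tx2, "AGA", 1L)),
               nrow(asg2))
})

test_that("codon filtering matches the brute-force window oracle on fuzzed reads", {
  cfg <- sim_config(n_genes = 6, cds_length_range = c(40, 80),
                    reads_per_library = 400, pause_gene_fraction = 0, seed = 44)
  tx <- simulate_transcriptome(cfg)
  lib <- simulate_footprints(tx, cfg, 1, "control")
  asg <- assign_asite(lib$footprints, lib$offsets, tx)
  for (w in 0:2) {
    kept <- filter_codon_asite_reads(asg, tx, codon = "AGA", window = w)
    cds <- setNames(substr(tx$sequence, tx$cds_start + 1, tx$cds_end),
                    tx$transcript_id)
    want_keep <- vapply(seq_len(nrow(asg)), function(i) {
      if (!asg$in_cds[i]) return(TRUE)
      !oracle_codon_hit(cds[[asg$transcript_id[i]]], asg$codon_index[i],
                        "AGA", w)
    }, logical(1))
    expect_setequal(kept$read_id, asg$read_id[want_keep])
  }
  # filtering never increases any count
  tec_full <- count_for_te(dplyr::mutate(asg, sample = "s"),
                           tibble::tibble(gene_id = tx$gene_id, sample = "s",
                                          count = 5L), tx)
  kept1 <- filter_codon_asite_reads(asg, tx, "AGA", 1L)
  tec_filt <- count_for_te(dplyr::mutate(kept1, sample = "s"),
                           tibble::tibble(gene_id = tx$gene_id, sample = "s",
                                          count = 5L), tx)
  j <- dplyr::left_join(tec_full, tec_filt, by = c("gene_id", "sample"),
                        suffix = c("_full", "_filt"))
  expect_true(all(dplyr::coalesce(j$footprint_filt, 0L) <= j$footprint_full))
})

test_that("TOP-gene reporting subsets detected genes and counts altered TE", {
  fx <- make_te_fixture(seed = 10, n_genes = 30, reads = 3e4)
  tec <- count_for_te(fx$asg, fx$rna, fx$tx, gene_filters())
  fit <- differential_te(tec, fx$conditions)
  top <- c(fit$gene_id[1:5], "not_a_gene")
  rep <- top_gene_report(fit, top)
  expect_equal(rep$n_detected, 5)
  expect_setequal(rep$table$gene_id, fit$gene_id[1:5])
  expect_equal(rep$n_altered,
               sum(fit$q_value[1:5] <= 0.05, na.rm = TRUE))
  empty <- top_gene_report(fit, "not_a_gene")
  expect_equal(empty$n_detected, 0)
  expect_equal(empty$n_altered, 0)
  expect_error(top_gene_report(fit, character()), "non-empty")
})

test_that("tidy and glance methods expose broom-style summaries", {
  fx <- make_te_fixture(seed = 12, n_genes = 20, reads = 2e4)
  tec <- count_for_te(fx$asg, fx$rna, fx$tx, gene_filters())
  fit <- differential_te(tec, fx$conditions)
  td <- generics::tidy(fit)
  expect_named(td, c("gene_id", "estimate", "statistic", "df", "p.value",
                     "q.value"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_genes, nrow(fit))
  expect_equal(gl$ref, "control"); expect_equal(gl$alt, "mutant")
})
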