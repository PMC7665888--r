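# Independent brute-force oracles used to cross-check the implementation.
# Each is written as plainly as possible (loops, no shared helpers with the
# package) so that agreement is evidence, not tautology.

# Spearman rho by explicit average-ranking and the Pearson sum formula.
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Benjamini-Hochberg step-up, literal definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  adj <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  q[o] <- pmin(adj, 1)
  q
}

# Within-window pause score and z per position, loop arithmetic.
oracle_pause_z <- function(counts) {
  mu <- sum(counts) / length(counts)
  sigma <- sqrt(sum((counts - mu)^2) / (length(counts) - 1))
  list(score = counts / mu, z = (counts - mu) / sigma)
}

# A-site codon by walking the transcript one nucleotide at a time.
oracle_assign <- function(five_prime_pos, a_offset, cds_start, cds_end) {
  nt <- five_prime_pos
  for (step in seq_len(a_offset)) nt <- nt + 1L
  if (nt < cds_start || nt >= cds_end) return(NA_integer_)
  idx <- 0L
  pos <- cds_start
  while (pos + 3L <= nt) {
    pos <- pos + 3L
    idx <- idx + 1L
  }
  idx
}

# Should this read be removed by the codon-window filter? Scan every codon
# of the window directly on the CDS string.
oracle_codon_hit <- function(cds_seq, a_codon_index, target, window) {
  n <- nchar(cds_seq) %/% 3L
  for (j in (a_codon_index - window):(a_codon_index + window)) {
    if (j < 0 || j > n - 1) next
    if (substr(cds_seq, 3 * j + 1, 3 * j + 3) == target) return(TRUE)
  }
  FALSE
}

# Modal value with ties broken toward the smaller value.
oracle_mode_min <- function(v) {
  best <- NULL; best_n <- -1L
  for (u in sort(unique(v))) {
    k <- sum(v == u)
    if (k > best_n) { best <- u; best_n <- k }
  }
  best
}

# --- fixture builders ------------------------------------------------------

# A transcriptome tibble from explicit CDS body codon strings.
make_tx <- function(bodies, utr5 = 30L, utr3 = 30L, stop_codon = "TAA",
                    gene_ids = NULL) {
  n <- length(bodies)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(n))
  u5 <- substr(strrep("ACGTT", ceiling(utr5 / 5)), 1, utr5)
  u3 <- substr(strrep("TTGCA", ceiling(utr3 / 5)), 1, utr3)
  cds <- paste0("ATG", bodies, stop_codon)
  tibble::tibble(
    transcript_id = sprintf("tx%04d", seq_len(n)),
    gene_id = gene_ids,
    sequence = paste0(u5, cds, u3),
    cds_start = utr5,
    cds_end = utr5 + nchar(cds),
    n_codons = nchar(cds) %/% 3L
  )
}

# Reads tibble for FASTQ-stage tests.
make_reads <- function(seqs, ids = sprintf("rd%03d", seq_along(seqs))) {
  tibble::tibble(read_id = ids, seq = seqs,
                 qual = vapply(nchar(seqs), function(n)
                   paste(rep("I", n), collapse = ""), character(1)))
}

# Sparse count tibble from a dense per-transcript count vector list.
make_counts <- function(tx, dense_list, sample = NULL) {
  out <- purrr::imap(dense_list, function(v, tid) {
    tibble::tibble(transcript_id = tid,
                   codon_index = seq_along(v) - 1L,
                   count = as.integer(v))
  }) |> dplyr::bind_rows() |> dplyr::filter(count > 0)
  if (!is.null(sample)) out$sample <- sample
  out
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

sense_codons_for_test <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}
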