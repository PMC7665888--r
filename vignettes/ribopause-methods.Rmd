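---
title: "Methods: codon-resolved ribosome pausing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-resolved ribosome pausing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When the pool of a cognate tRNA is limiting — the motivating case is the
brain-specific arginine tRNA decoding AGA in the C57BL/6J mouse background —
ribosomes dwell longer on the affected codon. Ribosome profiling reads this
out directly: the ~29–33 nt footprint of a translating 80S ribosome
identifies, after A-site offset calibration, the codon being decoded. This
package implements the analysis chain used to demonstrate codon-specific
pausing and its downstream consequences: per-read-length A-site calibration,
observed/expected codon occupancy, within-transcript pause z-scores with
replicate intersection, pause-versus-expression correlation, and
translational-efficiency (TE) analysis with codon-filtered re-analysis —
exercised end to end against a stochastic footprint simulator with known
ground truth.

# The statistics

## A-site offset calibration

For each retained read length $L$, the distance
$d = \text{cds\_start} - \text{five\_prime\_pos}$ is collected over reads
whose 5′ end lies upstream of the annotated start codon with a plausible
in-read P-site ($1 \le d \le L-4$). Initiating ribosomes hold the start
codon in the P-site, so the modal $d$ is the P-site offset; the A-site
offset is the mode plus 3 nt (one codon downstream, standard 80S geometry).
Ties break toward the smaller offset — deterministic and conservative.
Lengths with fewer than `min_support` (default 50) qualifying reads fall
back to the mode pooled across lengths, with a warning. Per-length offsets
are the primary mode; the global fallback covers thin length classes.

## Observed/expected codon occupancy

With $o(t,i)$ the A-site count at codon $i$ of transcript $t$ and footprints
assumed uniform across the coding region of each transcript, the expected
count is $e(t,i) = \text{total}(t)/n(t)$, constant per transcript. For a
codon identity $c$,

$$R_c = \frac{O_c}{E_c}
      = \frac{\sum_{(t,i):\,\mathrm{codon}(t,i)=c} o(t,i)}
             {\sum_{(t,i):\,\mathrm{codon}(t,i)=c} e(t,i)},$$

so $R_c \approx 1$ means average dwell and a slowly decoded codon shows
$R_c > 1$. Expectations are computed per transcript and then summed — never
pooled genome-wide — which makes $R_c$ insensitive to expression differences
between transcripts. The first and last CDS codons are excluded by default
(`exclude_start = exclude_end = 1`): initiation and termination geometry,
not elongation dwell, dominates them. Within the analysis window the sums
balance exactly, $\sum_c O_c = \sum_c E_c$. For `site = "P"` or `"E"` the
same reads are grouped by the codon one or two positions upstream of the
A-site index. Ratios across replicate libraries are summarised as
mean ± SEM.

## Pause z-scores

The pause statistic is defined within each transcript: over the analysis
window (CDS minus `trim = 5` codons at each end),

$$s(t,i) = \frac{o(t,i)}{\mu_t}, \qquad
  z(t,i) = \frac{o(t,i) - \mu_t}{\sigma_t},$$

with $\mu_t, \sigma_t$ the window mean and (sample) standard deviation. This
within-transcript standardisation is the central methodological choice: a
threshold as large as $z \ge 10$ is only meaningful for a spike measured
against the transcript's own background, and both statistics are invariant
under scaling all counts, so coverage depth alone can never create a pause.
A consequence worth knowing: a single spike among $m$ window positions
cannot exceed $z \approx \sqrt{m}$, so transcripts shorter than ~100 analysis
codons can never reach $z = 10$ regardless of pause strength. Transcripts
with $\sigma_t = 0$ are skipped (uniform coverage cannot pause).

Transcripts enter the analysis only if their read density (reads per CDS
codon) is at least 0.5 in **every** sample. Genes are called per replicate
when any site (optionally restricted to one codon identity, e.g. AGA)
reaches $z \ge 10$, both thresholds inclusive; the consensus set requires
calls in at least two biological replicates. Replicate sets are compared by
pairwise shared fractions $|A\cap B|/|A|$ and $|A\cap B|/|B|$ plus the full
three-set Venn partition: under stochastic per-replicate pausing with
per-gene probability $p$, the shared fractions centre on $p$, which is the
quantitative content of the "about half of pause genes are shared between
replicates" observation.

For the pause–expression comparison, a transcript's pause score is its
maximum $s(t,i)$, a gene's per-replicate score averages its transcripts,
the per-replicate scores are summed across replicates, and the sums are
Spearman-rank-correlated with gene-level expression effect sizes (beta,
natural-log scale). Ranks use average ties; the two-sided p-value is exact
by full permutation enumeration for $n \le 8$ and uses the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation above that. Exhaustive
enumeration up to $n = 10$ (0.4–3.6 million permutations) buys no practical
accuracy for this pipeline's reporting role, so the exact cutoff sits at 8.

## Translational efficiency

Footprint counts per gene are reads whose A-site lies in the CDS; RNA counts
are gene-level RNA-seq counts. Histone genes (case-sensitive name prefix
`Hist`) are removed, as are genes detected in only one assay. Each assay is
normalised by median-of-ratios size factors, then per gene and sample

$$\log_2 TE = \log_2\frac{FP + 0.5}{s^{FP}} - \log_2\frac{RNA + 0.5}{s^{RNA}},$$

followed by a per-gene Welch t-test between conditions and
Benjamini–Hochberg correction. The pseudocount 0.5 stabilises zeros and is
the only term that breaks exact scale invariance (by $O(0.5/\text{count})$).
The deliberately simple Welch-on-log-TE test answers "did TE change" without
pulling a count-model GLM into the core; parity with DESeq2-engine tools is
explicitly not attempted, and externally computed effect tables can be
supplied wherever the internal test would be used.

The codon-filtered re-analysis removes every read for which any codon within
±1 codon (clipped at CDS boundaries, never wrapped) of its assigned A-site
matches the target identity, then repeats the TE analysis — asking whether
TE changes survive removal of pause-associated footprints. The 5′TOP-gene
report restricts the fit to a supplied gene list and counts genes with
$q \le 0.05$.

# The synthetic-data generator

The generator defines the study conditions for every test. One transcript
per gene (a 1:1 map keeps ground truth unambiguous): 30 nt UTRs, ATG, a CDS
body of sense codons drawn i.i.d. from `codon_usage` (stop codons cannot
occur internally by construction), and a stop codon.

Elongation A-sites are drawn multinomially over codon instances with weight
(gene abundance) × (dwell weight $w_c$), excluding the start codon — which a
ribosome only holds in its P-site — and the stop codon. In the mutant
condition each gene independently per replicate receives a pause with
probability $p$ (`pause_gene_fraction`) at one uniformly chosen AGA
instance, multiplying that instance's weight by $k$ (`pause_multiplier`);
implanting exactly one site per selected gene per replicate is the simplest
model consistent with stochastic replicate overlap, and the implanted sites
are recorded as ground truth. A small fraction of reads (`init_fraction`,
default 2%) are initiation footprints with the start codon in the P-site:
real start-codon metagenes carry exactly this peak and the offset
calibration relies on it; at 2% it perturbs per-codon occupancy ratios by
well under the multinomial noise at the depths used. Read lengths follow a
26–34 nt distribution peaked at 30–31, each with a true A-site offset
(12–17 nt); the 5′ position is the A-site nucleotide minus that offset.
Every library contains exactly `reads_per_library` reads, and each library's
random stream is derived deterministically from (seed, replicate,
condition).

RNA-seq counts are negative binomial with log-uniform per-gene base means
(default 50–500) and dispersion 0.02 — typical for well-replicated bulk
data. A `de_fraction` of genes shifts expression by ±`de_effect` log2 units
in the mutant (both assays); a `te_shift_fraction` shifts footprint
abundance only, by ±`te_effect` log2 units, which is what makes the shift
translational.

Defaults were fixed by design analysis, not by iteration against tests:
CDS bodies of 150–300 codons, because the $z \le \sqrt{m}$ ceiling above
makes pauses on substantially shorter transcripts structurally undetectable
at $z \ge 10$; pause-run depths of ~2–3 reads/codon, comfortably above the
0.5 reads/codon analysis threshold; $k = 50$, strong enough to saturate the
within-transcript z; and an RNA dispersion/depth combination giving
per-sample log2 TE standard deviations near 0.25, for which a 3-vs-3 Welch
test has high power at one log2 unit.

**What the generator does not emulate:** sequencing errors, rRNA and other
contaminants, frame-periodicity noise, isoform mixtures, genome-space
placement, 5′ coverage ramps beyond the initiation peak, and biological
footprint overdispersion between replicates. Passing tests therefore
demonstrate correctness of the statistics under the stated model, not
robustness to every artefact of real libraries.

# Numerical and design choices

- Coordinates are 0-based, half-open, transcript-space everywhere;
  conversion happens only at file boundaries (BAM's 1-based `pos` is shifted
  on ingestion; primary alignments only, so multi-mapped reads count once).
- Adapter search is exact-match (bit-reproducible); a mismatch budget is a
  config extension point, not a default. Reads lacking the adapter are
  discarded by default — with 26–34 nt inserts on longer sequencing reads
  the adapter must be present — but `require_adapter = FALSE` passes them
  through, which makes clipping idempotent for pre-clipped input.
- Reads whose A-site falls in a UTR are excluded from all codon statistics
  and counted (`outside-CDS` is a value, not an error).
- Mode ties in calibration break toward the smaller offset; z-scores use the
  sample (n−1) standard deviation; BH correction via `stats::p.adjust`.
- Degenerate inputs: empty libraries give empty (not failing) count
  matrices; codons absent from the transcriptome give `NA` ratios; zero
  TE variance in both groups gives an `NA` p-value; all-equal occupancy
  ratios give all-zero z.
- The pipeline validates every stage's preconditions before any compute and
  reports all violations at once; identical config + seed give
  byte-identical artifacts, and any stage can resume from the serialized
  TSV intermediates of a previous run.

# Problem sizes in the shipped tests

The test suite exercises: null occupancy at 500 genes × 10^6 footprints;
pause recovery at 300 genes × 2×10^5 footprints with $k=50, p=1$ plus a
matched control; replicate overlap at $p = 0.5$ over 10 seeds × 2 replicates
(20 set pairs); offset round-trips at 100 genes × 2×10^5 reads; TE
calibration at 500 genes × 3-vs-3 over 20 null seeds (type-I) and 2
effect seeds (~100 shifted genes, power); and oracle-equivalence batches of
100+ fuzzed instances per statistic. These sizes give sub-percent Monte
Carlo error on the reported rates while keeping the default suite fast.

# Known limitations

- The within-transcript z is one member of a family of pause statistics;
  scores standardised against a transcriptome-wide background would scale
  differently and are not provided.
- The internal DE and TE tests are intentionally minimal; for real data,
  effect tables from dedicated tools are the intended input.
- Offset calibration assumes an initiation peak; libraries treated with
  initiation-depleting drugs would need externally supplied offsets (any
  tibble with `length` and `a_offset` columns works).
- TE counts footprints by A-site position only; paired-end RNA fragment
  counting subtleties (fractional multi-overlap assignment) are out of
  scope.
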