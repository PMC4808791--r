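---
title: "Pseudo-reference-based assembly decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-reference-based assembly decisions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pseudoref)
```

## The problem

RNA-seq can reconstruct a species' transcriptome either by mapping reads to
the species' own genome (reference-based assembly) or by stitching reads
together de novo. Reference-based assembly is more sensitive, especially for
weakly expressed genes, but most species have no sequenced genome. A middle
road is *pseudo-reference-based assembly* (PRA): map the reads to the genome
of a close relative. Whether that works, and with what aligner settings,
depends on how diverged the two species are. This package implements the
decision machinery around that idea:

1. estimate the **genetic distance** between the query species and a
   candidate pseudo-reference from marker sequences (one-to-one orthologs,
   16S rRNA, mitochondrial D-loop);
2. predict, from that distance, the **optimal mismatch rate** — the maximum
   allowed per-read mismatch fraction during mapping that maximizes the
   *unique* mapping rate — via a linear model trained on virtual mutated
   genomes;
3. **decide** among reference-based assembly, PRA and de novo assembly;
4. **score** a resulting assembly against a unified reference gene model
   (per-gene coverage, reconstruction rate, AUC of the cumulative coverage
   curve).

## Why the unique mapping rate peaks

Allowing more mismatches (`N`) lets diverged reads find their true locus, so
the overall mapped rate can only grow with `N`. But uniqueness counts *all*
placements within the budget: once `N` is large enough that a read also fits
a paralog or repeat copy, a formerly unique read becomes multi-mapped. The
unique-rate curve therefore rises and then falls, and its argmax `N*`
(smallest `N` on ties) balances divergence tolerance against repeat-induced
ambiguity. `optimal_mismatch_search()` reports the whole curve; the optimal
mismatch rate is `100 * N* / L` percent for read length `L`.

On a strictly repeat-free genome (such as the random genomes the training
procedure uses) there are no competing loci, so the curve rises to a plateau
and `N*` is the point where the last read becomes mappable — a maximum-order
statistic over the reads' per-locus mismatch counts. That makes desk-scale
`N*` estimates inherently noisy at roughly one percentage point; see
"Numerical behaviour" below.

## The mapper and its exactness guarantee

The internal mapper is deliberately simple — ungapped, base-quality-blind —
but **exact**: for a read of length `L` and budget `N` it reports *every*
placement, on either strand, with Hamming distance at most `N`. The search
splits the read into `s = floor(L/k)` disjoint k-mer segments. If every
segment of some placement had more than `floor(N/s)` mismatches, the total
would exceed `N`; hence at least one segment lies within Hamming distance
`d = floor(N/s)` of the genome. Each segment is therefore looked up together
with all of its `<= d` mismatch neighbours in a direct-addressed `4^k` table
(default `k = 9`, chosen so the table lives in cache while neighbour
enumeration at `d <= 3` stays small: `d = 2` for the default `L = 100`,
`N <= 30` regime). When `d` would exceed 3 — very short reads or extreme
budgets — the mapper falls back to a bit-parallel scan of every genome
window, which is trivially complete. Both paths are tested against a
brute-force all-windows oracle on hundreds of random fixtures.

Conventions that matter:

* `N` bases never match, on either side; they act as guaranteed mismatches.
  (For seeding, an N is encoded as `A`, which can only *shrink* a segment's
  seed distance, so completeness is unaffected; verification applies the
  never-matches rule.)
* The reverse strand is searched by mapping the reverse-complemented read
  against the forward text; a locus found by both orientations counts once.
* Uniqueness counts all placements within the budget, not only a best
  stratum — this is what produces the unique-rate peak.
* Gapped placement is out of scope for the internal mapper; alignments from
  an external spliced aligner can be ingested from plain SAM
  (`read_sam_min()` + `profile_from_sam()`).

A practical consequence of the placement-set view: sweeping `N` needs only
one mapping pass at `max(N_grid)`, because the placements at budget `N` are
exactly those with `mismatches <= N`.

## Virtual genomes and the linear model

The training procedure (`virtual_experiment()`) emulates divergence by
substitution-only mutagenesis: every non-N base of a genome is substituted
independently with probability `m`; given a substitution, a transition
(A↔G, C↔T) is chosen with probability `κ/(κ+1)` and otherwise one of the two
transversions uniformly. Defaults: fifteen rates `m = 1%..15%` in 1% steps,
`κ = 2.0` — a typical genome-wide vertebrate transition/transversion ratio,
supplied as a parameter because the appropriate value is lineage-specific.
There are no indels, no rate heterogeneity and no clustering; divergence by
independent per-site substitution is exactly the quantity the mismatch
budget must absorb.

Error-free single-end reads are simulated from the *original* genome and
mapped to each mutated genome; the observed optimal mismatch rates are
regressed on the mutation rates by ordinary least squares
(`fit_mismatch_model()`, `stats::lm` underneath). The default problem sizes
(200-kb genome, 20,000 reads of 100 nt, `N` swept 0..30) keep a full
experiment at a few minutes on one CPU while leaving every per-rate optimum
supported by tens of thousands of read observations. The bundled default
model (`default_model()`) is the training-point table of one such seeded run
(seed 11), shipped as a TSV and refit from its points at load — the package
never hard-codes coefficients.

Held-out accuracy is assessed by fitting on the odd rates (1%, 3%, ..., 15%)
and predicting the even ones (`odd_even_holdout_rmse()`), reported in
percentage points.

## Distances

Pairwise identity comes from a global Needleman–Wunsch alignment with affine
gaps (via `Biostrings::pairwiseAlignment`): match +1, mismatch −1, gap open
−2, gap extend −0.5. Identity is the fraction of identical columns among
columns where **both** sequences have a residue (gap columns excluded; `N`
is always a mismatch); distance is `1 − identity`. The gap-excluded
denominator is one of two defensible readings of "ratio of nucleotides
aligned"; the alternative (all alignment columns) is available via the
`denominator` argument. Because optimal-alignment tie-breaking is not
symmetric in the argument order, `genetic_distance()` aligns the pair in
canonical (lexicographic) order, making the distance exactly symmetric.

Two caveats worth knowing. For sequences that differ only by substitutions
the distance equals `k/length` exactly in the regime the toolkit operates in
(up to ~15% divergence); at 25%+ divergence the gap-friendly scoring can
occasionally let a gapped alignment shave the distance by a percent or two —
the same order as the differences between alignment programs. And genome-wide
distances are summarized as the *median* over one-to-one ortholog pairs
(`ortholog_set_distance()`), which is robust to a minority of misannotated
pairs.

Neighbor-joining trees over distance matrices (`nj_tree()`, `ape::nj`
underneath) are provided for visual sanity checks; the tree-path distance
between two leaves (`tree_path_distance()`) reproduces an additive input
matrix exactly. Negative NJ branch estimates are clamped to zero with a
warning, the standard practice.

## The decision flow

`decide_strategy()` implements the flow: if the species' own genome exists,
use it. Otherwise take the first available marker in the preference order
*orthologous transcriptome → 16S → D-loop* (slower-evolving, genome-wide
evidence is trusted first). PRA is recommended when the distance is within
the marker's threshold **and** the model-predicted optimal mismatch rate is
within the global bound; otherwise de novo. The shipped thresholds are
0.101 (ortholog), 0.189 (16S), 0.363 (D-loop) and 14.44% (rate bound) — the
largest values at which PRA still outperformed de novo assembly in the
published comparisons. Boundaries are **inclusive**: the borderline species
(at ortholog distance 0.101 exactly) was itself near the crossover, and the
summary statements of the source analyses phrase the PRA regime as "within"
those values, so equality favours PRA. Note that with a typical fitted model
the 14.44% rate bound binds before the 0.101 ortholog threshold does; both
checks are applied.

Reads with many ambiguous bases deserve caution: an `N` can never match, so
every `N` consumes mismatch budget and the observed optimum can exceed the
distance-based prediction. When the read set's N fraction exceeds 5%
(`ambiguous_fraction()`), the decision carries a warning rather than a
changed strategy.

## Assembly evaluation

The reference side is a *unified gene model*: per gene, the union of exons
over isoforms that are expressed (RPM ≥ 0.1) and have mature length > 200 nt
(`unify_gene_model()`; RPM and FPM are treated as the same depth-normalized
quantity, with paired mates counted once). Gene coverage is exact interval
arithmetic: the covered fraction of unified exonic bases
(`gene_coverage()`, IRanges underneath). The summary statistics
(`reconstruction_stats()`) are the reconstruction rate (fraction of genes
with non-zero coverage), the cumulative curve `C(t) = ` fraction of genes
with coverage ≥ `t`, and its AUC. `C` is standardized in this direction
because its integral over `[0, 1]` equals the mean gene coverage exactly;
the AUC is computed as that mean, and the reported grid curve
(`t = 0, 0.01, ..., 1`) integrates to the same value within 0.01.

Aligning assembled contigs to gene sequences uses a deterministic
seed-anchored stand-in for a local aligner at fixture scale
(`align_contigs_to_genes()`): contigs are chopped into 50-nt windows (step
25, plus an end-flush window) and each window is placed by the exact mapper
with a mismatch budget of `floor(0.05 * 50)`, i.e. ≥ 95% identity over
≥ 50 nt, both configurable. These cutoffs are a documented package choice —
published BLAST-based coverage analyses rarely state theirs. Tabular output
of a real local aligner can be ingested instead
(`alignment_intervals_from_tsv()`, outfmt-6-like columns).

## Synthetic data: what it does and does not emulate

`synth_transcriptome()` / `make_fixtures()` build a miniature study system:
a uniform-random genome (default 100 kb) with 50 non-overlapping multi-exon
genes (2–5 exons of 100–400 nt, introns 50–300 nt, one isoform per gene),
per-gene expression weights log-uniform over three orders of magnitude (so
simulated read sets span the low/mid/high FPM bins), a 5%-mutated
pseudo-reference with its substitution truth log, and paired-end reads
(error-free by default, so that truth-based assertions are sharp).

What this deliberately does *not* model: repeats and paralogs (a uniform
random genome is repeat-free, so unique-rate declines only appear in
fixtures that plant a diverged duplicate segment), indels and structural
divergence, alternative isoforms, biased base composition, quality-dependent
sequencing errors, and intron-spanning alignment (reads are simulated from
transcripts, the natural substrate for the unspliced mapper). Green tests on
these fixtures therefore validate the *computations* — exact placement sets,
interval arithmetic, regression algebra, decision logic — not the biological
generality of the thresholds, which come from the published cross-species
comparisons.

## Numerical choices and behaviour

* **Coordinates** are 0-based half-open everywhere inside the package; GTF
  (1-based inclusive) and SAM positions are converted at the boundary.
* **Seeds**: every randomized step takes an explicit seed and runs in an
  isolated RNG scope (R's Mersenne–Twister); series derive per-item seeds
  deterministically (`base_seed + 100 + i - 1` for the mutation series,
  `base_seed + 6` for reads), so whole experiments are bitwise reproducible.
* **Ties** in the mismatch sweep resolve to the smallest `N` (cheapest
  setting that achieves the maximum).
* **Degenerate inputs**: empty read sets, empty sequences, all-equal
  predictors, sub-3-taxon matrices and out-of-range rates raise immediate
  errors; reads shorter than the seed length are reported unmapped with a
  warning rather than an error.
* **Desk-scale noise**: on repeat-free training genomes the per-rate optimum
  is a maximum-order statistic, so replicate experiments scatter around the
  fitted line by about one percentage point. With fifteen training points
  this puts the regression's r² near 0.98–0.99 depending on the seed, and
  the odd/even held-out RMSE near 0.7–1.0 percentage points. The published
  full-scale analogues (r² = 0.985, RMSE = 2.40 against real species) sit
  within that range on the r² side and are much looser on the RMSE side.
* **Clamping**: model predictions are clamped to `[0, 100]`%; negative NJ
  branch lengths to 0 (flagged).

## Known limitations

The internal mapper is ungapped, so indel divergence is invisible to it
(budgeted only as mismatches when ingesting external SAM). The distance
module does pairwise alignment only — no multiple alignment, no
maximum-likelihood trees, no divergence-time calibration. Evaluation is
sensitivity-side only (coverage and reconstruction rate); precision-style
metrics such as chimera rates are out of scope. The decision thresholds are
shipped constants derived from vertebrate comparisons; for other clades they
should be re-derived with `virtual_experiment()` on an appropriate genome
and marker set.
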