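test_that("compute_rpm normalizes counts per million mapped reads", {
  counts <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                           count = c(1, 0, 100))
  rpm <- compute_rpm(counts, 1e6)
  expect_equal(rpm$rpm, c(1, 0, 100))
  expect_equal(compute_rpm(counts, 2e6)$rpm, c(0.5, 0, 50))
  expect_error(compute_rpm(counts, 0), "total_mapped_reads")
})

mk_exons <- function(...) {
  rows <- list(...)
  tibble::tibble(
    chrom = "chr1",
    start = vapply(rows, `[[`, numeric(1), 1),
    end = vapply(rows, `[[`, numeric(1), 2),
    strand = "+",
    gene_id = vapply(rows, `[[`, character(1), 3),
    transcript_id = vapply(rows, `[[`, character(1), 4)
  )
}

test_that("unify_gene_model filters by expression and length, then unions exons", {
  exons <- mk_exons(
    list(0, 100, "g1", "t1a"), list(150, 400, "g1", "t1a"),   # mature 350
    list(50, 150, "g1", "t1b"), list(150, 450, "g1", "t1b"),  # mature 400
    list(1000, 1500, "g2", "t2")                              # mature 500
  )
  expr <- tibble::tibble(transcript_id = c("t1a", "t1b", "t2"),
                         rpm = c(0.5, 0.2, 0.05))
  uni <- unify_gene_model(exons, expr)
  expect_equal(uni$gene_id, "g1")  # g2 below the 0.1 RPM floor
  expect_equal(uni$exons[[1]], tibble::tibble(start = 0L, end = 450L))
  expect_equal(uni$exonic_length, 450L)

  # one kept isoform: the unified model is its own exons
  solo <- unify_gene_model(
    mk_exons(list(0, 100, "g1", "t1"), list(200, 350, "g1", "t1")),
    tibble::tibble(transcript_id = "t1", rpm = 0.5)
  )
  expect_equal(solo$exons[[1]], tibble::tibble(start = c(0L, 200L), end = c(100L, 350L)))

  # partial-overlap union example: [0,100) u [50,150) = [0,150)
  both <- unify_gene_model(
    mk_exons(list(0, 100, "g1", "ta"), list(300, 550, "g1", "ta"),
             list(50, 150, "g1", "tb"), list(300, 550, "g1", "tb")),
    tibble::tibble(transcript_id = c("ta", "tb"), rpm = c(1, 1))
  )
  expect_equal(both$exons[[1]],
               tibble::tibble(start = c(0L, 300L), end = c(150L, 550L)))
  expect_equal(both$exonic_length, 400L)

  # short mature transcripts (<= 200 nt) are dropped
  short <- unify_gene_model(
    mk_exons(list(0, 100, "g1", "t1"), list(150, 250, "g1", "t1")),
    tibble::tibble(transcript_id = "t1", rpm = 5)
  )
  expect_equal(nrow(short), 0)

  expect_error(
    unify_gene_model(exons, tibble::tibble(transcript_id = "t1a", rpm = 1)),
    "expression"
  )
})

test_that("gene_coverage is exact interval arithmetic and monotone in evidence", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1",
    exons = list(tibble::tibble(start = 0L, end = 100L)),
    exonic_length = 100L
  )
  expect_equal(gene_coverage(genes, tibble::tibble(
    gene_id = "g1", start = -10L, end = 120L
  ))$coverage, 1)
  expect_equal(gene_coverage(genes, tibble::tibble(
    gene_id = character(), start = integer(), end = integer()
  ))$coverage, 0)
  aln <- tibble::tibble(gene_id = c("g1", "g1"), start = c(25L, 90L), end = c(75L, 120L))
  expect_equal(gene_coverage(genes, aln)$coverage, 0.6)  # (50 + 10) / 100
  # monotonicity: adding evidence never lowers coverage
  more <- dplyr::bind_rows(aln, tibble::tibble(gene_id = "g1", start = 0L, end = 10L))
  expect_gte(gene_coverage(genes, more)$coverage, 0.6)
})

test_that("align_contigs_to_genes recovers exact and slightly diverged contigs", {
  withr::local_seed(44)
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    seq = c(random_dna(600), random_dna(450))
  )
  # exact copy covers its gene fully
  aln <- align_contigs_to_genes(
    tibble::tibble(id = "c1", seq = genes$seq[1]), genes
  )
  expect_equal(aln, tibble::tibble(gene_id = "gA", start = 0L, end = 600L))

  # an unrelated random contig produces no intervals
  none <- align_contigs_to_genes(tibble::tibble(id = "bg", seq = random_dna(500)), genes)
  expect_equal(nrow(none), 0)

  # 2% diverged copy still covers >= 95% of the gene
  mut <- plant_substitutions(genes$seq[2], round(0.02 * 450))$seq
  aln <- align_contigs_to_genes(tibble::tibble(id = "c2", seq = mut), genes)
  covered <- sum(aln$end - aln$start)
  expect_equal(unique(aln$gene_id), "gB")
  expect_gte(covered / 450, 0.95)
})

test_that("reconstruction_stats computes rate, curve and AUC coherently", {
  rep0 <- reconstruction_stats(c(1, 1, 0, 0))
  expect_equal(rep0$reconstruction_rate, 0.5)
  expect_equal(rep0$auc, 0.5)
  expect_equal(reconstruction_stats(rep(0, 5))$reconstruction_rate, 0)
  expect_equal(reconstruction_stats(rep(0, 5))$auc, 0)
  expect_equal(reconstruction_stats(rep(1, 5))$auc, 1)

  withr::local_seed(50)
  cov <- round(runif(200), 2)
  rep1 <- reconstruction_stats(cov)
  expect_equal(rep1$auc, mean(cov))
  expect_true(all(diff(rep1$curve$fraction) <= 0))  # C is non-increasing
  expect_equal(rep1$curve$fraction[1], 1)           # C(0) = 1
  # grid integration of the curve agrees with the exact AUC within 0.01
  grid_auc <- sum(rep1$curve$fraction[-1] * 0.01)
  expect_lt(abs(grid_auc - rep1$auc), 0.01)
  # reconstruction rate equals C(t) just above zero for 0-or->=0.01 coverages
  expect_equal(rep1$reconstruction_rate, rep1$curve$fraction[rep1$curve$t == 0.01])

  expect_error(reconstruction_stats(numeric()), "no genes")
  expect_error(reconstruction_stats(c(0.5, 1.2)), "0, 1")
})

test_that("expression bins are half-open with an inclusion floor at 0.1", {
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    fpm = c(0.05, 0.1, 0.5, 1.0, 9.99, 10)
  )
  binned <- bin_by_expression(expr)
  expect_equal(nrow(binned), 5)  # 0.05 excluded
  expect_equal(
    as.character(binned$bin),
    c("low", "low", "mid", "mid", "high")
  )
})

test_that("tabular alignment ingestion filters by identity and length", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "c1\tgA\t99.0\t200\t1\t200",
    "c2\tgA\t90.0\t300\t250\t549",   # identity below cutoff
    "c3\tgB\t100.0\t30\t1\t30",      # too short
    "c4\tgB\t97.5\t120\t500\t381"    # minus orientation
  ), tsv)
  iv <- alignment_intervals_from_tsv(tsv)
  expect_equal(iv$gene_id, c("gA", "gB"))
  expect_equal(iv$start, c(0L, 380L))
  expect_equal(iv$end, c(200L, 500L))
})
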