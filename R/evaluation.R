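iranges_of <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)  # to 1-based inclusive
}

#' Reads (or fragments) per million mapped reads
#'
#' Depth-normalized expression: `rpm = count / total_mapped_reads * 1e6`.
#' Counted fragments and counted reads are treated as the same quantity
#' (paired mates count once when the caller counts fragments).
#'
#' @param counts Tibble with columns `transcript_id` and `count`.
#' @param total_mapped_reads Total mapped reads (or fragments), > 0.
#' @return The input with an added `rpm` column.
#' @export
compute_rpm <- function(counts, total_mapped_reads) {
  stopifnot(all(c("transcript_id", "count") %in% names(counts)))
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0) {
    abort("total_mapped_reads must be > 0")
  }
  counts %>% mutate(rpm = .data$count / total_mapped_reads * 1e6)
}

#' Unify expressed isoforms into per-gene standard gene models
#'
#' Keeps isoforms that are expressed (`rpm >= min_rpm`, default 0.1) and have
#' a mature transcript longer than `min_mature_len` (default 200 nt), then
#' unifies the exons of each gene's kept isoforms into a disjoint sorted
#' interval set -- the standard gene model that assemblies are scored
#' against. Genes with no kept isoform are excluded.
#'
#' @param exons Exon tibble as returned by [read_gtf()].
#' @param expression Tibble with `transcript_id` and `rpm` (every considered
#'   transcript must appear).
#' @param min_rpm Inclusive expression floor. Default 0.1.
#' @param min_mature_len Exclusive mature-length floor, nt. Default 200.
#' @return A tibble with one row per kept gene: `gene_id`, `chrom`, `exons`
#'   (list-column of tibbles `start`, `end`, disjoint and sorted, 0-based
#'   half-open) and `exonic_length`.
#' @export
unify_gene_model <- function(exons, expression, min_rpm = 0.1,
                             min_mature_len = 200L) {
  stopifnot(all(c("transcript_id", "rpm") %in% names(expression)))
  if (anyNA(exons$gene_id) || any(exons$gene_id == "")) {
    abort("transcript without gene_id")
  }
  if (!"mature_length" %in% names(exons)) {
    exons <- exons %>%
      group_by(.data$transcript_id) %>%
      mutate(mature_length = sum(.data$end - .data$start)) %>%
      ungroup()
  }
  missing <- setdiff(unique(exons$transcript_id), expression$transcript_id)
  if (length(missing) > 0) {
    abort(paste0("no expression value for transcript '", missing[1], "'"))
  }
  kept <- exons %>%
    left_join(select(expression, "transcript_id", "rpm"), by = "transcript_id") %>%
    filter(.data$rpm >= min_rpm, .data$mature_length > min_mature_len)
  if (nrow(kept) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(),
      exons = list(), exonic_length = integer()
    ))
  }
  kept %>%
    group_by(.data$gene_id, .data$chrom) %>%
    summarise(
      exons = {
        red <- IRanges::reduce(iranges_of(.data$start, .data$end))
        list(tibble(
          start = IRanges::start(red) - 1L,
          end = IRanges::end(red)
        ))
      },
      .groups = "drop"
    ) %>%
    mutate(exonic_length = vapply(
      .data$exons, function(e) sum(e$end - e$start), integer(1)
    )) %>%
    arrange(.data$gene_id)
}

#' Per-gene coverage of unified gene models by alignment evidence
#'
#' Coverage of a gene is the fraction of its unified exonic bases covered by
#' the union of the supplied alignment intervals, which must live in the same
#' coordinate system as the gene's exons (genomic coordinates, or
#' gene-sequence coordinates where the exon set is `[0, exonic_length)`).
#' Adding intervals can never decrease coverage; a gene without alignments
#' has coverage 0.
#'
#' @param genes Tibble from [unify_gene_model()] (or any tibble with
#'   `gene_id`, `exons` list-column and `exonic_length`).
#' @param alignments Tibble with `gene_id`, `start`, `end` (0-based
#'   half-open).
#' @return A tibble `gene_id`, `coverage` in `[0, 1]`, one row per gene in
#'   `genes`.
#' @export
gene_coverage <- function(genes, alignments) {
  stopifnot(all(c("gene_id", "exons", "exonic_length") %in% names(genes)))
  cov <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    aln <- alignments[alignments$gene_id == genes$gene_id[i], , drop = FALSE]
    if (nrow(aln) == 0 || nrow(ex) == 0) return(0)
    covered <- IRanges::intersect(
      IRanges::reduce(iranges_of(aln$start, aln$end)),
      iranges_of(ex$start, ex$end)
    )
    sum(IRanges::width(covered)) / genes$exonic_length[i]
  }, numeric(1))
  tibble(gene_id = genes$gene_id, coverage = cov)
}

#' Align assembled contigs to gene sequences
#'
#' Deterministic seed-anchored stand-in for a local aligner at fixture scale:
#' each contig is chopped into windows of `window` nt (step `window/2`, plus
#' a window flush with the contig end) and each window is placed on the gene
#' sequences by the exact mismatch-bounded mapper with a budget of
#' `floor((1 - min_identity) * window)` mismatches, both strands, all
#' placements. Matched windows become intervals on the gene sequence and are
#' merged per gene. Defaults require >= 95% identity over >= 50 nt.
#'
#' For real BLAST output use [alignment_intervals_from_tsv()] instead.
#'
#' @param contigs Tibble with `id` and `seq` (assembled transcripts).
#' @param genes Tibble with `gene_id` (or `id`) and `seq`: the unified exonic
#'   sequence of each gene.
#' @param min_identity Minimum per-window identity. Default 0.95.
#' @param window Window (and minimum alignment) length, nt. Default 50.
#' @return A tibble `gene_id`, `start`, `end` (0-based half-open intervals on
#'   the gene sequence), merged per gene.
#' @export
align_contigs_to_genes <- function(contigs, genes, min_identity = 0.95,
                                   window = 50L) {
  gene_ids <- if ("gene_id" %in% names(genes)) genes$gene_id else genes$id
  glens <- nchar(genes$seq)
  spacer <- strrep("N", window)  # windows can never match across a boundary
  concat <- paste(normalize_seq(genes$seq), collapse = spacer)
  offsets <- cumsum(c(0L, head(glens + window, -1)))
  index <- build_index(concat, k = 9L)
  budget <- floor((1 - min_identity) * window)
  out <- list()
  for (ci in seq_len(nrow(contigs))) {
    cseq <- normalize_seq(contigs$seq[ci])
    clen <- nchar(cseq)
    if (clen < window) next
    starts <- unique(c(seq(0L, clen - window, by = max(1L, window %/% 2L)), clen - window))
    wins <- substring(cseq, starts + 1L, starts + window)
    counts <- cpp_map_reads(index$ptr, wins, as.integer(budget))$placements
    for (w in seq_along(counts)) {
      m <- counts[[w]]
      if (nrow(m) == 0) next
      gi <- findInterval(m[, 1], offsets)
      gstart <- m[, 1] - offsets[gi]
      out[[length(out) + 1L]] <- tibble(
        gene_id = gene_ids[gi],
        start = pmax(gstart, 0L),
        end = pmin(gstart + window, glens[gi])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(gene_id = character(), start = integer(), end = integer()))
  }
  bind_rows(out) %>%
    filter(.data$end > .data$start) %>%
    group_by(.data$gene_id) %>%
    summarise(
      merged = {
        red <- IRanges::reduce(iranges_of(.data$start, .data$end))
        list(tibble(start = IRanges::start(red) - 1L, end = IRanges::end(red)))
      },
      .groups = "drop"
    ) %>%
    tidyr::unnest("merged") %>%
    arrange(.data$gene_id, .data$start)
}

#' Convert a tabular (BLAST outfmt-6-like) alignment file to intervals
#'
#' Ingestion path for precomputed local alignments: a TSV with columns
#' `qseqid, sseqid, pident, length, sstart, send` (1-based inclusive subject
#' coordinates, as BLAST prints them, in either orientation).
#'
#' @param path TSV path (no header, columns as above).
#' @param min_identity Minimum percent identity (0-100 scale). Default 95.
#' @param min_len Minimum alignment length, nt. Default 50.
#' @return A tibble `gene_id`, `start`, `end` (0-based half-open).
#' @export
alignment_intervals_from_tsv <- function(path, min_identity = 95, min_len = 50L) {
  tab <- readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "sstart", "send"),
    show_col_types = FALSE
  )
  tab %>%
    filter(.data$pident >= min_identity, .data$length >= min_len) %>%
    mutate(
      gene_id = .data$sseqid,
      start = pmin(.data$sstart, .data$send) - 1L,
      end = pmax(.data$sstart, .data$send)
    ) %>%
    select("gene_id", "start", "end")
}

#' Reconstruction statistics of an assembly
#'
#' Summarizes per-gene coverages into the reconstruction rate (fraction of
#' genes with non-zero coverage), the cumulative curve
#' `C(t) = fraction of genes with coverage >= t` on the grid `t = 0, 0.01,
#' ..., 1`, and the area under that curve. The AUC is computed exactly as the
#' mean coverage, which equals the integral of `C` over `[0, 1]`.
#'
#' @param coverages Numeric vector of per-gene coverages in `[0, 1]`, or a
#'   tibble from [gene_coverage()].
#' @return An object of class `reconstruction_report`: list with `coverage`
#'   (tibble), `reconstruction_rate`, `curve` (tibble `t`, `fraction`,
#'   non-increasing, `C(0) = 1`) and `auc`.
#' @export
reconstruction_stats <- function(coverages) {
  cov_tbl <- if (is.data.frame(coverages)) {
    stopifnot("coverage" %in% names(coverages))
    coverages
  } else {
    tibble(gene_id = paste0("g", seq_along(coverages)), coverage = as.numeric(coverages))
  }
  cv <- cov_tbl$coverage
  if (length(cv) == 0) abort("no genes")
  if (any(cv < 0 | cv > 1)) abort("coverages must be in [0, 1]")
  grid <- seq(0, 1, by = 0.01)
  structure(
    list(
      coverage = cov_tbl,
      reconstruction_rate = mean(cv > 0),
      curve = tibble(
        t = grid,
        fraction = vapply(grid, function(t) mean(cv >= t), numeric(1))
      ),
      auc = mean(cv)
    ),
    class = "reconstruction_report"
  )
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_report> %d genes: reconstruction rate %.3f, AUC %.3f\n",
    nrow(x$coverage), x$reconstruction_rate, x$auc
  ))
  invisible(x)
}

#' @rdname reconstruction_stats
#' @param x A `reconstruction_report`.
#' @param ... Unused.
#' @export
glance.reconstruction_report <- function(x, ...) {
  tibble(
    n_genes = nrow(x$coverage),
    reconstruction_rate = x$reconstruction_rate,
    auc = x$auc
  )
}

#' Bin genes by expression level
#'
#' Half-open expression bins: low `[0.1, 1)`, mid `[1, 10)`, high
#' `[10, Inf)` FPM. Genes below the 0.1 inclusion floor are excluded (they
#' are not part of the unified gene model either).
#'
#' @param expression Tibble with `gene_id` and `fpm`.
#' @return The rows at or above the floor, with an added `bin` factor
#'   (`low`, `mid`, `high`).
#' @export
bin_by_expression <- function(expression) {
  stopifnot(all(c("gene_id", "fpm") %in% names(expression)))
  expression %>%
    filter(.data$fpm >= 0.1) %>%
    mutate(bin = cut(
      .data$fpm, breaks = c(0.1, 1, 10, Inf),
      labels = c("low", "mid", "high"), right = FALSE
    ))
}
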