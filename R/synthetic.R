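#' Generate a random genome sequence
#'
#' Uniform i.i.d. bases; a deliberately repeat-free substrate so that reads
#' sampled from it map uniquely at sufficient length.
#'
#' @param length Genome length, nt.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @param id Record id.
#' @return A one-row tibble with `id` and `seq`.
#' @export
synth_genome <- function(length, seed = NULL, id = "synth_genome") {
  stopifnot(length >= 1)
  seq <- with_seed_if(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""
  ))
  tibble(id = id, seq = seq)
}

#' Generate a synthetic annotated genome with multi-exon genes
#'
#' A miniature study system: a random genome carrying `n_genes` non
#' overlapping multi-exon genes (2-5 exons of 100-400 nt separated by
#' 50-300 nt introns), one isoform per gene, plus per-gene expression weights
#' drawn log-uniformly over three orders of magnitude so that simulated read
#' sets span the low/mid/high FPM bins.
#'
#' @param genome_length Genome length, nt (default 100 kb).
#' @param n_genes Number of genes (default 50).
#' @param seed Integer seed.
#' @return A list with `genome` (tibble `id`, `seq`), `exons` (tibble in
#'   [read_gtf()] layout), `transcripts` (tibble `id`, `seq`, `gene_id`) and
#'   `weights` (tibble `transcript_id`, `gene_id`, `weight`).
#' @export
synth_transcriptome <- function(genome_length = 1e5, n_genes = 50L, seed = NULL) {
  with_seed_if(seed, {
    genome <- synth_genome(genome_length, seed = NULL)
    slot_len <- genome_length %/% n_genes
    exon_rows <- list()
    for (g in seq_len(n_genes)) {
      slot_start <- (g - 1L) * slot_len
      n_exons <- sample(2:5, 1)
      pos <- slot_start + 10L
      starts <- integer(0)
      ends <- integer(0)
      for (e in seq_len(n_exons)) {
        elen <- sample(100:400, 1)
        if (pos + elen > slot_start + slot_len - 10L) break
        starts <- c(starts, pos)
        ends <- c(ends, pos + elen)
        pos <- pos + elen + sample(50:300, 1)
      }
      if (length(starts) < 2) {  # force at least two exons per gene
        starts <- slot_start + c(10L, 220L)
        ends <- starts + c(150L, 150L)
      }
      exon_rows[[g]] <- tibble(
        chrom = genome$id,
        start = starts, end = ends,
        strand = sample(c("+", "-"), 1),
        gene_id = sprintf("gene%02d", g),
        transcript_id = sprintf("gene%02d.t1", g)
      )
    }
    exons <- bind_rows(exon_rows) %>%
      group_by(.data$transcript_id) %>%
      mutate(mature_length = sum(.data$end - .data$start)) %>%
      ungroup() %>%
      mutate(short_transcript = .data$mature_length <= 200L)
    spliced <- exons %>%
      group_by(.data$gene_id, .data$transcript_id, .data$strand) %>%
      summarise(
        seq = paste(substring(genome$seq, .data$start + 1L, .data$end), collapse = ""),
        .groups = "drop"
      )
    minus <- spliced$strand == "-"
    spliced$seq[minus] <- revcomp(spliced$seq[minus])
    weights <- tibble(
      transcript_id = spliced$transcript_id,
      gene_id = spliced$gene_id,
      weight = 10^runif(nrow(spliced), -1.5, 1.5)
    )
    list(
      genome = genome,
      exons = exons,
      transcripts = tibble(
        id = spliced$transcript_id, seq = spliced$seq, gene_id = spliced$gene_id
      ),
      weights = weights
    )
  })
}

#' Write a complete synthetic fixture set to a directory
#'
#' Generates a miniature "species pair" -- an annotated genome, its
#' transcript set with expression weights spanning the FPM bins, a mutated
#' pseudo-reference, and paired-end reads with truth logs -- and writes all
#' of it as plain-text FASTA/GTF/FASTQ/TSV so every other command of the
#' toolkit can run on it.
#'
#' @param outdir Output directory.
#' @param seed Integer seed; different seeds give different fixtures.
#' @param genome_length,n_genes Passed to [synth_transcriptome()].
#' @param n_read_pairs Number of simulated read pairs.
#' @param read_length Read length, nt.
#' @param error_rate Per-base read error rate. Default 0: fixture reads are
#'   exact transcript substrings, so truth-based checks are sharp; supply a
#'   positive rate to emulate sequencing noise.
#' @param pseudo_rate Substitution rate of the mutated pseudo-reference.
#' @param tstv Transition/transversion ratio of the pseudo-reference.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a named list of the written paths plus the seed.
#' @export
make_fixtures <- function(outdir, seed = 1L, genome_length = 1e5,
                          n_genes = 50L, n_read_pairs = 5000L,
                          read_length = 100L, error_rate = 0, pseudo_rate = 0.05,
                          tstv = 2.0, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force) {
    abort(paste0("output directory '", outdir, "' is not empty (use force = TRUE)"))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tx <- synth_transcriptome(genome_length, n_genes, seed = seed)
  pseudo <- mutate_genome(tx$genome, pseudo_rate, tstv = tstv, seed = seed + 1L)
  sim <- simulate_reads(
    tx$transcripts, n_reads = n_read_pairs, read_length = read_length,
    error_rate = error_rate, paired = TRUE,
    weights = tx$weights$weight[match(tx$transcripts$id, tx$weights$transcript_id)],
    seed = seed + 2L
  )
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "genes.gtf"),
    transcripts = file.path(outdir, "transcripts.fa"),
    pseudoref = file.path(outdir, "pseudoref.fa"),
    mutation_truth = file.path(outdir, "pseudoref_truth.tsv"),
    reads_1 = file.path(outdir, "reads_1.fastq"),
    reads_2 = file.path(outdir, "reads_2.fastq"),
    read_truth = file.path(outdir, "read_truth.tsv"),
    weights = file.path(outdir, "weights.tsv"),
    metadata = file.path(outdir, "metadata.json")
  )
  write_fasta(tx$genome, paths$genome)
  write_gtf(tx$exons, paths$gtf)
  write_fasta(tx$transcripts, paths$transcripts)
  write_fasta(pseudo$genome, paths$pseudoref)
  write_truth_tsv(pseudo, paths$mutation_truth)
  write_fastq(sim$reads[sim$reads$mate == 1L, ], paths$reads_1)
  write_fastq(sim$reads[sim$reads$mate == 2L, ], paths$reads_2)
  readr::write_tsv(
    sim$truth %>% mutate(error_pos = vapply(
      .data$error_pos, paste, character(1), collapse = ","
    )),
    paths$read_truth
  )
  readr::write_tsv(tx$weights, paths$weights)
  jsonlite::write_json(
    list(
      seed = seed, genome_length = genome_length, n_genes = n_genes,
      n_read_pairs = n_read_pairs, read_length = read_length,
      pseudo_rate = pseudo_rate, tstv = tstv,
      pseudo_realized_rate = pseudo$realized_rate,
      pseudo_realized_tstv = pseudo$realized_tstv
    ),
    paths$metadata, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, list(seed = seed)))
}
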