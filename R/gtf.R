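#' Read exon models from a GTF file
#'
#' Imports `exon` features and converts GTF's 1-based inclusive coordinates
#' to the 0-based half-open convention used throughout the package. Exons are
#' sorted within each transcript and the summed exonic (mature transcript)
#' length is attached per row; transcripts at or under `min_mature_len` are
#' flagged in `short_transcript` but not removed here — filtering happens in
#' [unify_gene_model()].
#'
#' @param path Path to a GTF file (Ensembl dialect: `gene_id` and
#'   `transcript_id` attributes on exon features).
#' @param min_mature_len Mature-transcript length (nt) at or below which a
#'   transcript is flagged as short. Default 200.
#' @return A tibble with one row per exon: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `transcript_id`, `mature_length`,
#'   `short_transcript`.
#' @export
read_gtf <- function(path, min_mature_len = 200L) {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) {
      abort(paste0("malformed GTF in '", path, "': ", conditionMessage(e)))
    }
  )
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) abort(paste0("no exon features in '", path, "'"))
  df <- as.data.frame(gr)
  if (!all(c("gene_id", "transcript_id") %in% names(df)) ||
      anyNA(df$transcript_id)) {
    abort(paste0("exon feature without transcript_id attribute in '", path, "'"))
  }
  if (anyNA(df$gene_id)) {
    abort(paste0("exon feature without gene_id attribute in '", path, "'"))
  }
  exons <- tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start - 1L),  # to 0-based half-open
    end = as.integer(df$end),
    strand = as.character(df$strand),
    gene_id = df$gene_id,
    transcript_id = df$transcript_id
  )
  exons <- exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(mature_length = sum(.data$end - .data$start)) %>%
    ungroup() %>%
    mutate(short_transcript = .data$mature_length <= min_mature_len)
  exons
}

#' Write exon models to GTF
#'
#' Converts the internal 0-based half-open coordinates back to GTF's 1-based
#' inclusive convention, so that a read/write round trip preserves the
#' printed coordinates.
#'
#' @param exons Tibble as returned by [read_gtf()] (columns `chrom`, `start`,
#'   `end`, `strand`, `gene_id`, `transcript_id`).
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "pseudoref") {
  stopifnot(all(c("chrom", "start", "end", "gene_id", "transcript_id") %in% names(exons)))
  strand <- if ("strand" %in% names(exons)) exons$strand else "+"
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$chrom, source, exons$start + 1L, exons$end, strand,
    exons$gene_id, exons$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Spliced transcript sequences from a genome and exon models
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements minus-strand transcripts. Useful for building
#' ortholog-style pairs between a genome and a mutated pseudo-reference with
#' shared coordinates.
#'
#' @param genome Character scalar or one-row tibble with `seq` (the
#'   chromosome the exons refer to).
#' @param exons Exon tibble as from [read_gtf()] (columns `start`, `end`,
#'   `strand`, `gene_id`, `transcript_id`; 0-based half-open).
#' @return A tibble with `id` (transcript_id), `seq` and `gene_id`.
#' @export
spliced_transcript_seqs <- function(genome, exons) {
  seq <- if (is.data.frame(genome)) genome$seq[1] else genome
  tx <- exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(
      seq = paste(substring(seq, .data$start + 1L, .data$end), collapse = ""),
      strand = .data$strand[1],
      .groups = "drop"
    )
  minus <- tx$strand == "-"
  tx$seq[minus] <- revcomp(tx$seq[minus])
  tibble(id = tx$transcript_id, seq = tx$seq, gene_id = tx$gene_id)
}
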