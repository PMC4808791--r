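#' Read a FASTA file into a sequence tibble
#'
#' Sequences are normalized on input: lowercase letters are folded to
#' uppercase and every non-ACGT letter (IUPAC ambiguity codes included) is
#' collapsed to `N`. `N` never counts as a match anywhere in the toolkit.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `seq` (character,
#'   alphabet `A,C,G,T,N`), one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgn", "NN"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      abort(paste0("malformed FASTA in '", path, "': ", conditionMessage(e)))
    }
  )
  tibble(id = names(x), seq = unname(normalize_seq(as.character(x))))
}

#' Write a sequence tibble to FASTA
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for wrapping sequence text.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' Sequences are normalized as in [read_fasta()]. The mate assignment is
#' parsed from a trailing `/1` or `/2` on the read id (kept verbatim in
#' `id`); reads without the suffix get `mate = NA`.
#'
#' @param path Path to a 4-line-block FASTQ file.
#' @return A tibble with columns `id`, `seq`, `qual` and `mate`
#'   (integer 1, 2 or NA).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0 || length(lines) %% 4 != 0) {
    abort(paste0("malformed FASTQ in '", path, "': not 4-line blocks"))
  }
  heads <- lines[seq(1, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad) > 0) {
    abort(paste0(
      "malformed FASTQ in '", path, "': '@' expected on line ", 4L * (bad[1] - 1L) + 1L
    ))
  }
  ids <- substring(heads, 2)
  seqs <- normalize_seq(lines[seq(2, length(lines), by = 4)])
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad) > 0) {
    abort(paste0(
      "FASTQ record '", ids[bad[1]], "' in '", path,
      "': quality string length differs from sequence length"
    ))
  }
  mate <- rep(NA_integer_, length(ids))
  mate[endsWith(ids, "/1")] <- 1L
  mate[endsWith(ids, "/2")] <- 2L
  tibble(id = ids, seq = seqs, qual = quals, mate = mate)
}

#' Write a read tibble to FASTQ
#'
#' Writing then re-reading with [read_fastq()] is the identity on normalized
#' records.
#'
#' @param reads Tibble with columns `id`, `seq` and optionally `qual`
#'   (missing or `NA` qualities are written as the maximal Phred+33 value
#'   `"I"`, which keeps 4-line blocks well formed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else rep(NA_character_, nrow(reads))
  qual <- ifelse(
    is.na(qual),
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1)),
    qual
  )
  if (any(nchar(qual) != nchar(reads$seq))) {
    abort("quality string length differs from sequence length")
  }
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), by = 4)] <- reads$seq
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Fraction of ambiguous (N) bases in a read set
#'
#' Reads whose sequences contain many ambiguous calls inflate the apparent
#' divergence between query reads and the pseudo-reference, because an N can
#' never match; the decision layer warns when this fraction exceeds its
#' threshold (default 5%) since the observed optimal mismatch rate may then
#' exceed what the distance-based model predicts.
#'
#' @param reads Tibble with a `seq` column, or a character vector of
#'   sequences.
#' @return A single number in `[0, 1]`: total N bases / total bases.
#' @export
ambiguous_fraction <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0) abort("empty read set")
  total <- sum(nchar(seqs))
  if (total == 0) abort("read set has no bases")
  n_count <- sum(nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE)))
  n_count / total
}
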