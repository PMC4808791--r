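apply_read_errors <- function(seqs, error_rate) {
  n <- length(seqs)
  error_pos <- vector("list", n)
  if (error_rate <= 0 || n == 0) {
    error_pos[] <- list(integer())
    return(list(seqs = seqs, error_pos = error_pos))
  }
  lens <- nchar(seqs)
  n_err <- rbinom(n, lens, error_rate)
  error_pos[] <- list(integer())
  for (i in which(n_err > 0)) {
    pos <- sort(sample.int(lens[i], n_err[i]))
    chars <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), chars[p])
      chars[p] <- alt[sample.int(length(alt), 1)]
    }
    seqs[i] <- paste(chars, collapse = "")
    error_pos[[i]] <- pos - 1L  # 0-based read coordinates
  }
  list(seqs = seqs, error_pos = error_pos)
}

#' Simulate RNA-seq-like reads with a truth log
#'
#' Draws reads from a set of source sequences (typically transcripts, so that
#' the unspliced mapper faces no introns). The source of each read (or pair)
#' is drawn proportionally to `weights` (uniform when absent); the start
#' position is uniform over valid starts; the strand is uniform. Sequencing
#' errors are independent per-base substitutions logged in the truth table,
#' so removing the logged error positions from a read recovers the exact
#' source substring.
#'
#' @param sources Tibble with columns `id` and `seq`.
#' @param n_reads Number of reads (pairs, when `paired`) to simulate.
#' @param read_length Read length L in nt (>= 20).
#' @param error_rate Per-base substitution error probability (< 0.5).
#' @param paired Simulate read pairs from fragments.
#' @param insert_mean,insert_sd Fragment length model for paired mode, in nt;
#'   a normal truncated to `[2L, source length]`.
#' @param weights Optional per-source expression weights (recycled by
#'   position against `sources`); non-negative, not all zero.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @return A list with `reads` (tibble `id`, `seq`, `qual`, `mate`) and
#'   `truth` (tibble `read_id`, `source_id`, `pos` 0-based start of the
#'   covered window on the source, `strand`, `error_pos` list-column of
#'   0-based read coordinates).
#' @export
simulate_reads <- function(sources, n_reads, read_length = 100L,
                           error_rate = 0, paired = FALSE,
                           insert_mean = 300, insert_sd = 30,
                           weights = NULL, seed = NULL) {
  stopifnot(all(c("id", "seq") %in% names(sources)))
  if (read_length < 20) abort("read_length must be >= 20")
  if (error_rate < 0 || error_rate >= 0.5) abort("error_rate must be in [0, 0.5)")
  lens <- nchar(sources$seq)
  min_len <- if (paired) 2L * read_length else read_length
  too_short <- which(lens < min_len)
  if (length(too_short) > 0) {
    abort(paste0(
      "source '", sources$id[too_short[1]], "' is shorter (", lens[too_short[1]],
      " nt) than required (", min_len, " nt)"
    ))
  }
  if (is.null(weights)) weights <- rep(1, nrow(sources))
  if (any(weights < 0) || sum(weights) == 0) {
    abort("weights must be non-negative and not all zero")
  }
  with_seed_if(seed, {
    src <- sample.int(nrow(sources), n_reads, replace = TRUE, prob = weights)
    if (!paired) {
      start <- floor(runif(n_reads) * (lens[src] - read_length + 1))
      minus <- runif(n_reads) < 0.5
      seqs <- substring(sources$seq[src], start + 1, start + read_length)
      seqs[minus] <- revcomp(seqs[minus])
      err <- apply_read_errors(seqs, error_rate)
      ids <- paste0("read", seq_len(n_reads))
      reads <- tibble(
        id = ids, seq = err$seqs,
        qual = strrep("I", read_length), mate = NA_integer_
      )
      truth <- tibble(
        read_id = ids, source_id = sources$id[src],
        pos = as.integer(start), strand = ifelse(minus, "-", "+"),
        error_pos = err$error_pos
      )
    } else {
      frag <- pmin(
        pmax(round(rnorm(n_reads, insert_mean, insert_sd)), 2L * read_length),
        lens[src]
      )
      start <- floor(runif(n_reads) * (lens[src] - frag + 1))
      minus <- runif(n_reads) < 0.5
      left <- substring(sources$seq[src], start + 1, start + read_length)
      right <- revcomp(substring(
        sources$seq[src], start + frag - read_length + 1, start + frag
      ))
      # mate 1 is the fragment's 5' read on its strand
      m1 <- ifelse(minus, right, left)
      m2 <- ifelse(minus, left, right)
      m1_pos <- ifelse(minus, start + frag - read_length, start)
      m2_pos <- ifelse(minus, start, start + frag - read_length)
      err1 <- apply_read_errors(m1, error_rate)
      err2 <- apply_read_errors(m2, error_rate)
      base <- paste0("read", seq_len(n_reads))
      reads <- tibble(
        id = c(paste0(base, "/1"), paste0(base, "/2")),
        seq = c(err1$seqs, err2$seqs),
        qual = strrep("I", read_length),
        mate = rep(1:2, each = n_reads)
      )
      truth <- tibble(
        read_id = reads$id,
        source_id = rep(sources$id[src], 2),
        pos = as.integer(c(m1_pos, m2_pos)),
        strand = c(ifelse(minus, "-", "+"), ifelse(minus, "+", "-")),
        error_pos = c(err1$error_pos, err2$error_pos)
      )
    }
    list(reads = reads, truth = truth)
  })
}

#' Randomly subsample a read set to emulate lower sequencing depth
#'
#' Each read -- or read pair: mates sharing an id up to a trailing `/1`/`/2`
#' are kept or dropped together -- is retained independently with probability
#' `fraction`. Deterministic given `seed`.
#'
#' @param reads Tibble with at least an `id` column.
#' @param fraction Keep probability in `(0, 1]`.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @return The subsampled tibble (row order preserved).
#' @export
subsample_reads <- function(reads, fraction, seed = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  if (fraction == 1) return(reads)
  key <- sub("/[12]$", "", reads$id)
  units <- unique(key)
  keep_unit <- with_seed_if(seed, runif(length(units)) < fraction)
  reads[keep_unit[match(key, units)], ]
}
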