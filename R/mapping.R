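#' Build a k-mer index over a genome
#'
#' Index for the exact mismatch-bounded mapper. Lookup of any k-mer returns
#' exactly its occurrence positions, forward and reverse-complement. The
#' mapper's placement search is complete (see [map_read()]) for any mismatch
#' budget; k only affects speed.
#'
#' @param genome Character scalar, or one-row tibble with `id` and `seq`.
#' @param k Seed length, 8..12. Default 9 balances seed-table locality
#'   against candidate counts for typical 50-150 nt reads.
#' @return An object of class `mapper_index`.
#' @export
build_index <- function(genome, k = 9L) {
  id <- if (is.data.frame(genome)) genome$id[1] else "genome"
  seq <- if (is.data.frame(genome)) genome$seq[1] else genome
  if (is.na(seq) || nchar(seq) == 0) abort("genome is empty")
  seq <- normalize_seq(seq)
  if (k > nchar(seq)) abort("k exceeds the genome length")
  structure(
    list(ptr = cpp_build_index(seq, as.integer(k)), id = id,
         k = as.integer(k), genome_length = nchar(seq)),
    class = "mapper_index"
  )
}

#' @export
print.mapper_index <- function(x, ...) {
  cat(sprintf("<mapper_index> %s: %d nt, k = %d\n", x$id, x$genome_length, x$k))
  invisible(x)
}

as_index <- function(x, k = 9L) {
  if (inherits(x, "mapper_index")) x else build_index(x, k = k)
}

#' Exact occurrences of a k-mer in an indexed genome
#'
#' @param index A `mapper_index`.
#' @param kmer Character scalar of length `k`. A k-mer containing `N` has no
#'   exact occurrence (N never matches).
#' @return A tibble with `pos` (0-based) and `strand` (`+` when the k-mer
#'   matches the forward text, `-` when its reverse complement does). A
#'   palindromic k-mer site is reported once, as `+`.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "mapper_index"))
  hit <- cpp_lookup_kmer(index$ptr, normalize_seq(kmer))
  tibble(pos = hit$pos, strand = ifelse(hit$strand == 0L, "+", "-"))
}

#' Map one read with a mismatch budget
#'
#' Reports ALL ungapped placements of the read, on either strand, with
#' Hamming mismatches `<= N` -- completeness is guaranteed by pigeonhole
#' seeding (see the package vignette), so the placement set equals a
#' brute-force scan of every genome window. `N` bases never match, on either
#' side. A placement found by both orientations at one locus counts once.
#'
#' Uniqueness counts all placements within the budget (not only a
#' best-stratum): a read whose best placement has 2 mismatches and second
#' best has 5 is `unique` at `N = 4` but `multi` at `N = 5`. This is what
#' makes the unique-mapping-rate curve peak and then fall as N grows.
#'
#' @param read Character scalar, or one-row tibble with a `seq` column.
#' @param index A `mapper_index` (or a genome, indexed on the fly).
#' @param N Maximum allowed mismatches per read (>= 0).
#' @return A list with `status` (`"unique"`, `"multi"` or `"unmapped"`) and
#'   `placements` (tibble `pos`, `strand`, `mismatches`).
#' @export
map_read <- function(read, index, N) {
  seq <- if (is.data.frame(read)) read$seq[1] else read
  index <- as_index(index)
  seq <- normalize_seq(seq)
  if (nchar(seq) < index$k) {
    warn(paste0("read shorter than seed length k = ", index$k, "; unmapped"))
    return(list(
      status = "unmapped",
      placements = tibble(pos = integer(), strand = character(), mismatches = integer())
    ))
  }
  m <- cpp_map_reads(index$ptr, seq, as.integer(N))$placements[[1]]
  placements <- tibble(
    pos = m[, 1],
    strand = ifelse(m[, 2] == 0L, "+", "-"),
    mismatches = m[, 3]
  )
  status <- if (nrow(placements) == 0) "unmapped"
            else if (nrow(placements) == 1) "unique" else "multi"
  list(status = status, placements = placements)
}

placement_counts <- function(reads, index, N_max) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0) abort("empty read set")
  seqs <- normalize_seq(seqs)
  if (any(nchar(seqs) < index$k)) {
    warn("reads shorter than the seed length are counted as unmapped")
  }
  cpp_placement_counts(index$ptr, seqs, as.integer(N_max), 2L)
}

#' Unique mapping rate of a read set
#'
#' Fraction of reads with exactly one placement within the mismatch budget.
#'
#' @param reads Tibble with a `seq` column, or a character vector.
#' @param index A `mapper_index` or a genome.
#' @param N Maximum allowed mismatches per read.
#' @return A number in `[0, 1]`.
#' @export
unique_mapping_rate <- function(reads, index, N) {
  index <- as_index(index)
  counts <- placement_counts(reads, index, N)
  mean(counts[, ncol(counts)] == 1L)
}

new_mismatch_profile <- function(grid, read_length) {
  peak <- max(grid$unique_rate)
  N_star <- grid$N[which(grid$unique_rate == peak)[1]]  # smallest N on ties
  structure(
    grid,
    N_star = N_star,
    read_length = read_length,
    optimal_mismatch_rate = 100 * N_star / read_length,
    class = c("mismatch_profile", class(grid))
  )
}

#' Find the mismatch budget that maximizes the unique mapping rate
#'
#' Sweeps the allowed mismatch count N over a grid and records the unique
#' and overall mapping rates at each N. The optimum `N*` is the argmax of the
#' unique rate (smallest N on ties); the optimal mismatch rate is
#' `100 * N* / L` percent. A single mapping pass at `max(N_grid)` yields the
#' whole profile, since the placements at budget N are exactly those with
#' `mismatches <= N`.
#'
#' @param reads Tibble with a `seq` column, or a character vector.
#' @param genome A `mapper_index` or a genome (character / tibble).
#' @param N_grid Sorted non-negative integer grid; default `0..ceiling(L/4)`.
#' @return A `mismatch_profile`: a tibble with columns `N`, `unique_rate`,
#'   `mapped_rate` and attributes `N_star`, `read_length`,
#'   `optimal_mismatch_rate`. `mapped_rate` is non-decreasing in N;
#'   `unique_rate <= mapped_rate`.
#' @export
optimal_mismatch_search <- function(reads, genome, N_grid = NULL) {
  index <- as_index(genome)
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0) abort("empty read set")
  lens <- nchar(seqs)
  L <- median(lens)
  if (length(unique(lens)) > 1) {
    warn("mixed read lengths: optimal rate converted with the median length")
  }
  if (is.null(N_grid)) N_grid <- 0:ceiling(0.25 * L)
  N_grid <- sort(unique(as.integer(N_grid)))
  if (length(N_grid) == 0 || any(N_grid < 0)) abort("invalid N_grid")
  counts <- placement_counts(reads, index, max(N_grid))
  grid <- tibble(
    N = N_grid,
    unique_rate = vapply(N_grid, function(N) mean(counts[, N + 1L] == 1L), numeric(1)),
    mapped_rate = vapply(N_grid, function(N) mean(counts[, N + 1L] >= 1L), numeric(1))
  )
  new_mismatch_profile(grid, L)
}

#' Build a mismatch profile from external aligner runs
#'
#' Ingests per-N alignment sets (e.g. parsed from SAM via [read_sam_min()])
#' from a spliced aligner run repeatedly with different allowed-mismatch
#' settings, and applies the same optimum rule as the internal search: a read
#' is uniquely mapped when its reported hit count is 1.
#'
#' @param runs A list; each element a list with `N` (the allowed-mismatch
#'   setting of the run), `alignments` (tibble from [read_sam_min()]) and
#'   `total_reads` (reads given to the aligner).
#' @param read_length Read length L used to convert `N*` to a percent rate.
#' @return A `mismatch_profile` (see [optimal_mismatch_search()]).
#' @export
profile_from_sam <- function(runs, read_length) {
  if (length(runs) == 0) abort("no runs supplied")
  Ns <- vapply(runs, function(r) as.integer(r$N), integer(1))
  if (anyDuplicated(Ns)) abort("duplicate N labels across runs")
  rows <- purrr::map(runs, function(r) {
    if (is.null(r$total_reads) || is.na(r$total_reads) || r$total_reads <= 0) {
      abort("each run needs a positive total_reads")
    }
    aln <- r$alignments
    per_read <- aln %>%
      distinct(.data$read_id, .data$n_hits) %>%
      group_by(.data$read_id) %>%
      summarise(n_hits = max(.data$n_hits), .groups = "drop")
    tibble(
      N = as.integer(r$N),
      unique_rate = sum(per_read$n_hits == 1L) / r$total_reads,
      mapped_rate = nrow(per_read) / r$total_reads
    )
  })
  grid <- bind_rows(rows) %>% arrange(.data$N)
  new_mismatch_profile(grid, read_length)
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat(sprintf(
    "<mismatch_profile> N* = %d (optimal mismatch rate %.2f%% of L = %d nt)\n",
    attr(x, "N_star"), attr(x, "optimal_mismatch_rate"), as.integer(attr(x, "read_length"))
  ))
  NextMethod()
}
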