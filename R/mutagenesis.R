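TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(
  A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G")
)

#' Mutate a genome by random substitution with a fixed Ts/Tv ratio
#'
#' Builds a virtual genome: every non-N base is substituted independently
#' with probability `rate`; given a substitution, a transition (A<->G,
#' C<->T) is chosen with probability `tstv / (tstv + 1)`, otherwise one of
#' the two transversions uniformly. Substitutions only -- no indels, no site
#' rate heterogeneity. Fully reproducible from `seed`.
#'
#' @param genome Character scalar or one-row tibble with `id` and `seq`.
#' @param rate Per-residue substitution probability in `[0, 1]`.
#' @param tstv Transition/transversion ratio kappa (> 0). Default 2.0, a
#'   typical genome-wide vertebrate value.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @return An object of class `mutated_genome`: a list with `genome`
#'   (one-row tibble `id`, `seq`), `truth` (tibble `pos` 0-based, `ref`,
#'   `alt`, `transition`), `rate`, `tstv`, `realized_rate` (substitutions /
#'   eligible bases) and `realized_tstv`, plus the `seed`.
#' @export
mutate_genome <- function(genome, rate, tstv = 2.0, seed = NULL) {
  id <- if (is.data.frame(genome)) genome$id[1] else "genome"
  seq <- if (is.data.frame(genome)) genome$seq[1] else genome
  if (is.na(seq) || nchar(seq) == 0) abort("genome sequence is empty")
  if (!is.numeric(rate) || rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  if (!is.numeric(tstv) || tstv <= 0) abort("tstv must be > 0")
  chars <- strsplit(normalize_seq(seq), "")[[1]]
  eligible <- chars != "N"
  n_eligible <- sum(eligible)
  truth <- with_seed_if(seed, {
    hit <- which(runif(length(chars)) < rate & eligible)
    if (length(hit) == 0) {
      tibble(
        pos = integer(), ref = character(), alt = character(),
        transition = logical()
      )
    } else {
      ref <- chars[hit]
      is_ts <- runif(length(hit)) < tstv / (tstv + 1)
      alt <- character(length(hit))
      alt[is_ts] <- TRANSITION[ref[is_ts]]
      if (any(!is_ts)) {
        tv_pick <- (runif(sum(!is_ts)) < 0.5) + 1L
        alt[!is_ts] <- mapply(
          function(b, i) TRANSVERSIONS[[b]][i], ref[!is_ts], tv_pick
        )
      }
      tibble(pos = hit - 1L, ref = ref, alt = alt, transition = is_ts)
    }
  })
  if (nrow(truth) > 0) chars[truth$pos + 1L] <- truth$alt
  n_ts <- sum(truth$transition)
  n_tv <- nrow(truth) - n_ts
  structure(
    list(
      genome = tibble(id = paste0(id, "_m", rate), seq = paste(chars, collapse = "")),
      truth = truth,
      rate = rate,
      tstv = tstv,
      seed = seed,
      realized_rate = if (n_eligible > 0) nrow(truth) / n_eligible else 0,
      realized_tstv = if (n_tv > 0) n_ts / n_tv else Inf
    ),
    class = "mutated_genome"
  )
}

#' @export
print.mutated_genome <- function(x, ...) {
  cat(sprintf(
    "<mutated_genome> %s: %d nt, target rate %.4f (realized %.4f), Ts/Tv target %.2f (realized %.2f), %d substitutions\n",
    x$genome$id, nchar(x$genome$seq), x$rate, x$realized_rate,
    x$tstv, x$realized_tstv, nrow(x$truth)
  ))
  invisible(x)
}

#' Generate a series of virtual genomes over a grid of mutation rates
#'
#' The default grid is fifteen rates, 1% to 15% in 1% steps -- the training
#' conditions of the mismatch-rate model. Seeds are derived deterministically
#' from `base_seed` (genome `i` uses `base_seed + 100 + i - 1`), so the same
#' `base_seed` always reproduces the identical series.
#'
#' @inheritParams mutate_genome
#' @param rates Numeric vector of per-residue substitution rates.
#' @param base_seed Integer; per-genome seeds are derived from it.
#' @return A list of `mutated_genome` objects, one per rate.
#' @export
make_virtual_series <- function(genome, rates = seq(0.01, 0.15, by = 0.01),
                                tstv = 2.0, base_seed = 1L) {
  if (length(rates) == 0) abort("rates must be non-empty")
  if (any(rates < 0 | rates > 1)) abort("every rate must be in [0, 1]")
  if (anyDuplicated(rates)) warn("duplicate mutation rates in series")
  purrr::imap(
    as.numeric(rates),
    function(r, i) mutate_genome(genome, r, tstv = tstv, seed = base_seed + 100L + i - 1L)
  )
}

#' Write a mutation truth log as TSV
#'
#' @param mg A `mutated_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(mg, path) {
  stopifnot(inherits(mg, "mutated_genome"))
  readr::write_tsv(mg$truth, path)
  invisible(path)
}
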