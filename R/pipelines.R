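#' Run the virtual-genome mutation experiment
#'
#' The model-training procedure: generate a random genome, mutate it at a
#' grid of per-residue rates (preserving the Ts/Tv ratio), simulate
#' error-free reads from the *original* genome, and for each mutated genome
#' sweep the allowed mismatch count to find the optimum `N*` that maximizes
#' the unique mapping rate. The observed optimal mismatch rates are then
#' regressed on the mutation rates by OLS.
#'
#' Seeds are derived from `seed`: the genome uses `seed`, mutated genome `i`
#' uses `seed + 100 + i - 1`, the read simulation uses `seed + 6`.
#'
#' @param seed Base integer seed.
#' @param genome_length Genome length, nt. Default 200 kb.
#' @param rates Mutation-rate grid. Default 1%..15% in 1% steps.
#' @param tstv Transition/transversion ratio. Default 2.0.
#' @param n_reads Number of simulated single-end reads. Default 20,000.
#' @param read_length Read length, nt. Default 100.
#' @param error_rate Sequencing error rate. Default 0 (error-free).
#' @param N_grid Allowed-mismatch sweep. Default 0..30.
#' @return An object of class `virtual_experiment`: list with `points`
#'   (tibble `mutation_rate`, `N_star`, `optimal_mismatch_rate`,
#'   `unique_rate`), `model` (a `pra_model` of the OLS fit) and `config`.
#' @export
virtual_experiment <- function(seed = 1L, genome_length = 2e5,
                               rates = seq(0.01, 0.15, by = 0.01),
                               tstv = 2.0, n_reads = 2e4, read_length = 100L,
                               error_rate = 0, N_grid = 0:30) {
  seed <- as.integer(seed)
  genome <- synth_genome(genome_length, seed = seed)
  series <- make_virtual_series(genome, rates = rates, tstv = tstv, base_seed = seed)
  sim <- simulate_reads(
    genome, n_reads = n_reads, read_length = read_length,
    error_rate = error_rate, seed = seed + 6L
  )
  points <- purrr::map_dfr(series, function(mg) {
    prof <- optimal_mismatch_search(sim$reads, mg$genome, N_grid = N_grid)
    tibble(
      mutation_rate = mg$rate,
      N_star = attr(prof, "N_star"),
      optimal_mismatch_rate = attr(prof, "optimal_mismatch_rate"),
      unique_rate = max(prof$unique_rate)
    )
  })
  structure(
    list(
      points = points,
      model = fit_mismatch_model(points),
      config = list(
        seed = seed, genome_length = genome_length, rates = rates,
        tstv = tstv, n_reads = n_reads, read_length = read_length,
        error_rate = error_rate, N_grid = N_grid
      )
    ),
    class = "virtual_experiment"
  )
}

#' @export
print.virtual_experiment <- function(x, ...) {
  cat(sprintf(
    "<virtual_experiment> %d mutation rates on a %d nt genome, %d reads\n",
    nrow(x$points), as.integer(x$config$genome_length), as.integer(x$config$n_reads)
  ))
  print(x$model)
  invisible(x)
}

#' @rdname virtual_experiment
#' @param x A `virtual_experiment`.
#' @param ... Unused.
#' @export
glance.virtual_experiment <- function(x, ...) {
  glance(x$model)
}

#' @rdname virtual_experiment
#' @export
tidy.virtual_experiment <- function(x, ...) {
  x$points
}

#' Odd/even held-out error of a virtual experiment
#'
#' Fits the linear model on the odd-indexed mutation rates (1%, 3%, ..., 15%
#' under the default grid) and reports the RMSE of its predictions on the
#' even rates (2%, ..., 14%) -- an out-of-sample check of the model's
#' percent-point accuracy.
#'
#' @param experiment A `virtual_experiment`.
#' @return A single number: held-out RMSE in percent points.
#' @export
odd_even_holdout_rmse <- function(experiment) {
  stopifnot(inherits(experiment, "virtual_experiment"))
  pts <- experiment$points %>% arrange(.data$mutation_rate)
  odd <- pts[seq(1, nrow(pts), by = 2), ]
  even <- pts[seq(2, nrow(pts), by = 2), ]
  holdout_rmse(odd, even)
}

#' Run the full assembly-strategy decision on raw inputs
#'
#' Computes marker distances from whatever evidence is supplied (one-to-one
#' ortholog pairs, a 16S rRNA pair, a D-loop pair), QCs the reads for
#' ambiguous bases, and runs [decide_strategy()].
#'
#' @param ref_available Is the query species' own genome available?
#' @param ortholog_pairs Tibble with `seq_a`, `seq_b`: one-to-one ortholog
#'   pairs (query vs pseudo-reference species).
#' @param marker_16s,marker_dloop Length-2 character vectors (or two-row
#'   tibbles with `seq`): the query and pseudo-reference marker sequence.
#' @param reads Optional read tibble for the ambiguous-base QC.
#' @param model,thresholds,read_length Passed to [decide_strategy()].
#' @return A list with `decision` (a `pra_decision`), `distances` (named
#'   numeric) and `read_qc` (list with `ambiguous_fraction` or NULL).
#' @export
full_decision <- function(ref_available = FALSE, ortholog_pairs = NULL,
                          marker_16s = NULL, marker_dloop = NULL,
                          reads = NULL, model = default_model(),
                          thresholds = decision_thresholds(),
                          read_length = NULL) {
  pair_dist <- function(m) {
    seqs <- if (is.data.frame(m)) m$seq else m
    if (length(seqs) != 2) abort("marker input must hold exactly two sequences")
    genetic_distance(seqs[1], seqs[2])$distance
  }
  distances <- c(
    ortholog = if (!is.null(ortholog_pairs)) ortholog_set_distance(ortholog_pairs) else NA_real_,
    `16s` = if (!is.null(marker_16s)) pair_dist(marker_16s) else NA_real_,
    dloop = if (!is.null(marker_dloop)) pair_dist(marker_dloop) else NA_real_
  )
  amb <- if (!is.null(reads)) ambiguous_fraction(reads) else NULL
  if (is.null(read_length)) {
    read_length <- if (!is.null(reads)) median(nchar(reads$seq)) else 100L
  }
  decision <- decide_strategy(
    ref_available = ref_available,
    distances = distances[!is.na(distances)],
    model = model, thresholds = thresholds,
    read_ambiguous_fraction = amb,
    read_length = read_length
  )
  list(
    decision = decision,
    distances = distances,
    read_qc = if (is.null(amb)) NULL else list(ambiguous_fraction = amb)
  )
}
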