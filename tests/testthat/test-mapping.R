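test_that("k-mer lookup returns exact occurrences on both strands", {
  ix <- build_index("ACGTACGT", k = 8)
  hit <- lookup_kmer(ix, "ACGTACGT")  # palindromic: one site, reported once
  expect_equal(hit, tibble::tibble(pos = 0L, strand = "+"))

  # "AAAACCCC" sits at 0 on the forward strand; its reverse complement
  # "GGGGTTTT" also occurs in this text, at 8, so both strands report
  g <- paste0("AAAACCCCGGGGTTTT", "ACGTACGTA")
  ix <- build_index(g, k = 8)
  expect_equal(nrow(lookup_kmer(ix, "AAAAAAAA")), 0)
  fwd <- lookup_kmer(ix, "AAAACCCC")
  expect_equal(fwd, tibble::tibble(pos = c(0L, 8L), strand = c("+", "-")))
  rc <- lookup_kmer(ix, "GGGGTTTT")
  expect_equal(rc, tibble::tibble(pos = c(8L, 0L), strand = c("+", "-")))

  expect_error(build_index(g, k = 7), ">= 8")
  expect_error(build_index("ACGT", k = 8), "exceeds")
})

test_that("map_read classifies unique/multi/unmapped and finds mismatched placements", {
  withr::local_seed(11)
  g <- random_dna(4000)
  ix <- build_index(g)
  read <- substr(g, 501, 600)
  expect_equal(map_read(read, ix, 0)$status, "unique")
  expect_equal(map_read(read, ix, 0)$placements$pos, 500L)

  dup <- paste0(g, substr(g, 501, 700))  # second copy of the read's locus
  ixd <- build_index(dup)
  expect_equal(map_read(read, ixd, 0)$status, "multi")

  mut <- plant_substitutions(read, 3)
  expect_equal(map_read(mut$seq, ix, 2)$status, "unmapped")
  res <- map_read(mut$seq, ix, 3)
  expect_equal(res$status, "unique")
  expect_equal(res$placements$mismatches, 3L)

  expect_warning(res <- map_read("ACGT", ix, 0), "shorter")
  expect_equal(res$status, "unmapped")
})

test_that("mapper placements equal the brute-force Hamming oracle", {
  withr::local_seed(2024)
  for (rep in 1:12) {
    alpha <- if (rep %% 3 == 0) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    prob <- if (length(alpha) == 5) c(rep(0.24, 4), 0.04) else NULL
    g <- random_dna(sample(300:1500, 1), alpha, prob)
    if (rep %% 4 == 0) g <- paste0(g, substr(g, 1, 120))
    ix <- build_index(g, k = sample(8:12, 1))
    for (j in 1:4) {
      L <- sample(c(20, 36, 50, 100), 1)
      p <- sample(nchar(g) - L + 1, 1)
      read <- substr(g, p, p + L - 1)
      nmut <- sample(0:6, 1)
      if (nmut > 0) read <- plant_substitutions(read, nmut)$seq
      if (runif(1) < 0.3) read <- revcomp_chr(read)
      N <- sample(0:25, 1)
      if (nchar(read) < ix$k) next
      got <- map_read(read, ix, N)$placements
      want <- oracle_placements(g, read, N)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$pos, want[, 1])
      expect_equal(got$mismatches, want[, 3])
      expect_equal(got$strand, ifelse(want[, 2] == 0, "+", "-"))
    }
  }
})

test_that("unique mapping rate is 1 on single-copy exact reads and 0 on a doubled genome", {
  withr::local_seed(15)
  g <- random_dna(3000)
  starts <- sample(2900, 50)
  reads <- substring(g, starts, starts + 99)
  expect_equal(unique_mapping_rate(reads, g, 0), 1)

  doubled <- paste0(g, g)  # two identical chromosomes in one text
  expect_equal(unique_mapping_rate(reads, doubled, 0), 0)
  expect_equal(unique_mapping_rate(reads, doubled, 10), 0)
  expect_error(unique_mapping_rate(character(), g, 0), "empty")
})

test_that("optimal_mismatch_search finds N* with the smallest-N tie rule", {
  withr::local_seed(19)
  g <- random_dna(5000)
  starts <- sample(4900, 200)
  reads <- substring(g, starts, starts + 99)
  prof <- optimal_mismatch_search(reads, g, N_grid = 0:5)
  expect_s3_class(prof, "mismatch_profile")
  expect_equal(attr(prof, "N_star"), 0L)  # error-free reads, repeat-free genome
  expect_equal(attr(prof, "optimal_mismatch_rate"), 0)
  expect_equal(prof$unique_rate, rep(1, 6))  # ties resolved to the smallest N
  expect_true(all(diff(prof$mapped_rate) >= 0))
  expect_true(all(prof$unique_rate <= prof$mapped_rate))

  mixed <- c(reads[1:5], substr(g, 1, 51))
  expect_warning(optimal_mismatch_search(mixed, g, N_grid = 0:2), "mixed")
})

test_that("a genome with a diverged duplicate segment yields a unique-rate peak then decline", {
  withr::local_seed(27)
  g <- random_dna(5000)
  dup <- plant_substitutions(substr(g, 1, 800), 16)$seq  # ~2% diverged copy
  genome <- paste0(g, dup)
  src <- tibble::tibble(id = "g", seq = genome)
  sim <- simulate_reads(src, 600, read_length = 100, error_rate = 0.01, seed = 4)
  prof <- optimal_mismatch_search(sim$reads, genome, N_grid = 0:12)
  peak <- which.max(prof$unique_rate)
  expect_gt(peak, 1)                   # errors need N > 0 to map
  expect_lt(peak, nrow(prof))          # and the curve declines after the peak
  expect_lt(prof$unique_rate[nrow(prof)], max(prof$unique_rate))
  expect_true(all(diff(prof$mapped_rate) >= 0))
})

test_that("profile_from_sam applies the unique rule and the argmax over runs", {
  aln1 <- tibble::tibble(
    read_id = paste0("r", 1:10), target = "c", pos = 0L,
    mismatches = 0L, n_hits = 1L
  )
  prof <- profile_from_sam(list(list(N = 2, alignments = aln1, total_reads = 10)),
                           read_length = 100)
  expect_equal(prof$unique_rate, 1)
  expect_equal(attr(prof, "N_star"), 2L)

  mk <- function(n_unique, n_multi, total) {
    tibble::tibble(
      read_id = c(paste0("u", seq_len(n_unique)), paste0("m", seq_len(n_multi))),
      target = "c", pos = 0L, mismatches = 0L,
      n_hits = c(rep(1L, n_unique), rep(2L, n_multi))
    )
  }
  runs <- list(
    list(N = 0, alignments = mk(6, 1, 10), total_reads = 10),
    list(N = 2, alignments = mk(8, 1, 10), total_reads = 10),
    list(N = 4, alignments = mk(7, 2, 10), total_reads = 10)
  )
  prof <- profile_from_sam(runs, read_length = 100)
  expect_equal(prof$unique_rate, c(0.6, 0.8, 0.7))
  expect_equal(attr(prof, "N_star"), 2L)
  expect_equal(attr(prof, "optimal_mismatch_rate"), 2)

  expect_error(
    profile_from_sam(c(runs, list(list(N = 2, alignments = aln1, total_reads = 10))), 100),
    "duplicate"
  )
  expect_error(
    profile_from_sam(list(list(N = 0, alignments = aln1, total_reads = NA)), 100),
    "total_reads"
  )
})
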