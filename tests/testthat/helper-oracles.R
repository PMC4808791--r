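# Independent oracles and fixture builders shared across tests.

random_dna <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(s, ""), function(x) paste(rev(x), collapse = ""), character(1)
  ))
}

# Brute-force Hamming placement oracle: for every window of the genome (both
# strands), count mismatches (N never matches) and keep windows <= N.
# Positions found by both orientations are reported once (smaller mismatch
# count, '+' on ties), matching the mapper's contract.
oracle_placements <- function(genome, read, N) {
  G <- nchar(genome)
  L <- nchar(read)
  if (L > G) return(matrix(integer(0), 0, 3))
  gch <- strsplit(genome, "")[[1]]
  rows <- list()
  for (strand in 0:1) {
    r <- if (strand == 0) read else revcomp_chr(read)
    rch <- strsplit(r, "")[[1]]
    mism <- integer(G - L + 1)
    for (j in seq_len(L)) {
      gseg <- gch[j:(G - L + j)]
      mism <- mism + (gseg != rch[j] | gseg == "N" | rch[j] == "N")
    }
    hit <- which(mism <= N)
    if (length(hit)) {
      rows[[length(rows) + 1]] <- cbind(hit - 1L, strand, mism[hit])
    }
  }
  if (!length(rows)) return(matrix(integer(0), 0, 3))
  m <- do.call(rbind, rows)
  m <- m[order(m[, 1], m[, 3], m[, 2]), , drop = FALSE]
  unname(m[!duplicated(m[, 1]), , drop = FALSE])
}

# Exhaustive global-alignment oracle for short sequences: enumerates every
# alignment (as an op string over M = align column, A = gap in b, B = gap in
# a) and scores it under the affine convention of align_pair (a gap run of
# length g costs -(gap_open) ... i.e. penalty gap_open + g * gap_extend,
# both negative). Returns the maximum score.
oracle_best_alignment_score <- function(a, b, scoring = list(
  match = 1, mismatch = -1, gap_open = -2, gap_extend = -0.5
)) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, last_op) {
    if (i > length(ac) && j > length(bc)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      s <- if (ac[i] == bc[j] && ac[i] != "N") scoring$match else scoring$mismatch
      recurse(i + 1, j + 1, score + s, "M")
    }
    if (i <= length(ac)) {  # gap in b
      pen <- scoring$gap_extend + if (last_op == "A") 0 else scoring$gap_open
      recurse(i + 1, j, score + pen, "A")
    }
    if (j <= length(bc)) {  # gap in a
      pen <- scoring$gap_extend + if (last_op == "B") 0 else scoring$gap_open
      recurse(i, j + 1, score + pen, "B")
    }
  }
  recurse(1, 1, 0, "")
  best
}

# score a gapped alignment pair under the same affine convention
score_gapped <- function(a_gapped, b_gapped, scoring = list(
  match = 1, mismatch = -1, gap_open = -2, gap_extend = -0.5
)) {
  ac <- strsplit(a_gapped, "")[[1]]
  bc <- strsplit(b_gapped, "")[[1]]
  stopifnot(length(ac) == length(bc))
  score <- 0
  last <- ""
  for (i in seq_along(ac)) {
    if (ac[i] == "-") {
      score <- score + scoring$gap_extend + if (last == "B") 0 else scoring$gap_open
      last <- "B"
    } else if (bc[i] == "-") {
      score <- score + scoring$gap_extend + if (last == "A") 0 else scoring$gap_open
      last <- "A"
    } else {
      score <- score +
        if (ac[i] == bc[i] && ac[i] != "N") scoring$match else scoring$mismatch
      last <- "M"
    }
  }
  score
}

# closed-form OLS via normal equations, independent of lm()
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  list(
    slope = slope, intercept = intercept,
    r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean((y - pred)^2))
  )
}

# plant k substitutions into a sequence at distinct positions
plant_substitutions <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  list(seq = paste(chars, collapse = ""), pos = sort(pos))
}
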