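default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -0.5)
}

scoring_matrix <- function(scoring) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- scoring$match
  # N never counts as a match, not even against another N
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' `Biostrings::pairwiseAlignment()`. The default scoring is match +1,
#' mismatch -1, gap open -2, gap extend -0.5; `N` is scored as a mismatch
#' against everything, including `N`.
#'
#' @param a,b Sequences: character scalars, or one-row tibbles with `id` and
#'   `seq` columns.
#' @param scoring Named list with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (gap penalties are negative numbers).
#' @return A list with `a_gapped`, `b_gapped` (equal-length gapped strings;
#'   removing `-` recovers the inputs) and `score`.
#' @export
align_pair <- function(a, b, scoring = default_scoring()) {
  a <- if (is.data.frame(a)) a$seq[1] else a
  b <- if (is.data.frame(b)) b$seq[1] else b
  if (is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
    abort("cannot align an empty sequence")
  }
  a <- normalize_seq(a)
  b <- normalize_seq(b)
  aln <- Biostrings::pairwiseAlignment(
    a, b,
    type = "global",
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = -scoring$gap_open,
    gapExtension = -scoring$gap_extend
  )
  list(
    a_gapped = as.character(Biostrings::alignedPattern(aln)),
    b_gapped = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

#' Genetic distance between two sequences
#'
#' Identity is the fraction of identically matching columns among alignment
#' columns where **both** sequences have a residue (gap columns excluded;
#' `N` counts as a mismatch). Distance is `1 - identity`. For two sequences
#' that differ only by `k` substitutions this gives exactly `k / length`.
#'
#' The gap-excluded denominator is one reading of "ratio of nucleotides
#' aligned to the corresponding sequence"; set
#' `denominator = "alignment_length"` to divide by all columns instead.
#'
#' @inheritParams align_pair
#' @param denominator `"aligned_residues"` (default) or `"alignment_length"`.
#' @param id_a,id_b Labels used in the output (default: `id` column when the
#'   input is a tibble, else `"a"`/`"b"`).
#' @return A one-row tibble: `id_a`, `id_b`, `identity`, `distance`,
#'   `aligned_columns`.
#' @export
genetic_distance <- function(a, b, scoring = default_scoring(),
                             denominator = c("aligned_residues", "alignment_length"),
                             id_a = NULL, id_b = NULL) {
  denominator <- match.arg(denominator)
  if (is.null(id_a)) id_a <- if (is.data.frame(a)) a$id[1] else "a"
  if (is.null(id_b)) id_b <- if (is.data.frame(b)) b$id[1] else "b"
  sa <- if (is.data.frame(a)) a$seq[1] else a
  sb <- if (is.data.frame(b)) b$seq[1] else b
  # align in canonical (lexicographic) order: the DP's internal tie-breaking
  # is not symmetric in its arguments, the distance must be
  aln <- if (!is.na(sa) && !is.na(sb) && sb < sa) {
    align_pair(sb, sa, scoring)
  } else {
    align_pair(sa, sb, scoring)
  }
  ca <- strsplit(aln$a_gapped, "")[[1]]
  cb <- strsplit(aln$b_gapped, "")[[1]]
  both <- ca != "-" & cb != "-"
  matches <- sum(both & ca == cb & ca != "N")
  denom <- if (denominator == "aligned_residues") sum(both) else length(ca)
  if (denom == 0) abort("alignment has no aligned residue columns")
  identity <- matches / denom
  tibble(
    id_a = id_a, id_b = id_b,
    identity = identity, distance = 1 - identity,
    aligned_columns = as.integer(sum(both))
  )
}

#' Median genetic distance over a set of ortholog pairs
#'
#' The genome-wide genetic distance between two species is summarized as the
#' median of per-ortholog-pair distances (mean of the two middle values for
#' an even count).
#'
#' @param pairs Tibble with columns `seq_a` and `seq_b` (one ortholog pair
#'   per row; an optional `id` column labels pairs), or a numeric vector of
#'   precomputed per-pair distances.
#' @inheritParams align_pair
#' @return A single number: the median pairwise distance.
#' @export
ortholog_set_distance <- function(pairs, scoring = default_scoring()) {
  if (is.numeric(pairs)) {
    if (length(pairs) == 0) abort("no ortholog pairs supplied")
    return(median(pairs))
  }
  if (nrow(pairs) == 0) abort("no ortholog pairs supplied")
  stopifnot(all(c("seq_a", "seq_b") %in% names(pairs)))
  d <- purrr::map2_dbl(
    pairs$seq_a, pairs$seq_b,
    function(a, b) genetic_distance(a, b, scoring)$distance
  )
  median(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via `ape::nj()`). Negative branch
#' length estimates, which NJ can produce on non-additive inputs, are clamped
#' to zero with a warning and flagged in the `clamped` attribute. For an
#' additive input matrix the tree path distances reproduce the matrix
#' exactly.
#'
#' @param m Symmetric numeric distance matrix with zero diagonal and row/col
#'   names (the taxa), or a `dist` object; at least 3 taxa.
#' @return An unrooted `phylo` tree with attribute `clamped` (logical).
#' @export
nj_tree <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (nrow(m) < 3) abort("neighbor joining needs at least 3 taxa")
  if (any(m < 0)) abort("negative distances are not allowed")
  if (max(abs(m - t(m))) > 1e-8) abort("distance matrix must be symmetric")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  tree <- ape::nj(as.dist(m))
  clamped <- any(tree$edge.length < 0)
  if (clamped) {
    warn("negative NJ branch length estimates clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped") <- clamped
  tree
}

#' Path distance between two leaves of a tree
#'
#' Sums branch lengths along the tree path between two tips, the tree-based
#' pairwise genetic distance between two species.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param a,b Tip labels.
#' @return A single non-negative number; 0 iff `a == b`.
#' @export
tree_path_distance <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) abort(paste0("unknown leaf: ", a))
  if (is.na(ib)) abort(paste0("unknown leaf: ", b))
  if (ia == ib) return(0)
  ape::dist.nodes(tree)[ia, ib]
}
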