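#' Read a minimal set of fields from a plain-text SAM file
#'
#' Ingestion path for alignments produced by an external (spliced) aligner.
#' Only the fields the toolkit needs are kept: read id, target, 0-based
#' position, mismatch count (`NM` tag) and number of reported placements
#' (`NH` tag). Unmapped records (FLAG bit 0x4) are dropped. When `NH` is
#' absent, the number of placements is recovered by counting lines per read
#' id. When `NM` is absent the mismatch count is recorded as `NA` and a
#' warning is raised.
#'
#' @param path Path to a SAM file (plain text; BAM is out of scope).
#' @return A tibble with columns `read_id`, `target`, `pos` (0-based),
#'   `mismatches` (integer or NA) and `n_hits` (integer >= 1).
#' @export
read_sam_min <- function(path) {
  if (!file.exists(path)) abort(paste0("SAM file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      read_id = character(), target = character(), pos = integer(),
      mismatches = integer(), n_hits = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short) > 0) {
    abort(paste0("SAM line ", short[1], " in '", path, "' has fewer than 11 fields"))
  }
  flag <- vapply(fields, function(f) suppressWarnings(as.integer(f[2])), integer(1))
  if (anyNA(flag)) abort(paste0("non-numeric FLAG field in '", path, "'"))
  get_tag <- function(f, tag) {
    hit <- f[startsWith(f, tag)][1]
    if (is.na(hit)) NA_integer_ else as.integer(sub(tag, "", hit, fixed = TRUE))
  }
  rec <- tibble(
    read_id = vapply(fields, `[`, character(1), 1),
    flag = flag,
    target = vapply(fields, `[`, character(1), 3),
    pos = vapply(fields, function(f) as.integer(f[4]), integer(1)) - 1L,
    mismatches = vapply(fields, get_tag, integer(1), tag = "NM:i:"),
    nh = vapply(fields, get_tag, integer(1), tag = "NH:i:")
  )
  rec <- rec[bitwAnd(rec$flag, 4L) == 0L, ]
  if (nrow(rec) > 0 && anyNA(rec$mismatches)) {
    warn("SAM records without NM tag: mismatch counts recorded as NA")
  }
  line_counts <- table(rec$read_id)
  rec$n_hits <- ifelse(
    is.na(rec$nh),
    as.integer(line_counts[rec$read_id]),
    rec$nh
  )
  rec %>% select("read_id", "target", "pos", "mismatches", "n_hits")
}
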