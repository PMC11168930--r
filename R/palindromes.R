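# Palindrome calling: turn candidate inverted hits into palindrome calls
# under the standard thresholds (arm identity >= 98%, arm length >= 8 kb,
# spacer <= 500 kb, repetitive content < 80%), plus the palindrome-level
# summary statistics (GC of arms vs spacers, chromosome coverage).

#' Palindrome-calling thresholds
#'
#' Defaults are the standard published thresholds: arms of at least 8 kb
#' aligning at >= 98% identity, separated by at most 500 kb of spacer, with
#' less than 80% of the candidate footprint covered by annotated repeats.
#'
#' @param min_arm_identity_pct Minimum arm-vs-arm identity (percent).
#' @param min_arm_len_bp Minimum length of each arm in bp.
#' @param max_spacer_bp Maximum spacer (arm1 end to arm2 start) in bp.
#' @param max_repeat_fraction Candidates at or above this repeat fraction are
#'   dropped (strict `<` keeps).
#' @param repeat_scope Whether the repeat fraction is measured over the full
#'   footprint (`"span"`, both arms plus spacer) or the arms only.
#' @return List of class `pk_palindrome_thresholds`.
#' @export
palindrome_thresholds <- function(min_arm_identity_pct = 98,
                                  min_arm_len_bp = 8000L,
                                  max_spacer_bp = 500000L,
                                  max_repeat_fraction = 0.80,
                                  repeat_scope = c("span", "arms")) {
  repeat_scope <- match.arg(repeat_scope)
  stopifnot(min_arm_identity_pct > 0, min_arm_identity_pct <= 100,
            min_arm_len_bp > 0, max_spacer_bp > 0,
            max_repeat_fraction > 0, max_repeat_fraction <= 1)
  structure(list(min_arm_identity_pct = min_arm_identity_pct,
                 min_arm_len_bp = as.integer(min_arm_len_bp),
                 max_spacer_bp = as.integer(max_spacer_bp),
                 max_repeat_fraction = max_repeat_fraction,
                 repeat_scope = repeat_scope),
            class = "pk_palindrome_thresholds")
}

#' Detect palindromes on a chromosome
#'
#' Runs [self_inverted_hits()] and keeps candidates that satisfy all four
#' thresholds.  Ids are `<chrom>_P<rank>` in order of `arm1_start`.
#'
#' @param seq Chromosome sequence (named string or `chrom` given).
#' @param repeat_track Repeat annotation track for this chromosome (used both
#'   to suppress seeding and to compute the repeat fraction).
#' @param thresholds [palindrome_thresholds()].
#' @param params [align_params()].
#' @param chrom Chromosome id; defaults to the name of `seq`.
#' @param non_redundant Keep only the longest palindrome per overlap group.
#' @return data.frame with columns `id`, `chrom`, `arm1_start`, `arm1_end`,
#'   `arm2_start`, `arm2_end`, `spacer_start`, `spacer_end`,
#'   `arm_identity_pct`, `repeat_fraction`, `total_span_bp`.
#' @export
detect_palindromes <- function(seq, repeat_track = NULL,
                               thresholds = palindrome_thresholds(),
                               params = align_params(), chrom = NULL,
                               non_redundant = FALSE) {
  chrom <- chrom %||% names(seq) %||% "chr"
  if (!is.null(repeat_track) && nrow(repeat_track) > 0 &&
      !all(repeat_track$chrom == chrom))
    stop("repeat_track is on a different chromosome than '", chrom, "'")
  hits <- self_inverted_hits(seq, params = params,
                             repeat_track = repeat_track, chrom = chrom)
  empty <- data.frame(id = character(), chrom = character(),
                      arm1_start = integer(), arm1_end = integer(),
                      arm2_start = integer(), arm2_end = integer(),
                      spacer_start = integer(), spacer_end = integer(),
                      arm_identity_pct = numeric(),
                      repeat_fraction = numeric(),
                      total_span_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  arm_len1 <- hits$arm1_end - hits$arm1_start
  arm_len2 <- hits$arm2_end - hits$arm2_start
  spacer <- hits$arm2_start - hits$arm1_end
  rf <- vapply(seq_len(nrow(hits)), function(r) {
    iv <- if (thresholds$repeat_scope == "span") {
      data.frame(start = hits$arm1_start[r], end = hits$arm2_end[r])
    } else {
      data.frame(start = c(hits$arm1_start[r], hits$arm2_start[r]),
                 end = c(hits$arm1_end[r], hits$arm2_end[r]))
    }
    repeat_fraction(iv, repeat_track)
  }, numeric(1))
  keep <- arm_len1 >= thresholds$min_arm_len_bp &
    arm_len2 >= thresholds$min_arm_len_bp &
    hits$identity_pct >= thresholds$min_arm_identity_pct &
    spacer <= thresholds$max_spacer_bp &
    rf < thresholds$max_repeat_fraction
  out <- hits[keep, , drop = FALSE]
  rf <- rf[keep]
  if (nrow(out) == 0) return(empty)
  res <- data.frame(
    id = sprintf("%s_P%d", chrom, seq_len(nrow(out))),
    chrom = out$chrom,
    arm1_start = out$arm1_start, arm1_end = out$arm1_end,
    arm2_start = out$arm2_start, arm2_end = out$arm2_end,
    spacer_start = out$arm1_end, spacer_end = out$arm2_start,
    arm_identity_pct = out$identity_pct,
    repeat_fraction = rf,
    total_span_bp = out$arm2_end - out$arm1_start,
    stringsAsFactors = FALSE)
  if (non_redundant && nrow(res) > 1) {
    span <- IRanges::IRanges(res$arm1_start + 1L, res$arm2_end)
    grp <- S4Vectors::subjectHits(
      IRanges::findOverlaps(span, IRanges::reduce(span)))
    keep <- unlist(lapply(split(seq_len(nrow(res)), grp), function(idx) {
      idx[which.max(res$total_span_bp[idx])]
    }))
    res <- res[sort(keep), , drop = FALSE]
    res$id <- sprintf("%s_P%d", chrom, seq_len(nrow(res)))
  }
  rownames(res) <- NULL
  res
}

#' Fraction of interval bases covered by repeats
#'
#' Both the intervals and the repeat track are reduced to unions first, so
#' overlapping annotations are never double-counted.
#'
#' @param intervals data.frame with `start`, `end` (0-based half-open).
#' @param repeat_track Repeat track (or `NULL` for none).
#' @param chrom_length Optional length used to validate the intervals.
#' @return Fraction in `[0, 1]`.
#' @export
repeat_fraction <- function(intervals, repeat_track = NULL,
                            chrom_length = NULL) {
  if (is.null(intervals) || nrow(intervals) == 0)
    stop("intervals must be non-empty")
  validate_intervals(intervals$start, intervals$end,
                     chrom_length = chrom_length)
  if (is.null(repeat_track) || nrow(repeat_track) == 0) return(0)
  iv <- IRanges::reduce(track_iranges(intervals))
  rp <- IRanges::reduce(track_iranges(repeat_track))
  covered <- sum(IRanges::width(IRanges::intersect(iv, rp)))
  covered / sum(IRanges::width(iv))
}

#' GC content of a sequence
#'
#' `N` bases are excluded from the denominator.
#'
#' @param residues Nucleotide string.
#' @return Percent GC in `[0, 100]`.
#' @export
gc_content <- function(residues) {
  if (nchar(residues) == 0) stop("empty sequence")
  raw <- charToRaw(toupper(residues))
  gc <- sum(raw == charToRaw("G") | raw == charToRaw("C"))
  at <- sum(raw == charToRaw("A") | raw == charToRaw("T"))
  if (gc + at == 0) stop("sequence has no unambiguous bases")
  100 * gc / (gc + at)
}

#' One-sided test for higher GC in palindrome arms than spacers
#'
#' Per palindrome, the GC of the concatenated arms and of the spacer form a
#' paired sample of groups; palindromes with empty spacers are excluded and
#' counted.  A Welch two-sample one-sided t test (alternative: arms greater)
#' is applied.
#'
#' @param palindromes Palindrome table from [detect_palindromes()].
#' @param seqs Named character vector holding the palindromes' chromosomes.
#' @return `pk_test` result with fields `statistic`, `p_value`,
#'   `alternative`, `n1`, `n2` and `n_excluded`.
#' @export
arm_vs_spacer_gc_test <- function(palindromes, seqs) {
  if (nrow(palindromes) < 2) stop("need at least 2 palindromes")
  has_spacer <- palindromes$spacer_end > palindromes$spacer_start
  n_excluded <- sum(!has_spacer)
  p <- palindromes[has_spacer, , drop = FALSE]
  if (nrow(p) < 2)
    stop("fewer than 2 palindromes with non-empty spacers (",
         n_excluded, " excluded)")
  arm_gc <- vapply(seq_len(nrow(p)), function(r) {
    s <- seqs[[p$chrom[r]]]
    gc_content(paste0(substr0(s, p$arm1_start[r], p$arm1_end[r]),
                      substr0(s, p$arm2_start[r], p$arm2_end[r])))
  }, numeric(1))
  spacer_gc <- vapply(seq_len(nrow(p)), function(r) {
    s <- seqs[[p$chrom[r]]]
    gc_content(substr0(s, p$spacer_start[r], p$spacer_end[r]))
  }, numeric(1))
  res <- t_test_two_sample(arm_gc, spacer_gc, alternative = "greater")
  res$n_excluded <- n_excluded
  res
}

#' Fraction of a chromosome covered by palindromes
#'
#' @param palindromes Palindrome table.
#' @param chrom_length Chromosome length in bp.
#' @param include_spacer Count the full span (arms plus spacer) rather than
#'   the arms only.
#' @return Fraction in `[0, 1]` (union; overlaps counted once).
#' @export
palindrome_coverage <- function(palindromes, chrom_length,
                                include_spacer = TRUE) {
  stopifnot(chrom_length > 0)
  if (nrow(palindromes) == 0) return(0)
  if (any(palindromes$arm2_end > chrom_length))
    stop("palindrome extends beyond chromosome length")
  ir <- if (include_spacer) {
    IRanges::IRanges(palindromes$arm1_start + 1L, palindromes$arm2_end)
  } else {
    IRanges::IRanges(
      c(palindromes$arm1_start, palindromes$arm2_start) + 1L,
      c(palindromes$arm1_end, palindromes$arm2_end))
  }
  sum(IRanges::width(IRanges::reduce(ir))) / chrom_length
}
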