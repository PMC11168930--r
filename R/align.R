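# Internal alignment engine: reverse complement, banded global pairwise
# alignment with metric reporting, and inverted self-alignment by exact
# k-mer seeding, collinear chaining and banded extension.  This is the
# discovery machinery behind palindrome calling; all knobs live in
# align_params() so external alignments can reproduce or replace it.

#' Alignment engine parameters
#'
#' @param k Seed length in bp (exact-match k-mers; >= 8).
#' @param max_seed_gap Maximum gap in bp between chained seeds.
#' @param match,mismatch,gap Integer alignment scores (linear gap cost).
#' @param band_width Half-width in bp of the banded extension.
#' @param min_arm_candidate Minimum candidate arm length in bp; shorter
#'   inverted hits are suppressed before threshold filtering.
#' @param max_kmer_occ Seeds whose k-mer occurs more often than this in the
#'   target are skipped (repeat damping).
#' @return List of class `pk_align_params`.
#' @export
align_params <- function(k = 21L, max_seed_gap = 5000L, match = 1L,
                         mismatch = -2L, gap = -3L, band_width = 200L,
                         min_arm_candidate = 1000L, max_kmer_occ = 64L) {
  stopifnot(k >= 8, band_width > 0, min_arm_candidate > 0, max_seed_gap > 0,
            max_kmer_occ >= 1)
  structure(list(k = as.integer(k), max_seed_gap = as.integer(max_seed_gap),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap), band_width = as.integer(band_width),
                 min_arm_candidate = as.integer(min_arm_candidate),
                 max_kmer_occ = as.integer(max_kmer_occ)),
            class = "pk_align_params")
}

#' Reverse complement of a nucleotide string
#'
#' Case is preserved (soft-masked bases stay lowercase); `N` maps to `N`.
#'
#' @param residues Character scalar over `A,C,G,T,N` in either case.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(residues) {
  if (length(residues) != 1) stop("residues must be a single string")
  if (grepl("[^ACGTNacgtn]", residues))
    stop("reverse_complement: residues outside {A,C,G,T,N}")
  rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", residues))))
}

#' Globally align two sequences and report alignment metrics
#'
#' Banded global alignment under the linear-gap scoring in `params`.
#' Identity is matches / alignment columns and the gap percentage is gap
#' columns / alignment columns (gaps count as columns).  Since the alignment
#' is global, each input is covered end to end.
#'
#' @param a,b Nucleotide strings.
#' @param params [align_params()].
#' @param query_chrom,target_chrom Optional sequence names for the record.
#' @param orientation Recorded orientation tag (`"direct"` or `"inverted"`);
#'   the caller reverse-complements `b` beforehand for inverted alignments.
#' @return One-row data.frame of alignment-record columns.
#' @export
align_pair <- function(a, b, params = align_params(), query_chrom = "query",
                       target_chrom = "target", orientation = "direct") {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  if (!grepl("[ACGTacgt]", a) || !grepl("[ACGTacgt]", b))
    stop("sequence contains no unambiguous bases")
  res <- banded_global_cpp(a, b, params$match, params$mismatch, params$gap,
                           params$band_width)
  data.frame(query_chrom = query_chrom, query_start = 0L,
             query_end = nchar(a), target_chrom = target_chrom,
             target_start = 0L, target_end = nchar(b),
             orientation = orientation,
             identity_pct = res$identity_pct, gap_pct = res$gap_pct,
             matched_bases = res$matches, qcov_pct = 100, tcov_pct = 100,
             stringsAsFactors = FALSE)
}

#' Find candidate inverted repeats by self-alignment
#'
#' Seeds exact k-mer matches between the chromosome and its reverse
#' complement (soft-masked bases never seed but are aligned through), chains
#' collinear inverted seeds, resolves overlaps greedily by chain support, and
#' scores each surviving candidate arm pair with a banded global alignment of
#' arm1 against the reverse complement of arm2.
#'
#' @param seq Chromosome sequence (single string, possibly named).
#' @param params [align_params()].
#' @param repeat_track Optional track whose intervals are soft-masked before
#'   seeding.
#' @param chrom Chromosome id; defaults to the name of `seq`.
#' @return data.frame with arm coordinates (`arm1_start`, `arm1_end`,
#'   `arm2_start`, `arm2_end`, 0-based half-open, arm1 5' of arm2),
#'   `identity_pct`, `gap_pct`, `matched_bases` and `n_seeds`, sorted by
#'   `arm1_start`.
#' @export
self_inverted_hits <- function(seq, params = align_params(),
                               repeat_track = NULL, chrom = NULL) {
  chrom <- chrom %||% names(seq) %||% "chr"
  seq <- first_string(unname(seq), "sequence")
  n <- nchar(seq)
  if (n < 2 * params$min_arm_candidate)
    stop("sequence shorter than twice min_arm_candidate")
  s <- apply_soft_mask(seq, repeat_track)
  rc <- reverse_complement(s)
  hits <- kmer_hits_cpp(s, rc, params$k, params$max_kmer_occ, FALSE, 1L)
  empty <- data.frame(chrom = character(), arm1_start = integer(),
                      arm1_end = integer(), arm2_start = integer(),
                      arm2_end = integer(), identity_pct = numeric(),
                      gap_pct = numeric(), matched_bases = numeric(),
                      n_seeds = integer(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  # partner start in chromosome coordinates: m = n - j - k
  m <- n - hits[, 2] - params$k
  keep <- hits[, 1] < m  # canonical orientation: arm1 left of arm2
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  ch <- chain_seeds(hits, params$k, params$max_seed_gap, params$band_width)
  # translate j-extents (reverse-complement coordinates) to arm2 intervals
  arm2_start <- n - ch$j_end
  arm2_end <- n - ch$j_start
  cand <- data.frame(arm1_start = ch$i_start, arm1_end = ch$i_end,
                     arm2_start = arm2_start, arm2_end = arm2_end,
                     n_seeds = ch$n_seeds)
  # trim candidates whose arms overlap around the centre (spacer-free calls)
  ov <- cand$arm1_end - cand$arm2_start
  ov[ov < 0] <- 0L
  trim <- as.integer(ceiling(ov / 2))
  cand$arm1_end <- cand$arm1_end - trim
  cand$arm2_start <- cand$arm2_start + trim
  cand <- cand[cand$arm1_end - cand$arm1_start >= params$min_arm_candidate &
               cand$arm2_end - cand$arm2_start >= params$min_arm_candidate, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # greedy overlap resolution: best-supported chain wins, ties by leftmost
  cand <- cand[order(-cand$n_seeds, cand$arm1_start), , drop = FALSE]
  kept <- logical(nrow(cand))
  occupied <- IRanges::IRanges()
  for (r in seq_len(nrow(cand))) {
    arms <- IRanges::IRanges(
      start = c(cand$arm1_start[r], cand$arm2_start[r]) + 1L,
      end = c(cand$arm1_end[r], cand$arm2_end[r]))
    if (length(occupied) == 0 ||
        sum(IRanges::countOverlaps(arms, occupied)) == 0) {
      kept[r] <- TRUE
      occupied <- c(occupied, arms)
    }
  }
  cand <- cand[kept, , drop = FALSE]
  # score each candidate: arm1 vs reverse complement of arm2
  stats <- lapply(seq_len(nrow(cand)), function(r) {
    a1 <- substr0(s, cand$arm1_start[r], cand$arm1_end[r])
    a2 <- reverse_complement(substr0(s, cand$arm2_start[r], cand$arm2_end[r]))
    banded_global_cpp(a1, a2, params$match, params$mismatch, params$gap,
                      params$band_width)
  })
  cand$identity_pct <- vapply(stats, `[[`, numeric(1), "identity_pct")
  cand$gap_pct <- vapply(stats, `[[`, numeric(1), "gap_pct")
  cand$matched_bases <- vapply(stats, `[[`, numeric(1), "matches")
  cand <- cand[order(cand$arm1_start), , drop = FALSE]
  rownames(cand) <- NULL
  cbind(data.frame(chrom = rep(chrom, nrow(cand)), stringsAsFactors = FALSE),
        cand[, c("arm1_start", "arm1_end", "arm2_start", "arm2_end",
                 "identity_pct", "gap_pct", "matched_bases", "n_seeds")])
}
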