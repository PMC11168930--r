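# Sequence-class annotation: partition a sex chromosome into pseudoautosomal
# (PAR), satellite (SAT), ampliconic (AMP) and ancestral (ANC) classes.
# PARs come from X-vs-Y terminal homology; SAT from merged dense repeat
# annotation; AMP from the union of palindrome footprints and windows with
# high intrachromosomal similarity; everything else is ANC, refined on the Y
# by gene-class overlap.  Precedence on overlap: PAR > SAT > AMP > ANC.

#' PAR detection parameters
#'
#' @param min_identity_pct Minimum X-vs-Y identity of the terminal block.
#' @param min_len_bp Minimum terminal block length.
#' @param max_interruption_bp Maximum unaligned interruption bridged within a
#'   block, and the maximum distance of the block from the chromosome end.
#' @param k Seed length for the X-vs-Y scan.
#' @param stride Seed subsampling stride (saves time on multi-Mb PARs;
#'   boundary resolution is ~`stride + k` bp).
#' @return List of class `pk_par_params`.
#' @export
par_params <- function(min_identity_pct = 99, min_len_bp = 50000L,
                       max_interruption_bp = 10000L, k = 21L, stride = 8L) {
  structure(list(min_identity_pct = min_identity_pct,
                 min_len_bp = as.integer(min_len_bp),
                 max_interruption_bp = as.integer(max_interruption_bp),
                 k = as.integer(k), stride = as.integer(stride)),
            class = "pk_par_params")
}

# merge chain x-extents into terminal blocks: grow from `from` ("left" or
# "right"), bridging interruptions <= max_int
terminal_block <- function(ch, side, len_x, len_y, max_int) {
  if (nrow(ch) == 0) return(NULL)
  if (side == "left") {
    ch <- ch[order(ch$i_start), , drop = FALSE]
    if (ch$i_start[1] > max_int) return(NULL)
    x_end <- 0L; y_end <- 0L
    rows <- logical(nrow(ch))
    for (r in seq_len(nrow(ch))) {
      if (ch$i_start[r] <= x_end + max_int) {
        x_end <- max(x_end, ch$i_end[r])
        y_end <- max(y_end, ch$j_end[r])
        rows[r] <- TRUE
      }
    }
    list(x = c(0L, x_end), y = c(0L, y_end), rows = which(rows))
  } else {
    ch <- ch[order(-ch$i_end), , drop = FALSE]
    if (len_x - ch$i_end[1] > max_int) return(NULL)
    x_start <- len_x; y_start <- len_y
    rows <- logical(nrow(ch))
    for (r in seq_len(nrow(ch))) {
      if (ch$i_end[r] >= x_start - max_int) {
        x_start <- min(x_start, ch$i_start[r])
        y_start <- min(y_start, ch$j_start[r])
        rows[r] <- TRUE
      }
    }
    list(x = c(x_start, len_x), y = c(y_start, len_y), rows = which(rows))
  }
}

# mean identity of sampled windows across a block, aligned along the block's
# local diagonal
sample_block_identity <- function(x_seq, y_seq, block, chains,
                                  align = align_params(), n_windows = 5L,
                                  window = 2000L) {
  ch <- chains[block$rows, , drop = FALSE]
  ids <- numeric(0)
  for (r in seq_len(min(nrow(ch), n_windows))) {
    w <- min(window, ch$i_end[r] - ch$i_start[r])
    if (w < 200) next
    xs <- ch$i_start[r]
    ys <- ch$j_start[r]
    a <- substr0(x_seq, xs, xs + w)
    b <- substr0(y_seq, ys, ys + w)
    ids <- c(ids, banded_global_cpp(a, b, align$match, align$mismatch,
                                    align$gap, align$band_width)$identity_pct)
  }
  if (length(ids) == 0) NA_real_ else mean(ids)
}

#' Detect pseudoautosomal regions by X-vs-Y terminal homology
#'
#' Finds maximal chromosome-terminal blocks where the X and Y sequences
#' align in direct orientation at high identity.  The block at the start of
#' the chromosomes is PAR1; a block at the opposite end, if present, PAR2.
#'
#' @param x_seq,y_seq X and Y chromosome sequences (named strings).
#' @param params [par_params()].
#' @param align [align_params()] for identity verification.
#' @return List with elements `X` and `Y`, each a track (`chrom`, `start`,
#'   `end`, `name` in `PAR1`/`PAR2`).  Empty tracks plus a warning when no
#'   terminal homology is found.
#' @export
detect_par <- function(x_seq, y_seq, params = par_params(),
                       align = align_params()) {
  x_name <- names(x_seq) %||% "chrX"
  y_name <- names(y_seq) %||% "chrY"
  xs <- first_string(unname(x_seq), "X sequence")
  ys <- first_string(unname(y_seq), "Y sequence")
  hits <- kmer_hits_cpp(xs, ys, params$k, 16L, FALSE, params$stride)
  chains <- chain_seeds(hits, params$k,
                        max_gap = params$max_interruption_bp,
                        band = max(align$band_width, 2L * params$stride))
  chains <- chains[chains$i_end - chains$i_start >= 200, , drop = FALSE]
  out_x <- empty_track()[, c("chrom", "start", "end", "name")]
  out_y <- out_x
  add <- function(block, label) {
    ident <- sample_block_identity(xs, ys, block, chains, align)
    if (is.na(ident) || ident < params$min_identity_pct) return(FALSE)
    if (block$x[2] - block$x[1] < params$min_len_bp ||
        block$y[2] - block$y[1] < params$min_len_bp) return(FALSE)
    out_x <<- rbind(out_x, data.frame(chrom = x_name, start = block$x[1],
                                      end = block$x[2], name = label,
                                      stringsAsFactors = FALSE))
    out_y <<- rbind(out_y, data.frame(chrom = y_name, start = block$y[1],
                                      end = block$y[2], name = label,
                                      stringsAsFactors = FALSE))
    TRUE
  }
  got1 <- got2 <- FALSE
  b1 <- terminal_block(chains, "left", nchar(xs), nchar(ys),
                       params$max_interruption_bp)
  if (!is.null(b1)) got1 <- add(b1, "PAR1")
  b2 <- terminal_block(chains, "right", nchar(xs), nchar(ys),
                       params$max_interruption_bp)
  if (!is.null(b2) && (!got1 || b2$x[1] > out_x$end[1]))
    got2 <- add(b2, "PAR2")
  if (!got1 && !got2)
    warning("no terminal X-Y homology found; no PAR reported")
  list(X = out_x, Y = out_y)
}

#' Merge repeat annotation into satellite intervals
#'
#' Adjacent repeat intervals within `merge_gap_bp` are merged; merged spans
#' strictly greater than `min_span_bp` are emitted as SAT.
#'
#' @param repeat_track Repeat annotation track.
#' @param merge_gap_bp Maximum gap merged across (inclusive).
#' @param min_span_bp Strict lower bound on the merged span.
#' @return Track with `name = "SAT"`.
#' @export
satellite_track <- function(repeat_track, merge_gap_bp = 1000L,
                            min_span_bp = 250000L) {
  if (is.null(repeat_track) || nrow(repeat_track) == 0)
    return(empty_track()[, c("chrom", "start", "end", "name")])
  out <- lapply(split(repeat_track, repeat_track$chrom), function(tr) {
    merged <- IRanges::reduce(track_iranges(tr),
                              min.gapwidth = merge_gap_bp + 1L)
    merged <- merged[IRanges::width(merged) > min_span_bp]
    iranges_track(merged, tr$chrom[1], name = "SAT")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Windows with high intrachromosomal similarity (ampliconic candidates)
#'
#' Tiles the chromosome into fixed windows (repeat-masked before seeding),
#' flags windows whose best seed-supported non-self locus aligns at or above
#' `min_identity_pct`, and emits maximal runs of consecutive qualifying
#' windows spanning strictly more than `min_span_bp`.  Only direct-
#' orientation copies are scanned; inverted copies enter the ampliconic
#' class through the palindrome-footprint union in [assign_classes()].
#'
#' @param seq Chromosome sequence (named string).
#' @param repeat_track Repeat track soft-masked before seeding.
#' @param window_bp Window size (terminal partial windows are skipped).
#' @param min_identity_pct Identity cutoff for a window's best non-self hit.
#' @param min_span_bp Strict lower bound on a qualifying run's span.
#' @param exclude Track of intervals (e.g. PARs) whose windows are skipped.
#' @param params [align_params()]; the seed length for this short-window
#'   task defaults to 11.
#' @param min_seeds Minimum co-diagonal seeds in a window before the
#'   candidate locus is aligned.  The default (10) makes chance candidates
#'   on unique sequence statistically negligible while genuine copies carry
#'   hundreds of seeds per window; effective sensitivity is bounded by exact
#'   k-mer seeding, as with word-hit seeded BLAST searches.
#' @param chrom Chromosome id.
#' @return Track of AMP candidate intervals.
#' @export
ampliconic_windows <- function(seq, repeat_track = NULL, window_bp = 5000L,
                               min_identity_pct = 50, min_span_bp = 90000L,
                               exclude = NULL,
                               params = align_params(k = 11L),
                               min_seeds = 10L, chrom = NULL) {
  if (window_bp <= 0) stop("window size must be positive")
  chrom <- chrom %||% names(seq) %||% "chr"
  s <- apply_soft_mask(first_string(unname(seq), "sequence"), repeat_track)
  n <- nchar(s)
  hits <- kmer_hits_cpp(s, s, params$k, params$max_kmer_occ, TRUE, 1L)
  n_windows <- n %/% window_bp
  empty <- empty_track()[, c("chrom", "start", "end", "name")]
  if (n_windows == 0 || nrow(hits) == 0) return(empty)
  # both directions of each i<j pair
  i <- c(hits[, 1], hits[, 2])
  j <- c(hits[, 2], hits[, 1])
  d <- j - i
  keep <- abs(d) >= window_bp  # non-self: target must lie outside the window
  i <- i[keep]; d <- d[keep]
  win <- i %/% window_bp
  excl_win <- integer(0)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    wir <- IRanges::IRanges(start = seq_len(n_windows) * window_bp -
                              window_bp + 1L,
                            width = window_bp)
    ov <- IRanges::countOverlaps(wir, track_iranges(exclude))
    excl_win <- which(ov > 0) - 1L
  }
  qualifies <- logical(n_windows)
  dbin <- round(d / params$band_width)
  key <- paste(win, dbin)
  counts <- table(key)
  cand_keys <- names(counts)[counts >= min_seeds]
  if (length(cand_keys)) {
    med_d <- vapply(split(d, key), stats::median, numeric(1))
    for (ck in cand_keys) {
      w <- as.integer(sub(" .*", "", ck))
      if (w %in% excl_win || w >= n_windows) next
      if (qualifies[w + 1L]) next
      dd <- as.integer(med_d[[ck]])
      ws <- w * window_bp
      we <- ws + window_bp
      ts <- max(0L, ws + dd)
      te <- min(n, we + dd)
      if (te - ts < window_bp / 2) next
      res <- banded_global_cpp(substr0(s, ws, we), substr0(s, ts, te),
                               params$match, params$mismatch, params$gap,
                               params$band_width)
      if (res$identity_pct >= min_identity_pct) qualifies[w + 1L] <- TRUE
    }
  }
  if (!any(qualifies)) return(empty)
  r <- rle(qualifies)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(ws = (starts - 1L) * window_bp, we = ends * window_bp,
                     q = r$values)
  runs <- runs[runs$q & (runs$we - runs$ws) > min_span_bp, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  data.frame(chrom = chrom, start = as.integer(runs$ws),
             end = as.integer(runs$we), name = "AMP",
             stringsAsFactors = FALSE)
}

#' Partition a chromosome into sequence classes
#'
#' AMP is the union of palindrome footprints and high-similarity candidate
#' intervals; overlaps resolve by precedence PAR > SAT > AMP > ANC; the
#' remainder is ANC.  On the Y, remaining ANC subregions overlapping a gene
#' labelled ampliconic are reassigned AMP (genes labelled ancestral confirm
#' ANC).  The result tiles `[0, chrom_length)` exactly.
#'
#' @param chrom_length Chromosome length in bp.
#' @param par Track of PAR intervals (name `PAR1`/`PAR2`), or `NULL`.
#' @param sat Track of satellite intervals, or `NULL`.
#' @param amp_candidates Track of high-similarity intervals, or `NULL`.
#' @param palindromes Palindrome table, or `NULL`.
#' @param gene_track Optional gene track with columns `start`, `end`,
#'   `class` (`"ancestral"`/`"ampliconic"`) used for the Y refinement.
#' @param chrom Chromosome id for the output.
#' @param include_spacer Use full palindrome spans (arms plus spacer) in the
#'   AMP union rather than arms only.
#' @return Track (`chrom`, `start`, `end`, `class`, `name`) tiling the
#'   chromosome; `class` in `PAR`, `SAT`, `AMP`, `ANC`; `name` keeps
#'   `PAR1`/`PAR2` labels.
#' @export
assign_classes <- function(chrom_length, par = NULL, sat = NULL,
                           amp_candidates = NULL, palindromes = NULL,
                           gene_track = NULL, chrom = "chr",
                           include_spacer = TRUE) {
  L <- as.integer(chrom_length)
  stopifnot(L > 0)
  chk <- function(track, what) {
    if (!is.null(track) && nrow(track) > 0)
      validate_intervals(track$start, track$end, chrom_length = L, what = what)
  }
  chk(par, "PAR"); chk(sat, "satellite"); chk(amp_candidates, "AMP candidate")
  if (!is.null(palindromes) && nrow(palindromes) > 0 &&
      any(palindromes$arm2_end > L))
    stop("palindrome extends beyond chromosome length")
  pal_ir <- if (is.null(palindromes) || nrow(palindromes) == 0) {
    IRanges::IRanges()
  } else if (include_spacer) {
    IRanges::IRanges(palindromes$arm1_start + 1L, palindromes$arm2_end)
  } else {
    IRanges::IRanges(c(palindromes$arm1_start, palindromes$arm2_start) + 1L,
                     c(palindromes$arm1_end, palindromes$arm2_end))
  }
  par_ir <- IRanges::reduce(track_iranges(par))
  sat_ir <- IRanges::reduce(track_iranges(sat))
  amp_ir <- IRanges::reduce(c(track_iranges(amp_candidates), pal_ir))
  whole <- IRanges::IRanges(1L, L)
  sat_ir <- IRanges::setdiff(sat_ir, par_ir)
  amp_ir <- IRanges::setdiff(IRanges::setdiff(amp_ir, par_ir), sat_ir)
  anc_ir <- IRanges::setdiff(whole, c(par_ir, sat_ir, amp_ir))
  # Y refinement: ANC subregions overlapping ampliconic-family genes -> AMP
  if (!is.null(gene_track) && nrow(gene_track) > 0 &&
      !is.null(gene_track$class)) {
    amp_genes <- track_iranges(gene_track[gene_track$class == "ampliconic", ,
                                          drop = FALSE])
    if (length(amp_genes)) {
      hitidx <- unique(S4Vectors::queryHits(
        IRanges::findOverlaps(anc_ir, amp_genes)))
      if (length(hitidx)) {
        amp_ir <- IRanges::reduce(c(amp_ir, anc_ir[hitidx]))
        anc_ir <- anc_ir[-hitidx]
      }
    }
  }
  seg <- function(ir, class) {
    if (length(ir) == 0) return(NULL)
    df <- iranges_track(ir, chrom)
    df$class <- class
    df$name <- class
    df
  }
  par_df <- NULL
  if (length(par_ir)) {
    par_df <- iranges_track(par_ir, chrom)
    par_df$class <- "PAR"
    # carry PAR1/PAR2 labels through by overlap with the input track
    par_df$name <- "PAR"
    if (!is.null(par) && !is.null(par$name)) {
      ov <- IRanges::findOverlaps(track_iranges(par_df), track_iranges(par))
      par_df$name[S4Vectors::queryHits(ov)] <- par$name[S4Vectors::subjectHits(ov)]
    }
  }
  out <- rbind(par_df, seg(sat_ir, "SAT"), seg(amp_ir, "AMP"),
               seg(anc_ir, "ANC"))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  # partition invariant: exact tiling of [0, L)
  if (nrow(out) == 0 || out$start[1] != 0L || out$end[nrow(out)] != L ||
      (nrow(out) > 1 && any(out$start[-1] != out$end[-nrow(out)])))
    stop("internal error: segments do not tile [0, chrom_length)")
  out
}

#' Filter segmental-duplication records
#'
#' Keeps records with identity strictly above 90%, length strictly above
#' 1 kb, and satellite content strictly below 70%.
#'
#' @param records data.frame with columns `identity_pct`, `length_bp`,
#'   `satellite_fraction`.
#' @param min_identity_pct,min_length_bp,max_satellite_fraction Strict
#'   bounds.
#' @return The kept rows of `records`.
#' @export
filter_segdups <- function(records, min_identity_pct = 90,
                           min_length_bp = 1000,
                           max_satellite_fraction = 0.70) {
  needed <- c("identity_pct", "length_bp", "satellite_fraction")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("missing field(s): ", paste(missing, collapse = ", "))
  for (col in needed)
    if (any(is.na(records[[col]]))) stop("NA in field ", col)
  keep <- records$identity_pct > min_identity_pct &
    records$length_bp > min_length_bp &
    records$satellite_fraction < max_satellite_fraction
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
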