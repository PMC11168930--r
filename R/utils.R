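# Internal helpers shared across modules.  The package-wide coordinate
# convention is 0-based half-open [start, end), as in BED.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a set of genomic intervals
#'
#' Asserts the package-wide 0-based half-open convention: `0 <= start < end`,
#' and, when a chromosome length is supplied, `end <= chrom_length`.
#'
#' @param start,end Integer vectors of interval bounds.
#' @param chrom_length Optional chromosome length in bp.
#' @param what Label used in error messages.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_intervals <- function(start, end, chrom_length = NULL,
                               what = "interval") {
  if (length(start) != length(end))
    stop("start and end differ in length")
  if (any(is.na(start)) || any(is.na(end)))
    stop(what, ": NA coordinate")
  bad <- which(start < 0)
  if (length(bad))
    stop(what, " ", bad[1], ": negative start (", start[bad[1]], ")")
  bad <- which(start >= end)
  if (length(bad))
    stop(what, " ", bad[1], ": start >= end (", start[bad[1]], " >= ",
         end[bad[1]], "); intervals are 0-based half-open")
  if (!is.null(chrom_length)) {
    bad <- which(end > chrom_length)
    if (length(bad))
      stop(what, " ", bad[1], ": end ", end[bad[1]],
           " exceeds chromosome length ", chrom_length)
  }
  invisible(TRUE)
}

# data.frame(chrom, start, end, ...) -> IRanges (1-based closed internally)
track_iranges <- function(track) {
  if (is.null(track) || nrow(track) == 0) return(IRanges::IRanges())
  IRanges::IRanges(start = track$start + 1L, end = track$end)
}

iranges_track <- function(ir, chrom, name = NULL) {
  df <- data.frame(chrom = rep(chrom, length(ir)),
                   start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- rep(name, length.out = nrow(df))
  df
}

empty_track <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), strand = character(),
             stringsAsFactors = FALSE)
}

# Total bases in the union of intervals (data.frame or IRanges)
union_bases <- function(track) {
  ir <- if (inherits(track, "IRanges")) track else track_iranges(track)
  sum(IRanges::width(IRanges::reduce(ir)))
}

# Lowercase the bases of `seq` covered by `track` (soft-masking).
apply_soft_mask <- function(seq, track) {
  if (is.null(track) || nrow(track) == 0) return(seq)
  raw <- charToRaw(seq)
  n <- length(raw)
  validate_intervals(track$start, track$end, chrom_length = n,
                     what = "mask interval")
  idx <- unlist(lapply(seq_len(nrow(track)), function(i) {
    seq.int(track$start[i] + 1L, track$end[i])
  }))
  idx <- unique(idx)
  # letters only: set bit 0x20
  raw[idx] <- as.raw(bitwOr(as.integer(raw[idx]), 0x20L))
  rawToChar(raw)
}

# Group seed hits (0-based i, j positions of k-mer starts) into collinear
# chains.  Hits on nearby diagonals (within `band`) separated by at most
# `max_gap` along i are chained; chains are then greedily merged while
# compatible.  Returns a data.frame of chain extents in (i, j) space.
chain_seeds <- function(hits, k, max_gap = 5000L, band = 200L) {
  empty <- data.frame(i_start = integer(), i_end = integer(),
                      j_start = integer(), j_end = integer(),
                      n_seeds = integer())
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  i <- hits[, 1]; j <- hits[, 2]
  d <- i - j
  ord <- order(d, i)
  i <- i[ord]; j <- j[ord]; d <- d[ord]
  grp <- cumsum(c(1L, as.integer(diff(d) > band)))
  chains <- lapply(split(seq_along(i), grp), function(idx) {
    oi <- idx[order(i[idx])]
    brk <- cumsum(c(1L, as.integer(diff(i[oi]) > max_gap)))
    lapply(split(oi, brk), function(s) {
      c(i_start = min(i[s]), i_end = max(i[s]) + k,
        j_start = min(j[s]), j_end = max(j[s]) + k,
        n_seeds = length(s))
    })
  })
  ch <- do.call(rbind, lapply(unlist(chains, recursive = FALSE), rbind))
  ch <- as.data.frame(ch)
  # merge pass: chains whose i-extents and j-extents are within max_gap and
  # whose diagonals agree within band are fragments of one alignment
  ch <- ch[order(ch$i_start), , drop = FALSE]
  repeat {
    merged <- FALSE
    if (nrow(ch) > 1) {
      out <- ch[1, , drop = FALSE]
      for (r in 2:nrow(ch)) {
        last <- nrow(out)
        dA <- out$i_start[last] - out$j_start[last]
        dB <- ch$i_start[r] - ch$j_start[r]
        if (ch$i_start[r] <= out$i_end[last] + max_gap &&
            abs(dB - dA) <= 2L * band &&
            ch$j_start[r] <= out$j_end[last] + max_gap) {
          out$i_end[last] <- max(out$i_end[last], ch$i_end[r])
          out$j_end[last] <- max(out$j_end[last], ch$j_end[r])
          out$j_start[last] <- min(out$j_start[last], ch$j_start[r])
          out$n_seeds[last] <- out$n_seeds[last] + ch$n_seeds[r]
          merged <- TRUE
        } else {
          out <- rbind(out, ch[r, , drop = FALSE])
        }
      }
      ch <- out
    }
    if (!merged) break
  }
  rownames(ch) <- NULL
  ch
}

# substring by 0-based half-open coordinates
substr0 <- function(seq, start, end) substr(seq, start + 1L, end)

first_string <- function(x, what) {
  if (is.null(x) || length(x) == 0) stop("no ", what, " supplied")
  if (length(x) > 1) x <- x[1]
  x
}
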