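# Reading and writing the standard formats the pipeline touches: FASTA
# (soft-masking by case), BED3/BED6 tracks, and tabular alignment records.
# Every coordinate crossing a module boundary is 0-based half-open.

ALN_COLUMNS <- c("query_chrom", "query_start", "query_end",
                 "target_chrom", "target_start", "target_end",
                 "orientation", "identity_pct", "gap_pct",
                 "matched_bases", "qcov_pct", "tcov_pct")

#' Read a (possibly soft-masked) FASTA file
#'
#' Residues must be over `A,C,G,T,N` in either case; lowercase marks
#' soft-masked bases and is preserved.  The id is the first whitespace-
#' delimited token of the header.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("empty sequence id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id '", ids[duplicated(ids)][1], "' in ", path)
  seqs <- as.character(set)
  names(seqs) <- ids
  for (id in ids) {
    s <- seqs[[id]]
    if (nchar(s) == 0) stop("empty sequence for id '", id, "'")
    bad <- regexpr("[^ACGTNacgtn]", s)
    if (bad > 0)
      stop("non-IUPAC residue '", substr(s, bad, bad), "' in '", id,
           "' at offset ", bad - 1L)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (case preserved).
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  set <- Biostrings::BStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Soft-masked runs of a sequence as a track
#'
#' @param seqs Named character vector as from [read_fasta()].
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) of lowercase runs.
#' @export
soft_masked_ranges <- function(seqs) {
  out <- lapply(names(seqs), function(id) {
    m <- gregexpr("[acgtn]+", seqs[[id]])[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(chrom = id, start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty_track()[, c("chrom", "start", "end")]
  out
}

#' Read a BED3+ file into a repeat/feature track
#'
#' Columns beyond the third are optional: column 4 becomes `name`, column 6
#' `strand`.  Coordinates are kept 0-based half-open; zero-length or negative
#' intervals are rejected with the offending line number.
#'
#' @param path Path to a tab-separated BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_track())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3))
    stop("line ", which(n < 3)[1], ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (any(is.na(start)) || any(is.na(end)))
    stop("line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  bad <- which(start < 0 | end < 0)
  if (length(bad)) stop("line ", bad[1], ": negative coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("line ", bad[1], ": start >= end (zero-length or inverted interval)")
  name <- ifelse(n >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                character(1)), "")
  strand <- ifelse(n >= 6, vapply(fields, function(f) f[min(6, length(f))],
                                  character(1)), ".")
  strand[!strand %in% c("+", "-")] <- "."
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, strand = strand, stringsAsFactors = FALSE)
}

#' Write a track as BED
#'
#' @param track data.frame with at least `chrom`, `start`, `end`; `name`,
#'   `score` and `strand` columns are written when present.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(track, path) {
  cols <- list(track$chrom, track$start, track$end)
  if (!is.null(track$name)) {
    cols <- c(cols, list(track$name,
                         track$score %||% rep(0L, nrow(track)),
                         track$strand %||% rep(".", nrow(track))))
  }
  df <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read tabular pairwise alignment records
#'
#' Two dialects are supported.  `generic-tsv` is the package's own headered
#' format with columns `r ALN_COLUMNS`.  `paf-like` is the conventional
#' 12-column PAF layout (`qname qlen qstart qend strand tname tlen tstart
#' tend nmatch alnlen mapq`), from which identity, gap and coverage
#' percentages are derived; reverse-strand rows become `inverted`.
#'
#' @param path Path to the table.
#' @param dialect `"generic-tsv"` or `"paf-like"`.
#' @return data.frame of alignment records in generic columns.
#' @export
read_alignment_table <- function(path, dialect = c("generic-tsv", "paf-like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "generic-tsv") {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    missing <- setdiff(ALN_COLUMNS, names(df))
    if (length(missing))
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    df <- df[, ALN_COLUMNS]
  } else {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 12) stop("paf-like input needs >= 12 columns")
    qspan <- raw[[4]] - raw[[3]]
    tspan <- raw[[9]] - raw[[8]]
    alnlen <- raw[[11]]
    mcols <- qspan + tspan - alnlen  # match/mismatch columns
    df <- data.frame(
      query_chrom = raw[[1]], query_start = raw[[3]], query_end = raw[[4]],
      target_chrom = raw[[6]], target_start = raw[[8]], target_end = raw[[9]],
      orientation = ifelse(raw[[5]] == "-", "inverted", "direct"),
      identity_pct = 100 * raw[[10]] / alnlen,
      gap_pct = 100 * (alnlen - mcols) / alnlen,
      matched_bases = raw[[10]],
      qcov_pct = 100 * qspan / raw[[2]],
      tcov_pct = 100 * tspan / raw[[7]],
      stringsAsFactors = FALSE)
  }
  validate_intervals(df$query_start, df$query_end, what = "query interval")
  validate_intervals(df$target_start, df$target_end, what = "target interval")
  if (!all(df$orientation %in% c("direct", "inverted")))
    stop("orientation must be 'direct' or 'inverted'")
  for (col in c("identity_pct", "gap_pct", "qcov_pct", "tcov_pct")) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v < 0 | v > 100))
      stop(col, " outside [0, 100]")
  }
  df
}

#' Write alignment records in the generic TSV dialect
#'
#' @param records data.frame of alignment records.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment_table <- function(records, path) {
  missing <- setdiff(ALN_COLUMNS, names(records))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  write.table(records[, ALN_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
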