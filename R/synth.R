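# Synthetic-fixture generator: chromosomes with planted palindromes,
# satellites, dispersed duplications, PAR blocks and genes, plus protein
# families with controlled identity structure.  Every generated object comes
# with a machine-readable truth table of realized coordinates, and identical
# spec + seed reproduce byte-identical output.

DNA_BASES <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (seed < 0 || seed >= 2^31))
    stop("seed must be a non-negative integer below 2^31")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @param base_comp Probabilities of A, C, G, T.
#' @param gc Shorthand: GC fraction (overrides `base_comp`).
#' @return A single DNA string.
#' @export
random_dna <- function(n, base_comp = c(0.25, 0.25, 0.25, 0.25), gc = NULL) {
  if (!is.null(gc))
    base_comp <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_comp),
        collapse = "")
}

#' Mutate a DNA sequence
#'
#' Independent per-base substitutions to a uniformly chosen different base at
#' rate `divergence`; optional small indels at rate `indel_rate` per base
#' (insertion or deletion with equal probability, geometric length with mean
#' 2 bp).  Deterministic for a given `seed`.
#'
#' @param residues DNA string.
#' @param divergence Substitution probability per base, in `[0, 0.5]`.
#' @param indel_rate Indel initiation probability per base.
#' @param seed Optional integer seed.
#' @return Mutated DNA string.
#' @export
mutate_sequence <- function(residues, divergence = 0, indel_rate = 0,
                            seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.5, indel_rate >= 0,
            indel_rate < 0.1)
  with_seed(seed, {
    chars <- strsplit(residues, "")[[1]]
    n <- length(chars)
    if (divergence > 0) {
      hit <- which(runif(n) < divergence & chars %in% DNA_BASES)
      if (length(hit)) {
        # uniformly chosen *different* base: shift by 1..3 in base order
        cur <- match(chars[hit], DNA_BASES)
        chars[hit] <- DNA_BASES[((cur - 1 +
                                    sample(1:3, length(hit),
                                           replace = TRUE)) %% 4) + 1]
      }
    }
    if (indel_rate > 0) {
      sites <- which(runif(n) < indel_rate)
      if (length(sites)) {
        pieces <- as.list(chars)
        for (s in sites) {
          len <- stats::rgeom(1, 0.5) + 1L
          if (runif(1) < 0.5) {  # insertion after s
            pieces[[s]] <- c(pieces[[s]],
                             sample(DNA_BASES, len, replace = TRUE))
          } else {               # deletion starting at s
            for (d in s:min(n, s + len - 1L)) pieces[[d]] <- character(0)
          }
        }
        chars <- unlist(pieces)
      }
    }
    paste(chars, collapse = "")
  })
}

feat <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "pk_feature")
}

#' Planted-feature constructors for synthetic chromosomes
#'
#' `feat_palindrome()` plants two inverted arms (arm2 is the mutated reverse
#' complement of arm1) separated by a background spacer; `feat_satellite()`
#' plants a tandem array of a random unit and annotates it in the repeat
#' track; `feat_duplication()` copies a region elsewhere with divergence;
#' `feat_gene()` records a gene annotation (no sequence change);
#' `feat_repeat_patch()` adds repeat annotation without touching sequence.
#'
#' @param start 0-based start of the feature (arm1 start for palindromes).
#' @param arm_len,spacer_len Palindrome arm and spacer lengths in bp.
#' @param divergence Substitution rate applied to the second copy.
#' @param indel_rate Indel rate applied to the second copy.
#' @param unit_len,n_copies Satellite unit length and copy count.
#' @param label Repeat-track or gene label.
#' @param length Feature length in bp.
#' @param copy_start Start of the duplicated copy.
#' @param gene Gene symbol.
#' @param class Gene class hint (`"ancestral"` or `"ampliconic"`).
#' @param end 0-based end of the patch.
#' @return A `pk_feature` for [synth_spec()].
#' @name synth-features
NULL

#' @rdname synth-features
#' @export
feat_palindrome <- function(start, arm_len, spacer_len, divergence = 0.01,
                            indel_rate = 0) {
  feat("palindrome", start = start, arm_len = arm_len,
       spacer_len = spacer_len, divergence = divergence,
       indel_rate = indel_rate)
}

#' @rdname synth-features
#' @export
feat_satellite <- function(start, unit_len = 171L, n_copies = 1000L,
                           label = "SAT_unit") {
  feat("satellite", start = start, unit_len = unit_len, n_copies = n_copies,
       label = label)
}

#' @rdname synth-features
#' @export
feat_duplication <- function(start, length, copy_start, divergence = 0.05) {
  feat("duplication", start = start, length = length,
       copy_start = copy_start, divergence = divergence)
}

#' @rdname synth-features
#' @export
feat_gene <- function(start, length, gene, class = "ancestral") {
  feat("gene", start = start, length = length, gene = gene, class = class)
}

#' @rdname synth-features
#' @export
feat_repeat_patch <- function(start, end, label = "REP") {
  feat("repeat_patch", start = start, end = end, label = label)
}

feature_footprint <- function(f) {
  switch(f$kind,
         palindrome = c(f$start, f$start + 2 * f$arm_len + f$spacer_len),
         satellite = c(f$start, f$start + f$unit_len * f$n_copies),
         duplication = rbind(c(f$start, f$start + f$length),
                             c(f$copy_start, f$copy_start + f$length)),
         gene = NULL,          # annotation only; may overlap anything
         repeat_patch = NULL)  # annotation only
}

#' Specification of a synthetic chromosome
#'
#' @param chrom Chromosome id.
#' @param length Chromosome length in bp.
#' @param base_comp Background base composition (A, C, G, T).
#' @param features List of planted features (see [feat_palindrome()] and
#'   friends).
#' @return Object of class `pk_synth_spec`.
#' @export
synth_spec <- function(chrom = "chrS", length = 1e6,
                       base_comp = c(0.25, 0.25, 0.25, 0.25),
                       features = list()) {
  stopifnot(length > 0, abs(sum(base_comp) - 1) < 1e-8)
  spec <- structure(list(chrom = chrom, length = as.integer(length),
                         base_comp = base_comp, features = features),
                    class = "pk_synth_spec")
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  fps <- list()
  for (idx in seq_along(spec$features)) {
    f <- spec$features[[idx]]
    fp <- feature_footprint(f)
    if (is.null(fp)) next
    if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
    if (any(fp[, 1] < 0) || any(fp[, 2] > spec$length))
      stop("feature ", idx, " (", f$kind, ") extends outside [0, ",
           spec$length, ")")
    fps[[length(fps) + 1]] <- cbind(fp, idx)
  }
  if (length(fps) > 1) {
    all_fp <- do.call(rbind, fps)
    ir <- IRanges::IRanges(all_fp[, 1] + 1L, all_fp[, 2])
    ov <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)[1]
      sh <- S4Vectors::subjectHits(ov)[1]
      stop("planted features overlap: feature ", all_fp[qh, 3],
           " and feature ", all_fp[sh, 3])
    }
  }
  invisible(TRUE)
}

write_region <- function(raw, start, replacement) {
  rep_raw <- charToRaw(replacement)
  end <- start + length(rep_raw)
  if (end > length(raw)) {
    rep_raw <- rep_raw[seq_len(length(raw) - start)]
    end <- length(raw)
  }
  raw[(start + 1):end] <- rep_raw
  raw
}

#' Generate a synthetic chromosome with planted features
#'
#' Palindrome arm2 is `mutate_sequence(reverse_complement(arm1))`;
#' satellites are tandem unit arrays recorded in the repeat track;
#' duplications copy the planted source region with divergence.  The truth
#' table records the realized coordinates of every planted feature.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; identical spec + seed give byte-identical
#'   output.
#' @return List with `seq` (named string), `repeats` (track), `genes`
#'   (track with `class` column), and `truth` (data.frame).
#' @export
synth_chromosome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pk_synth_spec"))
  validate_synth_spec(spec)
  with_seed(seed, {
    raw <- charToRaw(random_dna(spec$length, spec$base_comp))
    repeats <- list()
    genes <- list()
    truth <- list()
    add_truth <- function(...) truth[[length(truth) + 1]] <<-
        data.frame(..., stringsAsFactors = FALSE)
    for (f in spec$features) {
      if (f$kind == "palindrome") {
        arm1 <- random_dna(f$arm_len, spec$base_comp)
        arm2 <- mutate_sequence(reverse_complement(arm1), f$divergence,
                                f$indel_rate)
        a1s <- f$start; a1e <- a1s + f$arm_len
        a2s <- a1e + f$spacer_len; a2e <- a2s + nchar(arm2)
        raw <- write_region(raw, a1s, arm1)
        raw <- write_region(raw, a2s, arm2)
        add_truth(kind = "palindrome", chrom = spec$chrom,
                  start = a1s, end = a2e, arm1_start = a1s, arm1_end = a1e,
                  arm2_start = a2s, arm2_end = a2e,
                  divergence = f$divergence, label = NA_character_)
      } else if (f$kind == "satellite") {
        unit <- random_dna(f$unit_len, spec$base_comp)
        arr <- strrep(unit, f$n_copies)
        s <- f$start; e <- s + nchar(arr)
        raw <- write_region(raw, s, arr)
        repeats[[length(repeats) + 1]] <-
          data.frame(chrom = spec$chrom, start = s, end = e, name = f$label,
                     strand = ".", stringsAsFactors = FALSE)
        add_truth(kind = "satellite", chrom = spec$chrom, start = s, end = e,
                  arm1_start = NA, arm1_end = NA, arm2_start = NA,
                  arm2_end = NA, divergence = 0, label = f$label)
      } else if (f$kind == "duplication") {
        src <- rawToChar(raw[(f$start + 1):(f$start + f$length)])
        copy <- mutate_sequence(src, f$divergence, 0)
        raw <- write_region(raw, f$copy_start, copy)
        add_truth(kind = "duplication", chrom = spec$chrom, start = f$start,
                  end = f$start + f$length, arm1_start = f$copy_start,
                  arm1_end = f$copy_start + nchar(copy), arm2_start = NA,
                  arm2_end = NA, divergence = f$divergence,
                  label = NA_character_)
      } else if (f$kind == "gene") {
        genes[[length(genes) + 1]] <-
          data.frame(chrom = spec$chrom, start = f$start,
                     end = f$start + f$length, name = f$gene,
                     class = f$class, stringsAsFactors = FALSE)
        add_truth(kind = "gene", chrom = spec$chrom, start = f$start,
                  end = f$start + f$length, arm1_start = NA, arm1_end = NA,
                  arm2_start = NA, arm2_end = NA, divergence = 0,
                  label = f$gene)
      } else if (f$kind == "repeat_patch") {
        repeats[[length(repeats) + 1]] <-
          data.frame(chrom = spec$chrom, start = f$start, end = f$end,
                     name = f$label, strand = ".", stringsAsFactors = FALSE)
        add_truth(kind = "repeat_patch", chrom = spec$chrom, start = f$start,
                  end = f$end, arm1_start = NA, arm1_end = NA,
                  arm2_start = NA, arm2_end = NA, divergence = 0,
                  label = f$label)
      } else stop("unknown feature kind: ", f$kind)
    }
    seqs <- setNames(rawToChar(raw), spec$chrom)
    repeats <- if (length(repeats)) do.call(rbind, repeats) else
      empty_track()
    genes <- if (length(genes)) do.call(rbind, genes) else
      cbind(empty_track()[, c("chrom", "start", "end", "name")],
            data.frame(class = character()))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(kind = character())
    list(seq = seqs, repeats = repeats, genes = genes, truth = truth)
  })
}

#' Generate a homologous X/Y pair with shared pseudoautosomal blocks
#'
#' Generates the two chromosomes from their specs, then overwrites the
#' terminal blocks with copies of a shared PAR sequence mutated at the
#' haplotype divergence.  Features in either spec must keep clear of the
#' PAR blocks.
#'
#' @param x_spec,y_spec [synth_spec()] objects for X and Y.
#' @param par1_bp Length of the shared block at the chromosome starts.
#' @param par2_bp Length of the shared block at the ends (0 for none).
#' @param par_divergence Per-haplotype substitution rate within PARs.
#' @param seed Integer seed.
#' @return List with `X`, `Y` (as [synth_chromosome()]) and `truth` rows
#'   for the planted PARs.
#' @export
synth_xy_pair <- function(x_spec, y_spec, par1_bp = 300000L, par2_bp = 0L,
                          par_divergence = 0.001, seed = 1L) {
  for (sp in list(x_spec, y_spec)) {
    for (f in sp$features) {
      fp <- feature_footprint(f)
      if (is.null(fp)) next
      if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
      if (any(fp[, 1] < par1_bp) ||
          (par2_bp > 0 && any(fp[, 2] > sp$length - par2_bp)))
        stop("feature overlaps a PAR block in spec '", sp$chrom, "'")
    }
  }
  with_seed(seed, {
    X <- synth_chromosome(x_spec, seed = sample.int(2^31 - 1, 1))
    Y <- synth_chromosome(y_spec, seed = sample.int(2^31 - 1, 1))
    paste_block <- function(res, block, at_start) {
      s <- res$seq[[1]]
      n <- nchar(s)
      start <- if (at_start) 0L else n - nchar(block)
      raw <- write_region(charToRaw(s), start, block)
      res$seq <- setNames(rawToChar(raw), names(res$seq))
      res
    }
    par1 <- random_dna(par1_bp)
    truth <- list()
    X <- paste_block(X, mutate_sequence(par1, par_divergence), TRUE)
    Y <- paste_block(Y, mutate_sequence(par1, par_divergence), TRUE)
    truth[[1]] <- data.frame(kind = "PAR1", start = 0L, end = par1_bp,
                             stringsAsFactors = FALSE)
    if (par2_bp > 0) {
      par2 <- random_dna(par2_bp)
      X <- paste_block(X, mutate_sequence(par2, par_divergence), FALSE)
      Y <- paste_block(Y, mutate_sequence(par2, par_divergence), FALSE)
      truth[[2]] <- data.frame(kind = "PAR2",
                               start = NA_integer_, end = NA_integer_,
                               stringsAsFactors = FALSE)
    }
    list(X = X, Y = Y, truth = do.call(rbind, truth),
         par2_bp = as.integer(par2_bp))
  })
}

#' Generate synthetic protein families with controlled identity
#'
#' Each family descends from a random ancestor; member `i` carries
#' `round(divergence_i * length)` substitutions at interior positions
#' (the first and last 10 residues are conserved, emulating conserved
#' terminal domains and keeping local alignments full length).  The
#' realized identity of members `i`, `j` is close to
#' `1 - divergence_i - divergence_j`.  A requested within-species identity
#' above a requested cross-species identity for uniformly specified
#' families is infeasible on such a star tree and raises an error.
#'
#' @param families List of family specs: each a list with `gene`, `length`
#'   (residues) and either `members` (data.frame with `species`,
#'   `divergence`) or `copies` (named per-species counts) plus
#'   `within_identity` and `cross_identity` (percent).
#' @param seed Integer seed.
#' @param chrom Chromosome id written into the protein metadata.
#' @return List with `proteins` (data.frame as [read_protein_fasta()]) and
#'   `truth` (planted family per protein).
#' @export
synth_protein_families <- function(families, seed = 1L, chrom = "chrY") {
  with_seed(seed, {
    proteins <- list()
    truth <- list()
    locus <- 10000L
    mutate_protein <- function(seq, divergence) {
      L <- nchar(seq)
      n_sub <- round(divergence * L)
      chars <- strsplit(seq, "")[[1]]
      interior <- seq.int(11L, L - 10L)
      if (n_sub > length(interior))
        stop("divergence too high for protein length")
      if (n_sub > 0) {
        pos <- sample(interior, n_sub)
        cur <- match(chars[pos], AA20)
        chars[pos] <- AA20[((cur - 1 + sample(seq_len(19), n_sub,
                                              replace = TRUE)) %% 20) + 1]
      }
      paste(chars, collapse = "")
    }
    for (fi in seq_along(families)) {
      fam <- families[[fi]]
      L <- fam$length %||% 200L
      anc <- paste(sample(AA20, L, replace = TRUE), collapse = "")
      member_seq <- character()
      member_sp <- character()
      member_div <- numeric()
      if (is.null(fam$members)) {
        w <- fam$within_identity %||% 98
        cx <- fam$cross_identity %||% w
        if (cx > w)
          stop("family '", fam$gene,
               "': cross-species identity above within-species identity ",
               "is infeasible for uniformly specified members")
        copy_div <- (1 - w / 100) / 2
        branch_div <- ((1 - cx / 100) - (1 - w / 100)) / 2
        for (sp in names(fam$copies)) {
          sp_anc <- mutate_protein(anc, branch_div)
          for (ci in seq_len(fam$copies[[sp]])) {
            member_seq <- c(member_seq, mutate_protein(sp_anc, copy_div))
            member_sp <- c(member_sp, sp)
            member_div <- c(member_div, branch_div + copy_div)
          }
        }
      } else {
        for (mi in seq_len(nrow(fam$members))) {
          member_seq <- c(member_seq,
                          mutate_protein(anc, fam$members$divergence[mi]))
          member_sp <- c(member_sp, fam$members$species[mi])
          member_div <- c(member_div, fam$members$divergence[mi])
        }
      }
      for (mi in seq_along(member_seq)) {
        sp <- member_sp[mi]
        id <- sprintf("%s_%s_c%d", fam$gene, sp, mi)
        proteins[[length(proteins) + 1]] <- data.frame(
          id = id, gene = fam$gene, species = sp, chrom = chrom,
          start = locus, end = locus + 3L * L,
          residues = member_seq[mi], stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          id = id, family = fam$gene, species = sp,
          divergence = member_div[mi], stringsAsFactors = FALSE)
        locus <- locus + 10000L
      }
    }
    list(proteins = do.call(rbind, proteins), truth = do.call(rbind, truth))
  })
}
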