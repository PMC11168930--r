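# Shared fixture builders.  All fixtures are generated in code at test time
# from the package's own synthetic-data module; nothing is stored on disk.

# A 2-Mb chromosome with three qualifying palindromes and three decoys, each
# decoy violating exactly one calling threshold.  The decoy kinds rotate with
# the seed so all four violations are exercised across seeds.
palindrome_recovery_fixture <- function(seed) {
  qualifying <- list(
    feat_palindrome(60000, 10000, 2000, divergence = 0.005),
    feat_palindrome(150000, 12000, 40000, divergence = 0.01),
    feat_palindrome(300000, 9000, 90000, divergence = 0.005))
  decoy_pool <- list(
    identity = list(feat_palindrome(450000, 10000, 10000,
                                    divergence = 0.04)),
    short_arm = list(feat_palindrome(500000, 6000, 20000,
                                     divergence = 0.005)),
    repeat_rich = list(feat_palindrome(560000, 10000, 5000,
                                       divergence = 0.005),
                       feat_repeat_patch(560000, 581250, "SAT_decoy")),
    long_spacer = list(feat_palindrome(650000, 10000, 600000,
                                       divergence = 0.005)))
  kinds <- names(decoy_pool)[setdiff(1:4, (seed %% 4) + 1)]
  feats <- c(qualifying, unlist(decoy_pool[kinds], recursive = FALSE))
  spec <- synth_spec(chrom = "chrY", length = 2e6, features = feats)
  res <- synth_chromosome(spec, seed = seed)
  truth <- res$truth[res$truth$kind == "palindrome", , drop = FALSE]
  # first three palindrome rows are the qualifying ones (list order)
  list(res = res, truth_qualifying = truth[1:3, , drop = FALSE],
       truth_decoys = truth[-(1:3), , drop = FALSE],
       decoy_kinds = kinds)
}

# recall of planted palindromes: every planted one matched by a call with all
# four arm boundaries within `tol` bp
palindrome_recall <- function(calls, truth, tol = 100) {
  vapply(seq_len(nrow(truth)), function(r) {
    any(abs(calls$arm1_start - truth$arm1_start[r]) <= tol &
          abs(calls$arm1_end - truth$arm1_end[r]) <= tol &
          abs(calls$arm2_start - truth$arm2_start[r]) <= tol &
          abs(calls$arm2_end - truth$arm2_end[r]) <= tol)
  }, logical(1))
}

# calls overlapping any decoy footprint
decoy_emissions <- function(calls, truth_decoys) {
  if (nrow(calls) == 0 || nrow(truth_decoys) == 0) return(0L)
  sum(vapply(seq_len(nrow(calls)), function(r) {
    any(calls$arm1_start[r] < truth_decoys$end &
          calls$arm2_end[r] > truth_decoys$start)
  }, logical(1)))
}

# Random interval layout for sequence-class assignment: non-overlapping
# planted PAR/SAT/AMP features on a chromosome of random length, plus the
# per-base class oracle vector ("expected" classes; ANC elsewhere).
seqclass_interval_fixture <- function(seed) {
  set.seed(seed)
  L <- sample(300:800, 1) * 1000L
  par1 <- sample(40:80, 1) * 1000L
  par <- data.frame(chrom = "chrS", start = 0L, end = par1, name = "PAR1")
  if (runif(1) < 0.5) {
    par2 <- sample(20:50, 1) * 1000L
    par <- rbind(par, data.frame(chrom = "chrS", start = L - par2, end = L,
                                 name = "PAR2"))
  }
  # carve the non-PAR middle into feature slots with gaps
  cursor <- par1 + sample(5:20, 1) * 1000L
  right_limit <- if (nrow(par) == 2) par$start[2] else L
  sat <- amp <- pal <- NULL
  while (cursor + 60000 < right_limit - 20000) {
    kind <- sample(c("SAT", "AMP", "PAL", "gap"), 1)
    len <- sample(20:60, 1) * 1000L
    if (cursor + len > right_limit - 10000) break
    if (kind == "SAT") {
      sat <- rbind(sat, data.frame(chrom = "chrS", start = cursor,
                                   end = cursor + len, name = "SAT"))
    } else if (kind == "AMP") {
      amp <- rbind(amp, data.frame(chrom = "chrS", start = cursor,
                                   end = cursor + len, name = "AMP"))
    } else if (kind == "PAL") {
      arm <- max(8000L, as.integer(len %/% 3))
      pal <- rbind(pal, data.frame(
        id = sprintf("P%d", cursor), chrom = "chrS",
        arm1_start = cursor, arm1_end = cursor + arm,
        arm2_start = cursor + len - arm, arm2_end = cursor + len,
        spacer_start = cursor + arm, spacer_end = cursor + len - arm,
        arm_identity_pct = 99, repeat_fraction = 0,
        total_span_bp = len, stringsAsFactors = FALSE))
    }
    cursor <- cursor + len + sample(2:20, 1) * 1000L
  }
  oracle <- rep("ANC", L)
  fill <- function(track, cls) {
    if (is.null(track)) return()
    for (r in seq_len(nrow(track)))
      oracle[(track$start[r] + 1):track$end[r]] <<- cls
  }
  fill(par, "PAR")
  fill(sat, "SAT")
  fill(amp, "AMP")
  if (!is.null(pal)) {
    for (r in seq_len(nrow(pal)))
      oracle[(pal$arm1_start[r] + 1):pal$arm2_end[r]] <- "AMP"
  }
  list(L = L, par = par, sat = sat, amp = amp, pal = pal, oracle = oracle)
}

# expand an assign_classes() result to a per-base class vector
classes_per_base <- function(annotation, L) {
  out <- character(L)
  for (r in seq_len(nrow(annotation)))
    out[(annotation$start[r] + 1):annotation$end[r]] <- annotation$class[r]
  out
}

# Protein-family fixture: three species, one ampliconic family (98% within),
# one non-ampliconic multi-copy family (96% within), one family whose only
# high-identity pair is cross-species, and one cross-species-only component
# that the refinement must drop, plus two unrelated singletons.
protein_family_fixture <- function(seed, f2_within = 96) {
  fams <- list(
    list(gene = "GFA", length = 200L, copies = c(sp1 = 2L, sp2 = 2L),
         within_identity = 98, cross_identity = 93),
    list(gene = "GFB", length = 200L, copies = c(sp1 = 2L, sp3 = 2L),
         within_identity = f2_within, cross_identity = 91),
    list(gene = "GFC", length = 200L,
         members = data.frame(species = c("sp1", "sp1", "sp2"),
                              divergence = c(0.005, 0.095, 0.005))),
    list(gene = "GFD", length = 200L,
         members = data.frame(species = c("sp2", "sp3"),
                              divergence = c(0.05, 0.05))),
    list(gene = "SOLO1", length = 200L,
         members = data.frame(species = "sp1", divergence = 0)),
    list(gene = "SOLO2", length = 180L,
         members = data.frame(species = "sp3", divergence = 0)))
  synth_protein_families(fams, seed = seed)
}

# Biostrings local-alignment oracle for protein homology edges
oracle_protein_edges <- function(proteins, min_identity_pct = 50,
                                 min_aligned_fraction = 0.35) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  out <- list()
  for (p in seq_len(nrow(proteins) - 1)) {
    for (q in seq((p + 1), nrow(proteins))) {
      pa <- Biostrings::pairwiseAlignment(
        proteins$residues[p], proteins$residues[q], type = "local",
        substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 1)
      ident <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      pr <- pa@pattern@range
      sr <- pa@subject@range
      fa <- IRanges::width(pr) / nchar(proteins$residues[p])
      fb <- IRanges::width(sr) / nchar(proteins$residues[q])
      if (ident >= min_identity_pct && fa >= min_aligned_fraction &&
          fb >= min_aligned_fraction) {
        a <- proteins$id[p]; b <- proteins$id[q]
        out[[length(out) + 1]] <- if (a < b) c(a, b) else c(b, a)
      }
    }
  }
  if (length(out) == 0) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "~"))
}
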