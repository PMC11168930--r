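# Multi-copy and ampliconic gene-family calling from protein sequences:
# all-vs-all local alignment, homology at >= 50% identity over >= 35% of
# both protein lengths, single-linkage clustering with a within-species
# refinement, and the >= 97% within-species identity rule for the
# ampliconic flag.  Also gene density per sequence class with the
# goodness-of-fit test.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Read a protein FASTA with pipe-delimited metadata headers
#'
#' Headers are `id|gene|species|chrom|start|end`; coordinates are the
#' gene locus on its chromosome, 0-based half-open.
#'
#' @param path Path to the protein FASTA.
#' @return data.frame with columns `id`, `gene`, `species`, `chrom`,
#'   `start`, `end`, `residues`.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  fields <- strsplit(names(set), "|", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) != 6))
    stop("protein headers must be 'id|gene|species|chrom|start|end'")
  df <- data.frame(
    id = vapply(fields, `[[`, character(1), 1),
    gene = vapply(fields, `[[`, character(1), 2),
    species = vapply(fields, `[[`, character(1), 3),
    chrom = vapply(fields, `[[`, character(1), 4),
    start = as.integer(vapply(fields, `[[`, character(1), 5)),
    end = as.integer(vapply(fields, `[[`, character(1), 6)),
    residues = as.character(set), stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate protein id")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(df$residues))
  if (any(bad)) stop("non-standard residue in protein ", df$id[bad][1])
  df
}

#' Write proteins with pipe-delimited metadata headers
#'
#' @param proteins data.frame as from [read_protein_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqs <- proteins$residues
  names(seqs) <- with(proteins, paste(id, gene, species, chrom, start, end,
                                      sep = "|"))
  write_fasta(seqs, path)
}

#' Pairwise local protein alignment
#'
#' Affine-gap Smith-Waterman under BLOSUM62 (gap open 10, extend 1).
#' Identity is matches / alignment columns of the best local alignment.
#'
#' @param a,b Amino-acid strings.
#' @param gap_open,gap_ext Positive gap penalties.
#' @return List with `identity_pct`, `score`, `aligned_1`, `aligned_2`
#'   (aligned residue counts in each input) and alignment coordinates.
#' @export
protein_align <- function(a, b, gap_open = 10, gap_ext = 1) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty protein sequence")
  sub <- blosum62_matrix()
  res <- smith_waterman_cpp(a, b, sub, paste(rownames(sub), collapse = ""),
                            gap_open, gap_ext)
  res$aligned_1 <- res$end1 - res$start1
  res$aligned_2 <- res$end2 - res$start2
  res
}

#' All-vs-all protein homology edges
#'
#' An edge joins two proteins iff their best local alignment reaches
#' `min_identity_pct` identity and covers at least `min_aligned_fraction`
#' of both protein lengths.
#'
#' @param proteins data.frame as from [read_protein_fasta()].
#' @param min_identity_pct Identity cutoff (percent).
#' @param min_aligned_fraction Minimum aligned fraction of each protein.
#' @return data.frame of undirected edges: `a`, `b` (protein ids, a < b),
#'   `identity_pct`, `aligned_fraction_a`, `aligned_fraction_b`,
#'   `same_species`.
#' @export
protein_homology_edges <- function(proteins, min_identity_pct = 50,
                                   min_aligned_fraction = 0.35) {
  if (nrow(proteins) < 2) stop("need at least 2 proteins")
  if (any(nchar(proteins$residues) == 0)) stop("empty protein sequence")
  out <- list()
  for (p in seq_len(nrow(proteins) - 1)) {
    for (q in seq((p + 1), nrow(proteins))) {
      al <- protein_align(proteins$residues[p], proteins$residues[q])
      fa <- al$aligned_1 / nchar(proteins$residues[p])
      fb <- al$aligned_2 / nchar(proteins$residues[q])
      if (al$identity_pct >= min_identity_pct &&
          fa >= min_aligned_fraction && fb >= min_aligned_fraction) {
        a <- proteins$id[p]; b <- proteins$id[q]
        if (a > b) { tmp <- a; a <- b; b <- tmp
          tmpf <- fa; fa <- fb; fb <- tmpf }
        out[[length(out) + 1]] <- data.frame(
          a = a, b = b, identity_pct = al$identity_pct,
          aligned_fraction_a = fa, aligned_fraction_b = fb,
          same_species = proteins$species[p] == proteins$species[q],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(a = character(), b = character(),
                      identity_pct = numeric(),
                      aligned_fraction_a = numeric(),
                      aligned_fraction_b = numeric(),
                      same_species = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$a, res$b), , drop = FALSE]
}

#' Cluster proteins into multi-copy gene families
#'
#' Single linkage (transitive closure) over homology edges; components with
#' fewer than two members are never reported, and components containing no
#' within-species edge are removed (the refinement step).
#'
#' @param proteins data.frame as from [read_protein_fasta()].
#' @param edges Edges from [protein_homology_edges()].
#' @return data.frame of family membership: `family_id`, `id`, `gene`,
#'   `species`.
#' @export
cluster_families <- function(proteins, edges) {
  cl <- transitive_closure(proteins$id, data.frame(a = edges$a, b = edges$b))
  sizes <- table(cl$cluster_id)
  cl <- cl[cl$cluster_id %in% names(sizes)[sizes >= 2], , drop = FALSE]
  if (nrow(cl)) {
    within_root <- unique(cl$cluster_id[match(edges$a[edges$same_species],
                                              cl$node)])
    within_root <- within_root[!is.na(within_root)]
    cl <- cl[cl$cluster_id %in% within_root, , drop = FALSE]
  }
  idx <- match(cl$node, proteins$id)
  fam_rank <- match(cl$cluster_id, unique(cl$cluster_id))
  out <- data.frame(family_id = sprintf("F%d", fam_rank),
                    id = cl$node,
                    gene = proteins$gene[idx],
                    species = proteins$species[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag ampliconic gene families
#'
#' A family is ampliconic iff some within-species pair of members reaches
#' `min_identity_pct` protein identity.
#'
#' @param families Membership table from [cluster_families()].
#' @param edges Edges from [protein_homology_edges()] (identities reused).
#' @param min_identity_pct Within-species identity cutoff (default 97).
#' @return data.frame per family: `family_id`, `n_members`, `n_species`,
#'   `max_within_species_identity_pct`, `ampliconic`.
#' @export
call_ampliconic <- function(families, edges, min_identity_pct = 97) {
  fam_of <- families$family_id[match(edges$a, families$id)]
  per_family <- lapply(split(families, families$family_id), function(f) {
    e <- edges[!is.na(fam_of) & fam_of == f$family_id[1] &
                 edges$same_species, , drop = FALSE]
    mx <- if (nrow(e)) max(e$identity_pct) else NA_real_
    data.frame(family_id = f$family_id[1], n_members = nrow(f),
               n_species = length(unique(f$species)),
               max_within_species_identity_pct = mx,
               ampliconic = !is.na(mx) && mx >= min_identity_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_family)
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-species copy-number table of gene families
#'
#' @param families Membership table from [cluster_families()].
#' @param species Optional species to include (absent species count 0).
#' @return Integer matrix, species x family.
#' @export
copy_number_table <- function(families, species = NULL) {
  species <- species %||% sort(unique(families$species))
  fams <- unique(families$family_id)
  m <- matrix(0L, nrow = length(species), ncol = length(fams),
              dimnames = list(species, fams))
  if (nrow(families)) {
    tab <- table(families$species, families$family_id)
    m[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  m
}

#' Gene density per sequence class
#'
#' Each gene is assigned to the class containing its midpoint (avoiding
#' double counting at class boundaries); density is genes per Mb of class
#' length.
#'
#' @param annotation Sequence-class track from [assign_classes()].
#' @param gene_track data.frame with `start`, `end` per gene.
#' @return data.frame per class: `class`, `length_bp`, `n_genes`,
#'   `genes_per_mb`.
#' @export
gene_density <- function(annotation, gene_track) {
  classes <- unique(annotation$class)
  lengths <- vapply(classes, function(cl) {
    sum(annotation$end[annotation$class == cl] -
          annotation$start[annotation$class == cl])
  }, numeric(1))
  if (any(lengths <= 0)) stop("zero-length class")
  counts <- setNames(numeric(length(classes)), classes)
  if (nrow(gene_track)) {
    mid <- floor((gene_track$start + gene_track$end) / 2)
    seg <- findInterval(mid, annotation$start)
    bad <- seg < 1 | mid >= annotation$end[seg]
    if (any(bad)) stop("gene midpoint outside the annotated chromosome")
    tab <- table(annotation$class[seg])
    counts[names(tab)] <- as.numeric(tab)
  }
  data.frame(class = classes, length_bp = lengths, n_genes = counts[classes],
             genes_per_mb = counts[classes] / (lengths / 1e6),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Goodness-of-fit test for gene density differences
#'
#' Pearson chi-squared test of observed gene counts against expectations
#' proportional to class lengths, with Bonferroni adjustment for `m_tests`
#' comparisons.
#'
#' @param gene_counts Observed gene counts per class.
#' @param class_lengths Class lengths (same order).
#' @param m_tests Number of tests for the Bonferroni adjustment.
#' @return List with `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
density_gof_test <- function(gene_counts, class_lengths, m_tests = 1) {
  if (length(gene_counts) < 2 ||
      length(gene_counts) != length(class_lengths))
    stop("need >= 2 classes with matching lengths")
  expected <- sum(gene_counts) * class_lengths / sum(class_lengths)
  if (any(expected == 0)) stop("expected count of 0 in a class")
  res <- suppressWarnings(
    chisq.test(gene_counts, p = class_lengths / sum(class_lengths)))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value,
       p_adjusted = bonferroni(res$p.value, m_tests))
}
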