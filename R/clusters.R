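# Homologous palindrome clustering: arm-to-arm alignments are filtered by
# the standard discard rules (identity < 85%, gaps > 5%, < 500 matched bases,
# < 40% coverage of either arm), surviving alignments link palindromes, and
# clusters are the transitive closure (connected components) of the links.
# One filter serves both orthologous (cross-species) and paralogous
# (same-chromosome) links, so clusters may mix the two.

#' Arm-alignment filter rules
#'
#' An alignment is discarded iff any of the four conditions holds strictly:
#' identity below `min_identity_pct`, gap percentage above `max_gap_pct`,
#' fewer than `min_matched_bases` matched bases, or coverage of either arm
#' below `min_arm_coverage_pct`.  Boundary values are kept.
#'
#' @param min_identity_pct,max_gap_pct,min_matched_bases,min_arm_coverage_pct
#'   Filter thresholds (defaults 85, 5, 500, 40).
#' @return List of class `pk_arm_filter_rules`.
#' @export
arm_filter_rules <- function(min_identity_pct = 85, max_gap_pct = 5,
                             min_matched_bases = 500,
                             min_arm_coverage_pct = 40) {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            max_gap_pct >= 0, max_gap_pct <= 100, min_matched_bases >= 0,
            min_arm_coverage_pct >= 0, min_arm_coverage_pct <= 100)
  structure(list(min_identity_pct = min_identity_pct,
                 max_gap_pct = max_gap_pct,
                 min_matched_bases = min_matched_bases,
                 min_arm_coverage_pct = min_arm_coverage_pct),
            class = "pk_arm_filter_rules")
}

#' Keep/discard arm alignments under the filter rules
#'
#' @param records Alignment records (generic columns).
#' @param rules [arm_filter_rules()].
#' @return Logical vector, `TRUE` where the record is kept.
#' @export
filter_arm_alignment <- function(records, rules = arm_filter_rules()) {
  needed <- c("identity_pct", "gap_pct", "matched_bases", "qcov_pct",
              "tcov_pct")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("missing metric(s): ", paste(missing, collapse = ", "))
  for (col in needed)
    if (any(is.na(records[[col]]))) stop("NA in metric ", col)
  !(records$identity_pct < rules$min_identity_pct |
      records$gap_pct > rules$max_gap_pct |
      records$matched_bases < rules$min_matched_bases |
      records$qcov_pct < rules$min_arm_coverage_pct |
      records$tcov_pct < rules$min_arm_coverage_pct)
}

# canonical arm key: "<species>|<palindrome id>|<1 or 2>"
arm_key <- function(species, pal_id, arm) paste(species, pal_id, arm,
                                                sep = "|")

#' All-pairs arm alignments across palindrome sets
#'
#' Aligns every arm of every palindrome against every arm of every other
#' palindrome (within and across species), in both orientations, keeping the
#' better-scoring orientation.  Arms are named `<species>|<id>|<arm>` in the
#' resulting records.
#'
#' @param palindrome_sets Named list (species -> palindrome table from
#'   [detect_palindromes()]).
#' @param sequences Named list (species -> named character vector of
#'   chromosome sequences).
#' @param params [align_params()].
#' @return Alignment records in the generic columns.
#' @export
align_palindrome_arms <- function(palindrome_sets, sequences,
                                  params = align_params()) {
  arms <- do.call(rbind, lapply(names(palindrome_sets), function(sp) {
    p <- palindrome_sets[[sp]]
    if (nrow(p) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(p)), function(r) {
      s <- sequences[[sp]][[p$chrom[r]]]
      data.frame(key = c(arm_key(sp, p$id[r], 1), arm_key(sp, p$id[r], 2)),
                 seq = c(substr0(s, p$arm1_start[r], p$arm1_end[r]),
                         substr0(s, p$arm2_start[r], p$arm2_end[r])),
                 pal = paste(sp, p$id[r], sep = "|"),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(arms) || nrow(arms) < 2) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(ALN_COLUMNS)),
                                  ALN_COLUMNS), stringsAsFactors = FALSE)
    return(out)
  }
  recs <- list()
  for (a in seq_len(nrow(arms) - 1)) {
    for (b in seq((a + 1), nrow(arms))) {
      if (arms$pal[a] == arms$pal[b]) next  # self palindromes handled later
      direct <- align_pair(arms$seq[a], arms$seq[b], params,
                           query_chrom = arms$key[a],
                           target_chrom = arms$key[b],
                           orientation = "direct")
      inv <- align_pair(arms$seq[a], reverse_complement(arms$seq[b]), params,
                        query_chrom = arms$key[a],
                        target_chrom = arms$key[b],
                        orientation = "inverted")
      recs[[length(recs) + 1]] <-
        if (direct$matched_bases >= inv$matched_bases) direct else inv
    }
  }
  do.call(rbind, recs)
}

#' Link palindromes by surviving arm alignments
#'
#' An edge joins palindromes P and Q iff at least one arm-to-arm alignment
#' between them survives the filter rules.  Self edges are dropped.
#'
#' @param palindromes_by_species Named list (species -> palindrome table).
#' @param alignments Alignment records whose `query_chrom`/`target_chrom`
#'   name arms as `<species>|<palindrome id>|<arm>`.
#' @param rules [arm_filter_rules()].
#' @return data.frame of unique edges (`a`, `b`: `<species>|<palindrome>`).
#' @export
build_links <- function(palindromes_by_species, alignments,
                        rules = arm_filter_rules()) {
  known <- unlist(lapply(names(palindromes_by_species), function(sp) {
    p <- palindromes_by_species[[sp]]
    if (nrow(p) == 0) return(character())
    c(arm_key(sp, p$id, 1), arm_key(sp, p$id, 2))
  }))
  refs <- unique(c(alignments$query_chrom, alignments$target_chrom))
  unknown <- setdiff(refs, known)
  if (length(unknown))
    stop("alignment references unknown arm(s): ",
         paste(head(unknown, 3), collapse = ", "))
  keep <- filter_arm_alignment(alignments, rules)
  aln <- alignments[keep, , drop = FALSE]
  if (nrow(aln) == 0)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  pal_of <- function(key) sub("\\|[12]$", "", key)
  a <- pal_of(aln$query_chrom)
  b <- pal_of(aln$target_chrom)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  edges[edges$a != edges$b, , drop = FALSE]
}

#' Group nodes into clusters by transitive closure
#'
#' Connected components of the link graph (union-find); if pairs (A, B) and
#' (B, C) are linked, A, B and C form one cluster.  Singletons are retained
#' as their own clusters.  Cluster ids are the lexicographically smallest
#' member id.
#'
#' @param nodes Character vector of node ids.
#' @param edges data.frame with columns `a`, `b` over `nodes`.
#' @return data.frame with columns `cluster_id`, `node`.
#' @export
transitive_closure <- function(nodes, edges) {
  nodes <- unique(as.character(nodes))
  if (nrow(edges) > 0) {
    unknown <- setdiff(unique(c(edges$a, edges$b)), nodes)
    if (length(unknown))
      stop("edge references unknown node(s): ",
           paste(head(unknown, 3), collapse = ", "))
  }
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  if (nrow(edges) > 0) {
    ia <- match(edges$a, nodes)
    ib <- match(edges$b, nodes)
    for (e in seq_len(nrow(edges))) {
      ra <- find(ia[e]); rb <- find(ib[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_along(nodes), find, integer(1))
  comp <- split(nodes, root)
  ids <- vapply(comp, function(m) min(m), character(1))
  out <- do.call(rbind, lapply(seq_along(comp), function(ci) {
    data.frame(cluster_id = rep(unname(ids[ci]), length(comp[[ci]])),
               node = sort(unname(comp[[ci]])), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cluster_id, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster palindromes across species
#'
#' Convenience wrapper: [build_links()] then [transitive_closure()] over all
#' palindromes of all species.
#'
#' @inheritParams build_links
#' @return data.frame with columns `cluster_id`, `species`, `palindrome_id`.
#' @export
cluster_palindromes <- function(palindromes_by_species, alignments,
                                rules = arm_filter_rules()) {
  nodes <- unlist(lapply(names(palindromes_by_species), function(sp) {
    p <- palindromes_by_species[[sp]]
    if (nrow(p) == 0) return(character())
    paste(sp, p$id, sep = "|")
  }))
  edges <- build_links(palindromes_by_species, alignments, rules)
  cl <- transitive_closure(nodes, edges)
  parts <- strsplit(cl$node, "|", fixed = TRUE)
  data.frame(cluster_id = cl$cluster_id,
             species = vapply(parts, `[[`, character(1), 1),
             palindrome_id = vapply(parts, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Cluster sharing across species groups
#'
#' For each named species group, counts the clusters whose species set
#' contains the whole group; also tabulates clusters by their exact species
#' combination.
#'
#' @param clusters data.frame with columns `cluster_id`, `species` (one row
#'   per member, as from [cluster_palindromes()]).
#' @param species_groups Named list of character vectors.
#' @param species_universe Known species; defaults to those present in
#'   `clusters`.  Unknown species in a group raise an error.
#' @return List with `group_counts` (data.frame `group`, `n_clusters`) and
#'   `combination_counts` (data.frame `combination`, `n_clusters`).
#' @export
sharing_summary <- function(clusters, species_groups,
                            species_universe = NULL) {
  species_universe <- species_universe %||% unique(clusters$species)
  for (g in names(species_groups)) {
    unknown <- setdiff(species_groups[[g]], species_universe)
    if (length(unknown))
      stop("group '", g, "' names unknown species: ",
           paste(unknown, collapse = ", "))
  }
  sets <- lapply(split(clusters$species, clusters$cluster_id), unique)
  group_counts <- data.frame(
    group = names(species_groups),
    n_clusters = vapply(species_groups, function(grp) {
      sum(vapply(sets, function(s) all(grp %in% s), logical(1)))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  combos <- vapply(sets, function(s) paste(sort(s), collapse = "+"),
                   character(1))
  tab <- table(combos)
  combination_counts <- data.frame(combination = names(tab),
                                   n_clusters = as.integer(tab),
                                   stringsAsFactors = FALSE)
  rownames(group_counts) <- NULL
  list(group_counts = group_counts, combination_counts = combination_counts)
}
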