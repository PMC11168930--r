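aln_record <- function(identity = 99, gaps = 1, matched = 9000,
                       qcov = 90, tcov = 90,
                       query = "sp1|P1|1", target = "sp2|P1|1") {
  data.frame(query_chrom = query, query_start = 0L, query_end = 10000L,
             target_chrom = target, target_start = 0L, target_end = 10000L,
             orientation = "inverted", identity_pct = identity,
             gap_pct = gaps, matched_bases = matched, qcov_pct = qcov,
             tcov_pct = tcov, stringsAsFactors = FALSE)
}

test_that("arm-alignment filter applies the four discard rules strictly", {
  expect_false(filter_arm_alignment(aln_record(identity = 84.9)))
  expect_false(filter_arm_alignment(aln_record(gaps = 6)))
  expect_false(filter_arm_alignment(aln_record(matched = 499)))
  expect_false(filter_arm_alignment(aln_record(qcov = 39.9)))
  expect_false(filter_arm_alignment(aln_record(tcov = 39.9)))
  # boundary values are kept (discard rules are strict inequalities)
  expect_true(filter_arm_alignment(aln_record(identity = 85, gaps = 5,
                                              matched = 500, qcov = 40,
                                              tcov = 40)))
  expect_error(filter_arm_alignment(aln_record()[, -8]), "identity_pct")
})

test_that("links require a surviving alignment and exclude self edges", {
  pals <- list(
    sp1 = data.frame(id = c("P1", "P2"), stringsAsFactors = FALSE),
    sp2 = data.frame(id = "P1", stringsAsFactors = FALSE))
  aln <- rbind(aln_record(query = "sp1|P1|1", target = "sp2|P1|2"),
               aln_record(identity = 70, query = "sp1|P2|1",
                          target = "sp2|P1|1"),
               aln_record(query = "sp1|P1|1", target = "sp1|P1|2"))  # self
  edges <- build_links(pals, aln)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$a, "sp1|P1")
  expect_equal(edges$b, "sp2|P1")
  expect_error(build_links(pals, aln_record(query = "spX|P9|1")),
               "unknown arm")
})

test_that("transitive closure groups chains and keeps singletons apart", {
  cl <- transitive_closure(c("A", "B", "C"),
                           data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_setequal(cl$node, c("A", "B", "C"))
  cl <- transitive_closure(c("A", "B"), data.frame(a = character(),
                                                   b = character()))
  expect_equal(length(unique(cl$cluster_id)), 2L)
})

test_that("transitive closure equals graph connected components", {
  library(igraph)
  set.seed(61)
  for (rep in 1:10) {
    n <- 100
    nodes <- sprintf("n%03d", 1:n)
    m <- sample(0:150, 1)
    edges <- data.frame(a = sample(nodes, m, TRUE),
                        b = sample(nodes, m, TRUE))
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    mine <- transitive_closure(nodes, edges)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    comp <- igraph::components(g)$membership
    # same partition: grouping by my cluster ids equals grouping by igraph's
    mine_grp <- split(mine$node, mine$cluster_id)
    ig_grp <- split(names(comp), comp)
    key <- function(g) sort(unname(vapply(g, function(x)
      paste(sort(x), collapse = ","), character(1))))
    expect_equal(key(mine_grp), key(ig_grp))
  }
})

test_that("cluster count is monotone non-increasing under edge addition", {
  set.seed(62)
  nodes <- sprintf("n%02d", 1:40)
  all_edges <- t(combn(nodes, 2))
  picked <- all_edges[sample(nrow(all_edges), 60), , drop = FALSE]
  prev <- Inf
  for (m in c(0, 10, 30, 60)) {
    e <- data.frame(a = picked[seq_len(m), 1], b = picked[seq_len(m), 2])
    k <- length(unique(transitive_closure(nodes, e)$cluster_id))
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("sharing summary counts superset clusters and exact combinations", {
  clusters <- data.frame(
    cluster_id = c("c1", "c1", "c1", "c2", "c2", "c3"),
    species = c("human", "chimpanzee", "bonobo", "human", "chimpanzee",
                "gorilla"))
  s <- sharing_summary(clusters,
                       list(african = c("human", "chimpanzee", "bonobo"),
                            pan = c("human", "chimpanzee")))
  expect_equal(s$group_counts$n_clusters[s$group_counts$group == "african"], 1)
  expect_equal(s$group_counts$n_clusters[s$group_counts$group == "pan"], 2)
  expect_equal(sum(s$combination_counts$n_clusters), 3)
  expect_error(sharing_summary(clusters, list(bad = "orangutan")),
               "unknown species")
  empty <- sharing_summary(clusters[0, ], list(pan = "human"),
                           species_universe = "human")
  expect_equal(empty$group_counts$n_clusters, 0)
})

test_that("sharing counts match brute-force subset enumeration", {
  set.seed(63)
  species <- paste0("sp", 1:6)
  for (rep in 1:20) {
    k <- sample(5:30, 1)
    clusters <- do.call(rbind, lapply(1:k, function(ci) {
      members <- sample(species, sample(1:6, 1))
      data.frame(cluster_id = paste0("c", ci), species = members)
    }))
    groups <- lapply(1:4, function(g) sample(species, sample(1:4, 1)))
    names(groups) <- paste0("g", 1:4)
    s <- sharing_summary(clusters, groups, species_universe = species)
    sets <- lapply(split(clusters$species, clusters$cluster_id), unique)
    for (g in names(groups)) {
      brute <- sum(vapply(sets, function(x) all(groups[[g]] %in% x),
                          logical(1)))
      expect_equal(s$group_counts$n_clusters[s$group_counts$group == g],
                   brute)
    }
    # monotone: growing a group never increases its count
    ord <- order(lengths(groups))
    counts <- s$group_counts$n_clusters[match(names(groups)[ord],
                                              s$group_counts$group)]
    grown <- lapply(groups, function(g) unique(c(g, species[1])))
    s2 <- sharing_summary(clusters, grown, species_universe = species)
    expect_true(all(s2$group_counts$n_clusters <= s$group_counts$n_clusters))
  }
})

test_that("end-to-end clustering recovers planted cross-species homology", {
  set.seed(64)
  # one shared arm sequence planted in two species, plus private palindromes
  shared_arm <- random_dna(9000)
  mk <- function(chrom, arm1, arm2) {
    s <- paste0(random_dna(3000), arm1, random_dna(1500),
                reverse_complement(arm1), random_dna(4000), arm2,
                random_dna(2000), reverse_complement(arm2),
                random_dna(3000))
    setNames(s, chrom)
  }
  s1 <- mk("chr1", shared_arm, random_dna(8500))
  s2 <- mk("chr2", mutate_sequence(shared_arm, 0.03), random_dna(9500))
  p1 <- detect_palindromes(s1)
  p2 <- detect_palindromes(s2)
  expect_equal(nrow(p1), 2L)
  expect_equal(nrow(p2), 2L)
  sets <- list(sp1 = p1, sp2 = p2)
  aln <- align_palindrome_arms(sets, list(sp1 = s1, sp2 = s2))
  clusters <- cluster_palindromes(sets, aln)
  sizes <- table(clusters$cluster_id)
  expect_equal(sort(as.integer(sizes)), c(1L, 1L, 2L))
  shared <- names(sizes)[sizes == 2]
  members <- clusters[clusters$cluster_id == shared, ]
  expect_setequal(members$species, c("sp1", "sp2"))
  # the shared cluster is the planted first palindrome of each species
  expect_true(all(members$palindrome_id %in% c(p1$id[1], p2$id[1])))
})
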