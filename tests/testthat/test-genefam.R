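test_that("protein homology requires identity and coverage of both lengths", {
  set.seed(91)
  aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 n, replace = TRUE), collapse = "")
  p1 <- aa(100)
  proteins <- data.frame(id = c("a", "b"), gene = "g",
                         species = c("s1", "s1"), chrom = "c",
                         start = 0L, end = 300L,
                         residues = c(p1, p1), stringsAsFactors = FALSE)
  e <- protein_homology_edges(proteins)
  expect_equal(nrow(e), 1L)
  expect_equal(e$identity_pct, 100)
  expect_equal(e$aligned_fraction_a, 1)
  # a shared perfect 30-aa block in otherwise unrelated 100-aa proteins:
  # 0.30 < 0.35 coverage, no edge
  block <- aa(30)
  proteins$residues <- c(paste0(aa(35), block, aa(35)),
                         paste0(aa(35), block, aa(35)))
  e <- protein_homology_edges(proteins)
  expect_equal(nrow(e), 0L)
  proteins$residues[1] <- ""
  expect_error(protein_homology_edges(proteins), "empty")
})

test_that("family clustering is single linkage with within-species refinement", {
  ids <- c("A", "B", "C", "D", "E")
  proteins <- data.frame(id = ids, gene = ids,
                         species = c("s1", "s1", "s1", "s1", "s2"),
                         chrom = "c", start = 0L, end = 300L,
                         residues = "M", stringsAsFactors = FALSE)
  edges <- data.frame(a = c("A", "B"), b = c("B", "C"),
                      identity_pct = c(80, 80),
                      aligned_fraction_a = 1, aligned_fraction_b = 1,
                      same_species = c(TRUE, TRUE))
  fam <- cluster_families(proteins, edges)
  expect_equal(sort(fam$id), c("A", "B", "C"))
  expect_equal(length(unique(fam$family_id)), 1L)
  # a component whose only edge is cross-species is removed
  edges2 <- rbind(edges, data.frame(a = "D", b = "E", identity_pct = 85,
                                    aligned_fraction_a = 1,
                                    aligned_fraction_b = 1,
                                    same_species = FALSE))
  fam2 <- cluster_families(proteins, edges2)
  expect_false(any(c("D", "E") %in% fam2$id))
})

test_that("ampliconic flags need a within-species pair at 97%", {
  proteins <- data.frame(id = c("A", "B", "C", "D", "E", "F"),
                         gene = "g",
                         species = c("s1", "s1", "s1", "s1", "s1", "s2"),
                         chrom = "c", start = 0L, end = 300L,
                         residues = "M", stringsAsFactors = FALSE)
  edges <- data.frame(
    a = c("A", "C", "E"), b = c("B", "D", "F"),
    identity_pct = c(98, 96, 99),
    aligned_fraction_a = 1, aligned_fraction_b = 1,
    same_species = c(TRUE, TRUE, FALSE))
  fam <- cluster_families(proteins, edges)
  # E-F family has no within-species edge -> removed by refinement; make a
  # variant where it survives via a low-identity within-species edge
  edges3 <- rbind(edges, data.frame(a = "E", b = "E2", identity_pct = 80,
                                    aligned_fraction_a = 1,
                                    aligned_fraction_b = 1,
                                    same_species = TRUE))
  proteins3 <- rbind(proteins,
                     data.frame(id = "E2", gene = "g", species = "s1",
                                chrom = "c", start = 0L, end = 300L,
                                residues = "M"))
  fam3 <- cluster_families(proteins3, edges3)
  flags <- call_ampliconic(fam3, edges3)
  amp_of <- function(id) flags$ampliconic[flags$family_id ==
                                            fam3$family_id[fam3$id == id]]
  expect_true(amp_of("A"))    # 98% within-species
  expect_false(amp_of("C"))   # 96% within-species
  expect_false(amp_of("E"))   # only the cross-species pair reaches 99%
  # lowering the cutoff never unsets a flag (monotonicity)
  flags90 <- call_ampliconic(fam3, edges3, min_identity_pct = 90)
  expect_true(all(flags90$ampliconic[flags$ampliconic]))
})

test_that("planted protein families are recovered with correct flags", {
  fx <- protein_family_fixture(seed = 92)
  edges <- protein_homology_edges(fx$proteins)
  fam <- cluster_families(fx$proteins, edges)
  planted <- split(fx$truth$id, fx$truth$family)
  got <- split(fam$id, fam$family_id)
  key <- function(g) sort(unname(vapply(g, function(x)
    paste(sort(x), collapse = ","), character(1))))
  expect_equal(key(got),
               key(planted[c("GFA", "GFB", "GFC")]))
  flags <- call_ampliconic(fam, edges)
  amp_genes <- unique(fam$gene[fam$family_id %in%
                                 flags$family_id[flags$ampliconic]])
  expect_equal(amp_genes, "GFA")
  # homology edges equal the independent full-DP oracle
  mine <- sort(paste(edges$a, edges$b, sep = "~"))
  expect_equal(mine, oracle_protein_edges(fx$proteins))
})

test_that("copy-number table reflects per-species membership", {
  fam <- data.frame(family_id = c("F1", "F1", "F1"),
                    id = c("A", "B", "C"), gene = "g",
                    species = c("s1", "s1", "s2"))
  cn <- copy_number_table(fam, species = c("s1", "s2", "s3"))
  expect_equal(cn["s1", "F1"], 2L)
  expect_equal(cn["s2", "F1"], 1L)
  expect_equal(cn["s3", "F1"], 0L)
  expect_equal(dim(copy_number_table(fam[0, ], species = "s1")), c(1L, 0L))
})

test_that("gene density uses midpoints and conserves total gene count", {
  ann <- data.frame(chrom = "c", start = c(0, 2e6), end = c(2e6, 3e6),
                    class = c("ANC", "AMP"), name = c("ANC", "AMP"))
  genes <- data.frame(start = c(seq(0, 1.9e6, length.out = 10), 2.5e6),
                      end = c(seq(0, 1.9e6, length.out = 10), 2.5e6) + 1000)
  d <- gene_density(ann, genes)
  expect_equal(d$genes_per_mb[d$class == "ANC"], 5)
  expect_equal(d$genes_per_mb[d$class == "AMP"], 1)
  expect_equal(sum(d$genes_per_mb * d$length_bp / 1e6), nrow(genes))
  expect_equal(gene_density(ann, genes[0, ])$genes_per_mb, c(0, 0))
  set.seed(93)
  for (i in 1:20) {
    bounds <- sort(sample(1:99, 3)) * 1000L
    ann <- data.frame(chrom = "c", start = c(0, bounds),
                      end = c(bounds, 100000L),
                      class = c("PAR", "ANC", "AMP", "SAT"),
                      name = c("PAR1", "ANC", "AMP", "SAT"))
    g0 <- sample(0:99000, 20)
    genes <- data.frame(start = g0, end = g0 + sample(100:999, 20, TRUE))
    d <- gene_density(ann, genes)
    mid <- floor((genes$start + genes$end) / 2)
    brute <- table(cut(mid, c(0, bounds, 100000L), right = FALSE,
                       labels = ann$class))
    expect_equal(setNames(d$n_genes, d$class)[names(brute)],
                 setNames(as.numeric(brute), names(brute)))
  }
})

test_that("density goodness-of-fit matches the chi-squared reference", {
  # proportional counts: statistic 0, p 1
  r <- density_gof_test(c(20, 10), c(2e6, 1e6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # 30 vs 10 over equal lengths: Pearson statistic 10, df 1
  r <- density_gof_test(c(30, 10), c(1e6, 1e6), m_tests = 5)
  expect_equal(r$statistic, 10)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(10, 1, lower.tail = FALSE))
  expect_equal(r$p_adjusted, min(1, r$p_value * 5))
  expect_error(density_gof_test(c(30, 10), c(1e6, 0)), "expected")
})
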