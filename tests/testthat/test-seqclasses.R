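test_that("PAR detection recovers planted terminal homology on X and Y", {
  xsp <- synth_spec(chrom = "chrX", length = 1200000)
  ysp <- synth_spec(chrom = "chrY", length = 1000000)
  pair <- synth_xy_pair(xsp, ysp, par1_bp = 300000, par2_bp = 80000,
                        par_divergence = 0.001, seed = 71)
  pars <- detect_par(pair$X$seq, pair$Y$seq)
  expect_equal(pars$X$name, c("PAR1", "PAR2"))
  expect_equal(pars$X$start[1], 0)
  expect_lt(abs(pars$X$end[1] - 300000), 1000)
  expect_lt(abs(pars$Y$end[1] - 300000), 1000)
  expect_lt(abs(pars$X$start[2] - (1200000 - 80000)), 1000)
  expect_equal(pars$X$end[2], 1200000)
  expect_lt(abs(pars$Y$start[2] - (1000000 - 80000)), 1000)
})

test_that("non-homologous chromosomes give no PAR and a warning", {
  set.seed(72)
  x <- setNames(random_dna(200000), "chrX")
  y <- setNames(random_dna(150000), "chrY")
  expect_warning(pars <- detect_par(x, y), "no terminal")
  expect_equal(nrow(pars$X), 0L)
})

test_that("satellite merging follows the 1-kb / 0.25-Mb rule exactly", {
  tr <- function(starts, ends) data.frame(chrom = "c", start = starts,
                                          end = ends)
  # gap 900 bp: merged, span 260 kb > 250 kb -> one SAT
  s <- satellite_track(tr(c(0, 200900), c(200000, 260000)))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end), c(0, 260000))
  # single 250-kb repeat: span not > 0.25 Mb -> nothing
  expect_equal(nrow(satellite_track(tr(0, 250000))), 0L)
  # gap 1001 bp between two 200-kb repeats: not merged, neither emitted
  expect_equal(nrow(satellite_track(tr(c(0, 201001), c(200000, 401001)))), 0L)
  # gap exactly 1000 bp: merged ("within 1 kb" inclusive)
  s <- satellite_track(tr(c(0, 201000), c(200000, 451000)))
  expect_equal(nrow(s), 1L)
})

test_that("satellite merging is invariant to order and fragmentation", {
  set.seed(73)
  starts <- c(0, 100000, 300000, 301000, 700000)
  ends <- c(90000, 299000, 300500, 600000, 960000)
  tr <- data.frame(chrom = "c", start = starts, end = ends)
  base <- satellite_track(tr)
  shuffled <- satellite_track(tr[sample(nrow(tr)), ])
  expect_equal(base, shuffled)
  # fragment every interval into two abutting pieces: same base set
  mids <- floor((starts + ends) / 2)
  frag <- data.frame(chrom = "c", start = c(starts, mids),
                     end = c(mids, ends))
  expect_equal(satellite_track(frag), base)
})

test_that("ampliconic windows recover a planted two-copy duplication", {
  dsp <- synth_spec(chrom = "chrA", length = 1e6,
                    features = list(feat_duplication(100000, 120000, 600000,
                                                     divergence = 0.05)))
  d <- synth_chromosome(dsp, seed = 74)
  amp <- ampliconic_windows(d$seq)
  expect_equal(nrow(amp), 2L)
  cover <- function(lo, hi) any(amp$start <= lo & amp$end >= hi)
  expect_true(cover(100000, 220000))   # source locus
  expect_true(cover(600000, 720000))   # copy locus (symmetry)
  expect_lt(sum(amp$end - amp$start), 2 * 120000 + 4 * 5000)
  expect_error(ampliconic_windows(d$seq, window_bp = 0), "positive")
})

test_that("sub-90-kb duplications and unique sequence yield no AMP", {
  dsp <- synth_spec(chrom = "chrB", length = 5e5,
                    features = list(feat_duplication(50000, 60000, 300000,
                                                     divergence = 0.05)))
  d <- synth_chromosome(dsp, seed = 75)
  expect_equal(nrow(ampliconic_windows(d$seq)), 0L)
  u <- synth_chromosome(synth_spec(chrom = "chrU", length = 5e5), seed = 76)
  expect_equal(nrow(ampliconic_windows(u$seq)), 0L)
})

test_that("raising the span cutoff never adds AMP bases", {
  dsp <- synth_spec(chrom = "chrC", length = 1e6,
                    features = list(feat_duplication(100000, 150000, 600000,
                                                     divergence = 0.03)))
  d <- synth_chromosome(dsp, seed = 77)
  a90 <- ampliconic_windows(d$seq, min_span_bp = 90000)
  a140 <- ampliconic_windows(d$seq, min_span_bp = 140000)
  a200 <- ampliconic_windows(d$seq, min_span_bp = 200000)
  bases <- function(a) if (nrow(a) == 0) 0 else sum(a$end - a$start)
  expect_gte(bases(a90), bases(a140))
  expect_gte(bases(a140), bases(a200))
  expect_equal(bases(a200), 0)
})

test_that("class assignment tiles the chromosome and honours precedence", {
  fx <- seqclass_interval_fixture(81)
  ann <- assign_classes(fx$L, par = fx$par, sat = fx$sat,
                        amp_candidates = fx$amp, palindromes = fx$pal,
                        chrom = "chrS")
  # perfect tiling
  expect_equal(ann$start[1], 0)
  expect_equal(ann$end[nrow(ann)], fx$L)
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)]))
  # PAR1/PAR2 names survive
  expect_true("PAR1" %in% ann$name)
  # precedence: an interval planted both as satellite and PAR stays PAR
  par <- data.frame(chrom = "c", start = 0, end = 100000, name = "PAR1")
  sat <- data.frame(chrom = "c", start = 50000, end = 300000, name = "SAT")
  ann2 <- assign_classes(400000, par = par, sat = sat, chrom = "c")
  expect_equal(ann2$class[1:2], c("PAR", "SAT"))
  expect_equal(ann2$end[1], 100000)  # PAR wins the overlap
  expect_error(assign_classes(1000, par = data.frame(chrom = "c", start = 0,
                                                     end = 2000,
                                                     name = "PAR1")),
               "exceeds")
})

test_that("Y refinement reassigns gene-supported subregions to AMP", {
  genes <- data.frame(chrom = "c", start = c(120000, 310000),
                      end = c(125000, 315000), name = c("g1", "g2"),
                      class = c("ampliconic", "ancestral"))
  sat <- data.frame(chrom = "c", start = 200000, end = 300000, name = "SAT")
  ann <- assign_classes(400000, sat = sat, gene_track = genes, chrom = "c")
  cls_at <- function(pos) ann$class[ann$start <= pos & ann$end > pos]
  expect_equal(cls_at(122000), "AMP")   # ampliconic gene pulls ANC -> AMP
  expect_equal(cls_at(312000), "ANC")   # ancestral gene confirms ANC
  expect_equal(cls_at(250000), "SAT")   # refinement never touches SAT
})

test_that("segmental-duplication filtering applies the three strict rules", {
  recs <- data.frame(identity_pct = c(89, 95, 95, 90, 95, 95),
                     length_bp = c(5000, 900, 2000, 2000, 1000, 1500),
                     satellite_fraction = c(0.1, 0.1, 0.10, 0.1, 0.1, 0.70))
  kept <- filter_segdups(recs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$identity_pct, 95)
  expect_equal(kept$length_bp, 2000)
  expect_error(filter_segdups(recs[, -1]), "identity_pct")
})
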