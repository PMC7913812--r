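test_that("QC filter enforces strict thresholds on QUAL, missingness, depth", {
  calls <- matrix(0L, 100, 4, dimnames = list(sprintf("L%03d", 1:100), NULL))
  calls[1:21, 2] <- NA          # 21% missing
  calls[1:20, 3] <- NA          # 20% missing
  sites <- data.frame(chrom = "chrA", pos = c(10, 20, 30, 40),
                      qual = c(29.9, 50, 50, 30),
                      mean_dp = c(5, 5, 5, 1.49))
  gm <- genotype_matrix(sites, calls, chrom_lengths = c(chrA = 100))
  out <- qc_filter_snps(gm)
  expect_equal(out$sites$pos, 30)          # QUAL 29.9, 21% miss, DP 1.49 fail
  # identity when everything passes
  ok <- gm
  ok$sites$qual <- 40; ok$sites$mean_dp <- 3
  ok$calls[is.na(ok$calls)] <- 0L
  expect_identical(qc_filter_snps(ok)$sites$pos, ok$sites$pos)
  expect_lte(ncol(qc_filter_snps(gm)$calls), ncol(gm$calls))
})

test_that("clean change-point yields two segments with a midpoint breakpoint", {
  v <- c(rep(0L, 50), rep(2L, 50))
  gm <- toy_gm(v, pos = (1:100) * 1e4, L = 101e4)
  segs <- infer_line_segments(gm, window = 1, min_sites = 1)
  s <- segs$segments
  expect_equal(nrow(s), 2L)
  expect_equal(s$origin, c("recurrent", "donor"))
  expect_equal(s$end[1], floor((50e4 + 51e4) / 2))
  expect_equal(s$start[2], s$end[1])
  expect_equal(segs$breakpoints$pos, 505000)
})

test_that("isolated mis-calls are absorbed by the majority window", {
  v <- rep(0L, 50); v[25] <- 2L
  gm <- toy_gm(v)
  s <- infer_line_segments(gm, window = 15, min_sites = 5)$segments
  expect_equal(nrow(s), 1L)
  expect_equal(s$origin, "recurrent")
})

test_that("short-run absorption depends on min_sites", {
  v <- c(rep(0L, 20), rep(2L, 3), rep(0L, 20))
  gm <- toy_gm(v)
  s5 <- infer_line_segments(gm, window = 1, min_sites = 5)$segments
  expect_equal(nrow(s5), 1L)
  s2 <- infer_line_segments(gm, window = 1, min_sites = 2)$segments
  expect_equal(nrow(s2), 3L)
  expect_equal(s2$origin, c("recurrent", "donor", "recurrent"))
})

test_that("an all-missing chromosome is reported as no-call, not an error", {
  calls <- matrix(c(0L, 0L, NA, NA), 1, 4)
  sites <- data.frame(chrom = c("chrA", "chrA", "chrB", "chrB"),
                      pos = c(10, 20, 10, 20), qual = Inf, mean_dp = Inf)
  gm <- genotype_matrix(sites, calls,
                        chrom_lengths = c(chrA = 100, chrB = 100))
  s <- infer_line_segments(gm, window = 1, min_sites = 1)$segments
  expect_equal(s$origin[s$chrom == "chrB"], "no_call")
})

test_that("smoothing and absorption agree with the explicit-rule oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    v <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.1, 0.3))
    window <- sample(c(1, 3, 5, 7), 1)
    min_sites <- sample(1:4, 1)
    gm <- toy_gm(v)
    s <- infer_line_segments(gm, window = window, min_sites = min_sites)
    got <- rep(c(recurrent = 0L, het = 1L,
                 donor = 2L)[s$segments$origin], s$segments$n_sites)
    expect_equal(unname(got), smooth_oracle(v, window, min_sites),
                 info = sprintf("rep %d w=%d m=%d", rep, window, min_sites))
  }
})

test_that("breakpoint-union map merges co-segregating blocks and names markers", {
  # two lines, no breakpoints anywhere -> one marker per chromosome
  gm <- toy_gm(rbind(rep(0L, 10), rep(2L, 10)))
  segs <- infer_line_segments(gm, window = 1, min_sites = 1)
  map <- build_snpldb_map(segs)
  expect_equal(nrow(map$markers), 1L)
  expect_equal(map$markers$id, "chrA_LDB_1")
  expect_equal(unname(map$geno[, 1]), c(0L, 2L))
  # distinct breakpoints at 100 and 200 on a 300-bp chromosome -> 3 markers
  segs2 <- data.frame(
    line = c("a", "a", "b", "b"), chrom = "chrA",
    start = c(1, 100, 1, 200), end = c(100, 300, 200, 300),
    origin = c("recurrent", "donor", "donor", "recurrent"),
    n_sites = 1L)
  map2 <- build_snpldb_map(segs2, chrom_lengths = c(chrA = 300),
                           lines = c("a", "b"))
  expect_equal(nrow(map2$markers), 3L)
  expect_equal(map2$markers$id, paste0("chrA_LDB_", 1:3))
  # blocks share boundary coordinates: [1,100], [100,200], [200,300]; the
  # middle block lies inside line a's donor segment starting at 100
  expect_equal(unname(map2$geno["a", ]), c(0L, 2L, 2L))
  expect_equal(unname(map2$geno["b", ]), c(2L, 2L, 0L))
})

test_that("a double crossover inside one coarse interval breaks the segment", {
  # line with donor-recurrent-donor mosaic: the coarse map sees one donor
  # segment, the fine map three blocks
  v <- c(rep(2L, 10), rep(0L, 10), rep(2L, 10))
  gm <- toy_gm(v)
  fine <- infer_line_segments(gm, window = 1, min_sites = 1)
  map <- build_snpldb_map(fine)
  expect_equal(nrow(map$markers), 3L)
  coarse <- data.frame(line = "L001", chrom = "chrA", start = 1,
                       end = unname(gm$chrom_lengths), origin = "donor",
                       n_sites = 3L)
  cmp <- compare_maps(coarse, fine$segments)
  expect_equal(cmp$broken_sites[cmp$chrom == "totals"], 1L)
})

test_that("marker tiling and per-line composition close to 100 percent", {
  pop <- simulate_soja_population(seed = 13, n_lines = 30)
  map <- build_snpldb_map(pop$truth$segments,
                          chrom_lengths = pop$genotypes$chrom_lengths,
                          lines = rownames(pop$genotypes$calls))
  mlen <- map$markers$end - map$markers$start
  for (ch in names(map$chrom_lengths)) {
    expect_lte(abs(sum(mlen[map$markers$chrom == ch]) -
                     map$chrom_lengths[[ch]]), 1)
  }
  st <- compute_map_stats(map)
  tot <- st$per_line$recovery_pct + st$per_line$donor_pct +
    st$per_line$het_pct + st$per_line$nocall_pct
  expect_true(all(abs(tot - 100) < 1e-6))
})

test_that("segment inference round-trips the truth on noiseless data", {
  pop <- simulate_soja_population(seed = 17, n_lines = 25)
  segs <- infer_line_segments(pop$genotypes, window = 1, min_sites = 1)
  a <- segs$segments[order(segs$segments$line, segs$segments$chrom,
                           segs$segments$start), ]
  b <- pop$truth$segments[order(pop$truth$segments$line,
                                pop$truth$segments$chrom,
                                pop$truth$segments$start), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("map statistics reproduce printed-style interval arithmetic", {
  expect_equal(segment_length(45288662, 45566206), 277544)
  expect_equal(segment_length(52865890, 53515092) / 1e6, 0.65,
               tolerance = 0.002)
  # an all-recurrent line has full recovery and no donor segments
  segs <- data.frame(line = c("a", "b"), chrom = "chrA",
                     start = 1, end = 1000,
                     origin = c("recurrent", "donor"), n_sites = 5L)
  map <- build_snpldb_map(segs, chrom_lengths = c(chrA = 1000),
                          lines = c("a", "b"))
  st <- compute_map_stats(map)
  expect_equal(st$per_line$recovery_pct[st$per_line$line == "a"], 100)
  expect_equal(st$per_line$n_donor_segments[st$per_line$line == "a"], 0)
})

test_that("map comparison counts new and broken segments per the rules", {
  coarse <- data.frame(
    line = c("a", "b"), chrom = "chrA",
    start = c(100, 500), end = c(400, 700),
    origin = "donor", n_sites = 3L)
  # identical maps: nothing new, nothing broken
  cmp0 <- compare_maps(coarse, coarse)
  expect_equal(cmp0$new_segments[cmp0$chrom == "totals"], 0L)
  expect_equal(cmp0$broken_sites[cmp0$chrom == "totals"], 0L)
  # fine map: line a segment split in three, line b gains a new segment
  fine <- data.frame(
    line = c("a", "a", "a", "b", "b"), chrom = "chrA",
    start = c(100, 250, 350, 500, 900), end = c(200, 300, 400, 700, 950),
    origin = "donor", n_sites = 1L)
  cmp <- compare_maps(coarse, fine)
  expect_equal(cmp$broken_sites[cmp$chrom == "totals"], 2L)
  expect_equal(cmp$new_segments[cmp$chrom == "totals"], 1L)
  expect_error(compare_maps(coarse, fine[fine$line == "a", ]), "line sets")
})
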