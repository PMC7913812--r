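toy_models <- function(seed = 1) {
  simulate_gene_models(
    data.frame(chrom = "chrA", start = 1e5, end = 8e5),
    n_genes = 7, seed = seed)
}

test_that("interval membership uses any-overlap with inclusive boundaries", {
  models <- toy_models()
  spans <- t(vapply(models, function(m)
    c(min(m$exons$start), max(m$exons$end)), c(0, 0)))
  # query ending exactly at a gene start includes that gene
  g1 <- models[[3]]
  q_end <- min(g1$exons$start)
  ids <- genes_in_interval(models, "chrA", q_end - 5000, q_end)
  expect_true(g1$id %in% ids)
  # brute-force overlap oracle on a mid-chromosome interval
  qs <- 2.5e5; qe <- 5.5e5
  want <- vapply(models, function(m)
    min(m$exons$start) <= qe && max(m$exons$end) >= qs, logical(1))
  expect_setequal(genes_in_interval(models, "chrA", qs, qe),
                  vapply(models, function(m) m$id, "")[want])
  expect_error(genes_in_interval(models, "chrZ", 1, 10), "unknown chromosome")
})

test_that("expression filter applies the fold and floor rules", {
  tissues <- c("Leaf", "Flower", "14seed", "21seed", "28seed", "35seed",
               "7pod", "21pod")
  # profile shaped like a seed-coat candidate: >2-fold in 7 of 8 tissues
  donor <- c(1.52, 1.68, 1.80, 19.09, 1.60, 0.11, 0.26, 0.03)
  recur <- c(6.78, 5.09, 9.45, 39.32, 6.51, 4.81, 0.35, 0.73)
  expr <- rbind(
    data.frame(gene = "cand", tissue = tissues, parent = "donor",
               fpkm = donor),
    data.frame(gene = "cand", tissue = tissues, parent = "recurrent",
               fpkm = recur),
    data.frame(gene = "low", tissue = tissues, parent = "donor",
               fpkm = 1.9),
    data.frame(gene = "low", tissue = tissues, parent = "recurrent",
               fpkm = 1.9),
    data.frame(gene = "zero", tissue = tissues, parent = "donor",
               fpkm = c(0, rep(3, 7))),
    data.frame(gene = "zero", tissue = tissues, parent = "recurrent",
               fpkm = c(5, rep(3, 7))))
  fl <- expression_filter(expr)
  expect_equal(fl$de_tissues[fl$gene == "cand"], 7L)
  expect_true(fl$retained[fl$gene == "cand"])
  expect_true(fl$removed_low_expression[fl$gene == "low"])
  expect_false(fl$retained[fl$gene == "low"])
  # zero FPKM handled by the epsilon floor: 5/max(0, eps) is a DE tissue
  expect_equal(fl$de_tissues[fl$gene == "zero"], 1L)
})

test_that("filters are monotone in their thresholds", {
  set.seed(9)
  tissues <- c("Leaf", "Flower", "14seed", "21seed")
  expr <- do.call(rbind, lapply(sprintf("g%02d", 1:20), function(g)
    data.frame(gene = g, tissue = rep(tissues, 2),
               parent = rep(c("donor", "recurrent"), each = 4),
               fpkm = round(rlnorm(8, 1, 1.2), 2))))
  base <- expression_filter(expr, min_fpkm = 2, fold = 2)
  for (args in list(list(min_fpkm = 4, fold = 2),
                    list(min_fpkm = 2, fold = 3),
                    list(min_fpkm = 5, fold = 4))) {
    strict <- expression_filter(expr, min_fpkm = args$min_fpkm,
                                fold = args$fold)
    expect_true(all(strict$gene[strict$retained] %in%
                      base$gene[base$retained]))
  }
})

test_that("classifier handles canonical coding and splice cases", {
  # plus-strand single-exon gene, CDS ATG CGA ... TAA: CGA -> TGA stop gain
  cds <- paste0("ATG", "CGA", "GGT", "TCT", "TAA")
  seq <- paste0(strrep("T", 30), cds, strrep("C", 30))
  m <- gene_model("g+", "chr1", "+",
                  exons = data.frame(start = 31, end = 30 + nchar(cds)),
                  cds = data.frame(start = 31, end = 30 + nchar(cds)),
                  seq = seq, seq_start = 1, promoter_bp = 20)
  hit <- classify_variant_effect(
    m, list(chrom = "chr1", pos = 34, ref = "C", alt = "T"))
  expect_equal(hit$class, "stop_gain")
  expect_equal(classify_variant_effect(
    m, list(chrom = "chr1", pos = 35, ref = "G", alt = "A"))$class,
    "missense")
  # synonymous wobble at GGT -> GGC
  expect_equal(classify_variant_effect(
    m, list(chrom = "chr1", pos = 39, ref = "T", alt = "C"))$class,
    "synonymous")
  # stop loss at the natural stop codon
  expect_equal(classify_variant_effect(
    m, list(chrom = "chr1", pos = 44, ref = "A", alt = "C"))$class,
    "stop_loss")
  # promoter and intergenic positions
  expect_equal(classify_variant_effect(
    m, list(chrom = "chr1", pos = 15, ref = "T", alt = "G"))$class,
    "promoter")
  expect_equal(classify_variant_effect(
    m, list(chrom = "chr1", pos = 2, ref = "T", alt = "G"))$class,
    "intergenic")
  # reference mismatch is a hard error
  expect_error(classify_variant_effect(
    m, list(chrom = "chr1", pos = 34, ref = "G", alt = "T")),
    "mismatch")
})

test_that("splice-site positions outrank intron assignment", {
  models <- toy_models(seed = 11)
  two_exon <- Filter(function(m) nrow(m$exons) >= 2, models)[[1]]
  v <- plant_variant(two_exon, "splice_acceptor")
  expect_equal(classify_variant_effect(two_exon, v)$class, "splice_acceptor")
  vd <- plant_variant(two_exon, "splice_donor")
  expect_equal(classify_variant_effect(two_exon, vd)$class, "splice_donor")
  vi <- plant_variant(two_exon, "intron")
  expect_equal(classify_variant_effect(two_exon, vi)$class, "intron")
})

test_that("coding classification agrees with the translate-both-alleles oracle", {
  set.seed(12)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (i in 1:300) {
    m <- csslqtl:::.random_gene(sprintf("g%03d", i), "chr1",
                                gene_start = 3000, promoter_bp = 500)
    cds_pos <- csslqtl:::.cds_positions(m)
    pos <- sample(cds_pos, 1)
    ref <- substring(m$seq, pos - m$seq_start + 1, pos - m$seq_start + 1)
    alt <- sample(setdiff(bases, ref), 1)
    v <- list(chrom = "chr1", pos = pos, ref = ref, alt = alt)
    got <- classify_variant_effect(m, v)$class
    want <- translate_oracle(m, v)
    expect_identical(got, want,
                     info = sprintf("gene %d strand %s pos %d %s>%s",
                                    i, m$strand, pos, ref, alt))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
})

test_that("reverse-complementing a gene and its variants preserves classes", {
  set.seed(13)
  L <- 20000
  for (i in 1:25) {
    m <- csslqtl:::.random_gene(sprintf("g%03d", i), "chr1",
                                gene_start = 4000, promoter_bp = 1000)
    mm <- mirror_model(m, L)
    for (cls in c("missense", "synonymous", "intron", "promoter",
                  "splice_acceptor")) {
      v <- plant_variant(m, cls)[1, ]
      expect_identical(
        classify_variant_effect(mm, mirror_variant(v, L))$class,
        classify_variant_effect(m, v)$class,
        info = paste(i, m$strand, cls))
    }
  }
})

test_that("every planted effect class is recovered exactly (round trip)", {
  models <- toy_models(seed = 14)
  ids <- vapply(models, function(m) m$id, "")
  causal <- data.frame(gene = ids[c(1, 3, 5)],
                       class = c("stop_gain", "splice_acceptor", "promoter"))
  ev <- simulate_expression_and_variants(models, causal, seed = 15)
  for (i in seq_len(nrow(ev$variants))) {
    v <- ev$variants[i, ]
    m <- models[[which(ids == v$gene)]]
    expect_identical(classify_variant_effect(m, v)$class, v$class)
  }
  expect_error(simulate_expression_and_variants(
    models, data.frame(gene = "nope", class = "missense")), "absent")
})

test_that("candidate ranking puts the planted causal gene first", {
  models <- toy_models(seed = 16)
  ids <- vapply(models, function(m) m$id, "")
  causal <- data.frame(gene = ids[4], class = "missense")
  ev <- simulate_expression_and_variants(models, causal, seed = 17)
  fl <- expression_filter(ev$expression)
  effects <- do.call(rbind, lapply(seq_len(nrow(ev$variants)), function(i) {
    v <- ev$variants[i, ]
    classify_variant_effect(models[[which(ids == v$gene)]], v)
  }))
  rk <- rank_candidates(ids, fl, effects)
  expect_equal(rk$gene[rk$rank == 1 & !is.na(rk$rank)], ids[4])
})

test_that("ranking ties break on expression, and promoter sets count as impact", {
  fl <- data.frame(gene = c("a", "b", "c"),
                   max_fpkm = c(10, 50, 8), de_tissues = c(4L, 4L, 2L),
                   removed_low_expression = FALSE, retained = TRUE)
  eff <- data.frame(gene = c("a", "b", rep("c", 11)),
                    class = c("stop_gain", "missense", rep("promoter", 11)))
  rk <- rank_candidates(c("a", "b", "c"), fl, eff)
  # stop_gain and missense sit in the same impact tier: FPKM decides
  expect_equal(rk$gene[1:2], c("b", "a"))
  # 11 promoter SNPs and no coding change still counts as impactful
  expect_true(rk$impactful[rk$gene == "c"])
})
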