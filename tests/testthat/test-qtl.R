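test_that("line means average environment means, not raw observations", {
  ph <- data.frame(line = "a", env = c("e1", "e2", "e3"), rep = 1,
                   value = c(52, 53, 54))
  expect_equal(unname(env_means(ph)), 53)
  # unbalanced replication: env means first, then average across envs
  ph2 <- data.frame(line = "a",
                    env = c("e1", "e1", "e1", "e2"),
                    rep = c(1, 2, 3, 1),
                    value = c(10, 11, 12, 20))
  expect_equal(unname(env_means(ph2)), (11 + 20) / 2)
  # single environment is the identity on env means
  ph3 <- data.frame(line = c("a", "a"), env = "e1", rep = 1:2,
                    value = c(4, 6))
  expect_equal(unname(env_means(ph3)), 5)
})

test_that("heritability estimator matches aov mean squares on a balanced toy", {
  set.seed(1)
  d <- expand.grid(line = sprintf("g%02d", 1:12), env = c("e1", "e2", "e3"),
                   rep = 1:3)
  gv <- rnorm(12, 0, 2)
  d$value <- gv[as.integer(factor(d$line))] +
    rnorm(3, 0, 1)[as.integer(factor(d$env))] + rnorm(nrow(d), 0, 0.7)
  h <- heritability(d)
  ms <- summary(aov(value ~ line + env + line:env, data = d))[[1]][
    , "Mean Sq"]
  r <- 3; e <- 3
  s2e <- ms[4]; s2ge <- (ms[3] - ms[4]) / r; s2g <- (ms[1] - ms[3]) / (e * r)
  expect_equal(h$sigma2_e, s2e, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(h$sigma2_GE, max(s2ge, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(h$sigma2_G, max(s2g, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("heritability hits its degenerate limits", {
  d <- expand.grid(line = c("a", "b", "c"), env = c("e1", "e2"), rep = 1:2)
  # pure genetic signal, no noise, no interaction -> h2 = 1
  d$value <- c(a = 1, b = 5, c = 9)[as.character(d$line)]
  expect_equal(heritability(d)$h2, 1)
  # all lines share identical env/rep profiles -> sigma2_G = 0, h2 = 0
  d$value <- as.integer(factor(d$env)) + 0.1 * d$rep
  h <- heritability(d)
  expect_equal(h$sigma2_G, 0)
  expect_equal(h$h2, 0)
})

test_that("stepwise selection finds planted markers and respects thresholds", {
  set.seed(3)
  n <- 60
  X <- matrix(sample(c(-1, 1), n * 10, replace = TRUE, prob = c(0.8, 0.2)),
              n, 10, dimnames = list(NULL, paste0("m", 1:10)))
  # a planted single QTL with no noise is selected exactly
  y1 <- 2 * X[, 4]
  expect_identical(rstep_cofactors(y1, X), "m4")
  # two independent planted QTLs are both selected
  y2 <- 3 * X[, 2] - 2 * X[, 7] + rnorm(n, 0, 0.3)
  sel <- rstep_cofactors(y2, X)
  expect_setequal(sel, c("m2", "m7"))
  # collinear duplicate collapses to the leftmost representative
  X2 <- cbind(X, m4b = X[, 4])
  expect_identical(rstep_cofactors(y1, X2), "m4")
})

test_that("pure-noise phenotypes rarely select any cofactor", {
  set.seed(4)
  n <- 60
  X <- matrix(sample(c(-1, 1), n * 20, replace = TRUE, prob = c(0.85, 0.15)),
              n, 20, dimnames = list(NULL, paste0("m", 1:20)))
  empty <- vapply(1:30, function(i)
    length(rstep_cofactors(rnorm(n), X)) == 0L, logical(1))
  # with p_in = 0.001 over ~20 effective markers, expect ~(1-0.001)^20
  expect_gte(mean(empty), 0.9)
})

test_that("scan statistics match the exhaustive least-squares oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(15:30, 1)
    m <- sample(4:10, 1)
    X <- matrix(sample(c(-1, 0, 1), n * m, replace = TRUE,
                       prob = c(0.7, 0.05, 0.25)), n, m,
                dimnames = list(sprintf("L%03d", 1:n), paste0("m", 1:m)))
    y <- setNames(3 * X[, 1] + rnorm(n), rownames(X))
    cof <- colnames(X)[1]
    scan <- lrt_scan(y, X, cofactors = cof)
    for (j in seq_len(m)) {
      if (var(X[, j]) == 0) next
      B <- if (identical(X[, cof], X[, j])) NULL else X[, cof]
      if (qr(cbind(1, B, X[, j]))$rank < ncol(cbind(1, B, X[, j]))) next
      orc <- ls_oracle(y, cbind(rep(1, n), B), X[, j])
      expect_equal(scan$lod[j], orc$lod, tolerance = 1e-9)
      expect_equal(scan$add[j], orc$add, tolerance = 1e-9)
      expect_equal(scan$pve[j], orc$pve, tolerance = 1e-9)
    }
  }
})

test_that("a perfect fit caps LOD and reports full PVE", {
  n <- 24
  set.seed(6)
  x <- sample(c(-1, 1), n, replace = TRUE)
  X <- cbind(m1 = x)
  rownames(X) <- sprintf("L%03d", 1:n)
  y <- setNames(2 * x, rownames(X))
  scan <- lrt_scan(y, X)
  expect_equal(scan$lod[1], 1e6)
  expect_equal(scan$add[1], 2)
  expect_equal(scan$pve[1], 100)
  # zero-variance phenotype: all LOD zero
  scan0 <- lrt_scan(setNames(rep(1, n), rownames(X)), X)
  expect_true(all(scan0$lod == 0))
})

test_that("a marker is not masked by a collinear cofactor", {
  set.seed(7)
  n <- 40
  x <- sample(c(-1, 1), n, replace = TRUE)
  X <- cbind(m1 = x, m2 = x, m3 = sample(c(-1, 1), n, replace = TRUE))
  rownames(X) <- sprintf("L%03d", 1:n)
  y <- setNames(1.5 * x + rnorm(n, 0, 0.4), rownames(X))
  scan <- lrt_scan(y, X, cofactors = "m1")
  # m2 is identical to cofactor m1: the cofactor is dropped from its
  # background, so m2 shows the full signal rather than zero
  expect_gt(scan$lod[2], 5)
  expect_equal(scan$lod[2], scan$lod[1])
})

test_that("per-line tests against the recurrent parent match the t formulas", {
  ph <- expand.grid(line = c("RP", "same", "late"), env = c("e1", "e2"),
                    rep = 1:3)
  base <- c(RP = 50, same = 50, late = 58)[as.character(ph$line)]
  set.seed(8)
  ph$value <- base + rep(rnorm(6, 0, 0.4), each = 3)[
    as.integer(interaction(ph$line, ph$env))]
  res <- lines_vs_recurrent(ph, "RP")
  expect_false(res$significant[res$line == "same"])
  expect_true(res$significant[res$line == "late"])
  expect_equal(res$direction[res$line == "late"], "later")
  # closed-form pooled t for one line
  v1 <- ph$value[ph$line == "late"]; v0 <- ph$value[ph$line == "RP"]
  n1 <- length(v1); n0 <- length(v0)
  sp2 <- ((n1 - 1) * var(v1) + (n0 - 1) * var(v0)) / (n1 + n0 - 2)
  tstat <- (mean(v1) - mean(v0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  p <- 2 * pt(-abs(tstat), n1 + n0 - 2)
  expect_equal(res$p[res$line == "late"], p, tolerance = 1e-12)
})

test_that("significant lines are attributed to sign-matching QTL only", {
  geno <- rbind(L1 = c(2L, 0L), L2 = c(0L, 2L), L3 = c(2L, 0L))
  colnames(geno) <- c("q_pos", "q_neg")
  map <- structure(list(
    markers = data.frame(id = colnames(geno), chrom = "chrA",
                         start = c(1, 200), end = c(200, 400)),
    geno = geno, chrom_lengths = c(chrA = 400)), class = "physical_map")
  qtl <- data.frame(marker = c("q_pos", "q_neg"), chrom = "chrA",
                    start = c(1, 200), end = c(200, 400),
                    lod = c(10, 10), add = c(3, -2), add_se = 0.1,
                    pve = c(40, 20), declared = TRUE, peak = TRUE)
  flags <- data.frame(line = c("L1", "L2", "L3"),
                      mean = c(58, 47, 46), diff = c(8, -3, -4),
                      t = 0, p = 0.001, significant = TRUE,
                      direction = c("later", "earlier", "earlier"))
  out <- explain_significant_lines(qtl, map, flags)
  expect_setequal(out$explained, c("L1", "L2"))
  # L3 deviates early but carries only the positive-effect QTL
  expect_equal(out$unexplained, "L3")
  expect_equal(unname(out$per_qtl["q_pos"]), 1L)
})
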