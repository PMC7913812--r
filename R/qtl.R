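#' Per-line trait means across environments
#'
#' Environment means (over replicates) are computed first and then averaged
#' per line, so unbalanced replication does not weight environments
#' unequally. Missing cells are skipped.
#'
#' @param pheno data.frame with columns `line`, `env`, `rep`, `value`.
#' @return named numeric vector of line means.
#' @export
env_means <- function(pheno) {
  stopifnot(all(c("line", "env", "value") %in% names(pheno)))
  if (!nrow(pheno)) stop("empty phenotype table")
  cell <- tapply(pheno$value, list(pheno$line, pheno$env), mean,
                 na.rm = TRUE)
  out <- rowMeans(cell, na.rm = TRUE)
  if (anyNA(out)) stop("line(s) with no data: ",
                       paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Broad-sense heritability from a multi-environment trial
#'
#' Two-way ANOVA (line, environment, line x environment, residual) by the
#' expected-mean-squares method on an (approximately) balanced design:
#' sigma2_e = MS_err; sigma2_GE = (MS_GE - MS_err) / r;
#' sigma2_G = (MS_G - MS_GE) / (e * r); and
#' h2 = sigma2_G / (sigma2_G + sigma2_GE / e + sigma2_e / (e * r)),
#' the entry-mean (line-mean) basis. Negative component estimates are
#' truncated to zero. With a single environment the G x E component cannot
#' be separated and h2 is returned on the entry-mean basis without it
#' (flagged in the result).
#'
#' @param pheno data.frame with columns `line`, `env`, `rep`, `value`.
#' @return object of class `variance_components`: list with `sigma2_G`,
#'   `sigma2_GE`, `sigma2_e`, `h2`, `n_env`, `n_rep` and `single_env` flag.
#' @export
heritability <- function(pheno) {
  stopifnot(all(c("line", "env", "value") %in% names(pheno)))
  line <- as.character(pheno$line)
  env <- as.character(pheno$env)
  y <- pheno$value
  lines <- unique(line); envs <- unique(env)
  n <- length(lines); e <- length(envs)
  r <- nrow(pheno) / (n * e)
  if (r < 2 && e < 2)
    stop("need >= 2 environments or >= 2 replicates")
  cell <- tapply(y, list(factor(line, lines), factor(env, envs)), mean)
  gm <- mean(y)
  lm_ <- rowMeans(cell); em_ <- colMeans(cell)
  ss_g <- e * r * sum((lm_ - gm)^2)
  ss_e <- n * r * sum((em_ - gm)^2)
  ss_ge <- r * sum((sweep(sweep(cell, 1, lm_), 2, em_) + gm)^2)
  fit_cell <- cell[cbind(match(line, lines), match(env, envs))]
  ss_err <- sum((y - fit_cell)^2)
  df_err <- n * e * (r - 1)
  ms_g <- ss_g / (n - 1)
  if (e >= 2) {
    ms_ge <- ss_ge / ((n - 1) * (e - 1))
    ms_err <- if (df_err > 0) ss_err / df_err else 0
    s2_e <- max(ms_err, 0)
    s2_ge <- max((ms_ge - ms_err) / r, 0)
    s2_g <- max((ms_g - ms_ge) / (e * r), 0)
    h2 <- if (s2_g + s2_ge / e + s2_e / (e * r) > 0)
      s2_g / (s2_g + s2_ge / e + s2_e / (e * r)) else 0
    single <- FALSE
  } else {
    ms_err <- ss_err / df_err
    s2_e <- max(ms_err, 0)
    s2_ge <- NA_real_
    s2_g <- max((ms_g - ms_err) / r, 0)
    h2 <- if (s2_g + s2_e / r > 0) s2_g / (s2_g + s2_e / r) else 0
    single <- TRUE
    message("single environment: G x E component omitted from h2")
  }
  structure(list(sigma2_G = s2_g, sigma2_GE = s2_ge, sigma2_e = s2_e,
                 h2 = h2, n_env = e, n_rep = r, single_env = single),
            class = "variance_components")
}

# Marker matrix (x in {-1, 0, +1}) from a physical map; NA imputed to the
# recurrent code (the overwhelming background state in a CSSL panel).
#' Convert a physical map to a -1/0/+1 marker design matrix
#'
#' @param map a [build_snpldb_map()] result.
#' @param lines optional subset/order of lines.
#' @return numeric matrix lines x markers with donor-homozygous = +1,
#'   heterozygous = 0, recurrent-homozygous = -1; missing codes are imputed
#'   to -1 with a message.
#' @export
marker_matrix <- function(map, lines = NULL) {
  stopifnot(inherits(map, "physical_map"))
  g <- map$geno
  if (!is.null(lines)) g <- g[lines, , drop = FALSE]
  if (anyNA(g)) {
    message(sum(is.na(g)), " missing marker codes imputed to recurrent")
    g[is.na(g)] <- 0L
  }
  g - 1
}

#' Stepwise cofactor selection for the additive QTL scan
#'
#' Forward-backward stepwise least-squares selection on marker codes:
#' the marker with the smallest partial-F p-value < `p_in` is added, then
#' any included marker with partial-F p-value > `p_out` is dropped;
#' iterated to a fixed point or `max_cof` markers. Perfectly collinear
#' markers (identical code columns) are collapsed to their leftmost
#' representative before selection. The strict default entry threshold
#' (0.001, exit 2x that) follows the stepwise convention of QTL-mapping
#' software for line populations; at near-perfect heritability a liberal
#' threshold admits dozens of spurious cofactors whose carrier overlap
#' with small-effect QTL biases their effect estimates.
#'
#' @param y named numeric vector of line means.
#' @param X lines x markers matrix coded -1/0/+1 (see [marker_matrix()]).
#' @param p_in,p_out entry and exit p-value thresholds.
#' @param max_cof cap on the number of cofactors (default `n/5`, always
#'   capped at `n - 3`).
#' @return character vector of selected marker names.
#' @export
rstep_cofactors <- function(y, X, p_in = 0.001, p_out = 0.002,
                            max_cof = NULL) {
  n <- length(y)
  if (is.null(max_cof)) max_cof <- floor(n / 5)
  max_cof <- min(max_cof, n - 3L)
  if (max_cof < 1L) stop("too few lines for cofactor selection")
  key <- apply(X, 2, paste, collapse = "\r")
  keep <- !duplicated(key) & apply(X, 2, function(v) stats::var(v) > 0)
  Xu <- X[, keep, drop = FALSE]
  sel <- character(0)
  repeat {
    changed <- FALSE
    # forward
    Q <- qr.Q(qr(cbind(1, Xu[, sel, drop = FALSE])))
    ry <- y - Q %*% crossprod(Q, y)
    cand <- setdiff(colnames(Xu), sel)
    if (length(cand) && length(sel) < max_cof) {
      Xc <- Xu[, cand, drop = FALSE]
      Xp <- Xc - Q %*% crossprod(Q, Xc)
      ssx <- colSums(Xp^2)
      red <- drop(crossprod(Xp, ry))^2 / pmax(ssx, 1e-300)
      red[ssx < 1e-10] <- 0
      rss_cur <- sum(ry^2)
      df2 <- n - length(sel) - 2L
      Fst <- red / pmax((rss_cur - red) / df2, 1e-300)
      p <- stats::pf(Fst, 1, df2, lower.tail = FALSE)
      j <- which.min(p)
      if (p[j] < p_in) {
        sel <- c(sel, cand[j])
        changed <- TRUE
      }
    }
    # backward
    if (length(sel) > 1L) {
      Xf <- cbind(1, Xu[, sel, drop = FALSE])
      rss_full <- sum(stats::lm.fit(Xf, y)$residuals^2)
      df2 <- n - ncol(Xf)
      pdrop <- vapply(seq_along(sel), function(k) {
        rss0 <- sum(stats::lm.fit(Xf[, -(k + 1L), drop = FALSE],
                                  y)$residuals^2)
        Fst <- (rss0 - rss_full) / (rss_full / df2)
        stats::pf(Fst, 1, df2, lower.tail = FALSE)
      }, 0)
      worst <- which.max(pdrop)
      if (pdrop[worst] > p_out) {
        sel <- sel[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sel
}

#' Additive QTL scan by per-marker likelihood-ratio tests
#'
#' For each marker m, the background B is the cofactor set minus any
#' cofactor collinear with m; the full model `y ~ B + m` is compared with
#' the reduced `y ~ B` by least squares: LRT = n * ln(RSS0 / RSS1),
#' LOD = LRT / (2 * ln 10), ADD is the coefficient of m's -1/0/+1 code
#' (the donor-allele additive effect, half the carrier vs non-carrier mean
#' difference), and PVE = 100 * (RSS0 - RSS1) / TSS against the
#' cofactor-free total sum of squares. Markers reaching `lod_threshold`
#' are declared QTL; adjacent declared markers separated by no
#' recombination (identical code columns) are merged to the peak-LOD
#' representative.
#'
#' @param y named numeric vector of line means.
#' @param map a [build_snpldb_map()] result (marker metadata is taken from
#'   it), or a plain -1/0/+1 matrix.
#' @param cofactors character vector of cofactor marker names (subset of
#'   the markers), e.g. from [rstep_cofactors()].
#' @param lod_threshold declaration threshold (default 2.5).
#' @param lod_cap LOD value reported for numerically perfect fits.
#' @return object of class `qtl_result`: data.frame with marker, chrom,
#'   start, end, lod, add, add_se, pve, declared, peak (declared and
#'   surviving the no-recombination merge).
#' @export
lrt_scan <- function(y, map, cofactors = character(0), lod_threshold = 2.5,
                     lod_cap = 1e6) {
  if (inherits(map, "physical_map")) {
    X <- marker_matrix(map, lines = names(y))
    meta <- map$markers
  } else {
    X <- map[names(y), , drop = FALSE]
    meta <- data.frame(id = colnames(X), chrom = NA_character_,
                       start = NA_real_, end = NA_real_,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(cofactors %in% colnames(X)))
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  key <- apply(X, 2, paste, collapse = "\r")
  res <- data.frame(marker = colnames(X), chrom = meta$chrom,
                    start = meta$start, end = meta$end,
                    lod = 0, add = NA_real_, add_se = NA_real_, pve = 0,
                    stringsAsFactors = FALSE)
  if (tss < 1e-12) {           # zero-variance phenotype
    res$declared <- FALSE
    res$peak <- FALSE
    class(res) <- c("qtl_result", class(res))
    return(res)
  }
  for (j in seq_len(ncol(X))) {
    xm <- X[, j]
    if (stats::var(xm) == 0) next
    B <- cofactors[key[cofactors] != key[j]]
    X0 <- cbind(`(Intercept)` = 1, X[, B, drop = FALSE])
    X1 <- cbind(X0, m = xm)
    f0 <- stats::lm.fit(X0, y)
    f1 <- stats::lm.fit(X1, y)
    rss0 <- sum(f0$residuals^2)
    rss1 <- sum(f1$residuals^2)
    if (rss1 < 1e-12 * tss) {
      lod <- lod_cap
    } else {
      lod <- n * log(rss0 / rss1) / (2 * log(10))
    }
    dfres <- n - f1$rank
    sigma2 <- if (dfres > 0) rss1 / dfres else 0
    R <- qr.R(f1$qr)
    xtx_inv <- tryCatch(chol2inv(R), error = function(e) NULL)
    se <- if (!is.null(xtx_inv)) sqrt(sigma2 * xtx_inv[f1$rank, f1$rank])
      else NA_real_
    res$lod[j] <- max(lod, 0)
    res$add[j] <- unname(f1$coefficients["m"])
    res$add_se[j] <- se
    res$pve[j] <- 100 * (rss0 - rss1) / tss
  }
  res$declared <- res$lod >= lod_threshold
  # merge runs of adjacent declared markers with identical codes
  res$peak <- res$declared
  i <- 1L
  while (i <= nrow(res)) {
    if (res$declared[i]) {
      j <- i
      while (j < nrow(res) && res$declared[j + 1L] &&
             identical(res$chrom[j + 1L], res$chrom[i]) &&
             key[j + 1L] == key[i]) j <- j + 1L
      if (j > i) {
        block <- i:j
        res$peak[block] <- FALSE
        res$peak[block[which.max(res$lod[block])]] <- TRUE
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  class(res) <- c("qtl_result", class(res))
  res
}

#' Test each line against the recurrent parent
#'
#' Per line, a two-sided pooled-variance Student's t-test of its
#' environment x replicate observations against the recurrent parent's.
#'
#' @param pheno data.frame with columns `line`, `env`, `rep`, `value`.
#' @param recurrent_id line identifier of the recurrent parent.
#' @param alpha significance level.
#' @param var_equal pooled variance (classical Student's t) by default;
#'   set FALSE for Welch.
#' @return data.frame (line, mean, diff, t, p, significant, direction)
#'   where direction is `"later"`/`"earlier"` relative to the recurrent
#'   parent.
#' @export
lines_vs_recurrent <- function(pheno, recurrent_id, alpha = 0.05,
                               var_equal = TRUE) {
  if (!recurrent_id %in% pheno$line)
    stop("recurrent parent not present in phenotype table")
  rp <- pheno$value[pheno$line == recurrent_id]
  lines <- setdiff(unique(pheno$line), recurrent_id)
  rows <- lapply(lines, function(ln) {
    v <- pheno$value[pheno$line == ln]
    if (length(v) < 2L)
      stop("line ", ln, " has fewer than 2 observations")
    tt <- stats::t.test(v, rp, var.equal = var_equal)
    data.frame(line = ln, mean = mean(v), diff = mean(v) - mean(rp),
               t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < alpha,
               direction = if (mean(v) >= mean(rp)) "later" else "earlier",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attribute significant lines to declared QTL
#'
#' A significantly deviating line is "explained" if it carries the donor
#' code at at least one declared QTL whose additive-effect sign matches the
#' line's direction of deviation (positive ADD for later, negative for
#' earlier).
#'
#' @param qtl a [lrt_scan()] result.
#' @param map the [build_snpldb_map()] the scan was run on.
#' @param line_flags a [lines_vs_recurrent()] result.
#' @return list with `per_qtl` (marker, n_explained), `explained` and
#'   `unexplained` line ids.
#' @export
explain_significant_lines <- function(qtl, map, line_flags) {
  dec <- qtl[qtl$declared & qtl$peak, , drop = FALSE]
  sig <- line_flags[line_flags$significant, , drop = FALSE]
  expl <- character(0)
  per_qtl <- stats::setNames(integer(nrow(dec)), dec$marker)
  for (i in seq_len(nrow(sig))) {
    ln <- sig$line[i]
    want_pos <- sig$direction[i] == "later"
    hit <- FALSE
    for (k in seq_len(nrow(dec))) {
      m <- dec$marker[k]
      carries <- !is.na(map$geno[ln, m]) && map$geno[ln, m] == 2L
      if (carries && ((dec$add[k] > 0) == want_pos)) {
        per_qtl[m] <- per_qtl[m] + 1L
        hit <- TRUE
      }
    }
    if (hit) expl <- c(expl, ln)
  }
  list(per_qtl = per_qtl, explained = expl,
       unexplained = setdiff(sig$line, expl))
}
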