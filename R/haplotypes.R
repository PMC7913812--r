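#' Assign wild/cultivated haplotype labels at candidate genes
#'
#' A unit (CSSL or germplasm accession) is labelled `wild` at a gene when
#' all of the gene's diagnostic SNPs carry the donor-homozygous code,
#' `cultivated` when all carry the recurrent-homozygous code, `missing`
#' when any diagnostic call is missing, and `other` otherwise (the
#' genotype matches neither parental haplotype). Units labelled `other` or
#' `missing` are excluded from downstream contrasts.
#'
#' @param gm a [genotype_matrix()] covering the diagnostic SNPs.
#' @param diagnostic data.frame with columns `gene`, `chrom`, `pos`; each
#'   gene needs at least one diagnostic SNP present in `gm`.
#' @return character matrix units x genes of labels, class
#'   `haplotype_table`.
#' @export
assign_haplotypes <- function(gm, diagnostic) {
  stopifnot(inherits(gm, "genotype_matrix"),
            all(c("gene", "chrom", "pos") %in% names(diagnostic)))
  genes <- unique(diagnostic$gene)
  lines <- rownames(gm$calls)
  out <- matrix(NA_character_, length(lines), length(genes),
                dimnames = list(lines, genes))
  site_key <- paste(gm$sites$chrom, gm$sites$pos)
  for (g in genes) {
    d <- diagnostic[diagnostic$gene == g, , drop = FALSE]
    j <- match(paste(d$chrom, d$pos), site_key)
    if (anyNA(j))
      stop("diagnostic SNP(s) for ", g, " absent from the genotype matrix")
    sub <- gm$calls[, j, drop = FALSE]
    lab <- apply(sub, 1, function(v) {
      if (anyNA(v)) "missing"
      else if (all(v == 2L)) "wild"
      else if (all(v == 0L)) "cultivated"
      else "other"
    })
    out[, g] <- lab
  }
  class(out) <- c("haplotype_table", class(out))
  out
}

.stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Background-matched haplotype-effect contrast at one gene
#'
#' Group A holds units wild at the focal gene and cultivated at every
#' background gene; group B holds units cultivated at the focal and every
#' background gene (the shared all-cultivated background, identical for
#' every focal gene of a trait). Units labelled `other` or `missing` at any
#' involved gene are excluded. The difference mean(A) - mean(B) is tested
#' by a two-sided pooled-variance Student's t-test on the units' phenotype
#' values; groups of size < 2 are reported without a p-value.
#'
#' @param haplos a [assign_haplotypes()] result.
#' @param pheno named numeric vector of per-unit phenotype values (e.g.
#'   line means from [env_means()]).
#' @param focal_gene focal gene id.
#' @param background_genes character vector of the other trait genes
#'   (must not include the focal gene).
#' @return object of class `contrast_result`: list with group summaries
#'   (`n`, `range`, `mean`), `difference`, `t`, `p`, `stars`, and the unit
#'   ids of both groups.
#' @export
background_matched_contrast <- function(haplos, pheno, focal_gene,
                                        background_genes) {
  if (focal_gene %in% background_genes)
    stop("focal gene must not be in the background set")
  genes <- c(focal_gene, background_genes)
  stopifnot(all(genes %in% colnames(haplos)))
  units <- intersect(rownames(haplos), names(pheno))
  h <- haplos[units, genes, drop = FALSE]
  bg_ok <- if (length(background_genes))
    apply(h[, background_genes, drop = FALSE] == "cultivated", 1, all)
  else rep(TRUE, nrow(h))
  a_units <- units[h[, focal_gene] == "wild" & bg_ok]
  b_units <- units[h[, focal_gene] == "cultivated" & bg_ok]
  ya <- pheno[a_units]; yb <- pheno[b_units]
  summ <- function(y) list(n = length(y),
                           range = if (length(y)) range(y) else c(NA, NA),
                           mean = if (length(y)) mean(y) else NA_real_)
  tt <- if (length(ya) >= 2L && length(yb) >= 2L &&
            (stats::var(ya) + stats::var(yb)) > 0)
    stats::t.test(ya, yb, var.equal = TRUE)
  else NULL
  diff <- mean(ya) - mean(yb)
  p <- if (!is.null(tt)) tt$p.value
    else if (length(ya) >= 2L && length(yb) >= 2L &&
             stats::var(c(unname(ya), unname(yb))) == 0) 1
    else NA_real_
  structure(list(focal_gene = focal_gene,
                 focal = summ(ya), background = summ(yb),
                 difference = diff,
                 t = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
                 p = p, stars = .stars(p),
                 focal_units = a_units, background_units = b_units),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "%s: wild n=%d mean=%.1f vs cultivated n=%d mean=%.1f, diff=%+.1f d (p=%s %s)\n",
    x$focal_gene, x$focal$n, x$focal$mean, x$background$n,
    x$background$mean, x$difference,
    ifelse(is.na(x$p), "NA", format.pval(x$p, digits = 3)), x$stars))
  invisible(x)
}

#' Haplotype-phenotype coincidence for a categorical trait
#'
#' Percentage of units whose seed-coat category matches the category
#' predicted by their haplotype at the gene (wild -> the gene's colour,
#' cultivated -> the reference colour), computed with the phenotype-
#' genotype consistency formula over units carrying either parental
#' haplotype.
#'
#' @param haplos a [assign_haplotypes()] result.
#' @param scc data.frame with columns `line` and `scc` (categories).
#' @param gene focal gene id.
#' @param wild_category category expected for wild-haplotype carriers.
#' @param ref_category category expected for cultivated-haplotype carriers.
#' @return consistency in percent (see [cpg()]).
#' @export
scc_coincidence <- function(haplos, scc, gene, wild_category,
                            ref_category = "yellow") {
  units <- intersect(rownames(haplos), scc$line)
  lab <- haplos[units, gene]
  keep <- lab %in% c("wild", "cultivated")
  lab <- lab[keep]; units <- units[keep]
  pred <- ifelse(lab == "wild", wild_category, ref_category)
  obs <- scc$scc[match(units, scc$line)]
  cpg(sum(pred == obs), length(units))
}
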