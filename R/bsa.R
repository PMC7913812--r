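#' Phenotype-genotype consistency percentage
#'
#' C = n_pg / n_g * 100, where n_g is the number of lines carrying the
#' detected wild (donor) segment and n_pg the carriers whose phenotype
#' co-segregates with the genotype. The exact value is returned; reports
#' round to whole percent.
#'
#' @param n_pg concordant carriers (0 <= n_pg <= n_g).
#' @param n_g carriers (>= 1).
#' @return consistency in percent.
#' @export
cpg <- function(n_pg, n_g) {
  if (any(n_g < 1)) stop("consistency undefined for zero carriers")
  if (any(n_pg < 0 | n_pg > n_g)) stop("need 0 <= n_pg <= n_g")
  n_pg / n_g * 100
}

#' Partition lines by a categorical phenotype
#'
#' @param scc data.frame with columns `line` and a category column (named
#'   by `trait`, default `scc`). Lines with a missing category are excluded
#'   with a warning.
#' @param trait name of the category column.
#' @return object of class `pheno_groups`: named list of line-id vectors.
#' @export
group_lines <- function(scc, trait = "scc") {
  stopifnot("line" %in% names(scc), trait %in% names(scc))
  cat_ <- scc[[trait]]
  drop <- is.na(cat_) | cat_ == ""
  if (any(drop))
    warning(sum(drop), " line(s) without a phenotype excluded: ",
            paste(utils::head(scc$line[drop], 5L), collapse = ", "))
  groups <- split(scc$line[!drop], cat_[!drop])
  structure(groups, class = "pheno_groups")
}

#' Find markers co-segregating with a categorical trait
#'
#' For each non-reference category X, the contrast is run pairwise against
#' the reference (recurrent-parent-like) category, excluding lines of all
#' other categories — this sidesteps epistatic masking between the loci of
#' different categories. Within the contrast subset, n_g counts the lines
#' carrying the donor code at the marker (heterozygotes count as
#' non-carriers), n_pg counts carriers of category X, and a marker is
#' flagged co-segregating when its consistency is 100 percent and every
#' line of X carries the donor code. Markers with no carrier in a contrast
#' are omitted from that contrast.
#'
#' @param map a [build_snpldb_map()] result.
#' @param groups a [group_lines()] result.
#' @param reference name of the reference category (e.g. `"yellow"`).
#' @return data.frame (marker, contrast, n_pg, n_g, c_pg, c_pg_rounded,
#'   cosegregating).
#' @export
find_cosegregating_markers <- function(map, groups, reference) {
  stopifnot(inherits(map, "physical_map"), inherits(groups, "pheno_groups"))
  if (!reference %in% names(groups) || !length(groups[[reference]]))
    stop("reference group empty or absent")
  lines <- rownames(map$geno)
  res <- list()
  for (x in setdiff(names(groups), reference)) {
    subset_lines <- intersect(lines, c(groups[[x]], groups[[reference]]))
    gsub_ <- map$geno[subset_lines, , drop = FALSE]
    in_x <- subset_lines %in% groups[[x]]
    for (j in seq_len(ncol(gsub_))) {
      carrier <- !is.na(gsub_[, j]) & gsub_[, j] == 2L
      n_g <- sum(carrier)
      if (n_g == 0L) next
      n_pg <- sum(carrier & in_x)
      c_val <- cpg(n_pg, n_g)
      res[[length(res) + 1L]] <- data.frame(
        marker = colnames(gsub_)[j],
        contrast = paste0(reference, "_vs_", x),
        n_pg = n_pg, n_g = n_g, c_pg = c_val,
        c_pg_rounded = round(c_val),
        cosegregating = c_val == 100 && all(carrier[in_x]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(marker = character(), contrast = character(),
                      n_pg = integer(), n_g = integer(), c_pg = numeric(),
                      c_pg_rounded = numeric(), cosegregating = logical())
  rownames(out) <- NULL
  out
}
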