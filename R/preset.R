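#' Breeding-scheme sampler emulating a mixed-generation CSSL panel
#'
#' Lines derive from BC3, BC4 or BC5 material in proportions 103:46:28
#' (the generation census of the emulated panel, counting partially
#' re-backcrossed material with its total backcross number), each followed
#' by 7 selfing generations with recurrent-biased gamete selection.
#'
#' @param crossover_rate Morgans per chromosome per meiosis.
#' @param n_self selfing generations.
#' @return a function(i) usable as the `scheme` argument of
#'   [simulate_cssl_population()].
#' @export
soja_scheme_sampler <- function(crossover_rate = 1.25, n_self = 7L) {
  function(i) {
    nb <- sample(c(3L, 4L, 5L), 1L, prob = c(103, 46, 28))
    breeding_scheme(n_backcross = nb, n_self = n_self,
                    selection_mode = "recurrent_biased",
                    crossover_rate = crossover_rate)
  }
}

#' Simulate the full study-condition population
#'
#' Convenience preset: a soybean-like 20-chromosome genome, 177 lines bred
#' through the mixed BC3-BC5 scheme with biased selection, each line
#' guaranteed to carry at least one donor segment.
#'
#' @param seed integer seed.
#' @param n_lines number of lines.
#' @param genome a [genome_spec()] (default [soy_genome_spec()]).
#' @return as [simulate_cssl_population()], plus `parents`.
#' @export
simulate_soja_population <- function(seed = 1L, n_lines = 177L,
                                     genome = soy_genome_spec()) {
  parents <- simulate_parents(genome, seed = seed)
  pop <- simulate_cssl_population(parents, soja_scheme_sampler(),
                                  n_lines = n_lines, seed = seed + 1L,
                                  require_donor = TRUE)
  pop$parents <- parents
  pop
}

#' One parameter-recovery replicate of the additive QTL scan
#'
#' Simulates a full study-condition population and phenotype set, builds
#' the SNPLDB map from the true segments, runs cofactor selection and the
#' LRT scan, and reports, per planted QTL, the maximum-LOD declared marker
#' on its chromosome (the peak), its distance in markers from the block
#' containing the true position, and the estimated effect with its
#' standard error.
#'
#' @param seed integer seed (drives population, phenotypes and scan).
#' @param architecture a [trait_architecture()] (default
#'   [soja_trait_architecture()]).
#' @param n_lines population size.
#' @param lod_threshold declaration threshold for the scan.
#' @return data.frame with one row per planted QTL: chrom, pos, add_true,
#'   true_marker, peak_marker, peak_dist (markers, NA if nothing declared
#'   on the chromosome), pattern_match (TRUE when the peak's code column is
#'   identical to the true block's — a collinear twin the scan cannot
#'   distinguish from the true block), add_hat, add_se, lod.
#' @export
qtl_recovery_replicate <- function(seed, architecture =
                                     soja_trait_architecture(),
                                   n_lines = 177L, lod_threshold = 2.5) {
  pop <- simulate_soja_population(seed = seed, n_lines = n_lines)
  gm <- pop$genotypes
  map <- build_snpldb_map(pop$truth$segments,
                          chrom_lengths = gm$chrom_lengths,
                          lines = rownames(gm$calls))
  ph <- simulate_phenotypes(gm, architecture, seed = seed + 10000L)
  y <- env_means(ph$dtf)[rownames(gm$calls)]
  cof <- rstep_cofactors(y, marker_matrix(map))
  scan <- lrt_scan(y, map, cof, lod_threshold = lod_threshold)
  qtl <- architecture$dtf_qtl
  rows <- lapply(seq_len(nrow(qtl)), function(j) {
    ch <- qtl$chrom[j]; p <- qtl$pos[j]
    tb <- which(map$markers$chrom == ch & map$markers$start <= p &
                  map$markers$end >= p)[1]
    dec <- which(scan$peak & scan$chrom == ch)
    if (length(dec)) {
      pk <- dec[which.max(scan$lod[dec])]
      data.frame(chrom = ch, pos = p, add_true = qtl$add[j],
                 true_marker = scan$marker[tb],
                 peak_marker = scan$marker[pk], peak_dist = pk - tb,
                 pattern_match = identical(map$geno[, tb], map$geno[, pk]),
                 add_hat = scan$add[pk], add_se = scan$add_se[pk],
                 lod = scan$lod[pk], stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = ch, pos = p, add_true = qtl$add[j],
                 true_marker = scan$marker[tb],
                 peak_marker = NA_character_, peak_dist = NA_integer_,
                 pattern_match = FALSE,
                 add_hat = NA_real_, add_se = NA_real_,
                 lod = max(scan$lod[scan$chrom == ch]),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
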