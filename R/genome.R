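#' Define a genome for simulation
#'
#' A genome specification lists chromosomes with their physical lengths and
#' the positions of the biallelic SNP sites segregating between the two
#' parents. Positions are 1-based and strictly increasing within a
#' chromosome; every site is polymorphic between the donor and the recurrent
#' parent by construction.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   names are the chromosome identifiers (e.g. `"Gm01"`).
#' @param n_snps_per_chrom number of SNP sites per chromosome. Sites are
#'   placed on an even grid (deterministic), mimicking a thinned
#'   resequencing SNP set.
#' @return an object of class `genome_spec`: a list with `chrom`
#'   (data.frame of `chrom`, `length`) and `positions` (named list of sorted
#'   integer vectors).
#' @export
genome_spec <- function(chrom_lengths, n_snps_per_chrom = 200L) {
  if (length(chrom_lengths) == 0L)
    stop("genome must contain at least one chromosome")
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chromosome lengths must be uniquely named")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  n_snps_per_chrom <- rep_len(as.integer(n_snps_per_chrom),
                              length(chrom_lengths))
  positions <- mapply(function(L, n) {
    # even grid offset by half a step keeps sites off the chromosome ends
    step <- L / (n + 1)
    pos <- unique(pmax(1L, pmin(as.integer(round(seq_len(n) * step)), as.integer(L))))
    pos
  }, chrom_lengths, n_snps_per_chrom, SIMPLIFY = FALSE)
  names(positions) <- names(chrom_lengths)
  structure(
    list(chrom = data.frame(chrom = names(chrom_lengths),
                            length = as.numeric(chrom_lengths),
                            stringsAsFactors = FALSE),
         positions = positions),
    class = "genome_spec")
}

#' Soybean-like 20-chromosome genome preset
#'
#' Chromosome lengths approximate the cultivated soybean karyotype
#' (~950 Mb over 20 chromosomes). Used by the paper-emulating presets.
#'
#' @param n_snps_per_chrom SNP sites per chromosome (default 200).
#' @return a [genome_spec()] object.
#' @export
soy_genome_spec <- function(n_snps_per_chrom = 200L) {
  lens <- c(56.8, 48.6, 45.8, 52.4, 42.2, 51.0, 44.4, 47.8, 50.2, 51.6,
            34.8, 40.1, 45.9, 49.7, 51.8, 37.4, 41.6, 58.0, 50.7, 47.9) * 1e6
  names(lens) <- sprintf("Gm%02d", 1:20)
  genome_spec(lens, n_snps_per_chrom)
}

#' Describe a backcross-selfing breeding scheme
#'
#' @param n_backcross number of backcross generations to the recurrent
#'   parent (>= 1).
#' @param n_self number of selfing generations after the last backcross
#'   (>= 1); single-seed descent is simulated.
#' @param selection_mode `"none"` or `"recurrent_biased"`.
#'   `"recurrent_biased"` approximates marker-assisted selection by keeping,
#'   at each backcross, the gamete with fewer donor sites among two
#'   candidate gametes.
#' @param crossover_rate expected crossovers per chromosome per meiosis
#'   (Morgans); crossover counts are Poisson and positions uniform on
#'   physical length (no interference).
#' @return an object of class `breeding_scheme`.
#' @export
breeding_scheme <- function(n_backcross = 3L, n_self = 7L,
                            selection_mode = c("none", "recurrent_biased"),
                            crossover_rate = 1.25) {
  selection_mode <- match.arg(selection_mode)
  n_backcross <- as.integer(n_backcross)
  n_self <- as.integer(n_self)
  if (is.na(n_backcross) || n_backcross < 1L)
    stop("n_backcross must be an integer >= 1")
  if (is.na(n_self) || n_self < 1L)
    stop("n_self must be an integer >= 1")
  if (!is.finite(crossover_rate) || crossover_rate <= 0)
    stop("crossover_rate must be positive")
  structure(list(n_backcross = n_backcross, n_self = n_self,
                 selection_mode = selection_mode,
                 crossover_rate = crossover_rate),
            class = "breeding_scheme")
}

#' Describe the genetic architecture of the simulated traits
#'
#' Two traits are modelled: a two-locus epistatic seed-coat-colour (SCC)
#' trait (the black locus is epistatic over the green locus) and a
#' multi-QTL additive days-to-flowering (DTF) trait measured over several
#' environments and replicates.
#'
#' @param scc_I,scc_G lists `list(chrom =, pos =)` for the black (I) and
#'   green (G) seed-coat loci. Positions are snapped to the nearest SNP site.
#' @param dtf_qtl data.frame with columns `chrom`, `pos`, `add`: QTL
#'   positions and additive effects in days of the donor allele under
#'   -1/0/+1 genotype coding.
#' @param mu_recurrent expected DTF (days) of the recurrent parent, i.e. of
#'   a line recurrent-homozygous at every QTL.
#' @param h2_target broad-sense heritability the simulator calibrates the
#'   residual variance to (via the ANOVA estimator of [heritability()]).
#' @param n_env,n_rep environments and replicates per environment.
#' @param env_sd standard deviation (days) of the fixed environment effects.
#' @return an object of class `trait_architecture`.
#' @export
trait_architecture <- function(scc_I, scc_G, dtf_qtl,
                               mu_recurrent = 52.8, h2_target = 0.956,
                               n_env = 3L, n_rep = 3L, env_sd = 1.5) {
  stopifnot(is.list(scc_I), is.list(scc_G), is.data.frame(dtf_qtl))
  if (!all(c("chrom", "pos", "add") %in% names(dtf_qtl)))
    stop("dtf_qtl needs columns chrom, pos, add")
  if (!all(is.finite(dtf_qtl$add))) stop("additive effects must be finite")
  if (!(h2_target > 0 && h2_target < 1))
    stop("h2_target must lie strictly in (0, 1)")
  structure(list(scc_I = scc_I, scc_G = scc_G, dtf_qtl = dtf_qtl,
                 mu_recurrent = mu_recurrent, h2_target = h2_target,
                 n_env = as.integer(n_env), n_rep = as.integer(n_rep),
                 env_sd = env_sd),
            class = "trait_architecture")
}

#' Paper-emulating trait architecture preset
#'
#' Six DTF QTLs with the published additive-effect profile
#' (-0.58, 3.68, 2.63, -1.00, -0.72, 2.07 days) on six different
#' chromosomes, plus the two SCC loci (black epistatic over green), with
#' heritability target 0.956 over 3 environments x 3 replicates.
#'
#' @param genome a [genome_spec()]; QTL positions are placed mid-chromosome
#'   at genome SNP sites.
#' @return a [trait_architecture()].
#' @export
soja_trait_architecture <- function(genome = soy_genome_spec()) {
  at_pos <- function(chrom, frac) {
    p <- genome$positions[[chrom]]
    p[max(1L, round(frac * length(p)))]
  }
  dtf <- data.frame(
    chrom = c("Gm04", "Gm10", "Gm12", "Gm15", "Gm16", "Gm17"),
    pos = c(at_pos("Gm04", 0.80), at_pos("Gm10", 0.88),
            at_pos("Gm12", 0.14), at_pos("Gm15", 0.60),
            at_pos("Gm16", 0.01), at_pos("Gm17", 0.97)),
    add = c(-0.58, 3.68, 2.63, -1.00, -0.72, 2.07),
    stringsAsFactors = FALSE)
  trait_architecture(
    scc_I = list(chrom = "Gm08", pos = at_pos("Gm08", 0.17)),
    scc_G = list(chrom = "Gm01", pos = at_pos("Gm01", 0.94)),
    dtf_qtl = dtf)
}
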