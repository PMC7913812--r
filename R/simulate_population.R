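#' Construct a genotype matrix object
#'
#' The central genotype container: an ordered site table plus a lines x
#' sites matrix of genotype codes 0 (recurrent-homozygous), 1
#' (heterozygous), 2 (donor-homozygous) or `NA` (missing).
#'
#' @param sites data.frame with at least `chrom` and `pos` (1-based),
#'   optionally `qual`, `mean_dp`, `ref`, `alt`. Must be sorted by
#'   (chrom, pos).
#' @param calls integer matrix, one row per line (rownames = line ids), one
#'   column per site, values in \{0, 1, 2, NA\}.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   optional but required for segment inference.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls, chrom_lengths = NULL) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  if (nrow(sites) != ncol(calls))
    stop("calls must have one column per site")
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  bad <- setdiff(unique(calls[!is.na(calls)]), c(0L, 1L, 2L))
  if (length(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("L%03d", seq_len(nrow(calls)))
  if (is.null(sites$qual)) sites$qual <- Inf
  if (is.null(sites$mean_dp)) sites$mean_dp <- Inf
  structure(list(sites = sites, calls = calls,
                 chrom_lengths = chrom_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d sites on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$sites$chrom))))
  invisible(x)
}

#' Simulate the two fully homozygous parents
#'
#' Assigns reference (recurrent-parent) and alternate (donor-parent) bases
#' at every genome SNP site; the parents differ at every site.
#'
#' @param genome a [genome_spec()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return a list of class `parental_variant_set` with the genome and a
#'   site table carrying `ref` (recurrent) and `alt` (donor) alleles.
#' @export
simulate_parents <- function(genome, seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"))
  if (nrow(genome$chrom) == 0L) stop("genome has no chromosomes")
  set.seed(seed)
  sites <- data.frame(
    chrom = rep(genome$chrom$chrom, lengths(genome$positions)),
    pos = unlist(genome$positions, use.names = FALSE),
    stringsAsFactors = FALSE)
  n <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, n, replace = TRUE)
  # alt drawn from the three non-ref bases: every site is a fixed difference
  sites$alt <- vapply(sites$ref, function(b) sample(setdiff(bases, b), 1L), "")
  structure(list(genome = genome, sites = sites),
            class = "parental_variant_set")
}

# Flattened-genome cache: global site coordinates and per-site chromosome
# index, so one meiosis is a handful of vectorized operations.
.genome_cache <- function(genome) {
  n_per <- lengths(genome$positions)
  offset <- c(0, cumsum(genome$chrom$length))[seq_len(nrow(genome$chrom))]
  list(n_chr = nrow(genome$chrom),
       len = genome$chrom$length,
       offset = offset,
       gpos = unlist(genome$positions, use.names = FALSE) +
         rep.int(offset, n_per),
       chrom_idx = rep.int(seq_len(nrow(genome$chrom)), n_per))
}

# One meiosis over the whole genome. Haplotypes are flat logical vectors
# (TRUE = donor allele). Crossover counts are Poisson per chromosome with
# uniform physical positions; the starting phase is random per chromosome,
# so cut counts accumulated from other chromosomes only shift that
# Bernoulli phase and leave the within-chromosome mosaic law unchanged.
.gamete <- function(h1, h2, gc, rate) {
  n_co <- stats::rpois(gc$n_chr, rate)
  phase <- sample.int(2L, gc$n_chr, replace = TRUE) - 1L
  tot <- sum(n_co)
  if (tot == 0L) {
    take1 <- phase[gc$chrom_idx] == 0L
  } else {
    cuts <- stats::runif(tot) * rep.int(gc$len, n_co) +
      rep.int(gc$offset, n_co)
    seg <- findInterval(gc$gpos, sort(cuts))
    take1 <- ((seg + phase[gc$chrom_idx]) %% 2L) == 0L
  }
  g <- h2
  g[take1] <- h1[take1]
  g
}

# Simulate one line through the scheme; returns the flat code vector.
.simulate_line <- function(gc, scheme) {
  donor <- rep(TRUE, length(gc$gpos))
  recur <- !donor
  ind <- list(h1 = donor, h2 = recur)           # F1
  biased <- scheme$selection_mode == "recurrent_biased"
  for (b in seq_len(scheme$n_backcross)) {
    g <- .gamete(ind$h1, ind$h2, gc, scheme$crossover_rate)
    if (biased) {
      g2 <- .gamete(ind$h1, ind$h2, gc, scheme$crossover_rate)
      if (sum(g2) < sum(g)) g <- g2
    }
    ind <- list(h1 = g, h2 = recur)
  }
  for (s in seq_len(scheme$n_self))
    ind <- list(h1 = .gamete(ind$h1, ind$h2, gc, scheme$crossover_rate),
                h2 = .gamete(ind$h1, ind$h2, gc, scheme$crossover_rate))
  as.integer(ind$h1) + as.integer(ind$h2)
}

#' Simulate a CSSL population
#'
#' Each line is produced by simulating meioses through the breeding scheme:
#' an F1 is backcrossed `n_backcross` times to the recurrent parent, then
#' selfed `n_self` generations by single-seed descent. Crossover counts are
#' Poisson per chromosome with positions uniform on physical length. Under
#' `selection_mode = "recurrent_biased"`, each backcross keeps the gamete
#' with fewer donor sites among two candidates, approximating
#' marker-assisted selection for the recurrent genome. Without selection
#' the expected donor-genome fraction after BC_n (selfed) is (1/2)^(n+1).
#'
#' @param parents a [simulate_parents()] result.
#' @param scheme a [breeding_scheme()], or a list of schemes sampled per
#'   line (mixed-generation populations), or a function(i) returning one.
#' @param n_lines number of lines (>= 1).
#' @param seed integer seed.
#' @param require_donor if TRUE, a line that carries no donor allele at any
#'   site is redrawn (a substitution line carries at least one segment by
#'   definition); used by the paper-emulating preset.
#' @return list with `genotypes` (a noise-free [genotype_matrix()]) and
#'   `truth` (class `truth_record`): true segments per line
#'   (`segments`: line, chrom, start, end, origin, n_sites) and the
#'   per-line scheme used.
#' @export
simulate_cssl_population <- function(parents, scheme, n_lines, seed = 1L,
                                     require_donor = FALSE) {
  stopifnot(inherits(parents, "parental_variant_set"))
  if (n_lines < 1L) stop("n_lines must be >= 1")
  genome <- parents$genome
  schemes <- if (inherits(scheme, "breeding_scheme")) {
    function(i) scheme
  } else if (is.function(scheme)) {
    scheme
  } else if (is.list(scheme)) {
    function(i) scheme[[(i - 1L) %% length(scheme) + 1L]]
  } else stop("invalid scheme")
  set.seed(seed)
  line_ids <- sprintf("L%03d", seq_len(n_lines))
  per_chr <- lengths(genome$positions)
  calls <- matrix(NA_integer_, n_lines, sum(per_chr),
                  dimnames = list(line_ids, NULL))
  used_schemes <- vector("list", n_lines)
  gc_ <- .genome_cache(genome)
  for (i in seq_len(n_lines)) {
    sch <- schemes(i)
    if (!inherits(sch, "breeding_scheme")) stop("invalid scheme")
    codes <- .simulate_line(gc_, sch)
    if (require_donor) {
      tries <- 0L
      while (sum(codes) == 0L && tries < 50L) {
        codes <- .simulate_line(gc_, sch)
        tries <- tries + 1L
      }
    }
    calls[i, ] <- codes
    used_schemes[[i]] <- sch
  }
  sites <- parents$sites
  sites$qual <- Inf
  sites$mean_dp <- Inf
  lens <- stats::setNames(genome$chrom$length, genome$chrom$chrom)
  gm <- genotype_matrix(sites, calls, chrom_lengths = lens)
  truth_segments <- true_segments(gm)
  truth <- structure(list(segments = truth_segments, schemes = used_schemes,
                          genome = genome),
                     class = "truth_record")
  list(genotypes = gm, truth = truth)
}

#' True segment map of a noise-free genotype matrix
#'
#' Collapses the per-site codes of each line into maximal runs and converts
#' them to genomic segments using the same breakpoint-midpoint convention
#' as [infer_line_segments()], so noiseless round trips are exact.
#'
#' @param gm a noise-free [genotype_matrix()] with `chrom_lengths`.
#' @return data.frame (line, chrom, start, end, origin, n_sites).
#' @export
true_segments <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$chrom_lengths)) stop("genotype matrix lacks chrom_lengths")
  res <- list()
  chroms <- unique(gm$sites$chrom)
  idx_by_chrom <- split(seq_len(nrow(gm$sites)), gm$sites$chrom)[chroms]
  for (ch in chroms) {
    idx <- idx_by_chrom[[ch]]
    pos <- gm$sites$pos[idx]
    L <- gm$chrom_lengths[[ch]]
    for (ln in rownames(gm$calls)) {
      v <- gm$calls[ln, idx]
      res[[length(res) + 1L]] <-
        cbind(line = ln, chrom = ch, .runs_to_segments(v, pos, L))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Overlay an observation model on a true genotype matrix
#'
#' Per site and line, a read depth is drawn Poisson(`depth`); depth zero
#' yields a missing call, otherwise the genotype is mis-called to one of
#' the other two codes with probability `error_rate`; further calls are
#' dropped with probability `missing_rate`. Per-site QUAL and mean-depth
#' metadata are emitted for downstream QC filtering.
#'
#' @param gm a [genotype_matrix()] of true codes.
#' @param depth mean sequencing depth (>= 0).
#' @param error_rate,missing_rate probabilities in \[0, 1\].
#' @param seed integer seed.
#' @param lowq_frac fraction of sites given a sub-threshold QUAL (< 30) to
#'   exercise the QC filter; the rest draw QUAL from 30 + Exp(mean 40).
#' @return a [genotype_matrix()] with noisy calls and site metadata.
#' @export
observe_genotypes <- function(gm, depth = 3.04, error_rate = 0.01,
                              missing_rate = 0.02, seed = 1L,
                              lowq_frac = 0.03) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (depth < 0) stop("depth must be non-negative")
  if (any(c(error_rate, missing_rate) < 0 | c(error_rate, missing_rate) > 1))
    stop("rates must lie in [0, 1]")
  set.seed(seed)
  calls <- gm$calls
  n <- length(calls)
  dp <- matrix(stats::rpois(n, depth), nrow(calls), ncol(calls))
  obs <- calls
  obs[dp == 0L] <- NA_integer_
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate & dp > 0L & !is.na(calls))
    if (length(err)) {
      # symmetric mis-call to one of the two other codes
      shift <- sample(1:2, length(err), replace = TRUE)
      obs[err] <- (calls[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0)
    obs[stats::runif(n) < missing_rate] <- NA_integer_
  sites <- gm$sites
  m <- ncol(calls)
  lowq <- stats::runif(m) < lowq_frac
  sites$qual <- ifelse(lowq, stats::runif(m, 0, 29.9),
                       30 + stats::rexp(m, 1 / 40))
  sites$mean_dp <- colMeans(dp)
  genotype_matrix(sites, obs, chrom_lengths = gm$chrom_lengths)
}
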