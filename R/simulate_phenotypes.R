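#' Seed-coat colour from the two-locus epistatic model
#'
#' Black whenever the line is donor-homozygous at the black (I-equivalent)
#' locus; otherwise green if donor-homozygous at the green (G-equivalent)
#' locus; otherwise yellow. Heterozygotes behave as recurrent (the
#' population is near-homozygous), and the black locus is epistatic over
#' the green one.
#'
#' @param code_I,code_G genotype codes (0/1/2) at the two loci.
#' @return character vector in \{"black", "green", "yellow"\}.
#' @export
scc_from_genotypes <- function(code_I, code_G) {
  ifelse(code_I == 2L, "black", ifelse(code_G == 2L, "green", "yellow"))
}

# Genotype codes of every line at a causal locus, snapping the locus to
# the nearest SNP site on its chromosome.
.codes_at <- function(gm, chrom, pos) {
  idx <- which(gm$sites$chrom == chrom)
  if (!length(idx)) stop("causal locus on unknown chromosome ", chrom)
  j <- idx[which.min(abs(gm$sites$pos[idx] - pos))]
  gm$calls[, j]
}

#' Simulate seed-coat colour and days-to-flowering phenotypes
#'
#' SCC follows [scc_from_genotypes()]. DTF per line, environment and
#' replicate is mu + sum(a_j * x_j) + E_env + eps with x_j in \{-1, 0, +1\}
#' for recurrent-hom / het / donor-hom at each QTL, fixed environment
#' effects, and a residual whose scale is solved by bisection so that the
#' realized broad-sense heritability — as measured by the ANOVA estimator
#' of [heritability()] on the simulated table itself — matches the
#' architecture's target. The recurrent and donor parents are included in
#' the DTF table under `recurrent_id`/`donor_id` (all-recurrent and
#' all-donor genotypes).
#'
#' @param genotypes noise-free [genotype_matrix()] of the population (true
#'   codes, e.g. `simulate_cssl_population(...)$genotypes`).
#' @param architecture a [trait_architecture()] whose loci lie on the
#'   simulated genome.
#' @param seed integer seed.
#' @param recurrent_id,donor_id identifiers for the two parent entries.
#' @return list of class `phenotype_set`: `dtf` (long data.frame line,
#'   env, rep, value), `scc` (line, scc), `truth` (per-line genetic values
#'   and causal genotypes `x`), `env_effects`, `residual_sd`.
#' @export
simulate_phenotypes <- function(genotypes, architecture, seed = 1L,
                                recurrent_id = "RP", donor_id = "DP") {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(architecture, "trait_architecture"))
  a <- architecture
  set.seed(seed)
  lines <- rownames(genotypes$calls)
  code_I <- .codes_at(genotypes, a$scc_I$chrom, a$scc_I$pos)
  code_G <- .codes_at(genotypes, a$scc_G$chrom, a$scc_G$pos)
  scc <- data.frame(line = lines,
                    scc = scc_from_genotypes(code_I, code_G),
                    stringsAsFactors = FALSE)
  q <- nrow(a$dtf_qtl)
  x <- vapply(seq_len(q), function(j)
    .codes_at(genotypes, a$dtf_qtl$chrom[j], a$dtf_qtl$pos[j]) - 1,
    numeric(length(lines)))
  colnames(x) <- paste0("qtl", seq_len(q))
  adds <- a$dtf_qtl$add
  # mu such that the all-recurrent genotype averages mu_recurrent
  mu <- a$mu_recurrent + sum(adds)
  g <- mu + drop(x %*% adds)
  ids <- c(lines, recurrent_id, donor_id)
  gv <- c(g, mu - sum(adds), mu + sum(adds))
  env_eff <- stats::rnorm(a$n_env, 0, a$env_sd)
  envs <- paste0("E", seq_len(a$n_env))
  grid <- expand.grid(line = ids, env = envs,
                      rep = seq_len(a$n_rep), stringsAsFactors = FALSE)
  base <- gv[match(grid$line, ids)] + env_eff[match(grid$env, envs)]
  eps0 <- stats::rnorm(nrow(grid))
  make <- function(s) {
    d <- grid
    d$value <- base + s * eps0
    d
  }
  # realized-h2 calibration: the ANOVA estimator is monotone decreasing in
  # the residual scale, so bisection on s converges
  pop <- grid$line %in% lines
  h2_pop <- function(s) {
    d <- grid[pop, ]
    d$value <- base[pop] + s * eps0[pop]
    heritability(d)$h2
  }
  lo <- 1e-6; hi <- 1
  if (h2_pop(lo) < a$h2_target)
    stop("cannot reach target heritability (degenerate genetic variance?)")
  while (h2_pop(hi) > a$h2_target && hi < 1e4) hi <- hi * 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (h2_pop(mid) > a$h2_target) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  dtf <- make(s)
  truth <- list(genetic_values = stats::setNames(g, lines), x = x,
                mu = mu, adds = adds)
  structure(list(dtf = dtf, scc = scc, truth = truth,
                 env_effects = stats::setNames(env_eff, envs),
                 residual_sd = s,
                 recurrent_id = recurrent_id, donor_id = donor_id),
            class = "phenotype_set")
}
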