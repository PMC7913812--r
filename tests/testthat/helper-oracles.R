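# Independent oracles and small fixture builders used across the suite.

# Exhaustive least-squares oracle via explicit normal equations: LOD, ADD
# and PVE for testing marker x against background X0 (with intercept).
ls_oracle <- function(y, X0, x) {
  n <- length(y)
  beta0 <- solve(crossprod(X0), crossprod(X0, y))
  rss0 <- sum((y - X0 %*% beta0)^2)
  X1 <- cbind(X0, x)
  beta1 <- solve(crossprod(X1), crossprod(X1, y))
  rss1 <- sum((y - X1 %*% beta1)^2)
  tss <- sum((y - mean(y))^2)
  list(lod = n * log(rss0 / rss1) / (2 * log(10)),
       add = unname(beta1[length(beta1)]),
       pve = 100 * (rss0 - rss1) / tss)
}

# Translate-both-alleles oracle for coding variants: splice the full CDS
# out of the reference and mutated gene-local sequences, translate both
# proteins entirely, and call the class from the first amino-acid change.
translate_oracle <- function(model, variant) {
  i <- variant$pos - model$seq_start + 1
  stopifnot(substring(model$seq, i, i) == variant$ref)
  alt_seq <- model$seq
  substr(alt_seq, i, i) <- variant$alt
  prot <- lapply(list(ref = model$seq, alt = alt_seq), function(s) {
    cds <- paste(vapply(seq_len(nrow(model$cds)), function(k)
      substring(s, model$cds$start[k] - model$seq_start + 1,
                model$cds$end[k] - model$seq_start + 1), ""),
      collapse = "")
    d <- Biostrings::DNAString(cds)
    if (model$strand == "-") d <- Biostrings::reverseComplement(d)
    as.character(Biostrings::translate(d, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  })
  if (prot$ref == prot$alt) return("synonymous")
  pr <- strsplit(prot$ref, "")[[1]]
  pa <- strsplit(prot$alt, "")[[1]]
  d <- which(pr != pa)[1]
  if (pa[d] == "*") "stop_gain" else if (pr[d] == "*") "stop_loss"
  else "missense"
}

# Direct loop implementation of the sliding-majority smoothing and
# short-run absorption rules, independent of the package's vectorized path.
smooth_oracle <- function(v, window, min_sites) {
  n <- length(v)
  h <- (window - 1) %/% 2
  sm <- integer(n)
  for (i in seq_len(n)) {
    w <- v[max(1, i - h):min(n, i + h)]
    cnt <- vapply(0:2, function(k) sum(w == k), 0L)
    mx <- which(cnt == max(cnt)) - 1L
    sm[i] <- if (length(mx) > 1L) v[i] else mx
  }
  repeat {
    r <- rle(sm)
    k <- length(r$lengths)
    if (k <= 1L) break
    short <- which(r$lengths < min_sites)
    if (!length(short)) break
    i <- short[1]
    left <- if (i > 1L) r$lengths[i - 1L] else -Inf
    right <- if (i < k) r$lengths[i + 1L] else -Inf
    tgt <- if (left >= right) r$values[i - 1L] else r$values[i + 1L]
    ends <- cumsum(r$lengths)
    idx <- (ends[i] - r$lengths[i] + 1L):ends[i]
    sm[idx] <- tgt
  }
  sm
}

# Small two-chromosome genome for unit tests.
toy_genome <- function(n_snps = 50L, len = 1e6) {
  genome_spec(c(chrA = len, chrB = len), n_snps_per_chrom = n_snps)
}

# Genotype matrix built from an explicit per-line call matrix on one
# chromosome with evenly spaced sites.
toy_gm <- function(calls, chrom = "chrA", L = NULL, pos = NULL) {
  had_names <- is.matrix(calls) && !is.null(rownames(calls))
  calls <- rbind(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1e4
  if (is.null(L)) L <- max(pos) + 1e4
  sites <- data.frame(chrom = chrom, pos = pos,
                      qual = Inf, mean_dp = Inf,
                      stringsAsFactors = FALSE)
  if (!had_names)
    rownames(calls) <- sprintf("L%03d", seq_len(nrow(calls)))
  genotype_matrix(sites, calls, chrom_lengths = stats::setNames(L, chrom))
}

# Mirror a gene model and its variants through position L - pos + 1,
# flipping strand and complementing the sequence (strand-symmetry checks).
mirror_model <- function(model, L) {
  flip <- function(s, e) data.frame(start = L - e + 1, end = L - s + 1)
  seq_end <- model$seq_start + nchar(model$seq) - 1
  gene_model(
    id = model$id, chrom = model$chrom,
    strand = if (model$strand == "+") "-" else "+",
    exons = flip(model$exons$start, model$exons$end),
    cds = flip(model$cds$start, model$cds$end),
    seq = paste(rev(unname(c(A = "T", C = "G", G = "C",
                             T = "A")[strsplit(model$seq, "")[[1]]])),
                collapse = ""),
    seq_start = L - seq_end + 1,
    promoter_bp = model$promoter_bp)
}

mirror_variant <- function(variant, L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  data.frame(chrom = variant$chrom, pos = L - variant$pos + 1,
             ref = unname(comp[variant$ref]),
             alt = unname(comp[variant$alt]),
             stringsAsFactors = FALSE)
}
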