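.TISSUES <- c("Leaf", "Flower", "14seed", "21seed", "28seed", "35seed",
              "7pod", "21pod")
.STOPS <- c("TAA", "TAG", "TGA")

.rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.revcomp <- function(s) {
  paste(rev(unname(.COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
}

# Build one random toy gene: 2-3 exons, short UTRs, canonical GT..AG
# introns, CDS with a clean open reading frame.
.random_gene <- function(id, chrom, gene_start, strand = NULL,
                         n_codons = NULL, n_exons = NULL,
                         promoter_bp = 2000L, flank = 200L) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  if (is.null(n_codons)) n_codons <- sample(30:80, 1L)
  if (is.null(n_exons)) n_exons <- sample(2:3, 1L)
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE), .STOPS)
  cds_tx <- paste0("ATG",
                   paste(sample(non_stop, n_codons - 2L, replace = TRUE),
                         collapse = ""),
                   sample(.STOPS, 1L))
  u5 <- 6L; u3 <- 6L
  mature <- paste0(.rand_bases(u5), cds_tx, .rand_bases(u3))
  mlen <- nchar(mature)
  # split the mature transcript into n_exons pieces of >= 12 bases
  cuts <- sort(sample(seq(12L, mlen - 12L), n_exons - 1L))
  ex_tx_start <- c(1L, cuts + 1L)
  ex_tx_end <- c(cuts, mlen)
  intron_len <- sample(30:200, n_exons - 1L, replace = TRUE)
  introns <- vapply(intron_len, function(l)
    paste0("GT", .rand_bases(l - 4L), "AG"), "")
  pre <- character(0)
  pre_map <- integer(0)    # pre-mRNA index of each mature base
  off <- 0L
  for (i in seq_len(n_exons)) {
    piece <- substring(mature, ex_tx_start[i], ex_tx_end[i])
    pre <- c(pre, piece)
    pre_map <- c(pre_map, off + seq_len(nchar(piece)))
    off <- off + nchar(piece)
    if (i < n_exons) {
      pre <- c(pre, introns[i])
      off <- off + nchar(introns[i])
    }
  }
  pre <- paste(pre, collapse = "")
  M <- nchar(pre)
  gene_end <- gene_start + M - 1L
  tx2gen <- if (strand == "+") gene_start + seq_len(M) - 1L
            else gene_end - seq_len(M) + 1L
  # exon/CDS genomic intervals
  exon_pre <- mapply(function(s, e) range(pre_map[s:e]),
                     ex_tx_start, ex_tx_end)
  exon_gen <- apply(exon_pre, 2, function(r) sort(tx2gen[r[1]:r[2]][c(1,
                    r[2] - r[1] + 1L)]))
  exons <- data.frame(start = exon_gen[1, ], end = exon_gen[2, ])
  cds_mature <- (u5 + 1L):(u5 + 3L * n_codons)
  cds_gen <- tx2gen[pre_map[cds_mature]]
  r <- rle(c(TRUE, diff(sort(cds_gen)) == 1L))
  sg <- sort(cds_gen)
  brk <- which(diff(sg) != 1L)
  cds <- data.frame(start = sg[c(1L, brk + 1L)], end = sg[c(brk, length(sg))])
  gseq <- if (strand == "+") pre else .revcomp(pre)
  # local sequence covers the promoter window on both sides, so minus-strand
  # genes (promoter genomically downstream-right) are fully covered too
  seq_start <- gene_start - promoter_bp - flank
  full <- paste0(.rand_bases(promoter_bp + flank), gseq,
                 .rand_bases(promoter_bp + flank))
  gene_model(id, chrom, strand, exons, cds, full, seq_start,
             promoter_bp = promoter_bp)
}

#' Simulate toy gene models inside genomic regions
#'
#' Places non-overlapping random single-transcript gene models (2-3 exons,
#' canonical GT..AG introns, clean open reading frames, short UTRs) with
#' gene-local reference sequence covering the promoter window.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`.
#' @param n_genes genes per region.
#' @param seed integer seed.
#' @param promoter_bp promoter window (default 2000 bp).
#' @return list of [gene_model()] objects.
#' @export
simulate_gene_models <- function(regions, n_genes = 5L, seed = 1L,
                                 promoter_bp = 2000L) {
  set.seed(seed)
  models <- list()
  g <- 0L
  for (i in seq_len(nrow(regions))) {
    span <- regions$end[i] - regions$start[i]
    slot <- span / n_genes
    if (slot < promoter_bp + 2000)
      stop("region too small for ", n_genes, " genes")
    for (k in seq_len(n_genes)) {
      g <- g + 1L
      gene_start <- round(regions$start[i] + (k - 1) * slot + promoter_bp +
                            300)
      models[[g]] <- .random_gene(sprintf("gene%03d", g), regions$chrom[i],
                                  gene_start, promoter_bp = promoter_bp)
    }
  }
  models
}

# Find a single-base substitution in the CDS producing the requested
# protein-level class; returns genomic ref/alt and position.
.plant_coding <- function(model, class) {
  cds_gen <- .cds_positions(model)
  k <- length(cds_gen) / 3L
  codons <- if (class == "stop_loss") k else 2:(k - 1L)
  for (ci in codons) {
    cpos <- cds_gen[(ci - 1L) * 3L + 1:3]
    ref_codon <- paste(vapply(cpos, function(p) .tx_base(model, p), ""),
                       collapse = "")
    aa_ref <- .codon_aa(ref_codon)
    for (o in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"),
                        substring(ref_codon, o, o))) {
        alt_codon <- ref_codon
        substr(alt_codon, o, o) <- b
        aa_alt <- .codon_aa(alt_codon)
        hit <- switch(class,
          stop_gain = aa_ref != "*" && aa_alt == "*",
          stop_loss = aa_ref == "*" && aa_alt != "*",
          missense = aa_ref != "*" && aa_alt != "*" && aa_ref != aa_alt,
          synonymous = aa_ref == aa_alt)
        if (hit) {
          pos <- cpos[o]
          alt_gen <- if (model$strand == "-") unname(.COMPLEMENT[b]) else b
          return(data.frame(chrom = model$chrom, pos = pos,
                            ref = .gene_base(model, pos), alt = alt_gen,
                            gene = model$id, class = class,
                            stringsAsFactors = FALSE))
        }
      }
    }
  }
  stop("could not plant a ", class, " variant in ", model$id)
}

#' Plant a variant of a requested effect class in a gene model
#'
#' @param model a [gene_model()].
#' @param class one of missense, stop_gain, stop_loss, synonymous,
#'   splice_acceptor, splice_donor, intron, promoter, intergenic.
#' @param n_snps number of SNPs to plant (promoter class only).
#' @return data.frame (chrom, pos, ref, alt, gene, class), one row per SNP.
#' @export
plant_variant <- function(model, class, n_snps = 1L) {
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  at <- function(pos, class) {
    ref <- .gene_base(model, pos)
    data.frame(chrom = model$chrom, pos = pos, ref = ref,
               alt = other(ref), gene = model$id, class = class,
               stringsAsFactors = FALSE)
  }
  ex <- model$exons
  gene_start <- min(ex$start); gene_end <- max(ex$end)
  if (class %in% c("missense", "stop_gain", "stop_loss", "synonymous"))
    return(.plant_coding(model, class))
  if (class %in% c("splice_acceptor", "splice_donor")) {
    if (nrow(ex) < 2L) stop("gene has no intron")
    int_s <- ex$end[1L] + 1; int_e <- ex$start[2L] - 1
    pos <- if (model$strand == "+") {
      if (class == "splice_donor") int_s else int_e
    } else {
      if (class == "splice_donor") int_e else int_s
    }
    return(at(pos, class))
  }
  if (class == "intron") {
    if (nrow(ex) < 2L) stop("gene has no intron")
    return(at(floor((ex$end[1L] + ex$start[2L]) / 2), class))
  }
  if (class == "promoter") {
    w <- model$promoter_bp
    rng <- if (model$strand == "+") (gene_start - w):(gene_start - 1)
           else (gene_end + 1):(gene_end + w)
    pos <- sort(sample(rng, n_snps))
    return(do.call(rbind, lapply(pos, at, class = "promoter")))
  }
  if (class == "intergenic") {
    seq_end <- model$seq_start + nchar(model$seq) - 1
    pos <- if (model$strand == "+") seq_end - 10 else model$seq_start + 10
    return(at(pos, class))
  }
  stop("unknown class ", class)
}

#' Simulate parental expression tables and planted causal variants
#'
#' For each causal gene, parent FPKM profiles over 8 tissues differ by at
#' least the requested fold in at least 3 tissues with FPKM >= 2 somewhere,
#' and one variant of the assigned effect class is planted (a set of
#' promoter SNPs for the promoter class). Decoy genes receive either
#' uniformly low expression (FPKM < 2 everywhere) or sub-fold parental
#' differences, and synonymous/intronic decoy variants.
#'
#' @param models list of [gene_model()] (the annotation).
#' @param causal data.frame with columns `gene`, `class` and optionally
#'   `fold` (default 4) and `n_snps` (promoter SNP count, default 11);
#'   every gene must be present in `models`.
#' @param seed integer seed.
#' @param parents parent labels (donor first).
#' @return list with `expression` (gene, tissue, parent, fpkm long table)
#'   and `variants` (chrom, pos, ref, alt, gene, class).
#' @export
simulate_expression_and_variants <- function(models, causal, seed = 1L,
                                             parents = c("donor",
                                                         "recurrent")) {
  ids <- vapply(models, function(m) m$id, "")
  if (!all(causal$gene %in% ids))
    stop("causal gene(s) absent from annotation: ",
         paste(setdiff(causal$gene, ids), collapse = ", "))
  set.seed(seed)
  if (is.null(causal$fold)) causal$fold <- 4
  if (is.null(causal$n_snps)) causal$n_snps <- 11L
  expr <- list(); vars <- list()
  for (m in models) {
    is_causal <- m$id %in% causal$gene
    if (is_causal) {
      spec <- causal[causal$gene == m$id, ][1L, ]
      base <- stats::rlnorm(length(.TISSUES), log(8), 0.8)
      base[which.max(base)] <- max(base[which.max(base)], 5)
      de_t <- sample(length(.TISSUES), sample(3:6, 1L))
      up_parent <- sample(1:2, 1L)
      p <- rbind(base, base)
      p[up_parent, de_t] <- p[up_parent, de_t] * spec$fold
      vars[[m$id]] <- plant_variant(m, spec$class, n_snps = spec$n_snps)
    } else {
      if (stats::runif(1) < 0.5) {
        p <- rbind(stats::runif(length(.TISSUES), 0, 1.5),
                   stats::runif(length(.TISSUES), 0, 1.5))
      } else {
        base <- stats::rlnorm(length(.TISSUES), log(6), 0.8)
        p <- rbind(base, base * stats::runif(length(.TISSUES), 0.7, 1.4))
      }
      if (stats::runif(1) < 0.7)
        vars[[m$id]] <- plant_variant(m, sample(c("synonymous", "intron"),
                                                1L))
    }
    expr[[m$id]] <- data.frame(
      gene = m$id,
      tissue = rep(.TISSUES, 2L),
      parent = rep(parents, each = length(.TISSUES)),
      fpkm = round(c(p[1L, ], p[2L, ]), 2),
      stringsAsFactors = FALSE)
  }
  list(expression = do.call(rbind, c(expr, make.row.names = FALSE)),
       variants = do.call(rbind, c(vars, make.row.names = FALSE)))
}
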