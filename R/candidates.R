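.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Construct a single-transcript gene model
#'
#' @param id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame of 1-based inclusive `start`, `end` intervals,
#'   ordered by position and non-overlapping.
#' @param cds data.frame of CDS intervals, each contained in an exon; the
#'   total CDS length should be divisible by 3 (flagged otherwise).
#' @param seq character string of the local reference sequence.
#' @param seq_start genomic position of the first base of `seq`; `seq`
#'   should cover at least the promoter window through the gene end.
#' @param promoter_bp promoter window length upstream of the transcription
#'   start site (default 2000 bp).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(id, chrom, strand, exons, cds, seq, seq_start,
                       promoter_bp = 2000L) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), is.data.frame(cds))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  in_exon <- vapply(seq_len(nrow(cds)), function(i)
    any(cds$start[i] >= exons$start & cds$end[i] <= exons$end), logical(1))
  if (!all(in_exon)) stop("CDS intervals must lie within exons")
  cds_len <- sum(cds$end - cds$start + 1)
  frame_ok <- cds_len %% 3L == 0L
  if (!frame_ok)
    warning("CDS length of ", id, " not divisible by 3")
  structure(list(id = id, chrom = chrom, strand = strand, exons = exons,
                 cds = cds, seq = toupper(seq),
                 seq_start = as.numeric(seq_start),
                 promoter_bp = as.integer(promoter_bp),
                 frame_ok = frame_ok),
            class = "gene_model")
}

# Genomic base of the model's local sequence at position `pos`.
.gene_base <- function(model, pos) {
  i <- pos - model$seq_start + 1
  if (any(i < 1 | i > nchar(model$seq)))
    stop("position outside the gene-local sequence")
  substring(model$seq, i, i)
}

# CDS genomic positions in transcription (5'->3') order.
.cds_positions <- function(model) {
  p <- unlist(lapply(seq_len(nrow(model$cds)), function(i)
    seq(model$cds$start[i], model$cds$end[i])))
  if (model$strand == "-") rev(p) else p
}

# Transcript-strand base at genomic position `pos`.
.tx_base <- function(model, pos) {
  b <- .gene_base(model, pos)
  if (model$strand == "-") unname(.COMPLEMENT[b]) else b
}

.codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the effect of a SNP on a gene model
#'
#' Precedence: splice site (the 2 bp at either intron end) over coding
#' change (stop gain / stop loss / missense / synonymous via codon
#' translation in CDS-relative frame on the coding strand) over UTR over
#' intron over promoter (within `promoter_bp` upstream of the TSS) over
#' intergenic. Minus-strand genes are handled by complementing alleles and
#' reversing the reading order.
#'
#' @param model a [gene_model()].
#' @param variant list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (single bases). The `ref` allele must match the gene-local
#'   reference sequence, else a hard error is raised.
#' @return data.frame (chrom, pos, ref, alt, gene, class) with class one of
#'   synonymous, missense, stop_gain, stop_loss, splice_acceptor,
#'   splice_donor, intron, promoter, UTR, intergenic.
#' @export
classify_variant_effect <- function(model, variant) {
  stopifnot(inherits(model, "gene_model"))
  pos <- as.numeric(variant$pos)
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  ann <- function(class)
    data.frame(chrom = variant$chrom, pos = pos, ref = ref, alt = alt,
               gene = model$id, class = class, stringsAsFactors = FALSE)
  if (!identical(as.character(variant$chrom), model$chrom))
    return(ann("intergenic"))
  seq_end <- model$seq_start + nchar(model$seq) - 1
  if (pos >= model$seq_start && pos <= seq_end) {
    if (.gene_base(model, pos) != ref)
      stop("reference allele mismatch at ", model$chrom, ":", pos,
           " (expected ", .gene_base(model, pos), ", got ", ref, ")")
  }
  ex <- model$exons
  gene_start <- min(ex$start); gene_end <- max(ex$end)
  # splice sites: 2 bp at each intron end, donor at the transcription-5'
  # end of the intron, acceptor at the 3' end
  if (nrow(ex) > 1L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      int_s <- ex$end[i] + 1; int_e <- ex$start[i + 1L] - 1
      if (int_e < int_s) next
      left2 <- pos %in% c(int_s, min(int_s + 1, int_e))
      right2 <- pos %in% c(max(int_e - 1, int_s), int_e)
      if (left2 || right2) {
        if (model$strand == "+")
          return(ann(if (left2) "splice_donor" else "splice_acceptor"))
        else
          return(ann(if (right2) "splice_donor" else "splice_acceptor"))
      }
    }
  }
  cds_pos <- .cds_positions(model)
  i0 <- match(pos, cds_pos)
  if (!is.na(i0)) {
    codon_idx <- (i0 - 1L) %/% 3L
    offset <- (i0 - 1L) %% 3L
    cpos <- cds_pos[codon_idx * 3L + 1:3]
    if (anyNA(cpos)) return(ann("missense"))  # trailing partial codon
    ref_codon <- paste0(vapply(cpos, function(p) .tx_base(model, p), ""))
    ref_codon <- paste(ref_codon, collapse = "")
    alt_tx <- if (model$strand == "-") unname(.COMPLEMENT[alt]) else alt
    alt_codon <- ref_codon
    substr(alt_codon, offset + 1L, offset + 1L) <- alt_tx
    aa_ref <- .codon_aa(ref_codon)
    aa_alt <- .codon_aa(alt_codon)
    cls <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "stop_gain"
      else if (aa_ref == "*") "stop_loss"
      else "missense"
    return(ann(cls))
  }
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (in_exon) return(ann("UTR"))
  if (pos >= gene_start && pos <= gene_end) return(ann("intron"))
  w <- model$promoter_bp
  in_prom <- if (model$strand == "+")
    pos >= gene_start - w && pos <= gene_start - 1
  else
    pos >= gene_end + 1 && pos <= gene_end + w
  if (in_prom) return(ann("promoter"))
  ann("intergenic")
}

#' Genes overlapping a genomic interval
#'
#' Any-overlap rule on 1-based inclusive coordinates: a gene whose span
#' touches the interval boundary is included.
#'
#' @param models list of [gene_model()] objects.
#' @param chrom,start,end query interval.
#' @return character vector of gene ids in positional order.
#' @export
genes_in_interval <- function(models, chrom, start, end) {
  chroms <- vapply(models, function(m) m$chrom, "")
  if (!any(chroms == chrom)) stop("unknown chromosome ", chrom)
  spans <- do.call(rbind, lapply(models, function(m)
    data.frame(id = m$id, chrom = m$chrom, start = min(m$exons$start),
               end = max(m$exons$end), stringsAsFactors = FALSE)))
  spans <- spans[spans$chrom == chrom, , drop = FALSE]
  q <- IRanges::IRanges(start = start, end = end)
  s <- IRanges::IRanges(start = spans$start, end = spans$end)
  ov <- IRanges::overlapsAny(s, q)
  spans <- spans[ov, , drop = FALSE]
  spans$id[order(spans$start)]
}

#' Filter genes by expression level and parental fold change
#'
#' A gene is removed as low-expression only when its FPKM is below
#' `min_fpkm` in every tissue for both parents. The differential-expression
#' tissue count is the number of tissues where the parental FPKM ratio
#' (larger over smaller, with an epsilon floor of 0.01 on the denominator
#' to handle zeros) exceeds `fold`. Retained genes must further show at
#' least `min_tissues` differential tissues.
#'
#' @param expr data.frame with columns `gene`, `tissue`, `parent`
#'   (two levels: donor and recurrent), `fpkm`.
#' @param min_fpkm,fold,min_tissues thresholds (defaults 2.0, 2.0, 1).
#' @param eps denominator floor for the fold ratio.
#' @return data.frame (gene, max_fpkm, de_tissues, removed_low_expression,
#'   retained).
#' @export
expression_filter <- function(expr, min_fpkm = 2.0, fold = 2.0,
                              min_tissues = 1L, eps = 0.01) {
  stopifnot(all(c("gene", "tissue", "parent", "fpkm") %in% names(expr)))
  parents <- unique(expr$parent)
  if (length(parents) != 2L) stop("both parents must be present")
  rows <- lapply(split(expr, expr$gene), function(d) {
    w <- stats::reshape(d[, c("gene", "tissue", "parent", "fpkm")],
                        idvar = "tissue", timevar = "parent",
                        direction = "wide", drop = "gene")
    p1 <- w[[paste0("fpkm.", parents[1])]]
    p2 <- w[[paste0("fpkm.", parents[2])]]
    ok <- !is.na(p1) & !is.na(p2)
    if (!all(ok)) message("gene ", d$gene[1], ": ", sum(!ok),
                          " tissue(s) missing a parent, skipped")
    p1 <- p1[ok]; p2 <- p2[ok]
    ratio <- pmax(p1, p2) / pmax(pmin(p1, p2), eps)
    de <- sum(ratio > fold)
    low <- all(c(p1, p2) < min_fpkm)
    data.frame(gene = d$gene[1], max_fpkm = max(c(p1, p2)),
               de_tissues = de, removed_low_expression = low,
               retained = !low && de >= min_tissues,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Rank candidate genes in an interval by variant impact and expression
#'
#' The ranking key is (carries an impactful variant, differential-tissue
#' count, maximum FPKM), descending and lexicographic, with ties broken by
#' gene id. Impactful means any variant of class stop_gain, stop_loss,
#' missense, splice_acceptor or splice_donor, or at least
#' `min_promoter_snps` promoter variants.
#'
#' @param genes character vector of gene ids in the interval.
#' @param expr_flags an [expression_filter()] result covering these genes.
#' @param effects data.frame of classified variants (columns `gene`,
#'   `class`), e.g. rows from [classify_variant_effect()].
#' @param min_promoter_snps promoter-variant count that counts as
#'   impactful on its own (default 3).
#' @return data.frame (gene, retained, impactful, de_tissues, max_fpkm,
#'   classes, rank) sorted by rank; removed genes carry rank NA.
#' @export
rank_candidates <- function(genes, expr_flags, effects,
                            min_promoter_snps = 3L) {
  impact_classes <- c("stop_gain", "stop_loss", "missense",
                      "splice_acceptor", "splice_donor")
  rows <- lapply(genes, function(g) {
    fl <- expr_flags[expr_flags$gene == g, , drop = FALSE]
    ef <- effects[effects$gene == g, , drop = FALSE]
    n_prom <- sum(ef$class == "promoter")
    imp <- any(ef$class %in% impact_classes) || n_prom >= min_promoter_snps
    data.frame(gene = g,
               retained = if (nrow(fl)) fl$retained else FALSE,
               impactful = imp,
               de_tissues = if (nrow(fl)) fl$de_tissues else 0L,
               max_fpkm = if (nrow(fl)) fl$max_fpkm else 0,
               classes = paste(sort(unique(ef$class)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(!out$retained, !out$impactful, -out$de_tissues,
               -out$max_fpkm, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- ifelse(out$retained, cumsum(out$retained), NA_integer_)
  rownames(out) <- NULL
  out
}
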