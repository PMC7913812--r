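#' Write a genotype matrix as a minimal VCF
#'
#' One sample column per line; GT-only FORMAT plus a per-site INFO `DP`
#' carrying the mean depth. Codes 0/1/2/NA map to `0/0`, `0/1`, `1/1`,
#' `./.`; the donor allele is ALT.
#'
#' @param gm a [genotype_matrix()]; `ref`/`alt` site columns are used when
#'   present (defaulting to A/T).
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_min <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  if (is.null(s$ref)) s$ref <- "A"
  if (is.null(s$alt)) s$alt <- "T"
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(s), nrow(gm$calls))
  idx <- !is.na(t(gm$calls))
  gt[idx] <- gt_map[t(gm$calls)[idx] + 1L]
  qual <- ifelse(is.finite(s$qual), formatC(s$qual, format = "g"), ".")
  dp <- ifelse(is.finite(s$mean_dp),
               paste0("DP=", formatC(s$mean_dp, format = "g")), ".")
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, qual, "PASS", dp, "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=csslqtl",
              "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean depth\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(gm$calls)),
                    collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF into a genotype matrix
#'
#' Biallelic SNP records only; multiallelic and indel records are skipped
#' with a count message. GT `0/0`, `0/1` (or `1/0`), `1/1` and `./.` map to
#' codes 0, 1, 2 and NA; phased separators are accepted. QUAL and INFO
#' `DP` populate the site metadata.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param chrom_lengths optional named vector for downstream segment
#'   inference.
#' @return a [genotype_matrix()].
#' @export
read_vcf_min <- function(path, chrom_lengths = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", v@gt[1, "FORMAT"]))
    stop("VCF lacks a GT field")
  fix <- vcfR::getFIX(v)
  keep <- vcfR::is.biallelic(v) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  skipped <- sum(!keep)
  if (skipped) message(skipped, " non-biallelic-SNP record(s) skipped")
  v <- v[keep, ]
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gsub_gt <- gsub("\\|", "/", gt)
  code[gsub_gt == "0/0"] <- 0L
  code[gsub_gt %in% c("0/1", "1/0")] <- 1L
  code[gsub_gt == "1/1"] <- 2L
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]),
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                      mean_dp = dp,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  sites$qual[is.na(sites$qual)] <- Inf
  sites$mean_dp[is.na(sites$mean_dp)] <- Inf
  genotype_matrix(sites, t(code), chrom_lengths = chrom_lengths)
}

#' Write segments as BED (0-based half-open)
#'
#' Columns chrom, start, end, name (line id), score (0), strand (`.`),
#' with origin appended as a seventh column. The 1-based inclusive start is
#' converted by subtracting 1; the end is kept.
#'
#' @param segments data.frame (line, chrom, start, end, origin).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  if (any(segments$start < 1)) stop("coordinate underflow")
  out <- data.frame(chrom = segments$chrom,
                    start = as.integer(segments$start) - 1L,
                    end = as.integer(segments$end),
                    name = segments$line, score = 0L, strand = ".",
                    origin = segments$origin)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features for each single-transcript
#' model via rtracklayer.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_min <- function(models, path) {
  feats <- lapply(models, function(m) {
    span_s <- min(m$exons$start); span_e <- max(m$exons$end)
    # GFF3 phase: bases to skip to the next codon start, in transcription
    # order along the CDS pieces
    cds <- m$cds[if (m$strand == "-") rev(seq_len(nrow(m$cds)))
                 else seq_len(nrow(m$cds)), , drop = FALSE]
    before <- cumsum(c(0, utils::head(cds$end - cds$start + 1, -1)))
    cds$phase <- (3L - before %% 3L) %% 3L
    rbind(
      data.frame(chrom = m$chrom, start = span_s, end = span_e,
                 type = "gene", ID = m$id, Parent = NA_character_,
                 phase = NA_integer_),
      data.frame(chrom = m$chrom, start = span_s, end = span_e,
                 type = "mRNA", ID = paste0(m$id, ".1"), Parent = m$id,
                 phase = NA_integer_),
      data.frame(chrom = m$chrom, start = m$exons$start, end = m$exons$end,
                 type = "exon", ID = NA_character_,
                 Parent = paste0(m$id, ".1"), phase = NA_integer_),
      data.frame(chrom = m$chrom, start = cds$start, end = cds$end,
                 type = "CDS", ID = NA_character_,
                 Parent = paste0(m$id, ".1"), phase = cds$phase))
  })
  strands <- rep(vapply(models, function(m) m$strand, ""),
                 vapply(feats, nrow, 0L))
  tab <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = strands, type = tab$type, ID = tab$ID, Parent = tab$Parent,
    phase = tab$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 subset into gene models
#'
#' Expects gene/mRNA/exon/CDS features with ID/Parent attributes and one
#' transcript per gene. Gene-local sequence is taken from an optional
#' FASTA of full chromosomes (or promoter-padded gene regions named by
#' chromosome).
#'
#' @param path GFF3 file.
#' @param fasta optional FASTA path; without it the models carry an empty
#'   sequence and only positional classification is possible.
#' @param promoter_bp promoter window for the models.
#' @return list of [gene_model()] objects.
#' @export
read_gff3_min <- function(path, fasta = NULL, promoter_bp = 2000L) {
  gr <- rtracklayer::import(path, format = "gff3")
  seqs <- if (!is.null(fasta)) Biostrings::readDNAStringSet(fasta) else NULL
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*", "", names(seqs))
  genes <- gr[gr$type == "gene"]
  out <- lapply(seq_along(genes), function(i) {
    gid <- genes$ID[i]
    mrna <- gr[gr$type == "mRNA" & vapply(gr$Parent, function(p)
      gid %in% p, logical(1))]
    if (!length(mrna)) stop("gene ", gid, " has no mRNA")
    tid <- mrna$ID[1]
    child <- gr[vapply(gr$Parent, function(p) tid %in% p, logical(1))]
    ex <- child[child$type == "exon"]
    cd <- child[child$type == "CDS"]
    chrom <- as.character(GenomicRanges::seqnames(genes))[i]
    if (!is.null(seqs)) {
      if (!chrom %in% names(seqs)) stop("unknown chromosome ", chrom)
      seq_start <- max(1L, GenomicRanges::start(genes)[i] - promoter_bp -
                         200L)
      seq_end <- min(Biostrings::width(seqs[[chrom]]),
                     GenomicRanges::end(genes)[i] + 200L)
      sq <- as.character(Biostrings::subseq(seqs[[chrom]], seq_start,
                                            seq_end))
    } else {
      seq_start <- GenomicRanges::start(genes)[i]
      sq <- ""
    }
    gene_model(
      id = gid, chrom = chrom,
      strand = as.character(GenomicRanges::strand(genes))[i],
      exons = data.frame(start = GenomicRanges::start(ex),
                         end = GenomicRanges::end(ex)),
      cds = data.frame(start = GenomicRanges::start(cd),
                       end = GenomicRanges::end(cd)),
      seq = sq, seq_start = seq_start, promoter_bp = promoter_bp)
  })
  names(out) <- genes$ID
  out
}

#' Simple TSV helpers
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_tsv`: `path` invisibly; `read_tsv_min`: a data.frame
#'   (an empty file with a header yields an empty data.frame).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv_min <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a parental variant table as a minimal VCF
#'
#' One row per SNP with the donor allele as ALT and the planted or
#' classified effect class carried in the INFO field as `CLASS=`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   and optionally `class` (e.g. from
#'   [simulate_expression_and_variants()] or rows of
#'   [classify_variant_effect()]).
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  info <- if (!is.null(variants$class))
    paste0("CLASS=", variants$class) else "."
  ord <- order(variants$chrom, variants$pos)
  body <- paste(variants$chrom[ord], variants$pos[ord], ".",
                variants$ref[ord], variants$alt[ord], ".", "PASS",
                info[ord], sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=csslqtl",
              paste0("##INFO=<ID=CLASS,Number=1,Type=String,",
                     "Description=\"Variant effect class\">"),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO"), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
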