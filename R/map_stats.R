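#' Physical length of a 1-based inclusive interval
#'
#' Adjacent segments and markers share their boundary coordinate, so the
#' physical length of an interval is `end - start` bp (per-chromosome
#' marker lengths then telescope to the chromosome length). This is the
#' convention under which the published interval lengths (e.g. a 277,544 bp
#' block printed as 277.5 kb) are reproduced.
#'
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @return numeric length in bp.
#' @export
segment_length <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  end - start
}

#' Percentage helper
#'
#' @param n,total numerator and denominator; `total > 0`.
#' @return `n / total * 100`.
#' @export
percentage <- function(n, total) {
  if (any(total <= 0)) stop("total must be positive")
  n / total * 100
}

#' Per-line and per-chromosome statistics of a SNPLDB map
#'
#' Recovery percentage is the summed length of recurrent-coded markers over
#' the genome length; donor segments are maximal runs of donor-coded
#' markers per line and chromosome; chromosome coverage is the fraction of
#' the chromosome carried as donor by at least one line. Heterozygous
#' markers are counted separately and excluded from donor-segment
#' statistics.
#'
#' @param map a [build_snpldb_map()] result.
#' @return object of class `map_stats`: list with `per_line` (line,
#'   recovery_pct, donor_pct, het_pct, nocall_pct, n_donor_segments,
#'   n_het_segments), `per_chrom` (chrom, n_markers, n_donor_segments,
#'   avg_donor_length_mb, coverage_pct), `segment_lengths` (bp, donor
#'   only) and `totals`.
#' @export
compute_map_stats <- function(map) {
  stopifnot(inherits(map, "physical_map"))
  if (sum(map$chrom_lengths) <= 0) stop("zero-length genome")
  mlen <- segment_length(map$markers$start, map$markers$end)
  # per-line composition percentages are denominated by the marker-covered
  # span, so recovery + donor + het + no-call is exactly 100
  genome_len <- sum(mlen)
  lines <- rownames(map$geno)
  chrom_of <- map$markers$chrom
  chroms <- names(map$chrom_lengths)

  code_len_pct <- function(code) {
    m <- ifelse(is.na(map$geno), FALSE, map$geno == code)
    as.numeric(m %*% mlen) / genome_len * 100
  }
  nocall_pct <- as.numeric(is.na(map$geno) %*% mlen) / genome_len * 100

  run_count <- function(v, code) {
    r <- rle(!is.na(v) & v == code)
    sum(r$values)
  }
  seg_counts <- matrix(0L, length(lines), length(chroms),
                       dimnames = list(lines, chroms))
  het_counts <- seg_counts
  seg_lengths <- list()
  for (ch in chroms) {
    j <- which(chrom_of == ch)
    for (ln in lines) {
      v <- map$geno[ln, j]
      seg_counts[ln, ch] <- run_count(v, 2L)
      het_counts[ln, ch] <- run_count(v, 1L)
      if (seg_counts[ln, ch] > 0L) {
        r <- rle(!is.na(v) & v == 2L)
        ends <- cumsum(r$lengths)
        starts <- c(1L, utils::head(ends, -1L) + 1L)
        w <- which(r$values)
        seg_lengths[[length(seg_lengths) + 1L]] <- vapply(w, function(k)
          segment_length(map$markers$start[j[starts[k]]],
                         map$markers$end[j[ends[k]]]), 0)
      }
    }
  }
  per_line <- data.frame(
    line = lines,
    recovery_pct = code_len_pct(0L),
    donor_pct = code_len_pct(2L),
    het_pct = code_len_pct(1L),
    nocall_pct = nocall_pct,
    n_donor_segments = rowSums(seg_counts),
    n_het_segments = rowSums(het_counts),
    stringsAsFactors = FALSE)

  per_chrom <- do.call(rbind, lapply(chroms, function(ch) {
    j <- which(chrom_of == ch)
    donor_any <- colSums(!is.na(t(map$geno[, j, drop = FALSE])) &
                           t(map$geno[, j, drop = FALSE]) == 2L) > 0
    cov <- sum(mlen[j][donor_any]) / map$chrom_lengths[[ch]] * 100
    nseg <- sum(seg_counts[, ch])
    data.frame(chrom = ch, n_markers = length(j), n_donor_segments = nseg,
               coverage_pct = cov, stringsAsFactors = FALSE)
  }))
  all_lens <- unlist(seg_lengths)
  totals <- list(
    n_markers = nrow(map$markers),
    n_donor_segments = sum(seg_counts),
    mean_recovery_pct = mean(per_line$recovery_pct),
    mean_segments_per_line = mean(per_line$n_donor_segments),
    avg_donor_length_mb = if (length(all_lens)) mean(all_lens) / 1e6 else 0,
    coverage_pct = sum(vapply(chroms, function(ch) {
      j <- which(chrom_of == ch)
      donor_any <- apply(map$geno[, j, drop = FALSE], 2,
                         function(v) any(!is.na(v) & v == 2L))
      sum(mlen[j][donor_any])
    }, 0)) / genome_len * 100)
  structure(list(per_line = per_line, per_chrom = per_chrom,
                 segment_lengths = all_lens, totals = totals),
            class = "map_stats")
}

#' @export
print.map_stats <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("map_stats: %d markers, %d donor segments, mean ",
                     "recovery %.2f%%, %.1f segments/line, avg length %.2f Mb\n"),
              t$n_markers, t$n_donor_segments, t$mean_recovery_pct,
              t$mean_segments_per_line, t$avg_donor_length_mb))
  invisible(x)
}

# Overlap length of 1-based interval pairs under the shared-boundary
# convention (positive only when interiors intersect).
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Compare a coarse and a fine segment map line by line
#'
#' Reports, per chromosome: `new_segments` — donor segments present in the
#' fine map of a line with no overlap with any coarse-map donor segment of
#' the same line; `broken_sites` — for each coarse donor segment
#' overlapping k >= 2 fine donor segments of the same line, the k - 1 extra
#' pieces; and `misjudged_pct` — the fraction of coarse-map donor territory
#' not confirmed donor in the fine map.
#'
#' @param coarse,fine segment data.frames (line, chrom, start, end, origin)
#'   from [infer_line_segments()] (`$segments`) or [true_segments()]; the
#'   two maps must cover the same lines.
#' @return data.frame per chromosome plus a `"totals"` row.
#' @export
compare_maps <- function(coarse, fine) {
  if (inherits(coarse, "segment_set")) coarse <- coarse$segments
  if (inherits(fine, "segment_set")) fine <- fine$segments
  if (!setequal(unique(coarse$line), unique(fine$line)))
    stop("line sets differ between maps")
  cd <- coarse[coarse$origin == "donor", , drop = FALSE]
  fd <- fine[fine$origin == "donor", , drop = FALSE]
  chroms <- sort(unique(c(cd$chrom, fd$chrom)))
  rows <- lapply(chroms, function(ch) {
    cc <- cd[cd$chrom == ch, , drop = FALSE]
    ff <- fd[fd$chrom == ch, , drop = FALSE]
    new_segs <- 0L; broken <- 0L
    misjudged <- 0; coarse_len <- 0
    for (ln in unique(c(cc$line, ff$line))) {
      c1 <- cc[cc$line == ln, , drop = FALSE]
      f1 <- ff[ff$line == ln, , drop = FALSE]
      if (nrow(f1))
        new_segs <- new_segs + sum(vapply(seq_len(nrow(f1)), function(i)
          !nrow(c1) || all(.overlap_len(f1$start[i], f1$end[i],
                                        c1$start, c1$end) == 0),
          logical(1)))
      if (nrow(c1)) {
        coarse_len <- coarse_len + sum(segment_length(c1$start, c1$end))
        for (i in seq_len(nrow(c1))) {
          ov <- if (nrow(f1))
            .overlap_len(c1$start[i], c1$end[i], f1$start, f1$end)
          else numeric(0)
          k <- sum(ov > 0)
          if (k >= 2L) broken <- broken + (k - 1L)
          misjudged <- misjudged +
            segment_length(c1$start[i], c1$end[i]) - sum(ov)
        }
      }
    }
    data.frame(chrom = ch, new_segments = new_segs, broken_sites = broken,
               misjudged_pct = if (coarse_len > 0)
                 misjudged / coarse_len * 100 else 0,
               coarse_donor_bp = coarse_len, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot_mis <- sum(out$misjudged_pct * out$coarse_donor_bp) / 100
  totals <- data.frame(chrom = "totals",
                       new_segments = sum(out$new_segments),
                       broken_sites = sum(out$broken_sites),
                       misjudged_pct = if (sum(out$coarse_donor_bp) > 0)
                         tot_mis / sum(out$coarse_donor_bp) * 100 else 0,
                       coarse_donor_bp = sum(out$coarse_donor_bp),
                       stringsAsFactors = FALSE)
  rbind(out, totals)
}
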