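# Shared run -> segment conversion. `codes` are per-site genotype codes in
# site order on one chromosome (may contain NA only if the caller removed
# them already), `pos` the site positions, `L` the chromosome length.
# Convention: 1-based inclusive coordinates; the breakpoint between two
# adjacent runs is the floor of the inter-site midpoint; adjacent segments
# share that boundary coordinate, so segment length is end - start and the
# per-chromosome lengths telescope to L - 1. First/last segments are
# extended to the chromosome ends ("including the flanking parts").
.runs_to_segments <- function(codes, pos, L) {
  lab <- c(`0` = "recurrent", `1` = "het", `2` = "donor")
  if (length(codes) == 0L || all(is.na(codes)))
    return(data.frame(start = 1, end = as.numeric(L), origin = "no_call",
                      n_sites = 0L, stringsAsFactors = FALSE))
  keep <- !is.na(codes)
  codes <- codes[keep]; pos <- pos[keep]
  r <- rle(codes)
  k <- length(r$lengths)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
  if (k == 1L) {
    bps <- numeric(0)
  } else {
    bps <- floor((pos[ends_idx[-k]] + pos[starts_idx[-1L]]) / 2)
  }
  data.frame(start = c(1, bps), end = c(bps, as.numeric(L)),
             origin = unname(lab[as.character(r$values)]),
             n_sites = r$lengths, stringsAsFactors = FALSE)
}

#' QC-filter SNP sites of a genotype matrix
#'
#' Retains sites with `QUAL >= min_qual`, a missing-call fraction
#' `<= max_missing` and mean depth `>= min_mean_dp` (the defaults mirror a
#' standard low-coverage resequencing filter: minQ 30, max-missing 0.2,
#' min-mean DP 1.5). Site order is preserved; filtering never adds sites.
#'
#' @param gm a [genotype_matrix()].
#' @param min_qual,max_missing,min_mean_dp finite thresholds.
#' @return the filtered [genotype_matrix()].
#' @export
qc_filter_snps <- function(gm, min_qual = 30, max_missing = 0.2,
                           min_mean_dp = 1.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(is.finite(c(min_qual, max_missing, min_mean_dp))))
    stop("thresholds must be finite")
  if (ncol(gm$calls) == 0L) stop("empty genotype matrix")
  miss <- colMeans(is.na(gm$calls))
  keep <- gm$sites$qual >= min_qual & miss <= max_missing &
    gm$sites$mean_dp >= min_mean_dp
  keep[is.na(keep)] <- FALSE
  out <- gm
  out$sites <- gm$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$calls <- gm$calls[, keep, drop = FALSE]
  out
}

# Sliding majority vote over a centered window of `window` non-missing
# sites; ties keep the observed call. Edge windows shrink symmetrically.
.smooth_majority <- function(v, window) {
  n <- length(v)
  if (window <= 1L || n < 2L) return(v)
  h <- (window - 1L) %/% 2L
  counts <- vapply(0:2, function(k) cumsum(c(0L, v == k)), numeric(n + 1L))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  cnt <- counts[hi + 1L, , drop = FALSE] - counts[lo, , drop = FALSE]
  mx <- pmax(cnt[, 1L], cnt[, 2L], cnt[, 3L])
  ties <- (cnt[, 1L] == mx) + (cnt[, 2L] == mx) + (cnt[, 3L] == mx) > 1L
  sm <- max.col(cnt, ties.method = "first") - 1L
  sm[ties] <- v[ties]
  sm
}

# Absorb runs with fewer than min_sites supporting sites into the flanking
# run with more supporting sites (tie -> left); leftmost short run first.
.absorb_runs <- function(vals, lens, min_sites) {
  repeat {
    k <- length(vals)
    if (k <= 1L) break
    short <- which(lens < min_sites)
    if (!length(short)) break
    i <- short[1L]
    left <- if (i > 1L) lens[i - 1L] else -Inf
    right <- if (i < k) lens[i + 1L] else -Inf
    vals[i] <- if (left >= right) vals[i - 1L] else vals[i + 1L]
    # merge adjacent equal runs
    r <- rle(vals)
    grp <- rep(seq_along(r$lengths), r$lengths)
    lens <- as.integer(tapply(lens, grp, sum))
    vals <- r$values
  }
  list(vals = vals, lens = lens)
}

#' Infer donor/recurrent segments and breakpoints for every line
#'
#' Per line and chromosome, genotype calls are smoothed by majority vote in
#' a centered sliding window of `window` non-missing sites (ties leave the
#' call unchanged), runs are collapsed, and runs supported by fewer than
#' `min_sites` sites are absorbed into the flanking run with more support
#' (tie goes left). The breakpoint between two runs is placed at the
#' floor-rounded midpoint of the flanking sites; the first and last
#' segments are extended to the chromosome ends. A chromosome with no
#' non-missing call is reported as a single `no_call` segment.
#'
#' @param gm a [genotype_matrix()] with `chrom_lengths`.
#' @param window odd window size in non-missing sites (1 = no smoothing).
#' @param min_sites minimum supporting sites per retained run.
#' @return object of class `segment_set`: list with `segments` (line,
#'   chrom, start, end, origin, n_sites) and `breakpoints` (line, chrom,
#'   pos, left_origin, right_origin); line and chromosome sets as in `gm`.
#' @export
infer_line_segments <- function(gm, window = 15L, min_sites = 5L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$chrom_lengths)) stop("genotype matrix lacks chrom_lengths")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  chroms <- unique(gm$sites$chrom)
  idx_by_chrom <- split(seq_len(nrow(gm$sites)), gm$sites$chrom)[chroms]
  segs <- vector("list", 0L)
  for (ch in chroms) {
    idx <- idx_by_chrom[[ch]]
    pos_all <- gm$sites$pos[idx]
    L <- gm$chrom_lengths[[ch]]
    for (ln in rownames(gm$calls)) {
      v <- gm$calls[ln, idx]
      keep <- !is.na(v)
      if (!any(keep)) {
        segs[[length(segs) + 1L]] <- data.frame(
          line = ln, chrom = ch, start = 1, end = as.numeric(L),
          origin = "no_call", n_sites = 0L, stringsAsFactors = FALSE)
        next
      }
      vv <- v[keep]; pp <- pos_all[keep]
      sm <- .smooth_majority(vv, window)
      r <- rle(sm)
      ab <- .absorb_runs(r$values, r$lengths, min_sites)
      codes <- rep(ab$vals, ab$lens)
      segs[[length(segs) + 1L]] <-
        cbind(line = ln, chrom = ch, .runs_to_segments(codes, pp, L))
    }
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  bp <- segments[segments$start > 1, c("line", "chrom", "start", "origin")]
  if (nrow(bp)) {
    left <- segments$origin[match(paste(bp$line, bp$chrom, bp$start),
                                  paste(segments$line, segments$chrom,
                                        segments$end))]
    breakpoints <- data.frame(line = bp$line, chrom = bp$chrom,
                              pos = bp$start, left_origin = left,
                              right_origin = bp$origin,
                              stringsAsFactors = FALSE)
  } else {
    breakpoints <- data.frame(line = character(), chrom = character(),
                              pos = numeric(), left_origin = character(),
                              right_origin = character())
  }
  structure(list(segments = segments, breakpoints = breakpoints,
                 lines = rownames(gm$calls),
                 chrom_lengths = gm$chrom_lengths,
                 window = window, min_sites = min_sites),
            class = "segment_set")
}

#' Build the SNPLDB marker map from per-line segments
#'
#' The union of all lines' breakpoints partitions each chromosome into
#' blocks within which no line recombines; adjacent blocks whose per-line
#' code vectors are identical across the whole population are merged.
#' Each resulting block is one SNPLDB marker, named `<chrom>_LDB_<k>` with
#' k 1-based in positional order per chromosome.
#'
#' @param segset a `segment_set` from [infer_line_segments()], or a
#'   segments data.frame as returned by [true_segments()] (then
#'   `chrom_lengths` and `lines` must be supplied).
#' @param chrom_lengths,lines overrides when `segset` is a plain data.frame.
#' @return object of class `physical_map`: list with `markers` (id, chrom,
#'   start, end), `geno` (lines x markers code matrix: 0 recurrent, 1 het,
#'   2 donor, NA no-call) and `chrom_lengths`.
#' @export
build_snpldb_map <- function(segset, chrom_lengths = NULL, lines = NULL) {
  if (inherits(segset, "segment_set")) {
    segments <- segset$segments
    chrom_lengths <- segset$chrom_lengths
    lines <- segset$lines
  } else {
    segments <- segset
    if (is.null(chrom_lengths) || is.null(lines))
      stop("chrom_lengths and lines are required with a plain segment table")
  }
  code_of <- c(recurrent = 0L, het = 1L, donor = 2L, no_call = NA_integer_)
  chroms <- names(chrom_lengths)
  missing_ch <- setdiff(unique(segments$chrom), chroms)
  if (length(missing_ch))
    stop("segments reference chromosomes without lengths: ",
         paste(missing_ch, collapse = ", "))
  marker_list <- list()
  geno_list <- list()
  for (ch in chroms) {
    L <- chrom_lengths[[ch]]
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (!all(lines %in% s$line))
      stop("inconsistent line sets across chromosomes")
    bps <- sort(unique(s$start[s$start > 1]))
    starts <- c(1, bps)
    ends <- c(bps, as.numeric(L))
    mid <- (starts + ends) / 2
    # per line, assign each block the origin of the covering segment
    codes <- matrix(NA_integer_, length(lines), length(starts),
                    dimnames = list(lines, NULL))
    for (ln in lines) {
      sl <- s[s$line == ln, , drop = FALSE]
      sl <- sl[order(sl$start), , drop = FALSE]
      j <- findInterval(mid, sl$start)
      codes[ln, ] <- code_of[sl$origin[j]]
    }
    # merge adjacent blocks with identical population-wide code vectors
    if (ncol(codes) > 1L) {
      same <- vapply(seq_len(ncol(codes) - 1L), function(j)
        identical(codes[, j], codes[, j + 1L]), logical(1))
      grp <- cumsum(c(TRUE, !same))
    } else grp <- 1L
    ug <- unique(grp)
    m_start <- vapply(ug, function(g) min(starts[grp == g]), 0)
    m_end <- vapply(ug, function(g) max(ends[grp == g]), 0)
    m_codes <- codes[, !duplicated(grp), drop = FALSE]
    ids <- sprintf("%s_LDB_%d", ch, seq_along(ug))
    colnames(m_codes) <- ids
    marker_list[[ch]] <- data.frame(id = ids, chrom = ch, start = m_start,
                                    end = m_end, stringsAsFactors = FALSE)
    geno_list[[ch]] <- m_codes
  }
  markers <- do.call(rbind, marker_list)
  rownames(markers) <- NULL
  structure(list(markers = markers,
                 geno = do.call(cbind, geno_list),
                 chrom_lengths = chrom_lengths),
            class = "physical_map")
}

#' @export
print.physical_map <- function(x, ...) {
  cat(sprintf("physical_map: %d lines x %d SNPLDB markers on %d chromosome(s)\n",
              nrow(x$geno), nrow(x$markers), length(x$chrom_lengths)))
  invisible(x)
}
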