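# Reference integrity: alignment-end binning (misassembly candidates) and
# binned coverage / copy-number profiling.

#' Count alignment ends in genomic bins
#'
#' Every alignment contributes two ends: `bin(start)` and `bin(end - 1)`
#' with `bin(p) = floor(p / bin_bp)` (100 bp bins by default). Misjoined
#' reference positions accumulate ends because reads cannot align across
#' them.
#'
#' @param alignments Interval table (`chrom`, `start`, `end`, 0-based
#'   half-open) on a single chromosome.
#' @param chrom_len Chromosome length in bp.
#' @param config A [pipeline_config()]; `aef_bin_bp` sets the bin size.
#' @return List of class `bin_counts`: `chrom`, `bin_bp`, `counts`.
#' @export
count_alignment_ends <- function(alignments, chrom_len,
                                 config = pipeline_config()) {
  al <- as.data.frame(alignments)
  if (nrow(al) && length(unique(al$chrom)) > 1)
    stop("alignments must lie on a single chromosome")
  if (nrow(al) && (any(al$start < 0) || any(al$end > chrom_len)))
    stop("alignment exceeds chromosome bounds")
  bin <- config$aef_bin_bp
  nb <- as.integer(ceiling(chrom_len / bin))
  counts <- integer(nb)
  if (nrow(al)) {
    ends <- c(floor(al$start / bin), floor((al$end - 1) / bin)) + 1L
    tab <- tabulate(ends, nbins = nb)
    counts <- as.integer(tab)
  }
  structure(list(chrom = if (nrow(al)) al$chrom[1] else NA_character_,
                 bin_bp = bin, counts = counts, chrom_len = chrom_len),
            class = "bin_counts")
}

#' Call candidate misassembly regions from binned alignment ends
#'
#' Bins with at least `end_threshold` ends seed regions; seed bins whose
#' gap is smaller than `aef_group_dist_bp` (30 kbp) are merged by single
#' linkage. The default threshold is the 99.9th percentile of non-zero bin
#' counts (the published criterion is qualitative - "outstanding high
#' numbers" - so a scale-free default is used, overridable with an absolute
#' count).
#'
#' @param bins A [count_alignment_ends()] result.
#' @param end_threshold Absolute threshold; `NULL` for the percentile
#'   default.
#' @param config A [pipeline_config()].
#' @return data.frame of regions: `chrom`, `start`, `end` (bin-aligned),
#'   `total_ends`, `n_bins`, `max_bin_count`, sorted by decreasing
#'   `total_ends`.
#' @export
call_candidate_regions <- function(bins, end_threshold = NULL,
                                   config = pipeline_config()) {
  counts <- bins$counts
  if (is.null(end_threshold)) {
    nz <- counts[counts > 0]
    if (length(nz) == 0) return(.empty_regions())
    end_threshold <- as.numeric(quantile(nz, 0.999, names = FALSE))
  }
  if (end_threshold < 1) stop("end_threshold must be >= 1")
  seeds <- which(counts >= end_threshold)
  if (length(seeds) == 0) return(.empty_regions())
  bin <- bins$bin_bp
  # gap between consecutive seed bins in bp; merge when < grouping distance
  grp <- cumsum(c(0, ((seeds[-1] - seeds[-length(seeds)] - 1L) * bin) >=
                    config$aef_group_dist_bp))
  out <- do.call(rbind, lapply(split(seeds, grp), function(ss) {
    data.frame(chrom = bins$chrom,
               start = (min(ss) - 1L) * bin,
               end = max(ss) * bin,
               total_ends = sum(counts[ss]),
               n_bins = length(ss),
               max_bin_count = max(counts[ss]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_ends, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_regions <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             total_ends = numeric(), n_bins = integer(),
             max_bin_count = numeric(), stringsAsFactors = FALSE)
}

#' Binned read-depth profile
#'
#' Depth per bin = total aligned bases overlapping the bin divided by
#' `bin_bp`, so `sum(depth) * bin_bp` equals the total aligned bases.
#'
#' @param alignments Interval table on a single chromosome.
#' @param chrom_len Chromosome length in bp.
#' @param bin_bp Bin size (default 1000).
#' @return List of class `coverage_profile`: `chrom`, `bin_bp`, `depth`.
#' @export
coverage_profile <- function(alignments, chrom_len, bin_bp = 1000L) {
  al <- as.data.frame(alignments)
  if (nrow(al) && length(unique(al$chrom)) > 1)
    stop("alignments must lie on a single chromosome")
  d <- numeric(chrom_len + 1L)
  if (nrow(al)) {
    st <- pmax(0, al$start); en <- pmin(chrom_len, al$end)
    for (i in seq_len(nrow(al))) {
      d[st[i] + 1L] <- d[st[i] + 1L] + 1
      d[en[i] + 1L] <- d[en[i] + 1L] - 1
    }
  }
  cov <- cumsum(d)[seq_len(chrom_len)]
  nb <- as.integer(ceiling(chrom_len / bin_bp))
  grp <- rep(seq_len(nb), each = bin_bp, length.out = chrom_len)
  depth <- as.numeric(tapply(cov, grp, sum)) / bin_bp
  structure(list(chrom = if (nrow(al)) al$chrom[1] else NA_character_,
                 bin_bp = bin_bp, depth = depth, chrom_len = chrom_len),
            class = "coverage_profile")
}

#' Detect copy-number changes by run-length thresholding
#'
#' Maximal runs of bins whose depth relative to the genome median exceeds
#' `gain_fc` (or falls below `loss_fc`) and that span at least `min_len_bp`
#' are reported with their mean fold change.
#'
#' @param profile A [coverage_profile()].
#' @param min_len_bp Minimum run length (default 50 kbp).
#' @param gain_fc,loss_fc Fold-change thresholds (defaults 1.4 and 0.6).
#' @param genome_median Optional externally computed genome-wide median
#'   depth; defaults to the profile's own median.
#' @return data.frame of calls: `chrom`, `start`, `end`, `direction`,
#'   `fold_change`.
#' @export
detect_cnv <- function(profile, min_len_bp = 50000L, gain_fc = 1.4,
                       loss_fc = 0.6, genome_median = NULL) {
  if (length(profile$depth) < min_len_bp / profile$bin_bp)
    stop("profile shorter than the minimum call length")
  med <- genome_median %||% median(profile$depth)
  if (med <= 0) stop("median depth is zero; cannot normalize")
  fc <- profile$depth / med
  state <- ifelse(fc > gain_fc, "GAIN", ifelse(fc < loss_fc, "LOSS", "NEUTRAL"))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1) + 1L)
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] == "NEUTRAL") next
    len_bp <- r$lengths[i] * profile$bin_bp
    if (len_bp < min_len_bp) next
    sel <- seq.int(starts[i], ends[i])
    out[[length(out) + 1]] <- data.frame(
      chrom = profile$chrom,
      start = (starts[i] - 1L) * profile$bin_bp,
      end = min(ends[i] * profile$bin_bp, profile$chrom_len),
      direction = r$values[i],
      fold_change = mean(fc[sel]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), fold_change = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
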