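# T-DNA read detection: reference catalog, pipeline configuration,
# selection of insert-bearing reads, flank extraction and flank-read
# recruitment.

.CATEGORIES <- c("TDNA", "BVB", "NUCLEAR", "PLASTOME", "CHONDROME",
                 "AGROBACTERIUM")

#' Reference catalog of annotation targets
#'
#' Bundles the sequences the pipeline annotates against: T-DNA / binary
#' vector, nuclear chromosomes, plastome, chondrome and optionally the
#' agrobacterial genome, each tagged with exactly one category.
#'
#' @param records Named list of [seq_record()]s.
#' @param category Named character vector mapping every record id to one of
#'   `TDNA`, `BVB`, `NUCLEAR`, `PLASTOME`, `CHONDROME`, `AGROBACTERIUM`.
#' @param tdna_borders Optional named list: for each TDNA record id, a list
#'   with `lb` and `rb`, each a length-2 vector of 0-based half-open
#'   coordinates of the 25 bp border repeats on the vector sequence.
#' @return An object of class `reference_catalog`.
#' @export
reference_catalog <- function(records, category, tdna_borders = NULL) {
  ids <- vapply(records, function(r) r$id, character(1))
  names(records) <- ids
  if (is.null(names(category))) stop("category must be a named vector")
  if (!setequal(names(category), ids))
    stop("category must name every record exactly once")
  bad <- setdiff(unique(category), .CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  structure(list(records = records, category = category[ids],
                 tdna_borders = tdna_borders),
            class = "reference_catalog")
}

#' @export
print.reference_catalog <- function(x, ...) {
  tab <- table(x$category)
  cat(sprintf("<reference_catalog> %d records (%s)\n", length(x$records),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Record ids of a catalog category
#' @param catalog A [reference_catalog()].
#' @param categories Character vector of categories.
#' @return Character vector of record ids.
#' @export
catalog_ids <- function(catalog, categories) {
  names(catalog$category)[catalog$category %in% categories]
}

#' Pipeline configuration
#'
#' All numeric parameters of the workflow in one place. Defaults follow the
#' published procedure: 80% identity and E-value 1e-50 for T-DNA read
#' identification, a 10 bp permitted tiling overlap, 50 kbp flanks, a 1 kbp
#' floor for unannotated read parts, a 200/100 nt sliding quality window,
#' 100 bp alignment-end bins grouped below 30 kbp, and the E<=10 / word-size
#' 5 short-match filler re-search with 10-base extension. In a selected
#' segregating T2 family, two thirds of the chromosomes in the pool are
#' expected to carry the insertion.
#'
#' @param ... Named overrides of any default field.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tdna_min_identity = 0.80,
    tdna_max_evalue = 1e-50,
    min_aln_len = 50L,
    index_k = 12L,
    tile_max_overlap_bp = 10L,
    flank_extract_bp = 50000L,
    unannotated_min_bp = 1000L,
    qual_window_nt = 200L,
    qual_step_nt = 100L,
    low_q_threshold = 10,
    aef_bin_bp = 100L,
    aef_group_dist_bp = 30000L,
    filler_evalue = 10,
    filler_word_size = 5L,
    filler_extension_bp = 10L,
    junction_window_bp = 200L,
    junction_stage1_evalue = 1e-5,
    merge_window = 1000L,
    lb_slack = 3L,
    min_depth = 10L,
    expected_insert_chromosome_fraction = 2 / 3,
    rng_seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(unlist(cfg[num]) <= 0))
    stop("all numeric configuration values must be positive")
  if (cfg$expected_insert_chromosome_fraction > 1)
    stop("expected_insert_chromosome_fraction must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

# Attach catalog categories to a hit table.
.categorize_hits <- function(hits, catalog) {
  if (nrow(hits) == 0L) { hits$category <- character(0); return(hits) }
  hits$category <- unname(catalog$category[hits$subject_id])
  hits
}

#' Select reads containing T-DNA or vector-backbone sequence
#'
#' A read is selected iff it has at least one local alignment to a TDNA or
#' BVB catalog record passing the identity, E-value and length thresholds.
#' Backbone (BVB) hits count toward selection: BVB-only junction reads are
#' informative for array structure.
#'
#' @param reads Named list of [seq_record()]s.
#' @param catalog A [reference_catalog()] with at least one TDNA record.
#' @param config A [pipeline_config()].
#' @param scoring A [scoring_scheme()].
#' @return Named list mapping selected read ids to their TDNA/BVB hit
#'   tables.
#' @export
select_tdna_reads <- function(reads, catalog, config = pipeline_config(),
                              scoring = scoring_scheme()) {
  tdna_ids <- catalog_ids(catalog, c("TDNA", "BVB"))
  if (!any(catalog$category == "TDNA"))
    stop("catalog must contain at least one TDNA record")
  sub <- catalog$records[tdna_ids]
  idx <- build_index(sub, k = config$index_k)
  out <- list()
  for (r in reads) {
    if (nchar(r$bases) < config$index_k) next
    h <- find_local_hits(r, idx, scoring,
                         min_identity = config$tdna_min_identity,
                         max_evalue = config$tdna_max_evalue,
                         min_aln_len = config$min_aln_len)
    if (nrow(h) > 0L) out[[r$id]] <- .categorize_hits(h, catalog)
  }
  out
}

#' Extract genomic flanks around an insertion anchor
#'
#' Returns the up- and downstream reference sequence around an anchor
#' interval, by default 50 kbp on each side, truncated at contig ends (the
#' truncation is recorded in the record description).
#'
#' @param reference A [reference_catalog()] (nuclear records are used) or a
#'   named list of [seq_record()]s.
#' @param anchor A list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param config A [pipeline_config()]; `flank_extract_bp` sets the size.
#' @return List with `upstream` and `downstream` [seq_record()]s.
#' @export
extract_flanks <- function(reference, anchor, config = pipeline_config()) {
  recs <- if (inherits(reference, "reference_catalog")) reference$records else reference
  chrom <- as.character(anchor$chrom)
  if (inherits(reference, "reference_catalog") &&
      !identical(unname(reference$category[chrom]), "NUCLEAR"))
    stop(sprintf("anchor sequence '%s' is not a nuclear record", chrom))
  rec <- recs[[chrom]]
  if (is.null(rec)) stop(sprintf("unknown anchor sequence '%s'", chrom))
  n <- nchar(rec$bases)
  w <- config$flank_extract_bp
  a <- as.integer(anchor$start); b <- as.integer(anchor$end)
  if (a < 0 || b > n) stop("anchor outside sequence bounds")
  us <- max(0L, a - w)
  de <- min(n, b + w)
  up_desc <- sprintf("upstream flank %s:%d-%d%s", chrom, us, a,
                     if (a - us < w) " (truncated at contig end)" else "")
  dn_desc <- sprintf("downstream flank %s:%d-%d%s", chrom, b, de,
                     if (de - b < w) " (truncated at contig end)" else "")
  list(
    upstream = seq_record(sprintf("%s_flank_up_%d", chrom, a),
                          substr(rec$bases, us + 1L, a), description = up_desc),
    downstream = seq_record(sprintf("%s_flank_dn_%d", chrom, b),
                            substr(rec$bases, b + 1L, de), description = dn_desc)
  )
}

#' Recruit T-DNA-free reads matching a genomic flank
#'
#' Returns ids of reads that align to the flank at the detection thresholds
#' and carry no passing TDNA/BVB hit; these resolve junctions without T-DNA
#' (compensating translocation fusions, bare duplication borders).
#'
#' @param reads Named list of [seq_record()]s.
#' @param flank A [seq_record()] (e.g. from [extract_flanks()]).
#' @param tdna_read_ids Character vector of read ids already identified as
#'   T-DNA-bearing (excluded).
#' @param config A [pipeline_config()].
#' @param scoring A [scoring_scheme()].
#' @param detailed If `TRUE`, also return the subset of recruited reads
#'   whose flank alignment is clipped (the read continues for at least
#'   `min_clip` bases beyond an alignment end that stops inside the flank):
#'   the junction-informative reads.
#' @param min_clip Minimum unaligned read tail for the clipped subset (bp).
#' @param coarse If `TRUE`, reads whose seed coverage already shows an
#'   end-to-end match (or no match at all) skip the banded alignment; such
#'   contained reads are recruited with a synthetic whole-read hit. Much
#'   faster on large pools; exact alignments are still computed for every
#'   read whose seed footprint leaves a tail.
#' @return Character vector of recruited read ids; with `detailed = TRUE`, a
#'   list with `ids`, `clipped` and the per-read `hits`.
#' @export
recruit_flank_reads <- function(reads, flank, tdna_read_ids = character(),
                                config = pipeline_config(),
                                scoring = scoring_scheme(),
                                detailed = FALSE, min_clip = 500L,
                                coarse = FALSE) {
  if (nchar(flank$bases) == 0L) stop("flank sequence is empty")
  idx <- build_index(list(flank), k = config$index_k)
  flank_len <- nchar(flank$bases)
  out <- character(); clipped <- character(); hits <- list()
  for (r in reads) {
    if (r$id %in% tdna_read_ids) next
    rl <- nchar(r$bases)
    if (rl < config$index_k) next
    if (coarse) {
      scr <- .seed_screen_cpp(idx$ptr, r$bases)
      if (scr$frac < 0.02) next  # no substantial flank match
      if (!is.na(scr$q_lo) && scr$q_lo <= 400 && rl - scr$q_hi <= 400) {
        # matches end to end: recruited, cannot be junction-informative
        out <- c(out, r$id)
        if (detailed)
          hits[[r$id]] <- data.frame(query_id = r$id, q_start = scr$q_lo,
                                     q_end = scr$q_hi, strand = "*",
                                     subject_id = flank$id, s_start = NA,
                                     s_end = NA, identity = NA, score = NA,
                                     evalue = NA, aln_len = scr$q_hi - scr$q_lo,
                                     stringsAsFactors = FALSE)
        next
      }
    }
    h <- find_local_hits(r, idx, scoring,
                         min_identity = config$tdna_min_identity,
                         max_evalue = config$tdna_max_evalue,
                         min_aln_len = config$min_aln_len)
    if (nrow(h) == 0L) next
    out <- c(out, r$id)
    if (detailed) {
      hits[[r$id]] <- h
      # clipped: an unaligned read tail while the matching flank end is
      # well inside the flank (the read runs off into non-flank sequence)
      is_clip <- FALSE
      for (k in seq_len(nrow(h))) {
        left_tail <- h$q_start[k]
        right_tail <- rl - h$q_end[k]
        s_lo <- h$s_start[k]; s_hi <- flank_len - h$s_end[k]
        if (h$strand[k] == "-") { tmp <- s_lo; s_lo <- s_hi; s_hi <- tmp }
        if ((left_tail >= min_clip && s_lo > min_clip) ||
            (right_tail >= min_clip && s_hi > min_clip)) { is_clip <- TRUE; break }
      }
      if (is_clip) clipped <- c(clipped, r$id)
    }
  }
  if (detailed) list(ids = out, clipped = clipped, hits = hits) else out
}

# Is a recruited read informative for a junction at one end of the flank?
# Either its alignment stops well inside the flank with an unaligned read
# tail (internal clip), or it reaches the anchor-facing flank terminus and
# the read continues beyond it.
.junction_informative <- function(h, read_len, flank_len, anchor_at,
                                  min_clip = 500L) {
  if (any(is.na(h$s_start))) return(FALSE)  # coarse contained hit
  for (k in seq_len(nrow(h))) {
    left_tail <- h$q_start[k]
    right_tail <- read_len - h$q_end[k]
    s_lo <- h$s_start[k]; s_hi <- flank_len - h$s_end[k]
    if (h$strand[k] == "-") {
      tmp <- left_tail; left_tail <- right_tail; right_tail <- tmp
    }
    # after the swap, left_tail is the read tail on the flank's low side
    if ((left_tail >= min_clip && s_lo > min_clip) ||
        (right_tail >= min_clip && s_hi > min_clip)) return(TRUE)
    if (anchor_at == "right" && s_hi <= 200 && right_tail >= min_clip)
      return(TRUE)
    if (anchor_at == "left" && s_lo <= 200 && left_tail >= min_clip)
      return(TRUE)
  }
  FALSE
}
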