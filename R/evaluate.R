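# Validation harness: named fixture scenarios with planted truth, a
# scenario runner, truth scoring, and replicate experiments (zygosity
# calling, misjoin detection, simulator error rates).

.SCENARIOS <- c("canonical", "head_to_head", "array8_bvb",
                "reciprocal_translocation", "inverted_duplication",
                "cpdna_junction", "tdna_free_fusion")

#' Construct one of the named fixture scenarios
#'
#' Seven scenarios cover the event taxonomy: a canonical single-copy
#' insertion with a 13 bp target-site deletion; a head-to-head two-unit
#' inverted array with the quality drop on the second arm; an eight-unit
#' array with a backbone (BVB) fragment; a reciprocal translocation with
#' T-DNA at one fusion and none at the compensating fusion; an 80 kbp
#' inverted duplication with T-DNA at one border; a 652 bp plastome
#' fragment captured between genomic arms; and a T-DNA-free chromosome
#' fusion with 4 bp of junction microhomology.
#'
#' @param name Scenario name (see `Details`).
#' @param seed Integer seed; every scenario derives its own stream from it.
#' @param depth Sequencing depth (default 30).
#' @return List with `name`, `config`, `genome` ([make_genome()] output),
#'   `planted` ([plant_events()] output), `sim` ([simulate_reads()] output)
#'   and `recruit_anchors` (anchors for T-DNA-free analysis, when
#'   applicable).
#' @export
fixture_scenario <- function(name = .SCENARIOS, seed = 1L, depth = 30) {
  name <- match.arg(name)
  idx <- match(name, .SCENARIOS)
  base <- list(rng_seed = as.integer(seed * 100 + idx), depth = depth)
  two_chroms <- c(chr1 = 150000L, chr2 = 150000L)
  one_chrom <- c(chr1 = 150000L)

  cfg <- switch(name,
    canonical = ,
    head_to_head = ,
    array8_bvb = ,
    inverted_duplication = ,
    cpdna_junction = do.call(simulation_config,
                             c(base, list(chrom_sizes = one_chrom))),
    do.call(simulation_config, c(base, list(chrom_sizes = two_chroms))))

  g <- make_genome(cfg)
  vi <- g$vector_info
  anchors <- NULL
  events <- switch(name,
    canonical = list(event_spec("TDNA_ARRAY", chrom = "chr1", pos = 75000L,
                                units = tdna_units(vi, "+"),
                                target_deletion_bp = 13L)),
    head_to_head = list(event_spec("TDNA_ARRAY", chrom = "chr1", pos = 75000L,
                                   units = tdna_units(vi, c("+", "-")),
                                   target_deletion_bp = 8L)),
    array8_bvb = {
      tu <- data.frame(
        subject = c("TDNA", "TDNA", "TDNA", "TDNA", "BVB",
                    "TDNA", "TDNA", "TDNA", "TDNA"),
        s_start = c(3, 40, 3, 120, 100, 3, 60, 15, 3),
        s_end = c(5487, 5497, 5347, 5492, 1400, 5417, 5497, 5467, 5297),
        orientation = c("+", "+", "-", "-", "+", "+", "+", "-", "-"),
        stringsAsFactors = FALSE)
      list(event_spec("TDNA_ARRAY", chrom = "chr1", pos = 75000L, units = tu,
                      target_deletion_bp = 21L))
    },
    reciprocal_translocation = {
      anchors <- list(list(chrom = "chr2", start = 59999L, end = 60000L,
                            side = "up"))
      list(event_spec("TRANSLOCATION_PAIR", chrom_a = "chr1", pos_a = 90000L,
                      chrom_b = "chr2", pos_b = 60000L,
                      units = tdna_units(vi, "+")))
    },
    inverted_duplication = {
      anchors <- list(list(chrom = "chr1", start = 119999L, end = 120000L,
                            side = "down"))
      list(event_spec("INVERTED_DUPLICATION", chrom = "chr1", pos = 120000L,
                      span = 80000L, units = tdna_units(vi, "+")))
    },
    cpdna_junction = {
      anchors <- list(list(chrom = "chr1", start = 74999L, end = 75000L,
                            side = "up"))
      list(event_spec("CPDNA_FILLER_JUNCTION", chrom = "chr1", pos = 75000L,
                      cp_start = 5000L, cp_len = 652L,
                      target_deletion_bp = 10L))
    },
    tdna_free_fusion = {
      anchors <- list(list(chrom = "chr1", start = 69999L, end = 70000L,
                            side = "both"))
      list(event_spec("TDNA_FREE_FUSION", chrom_a = "chr1", pos_a = 70000L,
                      chrom_b = "chr2", pos_b = 80000L,
                      microhomology_bp = 4L))
    })

  set.seed(cfg$rng_seed)  # event tables above may not consume randomness
  pl <- plant_events(g$genome, g$catalog, events, cfg, vi)
  sim <- simulate_reads(pl, cfg, pl$truth)
  list(name = name, config = cfg, genome = g, planted = pl, sim = sim,
       recruit_anchors = anchors)
}

.scenario_cache <- new.env(parent = emptyenv())

#' Run the pipeline on a fixture scenario (cached)
#'
#' Builds the scenario, runs [run_pipeline()] (with flank recruitment for
#' the T-DNA-free scenarios) and attaches truth-based scores. Results are
#' memoized per `(name, seed, depth)` within the session.
#'
#' @inheritParams fixture_scenario
#' @return List: the scenario plus `result` (pipeline output) and `score`
#'   (see [score_scenario()]).
#' @export
run_scenario <- function(name, seed = 1L, depth = 30) {
  key <- sprintf("%s_%d_%g", name, seed, depth)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  fx <- fixture_scenario(name, seed, depth)
  pcfg <- pipeline_config(rng_seed = as.integer(seed))
  res <- run_pipeline(fx$sim$reads, fx$genome$catalog, pcfg,
                      recruit_anchors = fx$recruit_anchors)
  out <- c(fx, list(result = res, score = score_scenario(fx, res)))
  .scenario_cache[[key]] <- out
  out
}

#' Score pipeline output against planted truth
#'
#' For each planted reference junction anchor, the distance to the nearest
#' reported anchor of matching chromosome and direction; plus unit
#' count/orientation agreement for planted arrays and the set of reported
#' event types.
#'
#' @param fx A [fixture_scenario()].
#' @param res A [run_pipeline()] result.
#' @param tol Junction recovery tolerance in bp (default 10).
#' @return List with `junctions` (per-anchor data.frame: `err`,
#'   `recovered`), `junction_recovery`, `units_expected`, `units_found`,
#'   `orientations_ok`, `event_types`.
#' @export
score_scenario <- function(fx, res, tol = 10) {
  truth_anch <- fx$planted$truth$anchors
  rep_anch <- reported_anchors(res$structures)
  jt <- truth_anch
  jt$err <- NA_real_; jt$recovered <- FALSE
  for (i in seq_len(nrow(jt))) {
    cand <- rep_anch[rep_anch$chrom == jt$chrom[i] &
                       rep_anch$direction == jt$direction[i], , drop = FALSE]
    if (nrow(cand)) {
      jt$err[i] <- min(abs(cand$pos - jt$pos[i]))
      jt$recovered[i] <- jt$err[i] <= tol
    }
  }
  # planted vs recovered insert units (arrays)
  tb <- fx$planted$truth$blocks
  tu <- tb[tb$kind %in% c("TDNA", "BVB"), , drop = FALSE]
  units_found <- NULL; orientations_ok <- NA
  if (nrow(tu) > 0 && length(res$structures) > 0) {
    best <- NULL
    for (s in res$structures) {
      if (is.null(s$chain)) next
      su <- s$chain[s$chain$kind %in% c("TDNA", "BVB"), , drop = FALSE]
      if (is.null(best) || nrow(su) > nrow(best)) best <- su
    }
    if (!is.null(best)) {
      units_found <- nrow(best)
      sig_truth <- paste(tu$kind, tu$strand, sep = "", collapse = "|")
      sig_rc <- paste(rev(tu$kind), rev(ifelse(tu$strand == "+", "-", "+")),
                      sep = "", collapse = "|")
      sig_found <- paste(best$kind, best$orientation, sep = "", collapse = "|")
      orientations_ok <- sig_found == sig_truth || sig_found == sig_rc
    }
  }
  list(junctions = jt,
       junction_recovery = mean(jt$recovered),
       units_expected = nrow(tu),
       units_found = units_found,
       orientations_ok = orientations_ok,
       event_types = unique(res$events$event_type))
}

#' All reference anchors reported by a set of structures
#'
#' Terminal flank anchors use the consensus positions; interior
#' genome::genome breakpoints (duplication borders) come from the
#' backbone chain.
#'
#' @param structures List of [build_structure()] results.
#' @return data.frame with `chrom`, `pos`, `direction`.
#' @export
reported_anchors <- function(structures) {
  out <- list()
  for (s in structures) {
    if (!is.null(s$anchors) && nrow(s$anchors))
      out[[length(out) + 1]] <- s$anchors[, c("chrom", "pos", "direction")]
    if (!is.null(s$chain)) {
      a <- .chain_anchors(s$chain)
      if (nrow(a)) out[[length(out) + 1]] <- a[, c("chrom", "pos", "direction")]
    }
    for (fl in list(s$left_flank, s$right_flank)) {
      if (!is.null(fl))
        out[[length(out) + 1]] <- data.frame(chrom = fl$chrom, pos = fl$pos,
                                             direction = fl$direction,
                                             stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(data.frame(chrom = character(), pos = numeric(),
                                     direction = character(),
                                     stringsAsFactors = FALSE))
  unique(df)
}

# Shared interval-level read sampler (positions and lengths only; no
# sequence). Used by replicate experiments where only sampling noise
# matters.
.sample_read_intervals <- function(chrom_len, depth, median_len = 15000,
                                   sdlog = 0.9, min_len = 1000,
                                   max_len = 100000) {
  target <- depth * chrom_len
  emitted <- 0
  starts <- numeric(0); ends <- numeric(0)
  meanlog <- log(median_len)
  while (emitted < target) {
    L <- exp(rnorm(1, meanlog, sdlog))
    L <- max(min_len, min(max_len, round(L)))
    st <- floor(runif(1, 0, max(1, chrom_len - 200)))
    en <- min(chrom_len, st + L)
    if (en - st < 200) next
    starts <- c(starts, st); ends <- c(ends, en)
    emitted <- emitted + (en - st)
  }
  data.frame(start = starts, end = ends)
}

#' Replicate experiment: zygosity calling on segregating pools
#'
#' Simulates `n_rep` independent loci: a canonical insertion on the mutant
#' haplotype, reads drawn from the wild-type haplotype with probability
#' `wt_fraction` (1/3 for a selected T2 pool). Reads spanning the insertion
#' junctions support the insert allele; wild-type reads spanning the
#' unmodified interval support the wild-type allele. Each replicate's
#' counts are passed to [estimate_zygosity()].
#'
#' @param n_rep Number of replicate loci (default 100).
#' @param depth Haploid depth (default 30).
#' @param wt_fraction Wild-type allele fraction (default 1/3).
#' @param seed Integer seed.
#' @param chrom_len,insert_len Locus geometry (defaults 40 kbp / 5.5 kbp).
#' @return data.frame per replicate: `n_insert`, `n_wt`, `fraction`,
#'   `call`.
#' @export
zygosity_replicates <- function(n_rep = 100, depth = 30, wt_fraction = 1 / 3,
                                seed = 1L, chrom_len = 40000,
                                insert_len = 5500) {
  set.seed(seed)
  pos <- chrom_len / 2
  cfg <- pipeline_config()
  margin <- 200
  out <- lapply(seq_len(n_rep), function(r) {
    n_ins <- 0L; n_wt <- 0L
    # mutant haplotype (fraction 1 - wt_fraction), carries the insert
    mut_len <- chrom_len + insert_len
    mut <- .sample_read_intervals(mut_len, depth * (1 - wt_fraction))
    jl <- pos; jr <- pos + insert_len
    n_ins <- sum((mut$start < jl - margin & mut$end > jl + margin) |
                   (mut$start < jr - margin & mut$end > jr + margin))
    wt <- .sample_read_intervals(chrom_len, depth * wt_fraction)
    n_wt <- sum(wt$start < pos - margin & wt$end > pos + margin)
    z <- estimate_zygosity(sprintf("rep%d", r), n_ins, n_wt, cfg)
    data.frame(n_insert = n_ins, n_wt = n_wt,
               fraction = z$wt_allele_read_fraction, call = z$call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Replicate experiment: misjoin detection by alignment-end binning
#'
#' Simulates reads over two separate chromosomes, then evaluates them
#' against a misjoined assembly that concatenates the two: no read spans
#' the join, so read alignments pile their ends at the join position. The
#' function reports the candidate regions and the rank of the region
#' containing the join. Alignments touching the outer assembly termini are
#' excluded before binning: sequence ends accumulate alignment ends
#' trivially and are uninformative for internal misjoins.
#'
#' @param seed Integer seed.
#' @param chrom_len Length of each true chromosome (default 100 kbp).
#' @param depth Sequencing depth (default 30).
#' @param config A [pipeline_config()].
#' @return List with `regions`, `join_pos`, `join_rank` (NA when the join
#'   is not among the called regions).
#' @export
aef_misjoin_experiment <- function(seed = 1L, chrom_len = 100000, depth = 30,
                                   config = pipeline_config()) {
  set.seed(seed)
  a <- .sample_read_intervals(chrom_len, depth)
  b <- .sample_read_intervals(chrom_len, depth)
  b$start <- b$start + chrom_len; b$end <- b$end + chrom_len
  al <- genomic_intervals("asm", c(a$start, b$start), c(a$end, b$end))
  al <- al[al$start > 0 & al$end < 2 * chrom_len, , drop = FALSE]
  bins <- count_alignment_ends(al, 2 * chrom_len, config)
  regions <- call_candidate_regions(bins, config = config)
  hit <- which(regions$start <= chrom_len & regions$end >= chrom_len)
  list(regions = regions, join_pos = chrom_len,
       join_rank = if (length(hit)) min(hit) else NA_integer_)
}

#' Measure the simulator's realized error rates
#'
#' Simulates short reads from a clean genome and counts the errors actually
#' written into each read against its source fragment (the generator's edit
#' script - the truth alignment). As a sequence-level cross-check, each
#' read is also re-aligned to its fragment with [sw_align()] and the mean
#' alignment identity is reported; re-alignment is not used for the rates
#' themselves because parsimonious alignment merges adjacent insertions
#' and deletions into mismatch columns.
#'
#' @param seed Integer seed.
#' @param n_reads Number of reads to re-align for the identity check.
#' @return List with `mismatch`, `insertion`, `deletion` (per-base rates
#'   counted against the truth alignments), `aligned_identity` (mean
#'   re-aligned identity) and the configured rates.
#' @export
simulator_error_rates <- function(seed = 1L, n_reads = 60) {
  cfg <- simulation_config(rng_seed = as.integer(seed),
                           chrom_sizes = c(chrE = 60000L),
                           read_len_median = 2500, read_len_sdlog = 0.4,
                           read_len_min = 1000, read_len_max = 5000,
                           depth = 10, wt_allele_fraction = 0.5,
                           inverted_arm_drop = FALSE)
  g <- make_genome(cfg)
  pl <- plant_events(g$genome, g$catalog, list(), cfg, g$vector_info)
  sim <- simulate_reads(pl, cfg, pl$truth)
  tt <- sim$truth
  denom <- sum(tt$frag_len)
  ids <- 0; idn <- 0
  for (i in seq_len(min(n_reads, nrow(tt)))) {
    r <- tt[i, ]
    frag <- substr(g$genome[[r$chrom]]$bases, r$start + 1, r$end)
    qs <- sim$reads[[r$read_id]]$bases
    if (r$strand == "-") qs <- .rc_cpp(qs)
    a <- sw_align(qs, frag)
    if (a$aln_len < 0.8 * (r$end - r$start)) next
    ids <- ids + a$matches; idn <- idn + a$aln_len
  }
  list(mismatch = sum(tt$n_mm) / denom,
       insertion = sum(tt$n_ins) / denom,
       deletion = sum(tt$n_del) / denom,
       aligned_identity = ids / idn,
       configured = c(mismatch = cfg$err_mismatch,
                      insertion = cfg$err_insertion,
                      deletion = cfg$err_deletion))
}

#' Count wild-type and insert-supporting spanning reads at a locus
#'
#' Recruits reads against a window around the resolved locus and counts
#' those whose single contiguous alignment spans the unmodified reference
#' interval (wild-type allele) versus the structure's insert-supporting
#' reads.
#'
#' @param reads Named list of [seq_record()]s.
#' @param structure An [build_structure()] result with both flanks.
#' @param catalog A [reference_catalog()].
#' @param config A [pipeline_config()].
#' @param margin Window margin around the locus (default 2000 bp).
#' @return A [estimate_zygosity()] result with counts attached.
#' @export
locus_zygosity <- function(reads, structure, catalog,
                           config = pipeline_config(), margin = 2000L) {
  lf <- structure$left_flank; rf <- structure$right_flank
  if (is.null(lf) || is.null(rf) || lf$chrom != rf$chrom)
    stop("locus_zygosity requires same-chromosome flanks")
  rec <- catalog$records[[lf$chrom]]
  ws <- max(0L, lf$pos - margin); we <- min(nchar(rec$bases), rf$pos + margin)
  wrec <- seq_record("locus_window", substr(rec$bases, ws + 1, we))
  det <- recruit_flank_reads(reads, wrec,
                             tdna_read_ids = structure$supporting_reads,
                             config = config, detailed = TRUE)
  inner_lo <- (lf$pos - ws) - 200; inner_hi <- (rf$pos - ws) + 200
  n_wt <- 0L
  for (id in det$ids) {
    h <- det$hits[[id]]
    if (any(h$s_start <= inner_lo & h$s_end >= inner_hi)) n_wt <- n_wt + 1L
  }
  n_ins <- length(structure$supporting_reads)
  z <- estimate_zygosity(structure$locus_id, n_ins, n_wt, config)
  z$n_insert <- n_ins; z$n_wt <- n_wt
  z
}
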