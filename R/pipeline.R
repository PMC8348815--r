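# End-to-end orchestration and report rendering.

#' Run the insertion-analysis pipeline end to end
#'
#' Stages: detect T-DNA/BVB reads, annotate them against the catalog,
#' cluster annotated reads into loci, resolve structures, classify events,
#' analyse junctions; optionally recruit T-DNA-free reads around supplied
#' anchors to resolve fusions without T-DNA at the junction, and run
#' alignment-end/coverage profiling when read alignments are supplied.
#' Stage outputs are persisted under `outdir` together with a JSON manifest
#' (configuration snapshot, seed, per-stage record counts, output
#' checksums).
#'
#' @param reads Named list of [seq_record()]s (or a FASTQ path).
#' @param catalog A [reference_catalog()] (or a FASTA path plus `category`).
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created); `NULL` for no files.
#' @param recruit_anchors Optional list of anchors (`chrom`, `start`, `end`)
#'   around which T-DNA-free reads are recruited and analysed.
#' @param alignments Optional reference alignments (`genomic_intervals` or
#'   BED path) for the integrity stage.
#' @param chrom_lens Named lengths of reference chromosomes (required for
#'   the integrity stage).
#' @param scoring A [scoring_scheme()].
#' @return List with `structures`, `events`, `junctions`, `summary`,
#'   `zygosity`, `integrity`, `manifest` (and all intermediates).
#' @export
run_pipeline <- function(reads, catalog, config = pipeline_config(),
                         outdir = NULL, recruit_anchors = NULL,
                         alignments = NULL, chrom_lens = NULL,
                         scoring = scoring_scheme()) {
  t_start <- Sys.time()
  if (is.character(reads)) reads <- read_fastq(reads)
  if (length(reads) == 0) stop("empty input: no reads supplied")
  counts <- list(n_reads = length(reads))

  idx <- build_index(catalog, k = config$index_k)

  # stage 1: detect
  sel <- select_tdna_reads(reads, catalog, config, scoring)
  counts$n_tdna_reads <- length(sel)

  # stage 2: annotate
  anns <- annotate_reads(reads[names(sel)], catalog, config, scoring, index = idx)
  counts$n_annotated <- length(anns)

  # optional: recruit T-DNA-free reads around anchors and annotate the
  # junction-informative ones - reads whose flank alignment is clipped
  # inside the flank or that run past the anchor-facing flank terminus.
  # An anchor may carry `side = "up"`, `"down"` or `"both"` (default) to
  # restrict which flank is searched.
  rec_anns <- list()
  if (!is.null(recruit_anchors)) {
    for (anchor in recruit_anchors) {
      fl <- extract_flanks(catalog, anchor, config)
      sides <- switch(anchor$side %||% "both",
                      up = "upstream", down = "downstream",
                      c("upstream", "downstream"))
      for (side in sides) {
        rec <- recruit_flank_reads(reads, fl[[side]], names(sel), config,
                                   scoring, detailed = TRUE, coarse = TRUE)
        if (length(rec$ids) == 0) next
        anchor_at <- if (side == "upstream") "right" else "left"
        flank_len <- nchar(fl[[side]]$bases)
        inform <- rec$ids[vapply(rec$ids, function(id)
          .junction_informative(rec$hits[[id]], nchar(reads[[id]]$bases),
                                flank_len, anchor_at), logical(1))]
        inform <- setdiff(inform, names(rec_anns))
        if (length(inform) == 0) next
        ra <- annotate_reads(reads[inform], catalog, config, scoring,
                             index = idx)
        rec_anns[names(ra)] <- ra
      }
    }
  }
  counts$n_recruited <- length(rec_anns)
  all_anns <- c(anns, rec_anns[setdiff(names(rec_anns), names(anns))])

  # stage 3: cluster
  cl <- cluster_loci(all_anns, config)
  counts$n_loci <- length(cl$loci)
  counts$n_unanchored <- length(cl$unanchored)

  # stage 4: resolve + classify
  structures <- lapply(cl$loci, build_structure, annotations = all_anns,
                       catalog = catalog, config = config)
  events <- classify_event(structures)

  # stage 5: junctions
  junctions <- do.call(rbind, lapply(structures, function(s) {
    if (is.null(s$chain)) return(NULL)
    junction_report(s, reads, all_anns, catalog, config, index = idx, scoring)
  }))
  if (is.null(junctions)) junctions <- data.frame(junction_id = character())

  # stage 6: integrity (only when reference alignments are supplied)
  integrity <- NULL
  if (!is.null(alignments)) {
    if (is.character(alignments)) alignments <- read_bed(alignments)
    if (is.null(chrom_lens)) stop("chrom_lens required for the integrity stage")
    integrity <- lapply(names(chrom_lens), function(ch) {
      al <- alignments[alignments$chrom == ch, , drop = FALSE]
      bins <- count_alignment_ends(al, chrom_lens[[ch]], config)
      list(chrom = ch, bins = bins,
           regions = call_candidate_regions(bins, config = config),
           profile = coverage_profile(al, chrom_lens[[ch]]))
    })
    names(integrity) <- names(chrom_lens)
  }

  summary <- .summarize_events(structures, events)
  out <- list(selected = sel, annotations = all_anns, loci = cl,
              structures = structures, events = events, junctions = junctions,
              integrity = integrity, summary = summary, counts = counts)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- render_report(structures, events, junctions, integrity, outdir)
    manifest <- list(
      tool = "tdnalocus", version = as.character(utils::packageVersion("tdnalocus")),
      created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
      rng_seed = config$rng_seed,
      config = unclass(config),
      counts = counts,
      outputs = lapply(files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))))
    mpath <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    out$manifest <- manifest
    out$outdir <- outdir
  }
  out
}

.summarize_events <- function(structures, events) {
  main <- events[events$event_type != "CPDNA_INSERTION", , drop = FALSE]
  tab <- table(main$event_type)
  n_bvb <- sum(vapply(structures, function(s)
    !is.null(s$chain) && any(s$chain$kind == "BVB"), logical(1)))
  borders <- unlist(lapply(structures, function(s) {
    if (is.null(s$chain)) return(NULL)
    ch <- s$chain
    n <- nrow(ch)
    labs <- c()
    # outermost junction borders of the insert
    tu <- which(ch$kind %in% c("TDNA", "BVB"))
    if (length(tu)) {
      labs <- c(labs, ch$border_left[tu[1]], ch$border_right[tu[length(tu)]])
    }
    if (length(labs) == 0) return(NULL)
    labs[!is.na(labs) & !startsWith(labs, "INTERNAL")]
  }))
  rb_rb <- sum(vapply(structures, function(s)
    !is.null(s$internal_junctions) && nrow(s$internal_junctions) > 0 &&
      any(s$internal_junctions$rb_rb), logical(1)))
  list(n_loci = length(structures),
       events = as.list(tab),
       n_bvb_loci = n_bvb,
       junction_borders = as.list(table(borders)),
       n_rb_rb_loci = rb_rb)
}

#' Render the per-line report bundle
#'
#' Writes per-locus structure diagrams (text, Fig-style unit chains with
#' vector coordinates and 1-based flank positions), a structure table, an
#' event table, a junction table, flank-anchor BED and, when present,
#' candidate-misassembly BED and coverage TSV.
#'
#' @param structures List of [build_structure()] results.
#' @param events [classify_event()] table.
#' @param junctions [junction_report()] table.
#' @param integrity Integrity stage output of [run_pipeline()] (or `NULL`).
#' @param outdir Output directory.
#' @return Character vector of written file paths.
#' @export
render_report <- function(structures, events, junctions, integrity = NULL,
                          outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  # structure diagrams
  dia <- file.path(outdir, "structures.txt")
  con <- file(dia, "w")
  for (s in structures) writeLines(structure_diagram(s), con)
  close(con)
  files <- c(files, dia)

  # structure table (unit per row)
  st <- do.call(rbind, lapply(structures, function(s) {
    if (is.null(s$chain)) return(NULL)
    cbind(data.frame(locus_id = s$locus_id, stringsAsFactors = FALSE), s$chain)
  }))
  stp <- file.path(outdir, "structures.tsv")
  write.table(st %||% data.frame(), stp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, stp)

  evp <- file.path(outdir, "events.tsv")
  write.table(events, evp, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, evp)

  jp <- file.path(outdir, "junctions.tsv")
  write.table(junctions, jp, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, jp)

  anch <- do.call(rbind, lapply(structures, function(s) {
    fl <- list(s$left_flank, s$right_flank)
    fl <- fl[!vapply(fl, is.null, logical(1))]
    if (length(fl) == 0) return(NULL)
    data.frame(chrom = vapply(fl, `[[`, character(1), "chrom"),
               start = vapply(fl, `[[`, numeric(1), "pos"),
               end = vapply(fl, `[[`, numeric(1), "pos") + 1,
               name = paste0(s$locus_id, "_",
                             substr(vapply(fl, `[[`, character(1), "direction"),
                                    1, 1)),
               score = vapply(fl, `[[`, numeric(1), "support"),
               strand = ".", stringsAsFactors = FALSE)
  }))
  ap <- file.path(outdir, "flank_anchors.bed")
  if (!is.null(anch)) write_bed(anch, ap) else file.create(ap)
  files <- c(files, ap)

  if (!is.null(integrity)) {
    regs <- do.call(rbind, lapply(integrity, function(x) x$regions))
    if (!is.null(regs) && nrow(regs)) {
      rp <- file.path(outdir, "candidate_regions.bed")
      write_bed(genomic_intervals(regs$chrom, regs$start, regs$end,
                                  name = sprintf("ends_%d", regs$total_ends),
                                  score = regs$total_ends, strand = "."), rp)
      files <- c(files, rp)
    }
    cov <- do.call(rbind, lapply(integrity, function(x)
      data.frame(chrom = x$profile$chrom,
                 start = (seq_along(x$profile$depth) - 1L) * x$profile$bin_bp,
                 depth = x$profile$depth, stringsAsFactors = FALSE)))
    cp <- file.path(outdir, "coverage.tsv")
    write.table(cov, cp, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, cp)
  }
  files
}

#' Text diagram of one insertion structure
#'
#' One line per chain unit with subject coordinates (vector coordinates for
#' T-DNA/BVB units, 1-based genome positions for flanks) and border labels.
#'
#' @param s An [build_structure()] result.
#' @return Character vector of diagram lines.
#' @export
structure_diagram <- function(s) {
  hdr <- sprintf("== locus %s  (%d reads%s)", s$locus_id,
                 length(s$supporting_reads),
                 if (length(s$flags)) paste0("; ", paste(s$flags, collapse = ","))
                 else "")
  if (is.null(s$chain)) return(c(hdr, "  [unresolved]", ""))
  lines <- hdr
  for (i in seq_len(nrow(s$chain))) {
    u <- s$chain[i, ]
    width <- max(4L, min(40L, round((u$s_end - u$s_start) / 500)))
    bar <- paste(rep("=", ifelse(is.na(width), 6L, width)), collapse = "")
    borders <- ""
    if (!is.na(u$border_left) || !is.na(u$border_right))
      borders <- sprintf("  [%s | %s]",
                         ifelse(is.na(u$border_left), "-", u$border_left),
                         ifelse(is.na(u$border_right), "-", u$border_right))
    coords <- if (u$kind == "GENOMIC")
      sprintf("%s:%s-%s", u$subject_id,
              format(u$s_start + 1, big.mark = ",", scientific = FALSE),
              format(u$s_end, big.mark = ",", scientific = FALSE))
    else if (is.na(u$subject_id)) sprintf("%d bp", u$q_end - u$q_start)
    else sprintf("%s:%d-%d", u$subject_id, u$s_start + 1, u$s_end)
    lines <- c(lines, sprintf("  %-12s %s%s  %s%s", u$kind, bar, u$orientation,
                              coords, borders))
  }
  if (!is.na(s$target_site_deletion_bp))
    lines <- c(lines, sprintf("  target site deletion: %d bp",
                              s$target_site_deletion_bp))
  c(lines, "")
}
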