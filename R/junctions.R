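# Junction analysis: filler DNA classification (cascaded search) and
# microhomology at genome::insert and genome::genome junctions.

#' Longest exact microhomology between two joined ends
#'
#' Returns the length of the longest exact suffix of `left_seq` equal to a
#' prefix of `right_seq` - the canonical microhomology-mediated end-joining
#' overlap. `left_seq` ends at the junction; `right_seq` starts at it.
#'
#' @param left_seq,right_seq Sequence strings (non-empty).
#' @return Integer overlap length (0 when none).
#' @export
find_microhomology <- function(left_seq, right_seq) {
  l <- toupper(left_seq); r <- toupper(right_seq)
  nl <- nchar(l); nr <- nchar(r)
  if (nl == 0 || nr == 0) stop("both sequences must be non-empty")
  for (m in seq.int(min(nl, nr), 1L)) {
    if (substr(l, nl - m + 1L, nl) == substr(r, 1L, m)) return(m)
  }
  0L
}

#' Enumerate the junctions of an insertion structure
#'
#' Every boundary between consecutive chain units is a junction. When
#' `collapse_organellar` is set, a run of purely organellar/filler/unknown
#' units between two genomic units is treated as a single genome::genome
#' junction (its content becomes the unmatched middle of the window), which
#' is how captured organellar fragments present in junction analysis.
#'
#' @param structure An [build_structure()] result.
#' @param collapse_organellar Collapse organellar inserts (default `TRUE`).
#' @return data.frame with `left_unit`, `right_unit` chain indices.
#' @export
structure_junctions <- function(structure, collapse_organellar = TRUE) {
  ch <- structure$chain
  n <- nrow(ch)
  out <- data.frame(left_unit = integer(), right_unit = integer(),
                    stringsAsFactors = FALSE)
  if (n < 2) return(out)
  soft <- c("CPDNA", "CHONDRIO", "FILLER", "UNKNOWN_LOWQ")
  i <- 1L
  while (i < n) {
    j <- i + 1L
    if (collapse_organellar && ch$kind[i] == "GENOMIC") {
      k <- j
      while (k <= n && ch$kind[k] %in% soft) k <- k + 1L
      if (k <= n && k > j && ch$kind[k] == "GENOMIC") {
        out <- rbind(out, data.frame(left_unit = i, right_unit = k))
        i <- k
        next
      }
    }
    out <- rbind(out, data.frame(left_unit = i, right_unit = j))
    i <- j
  }
  out
}

#' Extract a junction window from a supporting read
#'
#' Selects the supporting read that covers both junction units at the
#' highest identity and cuts a window of `window_bp/2` into each assigned
#' side (plus whatever lies between the two tiled segments). The window is
#' reported on the locus's canonical orientation.
#'
#' @param structure An [build_structure()] result.
#' @param junction One row of [structure_junctions()] (or its index).
#' @param reads Named list of [seq_record()]s.
#' @param annotations Named list of [annotate_read()] results.
#' @param window_bp Window size (default 200: 100 bp per side).
#' @return List with `seq`, `left_end`/`right_start` (offsets of the
#'   assigned parts within the window), `left_origin`, `right_origin`,
#'   `read_id`, `truncated`.
#' @export
extract_junction_window <- function(structure, junction, reads, annotations,
                                    window_bp = 200L) {
  juncs <- structure_junctions(structure)
  if (is.numeric(junction)) {
    if (junction < 1 || junction > nrow(juncs)) stop("junction index out of range")
    junction <- juncs[junction, ]
  }
  bb <- structure$chain
  i <- junction$left_unit; j <- junction$right_unit
  half <- as.integer(window_bp / 2)

  best <- NULL; best_q <- -Inf
  for (rid in structure$supporting_reads) {
    ann <- annotations[[rid]]
    if (is.null(ann)) next
    ch <- read_chain(ann)
    for (flip in c(FALSE, TRUE)) {
      cc <- if (flip) flip_chain(ch) else ch
      al <- .chain_align(bb, cc)
      pi <- al$pairs[al$pairs[, 1] == i, 2]
      pj <- al$pairs[al$pairs[, 1] == j, 2]
      if (length(pi) == 1 && length(pj) == 1 && pj > pi) {
        q <- min(cc$identity[pi], cc$identity[pj], na.rm = TRUE)
        if (is.finite(q) && q > best_q) {
          best_q <- q
          best <- list(read_id = rid, chain = cc, pi = pi, pj = pj,
                       flipped = flip)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  rd <- reads[[best$read_id]]
  seqs <- if (best$flipped) .rc_cpp(rd$bases) else rd$bases
  n <- nchar(seqs)
  le <- best$chain$q_end[best$pi]; rs <- best$chain$q_start[best$pj]
  ws <- max(0L, le - half); we <- min(n, rs + half)
  list(seq = substr(seqs, ws + 1L, we),
       left_end = le - ws, right_start = rs - ws,
       left_origin = as.list(bb[i, c("kind", "subject_id", "s_start", "s_end",
                                     "orientation")]),
       right_origin = as.list(bb[j, c("kind", "subject_id", "s_start", "s_end",
                                      "orientation")]),
       read_id = best$read_id,
       truncated = (le - ws) < half || (we - rs) < half)
}

# Reference context flanking the junction on each assigned side, read from
# the catalog in chain orientation (for microhomology, which should not be
# degraded by read errors).
.origin_contexts <- function(left_origin, right_origin, catalog, ctx = 30L) {
  getrec <- function(o) catalog$records[[o$subject_id]]
  lctx <- rctx <- NULL
  lr <- getrec(left_origin)
  if (!is.null(lr)) {
    lctx <- if (left_origin$orientation == "+")
      substr(lr$bases, max(1, left_origin$s_end - ctx + 1), left_origin$s_end)
    else .rc_cpp(substr(lr$bases, left_origin$s_start + 1,
                        min(nchar(lr$bases), left_origin$s_start + ctx)))
  }
  rr <- getrec(right_origin)
  if (!is.null(rr)) {
    rctx <- if (right_origin$orientation == "+")
      substr(rr$bases, right_origin$s_start + 1,
             min(nchar(rr$bases), right_origin$s_start + ctx))
    else .rc_cpp(substr(rr$bases, max(1, right_origin$s_end - ctx + 1),
                        right_origin$s_end))
  }
  list(left = lctx, right = rctx)
}

#' Classify filler DNA at a junction with the cascaded search
#'
#' Stage 1 aligns the junction window against the catalog at default
#' stringency (E <= `junction_stage1_evalue`); the maximal middle part not
#' covered by the continuation of the two assigned flanks is the filler.
#' Stage 2 re-searches a non-empty filler with short-match sensitivity
#' (exact local alignment of the filler against every catalog sequence,
#' accepted at E <= `filler_evalue`, i.e. 10). Stage 3 extends the filler by
#' `filler_extension_bp` (10) bases up- and downstream within the window and
#' repeats stage 2; a filler copied from sequence adjacent to the junction
#' becomes detectable through the extension. Fillers with no hit at any
#' stage have origin `UNKNOWN`. Microhomology is computed from the
#' reference context of the two assigned origins.
#'
#' @param junction A window from [extract_junction_window()].
#' @param catalog A [reference_catalog()].
#' @param config A [pipeline_config()].
#' @param index Optional prebuilt catalog [build_index()].
#' @param scoring A [scoring_scheme()].
#' @return A one-row data.frame (`junction_report`): origins, filler length
#'   and sequence, filler origin category/subject, detection stage,
#'   microhomology length.
#' @export
classify_filler <- function(junction, catalog, config = pipeline_config(),
                            index = NULL, scoring = scoring_scheme()) {
  if (is.null(index)) index <- build_index(catalog, k = config$index_k)
  w <- junction$seq
  n <- nchar(w)
  hits <- find_local_hits(w, index, scoring,
                          min_identity = config$tdna_min_identity,
                          max_evalue = config$junction_stage1_evalue,
                          min_aln_len = 30L)
  hits <- .categorize_hits(hits, catalog)

  lsub <- junction$left_origin$subject_id
  rsub <- junction$right_origin$subject_id
  # How far each assigned flank covers the window, measured against the
  # junction-bounded reference context of that flank (the context ends at
  # the junction, so a gapped alignment cannot bridge across a short
  # filler and absorb it).
  lo <- junction$left_origin; ro <- junction$right_origin
  fs <- junction$left_end; fe <- junction$right_start
  lrec <- catalog$records[[lo$subject_id]]
  if (!is.null(lrec)) {
    ctx_len <- junction$left_end + 40L
    lctx <- if (lo$orientation == "+")
      substr(lrec$bases, max(1, lo$s_end - ctx_len + 1), lo$s_end)
    else .rc_cpp(substr(lrec$bases, lo$s_start + 1,
                        min(nchar(lrec$bases), lo$s_start + ctx_len)))
    la <- sw_align(w, lctx, scoring)
    if (la$score > 0 && la$q_start <= 25) fs <- la$q_end
  }
  rrec <- catalog$records[[ro$subject_id]]
  if (!is.null(rrec)) {
    ctx_len <- (n - junction$right_start) + 40L
    rctx <- if (ro$orientation == "+")
      substr(rrec$bases, ro$s_start + 1,
             min(nchar(rrec$bases), ro$s_start + ctx_len))
    else .rc_cpp(substr(rrec$bases, max(1, ro$s_end - ctx_len + 1), ro$s_end))
    ra <- sw_align(w, rctx, scoring)
    if (ra$score > 0 && ra$q_end >= n - 25) fe <- ra$q_start
  }
  fs <- min(fs, n); fe <- max(fe, 0L)

  filler <- if (fe > fs) substr(w, fs + 1L, fe) else ""
  origin_cat <- NA_character_; origin_sub <- NA_character_; stage <- NA_integer_
  best_e <- NA_real_

  if (nzchar(filler)) {
    inner <- hits[hits$q_start >= fs - 5 & hits$q_end <= fe + 5, , drop = FALSE]
    # drop arm continuations masquerading as filler origin
    inner <- inner[!(inner$subject_id %in% c(lsub, rsub)) |
                     inner$q_start >= fs | inner$q_end <= fe, , drop = FALSE]
    if (nrow(inner)) {
      b <- inner[order(-inner$score), ][1, ]
      origin_cat <- b$category; origin_sub <- b$subject_id
      stage <- 1L; best_e <- b$evalue
    } else {
      s2 <- .short_match_search(filler, catalog, config, scoring)
      if (!is.null(s2)) {
        origin_cat <- s2$category; origin_sub <- s2$subject_id
        stage <- 2L; best_e <- s2$evalue
      } else {
        ext <- config$filler_extension_bp
        es <- max(0L, fs - ext); ee <- min(n, fe + ext)
        s3 <- .short_match_search(substr(w, es + 1L, ee), catalog, config,
                                  scoring)
        if (!is.null(s3)) {
          origin_cat <- s3$category; origin_sub <- s3$subject_id
          stage <- 3L; best_e <- s3$evalue
        }
      }
    }
    if (is.na(origin_cat)) origin_cat <- "UNKNOWN"
  }

  ctx <- .origin_contexts(junction$left_origin, junction$right_origin, catalog)
  mh <- if (!is.null(ctx$left) && !is.null(ctx$right) &&
            nzchar(ctx$left) && nzchar(ctx$right))
    find_microhomology(ctx$left, ctx$right) else NA_integer_

  data.frame(read_id = junction$read_id,
             left_kind = junction$left_origin$kind,
             left_subject = lsub,
             right_kind = junction$right_origin$kind,
             right_subject = rsub,
             filler_len = nchar(filler), filler_seq = filler,
             filler_origin = if (nzchar(filler)) origin_cat else "",
             filler_origin_subject = if (nzchar(filler)) origin_sub else "",
             filler_stage = stage, filler_evalue = best_e,
             microhomology_len = mh, stringsAsFactors = FALSE)
}

# Exact local alignment of a short query against every catalog sequence
# (both strands); best hit with E-value at or below the short-match cutoff.
.short_match_search <- function(qseq, catalog, config, scoring) {
  if (!nzchar(qseq)) return(NULL)
  dblen <- sum(vapply(catalog$records, function(r) nchar(r$bases), numeric(1)))
  best <- NULL
  for (id in names(catalog$records)) {
    s <- catalog$records[[id]]$bases
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") qseq else .rc_cpp(qseq)
      a <- sw_align(qq, s, scoring)
      if (a$score <= 0) next
      e <- evalue(a$score, nchar(qseq), dblen, scoring)
      if (e <= config$filler_evalue &&
          (is.null(best) || a$score > best$score)) {
        best <- list(subject_id = id,
                     category = unname(catalog$category[id]),
                     score = a$score, evalue = e, strand = strand)
      }
    }
  }
  best
}

#' Junction reports for a resolved structure
#'
#' Runs [extract_junction_window()] and [classify_filler()] for every
#' junction of the structure.
#'
#' @inheritParams extract_junction_window
#' @inheritParams classify_filler
#' @param config A [pipeline_config()].
#' @return data.frame, one row per junction, with a `junction_id` column.
#' @export
junction_report <- function(structure, reads, annotations, catalog,
                            config = pipeline_config(), index = NULL,
                            scoring = scoring_scheme()) {
  juncs <- structure_junctions(structure)
  out <- list()
  for (k in seq_len(nrow(juncs))) {
    jw <- extract_junction_window(structure, juncs[k, ], reads, annotations,
                                  window_bp = config$junction_window_bp)
    if (is.null(jw)) next
    rep1 <- classify_filler(jw, catalog, config, index, scoring)
    rep1 <- cbind(data.frame(junction_id = sprintf("%s_j%d", structure$locus_id, k),
                             stringsAsFactors = FALSE), rep1)
    out[[length(out) + 1]] <- rep1
  }
  if (length(out) == 0)
    return(data.frame(junction_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
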