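# Local alignment: scoring, seed index, seed-and-extend search, E-values.

#' Alignment scoring scheme
#'
#' Match/mismatch scores and affine gap penalties, plus Karlin-Altschul
#' parameters used for E-value computation. A gap of length L costs
#' `gap_open + L * gap_extend`. The ungapped Karlin lambda is computed
#' numerically from the score distribution under uniform base composition
#' (the root of `E[exp(lambda * S)] = 1`); K is a declared constant since
#' E-values here serve as a filter, not as publishable statistics.
#'
#' @param match Match score (positive integer, default 2).
#' @param mismatch Mismatch score (negative integer, default -3).
#' @param gap_open Gap opening penalty (negative, default -5).
#' @param gap_extend Gap extension penalty per base (negative, default -2).
#' @param karlin_K Karlin-Altschul K (default 0.1).
#' @param karlin_lambda Karlin-Altschul lambda; computed numerically when `NULL`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, karlin_K = 0.1,
                           karlin_lambda = NULL) {
  if (match <= 0 || mismatch >= 0) stop("require match > 0 > mismatch")
  if (gap_open >= 0 || gap_extend >= 0) stop("gap penalties must be negative")
  if (is.null(karlin_lambda)) {
    f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
    karlin_lambda <- uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  }
  if (karlin_K <= 0 || karlin_lambda <= 0) stop("Karlin parameters must be positive")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 karlin_K = karlin_K, karlin_lambda = karlin_lambda),
            class = "scoring_scheme")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct local
#' alignments with score at least `S` between random sequences of lengths
#' `m` (query) and `n` (database).
#'
#' @param score Alignment score(s).
#' @param query_len Query length (positive).
#' @param db_len Total database length (positive).
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value(s).
#' @export
evalue <- function(score, query_len, db_len, scheme = scoring_scheme()) {
  if (any(query_len <= 0) || any(db_len <= 0))
    stop("query_len and db_len must be positive")
  scheme$karlin_K * as.numeric(query_len) * as.numeric(db_len) *
    exp(-scheme$karlin_lambda * as.numeric(score))
}

#' Build a seed index over a sequence catalog
#'
#' Forward-strand k-mers of every catalog sequence are indexed; k-mers
#' containing N are skipped. Both strands are represented at search time:
#' queries are scanned in both orientations, and [index_lookup()] reports
#' forward as well as reverse-complement occurrences.
#'
#' @param catalog A [reference_catalog()], a list of [seq_record()]s, or a
#'   named character vector of sequences.
#' @param k k-mer size, between 8 and 21 (default 12).
#' @return An object of class `seed_index`.
#' @export
build_index <- function(catalog, k = 12L) {
  k <- as.integer(k)
  if (k < 8L || k > 21L) stop("k must lie between 8 and 21")
  seqs <- .catalog_sequences(catalog)
  if (length(seqs) == 0L) stop("cannot index an empty catalog")
  ptr <- .build_seed_index_cpp(unname(seqs), names(seqs), k)
  info <- .index_info_cpp(ptr)
  structure(list(ptr = ptr, k = k, names = info$names,
                 lengths = setNames(info$lengths, info$names),
                 total_len = info$total_len),
            class = "seed_index")
}

# Accepts reference_catalog, list of seq_record, or named character vector.
.catalog_sequences <- function(catalog) {
  if (inherits(catalog, "reference_catalog"))
    return(vapply(catalog$records, function(r) r$bases, character(1)))
  if (is.list(catalog) && length(catalog) && inherits(catalog[[1]], "seq_record")) {
    out <- vapply(catalog, function(r) r$bases, character(1))
    names(out) <- vapply(catalog, function(r) r$id, character(1))
    return(out)
  }
  if (is.character(catalog)) {
    if (is.null(names(catalog)) || any(!nzchar(names(catalog))))
      stop("character catalogs must be named")
    return(toupper(catalog))
  }
  stop("unsupported catalog type")
}

#' Look up a k-mer in a seed index
#'
#' @param index A [build_index()] object.
#' @param kmer A k-length string.
#' @return A data.frame with `subject_id`, `pos` (0-based), `strand`:
#'   forward occurrences of `kmer` on `+` and occurrences of its reverse
#'   complement on `-`.
#' @export
index_lookup <- function(index, kmer) {
  if (nchar(kmer) != index$k) stop("kmer length must equal index k")
  fwd <- .index_lookup_cpp(index$ptr, toupper(kmer))
  rev <- .index_lookup_cpp(index$ptr, .rc_cpp(toupper(kmer)))
  out <- rbind(
    if (nrow(fwd)) cbind(fwd, strand = "+", stringsAsFactors = FALSE),
    if (nrow(rev)) cbind(rev, strand = "-", stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(subject_id = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  out
}

#' Exact local (Smith-Waterman) alignment of two sequences
#'
#' Full-matrix affine-gap local alignment; intended for short sequences
#' (oracle checks, junction fillers). Coordinates are 0-based half-open.
#'
#' @param query,subject Sequence strings or [seq_record()]s.
#' @param scoring A [scoring_scheme()].
#' @return A list with `score`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `matches`, `aln_len`, `identity`.
#' @export
sw_align <- function(query, subject, scoring = scoring_scheme()) {
  q <- if (inherits(query, "seq_record")) query$bases else toupper(query)
  s <- if (inherits(subject, "seq_record")) subject$bases else toupper(subject)
  r <- .sw_local_cpp(q, s, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  r$identity <- if (r$aln_len > 0) r$matches / r$aln_len else 0
  r
}

#' Find scored local alignments of a query against an indexed catalog
#'
#' Seed-and-extend search: exact k-mer anchors are chained greedily on
#' near-constant diagonals (diagonal tolerance 100) and each chain is
#' extended by a banded affine-gap local alignment whose band follows the
#' chain. When `query x subject` is at most `exact_cells` dynamic-programming
#' cells, the band spans the whole matrix and the search is exactly
#' Smith-Waterman. Overlapping alignments to the same subject and strand are
#' merged to the best-scoring representative. Hits are reported on the
#' query's stored orientation; `strand` records the subject orientation.
#'
#' @param query A [seq_record()] or a single (optionally named) string.
#' @param index A [build_index()] object.
#' @param scoring A [scoring_scheme()].
#' @param min_identity Minimum fraction of identical columns (default 0.80).
#' @param max_evalue Maximum E-value (default 1e-50).
#' @param min_aln_len Minimum alignment length in columns (default 50).
#' @param exact_cells Full-matrix threshold in DP cells (default 2.1e6).
#' @param band_min,band_max Band half-width bounds for chain extension.
#' @param pad Rectangle padding beyond the seed chain, bp.
#' @return A hit data.frame (possibly zero rows) sorted by decreasing score,
#'   ties broken by `(subject_id, s_start, q_start)`.
#' @export
find_local_hits <- function(query, index, scoring = scoring_scheme(),
                            min_identity = 0.80, max_evalue = 1e-50,
                            min_aln_len = 50L, exact_cells = 2.1e6,
                            band_min = 150L, band_max = 400L, pad = 900L) {
  if (inherits(query, "seq_record")) {
    qid <- query$id; qseq <- query$bases
  } else {
    qid <- if (!is.null(names(query))) names(query)[1] else "query"
    qseq <- toupper(as.character(query)[1])
  }
  nq <- nchar(qseq)
  if (nq < index$k) stop("query shorter than index k")

  scan1 <- function(qs) {
    .scan_hits_cpp(index$ptr, qs, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend, exact_cells,
                   3000L, 100L, as.integer(band_min), as.integer(band_max),
                   as.integer(pad), 64L)
  }
  fwd <- scan1(qseq)
  rev <- scan1(.rc_cpp(qseq))

  mk <- function(df, strand) {
    if (nrow(df) == 0L) return(NULL)
    qs <- df$q_start; qe <- df$q_end
    if (strand == "-") { tmp <- nq - qe; qe <- nq - qs; qs <- tmp }
    data.frame(query_id = qid, q_start = qs, q_end = qe, strand = strand,
               subject_id = index$names[df$subject], s_start = df$s_start,
               s_end = df$s_end,
               identity = ifelse(df$aln_len > 0, df$matches / df$aln_len, 0),
               score = df$score,
               evalue = evalue(df$score, nq, index$total_len, scoring),
               aln_len = df$aln_len, stringsAsFactors = FALSE)
  }
  hits <- rbind(mk(fwd, "+"), mk(rev, "-"))
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- empty_hits(); out$category <- NULL; return(out)
  }
  hits <- hits[hits$identity >= min_identity & hits$evalue <= max_evalue &
                 hits$aln_len >= min_aln_len, , drop = FALSE]
  if (nrow(hits) == 0L) { out <- empty_hits(); out$category <- NULL; return(out) }
  hits <- hits[order(-hits$score, hits$subject_id, hits$s_start, hits$q_start), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == nrow(hits)) break
    js <- which(keep)
    js <- js[js > i]
    for (j in js) {
      if (hits$subject_id[j] != hits$subject_id[i] ||
          hits$strand[j] != hits$strand[i]) next
      qo <- min(hits$q_end[i], hits$q_end[j]) - max(hits$q_start[i], hits$q_start[j])
      so <- min(hits$s_end[i], hits$s_end[j]) - max(hits$s_start[i], hits$s_start[j])
      qmin <- min(hits$q_end[i] - hits$q_start[i], hits$q_end[j] - hits$q_start[j])
      smin <- min(hits$s_end[i] - hits$s_start[i], hits$s_end[j] - hits$s_start[j])
      if (qo > 0.5 * qmin && so > 0.5 * smin) keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
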