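# Sequence and alignment record I/O.
#
# Internal coordinates are uniformly 0-based half-open; report writers that
# target human-readable output convert to 1-based inclusive at the boundary.

#' Create a sequence record
#'
#' A `seq_record` holds a named sequence with an optional per-base Phred
#' quality vector. Bases are uppercased on ingest and characters outside
#' `{A,C,G,T,N}` are mapped to `N`.
#'
#' @param id Record identifier (non-empty string).
#' @param bases Sequence string.
#' @param quals Optional integer vector of Phred scores in `[0, 93]`, same
#'   length as `bases`.
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `bases`, `quals`.
#' @export
seq_record <- function(id, bases, quals = NULL, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  bases <- toupper(as.character(bases))
  if (grepl("[^ACGTN]", bases)) {
    warning(sprintf("record '%s': characters outside {A,C,G,T,N} mapped to N", id))
    bases <- gsub("[^ACGTN]", "N", bases)
  }
  if (!is.null(quals)) {
    quals <- as.integer(quals)
    if (length(quals) != nchar(bases))
      stop(sprintf("record '%s': quality length (%d) != sequence length (%d)",
                   id, length(quals), nchar(bases)))
    if (any(quals < 0L | quals > 93L))
      stop(sprintf("record '%s': Phred scores must lie in [0, 93]", id))
  }
  structure(list(id = id, description = description, bases = bases, quals = quals),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  %d bp%s%s\n", x$id, nchar(x$bases),
              if (is.null(x$quals)) "" else "  [+quals]",
              if (nzchar(x$description)) paste0("  ", x$description) else ""))
  invisible(x)
}

#' Sequence length of a record
#' @param x A `seq_record`.
#' @return Integer length in bases.
#' @export
seq_len_of <- function(x) nchar(x$bases)

#' Reverse complement
#'
#' @param x Sequence string or `seq_record`.
#' @return Same type as the input, reverse complemented (qualities reversed).
#' @export
revcomp <- function(x) {
  if (inherits(x, "seq_record")) {
    r <- x
    r$bases <- .rc_cpp(x$bases)
    if (!is.null(x$quals)) r$quals <- rev(x$quals)
    return(r)
  }
  .rc_cpp(as.character(x))
}

.read_lines_clean <- function(path) {
  x <- readLines(path, warn = FALSE)
  sub("\r$", "", x)
}

#' Read a FASTA file
#'
#' Multi-line records and CRLF line endings are accepted; bases are
#' uppercased and characters outside `{A,C,G,T,N}` are mapped to `N` with a
#' warning.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [seq_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  lines <- .read_lines_clean(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop(sprintf("'%s': not a FASTA file (no '>' header found)", path))
  idx <- which(hdr)
  recs <- vector("list", length(idx))
  ids <- character(length(idx))
  bounds <- c(idx, length(lines) + 1L)
  for (i in seq_along(idx)) {
    header <- sub("^>", "", lines[idx[i]])
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    body <- lines[seq.int(idx[i] + 1L, length.out = bounds[i + 1L] - idx[i] - 1L)]
    seqs <- paste0(body[nzchar(body)], collapse = "")
    if (!nzchar(seqs))
      stop(sprintf("'%s': record '%s' has an empty sequence", path, id))
    recs[[i]] <- seq_record(id, seqs, description = desc)
    ids[i] <- id
  }
  if (anyDuplicated(ids))
    stop(sprintf("'%s': duplicated record id '%s'", path, ids[anyDuplicated(ids)]))
  names(recs) <- ids
  recs
}

#' Write records to a FASTA file
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @param width Line wrap width (default 80).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    n <- nchar(r$bases)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(r$bases, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path Path to a FASTQ file.
#' @return A named list of [seq_record()] objects with qualities.
#' @export
read_fastq <- function(path) {
  lines <- .read_lines_clean(path)
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop(sprintf("'%s': FASTQ line count (%d) is not a multiple of 4",
                 path, length(lines)))
  n <- length(lines) %/% 4L
  recs <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    off <- (i - 1L) * 4L
    if (!startsWith(lines[off + 1L], "@"))
      stop(sprintf("'%s': record %d does not start with '@'", path, i))
    if (!startsWith(lines[off + 3L], "+"))
      stop(sprintf("'%s': record %d is missing the '+' separator", path, i))
    header <- sub("^@", "", lines[off + 1L])
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    seqs <- lines[off + 2L]
    qstr <- lines[off + 4L]
    if (nchar(seqs) != nchar(qstr))
      stop(sprintf("'%s': record %d ('%s'): sequence and quality lengths differ",
                   path, i, id))
    quals <- as.integer(charToRaw(qstr)) - 33L
    recs[[i]] <- seq_record(id, seqs, quals = quals, description = desc)
    ids[i] <- id
  }
  names(recs) <- ids
  recs
}

#' Write records to a FASTQ file (Phred+33)
#'
#' @param records List of [seq_record()] objects; all must carry qualities.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    if (is.null(r$quals)) stop(sprintf("record '%s' has no qualities", r$id))
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(c(paste0("@", hdr), r$bases, "+",
                 rawToChar(as.raw(r$quals + 33L))), con)
  }
  invisible(path)
}

#' Create a genomic interval table
#'
#' @param chrom Chromosome/sequence names.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @param name Optional feature names.
#' @param score Optional numeric scores.
#' @param strand Optional strand (`"+"`, `"-"`, or `"."`).
#' @return A data.frame with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("intervals require start < end (0-based half-open)")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Write intervals as BED (3- or 6-column)
#'
#' BED output is 0-based half-open, tab-separated.
#'
#' @param intervals A data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(intervals)))
    cols <- c(cols, "name", "score", "strand")
  df <- as.data.frame(intervals)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval table
#' @param path Path to a 3+ column BED file.
#' @return A `genomic_intervals` data.frame.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 6) names(df)[4:6] <- c("name", "score", "strand")
  genomic_intervals(df$chrom, df$start, df$end,
                    name = if (ncol(df) >= 6) df$name else NULL,
                    score = if (ncol(df) >= 6) df$score else NULL,
                    strand = if (ncol(df) >= 6) df$strand else NULL)
}

.hits_columns <- c("query_id", "q_start", "q_end", "strand", "subject_id",
                   "s_start", "s_end", "identity", "score", "evalue",
                   "aln_len", "category")

#' Empty local-hit table
#' @return A zero-row data.frame with the 12 canonical hit columns.
#' @export
empty_hits <- function() {
  df <- data.frame(query_id = character(), q_start = integer(),
                   q_end = integer(), strand = character(),
                   subject_id = character(), s_start = integer(),
                   s_end = integer(), identity = numeric(), score = numeric(),
                   evalue = numeric(), aln_len = integer(),
                   category = character(), stringsAsFactors = FALSE)
  df
}

#' Write local hits as a 12-column TSV
#'
#' One row per hit with a fixed header, readable back losslessly with
#' [read_hits_tsv()]. Query and subject coordinates are 0-based half-open.
#'
#' @param hits Hit data.frame (as produced by [find_local_hits()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- as.data.frame(hits)
  if (is.null(df$category)) df$category <- NA_character_
  missing_cols <- setdiff(.hits_columns, names(df))
  if (length(missing_cols))
    stop("hit table is missing columns: ", paste(missing_cols, collapse = ", "))
  write.table(df[, .hits_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a 12-column hit TSV
#'
#' Extra columns beyond the canonical 12 are ignored, so tables produced by
#' external aligners can be ingested as long as the canonical columns are
#' present.
#'
#' @param path Path to a hit TSV written by [write_hits_tsv()] or compatible.
#' @return Hit data.frame.
#' @export
read_hits_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.hits_columns, names(df))
  if (length(missing_cols))
    stop("hit table is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, .hits_columns]
  df$strand <- as.character(df$strand)
  df$category <- as.character(df$category)
  df
}

#' Convert 0-based half-open coordinates to 1-based inclusive (for reports)
#' @param start,end 0-based half-open coordinates.
#' @return A list with `start` and `end`, 1-based inclusive.
#' @export
to_report_coords <- function(start, end) list(start = start + 1, end = end)

#' Convert 1-based inclusive coordinates to 0-based half-open
#' @param start,end 1-based inclusive coordinates.
#' @return A list with `start` and `end`, 0-based half-open.
#' @export
from_report_coords <- function(start, end) list(start = start - 1, end = end)
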