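# Locus resolution: cluster annotated reads into insertion loci, derive a
# consensus unit chain per locus, classify the genome-level event, call
# border status and estimate zygosity.

.KIND_MAP <- c(NUCLEAR = "GENOMIC", TDNA = "TDNA", BVB = "BVB",
               PLASTOME = "CPDNA", CHONDROME = "CHONDRIO",
               AGROBACTERIUM = "FILLER")

#' Convert a read annotation into an ordered unit chain
#'
#' Segments become chain units ordered along the read; interior unannotated
#' gaps become `UNKNOWN_LOWQ` units (candidate low-quality inverted-repeat
#' arms). Terminal unannotated read ends are not units.
#'
#' @param annotation A [annotate_read()] result.
#' @return data.frame of units with read coordinates, subject coordinates,
#'   orientation and (for gaps) mean Phred.
#' @export
read_chain <- function(annotation) {
  seg <- annotation$segments
  units <- data.frame(kind = character(), subject_id = character(),
                      s_start = numeric(), s_end = numeric(),
                      orientation = character(), q_start = numeric(),
                      q_end = numeric(), score = numeric(),
                      identity = numeric(), mean_phred = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(seg) > 0) {
    units <- data.frame(kind = unname(.KIND_MAP[seg$category]),
                        subject_id = seg$subject_id, s_start = seg$s_start,
                        s_end = seg$s_end, orientation = seg$strand,
                        q_start = seg$q_start, q_end = seg$q_end,
                        score = seg$score, identity = seg$identity,
                        mean_phred = NA_real_, stringsAsFactors = FALSE)
  }
  gaps <- annotation$gaps
  if (!is.null(gaps) && nrow(gaps) > 0 && nrow(seg) > 0) {
    lo <- min(seg$q_start); hi <- max(seg$q_end)
    interior <- gaps[gaps$q_start >= lo - 10 & gaps$q_end <= hi + 10, ,
                     drop = FALSE]
    if (nrow(interior) > 0) {
      gu <- data.frame(kind = "UNKNOWN_LOWQ", subject_id = NA_character_,
                       s_start = NA_real_, s_end = NA_real_, orientation = "+",
                       q_start = interior$q_start, q_end = interior$q_end,
                       score = 0, identity = NA_real_,
                       mean_phred = if ("mean_phred" %in% names(interior))
                         interior$mean_phred else NA_real_,
                       stringsAsFactors = FALSE)
      units <- rbind(units, gu)
    }
  }
  units <- units[order(units$q_start, units$q_end), , drop = FALSE]
  rownames(units) <- NULL
  attr(units, "read_id") <- annotation$read_id
  attr(units, "read_len") <- annotation$read_len
  attr(units, "flipped") <- FALSE
  units
}

#' Reverse-complement a unit chain
#' @param chain A [read_chain()] table.
#' @return The chain as seen from the opposite read orientation.
#' @export
flip_chain <- function(chain) {
  n <- attr(chain, "read_len")
  out <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
  out$orientation <- ifelse(out$orientation == "+", "-", "+")
  qs <- n - out$q_end; qe <- n - out$q_start
  out$q_start <- qs; out$q_end <- qe
  rownames(out) <- NULL
  attr(out, "read_id") <- attr(chain, "read_id")
  attr(out, "read_len") <- n
  attr(out, "flipped") <- !attr(chain, "flipped")
  out
}

# Reference anchors implied by a chain: genomic unit edges at junctions.
# direction LEFT_OF_INSERT: genomic sequence continues to lower reference
# coordinates left of the breakpoint, the insert attaches on its right.
.chain_anchors <- function(chain, tol = 100) {
  out <- data.frame(chrom = character(), pos = numeric(),
                    direction = character(), unit = integer(),
                    stringsAsFactors = FALSE)
  n <- nrow(chain)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    u <- chain[i, ]; v <- chain[i + 1, ]
    if (u$kind == "GENOMIC" && v$kind == "GENOMIC") {
      contiguous <- identical(u$subject_id, v$subject_id) &&
        u$orientation == v$orientation &&
        ((u$orientation == "+" && abs(v$s_start - u$s_end) <= tol) ||
         (u$orientation == "-" && abs(u$s_start - v$s_end) <= tol))
      if (contiguous) next
    }
    if (u$kind == "GENOMIC") {
      if (u$orientation == "+")
        out <- rbind(out, data.frame(chrom = u$subject_id, pos = u$s_end,
                                     direction = "LEFT_OF_INSERT", unit = i))
      else
        out <- rbind(out, data.frame(chrom = u$subject_id, pos = u$s_start,
                                     direction = "RIGHT_OF_INSERT", unit = i))
    }
    if (v$kind == "GENOMIC") {
      if (v$orientation == "+")
        out <- rbind(out, data.frame(chrom = v$subject_id, pos = v$s_start,
                                     direction = "RIGHT_OF_INSERT", unit = i + 1L))
      else
        out <- rbind(out, data.frame(chrom = v$subject_id, pos = v$s_end,
                                     direction = "LEFT_OF_INSERT", unit = i + 1L))
    }
  }
  out
}

# Similarity of two chain units (0 = incompatible).
.unit_sim <- function(u, v) {
  ku <- u$kind; kv <- v$kind
  if (ku == "UNKNOWN_LOWQ" || kv == "UNKNOWN_LOWQ") {
    known <- if (ku == "UNKNOWN_LOWQ") v else u
    unk <- if (ku == "UNKNOWN_LOWQ") u else v
    if (known$kind %in% c("TDNA", "BVB", "UNKNOWN_LOWQ")) {
      lu <- unk$q_end - unk$q_start
      lk <- if (known$kind == "UNKNOWN_LOWQ") known$q_end - known$q_start
            else known$s_end - known$s_start
      r <- lu / max(1, lk)
      if (r > 0.4 && r < 2.5) return(0.2)
    }
    return(0)
  }
  if (ku != kv) return(0)
  if (!identical(u$subject_id, v$subject_id)) return(0)
  if (u$orientation != v$orientation) return(0)
  inter <- min(u$s_end, v$s_end) - max(u$s_start, v$s_start)
  if (inter <= 0) return(0)
  uni <- max(u$s_end, v$s_end) - min(u$s_start, v$s_start)
  inter / uni
}

# Order-preserving alignment of two unit chains (LCS-style DP, gap cost 0).
# Returns total score and the matched index pairs.
.chain_align <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(list(score = 0, pairs = cbind(integer(0), integer(0))))
  S <- matrix(0, na + 1, nb + 1)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    m <- .unit_sim(a[i, ], b[j, ])
    S[i + 1, j + 1] <- max(S[i, j] + m, S[i, j + 1], S[i + 1, j])
  }
  pairs <- NULL
  i <- na; j <- nb
  while (i > 0 && j > 0) {
    m <- .unit_sim(a[i, ], b[j, ])
    if (m > 0 && S[i + 1, j + 1] == S[i, j] + m) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1]) i <- i - 1
    else j <- j - 1
  }
  if (is.null(pairs)) pairs <- cbind(integer(0), integer(0))
  list(score = S[na + 1, nb + 1], pairs = pairs)
}

#' Cluster annotated reads into insertion loci
#'
#' Reference projections of genome::insert changeovers are single-linkage
#' clustered per chromosome within `merge_window` (default 1 kbp); reads
#' sharing an anchor cluster are joined transitively into one locus. Reads
#' with no genomic segment form an unanchored pool.
#'
#' @param annotations Named list of [annotate_read()] results.
#' @param config A [pipeline_config()].
#' @return List with `loci` (each: `read_ids`, `anchors` data.frame) and
#'   `unanchored` read ids.
#' @export
cluster_loci <- function(annotations, config = pipeline_config()) {
  chains <- lapply(annotations, read_chain)
  anch <- list()
  for (k in seq_along(chains)) {
    a <- .chain_anchors(chains[[k]])
    if (nrow(a) > 0) {
      a$read_id <- attr(chains[[k]], "read_id")
      anch[[length(anch) + 1]] <- a
    }
  }
  has_genomic <- vapply(chains, function(ch) any(ch$kind == "GENOMIC"), logical(1))
  unanchored <- names(annotations)[!has_genomic]
  if (length(anch) == 0)
    return(list(loci = list(), unanchored = names(annotations)))
  anch <- do.call(rbind, anch)

  # single-linkage position clustering per (chromosome, direction): the two
  # fusions of a reciprocal translocation share breakpoint positions but
  # opposite directions and must remain distinct loci; the two junctions of
  # one insertion are joined through the reads that span both
  anch$cluster <- NA_integer_
  cl <- 0L
  for (key in unique(paste(anch$chrom, anch$direction))) {
    sel <- which(paste(anch$chrom, anch$direction) == key)
    ord <- sel[order(anch$pos[sel])]
    brk <- c(0, cumsum(diff(anch$pos[ord]) > config$merge_window))
    anch$cluster[ord] <- cl + 1L + brk
    cl <- max(anch$cluster[ord])
  }

  # union-find over reads sharing a cluster
  rids <- unique(anch$read_id)
  parent <- seq_along(rids); names(parent) <- rids
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (cc in unique(anch$cluster)) {
    rr <- match(unique(anch$read_id[anch$cluster == cc]), rids)
    if (length(rr) > 1) for (t in rr[-1]) {
      a <- findp(rr[1]); b <- findp(t); if (a != b) parent[b] <- a
    }
  }
  comp <- vapply(seq_along(rids), findp, integer(1))
  loci <- lapply(unique(comp), function(cc) {
    ids <- rids[comp == cc]
    list(read_ids = ids,
         anchors = anch[anch$read_id %in% ids,
                        c("chrom", "pos", "direction", "cluster", "read_id")])
  })
  # deterministic order: by first anchor position
  key <- vapply(loci, function(l) sprintf("%s:%012.0f", l$anchors$chrom[1],
                                          min(l$anchors$pos)), character(1))
  loci <- loci[order(key)]
  list(loci = loci, unanchored = setdiff(unanchored, anch$read_id))
}

# Orient every chain consistently with a reference chain.
.orient_chains <- function(chains) {
  nu <- vapply(chains, nrow, integer(1))
  rl <- vapply(chains, function(c) attr(c, "read_len"), numeric(1))
  ref_i <- order(-nu, -rl)[1]
  ref <- chains[[ref_i]]
  fg <- which(ref$kind == "GENOMIC")
  if (length(fg) && ref$orientation[fg[1]] == "-") ref <- flip_chain(ref)
  out <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    if (i == ref_i) { out[[i]] <- ref; next }
    asis <- .chain_align(ref, chains[[i]])$score
    flipped <- .chain_align(ref, flip_chain(chains[[i]]))$score
    out[[i]] <- if (flipped > asis) flip_chain(chains[[i]]) else chains[[i]]
  }
  list(chains = out, ref_index = ref_i)
}

#' Build the consensus insertion structure of one locus
#'
#' Individual reads determine the structure: each supporting read's tiled
#' annotation becomes an oriented unit chain; the chain resolving the most
#' units (preferring reads spanning from genomic flank to genomic flank)
#' becomes the backbone. An `UNKNOWN_LOWQ` unit in the backbone that aligns
#' with a well-annotated T-DNA/BVB unit in another (typically
#' opposite-orientation) read is replaced by that unit - the rescue that
#' resolves inverted repeats whose second arm is emitted at low quality.
#' Where reads disagree on a unit's extent, the largest extent supported by
#' any single read is chosen ("largest possible T-DNA"). Flank anchors are
#' the median changeover projections over supporting reads.
#'
#' @param locus One locus group from [cluster_loci()].
#' @param annotations Named list of [annotate_read()] results.
#' @param catalog A [reference_catalog()].
#' @param config A [pipeline_config()].
#' @return An object of class `insertion_structure`.
#' @export
build_structure <- function(locus, annotations, catalog,
                            config = pipeline_config()) {
  chains <- lapply(annotations[locus$read_ids], read_chain)
  chains <- chains[vapply(chains, nrow, integer(1)) > 0]
  ori <- .orient_chains(chains)
  chains <- ori$chains

  is_insert <- function(k) !(k %in% c("GENOMIC"))
  spanning <- vapply(chains, function(ch) {
    n <- nrow(ch)
    n >= 3 && ch$kind[1] == "GENOMIC" && ch$kind[n] == "GENOMIC" &&
      any(is_insert(ch$kind))
  }, logical(1))

  flags <- character(0)
  if (any(spanning)) {
    cand <- which(spanning)
    nins <- vapply(cand, function(i) sum(is_insert(chains[[i]]$kind)), numeric(1))
    span <- vapply(cand, function(i) {
      ins <- chains[[i]][is_insert(chains[[i]]$kind), , drop = FALSE]
      sum(ins$q_end - ins$q_start)
    }, numeric(1))
    backbone <- chains[[cand[order(-nins, -span)[1]]]]
  } else {
    merged <- .merge_partial_chains(chains)
    backbone <- merged$chain
    flags <- c(flags, merged$flags)
  }
  if (is.null(backbone) || nrow(backbone) == 0) {
    return(structure(list(locus_id = NA, chain = NULL, flags = "UNRESOLVED",
                          supporting_reads = locus$read_ids,
                          candidate_chains = chains),
                     class = "insertion_structure"))
  }

  # Low-quality gaps: first try to explain a gap as the eroded edge of an
  # adjacent truncated insert unit (the unannotatable start of a
  # low-quality inverted-repeat arm); unexplained gaps that match a whole
  # well-annotated T-DNA/BVB unit in another (typically opposite
  # orientation) read are replaced by that unit.
  sub_len <- function(id) nchar(catalog$records[[id]]$bases)
  unknown <- which(backbone$kind == "UNKNOWN_LOWQ")
  absorb <- logical(nrow(backbone))
  for (i in unknown) {
    gap_len <- backbone$q_end[i] - backbone$q_start[i]
    explained <- FALSE
    if (i > 1 && backbone$kind[i - 1] %in% c("TDNA", "BVB")) {
      u <- backbone[i - 1, ]  # gap faces this unit's chain-right edge
      missing <- if (u$orientation == "+") sub_len(u$subject_id) - u$s_end
                 else u$s_start
      if (missing >= 0.6 * gap_len) explained <- TRUE
    }
    if (!explained && i < nrow(backbone) &&
        backbone$kind[i + 1] %in% c("TDNA", "BVB")) {
      u <- backbone[i + 1, ]  # gap faces this unit's chain-left edge
      missing <- if (u$orientation == "+") u$s_start
                 else sub_len(u$subject_id) - u$s_end
      if (missing >= 0.6 * gap_len) explained <- TRUE
    }
    absorb[i] <- explained
  }
  bb_flip <- attr(backbone, "flipped")
  order_pref <- order(!vapply(chains, function(c)
    xor(attr(c, "flipped"), bb_flip), logical(1)))
  for (i in setdiff(unknown, which(absorb))) {
    gap_len <- backbone$q_end[i] - backbone$q_start[i]
    for (ci in order_pref) {
      al <- .chain_align(backbone, chains[[ci]])
      hit <- al$pairs[al$pairs[, 1] == i, , drop = FALSE]
      if (nrow(hit) == 1) {
        part <- chains[[ci]][hit[1, 2], ]
        part_len <- part$s_end - part$s_start
        if (part$kind %in% c("TDNA", "BVB") && !is.na(part_len) &&
            gap_len >= 0.5 * part_len) {
          keepq <- c("kind", "subject_id", "s_start", "s_end", "orientation",
                     "score", "identity")
          backbone[i, keepq] <- part[, keepq]
          break
        }
      }
    }
  }
  if (any(absorb)) {
    rl <- attr(backbone, "read_len"); rid <- attr(backbone, "read_id")
    backbone <- backbone[!absorb, , drop = FALSE]
    rownames(backbone) <- NULL
    attr(backbone, "read_len") <- rl; attr(backbone, "read_id") <- rid
    attr(backbone, "flipped") <- bb_flip
  }

  # largest single-read-supported extent per insert unit
  for (i in which(is_insert(backbone$kind) & backbone$kind != "UNKNOWN_LOWQ")) {
    best_len <- backbone$s_end[i] - backbone$s_start[i]
    for (ci in seq_along(chains)) {
      al <- .chain_align(backbone, chains[[ci]])
      hit <- al$pairs[al$pairs[, 1] == i, , drop = FALSE]
      if (nrow(hit) == 1) {
        part <- chains[[ci]][hit[1, 2], ]
        if (part$kind == backbone$kind[i] &&
            identical(part$subject_id, backbone$subject_id[i]) &&
            part$orientation == backbone$orientation[i]) {
          len <- part$s_end - part$s_start
          if (!is.na(len) && len > best_len) {
            best_len <- len
            backbone$s_start[i] <- part$s_start; backbone$s_end[i] <- part$s_end
          }
        }
      }
    }
  }

  # flank anchors: consensus over supporting reads
  bb_anch <- .chain_anchors(backbone)
  consensus_anchor <- function(target) {
    if (is.null(target)) return(NULL)
    ps <- numeric(0)
    for (ci in seq_along(chains)) {
      a <- .chain_anchors(chains[[ci]])
      a <- a[a$chrom == target$chrom & a$direction == target$direction &
               abs(a$pos - target$pos) <= config$merge_window, , drop = FALSE]
      if (nrow(a) > 0) ps <- c(ps, a$pos[which.min(abs(a$pos - target$pos))])
    }
    if (length(ps) == 0) ps <- target$pos
    list(chrom = target$chrom, pos = round(median(ps)),
         direction = target$direction, support = length(ps))
  }
  left <- if (nrow(bb_anch)) consensus_anchor(bb_anch[1, ]) else NULL
  right <- if (nrow(bb_anch) > 1) consensus_anchor(bb_anch[nrow(bb_anch), ]) else NULL

  tsd <- NA_integer_
  if (!is.null(left) && !is.null(right) && left$chrom == right$chrom &&
      left$direction == "LEFT_OF_INSERT" && right$direction == "RIGHT_OF_INSERT")
    tsd <- max(0L, as.integer(right$pos - left$pos))

  # all junction anchors observed across supporting reads (the backbone
  # need not traverse every breakpoint of the locus, e.g. the far border
  # of a large duplication)
  allan <- do.call(rbind, lapply(chains, .chain_anchors))
  anchors <- NULL
  if (!is.null(allan) && nrow(allan)) {
    grp_key <- paste(allan$chrom, allan$direction)
    anchors <- do.call(rbind, lapply(split(allan, grp_key), function(a) {
      a <- a[order(a$pos), , drop = FALSE]
      cls <- cumsum(c(0, diff(a$pos) > config$merge_window))
      do.call(rbind, lapply(split(a, cls), function(b)
        data.frame(chrom = b$chrom[1], pos = round(median(b$pos)),
                   direction = b$direction[1], support = nrow(b),
                   stringsAsFactors = FALSE)))
    }))
    rownames(anchors) <- NULL
  }

  if (length(chains) == 1) flags <- c(flags, "LOW_SUPPORT")
  locus_id <- if (!is.null(left)) sprintf("%s_%d", left$chrom, left$pos)
              else sprintf("locus_%s", locus$read_ids[1])

  bs <- border_status(backbone, catalog, lb_slack = config$lb_slack)
  structure(list(locus_id = locus_id, chain = bs$chain,
                 internal_junctions = bs$internal,
                 left_flank = left, right_flank = right,
                 anchors = anchors,
                 target_site_deletion_bp = tsd,
                 supporting_reads = locus$read_ids, flags = flags),
            class = "insertion_structure")
}

# Greedy left-to-right merge of partial chains when no read spans the
# whole insert.
.merge_partial_chains <- function(chains) {
  has_left <- vapply(chains, function(ch) ch$kind[1] == "GENOMIC", logical(1))
  flags <- character(0)
  if (!any(has_left)) {
    nu <- vapply(chains, nrow, integer(1))
    return(list(chain = chains[[which.max(nu)]], flags = "UNRESOLVED"))
  }
  start_i <- which(has_left)[which.max(vapply(which(has_left),
                                              function(i) nrow(chains[[i]]), integer(1)))]
  cons <- chains[[start_i]]
  used <- rep(FALSE, length(chains)); used[start_i] <- TRUE
  repeat {
    best <- NULL; best_gain <- 0; best_i <- NA
    for (i in seq_along(chains)) {
      if (used[i]) next
      al <- .chain_align(cons, chains[[i]])
      if (nrow(al$pairs) == 0) next
      gain <- nrow(chains[[i]]) - max(al$pairs[, 2])
      if (gain > best_gain &&
          max(al$pairs[, 1]) >= nrow(cons) - 1) { # overlap near consensus tail
        best_gain <- gain; best_i <- i
        best <- chains[[i]][seq.int(max(al$pairs[, 2]) + 1, nrow(chains[[i]])), ,
                            drop = FALSE]
      }
    }
    if (is.null(best)) break
    rl <- attr(cons, "read_len"); rid <- attr(cons, "read_id")
    fl <- attr(cons, "flipped")
    cons <- rbind(cons, best)
    attr(cons, "read_len") <- rl; attr(cons, "read_id") <- rid
    attr(cons, "flipped") <- fl
    used[best_i] <- TRUE
  }
  if (cons$kind[nrow(cons)] != "GENOMIC") flags <- c(flags, "PARTIAL")
  flags <- c(flags, "MERGED")
  list(chain = cons, flags = flags)
}

#' Annotate border status of the T-DNA units of a chain
#'
#' For each T-DNA unit edge: `LB_INTACT` when the unit extends to within
#' `lb_slack` (default 3 bp) of the start of the 25 bp LB repeat at vector
#' position 1 (so the conventional transfer start at position 4 still counts
#' as intact), `RB_INTACT` analogously at the RB repeat, otherwise the
#' corresponding `_TRUNCATED` label. Chain edges between two insert units
#' are `INTERNAL`; edges where two units meet at their RB-proximal ends are
#' flagged `RB::RB` fusions.
#'
#' @param chain A unit chain (from [read_chain()] or [build_structure()]).
#' @param catalog A [reference_catalog()] with `tdna_borders`.
#' @param lb_slack Border slack in bp (default 3).
#' @return List: `chain` with `border_left`/`border_right` columns and
#'   `internal` (data.frame of internal edges with their facing borders).
#' @export
border_status <- function(chain, catalog, lb_slack = 3L) {
  chain$border_left <- NA_character_
  chain$border_right <- NA_character_
  edge_label <- function(u, side) {
    bd <- catalog$tdna_borders[[u$subject_id]]
    if (is.null(bd)) return(NA_character_)
    lo_edge <- if (u$orientation == "+") side == "left" else side == "right"
    if (lo_edge) {
      if (u$s_start <= bd$lb[1] + lb_slack) "LB_INTACT" else "LB_TRUNCATED"
    } else {
      if (u$s_end >= bd$rb[2] - lb_slack) "RB_INTACT" else "RB_TRUNCATED"
    }
  }
  tu <- which(chain$kind == "TDNA")
  for (i in tu) {
    chain$border_left[i] <- edge_label(chain[i, ], "left")
    chain$border_right[i] <- edge_label(chain[i, ], "right")
  }
  internal <- data.frame(left_unit = integer(), right_unit = integer(),
                         label = character(), rb_rb = logical(),
                         stringsAsFactors = FALSE)
  for (i in tu) {
    nb <- i + 1L
    if (nb <= nrow(chain) && chain$kind[nb] %in% c("TDNA", "BVB")) {
      lface <- sub("_.*", "", chain$border_right[i])      # LB or RB
      rface <- if (chain$kind[nb] == "TDNA")
        sub("_.*", "", chain$border_left[nb]) else "BVB"
      internal <- rbind(internal, data.frame(
        left_unit = i, right_unit = nb,
        label = paste0(lface, "::", rface),
        rb_rb = identical(lface, "RB") && identical(rface, "RB"),
        stringsAsFactors = FALSE))
      chain$border_right[i] <- paste0("INTERNAL_", chain$border_right[i])
      if (chain$kind[nb] == "TDNA")
        chain$border_left[nb] <- paste0("INTERNAL_",
                                        edge_label(chain[nb, ], "left"))
    }
  }
  # also mark left edges adjacent to a preceding insert unit
  for (i in tu) {
    if (i > 1 && chain$kind[i - 1] %in% c("TDNA", "BVB") &&
        !startsWith(chain$border_left[i], "INTERNAL"))
      chain$border_left[i] <- paste0("INTERNAL_", chain$border_left[i])
  }
  list(chain = chain, internal = internal)
}

#' Classify genome-level events of resolved structures
#'
#' Flanks on different chromosomes give `TRANSLOCATION_FUSION`; a structure
#' without insert units whose genomic flanks are discontinuous gives
#' `TDNA_FREE_FUSION`; same-chromosome flanks whose terminal genomic units
#' have opposite orientations give `INVERTED_DUPLICATION`; one T-DNA unit
#' gives `CANONICAL_INSERTION`; two or more insert units give
#' `COMPLEX_ARRAY`. A chain containing an organellar (cpDNA) unit yields an
#' additional `CPDNA_INSERTION` call. Translocation-type fusions joining
#' the same chromosome pair with complementary arms are paired as
#' reciprocal partners in `notes`.
#'
#' @param structures List of [build_structure()] results.
#' @return data.frame: `locus_id`, `event_type`, `partners`, `notes`.
#' @export
classify_event <- function(structures) {
  rows <- list()
  for (s in structures) {
    if (is.null(s$chain) || "UNRESOLVED" %in% s$flags) {
      rows[[length(rows) + 1]] <- data.frame(locus_id = s$locus_id %||% NA,
                                             event_type = "UNRESOLVED",
                                             partners = NA, notes = "",
                                             stringsAsFactors = FALSE)
      next
    }
    ch <- s$chain
    ins <- ch[!(ch$kind %in% c("GENOMIC", "UNKNOWN_LOWQ")), , drop = FALSE]
    n_tdna <- sum(ins$kind %in% c("TDNA", "BVB"))
    gen <- ch[ch$kind == "GENOMIC", , drop = FALSE]
    lf <- s$left_flank; rf <- s$right_flank
    ev <- NULL; partners <- NA; notes <- character(0)
    diff_chrom <- !is.null(lf) && !is.null(rf) && lf$chrom != rf$chrom
    if (nrow(ins) == 0) {
      ev <- "TDNA_FREE_FUSION"
      partners <- if (diff_chrom) paste(lf$chrom, rf$chrom, sep = "|")
                  else if (!is.null(lf)) lf$chrom else NA
    } else if (diff_chrom) {
      ev <- "TRANSLOCATION_FUSION"
      partners <- paste(lf$chrom, rf$chrom, sep = "|")
    } else if (nrow(gen) >= 2 &&
               gen$orientation[1] != gen$orientation[nrow(gen)]) {
      ev <- "INVERTED_DUPLICATION"
      partners <- lf$chrom
      dup <- gen[gen$orientation == "-", , drop = FALSE]
      if (nrow(dup))
        notes <- c(notes, sprintf("duplicated_span=%d",
                                  as.integer(max(dup$s_end) - min(dup$s_start))))
    } else if (n_tdna == 0 && any(ins$kind == "CPDNA")) {
      ev <- "CPDNA_INSERTION"
      partners <- if (!is.null(lf)) lf$chrom else NA
    } else if (n_tdna == 1 && nrow(ins) == 1) {
      ev <- "CANONICAL_INSERTION"
      partners <- if (!is.null(lf)) lf$chrom else NA
    } else {
      ev <- "COMPLEX_ARRAY"
      partners <- if (!is.null(lf)) lf$chrom else NA
      notes <- c(notes, sprintf("n_units=%d", nrow(ins)))
    }
    if (any(ch$kind == "BVB")) notes <- c(notes, "BVB_present")
    rows[[length(rows) + 1]] <- data.frame(locus_id = s$locus_id,
                                           event_type = ev, partners = partners,
                                           notes = paste(notes, collapse = ";"),
                                           stringsAsFactors = FALSE)
    if (any(ch$kind == "CPDNA") && ev != "CPDNA_INSERTION")
      rows[[length(rows) + 1]] <- data.frame(locus_id = s$locus_id,
                                             event_type = "CPDNA_INSERTION",
                                             partners = partners, notes = "",
                                             stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) return(data.frame(locus_id = character(),
                                     event_type = character(),
                                     partners = character(), notes = character(),
                                     stringsAsFactors = FALSE))
  # reciprocal pairing of fusion events on the same chromosome pair
  fus <- which(ev$event_type %in% c("TRANSLOCATION_FUSION", "TDNA_FREE_FUSION") &
                 grepl("\\|", ev$partners))
  if (length(fus) > 1) {
    key <- vapply(strsplit(ev$partners[fus], "\\|"), function(p)
      paste(sort(p), collapse = "|"), character(1))
    for (kk in unique(key[duplicated(key)])) {
      grp <- fus[key == kk]
      arms <- ev$partners[grp]
      if (length(unique(arms)) > 1) {
        for (g in grp) {
          mates <- setdiff(grp[ev$partners[grp] != ev$partners[g]], g)
          if (length(mates))
            ev$notes[g] <- paste(c(ev$notes[g][nzchar(ev$notes[g])],
                                   sprintf("reciprocal_pair=%s",
                                           paste(ev$locus_id[mates],
                                                 collapse = ","))),
                                 collapse = ";")
        }
      }
    }
  }
  rownames(ev) <- NULL
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate locus zygosity from spanning-read counts
#'
#' In a selected segregating T2 pool two thirds of chromosomes carry the
#' insertion, so the wild-type allele contributes ~1/3 of spanning reads. A
#' wild-type fraction in `[0.15, 0.60]` is called `SEGREGATING`, below 0.15
#' `HOMOZYGOUS`; anything else, or fewer than `min_depth` spanning reads,
#' is `UNDETERMINED`.
#'
#' @param locus_id Locus identifier.
#' @param n_insert Number of insert-supporting reads.
#' @param n_wt Number of reads spanning the unmodified reference interval.
#' @param config A [pipeline_config()].
#' @return List of class `zygosity_estimate`: `locus_id`,
#'   `wt_allele_read_fraction`, `call`.
#' @export
estimate_zygosity <- function(locus_id, n_insert, n_wt,
                              config = pipeline_config()) {
  total <- n_insert + n_wt
  if (total < config$min_depth) {
    return(structure(list(locus_id = locus_id,
                          wt_allele_read_fraction = NA_real_,
                          call = "UNDETERMINED"), class = "zygosity_estimate"))
  }
  fr <- n_wt / total
  call <- if (fr < 0.15) "HOMOZYGOUS"
          else if (fr <= 0.60) "SEGREGATING"
          else "UNDETERMINED"
  structure(list(locus_id = locus_id, wt_allele_read_fraction = fr,
                 call = call), class = "zygosity_estimate")
}

#' @export
print.insertion_structure <- function(x, ...) {
  cat(sprintf("<insertion_structure> %s  %d reads%s\n", x$locus_id,
              length(x$supporting_reads),
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  if (!is.null(x$chain)) {
    for (i in seq_len(nrow(x$chain))) {
      u <- x$chain[i, ]
      cat(sprintf("  %-12s %-10s %s %9.0f-%9.0f\n", u$kind,
                  ifelse(is.na(u$subject_id), "-", u$subject_id),
                  u$orientation, u$s_start, u$s_end))
    }
  }
  invisible(x)
}
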