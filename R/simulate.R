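# Synthetic data: genomes with planted integration events and ONT-like
# reads with per-read truth. Every planted feature (junction anchor, unit
# chain, filler, microhomology, inverted-repeat arm) is recorded so pipeline
# output can be scored without re-simulation.

#' Simulation configuration
#'
#' Defaults emulate a selected segregating T2 read pool: five 150 kbp
#' chromosomes plus a 20 kbp plastome and a binary vector (5.5 kbp T-DNA
#' between 25 bp border repeats, 1.5 kbp backbone); log-normal read lengths
#' with median 15 kbp truncated to 1-100 kbp; i.i.d. per-base errors
#' (mismatch 0.04, insertion 0.03, deletion 0.04) at mean Phred 13; a
#' quality drop to mean Phred 7 with tripled substitution rate on the second
#' arm of planted inverted repeats; and a wild-type allele fraction of 1/3
#' (two thirds of chromosomes in the pool carry the insertion).
#'
#' @param ... Named overrides of any default field.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    rng_seed = 1L,
    chrom_sizes = c(chr1 = 150000L, chr2 = 150000L, chr3 = 150000L,
                    chr4 = 150000L, chr5 = 150000L),
    plastome_bp = 20000L,
    tdna_bp = 5500L,
    bvb_bp = 1500L,
    border_bp = 25L,
    read_len_median = 15000,
    read_len_sdlog = 0.9,
    read_len_min = 1000,
    read_len_max = 100000,
    err_mismatch = 0.04,
    err_insertion = 0.03,
    err_deletion = 0.04,
    phred_mean = 13,
    phred_sd = 3,
    inverted_arm_drop = TRUE,
    arm_phred_mean = 7,
    arm_phred_sd = 2,
    arm_mismatch_factor = 3,
    depth = 30,
    wt_allele_fraction = 1 / 3
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown simulation fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  rates <- c(cfg$err_mismatch, cfg$err_insertion, cfg$err_deletion)
  if (any(rates < 0 | rates >= 1)) stop("error rates must lie in [0, 1)")
  if (cfg$depth <= 0) stop("depth must be positive")
  structure(cfg, class = "simulation_config")
}

.random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

#' Generate a wild-type genome and reference catalog
#'
#' Deterministic under `rng_seed`. The binary vector is split into a TDNA
#' record (LB repeat at vector positions 1-25, RB repeat in the last 25
#' bases; transferred DNA conventionally starts at position 4, 3 bp inside
#' LB) and a separate BVB (backbone) record.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named list of nuclear [seq_record()]s),
#'   `catalog` (a [reference_catalog()]) and `vector_info` (T-DNA/BVB ids,
#'   lengths and border coordinates).
#' @export
make_genome <- function(config = simulation_config()) {
  set.seed(config$rng_seed)
  chroms <- lapply(names(config$chrom_sizes), function(nm)
    seq_record(nm, .random_seq(config$chrom_sizes[[nm]])))
  names(chroms) <- names(config$chrom_sizes)
  plast <- seq_record("plastome", .random_seq(config$plastome_bp))
  tdna <- seq_record("pTL1_TDNA", .random_seq(config$tdna_bp))
  bvb <- seq_record("pTL1_BVB", .random_seq(config$bvb_bp))
  recs <- c(chroms, list(plastome = plast, pTL1_TDNA = tdna, pTL1_BVB = bvb))
  category <- c(setNames(rep("NUCLEAR", length(chroms)), names(chroms)),
                plastome = "PLASTOME", pTL1_TDNA = "TDNA", pTL1_BVB = "BVB")
  b <- config$border_bp
  vector_info <- list(tdna_id = "pTL1_TDNA", bvb_id = "pTL1_BVB",
                      tdna_len = config$tdna_bp, bvb_len = config$bvb_bp,
                      lb = c(0L, b), rb = c(config$tdna_bp - b, config$tdna_bp))
  catalog <- reference_catalog(recs, category,
                               tdna_borders = list(pTL1_TDNA = list(
                                 lb = vector_info$lb, rb = vector_info$rb)))
  list(genome = chroms, catalog = catalog, vector_info = vector_info)
}

#' Specify a structural event to plant
#'
#' @param kind One of `TDNA_ARRAY`, `TRANSLOCATION_PAIR`,
#'   `INVERTED_DUPLICATION`, `CPDNA_FILLER_JUNCTION`, `TDNA_FREE_FUSION`.
#' @param ... Kind-specific parameters:
#'   \describe{
#'   \item{TDNA_ARRAY}{`chrom`, `pos`, `units` (data.frame with `subject`
#'     ("TDNA"/"BVB"), `s_start`, `s_end`, `orientation`),
#'     `target_deletion_bp`, optional `filler_len`/`filler_origin`
#'     ("PLASTOME", "NEAR", "RANDOM") at the left junction, optional
#'     `microhomology_bp` at the left junction.}
#'   \item{TRANSLOCATION_PAIR}{`chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'     optional `units` for T-DNA at the A::B fusion (the compensating
#'     B::A fusion carries no T-DNA).}
#'   \item{INVERTED_DUPLICATION}{`chrom`, `pos`, `span`, `units` (T-DNA at
#'     the left border of the inverted copy).}
#'   \item{CPDNA_FILLER_JUNCTION}{`chrom`, `pos`, `cp_start`, `cp_len`
#'     (default 652), `target_deletion_bp`.}
#'   \item{TDNA_FREE_FUSION}{`chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'     optional `microhomology_bp`.}
#'   }
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(kind, ...) {
  kinds <- c("TDNA_ARRAY", "TRANSLOCATION_PAIR", "INVERTED_DUPLICATION",
             "CPDNA_FILLER_JUNCTION", "TDNA_FREE_FUSION")
  kind <- match.arg(kind, kinds)
  structure(c(list(kind = kind), list(...)), class = "event_spec")
}

#' Default full-length T-DNA unit table
#' @param vector_info Vector geometry from [make_genome()].
#' @param orientations Character vector of `+`/`-` per unit.
#' @param jitter Integer truncation jitter applied per unit end (bp).
#' @return Unit data.frame for [event_spec()].
#' @export
tdna_units <- function(vector_info, orientations = "+", jitter = 0L) {
  n <- length(orientations)
  ss <- rep(3L, n); se <- rep(vector_info$tdna_len - 3L, n)
  if (jitter > 0L) {
    ss <- ss + sample.int(jitter, n, replace = TRUE) - 1L
    se <- se - sample.int(jitter, n, replace = TRUE) + 1L
  }
  data.frame(subject = "TDNA", s_start = ss, s_end = se,
             orientation = orientations, stringsAsFactors = FALSE)
}

# One haplotype block: a stretch of the mutant chromosome with its origin.
.block <- function(seq, kind, ref_chrom = NA, ref_start = NA, ref_end = NA,
                   strand = "+", subject = NA, s_start = NA, s_end = NA) {
  list(seq = seq, kind = kind, ref_chrom = ref_chrom, ref_start = ref_start,
       ref_end = ref_end, strand = strand, subject = subject,
       s_start = s_start, s_end = s_end)
}

.blocks_to_df <- function(blocks, hap_chrom) {
  lens <- vapply(blocks, function(b) nchar(b$seq), numeric(1))
  ends <- cumsum(lens)
  data.frame(hap_chrom = hap_chrom, h_start = c(0, head(ends, -1)),
             h_end = ends,
             kind = vapply(blocks, `[[`, character(1), "kind"),
             ref_chrom = vapply(blocks, function(b) as.character(b$ref_chrom), character(1)),
             ref_start = vapply(blocks, function(b) as.numeric(b$ref_start), numeric(1)),
             ref_end = vapply(blocks, function(b) as.numeric(b$ref_end), numeric(1)),
             strand = vapply(blocks, `[[`, character(1), "strand"),
             subject = vapply(blocks, function(b) as.character(b$subject), character(1)),
             s_start = vapply(blocks, function(b) as.numeric(b$s_start), numeric(1)),
             s_end = vapply(blocks, function(b) as.numeric(b$s_end), numeric(1)),
             stringsAsFactors = FALSE)
}

# Genomic::non-genomic (and discontinuous genomic::genomic) boundaries of a
# block table, expressed as reference anchors the pipeline should recover.
.blockmap_anchors <- function(blocks) {
  out <- data.frame(chrom = character(), pos = numeric(), direction = character(),
                    stringsAsFactors = FALSE)
  n <- nrow(blocks)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    u <- blocks[i, ]; v <- blocks[i + 1, ]
    both_genomic <- u$kind == "GENOMIC" && v$kind == "GENOMIC"
    if (both_genomic) {
      contiguous <- identical(u$ref_chrom, v$ref_chrom) &&
        u$strand == v$strand &&
        ((u$strand == "+" && u$ref_end == v$ref_start) ||
         (u$strand == "-" && u$ref_start == v$ref_end))
      if (contiguous) next
    }
    if (u$kind == "GENOMIC") {
      if (u$strand == "+")
        out <- rbind(out, data.frame(chrom = u$ref_chrom, pos = u$ref_end,
                                     direction = "LEFT_OF_INSERT"))
      else
        out <- rbind(out, data.frame(chrom = u$ref_chrom, pos = u$ref_start,
                                     direction = "RIGHT_OF_INSERT"))
    }
    if (v$kind == "GENOMIC") {
      if (v$strand == "+")
        out <- rbind(out, data.frame(chrom = v$ref_chrom, pos = v$ref_start,
                                     direction = "RIGHT_OF_INSERT"))
      else
        out <- rbind(out, data.frame(chrom = v$ref_chrom, pos = v$ref_end,
                                     direction = "LEFT_OF_INSERT"))
    }
  }
  unique(out)
}

.insert_blocks <- function(units, catalog, vector_info) {
  lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    id <- if (u$subject == "TDNA") vector_info$tdna_id else vector_info$bvb_id
    s <- substr(catalog$records[[id]]$bases, u$s_start + 1, u$s_end)
    if (u$orientation == "-") s <- .rc_cpp(s)
    .block(s, kind = u$subject, strand = u$orientation, subject = id,
           s_start = u$s_start, s_end = u$s_end)
  })
}

.filler_block <- function(origin, len, catalog, chrom_seq, pos) {
  if (origin == "PLASTOME") {
    cp <- catalog$records$plastome$bases
    st <- 5000L
    .block(substr(cp, st + 1, st + len), kind = "FILLER", subject = "plastome",
           s_start = st, s_end = st + len)
  } else if (origin == "NEAR") {
    st <- pos - len - 15L
    .block(substr(chrom_seq, st + 1, st + len), kind = "FILLER",
           subject = "NEAR", s_start = st, s_end = st + len)
  } else {
    .block(.random_seq(len), kind = "FILLER", subject = NA)
  }
}

#' Plant structural events into a wild-type genome
#'
#' Produces the mutant haplotype, an identity block map for the wild-type
#' haplotype, and a truth set sufficient to score every pipeline output:
#' per-chromosome block maps (origin of every mutant base), reference
#' junction anchors, planted unit chains, fillers, microhomologies, and the
#' arm pairs of planted inverted repeats. When a planted microhomology is
#' requested the wild-type flank is edited so that the last bases before the
#' junction equal the first bases of the inserted sequence, which is how
#' microhomology presents in real junctions.
#'
#' @param genome Named list of wild-type nuclear [seq_record()]s.
#' @param catalog The [reference_catalog()] from [make_genome()].
#' @param events List of [event_spec()]s.
#' @param config A [simulation_config()].
#' @param vector_info Vector geometry from [make_genome()].
#' @return List with `mutant` (named list of [seq_record()]s), `wildtype`,
#'   `truth` (list: `blocks`, `wt_blocks`, `anchors`, `events`, `arms`,
#'   `fillers`) and the updated `genome` (flank edits applied).
#' @export
plant_events <- function(genome, catalog, events, config = simulation_config(),
                         vector_info) {
  # validate non-overlapping footprints
  foot <- list()
  for (ev in events) {
    f <- switch(ev$kind,
      TDNA_ARRAY = data.frame(chrom = ev$chrom, s = ev$pos - 1,
                              e = ev$pos + .nz(ev$target_deletion_bp) + 1),
      CPDNA_FILLER_JUNCTION = data.frame(chrom = ev$chrom, s = ev$pos - 1,
                                         e = ev$pos + .nz(ev$target_deletion_bp) + 1),
      INVERTED_DUPLICATION = data.frame(chrom = ev$chrom, s = ev$pos - ev$span,
                                        e = ev$pos + 1),
      TRANSLOCATION_PAIR = data.frame(chrom = c(ev$chrom_a, ev$chrom_b),
                                      s = c(ev$pos_a, ev$pos_b) - 1,
                                      e = c(ev$pos_a, ev$pos_b) + 1),
      TDNA_FREE_FUSION = data.frame(chrom = c(ev$chrom_a, ev$chrom_b),
                                    s = c(ev$pos_a, ev$pos_b) - 1,
                                    e = c(ev$pos_a, ev$pos_b) + 1))
    foot[[length(foot) + 1]] <- f
  }
  foot <- do.call(rbind, foot)
  if (!is.null(foot) && nrow(foot) > 1) {
    for (i in seq_len(nrow(foot) - 1)) for (j in seq.int(i + 1, nrow(foot))) {
      if (foot$chrom[i] == foot$chrom[j] &&
          foot$s[i] < foot$e[j] && foot$s[j] < foot$e[i])
        stop("planted events overlap on ", foot$chrom[i])
    }
  }

  # apply microhomology flank edits to the wild type first
  for (ev in events) {
    m <- .nz(ev$microhomology_bp)
    if (m > 0) {
      if (ev$kind == "TDNA_FREE_FUSION") {
        first <- substr(genome[[ev$chrom_b]]$bases, ev$pos_b + 1, ev$pos_b + m)
        g <- genome[[ev$chrom_a]]
        g$bases <- paste0(substr(g$bases, 1, ev$pos_a - m), first,
                          substr(g$bases, ev$pos_a + 1, nchar(g$bases)))
        genome[[ev$chrom_a]] <- g
      } else if (ev$kind == "TDNA_ARRAY") {
        u <- ev$units[1, ]
        id <- if (u$subject == "TDNA") vector_info$tdna_id else vector_info$bvb_id
        us <- substr(catalog$records[[id]]$bases, u$s_start + 1, u$s_end)
        if (u$orientation == "-") us <- .rc_cpp(us)
        first <- substr(us, 1, m)
        g <- genome[[ev$chrom]]
        g$bases <- paste0(substr(g$bases, 1, ev$pos - m), first,
                          substr(g$bases, ev$pos + 1, nchar(g$bases)))
        genome[[ev$chrom]] <- g
      }
    }
  }

  hap <- lapply(genome, function(g)
    list(.block(g$bases, "GENOMIC", ref_chrom = g$id, ref_start = 0,
                ref_end = nchar(g$bases))))
  names(hap) <- names(genome)
  arms <- data.frame(hap_chrom = character(), a1_start = numeric(),
                     a1_end = numeric(), a2_start = numeric(), a2_end = numeric(),
                     stringsAsFactors = FALSE)
  fillers <- data.frame(event = integer(), len = integer(), origin = character(),
                        seq = character(), stringsAsFactors = FALSE)
  drop_chroms <- character()

  for (k in seq_along(events)) {
    ev <- events[[k]]
    if (ev$kind %in% c("TDNA_ARRAY", "CPDNA_FILLER_JUNCTION")) {
      g <- genome[[ev$chrom]]$bases
      del <- .nz(ev$target_deletion_bp)
      left <- .block(substr(g, 1, ev$pos), "GENOMIC", ev$chrom, 0, ev$pos)
      right <- .block(substr(g, ev$pos + del + 1, nchar(g)), "GENOMIC",
                      ev$chrom, ev$pos + del, nchar(g))
      mid <- list()
      if (ev$kind == "TDNA_ARRAY") {
        if (.nz(ev$filler_len) > 0) {
          fb <- .filler_block(ev$filler_origin, ev$filler_len, catalog, g, ev$pos)
          mid <- c(mid, list(fb))
          fillers <- rbind(fillers, data.frame(event = k, len = ev$filler_len,
                                               origin = ev$filler_origin,
                                               seq = fb$seq,
                                               stringsAsFactors = FALSE))
        }
        mid <- c(mid, .insert_blocks(ev$units, catalog, vector_info))
      } else {
        cp <- catalog$records$plastome$bases
        len <- if (is.null(ev$cp_len)) 652L else ev$cp_len
        mid <- list(.block(substr(cp, ev$cp_start + 1, ev$cp_start + len),
                           "CPDNA", subject = "plastome",
                           s_start = ev$cp_start, s_end = ev$cp_start + len))
      }
      hap[[ev$chrom]] <- c(list(left), mid, list(right))
      # adjacent opposite-orientation T-DNA pairs form inverted-repeat arms
      if (ev$kind == "TDNA_ARRAY" && isTRUE(config$inverted_arm_drop)) {
        lens <- vapply(c(list(left), mid, list(right)),
                       function(b) nchar(b$seq), numeric(1))
        ends <- cumsum(lens); starts <- c(0, head(ends, -1))
        kinds <- vapply(c(list(left), mid, list(right)), `[[`, character(1), "kind")
        ori <- vapply(c(list(left), mid, list(right)), `[[`, character(1), "strand")
        tu <- which(kinds == "TDNA")
        for (t in tu[-length(tu)]) {
          if ((t + 1) %in% tu && ori[t] != ori[t + 1]) {
            arms <- rbind(arms, data.frame(hap_chrom = ev$chrom,
                                           a1_start = starts[t], a1_end = ends[t],
                                           a2_start = starts[t + 1],
                                           a2_end = ends[t + 1],
                                           stringsAsFactors = FALSE))
          }
        }
      }
    } else if (ev$kind == "INVERTED_DUPLICATION") {
      g <- genome[[ev$chrom]]$bases
      d0 <- ev$pos - ev$span
      left <- .block(substr(g, 1, ev$pos), "GENOMIC", ev$chrom, 0, ev$pos)
      dup <- .block(.rc_cpp(substr(g, d0 + 1, ev$pos)), "GENOMIC", ev$chrom,
                    d0, ev$pos, strand = "-")
      right <- .block(substr(g, ev$pos + 1, nchar(g)), "GENOMIC", ev$chrom,
                      ev$pos, nchar(g))
      mid <- .insert_blocks(ev$units, catalog, vector_info)
      hap[[ev$chrom]] <- c(list(left), mid, list(dup, right))
    } else { # fusions (with or without T-DNA at the A::B junction)
      ga <- genome[[ev$chrom_a]]$bases; gb <- genome[[ev$chrom_b]]$bases
      mid <- if (!is.null(ev$units)) .insert_blocks(ev$units, catalog, vector_info)
             else list()
      der1 <- c(list(.block(substr(ga, 1, ev$pos_a), "GENOMIC", ev$chrom_a,
                            0, ev$pos_a)),
                mid,
                list(.block(substr(gb, ev$pos_b + 1, nchar(gb)), "GENOMIC",
                            ev$chrom_b, ev$pos_b, nchar(gb))))
      der2 <- list(.block(substr(gb, 1, ev$pos_b), "GENOMIC", ev$chrom_b,
                          0, ev$pos_b),
                   .block(substr(ga, ev$pos_a + 1, nchar(ga)), "GENOMIC",
                          ev$chrom_a, ev$pos_a, nchar(ga)))
      hap[[paste0("der_", ev$chrom_a, "_", ev$chrom_b)]] <- der1
      hap[[paste0("der_", ev$chrom_b, "_", ev$chrom_a)]] <- der2
      drop_chroms <- c(drop_chroms, ev$chrom_a, ev$chrom_b)
    }
  }
  hap <- hap[setdiff(names(hap), drop_chroms)]

  mutant <- lapply(names(hap), function(nm)
    seq_record(nm, paste(vapply(hap[[nm]], `[[`, character(1), "seq"),
                         collapse = "")))
  names(mutant) <- names(hap)
  blocks <- do.call(rbind, lapply(names(hap), function(nm)
    .blocks_to_df(hap[[nm]], nm)))
  wt_blocks <- do.call(rbind, lapply(genome, function(g)
    data.frame(hap_chrom = g$id, h_start = 0, h_end = nchar(g$bases),
               kind = "GENOMIC", ref_chrom = g$id, ref_start = 0,
               ref_end = nchar(g$bases), strand = "+", subject = NA,
               s_start = NA, s_end = NA, stringsAsFactors = FALSE)))
  anchors <- do.call(rbind, lapply(names(hap), function(nm)
    .blockmap_anchors(blocks[blocks$hap_chrom == nm, , drop = FALSE])))
  if (is.null(anchors))
    anchors <- data.frame(chrom = character(), pos = numeric(),
                          direction = character(), stringsAsFactors = FALSE)
  anchors <- unique(anchors)
  rownames(anchors) <- NULL

  list(mutant = mutant, wildtype = genome, genome = genome,
       truth = list(blocks = blocks, wt_blocks = wt_blocks, anchors = anchors,
                    events = events, arms = arms, fillers = fillers))
}

.nz <- function(x) if (is.null(x) || is.na(x)) 0L else as.integer(x)

# Apply the error model to one fragment piece; returns emitted chars/quals
# and bookkeeping counts.
.mutate_piece <- function(chars, pm, pins, pdel, qmean, qsd) {
  n <- length(chars)
  if (n == 0L)
    return(list(chars = character(0), quals = integer(0), n_mm = 0L,
                n_ins = 0L, n_del = 0L))
  bases <- c("A", "C", "G", "T")
  mm <- which(runif(n) < pm)
  if (length(mm)) {
    shift <- sample.int(3L, length(mm), replace = TRUE)
    cur <- match(chars[mm], bases)
    cur[is.na(cur)] <- sample.int(4L, sum(is.na(cur)), replace = TRUE)
    chars[mm] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  keep <- runif(n) >= pdel
  ins <- runif(n) < pins
  n_ins <- sum(ins)
  ins_chars <- rep(NA_character_, n)
  if (n_ins) ins_chars[ins] <- sample(bases, n_ins, replace = TRUE)
  kept_chars <- ifelse(keep, chars, NA_character_)
  inter <- as.vector(rbind(kept_chars, ins_chars))
  emitted <- inter[!is.na(inter)]
  q <- as.integer(pmax(2, pmin(40, round(rnorm(length(emitted), qmean, qsd)))))
  list(chars = emitted, quals = q, n_mm = length(mm), n_ins = n_ins,
       n_del = sum(!keep))
}

#' Simulate ONT-like reads from a haplotype pair
#'
#' Reads are drawn from the mutant or wild-type haplotype with probability
#' `1 - wt_allele_fraction` / `wt_allele_fraction`, from chromosomes in
#' proportion to length, with log-normal lengths and uniform start
#' positions, until `depth` times the mutant genome length has been
#' emitted. Errors are i.i.d. per base. When a read traverses a planted
#' inverted repeat, the arm encountered second in the read's own direction
#' is emitted at the dropped quality with a tripled substitution rate,
#' regardless of strand. Deterministic under `rng_seed`.
#'
#' @param genomes List with `mutant` and `wildtype` named lists of
#'   [seq_record()]s (as from [plant_events()]).
#' @param config A [simulation_config()].
#' @param truth Truth list from [plant_events()] (for inverted-repeat arms);
#'   may be `NULL`.
#' @return List with `reads` (named list of [seq_record()]s with qualities)
#'   and `truth` (per-read data.frame: haplotype, chromosome, fragment
#'   coordinates, strand, error counts, quality-drop arm in read
#'   coordinates).
#' @export
simulate_reads <- function(genomes, config = simulation_config(), truth = NULL) {
  set.seed(config$rng_seed + 1L)
  mut <- genomes$mutant; wt <- genomes$wildtype
  target <- config$depth * sum(vapply(mut, function(g) nchar(g$bases), numeric(1)))
  arms <- if (!is.null(truth)) truth$arms else NULL

  reads <- list(); rows <- list()
  emitted <- 0; i <- 0L
  meanlog <- log(config$read_len_median)
  while (emitted < target) {
    i <- i + 1L
    hapname <- if (runif(1) < config$wt_allele_fraction) "wt" else "mut"
    hap <- if (hapname == "wt") wt else mut
    lens <- vapply(hap, function(g) nchar(g$bases), numeric(1))
    ci <- sample.int(length(hap), 1L, prob = lens)
    g <- hap[[ci]]
    L <- exp(rnorm(1, meanlog, config$read_len_sdlog))
    L <- max(config$read_len_min, min(config$read_len_max, round(L)))
    st <- floor(runif(1, 0, max(1, lens[ci] - 200)))
    en <- min(lens[ci], st + L)
    if (en - st < 200) next
    strand <- if (runif(1) < 0.5) "+" else "-"

    # quality-drop arm: second inverted-repeat arm in read direction
    drop <- NULL
    if (hapname == "mut" && !is.null(arms) && nrow(arms) > 0 &&
        isTRUE(config$inverted_arm_drop)) {
      av <- arms[arms$hap_chrom == g$id, , drop = FALSE]
      for (a in seq_len(nrow(av))) {
        first_arm <- if (strand == "+") c(av$a1_start[a], av$a1_end[a])
                     else c(av$a2_start[a], av$a2_end[a])
        second_arm <- if (strand == "+") c(av$a2_start[a], av$a2_end[a])
                      else c(av$a1_start[a], av$a1_end[a])
        ov1 <- min(en, first_arm[2]) - max(st, first_arm[1])
        ov2 <- min(en, second_arm[2]) - max(st, second_arm[1])
        if (ov1 >= 100 && ov2 >= 1) {
          drop <- c(max(st, second_arm[1]), min(en, second_arm[2]))
          break
        }
      }
    }

    frag <- substr(g$bases, st + 1, en)
    pieces <- if (is.null(drop)) list(c(st, en))
              else list(c(st, drop[1]), c(drop[1], drop[2]), c(drop[2], en))
    chars_all <- character(0); quals_all <- integer(0)
    n_mm <- n_ins <- n_del <- 0L
    drop_out <- c(NA_real_, NA_real_)
    for (p in seq_along(pieces)) {
      pc <- pieces[[p]]
      if (pc[2] <= pc[1]) next
      is_drop <- !is.null(drop) && p == 2L
      seg <- strsplit(substr(g$bases, pc[1] + 1, pc[2]), "", fixed = TRUE)[[1]]
      mp <- .mutate_piece(seg,
                          pm = config$err_mismatch *
                            (if (is_drop) config$arm_mismatch_factor else 1),
                          pins = config$err_insertion,
                          pdel = config$err_deletion,
                          qmean = if (is_drop) config$arm_phred_mean else config$phred_mean,
                          qsd = if (is_drop) config$arm_phred_sd else config$phred_sd)
      if (is_drop) drop_out <- c(length(chars_all), length(chars_all) + length(mp$chars))
      chars_all <- c(chars_all, mp$chars)
      quals_all <- c(quals_all, mp$quals)
      n_mm <- n_mm + mp$n_mm; n_ins <- n_ins + mp$n_ins; n_del <- n_del + mp$n_del
    }
    out_len <- length(chars_all)
    if (strand == "-") {
      bases_str <- .rc_cpp(paste(chars_all, collapse = ""))
      quals_all <- rev(quals_all)
      if (!is.na(drop_out[1]))
        drop_out <- c(out_len - drop_out[2], out_len - drop_out[1])
    } else {
      bases_str <- paste(chars_all, collapse = "")
    }
    id <- sprintf("read%05d", i)
    reads[[id]] <- seq_record(id, bases_str, quals = quals_all,
                              description = sprintf("hap=%s %s:%d-%d %s",
                                                    hapname, g$id, st, en, strand))
    rows[[length(rows) + 1]] <- data.frame(
      read_id = id, hap = hapname, chrom = g$id, start = st, end = en,
      strand = strand, frag_len = en - st, out_len = out_len,
      n_mm = n_mm, n_ins = n_ins, n_del = n_del,
      drop_applied = !is.null(drop),
      drop_q_start = drop_out[1], drop_q_end = drop_out[2],
      stringsAsFactors = FALSE)
    emitted <- emitted + (en - st)
  }
  list(reads = reads, truth = do.call(rbind, rows))
}

#' Project simulated reads onto reference coordinates
#'
#' Splits each read's true haplotype interval at the haplotype block
#' boundaries and maps genomic blocks to reference intervals: the split
#' alignments an exact long-read mapper would produce.
#'
#' @param read_truth Per-read truth from [simulate_reads()].
#' @param blocks Block table (`truth$blocks` or `truth$wt_blocks` from
#'   [plant_events()], or a custom assembly block map).
#' @return A `genomic_intervals` data.frame with `name` = read id.
#' @export
truth_to_alignments <- function(read_truth, blocks) {
  out <- list()
  for (i in seq_len(nrow(read_truth))) {
    r <- read_truth[i, ]
    bl <- blocks[blocks$hap_chrom == r$chrom & blocks$h_start < r$end &
                   blocks$h_end > r$start & blocks$kind == "GENOMIC", ,
                 drop = FALSE]
    if (nrow(bl) == 0) next
    for (j in seq_len(nrow(bl))) {
      b <- bl[j, ]
      hs <- max(r$start, b$h_start); he <- min(r$end, b$h_end)
      if (b$strand == "+") {
        rs <- b$ref_start + (hs - b$h_start); re <- b$ref_start + (he - b$h_start)
      } else {
        re <- b$ref_end - (hs - b$h_start); rs <- b$ref_end - (he - b$h_start)
      }
      out[[length(out) + 1]] <- data.frame(chrom = b$ref_chrom, start = rs,
                                           end = re, name = r$read_id,
                                           stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(genomic_intervals(character(0), numeric(0), numeric(0)))
  genomic_intervals(df$chrom, df$start, df$end, name = df$name)
}
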