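# Helpers to build synthetic annotations without running the aligner.
mk_seg <- function(category, subject, s_start, s_end, strand, q_start, q_end,
                   score = 1000, identity = 0.92) {
  data.frame(category = category, subject_id = subject, s_start = s_start,
             s_end = s_end, strand = strand, q_start = q_start, q_end = q_end,
             score = score, identity = identity, stringsAsFactors = FALSE)
}

mk_ann <- function(read_id, read_len, segments,
                   gaps = data.frame(q_start = numeric(0), q_end = numeric(0))) {
  structure(list(read_id = read_id, read_len = read_len, segments = segments,
                 gaps = gaps), class = "read_annotation")
}

# A canonical-locus read: genomic | T-DNA | genomic with given flank coords.
canonical_ann <- function(id, left_end, right_start, chrom = "chr1",
                          v_end = 5497) {
  segs <- rbind(
    mk_seg("NUCLEAR", chrom, left_end - 8000, left_end, "+", 0, 8000),
    mk_seg("TDNA", "pTL1_TDNA", 3, v_end, "+", 8005, 8005 + (v_end - 3)),
    mk_seg("NUCLEAR", chrom, right_start, right_start + 7000, "+",
           8010 + (v_end - 3), 15010 + (v_end - 3)))
  mk_ann(id, 15010 + (v_end - 3), segs)
}

test_that("changeover clustering separates distant loci and joins nearby reads", {
  cfg <- pipeline_config()
  anns <- list(
    a = canonical_ann("a", 27742100, 27742113),
    b = canonical_ann("b", 27742350, 27742363),   # 250 bp away: same locus
    c = canonical_ann("c", 31742100, 31742113))   # 4 Mbp away: distinct locus
  cl <- cluster_loci(anns, cfg)
  expect_equal(length(cl$loci), 2)
  sizes <- sort(vapply(cl$loci, function(l) length(l$read_ids), integer(1)))
  expect_equal(sizes, c(1L, 2L))
  expect_equal(length(cluster_loci(list(), cfg)$loci), 0)
})

test_that("chain flipping is an involution and orientation is canonicalized", {
  ann <- canonical_ann("a", 50000, 50013)
  ch <- read_chain(ann)
  expect_identical(flip_chain(flip_chain(ch)), ch)
  # a locus given only reverse-orientation reads resolves identically
  flip_seg <- function(a) {
    n <- a$read_len
    s <- a$segments
    s$strand <- ifelse(s$strand == "+", "-", "+")
    qs <- n - s$q_end; qe <- n - s$q_start
    s$q_start <- qs; s$q_end <- qe
    a$segments <- s[rev(seq_len(nrow(s))), ]
    a
  }
  g <- tiny_catalog()
  cfg <- pipeline_config()
  anns_fwd <- list(a = canonical_ann("a", 5000, 5013),
                   b = canonical_ann("b", 5001, 5013))
  anns_rev <- lapply(anns_fwd, flip_seg)
  cl_f <- cluster_loci(anns_fwd, cfg)
  cl_r <- cluster_loci(anns_rev, cfg)
  st_f <- build_structure(cl_f$loci[[1]], anns_fwd, g$catalog, cfg)
  st_r <- build_structure(cl_r$loci[[1]], anns_rev, g$catalog, cfg)
  expect_equal(st_f$chain$kind, st_r$chain$kind)
  expect_equal(st_f$chain$orientation, st_r$chain$orientation)
  expect_equal(st_f$left_flank$pos, st_r$left_flank$pos)
  expect_equal(st_f$right_flank$pos, st_r$right_flank$pos)
})

test_that("disagreeing unit extents resolve to the largest single-read extent", {
  g <- tiny_catalog()
  cfg <- pipeline_config()
  anns <- list(a = canonical_ann("a", 5000, 5013, v_end = 5500),
               b = canonical_ann("b", 5000, 5013, v_end = 5300))
  cl <- cluster_loci(anns, cfg)
  st <- build_structure(cl$loci[[1]], anns, g$catalog, cfg)
  tu <- st$chain[st$chain$kind == "TDNA", ]
  expect_equal(tu$s_end, 5500)
  expect_equal(st$target_site_deletion_bp, 13L)
})

test_that("border status follows the 3 bp slack and flags RB::RB fusions", {
  g <- tiny_catalog()
  ch <- data.frame(kind = "TDNA", subject_id = "pTL1_TDNA", s_start = 3,
                   s_end = 5497, orientation = "+", stringsAsFactors = FALSE)
  bs <- border_status(ch, g$catalog)
  expect_equal(bs$chain$border_left, "LB_INTACT")   # position 4, 1-based
  expect_equal(bs$chain$border_right, "RB_INTACT")

  ch2 <- ch; ch2$s_start <- 40; ch2$s_end <- 4300   # 1.2 kbp short of RB
  bs2 <- border_status(ch2, g$catalog)
  expect_equal(bs2$chain$border_left, "LB_TRUNCATED")
  expect_equal(bs2$chain$border_right, "RB_TRUNCATED")

  # + / - units meeting at their RB-proximal ends
  ch3 <- rbind(ch, ch)
  ch3$orientation <- c("+", "-")
  bs3 <- border_status(ch3, g$catalog)
  expect_equal(nrow(bs3$internal), 1)
  expect_true(bs3$internal$rb_rb)
  expect_equal(bs3$internal$label, "RB::RB")

  # + / + tandem meets RB::LB
  ch4 <- rbind(ch, ch)
  bs4 <- border_status(ch4, g$catalog)
  expect_false(bs4$internal$rb_rb)
  expect_equal(bs4$internal$label, "RB::LB")
})

test_that("event classification distinguishes the taxonomy", {
  mkst <- function(chain, lf, rf, flags = character(0)) {
    structure(list(locus_id = "L", chain = chain, left_flank = lf,
                   right_flank = rf, supporting_reads = "r", flags = flags,
                   target_site_deletion_bp = NA), class = "insertion_structure")
  }
  gen <- function(chrom, ori = "+") data.frame(kind = "GENOMIC",
    subject_id = chrom, s_start = 0, s_end = 1000, orientation = ori,
    border_left = NA, border_right = NA, stringsAsFactors = FALSE)
  td <- data.frame(kind = "TDNA", subject_id = "pT", s_start = 3, s_end = 5000,
                   orientation = "+", border_left = "LB_INTACT",
                   border_right = "RB_TRUNCATED", stringsAsFactors = FALSE)
  cp <- td; cp$kind <- "CPDNA"; cp$subject_id <- "plastome"
  fl <- function(chrom, pos, dir) list(chrom = chrom, pos = pos,
                                       direction = dir, support = 5)

  st1 <- mkst(rbind(gen("chr1"), td, gen("chr1")),
              fl("chr1", 100, "LEFT_OF_INSERT"),
              fl("chr1", 113, "RIGHT_OF_INSERT"))
  expect_equal(classify_event(list(st1))$event_type, "CANONICAL_INSERTION")

  st2 <- mkst(rbind(gen("chr3"), td, gen("chr5")),
              fl("chr3", 100, "LEFT_OF_INSERT"),
              fl("chr5", 10000, "RIGHT_OF_INSERT"))
  ev2 <- classify_event(list(st2))
  expect_equal(ev2$event_type, "TRANSLOCATION_FUSION")
  expect_equal(ev2$partners, "chr3|chr5")

  st3 <- mkst(rbind(gen("chr2"), gen("chr4")),
              fl("chr2", 100, "LEFT_OF_INSERT"),
              fl("chr4", 900, "RIGHT_OF_INSERT"))
  expect_equal(classify_event(list(st3))$event_type, "TDNA_FREE_FUSION")

  st4 <- mkst(rbind(gen("chr2"), td, gen("chr2", "-")),
              fl("chr2", 100, "LEFT_OF_INSERT"),
              fl("chr2", 100, "LEFT_OF_INSERT"))
  expect_equal(classify_event(list(st4))$event_type, "INVERTED_DUPLICATION")

  st5 <- mkst(rbind(gen("chr1"), cp, gen("chr1")),
              fl("chr1", 100, "LEFT_OF_INSERT"),
              fl("chr1", 110, "RIGHT_OF_INSERT"))
  ev5 <- classify_event(list(st5))
  expect_true("CPDNA_INSERTION" %in% ev5$event_type)

  # reciprocal pairing of complementary fusions
  st6 <- mkst(rbind(gen("chr5"), gen("chr3")),
              fl("chr5", 10000, "LEFT_OF_INSERT"),
              fl("chr3", 100, "RIGHT_OF_INSERT"))
  ev <- classify_event(list(st2, st6))
  expect_match(ev$notes[1], "reciprocal_pair")
  expect_match(ev$notes[2], "reciprocal_pair")
})

test_that("zygosity calls follow the segregating-pool thresholds", {
  cfg <- pipeline_config()
  z <- estimate_zygosity("L", 10, 5, cfg)
  expect_equal(z$wt_allele_read_fraction, 1 / 3, tolerance = 1e-9)
  expect_equal(z$call, "SEGREGATING")
  expect_equal(estimate_zygosity("L", 20, 0, cfg)$call, "HOMOZYGOUS")
  expect_equal(estimate_zygosity("L", 3, 1, cfg)$call, "UNDETERMINED")
  expect_equal(estimate_zygosity("L", 5, 10, cfg)$call, "UNDETERMINED")
})
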