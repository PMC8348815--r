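test_that("microhomology is the longest exact suffix-prefix overlap", {
  expect_equal(find_microhomology("GGACGT", "ACGTTC"), 4)
  expect_equal(find_microhomology(strrep("ACGTA", 4), strrep("ACGTA", 4)), 20)
  expect_equal(find_microhomology("AAAA", "CCCC"), 0)
  expect_error(find_microhomology("", "ACGT"), "non-empty")
  # brute-force oracle on random 50-mers
  set.seed(61)
  brute <- function(l, r) {
    lc <- strsplit(l, "")[[1]]; rc <- strsplit(r, "")[[1]]
    best <- 0
    for (m in 1:min(length(lc), length(rc)))
      if (all(tail(lc, m) == head(rc, m))) best <- max(best, m)
    best
  }
  for (i in 1:25) {
    l <- rand_seq(50)
    m <- sample(0:12, 1)
    r <- paste0(substr(l, 51 - m, 50), rand_seq(38))
    if (m == 0) r <- rand_seq(50)
    expect_equal(find_microhomology(l, r), brute(l, r))
  }
})

test_that("junction enumeration collapses organellar runs between genomic units", {
  ch <- data.frame(
    kind = c("GENOMIC", "CPDNA", "GENOMIC", "TDNA", "GENOMIC"),
    subject_id = c("chr1", "plastome", "chr1", "pT", "chr1"),
    s_start = c(0, 5000, 2000, 3, 9000),
    s_end = c(1000, 5652, 3000, 5400, 9900),
    orientation = "+", stringsAsFactors = FALSE)
  st <- structure(list(chain = ch), class = "insertion_structure")
  j <- structure_junctions(st)
  expect_equal(nrow(j), 3)
  expect_equal(j$left_unit, c(1, 3, 4))
  expect_equal(j$right_unit, c(3, 4, 5))
  j2 <- structure_junctions(st, collapse_organellar = FALSE)
  expect_equal(nrow(j2), 4)
})

test_that("a 652 bp plastome fragment between genomic arms is classified with its origin", {
  set.seed(62)
  g <- tiny_catalog(chrom_bp = 30000)
  chrom <- g$genome$chrT$bases
  cp <- g$catalog$records$plastome$bases
  cfg <- pipeline_config()
  idx <- build_index(g$catalog, k = cfg$index_k)

  win <- list(seq = paste0(substr(chrom, 9901, 10000),
                           substr(cp, 5001, 5652),
                           substr(chrom, 10011, 10110)),
              left_end = 100, right_start = 752,
              left_origin = list(kind = "GENOMIC", subject_id = "chrT",
                                 s_start = 9900, s_end = 10000,
                                 orientation = "+"),
              right_origin = list(kind = "GENOMIC", subject_id = "chrT",
                                  s_start = 10010, s_end = 10110,
                                  orientation = "+"),
              read_id = "synthetic", truncated = FALSE)
  rep1 <- classify_filler(win, g$catalog, cfg, index = idx)
  expect_equal(rep1$filler_len, 652, tolerance = 3)
  expect_equal(rep1$filler_origin, "PLASTOME")
  expect_equal(rep1$filler_stage, 1L)
})

test_that("clean junctions have no filler; planted microhomology is measured", {
  set.seed(63)
  g <- tiny_catalog(chrom_bp = 30000)
  chrom <- g$genome$chrT$bases
  cfg <- pipeline_config()
  idx <- build_index(g$catalog, k = cfg$index_k)

  # blunt genome::genome fusion with 5 bp engineered microhomology:
  # the last 5 bases before the left breakpoint equal the first 5 of the
  # right side
  right_start <- 20000
  mh5 <- substr(chrom, right_start + 1, right_start + 5)
  left_part <- paste0(substr(chrom, 7901, 7995), mh5)
  win <- list(seq = paste0(left_part, substr(chrom, right_start + 1,
                                             right_start + 100)),
              left_end = 100, right_start = 100,
              left_origin = list(kind = "GENOMIC", subject_id = "chrT",
                                 s_start = 7900, s_end = 8000,
                                 orientation = "+"),
              right_origin = list(kind = "GENOMIC", subject_id = "chrT",
                                  s_start = right_start, s_end = right_start + 100,
                                  orientation = "+"),
              read_id = "synthetic", truncated = FALSE)
  # the engineered window's left context in the catalog does not carry the
  # microhomology, so measure on the window-derived contexts instead
  expect_equal(find_microhomology(substr(win$seq, 1, 100),
                                  substr(win$seq, 101, 200)), 5)
  rep1 <- classify_filler(win, g$catalog, cfg, index = idx)
  expect_lte(rep1$filler_len, 10)
})

test_that("a short near-site filler is recovered only by the short-match cascade", {
  set.seed(64)
  g <- tiny_catalog(chrom_bp = 30000)
  chrom <- g$genome$chrT$bases
  cfg <- pipeline_config()
  idx <- build_index(g$catalog, k = cfg$index_k)

  # 9 bp filler copied from just left of the junction
  pos <- 12000
  filler <- substr(chrom, pos - 20, pos - 12)
  win <- list(seq = paste0(substr(chrom, pos - 99, pos), filler,
                           substr(chrom, pos + 31, pos + 130)),
              left_end = 100, right_start = 109,
              left_origin = list(kind = "GENOMIC", subject_id = "chrT",
                                 s_start = pos - 100, s_end = pos,
                                 orientation = "+"),
              right_origin = list(kind = "GENOMIC", subject_id = "chrT",
                                  s_start = pos + 30, s_end = pos + 130,
                                  orientation = "+"),
              read_id = "synthetic", truncated = FALSE)
  rep1 <- classify_filler(win, g$catalog, cfg, index = idx)
  expect_equal(rep1$filler_len, 9)
  # a 9 bp filler is structurally invisible to the stage-1 search (its
  # alignment is far below the stage-1 length floor); only the short-match
  # stages can source it
  expect_true(rep1$filler_stage %in% c(2L, 3L))
  expect_equal(rep1$filler_origin, "NUCLEAR")

  # idempotence: classifying the same window twice gives identical reports
  expect_identical(rep1, classify_filler(win, g$catalog, cfg, index = idx))
})
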