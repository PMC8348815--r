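mk_hits <- function(qs, qe, score, subject = NULL, query = "r1") {
  n <- length(qs)
  data.frame(query_id = query, q_start = qs, q_end = qe, strand = "+",
             subject_id = subject %||% paste0("s", seq_len(n)),
             s_start = 0L, s_end = qe - qs, identity = 0.95,
             score = score, evalue = 1e-60, aln_len = qe - qs,
             category = "NUCLEAR", stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("greedy tiling keeps 10 bp overlaps, discards larger, hand-traced case", {
  cfg <- pipeline_config()
  # overlap of exactly 10: both kept
  h <- mk_hits(c(0, 990), c(1000, 1500), c(900, 450))
  out <- tile_annotation(h, 2000, cfg)
  expect_equal(nrow(out), 2)
  # overlap of 15: second discarded
  h <- mk_hits(c(0, 985), c(1000, 1500), c(900, 450))
  out <- tile_annotation(h, 2000, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$q_start, 0)
  # hand-executed greedy cascade: only the top-scoring survives
  h <- mk_hits(c(0, 50, 120), c(100, 150, 200), c(50, 60, 40))
  out <- tile_annotation(h, 300, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$q_start, 50)
  expect_equal(out$q_end, 150)
})

test_that("tiling is invariant to input permutation and preserves coordinates", {
  set.seed(31)
  cfg <- pipeline_config()
  qs <- sort(sample(0:5000, 12)) * 3L
  base <- mk_hits(qs = qs, qe = qs + sample(200:900, 12),
                  score = sample(100:999, 12))
  ref <- tile_annotation(base, 20000, cfg)
  for (i in 1:5) {
    perm <- base[sample(nrow(base)), ]
    expect_equal(tile_annotation(perm, 20000, cfg), ref)
  }
  # accepted rows are a subset of the input with unchanged coordinates
  key <- paste(ref$q_start, ref$q_end, ref$score)
  expect_true(all(key %in% paste(base$q_start, base$q_end, base$score)))
  expect_error(tile_annotation(rbind(base, mk_hits(0, 10, 5, query = "other")),
                               20000, cfg), "single query")
})

test_that("gap finding applies the strict >1 kbp floor and partitions the read", {
  cfg <- pipeline_config()
  seg <- mk_hits(c(0, 3500), c(2000, 6000), c(900, 800))
  g <- find_gaps(seg, 6000, cfg)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$q_start, g$q_end), c(2000, 3500))

  seg_full <- mk_hits(0, 6000, 900)
  expect_equal(nrow(find_gaps(seg_full, 6000, cfg)), 0)

  seg800 <- mk_hits(c(0, 2800), c(2000, 6000), c(900, 800))
  expect_equal(nrow(find_gaps(seg800, 6000, cfg)), 0)

  # exact 1000 bp gap is not "> 1 kbp"
  seg1000 <- mk_hits(c(0, 3000), c(2000, 6000), c(900, 800))
  expect_equal(nrow(find_gaps(seg1000, 6000, cfg)), 0)

  # covered + uncovered lengths account for the whole read
  unc <- tdnalocus:::.uncovered_intervals(seg, 6000)
  cov_len <- sum(seg$q_end - seg$q_start)
  expect_equal(cov_len + sum(unc$q_end - unc$q_start), 6000)
})

test_that("sliding Phred windows anchor at multiples of the step", {
  cfg <- pipeline_config()
  r <- seq_record("r", strrep("A", 500), quals = rep(12L, 500))
  tr <- sliding_phred(r, cfg)
  expect_equal(length(tr$means), 4)
  expect_equal(tr$starts, c(0, 100, 200, 300))
  expect_true(all(tr$means == 12))

  short <- seq_record("s", strrep("A", 150), quals = rep(9L, 150))
  expect_error(sliding_phred(short, cfg), "shorter")
  expect_equal(sliding_phred(short, cfg, allow_short = TRUE)$means, 9)

  mixed <- seq_record("m", strrep("A", 600),
                      quals = c(rep(20L, 300), rep(7L, 300)))
  tm <- sliding_phred(mixed, cfg)
  expect_true(all(diff(tm$means) <= 0))
  expect_equal(tm$means[1], 20)
  expect_equal(tm$means[length(tm$means)], 7)
})

test_that("low-quality gaps flanked by T-DNA are flagged as candidate inverted arms", {
  cfg <- pipeline_config()
  seg <- mk_hits(c(0, 3500), c(2000, 6000), c(900, 800),
                 subject = c("pT_TDNA", "pT_TDNA"))
  seg$category <- "TDNA"
  ann <- structure(list(read_id = "m", read_len = 6000, segments = seg,
                        gaps = data.frame(q_start = 2000, q_end = 3500)),
                   class = "read_annotation")
  quals <- rep(13L, 6000); quals[2001:3500] <- 7L
  tr <- sliding_phred(seq_record("m", strrep("A", 6000), quals = quals), cfg)
  fl <- flag_quality_drop(tr, ann, low_q_threshold = 10)
  expect_equal(fl$verdict, "CANDIDATE_INVERTED_ARM")

  seg2 <- seg; seg2$category <- "NUCLEAR"
  ann2 <- ann; ann2$segments <- seg2
  fl2 <- flag_quality_drop(tr, ann2, low_q_threshold = 10)
  expect_equal(fl2$verdict, "LOW_QUALITY")

  quals3 <- rep(13L, 6000)
  tr3 <- sliding_phred(seq_record("m", strrep("A", 6000), quals = quals3), cfg)
  fl3 <- flag_quality_drop(tr3, ann, low_q_threshold = 10)
  expect_equal(fl3$verdict, "UNEXPLAINED")

  ann4 <- ann; ann4$gaps <- ann4$gaps[0, ]
  expect_equal(nrow(flag_quality_drop(tr, ann4)), 0)
})
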