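test_that("E-values follow the Karlin-Altschul form and its monotonicities", {
  sc <- scoring_scheme(karlin_K = 0.5, karlin_lambda = 1.0)
  expect_equal(evalue(20, 1000, 1000, sc), 0.5 * 1e6 * exp(-20),
               tolerance = 1e-12)
  expect_equal(evalue(20, 1000, 2000, sc) / evalue(20, 1000, 1000, sc), 2)
  expect_lt(evalue(40, 1000, 1000, sc), evalue(20, 1000, 1000, sc))
  expect_error(evalue(20, 0, 1000, sc), "positive")
  # the default lambda satisfies the score-distribution equation
  sc0 <- scoring_scheme()
  expect_equal(0.25 * exp(sc0$karlin_lambda * sc0$match) +
                 0.75 * exp(sc0$karlin_lambda * sc0$mismatch), 1,
               tolerance = 1e-8)
})

test_that("seed index covers both strands, skips N k-mers, validates k", {
  idx <- build_index(c(s = "ACGTACGTAA"), k = 8)
  hit <- index_lookup(idx, "ACGTACGT")
  expect_true(any(hit$strand == "+" & hit$pos == 0))
  rc <- index_lookup(idx, revcomp("ACGTACGT"))
  expect_true(any(rc$strand == "-"))
  expect_equal(build_index(c(s = strrep("N", 50)), k = 8)$total_len, 50)
  expect_equal(tdnalocus:::.index_info_cpp(build_index(c(s = strrep("N", 50)), k = 8)$ptr)$n_kmers, 0)
  expect_error(build_index(c(s = "ACGT"), k = 4), "between 8 and 21")
  expect_error(build_index(character(0), k = 12), "empty|named")
})

test_that("exact substrings align full-length with identity 1 and mirrored strands", {
  set.seed(21)
  s <- rand_seq(5000)
  q <- substr(s, 2001, 2500)
  idx <- build_index(c(subj = s), k = 12)
  h <- find_local_hits(q, idx, max_evalue = 1e-10)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1.0)
  expect_equal(h$q_start, 0); expect_equal(h$q_end, 500)
  expect_equal(h$s_start, 2000); expect_equal(h$s_end, 2500)
  expect_equal(h$strand, "+")

  h2 <- find_local_hits(revcomp(q), idx, max_evalue = 1e-10)
  expect_equal(h2$strand, "-")
  expect_equal(h2$s_start, 2000); expect_equal(h2$s_end, 2500)
  expect_equal(h2$score, h$score)
})

test_that("25% uniformly spaced mismatches fail the 80% identity cutoff but score the SW optimum", {
  set.seed(22)
  s <- rand_seq(4000)
  q <- mutate_seq(substr(s, 1001, 1300), frac = NA, spacing = 4)  # 25% mismatches
  idx <- build_index(c(subj = s), k = 8)
  h <- find_local_hits(q, idx, min_identity = 0.80, max_evalue = 1e-5,
                       min_aln_len = 50)
  expect_true(nrow(h) == 0 || all(h$identity >= 0.80 & h$aln_len < 300))
  hall <- find_local_hits(q, idx, min_identity = 0, max_evalue = Inf,
                          min_aln_len = 1)
  expect_equal(max(hall$score), as.numeric(biostrings_sw(q, s)))
})

test_that("hit search is deterministic and strand-symmetric on mutated copies", {
  set.seed(23)
  s <- rand_seq(30000)
  idx <- build_index(c(subj = s), k = 12)
  for (i in 1:5) {
    q <- mutate_seq(substr(s, 5000 + i * 1000, 5000 + i * 1000 + 1500),
                    frac = 0.08)
    h1 <- find_local_hits(q, idx, min_identity = 0, max_evalue = Inf,
                          min_aln_len = 1)
    h2 <- find_local_hits(q, idx, min_identity = 0, max_evalue = Inf,
                          min_aln_len = 1)
    expect_identical(h1, h2)
    expect_equal(max(h1$score), as.numeric(biostrings_sw(q, s)))
    hr <- find_local_hits(revcomp(q), idx, min_identity = 0, max_evalue = Inf,
                          min_aln_len = 1)
    expect_equal(max(hr$score), max(h1$score))
    expect_equal(hr$s_start[1], h1$s_start[1])
    expect_equal(hr$s_end[1], h1$s_end[1])
  }
})

test_that("a read spanning several catalog segments yields one hit per segment", {
  set.seed(24)
  chrom <- rand_seq(20000)
  vec <- rand_seq(3000)
  read <- paste0(substr(chrom, 1001, 3000), vec,
                 substr(chrom, 3001, 5000))
  idx <- build_index(c(chrT = chrom, vecT = vec), k = 12)
  h <- find_local_hits(read, idx, max_evalue = 1e-20)
  h <- h[order(h$q_start), ]
  expect_equal(nrow(h), 3)
  expect_equal(h$subject_id, c("chrT", "vecT", "chrT"))
  expect_equal(h$q_start, c(0, 2000, 5000))
})
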