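test_that("genome generation is seed-deterministic with retrievable borders", {
  cfg <- simulation_config(rng_seed = 9, chrom_sizes = c(chr1 = 20000L))
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$genome$chr1$bases, g2$genome$chr1$bases)
  expect_identical(g1$catalog$records$pTL1_TDNA$bases,
                   g2$catalog$records$pTL1_TDNA$bases)
  g3 <- make_genome(simulation_config(rng_seed = 10,
                                      chrom_sizes = c(chr1 = 20000L)))
  expect_false(identical(g1$genome$chr1$bases, g3$genome$chr1$bases))
  # LB repeat occupies vector positions 1-25 (1-based)
  vi <- g1$vector_info
  expect_equal(vi$lb, c(0L, 25L))
  lb_seq <- substr(g1$catalog$records$pTL1_TDNA$bases, 1, 25)
  expect_equal(nchar(lb_seq), 25)
  expect_equal(g1$catalog$tdna_borders$pTL1_TDNA$lb, c(0L, 25L))
})

test_that("planted events are recorded exactly in the truth set", {
  cfg <- simulation_config(rng_seed = 12, chrom_sizes = c(chr1 = 60000L,
                                                          chr2 = 60000L))
  g <- make_genome(cfg)
  vi <- g$vector_info

  # empty event list: mutant equals wild type
  pl0 <- plant_events(g$genome, g$catalog, list(), cfg, vi)
  expect_identical(pl0$mutant$chr1$bases, g$genome$chr1$bases)

  ev <- list(event_spec("TDNA_ARRAY", chrom = "chr1", pos = 30000L,
                        units = tdna_units(vi, c("+", "-")),
                        target_deletion_bp = 13L))
  pl <- plant_events(g$genome, g$catalog, ev, cfg, vi)
  tb <- pl$truth$blocks
  tu <- tb[tb$kind == "TDNA", ]
  expect_equal(nrow(tu), 2)
  expect_equal(tu$strand, c("+", "-"))
  anch <- pl$truth$anchors
  expect_setequal(anch$pos, c(30000, 30013))
  expect_equal(nrow(pl$truth$arms), 1)  # head-to-head pair forms one arm pair
  # mutant sequence is flank + insert + flank with the 13 bp deleted
  ins_len <- sum(tu$h_end - tu$h_start)
  expect_equal(nchar(pl$mutant$chr1$bases), 60000 - 13 + ins_len)

  ev2 <- list(event_spec("TRANSLOCATION_PAIR", chrom_a = "chr1", pos_a = 40000L,
                         chrom_b = "chr2", pos_b = 20000L,
                         units = tdna_units(vi, "+")))
  pl2 <- plant_events(g$genome, g$catalog, ev2, cfg, vi)
  expect_setequal(names(pl2$mutant), c("der_chr1_chr2", "der_chr2_chr1"))
  expect_equal(nrow(pl2$truth$anchors), 4)

  # overlapping events are rejected
  ev3 <- list(event_spec("TDNA_ARRAY", chrom = "chr1", pos = 30000L,
                         units = tdna_units(vi, "+")),
              event_spec("TDNA_ARRAY", chrom = "chr1", pos = 30000L,
                         units = tdna_units(vi, "+")))
  expect_error(plant_events(g$genome, g$catalog, ev3, cfg, vi), "overlap")
})

test_that("read simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(rng_seed = 13, chrom_sizes = c(chr1 = 30000L),
                           depth = 4)
  g <- make_genome(cfg)
  pl <- plant_events(g$genome, g$catalog, list(), cfg, g$vector_info)
  s1 <- simulate_reads(pl, cfg, pl$truth)
  g2 <- make_genome(cfg)
  pl2 <- plant_events(g2$genome, g2$catalog, list(), cfg, g2$vector_info)
  s2 <- simulate_reads(pl2, cfg, pl2$truth)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(s1$reads, f1)
  write_fastq(s2$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_gt(length(s1$reads), 0)
  # wild-type and mutant draws both occur at the configured fraction
  frac_wt <- mean(s1$truth$hap == "wt")
  expect_gt(frac_wt, 0.1); expect_lt(frac_wt, 0.6)
})

test_that("realized error rates match the configured model within 20%", {
  er <- simulator_error_rates(seed = 3)
  expect_lt(abs(er$mismatch - er$configured["mismatch"]),
            0.2 * er$configured["mismatch"])
  expect_lt(abs(er$insertion - er$configured["insertion"]),
            0.2 * er$configured["insertion"])
  expect_lt(abs(er$deletion - er$configured["deletion"]),
            0.2 * er$configured["deletion"])
  # sequence-level cross-check: re-aligned identity matches the model
  expect_gt(er$aligned_identity, 0.86)
  expect_lt(er$aligned_identity, 0.92)
})

test_that("the quality drop hits the second inverted-repeat arm in either direction", {
  cfg <- simulation_config(rng_seed = 14, chrom_sizes = c(chr1 = 40000L),
                           depth = 25, wt_allele_fraction = 0.01,
                           read_len_median = 12000)
  g <- make_genome(cfg)
  ev <- list(event_spec("TDNA_ARRAY", chrom = "chr1", pos = 20000L,
                        units = tdna_units(g$vector_info, c("+", "-"))))
  pl <- plant_events(g$genome, g$catalog, ev, cfg, g$vector_info)
  sim <- simulate_reads(pl, cfg, pl$truth)
  tt <- sim$truth
  dropped <- tt[tt$drop_applied, ]
  expect_gt(nrow(dropped), 3)
  expect_true(any(dropped$strand == "+") && any(dropped$strand == "-"))
  arms <- pl$truth$arms
  for (i in seq_len(nrow(dropped))) {
    r <- dropped[i, ]
    rd <- sim$reads[[r$read_id]]
    sel <- seq.int(r$drop_q_start + 1, r$drop_q_end)
    expect_lt(mean(rd$quals[sel]), 10)                  # dropped arm is low-Q
    expect_gt(mean(rd$quals[-sel]), 10)                 # the rest is not
    # the dropped genome interval is the arm encountered second in read
    # direction: the right arm for forward reads, the left arm for reverse
    second <- if (r$strand == "+") c(arms$a2_start, arms$a2_end)
              else c(arms$a1_start, arms$a1_end)
    ds <- max(r$start, second[1]); de <- min(r$end, second[2])
    expect_equal(r$drop_q_end - r$drop_q_start, de - ds, tolerance = 0.15)
  }
})

test_that("truth projection splits reads at block boundaries", {
  cfg <- simulation_config(rng_seed = 15, chrom_sizes = c(chr1 = 50000L),
                           depth = 3)
  g <- make_genome(cfg)
  ev <- list(event_spec("TDNA_ARRAY", chrom = "chr1", pos = 25000L,
                        units = tdna_units(g$vector_info, "+")))
  pl <- plant_events(g$genome, g$catalog, ev, cfg, g$vector_info)
  rt <- data.frame(read_id = "x", hap = "mut", chrom = "chr1",
                   start = 20000, end = 35000, strand = "+",
                   stringsAsFactors = FALSE)
  al <- truth_to_alignments(rt, pl$truth$blocks)
  expect_equal(nrow(al), 2)  # split across the insert
  expect_equal(al$start, c(20000, 25000))
  expect_true(all(al$end <= 35000))
  # median per-bin coverage of a simulated pool is close to the target depth
  cfg2 <- simulation_config(rng_seed = 16, chrom_sizes = c(chr1 = 150000L),
                            depth = 30)
  g2 <- make_genome(cfg2)
  pl2 <- plant_events(g2$genome, g2$catalog, list(), cfg2, g2$vector_info)
  sim2 <- simulate_reads(pl2, cfg2, pl2$truth)
  al2 <- truth_to_alignments(sim2$truth, rbind(pl2$truth$blocks))
  prof <- coverage_profile(al2, 150000, bin_bp = 1000)
  expect_lt(abs(median(prof$depth) - 30), 3)
})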