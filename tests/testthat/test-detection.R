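test_that("reads are selected iff they carry a passing T-DNA/BVB alignment", {
  set.seed(41)
  g <- tiny_catalog()
  chrom <- g$genome$chrT$bases
  tdna <- g$catalog$records$pTL1_TDNA$bases
  cfg <- pipeline_config()

  r_mix <- seq_record("mix", paste0(substr(tdna, 1, 2000),
                                    substr(chrom, 5001, 8000)))
  r_gen <- seq_record("gen", substr(chrom, 1001, 6000))
  # T-DNA segment degraded to ~70% identity: below the 80% cutoff
  r_deg <- seq_record("deg", paste0(substr(chrom, 9001, 10000),
                                    mutate_seq(substr(tdna, 3001, 3300), 0.30)))
  reads <- list(mix = r_mix, gen = r_gen, deg = r_deg)

  sel <- select_tdna_reads(reads, g$catalog, cfg)
  expect_true("mix" %in% names(sel))
  expect_false("gen" %in% names(sel))
  expect_false("deg" %in% names(sel))
  h <- sel$mix
  expect_true(all(h$category %in% c("TDNA", "BVB")))
  expect_lt(abs(h$q_start[1] - 0), 20)
  expect_lt(abs(h$q_end[1] - 2000), 20)

  # oracle: no >=80%-identity local alignment of >=50 columns exists for
  # the degraded segment
  sw <- sw_align(substr(r_deg$bases, 1001, 1300), tdna)
  expect_true(sw$identity < 0.80 || sw$aln_len < 50)
})

test_that("flank extraction returns 50 kbp (or truncates at contig ends)", {
  set.seed(42)
  cfg <- simulation_config(rng_seed = 5, chrom_sizes = c(chrF = 200000L))
  g <- make_genome(cfg)
  pcfg <- pipeline_config()

  fl <- extract_flanks(g$catalog, list(chrom = "chrF", start = 60000, end = 60001),
                       pcfg)
  expect_equal(nchar(fl$upstream$bases), 50000)
  expect_equal(nchar(fl$downstream$bases), 50000)
  expect_equal(fl$upstream$bases,
               substr(g$genome$chrF$bases, 10001, 60000))

  fl2 <- extract_flanks(g$catalog, list(chrom = "chrF", start = 10000, end = 10001),
                        pcfg)
  expect_equal(nchar(fl2$upstream$bases), 10000)
  expect_match(fl2$upstream$description, "truncated")

  expect_error(extract_flanks(g$catalog,
                              list(chrom = "nope", start = 1, end = 2), pcfg),
               "nuclear|unknown")
})

test_that("flank recruitment excludes T-DNA reads and is disjoint from selection", {
  set.seed(43)
  g <- tiny_catalog()
  chrom <- g$genome$chrT$bases
  tdna <- g$catalog$records$pTL1_TDNA$bases
  cfg <- pipeline_config()
  flank <- seq_record("flank", substr(chrom, 4001, 12000))

  reads <- list(
    wt = seq_record("wt", substr(chrom, 5001, 11000)),
    td = seq_record("td", paste0(substr(chrom, 5001, 8000),
                                 substr(tdna, 1, 2000))),
    far = seq_record("far", substr(chrom, 14001, 19000)))

  sel <- select_tdna_reads(reads, g$catalog, cfg)
  rec <- recruit_flank_reads(reads, flank, names(sel), cfg)
  expect_true("wt" %in% rec)
  expect_false("td" %in% rec)   # carries T-DNA
  expect_false("far" %in% rec)  # no flank overlap
  expect_length(intersect(names(sel), rec), 0)
  expect_length(recruit_flank_reads(list(), flank, character(), cfg), 0)

  det <- recruit_flank_reads(reads, flank, names(sel), cfg, detailed = TRUE)
  expect_equal(det$ids, rec)
  # fully contained read is not junction-informative
  expect_false("wt" %in% det$clipped)
})

test_that("pipeline configuration rejects unknown fields and bad values", {
  expect_error(pipeline_config(bogus = 1), "unknown")
  expect_error(pipeline_config(tile_max_overlap_bp = -1), "positive")
  expect_error(pipeline_config(expected_insert_chromosome_fraction = 1.5),
               "fraction")
  cfg <- pipeline_config(tdna_max_evalue = 1e-30)
  expect_equal(cfg$tdna_max_evalue, 1e-30)
  expect_equal(cfg$flank_extract_bp, 50000L)
  expect_equal(cfg$aef_group_dist_bp, 30000L)
})

test_that("reference catalogs validate category assignments", {
  recs <- list(a = seq_record("a", "ACGTACGTAC"), b = seq_record("b", "GGGTTTAAAC"))
  expect_error(reference_catalog(recs, c(a = "NUCLEAR")), "every record")
  expect_error(reference_catalog(recs, c(a = "NUCLEAR", b = "WEIRD")), "unknown")
  cat <- reference_catalog(recs, c(a = "NUCLEAR", b = "TDNA"))
  expect_equal(catalog_ids(cat, "TDNA"), "b")
  reads <- list(r = seq_record("r", strrep("ACGT", 30)))
  cat_no_tdna <- reference_catalog(recs, c(a = "NUCLEAR", b = "BVB"))
  expect_error(select_tdna_reads(reads, cat_no_tdna), "TDNA")
})
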