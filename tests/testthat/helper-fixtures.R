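# Shared helpers: random sequences, mutated copies, a miniature catalog.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Copy of `seqs` with a fraction of positions substituted.
mutate_seq <- function(seqs, frac, spacing = NULL) {
  ch <- strsplit(seqs, "", fixed = TRUE)[[1]]
  n <- length(ch)
  idx <- if (!is.null(spacing)) seq(1, n, by = spacing)
         else sample(n, round(frac * n))
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

# Small catalog: one chromosome, a plastome, a vector split into T-DNA and
# backbone records with known border coordinates.
tiny_catalog <- function(seed = 7, chrom_bp = 20000) {
  cfg <- simulation_config(rng_seed = seed,
                           chrom_sizes = c(chrT = as.integer(chrom_bp)),
                           plastome_bp = 8000L)
  make_genome(cfg)
}

biostrings_sw <- function(q, s, scheme = scoring_scheme()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                                  mismatch = scheme$mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(q, s, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = -scheme$gap_open,
                                gapExtension = -scheme$gap_extend,
                                scoreOnly = TRUE)
}
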