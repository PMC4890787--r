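# Shared fixture builders: everything is generated in code at test time.

# Scaled-down Mb rearrangement scenario: reference + derived haplotype +
# error-free reads; scale divides the printed breakpoints.
make_mb_scenario <- function(scale = 50, coverage = 15, seed = 42,
                             read_seed = 7) {
  spec <- mb_sv_spec(scale)
  bp <- mb_breakpoints(scale)
  ref0 <- random_toy_genome(max(bp$end) + 3000, seed = seed,
                            chrom_name = "chr27")
  der <- build_derived_haplotype(ref0, spec)
  reads <- simulate_junction_reads(der, read_len = 150, coverage = coverage,
                                   error_rate = 0, seed = read_seed)
  list(spec = spec, bp = bp, ref = attr(der, "reference"), derived = der,
       reads = reads)
}

# Random 3-segment rearrangement on a small toy genome. Segments are placed
# with generous gaps so reads span at most one junction and boundaries are
# unambiguous; the cassette order is a random permutation of the segments.
random_sv_scenario <- function(seed, n_seg = 3L, genome_len = 30000L) {
  set.seed(seed)
  seg_len <- sample(400:800, n_seg, replace = TRUE)
  gap <- 1500L
  starts <- cumsum(c(sample(2000:3000, 1), utils::head(seg_len, -1) + gap +
                       sample(0:500, n_seg - 1, replace = TRUE)))
  ends <- starts + seg_len - 1L
  perm <- sample(n_seg)
  ## insertion point: mid-backbone after the last segment, or a tandem-style
  ## point directly at a segment end
  insertion_after <- if (stats::runif(1) < 0.3) {
    ends[perm[length(perm)]]
  } else {
    max(ends) + sample(500:1000, 1)
  }
  n_novel <- n_seg + as.integer(insertion_after != ends[perm[n_seg]])
  jn <- lapply(seq_len(n_novel), function(i) {
    if (stats::runif(1) < 0.5) junction_homology(sample(0:3, 1))
    else junction_insertion(paste(sample(c("A", "C", "G", "T"),
                                         sample(1:8, 1), replace = TRUE),
                                  collapse = ""))
  })
  spec <- sv_spec(Map(c, starts[perm], ends[perm]), insertion_after, jn)
  ref0 <- random_toy_genome(genome_len, seed = seed + 1000L)
  der <- build_derived_haplotype(ref0, spec)
  list(spec = spec, ref = attr(der, "reference"), derived = der, perm = perm,
       starts = starts, ends = ends)
}

# Genotype matrix of independent markers (for null calibration / QC tests)
random_genotype_matrix <- function(n = 100, m = 200, maf = 0.5, miss = 0,
                                   seed = 1, chrom = "chr1") {
  set.seed(seed)
  calls <- matrix(stats::rbinom(n * m, 2L, maf), n, m)
  if (miss > 0) calls[stats::runif(n * m) < miss] <- NA
  rownames(calls) <- sprintf("I%04d", seq_len(n))
  colnames(calls) <- sprintf("S%04d", seq_len(m))
  genotype_matrix(calls, data.frame(id = colnames(calls), chrom = chrom,
                                    bp = seq_len(m) * 1000,
                                    stringsAsFactors = FALSE))
}

# Minimal pedigree where everyone is a founder (no trios)
founder_pedigree <- function(ids, sex = NULL) {
  data.frame(id = ids, sire = NA_character_, dam = NA_character_,
             sex = if (is.null(sex)) rep("M", length(ids)) else sex,
             stringsAsFactors = FALSE)
}
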