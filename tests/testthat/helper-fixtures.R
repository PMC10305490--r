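# shared fixture builders; everything is generated in code at test time

# constant-depth track
ct <- function(depth, len, ref = "rDNA", start = 1L) {
  depth_track(ref, start, rep(depth, len))
}

# random candidate-region table
random_candidates <- function(n, kind) {
  genes <- sprintf("G%02d", sample(ceiling(n / 2), n, replace = TRUE))
  start <- sample(1e5, n)
  len <- sample(50:12000, n, replace = TRUE)
  candidate_regions(region_id = sprintf("R%03d", seq_len(n)),
                    gene_id = genes, kind = kind,
                    chrom = sample(c("chr13", "chr21"), n, replace = TRUE),
                    start = start, end = start + len - 1L,
                    has_ambiguous_hit = stats::runif(n) < 0.2)
}

# small deterministic cohort configuration for fast tests
tiny_config <- function(...) {
  args <- list(n_samples = 8L, n_exons = 4L, n_introns = 4L,
               background_depth_mean = 30, seed = 11L)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# stack per-sample methylation bins into the long format the regression takes
stack_bins <- function(sim, min_reads = 10L, min_cpgs = 4L) {
  L <- sim$config$reference$total_length
  do.call(rbind, lapply(names(sim$samples), function(id) {
    b <- bin_methylation(sim$samples[[id]]$cov, L,
                         bin_len = sim$config$bin_len,
                         min_reads = min_reads, min_cpgs = min_cpgs)
    cbind(sample_id = id, b)
  }))
}

# CN per sample for a segment from in-memory simulated tracks
cohort_cn <- function(sim, window, trim = 0.05) {
  ex_ids <- sim$regions$region_id[sim$regions$kind == "exon"]
  in_ids <- sim$regions$region_id[sim$regions$kind == "intron"]
  do.call(rbind, lapply(names(sim$samples), function(id) {
    s <- sim$samples[[id]]
    brd <- compute_brd(s$background[ex_ids], s$background[in_ids], trim)$brd
    estimate_cn(s$rdna, window, brd, sample_id = id, segment = "18S")
  }))
}
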