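# CpG strand merging, 200-bp bin aggregation with coverage filters, and the
# per-sample global methylation summary.

#' Merge complementary CpG strand records into dyads
#'
#' A CpG dyad occupies positions (p, p+1) on the two strands. Counts observed
#' at p and p+1 are summed into a single record at the top-strand position p,
#' mirroring what coverage2cytosine's CpG-merging mode does at the read level.
#' Records at positions not belonging to any dyad pass through unchanged.
#'
#' @param records CpG record table ([cpg_records()]), position-sorted.
#' @param cpg_positions integer vector of dyad top-strand positions `p`;
#'   dyads must not overlap (no `p` may equal another dyad's `p + 1`).
#' @return merged CpG record table, one record per dyad or orphan position.
#' @export
merge_strand_cpgs <- function(records, cpg_positions) {
  cpg_positions <- sort(unique(as.integer(cpg_positions)))
  if (any(diff(cpg_positions) == 1L)) {
    stop2("overlapping CpG dyads: adjacent top-strand positions supplied")
  }
  top <- match(records$position, cpg_positions)
  bottom <- match(records$position, cpg_positions + 1L)
  dyad <- ifelse(!is.na(top), top, bottom)
  key <- ifelse(is.na(dyad), -records$position, dyad)
  m <- tapply(records$count_methylated, key, sum)
  u <- tapply(records$count_unmethylated, key, sum)
  k <- as.numeric(names(m))
  pos <- ifelse(k > 0, cpg_positions[pmax(k, 1)], -k)
  cpg_records(as.integer(pos), as.integer(m), as.integer(u))
}

#' Aggregate CpG methylation into fixed-length bins
#'
#' Partitions `[1, locus_length]` into consecutive non-overlapping bins of
#' `bin_len` bp. Within each bin the methylation percentage of every covered
#' CpG is computed from its counts and the bin mean is the unweighted mean of
#' those percentages (a coverage-weighted mean is available via `weighted`).
#' A bin passes the filters iff its summed read coverage is at least
#' `min_reads` and at least `min_cpgs` CpGs are covered; with
#' `per_cpg_reads = TRUE` the read minimum is instead required of every
#' covered CpG individually. The final partial bin (shorter than `bin_len`)
#' is emitted but flagged and never passes.
#'
#' @param records merged CpG record table.
#' @param locus_length locus length in bp.
#' @param bin_len bin length (default 200).
#' @param min_reads minimum summed coverage per bin (default 10).
#' @param min_cpgs minimum covered CpGs per bin (default 4).
#' @param weighted use a coverage-weighted bin mean.
#' @param per_cpg_reads apply `min_reads` to each CpG instead of the bin sum.
#' @return data.frame with one row per bin: `start`, `end`,
#'   `n_cpgs_covered`, `total_reads`, `mean_meth` (NA when no covered CpG),
#'   `partial`, `pass`.
#' @export
bin_methylation <- function(records, locus_length, bin_len = 200L,
                            min_reads = 10L, min_cpgs = 4L,
                            weighted = FALSE, per_cpg_reads = FALSE) {
  if (any(records$position < 1 | records$position > locus_length)) {
    stop2("CpG positions outside [1, locus_length]")
  }
  n_bins <- ceiling(locus_length / bin_len)
  start <- (seq_len(n_bins) - 1L) * bin_len + 1L
  end <- pmin(start + bin_len - 1L, as.integer(locus_length))
  covered <- records[records$coverage > 0, , drop = FALSE]
  bin_of <- (covered$position - 1L) %/% bin_len + 1L
  out <- data.frame(start = start, end = end,
                    n_cpgs_covered = 0L, total_reads = 0L,
                    mean_meth = NA_real_,
                    partial = (end - start + 1L) < bin_len,
                    pass = FALSE)
  if (nrow(covered)) {
    n_cov <- tabulate(bin_of, n_bins)
    out$n_cpgs_covered <- n_cov
    out$total_reads <- as.integer(
      vapply(seq_len(n_bins),
             function(b) sum(covered$coverage[bin_of == b]), numeric(1)))
    mm <- vapply(seq_len(n_bins), function(b) {
      r <- covered[bin_of == b, , drop = FALSE]
      if (!nrow(r)) return(NA_real_)
      if (weighted) 100 * sum(r$count_methylated) / sum(r$coverage)
      else mean(r$meth_pct)
    }, numeric(1))
    out$mean_meth <- mm
    min_ok <- if (per_cpg_reads) {
      vapply(seq_len(n_bins), function(b)
        nrow(covered[bin_of == b, ]) > 0 &&
          all(covered$coverage[bin_of == b] >= min_reads), logical(1))
    } else out$total_reads >= min_reads
    out$pass <- min_ok & out$n_cpgs_covered >= min_cpgs & !out$partial
  }
  out
}

#' Coverage-weighted global methylation level of a sample
#'
#' `100 * sum(methylated) / (sum(methylated) + sum(unmethylated))` over all
#' covered CpGs — the per-sample summary used to compare methylation across
#' tissues.
#'
#' @param records CpG record table.
#' @return percentage in `[0, 100]`.
#' @export
global_methylation <- function(records) {
  tot <- sum(records$coverage)
  if (!tot) stop2("zero total CpG coverage")
  100 * sum(records$count_methylated) / tot
}
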