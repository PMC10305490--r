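# Window selection, background read depth (BRD), and relative copy number.
#
# CN = ARD(segment window) / BRD, where ARD is the untrimmed mean per-base
# depth over the selected 150-bp window and BRD is the mean of the upper-tail
# trimmed average depths of single-copy exons and single-copy introns.

#' Sliding-window coefficient-of-variation scan over a segment
#'
#' The 45S locus shows strong positional coverage variation, so copy number is
#' quantified in a window where depth is stable across samples. For every
#' window position the per-sample window mean depth is computed; within each
#' library group the coefficient of variation (population SD / mean) of those
#' means is taken, and windows are ranked by the unweighted mean CV across
#' groups. Windows overlapping the exclusion zone (18S homology artifact) are
#' not scanned; windows where any group has zero mean depth are skipped.
#'
#' @param tracks named list of [depth_track()], one per sample, all covering
#'   the segment interval.
#' @param segment 1-based closed interval to scan.
#' @param groups named character vector mapping sample name to library-group
#'   label; defaults to a single group.
#' @param window_len window length in bp (150).
#' @param step scan step in bp (1).
#' @param exclusion optional 1-based closed interval; overlapping windows are
#'   omitted.
#' @return data.frame of window stats (`start`, `end`, one `cv_<group>`
#'   column per group, `mean_cv`), sorted by position. The number of windows
#'   skipped for a zero-mean group is recorded in attribute `n_skipped`.
#' @export
window_scan <- function(tracks, segment, groups = NULL, window_len = 150L,
                        step = 1L, exclusion = NULL) {
  if (length(tracks) < 2L) stop2("window_scan needs >= 2 samples")
  if (!interval_ok(segment)) stop2("`segment` is not a valid interval")
  if (interval_len(segment) < window_len) {
    stop2("segment shorter than the window length")
  }
  nms <- names(tracks)
  if (is.null(nms)) nms <- as.character(seq_along(tracks))
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(nms)), nms)
  groups <- groups[nms]
  starts <- seq.int(segment[1], segment[2] - window_len + 1L, by = step)
  ends <- starts + window_len - 1L
  if (!is.null(exclusion)) {
    keep <- ends < exclusion[1] | starts > exclusion[2]
    starts <- starts[keep]
    ends <- ends[keep]
  }
  if (!length(starts)) stop2("no scannable windows after exclusion")
  # per-sample window means via cumulative sums
  win_means <- vapply(tracks, function(tr) {
    d <- track_slice(tr, segment)
    cs <- c(0, cumsum(d))
    i <- starts - segment[1] + 1L
    (cs[i + window_len] - cs[i]) / window_len
  }, numeric(length(starts)))
  if (is.null(dim(win_means))) win_means <- matrix(win_means, nrow = 1L)
  glabels <- unique(groups)
  cvs <- matrix(NA_real_, nrow = length(starts), ncol = length(glabels),
                dimnames = list(NULL, paste0("cv_", glabels)))
  for (j in seq_along(glabels)) {
    m <- win_means[, groups == glabels[j], drop = FALSE]
    mu <- rowMeans(m)
    sdev <- sqrt(rowMeans((m - mu)^2))   # population SD
    cvs[, j] <- ifelse(mu > 0, sdev / mu, NA_real_)
  }
  mean_cv <- rowMeans(cvs)
  ok <- !is.na(mean_cv)
  out <- data.frame(start = starts[ok], end = ends[ok])
  out <- cbind(out, as.data.frame(cvs[ok, , drop = FALSE]))
  out$mean_cv <- mean_cv[ok]
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Select the quantification window with minimal mean CV
#'
#' @param stats data.frame from [window_scan()].
#' @return the single winning row; ties broken by smallest start.
#' @export
select_window <- function(stats) {
  if (is.null(stats) || !nrow(stats)) stop2("no windows to select from")
  i <- which(stats$mean_cv == min(stats$mean_cv))[1]  # leftmost tie-break
  stats[i, , drop = FALSE]
}

#' Upper-tail trimmed mean depth
#'
#' Sorts the per-base depths and removes the top `ceiling(n * upper_fraction)`
#' values before averaging, guarding the background estimate against local
#' alignment pile-ups.
#'
#' @param depths numeric vector of per-base depths.
#' @param upper_fraction fraction of the upper tail to drop, in `[0, 1)`.
#' @return mean of the retained values.
#' @export
trimmed_mean_depth <- function(depths, upper_fraction = 0.05) {
  n <- length(depths)
  if (!n) stop2("empty depth vector")
  if (upper_fraction < 0 || upper_fraction >= 1) {
    stop2("`upper_fraction` must be in [0, 1)")
  }
  drop <- ceiling(n * upper_fraction)
  if (drop >= n) stop2("trimming would remove all values")
  if (drop == 0L) return(mean(depths))
  s <- sort(depths)
  mean(s[seq_len(n - drop)])
}

#' Background read depth from single-copy exons and introns
#'
#' Pools per-base depths across all exon regions of a sample, applies
#' [trimmed_mean_depth()] to get the exon average read depth; the same for
#' introns; BRD is the mean of the two.
#'
#' @param exon_tracks,intron_tracks lists of [depth_track()] (one per
#'   region) for one sample.
#' @param upper_fraction upper-tail trim fraction (default 0.05).
#' @return list with `ard_exons`, `ard_introns`, `brd`.
#' @export
compute_brd <- function(exon_tracks, intron_tracks, upper_fraction = 0.05) {
  pool <- function(tracks, what) {
    if (!length(tracks)) stop2("empty ", what, " track set")
    unlist(lapply(tracks, `[[`, "depths"), use.names = FALSE)
  }
  ard_ex <- trimmed_mean_depth(pool(exon_tracks, "exon"), upper_fraction)
  ard_in <- trimmed_mean_depth(pool(intron_tracks, "intron"), upper_fraction)
  list(ard_exons = ard_ex, ard_introns = ard_in, brd = (ard_ex + ard_in) / 2)
}

#' Relative rDNA copy number for one sample and segment
#'
#' `cn = ARD / BRD` where ARD is the plain (untrimmed) mean depth over the
#' quantification window.
#'
#' @param track [depth_track()] covering the window.
#' @param window 1-based closed interval (the selected 150-bp window).
#' @param brd background read depth (> 0).
#' @param sample_id,segment identifiers carried into the result.
#' @return one-row data.frame (`sample_id`, `segment`, `ard`, `brd`, `cn`).
#' @export
estimate_cn <- function(track, window, brd, sample_id = NA_character_,
                        segment = NA_character_) {
  if (!is.numeric(brd) || length(brd) != 1L || !is.finite(brd) || brd <= 0) {
    stop2("`brd` must be a single positive number")
  }
  ard <- mean(track_slice(track, window))
  data.frame(sample_id = sample_id, segment = segment,
             ard = ard, brd = brd, cn = ard / brd,
             stringsAsFactors = FALSE)
}

#' Copy-number and methylation stability under depth thinning
#'
#' Emulates re-sequencing at reduced coverage by binomially thinning every
#' depth value (rDNA and background alike) and every CpG count at each keep
#' fraction, then re-estimating CN per segment and the global methylation
#' level.
#'
#' @param rdna_track [depth_track()] over the 45S reference.
#' @param exon_tracks,intron_tracks background region tracks.
#' @param windows named list of quantification windows per segment.
#' @param cov optional CpG record table for global methylation.
#' @param fractions keep fractions in (0, 1].
#' @param seed integer seed for the thinning draws.
#' @param upper_fraction BRD trim fraction.
#' @param sample_id identifier carried into the result.
#' @return tidy data.frame: one row per fraction with `cn_<segment>` columns
#'   and `global_meth` (NA when `cov` is NULL).
#' @export
stability_profile <- function(rdna_track, exon_tracks, intron_tracks, windows,
                              cov = NULL, fractions = seq(1, 0.1, by = -0.1),
                              seed = 1L, upper_fraction = 0.05,
                              sample_id = NA_character_) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop2("fractions must lie in (0, 1]")
  }
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    s <- derive_seed(seed, i)
    rt <- thin_depth(rdna_track, f, seed = s)
    et <- lapply(seq_along(exon_tracks), function(j)
      thin_depth(exon_tracks[[j]], f, seed = derive_seed(s, j)))
    it <- lapply(seq_along(intron_tracks), function(j)
      thin_depth(intron_tracks[[j]], f, seed = derive_seed(s, 1000 + j)))
    brd <- compute_brd(et, it, upper_fraction)$brd
    row <- data.frame(sample_id = sample_id, fraction = f)
    for (seg in names(windows)) {
      row[[paste0("cn_", seg)]] <-
        estimate_cn(rt, windows[[seg]], brd)$cn
    }
    row$global_meth <- if (is.null(cov)) NA_real_ else {
      thinned <- thin_cpg_records(cov, f, seed = derive_seed(s, 999983))
      global_methylation(thinned)
    }
    row
  })
  do.call(rbind, rows)
}
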