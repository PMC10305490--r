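# Synthetic cohort generator. Emits the exact on-disk dialects the readers in
# io.R consume, together with a ground-truth table, so every downstream
# estimator can be checked against known values.
#
# Generative model, per sample i with true relative copy number c_i:
#   c_i ~ LogNormal(cn_log_mean, cn_log_sd)
#   background depth(pos) ~ NB(mu = background_depth_mean, size = dispersion)
#   rDNA depth(pos) ~ NB(mu = c_i * background_depth_mean * profile_i(pos)
#                             * artifact(pos) * chemistry_bias[chem_i], size)
#   bin methylation mean = clamp(intercept + slope * c_i * effect(bin)
#                                + beta_age * age + beta_sex * sex
#                                + beta_group * group, 0, 100)
#   per-CpG methylated count ~ Binomial(coverage, mean / 100)
#
# profile_i is a smooth per-sample positional multiplier, exp(amp(pos) * s_i),
# with s_i a seeded spline through Gaussian knots. Its amplitude amp(pos) is
# zero in a "stable zone" around each default quantification window, so a
# minimum-CV window genuinely exists, and the noise-free limit recovers c_i
# exactly. artifact(pos) boosts depth inside the 18S homology zone.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a realistic WGBS brain cohort: 30 samples, ~30x
#' single-copy background coverage, lognormal copy number centred near 200
#' copies with high inter-individual spread (roughly 100--400), overdispersed
#' per-base depth, a 3x homology artifact over the first 900 bp of 18S, and
#' bin methylation rising ~0.1 percentage points per rDNA copy from a 10%
#' baseline in every 200-bp bin except the first three (which stay flat).
#'
#' @param n_samples cohort size.
#' @param cn_log_mean,cn_log_sd lognormal parameters of true relative CN.
#' @param background_depth_mean mean per-base background depth (x coverage).
#' @param background_depth_dispersion negative-binomial size parameter;
#'   `Inf` gives Poisson-like behaviour (smaller = noisier).
#' @param profile_smoothness spacing (bp) of the spline knots of the smooth
#'   positional coverage profile.
#' @param profile_sd amplitude (log scale) of the positional profile outside
#'   the stable zones; 0 disables positional variability.
#' @param artifact_boost depth multiplier inside the 18S exclusion zone.
#' @param chemistry_bias named numeric vector: multiplicative bias applied to
#'   rDNA depth (and CpG coverage) only, per library-chemistry label; samples
#'   are assigned labels round-robin.
#' @param meth_intercept baseline bin methylation (%).
#' @param meth_slope_per_copy methylation change (% per rDNA copy) in effect
#'   bins.
#' @param meth_age_effect,meth_sex_effect,meth_group_effect covariate effects
#'   on bin methylation (%).
#' @param n_cpg_per_bin_range integer range of CpG dyads per 200-bp bin.
#' @param null_bins indices of bins that carry no CN effect; default the
#'   first three bins of the locus.
#' @param bin_len methylation bin length (bp).
#' @param age_range uniform age range (years).
#' @param case_fraction fraction of samples labelled as disease cases.
#' @param n_exons,n_introns number of synthetic background regions.
#' @param noise `FALSE` replaces every random depth/count draw by its exact
#'   expectation (the deterministic limit used for exact-recovery checks).
#' @param reference [rdna_reference()] the cohort is simulated on.
#' @param seed integer master seed; all randomness derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 30L,
                       cn_log_mean = log(200), cn_log_sd = 0.35,
                       background_depth_mean = 30,
                       background_depth_dispersion = 20,
                       profile_smoothness = 500,
                       profile_sd = 0.6,
                       artifact_boost = 3,
                       chemistry_bias = c(default = 1),
                       meth_intercept = 10,
                       meth_slope_per_copy = 0.1,
                       meth_age_effect = 0.05,
                       meth_sex_effect = 1,
                       meth_group_effect = 0,
                       n_cpg_per_bin_range = c(4L, 10L),
                       null_bins = 1:3,
                       bin_len = 200L,
                       age_range = c(20, 80),
                       case_fraction = 0.5,
                       n_exons = 12L, n_introns = 12L,
                       noise = TRUE,
                       reference = rdna_reference(),
                       seed = 1L) {
  stopifnot(n_samples >= 1, background_depth_mean > 0,
            background_depth_dispersion > 0, artifact_boost > 0,
            all(chemistry_bias > 0), bin_len >= 1,
            n_cpg_per_bin_range[1] >= 1,
            n_cpg_per_bin_range[2] >= n_cpg_per_bin_range[1])
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# amplitude of the positional profile: profile_sd everywhere except a stable
# zone (window +- 175 bp) around each default window, where it is exactly 0
profile_amplitude <- function(cfg) {
  amp <- rep(cfg$profile_sd, cfg$reference$total_length)
  for (w in stable_zones(cfg$reference)) amp[w[1]:w[2]] <- 0
  amp
}

stable_zones <- function(ref, pad = 175L) {
  lapply(ref$default_windows, function(w)
    c(max(1L, w[1] - pad), min(ref$total_length, w[2] + pad)))
}

sample_profile <- function(cfg, amp) {
  L <- cfg$reference$total_length
  if (cfg$profile_sd == 0) return(rep(1, L))
  knots <- seq(1, L, by = cfg$profile_smoothness)
  if (knots[length(knots)] != L) knots <- c(knots, L)
  vals <- stats::rnorm(length(knots))
  # zero the field at and next to each stable zone so that it ramps smoothly
  # from zero there: windows straddling a zone edge then carry per-sample
  # distortion that vanishes with their distance into the variable region,
  # keeping the scan's minimum identifiable against chance dips
  for (z in stable_zones(cfg$reference)) {
    vals[knots >= z[1] - cfg$profile_smoothness &
           knots <= z[2] + cfg$profile_smoothness] <- 0
  }
  s <- stats::spline(knots, vals, xout = seq_len(L))$y
  exp(amp * s)
}

nb_draw <- function(n, mu, size, noise) {
  if (!noise) return(mu)
  if (is.infinite(size)) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate a cohort of depth and methylation files with known truth
#'
#' Generates, per sample: an rDNA [depth_track()] over the full modified
#' reference, one background track per synthetic single-copy exon/intron
#' region, and a table of per-CpG methylation counts whose bin means follow
#' the configured linear CN--methylation model. When `out_dir` is given,
#' everything is written in the package's I/O dialects (depth TSV, Bismark
#' `.cov`, BED, CSV sample sheet, truth TSV); outputs are byte-identical for
#' identical seeds.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory; created if missing.
#' @return invisibly, a list with `truth` (per-sample true CN, chemistry and
#'   covariates), `bin_effects` (which bins carry the CN slope),
#'   `samples` (in-memory tracks and CpG tables per sample), `regions`
#'   (background region table), `sample_sheet`, and `paths` when written.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  ref <- cfg$reference
  L <- ref$total_length
  n <- cfg$n_samples

  # cohort-level truth
  true_cn <- stats::rlnorm(n, cfg$cn_log_mean, cfg$cn_log_sd)
  chem <- rep(names(cfg$chemistry_bias), length.out = n)
  age <- round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]), 1)
  sex <- stats::rbinom(n, 1, 0.5)
  group <- as.integer(seq_len(n) <= round(n * cfg$case_fraction))
  sample_id <- sprintf("S%02d", seq_len(n))

  # synthetic single-copy background regions on acrocentric chromosomes
  acro <- c("chr13", "chr14", "chr15", "chr21", "chr22")
  reg_len <- function(k, kind) {
    if (kind == "exon") sample(301:2000, k, replace = TRUE)
    else sample(301:8000, k, replace = TRUE)
  }
  mk_regions <- function(k, kind, prefix) {
    len <- reg_len(k, kind)
    start <- sample(1e6:2e6, k)
    candidate_regions(region_id = sprintf("%s%02d", prefix, seq_len(k)),
                      gene_id = sprintf("G_%s%02d", prefix, seq_len(k)),
                      kind = kind,
                      chrom = sample(acro, k, replace = TRUE),
                      start = start, end = start + len - 1L)
  }
  regions <- rbind(mk_regions(cfg$n_exons, "exon", "EX"),
                   mk_regions(cfg$n_introns, "intron", "IN"))

  # fixed CpG dyad layout shared by the cohort
  n_bins <- ceiling(L / cfg$bin_len)
  bin_start <- (seq_len(n_bins) - 1L) * cfg$bin_len + 1L
  bin_end <- pmin(bin_start + cfg$bin_len - 1L, L)
  cpg_bin <- integer(0)
  cpg_pos <- integer(0)
  for (b in seq_len(n_bins)) {
    k <- sample(seq(cfg$n_cpg_per_bin_range[1], cfg$n_cpg_per_bin_range[2]),
                1L)
    # top-strand positions of CpG dyads (p, p+1), kept non-adjacent
    cand <- seq(bin_start[b], bin_end[b] - 1L, by = 3L)
    k <- min(k, length(cand))
    cpg_pos <- c(cpg_pos, sort(sample(cand, k)))
    cpg_bin <- c(cpg_bin, rep(b, k))
  }
  effect <- !(seq_len(n_bins) %in% cfg$null_bins)
  bin_effects <- data.frame(bin = seq_len(n_bins), start = bin_start,
                            end = bin_end, effect = effect)

  amp <- profile_amplitude(cfg)
  artifact <- rep(1, L)
  ez <- ref$exclusion_zone
  artifact[ez[1]:ez[2]] <- cfg$artifact_boost

  samples <- vector("list", n)
  names(samples) <- sample_id
  for (i in seq_len(n)) {
    bias <- cfg$chemistry_bias[[chem[i]]]
    prof <- sample_profile(cfg, amp)
    mu_rdna <- true_cn[i] * cfg$background_depth_mean * prof * artifact * bias
    rdna <- depth_track("rDNA", 1L,
                        nb_draw(L, mu_rdna, cfg$background_depth_dispersion,
                                cfg$noise))
    bg <- lapply(seq_len(nrow(regions)), function(r) {
      len <- regions$length[r]
      depth_track(regions$region_id[r], regions$start[r],
                  nb_draw(len, rep(cfg$background_depth_mean, len),
                          cfg$background_depth_dispersion, cfg$noise))
    })
    names(bg) <- regions$region_id

    mean_meth <- cfg$meth_intercept +
      cfg$meth_slope_per_copy * true_cn[i] * effect[cpg_bin] +
      cfg$meth_age_effect * age[i] + cfg$meth_sex_effect * sex[i] +
      cfg$meth_group_effect * group[i]
    mean_meth <- pmin(100, pmax(0, mean_meth))
    mu_cov <- true_cn[i] * cfg$background_depth_mean * bias
    coverage <- if (cfg$noise) {
      stats::rnbinom(length(cpg_pos), mu = mu_cov,
                     size = cfg$background_depth_dispersion)
    } else rep(round(mu_cov), length(cpg_pos))
    m <- if (cfg$noise) {
      stats::rbinom(length(cpg_pos), coverage, mean_meth / 100)
    } else round(coverage * mean_meth / 100)
    samples[[i]] <- list(rdna = rdna, background = bg,
                         cov = cpg_records(cpg_pos, m, coverage - m))
  }

  truth <- data.frame(sample_id = sample_id, true_cn = true_cn,
                      chemistry = chem, age = age, sex = sex, group = group,
                      stringsAsFactors = FALSE)
  sheet <- truth[, c("sample_id", "age", "sex", "group", "chemistry")]

  out <- list(truth = truth, bin_effects = bin_effects,
              meth_slope_per_copy = cfg$meth_slope_per_copy,
              samples = samples, regions = regions, sample_sheet = sheet,
              config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop2("cannot create output dir: ", out_dir)
    paths <- list()
    # paths in the sheet are relative to the sheet's directory, so a cohort
    # directory is relocatable and byte-identical across runs
    sheet$rdna_depth <- paste0(sample_id, ".rdna.depth.tsv")
    sheet$background_depth <- paste0(sample_id, ".bg.depth.tsv")
    sheet$cov_file <- paste0(sample_id, ".CpG.cov")
    for (i in seq_len(n)) {
      s <- samples[[i]]
      write_depth_table(s$rdna, file.path(out_dir, sheet$rdna_depth[i]))
      write_depth_table(s$background,
                        file.path(out_dir, sheet$background_depth[i]))
      write_bismark_cov(s$cov, file.path(out_dir, sheet$cov_file[i]))
    }
    paths$sample_sheet <- file.path(out_dir, "samples.csv")
    write_sample_sheet(sheet, paths$sample_sheet)
    paths$regions_bed <- file.path(out_dir, "background_regions.bed")
    write_regions_bed(regions, paths$regions_bed)
    paths$truth <- file.path(out_dir, "truth.tsv")
    write_result_tsv(truth, paths$truth, seed = cfg$seed)
    paths$bin_effects <- file.path(out_dir, "bin_effects.tsv")
    write_result_tsv(bin_effects, paths$bin_effects, seed = cfg$seed)
    out$sample_sheet <- sheet
    out$paths <- paths
  }
  invisible(out)
}

#' Binomially thin a depth track
#'
#' Replaces each per-base depth `d` by a `Binomial(d, fraction)` draw,
#' emulating sequencing at a reduced read fraction (the depth-level
#' equivalent of splitting a read file and keeping a subset).
#'
#' @param track a [depth_track()].
#' @param fraction keep probability in (0, 1].
#' @param seed optional seed for the draw.
#' @return the thinned [depth_track()]; `fraction = 1` returns the input
#'   unchanged.
#' @export
thin_depth <- function(track, fraction, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop2("`fraction` must be in (0, 1]")
  }
  if (fraction == 1) return(track)
  if (!is.null(seed)) set.seed(seed)
  depth_track(track$ref_name, track$start,
              stats::rbinom(length(track$depths), track$depths, fraction))
}

#' Binomially thin per-CpG methylation counts
#'
#' Methylated and unmethylated read counts are thinned independently with the
#' same keep probability, matching what discarding a random read subset does
#' to a coverage file.
#'
#' @param records CpG record table ([cpg_records()]).
#' @param fraction keep probability in (0, 1].
#' @param seed optional seed.
#' @return thinned CpG record table.
#' @export
thin_cpg_records <- function(records, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop2("`fraction` must be in (0, 1]")
  if (fraction == 1) return(records)
  if (!is.null(seed)) set.seed(seed)
  m <- stats::rbinom(nrow(records), records$count_methylated, fraction)
  u <- stats::rbinom(nrow(records), records$count_unmethylated, fraction)
  cpg_records(records$position, m, u)
}
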