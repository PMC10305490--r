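# End-to-end orchestration: simulate (optional) -> window selection -> BRD ->
# CN -> methylation bins -> association -> group test -> stability (optional).
# Every run writes a machine-readable manifest; result tables are
# byte-identical across runs with the same config and seed.

#' Read a flat reference-configuration file
#'
#' Whitespace-separated `key value...` lines:
#' `total_length <bp>`, `segment <name> <start> <end>`,
#' `window <name> <start> <end>`, `exclusion <start> <end>`.
#' Lines starting with `#` are ignored.
#'
#' @param path config path.
#' @return an [rdna_reference()].
#' @export
read_reference_config <- function(path) {
  if (!file.exists(path)) stop2("reference config not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  total <- 15979L
  segs <- list()
  wins <- list()
  excl <- NULL
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    switch(f[1],
           total_length = { total <- as.integer(f[2]) },
           segment = { segs[[f[2]]] <- as.integer(f[3:4]) },
           window = { wins[[f[2]]] <- as.integer(f[3:4]) },
           exclusion = { excl <- as.integer(f[2:3]) },
           stop2("unknown reference config key: ", f[1]))
  }
  rdna_reference(segments = if (length(segs)) segs else NULL,
                 total_length = total,
                 exclusion_zone = excl,
                 windows = if (length(wins)) wins else NULL)
}

#' Pipeline run configuration
#'
#' @param sample_sheet path to the cohort CSV ([read_sample_sheet()]).
#' @param regions_bed path to the background-regions BED.
#' @param out_dir output directory for result tables.
#' @param reference an [rdna_reference()] or a path readable by
#'   [read_reference_config()].
#' @param fixed_windows `TRUE` skips the CV scan and quantifies in the
#'   reference's default windows; a named list of intervals overrides them.
#' @param window_len,step sliding-window scan parameters.
#' @param trim_fraction upper-tail trim for BRD.
#' @param bin_len,min_reads,min_cpgs methylation bin parameters.
#' @param stability_fractions keep fractions for the depth-robustness table;
#'   `NULL` skips the stage.
#' @param seed integer seed recorded in outputs and used for thinning.
#' @param verbose log stage progress to stderr.
#' @return a `run_config` list, validated for path existence.
#' @export
run_config <- function(sample_sheet, regions_bed, out_dir,
                       reference = rdna_reference(),
                       fixed_windows = FALSE,
                       window_len = 150L, step = 1L,
                       trim_fraction = 0.05,
                       bin_len = 200L, min_reads = 10L, min_cpgs = 4L,
                       stability_fractions = NULL,
                       seed = 1L, verbose = FALSE) {
  for (p in c(sample_sheet, regions_bed)) {
    if (!file.exists(p)) stop2("config error: path does not exist: ", p)
  }
  if (is.character(reference)) reference <- read_reference_config(reference)
  stopifnot(inherits(reference, "rdna_reference"))
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

log_stage <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[rdnacopy] ", ...)
}

#' Run the full analysis pipeline
#'
#' Stages: load inputs; select a quantification window per segment (CV scan,
#' or fixed windows); compute per-sample BRD and CN; bin CpG methylation and
#' summarize global methylation; regress CN on bin methylation with
#' covariate adjustment and FDR; logistic case-control comparison; optional
#' depth-thinning stability table. Any stage failure aborts with the stage
#' name; partial outputs are marked with a `.partial` file that is removed on
#' success.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a named list of the result data.frames plus the output
#'   file paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(cfg$out_dir, ".partial")
  file.create(marker)
  stage <- "load"
  res <- tryCatch({
    log_stage(cfg, "stage: load inputs")
    sheet <- read_sample_sheet(cfg$sample_sheet)
    need <- c("rdna_depth", "background_depth", "cov_file")
    miss <- setdiff(need, names(sheet))
    if (length(miss)) {
      stop2("sample sheet lacks path column(s): ", paste(miss, collapse = ", "))
    }
    # relative paths resolve against the sample sheet's directory
    sheet_dir <- dirname(cfg$sample_sheet)
    for (col in need) {
      rel <- !grepl("^(/|[A-Za-z]:)", sheet[[col]])
      sheet[[col]][rel] <- file.path(sheet_dir, sheet[[col]][rel])
    }
    regions <- read_regions_bed(cfg$regions_bed)
    exons <- filter_single_copy_regions(
      regions[regions$kind == "exon", ], "exon")
    introns <- filter_single_copy_regions(
      regions[regions$kind == "intron", ], "intron")
    ref <- cfg$reference

    n <- nrow(sheet)
    rdna <- vector("list", n)
    bg <- vector("list", n)
    cov <- vector("list", n)
    for (i in seq_len(n)) {
      rdna[[i]] <- read_depth_table(sheet$rdna_depth[i])[[1]]
      bg[[i]] <- read_depth_table(sheet$background_depth[i])
      cov[[i]] <- read_bismark_cov(sheet$cov_file[i])
    }
    names(rdna) <- names(bg) <- names(cov) <- sheet$sample_id
    split_bg <- function(tracks, ids) tracks[names(tracks) %in% ids]

    stage <- "windows"
    log_stage(cfg, "stage: window selection")
    groups <- stats::setNames(sheet$chemistry, sheet$sample_id)
    windows <- list()
    window_stats <- NULL
    if (isTRUE(cfg$fixed_windows)) {
      windows <- ref$default_windows
    } else if (is.list(cfg$fixed_windows)) {
      windows <- cfg$fixed_windows
    } else {
      for (seg in names(ref$segments)) {
        excl <- if (intervals_overlap(ref$exclusion_zone,
                                      ref$segments[[seg]]))
          ref$exclusion_zone else NULL
        ws <- window_scan(rdna, ref$segments[[seg]], groups = groups,
                          window_len = cfg$window_len, step = cfg$step,
                          exclusion = excl)
        ws$segment <- seg
        window_stats <- rbind(window_stats, ws)
        sel <- select_window(ws)
        windows[[seg]] <- c(sel$start, sel$end)
      }
    }

    stage <- "cn"
    log_stage(cfg, "stage: copy number")
    cn_rows <- lapply(seq_len(n), function(i) {
      b <- compute_brd(split_bg(bg[[i]], exons$region_id),
                       split_bg(bg[[i]], introns$region_id),
                       cfg$trim_fraction)
      do.call(rbind, lapply(names(windows), function(seg)
        estimate_cn(rdna[[i]], windows[[seg]], b$brd,
                    sample_id = sheet$sample_id[i], segment = seg)))
    })
    cn_tab <- do.call(rbind, cn_rows)

    stage <- "methylation"
    log_stage(cfg, "stage: methylation bins")
    bins_tab <- do.call(rbind, lapply(seq_len(n), function(i) {
      b <- bin_methylation(cov[[i]], ref$total_length, cfg$bin_len,
                           cfg$min_reads, cfg$min_cpgs)
      cbind(sample_id = sheet$sample_id[i], b)
    }))
    glob_tab <- data.frame(
      sample_id = sheet$sample_id,
      global_meth = vapply(cov, global_methylation, numeric(1)))

    stage <- "association"
    log_stage(cfg, "stage: association")
    covars <- sheet[, c("sample_id", "age", "sex", "group")]
    assoc_tab <- do.call(rbind, lapply(names(windows), function(seg) {
      a <- per_bin_regression(cn_tab[cn_tab$segment == seg, ],
                              bins_tab, covars)
      cbind(segment = seg, a)
    }))

    stage <- "group_test"
    log_stage(cfg, "stage: group comparison")
    group_tab <- do.call(rbind, lapply(names(windows), function(seg)
      group_comparison(cn_tab[cn_tab$segment == seg, ], covars,
                       segment = seg)))

    stab_tab <- NULL
    if (!is.null(cfg$stability_fractions)) {
      stage <- "stability"
      log_stage(cfg, "stage: stability")
      stab_tab <- do.call(rbind, lapply(seq_len(n), function(i)
        stability_profile(rdna[[i]],
                          split_bg(bg[[i]], exons$region_id),
                          split_bg(bg[[i]], introns$region_id),
                          windows, cov = cov[[i]],
                          fractions = cfg$stability_fractions,
                          seed = derive_seed(cfg$seed, i),
                          upper_fraction = cfg$trim_fraction,
                          sample_id = sheet$sample_id[i])))
    }

    stage <- "write"
    log_stage(cfg, "stage: write results")
    paths <- list()
    wtab <- function(df, name) {
      p <- file.path(cfg$out_dir, name)
      write_result_tsv(df, p, seed = cfg$seed)
      p
    }
    if (!is.null(window_stats)) paths$windows <- wtab(window_stats,
                                                      "windows.tsv")
    paths$cn <- wtab(cn_tab, "cn.tsv")
    paths$bins <- wtab(bins_tab, "bins.tsv")
    paths$global_meth <- wtab(glob_tab, "global_meth.tsv")
    paths$association <- wtab(assoc_tab, "association.tsv")
    paths$group_test <- wtab(group_tab, "group_test.tsv")
    if (!is.null(stab_tab)) paths$stability <- wtab(stab_tab,
                                                    "stability.tsv")
    manifest <- list(
      tool = "rdnacopy",
      version = as.character(utils::packageVersion("rdnacopy")),
      seed = cfg$seed,
      inputs = list(sample_sheet = cfg$sample_sheet,
                    regions_bed = cfg$regions_bed),
      parameters = list(window_len = cfg$window_len, step = cfg$step,
                        trim_fraction = cfg$trim_fraction,
                        bin_len = cfg$bin_len, min_reads = cfg$min_reads,
                        min_cpgs = cfg$min_cpgs,
                        fixed_windows = !identical(cfg$fixed_windows, FALSE)),
      windows = windows,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    paths$manifest <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
    list(windows = windows, window_stats = window_stats, cn = cn_tab,
         bins = bins_tab, global_meth = glob_tab, association = assoc_tab,
         group_test = group_tab, stability = stab_tab, paths = paths)
  }, error = function(e) {
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  unlink(marker)
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `all` (run the full
#' pipeline), `cn`, `meth`, `associate`, `stability` (run the pipeline but
#' keep only the corresponding outputs). Flags mirror [run_config()]:
#' `--sample-sheet`, `--regions-bed`, `--out`, `--reference-config`,
#' `--seed`, `--fixed-windows`, `--trim-fraction`, `--bin-length`,
#' `--min-reads`, `--min-cpgs`, `--window-length`, `--step`,
#' `--n-samples` (simulate), `--verbose`. Logs go to stderr; results only to
#' files.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
rdnacopy_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: rdnacopy <simulate|all|cn|meth|associate|stability> ",
    "--out DIR [--sample-sheet CSV --regions-bed BED] [options]")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- list(seed = 1L, `trim-fraction` = 0.05, `bin-length` = 200L,
               `min-reads` = 10L, `min-cpgs` = 4L, `window-length` = 150L,
               step = 1L, `n-samples` = 30L, `fixed-windows` = FALSE,
               verbose = FALSE)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (key %in% c("fixed-windows", "verbose")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i + 1L > length(args)) stop2("missing value for --", key)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  if (is.null(opts$out)) stop2("--out is required\n", usage)
  num <- function(x) as.numeric(x)
  if (cmd == "simulate") {
    cfg <- sim_config(n_samples = as.integer(opts$`n-samples`),
                      seed = as.integer(opts$seed))
    simulate_cohort(cfg, out_dir = opts$out)
    message("wrote synthetic cohort to ", opts$out)
    return(invisible(0L))
  }
  if (!cmd %in% c("all", "cn", "meth", "associate", "stability")) {
    stop2("unknown subcommand: ", cmd, "\n", usage)
  }
  rc <- run_config(
    sample_sheet = opts$`sample-sheet` %||%
      stop2("--sample-sheet is required"),
    regions_bed = opts$`regions-bed` %||% stop2("--regions-bed is required"),
    out_dir = opts$out,
    reference = if (!is.null(opts$`reference-config`))
      opts$`reference-config` else rdna_reference(),
    fixed_windows = isTRUE(opts$`fixed-windows`),
    window_len = as.integer(num(opts$`window-length`)),
    step = as.integer(num(opts$step)),
    trim_fraction = num(opts$`trim-fraction`),
    bin_len = as.integer(num(opts$`bin-length`)),
    min_reads = as.integer(num(opts$`min-reads`)),
    min_cpgs = as.integer(num(opts$`min-cpgs`)),
    stability_fractions = if (cmd %in% c("stability", "all"))
      seq(1, 0.1, by = -0.1) else NULL,
    seed = as.integer(opts$seed),
    verbose = isTRUE(opts$verbose))
  run_pipeline(rc)
  message("results written to ", opts$out)
  invisible(0L)
}
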