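# Readers and writers for the on-disk dialects the pipeline consumes:
# samtools-depth TSV, Bismark-style .cov, BED, and the CSV sample sheet.
# Coordinate conventions: depth tables and .cov are 1-based; BED is 0-based
# half-open on disk and converted here, never elsewhere.

#' Construct a per-base depth track
#'
#' @param ref_name reference sequence name.
#' @param start 1-based position of the first element of `depths`.
#' @param depths non-negative per-base depth, contiguous from `start`.
#' @return object of class `depth_track`.
#' @export
depth_track <- function(ref_name, start, depths) {
  if (length(depths) < 1L) stop2("`depths` must have length >= 1")
  if (anyNA(depths) || any(depths < 0)) {
    stop2("depths must be non-negative and non-missing")
  }
  structure(list(ref_name = as.character(ref_name),
                 start = as.integer(start),
                 depths = as.numeric(depths)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track %s:%d-%d  mean %.2f\n", x$ref_name, x$start,
              x$start + length(x$depths) - 1L, mean(x$depths)))
  invisible(x)
}

track_positions <- function(track) {
  seq.int(track$start, length.out = length(track$depths))
}

# slice of the track over a 1-based closed interval; errors if not covered
track_slice <- function(track, interval) {
  lo <- interval[1] - track$start + 1L
  hi <- interval[2] - track$start + 1L
  if (lo < 1L || hi > length(track$depths)) {
    stop2("track ", track$ref_name, " does not cover [", interval[1], ", ",
          interval[2], "]")
  }
  track$depths[lo:hi]
}

#' Read a samtools-depth style table
#'
#' Three tab-separated columns: reference name, 1-based position, integer
#' depth. Positions must be sorted within each reference. Many producers omit
#' zero-depth rows; with `fill_missing_with_zero = TRUE` (the default) gaps
#' between the first and last observed position of each reference are filled
#' with depth 0, which matters because copy-number denominators must count
#' zero-coverage bases.
#'
#' @param path file path.
#' @param fill_missing_with_zero fill positional gaps with zero depth.
#' @return named list of [depth_track()], one per reference name.
#' @export
read_depth_table <- function(path, fill_missing_with_zero = TRUE) {
  if (!file.exists(path)) stop2("depth table not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) != 3L) stop2(path, ": expected 3 tab-separated columns")
  pos <- suppressWarnings(as.integer(raw[[2]]))
  dep <- suppressWarnings(as.integer(raw[[3]]))
  bad <- which(is.na(pos) | is.na(dep) | dep < 0)
  if (length(bad)) {
    stop2(path, " line ", bad[1], ": non-integer position or depth")
  }
  out <- list()
  for (nm in unique(raw[[1]])) {
    sel <- raw[[1]] == nm
    p <- pos[sel]
    d <- dep[sel]
    if (is.unsorted(p, strictly = TRUE)) {
      stop2(path, ": positions for '", nm, "' are not strictly increasing")
    }
    if (fill_missing_with_zero && length(p) > 1L) {
      full <- numeric(p[length(p)] - p[1] + 1L)
      full[p - p[1] + 1L] <- d
      out[[nm]] <- depth_track(nm, p[1], full)
    } else {
      if (!fill_missing_with_zero && length(p) > 1L &&
          any(diff(p) != 1L)) {
        stop2(path, ": '", nm, "' has positional gaps and gap-fill is off")
      }
      out[[nm]] <- depth_track(nm, p[1], d)
    }
  }
  out
}

#' Write depth tracks as a samtools-depth style table
#'
#' Zero-depth positions are written explicitly so the file round-trips
#' losslessly regardless of the gap-fill setting.
#'
#' @param tracks a `depth_track` or list of them.
#' @param path output path.
#' @export
write_depth_table <- function(tracks, path) {
  if (inherits(tracks, "depth_track")) tracks <- list(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    d <- tr$depths
    if (any(d != floor(d))) {
      stop2("non-integer depths in track '", tr$ref_name,
            "' cannot be serialized")
    }
    writeLines(paste(tr$ref_name, track_positions(tr), format(d, scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a Bismark-style CpG coverage file
#'
#' Six tab-separated columns: reference name, start, end, methylation
#' percentage, methylated count, unmethylated count. The percentage column is
#' treated as derived: it is recomputed from the counts, which are
#' authoritative. Records must be position-sorted.
#'
#' @param path file path.
#' @return data.frame with columns `position`, `count_methylated`,
#'   `count_unmethylated`, `coverage`, `meth_pct` (NA when coverage is 0).
#' @export
read_bismark_cov <- function(path) {
  if (!file.exists(path)) stop2("coverage file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) != 6L) stop2(path, ": expected 6 tab-separated columns")
  pos <- suppressWarnings(as.integer(raw[[2]]))
  m <- suppressWarnings(as.integer(raw[[5]]))
  u <- suppressWarnings(as.integer(raw[[6]]))
  bad <- which(is.na(pos) | is.na(m) | is.na(u) | m < 0 | u < 0)
  if (length(bad)) {
    stop2(path, " line ", bad[1], ": malformed coverage record")
  }
  if (is.unsorted(pos, strictly = TRUE)) {
    stop2(path, ": records are not sorted by position")
  }
  cpg_records(pos, m, u)
}

#' Construct a table of per-CpG methylation records
#'
#' @param position 1-based positions.
#' @param count_methylated,count_unmethylated read counts.
#' @return data.frame sorted by position with derived `coverage` and
#'   `meth_pct` (percentage, NA where coverage is 0).
#' @export
cpg_records <- function(position, count_methylated, count_unmethylated) {
  if (any(count_methylated < 0) || any(count_unmethylated < 0)) {
    stop2("CpG counts must be non-negative")
  }
  cov <- count_methylated + count_unmethylated
  df <- data.frame(position = as.integer(position),
                   count_methylated = as.integer(count_methylated),
                   count_unmethylated = as.integer(count_unmethylated),
                   coverage = as.integer(cov),
                   meth_pct = ifelse(cov > 0, 100 * count_methylated / cov,
                                     NA_real_))
  df[order(df$position), , drop = FALSE]
}

#' Write CpG records in Bismark coverage format
#' @param records data.frame from [cpg_records()] or [read_bismark_cov()].
#' @param path output path.
#' @param ref_name reference name for column 1.
#' @export
write_bismark_cov <- function(records, path, ref_name = "rDNA") {
  pct <- ifelse(records$coverage > 0,
                100 * records$count_methylated / records$coverage, 0)
  writeLines(paste(ref_name, records$position, records$position,
                   format(pct, scientific = FALSE, trim = TRUE),
                   records$count_methylated, records$count_unmethylated,
                   sep = "\t"),
             path)
  invisible(path)
}

#' Read a BED file of background regions
#'
#' Standard BED coordinates (0-based half-open) are converted to the package's
#' 1-based closed convention on read. Columns beyond the first four, when
#' present, are interpreted as `gene_id`, `kind`, `has_ambiguous_hit`
#' (0/1) to carry the candidate-region annotation.
#'
#' @param path BED path.
#' @return candidate-region data.frame (see [candidate_regions()]); regions
#'   without annotation columns get `kind = "exon"` and no ambiguous hit.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop2("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) < 4L) stop2(path, ": expected at least 4 BED columns")
  start0 <- as.integer(raw[[2]])
  end0 <- as.integer(raw[[3]])
  if (anyNA(start0) || anyNA(end0) || any(end0 <= start0)) {
    stop2(path, ": invalid BED coordinates")
  }
  candidate_regions(
    region_id = raw[[4]],
    gene_id = if (ncol(raw) >= 5L) raw[[5]] else raw[[4]],
    kind = if (ncol(raw) >= 6L) raw[[6]] else "exon",
    chrom = raw[[1]],
    start = start0 + 1L, end = end0,
    has_ambiguous_hit = if (ncol(raw) >= 7L) raw[[7]] == "1" else FALSE)
}

#' Write candidate/filtered regions as BED
#' @param regions candidate-region data.frame (1-based closed).
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(paste(regions$chrom, regions$start - 1L, regions$end,
                   regions$region_id, regions$gene_id, regions$kind,
                   as.integer(regions$has_ambiguous_hit), sep = "\t"),
             path)
  invisible(path)
}

#' Read the cohort sample sheet
#'
#' CSV with header; required columns: `sample_id`, `age`, `sex`, `group`,
#' `chemistry`. Optional path columns (`rdna_depth`, `background_depth`,
#' `cov_file`) are passed through. `sex` is encoded deterministically to 0/1
#' (F/female -> 0, M/male -> 1); `group` to 0/1 (control -> 0, case/disease
#' -> 1); numeric 0/1 values pass through. Missing covariates are allowed at
#' load time and rejected only when a sample enters a regression.
#'
#' @param path CSV path.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop2("sample sheet not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "age", "sex", "group", "chemistry")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop2("sample sheet lacks required column(s): ",
          paste(miss, collapse = ", "))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop2("duplicate sample_id in sample sheet: ",
          paste(unique(dup), collapse = ", "))
  }
  df$sex <- encode_binary(df$sex, zero = c("f", "female", "0"),
                          one = c("m", "male", "1"), what = "sex")
  df$group <- encode_binary(df$group, zero = c("control", "ctrl", "0"),
                            one = c("case", "disease", "1"), what = "group")
  df
}

encode_binary <- function(x, zero, one, what) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, NA))) stop2("`", what, "` must be coded 0/1")
    return(as.integer(x))
  }
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[lx %in% zero] <- 0L
  out[lx %in% one] <- 1L
  bad <- !is.na(x) & nzchar(lx) & is.na(out)
  if (any(bad)) {
    stop2("unrecognized `", what, "` value(s): ",
          paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Write a sample sheet
#' @param samples data.frame with the sample-sheet columns.
#' @param path output CSV path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# result tables carry a schema comment so downstream readers can check it
write_result_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rdnacopy schema 1",
                    if (!is.null(seed)) paste0(" seed=", seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by the pipeline
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
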