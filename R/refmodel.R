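#' Coordinate model of the modified 45S rDNA reference
#'
#' The quantification reference is a modified 45S repeat unit built by
#' concatenating the last 1,979 bp of the canonical repeat with its first
#' 14,000 bp, so that the promoter, 5' ETS, 18S, 5.8S, 28S and 3' ETS are all
#' contained in a single 15,979-bp sequence. All coordinates handled by this
#' package are 1-based closed intervals in the frame of this modified
#' reference.
#'
#' Defaults encode the canonical rRNA annotation shifted by +1,979:
#' 18S at 5636--7506 and 28S at 9914--14948. The first 900 bp of 18S share
#' homology with chr21 and contig GL000220, and are excluded from window
#' scanning. The default fixed quantification windows are 18S 6986--7135 and
#' 28S 11564--11713 (both 150 bp).
#'
#' @param segments named list of length-2 integer vectors (1-based closed
#'   spans); must contain at least `"18S"` and `"28S"`.
#' @param total_length total reference length in bp.
#' @param exclusion_zone 1-based closed interval to exclude from window
#'   scanning; defaults to the first 900 bp of the 18S segment.
#' @param windows named list of default 150-bp quantification windows, one per
#'   segment.
#' @return an object of class `rdna_reference`.
#' @examples
#' ref <- rdna_reference()
#' ref$segments$`18S`
#' @export
rdna_reference <- function(segments = NULL,
                           total_length = 15979L,
                           exclusion_zone = NULL,
                           windows = NULL) {
  if (is.null(segments)) {
    segments <- list(`18S` = c(5636L, 7506L), `28S` = c(9914L, 14948L))
  }
  if (is.null(windows)) {
    windows <- list(`18S` = c(6986L, 7135L), `28S` = c(11564L, 11713L))
  }
  if (!is.numeric(total_length) || length(total_length) != 1L ||
      total_length < 1) {
    stop2("`total_length` must be a single positive number")
  }
  if (!all(c("18S", "28S") %in% names(segments))) {
    stop2("`segments` must contain at least \"18S\" and \"28S\"")
  }
  for (nm in names(segments)) {
    seg <- segments[[nm]]
    if (!interval_ok(seg)) {
      stop2("segment '", nm, "' is not a valid 1-based closed interval")
    }
    if (!interval_within(seg, c(1, total_length))) {
      stop2("segment '", nm, "' [", seg[1], ", ", seg[2],
            "] lies outside [1, ", total_length, "]")
    }
  }
  if (intervals_overlap(segments[["18S"]], segments[["28S"]])) {
    stop2("segments '18S' and '28S' must be disjoint")
  }
  if (is.null(exclusion_zone)) {
    s18 <- segments[["18S"]]
    exclusion_zone <- c(s18[1], min(s18[1] + 899L, s18[2]))
  }
  if (!interval_ok(exclusion_zone) ||
      !interval_within(exclusion_zone, segments[["18S"]])) {
    stop2("`exclusion_zone` must be a valid interval within the 18S segment")
  }
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (!interval_ok(w) || interval_len(w) != 150) {
      stop2("default window for '", nm, "' must be a 150-bp interval")
    }
    if (is.null(segments[[nm]]) || !interval_within(w, segments[[nm]])) {
      stop2("default window for '", nm, "' lies outside its segment")
    }
  }
  structure(
    list(total_length = as.integer(total_length),
         segments = lapply(segments, as.integer),
         exclusion_zone = as.integer(exclusion_zone),
         default_windows = lapply(windows, as.integer)),
    class = "rdna_reference")
}

#' @export
print.rdna_reference <- function(x, ...) {
  cat("Modified 45S rDNA reference (", x$total_length, " bp)\n", sep = "")
  for (nm in names(x$segments)) {
    s <- x$segments[[nm]]
    w <- x$default_windows[[nm]]
    cat(sprintf("  %-4s %5d-%5d  window %d-%d\n", nm, s[1], s[2],
                if (is.null(w)) NA else w[1], if (is.null(w)) NA else w[2]))
  }
  cat(sprintf("  scan exclusion zone %d-%d\n",
              x$exclusion_zone[1], x$exclusion_zone[2]))
  invisible(x)
}

#' Build a table of candidate single-copy background regions
#'
#' @param region_id,gene_id character identifiers.
#' @param kind `"exon"` or `"intron"`.
#' @param chrom chromosome name.
#' @param start,end 1-based closed coordinates.
#' @param has_ambiguous_hit logical; whether the region has a significant
#'   cross-hit (E < 1e-6) to another region of the same kind. This annotation
#'   is an input: the homology search itself is upstream of this package.
#' @return a `data.frame` with one row per candidate and a derived `length`
#'   column.
#' @export
candidate_regions <- function(region_id, gene_id, kind, chrom, start, end,
                              has_ambiguous_hit = FALSE) {
  kind <- as.character(kind)
  if (!all(kind %in% c("exon", "intron"))) {
    stop2("`kind` values must be \"exon\" or \"intron\"")
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(end < start) || any(start < 1)) {
    stop2("all regions need 1 <= start <= end")
  }
  data.frame(region_id = as.character(region_id),
             gene_id = as.character(gene_id),
             kind = kind, chrom = as.character(chrom),
             start = start, end = end,
             length = end - start + 1L,
             has_ambiguous_hit = rep_len(as.logical(has_ambiguous_hit),
                                         length(region_id)),
             stringsAsFactors = FALSE)
}

#' Filter candidate regions down to usable single-copy background regions
#'
#' Applies, in order: removal of regions with an ambiguous cross-hit
#' (E < 1e-6 to another region of the same kind), retention of only the
#' largest region per gene (ties broken by smaller start coordinate), and a
#' length filter — exons must be > 300 bp; introns must be > 300 bp and
#' <= 10,000 bp.
#'
#' @param candidates data.frame as built by [candidate_regions()].
#' @param kind `"exon"` or `"intron"`; all candidates must be of this kind.
#' @return the surviving subset (possibly empty, with a warning), with a
#'   `kind` attribute.
#' @export
filter_single_copy_regions <- function(candidates, kind = c("exon", "intron")) {
  kind <- match.arg(kind)
  req <- c("region_id", "gene_id", "kind", "start", "end", "length",
           "has_ambiguous_hit")
  if (!all(req %in% names(candidates))) {
    stop2("`candidates` lacks required columns: ",
          paste(setdiff(req, names(candidates)), collapse = ", "))
  }
  if (nrow(candidates) && !all(candidates$kind == kind)) {
    stop2("all candidates must have kind \"", kind, "\"")
  }
  x <- candidates[!candidates$has_ambiguous_hit, , drop = FALSE]
  if (nrow(x)) {
    # largest per gene; tie -> leftmost start
    ord <- order(x$gene_id, -x$length, x$start)
    x <- x[ord, , drop = FALSE]
    x <- x[!duplicated(x$gene_id), , drop = FALSE]
  }
  keep <- x$length > 300
  if (kind == "intron") keep <- keep & x$length <= 10000
  x <- x[keep, , drop = FALSE]
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  if (!nrow(x)) {
    warning("no ", kind, " candidates survive filtering", call. = FALSE)
  }
  attr(x, "kind") <- kind
  x
}
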