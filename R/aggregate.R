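# Metaprofiles and windowed accessibility scores around feature centers.
#
# Accessibility around a feature set (DHS peaks, TF binding sites,
# nucleosome positions, ...) is summarized by binning RPM in fixed-width
# windows at fixed offsets from the feature centers, dividing by the
# number of features. The same machinery applied to a site-density table
# (one pseudo-read per site, density_counts()) gives the baseline that
# controls for the non-uniform genomic distribution of recognition sites.

#' Construct a feature set from intervals
#'
#' @param chrom,start,end Interval coordinates (0-based, half-open).
#' @param name Optional feature names.
#' @param strand Optional strand (`+`/`-`), used only when a profile is
#'   computed with `flip_minus = TRUE`.
#' @return data.frame with a `center` column, `floor((start + end) / 2)`.
#' @export
feature_set <- function(chrom, start, end, name = NULL, strand = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("feature intervals need start < end", call. = FALSE)
  fs <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   center = as.integer(floor((start + end) / 2)),
                   stringsAsFactors = FALSE)
  fs$name <- if (is.null(name)) paste0("feature_", seq_len(nrow(fs))) else as.character(name)
  if (!is.null(strand)) fs$strand <- as.character(strand)
  fs
}

#' Read a feature set from a BED file
#'
#' @param path BED path (3+ columns; column 4 names, column 6 strand used
#'   when present).
#' @return A [feature_set()].
#' @export
read_features <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  feature_set(bed[[1]], bed[[2]], bed[[3]],
              name = if (ncol(bed) >= 4L) bed[[4]],
              strand = if (ncol(bed) >= 6L) bed[[6]])
}

# Positioned per-site signal: site RPM placed at the plus-strand cut
# coordinate. Accepts a cut_count_table (+ index) or a ready-made
# data.frame(chrom, pos, value) coverage-style track.
positioned_signal <- function(x, index = NULL, use_raw = FALSE) {
  if (inherits(x, "cut_count_table")) {
    if (is.null(index)) stop("an rs_index is required to place cut counts",
                             call. = FALSE)
    if (is.null(x$rpm) && !use_raw) x <- normalize_rpm(x)
    m <- match(x$site_id, index$site_id)
    if (anyNA(m)) stop("count table site_ids absent from index", call. = FALSE)
    data.table::data.table(chrom = index$chrom[m], pos = index$cut_plus[m],
                           value = if (use_raw) as.numeric(x$raw) else x$rpm)
  } else {
    if (!all(c("chrom", "pos", "value") %in% names(x)))
      stop("a positioned track needs columns chrom, pos, value", call. = FALSE)
    data.table::as.data.table(x[, c("chrom", "pos", "value")])
  }
}

#' Binned average accessibility around feature centers
#'
#' For each offset bin `[o, o + bin)` with `o` in `-flank, -flank + bin,
#' ..., flank - bin`, the profile value is the summed signal (RPM for a
#' normalized cut table; one pseudo-read per site for a density table)
#' falling in that bin across all features, divided by the number of
#' features. Cut counts are placed at their site's plus-strand cut
#' coordinate; a position at offset `o` from a center contributes to bin
#' `floor((o + flank) / bin)` (left-closed, right-open bins). Overlapping
#' features each receive full contributions.
#'
#' @param x A [cut_count_table()] (give `index` too) or a
#'   data.frame(chrom, pos, value) positioned track.
#' @param features A [feature_set()].
#' @param flank Half-width of the profiled region (bp), default 1000.
#' @param bin Bin width (bp), default 50; must divide `flank`.
#' @param index `rs_index` used to place cut counts.
#' @param flip_minus If `TRUE` and features carry strand, offsets of
#'   minus-strand features are negated (TSS-style orientation).
#' @return A `meta_profile`: data.frame with `offset` (bin start relative
#'   to center) and `value`, with `n_features`, `bin` and `flank`
#'   attributes. Features overhanging chromosome ends (when the index
#'   carries sequence lengths) are counted in the `n_overhanging`
#'   attribute; their bins are computed from the available data.
#' @export
metaprofile <- function(x, features, flank = 1000L, bin = 50L, index = NULL,
                        flip_minus = FALSE) {
  if (!nrow(features)) stop("empty feature set", call. = FALSE)
  flank <- as.integer(flank); bin <- as.integer(bin)
  if (bin <= 0L || flank <= 0L || flank %% bin != 0L)
    stop("bin must be positive and divide flank", call. = FALSE)
  sig <- positioned_signal(x, index)
  nbins <- 2L * flank %/% bin
  offsets <- seq(-flank, flank - bin, by = bin)

  fdt <- data.table::data.table(chrom = features$chrom,
                                center = as.integer(features$center),
                                fid = seq_len(nrow(features)))
  fdt[, `:=`(wstart = center - flank, wend = center + flank)]
  sig2 <- sig[value != 0]
  sig2[, `:=`(p1 = pos, p2 = pos)]
  hits <- sig2[fdt, on = .(chrom, p1 >= wstart, p2 < wend), nomatch = NULL,
               .(fid, off = x.pos - center, value = x.value)]
  flipped <- FALSE
  if (flip_minus && !is.null(features$strand)) {
    neg <- features$strand[hits$fid] == "-"
    # a base at offset o maps to -o-1 under reflection of half-open coords
    hits$off[neg] <- -hits$off[neg] - 1L
    flipped <- TRUE
  }
  prof <- numeric(nbins)
  if (nrow(hits)) {
    b <- (hits$off + flank) %/% bin + 1L
    agg <- rowsum(hits$value, b)
    prof[as.integer(rownames(agg))] <- agg[, 1L]
  }
  n_over <- 0L
  sl <- attr(index, "seqlengths")
  if (!is.null(sl)) {
    lim <- sl[features$chrom]
    n_over <- sum(!is.na(lim) &
                    (features$center - flank < 0L | features$center + flank > lim))
  }
  structure(data.frame(offset = offsets, value = prof / nrow(features)),
            n_features = nrow(features), bin = bin, flank = flank,
            n_overhanging = n_over, flipped = flipped,
            class = c("meta_profile", "data.frame"))
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile: %d bins of %d bp over +/-%d bp, %d features%s\n",
              nrow(x), attr(x, "bin"), attr(x, "flank"), attr(x, "n_features"),
              if (attr(x, "n_overhanging") > 0L)
                sprintf(" (%d overhang chromosome ends)", attr(x, "n_overhanging"))
              else ""))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Windowed per-feature accessibility scores
#'
#' For each feature, the summed RPM within `center +/- halfwidth`
#' (inclusive bounds on base coordinates), in input feature order. These
#' are the per-feature scalars compared between replicate libraries or
#' conditions with [featureset_comparison()].
#'
#' @inheritParams metaprofile
#' @param halfwidth Window half-width in bp, default 200.
#' @return data.frame `(name, chrom, center, score)` in input order.
#' @export
window_score <- function(x, features, halfwidth = 200L, index = NULL) {
  if (!nrow(features)) stop("empty feature set", call. = FALSE)
  halfwidth <- as.integer(halfwidth)
  sig <- positioned_signal(x, index)
  fdt <- data.table::data.table(chrom = features$chrom,
                                center = as.integer(features$center),
                                fid = seq_len(nrow(features)))
  fdt[, `:=`(wstart = center - halfwidth, wend = center + halfwidth)]
  sig2 <- sig[value != 0]
  sig2[, `:=`(p1 = pos, p2 = pos)]
  hits <- sig2[fdt, on = .(chrom, p1 >= wstart, p2 <= wend), nomatch = NULL,
               .(fid, value = x.value)]
  score <- numeric(nrow(features))
  if (nrow(hits)) {
    agg <- rowsum(hits$value, hits$fid)
    score[as.integer(rownames(agg))] <- agg[, 1L]
  }
  data.frame(name = features$name, chrom = features$chrom,
             center = features$center, score = score,
             stringsAsFactors = FALSE)
}

#' Write a metaprofile as TSV
#' @param profile A `meta_profile`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(data.frame(bin_start_offset = profile$offset,
                                value = profile$value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
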