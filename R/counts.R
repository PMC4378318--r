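# Per-site cut count tables and RPM normalization.

#' Per-site cut counts for one library
#'
#' @param site_id Integer site identifiers (the table's site universe).
#' @param raw Non-negative integer read counts, one per site.
#' @param library Library name.
#' @param rpm Optional precomputed RPM values (normally added by
#'   [normalize_rpm()]).
#' @return A `cut_count_table`: data.frame with columns `site_id`, `raw`
#'   (and `rpm` once normalized), with the library name and total
#'   assigned-read count as attributes.
#' @export
cut_count_table <- function(site_id, raw, library = "library", rpm = NULL) {
  site_id <- as.integer(site_id)
  if (anyDuplicated(site_id)) stop("duplicate site_id in count table", call. = FALSE)
  raw <- as.integer(raw)
  if (length(raw) != length(site_id) || anyNA(raw) || any(raw < 0L))
    stop("raw counts must be non-negative integers, one per site", call. = FALSE)
  tab <- data.frame(site_id = site_id, raw = raw)
  if (!is.null(rpm)) tab$rpm <- as.numeric(rpm)
  structure(tab, library = library, total = sum(as.numeric(raw)),
            class = c("cut_count_table", "data.frame"))
}

#' @export
print.cut_count_table <- function(x, ...) {
  cat(sprintf("cut_count_table '%s': %d sites, %s assigned reads%s\n",
              attr(x, "library"), nrow(x),
              format(attr(x, "total"), big.mark = ","),
              if (!is.null(x$rpm)) " (RPM-normalized)" else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Normalize cut counts to reads per million
#'
#' `rpm_i = raw_i * 1e6 / total`, where `total` is the library's assigned
#' read count; raw counts are preserved and `sum(rpm) == 1e6` up to
#' floating-point rounding.
#'
#' @param table A [cut_count_table()].
#' @return The table with an `rpm` column.
#' @export
normalize_rpm <- function(table) {
  stopifnot(inherits(table, "cut_count_table"))
  total <- attr(table, "total")
  if (total <= 0) stop("empty library: cannot normalize a table with zero reads",
                       call. = FALSE)
  table$rpm <- table$raw * 1e6 / total
  table
}

#' Cut frequency summarized by concrete motif variant
#'
#' Aggregates a count table over the concrete recognition-sequence
#' variants of the index (e.g. the four expansions of `GGNCC`), exposing
#' cleavage-efficiency differences between variants such as the elevated
#' GGTCC efficiency seen with Sau96I. Variants of the enzyme motifs with
#' no genomic occurrence are reported with `n_sites = 0` and flagged.
#'
#' @param table A [cut_count_table()] (normalized or not; RPM is computed
#'   if missing).
#' @param index The `rs_index` the table was counted against.
#' @return data.frame with one row per (enzyme, variant): `n_sites`,
#'   `reads` (assigned-read sum), `mean_rpm_per_site`, and `absent`
#'   (`TRUE` for motif expansions unseen in the genome).
#' @export
variant_cut_frequency <- function(table, index) {
  stopifnot(inherits(table, "cut_count_table"), inherits(index, "rs_index"))
  if (is.null(table$rpm)) table <- normalize_rpm(table)
  m <- match(table$site_id, index$site_id)
  if (anyNA(m)) stop("count table contains site_ids absent from the index",
                     call. = FALSE)
  dt <- data.table::data.table(enzyme = index$enzyme[m],
                               variant = index$variant[m],
                               raw = table$raw, rpm = table$rpm)
  obs <- dt[, .(n_sites = .N, reads = sum(raw),
                mean_rpm_per_site = mean(rpm)), by = .(enzyme, variant)]
  full <- data.table::rbindlist(lapply(attr(index, "enzymes"), function(e)
    data.table::data.table(enzyme = e$name, variant = iupac_expand(e$motif))))
  out <- merge(full, obs, by = c("enzyme", "variant"), all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L, reads = 0L, mean_rpm_per_site = NA_real_)]
  out[, absent := n_sites == 0L]
  data.table::setorder(out, enzyme, variant)
  as.data.frame(out)
}

#' Write a per-site count table as TSV
#'
#' Columns: `site_id, chrom, motif_start, enzyme, variant, raw, rpm`.
#'
#' @param table A [cut_count_table()].
#' @param index Matching `rs_index`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(table, index, path) {
  if (is.null(table$rpm)) table <- normalize_rpm(table)
  m <- match(table$site_id, index$site_id)
  out <- data.frame(site_id = table$site_id, chrom = index$chrom[m],
                    motif_start = index$motif_start[m],
                    enzyme = index$enzyme[m], variant = index$variant[m],
                    raw = table$raw, rpm = table$rpm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_counts()]
#' @param path TSV path.
#' @param library Library name to record.
#' @return A [cut_count_table()].
#' @export
read_counts <- function(path, library = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  cut_count_table(tab$site_id, tab$raw, library = library, rpm = tab$rpm)
}

#' Write RPM values as a bedGraph track
#'
#' Each site contributes one record at its plus-strand cut coordinate, for
#' genome-browser display.
#'
#' @param table A [cut_count_table()].
#' @param index Matching `rs_index`.
#' @param path Output bedGraph path.
#' @param name Track name.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(table, index, path, name = attr(table, "library")) {
  if (is.null(table$rpm)) table <- normalize_rpm(table)
  m <- match(table$site_id, index$site_id)
  keep <- table$raw > 0L
  df <- data.frame(chrom = index$chrom[m], start = index$cut_plus[m],
                   end = index$cut_plus[m] + 1L, value = table$rpm)[keep, ]
  df <- df[order(df$chrom, df$start), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
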