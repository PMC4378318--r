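# Assignment of aligned read 5' ends to unique restriction sites.

#' Read aligned read ends from SAM/BAM or BED
#'
#' For SAM/BAM, the informative 5' end is the alignment start for plus
#' strand reads and the alignment end for minus strand reads (recorded,
#' like everywhere in this package, as the 0-based exclusive end
#' coordinate). For BED, `start` is taken for `+` records and `end` for
#' `-` records, so single-base BED intervals of precomputed 5' ends work
#' directly.
#'
#' @param path Path to a `.sam`, `.bam` or `.bed` file.
#' @param sample Optional sample label attached to every read.
#' @return data.frame with columns `chrom`, `strand`, `five_prime` (and
#'   `sample` if given) — the input expected by [assign_reads()].
#' @export
read_alignments <- function(path, sample = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("sam", "bam")) {
    bam <- if (ext == "sam") {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    } else path
    aln <- GenomicAlignments::readGAlignments(bam)
    plus <- as.character(BiocGenerics::strand(aln)) == "+"
    reads <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(aln)),
      strand = as.character(BiocGenerics::strand(aln)),
      five_prime = ifelse(plus,
                          BiocGenerics::start(aln) - 1L,   # to 0-based
                          BiocGenerics::end(aln)),         # 0-based exclusive
      stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("read-end BED must have 6 columns (strand needed)",
                             call. = FALSE)
    reads <- data.frame(chrom = bed[[1]], strand = bed[[6]],
                        five_prime = ifelse(bed[[6]] == "+", bed[[2]], bed[[3]]),
                        stringsAsFactors = FALSE)
  } else stop("unsupported alignment format: .", ext, call. = FALSE)
  if (!is.null(sample)) reads$sample <- sample
  reads
}

#' Assign read 5' ends to unique restriction sites
#'
#' Each read is assigned to the site whose strand-appropriate expected cut
#' end ([expected_end()]) is nearest to the read's 5' end and within
#' `tolerance` bases; every read contributes to at most one site. A read
#' exactly equidistant between two sites goes to the one with the lower
#' `motif_start` (leftmost), a deterministic documented tie-break that
#' also resolves dual-enzyme collisions. Reads on chromosomes absent from
#' the index, or farther than `tolerance` from any site, are tallied as
#' unassigned with a reason.
#'
#' @param reads data.frame with columns `chrom`, `strand` (`+`/`-`) and
#'   `five_prime` (0-based; exclusive end coordinate for minus strand), in
#'   any order. See [read_alignments()].
#' @param index An `rs_index` from [build_index()].
#' @param tolerance Maximum distance (bases) between a read 5' end and a
#'   site's expected cut end; default 2 absorbs end-repair raggedness.
#' @param library Library name for the output table.
#' @param dedup If `TRUE`, identical `(chrom, strand, five_prime)` tuples
#'   are collapsed to one read before assignment.
#' @return List with `counts` (a [cut_count_table()] over all index
#'   sites), `log` (totals and unassigned reasons) and `assignments`
#'   (per-read `site_id`, `NA` when unassigned, in input order).
#' @export
assign_reads <- function(reads, index, tolerance = 2L, library = "library",
                         dedup = FALSE) {
  stopifnot(inherits(index, "rs_index"))
  tolerance <- as.integer(tolerance)
  if (is.na(tolerance) || tolerance < 0L) stop("tolerance must be >= 0", call. = FALSE)
  need <- c("chrom", "strand", "five_prime")
  if (!all(need %in% names(reads)))
    stop("reads need columns chrom, strand, five_prime", call. = FALSE)
  rd <- data.table::data.table(chrom = as.character(reads$chrom),
                               strand = as.character(reads$strand),
                               five_prime = as.integer(reads$five_prime))
  if (dedup) rd <- unique(rd)
  rd[, read_idx := .I]
  n_input <- nrow(rd)

  # candidate cut ends, one row per (site, strand); ties at an identical
  # coordinate are represented by the leftmost site
  cand <- data.table::data.table(
    chrom = rep(index$chrom, 2L),
    strand = rep(c("+", "-"), each = nrow(index)),
    pos = c(index$cut_plus, index$cut_minus),
    motif_start = rep(index$motif_start, 2L),
    site_id = rep(index$site_id, 2L))
  data.table::setorder(cand, chrom, strand, pos, motif_start, site_id)
  cand <- cand[!duplicated(cand[, .(chrom, strand, pos)])]

  rd[, site_id := NA_integer_]
  rd[, reason := NA_character_]
  known <- unique(index$chrom)
  rd[!chrom %in% known, reason := "chromosome_not_in_index"]

  for (grp in split(seq_len(nrow(rd))[is.na(rd$reason)],
                    paste(rd$chrom[is.na(rd$reason)], rd$strand[is.na(rd$reason)]))) {
    if (!length(grp)) next
    ch <- rd$chrom[grp[1L]]; st <- rd$strand[grp[1L]]
    cc <- cand[chrom == ch & strand == st]
    if (!nrow(cc)) { rd[grp, reason := "no_site_within_tolerance"]; next }
    x <- rd$five_prime[grp]
    i <- findInterval(x, cc$pos)
    li <- pmax(i, 1L)                     # nearest candidate at or left of x
    ri <- pmin(i + 1L, nrow(cc))          # nearest candidate right of x
    dl <- ifelse(i >= 1L, x - cc$pos[li], NA_integer_)
    dr <- ifelse(i < nrow(cc), cc$pos[ri] - x, NA_integer_)
    # nearest wins; exact ties go left, i.e. to the lower motif_start
    use_left <- !is.na(dl) & (is.na(dr) | dl <= dr)
    pick <- ifelse(use_left, li, ri)
    dist <- ifelse(use_left, dl, dr)
    ok <- dist <= tolerance
    rd[grp[ok], site_id := cc$site_id[pick[ok]]]
    rd[grp[!ok], reason := "no_site_within_tolerance"]
  }

  counts_dt <- rd[!is.na(site_id), .N, by = site_id]
  raw <- integer(nrow(index))
  raw[match(counts_dt$site_id, index$site_id)] <- counts_dt$N
  tab <- cut_count_table(index$site_id, raw, library = library)
  reasons <- table(rd$reason[!is.na(rd$reason)])
  list(counts = tab,
       log = list(n_input = n_input,
                  n_assigned = sum(!is.na(rd$site_id)),
                  n_unassigned = sum(is.na(rd$site_id)),
                  unassigned_by_reason = as.list(reasons),
                  tolerance = tolerance,
                  dedup = dedup),
       assignments = rd$site_id[order(rd$read_idx)])
}
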