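# Restriction-site scanning and genome-wide site indexing.
#
# Coordinates are 0-based, half-open (BED convention) throughout.

#' Scan one sequence for restriction sites
#'
#' Finds every occurrence of the enzyme's recognition motif. Palindromic
#' motifs (such as Sau96I's `GGNCC`) are fully covered by a forward-strand
#' scan; for non-palindromic motifs the reverse strand is scanned as well
#' (as the forward-strand match of the reverse-complemented motif) and
#' duplicate positions are collapsed. Overlapping matches are distinct
#' sites. Ambiguous genome bases (`N` etc.) never match, so assembly gaps
#' produce no phantom sites.
#'
#' @param seq A [Biostrings::DNAString], or a character scalar.
#' @param enzyme An [enzyme_spec()].
#' @param chrom Chromosome name recorded in the output.
#' @return `data.frame` with columns `chrom`, `motif_start` (0-based),
#'   `motif_end` (exclusive), `enzyme`, `variant` (the concrete genome
#'   sequence matched, reverse-complemented for minus-strand matches of a
#'   non-palindromic motif so it always reads in motif orientation).
#' @export
scan_sequence <- function(seq, enzyme, chrom = "chr") {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  w <- nchar(enzyme$motif)
  if (length(seq) < w) {
    return(data.frame(chrom = character(), motif_start = integer(),
                      motif_end = integer(), enzyme = character(),
                      variant = character(), stringsAsFactors = FALSE))
  }
  motifs <- enzyme$motif
  if (!enzyme$palindromic) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(enzyme$motif)))
    motifs <- unique(c(motifs, rc))
  }
  starts0 <- integer(0)
  for (m in motifs) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(m), seq, fixed = "subject")
    starts0 <- c(starts0, BiocGenerics::start(hits) - 1L)
  }
  starts0 <- sort(unique(starts0))
  if (!length(starts0)) {
    return(data.frame(chrom = character(), motif_start = integer(),
                      motif_end = integer(), enzyme = character(),
                      variant = character(), stringsAsFactors = FALSE))
  }
  variant <- as.character(Biostrings::extractAt(
    seq, IRanges::IRanges(start = starts0 + 1L, width = w)))
  # drop matches spanning ambiguous genome bases (pattern N is a wildcard
  # in Biostrings and would otherwise pair with a literal N)
  clean <- !grepl("[^ACGT]", variant)
  starts0 <- starts0[clean]; variant <- variant[clean]
  if (!length(starts0)) {
    return(data.frame(chrom = character(), motif_start = integer(),
                      motif_end = integer(), enzyme = character(),
                      variant = character(), stringsAsFactors = FALSE))
  }
  # report minus-strand-only matches of non-palindromic motifs in motif
  # orientation
  if (!enzyme$palindromic && length(variant)) {
    matcher <- compile_motif(enzyme$motif)
    flip <- !motif_accepts(matcher, variant)
    if (any(flip))
      variant[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(variant[flip])))
  }
  data.frame(chrom = chrom, motif_start = starts0, motif_end = starts0 + w,
             enzyme = enzyme$name, variant = variant, stringsAsFactors = FALSE)
}

#' Build a genome-wide restriction-site index
#'
#' Scans every chromosome for every enzyme's sites and assigns dense,
#' stable site identifiers (ordered by chromosome name, then motif start,
#' then enzyme name). Supports dual-enzyme digests (e.g. Sau96I + DdeI).
#'
#' @param genome Path to a FASTA file (gzip allowed) or a named
#'   [Biostrings::DNAStringSet].
#' @param enzymes An [enzyme_spec()], a list of them, or a character
#'   vector of built-in enzyme names.
#' @param genome_id Label stored with the index.
#' @return An `rs_index`: a `data.frame` with columns `site_id`, `chrom`,
#'   `motif_start`, `motif_end`, `enzyme`, `variant`, `cut_plus`,
#'   `cut_minus` (expected 5'-end coordinates of plus/minus strand reads
#'   from a cut at this site, see [expected_end()]), with the enzyme list
#'   and chromosome lengths attached as attributes.
#' @export
build_index <- function(genome, enzymes, genome_id = "genome") {
  enzymes <- as_enzyme_list(enzymes)
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("cannot read FASTA: ", genome, call. = FALSE)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names in genome", call. = FALSE)
  pieces <- list()
  for (chrom in names(genome)) {
    for (enz in enzymes) {
      pieces[[length(pieces) + 1L]] <- scan_sequence(genome[[chrom]], enz, chrom)
    }
  }
  sites <- do.call(rbind, pieces)
  if (is.null(sites) || !nrow(sites)) {
    warning("no restriction sites found; returning an empty index")
    sites <- data.frame(chrom = character(), motif_start = integer(),
                        motif_end = integer(), enzyme = character(),
                        variant = character(), stringsAsFactors = FALSE)
  }
  sites <- sites[!duplicated(sites[c("chrom", "motif_start", "enzyme")]), ]
  ord <- order(sites$chrom, sites$motif_start, sites$enzyme, method = "radix")
  sites <- sites[ord, , drop = FALSE]
  off <- vapply(enzymes[sites$enzyme], `[[`, 0L, "cut_offset")
  wid <- nchar(vapply(enzymes[sites$enzyme], `[[`, "", "motif"))
  sites$cut_plus <- sites$motif_start + as.integer(off)
  sites$cut_minus <- sites$motif_start + as.integer(wid) - as.integer(off)
  sites <- cbind(site_id = seq_len(nrow(sites)), sites)
  rownames(sites) <- NULL
  structure(sites,
            enzymes = enzymes,
            genome_id = genome_id,
            seqlengths = stats::setNames(BiocGenerics::width(genome), names(genome)),
            class = c("rs_index", "data.frame"))
}

#' @export
print.rs_index <- function(x, ...) {
  cat(sprintf("rs_index: %d site%s on %d sequence%s (%s; enzymes: %s)\n",
              nrow(x), if (nrow(x) == 1L) "" else "s",
              length(unique(x$chrom)), if (length(unique(x$chrom)) == 1L) "" else "s",
              attr(x, "genome_id"),
              paste(names(attr(x, "enzymes")), collapse = " + ")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Expected read 5'-end coordinate at a site
#'
#' A cut at a restriction site yields two sequenceable ends. The plus
#' strand read begins at `motif_start + cut_offset` (so its sequence
#' starts with the enzyme's `read_prefix`); the minus strand read of the
#' upstream fragment ends at the symmetric position
#' `motif_start + motif_length - cut_offset` (recorded as the 0-based
#' exclusive end coordinate, which is how minus-strand 5' ends are
#' represented throughout).
#'
#' @param index An [build_index()] result (or any data.frame carrying
#'   `cut_plus`/`cut_minus`).
#' @param strand `"+"` or `"-"` (recycled).
#' @return Integer vector of expected 5'-end coordinates, one per site.
#' @export
expected_end <- function(index, strand) {
  strand <- rep_len(as.character(strand), nrow(index))
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  ifelse(strand == "+", index$cut_plus, index$cut_minus)
}

#' Restriction-site density baseline
#'
#' Assigns one pseudo-read to every site of the index. After RPM
#' normalization and metaprofile aggregation this yields the site-density
#' baseline that separates true accessibility signal from the non-uniform
#' genomic distribution of recognition motifs.
#'
#' @param index An `rs_index`.
#' @param library Name recorded on the resulting table.
#' @return A [cut_count_table()] with raw count 1 at every site.
#' @export
density_counts <- function(index, library = "rs_density") {
  if (!nrow(index)) stop("density baseline undefined for an empty index", call. = FALSE)
  cut_count_table(site_id = index$site_id,
                  raw = rep(1L, nrow(index)),
                  library = library)
}

#' Write a site index as BED plus a sidecar TSV
#'
#' BED6 columns: chrom, motif_start, motif_end, `enzyme|variant`, score 0,
#' strand `+`. The sidecar TSV carries `site_id, chrom, motif_start,
#' enzyme, variant`.
#'
#' @param index An `rs_index`.
#' @param bed Output BED path.
#' @param tsv Optional sidecar TSV path (default: `bed` with a `.tsv`
#'   extension).
#' @return Invisibly, the BED path.
#' @export
write_sites <- function(index, bed, tsv = NULL) {
  if (is.null(tsv)) tsv <- paste0(tools::file_path_sans_ext(bed), ".tsv")
  bed_df <- data.frame(index$chrom, index$motif_start, index$motif_end,
                       paste0(index$enzyme, "|", index$variant), 0L, "+")
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    index[c("site_id", "chrom", "motif_start", "enzyme", "variant")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed)
}

#' Read a site index written by [write_sites()]
#'
#' Rebuilds an `rs_index` from the BED + TSV pair. Cut coordinates are
#' recomputed from the supplied enzyme definitions.
#'
#' @param bed BED path written by [write_sites()].
#' @param enzymes Enzymes used to build the original index.
#' @param tsv Sidecar TSV path (default: derived from `bed`).
#' @return An `rs_index`.
#' @export
read_sites <- function(bed, enzymes, tsv = NULL) {
  enzymes <- as_enzyme_list(enzymes)
  if (is.null(tsv)) tsv <- paste0(tools::file_path_sans_ext(bed), ".tsv")
  sites <- utils::read.table(tsv, header = TRUE, sep = "\t",
                             colClasses = c("integer", "character", "integer",
                                            "character", "character"))
  wid <- nchar(vapply(enzymes[sites$enzyme], `[[`, "", "motif"))
  off <- vapply(enzymes[sites$enzyme], `[[`, 0L, "cut_offset")
  sites$motif_end <- sites$motif_start + as.integer(wid)
  sites$cut_plus <- sites$motif_start + as.integer(off)
  sites$cut_minus <- sites$motif_start + as.integer(wid) - as.integer(off)
  sites <- sites[c("site_id", "chrom", "motif_start", "motif_end",
                   "enzyme", "variant", "cut_plus", "cut_minus")]
  structure(sites, enzymes = enzymes, genome_id = basename(bed),
            seqlengths = NULL, class = c("rs_index", "data.frame"))
}
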