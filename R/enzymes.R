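# IUPAC nucleotide codes and restriction enzyme definitions.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC motif into its concrete k-mers
#'
#' A degenerate recognition motif such as `GGNCC` stands for a set of
#' concrete DNA words (here `GGACC`, `GGCCC`, `GGGCC`, `GGTCC`). This
#' expansion drives brute-force matching, per-variant reporting and
#' simulator efficiency weights.
#'
#' @param motif IUPAC nucleotide string.
#' @return Character vector of all concrete k-mers consistent with `motif`.
#' @examples
#' iupac_expand("GGNCC")
#' @export
iupac_expand <- function(motif) {
  chars <- validate_iupac(motif)
  sets <- IUPAC_SETS[chars]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(grid)))
}

validate_iupac <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("motif must be a non-empty character scalar", call. = FALSE)
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC character(s) in motif '%s': %s",
                 motif, paste(bad, collapse = ", ")), call. = FALSE)
  chars
}

#' Compile a degenerate motif into a k-mer matcher
#'
#' @param motif IUPAC nucleotide string (invalid characters are rejected
#'   with an error naming the offending character).
#' @return An object of class `motif_matcher` with elements `motif`,
#'   `width`, `kmers` (all concrete expansions), `n_expansions`, and
#'   `palindromic` (`TRUE` iff the motif equals its IUPAC reverse
#'   complement). Use [motif_accepts()] to test concrete words against it.
#' @examples
#' m <- compile_motif("GGNCC")
#' m$n_expansions       # 4
#' motif_accepts(m, "GGTCC")
#' @export
compile_motif <- function(motif) {
  chars <- validate_iupac(motif)
  kmers <- iupac_expand(motif)
  structure(
    list(motif = paste(chars, collapse = ""),
         width = length(chars),
         kmers = kmers,
         n_expansions = length(kmers),
         palindromic = is_palindromic(paste(chars, collapse = ""))),
    class = "motif_matcher")
}

#' @rdname compile_motif
#' @param matcher A `motif_matcher`.
#' @param x Character vector of concrete k-mers to test.
#' @return `motif_accepts()`: logical vector, `TRUE` where `x` is a
#'   concrete word consistent with the motif. Words containing ambiguous
#'   bases (including `N`) are never accepted.
#' @export
motif_accepts <- function(matcher, x) {
  stopifnot(inherits(matcher, "motif_matcher"))
  toupper(x) %in% matcher$kmers
}

#' @export
print.motif_matcher <- function(x, ...) {
  cat(sprintf("motif_matcher: %s (%d bp, %d concrete k-mer%s%s)\n",
              x$motif, x$width, x$n_expansions,
              if (x$n_expansions == 1L) "" else "s",
              if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Is a motif its own IUPAC reverse complement?
#'
#' Palindromic recognition sites (e.g. `GGNCC`) are matched completely by
#' a forward-strand scan; non-palindromic motifs require scanning both
#' strands.
#'
#' @param motif IUPAC nucleotide string.
#' @return Logical scalar.
#' @export
is_palindromic <- function(motif) {
  validate_iupac(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  toupper(motif) == rc
}

#' Define a restriction enzyme
#'
#' An enzyme is its recognition motif (IUPAC), the offset of the
#' top-strand cut point from the motif start, and the sequence expected at
#' the start of a cleaved, end-repaired fragment. For Sau96I (`G^GNCC`)
#' the cut offset is 1 and a blunted fragment begins `GNCC`.
#'
#' @param name Enzyme name.
#' @param motif IUPAC recognition motif, length >= 4.
#' @param cut_offset Bases from motif start to the top-strand cut point,
#'   in `[0, nchar(motif)]`.
#' @return An `enzyme_spec` with fields `name`, `motif`, `cut_offset` and
#'   `read_prefix` (the motif from the cut point to its end).
#' @examples
#' enzyme_spec("Sau96I", "GGNCC", 1L)
#' @export
enzyme_spec <- function(name, motif, cut_offset) {
  chars <- validate_iupac(motif)
  if (length(chars) < 4L)
    stop("recognition motif must be at least 4 bp", call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > length(chars))
    stop("cut_offset must lie within [0, motif length]", call. = FALSE)
  motif <- paste(chars, collapse = "")
  structure(
    list(name = as.character(name),
         motif = motif,
         cut_offset = cut_offset,
         read_prefix = substr(motif, cut_offset + 1L, nchar(motif)),
         palindromic = is_palindromic(motif)),
    class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("enzyme_spec: %s  %s^%s  (cut offset %d%s)\n",
              x$name,
              substr(x$motif, 1, x$cut_offset),
              x$read_prefix, x$cut_offset,
              if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Built-in enzyme definitions
#'
#' Sau96I (`G^GNCC`) and DdeI (`C^TNAG`), the two enzymes used for
#' chromatin digestion in this assay. Definitions can equally be supplied
#' from a YAML/JSON config via [load_enzymes()], so nothing is hard-coded.
#'
#' @param names Optional character vector selecting a subset by name.
#' @return Named list of [enzyme_spec()] objects.
#' @export
builtin_enzymes <- function(names = NULL) {
  all <- list(
    Sau96I = enzyme_spec("Sau96I", "GGNCC", 1L),
    DdeI   = enzyme_spec("DdeI",   "CTNAG", 1L)
  )
  if (is.null(names)) return(all)
  missing <- setdiff(names, names(all))
  if (length(missing))
    stop("unknown built-in enzyme(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  all[names]
}

#' Load enzyme definitions from a YAML or JSON config
#'
#' The file holds a list of records with fields `name`, `motif` and
#' `cut_offset`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [enzyme_spec()] objects.
#' @export
load_enzymes <- function(path) {
  if (!file.exists(path)) stop("enzyme config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
          else stop("enzyme config must be YAML or JSON", call. = FALSE)
  if (!is.null(recs$name)) recs <- list(recs)  # single record at top level
  specs <- lapply(recs, function(r) {
    if (is.null(r$name) || is.null(r$motif) || is.null(r$cut_offset))
      stop("each enzyme record needs name, motif and cut_offset", call. = FALSE)
    enzyme_spec(r$name, r$motif, r$cut_offset)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# Normalize the various ways callers can hand over enzymes: a single
# enzyme_spec, a list of them, or a character vector of built-in names.
as_enzyme_list <- function(enzymes) {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  if (is.character(enzymes)) enzymes <- builtin_enzymes(enzymes)
  if (!length(enzymes) || !all(vapply(enzymes, inherits, TRUE, "enzyme_spec")))
    stop("expected one or more enzyme_spec objects", call. = FALSE)
  names(enzymes) <- vapply(enzymes, `[[`, "", "name")
  if (anyDuplicated(names(enzymes)))
    stop("duplicate enzyme names", call. = FALSE)
  enzymes
}
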