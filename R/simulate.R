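# Ground-truth simulation of chromatin digestion libraries.
#
# The simulator emulates the library chemistry in silico: independent
# chromosome copies ("molecules") are digested site-by-site with
# per-site Bernoulli cleavage probabilities derived from a chromatin
# model (nucleosome cores occlude their DNA, linkers and nucleosome-free
# regions are exposed, variant nucleosomes are partially exposed);
# fragments run from each cut to the nearer of the next cut and a
# sonication breakpoint; fragments outside the size-selection window are
# discarded; each surviving fragment is sequenced from its cut end, so
# every read begins (after the sample barcode) with the enzyme's
# post-cleavage prefix and traces to exactly one cut at one site.

#' Simulate a random genome
#'
#' I.i.d. sequence with a given GC content, with optional planting of
#' exact subsequences (e.g. restriction-site variants at controlled
#' spacings) at specified coordinates.
#'
#' @param lengths Named integer vector of chromosome lengths (>= 1 kb
#'   each); an unnamed scalar makes a single `chr1`.
#' @param gc_fraction Probability of G or C at each position, in `[0, 1]`.
#' @param seed Random seed (mandatory: genomes are reproducible).
#' @param plant Optional data.frame `(chrom, pos, seq)`: `seq` is written
#'   over the random background at 0-based position `pos`.
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(lengths, gc_fraction = 0.42, seed, plant = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  lengths <- stats::setNames(as.integer(lengths), names(lengths))
  if (any(lengths < 1000L)) stop("chromosome lengths must be >= 1 kb", call. = FALSE)
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  set.seed(seed)
  pr <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
          G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(lengths, function(L)
    paste(sample(names(pr), L, replace = TRUE, prob = pr), collapse = ""), "")
  if (!is.null(plant)) {
    for (i in seq_len(nrow(plant))) {
      ch <- as.character(plant$chrom[i]); p0 <- as.integer(plant$pos[i])
      s <- toupper(as.character(plant$seq[i]))
      if (!ch %in% names(seqs)) stop("plant chrom not in genome: ", ch, call. = FALSE)
      if (p0 < 0L || p0 + nchar(s) > nchar(seqs[[ch]]))
        stop("planted sequence overhangs chromosome ", ch, call. = FALSE)
      substr(seqs[[ch]], p0 + 1L, p0 + nchar(s)) <- s
    }
  }
  Biostrings::DNAStringSet(seqs)
}

#' Build a nucleosome-array chromatin model
#'
#' Tiles each chromosome with 147 bp nucleosome cores separated by linker
#' gaps (truncated-normal, mean ~30 bp as in ESC chromatin), removes
#' cores overlapping designated nucleosome-free regions (NFRs), and
#' labels a fraction of the remaining cores as variant nucleosomes (the
#' H2A.Z/H3.3 analog) with elevated cleavage accessibility.
#'
#' @param seqlengths Named integer vector of chromosome lengths (e.g.
#'   `attr(index, "seqlengths")`).
#' @param nfr Optional data.frame `(chrom, start, end)` of nucleosome-free
#'   intervals (0-based half-open).
#' @param seed Random seed (mandatory).
#' @param linker_mean,linker_sd Linker-length distribution (bp), truncated
#'   below at `min_linker`.
#' @param min_linker Minimum linker length (bp).
#' @param core_width Nucleosome core width (bp), default 147.
#' @param variant_fraction Fraction of cores labeled variant.
#' @param occlusion Cleavage-probability multiplier under a canonical
#'   core, in `[0, 1]`; default 0.05.
#' @param variant_multiplier Fold increase of variant-core accessibility
#'   over canonical cores (`m`); variant cores get
#'   `min(1, m * occlusion)`.
#' @param weights Optional named vector of per-motif-variant cleavage
#'   efficiency weights (e.g. `c(GGTCC = 2)`); unlisted variants get 1.
#' @param regular_spacing If `TRUE`, linkers are fixed at `linker_mean`
#'   (regularly phased arrays).
#' @return A `chromatin_model`: list with `cores` (data.frame `chrom,
#'   start, end, class`), `nfr`, and the parameters.
#' @export
chromatin_model <- function(seqlengths, nfr = NULL, seed,
                            linker_mean = 30, linker_sd = 10, min_linker = 2L,
                            core_width = 147L, variant_fraction = 0.1,
                            occlusion = 0.05, variant_multiplier = 5,
                            weights = NULL, regular_spacing = FALSE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (occlusion < 0 || occlusion > 1) stop("occlusion must be in [0, 1]", call. = FALSE)
  if (variant_multiplier <= 0) stop("variant_multiplier must be > 0", call. = FALSE)
  if (!is.null(weights) && any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  set.seed(seed)
  pieces <- list()
  for (ch in names(seqlengths)) {
    L <- seqlengths[[ch]]
    n_max <- ceiling(L / (core_width + max(min_linker, 1)))
    linkers <- if (regular_spacing) rep(linker_mean, n_max)
               else pmax(min_linker, round(stats::rnorm(n_max, linker_mean, linker_sd)))
    starts <- cumsum(c(linkers[1L], core_width + linkers[-1L]))
    starts <- starts[starts + core_width <= L]
    if (!length(starts)) next
    pieces[[ch]] <- data.frame(chrom = ch, start = as.integer(starts),
                               end = as.integer(starts + core_width),
                               stringsAsFactors = FALSE)
  }
  cores <- do.call(rbind, pieces)
  rownames(cores) <- NULL
  if (!is.null(nfr) && nrow(nfr)) {
    keep <- rep(TRUE, nrow(cores))
    for (i in seq_len(nrow(nfr))) {
      hit <- cores$chrom == nfr$chrom[i] &
        cores$start < nfr$end[i] & cores$end > nfr$start[i]
      keep[hit] <- FALSE
    }
    cores <- cores[keep, , drop = FALSE]
  }
  cores$class <- ifelse(stats::runif(nrow(cores)) < variant_fraction,
                        "variant", "canonical")
  structure(
    list(cores = cores,
         nfr = if (is.null(nfr)) data.frame(chrom = character(),
                                            start = integer(), end = integer())
               else nfr[c("chrom", "start", "end")],
         seqlengths = seqlengths,
         occlusion = occlusion, variant_multiplier = variant_multiplier,
         weights = weights, core_width = core_width,
         linker_mean = linker_mean, seed = seed),
    class = "chromatin_model")
}

#' @export
print.chromatin_model <- function(x, ...) {
  cat(sprintf(paste0("chromatin_model: %d cores (%d variant) on %d chromosome%s,",
                     " %d NFR(s), occlusion %.3g, variant multiplier %.3g\n"),
              nrow(x$cores), sum(x$cores$class == "variant"),
              length(x$seqlengths), if (length(x$seqlengths) == 1L) "" else "s",
              nrow(x$nfr), x$occlusion, x$variant_multiplier))
  invisible(x)
}

#' Simulation configuration
#'
#' @param seed Random seed (mandatory).
#' @param n_molecules Number of independent chromosome copies digested.
#' @param p0 Baseline per-site, per-molecule cleavage probability of a
#'   fully exposed site, in `(0, 1]`.
#' @param naked If `TRUE`, the chromatin model is ignored: every site is
#'   fully exposed (deproteinized DNA control).
#' @param sonication_mean,sonication_sd Sonication fragment-length
#'   distribution (truncated normal, bp).
#' @param size_min,size_max Size-selection window (bp), default 200-350.
#' @param read_length Sequenced bases after the barcode.
#' @param barcode 4 bp sample barcode prepended to every read.
#' @param sample Sample name recorded in the truth table.
#' @param error_rate Uniform per-base substitution rate applied to read
#'   sequences (default 0: reads are error-free).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_molecules = 1e5, p0 = 0.01, naked = FALSE,
                       sonication_mean = 200, sonication_sd = 50,
                       size_min = 200L, size_max = 350L,
                       read_length = 36L, barcode = "ACGT", sample = "sim",
                       error_rate = 0) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (p0 <= 0 || p0 > 1) stop("p0 must lie in (0, 1]", call. = FALSE)
  if (size_min <= 0L || size_max < size_min)
    stop("size-selection window must be positive", call. = FALSE)
  validate_barcodes(stats::setNames(barcode, sample))
  structure(list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
                 p0 = p0, naked = naked,
                 sonication_mean = sonication_mean, sonication_sd = sonication_sd,
                 size_min = as.integer(size_min), size_max = as.integer(size_max),
                 read_length = as.integer(read_length), barcode = barcode,
                 sample = sample, error_rate = error_rate),
            class = "sim_config")
}

#' Per-site cleavage probabilities under a chromatin model
#'
#' Naked mode: `p = p0 * w(variant)`. Chromatin mode: `p = p0 *
#' w(variant) * a`, where the accessibility factor `a` is 1 in NFRs and
#' linkers, the occlusion factor under canonical cores, and
#' `min(1, m * occlusion)` under variant cores. A site's position is its
#' plus-strand cut coordinate. Sites on chromosomes outside the model are
#' treated as linker (`a = 1`) with a warning.
#'
#' @param index An `rs_index` built on the simulated genome.
#' @param model A [chromatin_model()] (ignored in naked mode).
#' @param config A [sim_config()].
#' @return Numeric vector of probabilities aligned to `index` rows, with
#'   the per-site class (`"nfr"`, `"linker"`, `"canonical"`, `"variant"`,
#'   or `"naked"`) in attribute `site_class`.
#' @export
cut_probabilities <- function(index, model = NULL, config) {
  stopifnot(inherits(index, "rs_index"), inherits(config, "sim_config"))
  pos <- index$cut_plus
  w <- rep(1, nrow(index))
  wts <- if (!is.null(model)) model$weights else NULL
  if (!is.null(wts)) {
    hit <- match(index$variant, names(wts))
    w[!is.na(hit)] <- wts[hit[!is.na(hit)]]
  }
  if (config$naked || is.null(model)) {
    p <- pmin(1, config$p0 * w)
    attr(p, "site_class") <- rep("naked", nrow(index))
    return(p)
  }
  stopifnot(inherits(model, "chromatin_model"))
  a <- rep(1, nrow(index))
  cls <- rep("linker", nrow(index))
  covered <- index$chrom %in% names(model$seqlengths)
  if (any(!covered)) {
    warning("sites on chromosome(s) outside the chromatin model treated as linker: ",
            paste(unique(index$chrom[!covered]), collapse = ", "))
    cls[!covered] <- "linker"
  }
  loc <- locate_in_model(index$chrom, pos, model)
  a[loc == "canonical"] <- model$occlusion
  a[loc == "variant"] <- min(1, model$variant_multiplier * model$occlusion)
  cls[covered] <- loc[covered]
  p <- pmin(1, config$p0 * w * a)
  attr(p, "site_class") <- cls
  p
}

# classify positions as nfr / variant / canonical / linker
locate_in_model <- function(chrom, pos, model) {
  out <- rep("linker", length(pos))
  q <- data.table::data.table(chrom = chrom, p1 = pos, p2 = pos,
                              qid = seq_along(pos))
  if (nrow(model$cores)) {
    co <- data.table::as.data.table(model$cores)
    hit <- co[q, on = .(chrom, start <= p1, end > p2), nomatch = NULL,
              .(qid, class = x.class)]
    out[hit$qid] <- hit$class
  }
  if (nrow(model$nfr)) {
    nf <- data.table::as.data.table(model$nfr)
    hit <- nf[q, on = .(chrom, start <= p1, end > p2), nomatch = NULL, .(qid)]
    out[hit$qid] <- "nfr"
  }
  out
}

#' Generate a simulated sequencing library
#'
#' Digests `n_molecules` independent copies of the genome with the given
#' per-site probabilities and carries the fragments through sonication,
#' size selection and cut-end sequencing (see the module header). Every
#' read derives from exactly one cut at one site; the truth table records
#' that provenance, which downstream recovery tests compare against.
#'
#' @param genome Named [Biostrings::DNAStringSet] the index was built on.
#' @param index The `rs_index` over `genome`.
#' @param probs Per-site cleavage probabilities from [cut_probabilities()].
#' @param config A [sim_config()].
#' @param emit_fastq If `FALSE`, skip building read sequences (the truth
#'   table of read ends is enough for assignment-level analyses and much
#'   cheaper at high depth).
#' @param outdir If non-NULL, write `genome.fa`, `reads.fastq`,
#'   `truth_ends.bed`, `provenance.tsv` and `model.json` there.
#' @return List with `truth` (data.frame: `chrom, strand, five_prime,
#'   site_id, molecule, sample`; one row per read), `fastq`
#'   (`QualityScaledDNAStringSet` or NULL), `n_cut_events`, `probs`,
#'   `config`.
#' @export
generate_library <- function(genome, index, probs, config,
                             emit_fastq = TRUE, outdir = NULL) {
  stopifnot(inherits(index, "rs_index"), inherits(config, "sim_config"),
            length(probs) == nrow(index))
  set.seed(config$seed)
  n_mol <- config$n_molecules
  seqlen <- stats::setNames(BiocGenerics::width(genome), names(genome))

  # Bernoulli digestion: per site, the molecules it cuts in
  n_cuts <- stats::rbinom(nrow(index), n_mol, probs)
  ev <- data.table::data.table(
    row = rep.int(seq_len(nrow(index)), n_cuts),
    mol = unlist(lapply(which(n_cuts > 0L), function(i)
      sample.int(n_mol, n_cuts[i])), use.names = FALSE))
  if (!nrow(ev))
    stop("no cut events: increase n_molecules or p0", call. = FALSE)
  ev[, `:=`(chrom = index$chrom[row],
            e_plus = index$cut_plus[row],
            e_minus = index$cut_minus[row],
            site_id = index$site_id[row])]
  data.table::setorder(ev, chrom, mol, e_plus)
  # neighbor cuts within the same molecule bound the cut-to-cut fragments
  ev[, `:=`(next_minus = data.table::shift(e_minus, -1L),
            prev_plus = data.table::shift(e_plus, 1L)),
     by = .(chrom, mol)]
  ev[is.na(next_minus), next_minus := seqlen[chrom]]
  ev[is.na(prev_plus), prev_plus := 0L]

  # each cut exposes two sequenceable ends; fragment length is capped by
  # the neighboring cut (or chromosome end) and a sonication breakpoint
  son <- function(n) pmax(1, round(stats::rnorm(n, config$sonication_mean,
                                                config$sonication_sd)))
  len_right <- pmin(son(nrow(ev)), ev$next_minus - ev$e_plus)
  len_left <- pmin(son(nrow(ev)), ev$e_minus - ev$prev_plus)
  keep_r <- len_right >= config$size_min & len_right <= config$size_max
  keep_l <- len_left >= config$size_min & len_left <= config$size_max

  truth <- data.table::rbindlist(list(
    ev[keep_r, .(chrom, strand = "+", five_prime = e_plus, site_id, mol)],
    ev[keep_l, .(chrom, strand = "-", five_prime = e_minus, site_id, mol)]))
  if (!nrow(truth))
    stop("no fragments survived size selection: increase n_molecules",
         call. = FALSE)
  data.table::setorder(truth, chrom, five_prime, strand, mol)
  truth[, sample := config$sample]

  fq <- NULL
  if (emit_fastq) fq <- build_reads(genome, truth, config)

  out <- list(truth = as.data.frame(truth), fastq = fq,
              n_cut_events = nrow(ev), probs = probs, config = config)
  if (!is.null(outdir)) write_simulation(out, genome, outdir)
  invisible(out)
}

# read sequences: barcode + genomic sequence starting at the cut end
build_reads <- function(genome, truth, config) {
  rl <- config$read_length
  seqs <- character(nrow(truth))
  for (ch in unique(truth$chrom)) {
    i <- which(truth$chrom == ch)
    L <- length(genome[[ch]])
    plus <- truth$strand[i] == "+"
    start <- ifelse(plus, truth$five_prime[i] + 1L, truth$five_prime[i] - rl + 1L)
    start <- pmax(1L, start)
    end <- pmin(L, ifelse(plus, truth$five_prime[i] + rl, truth$five_prime[i]))
    frag <- Biostrings::extractAt(genome[[ch]],
                                  IRanges::IRanges(start = start, end = end))
    frag <- Biostrings::DNAStringSet(frag)
    if (any(!plus))
      frag[!plus] <- Biostrings::reverseComplement(frag[!plus])
    seqs[i] <- as.character(frag)
  }
  if (config$error_rate > 0) {
    n_err <- stats::rbinom(length(seqs), nchar(seqs), config$error_rate)
    for (j in which(n_err > 0L)) {
      at <- sample.int(nchar(seqs[j]), n_err[j])
      for (p in at)
        substr(seqs[j], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                substr(seqs[j], p, p)), 1L)
    }
  }
  reads <- Biostrings::DNAStringSet(paste0(config$barcode, seqs))
  names(reads) <- sprintf("sim_%s_%07d", config$sample, seq_along(reads))
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads), function(w) strrep("I", w), ""))
  Biostrings::QualityScaledDNAStringSet(reads, quals)
}

write_simulation <- function(sim, genome, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
  if (!is.null(sim$fastq))
    write_fastq(sim$fastq, file.path(outdir, "reads.fastq"))
  tr <- sim$truth
  bed <- data.frame(tr$chrom,
                    ifelse(tr$strand == "+", tr$five_prime, tr$five_prime - 1L),
                    ifelse(tr$strand == "+", tr$five_prime + 1L, tr$five_prime),
                    paste0("site", tr$site_id), 0L, tr$strand)
  utils::write.table(bed, file.path(outdir, "truth_ends.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(tr, file.path(outdir, "provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  jsonlite::write_json(list(config = unclass(cfg),
                            n_cut_events = sim$n_cut_events,
                            n_reads = nrow(tr)),
                       file.path(outdir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
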