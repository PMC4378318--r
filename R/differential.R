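# Differential cut analysis between libraries and feature-level
# comparisons.
#
# Per site, the question is whether the site's share of library A's reads
# differs from its share of library B's: a 2x2 table (site vs rest of
# library) x (A vs B), tested with Fisher's exact test (exact at low
# counts, no distributional fit) and corrected across sites with
# Benjamini-Hochberg.

# Two-sided Fisher exact p-values for many 2x2 tables at once.
# Table i is rbind(c(a[i], totalA - a[i]), c(b[i], totalB - b[i])).
# p = sum of hypergeometric probabilities <= p_obs * (1 + 1e-7), the
# standard relative-error guard against ties lost to rounding.
fisher2x2_p <- function(a, b, totalA, totalB) {
  n <- length(a)
  stopifnot(length(b) == n)
  k <- a + b                       # site margin
  lo <- pmax(0, k - totalB)        # support of a under the null
  hi <- pmin(k, totalA)
  sup_len <- hi - lo + 1
  idx <- rep.int(seq_len(n), sup_len)
  x <- unlist(lapply(seq_len(n), function(i) lo[i]:hi[i]), use.names = FALSE)
  d <- stats::dhyper(x, totalA, totalB, k[idx])
  d_obs <- stats::dhyper(a, totalA, totalB, k)
  keep <- d <= d_obs[idx] * (1 + 1e-7)
  p <- rowsum(d * keep, idx)[, 1L]
  pmin(1, p)
}

#' Per-site differential cut analysis between two libraries
#'
#' For every site, tests the 2x2 table (site count vs remainder of
#' library) x (library A vs library B) with Fisher's exact test
#' (two-sided), adjusts p-values across tested sites with
#' Benjamini-Hochberg, and reports a log2 RPM ratio as effect size with a
#' pseudo-RPM `pseudo` added to both terms (the pseudo-count enters the
#' effect only, never the test). Sites with zero counts in both libraries
#' carry no evidence and are excluded from testing (`tested = FALSE`,
#' `p`/`q` = `NA`).
#'
#' @param tableA,tableB [cut_count_table()]s over the same site universe.
#' @param pseudo Pseudo-RPM added in the effect-size ratio; default 1.
#' @return data.frame with `site_id`, `rawA`, `rawB`, `rpmA`, `rpmB`,
#'   `effect_log2`, `p`, `q`, `tested`; library names and totals attached
#'   as attributes.
#' @export
site_differential <- function(tableA, tableB, pseudo = 1) {
  stopifnot(inherits(tableA, "cut_count_table"),
            inherits(tableB, "cut_count_table"))
  if (nrow(tableA) != nrow(tableB) ||
      !all(sort(tableA$site_id) == sort(tableB$site_id)))
    stop("count tables are over different site universes", call. = FALSE)
  if (pseudo <= 0) stop("pseudo must be > 0 for finite effects", call. = FALSE)
  tableB <- tableB[match(tableA$site_id, tableB$site_id), ]
  totalA <- attr(tableA, "total"); totalB <- attr(tableB, "total")
  if (totalA <= 0 || totalB <= 0)
    stop("both libraries must contain reads", call. = FALSE)
  a <- tableA$raw; b <- tableB$raw
  rpmA <- a * 1e6 / totalA; rpmB <- b * 1e6 / totalB
  tested <- (a + b) > 0L
  p <- rep(NA_real_, length(a))
  if (any(tested)) p[tested] <- fisher2x2_p(a[tested], b[tested], totalA, totalB)
  q <- rep(NA_real_, length(a))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  structure(
    data.frame(site_id = tableA$site_id, rawA = a, rawB = b,
               rpmA = rpmA, rpmB = rpmB,
               effect_log2 = log2((rpmA + pseudo) / (rpmB + pseudo)),
               p = p, q = q, tested = tested),
    libraries = c(attr(tableA, "library"), attr(tableB, "library")),
    totals = c(totalA, totalB), pseudo = pseudo,
    class = c("site_differential", "data.frame"))
}

#' Write a differential table as TSV
#'
#' Columns: `site_id, chrom, pos, rawA, rawB, rpmA, rpmB, effect_log2, p, q`.
#'
#' @param diff A [site_differential()] result.
#' @param index Matching `rs_index` (for coordinates).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_differential <- function(diff, index, path) {
  m <- match(diff$site_id, index$site_id)
  out <- cbind(data.frame(site_id = diff$site_id, chrom = index$chrom[m],
                          pos = index$cut_plus[m]),
               diff[c("rawA", "rawB", "rpmA", "rpmB", "effect_log2", "p", "q")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare paired per-feature accessibility scores between conditions
#'
#' Takes feature-aligned score vectors from two conditions (e.g.
#' [window_score()] of replicate libraries over the same features) and
#' tests the paired per-feature differences with the Wilcoxon signed-rank
#' test, a robust choice for skewed per-feature accessibility scores.
#' When every paired difference is zero the comparison is degenerate and
#' `p = 1` is reported with a flag.
#'
#' @param scoresA,scoresB Numeric vectors of equal length (feature
#'   aligned), or [window_score()] outputs (their `score` columns are
#'   used and feature alignment is checked by name).
#' @return List with `n`, `meanA`, `meanB`, `mean_difference`, `p_value`,
#'   `degenerate`.
#' @export
featureset_comparison <- function(scoresA, scoresB) {
  if (is.data.frame(scoresA)) {
    if (is.data.frame(scoresB) && !identical(scoresA$name, scoresB$name))
      stop("score tables are not feature-aligned", call. = FALSE)
    scoresA <- scoresA$score
  }
  if (is.data.frame(scoresB)) scoresB <- scoresB$score
  if (length(scoresA) != length(scoresB))
    stop("score vectors must be equal length and feature-aligned", call. = FALSE)
  if (length(scoresA) < 10L)
    stop("need at least 10 paired features for a meaningful comparison",
         call. = FALSE)
  d <- scoresA - scoresB
  degenerate <- all(d == 0)
  p <- if (degenerate) 1 else
    stats::wilcox.test(scoresA, scoresB, paired = TRUE, exact = FALSE)$p.value
  list(n = length(scoresA), meanA = mean(scoresA), meanB = mean(scoresB),
       mean_difference = mean(d), p_value = p, degenerate = degenerate)
}

#' Annotate positions with their nearest feature interval
#'
#' For each query position, finds the interval minimizing distance
#' (0 when the position lies inside the interval) and reports a signed
#' distance: negative when the position lies upstream of (left of) the
#' interval start, positive when downstream of its end. Exact ties go to
#' the leftmost interval (lower start). Queries on chromosomes with no
#' annotation get `NA`.
#'
#' @param x A [site_differential()] result (give `index` too), an
#'   `rs_index`, or a data.frame with `chrom` and `pos` columns.
#' @param annotations A [feature_set()] (or any data.frame with `chrom`,
#'   `start`, `end`, optional `name`).
#' @param index `rs_index` used to locate sites when `x` is a
#'   differential table.
#' @return `x`'s rows with `nearest` (annotation name) and
#'   `distance_signed` columns appended.
#' @export
annotate_nearest <- function(x, annotations, index = NULL) {
  if (!nrow(annotations)) stop("empty annotation set", call. = FALSE)
  if (inherits(x, "site_differential")) {
    if (is.null(index)) stop("index needed to locate differential sites",
                             call. = FALSE)
    m <- match(x$site_id, index$site_id)
    pos <- data.frame(chrom = index$chrom[m], pos = index$cut_plus[m])
  } else if (inherits(x, "rs_index")) {
    pos <- data.frame(chrom = x$chrom, pos = x$cut_plus)
  } else {
    stopifnot(all(c("chrom", "pos") %in% names(x)))
    pos <- x[c("chrom", "pos")]
  }
  ann <- annotations[order(annotations$chrom, annotations$start,
                           annotations$end, method = "radix"), , drop = FALSE]
  if (is.null(ann$name)) ann$name <- paste0("interval_", seq_len(nrow(ann)))
  nearest <- rep(NA_character_, nrow(pos))
  dist <- rep(NA_integer_, nrow(pos))
  for (ch in unique(pos$chrom)) {
    qi <- which(pos$chrom == ch)
    ai <- which(ann$chrom == ch)
    if (!length(ai)) next
    q <- pos$pos[qi]
    s <- ann$start[ai]; e <- ann$end[ai]
    # signed distance from every query to every interval on this
    # chromosome; interval counts are small in annotation use, and the
    # dense form keeps the leftmost tie-break transparent
    dmat <- vapply(seq_along(ai), function(j) {
      dd <- integer(length(q))
      dd[q < s[j]] <- q[q < s[j]] - s[j]          # upstream: negative
      dd[q >= e[j]] <- q[q >= e[j]] - (e[j] - 1L) # downstream: positive
      dd
    }, integer(length(q)))
    dmat <- matrix(dmat, nrow = length(q))
    pick <- apply(abs(dmat), 1L, which.min)       # first (leftmost) minimum
    nearest[qi] <- ann$name[ai[pick]]
    dist[qi] <- dmat[cbind(seq_along(q), pick)]
  }
  out <- as.data.frame(x)
  out$nearest <- nearest
  out$distance_signed <- dist
  out
}
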