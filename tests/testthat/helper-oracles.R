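# Independent brute-force oracles used across the suite. These stay
# deliberately naive (string comparison, exhaustive loops) so they share
# no code path with the implementation they check.

# All motif match positions (0-based) on either strand of seq_str, by
# expanding the motif to concrete k-mers and comparing substrings.
oracle_scan <- function(seq_str, motif) {
  kmers <- iupac_expand(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  accept <- unique(c(kmers, rc))
  w <- nchar(motif)
  n <- nchar(seq_str)
  if (n < w) return(integer(0))
  hits <- integer(0)
  for (p in 0:(n - w)) {
    if (substr(seq_str, p + 1, p + w) %in% accept) hits <- c(hits, p)
  }
  hits
}

# Nearest-site assignment by exhaustive search over every site, mirroring
# the documented rule: minimum distance to the strand-appropriate
# expected end, ties to the lower expected-end coordinate, then lower
# motif_start, then lower site_id; NA beyond tolerance.
oracle_assign <- function(reads, index, tolerance) {
  out <- rep(NA_integer_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    on_chrom <- index$chrom == reads$chrom[i]
    if (!any(on_chrom)) next
    ends <- if (reads$strand[i] == "+") index$cut_plus else index$cut_minus
    d <- abs(reads$five_prime[i] - ends)
    d[!on_chrom] <- NA
    best <- min(d, na.rm = TRUE)
    if (best > tolerance) next
    cand <- which(!is.na(d) & d == best)
    cand <- cand[order(ends[cand], index$motif_start[cand], index$site_id[cand])]
    out[i] <- index$site_id[cand[1L]]
  }
  out
}

# Two-sided Fisher exact p for a single 2x2 table rbind(c(a, tA - a),
# c(b, tB - b)), by literal summation over the hypergeometric support.
oracle_fisher <- function(a, b, tA, tB) {
  k <- a + b
  support <- max(0, k - tB):min(k, tA)
  probs <- vapply(support, function(x) stats::dhyper(x, tA, tB, k), 0)
  obs <- stats::dhyper(a, tA, tB, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Sign-flip permutation p-value for paired scores (two-sided, on the mean
# difference).
oracle_signflip <- function(d, n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(d))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    flip <- sample(c(-1, 1), length(d), replace = TRUE)
    if (abs(mean(d * flip)) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Random DNA string with no ambiguity codes.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Tiny index straight from coordinates (Sau96I-like geometry) for
# assignment tests that need full control over site placement.
toy_index <- function(motif_start, chrom = "chr1", enzyme = "Sau96I",
                      variant = "GGACC", width = 5L, cut_offset = 1L,
                      seqlen = NULL) {
  chrom <- rep_len(chrom, length(motif_start))
  o <- order(chrom, motif_start)
  df <- data.frame(site_id = seq_along(motif_start),
                   chrom = chrom[o],
                   motif_start = as.integer(motif_start[o]),
                   motif_end = as.integer(motif_start[o] + width),
                   enzyme = enzyme,
                   variant = rep_len(variant, length(motif_start))[o],
                   cut_plus = as.integer(motif_start[o] + cut_offset),
                   cut_minus = as.integer(motif_start[o] + width - cut_offset))
  structure(df, enzymes = builtin_enzymes("Sau96I"), genome_id = "toy",
            seqlengths = seqlen, class = c("rs_index", "data.frame"))
}
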