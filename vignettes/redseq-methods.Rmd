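---
title: "Restriction enzyme accessibility profiling: models and methods"
author: "redseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restriction enzyme accessibility profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redseqr)
```

## The measurement model

Restriction enzyme accessibility sequencing probes chromatin structure by
digesting permeabilized cells with a restriction endonuclease, capturing
the cut ends, and sequencing them. Because a restriction enzyme needs
physical access to its recognition site, the read count assigned to a
site is a direct readout of how exposed that site is in the cell
population: nucleosome-free regions and linkers cut readily, DNA buried
in a nucleosome core is protected. Unlike DNase- or FAIRE-style assays,
which report only large nucleosome-depleted regions, a single cut
suffices for a fragment to enter the library, so the assay quantifies
accessibility *within* nucleosome arrays as well.

The unit of measurement is the **restriction site (RS)**: a genomic
occurrence of the enzyme's recognition motif. The default enzyme is
Sau96I, whose degenerate 5-mer motif `GGNCC` is cut after the first base
(`G^GNCC`), so a cleaved, end-repaired fragment begins with `GNCC`. A
second enzyme, DdeI (`C^TNAG`), can be combined with Sau96I for higher
site density; both are supplied as built-ins and arbitrary enzymes can
be loaded from a YAML/JSON config (`load_enzymes()`). Enzymes whose cut
site lies outside the recognition motif (Type IIS) are out of scope.

Accessibility at site $i$ in a library of $N$ assigned reads is
expressed in reads per million:

$$\mathrm{RPM}_i = \frac{c_i \times 10^6}{N},$$

where $c_i$ is the number of read 5' ends assigned to site $i$. RPM sums
to $10^6$ by construction, which makes libraries of different depth
comparable and is checked to $10^{-6}$ relative tolerance in the tests.

## Coordinates and cut geometry

All coordinates are 0-based, half-open (BED convention). For an enzyme
with motif length $L$ and cut offset $o$, a cut at a site starting at
$s$ yields two sequenceable ends:

* plus strand: the read starts at $s + o$ and begins with the enzyme's
  post-cleavage prefix (Sau96I: `GNCC` — visible in raw barcoded reads
  as a G at cycle 5 and CC at cycles 7–8);
* minus strand: the upstream fragment's read 5' end sits at
  $s + L - o$, recorded as an exclusive end coordinate.

These two expected ends drive read assignment, and the plus-strand cut
coordinate is used as the site's point position when signal is
aggregated.

## Read processing

Reads carry a 4 bp inline sample barcode. `demultiplex()` bins reads by
**exact** barcode match — a 4 bp barcode cannot absorb mismatches
without colliding with other barcodes, and no mismatch tolerance is
assumed. After trimming, the fraction of reads beginning with the
enzyme's post-cleavage prefix is reported as library QC. Signature
filtering is off by default (the signature is evidence of library
quality, not a stated read filter); `strict_signature = TRUE` diverts
failing reads to a separate bin. Only single-end reads are modeled: the
library chemistry sequences the cut-proximal end of each fragment, so
there is exactly one informative end per fragment.

## Assignment of reads to sites

`assign_reads()` assigns each aligned 5' end to the site whose
strand-appropriate expected end is nearest, within a tolerance (default
2 bp, absorbing end-repair raggedness); each read counts toward at most
one site. Exact ties go to the leftmost site (lower motif start) — a
deterministic, documented tie-break that also settles dual-enzyme
collisions. The implementation is a sorted-coordinate binary search
(`findInterval`); the test suite proves it identical to a brute-force
nearest-site scan on 1,000 reads against a 100-site index, tie cases
included. Reads are not deduplicated by default (`dedup = TRUE`
collapses identical `(chrom, strand, five_prime)` tuples for users who
want it).

Duplicate-free site identifiers are assigned in chromosome-name
lexicographic order, then motif start — stable across runs, so
identical inputs produce byte-identical index dumps. Overlapping motif
matches (e.g. `GGGCC` and `GGCCC` inside `GGGCCC`) are distinct sites.
Ambiguous genome bases (`N`) never match any motif code, so assembly
gaps yield no phantom sites.

## Aggregation around features

`metaprofile()` bins signal in 50 bp windows across ±1000 bp around
feature centers (both tunable; the flank must be a bin multiple). A
position at offset $d$ from a center contributes to bin
$\lfloor (d + \mathrm{flank}) / \mathrm{bin} \rfloor$ (left-closed
bins), and the per-bin sum is divided by the number of features.
Overlapping features each receive full contributions — the estimator is
"average signal per feature", not a union coverage. Features are
unstranded by default (peak centers); `flip_minus = TRUE` mirrors
minus-strand features for TSS-style inputs.

Because recognition motifs are distributed non-uniformly, raw
metaprofiles confound accessibility with site density.
`density_counts()` assigns one pseudo-read to every site; running the
identical normalization and aggregation on this table produces the
**RS density baseline** curve against which accessibility profiles are
read. Both curves are emitted unscaled; any rescaling for joint display
is left to the user.

`window_score()` sums RPM within ±200 bp (tunable) of each feature
center, giving the per-feature scalar used for replicate and condition
comparisons.

## Differential analysis

`site_differential()` tests, per site, the 2×2 table (site count vs
remainder of library) × (library A vs B) with a two-sided Fisher's
exact test. The test is exact at low counts and assumes no
distributional model, which suits sparse per-site counts; replicate
dispersion modeling (negative-binomial GLMs) is deliberately out of
scope. P-values are computed by a vectorized hypergeometric summation
(all outcomes with probability ≤ observed, with the standard
$1+10^{-7}$ relative guard), validated in the tests against both
`stats::fisher.test()` and a literal exhaustive summation to
$10^{-10}$. Benjamini–Hochberg correction is applied across tested
sites; sites with zero counts in both libraries carry no evidence and
are excluded (flagged, not silently dropped). Effect sizes are
$\log_2((\mathrm{RPM}_A + c)/(\mathrm{RPM}_B + c))$ with a pseudo-RPM
$c = 1$ used only in the ratio, never in the test.

`featureset_comparison()` compares paired per-feature window scores
between conditions with the Wilcoxon signed-rank test — robust to the
heavy right tail of accessibility scores; an all-zero difference vector
is reported as degenerate with $p = 1$ rather than an error.
`annotate_nearest()` reports the nearest annotation interval and a
signed distance (negative upstream of the interval start), with exact
ties to the leftmost interval.

## The digestion simulator

Every stage above is validated against `generate_library()`, a
ground-truth simulator of the library chemistry:

1. **Genome** — i.i.d. sequence at a chosen GC content (default 0.42,
   mammalian-like), with optional exact motif planting for controlled
   geometries.
2. **Chromatin** — 147 bp nucleosome cores tiled with truncated-normal
   linkers (mean 30 bp, sd 10, min 2 — short linkers typical of ESC
   chromatin; `regular_spacing = TRUE` gives phased arrays). Designated
   nucleosome-free intervals remove overlapping cores; a fraction of
   cores (default 10%) is labeled *variant*, the analog of
   H2A.Z/H3.3-containing nucleosomes.
3. **Cleavage** — per molecule (an independent chromosome copy), each
   site cuts with probability $p = p_0\, w(v)\, a$: $p_0$ is the
   baseline for a fully exposed site (default 0.01, a partial digest),
   $w(v)$ an optional per-motif-variant efficiency weight (the device
   for emulating the elevated GGTCC cleavage efficiency seen with
   Sau96I), and $a$ the accessibility factor — 1 in linkers and NFRs,
   the occlusion factor (default 0.05) under canonical cores, and
   $\min(1, m \times \mathrm{occlusion})$ under variant cores with
   multiplier $m$ (default 5). The occlusion default makes chromatin
   libraries dominated by accessible-region reads, as observed in real
   digests. $m$ is a pipeline-validation device, not a biological claim
   about variant-nucleosome kinetics.
4. **Fragmentation** — fragments run from each cut toward the nearer of
   the neighboring cut (in the same molecule) and a sonication
   breakpoint (truncated normal, mean 200 bp, sd 50 — only the mean is
   constrained by the protocol; the sd is this package's choice of a
   realistic sonicator spread). Fragments outside the 200–350 bp
   size-selection window are discarded. This reproduces the known
   artifact that two cuts closer than the window's lower bound deplete
   each other's recovery in naked-DNA digests.
5. **Sequencing** — each surviving fragment yields one read from its
   cut end: barcode + genomic sequence beginning with the enzyme's
   post-cleavage prefix. Reads are error-free by default; a uniform
   substitution rate is available for robustness tests. Every read
   traces to exactly one cut at one site, and that provenance is the
   ground truth the tests recover.

The simulator emulates digestion, sonication, size selection and
cut-end sequencing; it does **not** model PCR duplicates, GC
amplification bias, sequencing-quality decay, partial-digestion
kinetics beyond per-site Bernoulli cuts, or real nucleosome-positioning
sequence preferences. Passing recovery tests therefore demonstrates the
correctness of the pipeline's bookkeeping and statistics under the
stated generative model, not robustness to every artifact of real
libraries.

## Numerical and design choices

* **Bernoulli digestion at scale** is realized site-by-site
  (`rbinom` over molecules, sampling molecule identities without
  replacement), then fragment bounds are resolved by per-molecule
  neighbor joins — exact with respect to the model, and fast enough
  for $10^6$ molecules over a megabase in seconds.
* **Fisher support enumeration** is grouped across sites into a single
  `dhyper` call; the per-table support is the full hypergeometric range,
  so no approximation enters.
* **Tie-breaks** are everywhere deterministic and leftmost; assignment
  is invariant to read order, and simulation output is byte-identical
  under a fixed seed.
* **Degenerate inputs** fail loudly: empty libraries cannot be
  normalized, empty feature sets cannot be profiled, an empty site
  index has no density baseline, all-zero paired differences are
  flagged. Empty read sets report a *missing* (not zero) signature
  fraction.
* **Problem sizes in the shipped checks** were chosen to exercise the
  stated guarantees at realistic scale: the recovery checks run on a
  1 Mb genome at $10^6$ molecules; null calibration uses $10^4$ sites at
  $5 \times 10^6$ reads per library, deep enough that the exact test's
  discreteness does not dominate the rejection-rate estimate; the
  rank-correlation recovery check crosses chromatin classes with
  per-variant weights, since a model with only a handful of tied
  probability levels mechanically caps the achievable rank correlation
  regardless of depth.

## Worked example

```{r example, eval = FALSE}
library(redseqr)

# simulate a 1 Mb genome and a chromatin digestion library
genome <- simulate_genome(1e6, gc_fraction = 0.42, seed = 1)
index <- build_index(genome, "Sau96I", genome_id = "sim")
model <- chromatin_model(attr(index, "seqlengths"), seed = 2)
config <- sim_config(seed = 3, n_molecules = 1e6, p0 = 0.01)
sim <- generate_library(genome, index,
                        cut_probabilities(index, model, config), config)

# demultiplex and QC the cleavage signature
dm <- demultiplex(sim$fastq, c(sim = "ACGT"), "Sau96I")
dm$report$prefix_match_fraction       # 1.0 for error-free reads

# count cuts per site and normalize
counts <- normalize_rpm(assign_reads(sim$truth, index)$counts)

# accessibility metaprofile vs the site-density baseline
peaks <- feature_set("chr1", seq(24900, 974900, 1e4), seq(25100, 975100, 1e4))
acc <- metaprofile(counts, peaks, flank = 1000, bin = 50, index = index)
dens <- metaprofile(normalize_rpm(density_counts(index)), peaks,
                    flank = 1000, bin = 50, index = index)
```

## Known limitations

* Alignment is external: the package consumes SAM/BAM or read-end BED,
  it does not map reads.
* Peak calling, plotting and gene-model annotation beyond
  nearest-interval lookup are out of scope.
* The nearest-feature annotator materializes a per-chromosome
  query × interval distance matrix; it is meant for annotation-sized
  interval sets (up to a few thousand per chromosome), not for
  genome-scale interval algebra.
* Dual-enzyme mode treats the enzymes as independent cutters; no
  enzyme-enzyme interference is modeled.
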