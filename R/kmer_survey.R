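# Read QC, k-mer spectrum genome survey, and assembly summary statistics.

#' Read-pair quality filter parameters
#'
#' Defaults encode the survey-sequencing cleaning rules: a read fails when
#' it has 10% or more unidentified nucleotides (N), when more than
#' `max_adapter_overlap` of its 3' bases align to the adapter with at most
#' `max_mismatch_fraction` mismatches, or when more than `max_lowq_fraction`
#' of its bases have phred quality below `lowq_phred`. A pair is dropped if
#' either mate fails; with `dedupe`, exact duplicate pairs (putative PCR
#' duplicates) are removed.
#'
#' @param max_n_fraction keep requires N fraction strictly below this.
#' @param max_adapter_overlap bases; adapter overlaps longer than this drop
#'   the read.
#' @param max_mismatch_fraction tolerated mismatch fraction in the adapter
#'   overlap.
#' @param max_lowq_fraction keep requires low-quality base fraction <= this.
#' @param lowq_phred phred threshold defining a low-quality base.
#' @param dedupe remove exact duplicate pairs.
#' @param adapter adapter sequence matched against read 3' ends.
#' @return List of class `read_filter_params`.
#' @export
read_filter_params <- function(max_n_fraction = 0.10,
                               max_adapter_overlap = 10L,
                               max_mismatch_fraction = 0.10,
                               max_lowq_fraction = 0.50, lowq_phred = 5L,
                               dedupe = TRUE,
                               adapter = "AGATCGGAAGAGC") {
  check_fraction(max_n_fraction, "max_n_fraction")
  check_fraction(max_mismatch_fraction, "max_mismatch_fraction")
  check_fraction(max_lowq_fraction, "max_lowq_fraction")
  structure(list(max_n_fraction = max_n_fraction,
                 max_adapter_overlap = as.integer(max_adapter_overlap),
                 max_mismatch_fraction = max_mismatch_fraction,
                 max_lowq_fraction = max_lowq_fraction,
                 lowq_phred = as.integer(lowq_phred), dedupe = dedupe,
                 adapter = toupper(adapter)),
            class = "read_filter_params")
}

fail_n <- function(seqs, max_frac) {
  nfrac <- (nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))) /
    pmax(nchar(seqs), 1L)
  nfrac >= max_frac
}

fail_lowq <- function(quals, max_frac, phred) {
  vapply(quals, function(q) {
    mean(utf8ToInt(q) - 33L < phred) > max_frac
  }, logical(1), USE.NAMES = FALSE)
}

fail_adapter <- function(seqs, params) {
  # Longest 3'-suffix of the read aligning ungapped to the adapter 5' end
  # within the mismatch tolerance; reads exceeding the overlap cap fail.
  subj <- Biostrings::DNAStringSet(seqs)
  trimmed <- Biostrings::trimLRPatterns(
    Rpattern = Biostrings::DNAString(params$adapter), subject = subj,
    max.Rmismatch = params$max_mismatch_fraction, ranges = TRUE)
  overlap <- Biostrings::width(subj) - BiocGenerics::end(trimmed)
  overlap > params$max_adapter_overlap
}

#' Filter paired-end reads
#'
#' @param pairs a `paired_reads` object (see [simulate_reads()]), or a list
#'   with [fastq_reads] elements `r1`, `r2` of equal length.
#' @param params a [read_filter_params()].
#' @return List with `pairs` (clean `paired_reads`) and `counts`: pairs in,
#'   pairs kept, pairs violating each rule (not mutually exclusive), and
#'   duplicates removed.
#' @export
filter_reads <- function(pairs, params = read_filter_params()) {
  r1 <- pairs$r1; r2 <- pairs$r2
  if (length(r1) != length(r2))
    stop2("read 1 and read 2 record counts differ")
  f_n <- fail_n(r1$seq, params$max_n_fraction) |
    fail_n(r2$seq, params$max_n_fraction)
  f_a <- fail_adapter(r1$seq, params) | fail_adapter(r2$seq, params)
  f_q <- fail_lowq(r1$qual, params$max_lowq_fraction, params$lowq_phred) |
    fail_lowq(r2$qual, params$max_lowq_fraction, params$lowq_phred)
  keep <- !(f_n | f_a | f_q)
  n_dup <- 0L
  if (params$dedupe) {
    # count duplicates only among otherwise-kept pairs
    key <- paste(r1$seq, r2$seq, sep = "|")
    dup_kept <- duplicated(key[keep])
    n_dup <- sum(dup_kept)
    keep[keep][dup_kept] <- FALSE
  }
  idx <- which(keep)
  clean <- structure(list(
    r1 = fastq_reads(r1$id[idx], r1$seq[idx], r1$qual[idx]),
    r2 = fastq_reads(r2$id[idx], r2$seq[idx], r2$qual[idx])),
    class = "paired_reads")
  list(pairs = clean,
       counts = list(n_input = length(r1$seq), n_kept = length(idx),
                     n_fail_n = sum(f_n), n_fail_adapter = sum(f_a),
                     n_fail_lowq = sum(f_q), n_duplicates_removed = n_dup))
}

#' Count canonical k-mers into a depth histogram
#'
#' K-mers are counted strand-collapsed (the lexicographic minimum of the
#' k-mer and its reverse complement under 2-bit encoding); k-mers containing
#' an N are skipped.
#'
#' @param reads a `paired_reads` object, [fastq_reads], character vector of
#'   sequences, or `DNAStringSet`.
#' @param k k-mer size (default 25; must not exceed the longest read).
#' @return Object of class `kmer_histogram`: list with `k`, `counts`
#'   (data.frame `depth`, `count` = number of distinct k-mers at that
#'   depth) and `kmer_num` = total k-mer occurrences
#'   (`sum(depth * count)`).
#' @export
kmer_histogram <- function(reads, k = 25L) {
  seqs <- if (inherits(reads, "paired_reads")) c(reads$r1$seq, reads$r2$seq)
  else if (inherits(reads, "fastq_reads")) reads$seq
  else if (is(reads, "DNAStringSet")) as.character(reads)
  else as.character(reads)
  if (!length(seqs)) stop2("no reads supplied")
  if (k < 1L) stop2("k must be >= 1")
  if (k > max(nchar(seqs)))
    stop2("k (", k, ") exceeds the longest read (", max(nchar(seqs)), ")")
  df <- .kmer_hist_cpp(seqs, as.integer(k))
  as_kmer_histogram(df, k)
}

#' Assemble a k-mer histogram object from a depth/count table
#'
#' @param counts data.frame with columns `depth` and `count`.
#' @param k the k-mer size the table was computed with.
#' @rdname kmer_histogram
#' @export
as_kmer_histogram <- function(counts, k) {
  stopifnot(all(c("depth", "count") %in% names(counts)))
  counts <- counts[order(counts$depth), c("depth", "count")]
  rownames(counts) <- NULL
  structure(list(k = as.integer(k), counts = counts,
                 kmer_num = sum(as.numeric(counts$depth) * counts$count)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("kmer_histogram: k =", x$k, ", kmer_num =", format(x$kmer_num),
      ", depths", min(x$counts$depth), "-", max(x$counts$depth), "\n")
  invisible(x)
}

# Error-region boundary and coverage peak. The error spike decays from
# depth 1; the boundary is the first depth where the count stops
# decreasing, and the peak is the maximum beyond it.
find_peak <- function(hist) {
  d_max <- max(hist$counts$depth)
  full <- numeric(d_max)
  full[hist$counts$depth] <- hist$counts$count
  if (d_max < 2L) stop2("no coverage peak: histogram is degenerate")
  inc <- which(diff(full) > 0)
  if (!length(inc)) stop2("no coverage peak: histogram decreases monotonically")
  valley <- inc[1L]
  peak <- valley + which.max(full[(valley + 1L):d_max])
  list(valley = valley, peak_depth = peak, full = full)
}

#' Estimate genome size from a k-mer histogram
#'
#' `genome size = k-mer num / peak depth`, with the peak taken as the modal
#' depth beyond the error region (first local minimum from depth 1).
#'
#' @param hist a [kmer_histogram()].
#' @return List with `genome_size_estimate` (bases), `peak_depth`,
#'   `error_boundary`, `kmer_num`.
#' @export
estimate_genome_size <- function(hist) {
  stopifnot(inherits(hist, "kmer_histogram"))
  pk <- find_peak(hist)
  list(genome_size_estimate = hist$kmer_num / pk$peak_depth,
       peak_depth = pk$peak_depth, error_boundary = pk$valley,
       kmer_num = hist$kmer_num)
}

#' Heuristic heterozygosity and repeat-content estimates
#'
#' Heterozygous k-mers accumulate in a subpeak near half the main peak
#' depth: the distinct-k-mer mass inside `het_window * peak` over the total
#' non-error distinct mass approximates `2k` times the per-base
#' heterozygosity. Repetitive content shows up beyond `repeat_mult * peak`:
#' its occurrence mass (depth x count) over the total non-error occurrence
#' mass approximates the repetitive genome fraction. Both windows are
#' heuristics and configurable; treat results as rough survey figures.
#'
#' @param hist a [kmer_histogram()].
#' @param het_window multiples of the peak bounding the heterozygous
#'   subpeak (default `c(0.4, 0.6)`).
#' @param repeat_mult depth multiple of the peak beyond which k-mers are
#'   counted repetitive (default 1.8).
#' @return List with `het_rate` and `repeat_fraction`.
#' @export
estimate_het_repeat <- function(hist, het_window = c(0.4, 0.6),
                                repeat_mult = 1.8) {
  stopifnot(inherits(hist, "kmer_histogram"))
  pk <- find_peak(hist)
  d <- seq_along(pk$full)
  nonerr <- d > pk$valley
  lo <- het_window[1L] * pk$peak_depth
  hi <- het_window[2L] * pk$peak_depth
  het_mass <- sum(pk$full[nonerr & d >= lo & d <= hi])
  tot_distinct <- sum(pk$full[nonerr])
  het_rate <- if (tot_distinct > 0)
    (het_mass / tot_distinct) / (2 * hist$k) else 0
  occ <- pk$full * d
  rep_mass <- sum(occ[nonerr & d > repeat_mult * pk$peak_depth])
  tot_occ <- sum(occ[nonerr])
  repeat_fraction <- if (tot_occ > 0) rep_mass / tot_occ else 0
  list(het_rate = het_rate, repeat_fraction = repeat_fraction,
       peak_depth = pk$peak_depth)
}

#' Assembly summary statistics
#'
#' N50/N90, counts above length thresholds, base composition and GC
#' content. GC is computed over called bases only:
#' `(C + G) / (A + C + G + T) * 100`.
#'
#' @param x `DNAStringSet`, named character vector, or path to a FASTA file.
#' @param thresholds length thresholds (bases) to count sequences at.
#' @return List of class `assembly_stats`.
#' @export
assembly_stats <- function(x, thresholds = c(500L, 1000L, 10000L)) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- read_fasta(x)
  if (!is(x, "DNAStringSet"))
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  if (length(x) == 0L) stop2("no sequences")
  len <- Biostrings::width(x)
  nx <- function(q) {
    sl <- sort(len, decreasing = TRUE)
    sl[which(cumsum(as.numeric(sl)) >= q * sum(as.numeric(sl)))[1L]]
  }
  af <- colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T", "N"),
                                                 drop = FALSE])
  acgt <- sum(af[c("A", "C", "G", "T")])
  structure(list(
    n50 = nx(0.5), n90 = nx(0.9), total_size = sum(as.numeric(len)),
    total_number = length(x),
    counts_at_threshold = vapply(thresholds,
                                 function(t) sum(len >= t), integer(1)),
    thresholds = thresholds,
    base_counts = af,
    gc_content = unname(100 * sum(af[c("C", "G")]) / acgt)),
    class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("assembly:", x$total_number, "sequences,", format(x$total_size),
      "bp; N50", x$n50, "; N90", x$n90, "; GC",
      sprintf("%.2f%%", x$gc_content), "\n")
  invisible(x)
}

#' Per-library sequencing depth
#'
#' `depth = clean_length / genome_size`, reported to two decimals; both in
#' the same unit (e.g. Gb).
#'
#' @param clean_length clean yield (vectorized).
#' @param genome_size estimated genome size (> 0).
#' @return Numeric vector of fold-coverages rounded to 2 decimals.
#' @export
library_depth <- function(clean_length, genome_size) {
  if (any(genome_size <= 0)) stop2("genome_size must be > 0")
  round(clean_length / genome_size, 2)
}

#' Write a k-mer histogram as two-column TSV
#'
#' @param hist a [kmer_histogram()].
#' @param path output path.
#' @export
write_kmer_tsv <- function(hist, path) {
  write_tsv(hist$counts, path,
            comment = sprintf("k-mer depth histogram, k = %d", hist$k))
}
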