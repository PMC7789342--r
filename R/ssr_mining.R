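# SSR mining: perfect microsatellite detection, motif canonicalization, and
# assembly-level summaries.

#' Default minimum repeat numbers per motif length
#'
#' MISA-style thresholds: mononucleotide runs need at least 8 repeats,
#' di- through hexanucleotide motifs at least 5.
#'
#' @param mono,di,tri,tetra,penta,hexa minimum repeat counts (all >= 2).
#' @return Named integer vector of length 6 (names "1".."6").
#' @export
ssr_thresholds <- function(mono = 8L, di = 5L, tri = 5L, tetra = 5L,
                           penta = 5L, hexa = 5L) {
  thr <- c(`1` = mono, `2` = di, `3` = tri, `4` = tetra, `5` = penta,
           `6` = hexa)
  if (any(thr < 2L)) stop2("all SSR repeat thresholds must be >= 2")
  storage.mode(thr) <- "integer"
  thr
}

rotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n) - 1L, function(i)
    paste0(substr(m, i + 1L, n), substr(m, 1L, i)), character(1))
}

# A motif is primitive if it is not a whole number of copies of a shorter one.
is_primitive_motif <- function(m) {
  n <- nchar(m)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L && strrep(substr(m, 1L, d), n %/% d) == m) return(FALSE)
  }
  TRUE
}

#' Canonical motif class of an SSR motif
#'
#' Motifs that are cyclic rotations of one another, or rotations of each
#' other's reverse complement, describe the same repeat and are collapsed
#' into one class. The class representative is the lexicographically
#' smallest rotation over the motif and its reverse complement, except that
#' when the class contains a rotation equal to its own reverse complement
#' (e.g. CATG) the smallest such palindromic rotation is preferred, so the
#' class label renders as "CATG/CATG" rather than splitting the palindrome.
#' The label is `"representative/revcomp(representative)"`.
#'
#' @param motif character vector of primitive motifs over A/C/G/T, length 1-6.
#' @return Character vector of class labels, e.g. `"AG/CT"`, `"A/T"`.
#' @examples
#' canonical_motif(c("GA", "T", "CATG"))
#' @export
canonical_motif <- function(motif) {
  vapply(toupper(motif), function(m) {
    if (!grepl("^[ACGT]{1,6}$", m))
      stop2("motif must be 1-6 bases over A/C/G/T: ", m)
    if (!is_primitive_motif(m))
      stop2("motif is not primitive: ", m)
    cand <- unique(c(rotations(m), rotations(revcomp(m))))
    pal <- cand[cand == revcomp(cand)]
    rep <- if (length(pal)) min(pal) else min(cand)
    paste0(rep, "/", revcomp(rep))
  }, character(1), USE.NAMES = FALSE)
}

#' Detect perfect SSRs in DNA sequences
#'
#' Finds maximal non-extendable perfect runs of primitive 1-6 nt motifs that
#' meet the per-motif-length repeat thresholds. Runs are reported once under
#' their primitive motif in its leftmost phase; partial trailing motif copies
#' are not counted. Runs never span an N.
#'
#' @param x a `DNAStringSet`, named character vector of sequences, or a
#'   single character string.
#' @param thresholds named vector from [ssr_thresholds()].
#' @return A data.frame with columns `scaffold`, `start`, `end` (1-based
#'   inclusive), `motif`, `canonical_class`, `repeats`, `length`.
#' @export
detect_ssrs <- function(x, thresholds = ssr_thresholds()) {
  if (is(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else {
    seqs <- toupper(x)
    names(seqs) <- names(x)
  }
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  out <- vector("list", length(seqs) * 6L)
  ii <- 0L
  for (s in seq_along(seqs)) {
    sq <- seqs[[s]]
    for (m in 1:6) {
      thr <- thresholds[[as.character(m)]]
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", m, thr - 1L)
      hits <- gregexpr(pat, sq, perl = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      starts <- as.integer(hits)
      lens <- attr(hits, "match.length")
      motifs <- substring(sq, starts, starts + m - 1L)
      keep <- vapply(motifs, is_primitive_motif, logical(1))
      if (!any(keep)) next
      starts <- starts[keep]; lens <- lens[keep]; motifs <- motifs[keep]
      reps <- lens %/% m
      ii <- ii + 1L
      out[[ii]] <- data.frame(
        scaffold = names(seqs)[s], start = starts,
        end = starts + reps * m - 1L, motif = motifs,
        canonical_class = canonical_motif(motifs), repeats = reps,
        length = reps * m, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (ii == 0L)
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), motif = character(),
                      canonical_class = character(), repeats = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(ii)])
  res <- res[order(match(res$scaffold, names(seqs)), res$start, res$end), ]
  rownames(res) <- NULL
  res
}

#' Summarize detected SSRs by motif class and repeat number
#'
#' Produces the assembly-level motif statistics: counts and percentage
#' ratios per motif-length class (mono- through hexanucleotide) with
#' accumulated ratios, a canonical-class by repeat-number contingency table
#' (repeat numbers binned 5..20 and ">20"), and scaffold-level counts.
#'
#' @param loci data.frame from [detect_ssrs()].
#' @param n_scaffolds total number of scaffolds in the assembly (for
#'   percentages of scaffolds carrying SSRs).
#' @return A list of class `motif_summary` with elements `by_length`
#'   (Motif, Number, Ratio, AccumRatio), `by_repeat` (class x repeat-bin
#'   matrix), `total`, `scaffolds_with_ssr`, `single_ssr_scaffolds`.
#' @export
summarize_ssrs <- function(loci, n_scaffolds = NA_integer_) {
  classes <- c("Mono-nucleotide", "Di-nucleotide", "Tri-nucleotide",
               "Tetra-nucleotide", "Penta-nucleotide", "Hexa-nucleotide")
  mlen <- nchar(loci$motif)
  cnt <- vapply(1:6, function(m) sum(mlen == m), integer(1))
  tot <- sum(cnt)
  ratio <- if (tot > 0) 100 * cnt / tot else rep(0, 6)
  by_length <- data.frame(Motif = classes, Number = cnt,
                          Ratio = round(ratio, 2),
                          AccumRatio = round(cumsum(ratio), 2),
                          stringsAsFactors = FALSE)
  bins <- c(as.character(5:20), ">20")
  bin_of <- ifelse(loci$repeats > 20, ">20", as.character(loci$repeats))
  bin_of[loci$repeats < 5] <- NA  # mononucleotide minimum is 8 anyway
  by_repeat <- table(factor(loci$canonical_class),
                     factor(bin_of, levels = bins))
  per_scaf <- table(loci$scaffold)
  structure(list(by_length = by_length, by_repeat = by_repeat, total = tot,
                 n_scaffolds = n_scaffolds,
                 scaffolds_with_ssr = length(per_scaf),
                 single_ssr_scaffolds = sum(per_scaf == 1L)),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("SSR motif summary:", x$total, "SSRs on", x$scaffolds_with_ssr,
      "scaffolds\n")
  print(x$by_length, row.names = FALSE)
  invisible(x)
}

#' Scaffolds carrying a unique single-locus SSR
#'
#' A scaffold qualifies when it contains exactly one detected SSR and the
#' flanking context of that SSR (`flank` bases on each side) occurs at
#' exactly one site in the whole assembly, counting exact matches of the
#' flank and of its reverse complement. Scaffolds whose SSR sits closer
#' than `flank` bases to a scaffold edge are excluded (the context is not
#' assessable).
#'
#' @param loci data.frame from [detect_ssrs()] computed on `assembly`.
#' @param assembly `DNAStringSet` (or named character vector).
#' @param flank flank width in bases (default 100).
#' @return Character vector of qualifying scaffold names.
#' @export
single_ssr_scaffolds <- function(loci, assembly, flank = 100L) {
  if (!is(assembly, "DNAStringSet")) {
    nms <- names(assembly)
    assembly <- Biostrings::DNAStringSet(toupper(as.character(assembly)))
    names(assembly) <- nms
  }
  per_scaf <- table(loci$scaffold)
  singles <- names(per_scaf)[per_scaf == 1L]
  keep <- character(0)
  for (sc in singles) {
    row <- loci[loci$scaffold == sc, ]
    L <- Biostrings::width(assembly[sc])
    if (row$start - flank < 1L || row$end + flank > L) next
    lf <- substr(as.character(assembly[[sc]]), row$start - flank,
                 row$start - 1L)
    rf <- substr(as.character(assembly[[sc]]), row$end + 1L, row$end + flank)
    ok <- TRUE
    for (fl in c(lf, rf)) {
      n_fwd <- sum(Biostrings::vcountPattern(fl, assembly))
      n_rev <- sum(Biostrings::vcountPattern(revcomp(fl), assembly))
      if (n_fwd + n_rev != 1L) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, sc)
  }
  keep
}

#' Write an SSR locus table as TSV
#'
#' @param loci data.frame from [detect_ssrs()].
#' @param path output path.
#' @export
write_ssr_tsv <- function(loci, path) {
  write_tsv(loci, path,
            comment = "perfect SSR loci; coordinates 1-based inclusive")
}
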