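# Primer candidate design around SSRs and in-silico PCR classification.

#' Primer design constraints
#'
#' Defaults mirror common SSR marker design settings: 18-27 bp primers,
#' melting temperature 55-65 degrees C, GC 30-70%, product 100-300 bp.
#' A homopolymer-run cap (> `max_homopolymer` identical bases rejects the
#' candidate) guards against slippage-prone oligos.
#'
#' @param size_range,tm_range,gc_range,product_range numeric `c(min, max)`.
#' @param max_homopolymer longest tolerated homopolymer run in a primer.
#' @return List of class `primer_constraints`.
#' @export
primer_constraints <- function(size_range = c(18L, 27L),
                               tm_range = c(55, 65),
                               gc_range = c(30, 70),
                               product_range = c(100L, 300L),
                               max_homopolymer = 4L) {
  for (r in list(size_range, tm_range, gc_range, product_range))
    if (length(r) != 2L || r[1L] > r[2L])
      stop2("every constraint range must be c(min, max) with min <= max")
  structure(list(size_range = size_range, tm_range = tm_range,
                 gc_range = gc_range, product_range = product_range,
                 max_homopolymer = as.integer(max_homopolymer)),
            class = "primer_constraints")
}

# SantaLucia (1998) unified nearest-neighbor parameters.
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Nearest-neighbor oligo melting temperature
#'
#' Unified nearest-neighbor thermodynamics with entropy-based monovalent
#' salt correction (`0.368 * (n - 1) * ln[Na+]`), for non-self-complementary
#' oligos at concentration `conc_nm` against `Tm = dH / (dS + R ln(C/4))`.
#'
#' @param seq character vector of primer sequences (5'->3').
#' @param conc_nm oligo concentration in nM (default 50).
#' @param na_mm monovalent cation concentration in mM (default 50).
#' @return Melting temperatures in degrees C.
#' @export
primer_tm <- function(seq, conc_nm = 50, na_mm = 50) {
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    if (n < 2L) stop2("primer too short for nearest-neighbor Tm")
    steps <- substring(s, 1:(n - 1L), 2:n)
    dh <- sum(.nn_dh[steps])
    ds <- sum(.nn_ds[steps])
    for (term in c(substr(s, 1L, 1L), substr(s, n, n))) {
      if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1L) * log(na_mm / 1000)
    tm_k <- dh * 1000 / (ds + 1.9872 * log(conc_nm * 1e-9 / 4))
    tm_k - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

gc_percent <- function(seq) {
  seq <- toupper(seq)
  100 * (nchar(gsub("[^GC]", "", seq))) / nchar(seq)
}

max_homopolymer_run <- function(seq) {
  vapply(strsplit(toupper(seq), "", fixed = TRUE), function(ch) {
    if (!length(ch)) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}

#' Design primer pair candidates flanking an SSR
#'
#' Enumerates all (start, size) windows in the flanks compatible with the
#' product range, filters both primers on size, GC, Tm and homopolymer
#' constraints, then ranks surviving pairs by Tm balance (`|Tm_f - Tm_r|`),
#' then by closeness of the product length to the product-range midpoint,
#' with ties broken by leftmost forward position.
#'
#' @param scaffold_seq the template sequence (character or `DNAString`).
#' @param ssr one row of a [detect_ssrs()] table (needs `start`, `end`; a
#'   list with those elements also works).
#' @param constraints a [primer_constraints()].
#' @param n_candidates maximum number of ranked pairs to return.
#' @param tm_args list of arguments forwarded to [primer_tm()].
#' @return data.frame of class `primer_pairs` with columns `forward`,
#'   `reverse` (5'->3' on the opposite strand), `tm_f`, `tm_r`, `gc_f`,
#'   `gc_r`, `fwd_start`, `rev_end`, `product_length`. Zero rows when no
#'   candidate satisfies the constraints.
#' @export
design_primers <- function(scaffold_seq, ssr,
                           constraints = primer_constraints(),
                           n_candidates = 3L, tm_args = list()) {
  s <- toupper(as.character(scaffold_seq))
  L <- nchar(s)
  cs <- constraints
  smin <- cs$size_range[1L]; smax <- cs$size_range[2L]
  pmax_ <- cs$product_range[2L]; pmin_ <- cs$product_range[1L]
  empty <- data.frame(forward = character(), reverse = character(),
                      tm_f = numeric(), tm_r = numeric(), gc_f = numeric(),
                      gc_r = numeric(), fwd_start = integer(),
                      rev_end = integer(), product_length = integer(),
                      stringsAsFactors = FALSE)
  cand_side <- function(lo, hi) {
    # all windows [a, a+w-1] within [lo, hi]
    out <- list()
    for (w in smin:smax) {
      a <- seq.int(lo, hi - w + 1L)
      a <- a[a >= 1L]
      if (!length(a)) next
      out[[length(out) + 1L]] <- data.frame(start = a, end = a + w - 1L)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  flo <- max(1L, ssr$start - (pmax_ - (ssr$end - ssr$start + 1L)))
  fwd <- cand_side(flo, ssr$start - 1L)
  rev <- cand_side(ssr$end + 1L, min(L, ssr$end + pmax_))
  if (is.null(fwd) || is.null(rev)) return(structure(empty,
                                                     class = c("primer_pairs", "data.frame")))
  screen <- function(df, seqs) {
    gc <- gc_percent(seqs)
    hp <- max_homopolymer_run(seqs)
    ok <- gc >= cs$gc_range[1L] & gc <= cs$gc_range[2L] &
      hp <= cs$max_homopolymer
    df <- df[ok, , drop = FALSE]; seqs <- seqs[ok]; gc <- gc[ok]
    if (!nrow(df)) return(NULL)
    tm <- do.call(primer_tm, c(list(seqs), tm_args))
    ok <- tm >= cs$tm_range[1L] & tm <= cs$tm_range[2L]
    cbind(df[ok, , drop = FALSE],
          data.frame(seq = seqs[ok], gc = gc[ok], tm = tm[ok],
                     stringsAsFactors = FALSE))
  }
  fwd <- screen(fwd, substring(s, fwd$start, fwd$end))
  rev <- screen(rev, revcomp(substring(s, rev$start, rev$end)))
  if (is.null(fwd) || is.null(rev) || !nrow(fwd) || !nrow(rev))
    return(structure(empty, class = c("primer_pairs", "data.frame")))
  # pair under the product constraint
  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  prod_len <- rev$end[grid$r] - fwd$start[grid$f] + 1L
  ok <- prod_len >= pmin_ & prod_len <= pmax_
  grid <- grid[ok, , drop = FALSE]; prod_len <- prod_len[ok]
  if (!nrow(grid))
    return(structure(empty, class = c("primer_pairs", "data.frame")))
  dt <- abs(fwd$tm[grid$f] - rev$tm[grid$r])
  mid <- mean(cs$product_range)
  ord <- order(dt, abs(prod_len - mid), fwd$start[grid$f])
  pick <- head(ord, n_candidates)
  out <- data.frame(
    forward = fwd$seq[grid$f[pick]], reverse = rev$seq[grid$r[pick]],
    tm_f = fwd$tm[grid$f[pick]], tm_r = rev$tm[grid$r[pick]],
    gc_f = fwd$gc[grid$f[pick]], gc_r = rev$gc[grid$r[pick]],
    fwd_start = fwd$start[grid$f[pick]], rev_end = rev$end[grid$r[pick]],
    product_length = prod_len[pick], stringsAsFactors = FALSE)
  structure(out, class = c("primer_pairs", "data.frame"))
}

match_sites <- function(primer, subject, max_mismatches, anchor,
                        anchor_end = c("right", "left")) {
  # Occurrences of `primer` on the forward strand of `subject` with at most
  # max_mismatches, requiring the `anchor` bases at the primer 3' end
  # (right for a forward-oriented site, left for a reverse-oriented site)
  # to match exactly. Degenerate template bases never match (fixed = TRUE).
  anchor_end <- match.arg(anchor_end)
  m <- Biostrings::matchPattern(primer, subject,
                                max.mismatch = max_mismatches, fixed = TRUE)
  if (length(m) == 0L) return(data.frame(start = integer(), end = integer(),
                                         mismatches = integer()))
  st <- Biostrings::start(m); en <- Biostrings::end(m)
  keep <- st >= 1L & en <= length(subject)
  st <- st[keep]; en <- en[keep]
  if (!length(st)) return(data.frame(start = integer(), end = integer(),
                                     mismatches = integer()))
  pat <- strsplit(as.character(primer), "")[[1L]]
  n <- length(pat)
  mm <- integer(length(st)); ok <- logical(length(st))
  subj_chr <- as.character(subject)
  for (i in seq_along(st)) {
    site <- strsplit(substr(subj_chr, st[i], en[i]), "")[[1L]]
    d <- site != pat
    mm[i] <- sum(d)
    anchor_idx <- if (anchor_end == "right") (n - anchor + 1L):n
    else 1L:anchor
    ok[i] <- mm[i] <= max_mismatches && !any(d[anchor_idx])
  }
  data.frame(start = st[ok], end = en[ok], mismatches = mm[ok])
}

#' In-silico PCR of a primer pair against an assembly
#'
#' Finds every site where the two primers bind opposite strands with their
#' 3' ends converging, each with at most `max_mismatches` mismatches and an
#' exact match over the 3'-terminal `anchor` bases, producing a product no
#' longer than `product_cap`. Both primer-role orientations are searched.
#'
#' @param pair one row of a [design_primers()] result (or list with
#'   `forward`, `reverse`).
#' @param assembly `DNAStringSet` or named character vector.
#' @param max_mismatches per-primer mismatch allowance (default 0, the
#'   strictest mapping rule).
#' @param product_cap longest product considered amplifiable (default 1000).
#' @param anchor number of 3'-terminal bases that must match exactly.
#' @return data.frame with `scaffold`, `start`, `end`, `product_length`,
#'   `mm_forward`, `mm_reverse` (one row per amplicon).
#' @export
in_silico_pcr <- function(pair, assembly, max_mismatches = 0L,
                          product_cap = 1000L, anchor = 3L) {
  if (!is(assembly, "DNAStringSet")) {
    nms <- names(assembly)
    assembly <- Biostrings::DNAStringSet(toupper(as.character(assembly)))
    names(assembly) <- nms
  }
  if (is.null(names(assembly)))
    names(assembly) <- sprintf("seq%03d", seq_along(assembly))
  fwd <- toupper(pair$forward); rev <- toupper(pair$reverse)
  hits <- list()
  layout <- function(p_left, p_right, subj, scaf, mm_names) {
    # p_left binds the forward strand (3' end rightwards); p_right given
    # 5'->3' on the reverse strand, so its forward-strand site is
    # revcomp(p_right) with the primer 3' end at the site's left edge.
    lf <- match_sites(Biostrings::DNAString(p_left), subj, max_mismatches,
                      anchor, "right")
    if (!nrow(lf)) return(NULL)
    rt <- match_sites(Biostrings::DNAString(revcomp(p_right)), subj,
                      max_mismatches, anchor, "left")
    if (!nrow(rt)) return(NULL)
    out <- list()
    for (i in seq_len(nrow(lf))) {
      ok <- rt$start > lf$end[i] & rt$end - lf$start[i] + 1L <= product_cap
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        scaffold = scaf, start = lf$start[i], end = rt$end[ok],
        product_length = rt$end[ok] - lf$start[i] + 1L,
        mm_left = lf$mismatches[i], mm_right = rt$mismatches[ok],
        stringsAsFactors = FALSE)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  for (sc in names(assembly)) {
    subj <- assembly[[sc]]
    h1 <- layout(fwd, rev, subj, sc)
    if (!is.null(h1)) {
      names(h1)[names(h1) == "mm_left"] <- "mm_forward"
      names(h1)[names(h1) == "mm_right"] <- "mm_reverse"
      hits[[length(hits) + 1L]] <- h1
    }
    h2 <- layout(rev, fwd, subj, sc)
    if (!is.null(h2)) {
      names(h2)[names(h2) == "mm_left"] <- "mm_reverse"
      names(h2)[names(h2) == "mm_right"] <- "mm_forward"
      hits[[length(hits) + 1L]] <-
        h2[, c("scaffold", "start", "end", "product_length", "mm_forward",
               "mm_reverse")]
    }
  }
  if (!length(hits))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), product_length = integer(),
                      mm_forward = integer(), mm_reverse = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, hits)
  res <- res[!duplicated(res[, c("scaffold", "start", "end")]), ]
  res <- res[order(res$scaffold, res$start, res$end), ]
  rownames(res) <- NULL
  res
}

#' Classify a marker from its in-silico amplification sites
#'
#' @param hits data.frame from [in_silico_pcr()].
#' @return List with `verdict` (`"single"`, `"multi"` or `"none"`) and
#'   `n_sites`.
#' @export
classify_in_silico <- function(hits) {
  n <- nrow(hits)
  verdict <- if (n == 0L) "none" else if (n == 1L) "single" else "multi"
  list(verdict = verdict, n_sites = n)
}

#' Classify a marker from gel band counts
#'
#' The gel rule for diploids: a polymorphic primer whose maximum band count
#' over accessions is at most 2 is a single-locus marker; more than 2 bands
#' with polymorphism marks a multi-locus marker; monomorphic primers are
#' discarded.
#'
#' @param band_counts integer vector of amplified band counts per accession.
#' @param polymorphic logical flag, whether the primer is polymorphic
#'   across accessions.
#' @return List with `verdict` (`"single"`, `"multi"`, `"discarded"`),
#'   `max_bands`, `polymorphic`.
#' @export
classify_by_bands <- function(band_counts, polymorphic) {
  if (any(band_counts < 0L)) stop2("band counts must be >= 0")
  mx <- max(band_counts)
  verdict <- if (!polymorphic) "discarded"
  else if (mx <= 2L) "single" else "multi"
  list(verdict = verdict, max_bands = mx, polymorphic = polymorphic)
}
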