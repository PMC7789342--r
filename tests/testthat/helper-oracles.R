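# Independent oracles used to cross-check the implementation by a different
# algorithmic route.

# Maximal perfect repeats via the period-comparison vector s[t] == s[t + m]
# (no regex): an eq-run [i, j] marks a region [i, j + m] periodic with
# period m; full motif copies are counted and non-primitive motifs skipped.
oracle_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(ch)
  acgt <- ch %in% c("A", "C", "G", "T")
  out <- list()
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    if (n < m * thr) next
    idx <- 1:(n - m)
    eq <- ch[idx] == ch[idx + m] & acgt[idx] & acgt[idx + m]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (i in seq_along(r$lengths)) {
      if (!r$values[i]) next
      start <- pos[i]
      reps <- (r$lengths[i] + m) %/% m
      if (reps < thr) next
      motif <- paste(ch[start:(start + m - 1L)], collapse = "")
      if (!ssrpipe:::is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        start = start, end = start + reps * m - 1L, motif = motif,
        repeats = reps, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), repeats = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# N50/N90 by explicit cumulative scan over sorted lengths.
oracle_nx <- function(lens, q) {
  sl <- sort(lens, decreasing = TRUE)
  cum <- cumsum(as.numeric(sl))
  sl[which(cum >= q * sum(as.numeric(sl)))[1L]]
}

# AMOVA sums of squares via centroids in allele-count space (complete data
# only): squared genotype distances are half squared Euclidean distances of
# allele-count vectors, so SS can be computed from deviations directly.
oracle_amova_ss <- function(gt, grp) {
  alleles <- sort(unique(unlist(strsplit(as.vector(gt), "/", fixed = TRUE))))
  embed <- function(call) {
    a <- strsplit(call, "/", fixed = TRUE)[[1L]]
    vapply(alleles, function(x) sum(a == x), numeric(1))
  }
  Y <- t(apply(gt, 1L, function(row) unlist(lapply(row, embed)))) / sqrt(2)
  centroid <- colMeans(Y)
  ssw <- 0
  ssa <- 0
  for (g in unique(grp)) {
    yg <- Y[grp == g, , drop = FALSE]
    cg <- colMeans(yg)
    ssw <- ssw + sum(sweep(yg, 2L, cg)^2)
    ssa <- ssa + nrow(yg) * sum((cg - centroid)^2)
  }
  list(ss_among = ssa, ss_within = ssw)
}

# Random DNA string.
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

# Brute-force exact e-PCR at zero mismatches: substring positions of the
# forward primer and of the reverse primer's reverse complement.
oracle_epcr0 <- function(fwd, rev, seqs, product_cap = 1000L) {
  hits <- list()
  find_all <- function(p, s) {
    out <- integer(0); from <- 1L
    repeat {
      i <- regexpr(p, substr(s, from, nchar(s)), fixed = TRUE)
      if (i == -1L) break
      out <- c(out, from + i - 1L)
      from <- from + i
    }
    out
  }
  rc <- ssrpipe:::revcomp
  for (sc in names(seqs)) {
    s <- seqs[[sc]]
    for (pr in list(c(fwd, rev), c(rev, fwd))) {
      fs <- find_all(pr[1L], s)
      rs <- find_all(rc(pr[2L]), s)
      for (f in fs) for (r in rs) {
        end <- r + nchar(pr[2L]) - 1L
        if (r > f + nchar(pr[1L]) - 1L && end - f + 1L <= product_cap)
          hits[[length(hits) + 1L]] <- data.frame(
            scaffold = sc, start = f, end = end, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer()))
  res <- unique(do.call(rbind, hits))
  res[order(res$scaffold, res$start, res$end), , drop = FALSE]
}

# Small worked-example genotype panel: 27 accessions in three groups
# (8, 6, 13), loci constructed so per-group polymorphism percentages are
# exactly 90 / 60 / 100.
worked_panel <- function() {
  n <- c(8L, 6L, 13L)
  grp <- rep(c("MGL", "SI", "QTP"), n)
  acc <- sprintf("acc%02d", seq_len(sum(n)))
  gt <- matrix("1/1", sum(n), 10L,
               dimnames = list(acc, sprintf("L%02d", 1:10)))
  poly_in <- list(MGL = 1:9, SI = 1:6, QTP = 1:10)
  for (g in names(poly_in)) {
    rows <- which(grp == g)
    gt[rows[1L], poly_in[[g]]] <- "1/2"
  }
  list(genotypes = gt,
       groups = data.frame(accession = acc, group = grp,
                           stringsAsFactors = FALSE))
}
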