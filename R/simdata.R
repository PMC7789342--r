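# Synthetic data generators with exact ground truth: genomes with planted
# SSRs, paired-end reads, and structured diploid genotype / band panels.

#' Specification of a synthetic genome with planted SSRs
#'
#' @param n_scaffolds number of background scaffolds.
#' @param scaffold_length length of each scaffold in bases (scalar or vector).
#' @param gc_fraction background GC proportion in \[0, 1\].
#' @param planted_ssrs data.frame with columns `motif` (1-6 nt), `repeats`,
#'   `scaffold` (index), and optionally `pos` (1-based start; `NA` = place
#'   randomly with a 150 bp margin from scaffold ends). Planted intervals
#'   must not overlap and must fit their scaffold.
#' @param duplication_fraction proportion of scaffolds copied verbatim
#'   (creates multi-locus sites).
#' @param seed integer RNG seed; the generator is a pure function of it.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_scaffolds, scaffold_length, gc_fraction = 0.44,
                        planted_ssrs = NULL, duplication_fraction = 0,
                        seed = 1L) {
  check_fraction(gc_fraction, "gc_fraction")
  check_fraction(duplication_fraction, "duplication_fraction")
  stopifnot(n_scaffolds >= 1, all(scaffold_length >= 1))
  len <- rep_len(as.integer(scaffold_length), n_scaffolds)
  if (!is.null(planted_ssrs) && nrow(planted_ssrs)) {
    p <- planted_ssrs
    if (is.null(p$pos)) p$pos <- NA_integer_
    stopifnot(all(nchar(p$motif) >= 1), all(nchar(p$motif) <= 6),
              all(p$repeats >= 1), all(p$scaffold >= 1),
              all(p$scaffold <= n_scaffolds))
    too_long <- nchar(p$motif) * p$repeats > len[p$scaffold]
    if (any(too_long))
      stop2("planted SSR longer than its scaffold (row ",
            which(too_long)[1L], ")")
    fixed <- !is.na(p$pos)
    if (any(fixed)) {
      ends <- p$pos[fixed] + nchar(p$motif[fixed]) * p$repeats[fixed] - 1L
      if (any(p$pos[fixed] < 1L) || any(ends > len[p$scaffold[fixed]]))
        stop2("planted SSR position does not fit within its scaffold")
      for (sc in unique(p$scaffold[fixed])) {
        i <- fixed & p$scaffold == sc
        iv <- cbind(p$pos[i], p$pos[i] + nchar(p$motif[i]) * p$repeats[i] - 1L)
        iv <- iv[order(iv[, 1L]), , drop = FALSE]
        if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
          stop2("planted SSR intervals overlap on scaffold ", sc)
      }
    }
    planted_ssrs <- p
  }
  structure(list(n_scaffolds = as.integer(n_scaffolds), scaffold_length = len,
                 gc_fraction = gc_fraction, planted_ssrs = planted_ssrs,
                 duplication_fraction = duplication_fraction,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

sample_background <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Break every detected run that is not an exact planted interval by point
# substitution outside the planted intervals (rejection repair; keeps truth
# tables exact).
repair_background <- function(seqs, truth, thresholds) {
  for (iter in 1:100) {
    det <- detect_ssrs(seqs, thresholds)
    key <- function(d) paste(d$scaffold, d$start, d$end, d$motif)
    extra <- det[!(key(det) %in% key(truth)), , drop = FALSE]
    if (!nrow(extra)) return(seqs)
    for (i in seq_len(nrow(extra))) {
      sc <- extra$scaffold[i]
      prot <- truth[truth$scaffold == sc, , drop = FALSE]
      cand <- setdiff(seq(extra$start[i], extra$end[i]),
                      unlist(mapply(seq, prot$start, prot$end,
                                    SIMPLIFY = FALSE)))
      if (!length(cand)) next
      pos <- cand[(length(cand) + 1L) %/% 2L]
      s <- seqs[[sc]]
      nb <- c(substr(s, max(pos - 1L, 1L), max(pos - 1L, 1L)),
              substr(s, pos, pos),
              substr(s, min(pos + 1L, nchar(s)), min(pos + 1L, nchar(s))))
      repl <- setdiff(c("A", "C", "G", "T"), nb)[1L]
      substr(s, pos, pos) <- repl
      seqs[[sc]] <- s
    }
  }
  stop2("could not purge accidental SSRs from background after 100 passes")
}

#' Simulate a genome with planted perfect SSRs
#'
#' Background sequence is i.i.d. with the requested GC content; any
#' accidental run meeting the detection thresholds is broken by point
#' substitution so the returned truth table is exhaustive: [detect_ssrs()]
#' on the result recovers exactly the planted loci. With
#' `duplication_fraction > 0`, that proportion of scaffolds is appended as
#' verbatim copies (suffix `_dup`), truth rows included.
#'
#' @param spec a [genome_spec()].
#' @param thresholds detection thresholds the truth table is exact against.
#' @return List with `sequences` (named `DNAStringSet`) and `truth`
#'   (data.frame `scaffold`, `start`, `end`, `motif`, `canonical_class`,
#'   `repeats`, `length`).
#' @export
simulate_genome <- function(spec, thresholds = ssr_thresholds()) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    nm <- sprintf("scaffold_%03d", seq_len(spec$n_scaffolds))
    seqs <- vapply(spec$scaffold_length, sample_background,
                   character(1), gc = spec$gc_fraction)
    names(seqs) <- nm
    truth <- data.frame(scaffold = character(), start = integer(),
                        end = integer(), motif = character(),
                        canonical_class = character(), repeats = integer(),
                        length = integer(), stringsAsFactors = FALSE)
    p <- spec$planted_ssrs
    if (!is.null(p) && nrow(p)) {
      p$motif <- toupper(p$motif)
      # place unpositioned SSRs scaffold by scaffold, non-overlapping
      for (i in seq_len(nrow(p))) {
        if (!is.na(p$pos[i])) next
        sc <- p$scaffold[i]
        L <- spec$scaffold_length[sc]
        w <- nchar(p$motif[i]) * p$repeats[i]
        margin <- min(150L, max(0L, (L - w) %/% 4L))
        taken <- p[!is.na(p$pos) & p$scaffold == sc, , drop = FALSE]
        ok <- FALSE
        for (try in 1:200) {
          lo <- 1L + margin
          hi <- L - w + 1L - margin
          if (hi < lo) { lo <- 1L; hi <- L - w + 1L }
          pos <- sample(lo:hi, 1L)
          if (!nrow(taken) ||
              all(pos + w - 1L < taken$pos - 1L |
                  pos > taken$pos + nchar(taken$motif) * taken$repeats)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop2("could not place planted SSR ", i,
                       " without overlap")
        p$pos[i] <- pos
      }
      for (i in seq_len(nrow(p))) {
        sc <- p$scaffold[i]
        run <- strrep(p$motif[i], p$repeats[i])
        s <- seqs[[sc]]
        substr(s, p$pos[i], p$pos[i] + nchar(run) - 1L) <- run
        seqs[[sc]] <- s
      }
      truth <- data.frame(scaffold = nm[p$scaffold], start = p$pos,
                          end = p$pos + nchar(p$motif) * p$repeats - 1L,
                          motif = p$motif,
                          canonical_class = canonical_motif(p$motif),
                          repeats = as.integer(p$repeats),
                          length = nchar(p$motif) * p$repeats,
                          stringsAsFactors = FALSE)
    }
    seqs <- repair_background(seqs, truth, thresholds)
    n_dup <- round(spec$duplication_fraction * spec$n_scaffolds)
    if (n_dup > 0) {
      dup_idx <- sort(sample.int(spec$n_scaffolds, n_dup))
      dup <- seqs[dup_idx]
      names(dup) <- paste0(nm[dup_idx], "_dup")
      seqs <- c(seqs, dup)
      extra <- truth[truth$scaffold %in% nm[dup_idx], , drop = FALSE]
      if (nrow(extra)) {
        extra$scaffold <- paste0(extra$scaffold, "_dup")
        truth <- rbind(truth, extra)
      }
    }
    truth <- truth[order(match(truth$scaffold, names(seqs)), truth$start), ]
    rownames(truth) <- NULL
    list(sequences = Biostrings::DNAStringSet(seqs), truth = truth)
  })
}

#' Specification of a paired-end read simulation
#'
#' Uniform-coverage paired-end reads with a fixed insert size, independent
#' per-base substitution errors, per-base N masking, a two-state (high/low)
#' phred quality model, and optional exact PCR duplicates.
#'
#' @param read_length read length in bases.
#' @param insert_size insert (fragment) size in bases; must be >=
#'   `read_length`. Default 270, the short-insert library layout emulated.
#' @param depth target fold-coverage (> 0).
#' @param error_rate per-base substitution probability.
#' @param n_rate per-base probability of an N call.
#' @param lowq_rate per-base probability of the low quality state.
#' @param duplicate_fraction proportion of output pairs that are exact
#'   copies of another pair.
#' @param qual_high,qual_low phred scores of the two quality states; N and
#'   low-state bases receive `qual_low` (default 2, i.e. below the phred-5
#'   filter threshold), all others `qual_high`.
#' @param seed integer RNG seed.
#' @return An object of class `readsim_spec`.
#' @export
readsim_spec <- function(read_length = 150L, insert_size = 270L, depth = 30,
                         error_rate = 0.001, n_rate = 0, lowq_rate = 0,
                         duplicate_fraction = 0, qual_high = 38L,
                         qual_low = 2L, seed = 1L) {
  if (depth <= 0) stop2("depth must be > 0")
  if (insert_size < read_length) stop2("insert_size must be >= read_length")
  for (nmv in c("error_rate", "n_rate", "lowq_rate", "duplicate_fraction"))
    check_fraction(get(nmv), nmv)
  structure(list(read_length = as.integer(read_length),
                 insert_size = as.integer(insert_size), depth = depth,
                 error_rate = error_rate, n_rate = n_rate,
                 lowq_rate = lowq_rate,
                 duplicate_fraction = duplicate_fraction,
                 qual_high = as.integer(qual_high),
                 qual_low = as.integer(qual_low), seed = as.integer(seed)),
            class = "readsim_spec")
}

mutate_reads <- function(seqs, rate, replacement = NULL) {
  # substitute bases at i.i.d. positions; replacement NULL = random other base
  if (rate <= 0) return(list(seq = seqs, hit = vector("list", length(seqs))))
  n <- nchar(seqs)
  hits <- vector("list", length(seqs))
  nerr <- rbinom(length(seqs), n, rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    pos <- sample.int(n[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    if (is.null(replacement)) {
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    } else ch[pos] <- replacement
    seqs[i] <- paste(ch, collapse = "")
    hits[[i]] <- pos
  }
  list(seq = seqs, hit = hits)
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly along scaffolds (length-weighted); read 1
#' is the fragment 5' end, read 2 the reverse complement of its 3' end.
#' Expected base yield is `depth * genome length` up to the rounding of the
#' pair count.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param spec a [readsim_spec()].
#' @return List of class `paired_reads` with [fastq_reads] elements `r1`,
#'   `r2` (ids carry `/1` and `/2` suffixes).
#' @export
simulate_reads <- function(genome, spec) {
  stopifnot(inherits(spec, "readsim_spec"))
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  genome <- toupper(genome)
  if (!length(genome) || !sum(nchar(genome)))
    stop2("genome is empty")
  len <- nchar(genome)
  usable <- which(len >= spec$insert_size)
  if (!length(usable))
    stop2("no scaffold is at least insert_size long")
  G <- sum(len)
  rl <- spec$read_length
  n_pairs <- as.integer(ceiling(spec$depth * G / (2 * rl)))
  n_dup <- round(n_pairs * spec$duplicate_fraction / 2)
  n_unique <- n_pairs - n_dup
  with_seed(spec$seed, {
    sc <- usable[sample.int(length(usable), n_unique, replace = TRUE,
                            prob = len[usable])]
    start <- floor(runif(n_unique) * (len[sc] - spec$insert_size + 1)) + 1L
    frag_end <- start + spec$insert_size - 1L
    r1 <- substring(genome[sc], start, start + rl - 1L)
    r2 <- revcomp(substring(genome[sc], frag_end - rl + 1L, frag_end))
    if (n_dup > 0) {
      di <- sample.int(n_unique, n_dup, replace = FALSE)
      r1 <- c(r1, r1[di]); r2 <- c(r2, r2[di])
    }
    finish <- function(seqs) {
      er <- mutate_reads(seqs, spec$error_rate)
      nn <- mutate_reads(er$seq, spec$n_rate, replacement = "N")
      seqs2 <- nn$seq
      q <- strrep(intToUtf8(spec$qual_high + 33L), nchar(seqs2))
      low_char <- intToUtf8(spec$qual_low + 33L)
      # low-quality state positions
      if (spec$lowq_rate > 0) {
        nlow <- rbinom(length(seqs2), nchar(seqs2), spec$lowq_rate)
        for (i in which(nlow > 0L)) {
          pos <- sample.int(nchar(seqs2[i]), nlow[i])
          for (p in pos) substr(q[i], p, p) <- low_char
        }
      }
      # N positions get the low quality too
      for (i in which(lengths(nn$hit) > 0L))
        for (p in nn$hit[[i]]) substr(q[i], p, p) <- low_char
      list(seq = seqs2, qual = q)
    }
    f1 <- finish(r1); f2 <- finish(r2)
    ids <- sprintf("sim_%06d", seq_along(f1$seq))
    structure(list(
      r1 = fastq_reads(paste0(ids, "/1"), f1$seq, f1$qual),
      r2 = fastq_reads(paste0(ids, "/2"), f2$seq, f2$qual)),
      class = "paired_reads")
  })
}

#' @export
print.paired_reads <- function(x, ...) {
  cat("paired_reads:", length(x$r1), "pairs\n")
  invisible(x)
}

#' Specification of a structured diploid genotype panel
#'
#' Groups diverge from a common ancestral allele-frequency vector by a
#' Balding-Nichols (Dirichlet) draw calibrated so that the *expected
#' AMOVA-estimated Fst (PhiPT)* over many loci equals `target_fst`. Because
#' PhiPT is computed from diploid genotype distances, the Dirichlet
#' concentration uses theta = target_fst / (2 - target_fst) rather than
#' target_fst itself (see the methods vignette).
#'
#' @param group_sizes integer vector of per-group sample sizes (all >= 2).
#' @param n_loci number of loci.
#' @param alleles_per_locus either a single allele count or a range
#'   `c(min, max)` within 2-5 sampled uniformly per locus.
#' @param target_fst target differentiation in \[0, 1).
#' @param missing_rate per-call missing probability.
#' @param seed integer RNG seed.
#' @return An object of class `popsim_spec`.
#' @export
popsim_spec <- function(group_sizes = c(8L, 6L, 13L), n_loci = 10L,
                        alleles_per_locus = c(2L, 5L), target_fst = 0.25,
                        missing_rate = 0, seed = 1L) {
  if (any(group_sizes < 2L)) stop2("all group sizes must be >= 2")
  if (target_fst < 0 || target_fst >= 1) stop2("target_fst must be in [0, 1)")
  check_fraction(missing_rate, "missing_rate")
  k <- range(alleles_per_locus)
  if (k[1L] < 2L) stop2("alleles_per_locus must be >= 2")
  if (k[2L] > 5L) stop2("alleles_per_locus must be <= 5")
  structure(list(group_sizes = as.integer(group_sizes),
                 n_loci = as.integer(n_loci), alleles_per_locus = k,
                 target_fst = target_fst, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "popsim_spec")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a structured codominant genotype panel
#'
#' @param spec a [popsim_spec()].
#' @return List with `genotypes` (accession x locus character matrix of
#'   `"a/b"` calls, `NA` = missing), `groups` (data.frame `accession`,
#'   `group`), and `freqs` (list per locus of group x allele frequency
#'   matrices — the simulation truth).
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "popsim_spec"))
  k_groups <- length(spec$group_sizes)
  N <- sum(spec$group_sizes)
  grp <- rep(seq_len(k_groups), spec$group_sizes)
  F <- spec$target_fst
  theta <- F / (2 - F)  # PhiPT calibration, see vignette
  with_seed(spec$seed, {
    gt <- matrix(NA_character_, N, spec$n_loci)
    freqs <- vector("list", spec$n_loci)
    for (l in seq_len(spec$n_loci)) {
      K <- if (spec$alleles_per_locus[1L] == spec$alleles_per_locus[2L])
        spec$alleles_per_locus[1L]
      else sample(spec$alleles_per_locus[1L]:spec$alleles_per_locus[2L], 1L)
      p <- rdirichlet1(rep(1, K))
      pg <- if (theta == 0) matrix(rep(p, each = k_groups), k_groups, K)
      else t(vapply(seq_len(k_groups),
                    function(g) rdirichlet1(p * (1 - theta) / theta),
                    numeric(K)))
      rownames(pg) <- paste0("G", seq_len(k_groups))
      colnames(pg) <- seq_len(K)
      freqs[[l]] <- pg
      for (i in seq_len(N)) {
        a <- sort(sample.int(K, 2L, replace = TRUE, prob = pg[grp[i], ]))
        gt[i, l] <- paste(a, collapse = "/")
      }
    }
    if (spec$missing_rate > 0) {
      miss <- runif(length(gt)) < spec$missing_rate
      gt[miss] <- NA_character_
    }
    acc <- sprintf("acc%02d", seq_len(N))
    rownames(gt) <- acc
    colnames(gt) <- sprintf("L%03d", seq_len(spec$n_loci))
    list(genotypes = gt,
         groups = data.frame(accession = acc, group = paste0("G", grp),
                             stringsAsFactors = FALSE),
         freqs = freqs)
  })
}

#' Convert a codominant panel to a dominant (0/1 band) matrix
#'
#' Every allele at every locus becomes a presence/absence band column;
#' `extra_bands` monomorphic (all-1) noise columns are appended. Missing
#' genotypes produce `NA` bands for that locus.
#'
#' @param pop result of [simulate_population()] or a genotype matrix.
#' @param extra_bands number of monomorphic noise columns to append.
#' @param seed RNG seed (kept for interface symmetry; generation is
#'   deterministic given `pop`).
#' @return Accession x band integer matrix of class `dominant_matrix`
#'   attributes aside, colnames `<locus>_<allele>` plus `noise_<i>`.
#' @export
simulate_bands <- function(pop, extra_bands = 0L, seed = 1L) {
  gt <- if (is.list(pop) && !is.null(pop$genotypes)) pop$genotypes else pop
  stopifnot(is.matrix(gt))
  cols <- list()
  for (l in seq_len(ncol(gt))) {
    calls <- gt[, l]
    al <- strsplit(calls, "/", fixed = TRUE)
    alleles <- sort(unique(unlist(al[!is.na(calls)])))
    for (a in alleles) {
      v <- vapply(seq_along(calls), function(i) {
        if (is.na(calls[i])) NA_integer_
        else as.integer(a %in% al[[i]])
      }, integer(1))
      cols[[paste0(colnames(gt)[l], "_", a)]] <- v
    }
  }
  with_seed(seed, {
    if (extra_bands > 0L)
      for (i in seq_len(extra_bands))
        cols[[sprintf("noise_%02d", i)]] <- rep(1L, nrow(gt))
  })
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(gt)
  out
}

#' Write/read the panel TSV formats
#'
#' Genotype matrices are written accessions x loci with `"a1/a2"` cells and
#' `"."` for missing; band matrices as 0/1; groups as two columns.
#'
#' @param x matrix or data.frame to write.
#' @param path file path.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_genotypes_tsv <- function(x, path) {
  df <- data.frame(accession = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comment = "codominant genotypes, cell = a1/a2 or .")
}

#' @rdname panel_io
#' @export
read_genotypes_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname panel_io
#' @export
write_bands_tsv <- function(x, path) {
  df <- data.frame(accession = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comment = "dominant band matrix, cell = 0/1 or .")
}

#' @rdname panel_io
#' @export
read_bands_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname panel_io
#' @export
write_groups_tsv <- function(x, path) {
  write_tsv(x, path, comment = "accession-to-group assignment")
}

#' @rdname panel_io
#' @export
read_groups_tsv <- function(path) {
  read_tsv(path)
}
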