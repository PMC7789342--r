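# Marker evaluation: codominant/dominant diversity statistics, Nei distance,
# UPGMA with bootstrap, PCoA, AMOVA/PhiPT/Nm, Mann-Whitney comparison.

split_calls <- function(calls) strsplit(calls, "/", fixed = TRUE)

allele_freqs <- function(calls) {
  al <- unlist(split_calls(calls[!is.na(calls)]))
  if (!length(al)) return(numeric(0))
  tab <- table(al)
  as.numeric(tab) / sum(tab) -> p
  names(p) <- names(tab)
  p
}

#' Polymorphism information content of a codominant locus
#'
#' Botstein's PIC: `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p vector of allele frequencies (sums to 1).
#' @return PIC value.
#' @export
pic_codominant <- function(p) {
  if (!length(p)) return(NA_real_)
  s2 <- sum(p^2)
  cross <- (sum(p^2)^2 - sum(p^4)) / 2
  1 - s2 - 2 * cross
}

#' Per-locus diversity statistics of a codominant genotype matrix
#'
#' For each locus, over non-missing genotypes: sample size `n`, observed
#' allele number `Na`, effective allele number `Ne = 1/sum(p^2)`, Shannon
#' index `I = -sum(p log p)`, observed heterozygosity `Ho`, expected
#' heterozygosity `He = 1 - sum(p^2)` (uncorrected; `unbiased = TRUE`
#' applies the `2n/(2n-1)` factor), and PIC.
#'
#' @param mat accession x locus character matrix of `"a1/a2"` calls
#'   (`NA` = missing).
#' @param unbiased use the small-sample-corrected He.
#' @return data.frame with one row per locus (all-missing loci get NA and
#'   are flagged in the `ok` column).
#' @export
locus_stats <- function(mat, unbiased = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  res <- lapply(seq_len(ncol(mat)), function(l) {
    calls <- mat[, l]
    n <- sum(!is.na(calls))
    if (n == 0L)
      return(data.frame(locus = colnames(mat)[l], n = 0L, Na = NA, Ne = NA,
                        I = NA, Ho = NA, He = NA, PIC = NA, ok = FALSE))
    p <- allele_freqs(calls)
    het <- vapply(split_calls(calls[!is.na(calls)]),
                  function(a) a[1L] != a[2L], logical(1))
    he <- 1 - sum(p^2)
    if (unbiased) he <- he * 2 * n / (2 * n - 1)
    data.frame(locus = colnames(mat)[l] %||% l, n = n, Na = length(p),
               Ne = 1 / sum(p^2), I = -sum(p * log(p)), Ho = mean(het),
               He = he, PIC = pic_codominant(p), ok = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-group diversity summary (codominant data)
#'
#' Computes [locus_stats()] within each group and summarizes: per-group
#' means over loci of Na, Ne, I, Ho, He, plus `PP` = percentage of loci
#' polymorphic (Na >= 2) within the group, and a final `Mean` row taken as
#' the unweighted mean over groups.
#'
#' @param mat accession x locus genotype matrix.
#' @param groups data.frame with columns `accession`, `group` assigning
#'   every row of `mat` to exactly one group.
#' @param unbiased passed to [locus_stats()].
#' @return data.frame with columns `group`, `N`, `Na`, `Ne`, `I`, `Ho`,
#'   `He`, `PP`.
#' @export
group_diversity <- function(mat, groups, unbiased = FALSE) {
  stopifnot(all(rownames(mat) %in% groups$accession))
  g_of <- groups$group[match(rownames(mat), groups$accession)]
  if (anyNA(g_of)) stop2("every accession must be assigned to a group")
  gs <- unique(g_of)
  rows <- lapply(gs, function(g) {
    sub <- mat[g_of == g, , drop = FALSE]
    st <- locus_stats(sub, unbiased = unbiased)
    st <- st[st$ok, , drop = FALSE]
    data.frame(group = g, N = sum(g_of == g), Na = mean(st$Na),
               Ne = mean(st$Ne), I = mean(st$I), Ho = mean(st$Ho),
               He = mean(st$He), PP = 100 * mean(st$Na >= 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(group = "Mean", N = NA,
                         Na = mean(out$Na), Ne = mean(out$Ne),
                         I = mean(out$I), Ho = mean(out$Ho),
                         He = mean(out$He), PP = mean(out$PP),
                         stringsAsFactors = FALSE)
  out <- rbind(out, mean_row)
  rownames(out) <- NULL
  out
}

#' Dominant (band) marker indices
#'
#' Per band, with presence frequency `f` over scored accessions:
#' `PIC_dom = 2 f (1 - f)` and band informativeness `Ib = 1 - 2|0.5 - f|`.
#' Per primer (or for the whole matrix when `band_groups` is omitted):
#' polymorphic band count (`0 < f < 1`), polymorphism percentage, mean
#' `PIC_dom` over bands, `BI` = mean `Ib`, `Rp` = sum of `Ib`
#' (resolving power), and `MI = mean PIC_dom x polymorphic band count`.
#'
#' @param bands accession x band 0/1 matrix (`NA` allowed).
#' @param band_groups optional factor/character mapping each band column to
#'   a primer.
#' @return List with `per_band` and `per_primer` data.frames.
#' @export
dominant_stats <- function(bands, band_groups = NULL) {
  stopifnot(is.matrix(bands))
  vals <- bands[!is.na(bands)]
  if (!all(vals %in% c(0L, 1L))) stop2("band matrix must be binary 0/1")
  f <- colMeans(bands, na.rm = TRUE)
  per_band <- data.frame(band = colnames(bands) %||% seq_len(ncol(bands)),
                         f = f, polymorphic = f > 0 & f < 1,
                         pic_dom = 2 * f * (1 - f),
                         ib = 1 - 2 * abs(0.5 - f),
                         stringsAsFactors = FALSE)
  rownames(per_band) <- NULL
  grp <- if (is.null(band_groups)) rep("all", ncol(bands))
  else as.character(band_groups)
  per_primer <- do.call(rbind, lapply(unique(grp), function(g) {
    b <- per_band[grp == g, , drop = FALSE]
    npoly <- sum(b$polymorphic)
    data.frame(primer = g, n_bands = nrow(b), n_polymorphic = npoly,
               polymorphism_pct = 100 * npoly / nrow(b),
               PIC = mean(b$pic_dom), BI = mean(b$ib),
               Rp = sum(b$ib), MI = mean(b$pic_dom) * npoly,
               stringsAsFactors = FALSE)
  }))
  rownames(per_primer) <- NULL
  list(per_band = per_band, per_primer = per_primer)
}

#' Nei genetic distance matrix among accessions
#'
#' Codominant data: Nei (1972) standard distance on per-accession allele
#' profiles, `D = -ln( Jxy / sqrt(Jx Jy) )` with the identities averaged
#' over loci scored in both accessions. Dominant data: one minus the Dice
#' (Nei-Li) similarity on band vectors.
#'
#' @param x genotype matrix (codominant) or 0/1 band matrix (dominant).
#' @param type `"codominant"` or `"dominant"`; guessed from the matrix
#'   contents by default.
#' @return A symmetric `matrix` of distances with zero diagonal.
#' @export
nei_distance <- function(x, type = c("auto", "codominant", "dominant")) {
  type <- match.arg(type)
  if (type == "auto")
    type <- if (is.numeric(x)) "dominant" else "codominant"
  n <- nrow(x)
  if (n < 2L) stop2("need at least 2 accessions")
  D <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  if (type == "codominant") {
    # per-accession, per-locus allele frequency profiles (0 / 0.5 / 1)
    al <- lapply(seq_len(ncol(x)), function(l) split_calls(x[, l]))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      jx <- jy <- jxy <- nl <- 0
      for (l in seq_len(ncol(x))) {
        ai <- al[[l]][[i]]; aj <- al[[l]][[j]]
        if (is.na(x[i, l]) || is.na(x[j, l])) next
        alleles <- unique(c(ai, aj))
        pi <- vapply(alleles, function(a) mean(ai == a), numeric(1))
        pj <- vapply(alleles, function(a) mean(aj == a), numeric(1))
        jx <- jx + sum(pi^2); jy <- jy + sum(pj^2)
        jxy <- jxy + sum(pi * pj); nl <- nl + 1
      }
      if (nl == 0) { D[i, j] <- D[j, i] <- NA_real_; next }
      d <- if (jxy == 0) Inf else -log(jxy / sqrt(jx * jy))
      D[i, j] <- D[j, i] <- d
    }
  } else {
    xb <- x
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(xb[i, ]) & !is.na(xb[j, ])
      a <- sum(xb[i, ok] == 1 & xb[j, ok] == 1)
      bc <- sum(xb[i, ok] != xb[j, ok])
      d <- if (2 * a + bc == 0) 0 else 1 - 2 * a / (2 * a + bc)
      D[i, j] <- D[j, i] <- d
    }
  }
  if (any(is.infinite(D))) {
    mx <- max(D[is.finite(D)])
    warning("accession pairs share no alleles; capping infinite distances")
    D[is.infinite(D)] <- mx * 1.1
  }
  D
}

#' UPGMA dendrogram with optional locus bootstrap
#'
#' Average-linkage agglomeration of a Nei distance matrix; the result is
#' ultrametric with root height `max(cophenetic)/2`. With
#' `bootstrap > 0`, loci (columns) are resampled with replacement,
#' distances recomputed, and clade support reported as percentages in
#' `tree$node.label`.
#'
#' @param x genotype/band matrix (required for bootstrapping) or a distance
#'   matrix (bootstrap must then be 0).
#' @param type passed to [nei_distance()].
#' @param bootstrap number of bootstrap replicates (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return An `ape::phylo` tree (ultrametric).
#' @export
upgma <- function(x, type = "auto", bootstrap = 0L, seed = 1L) {
  is_dist <- (is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x) &&
                all(abs(diag(x)) < 1e-12)) || inherits(x, "dist")
  build <- function(d) {
    hc <- hclust(as.dist(d), method = "average")
    ape::as.phylo(hc)
  }
  if (is_dist) {
    if (bootstrap > 0L) stop2("bootstrap needs the locus-level matrix")
    return(build(as.matrix(x)))
  }
  tree <- build(nei_distance(x, type))
  if (bootstrap > 0L) {
    bts <- with_seed(seed, {
      lapply(seq_len(bootstrap), function(b) {
        cols <- sample.int(ncol(x), replace = TRUE)
        build(nei_distance(x[, cols, drop = FALSE], type))
      })
    })
    supp <- ape::prop.clades(tree, bts, rooted = TRUE)
    supp[is.na(supp)] <- 0
    tree$node.label <- round(100 * supp / bootstrap, 1)
  }
  tree
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of the positive
#' eigenvalues. Negative eigenvalues are reported, not corrected.
#'
#' @param d distance matrix (symmetric, zero diagonal).
#' @return List with `points` (n x m coordinates for the m positive
#'   eigenvalues), `eigenvalues` (all n, decreasing), and
#'   `rel_eig` (eigenvalue proportions of the positive mass).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L || any(abs(d - t(d)) > 1e-8)) stop2("d must be symmetric")
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = e$values,
       rel_eig = e$values[pos] / sum(e$values[pos]))
}

# ---- AMOVA ------------------------------------------------------------------

#' Squared inter-individual distances for AMOVA
#'
#' Codominant matrices use half the squared Euclidean distance between
#' allele-count vectors, summed over loci scored in both individuals
#' (identical genotypes 0; one shared allele 1; AA vs BB 4; AB vs CD 2).
#' Dominant matrices use the squared Euclidean distance on band vectors.
#'
#' @param x genotype or band matrix.
#' @param type as in [nei_distance()].
#' @return n x n matrix of squared distances.
#' @export
amova_distance <- function(x, type = c("auto", "codominant", "dominant")) {
  type <- match.arg(type)
  if (type == "auto")
    type <- if (is.numeric(x)) "dominant" else "codominant"
  n <- nrow(x)
  D2 <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  if (type == "dominant") {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      D2[i, j] <- D2[j, i] <- sum((x[i, ok] - x[j, ok])^2)
    }
    return(D2)
  }
  al <- lapply(seq_len(ncol(x)), function(l) split_calls(x[, l]))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- 0
    for (l in seq_len(ncol(x))) {
      if (is.na(x[i, l]) || is.na(x[j, l])) next
      ai <- al[[l]][[i]]; aj <- al[[l]][[j]]
      alleles <- unique(c(ai, aj))
      yi <- vapply(alleles, function(a) sum(ai == a), numeric(1))
      yj <- vapply(alleles, function(a) sum(aj == a), numeric(1))
      tot <- tot + sum((yi - yj)^2) / 2
    }
    D2[i, j] <- D2[j, i] <- tot
  }
  D2
}

ss_within <- function(D2, grp) {
  tot <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    tot <- tot + sum(D2[idx, idx]) / (2 * length(idx))
  }
  tot
}

#' Variance components and PhiPT from AMOVA sums of squares
#'
#' The one-level AMOVA bookkeeping: `df_among = k - 1`,
#' `df_within = N - k`, mean squares `MS = SS/df`,
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)`, `sigma2_among = (MSa - MSw)/n0`
#' (truncated at 0 with a warning), `sigma2_within = MSw`, percentages of
#' molecular variance, `Fst` (PhiPT) `= sigma2_among / total`, and gene
#' flow `Nm = (1 - Fst)/(4 Fst)`.
#'
#' @param ss_among,ss_within sums of squares.
#' @param group_sizes integer vector of group sizes.
#' @return List of class `amova_result`.
#' @export
amova_components <- function(ss_among, ss_within, group_sizes) {
  k <- length(group_sizes)
  N <- sum(group_sizes)
  df_among <- k - 1L
  df_within <- N - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(group_sizes^2) / N) / df_among
  s2a <- (ms_among - ms_within) / n0
  if (s2a < 0) {
    warning("negative among-group variance component truncated to 0")
    s2a <- 0
  }
  s2w <- ms_within
  tot <- s2a + s2w
  fst <- if (tot > 0) s2a / tot else 0
  structure(list(df_among = df_among, df_within = df_within,
                 ss_among = ss_among, ss_within = ss_within,
                 ms_among = ms_among, ms_within = ms_within, n0 = n0,
                 sigma2_among = s2a, sigma2_within = s2w,
                 pmv_among = 100 * fst, pmv_within = 100 * (1 - fst),
                 fst = fst,
                 nm = if (fst > 0 && fst < 1) (1 - fst) / (4 * fst)
                 else NA_real_,
                 p_value = NA_real_),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf(
    "AMOVA: df %d/%d  SS %.3f/%.3f  PMV %.2f%%/%.2f%%  Fst %.3f  Nm %s  p %s\n",
    x$df_among, x$df_within, x$ss_among, x$ss_within, x$pmv_among,
    x$pmv_within, x$fst,
    ifelse(is.na(x$nm), "NA", sprintf("%.4f", x$nm)),
    ifelse(is.na(x$p_value), "NA", format.pval(x$p_value))))
  invisible(x)
}

#' Analysis of molecular variance (one grouping level)
#'
#' Partitions the squared-distance matrix from [amova_distance()] into
#' among- and within-group sums of squares, derives variance components and
#' PhiPT/Fst via [amova_components()], and attaches a permutation p-value
#' (group labels permuted over individuals; `p = (1 + #{Fst* >= Fst}) /
#' (permutations + 1)`).
#'
#' @param x genotype or band matrix, or a precomputed squared-distance
#'   matrix (with `type = "distance2"`).
#' @param groups data.frame (`accession`, `group`) or a vector of group
#'   labels aligned with rows of `x`.
#' @param permutations number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param type `"auto"`, `"codominant"`, `"dominant"`, or `"distance2"`.
#' @return An `amova_result` (see [amova_components()]).
#' @export
amova <- function(x, groups, permutations = 999L, seed = 1L,
                  type = "auto") {
  grp <- if (is.data.frame(groups)) {
    stopifnot(!is.null(rownames(x)))
    g <- groups$group[match(rownames(x), groups$accession)]
    if (anyNA(g)) stop2("every accession must be assigned to a group")
    g
  } else as.character(groups)
  sizes <- table(grp)
  if (length(sizes) < 2L) stop2("need at least 2 groups")
  if (any(sizes < 2L)) stop2("every group must have at least 2 members")
  D2 <- if (identical(type, "distance2")) as.matrix(x)
  else amova_distance(x, type)
  N <- nrow(D2)
  ss_tot <- sum(D2) / (2 * N)
  ssw <- ss_within(D2, grp)
  res <- amova_components(ss_tot - ssw, ssw, as.integer(sizes))
  if (permutations > 0L) {
    obs <- res$fst
    perm_fst <- with_seed(seed, {
      vapply(seq_len(permutations), function(b) {
        pg <- sample(grp)
        sswp <- ss_within(D2, pg)
        comp <- suppressWarnings(
          amova_components(ss_tot - sswp, sswp, as.integer(sizes)))
        comp$fst
      }, numeric(1))
    })
    res$p_value <- (1 + sum(perm_fst >= obs)) / (permutations + 1)
  }
  res
}

#' Gene flow from Fst
#'
#' Island-model translation `Nm = (1 - Fst) / (4 Fst)`.
#'
#' @param fst differentiation coefficient in (0, 1].
#' @return Nm.
#' @export
gene_flow <- function(fst) {
  if (any(fst <= 0 | fst > 1)) stop2("fst must be in (0, 1]")
  (1 - fst) / (4 * fst)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For samples of at most 10 per side the p-value
#' is computed by exhaustive enumeration of all group assignments
#' (a permutation test on `|U - n1 n2 / 2|`, exact under ties); larger
#' samples use the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param a,b numeric samples.
#' @return List with `U` (for sample `a`), `p_value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop2("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= 10L) {
    idx <- combn(n1 + n2, n1)
    dev <- abs(U - mu)
    us <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= dev - 1e-9)
    list(U = U, p_value = p, method = "exact enumeration")
  } else {
    ties <- table(pooled)
    nn <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- (U - mu) / sqrt(sigma2)
    list(U = U, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal approximation with tie correction")
  }
}

# ---- report tables ----------------------------------------------------------

#' Layout helpers mirroring the marker-evaluation report tables
#'
#' `diversity_table()` renders per-marker Na/PIC/Ho with Total/Min/Max/Mean
#' rows; `amova_table()` renders the two-source AMOVA layout
#' (Source, df, SS, PMV, Fst, Nm, p).
#'
#' @param stats data.frame from [locus_stats()].
#' @return data.frame ready for TSV output.
#' @export
diversity_table <- function(stats) {
  st <- stats[stats$ok, , drop = FALSE]
  body <- data.frame(Primer = st$locus, Na = st$Na,
                     PIC = round(st$PIC, 3), Ho = round(st$Ho, 3),
                     stringsAsFactors = FALSE)
  summary_rows <- data.frame(
    Primer = c("Total", "Minimum", "Maximum", "Mean"),
    Na = c(sum(st$Na), min(st$Na), max(st$Na), mean(st$Na)),
    PIC = round(c(NA, min(st$PIC), max(st$PIC), mean(st$PIC)), 3),
    Ho = round(c(NA, min(st$Ho), max(st$Ho), mean(st$Ho)), 3),
    stringsAsFactors = FALSE)
  rbind(body, summary_rows)
}

#' @param result an `amova_result`.
#' @rdname diversity_table
#' @export
amova_table <- function(result) {
  data.frame(
    Source = c("Among groups", "Within groups"),
    df = c(result$df_among, result$df_within),
    SS = round(c(result$ss_among, result$ss_within), 3),
    PMV = paste0(round(c(result$pmv_among, result$pmv_within), 2), "%"),
    Fst = c(round(result$fst, 3), NA),
    Nm = c(round(result$nm, 4), NA),
    p = c(result$p_value, NA),
    stringsAsFactors = FALSE)
}
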