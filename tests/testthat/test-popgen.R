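make_locus <- function(calls) {
  matrix(calls, length(calls), 1,
         dimnames = list(sprintf("a%02d", seq_along(calls)), "L1"))
}

test_that("locus_stats reproduces the printed single-locus worked examples", {
  # 26 heterozygotes + 1 homozygote out of 27
  m <- make_locus(c(rep("1/2", 26), "1/1"))
  st <- locus_stats(m)
  expect_equal(round(st$Ho, 3), 0.963)
  expect_equal(round(st$PIC, 3), 0.375)
  expect_equal(st$Na, 2L)
  # 25 homozygotes + 2 heterozygotes
  m2 <- make_locus(c(rep("1/1", 25), rep("1/2", 2)))
  st2 <- locus_stats(m2)
  expect_equal(round(st2$Ho, 3), 0.074)
  expect_equal(round(st2$PIC, 3), 0.069)
})

test_that("locus_stats closed forms at p = q = 0.5 and edge handling", {
  m <- make_locus(c("1/1", "2/2", "1/2", "1/2"))
  st <- locus_stats(m)
  expect_equal(st$Ne, 2)
  expect_equal(st$He, 0.5)
  expect_equal(st$I, log(2))
  # missing genotypes are excluded from the denominator (2/23 style)
  m3 <- make_locus(c(rep("1/1", 21), rep("1/2", 2), rep(NA, 4)))
  st3 <- locus_stats(m3)
  expect_equal(st3$n, 23L)
  expect_equal(st3$Ho, 2 / 23)
  # an all-missing locus is flagged, not averaged
  mm <- cbind(m3, L2 = rep(NA_character_, 27))
  st4 <- locus_stats(mm)
  expect_false(st4$ok[2])
  # monomorphic locus degenerates correctly
  mono <- locus_stats(make_locus(rep("3/3", 5)))
  expect_equal(mono$Ne, 1)
  expect_equal(mono$He, 0)
  expect_equal(mono$PIC, 0)
  expect_equal(mono$I, 0)
})

test_that("PIC never exceeds He and Ne never exceeds Na", {
  set.seed(1)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    p <- ssrpipe:::rdirichlet1(rep(1, k))
    pic <- pic_codominant(p)
    expect_lte(pic, 1 - sum(p^2) + 1e-12)
    expect_gte(pic, 0)
    expect_lte(1 / sum(p^2), k)
  }
})

test_that("group_diversity means and PP match direct recomputation", {
  wp <- worked_panel()
  gd <- group_diversity(wp$genotypes, wp$groups)
  expect_equal(gd$PP[match(c("MGL", "SI", "QTP"), gd$group)],
               c(90, 60, 100))
  expect_equal(gd$PP[gd$group == "Mean"], 83.33, tolerance = 1e-3)

  pop <- simulate_population(popsim_spec(c(5, 5), 20, target_fst = 0.3,
                                         missing_rate = 0.05, seed = 12))
  gd2 <- group_diversity(pop$genotypes, pop$groups)
  for (g in c("G1", "G2")) {
    sub <- pop$genotypes[pop$groups$accession[pop$groups$group == g], ,
                         drop = FALSE]
    st <- locus_stats(sub)
    expect_equal(gd2$Na[gd2$group == g], mean(st$Na))
    expect_equal(gd2$Ho[gd2$group == g], mean(st$Ho))
    expect_equal(gd2$PP[gd2$group == g], 100 * mean(st$Na >= 2))
  }
  expect_equal(gd2$Ne[gd2$group == "Mean"],
               mean(gd2$Ne[gd2$group %in% c("G1", "G2")]))
  # all-monomorphic group
  mono <- matrix("1/1", 4, 3, dimnames = list(paste0("a", 1:4), NULL))
  colnames(mono) <- paste0("L", 1:3)
  gdm <- group_diversity(mono, data.frame(accession = paste0("a", 1:4),
                                          group = "only"))
  expect_equal(gdm$PP[1], 0)
})

test_that("dominant indices equal a hand-computed oracle", {
  set.seed(3)
  bands <- matrix(rbinom(80, 1, 0.5), 8, 10,
                  dimnames = list(paste0("a", 1:8), paste0("b", 1:10)))
  bands[, 10] <- 1L  # force one monomorphic band
  ds <- dominant_stats(bands)
  f <- colMeans(bands)
  expect_equal(ds$per_band$pic_dom, unname(2 * f * (1 - f)))
  pp <- ds$per_primer
  expect_equal(pp$n_polymorphic, sum(f > 0 & f < 1))
  expect_equal(pp$PIC, mean(2 * f * (1 - f)))
  expect_equal(pp$BI, mean(1 - 2 * abs(0.5 - f)))
  expect_equal(pp$Rp, sum(1 - 2 * abs(0.5 - f)))
  expect_equal(pp$MI, mean(2 * f * (1 - f)) * sum(f > 0 & f < 1))
  # half-frequency band reaches the dominant PIC maximum of 0.5
  expect_equal(dominant_stats(
    matrix(c(1, 1, 0, 0), 4, 1))$per_band$pic_dom, 0.5)
})

test_that("Nei distance: identity, symmetry, and a textbook hand example", {
  gt <- rbind(a1 = c("1/1", "1/2"), a2 = c("1/2", "2/2"))
  colnames(gt) <- c("L1", "L2")
  D <- nei_distance(gt)
  # per-accession profiles: Jx = mean(1, .5), Jy = mean(.5, 1), Jxy = .5
  expect_equal(D["a1", "a2"], -log(0.5 / sqrt(0.75 * 0.75)))
  expect_equal(diag(D), c(a1 = 0, a2 = 0))

  pop <- simulate_population(popsim_spec(c(4, 4), 15, seed = 9))
  D2 <- nei_distance(pop$genotypes)
  expect_equal(D2, t(D2))
  expect_true(all(diag(D2) == 0))
  expect_true(all(D2 >= 0))
  # identical accessions at distance zero
  same <- rbind(x = c("1/2", "3/3"), y = c("1/2", "3/3"))
  colnames(same) <- c("L1", "L2")
  expect_equal(nei_distance(same)["x", "y"], 0)
  # dominant route: one minus Dice
  bd <- rbind(x = c(1L, 1L, 0L), y = c(1L, 0L, 1L))
  expect_equal(nei_distance(bd)["x", "y"], 1 - 2 * 1 / (2 * 1 + 2))
})

test_that("upgma is ultrametric and solves the three-point case exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_true(ape::is.ultrametric(tr))
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["A", "B"], 2)
  expect_equal(co["A", "C"], 4)
  # root height = max distance / 2
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)
  # newick round-trip
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::cophenetic.phylo(back)[rownames(co), colnames(co)], co)
})

test_that("upgma bootstrap supports strong structure", {
  pop <- simulate_population(popsim_spec(c(6, 6), 60, target_fst = 0.5,
                                         seed = 13))
  tr <- upgma(pop$genotypes, bootstrap = 60, seed = 2)
  expect_true(ape::is.ultrametric(tr))
  expect_equal(length(tr$node.label), tr$Nnode)
  g1 <- pop$groups$accession[pop$groups$group == "G1"]
  expect_true(ape::is.monophyletic(tr, g1))
  # the split separating the two groups should have high support
  mrca <- ape::getMRCA(tr, g1)
  expect_gt(tr$node.label[mrca - ape::Ntip(tr)], 60)
})

test_that("pcoa satisfies its algebraic identities", {
  # collinear 1-D points: first axis carries all positive mass
  x <- c(0, 1, 3, 6)
  d <- as.matrix(dist(x))
  p <- pcoa(d)
  expect_equal(p$rel_eig[1], 1)
  # Euclidean input: distances reconstructed exactly from full coordinates
  set.seed(5)
  y <- matrix(rnorm(5 * 3), 5, 3)
  d2 <- as.matrix(dist(y))
  p2 <- pcoa(d2)
  rec <- as.matrix(dist(p2$points))
  expect_equal(rec, d2, ignore_attr = TRUE, tolerance = 1e-8)
  # trace identity: sum of eigenvalues = sum(d^2)/n
  expect_equal(sum(p2$eigenvalues), sum(d2^2) / (2 * nrow(d2)),
               tolerance = 1e-8)
  # agreement with the classical-scaling oracle
  cmd <- stats::cmdscale(d2, k = 2, eig = TRUE)
  expect_equal(abs(p2$points[, 1:2]), abs(cmd$points), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("amova_components reproduces the printed two-source table", {
  sl <- amova_components(74.960, 78.003, c(8, 6, 13))
  expect_equal(round(sl$pmv_among, 2), 55.28)
  expect_equal(round(sl$fst, 3), 0.553)
  expect_equal(sl$n0, 8.5185, tolerance = 1e-4)
  expect_equal(sl$df_among, 2L)
  expect_equal(sl$df_within, 24L)
  ml <- amova_components(292.330, 281.744, c(8, 6, 13))
  expect_equal(round(ml$pmv_among, 2), 57.34)
  expect_equal(round(ml$fst, 3), 0.573)
  # negative component truncates with a warning
  expect_warning(z <- amova_components(1, 100, c(5, 5)), "truncated")
  expect_equal(z$fst, 0)
})

test_that("amova equals the centroid-decomposition oracle", {
  set.seed(21)
  for (rep in 1:5) {
    pop <- simulate_population(popsim_spec(c(4, 4, 4), 8, target_fst = 0.3,
                                           seed = 300 + rep))
    grp <- pop$groups$group
    D2 <- amova_distance(pop$genotypes)
    want <- oracle_amova_ss(pop$genotypes, grp)
    got <- amova(pop$genotypes, pop$groups, permutations = 0)
    expect_equal(got$ss_within, want$ss_within, tolerance = 1e-9)
    expect_equal(got$ss_among, want$ss_among, tolerance = 1e-9)
  }
})

test_that("amova squared genotype distances follow the shared-allele rules", {
  gt <- rbind(i = "1/1", j = "1/2", k = "2/2", l = "2/3", m = "4/5")
  colnames(gt) <- "L1"
  D2 <- amova_distance(gt)
  expect_equal(D2["i", "j"], 1)  # AA vs AB
  expect_equal(D2["i", "k"], 4)  # AA vs BB
  expect_equal(D2["i", "l"], 3)  # AA vs BC
  expect_equal(D2["j", "l"], 1)  # AB vs BC
  expect_equal(D2["j", "j"], 0)
  expect_equal(D2["l", "m"], 2)  # AB vs CD
})

test_that("amova permutation p is well-behaved and input checks fire", {
  pop <- simulate_population(popsim_spec(c(6, 6), 30, target_fst = 0.4,
                                         seed = 31))
  am <- amova(pop$genotypes, pop$groups, permutations = 199, seed = 4)
  expect_lt(am$p_value, 0.05)
  expect_equal(amova(pop$genotypes, pop$groups, permutations = 199,
                     seed = 4)$p_value, am$p_value)
  bad <- pop$groups
  bad$group[bad$accession == "acc01"] <- "G3"
  expect_error(amova(pop$genotypes, bad, permutations = 0), "at least 2")
})

test_that("gene_flow follows the island-model closed form", {
  expect_equal(gene_flow(0.25), 0.75)
  expect_equal(gene_flow(0.5), 0.25)
  expect_lt(gene_flow(1 - 1e-9), 1e-8)
  expect_error(gene_flow(0), "fst")
})

test_that("mann_whitney: exact enumeration, ties, and the normal branch", {
  r <- mann_whitney(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 20)  # the two extreme arrangements of 20
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # agreement with the exact rank-sum oracle when there are no ties
  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:100, 6); b <- sample(101:200, 5)
    spl <- sample(c(a, b)); a <- spl[1:6]; b <- spl[7:11]
    ours <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  big <- mann_whitney(rnorm(30), rnorm(25) + 2)
  expect_equal(big$method, "normal approximation with tie correction")
  expect_lt(big$p_value, 0.01)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("report tables assemble the printed layouts", {
  na <- c(3, 5, 3, 3, 2, 2, 4, 2, 3, 2)
  pic <- c(0.515, 0.506, 0.448, 0.519, 0.103, 0.221, 0.595, 0.069, 0.558,
           0.375)
  ho <- c(0.087, 0.481, 0.231, 0.852, 0.115, 0.222, 0.926, 0.074, 0.852,
          0.963)
  st <- data.frame(locus = sprintf("M%02d", 1:10), n = 27, Na = na,
                   Ne = NA, I = NA, Ho = ho, He = NA, PIC = pic, ok = TRUE)
  tab <- diversity_table(st)
  expect_equal(tab$Na[tab$Primer == "Total"], 29)
  expect_equal(tab$PIC[tab$Primer == "Mean"], 0.391)
  expect_equal(tab$Ho[tab$Primer == "Mean"], 0.480)
  expect_equal(tab$PIC[tab$Primer == "Maximum"], 0.595)

  am <- amova_components(74.960, 78.003, c(8, 6, 13))
  at <- amova_table(am)
  expect_equal(at$df, c(2L, 24L))
  expect_equal(at$PMV, c("55.28%", "44.72%"))
  expect_equal(at$Fst[1], 0.553)
})
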