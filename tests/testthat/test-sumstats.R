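test_that("joint SFS puts each site in exactly one cell", {
  # no segregating sites: all mass at (0,0)
  empty <- datasetFromMatrix(matrix(integer(), nrow = 8, ncol = 0),
                             pops = c("A", "A", "B", "B"))
  s0 <- jointSfs(empty, "A", "B")
  expect_equal(sum(s0@counts), 0)

  # one site at derived count 2/4 in A, 0/4 in B -> unfolded cell (2,0)
  mat <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), ncol = 1)
  one <- datasetFromMatrix(mat, pops = c("A", "A", "B", "B"))
  s1 <- jointSfs(one, "A", "B")
  expect_equal(s1@counts[3, 1], 1)
  expect_equal(sum(s1@counts), 1)
})

test_that("folded and unfolded spectra match a brute-force per-site recount", {
  m <- twoPopModel(theta = 0.003, tau = 0.002)
  ds <- simulateDataset(m, c(A = 2, B = 2), n_loci = 120, locus_length = 500,
                        missingness_rate = 0.15, seed = 5)
  for (folded in c(FALSE, TRUE)) {
    s <- jointSfs(ds, "A", "B", folded = folded)
    expect_equal(s@counts, bruteForceSfs(ds, "A", "B", folded = folded))
  }
  # folding maps cells by the pooled minor-allele rule
  su <- jointSfs(ds, "A", "B", FALSE)@counts
  sf <- jointSfs(ds, "A", "B", TRUE)@counts
  expect_equal(sum(su), sum(sf))
})

test_that("weighted F_ST behaves at the structure limits", {
  # a single panmictic population split into two labels: F_ST ~ 0
  set.seed(21)
  ds <- simulateDataset(onePopModel(0.002, "P"), c(P = 8), n_loci = 2000,
                        locus_length = 1000)
  ind <- ds@individuals
  ind$population <- rep(c("A", "B"), each = 4)
  ds@individuals <- ind
  f0 <- weightedFst(jointSfs(ds, "A", "B", folded = TRUE))
  expect_lt(abs(as.numeric(f0)), 0.01)

  # single fixed difference: F_ST = 1 exactly, both estimators
  cts <- matrix(0, 5, 5); cts[5, 1] <- 1
  sfix <- new("SFS2D", counts = cts, n1 = 4L, n2 = 4L, folded = FALSE,
              pops = c("A", "B"))
  expect_equal(as.numeric(weightedFst(sfix, "hudson")), 1)
  expect_equal(as.numeric(weightedFst(sfix, "reynolds")), 1)
})

test_that("weighted F_ST equals the per-site spreadsheet oracle", {
  sites <- rbind(c(2, 0), c(1, 1), c(4, 4))
  cts <- matrix(0, 5, 5)
  for (r in seq_len(nrow(sites)))
    cts[sites[r, 1] + 1, sites[r, 2] + 1] <-
      cts[sites[r, 1] + 1, sites[r, 2] + 1] + 1
  s <- new("SFS2D", counts = cts, n1 = 4L, n2 = 4L, folded = FALSE,
           pops = c("A", "B"))
  expect_equal(as.numeric(weightedFst(s)), bruteForceHudsonFst(sites, 4, 4))
})

test_that("ratio-of-sums weighting is invariant to site duplication", {
  sites <- rbind(c(3, 1), c(1, 0), c(2, 2), c(4, 0))
  cts <- matrix(0, 5, 5)
  for (r in seq_len(nrow(sites)))
    cts[sites[r, 1] + 1, sites[r, 2] + 1] <-
      cts[sites[r, 1] + 1, sites[r, 2] + 1] + 1
  s1 <- new("SFS2D", counts = cts, n1 = 4L, n2 = 4L, folded = FALSE,
            pops = c("A", "B"))
  s2 <- new("SFS2D", counts = 2 * cts, n1 = 4L, n2 = 4L, folded = FALSE,
            pops = c("A", "B"))
  expect_equal(as.numeric(weightedFst(s1)), as.numeric(weightedFst(s2)))
  # a mean-of-ratios estimator would not be invariant when instead sites
  # are duplicated unevenly
  cts3 <- cts; cts3[4, 2] <- 5
  s3 <- new("SFS2D", counts = cts3, n1 = 4L, n2 = 4L, folded = FALSE,
            pops = c("A", "B"))
  expect_false(isTRUE(all.equal(as.numeric(weightedFst(s3)),
                                as.numeric(weightedFst(s1)))))
})

test_that("Slatkin linearization is the closed form", {
  expect_equal(slatkinLinearize(0), 0)
  expect_equal(slatkinLinearize(0.5), 1)
  expect_equal(slatkinLinearize(0.2), 0.25)
  expect_error(slatkinLinearize(1), "undefined")
})

test_that("Watterson estimator uses the harmonic-number denominator", {
  # n = 2 haplotypes, one locus of 1000 bp, S = 5: theta_W = 0.005
  mat2 <- matrix(c(1L, 0L), nrow = 2, ncol = 5)
  d2 <- datasetFromMatrix(mat2, pops = "A", length = 1000)
  st2 <- diversityStats(d2, "A")
  expect_equal(st2$theta_w, 5 / 1000)
  expect_equal(st2$s_per_site, 5 / 1000)

  # n = 4, S = 11 -> 11 / (1.8333 * 1000)
  mat4 <- matrix(0L, nrow = 4, ncol = 11)
  mat4[1, ] <- 1L
  d4 <- datasetFromMatrix(mat4, pops = c("A", "A"), length = 1000)
  st4 <- diversityStats(d4, "A")
  expect_equal(st4$theta_w, 11 / ((1 + 1/2 + 1/3) * 1000))
})

test_that("moment estimators recover zero divergence within a population", {
  set.seed(22)
  ds <- simulateDataset(onePopModel(0.002, "P"), c(P = 8), n_loci = 1200,
                        locus_length = 300)
  ind <- ds@individuals
  ind$population <- rep(c("A", "B"), each = 4)
  ds@individuals <- ind
  est <- momentEstimates(ds, "A", "B")
  # tau-hat for a relabeled single population is 0 in expectation
  expect_lt(abs(est$tau), 2e-4)
})

test_that("individual distances match a site-by-site brute-force recount", {
  m <- twoPopModel(theta = 0.004, tau = 0.003)
  ds <- simulateDataset(m, c(A = 2, B = 2), n_loci = 60, locus_length = 300,
                        missingness_rate = 0.1, seed = 8)
  ind <- individuals(ds)
  for (metric in c("allele-sharing", "euclidean-dosage")) {
    D <- geneticDistanceMatrix(ds, metric)
    expect_true(all(diag(D) == 0))
    expect_equal(D, t(D))
    # brute force for one pair
    a <- 1; b <- 3
    tot <- 0; S <- 0
    for (k in seq_len(nLoci(ds))) {
      if (missingMask(ds)[a, k] || missingMask(ds)[b, k]) next
      da <- ds@loci[[k]]$mat[ind$hap1[a], ] + ds@loci[[k]]$mat[ind$hap2[a], ]
      db <- ds@loci[[k]]$mat[ind$hap1[b], ] + ds@loci[[k]]$mat[ind$hap2[b], ]
      S <- S + length(da)
      tot <- tot + if (metric == "allele-sharing") sum(abs(da - db)) else
        sum((da - db)^2)
    }
    want <- if (metric == "allele-sharing") tot / (2 * S) else sqrt(tot / S)
    expect_equal(unname(D[a, b]), want)
  }
})

test_that("opposite homozygotes at every site are at allele-sharing distance 1", {
  ds <- datasetFromMatrix(rbind(matrix(0L, 2, 10), matrix(1L, 2, 10)),
                          pops = c("A", "B"))
  D <- geneticDistanceMatrix(ds, "allele-sharing")
  expect_equal(unname(D[1, 2]), 1)
})

test_that("statistics are invariant to individual and locus ordering", {
  m <- twoPopModel(theta = 0.003, tau = 0.001)
  ds <- simulateDataset(m, c(A = 2, B = 2), n_loci = 40, locus_length = 300,
                        seed = 31)
  perm <- rev(seq_len(nLoci(ds)))
  ds_rev <- ds
  ds_rev@loci <- ds@loci[perm]
  ds_rev@missing <- ds@missing[, perm, drop = FALSE]
  expect_equal(as.numeric(weightedFst(jointSfs(ds, "A", "B", TRUE))),
               as.numeric(weightedFst(jointSfs(ds_rev, "A", "B", TRUE))))
  expect_equal(diversityStats(ds, "A"), diversityStats(ds_rev, "A"))

  iperm <- c(3, 1, 4, 2)
  ds_i <- ds
  ds_i@individuals <- ds@individuals[iperm, ]
  ds_i@missing <- ds@missing[iperm, , drop = FALSE]
  expect_equal(as.numeric(weightedFst(jointSfs(ds_i, "A", "B", TRUE))),
               as.numeric(weightedFst(jointSfs(ds, "A", "B", TRUE))))
})

test_that("Mantel statistic and permutation p behave as specified", {
  set.seed(23)
  D1 <- randomDistanceMatrix(6)
  D2 <- 2 * D1 + 1; diag(D2) <- 0
  res <- mantelTest(D1, D2, n_permutations = 99, seed = 1)
  expect_equal(res$r, 1)

  # exhaustive enumeration oracle at n = 5: all 120 joint permutations
  set.seed(24)
  E1 <- randomDistanceMatrix(5)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:5)), ]
  lt <- lower.tri(E1)
  r_obs <- 1  # D2 = D1
  r_all <- apply(perms, 1, function(p) stats::cor(E1[lt], E1[p, p][lt]))
  exact_p <- sum(r_all >= r_obs - 1e-10) / nrow(perms)
  res2 <- mantelTest(E1, E1, n_permutations = 999, seed = 2)
  # sampled p converges to the exact enumeration value
  expect_lt(abs(res2$p - exact_p), 3 * sqrt(exact_p * (1 - exact_p) / 999) + 2e-3)

  # independent package cross-check of the observed statistic
  skip_if_not_installed("vegan")
  set.seed(25)
  G1 <- randomDistanceMatrix(8); G2 <- randomDistanceMatrix(8)
  vr <- vegan::mantel(stats::as.dist(G1), stats::as.dist(G2),
                      permutations = 99)
  expect_equal(mantelTest(G1, G2, 99, seed = 3)$r, unname(vr$statistic),
               tolerance = 1e-12)
})

test_that("Mantel errors on degenerate input", {
  D <- randomDistanceMatrix(3)
  expect_error(mantelTest(D, D), "at least 4")
  Z <- matrix(0, 5, 5)
  expect_error(mantelTest(Z, Z), "zero variance")
  A <- randomDistanceMatrix(5); B <- randomDistanceMatrix(5, letters[1:5])
  expect_error(mantelTest(A, B), "labels")
})

test_that("SFS and distance matrices round-trip through their TSV formats", {
  m <- twoPopModel()
  ds <- simulateDataset(m, c(A = 2, B = 2), n_loci = 30, seed = 77)
  s <- jointSfs(ds, "A", "B", folded = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSfs(s, f)
  s2 <- readSfs(f)
  expect_equal(s2@counts, s@counts)
  expect_equal(s2@folded, s@folded)
  expect_equal(s2@pops, s@pops)

  D <- geneticDistanceMatrix(ds)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrix(D, f2)
  D2 <- readDistanceMatrix(f2)
  expect_equal(D2, D[, ], tolerance = 1e-12)  # subsetting drops the metric tag
})
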