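test_that("gdi point values follow the closed form", {
  expect_equal(gdiPoint(0, 0.002), 0)
  expect_equal(gdiPoint(log(2) / 2 * 0.002, 0.002), 0.5)
  expect_equal(gdiPoint(0.001, 0.002), 1 - exp(-1))
  expect_error(gdiPoint(0.001, 0), "theta")
  expect_error(gdiPoint(-1, 0.1), "tau")
})

test_that("gdi is increasing in tau and decreasing in theta", {
  set.seed(51)
  # grid kept away from saturation (2 tau / theta <= ~2) so that strict
  # inequalities remain resolvable in double precision
  for (i in 1:50) {
    tau <- stats::runif(1, 1e-5, 1e-3)
    theta <- stats::runif(1, 1e-3, 1e-2)
    eps <- 1e-6
    expect_gt(gdiPoint(tau + eps, theta), gdiPoint(tau, theta))
    expect_lt(gdiPoint(tau, theta + eps * theta), gdiPoint(tau, theta))
  }
})

test_that("classification applies the 0.2 / 0.7 rule with ambiguous boundaries", {
  expect_equal(classifyGdi(0.15), "intraspecific")
  expect_equal(classifyGdi(0.933), "species-level")
  expect_equal(classifyGdi(0.5), "ambiguous")
  expect_equal(classifyGdi(c(0.2, 0.7)), c("ambiguous", "ambiguous"))
  expect_error(classifyGdi(1), "\\[0, 1\\)")
})

test_that("posterior gdi reduces to the point value on a constant trace", {
  m <- twoPopModel()
  tr <- syntheticTrace(m, n_samples = 100, n_chains = 1, rel_sd = 1e-15,
                       seed = 3)
  est <- gdiPosterior(tr, "R", "A")
  want <- gdiPoint(0.001, 0.002)
  expect_equal(est$mean, want, tolerance = 1e-9)
  expect_equal(est$lower, est$mean, tolerance = 1e-9)

  # smaller theta gives larger gdi when swapping the reference daughter
  m2 <- twoPopModel(theta = c(0.001, 0.004))
  tr2 <- syntheticTrace(m2, n_samples = 100, n_chains = 1, rel_sd = 1e-15,
                        seed = 3)
  expect_gt(gdiPosterior(tr2, "R", "A")$mean, gdiPosterior(tr2, "R", "B")$mean)
})

test_that("posterior mean gdi matches direct numerical integration", {
  set.seed(52)
  n <- 200000
  tau <- stats::rnorm(n, 0.001, 1e-4)
  tau <- tau[tau > 0]
  theta <- 0.002
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(`tau_R` = tau, `theta_A` = theta,
                                check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- readTrace(f, burnin_fraction = 0)
  est <- gdiPosterior(tr, "R", "A")
  quad <- stats::integrate(function(t)
    (1 - exp(-2 * t / theta)) * stats::dnorm(t, 0.001, 1e-4) /
      stats::pnorm(0.001 / 1e-4),
    lower = 0, upper = 0.002)$value
  expect_lt(abs(est$mean - quad), 5e-4)  # MC standard error is ~1e-4
})

test_that("gdi equals the probability of coalescence before the split", {
  set.seed(53)
  theta <- 0.002
  for (ratio in c(0.5, 2)) {
    tau <- ratio * theta / 2  # so 2 tau / theta = ratio
    m <- twoPopModel(theta = theta, tau = tau, theta_anc = theta)
    tt <- pairCoalTimes(m, c(A = 2), 4000, haplotypes = TRUE)
    phat <- mean(tt < tau)
    want <- gdiPoint(tau, theta)
    ci <- 2.58 * sqrt(want * (1 - want) / 4000)
    expect_lt(abs(phat - want), ci + 1e-3)
  }
})

test_that("aggregation averages pairs and theta choices per posterior sample", {
  m <- exampleDemography()
  nomig <- m
  nomig@bands <- m@bands[0, ]
  tr <- syntheticTrace(nomig, n_samples = 300, n_chains = 2, seed = 9)
  set1 <- c("Sahamamy", "Andobo")
  set2 <- c("VohiposaSahafina", "Antanambao")
  agg <- gdiAggregate(tr, m, set1, set2)

  # brute-force recomputation over pairs x theta choices x samples
  s <- traceSamples(tr)
  acc <- 0; cnt <- 0
  for (a in set1) for (b in set2) {
    nd <- mrcaNode(m, a, b)
    for (th in c(a, b)) {
      acc <- acc + gdiPoint(s[, paste0("tau_", nd)], s[, paste0("theta_", th)])
      cnt <- cnt + 1
    }
  }
  g <- acc / cnt
  expect_equal(agg$mean, mean(g), tolerance = 1e-12)
  expect_equal(c(agg$lower, agg$upper), unname(hpdInterval(g)),
               tolerance = 1e-12)

  # one population per side reduces to the mean of the two theta choices
  one <- gdiAggregate(tr, m, "Sahamamy", "Andobo")
  nd <- mrcaNode(m, "Sahamamy", "Andobo")
  gg <- (gdiPoint(s[, paste0("tau_", nd)], s[, "theta_Sahamamy"]) +
         gdiPoint(s[, paste0("tau_", nd)], s[, "theta_Andobo"])) / 2
  expect_equal(one$mean, mean(gg), tolerance = 1e-12)
})

test_that("a migration-model trace triggers the convention warning", {
  m <- twoPopModel(m = 10)
  tr <- syntheticTrace(m, n_samples = 60, n_chains = 1, seed = 12)
  expect_warning(gdiPosterior(tr, "R", "A"), "no-migration")
})

test_that("the gdi table reports two theta choices per internal node", {
  m <- exampleDemography()
  nomig <- m
  nomig@bands <- m@bands[0, ]
  tr <- syntheticTrace(nomig, n_samples = 100, n_chains = 1, seed = 13)
  tab <- gdiTable(tr, nomig)
  expect_equal(nrow(tab), 12)  # 6 internal nodes x 2 daughters
  expect_true(all(tab$category %in%
                  c("intraspecific", "ambiguous", "species-level")))
})
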