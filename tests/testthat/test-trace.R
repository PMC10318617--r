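writeToyTrace <- function(path, n = 100, cols = c("Sample", "theta_A",
                                                  "tau_R", "m_A->B"),
                          gen = NULL) {
  if (is.null(gen))
    gen <- function(cn, n) if (cn == "Sample") seq_len(n) else
      stats::runif(n, 0.001, 0.002)
  df <- as.data.frame(lapply(cols, gen, n = n), check.names = FALSE)
  names(df) <- cols
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("burn-in removal and chain concatenation follow the ceiling rule", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(41)
  writeToyTrace(f, n = 1000)
  tr <- readTrace(f, burnin_fraction = 0.10)
  expect_equal(nrow(traceSamples(tr)), 900)
  tr0 <- readTrace(f, burnin_fraction = 0)
  expect_equal(nrow(traceSamples(tr0)), 1000)

  fs <- replicate(4, writeToyTrace(tempfile(fileext = ".tsv"), n = 100))
  withr::defer(unlink(fs))
  tr4 <- readTrace(fs, burnin_fraction = 0.10)
  expect_equal(nrow(traceSamples(tr4)), 360)
  expect_equal(as.vector(table(traceChains(tr4))), rep(90L, 4))

  # column roles
  roles <- traceRoles(tr)
  expect_equal(roles$role, c("other", "theta", "tau", "m"))
  expect_equal(roles$id[4], "A->B")
  expect_equal(roles$source[4], "A")
})

test_that("trace reading rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("theta_A\ttau_R", "0.1\tx", "0.2\t0.3"), f)
  expect_error(readTrace(f), "non-numeric")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("theta_A", "0.1"), f2)
  expect_error(readTrace(f2, burnin_fraction = 0.9), "zero retained")
})

test_that("traces round-trip through write and read", {
  m <- twoPopModel(m = 10)
  tr <- syntheticTrace(m, n_samples = 50, n_chains = 2, seed = 4)
  base <- withr::local_tempfile(fileext = ".tsv")
  paths <- writeTrace(tr, base)
  tr2 <- readTrace(paths, burnin_fraction = 0)
  expect_equal(traceSamples(tr2), traceSamples(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(traceChains(tr2), traceChains(tr))
})

test_that("HPD is the narrowest sorted window, first on ties", {
  expect_equal(hpdInterval(rep(3.3, 10)), c(3.3, 3.3))
  expect_equal(hpdInterval(1:100, 0.95), c(1, 95))
  set.seed(42)
  for (i in 1:200) {
    x <- switch(1 + i %% 3,
                stats::rnorm(sample(10:200, 1)),
                stats::rexp(sample(10:200, 1)),
                sample(1:20, sample(10:50, 1), replace = TRUE))
    mass <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_equal(hpdInterval(x, mass), bruteForceHpd(x, mass))
  }
})

test_that("ESS matches closed forms for iid and AR(1) series", {
  set.seed(43)
  x <- stats::rnorm(10000)
  expect_lt(abs(effectiveSampleSize(x) - 10000) / 10000, 0.1)

  phi <- 0.5
  n <- 40000
  ar <- stats::arima.sim(list(ar = phi), n)
  want <- n * (1 - phi) / (1 + phi)
  expect_lt(abs(effectiveSampleSize(as.numeric(ar)) - want) / want, 0.1)

  alt <- rep(c(1, -1), 500)
  expect_equal(effectiveSampleSize(alt), 1000)  # capped at n
  expect_warning(essc <- effectiveSampleSize(rep(2, 100)), "constant")
  expect_equal(as.numeric(essc), 100)
})

test_that("calibration draws hit the stated lognormal and gamma moments", {
  set.seed(44)
  cal <- drawCalibrations(scaleConfig(), 100000)
  expect_lt(abs(stats::median(cal$g) - 3.5) / 3.5, 0.01)
  expect_lt(abs(mean(cal$mu) - 1.236e-8) / 1.236e-8, 0.005)
  expect_lt(abs(stats::sd(cal$mu) - 0.107e-8) / 0.107e-8, 0.02)

  fixed <- drawCalibrations(scaleConfig(g_fixed = 3.5, mu_fixed = 1.236e-8), 50)
  expect_true(all(fixed$g == 3.5) && all(fixed$mu == 1.236e-8))
})

test_that("unit conversion arithmetic is exact", {
  r <- convertSample(theta = 0.001, tau = 0.0015, m = 100,
                     theta_target = 0.002, g = 3.5, mu = 1.236e-8)
  expect_equal(r$Ne, 0.001 / (4 * 1.236e-8))      # ~20,227
  expect_equal(r$T_years, 0.0015 / 1.236e-8 * 3.5) # ~424,757
  expect_equal(r$Nm2, 0.1)
  expect_equal(convertSample(m = 0, theta_target = 5)$Nm2, 0)
  # 2Nm does not involve mu or g at all
  r2 <- convertSample(m = 100, theta_target = 0.002, g = 99, mu = 1)
  expect_equal(r2$Nm2, 0.1)
  expect_error(convertSample(theta = 1, mu = 0), "mu")
})

test_that("Monte-Carlo conversion is deterministic under fixed calibrations", {
  m <- twoPopModel(m = 25)
  tr <- syntheticTrace(m, n_samples = 200, n_chains = 2, seed = 6)
  sc <- scaleConfig(g_fixed = 3.5, mu_fixed = 1.236e-8)
  cv <- monteCarloConvert(tr, m, sc, seed = 1)
  s <- traceSamples(tr)
  expect_equal(unname(cv@samples[, "Ne_A"]),
               unname(s[, "theta_A"] / (4 * 1.236e-8)))
  expect_equal(unname(cv@samples[, "T_R"]),
               unname(s[, "tau_R"] / 1.236e-8 * 3.5))
  expect_equal(unname(cv@samples[, "M2Nm_A.B"]),
               unname(s[, "m_A->B"] * s[, "theta_B"] / 2))
  # identical across seeds in fixed mode
  cv2 <- monteCarloConvert(tr, m, sc, seed = 999)
  expect_equal(cv@samples, cv2@samples)
})

test_that("widening the generation-time prior widens every divergence HPD", {
  m <- twoPopModel(m = 0)
  tr <- syntheticTrace(m, n_samples = 400, n_chains = 1, seed = 7)
  for (s in 1:10) {
    narrow <- monteCarloConvert(tr, m, scaleConfig(), seed = s)
    wide <- monteCarloConvert(tr, m, scaleConfig(g_sdlog = 2 * log(1.16)),
                              seed = s)
    hn <- hpdInterval(narrow@samples[, "T_R"])
    hw <- hpdInterval(wide@samples[, "T_R"])
    expect_gt(diff(hw), diff(hn))
  }
})

test_that("a degenerate trace isolates the calibration-induced HPD width", {
  m <- twoPopModel()
  tau0 <- 0.001
  tr <- syntheticTrace(m, n_samples = 5000, n_chains = 1, rel_sd = 1e-12,
                       seed = 8)
  cv <- monteCarloConvert(tr, m, scaleConfig(), seed = 9)
  hT <- hpdInterval(cv@samples[, "T_R"])
  # direct simulation of (tau/mu) * g with the same calibration laws
  set.seed(10)
  cal <- drawCalibrations(scaleConfig(), 200000)
  hRef <- hpdInterval(tau0 / cal$mu * cal$g)
  expect_lt(abs(diff(hT) - diff(hRef)) / diff(hRef), 0.1)
})

test_that("posterior summaries report both replicate-run conventions", {
  s <- summarizePosterior(rep(4.2, 10))
  expect_equal(s$mean, 4.2)
  expect_equal(c(s$lower, s$upper), c(4.2, 4.2))

  two <- summarizePosterior(c(rep(1, 50), rep(3, 50)),
                            chain = rep(1:2, each = 50))
  expect_equal(two$mean_of_chain_means, 2)

  set.seed(45)
  u <- stats::runif(100000)
  su <- summarizePosterior(u)
  expect_lt(abs(su$mean - 0.5), 0.01)
  expect_lt(abs((su$upper - su$lower) - 0.95), 0.01)
})

test_that("band screening keeps exactly the bands bounded away from zero", {
  set.seed(46)
  n <- 2000
  cols <- list(Sample = seq_len(n))
  for (i in 1:12) cols[[sprintf("m_P%02d->Q%02d", i, i)]] <-
    stats::rlnorm(n, log(10 + i), 0.2)        # support well above 0
  for (i in 13:20) cols[[sprintf("m_P%02d->Q%02d", i, i)]] <-
    stats::rexp(n) * stats::rbinom(n, 1, 0.5) # >= 5% exact zeros
  df <- as.data.frame(cols, check.names = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- readTrace(f, burnin_fraction = 0)
  rep_ <- screenMigrationBands(tr)
  expect_equal(sum(rep_$retained), 12)
  expect_true(all(rep_$retained[1:12]))
  expect_false(any(rep_$retained[13:20]))
  # a band with every sample >= 10 is retained
  expect_true(all(rep_$lower[1:12] > 0))
})
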