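# Shared model builders and oracles for the test suite.

# single panmictic population (no internal nodes)
onePopModel <- function(theta = 0.002, id = "P") {
  demographyModel(
    populations = data.frame(id = id, tip = TRUE),
    edges = data.frame(child = character(), parent = character()),
    theta = stats::setNames(theta, id),
    tau = stats::setNames(numeric(0), character(0))
  )
}

# two tips A, B under root R, optional symmetric migration
twoPopModel <- function(theta = 0.002, tau = 0.001, theta_anc = theta[1],
                        m = 0) {
  th <- if (length(theta) == 1) c(A = theta, B = theta) else
    c(A = theta[1], B = theta[2])
  mod <- demographyModel(
    populations = data.frame(id = c("A", "B", "R"),
                             tip = c(TRUE, TRUE, FALSE)),
    edges = data.frame(child = c("A", "B"), parent = c("R", "R")),
    theta = c(th, R = theta_anc),
    tau = c(R = tau)
  )
  if (m > 0) mod <- addBidirectionalBand(mod, "A", "B", m)
  mod
}

# three-level tree: ((A,B)AB,C)R — for interval and MRCA logic
threePopModel <- function(tau1 = 0.001, tau2 = 0.002, theta = 0.002) {
  demographyModel(
    populations = data.frame(id = c("A", "B", "C", "AB", "R"),
                             tip = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
    edges = data.frame(child = c("A", "B", "AB", "C"),
                       parent = c("AB", "AB", "R", "R")),
    theta = stats::setNames(rep(theta, 5), c("A", "B", "C", "AB", "R")),
    tau = c(AB = tau1, R = tau2)
  )
}

# TMRCA of replicate pairwise simulations
pairCoalTimes <- function(model, samples, n, haplotypes = TRUE) {
  vapply(seq_len(n), function(i)
    tmrca(simulateGenealogy(model, samples, haplotypes = haplotypes)),
    numeric(1))
}

# hand-built MultilocusDataset: one locus from an explicit haplotype matrix
datasetFromMatrix <- function(mat, pops, length = 1000, positions = NULL) {
  n <- nrow(mat)
  stopifnot(n %% 2 == 0, length(pops) == n / 2)
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  ind <- data.frame(
    id = paste0(pops, "_", stats::ave(seq_along(pops), pops, FUN = seq_along)),
    population = pops,
    hap1 = seq(1, n, by = 2), hap2 = seq(2, n, by = 2),
    stringsAsFactors = FALSE)
  new("MultilocusDataset",
      loci = list(list(length = length, mat = mat, positions = positions)),
      individuals = ind,
      missing = matrix(FALSE, n / 2, 1),
      provenance = list())
}

# brute-force per-site recount of the joint SFS (independent of jointSfs)
bruteForceSfs <- function(dataset, popA, popB, folded = FALSE) {
  ind <- individuals(dataset)
  ia <- which(ind$population == popA); ib <- which(ind$population == popB)
  ra <- c(ind$hap1[ia], ind$hap2[ia]); rb <- c(ind$hap1[ib], ind$hap2[ib])
  n1 <- length(ra); n2 <- length(rb)
  counts <- matrix(0, n1 + 1, n2 + 1)
  for (k in seq_len(nLoci(dataset))) {
    if (any(missingMask(dataset)[c(ia, ib), k])) next
    mat <- dataset@loci[[k]]$mat
    for (s in seq_len(ncol(mat))) {
      i <- sum(mat[ra, s]); j <- sum(mat[rb, s])
      if (folded && (i + j) > (n1 + n2) / 2) { i <- n1 - i; j <- n2 - j }
      counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1
    }
  }
  counts
}

# independent per-site ratio-of-sums Hudson F_ST (spreadsheet-style oracle)
bruteForceHudsonFst <- function(sites, n1, n2) {
  num <- 0; den <- 0
  for (r in seq_len(nrow(sites))) {
    i <- sites[r, 1]; j <- sites[r, 2]
    if ((i == 0 && j == 0) || (i == n1 && j == n2)) next
    p1 <- i / n1; p2 <- j / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

# brute-force narrowest-window HPD scan (oracle for hpdInterval)
bruteForceHpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[k]); bw <- x[k] - x[1]
  for (i in 2:(n - k + 1)) {
    w <- x[i + k - 1] - x[i]
    if (w < bw - 0) { bw <- w; best <- c(x[i], x[i + k - 1]) }
  }
  best
}

# random symmetric distance matrix with zero diagonal
randomDistanceMatrix <- function(n, labels = paste0("s", seq_len(n))) {
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  M[lower.tri(M)] <- stats::runif(n * (n - 1) / 2)
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

# pairwise coalescence times from msprime (independent coalescent engine),
# 2-population isolation-with-migration, one haplotype per population,
# symmetric mutation-scaled migration. Time is scaled so one msprime
# generation equals one tau unit (population size theta/2 at ploidy 1 gives
# pairwise rate 2/theta).
msprimePairTimes <- function(theta1, theta2, theta_anc, tau, m, n, seed) {
  script <- sprintf('
import msprime
dem = msprime.Demography()
dem.add_population(name="A", initial_size=%.17g)
dem.add_population(name="B", initial_size=%.17g)
dem.add_population(name="anc", initial_size=%.17g)
dem.add_population_split(time=%.17g, derived=["A", "B"], ancestral="anc")
dem.set_migration_rate(source="A", dest="B", rate=%.17g)
dem.set_migration_rate(source="B", dest="A", rate=%.17g)
for ts in msprime.sim_ancestry(samples={"A": 1, "B": 1}, ploidy=1,
                               demography=dem, num_replicates=%d,
                               random_seed=%d):
    print(ts.max_root_time)
', theta1 / 2, theta2 / 2, theta_anc / 2, tau, m, m, n, seed)
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = FALSE))
  times <- suppressWarnings(as.numeric(out))
  times[is.finite(times)]
}

# per-locus statistics (for standard-error computations across loci)
perLocusPi <- function(dataset, pop) {
  ind <- individuals(dataset)
  sel <- which(ind$population == pop)
  rows <- c(ind$hap1[sel], ind$hap2[sel])
  n <- length(rows)
  vapply(seq_len(nLoci(dataset)), function(k) {
    loc <- dataset@loci[[k]]
    if (ncol(loc$mat) == 0) return(0)
    i <- colSums(loc$mat[rows, , drop = FALSE])
    sum(2 * i * (n - i)) / (n * (n - 1)) / loc$length
  }, numeric(1))
}

perLocusS <- function(dataset, pop) {
  ind <- individuals(dataset)
  sel <- which(ind$population == pop)
  rows <- c(ind$hap1[sel], ind$hap2[sel])
  n <- length(rows)
  vapply(seq_len(nLoci(dataset)), function(k) {
    loc <- dataset@loci[[k]]
    if (ncol(loc$mat) == 0) return(0)
    i <- colSums(loc$mat[rows, , drop = FALSE])
    sum(i > 0 & i < n) / loc$length
  }, numeric(1))
}

perLocusDxy <- function(dataset, popA, popB) {
  ind <- individuals(dataset)
  sa <- which(ind$population == popA); sb <- which(ind$population == popB)
  ra <- c(ind$hap1[sa], ind$hap2[sa]); rb <- c(ind$hap1[sb], ind$hap2[sb])
  n1 <- length(ra); n2 <- length(rb)
  vapply(seq_len(nLoci(dataset)), function(k) {
    loc <- dataset@loci[[k]]
    if (ncol(loc$mat) == 0) return(0)
    i <- colSums(loc$mat[ra, , drop = FALSE])
    j <- colSums(loc$mat[rb, , drop = FALSE])
    sum(i * (n2 - j) + (n1 - i) * j) / (n1 * n2) / loc$length
  }, numeric(1))
}
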