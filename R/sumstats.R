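# Population-genetic summaries on MultilocusDataset objects. All statistics
# are complete-case per site within each computation (whole-locus dropout is
# the missingness mode, so a site is complete iff every individual of the
# populations involved carries the locus), invariant to individual and locus
# ordering, and weighted across loci by locus length where per-site rates
# are reported.

# haplotype row indices of a population's individuals (error if unknown)
.hapRows <- function(dataset, pop) {
  ind <- dataset@individuals
  sel <- ind$population == pop
  if (!any(sel)) .stopf("unknown population '%s'", pop)
  list(rows = c(ind$hap1[sel], ind$hap2[sel]), ind = which(sel))
}

#' Joint two-population site frequency spectrum
#'
#' Counts every complete-case biallelic site into one cell of the
#' `(n1 + 1) x (n2 + 1)` matrix of derived-allele counts. In folded mode each
#' site is oriented by the pooled two-population minor allele (sites at
#' exactly 50% pooled frequency keep their derived orientation), matching
#' MAF spectra produced jointly per population pair.
#'
#' @param dataset a `MultilocusDataset`.
#' @param popA,popB population ids.
#' @param folded orient sites by the pooled minor allele.
#' @return an [SFS2D-class].
#' @export
jointSfs <- function(dataset, popA, popB, folded = FALSE) {
  a <- .hapRows(dataset, popA)
  b <- .hapRows(dataset, popB)
  n1 <- length(a$rows); n2 <- length(b$rows)
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  usable <- 0L
  for (k in seq_len(nLoci(dataset))) {
    if (any(dataset@missing[c(a$ind, b$ind), k])) next
    usable <- usable + 1L
    mat <- dataset@loci[[k]]$mat
    if (ncol(mat) == 0) next
    i <- colSums(mat[a$rows, , drop = FALSE])
    j <- colSums(mat[b$rows, , drop = FALSE])
    if (folded) {
      flip <- (i + j) > (n1 + n2) / 2
      i[flip] <- n1 - i[flip]
      j[flip] <- n2 - j[flip]
    }
    tab <- table(factor(i, levels = 0:n1), factor(j, levels = 0:n2))
    counts <- counts + unclass(tab)
  }
  if (usable == 0L) .stopf("no locus is complete in both populations")
  dimnames(counts) <- NULL
  new("SFS2D", counts = counts, n1 = as.integer(n1), n2 = as.integer(n2),
      folded = folded, pops = c(popA, popB))
}

#' @export
setMethod("show", "SFS2D", function(object) {
  cat(sprintf("SFS2D (%s): %s (n1=%d) x %s (n2=%d), %d sites, %d polymorphic\n",
              if (object@folded) "folded" else "unfolded",
              object@pops[1], object@n1, object@pops[2], object@n2,
              sum(object@counts),
              sum(object@counts) - object@counts[1, 1] -
                object@counts[object@n1 + 1, object@n2 + 1]))
  invisible(object)
})

# Per-cell numerator/denominator of the two ratio-of-sums F_ST estimators
# (haploid sample sizes n1, n2; sample frequencies p1, p2).
# hudson: num = (p1-p2)^2 - p1 q1/(n1-1) - p2 q2/(n2-1), den = p1 q2 + p2 q1.
# reynolds: method-of-moments coancestry estimator in the
# Reynolds-Weir-Cockerham framework, which corrects the squared frequency
# difference with the sample-size-weighted POOLED unbiased gene diversity
# hbar = [n1^2/(n1-1) 2 p1 q1 + n2^2/(n2-1) 2 p2 q2] / (n1 + n2):
#   a = 2 (p1-p2)^2 - hbar (1/n1 + 1/n2)   (E[a] = 2 theta P)
#   b = 2 hbar                             (E[b] = 2 (1-theta) P)
# and F = a / (a + b). Both estimators give 1 on fixed differences, are
# invariant to folding, and agree as n1, n2 -> Inf; they differ at finite n
# through the per-population versus pooled heterozygosity correction (see
# the methods vignette for the derivation).
.fstCell <- function(i, j, n1, n2, estimator) {
  p1 <- i / n1; p2 <- j / n2
  q1 <- 1 - p1; q2 <- 1 - p2
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * q1 / (n1 - 1) - p2 * q2 / (n2 - 1)
    den <- p1 * q2 + p2 * q1
  } else {
    hbar <- (n1^2 / (n1 - 1) * 2 * p1 * q1 +
             n2^2 / (n2 - 1) * 2 * p2 * q2) / (n1 + n2)
    num <- 2 * (p1 - p2)^2 - hbar * (1 / n1 + 1 / n2)
    den <- num + 2 * hbar
  }
  c(num, den)
}

#' Weighted F_ST from a joint SFS
#'
#' Ratio-of-sums ("weighted") fixation index: per-site numerators and
#' denominators are summed over all sites polymorphic in the pooled pair and
#' the ratio is taken once, \eqn{F_{ST} = \sum num / \sum den}. Cells
#' monomorphic across the pooled pair contribute nothing. The `hudson`
#' estimator is the default; `reynolds` implements the
#' Reynolds-Weir-Cockerham coancestry numerator/denominator under the same
#' weighting (both share the unbiased numerator and agree at large sample
#' sizes). Both are invariant to folding.
#'
#' @param sfs an `SFS2D` with `n1, n2 >= 2`.
#' @param estimator `"hudson"` (default) or `"reynolds"`.
#' @return F_ST value with attribute `estimator`.
#' @export
weightedFst <- function(sfs, estimator = c("hudson", "reynolds")) {
  estimator <- match.arg(estimator)
  n1 <- sfs@n1; n2 <- sfs@n2
  if (n1 < 2 || n2 < 2) .stopf("need n1, n2 >= 2")
  num <- 0; den <- 0
  nz <- which(sfs@counts > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1] - 1L; j <- nz[r, 2] - 1L
    if ((i == 0 && j == 0) || (i == n1 && j == n2)) next
    nd <- .fstCell(i, j, n1, n2, estimator)
    cnt <- sfs@counts[nz[r, 1], nz[r, 2]]
    num <- num + cnt * nd[1]
    den <- den + cnt * nd[2]
  }
  if (den == 0) .stopf("no polymorphic sites: F_ST undefined")
  structure(num / den, estimator = estimator)
}

#' Slatkin's linearization of F_ST
#'
#' `fst / (1 - fst)`, the monotone transform plotted against log geographic
#' distance in isolation-by-distance analyses.
#'
#' @param fst F_ST value(s), each `< 1`.
#' @return linearized value(s).
#' @export
slatkinLinearize <- function(fst) {
  fst <- as.numeric(fst)
  if (any(fst >= 1)) .stopf("Slatkin linearization undefined for fst >= 1")
  fst / (1 - fst)
}

#' Diversity and divergence statistics
#'
#' Within-population nucleotide diversity \eqn{\pi} (mean pairwise
#' difference per site), segregating sites per site, and Watterson's
#' \eqn{\hat\theta_W = S / (a_{n-1} \sum L)} with
#' \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i}; for a pair of populations also the
#' mean between-population pairwise difference per site \eqn{d_{xy}}. All
#' per-site rates are totals over complete-case loci divided by the total
#' length of those loci.
#'
#' @param dataset a `MultilocusDataset`.
#' @param pop one population id, or a character vector of two.
#' @return named list: `pi`, `s_per_site`, `theta_w` for one population;
#'   for a pair, those per population (suffixed by id) plus `dxy`.
#' @export
diversityStats <- function(dataset, pop) {
  if (length(pop) == 1) return(.withinStats(dataset, pop))
  if (length(pop) != 2) .stopf("pop must name one or two populations")
  a <- .withinStats(dataset, pop[1])
  b <- .withinStats(dataset, pop[2])
  out <- list(pi = stats::setNames(c(a$pi, b$pi), pop),
              s_per_site = stats::setNames(c(a$s_per_site, b$s_per_site), pop),
              theta_w = stats::setNames(c(a$theta_w, b$theta_w), pop),
              dxy = dxy(dataset, pop[1], pop[2]))
  out
}

.withinStats <- function(dataset, pop) {
  h <- .hapRows(dataset, pop)
  n <- length(h$rows)
  if (n < 2) .stopf("need >= 2 haplotypes in '%s'", pop)
  an <- sum(1 / seq_len(n - 1))
  diffs <- 0; S <- 0; totlen <- 0
  for (k in seq_len(nLoci(dataset))) {
    if (any(dataset@missing[h$ind, k])) next
    loc <- dataset@loci[[k]]
    totlen <- totlen + loc$length
    if (ncol(loc$mat) == 0) next
    i <- colSums(loc$mat[h$rows, , drop = FALSE])
    seg <- i > 0 & i < n
    S <- S + sum(seg)
    diffs <- diffs + sum(2 * i * (n - i)) / (n * (n - 1))
  }
  if (totlen == 0) .stopf("no complete locus for population '%s'", pop)
  list(pi = diffs / totlen, s_per_site = S / totlen,
       theta_w = S / (an * totlen))
}

#' Mean between-population divergence per site
#' @inheritParams diversityStats
#' @param popA,popB population ids.
#' @return \eqn{d_{xy}} per site.
#' @export
dxy <- function(dataset, popA, popB) {
  a <- .hapRows(dataset, popA)
  b <- .hapRows(dataset, popB)
  n1 <- length(a$rows); n2 <- length(b$rows)
  diffs <- 0; totlen <- 0
  for (k in seq_len(nLoci(dataset))) {
    if (any(dataset@missing[c(a$ind, b$ind), k])) next
    loc <- dataset@loci[[k]]
    totlen <- totlen + loc$length
    if (ncol(loc$mat) == 0) next
    i <- colSums(loc$mat[a$rows, , drop = FALSE])
    j <- colSums(loc$mat[b$rows, , drop = FALSE])
    diffs <- diffs + sum(i * (n2 - j) + (n1 - i) * j) / (n1 * n2)
  }
  if (totlen == 0) .stopf("no locus complete in both populations")
  diffs / totlen
}

#' Moment estimators of theta and divergence time
#'
#' Watterson's estimator per population and the net-divergence time
#' estimator \eqn{\hat\tau = [d_{xy} - (\pi_A + \pi_B)/2] / 2}, unbiased in
#' expectation under isolation without migration when the ancestral theta
#' equals the contemporary ones (biased otherwise; a lightweight recovery
#' check, not an inference method).
#'
#' @param dataset a `MultilocusDataset`.
#' @param popA,popB population ids.
#' @return list with `theta_A`, `theta_B`, `tau`.
#' @export
momentEstimates <- function(dataset, popA, popB) {
  a <- .withinStats(dataset, popA)
  b <- .withinStats(dataset, popB)
  d <- dxy(dataset, popA, popB)
  list(theta_A = a$theta_w, theta_B = b$theta_w,
       tau = (d - (a$pi + b$pi) / 2) / 2)
}

#' Individual genetic distance matrix
#'
#' Pairwise distances between diploid individuals over pairwise-complete
#' sites. `allele-sharing` is one minus the proportion of shared alleles,
#' \eqn{\sum_s |d_a - d_b| / (2 S)} on 0/1/2 dosages; `euclidean-dosage` is
#' the Euclidean dosage distance scaled by the square root of the number of
#' compared sites, \eqn{\sqrt{\sum_s (d_a - d_b)^2 / S}}.
#'
#' @param dataset a `MultilocusDataset`.
#' @param metric `"allele-sharing"` (default) or `"euclidean-dosage"`.
#' @return symmetric labelled matrix with zero diagonal and attribute
#'   `metric`.
#' @export
geneticDistanceMatrix <- function(dataset,
                                  metric = c("allele-sharing",
                                             "euclidean-dosage")) {
  metric <- match.arg(metric)
  ind <- dataset@individuals
  ni <- nrow(ind)
  if (ni < 2) .stopf("need >= 2 individuals")
  nl <- nLoci(dataset)
  dosage <- lapply(seq_len(nl), function(k) {
    loc <- dataset@loci[[k]]
    loc$mat[ind$hap1, , drop = FALSE] + loc$mat[ind$hap2, , drop = FALSE]
  })
  nsites <- vapply(dosage, ncol, integer(1))
  D <- matrix(0, ni, ni, dimnames = list(ind$id, ind$id))
  for (a in seq_len(ni - 1)) {
    for (b in seq((a + 1), ni)) {
      ok <- !dataset@missing[a, ] & !dataset@missing[b, ]
      S <- sum(nsites[ok])
      if (S == 0)
        .stopf("individuals '%s' and '%s' share no genotyped site",
               ind$id[a], ind$id[b])
      tot <- 0
      for (k in which(ok & nsites > 0)) {
        dd <- dosage[[k]][a, ] - dosage[[k]][b, ]
        tot <- tot + if (metric == "allele-sharing") sum(abs(dd)) else
          sum(dd * dd)
      }
      D[a, b] <- D[b, a] <- if (metric == "allele-sharing")
        tot / (2 * S) else sqrt(tot / S)
    }
  }
  attr(D, "metric") <- metric
  D
}

#' Collapse an individual distance matrix to population level
#'
#' Mean over cross-population individual pairs, the convention used when
#' pairing genetic with geographic distances; diagonal zero.
#'
#' @param D labelled individual distance matrix.
#' @param popmap data.frame with columns `sample`, `population` covering all
#'   row labels of `D`.
#' @return symmetric population-level matrix.
#' @export
populationDistanceMatrix <- function(D, popmap) {
  popOf <- stats::setNames(popmap$population, popmap$sample)
  if (any(!rownames(D) %in% names(popOf)))
    .stopf("popmap does not cover all individuals")
  pops <- unique(unname(popOf[rownames(D)]))
  P <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (x in seq_along(pops)) {
    for (y in seq_along(pops)) {
      if (x >= y) next
      ra <- which(popOf[rownames(D)] == pops[x])
      rb <- which(popOf[rownames(D)] == pops[y])
      P[x, y] <- P[y, x] <- mean(D[ra, rb, drop = FALSE])
    }
  }
  attr(P, "metric") <- attr(D, "metric")
  P
}

#' Mantel permutation test
#'
#' Pearson correlation of the lower-triangle vectors of two labelled
#' distance matrices, with a permutation null obtained by jointly permuting
#' rows and columns of the second matrix. The p-value is one-tailed
#' ("greater") with the add-one ranking rule
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}; permuted
#' correlations within 1e-10 of the observed one count as ties.
#'
#' @param D1,D2 symmetric matrices with identical labels in identical order
#'   (labels optional but checked when present), `n >= 4`.
#' @param n_permutations number of random permutations (default 9999).
#' @param seed optional integer seed.
#' @return list with `r`, `p`, `n_permutations`, `tail`, `seed`.
#' @export
mantelTest <- function(D1, D2, n_permutations = 9999, seed = NULL) {
  if (!all(dim(D1) == dim(D2))) .stopf("matrix dimensions differ")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    .stopf("matrix labels differ or are ordered differently")
  n <- nrow(D1)
  if (n < 4) .stopf("need at least 4 labels")
  lt <- lower.tri(D1)
  v1 <- D1[lt]
  if (stats::sd(v1) == 0 || stats::sd(D2[lt]) == 0)
    .stopf("zero variance on the off-diagonal: r undefined")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(v1, D2[lt])
  hits <- 0L
  for (k in seq_len(n_permutations)) {
    p <- sample.int(n)
    rp <- stats::cor(v1, D2[p, p][lt])
    if (rp >= r_obs - 1e-10) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_permutations),
       n_permutations = n_permutations, tail = "greater", seed = seed)
}

# ---- table I/O ------------------------------------------------------------

#' Write / read a joint SFS as tab-separated matrix with '#' metadata
#' @param sfs an `SFS2D`.
#' @param path file path.
#' @return the path ([writeSfs()]) or an `SFS2D` ([readSfs()]).
#' @export
writeSfs <- function(sfs, path) {
  hdr <- c(.provenanceHeader(), sprintf("# pops: %s %s", sfs@pops[1], sfs@pops[2]),
           sprintf("# n1: %d", sfs@n1), sprintf("# n2: %d", sfs@n2),
           sprintf("# folded: %s", sfs@folded))
  df <- as.data.frame(sfs@counts)
  names(df) <- paste0("j", 0:sfs@n2)
  .writeTsv(df, path, hdr)
}

#' @rdname writeSfs
#' @export
readSfs <- function(path) {
  meta <- grep("^#", readLines(path), value = TRUE)
  getm <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), meta, value = TRUE))
  counts <- as.matrix(.readTsv(path))
  dimnames(counts) <- NULL
  pops <- strsplit(getm("pops"), " ")[[1]]
  new("SFS2D", counts = counts, n1 = as.integer(getm("n1")),
      n2 = as.integer(getm("n2")), folded = as.logical(getm("folded")),
      pops = pops)
}

#' Write / read a labelled square distance matrix as TSV
#' @param D labelled symmetric matrix.
#' @param path file path.
#' @return the path ([writeDistanceMatrix()]) or a matrix
#'   ([readDistanceMatrix()]).
#' @export
writeDistanceMatrix <- function(D, path) {
  df <- data.frame(id = rownames(D), as.data.frame(D, check.names = FALSE),
                   check.names = FALSE)
  .writeTsv(df, path, c(.provenanceHeader(),
                        sprintf("# metric: %s",
                                ifelse(is.null(attr(D, "metric")), "unknown",
                                       attr(D, "metric")))))
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- .readTsv(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$id
  M
}
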