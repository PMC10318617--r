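# Structured coalescent with divergence and directional migration bands.
#
# Backward-in-time event-driven simulation between consecutive divergence
# breakpoints: within a population holding k lineages and parameter theta,
# coalescence occurs at total rate k(k-1)/theta per unit tau; for a forward
# band source -> target, each lineage currently in the target jumps to the
# source at rate m (donor/recipient read backwards); at each internal node's
# tau all lineages of the two daughter populations relabel to the parent and
# rates are rebuilt. Continuous clocks make exact event-time ties a
# measure-zero event; the category draw resolves any floating-point ties in
# the fixed order coalescence-before-migration.

# Precompute everything about the model that does not depend on the sample.
.simContext <- function(model) {
  v <- validateDemography(model)
  if (length(v)) .stopf("invalid model: %s", paste(v, collapse = "; "))
  tau <- taus(model)
  internal <- model@populations$id[!model@populations$tip]
  ord <- order(tau[internal])
  bp <- internal[ord]
  bands <- model@bands
  if (nrow(bands)) {
    act <- t(vapply(seq_len(nrow(bands)),
                    function(i) bandActivityInterval(model, bands[i, ]),
                    numeric(2)))
    bands$t0 <- act[, 1]
    bands$t1 <- act[, 2]
  }
  kids <- lapply(bp, function(nd) childrenOf(model, nd))
  names(kids) <- bp
  list(theta = model@theta, tau = tau,
       bp_id = bp, bp_time = unname(tau[bp]), bp_children = kids,
       bands = bands)
}

# One genealogy for haplotypes sampled (at time 0) in populations `hapPops`.
# Uses the current RNG state.
.simGenealogy <- function(ctx, hapPops) {
  n <- length(hapPops)
  if (n < 2) .stopf("need at least 2 haplotypes in total")
  nn <- 2L * n - 1L
  time <- numeric(nn)
  parent <- rep(NA_integer_, nn)
  lin <- seq_len(n)            # active lineage node ids
  pop <- as.character(hapPops) # current population of each active lineage
  nxt <- n + 1L                # next internal node id
  mig <- list()
  t <- 0
  nb <- 1L
  nbp <- length(ctx$bp_id)
  bands <- ctx$bands
  nbands <- nrow(bands)

  while (length(lin) > 1L) {
    kcount <- table(pop)
    pops_here <- names(kcount)
    k <- as.numeric(kcount)
    crate <- k * (k - 1) / ctx$theta[pops_here]
    if (nbands) {
      bk <- k[match(bands$target, pops_here)]
      bk[is.na(bk)] <- 0
      active <- bands$t0 <= t & t < bands$t1 & bk > 0
      mrate <- ifelse(active, bands$rate * bk, 0)
    } else {
      mrate <- numeric(0)
    }
    R <- sum(crate) + sum(mrate)
    t_end <- if (nb <= nbp) ctx$bp_time[nb] else Inf

    jump <- if (R > 0) stats::rexp(1L, R) else Inf
    if (t + jump >= t_end) {
      if (!is.finite(t_end))
        .stopf("internal error: no events possible and no breakpoint left")
      t <- t_end
      ch <- ctx$bp_children[[nb]]
      pop[pop %in% ch] <- ctx$bp_id[nb]
      nb <- nb + 1L
      next
    }
    t <- t + jump
    w <- c(crate, mrate)
    ev <- sample.int(length(w), 1L, prob = w)
    if (ev <= length(crate)) {
      p <- pops_here[ev]
      at <- which(pop == p)
      pick <- at[sample.int(length(at), 2L)]
      node <- nxt; nxt <- nxt + 1L
      time[node] <- t
      parent[lin[pick]] <- node
      lin <- c(lin[-pick], node)
      pop <- c(pop[-pick], p)
    } else {
      b <- ev - length(crate)
      at <- which(pop == bands$target[b])
      pick <- at[sample.int(length(at), 1L)]
      mig[[length(mig) + 1L]] <- data.frame(
        lineage = lin[pick], band = bands$id[b], time = t,
        from = bands$target[b], to = bands$source[b],
        stringsAsFactors = FALSE)
      pop[pick] <- bands$source[b]
    }
  }
  structure(list(
    n_tips = n,
    parent = parent,
    time = time,
    tip_population = as.character(hapPops),
    migrations = if (length(mig)) do.call(rbind, mig) else
      data.frame(lineage = integer(), band = character(), time = numeric(),
                 from = character(), to = character(), stringsAsFactors = FALSE)
  ), class = "Genealogy")
}

#' Simulate one genealogy under an isolation-with-migration model
#'
#' Event-driven structured coalescent in mutation-scaled time: coalescence
#' at rate \eqn{k(k-1)/\theta} within each population, backward lineage
#' movement at rate \eqn{m} per lineage for each active directed band, and
#' instantaneous relabelling of daughter lineages at each divergence time.
#'
#' @param model a valid `DemographyModel`.
#' @param samples named integer vector: diploid individuals per tip
#'   population (haplotypes = 2 x individuals), or haplotype counts when
#'   `haplotypes = TRUE`.
#' @param seed optional integer seed.
#' @param haplotypes interpret `samples` as haplotype counts (for
#'   genealogy-level analyses such as pairwise coalescence times).
#' @return a `Genealogy`: list with `n_tips`, `parent` (node parent ids,
#'   `NA` at the root), `time` (node times, tau units), `tip_population`,
#'   and a `migrations` event table.
#' @examples
#' m <- demographyModel(
#'   populations = data.frame(id = c("A", "B", "R"), tip = c(TRUE, TRUE, FALSE)),
#'   edges = data.frame(child = c("A", "B"), parent = c("R", "R")),
#'   theta = c(A = 0.002, B = 0.002, R = 0.002), tau = c(R = 0.001)
#' )
#' g <- simulateGenealogy(m, c(A = 1, B = 1), seed = 1)
#' @export
simulateGenealogy <- function(model, samples, seed = NULL,
                              haplotypes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- .simContext(model)
  hapPops <- .expandSamples(model, samples, haplotypes)
  .simGenealogy(ctx, hapPops)
}

# Expand a sample configuration into one population label per haplotype,
# validating against the model's tips.
.expandSamples <- function(model, samples, haplotypes = FALSE) {
  if (is.null(names(samples)) || any(names(samples) == ""))
    .stopf("samples must be a named vector (population -> count)")
  bad <- setdiff(names(samples), tipIds(model))
  if (length(bad))
    .stopf("samples reference non-tip population(s): %s",
           paste(bad, collapse = ", "))
  if (any(samples < 0)) .stopf("sample counts must be >= 0")
  per <- if (haplotypes) as.integer(samples) else 2L * as.integer(samples)
  hap <- rep(names(samples), times = per)
  if (length(hap) < 2L) .stopf("need at least two haplotypes in total")
  hap
}

#' Total tree height of a genealogy (time to most recent common ancestor)
#' @param genealogy a `Genealogy`.
#' @return time of the root node in tau units.
#' @export
tmrca <- function(genealogy) max(genealogy$time)

#' @export
print.Genealogy <- function(x, ...) {
  cat(sprintf("Genealogy: %d tips, TMRCA = %g (tau units), %d migration events\n",
              x$n_tips, tmrca(x), nrow(x$migrations)))
  invisible(x)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each branch of length `b` (tau units) receives `Poisson(b * locus_length)`
#' mutations; every mutation creates a new segregating site at a uniform
#' unique integer position, carried by all haplotypes below the branch.
#'
#' @param genealogy a `Genealogy`.
#' @param locus_length locus length in bp (>= 1).
#' @param seed optional integer seed.
#' @return haplotype x site 0/1 integer matrix with attribute `positions`
#'   (sorted unique 1-based positions).
#' @export
dropMutations <- function(genealogy, locus_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (locus_length < 1) .stopf("locus_length must be >= 1")
  .dropMutations(genealogy, locus_length)
}

.dropMutations <- function(gen, L) {
  n <- gen$n_tips
  nn <- 2L * n - 1L
  root <- which(is.na(gen$parent))
  nodes <- setdiff(seq_len(nn), root)
  blen <- gen$time[gen$parent[nodes]] - gen$time[nodes]
  nm <- stats::rpois(length(nodes), blen * L)
  S <- sum(nm)
  mat <- matrix(0L, n, S)
  if (S == 0L) {
    attr(mat, "positions") <- integer(0)
    return(mat)
  }
  if (S > L)
    .stopf("infinite-sites saturation: %d mutations on a %d bp locus", S, L)
  # descendant leaf sets; internal ids were assigned in increasing time order
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  for (nd in seq.int(n + 1L, nn)) {
    ch <- which(gen$parent == nd)
    desc[[nd]] <- c(desc[[ch[1]]], desc[[ch[2]]])
  }
  branchOf <- rep(nodes, times = nm)
  branchOf <- branchOf[sample.int(S)]
  positions <- sort(sample.int(L, S))
  for (k in seq_len(S)) mat[desc[[branchOf[k]]], k] <- 1L
  attr(mat, "positions") <- positions
  mat
}

#' Simulate a RAD-like multilocus dataset
#'
#' Independent loci (genealogy + infinite-sites mutations), haplotypes
#' paired into diploid individuals within populations, and whole-locus
#' dropout applied per (individual, locus) independently. Fully reproducible
#' from the seed. Defaults emulate thousands of independent ~649 bp RAD loci
#' with two diploid individuals per population.
#'
#' @param model a valid `DemographyModel`.
#' @param samples named integer vector: diploids per tip population.
#' @param n_loci number of independent loci (>= 1).
#' @param locus_length locus length in bp.
#' @param missingness_rate per-(individual, locus) dropout probability in
#'   `[0, 1)`.
#' @param seed optional integer seed.
#' @return a [MultilocusDataset-class].
#' @export
simulateDataset <- function(model, samples, n_loci, locus_length = 649,
                            missingness_rate = 0, seed = NULL) {
  if (n_loci < 1) .stopf("n_loci must be >= 1")
  if (missingness_rate < 0 || missingness_rate >= 1)
    .stopf("missingness_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  ctx <- .simContext(model)
  hapPops <- .expandSamples(model, samples)

  # diploid individuals: random within-population haplotype pairing
  pops <- names(samples)[samples > 0]
  ind <- list()
  for (p in pops) {
    idx <- which(hapPops == p)
    perm <- idx[sample.int(length(idx))]
    np <- length(idx) %/% 2L
    ind[[p]] <- data.frame(
      id = sprintf("%s_%d", p, seq_len(np)),
      population = p,
      hap1 = perm[seq(1L, by = 2L, length.out = np)],
      hap2 = perm[seq(2L, by = 2L, length.out = np)],
      stringsAsFactors = FALSE)
  }
  individuals <- do.call(rbind, ind)
  rownames(individuals) <- NULL

  loci <- vector("list", n_loci)
  for (k in seq_len(n_loci)) {
    gen <- .simGenealogy(ctx, hapPops)
    mat <- .dropMutations(gen, locus_length)
    loci[[k]] <- list(length = locus_length, mat = mat,
                      positions = attr(mat, "positions"))
  }
  ni <- nrow(individuals)
  miss <- matrix(stats::runif(ni * n_loci) < missingness_rate, ni, n_loci)
  new("MultilocusDataset",
      loci = loci, individuals = individuals, missing = miss,
      provenance = list(seed = if (is.null(seed)) NA_integer_ else seed,
                        demography = demographyHash(model),
                        n_loci = n_loci, locus_length = locus_length,
                        missingness_rate = missingness_rate))
}

#' @describeIn datasetAccessors number of loci
#' @export
nLoci <- function(dataset) length(dataset@loci)

#' Accessors for MultilocusDataset
#' @param dataset a `MultilocusDataset`.
#' @param locus locus index.
#' @name datasetAccessors
NULL

#' @describeIn datasetAccessors individual metadata table
#' @export
individuals <- function(dataset) dataset@individuals

#' @describeIn datasetAccessors logical missingness mask (individuals x loci)
#' @export
missingMask <- function(dataset) dataset@missing

#' @describeIn datasetAccessors diploid dosage matrix (individuals x sites,
#'   values 0/1/2, `NA` where the individual is missing at the locus)
#' @export
genotypeMatrix <- function(dataset, locus) {
  loc <- dataset@loci[[locus]]
  ind <- dataset@individuals
  d <- loc$mat[ind$hap1, , drop = FALSE] + loc$mat[ind$hap2, , drop = FALSE]
  d[dataset@missing[, locus], ] <- NA_integer_
  rownames(d) <- ind$id
  d
}

#' @export
setMethod("show", "MultilocusDataset", function(object) {
  S <- sum(vapply(object@loci, function(l) ncol(l$mat), integer(1)))
  cat(sprintf(
    "MultilocusDataset: %d loci (%d segregating sites), %d individuals in %d populations\n",
    length(object@loci), S, nrow(object@individuals),
    length(unique(object@individuals$population))))
  cat(sprintf("  missingness: %.1f%%\n", 100 * mean(object@missing)))
  invisible(object)
})
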