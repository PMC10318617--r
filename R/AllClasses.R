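#' @import methods
NULL

#' Isolation-with-migration demographic model
#'
#' An S4 container for a rooted binary population tree in mutation-scaled
#' units: one theta (\eqn{\theta = 4 N_e \mu}, per site) per branch (tips and
#' ancestral branches alike), one tau (\eqn{\tau}, expected substitutions per
#' site per lineage) per internal node, and a set of directed migration bands
#' (rate \eqn{m} = per-generation migration probability divided by \eqn{\mu}).
#' Tips implicitly have \eqn{\tau = 0}. Absolute units (individuals, years,
#' migrants per generation) exist only after calibration via
#' [monteCarloConvert()].
#'
#' A population (tip or ancestral) exists on the half-open time interval
#' `[birth, death)` where `birth` is 0 for tips and its own tau for internal
#' nodes, and `death` is the parent's tau (`Inf` for the root). A migration
#' band is active on the intersection of the existence intervals of its two
#' endpoint populations.
#'
#' @slot populations data.frame with columns `id`, `name`, `tip`.
#' @slot edges data.frame with columns `child`, `parent` (node ids).
#' @slot theta named numeric, one entry per node id.
#' @slot tau named numeric, one entry per internal node id.
#' @slot bands data.frame with columns `id`, `source`, `target`, `rate`,
#'   `pair` (a shared pair identifier for the two directions of a
#'   bidirectional band; `NA` for a lone directed band). `source` is the
#'   forward-time donor and `target` the forward-time recipient.
#'
#' @seealso [demographyModel()], [loadDemography()], [validateDemography()]
#' @export
setClass("DemographyModel",
  slots = c(
    populations = "data.frame",
    edges       = "data.frame",
    theta       = "numeric",
    tau         = "numeric",
    bands       = "data.frame"
  )
)

setValidity("DemographyModel", function(object) {
  v <- validateDemography(object)
  if (length(v) == 0) TRUE else v
})

#' Multilocus haplotype dataset
#'
#' Independent non-recombining loci of biallelic 0/1 haplotype matrices with
#' diploid individual metadata and a whole-locus missingness mask, emulating
#' RAD data. Rows of each locus matrix are haplotypes; individuals own two
#' haplotype rows each (`hap1`, `hap2`).
#'
#' @slot loci list; each element a list with `length` (bp), `mat` (haplotype
#'   x segregating-site 0/1 integer matrix) and `positions` (1-based unique
#'   integer site positions within the locus).
#' @slot individuals data.frame with columns `id`, `population`, `hap1`,
#'   `hap2` (row indices into the locus matrices).
#' @slot missing logical matrix, individuals x loci; `TRUE` marks a dropped
#'   (individual, locus) cell.
#' @slot provenance list (seed, demography hash, call parameters).
#' @seealso [simulateDataset()], [exportVcf()], [importVcf()]
#' @export
setClass("MultilocusDataset",
  slots = c(
    loci        = "list",
    individuals = "data.frame",
    missing     = "matrix",
    provenance  = "list"
  )
)

setValidity("MultilocusDataset", function(object) {
  msgs <- character()
  ni <- nrow(object@individuals)
  nl <- length(object@loci)
  if (!all(dim(object@missing) == c(ni, nl)))
    msgs <- c(msgs, "missingness mask must be individuals x loci")
  need <- c("id", "population", "hap1", "hap2")
  if (!all(need %in% names(object@individuals)))
    msgs <- c(msgs, "individuals must have columns id, population, hap1, hap2")
  for (k in seq_len(nl)) {
    loc <- object@loci[[k]]
    if (!all(c("length", "mat", "positions") %in% names(loc))) {
      msgs <- c(msgs, sprintf("locus %d lacks length/mat/positions", k))
      next
    }
    s <- ncol(loc$mat)
    if (length(loc$positions) != s)
      msgs <- c(msgs, sprintf("locus %d: positions/site count mismatch", k))
    if (anyDuplicated(loc$positions))
      msgs <- c(msgs, sprintf("locus %d: duplicated positions", k))
    # both alleles must be present before masking; once an individual is
    # masked at the locus the pre-mask state is unknowable (VCF import),
    # so the check applies only to fully observed loci
    if (s > 0 && !any(object@missing[, k])) {
      cs <- colSums(loc$mat)
      if (any(cs == 0 | cs == nrow(loc$mat)))
        msgs <- c(msgs, sprintf("locus %d: non-segregating column", k))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Joint two-population site frequency spectrum
#'
#' Counts of sites indexed by derived (or pooled-minor, when folded) allele
#' count in two populations. Entry `[i + 1, j + 1]` counts sites with allele
#' count `i` of `n1` haplotypes in the first population and `j` of `n2` in
#' the second.
#'
#' @slot counts numeric matrix, `(n1 + 1) x (n2 + 1)`.
#' @slot n1,n2 haploid sample sizes.
#' @slot folded logical; if `TRUE` each site was oriented by the pooled
#'   two-population minor allele.
#' @slot pops character(2), population ids.
#' @seealso [jointSfs()], [weightedFst()]
#' @export
setClass("SFS2D",
  slots = c(
    counts = "matrix",
    n1     = "integer",
    n2     = "integer",
    folded = "logical",
    pops   = "character"
  )
)

setValidity("SFS2D", function(object) {
  msgs <- character()
  if (!all(dim(object@counts) == c(object@n1 + 1L, object@n2 + 1L)))
    msgs <- c(msgs, "counts must be (n1+1) x (n2+1)")
  if (any(object@counts < 0)) msgs <- c(msgs, "negative SFS entries")
  if (length(msgs)) msgs else TRUE
})

#' Mutation-scaled MCMC posterior trace
#'
#' Retained (post-burn-in) samples of a coalescent sampler run, with columns
#' classified into roles: `theta` (a population or ancestral branch), `tau`
#' (an internal node), `m` (a directed migration band) or `other`
#' (likelihoods, iteration counters).
#'
#' @slot samples numeric matrix, rows = retained samples.
#' @slot roles data.frame with columns `column`, `role`, `id`, `source`,
#'   `target` (the latter two only for `m` columns).
#' @slot chain integer vector, chain id per row.
#' @slot burnin numeric, burn-in fraction removed per chain.
#' @slot files character, source file paths.
#' @seealso [readTrace()], [summarizePosterior()], [screenMigrationBands()]
#' @export
setClass("PosteriorTrace",
  slots = c(
    samples = "matrix",
    roles   = "data.frame",
    chain   = "integer",
    burnin  = "numeric",
    files   = "character"
  )
)

setValidity("PosteriorTrace", function(object) {
  msgs <- character()
  if (nrow(object@samples) < 2)
    msgs <- c(msgs, "need at least 2 retained samples")
  if (length(object@chain) != nrow(object@samples))
    msgs <- c(msgs, "chain vector length must match sample rows")
  keep <- object@roles$role %in% c("theta", "tau", "m")
  if (any(keep)) {
    vals <- object@samples[, object@roles$column[keep], drop = FALSE]
    if (any(vals < 0, na.rm = TRUE))
      msgs <- c(msgs, "theta/tau/m samples must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Posterior trace converted to absolute units
#'
#' Per retained MCMC sample: the drawn generation time `g` (years) and
#' mutation rate `mu` (per site per generation), effective population sizes
#' `Ne_<id>` (individuals), divergence times `T_<id>` (years) and population
#' migration rates `M2Nm_<source.target>` (migrant gene copies per
#' generation).
#'
#' @slot samples numeric matrix of converted quantities.
#' @slot roles data.frame mapping columns to quantity/id.
#' @slot chain integer chain id per row.
#' @seealso [monteCarloConvert()]
#' @export
setClass("ConvertedPosterior",
  slots = c(
    samples = "matrix",
    roles   = "data.frame",
    chain   = "integer"
  )
)

setValidity("ConvertedPosterior", function(object) {
  if (length(object@chain) != nrow(object@samples))
    "chain vector length must match sample rows" else TRUE
})
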