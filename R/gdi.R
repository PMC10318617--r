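# Genealogical divergence index: gdi = 1 - exp(-2 tau / theta), the
# probability that two lineages sampled in a daughter population coalesce
# more recently than the divergence at tau. Rule of thumb: < 0.2
# intraspecific differentiation, > 0.7 species-level divergence, in between
# ambiguous.

#' Genealogical divergence index from point values
#'
#' \eqn{gdi = 1 - e^{-2\tau/\theta}}, strictly increasing in tau and
#' strictly decreasing in theta; equals the probability that two lineages
#' of the daughter population (parameter theta) coalesce before the
#' divergence time tau.
#'
#' @param tau mutation-scaled divergence time (>= 0), vectorized.
#' @param theta mutation-scaled size of the reference daughter lineage
#'   (> 0), vectorized.
#' @return value(s) in `[0, 1)`.
#' @export
gdiPoint <- function(tau, theta) {
  if (any(theta <= 0)) .stopf("theta must be > 0")
  if (any(tau < 0)) .stopf("tau must be >= 0")
  1 - exp(-2 * tau / theta)
}

#' Classify a gdi value
#'
#' Values below 0.2 indicate intraspecific differentiation, above 0.7
#' species-level divergence; the zone in between is ambiguous. The rule of
#' thumb uses strict inequalities on both sides, so the boundary values 0.2
#' and 0.7 classify as ambiguous.
#'
#' @param value gdi value(s) in `[0, 1)`.
#' @return character vector: `"intraspecific"`, `"ambiguous"` or
#'   `"species-level"`.
#' @export
classifyGdi <- function(value) {
  if (any(value < 0 | value >= 1)) .stopf("gdi must be in [0, 1)")
  ifelse(value < 0.2, "intraspecific",
         ifelse(value > 0.7, "species-level", "ambiguous"))
}

.gdiSummaryRow <- function(g, chain, node, theta_lineage, aggregation,
                           mass = 0.95) {
  s <- summarizePosterior(g, chain = chain, mass = mass)
  data.frame(node = node, theta_lineage = theta_lineage,
             mean = s$mean, lower = s$lower, upper = s$upper,
             category = classifyGdi(s$mean),
             aggregation = aggregation, stringsAsFactors = FALSE)
}

#' Posterior gdi at one node
#'
#' Applies [gdiPoint()] row-wise to a posterior trace, using the tau column
#' of `node` and the theta column of the chosen daughter lineage, and
#' summarizes with mean and 95% HPD. Because the index depends on which
#' daughter's theta is used, both choices are typically reported per node.
#' Traces from models with migration are accepted with a warning: the index
#' is conventionally computed from a no-migration model.
#'
#' @param trace a `PosteriorTrace`.
#' @param node internal node id (tau column `tau_<node>` must exist).
#' @param theta_lineage id of the daughter lineage whose theta to use.
#' @param mass HPD mass.
#' @return one-row data.frame: `node`, `theta_lineage`, `mean`, `lower`,
#'   `upper`, `category`, `aggregation`.
#' @export
gdiPosterior <- function(trace, node, theta_lineage, mass = 0.95) {
  roles <- trace@roles
  if (any(roles$role == "m"))
    warning("trace contains migration bands; gdi is conventionally computed ",
            "from the no-migration model")
  ti <- which(roles$role == "tau" & roles$id == node)
  hi <- which(roles$role == "theta" & roles$id == theta_lineage)
  if (length(ti) != 1) .stopf("no tau column for node '%s'", node)
  if (length(hi) != 1) .stopf("no theta column for lineage '%s'", theta_lineage)
  g <- gdiPoint(trace@samples[, roles$column[ti]],
                trace@samples[, roles$column[hi]])
  .gdiSummaryRow(g, trace@chain, node, theta_lineage, "single", mass)
}

#' Most recent common ancestor of two populations
#'
#' @param model a `DemographyModel`.
#' @param a,b population ids.
#' @return internal node id.
#' @export
mrcaNode <- function(model, a, b) {
  anc <- function(id) {
    path <- id
    while (!is.na(id <- parentOf(model, id))) path <- c(path, id)
    path
  }
  pa <- anc(a)
  pb <- anc(b)
  hit <- pa[pa %in% pb]
  if (!length(hit)) .stopf("no common ancestor of '%s' and '%s'", a, b)
  hit[1]
}

#' Aggregate gdi across a two-set population partition
#'
#' For every cross-partition population pair, the per-sample gdi is
#' computed with tau at the pair's MRCA node and, by default, each of the
#' two tip thetas in turn; the aggregate per posterior sample is the mean
#' over all pairs and theta choices (averaging before summarizing preserves
#' the joint correlation structure, which a mean of summary values would
#' not). The summary is the mean and HPD of that per-sample aggregate.
#'
#' @param trace a `PosteriorTrace` (no-migration model conventionally).
#' @param model a `DemographyModel` resolving the trace columns.
#' @param set1,set2 non-overlapping character vectors of population ids.
#' @param mass HPD mass.
#' @return one-row data.frame as in [gdiPosterior()], with `aggregation`
#'   listing the pairs averaged.
#' @export
gdiAggregate <- function(trace, model, set1, set2, mass = 0.95) {
  if (!length(set1) || !length(set2)) .stopf("both sets must be nonempty")
  if (length(intersect(set1, set2))) .stopf("sets must not overlap")
  roles <- trace@roles
  col <- function(role, id) {
    i <- which(roles$role == role & roles$id == id)
    if (length(i) != 1) .stopf("no %s column for '%s'", role, id)
    roles$column[i]
  }
  acc <- NULL
  nterms <- 0L
  pairs <- character()
  for (a in set1) {
    for (b in set2) {
      nd <- mrcaNode(model, a, b)
      tauv <- trace@samples[, col("tau", nd)]
      for (th in c(a, b)) {
        g <- gdiPoint(tauv, trace@samples[, col("theta", th)])
        acc <- if (is.null(acc)) g else acc + g
        nterms <- nterms + 1L
      }
      pairs <- c(pairs, paste0(a, "|", b))
    }
  }
  .gdiSummaryRow(acc / nterms, trace@chain,
                 node = paste(pairs, collapse = ","),
                 theta_lineage = "both-tips",
                 aggregation = sprintf("mean over %d pairs x 2 theta choices",
                                       length(pairs)),
                 mass = mass)
}

#' gdi table for every internal node of a model
#'
#' Two estimates per node (one per daughter lineage's theta).
#'
#' @param trace a `PosteriorTrace`.
#' @param model a `DemographyModel`.
#' @param mass HPD mass.
#' @return data.frame of [gdiPosterior()] rows.
#' @export
gdiTable <- function(trace, model, mass = 0.95) {
  internal <- model@populations$id[!model@populations$tip]
  have_tau <- trace@roles$id[trace@roles$role == "tau"]
  rows <- list()
  for (nd in intersect(internal, have_tau)) {
    for (ch in childrenOf(model, nd)) {
      if (ch %in% trace@roles$id[trace@roles$role == "theta"])
        rows[[length(rows) + 1L]] <-
          suppressWarnings(gdiPosterior(trace, nd, ch, mass))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
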