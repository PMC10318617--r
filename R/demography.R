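#' Construct an isolation-with-migration demographic model
#'
#' Builds and validates a [DemographyModel-class] from its parts. All units
#' are mutation-scaled: `theta` \eqn{= 4 N_e \mu} per site, `tau` in expected
#' substitutions per site per lineage, band rates `m` = per-generation
#' migration probability over \eqn{\mu}.
#'
#' @param populations data.frame with columns `id`, `name`, `tip`; `name`
#'   may be omitted (defaults to `id`).
#' @param edges data.frame with columns `child`, `parent`.
#' @param theta named numeric, one positive value per node id.
#' @param tau named numeric, one value per internal node id (tips have
#'   \eqn{\tau = 0} implicitly).
#' @param bands data.frame with columns `source`, `target`, `rate` and
#'   optionally `id` and `pair`; may be `NULL` for a no-migration model.
#' @return a validated `DemographyModel`.
#' @examples
#' m <- demographyModel(
#'   populations = data.frame(id = c("A", "B", "R"), tip = c(TRUE, TRUE, FALSE)),
#'   edges = data.frame(child = c("A", "B"), parent = c("R", "R")),
#'   theta = c(A = 0.002, B = 0.002, R = 0.002),
#'   tau = c(R = 0.001)
#' )
#' @export
demographyModel <- function(populations, edges, theta, tau, bands = NULL) {
  if (is.null(populations$name)) populations$name <- populations$id
  populations <- data.frame(
    id = as.character(populations$id),
    name = as.character(populations$name),
    tip = as.logical(populations$tip),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    child = as.character(edges$child),
    parent = as.character(edges$parent),
    stringsAsFactors = FALSE
  )
  if (is.null(bands) || NROW(bands) == 0) {
    bands <- data.frame(id = character(), source = character(),
                        target = character(), rate = numeric(),
                        pair = character(), stringsAsFactors = FALSE)
  } else {
    bands <- as.data.frame(bands, stringsAsFactors = FALSE)
    if (is.null(bands$id))
      bands$id <- paste0(bands$source, "->", bands$target)
    if (is.null(bands$pair)) bands$pair <- NA_character_
    bands <- data.frame(id = as.character(bands$id),
                        source = as.character(bands$source),
                        target = as.character(bands$target),
                        rate = as.numeric(bands$rate),
                        pair = as.character(bands$pair),
                        stringsAsFactors = FALSE)
  }
  obj <- new("DemographyModel", populations = populations, edges = edges,
             theta = theta, tau = tau, bands = bands)
  obj
}

#' Add both directions of a bidirectional migration band
#'
#' A bidirectional band between `a` and `b` is stored as two directed bands
#' sharing a `pair` id, so posterior screening can retain one direction and
#' drop the other.
#'
#' @param model a `DemographyModel`.
#' @param a,b population ids.
#' @param rate_ab,rate_ba mutation-scaled rates for the two directions
#'   (forward-time donor first).
#' @return the model with the two bands appended.
#' @export
addBidirectionalBand <- function(model, a, b, rate_ab, rate_ba = rate_ab) {
  pair <- paste0(a, "~", b)
  add <- data.frame(
    id = c(paste0(a, "->", b), paste0(b, "->", a)),
    source = c(a, b), target = c(b, a),
    rate = c(rate_ab, rate_ba), pair = pair,
    stringsAsFactors = FALSE
  )
  model@bands <- rbind(model@bands, add)
  validObject(model)
  model
}

# ---- accessors ------------------------------------------------------------

#' @describeIn demographyAccessors ids of all populations (tip and ancestral)
#' @export
populationIds <- function(model) model@populations$id

#' Accessors for DemographyModel
#'
#' @param model a `DemographyModel`.
#' @param id a node id.
#' @name demographyAccessors
NULL

#' @describeIn demographyAccessors ids of tip populations
#' @export
tipIds <- function(model) model@populations$id[model@populations$tip]

#' @describeIn demographyAccessors id of the root node
#' @export
rootId <- function(model) {
  setdiff(model@populations$id, model@edges$child)
}

#' @describeIn demographyAccessors parent node id (`NA` for the root)
#' @export
parentOf <- function(model, id) {
  i <- match(id, model@edges$child)
  ifelse(is.na(i), NA_character_, model@edges$parent[i])
}

#' @describeIn demographyAccessors children node ids (empty for tips)
#' @export
childrenOf <- function(model, id) {
  model@edges$child[model@edges$parent == id]
}

#' @describeIn demographyAccessors per-branch theta vector
#' @export
thetas <- function(model) model@theta

#' @describeIn demographyAccessors per-node tau vector (tips are 0)
#' @export
taus <- function(model) {
  tau <- stats::setNames(rep(0, nrow(model@populations)), model@populations$id)
  tau[names(model@tau)] <- model@tau
  tau
}

#' @describeIn demographyAccessors migration band table
#' @export
migrationBands <- function(model) model@bands

#' Existence interval of a population
#'
#' A tip exists on `[0, tau(parent))`; an ancestral population on
#' `[tau(self), tau(parent))`; the root on `[tau(root), Inf)`.
#'
#' @param model a `DemographyModel`.
#' @param id population id.
#' @return numeric(2): birth and death time in tau units.
#' @export
existenceInterval <- function(model, id) {
  if (!id %in% model@populations$id) .stopf("unknown population '%s'", id)
  tau <- taus(model)
  birth <- unname(tau[id])
  p <- parentOf(model, id)
  death <- if (is.na(p)) Inf else unname(tau[p])
  c(birth, death)
}

#' Activity interval of a migration band
#'
#' The intersection of the existence intervals of the band's two endpoint
#' populations; the band exchanges lineages only on this interval. Errors if
#' the intersection is empty.
#'
#' @param model a `DemographyModel`.
#' @param band a one-row band data.frame (a row of [migrationBands()]) or a
#'   band id.
#' @return numeric(2): `(t_start, t_end)` in tau units.
#' @export
bandActivityInterval <- function(model, band) {
  if (is.character(band) && length(band) == 1) {
    i <- match(band, model@bands$id)
    if (is.na(i)) .stopf("unknown band '%s'", band)
    band <- model@bands[i, ]
  }
  a <- existenceInterval(model, band$source)
  b <- existenceInterval(model, band$target)
  t0 <- max(a[1], b[1])
  t1 <- min(a[2], b[2])
  if (!(t0 < t1))
    .stopf("band %s->%s: existence intervals do not overlap",
           band$source, band$target)
  c(t0, t1)
}

# ---- validation -----------------------------------------------------------

#' Validate an isolation-with-migration model
#'
#' Checks every structural invariant and returns a character vector of
#' violations (empty when the model is valid): the tree must be rooted,
#' binary and connected; theta positive on every branch; tau of a parent
#' strictly greater than tau of each internal child; every band must connect
#' two distinct populations with overlapping existence intervals and have a
#' non-negative rate.
#'
#' @param model a `DemographyModel` (possibly not yet validated).
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validateDemography <- function(model) {
  msgs <- character()
  pops <- model@populations
  edges <- model@edges
  ids <- pops$id

  if (anyDuplicated(ids))
    msgs <- c(msgs, "duplicated population ids")
  if (!all(edges$child %in% ids) || !all(edges$parent %in% ids))
    return(c(msgs, "edge references unknown node id"))

  roots <- setdiff(ids, edges$child)
  if (length(roots) != 1)
    return(c(msgs, sprintf("tree must have exactly one root (found %d)",
                           length(roots))))
  if (anyDuplicated(edges$child))
    msgs <- c(msgs, "a node has more than one parent")

  internal <- ids[!pops$tip]
  for (nd in internal) {
    k <- sum(edges$parent == nd)
    if (k != 2)
      msgs <- c(msgs, sprintf("internal node '%s' must have 2 children (has %d)",
                              nd, k))
  }
  for (nd in ids[pops$tip]) {
    if (any(edges$parent == nd))
      msgs <- c(msgs, sprintf("tip '%s' has children", nd))
  }

  # connectivity from root
  reach <- roots
  repeat {
    nxt <- unique(c(reach, edges$child[edges$parent %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (!setequal(reach, ids))
    msgs <- c(msgs, "tree is not connected")

  # theta
  if (!setequal(names(model@theta), ids))
    msgs <- c(msgs, "theta must be defined for every node")
  bad <- names(model@theta)[!(model@theta > 0)]
  for (b in bad)
    msgs <- c(msgs, sprintf("theta > 0 violated at '%s'", b))

  # tau
  if (!setequal(names(model@tau), internal))
    msgs <- c(msgs, "tau must be defined exactly for internal nodes")
  tau <- taus(model)
  for (i in seq_len(nrow(edges))) {
    ch <- edges$child[i]; pa <- edges$parent[i]
    if (!is.na(tau[pa]) && !is.na(tau[ch]) && !(tau[pa] > tau[ch]))
      msgs <- c(msgs, sprintf(
        "tau(parent) > tau(child) violated at edge %s -> %s", ch, pa))
  }

  # bands
  if (nrow(model@bands)) {
    for (i in seq_len(nrow(model@bands))) {
      bd <- model@bands[i, ]
      if (!bd$source %in% ids || !bd$target %in% ids) {
        msgs <- c(msgs, sprintf("band '%s' references unknown population", bd$id))
        next
      }
      if (bd$source == bd$target)
        msgs <- c(msgs, sprintf("band '%s': source equals target", bd$id))
      if (!(bd$rate >= 0))
        msgs <- c(msgs, sprintf("band '%s': m >= 0 violated", bd$id))
      if (bd$source != bd$target) {
        a <- existenceInterval(model, bd$source)
        b <- existenceInterval(model, bd$target)
        if (!(max(a[1], b[1]) < min(a[2], b[2])))
          msgs <- c(msgs, sprintf(
            "band '%s': non-overlapping existence intervals", bd$id))
      }
    }
  }
  msgs
}

# ---- JSON I/O -------------------------------------------------------------

#' Read a demography configuration document
#'
#' Parses the package's JSON demography dialect, resolves node references
#' and returns a validated model. The document round-trips losslessly
#' through [saveDemography()].
#'
#' @param path path to a JSON document (or a JSON string).
#' @return a `DemographyModel`.
#' @export
loadDemography <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) .stopf("demography parse failure: %s", conditionMessage(e))
  )
  need <- c("populations", "edges", "theta", "tau")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    .stopf("demography document lacks field(s): %s", paste(miss, collapse = ", "))
  theta <- unlist(doc$theta)
  tau <- unlist(doc$tau)
  if (is.null(tau)) tau <- stats::setNames(numeric(0), character(0))
  bands <- doc$migration_bands
  model <- demographyModel(doc$populations, doc$edges, theta, tau, bands)
  v <- validateDemography(model)
  if (length(v)) .stopf("invalid demography: %s", paste(v, collapse = "; "))
  model
}

#' Write a demography configuration document
#'
#' Canonical writer: populations and edges sorted by id/child, theta and tau
#' keys sorted, bands sorted by id, fixed key order, full numeric precision.
#' `saveDemography(loadDemography(p), q)` reproduces `p` byte-identically
#' when `p` itself was written by this function.
#'
#' @param model a `DemographyModel`.
#' @param path output path; if `NULL`, the JSON string is returned.
#' @return the path (or the JSON string), invisibly for paths.
#' @export
saveDemography <- function(model, path = NULL) {
  pops <- model@populations[order(model@populations$id), , drop = FALSE]
  edges <- model@edges[order(model@edges$child), , drop = FALSE]
  rownames(pops) <- rownames(edges) <- NULL
  theta <- as.list(model@theta[order(names(model@theta))])
  tau <- as.list(model@tau[order(names(model@tau))])
  doc <- list(
    populations = pops,
    edges = edges,
    theta = theta,
    tau = tau,
    migration_bands = {
      b <- model@bands[order(model@bands$id), , drop = FALSE]
      rownames(b) <- NULL
      b
    }
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          na = "null")
  txt <- paste0(txt, "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Export the population tree as Newick
#'
#' Topology with branch lengths equal to `tau(parent) - tau(child)` in
#' mutation-scaled units; theta and migration bands are not representable in
#' Newick and are omitted.
#'
#' @param model a `DemographyModel`.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
exportNewick <- function(model, path = NULL) {
  tau <- taus(model)
  build <- function(id) {
    kids <- childrenOf(model, id)
    if (length(kids) == 0) return(id)
    sub <- vapply(kids, function(k) {
      paste0(build(k), ":", format(tau[id] - tau[k], digits = 15))
    }, character(1))
    paste0("(", paste(sub, collapse = ","), ")", id)
  }
  nwk <- paste0(build(rootId(model)), ";")
  # validate through ape
  tr <- ape::read.tree(text = nwk)
  if (is.null(tr)) .stopf("internal error: invalid Newick produced")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Packaged demography of the Gerp's mouse lemur study system (synthetic)
#'
#' A seven-tip isolation-with-migration model of the *Microcebus gerpi*
#' populations (VohiposaSahafina, Ambodisakoana, Antanambao south of the
#' Rianila river; Sahamamy, Andobo north of it) and the two sister species
#' *M. jollyae* and *M. marohita*, with twelve directed migration bands.
#' Divergence times and the two published effective population sizes follow
#' the study system's reported values (converted to mutation-scaled units at
#' \eqn{\mu = 1.236\times 10^{-8}}, g = 3.5 years); the remaining thetas,
#' one internal split time and most band rates are synthetic fill-ins chosen
#' to be of realistic magnitude (see the methods vignette).
#'
#' @return a `DemographyModel`.
#' @export
exampleDemography <- function() {
  loadDemography(system.file("extdata", "gerpi_demography_synthetic.json",
                             package = "imcoal", mustWork = TRUE))
}

#' @export
setMethod("show", "DemographyModel", function(object) {
  cat(sprintf("DemographyModel: %d tips, %d internal nodes, %d migration bands\n",
              sum(object@populations$tip), sum(!object@populations$tip),
              nrow(object@bands)))
  cat("  tips:", paste(tipIds(object), collapse = ", "), "\n")
  tau <- object@tau
  if (length(tau))
    cat(sprintf("  tau range: [%g, %g]\n", min(tau), max(tau)))
  cat(sprintf("  theta range: [%g, %g]\n", min(object@theta), max(object@theta)))
  invisible(object)
})

#' Hash of a model's canonical document
#'
#' @param model a `DemographyModel`.
#' @return 8-hex-digit string identifying the model content.
#' @export
demographyHash <- function(model) .fnv1a(saveDemography(model, NULL))
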