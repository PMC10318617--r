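# Post-processing of mutation-scaled coalescent MCMC traces: burn-in,
# column-role classification, HPD intervals, effective sample sizes,
# Monte-Carlo conversion to absolute units and migration-band screening.

#' Default trace column-role patterns
#'
#' Regexes classifying trace columns into roles. The first capture group is
#' the node/population id; for migration columns the two groups are the
#' forward-time source and target. The shipped defaults match the
#' `theta_<id>` / `tau_<id>` / `m_<src>-><tgt>` dialect of coalescent
#' sampler traces (also accepting `-` and `.` separators).
#'
#' @return named list of regex patterns (`theta`, `tau`, `m`).
#' @export
defaultRolePatterns <- function() {
  list(
    theta = "^theta[._-](.+)$",
    tau   = "^tau[._-](.+)$",
    m     = "^m[._-](.+?)->(.+)$"
  )
}

.classifyColumns <- function(cols, patterns) {
  roles <- data.frame(column = cols, role = "other", id = NA_character_,
                      source = NA_character_, target = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    cn <- cols[i]
    if (grepl(patterns$m, cn)) {
      roles$role[i] <- "m"
      roles$source[i] <- sub(patterns$m, "\\1", cn)
      roles$target[i] <- sub(patterns$m, "\\2", cn)
      roles$id[i] <- paste0(roles$source[i], "->", roles$target[i])
    } else if (grepl(patterns$theta, cn)) {
      roles$role[i] <- "theta"
      roles$id[i] <- sub(patterns$theta, "\\1", cn)
    } else if (grepl(patterns$tau, cn)) {
      roles$role[i] <- "tau"
      roles$id[i] <- sub(patterns$tau, "\\1", cn)
    }
  }
  roles
}

#' Read mutation-scaled MCMC trace files
#'
#' Tab-separated files with a header row of parameter names and one numeric
#' row per sample. Burn-in (`ceiling(burnin_fraction * rows)` rows) is
#' discarded per chain before chains are concatenated; chain ids are
#' preserved. Columns are classified into theta/tau/m roles by configurable
#' regexes; unmatched columns (iteration counters, likelihoods) get role
#' `other`.
#'
#' @param paths one or more trace file paths (one per chain).
#' @param burnin_fraction fraction in `[0, 1)` discarded from the head of
#'   each chain (default 0.10).
#' @param patterns role regexes, see [defaultRolePatterns()].
#' @param model optional `DemographyModel`; when given, classified ids are
#'   checked to resolve against its nodes and bands.
#' @return a [PosteriorTrace-class].
#' @export
readTrace <- function(paths, burnin_fraction = 0.10,
                      patterns = defaultRolePatterns(), model = NULL) {
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    .stopf("burnin_fraction must be in [0, 1)")
  mats <- list(); chains <- list()
  for (ci in seq_along(paths)) {
    df <- utils::read.delim(paths[ci], check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      bad <- names(df)[!vapply(df, is.numeric, logical(1))]
      .stopf("non-numeric cells in column(s): %s", paste(bad, collapse = ", "))
    }
    drop <- ceiling(burnin_fraction * nrow(m))
    if (drop >= nrow(m)) .stopf("zero retained rows in '%s'", paths[ci])
    if (drop > 0) m <- m[-seq_len(drop), , drop = FALSE]
    mats[[ci]] <- m
    chains[[ci]] <- rep(ci, nrow(m))
  }
  cols <- colnames(mats[[1]])
  for (m in mats)
    if (!identical(colnames(m), cols)) .stopf("chain files have differing columns")
  samples <- do.call(rbind, mats)
  roles <- .classifyColumns(cols, patterns)
  if (!is.null(model)) .checkRoles(roles, model)
  new("PosteriorTrace", samples = samples, roles = roles,
      chain = as.integer(unlist(chains)), burnin = burnin_fraction,
      files = as.character(paths))
}

.checkRoles <- function(roles, model) {
  ids <- populationIds(model)
  bad <- with(roles, id[role %in% c("theta", "tau") & !id %in% ids])
  if (length(bad))
    .stopf("trace column id(s) not in model: %s", paste(unique(bad), collapse = ", "))
  if (any(roles$role == "m")) {
    bids <- paste0(model@bands$source, "->", model@bands$target)
    badm <- with(roles, id[role == "m" & !id %in% bids])
    if (length(badm))
      .stopf("trace migration column(s) not in model: %s",
             paste(unique(badm), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a PosteriorTrace back to a tab-separated file
#'
#' One file per chain is produced when the trace holds several chains
#' (suffix `_chain<k>`); round-trips numerically through [readTrace()] with
#' `burnin_fraction = 0`.
#'
#' @param trace a `PosteriorTrace`.
#' @param path output path (base path for multi-chain traces).
#' @return character vector of written paths, invisibly.
#' @export
writeTrace <- function(trace, path) {
  chains <- unique(trace@chain)
  out <- character()
  for (ci in chains) {
    p <- if (length(chains) == 1) path else
      sub("(\\.[^.]*)?$", sprintf("_chain%d\\1", ci), path)
    df <- as.data.frame(trace@samples[trace@chain == ci, , drop = FALSE])
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, p)
  }
  invisible(out)
}

#' @describeIn traceAccessors retained sample matrix
#' @export
traceSamples <- function(trace) trace@samples

#' Accessors for PosteriorTrace
#' @param trace a `PosteriorTrace`.
#' @name traceAccessors
NULL

#' @describeIn traceAccessors column-role table
#' @export
traceRoles <- function(trace) trace@roles

#' @describeIn traceAccessors chain id per retained row
#' @export
traceChains <- function(trace) trace@chain

#' @export
setMethod("show", "PosteriorTrace", function(object) {
  tab <- table(object@roles$role)
  cat(sprintf("PosteriorTrace: %d samples, %d chains, burn-in %.0f%%\n",
              nrow(object@samples), length(unique(object@chain)),
              100 * object@burnin))
  cat("  columns:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(object)
})

#' Highest posterior density interval
#'
#' The narrowest window of `ceiling(mass * n)` consecutive sorted values —
#' the shortest interval containing at least `mass` of the samples. Ties on
#' width resolve to the window with the lowest start.
#'
#' @param samples numeric vector (>= 2 finite values).
#' @param mass interval mass in (0, 1), default 0.95.
#' @return numeric(2): lower and upper bound.
#' @export
hpdInterval <- function(samples, mass = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2) .stopf("need at least 2 finite samples")
  if (mass <= 0 || mass >= 1) .stopf("mass must be in (0, 1)")
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)  # first minimum on ties
  c(x[i], x[i + k - 1L])
}

#' Effective sample size of an MCMC series
#'
#' `n / (1 + 2 * sum(rho_k))` with empirical autocorrelations summed up to
#' (excluding) the first non-positive estimate (initial-positive-sequence
#' truncation). Deterministic for fixed input; capped at `n`. A constant
#' series has undefined ESS and returns `n` with a warning and attribute
#' `constant = TRUE`.
#'
#' @param samples numeric vector (>= 10 values).
#' @return ESS value.
#' @export
effectiveSampleSize <- function(samples) {
  n <- length(samples)
  if (n < 10) .stopf("need at least 10 samples")
  if (stats::sd(samples) == 0) {
    warning("constant series: ESS undefined, reporting n")
    return(structure(as.numeric(n), constant = TRUE))
  }
  lagmax <- n - 1L
  rho <- stats::acf(samples, lag.max = lagmax, plot = FALSE,
                    demean = TRUE)$acf[-1]
  cut <- which(rho <= 0)
  s <- if (length(cut)) sum(rho[seq_len(cut[1] - 1L)]) else sum(rho)
  min(n / (1 + 2 * s), n)
}

#' Calibration configuration for absolute-unit conversion
#'
#' Distributions for generation time `g` (lognormal on the log scale:
#' location `log(3.5)`, scale `log(1.16)` by default, in years) and
#' per-site per-generation mutation rate `mu` (gamma parameterized by mean
#' `1.236e-8` and standard deviation `0.107e-8` by default). Either can be
#' fixed to a constant, which bypasses random draws deterministically.
#'
#' The gamma spread is a standard deviation: a literal variance of
#' `0.107e-8` would exceed the squared mean by many orders of magnitude and
#' collapse the distribution onto zero, so the printed "variance" of such
#' calibrations is interpreted as an SD (see the methods vignette).
#'
#' @param g_meanlog,g_sdlog lognormal parameters of `g`.
#' @param mu_mean,mu_sd gamma mean and SD of `mu`.
#' @param g_fixed,mu_fixed optional constants overriding the distributions.
#' @return object of class `ScaleConfig` (list-based).
#' @export
scaleConfig <- function(g_meanlog = log(3.5), g_sdlog = log(1.16),
                        mu_mean = 1.236e-8, mu_sd = 0.107e-8,
                        g_fixed = NULL, mu_fixed = NULL) {
  if (any(c(g_sdlog, mu_mean, mu_sd) <= 0) ||
      (!is.null(g_fixed) && g_fixed <= 0) ||
      (!is.null(mu_fixed) && mu_fixed <= 0))
    .stopf("all calibration hyperparameters must be strictly positive")
  structure(list(g_meanlog = g_meanlog, g_sdlog = g_sdlog,
                 mu_mean = mu_mean, mu_sd = mu_sd,
                 g_fixed = g_fixed, mu_fixed = mu_fixed),
            class = "ScaleConfig")
}

#' Draw paired calibration values
#'
#' Independent draws of generation time and mutation rate from the
#' configured distributions (or constants in fixed mode). The gamma for
#' `mu` uses shape `(mean/sd)^2` and scale `sd^2/mean`.
#'
#' @param scale a [scaleConfig()] object.
#' @param n_draws number of paired draws (>= 1).
#' @param seed optional integer seed.
#' @return data.frame with columns `g` (years) and `mu` (per site per
#'   generation).
#' @export
drawCalibrations <- function(scale, n_draws, seed = NULL) {
  stopifnot(inherits(scale, "ScaleConfig"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- if (!is.null(scale$g_fixed)) rep(scale$g_fixed, n_draws) else
    stats::rlnorm(n_draws, scale$g_meanlog, scale$g_sdlog)
  mu <- if (!is.null(scale$mu_fixed)) rep(scale$mu_fixed, n_draws) else {
    shape <- (scale$mu_mean / scale$mu_sd)^2
    stats::rgamma(n_draws, shape = shape, scale = scale$mu_sd^2 / scale$mu_mean)
  }
  data.frame(g = g, mu = mu)
}

#' Convert mutation-scaled quantities to absolute units
#'
#' \eqn{N_e = \theta / (4\mu)} (individuals), \eqn{T = (\tau/\mu) \cdot g}
#' (years), and the population migration rate
#' \eqn{2Nm = m \cdot \theta_{target} / 2} (migrant gene copies per
#' generation into the receiving population), which cancels \eqn{\mu} and
#' `g` by construction. All arguments vectorize.
#'
#' @param theta,tau,m mutation-scaled values (any may be `NULL` to skip).
#' @param theta_target theta of the receiving population, for `m`.
#' @param g generation time in years.
#' @param mu mutation rate per site per generation.
#' @return list with `Ne`, `T_years`, `Nm2` (only the requested parts).
#' @export
convertSample <- function(theta = NULL, tau = NULL, m = NULL,
                          theta_target = NULL, g = NULL, mu = NULL) {
  out <- list()
  if (!is.null(theta) || !is.null(tau)) {
    if (is.null(mu) || any(mu <= 0)) .stopf("mu must be > 0")
  }
  if (!is.null(theta)) out$Ne <- theta / (4 * mu)
  if (!is.null(tau)) {
    if (is.null(g) || any(g <= 0)) .stopf("g must be > 0")
    out$T_years <- (tau / mu) * g
  }
  if (!is.null(m)) {
    if (is.null(theta_target)) .stopf("theta_target required for m")
    out$Nm2 <- m * theta_target / 2
  }
  out
}

#' Monte-Carlo conversion of a posterior trace to absolute units
#'
#' Draws one independent (g, mu) calibration pair per retained sample and
#' converts row-wise: every theta column to `Ne_<id>`, every tau column to
#' `T_<id>` (years) and every migration column to `M2Nm_<source.target>`
#' using the same row's theta of the receiving population. Calibration
#' uncertainty therefore propagates into every converted posterior.
#'
#' @param trace a `PosteriorTrace`.
#' @param model a `DemographyModel` the trace columns resolve against.
#' @param scale a [scaleConfig()].
#' @param seed optional integer seed for the calibration draws.
#' @return a [ConvertedPosterior-class].
#' @export
monteCarloConvert <- function(trace, model, scale = scaleConfig(),
                              seed = NULL) {
  .checkRoles(trace@roles, model)
  n <- nrow(trace@samples)
  cal <- drawCalibrations(scale, n, seed = seed)
  roles <- trace@roles
  out <- list(g = cal$g, mu = cal$mu)
  meta <- data.frame(column = c("g", "mu"), quantity = c("g", "mu"),
                     id = NA_character_, stringsAsFactors = FALSE)
  for (i in which(roles$role == "theta")) {
    cn <- paste0("Ne_", roles$id[i])
    out[[cn]] <- trace@samples[, roles$column[i]] / (4 * cal$mu)
    meta <- rbind(meta, data.frame(column = cn, quantity = "Ne",
                                   id = roles$id[i]))
  }
  for (i in which(roles$role == "tau")) {
    cn <- paste0("T_", roles$id[i])
    out[[cn]] <- (trace@samples[, roles$column[i]] / cal$mu) * cal$g
    meta <- rbind(meta, data.frame(column = cn, quantity = "T_years",
                                   id = roles$id[i]))
  }
  for (i in which(roles$role == "m")) {
    tgt <- roles$target[i]
    j <- which(roles$role == "theta" & roles$id == tgt)
    if (length(j) != 1)
      .stopf("no theta column for receiving population '%s'", tgt)
    cn <- paste0("M2Nm_", roles$source[i], ".", roles$target[i])
    out[[cn]] <- trace@samples[, roles$column[i]] *
      trace@samples[, roles$column[j]] / 2
    meta <- rbind(meta, data.frame(column = cn, quantity = "2Nm",
                                   id = roles$id[i]))
  }
  new("ConvertedPosterior", samples = do.call(cbind, out), roles = meta,
      chain = trace@chain)
}

#' @export
setMethod("show", "ConvertedPosterior", function(object) {
  cat(sprintf("ConvertedPosterior: %d samples, %d quantities\n",
              nrow(object@samples), ncol(object@samples)))
  invisible(object)
})

#' Summarize a posterior sample vector
#'
#' Pooled mean, 95% HPD interval and ESS. When chain ids are supplied, the
#' mean of per-chain means is additionally reported (the replicate-run
#' convention for point estimates) while the HPD pools all samples, and the
#' ESS is the sum of per-chain ESS values.
#'
#' @param values numeric vector (>= 2 values).
#' @param chain optional integer chain id per value.
#' @param mass HPD mass (default 0.95).
#' @return list: `mean`, `lower`, `upper`, `mass`, `ess`, and
#'   `mean_of_chain_means` when `chain` is given.
#' @export
summarizePosterior <- function(values, chain = NULL, mass = 0.95) {
  if (length(values) < 2) .stopf("need at least 2 values")
  hpd <- hpdInterval(values, mass)
  ess <- if (stats::sd(values) == 0) {
    length(values)
  } else if (is.null(chain)) {
    effectiveSampleSize(values)
  } else {
    sum(vapply(split(values, chain), function(v)
      if (length(v) >= 10 && stats::sd(v) > 0)
        effectiveSampleSize(v) else length(v), numeric(1)))
  }
  out <- list(mean = mean(values), lower = hpd[1], upper = hpd[2],
              mass = mass, ess = ess)
  if (!is.null(chain))
    out$mean_of_chain_means <- mean(vapply(split(values, chain), mean,
                                           numeric(1)))
  out
}

#' Screen migration bands by posterior support
#'
#' A band is retained iff the lower bound of the HPD interval of its
#' migration-rate samples is strictly greater than zero (at the precision of
#' the parsed trace; no epsilon). This is the rule used to carry exploratory
#' bands into a final model.
#'
#' @param trace a `PosteriorTrace` with migration columns.
#' @param bands optional character vector of band ids (`"src->tgt"`);
#'   default all migration columns of the trace.
#' @param mass HPD mass (default 0.95).
#' @return data.frame: `band`, `source`, `target`, `mean`, `lower`,
#'   `upper`, `retained`.
#' @export
screenMigrationBands <- function(trace, bands = NULL, mass = 0.95) {
  roles <- trace@roles
  midx <- which(roles$role == "m")
  if (!is.null(bands)) {
    miss <- setdiff(bands, roles$id[midx])
    if (length(miss))
      .stopf("trace lacks migration column(s): %s", paste(miss, collapse = ", "))
    midx <- midx[roles$id[midx] %in% bands]
  }
  if (!length(midx)) .stopf("no migration columns in trace")
  res <- lapply(midx, function(i) {
    x <- trace@samples[, roles$column[i]]
    hpd <- hpdInterval(x, mass)
    data.frame(band = roles$id[i], source = roles$source[i],
               target = roles$target[i], mean = mean(x),
               lower = hpd[1], upper = hpd[2],
               retained = hpd[1] > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summary table for all classified trace columns
#'
#' Applies [summarizePosterior()] to every theta/tau/m column.
#'
#' @param trace a `PosteriorTrace`.
#' @param mass HPD mass.
#' @return data.frame with one row per parameter column.
#' @export
summarizeTrace <- function(trace, mass = 0.95) {
  roles <- trace@roles
  keep <- which(roles$role %in% c("theta", "tau", "m"))
  res <- lapply(keep, function(i) {
    s <- summarizePosterior(trace@samples[, roles$column[i]],
                            chain = trace@chain, mass = mass)
    data.frame(column = roles$column[i], role = roles$role[i],
               id = roles$id[i], mean = s$mean,
               mean_of_chain_means = s$mean_of_chain_means,
               lower = s$lower, upper = s$upper, ess = s$ess,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
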