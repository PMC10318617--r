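# End-to-end entry points tying the modules together. These functions are
# the programmatic equivalents of the shipped command-line wrapper
# (inst/scripts/imcoal.R); every output table carries a provenance header
# and every stochastic step takes an explicit seed.

#' Generate a synthetic posterior trace around a model's parameters
#'
#' Emulates a converged coalescent-sampler run: each theta/tau/m column is
#' lognormal around the model's value (relative spread `rel_sd` on the log
#' scale) with mild AR(1) autocorrelation, independently per chain. Useful
#' for demonstrating the post-processing workflow offline; the values carry
#' no inferential meaning.
#'
#' @param model a `DemographyModel`.
#' @param n_samples rows per chain (pre-burn-in).
#' @param n_chains number of replicate chains.
#' @param rel_sd lognormal scale parameter.
#' @param ar AR(1) coefficient of the latent log series.
#' @param seed optional integer seed.
#' @return a [PosteriorTrace-class] with `burnin = 0` (the synthetic chains
#'   have no transient; apply burn-in at [readTrace()] time if written out).
#' @export
syntheticTrace <- function(model, n_samples = 1000, n_chains = 4,
                           rel_sd = 0.05, ar = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tau <- model@tau
  vals <- c(stats::setNames(model@theta, paste0("theta_", names(model@theta))),
            stats::setNames(tau, paste0("tau_", names(tau))))
  if (nrow(model@bands))
    vals <- c(vals, stats::setNames(
      model@bands$rate, paste0("m_", model@bands$source, "->",
                               model@bands$target)))
  sim_col <- function(v) {
    z <- numeric(n_samples)
    z[1] <- stats::rnorm(1)
    for (t in 2:n_samples)
      z[t] <- ar * z[t - 1] + sqrt(1 - ar^2) * stats::rnorm(1)
    v * exp(rel_sd * z - rel_sd^2 / 2)
  }
  mats <- lapply(seq_len(n_chains), function(ci) {
    m <- vapply(vals, sim_col, numeric(n_samples))
    cbind(Sample = seq_len(n_samples), m)
  })
  new("PosteriorTrace",
      samples = do.call(rbind, mats),
      roles = .classifyColumns(colnames(mats[[1]]), defaultRolePatterns()),
      chain = rep(seq_len(n_chains), each = n_samples),
      burnin = 0, files = character())
}

#' Simulate a dataset and write VCF, popmap and manifest
#'
#' @param demography path to a demography JSON (or a `DemographyModel`).
#' @param out_dir output directory (created if needed).
#' @param samples named integer vector: diploids per tip population;
#'   default 2 per tip.
#' @param n_loci,locus_length,missingness_rate forwarded to
#'   [simulateDataset()].
#' @param seed integer seed (required: the manifest records it).
#' @return invisible list of written paths and the dataset.
#' @export
runSimulate <- function(demography, out_dir, samples = NULL, n_loci = 100,
                        locus_length = 649, missingness_rate = 0, seed = 1) {
  model <- if (is(demography, "DemographyModel")) demography else
    loadDemography(demography)
  if (is.null(samples))
    samples <- stats::setNames(rep(2L, length(tipIds(model))), tipIds(model))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulateDataset(model, samples, n_loci = n_loci,
                        locus_length = locus_length,
                        missingness_rate = missingness_rate, seed = seed)
  vcf <- file.path(out_dir, "dataset.vcf")
  exportVcf(ds, vcf)
  pm <- file.path(out_dir, "popmap.tsv")
  utils::write.table(individuals(ds)[, c("id", "population")], pm,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    tool = "imcoal", version = as.character(utils::packageVersion("imcoal")),
    seed = seed, demography_hash = demographyHash(model),
    n_loci = n_loci, locus_length = locus_length,
    missingness_rate = missingness_rate,
    samples = as.list(samples)
  ), manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(vcf = vcf, popmap = pm, manifest = manifest, dataset = ds))
}

#' Compute summary-statistic tables from a VCF and population map
#'
#' Per-population-pair weighted F_ST (raw and Slatkin-linearized) from the
#' joint folded SFS, individual and population distance matrices, and, when
#' coordinates are supplied, a Mantel isolation-by-distance test of
#' linearized F_ST against log10 great-circle kilometers with 9999
#' permutations by default.
#'
#' @param vcf path to a VCF.
#' @param popmap path to a tab-separated sample/population map.
#' @param out_dir output directory.
#' @param estimator F_ST estimator mode (recorded in outputs).
#' @param metric individual distance metric.
#' @param coords optional data.frame (`id`, `lon`, `lat`) of population
#'   coordinates for the Mantel test.
#' @param n_permutations Mantel permutations (default 9999).
#' @param seed integer seed (Mantel permutations).
#' @return invisible list with the computed tables.
#' @export
runSumstats <- function(vcf, popmap, out_dir, estimator = "hudson",
                        metric = "allele-sharing", coords = NULL,
                        n_permutations = 9999, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pm <- readPopmap(popmap)
  ds <- importVcf(vcf, pm)
  pops <- unique(pm$population)
  rows <- list()
  for (x in seq_along(pops)) {
    for (y in seq_along(pops)) {
      if (x >= y) next
      sfs <- jointSfs(ds, pops[x], pops[y], folded = TRUE)
      f <- weightedFst(sfs, estimator)
      rows[[length(rows) + 1L]] <- data.frame(
        popA = pops[x], popB = pops[y], fst = as.numeric(f),
        fst_linearized = slatkinLinearize(min(as.numeric(f), 1 - 1e-12)),
        estimator = estimator, stringsAsFactors = FALSE)
    }
  }
  fst_tab <- do.call(rbind, rows)
  .writeTsv(fst_tab, file.path(out_dir, "fst.tsv"),
            .provenanceHeader(seed, sprintf("# estimator: %s", estimator)))
  Di <- geneticDistanceMatrix(ds, metric)
  writeDistanceMatrix(Di, file.path(out_dir, "dist_individuals.tsv"))
  Dp <- populationDistanceMatrix(Di, pm)
  writeDistanceMatrix(Dp, file.path(out_dir, "dist_populations.tsv"))
  mant <- NULL
  if (!is.null(coords)) {
    G <- greatCircleDistanceMatrix(coords)
    G <- G[rownames(Dp), rownames(Dp)]
    Fm <- matrix(0, nrow(Dp), ncol(Dp), dimnames = dimnames(Dp))
    for (i in seq_len(nrow(fst_tab))) {
      Fm[fst_tab$popA[i], fst_tab$popB[i]] <-
        Fm[fst_tab$popB[i], fst_tab$popA[i]] <- fst_tab$fst_linearized[i]
    }
    mant <- mantelTest(Fm, log10(pmax(G, 1e-6)), n_permutations, seed = seed)
    jsonlite::write_json(mant, file.path(out_dir, "mantel.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(fst = fst_tab, dist_individuals = Di, dist_populations = Dp,
                 mantel = mant))
}

#' Post-process coalescent MCMC traces
#'
#' Reads replicate chain files with per-chain burn-in, writes
#' mutation-scaled parameter summaries (pooled and per-chain-mean
#' conventions, HPD, ESS), the migration-band screening report, converted
#' absolute-unit summaries (Ne, years, 2Nm) under Monte-Carlo calibration,
#' and a gdi table for every internal node when the trace has no migration
#' bands.
#'
#' @param trace_paths character vector of trace files (one per chain).
#' @param demography path to a demography JSON (or a `DemographyModel`).
#' @param out_dir output directory.
#' @param burnin_fraction per-chain burn-in (default 0.10).
#' @param scale a [scaleConfig()].
#' @param seed integer seed (calibration draws).
#' @return invisible list with the computed tables.
#' @export
runPostprocess <- function(trace_paths, demography, out_dir,
                           burnin_fraction = 0.10, scale = scaleConfig(),
                           seed = 1) {
  model <- if (is(demography, "DemographyModel")) demography else
    loadDemography(demography)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- readTrace(trace_paths, burnin_fraction, model = model)
  summ <- summarizeTrace(tr)
  .writeTsv(summ, file.path(out_dir, "trace_summary.tsv"),
            .provenanceHeader(seed, sprintf("# burnin: %g", burnin_fraction)))
  conv <- monteCarloConvert(tr, model, scale, seed = seed)
  crow <- lapply(seq_len(ncol(conv@samples)), function(i) {
    s <- summarizePosterior(conv@samples[, i], chain = conv@chain)
    data.frame(column = colnames(conv@samples)[i],
               quantity = conv@roles$quantity[i], id = conv@roles$id[i],
               mean = s$mean, mean_of_chain_means = s$mean_of_chain_means,
               lower = s$lower, upper = s$upper, stringsAsFactors = FALSE)
  })
  conv_tab <- do.call(rbind, crow)
  .writeTsv(conv_tab, file.path(out_dir, "converted_summary.tsv"),
            .provenanceHeader(seed))
  bands_tab <- NULL
  if (any(tr@roles$role == "m")) {
    bands_tab <- screenMigrationBands(tr)
    .writeTsv(bands_tab, file.path(out_dir, "band_screening.tsv"),
              .provenanceHeader(seed))
  }
  gdi_tab <- NULL
  if (!any(tr@roles$role == "m")) {
    gdi_tab <- gdiTable(tr, model)
    .writeTsv(gdi_tab, file.path(out_dir, "gdi.tsv"), .provenanceHeader(seed))
  }
  jsonlite::write_json(
    list(trace_summary = summ, converted = conv_tab,
         band_screening = bands_tab, gdi = gdi_tab),
    file.path(out_dir, "postprocess.json"), auto_unbox = TRUE, pretty = TRUE,
    dataframe = "rows")
  invisible(list(trace = tr, summary = summ, converted = conv_tab,
                 bands = bands_tab, gdi = gdi_tab))
}

#' Write the packaged example bundle
#'
#' A runnable offline example for every entry point: the synthetic
#' demography of the study system, a small simulated dataset (VCF +
#' popmap + manifest), and four synthetic replicate trace files (with and
#' without migration columns). Deterministic for a fixed seed.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_loci loci in the example dataset.
#' @return invisible list of written paths.
#' @export
runFixtures <- function(out_dir, seed = 1, n_loci = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- exampleDemography()
  demo_path <- file.path(out_dir, "demography.json")
  saveDemography(model, demo_path)
  sim <- runSimulate(model, file.path(out_dir, "dataset"), n_loci = n_loci,
                     seed = seed)
  tr_mig <- syntheticTrace(model, n_samples = 500, n_chains = 4, seed = seed)
  mig_paths <- writeTrace(tr_mig, file.path(out_dir, "trace_migration.tsv"))
  nomig <- model
  nomig@bands <- model@bands[0, ]
  tr_nomig <- syntheticTrace(nomig, n_samples = 500, n_chains = 4,
                             seed = seed + 1L)
  nomig_paths <- writeTrace(tr_nomig, file.path(out_dir, "trace_nomigration.tsv"))
  invisible(list(demography = demo_path, dataset = sim,
                 trace_migration = mig_paths, trace_nomigration = nomig_paths))
}
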