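# Minimal VCF 4.2 dialect: one pseudo-contig per locus, biallelic SNPs with
# REF = ancestral "A" and ALT = derived "T", unphased diploid genotypes,
# whole-locus missingness as "./." at every site of the locus.

.locusName <- function(k) sprintf("locus_%05d", k)

#' Export a multilocus dataset as minimal VCF 4.2
#'
#' @param dataset a `MultilocusDataset`.
#' @param path output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @seealso [importVcf()]
#' @export
exportVcf <- function(dataset, path) {
  if (nLoci(dataset) == 0) .stopf("dataset has no loci")
  ind <- dataset@individuals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=imcoal_%s", as.character(utils::packageVersion("imcoal"))),
    sprintf("##contig=<ID=%s,length=%d>",
            vapply(seq_len(nLoci(dataset)), .locusName, character(1)),
            vapply(dataset@loci, function(l) as.integer(l$length), integer(1))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind$id), collapse = "\t")
  ), con)
  for (k in seq_len(nLoci(dataset))) {
    loc <- dataset@loci[[k]]
    S <- ncol(loc$mat)
    if (S == 0) next
    a1 <- loc$mat[ind$hap1, , drop = FALSE]
    a2 <- loc$mat[ind$hap2, , drop = FALSE]
    gt <- matrix(paste0(pmin(a1, a2), "/", pmax(a1, a2)), nrow(ind), S)
    gt[dataset@missing[, k], ] <- "./."
    for (s in seq_len(S)) {
      writeLines(paste(c(.locusName(k), loc$positions[s],
                         sprintf("%s_s%d", .locusName(k), s),
                         "A", "T", ".", "PASS", ".", "GT", gt[, s]),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Import a minimal VCF into a MultilocusDataset
#'
#' Reads a VCF (the package's own dialect, or any biallelic-SNP VCF with GT
#' fields) through `vcfR`. Haplotype phase is not encoded in unphased
#' genotypes: heterozygotes are stored with the derived allele on the first
#' haplotype, so genotype (dosage) matrices round-trip exactly through
#' [exportVcf()] while haplotype order within an individual does not.
#' An (individual, locus) pair is marked missing when all its genotypes at
#' the locus are missing.
#'
#' @param path VCF path.
#' @param popmap optional data.frame with columns `sample`, `population`
#'   (tab-separated file path also accepted); defaults to population
#'   `"pop1"` for all samples.
#' @return a [MultilocusDataset-class].
#' @export
importVcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  samplesIds <- colnames(gt)
  if (is.character(popmap) && length(popmap) == 1) popmap <- readPopmap(popmap)
  if (is.null(popmap)) {
    popmap <- data.frame(sample = samplesIds, population = "pop1",
                         stringsAsFactors = FALSE)
  }
  popOf <- stats::setNames(popmap$population, popmap$sample)
  if (any(!samplesIds %in% names(popOf)))
    .stopf("popmap lacks sample(s): %s",
           paste(setdiff(samplesIds, names(popOf)), collapse = ", "))

  chroms <- unique(fix[, "CHROM"])
  # contig lengths from header when present
  meta <- v@meta
  clen <- stats::setNames(rep(NA_integer_, length(chroms)), chroms)
  for (ln in grep("^##contig=", meta, value = TRUE)) {
    id <- sub('.*ID=([^,>]+).*', "\\1", ln)
    len <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", ln)))
    if (id %in% chroms) clen[id] <- len
  }
  allChroms <- union(
    chroms,
    sub('.*ID=([^,>]+).*', "\\1", grep("^##contig=", meta, value = TRUE)))

  ni <- length(samplesIds)
  individuals <- data.frame(
    id = samplesIds,
    population = unname(popOf[samplesIds]),
    hap1 = seq(1L, by = 2L, length.out = ni),
    hap2 = seq(2L, by = 2L, length.out = ni),
    stringsAsFactors = FALSE)

  loci <- list()
  missL <- list()
  for (ch in allChroms) {
    rows <- which(fix[, "CHROM"] == ch)
    pos <- as.integer(fix[rows, "POS"])
    S <- length(rows)
    mat <- matrix(0L, 2L * ni, S)
    missInd <- rep(FALSE, ni)
    if (S > 0) {
      g <- gt[rows, , drop = FALSE]              # sites x samples
      h1 <- suppressWarnings(as.integer(substr(g, 1, 1)))
      h2 <- suppressWarnings(as.integer(substr(g, 3, 3)))
      h1 <- matrix(h1, S, ni); h2 <- matrix(h2, S, ni)
      missCell <- is.na(h1) | is.na(h2)
      missInd <- apply(missCell, 2, all)
      h1[missCell] <- 0L; h2[missCell] <- 0L
      # het stored derived-first; phase is not recoverable from "0/1"
      swap <- h1 < h2
      tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
      mat[individuals$hap1, ] <- t(h1)
      mat[individuals$hap2, ] <- t(h2)
    }
    L <- clen[ch]
    if (is.na(L)) L <- max(pos, 1L)
    loci[[length(loci) + 1L]] <- list(length = as.integer(L), mat = mat,
                                      positions = pos)
    missL[[length(missL) + 1L]] <- missInd
  }
  miss <- do.call(cbind, missL)
  new("MultilocusDataset", loci = loci, individuals = individuals,
      missing = miss, provenance = list(source = path))
}

#' Read a tab-separated population map
#'
#' @param path two-column tab-separated file: sample, population (no
#'   header, or a header line `sample<TAB>population`).
#' @return data.frame with columns `sample`, `population`.
#' @export
readPopmap <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1, ])), c("sample", "population")))
    df <- df[-1, , drop = FALSE]
  stats::setNames(df[, 1:2], c("sample", "population"))
}
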