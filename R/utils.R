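# Small internal helpers shared across modules.

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
# provenance blocks; not cryptographic.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor and multiply in 16-bit halves: doubles lose no precision this way
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- ((lo * 16777619) %% 4294967296 +
          ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Provenance header lines written at the top of every output table.
.provenanceHeader <- function(seed = NA, extra = character()) {
  c(
    sprintf("# imcoal %s", as.character(utils::packageVersion("imcoal"))),
    sprintf("# seed: %s", ifelse(is.na(seed), "none", format(seed))),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    extra
  )
}

# Write a data.frame as TSV preceded by '#' metadata lines.
.writeTsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by .writeTsv (skips '#' lines).
.readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Great-circle distance matrix from coordinates
#'
#' Pairwise great-circle distances in kilometers between labelled points,
#' suitable as the geographic side of a Mantel isolation-by-distance test.
#'
#' @param coords data.frame with columns `id`, `lon`, `lat` (decimal
#'   degrees).
#' @return symmetric numeric matrix (km) with dimnames `id`.
#' @export
greatCircleDistanceMatrix <- function(coords) {
  stopifnot(all(c("id", "lon", "lat") %in% names(coords)))
  n <- nrow(coords)
  d <- matrix(0, n, n, dimnames = list(coords$id, coords$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      km <- geosphere::distHaversine(
        c(coords$lon[i], coords$lat[i]),
        c(coords$lon[j], coords$lat[j])
      ) / 1000
      d[i, j] <- d[j, i] <- km
    }
  }
  d
}
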