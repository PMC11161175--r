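#' Define a karyotype as chromosome lengths and centromere positions
#'
#' A genome map is the coordinate system every simulation and scan operates
#' on: an ordered set of chromosomes, each with a length in bp and a
#' centromere coordinate. All coordinates in the package are 0-based,
#' half-open: a chromosome of length L covers positions `0 .. L-1`.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths (bp), all `> 0`.
#' @param centromere integer vector of centromere positions, strictly inside
#'   each chromosome (`0 < centromere < length`).
#' @return A `genome_map`: a data frame with columns `chrom`, `length`,
#'   `centromere`.
#' @examples
#' genome_map(c("chr1", "chr2"), c(5e6, 3e6), c(2.5e6, 6e4))
#' @export
genome_map <- function(chrom, length, centromere) {
  abort_if(anyDuplicated(chrom) > 0L, "chromosome names must be unique")
  abort_if(any(length <= 0), "chromosome lengths must be positive")
  abort_if(any(centromere <= 0 | centromere >= length),
           "centromere positions must satisfy 0 < centromere < length")
  gm <- data.frame(chrom = as.character(chrom),
                   length = as.numeric(length),
                   centromere = as.numeric(centromere),
                   stringsAsFactors = FALSE)
  class(gm) <- c("genome_map", "data.frame")
  gm
}

#' Built-in example karyotypes
#'
#' Two single-format fixtures (a metacentric and an acrocentric chromosome
#' pair) plus the multi-chromosome karyotype used by the simulated cohorts:
#' eight 5-Mb near-acrocentric chromosomes with the centromere at 2% of the
#' chromosome length, a minimal stand-in for a lizard macrochromosome set.
#'
#' @param type one of `"metacentric"`, `"acrocentric"`, `"cohort"`.
#' @param n_chrom,chrom_length cohort karyotype dimensions.
#' @return a [genome_map()].
#' @export
default_karyotype <- function(type = c("cohort", "metacentric", "acrocentric"),
                              n_chrom = 8L, chrom_length = 5e6) {
  type <- match.arg(type)
  switch(type,
    metacentric = genome_map(c("chrM1", "chrM2"), c(1e7, 8e6), c(5e6, 4e6)),
    acrocentric = genome_map(c("chrA1", "chrA2"), c(1e7, 8e6), c(2e5, 1.6e5)),
    cohort = genome_map(sprintf("chr%d", seq_len(n_chrom)),
                        rep(chrom_length, n_chrom),
                        rep(round(0.02 * chrom_length), n_chrom))
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosome(s), %.1f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

map_chrom <- function(gm, chrom) {
  i <- match(chrom, gm$chrom)
  abort_if(anyNA(i), paste("unknown chromosome:", chrom[which(is.na(i))[1L]]))
  i
}
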