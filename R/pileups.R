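#' Simulate per-site read pileups for a genotyped individual
#'
#' Emulates the per-position read tally a WGS alignment would yield at the
#' genotyped sites. Coverage is Poisson(`mean_coverage`) per site; each
#' read samples one of the two genotype alleles with probability 1/2, then
#' is miscalled to one of the three other bases, uniformly, with
#' probability `error_rate`.
#'
#' @param x an `offspring_genome` or `maternal_genotype`.
#' @param mean_coverage expected reads per site (> 0).
#' @param error_rate per-read miscall probability, in `[0, 0.25)`.
#' @param seed optional integer seed.
#' @return a `pileup`: data frame with columns `chrom`, `pos` (0-based)
#'   and read counts `A`, `C`, `G`, `T`.
#' @examples
#' gm <- default_karyotype("metacentric")
#' mom <- simulate_maternal_genome(gm, 1e-5, seed = 1)
#' pu <- simulate_pileups(mom, mean_coverage = 20, error_rate = 0, seed = 2)
#' head(pu)
#' @export
simulate_pileups <- function(x, mean_coverage, error_rate = 0, seed = NULL) {
  abort_if(mean_coverage <= 0, "mean_coverage must be > 0")
  abort_if(error_rate < 0 || error_rate >= 0.25,
           "error_rate must be in [0, 0.25)")
  gt <- genotype_table(x)
  n <- nrow(gt)
  with_seed(seed, {
    cov <- stats::rpois(n, mean_coverage)
    n1 <- stats::rbinom(n, cov, 0.5)   # reads from allele1
    n2 <- cov - n1
    counts <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, BASES))
    i1 <- match(gt$allele1, BASES)
    i2 <- match(gt$allele2, BASES)
    if (error_rate > 0) {
      e1 <- stats::rbinom(n, n1, error_rate)
      e2 <- stats::rbinom(n, n2, error_rate)
      n1 <- n1 - e1
      n2 <- n2 - e2
    } else {
      e1 <- e2 <- integer(n)
    }
    counts[cbind(seq_len(n), i1)] <- counts[cbind(seq_len(n), i1)] + n1
    counts[cbind(seq_len(n), i2)] <- counts[cbind(seq_len(n), i2)] + n2
    for (s in which(e1 + e2 > 0L)) {
      if (e1[s] > 0L) {
        dest <- sample(setdiff(seq_len(4L), i1[s]), e1[s], replace = TRUE)
        counts[s, ] <- counts[s, ] + tabulate(dest, 4L)
      }
      if (e2[s] > 0L) {
        dest <- sample(setdiff(seq_len(4L), i2[s]), e2[s], replace = TRUE)
        counts[s, ] <- counts[s, ] + tabulate(dest, 4L)
      }
    }
    pu <- data.frame(chrom = gt$chrom, pos = gt$pos, stringsAsFactors = FALSE)
    pu$A <- counts[, "A"]; pu$C <- counts[, "C"]
    pu$G <- counts[, "G"]; pu$T <- counts[, "T"]
    class(pu) <- c("pileup", "data.frame")
    pu
  })
}

as_pileup <- function(df) {
  need <- c("chrom", "pos", BASES)
  abort_if(!all(need %in% names(df)),
           paste("pileup needs columns:", paste(need, collapse = ", ")))
  abort_if(any(df$A < 0 | df$C < 0 | df$G < 0 | df$T < 0),
           "negative read counts in pileup")
  dup <- duplicated(paste(df$chrom, df$pos))
  abort_if(any(dup), "duplicated positions in pileup")
  df <- df[, need]
  class(df) <- c("pileup", "data.frame")
  df
}

pileup_coverage <- function(pileup) {
  pileup$A + pileup$C + pileup$G + pileup$T
}
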