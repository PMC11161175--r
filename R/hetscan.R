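#' Mean sequencing coverage of a pileup
#'
#' Arithmetic mean of per-site coverage (sum of the four base counts) over
#' all sites present in the pileup.
#'
#' @param pileup a `pileup` data frame (see [simulate_pileups()]).
#' @return the mean coverage (numeric scalar).
#' @export
mean_coverage <- function(pileup) {
  abort_if(nrow(pileup) == 0L, "empty pileup")
  mean(pileup_coverage(pileup))
}

#' Round a mean coverage up to the analysis target coverage
#'
#' The allele-balance heterozygosity rule needs a site coverage at which
#' reads can split evenly between two alleles, so the scan is restricted
#' to sites whose coverage equals the mean rounded to the next even
#' integer: the smallest even integer greater than or equal to the mean
#' (18.31 -> 20; 18 stays 18).
#'
#' @param mean mean coverage (> 0).
#' @return an even integer.
#' @export
target_coverage <- function(mean) {
  abort_if(mean <= 0, "mean coverage must be > 0")
  as.integer(2 * ceiling(mean / 2))
}

#' Configuration for the heterozygosity caller
#'
#' @param mode `"mean_coverage"` restricts the scan to sites whose
#'   coverage equals [target_coverage()] of the pileup mean (the guard
#'   against collapsed repeats at above-average coverage);
#'   `"even_split"` considers every site with even, non-zero coverage.
#' @param window_size,window_step sliding-window geometry in bp for the
#'   per-window heterozygous-site track. Default 10 kb tumbling windows
#'   (`step == size`).
#' @param mean_coverage_value optionally fix the mean coverage instead of
#'   estimating it from the pileup.
#' @param target_override optionally fix the even target coverage itself.
#' @return a `het_call_config` list.
#' @export
het_call_config <- function(mode = c("mean_coverage", "even_split"),
                            window_size = 10000, window_step = window_size,
                            mean_coverage_value = NULL, target_override = NULL) {
  mode <- match.arg(mode)
  abort_if(window_size <= 0, "window_size must be > 0")
  abort_if(window_step <= 0 || window_step > window_size,
           "window_step must satisfy 0 < step <= size")
  structure(list(mode = mode, window_size = window_size,
                 window_step = window_step,
                 mean_coverage_value = mean_coverage_value,
                 target_override = target_override),
            class = "het_call_config")
}

#' Call heterozygous sites with the strict allele-balance rule
#'
#' A site is heterozygous iff its coverage is even, exactly two bases have
#' non-zero read counts, and the two counts are equal. Sites with odd
#' coverage are filtered out; sites with three or more supported alleles
#' are never heterozygous and are tallied separately as triallelic. In
#' `mean_coverage` mode only sites whose coverage equals the target
#' coverage enter the analysis at all (numerator and denominator).
#'
#' @param pileup a `pileup`.
#' @param config a [het_call_config()].
#' @param genome_map optional [genome_map()]; if supplied, the per-window
#'   heterozygous-site track is computed immediately.
#' @return a `het_calls` object: `target_coverage`, `mode`,
#'   `sites` (`chrom`, `pos`, `coverage`, `considered`, `is_het`),
#'   `n_het_sites`, `n_sites_considered`, `n_triallelic`, `mean_coverage`,
#'   and `windows` (NULL unless `genome_map` given).
#' @examples
#' pu <- as_pileup(data.frame(chrom = "chr1", pos = c(100, 200, 300),
#'                            A = c(10, 20, 11), C = 0, G = c(10, 0, 9), T = 0))
#' calls <- call_het_sites(pu, het_call_config(target_override = 20))
#' calls$n_het_sites  # only the 10/10 site qualifies
#' @export
call_het_sites <- function(pileup, config = het_call_config(),
                           genome_map = NULL) {
  stopifnot(inherits(config, "het_call_config"))
  pileup <- as_pileup(pileup)
  cov <- pileup_coverage(pileup)
  xbar <- config$mean_coverage_value %||% mean_coverage(pileup)
  target <- config$target_override %||% target_coverage(xbar)
  considered <- if (config$mode == "mean_coverage") cov == target
                else cov %% 2 == 0 & cov > 0
  counts <- as.matrix(pileup[, BASES])
  n_alleles <- rowSums(counts > 0L)
  max_count <- pmax(counts[, 1L], counts[, 2L], counts[, 3L], counts[, 4L])
  is_het <- considered & n_alleles == 2L & max_count * 2L == cov
  sites <- data.frame(chrom = pileup$chrom, pos = pileup$pos, coverage = cov,
                      considered = considered, is_het = is_het,
                      stringsAsFactors = FALSE)
  res <- structure(list(target_coverage = target, mode = config$mode,
                        mean_coverage = xbar, sites = sites,
                        n_het_sites = sum(is_het),
                        n_sites_considered = sum(considered),
                        n_triallelic = sum(considered & n_alleles >= 3L),
                        window_size = config$window_size,
                        window_step = config$window_step, windows = NULL),
                   class = "het_calls")
  if (!is.null(genome_map)) {
    res$windows <- window_counts(res, genome_map,
                                 config$window_size, config$window_step)
  }
  res
}

#' Count heterozygous calls in sliding windows
#'
#' Windows are half-open `[start, start + size)` intervals stepped by
#' `window_step` along each chromosome; the final window is clipped at the
#' chromosome end. With `step == size` (tumbling windows) every call is
#' counted exactly once.
#'
#' @param calls a `het_calls` object.
#' @param genome_map a [genome_map()] providing chromosome lengths.
#' @param window_size,window_step window geometry in bp.
#' @return a `window_track` data frame: `chrom`, `start`, `end`, `count`.
#' @export
window_counts <- function(calls, genome_map, window_size = 10000,
                          window_step = window_size) {
  stopifnot(inherits(calls, "het_calls"))
  abort_if(window_size <= 0 || window_step <= 0 || window_step > window_size,
           "invalid window parameters")
  het <- calls$sites[calls$sites$is_het, , drop = FALSE]
  out <- lapply(seq_len(nrow(genome_map)), function(i) {
    L <- genome_map$length[i]
    starts <- seq(0, max(0, L - 1), by = window_step)
    ends <- pmin(starts + window_size, L)
    pos <- het$pos[het$chrom == genome_map$chrom[i]]
    count <- vapply(seq_along(starts), function(w)
      sum(pos >= starts[w] & pos < ends[w]), numeric(1))
    data.frame(chrom = genome_map$chrom[i], start = starts, end = ends,
               count = count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("window_track", "data.frame")
  out
}

#' Percent heterozygosity of an individual
#'
#' `100 * n_het_sites / n_sites_considered`: heterozygous positions as a
#' percentage of all positions that entered the scan (sites at target
#' coverage in `mean_coverage` mode).
#'
#' @param calls a `het_calls` object, or a list/data row with
#'   `n_het_sites` and `n_sites_considered`.
#' @return percent heterozygosity in `[0, 100]`.
#' @export
percent_heterozygosity <- function(calls) {
  abort_if(calls$n_sites_considered == 0, "no sites considered")
  100 * calls$n_het_sites / calls$n_sites_considered
}

#' @export
print.het_calls <- function(x, ...) {
  cat(sprintf(
    "het_calls (%s): target coverage %d (mean %.2f)\n  %d heterozygous of %d considered sites (%.4f%%); %d triallelic\n",
    x$mode, x$target_coverage, x$mean_coverage, x$n_het_sites,
    x$n_sites_considered,
    if (x$n_sites_considered > 0) 100 * x$n_het_sites / x$n_sites_considered else NA_real_,
    x$n_triallelic))
  invisible(x)
}

#' Plot a heterozygosity window track
#'
#' @param x a `het_calls` object with a computed `windows` track, or a
#'   `window_track` data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.het_calls <- function(x, ...) {
  abort_if(is.null(x$windows), "no window track: pass genome_map to call_het_sites")
  plot.window_track(x$windows, ...)
}

#' @export
plot.window_track <- function(x, ...) {
  chroms <- unique(x$chrom)
  offset <- c(0, cumsum(tapply(x$end, factor(x$chrom, levels = chroms), max)))
  xpos <- x$start + offset[match(x$chrom, chroms)]
  graphics::plot(xpos, x$count, type = "h", xlab = "genome position (bp)",
                 ylab = "het sites / window", ...)
  graphics::abline(v = offset[-1], col = "red", lty = 2)
  invisible(x)
}
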