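#' Ploidy class fractions from erythrocyte counts
#'
#' @param sample a `cell_sample` (see [simulate_cell_sample()]) or a list
#'   with `n_diploid`, `n_haploid`, `n_binucleated`.
#' @return a `ploidy_fractions` list: `percent_diploid`,
#'   `percent_haploid`, `percent_binucleated` (summing to 100), `n_total`.
#' @examples
#' count_fractions(list(n_diploid = 844, n_haploid = 87, n_binucleated = 12))
#' @export
count_fractions <- function(sample) {
  n <- c(sample$n_diploid, sample$n_haploid, sample$n_binucleated)
  abort_if(any(n < 0), "negative class counts")
  total <- sum(n)
  abort_if(total == 0, "no cells counted")
  structure(list(percent_diploid = 100 * n[1L] / total,
                 percent_haploid = 100 * n[2L] / total,
                 percent_binucleated = 100 * n[3L] / total,
                 n_total = total),
            class = "ploidy_fractions")
}

#' @export
print.ploidy_fractions <- function(x, ...) {
  cat(sprintf("ploidy_fractions (n = %d): diploid %.2f%%, haploid %.2f%%, binucleated %.2f%%\n",
              x$n_total, x$percent_diploid, x$percent_haploid,
              x$percent_binucleated))
  invisible(x)
}

#' Detect ploidy peaks in a DNA-content histogram
#'
#' Bins fluorescence intensities with Freedman-Diaconis bin widths,
#' lightly smooths the counts (5-bin running mean), and takes local
#' maxima as candidate peaks; maxima within 8 bins of a taller one are
#' suppressed. Events are assigned to the nearest surviving peak and
#' peaks holding less than `min_fraction` of events are dropped (with one
#' re-assignment pass). A haploid population is called when a peak lies
#' within `haploid_window` (default +/-15%) of half the 2n reference
#' intensity.
#'
#' @param events numeric intensities (>= 1000 events required).
#' @param reference_2n intensity of the 2n peak (from a diploid control).
#' @param min_fraction minimum event share for a reported peak.
#' @param haploid_window relative window around `0.5 * reference_2n`.
#' @return a `dna_peaks` list: `peaks` (data frame `position`,
#'   `proportion`), `reference_2n`, `haploid_call`, `haploid_proportion`.
#' @examples
#' ev <- simulate_dna_content(5000, haploid_prop = 0.1, seed = 1)
#' detect_ploidy_peaks(ev, reference_2n = 200)
#' @export
detect_ploidy_peaks <- function(events, reference_2n, min_fraction = 0.01,
                                haploid_window = 0.15) {
  abort_if(length(events) < 1000L, "need at least 1000 events")
  abort_if(any(events <= 0), "intensities must be positive")
  abort_if(reference_2n <= 0, "reference_2n must be positive")
  h <- graphics::hist(events, breaks = "FD", plot = FALSE)
  counts <- as.numeric(stats::filter(h$counts, rep(1 / 5, 5), sides = 2))
  counts[is.na(counts)] <- 0
  nb <- length(counts)
  is_max <- counts > c(-Inf, counts[-nb]) & counts >= c(counts[-1L], -Inf)
  cand <- which(is_max & counts > 0)
  cand <- cand[order(counts[cand], decreasing = TRUE)]
  # non-maximum suppression: drop maxima within 20% relative intensity of
  # an accepted taller peak (ploidy classes sit at integer multiples of
  # the 1n intensity, i.e. at least 33% apart)
  peaks_bin <- integer()
  for (b in cand) {
    if (all(abs(h$mids[b] - h$mids[peaks_bin]) > 0.2 * h$mids[peaks_bin]))
      peaks_bin <- c(peaks_bin, b)
  }
  abort_if(length(peaks_bin) == 0L, "no peaks found")
  pos <- h$mids[peaks_bin]
  for (pass in 1:2) {
    assign <- max.col(-abs(outer(events, pos, "-")), ties.method = "first")
    prop <- tabulate(assign, length(pos)) / length(events)
    # refine peak positions to the mean of their assigned events
    pos <- vapply(seq_along(pos), function(i)
      if (prop[i] > 0) mean(events[assign == i]) else pos[i], numeric(1))
    keep <- prop >= min_fraction
    if (all(keep)) break
    pos <- pos[keep]
    prop <- prop[keep]
  }
  o <- order(pos)
  pos <- pos[o]; prop <- prop[o]
  half <- reference_2n / 2
  hap <- which(abs(pos - half) <= haploid_window * half)
  structure(list(peaks = data.frame(position = pos, proportion = prop),
                 reference_2n = reference_2n,
                 haploid_call = length(hap) > 0,
                 haploid_proportion = if (length(hap) > 0) sum(prop[hap]) else 0),
            class = "dna_peaks")
}

#' @export
print.dna_peaks <- function(x, ...) {
  cat(sprintf("dna_peaks: %d peak(s); haploid call: %s (%.2f%% of events)\n",
              nrow(x$peaks), x$haploid_call, 100 * x$haploid_proportion))
  print(x$peaks, row.names = FALSE, digits = 4)
  invisible(x)
}
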