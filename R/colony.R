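#' Simulate colony breeding records
#'
#' Each egg record is independently parthenogenetic (mode
#' `gamete_duplication`, no father on record) with probability `fp_rate`,
#' otherwise sexual. Developmental outcome is drawn conditionally on
#' origin: FP eggs hatch defect-free with probability
#' `hatch_normal_given_fp`, with the remainder split between hatching
#' with defects and dying in ovum in the ratio 8:9 (the observed outcome
#' ratio among confirmed FP incidences); sexual eggs hatch defect-free
#' with probability 0.9.
#'
#' @param n_eggs number of egg records.
#' @param fp_rate per-egg probability of parthenogenetic development.
#' @param hatch_normal_given_fp P(defect-free hatch | FP), default 6/16.
#' @param seed optional integer seed.
#' @return a `colony_records` data frame: `egg_id`, `mother_id`,
#'   `father_id` (NA for FP), `outcome`, `mode`.
#' @export
simulate_colony <- function(n_eggs, fp_rate, hatch_normal_given_fp = 6 / 16,
                            seed = NULL) {
  abort_if(fp_rate < 0 || fp_rate > 1, "fp_rate must be in [0, 1]")
  abort_if(hatch_normal_given_fp < 0 || hatch_normal_given_fp > 1,
           "hatch_normal_given_fp must be in [0, 1]")
  with_seed(seed, {
    fp <- stats::runif(n_eggs) < fp_rate
    rest <- (1 - hatch_normal_given_fp) * c(8, 9) / 17
    p_fp <- c(hatched_normal = hatch_normal_given_fp,
              hatched_defect = rest[1L], died_in_ovum = rest[2L],
              no_development = 0)
    p_sex <- c(hatched_normal = 0.9, hatched_defect = 0.02,
               died_in_ovum = 0.05, no_development = 0.03)
    outcome <- character(n_eggs)
    cls <- names(p_fp)
    outcome[fp] <- sample(cls, sum(fp), replace = TRUE, prob = p_fp)
    outcome[!fp] <- sample(cls, sum(!fp), replace = TRUE, prob = p_sex)
    rec <- data.frame(
      egg_id = sprintf("egg%05d", seq_len(n_eggs)),
      mother_id = sprintf("F%03d", sample.int(20L, n_eggs, replace = TRUE)),
      father_id = ifelse(fp, NA_character_,
                         sprintf("M%03d", sample.int(5L, n_eggs, replace = TRUE))),
      outcome = outcome,
      mode = ifelse(fp, "gamete_duplication", "sexual"),
      stringsAsFactors = FALSE)
    class(rec) <- c("colony_records", "data.frame")
    rec
  })
}

#' Simulate an erythrocyte sample with mixoploid classes
#'
#' Cell class counts (diploid, haploid, binucleated) are multinomial with
#' the given fractions; the diploid fraction is the remainder.
#'
#' @param n_cells total cells scored.
#' @param haploid_frac,binucleated_frac class probabilities; their sum
#'   must not exceed 1.
#' @param seed optional integer seed.
#' @return a `cell_sample` list: `n_diploid`, `n_haploid`, `n_binucleated`.
#' @export
simulate_cell_sample <- function(n_cells, haploid_frac = 0.092,
                                 binucleated_frac = 0.0127, seed = NULL) {
  abort_if(haploid_frac < 0 || binucleated_frac < 0, "fractions must be >= 0")
  abort_if(haploid_frac + binucleated_frac > 1,
           "class fractions sum to more than 1")
  with_seed(seed, {
    counts <- stats::rmultinom(1L, n_cells,
                               c(1 - haploid_frac - binucleated_frac,
                                 haploid_frac, binucleated_frac))[, 1L]
    structure(list(n_diploid = counts[1L], n_haploid = counts[2L],
                   n_binucleated = counts[3L]), class = "cell_sample")
  })
}

#' Simulate a DNA-content (flow-cytometry) event list
#'
#' A two-component Gaussian mixture: a 1n peak at half the 2n reference
#' intensity and the 2n peak at the reference, both with coefficient of
#' variation `cv` (propidium-iodide staining spread).
#'
#' @param n_events number of events (default 44060, a typical acquisition).
#' @param haploid_prop proportion of haploid events.
#' @param ref_2n 2n peak intensity (arbitrary fluorescence units).
#' @param cv per-peak coefficient of variation.
#' @param seed optional integer seed.
#' @return numeric vector of positive intensities.
#' @export
simulate_dna_content <- function(n_events = 44060L, haploid_prop = 0.0962,
                                 ref_2n = 200, cv = 0.04, seed = NULL) {
  abort_if(haploid_prop < 0 || haploid_prop > 1, "haploid_prop must be in [0, 1]")
  with_seed(seed, {
    hap <- stats::runif(n_events) < haploid_prop
    mu <- ifelse(hap, ref_2n / 2, ref_2n)
    pmax(stats::rnorm(n_events, mu, cv * mu), .Machine$double.eps)
  })
}
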