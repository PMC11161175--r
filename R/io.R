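#' Read and write pileup tables
#'
#' Pileups are tab-separated text with header `chrom pos A C G T`,
#' positions 0-based. Rows whose base-count fields are not non-negative
#' integers are rejected with the offending line number; rows with
#' unknown extra base columns are rejected with a warning naming them.
#'
#' @param path file path.
#' @return [read_pileup()] returns a `pileup`; [write_pileup()] returns
#'   `path` invisibly.
#' @export
read_pileup <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  extra <- setdiff(names(df), c("chrom", "pos", BASES))
  if (length(extra) > 0) {
    warning(sprintf("ignoring unknown pileup column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    df <- df[, setdiff(names(df), extra)]
  }
  for (b in BASES) {
    bad <- which(!is.finite(df[[b]]) | df[[b]] < 0 | df[[b]] != floor(df[[b]]))
    abort_if(length(bad) > 0,
             sprintf("malformed count in column %s at line %d", b, bad[1L] + 1L))
  }
  abort_if(any(df$pos < 0), "negative position in pileup")
  as_pileup(df)
}

#' @rdname read_pileup
#' @param pileup a `pileup` data frame.
#' @export
write_pileup <- function(pileup, path) {
  pileup <- as_pileup(pileup)
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write BED window tracks
#'
#' Standard 0-based half-open BED: a record `(chr1, 0, 10000)` covers
#' positions 0..9999. The fourth column holds the per-window
#' heterozygous-site count.
#'
#' @param path file path.
#' @return [read_bed()] returns a `window_track` data frame.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "count"))
  abort_if(any(df$start < 0), "negative BED start coordinate")
  abort_if(any(df$end <= df$start), "BED intervals must satisfy start < end")
  class(df) <- c("window_track", "data.frame")
  df
}

#' @rdname read_bed
#' @param track a `window_track` data frame.
#' @export
write_bed <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write microsatellite panels
#'
#' CSV with columns `individual`, `locus`, `allele1`, `allele2`.
#'
#' @param path file path.
#' @export
read_panels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "locus", "allele1", "allele2")
  abort_if(!all(need %in% names(df)),
           paste("panel CSV needs columns:", paste(need, collapse = ", ")))
  canonicalize_panel(df[, need])
}

#' @rdname read_panels
#' @param panel an `ms_panel` data frame.
#' @export
write_panels <- function(panel, path) {
  utils::write.csv(canonicalize_panel(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected by name, so typos never silently fall back
#' to defaults. See [default_pipeline_config()] for the keys and their
#' meanings.
#'
#' @param path YAML file path.
#' @return a validated config list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  abort_if(length(unknown) > 0,
           paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, cfg)
}

#' Default pipeline configuration
#'
#' The simulated study conditions: a 23-chromosome telocentric karyotype
#' (1 Mb per chromosome, a length-reduced stand-in for the assembly's 23
#' chromosomes; whiptail macrochromosomes are acrocentric to
#' telocentric); maternal heterozygous-site density 1e-3
#' per bp (about 23,000 sites genome-wide, the order observed for
#' sexually produced whiptail mothers); two crossovers expected per
#' chromosome arm with an
#' obligate chiasma; mean coverage 18.37 with a per-read error rate of
#' 1e-3; even-split heterozygosity calling aggregated in 250-kb tumbling
#' windows for the interspersion contrast.
#'
#' @param ... overrides for individual keys.
#' @return a config list.
#' @export
default_pipeline_config <- function(...) {
  validate_config(utils::modifyList(config_defaults(), list(...)))
}

config_defaults <- function() {
  list(
    seed = 1L,
    n_chromosomes = 23L,
    chrom_length = 1e6,
    centromere_frac = 0.001,
    het_density = 1e-3,
    crossover_rate = 2,
    obligate_crossover = TRUE,
    mean_coverage = 18.37,
    error_rate = 1e-3,
    call_mode = "even_split",
    window_size = 100000,
    window_step = 100000,
    n_bins = 10L,
    modes = as.list(stats::setNames(rep(10L, 4L), REPRODUCTION_MODES)),
    thresholds = list(),
    out = NULL)
}

#' Run the simulate -> call -> classify pipeline
#'
#' Simulates a mother (and a father for the sexual arm), produces
#' offspring cohorts under each configured reproduction mode, generates
#' pileups, calls heterozygous sites, and classifies each offspring's
#' mechanism against the mother. Fully deterministic under a fixed
#' config seed. If `config$out` is set, the per-offspring table, the
#' mother's window track (BED) and a JSON run summary embedding the seed
#' and a config hash are written there.
#'
#' @param config a config list ([default_pipeline_config()] /
#'   [load_config()]).
#' @return a `pipeline_result`: `calls` data frame (`id`, `true_mode`,
#'   `label`, `retained`, `interspersion`, `trend_rho`, `percent_het`),
#'   `mother_calls`, `accuracy`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- validate_config(config)
  gm <- genome_map(sprintf("chr%d", seq_len(config$n_chromosomes)),
                   rep(config$chrom_length, config$n_chromosomes),
                   rep(round(config$centromere_frac * config$chrom_length),
                       config$n_chromosomes))
  n_off <- sum(unlist(config$modes))
  seeds <- derive_seeds(config$seed, 4L + 2L * n_off)
  mom <- simulate_maternal_genome(gm, config$het_density, seed = seeds[[1L]])
  dad <- simulate_paternal_genome(mom, seed = seeds[[2L]])
  ccfg <- het_call_config(mode = config$call_mode,
                          window_size = config$window_size,
                          window_step = config$window_step)
  mom_pu <- simulate_pileups(mom, config$mean_coverage, config$error_rate,
                             seed = seeds[[3L]])
  mom_calls <- call_het_sites(mom_pu, ccfg, genome_map = gm)

  rows <- list()
  s <- 3L
  for (mode in names(config$modes)) {
    for (rep_i in seq_len(config$modes[[mode]])) {
      s <- s + 2L
      tet <- simulate_meiosis(mom, config$crossover_rate,
                              config$obligate_crossover, seed = seeds[[s - 1L]])
      off <- make_offspring(tet, mode, mom,
                            paternal = if (mode == "sexual") dad else NULL,
                            seed = seeds[[s - 1L]],
                            crossover_rate = config$crossover_rate,
                            obligate_crossover = config$obligate_crossover,
                            id = sprintf("%s_%03d", mode, rep_i))
      pu <- simulate_pileups(off, config$mean_coverage, config$error_rate,
                             seed = seeds[[s]])
      calls <- call_het_sites(pu, ccfg, genome_map = gm)
      mc <- infer_mechanism(mom_calls, calls, gm, n_bins = config$n_bins,
                            thresholds = config$thresholds)
      rows[[length(rows) + 1L]] <- data.frame(
        id = off$id, true_mode = mode, label = mc$label,
        retained = mc$retained_fraction, interspersion = mc$interspersion,
        trend_rho = mc$trend_rho,
        percent_het = percent_heterozygosity(calls),
        stringsAsFactors = FALSE)
    }
  }
  calls_df <- do.call(rbind, rows)
  res <- structure(list(calls = calls_df, mother_calls = mom_calls,
                        accuracy = mean(calls_df$label == mode_label(calls_df$true_mode)),
                        config = config, config_hash = config_hash(config)),
                   class = "pipeline_result")
  if (!is.null(config$out)) write_pipeline_outputs(res, config$out)
  res
}

# Expected classifier label for each simulated reproduction mode.
mode_label <- function(mode) {
  ifelse(mode == "gamete_duplication", "post_meiotic_duplication", mode)
}

config_hash <- function(config) {
  config$out <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2L)
  unname(tools::md5sum(f))
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = res$config$seed, config_hash = res$config_hash)
  utils::write.table(cbind(res$calls, seed = stamp$seed,
                           config_hash = stamp$config_hash),
                     file.path(dir, "mechanism_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(res$mother_calls$windows, file.path(dir, "mother_windows.bed"))
  jsonlite::write_json(
    c(stamp, list(accuracy = res$accuracy,
                  n_offspring = nrow(res$calls),
                  labels = as.list(table(res$calls$label)))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d offspring, %.1f%% correctly classified\n",
              nrow(x$calls), 100 * x$accuracy))
  print(table(true = x$calls$true_mode, called = x$calls$label))
  invisible(x)
}
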