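# Deterministic miniature fixtures shared across test files.

# Single telocentric chromosome with heterozygous sites at fixed fractions.
fixture_mom <- function(site_fracs = c(0.1, 0.3, 0.55, 0.8, 0.95),
                        L = 1e6, cen = 1) {
  gm <- genome_map("c1", L, cen)
  structure(list(genome_map = gm,
                 sites = data.frame(chrom = "c1", pos = round(site_fracs * L),
                                    allele_a = "A", allele_b = "G",
                                    is_het = TRUE, stringsAsFactors = FALSE)),
            class = "maternal_genotype")
}

fixture_dad <- function(mom) {
  s <- mom$sites
  s$allele_a <- "C"
  s$allele_b <- "T"
  structure(list(genome_map = mom$genome_map, sites = s),
            class = "maternal_genotype")
}

# Minimal pileup from explicit per-site base counts (list of named vectors).
fixture_pileup <- function(counts, pos = NULL) {
  n <- length(counts)
  pu <- data.frame(chrom = "c1", pos = pos %||% (seq_len(n) * 100),
                   A = 0L, C = 0L, G = 0L, T = 0L)
  for (i in seq_len(n)) for (b in names(counts[[i]])) pu[i, b] <- counts[[i]][[b]]
  as_pileup(pu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# het_calls stub for classifier unit tests.
fixture_calls <- function(pos, considered, is_het, coverage = 20L) {
  structure(list(target_coverage = coverage, mode = "mean_coverage",
                 mean_coverage = coverage,
                 sites = data.frame(chrom = "c1", pos = pos,
                                    coverage = coverage,
                                    considered = considered, is_het = is_het,
                                    stringsAsFactors = FALSE),
                 n_het_sites = sum(is_het), n_sites_considered = sum(considered),
                 n_triallelic = 0L, window_size = 1e4, window_step = 1e4,
                 windows = NULL),
            class = "het_calls")
}
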