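#' Simulate a phased heterozygous maternal genome
#'
#' Draws heterozygous SNP sites along each chromosome: per-chromosome site
#' counts are Poisson with mean `het_density * length`, positions uniform,
#' then sorted and deduplicated. Each site carries two distinct alleles
#' (one per homolog): `allele_a` lives on homolog A, `allele_b` on homolog
#' B. Homozygous positions are not materialised -- they carry no
#' information about the diploidy-restoration mechanism.
#'
#' @param genome_map a [genome_map()].
#' @param het_density expected heterozygous sites per bp (e.g. `1e-3`).
#' @param seed optional integer seed.
#' @return A `maternal_genotype`: list with `genome_map` and `sites`
#'   (data frame `chrom`, `pos`, `allele_a`, `allele_b`, `is_het`).
#' @examples
#' gm <- default_karyotype("cohort", n_chrom = 2)
#' mom <- simulate_maternal_genome(gm, het_density = 1e-4, seed = 1)
#' nrow(mom$sites)
#' @export
simulate_maternal_genome <- function(genome_map, het_density, seed = NULL) {
  stopifnot(inherits(genome_map, "genome_map"))
  abort_if(het_density < 0, "het_density must be >= 0")
  with_seed(seed, {
    per <- lapply(seq_len(nrow(genome_map)), function(i) {
      n <- stats::rpois(1L, het_density * genome_map$length[i])
      if (n == 0L) {
        return(data.frame(chrom = character(), pos = numeric(),
                          allele_a = character(), allele_b = character(),
                          stringsAsFactors = FALSE))
      }
      pos <- sort(unique(floor(stats::runif(n, 0, genome_map$length[i]))))
      a <- sample(BASES, length(pos), replace = TRUE)
      # second allele drawn from the three remaining bases
      b <- vapply(a, function(x) sample(setdiff(BASES, x), 1L), character(1L))
      data.frame(chrom = genome_map$chrom[i], pos = pos,
                 allele_a = a, allele_b = unname(b), stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, per)
    sites$is_het <- sites$allele_a != sites$allele_b
    structure(list(genome_map = genome_map, sites = sites),
              class = "maternal_genotype")
  })
}

#' Simulate a paternal genome matched to a maternal site list
#'
#' For sexual-control offspring the father is genotyped at the same sites
#' as the mother. By default his two alleles at each site are drawn from
#' the bases *not* carried by the mother, so every paternal contribution
#' is recognisably non-maternal (maximally informative pedigree); set
#' `disjoint = FALSE` to draw them independently of the maternal alleles.
#'
#' @param maternal a `maternal_genotype`.
#' @param disjoint draw paternal alleles disjoint from the maternal pair?
#' @param seed optional integer seed.
#' @return a `maternal_genotype`-shaped object (same structure, paternal).
#' @export
simulate_paternal_genome <- function(maternal, disjoint = TRUE, seed = NULL) {
  stopifnot(inherits(maternal, "maternal_genotype"))
  s <- maternal$sites
  with_seed(seed, {
    if (disjoint) {
      ab <- t(mapply(function(a, b) {
        pool <- setdiff(BASES, c(a, b))
        if (length(pool) == 1L) pool <- rep(pool, 2L)
        sample(pool, 2L, replace = FALSE)
      }, s$allele_a, s$allele_b))
    } else {
      ab <- cbind(sample(BASES, nrow(s), replace = TRUE),
                  sample(BASES, nrow(s), replace = TRUE))
    }
    s$allele_a <- ab[, 1L]
    s$allele_b <- ab[, 2L]
    s$is_het <- s$allele_a != s$allele_b
    structure(list(genome_map = maternal$genome_map, sites = s),
              class = "maternal_genotype")
  })
}

#' @export
print.maternal_genotype <- function(x, ...) {
  cat(sprintf("maternal_genotype: %d heterozygous sites on %d chromosome(s)\n",
              sum(x$sites$is_het), nrow(x$genome_map)))
  invisible(x)
}
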