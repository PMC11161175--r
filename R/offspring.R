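#' Reproduction modes
#'
#' The four ways a diploid offspring genome can arise from a female
#' meiosis: `sexual` (egg chromatid plus a paternal gamete),
#' `central_automixis` (egg fused with a first-polar-body product),
#' `terminal_automixis` (egg fused with its sister chromatid from the
#' second polar body), and `gamete_duplication` (post-meiotic duplication
#' of the egg genome without cell division, producing a fully homozygous
#' diploid).
#'
#' @format A character vector of the four mode names.
#' @export
REPRODUCTION_MODES <- c("sexual", "central_automixis",
                        "terminal_automixis", "gamete_duplication")

#' Build an offspring genome from a meiotic tetrad
#'
#' Combines the egg chromatid with a second chromatid determined by the
#' reproduction mode: the paternal gamete (sexual), one of the two
#' first-polar-body chromatids chosen uniformly (central automixis), the
#' egg's sister chromatid (terminal automixis), or an identical copy of
#' the egg (gamete duplication). The offspring is genotyped at every
#' maternal heterozygous site.
#'
#' @param tetrad a [simulate_meiosis()] tetrad of the mother.
#' @param mode one of [REPRODUCTION_MODES].
#' @param maternal the `maternal_genotype` the tetrad was simulated from.
#' @param paternal paternal genotype (required iff `mode = "sexual"`; see
#'   [simulate_paternal_genome()]).
#' @param seed optional integer seed.
#' @param paternal_tetrad optional pre-simulated paternal tetrad; if
#'   absent a paternal meiosis is simulated with `crossover_rate` /
#'   `obligate_crossover`.
#' @param crossover_rate,obligate_crossover parameters for the internally
#'   simulated paternal meiosis (sexual mode only).
#' @param id,mother_id,father_id optional individual labels.
#' @return an `offspring_genome`: list with `genome_map`, `sites` (data
#'   frame `chrom`, `pos`, `allele1`, `allele2`, `is_het`), `true_mode`
#'   and parent ids.
#' @examples
#' gm <- default_karyotype("metacentric")
#' mom <- simulate_maternal_genome(gm, 1e-5, seed = 1)
#' tet <- simulate_meiosis(mom, crossover_rate = 1, seed = 2)
#' off <- make_offspring(tet, "gamete_duplication", mom, seed = 3)
#' mean(off$sites$is_het)  # 0: duplication forces homozygosity
#' @export
make_offspring <- function(tetrad, mode, maternal, paternal = NULL, seed = NULL,
                           paternal_tetrad = NULL, crossover_rate = 1,
                           obligate_crossover = TRUE, id = NULL,
                           mother_id = NULL, father_id = NULL) {
  stopifnot(inherits(tetrad, "tetrad"), inherits(maternal, "maternal_genotype"))
  mode <- match.arg(mode, REPRODUCTION_MODES)
  if (mode == "sexual") {
    abort_if(is.null(paternal) && is.null(paternal_tetrad),
             "sexual mode requires a paternal genome")
  } else {
    abort_if(!is.null(paternal) || !is.null(paternal_tetrad),
             "paternal genome supplied to a non-sexual mode")
  }
  gm <- maternal$genome_map
  sites <- maternal$sites
  with_seed(seed, {
    if (mode == "sexual" && is.null(paternal_tetrad)) {
      paternal_tetrad <- simulate_meiosis(paternal, crossover_rate,
                                          obligate_crossover)
    }
    allele1 <- character(nrow(sites))
    allele2 <- character(nrow(sites))
    for (i in seq_len(nrow(gm))) {
      ch <- tetrad$chromosomes[[gm$chrom[i]]]
      sel <- which(sites$chrom == gm$chrom[i])
      if (length(sel) == 0L) next
      pos <- sites$pos[sel]
      egg <- ch$chromatids[[ch$roles[["egg"]]]]
      o1 <- origin_at(egg, pos)
      allele1[sel] <- ifelse(o1 == 1L, sites$allele_a[sel], sites$allele_b[sel])
      if (mode == "gamete_duplication") {
        allele2[sel] <- allele1[sel]
      } else if (mode == "terminal_automixis") {
        o2 <- origin_at(ch$chromatids[[ch$roles[["pb2_sister"]]]], pos)
        allele2[sel] <- ifelse(o2 == 1L, sites$allele_a[sel], sites$allele_b[sel])
      } else if (mode == "central_automixis") {
        role <- if (stats::runif(1L) < 0.5) "pb1_x" else "pb1_y"
        o2 <- origin_at(ch$chromatids[[ch$roles[[role]]]], pos)
        allele2[sel] <- ifelse(o2 == 1L, sites$allele_a[sel], sites$allele_b[sel])
      } else { # sexual: egg + the paternal tetrad's egg chromatid
        pch <- paternal_tetrad$chromosomes[[gm$chrom[i]]]
        gam <- pch$chromatids[[pch$roles[["egg"]]]]
        o2 <- origin_at(gam, pos)
        psites <- if (is.null(paternal)) maternal$sites else paternal$sites
        allele2[sel] <- ifelse(o2 == 1L, psites$allele_a[sel], psites$allele_b[sel])
      }
    }
    out_sites <- data.frame(chrom = sites$chrom, pos = sites$pos,
                            allele1 = allele1, allele2 = allele2,
                            is_het = allele1 != allele2,
                            stringsAsFactors = FALSE)
    structure(list(genome_map = gm, sites = out_sites, true_mode = mode,
                   id = id, mother_id = mother_id, father_id = father_id),
              class = "offspring_genome")
  })
}

#' @export
print.offspring_genome <- function(x, ...) {
  cat(sprintf("offspring_genome (%s): %d sites, %.1f%% heterozygous\n",
              x$true_mode, nrow(x$sites), 100 * mean(x$sites$is_het)))
  invisible(x)
}

# Normalise maternal/offspring genotypes to a two-allele site table.
genotype_table <- function(x) {
  if (inherits(x, "offspring_genome")) {
    data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
               allele1 = x$sites$allele1, allele2 = x$sites$allele2,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "maternal_genotype")) {
    data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
               allele1 = x$sites$allele_a, allele2 = x$sites$allele_b,
               stringsAsFactors = FALSE)
  } else stop("expected an offspring_genome or maternal_genotype", call. = FALSE)
}
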