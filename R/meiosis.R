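#' Simulate one female meiosis as a four-chromatid tetrad
#'
#' Models canonical meiosis for each chromosome of a phased diploid genome.
#' The bivalent starts as four chromatids: 1 and 2 are the sisters of
#' homolog A, 3 and 4 of homolog B (sisterhood is defined by centromere
#' origin, which crossovers never change). Crossover counts are Poisson
#' with mean `crossover_rate` per chromosome arm, positions uniform within
#' the arm; each crossover involves one chromatid of each homolog, chosen
#' uniformly and independently (no chromatid interference), and exchanges
#' the chromatid segments on the telomere side of the crossover point.
#' With `obligate_crossover` a chromosome that drew zero crossovers
#' receives one at a uniform position (length-weighted across arms),
#' mimicking the obligate chiasma.
#'
#' Meiotic segregation is randomised per chromosome: which homolog pair
#' becomes the egg lineage at MI, and which sister becomes the egg at MII,
#' are independent fair coin flips. Roles are recorded as `egg`,
#' `pb2_sister` (the egg's sister, expelled in the second polar body), and
#' `pb1_x`/`pb1_y` (the first-polar-body pair).
#'
#' @param maternal a `maternal_genotype` (or paternal, same structure).
#' @param crossover_rate expected crossovers per chromosome arm.
#' @param obligate_crossover force at least one crossover per chromosome.
#' @param seed optional integer seed.
#' @param crossover_positions optional named list (chromosome name ->
#'   numeric bp positions) overriding the random crossover draw; chromatid
#'   choice and segregation stay random. Chromosomes absent from the list
#'   get no crossovers.
#' @return a `tetrad`: list with `genome_map` and one entry per chromosome
#'   carrying `chromatids` (four `(breaks, origins)` step functions),
#'   `crossovers`, and `roles`.
#' @examples
#' mom <- simulate_maternal_genome(default_karyotype("metacentric"), 1e-5, seed = 1)
#' tet <- simulate_meiosis(mom, crossover_rate = 1, seed = 2)
#' tet$chromosomes[[1]]$roles
#' @export
simulate_meiosis <- function(maternal, crossover_rate = 1, obligate_crossover = TRUE,
                             seed = NULL, crossover_positions = NULL) {
  stopifnot(inherits(maternal, "maternal_genotype"))
  abort_if(crossover_rate < 0, "crossover_rate must be >= 0")
  gm <- maternal$genome_map
  with_seed(seed, {
    chroms <- lapply(seq_len(nrow(gm)), function(i) {
      L <- gm$length[i]
      cen <- gm$centromere[i]
      if (!is.null(crossover_positions)) {
        xo <- as.numeric(crossover_positions[[gm$chrom[i]]] %||% numeric())
        abort_if(any(xo < 0 | xo >= L), "crossover position outside chromosome")
      } else {
        k_p <- stats::rpois(1L, crossover_rate)
        k_q <- stats::rpois(1L, crossover_rate)
        xo <- c(stats::runif(k_p, 0, cen), stats::runif(k_q, cen, L))
        if (obligate_crossover && length(xo) == 0L) xo <- stats::runif(1L, 0, L)
      }
      meiosis_one_chrom(L, cen, xo)
    })
    names(chroms) <- gm$chrom
    structure(list(genome_map = gm, chromosomes = chroms), class = "tetrad")
  })
}

# One bivalent: apply crossovers (proximal-to-distal within each arm),
# then randomise MI/MII segregation roles.
meiosis_one_chrom <- function(L, cen, xo) {
  chrom_seg <- function(origin) list(breaks = c(0, L), origins = origin)
  tet <- list(chrom_seg(1L), chrom_seg(1L), chrom_seg(2L), chrom_seg(2L))
  # q-arm crossovers swap [x, L) and compose outward (ascending positions);
  # p-arm crossovers swap [0, x) and compose outward from the centromere
  # (descending positions). The two arms touch disjoint intervals.
  q_arm <- sort(xo[xo >= cen])
  p_arm <- sort(xo[xo < cen], decreasing = TRUE)
  for (x in c(p_arm, q_arm)) {
    p <- sample.int(2L, 1L)        # chromatid of homolog A
    q <- sample.int(2L, 1L) + 2L   # chromatid of homolog B
    if (x >= cen) { a <- x; b <- L } else { a <- 0; b <- x }
    swapped <- swap_region(tet[[p]], tet[[q]], a, b, L)
    tet[[p]] <- swapped[[1L]]
    tet[[q]] <- swapped[[2L]]
  }
  egg_pair <- if (stats::runif(1L) < 0.5) 1:2 else 3:4
  pb1_pair <- setdiff(1:4, egg_pair)
  if (stats::runif(1L) < 0.5) egg_pair <- rev(egg_pair)
  if (stats::runif(1L) < 0.5) pb1_pair <- rev(pb1_pair)
  list(chromatids = tet, crossovers = sort(xo),
       roles = c(egg = egg_pair[1L], pb2_sister = egg_pair[2L],
                 pb1_x = pb1_pair[1L], pb1_y = pb1_pair[2L]))
}

# Exchange the [a, b) interval between two segment step functions.
swap_region <- function(p, q, a, b, L) {
  piece <- function(ch, lo, hi) {
    s <- pmax(ch$breaks[-length(ch$breaks)], lo)
    e <- pmin(ch$breaks[-1L], hi)
    keep <- s < e
    list(starts = s[keep], origins = ch$origins[keep])
  }
  stitch <- function(p1, p2, p3) {
    starts <- c(p1$starts, p2$starts, p3$starts)
    list(breaks = c(starts, L), origins = c(p1$origins, p2$origins, p3$origins))
  }
  new_p <- stitch(piece(p, 0, a), piece(q, a, b), piece(p, b, L))
  new_q <- stitch(piece(q, 0, a), piece(p, a, b), piece(q, b, L))
  list(new_p, new_q)
}

# Homolog origin (1 = A, 2 = B) of a chromatid at each position.
origin_at <- function(chromatid, pos) {
  chromatid$origins[findInterval(pos, chromatid$breaks)]
}

#' @export
print.tetrad <- function(x, ...) {
  n_xo <- sum(vapply(x$chromosomes, function(ch) length(ch$crossovers), numeric(1)))
  cat(sprintf("tetrad: %d chromosome(s), %d crossover(s) total\n",
              length(x$chromosomes), n_xo))
  invisible(x)
}
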