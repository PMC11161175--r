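#' Simulate a microsatellite panel for a breeding group
#'
#' Generates parental microsatellite genotypes (allele sizes in bp on a
#' dinucleotide-step ladder) and offspring panels under the stated
#' reproduction modes: a sexual offspring inherits one maternal and one
#' paternal allele per locus; a parthenogenetic (gamete-duplication)
#' offspring inherits a single maternal allele per locus, twice. With
#' probability `jitter_prob` each *observed* size is shifted by +/-1 bp,
#' emulating capillary-electrophoresis binning artifacts.
#'
#' @param modes named character vector: offspring id -> reproduction mode
#'   (`"sexual"` or `"gamete_duplication"`).
#' @param n_loci number of markers (default 8, a typical panel).
#' @param jitter_prob per-observation +/-1 bp binning-noise probability.
#' @param p_het_parent probability a parent is heterozygous at a locus.
#' @param disjoint_parents force paternal allele sizes to never coincide
#'   with maternal ones (fully informative panel).
#' @param mother_id,father_id parent labels.
#' @param seed optional integer seed.
#' @return a list: `panel` (`ms_panel` data frame `individual`, `locus`,
#'   `allele1`, `allele2` of observed sizes for parents and offspring),
#'   `truth` (offspring id -> true mode), `true_panel` (jitter-free).
#' @export
simulate_ms_panel <- function(modes, n_loci = 8L, jitter_prob = 0,
                              p_het_parent = 0.65, disjoint_parents = FALSE,
                              mother_id = "mother", father_id = "father",
                              seed = NULL) {
  abort_if(n_loci < 1, "n_loci must be >= 1")
  modes <- vapply(modes, match.arg, character(1L),
                  choices = c("sexual", "gamete_duplication"))
  with_seed(seed, {
    loci <- sprintf("MS%02d", seq_len(n_loci))
    draw_parent <- function(offset) t(vapply(seq_len(n_loci), function(l) {
      base <- sample(seq(150L, 300L, by = 2L), 1L) + offset
      if (stats::runif(1L) < p_het_parent) c(base, base + 2L * sample(1:6, 1L))
      else c(base, base)
    }, numeric(2L)))
    mom <- draw_parent(0L)
    dad <- draw_parent(if (disjoint_parents) 1L else 0L)  # odd sizes: disjoint
    rows <- list(
      data.frame(individual = mother_id, locus = loci,
                 allele1 = mom[, 1L], allele2 = mom[, 2L]),
      data.frame(individual = father_id, locus = loci,
                 allele1 = dad[, 1L], allele2 = dad[, 2L]))
    for (oid in names(modes)) {
      m_allele <- ifelse(stats::runif(n_loci) < 0.5, mom[, 1L], mom[, 2L])
      if (modes[[oid]] == "gamete_duplication") {
        a1 <- m_allele; a2 <- m_allele
      } else {
        a1 <- m_allele
        a2 <- ifelse(stats::runif(n_loci) < 0.5, dad[, 1L], dad[, 2L])
      }
      rows[[length(rows) + 1L]] <- data.frame(individual = oid, locus = loci,
                                              allele1 = a1, allele2 = a2)
    }
    panel <- do.call(rbind, rows)
    true_panel <- canonicalize_panel(panel)
    if (jitter_prob > 0) {
      jit <- function(x) x + (stats::runif(length(x)) < jitter_prob) *
        sample(c(-1L, 1L), length(x), replace = TRUE)
      panel$allele1 <- jit(panel$allele1)
      panel$allele2 <- jit(panel$allele2)
    }
    panel <- canonicalize_panel(panel)
    list(panel = panel, truth = modes, true_panel = true_panel)
  })
}

canonicalize_panel <- function(panel) {
  abort_if(any(panel$allele1 <= 0 | panel$allele2 <= 0),
           "allele sizes must be positive")
  a1 <- pmin(panel$allele1, panel$allele2)
  a2 <- pmax(panel$allele1, panel$allele2)
  panel$allele1 <- a1
  panel$allele2 <- a2
  class(panel) <- unique(c("ms_panel", class(panel)))
  panel
}

#' Bin microsatellite allele sizes across a comparison set
#'
#' Within each locus, allele sizes observed across the compared
#' individuals are clustered by single-linkage with link distance
#' `tolerance_bp`: sizes differing by at most the tolerance are chained
#' into one cluster. A cluster no wider than `2 * tolerance_bp` is merged
#' to its modal size (ties to the smaller size); a warning reports chains
#' wider than the tolerance. Chains exceeding the cap are left unmerged
#' with a warning, since collapsing them would erase real allele classes.
#'
#' @param panel an `ms_panel` data frame (`individual`, `locus`,
#'   `allele1`, `allele2`).
#' @param tolerance_bp sizes differing by at most this are one allele
#'   class (default 1 bp, the standard binning-artifact allowance).
#' @return the panel with sizes replaced by canonical cluster sizes.
#' @export
bin_alleles <- function(panel, tolerance_bp = 1) {
  abort_if(tolerance_bp < 0, "tolerance must be >= 0")
  panel <- canonicalize_panel(panel)
  for (loc in unique(panel$locus)) {
    sel <- panel$locus == loc
    sizes <- c(panel$allele1[sel], panel$allele2[sel])
    u <- sort(unique(sizes))
    if (length(u) < 2L) next
    cl <- cumsum(c(1, diff(u) > tolerance_bp))  # single-linkage chains
    remap <- u
    for (g in unique(cl)) {
      member <- u[cl == g]
      width <- max(member) - min(member)
      if (width == 0) next
      if (width > 2 * tolerance_bp) {
        warning(sprintf("locus %s: size chain %s wider than 2x tolerance; left unmerged",
                        loc, paste(member, collapse = "/")), call. = FALSE)
        next
      }
      if (width > tolerance_bp)
        warning(sprintf("locus %s: chained sizes %s merged to one class (width %g)",
                        loc, paste(member, collapse = "/"), width), call. = FALSE)
      tab <- table(sizes[sizes %in% member])
      modal <- as.numeric(names(tab)[which.max(tab)])  # ties -> smallest
      remap[cl == g] <- modal
    }
    panel$allele1[sel] <- remap[match(panel$allele1[sel], u)]
    panel$allele2[sel] <- remap[match(panel$allele2[sel], u)]
  }
  canonicalize_panel(panel)
}

panel_genotypes <- function(panel, id) {
  p <- panel[panel$individual == id, , drop = FALSE]
  abort_if(nrow(p) == 0L, paste("individual not in panel:", id))
  p
}

#' Parentage exclusion and facultative-parthenogenesis call
#'
#' Implements exclusion-based parentage over binned allele sizes. A
#' candidate mother is *compatible* if she shares at least one allele
#' with the offspring at every locus, and *fully maternal* if every
#' offspring allele is present in her genotype. A candidate father is
#' excluded at a locus where the offspring's non-maternal allele (or its
#' single allele, if homozygous) is absent from his genotype; a locus
#' where mother and father both carry that allele is uninformative.
#'
#' Calls: `FP` iff the offspring is homozygous at every scored locus,
#' fully maternal-consistent, and every candidate father is excluded at
#' at least `min_exclusions` loci. `sexual` iff a compatible mother and
#' exactly one unexcluded father explain all loci. Otherwise `ambiguous`.
#'
#' @param offspring_id id of the offspring within `panel`.
#' @param panel a binned `ms_panel` (run [bin_alleles()] first when sizes
#'   come from fragment analysis).
#' @param mothers,fathers candidate parent ids.
#' @param min_exclusions exclusion loci required to reject a father.
#' @param tolerance_bp allele-size matching tolerance for all comparisons
#'   (sharing, containment, homozygosity, exclusion). Residual 1-bp
#'   binning artifacts that single-linkage merging could not resolve
#'   (for example chains capped by an adjacent unrelated allele) are then
#'   still scored as the same allele. Default 0: sizes compare exactly.
#' @return a `parentage_result`: `call` (`"FP"`, `"sexual"`, `"ambiguous"`),
#'   `mother`, `father`, `n_loci`, `n_homozygous_loci`, per-father
#'   exclusion counts and the per-locus flag table.
#' @export
classify_offspring <- function(offspring_id, panel, mothers, fathers,
                               min_exclusions = 1L, tolerance_bp = 0) {
  panel <- canonicalize_panel(panel)
  off <- panel_genotypes(panel, offspring_id)
  abort_if(nrow(off) < 1L, "no scored loci")
  n_loci <- nrow(off)
  near <- function(a, b) abs(a - b) <= tolerance_bp
  has <- function(size, g) near(size, g$allele1) | near(size, g$allele2)
  homo <- near(off$allele1, off$allele2)

  mat_info <- lapply(mothers, function(mid) {
    mom <- panel_genotypes(panel, mid)
    mom <- mom[match(off$locus, mom$locus), ]
    in_mom1 <- has(off$allele1, mom)
    in_mom2 <- has(off$allele2, mom)
    share <- in_mom1 | in_mom2
    contain <- in_mom1 & in_mom2
    list(id = mid, mom = mom, compatible = all(share), full = all(contain),
         share = share)
  })
  compat <- Filter(function(m) m$compatible, mat_info)
  if (length(compat) == 0L) {
    return(structure(list(call = "ambiguous", offspring = offspring_id,
                          mother = NA_character_, father = NA_character_,
                          n_loci = n_loci, n_homozygous_loci = sum(homo),
                          exclusions = NULL, loci = NULL,
                          note = "no maternal candidate consistent at all loci"),
                     class = "parentage_result"))
  }
  m <- compat[[1L]]  # best (first) compatible mother
  mom <- m$mom
  # non-maternal allele per locus: the offspring allele a sexual father
  # must have contributed (for homozygotes, the shared allele itself)
  nonmat <- ifelse(homo, off$allele1,
            ifelse(has(off$allele1, mom), off$allele2, off$allele1))
  fat_tab <- lapply(fathers, function(fid) {
    dad <- panel_genotypes(panel, fid)
    dad <- dad[match(off$locus, dad$locus), ]
    dad_has <- has(nonmat, dad)
    mom_has <- has(nonmat, mom)
    data.frame(father = fid, locus = off$locus, excludes = !dad_has,
               uninformative = dad_has & mom_has, stringsAsFactors = FALSE)
  })
  n_excl <- vapply(fat_tab, function(t) sum(t$excludes), numeric(1L))
  names(n_excl) <- fathers
  all_excluded <- length(fathers) == 0L || all(n_excl >= min_exclusions)
  unexcluded <- fathers[n_excl == 0L]

  call <- if (all(homo) && m$full && all_excluded) "FP"
    else if (!all(homo) && length(unexcluded) == 1L) "sexual"
    else "ambiguous"
  structure(list(call = call, offspring = offspring_id, mother = m$id,
                 father = if (call == "sexual") unexcluded else NA_character_,
                 n_loci = n_loci, n_homozygous_loci = sum(homo),
                 exclusions = n_excl,
                 loci = do.call(rbind, fat_tab), note = NULL),
            class = "parentage_result")
}

#' @export
print.parentage_result <- function(x, ...) {
  cat(sprintf("parentage_result for %s: %s (mother %s%s)\n  %d/%d loci homozygous; father exclusions: %s\n",
              x$offspring, x$call, x$mother,
              if (!is.na(x$father)) paste0(", father ", x$father) else "",
              x$n_homozygous_loci, x$n_loci,
              if (is.null(x$exclusions)) "-" else
                paste(names(x$exclusions), x$exclusions, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Summarise facultative-parthenogenesis incidence in colony records
#'
#' @param records a `colony_records` data frame (see [simulate_colony()])
#'   or any data frame with a `mode` column (`"gamete_duplication"`
#'   marking FP) and an `outcome` column.
#' @return list: `n_records`, `n_fp`, `percent`, and `outcomes` tallies
#'   within FP records.
#' @export
colony_incidence <- function(records) {
  abort_if(nrow(records) == 0L, "empty colony records")
  fp <- records$mode == "gamete_duplication"
  out <- list(n_records = nrow(records), n_fp = sum(fp),
              percent = 100 * sum(fp) / nrow(records),
              outcomes = table(records$outcome[fp]))
  class(out) <- "colony_incidence"
  out
}

#' @export
print.colony_incidence <- function(x, ...) {
  cat(sprintf("colony_incidence: %d FP of %d records (%.2f%%)\n",
              x$n_fp, x$n_records, x$percent))
  if (x$n_fp > 0) print(x$outcomes)
  invisible(x)
}
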