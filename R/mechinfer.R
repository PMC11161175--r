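#' Genome-wide heterozygosity retention of an offspring
#'
#' The fraction of maternal heterozygous calls still heterozygous in the
#' offspring, computed over positions that entered the scan in *both*
#' individuals (so caller sensitivity cancels): offspring heterozygous
#' calls divided by maternal heterozygous calls among jointly-considered
#' sites.
#'
#' @param offspring_calls,maternal_calls `het_calls` from the same genome.
#' @return retention fraction (can exceed 1 under sampling noise).
#' @export
retained_fraction <- function(offspring_calls, maternal_calls) {
  j <- joint_considered(offspring_calls, maternal_calls)
  abort_if(sum(j$m_het) == 0, "no maternal heterozygous calls among jointly considered sites")
  sum(j$o_het) / sum(j$m_het)
}

# Align two call sets on (chrom, pos) and keep sites considered in both.
joint_considered <- function(offspring_calls, maternal_calls) {
  o <- offspring_calls$sites
  m <- maternal_calls$sites
  key_o <- paste(o$chrom, o$pos)
  key_m <- paste(m$chrom, m$pos)
  i <- match(key_o, key_m)
  keep <- !is.na(i) & o$considered & m$considered[i]
  list(chrom = o$chrom[keep], pos = o$pos[keep],
       o_het = o$is_het[keep], m_het = m$is_het[i[keep]])
}

#' Heterozygosity retention by distance from the centromere
#'
#' Bins jointly-considered positions by normalized centromere distance
#' `d = |pos - centromere| / max arm length` and reports per-bin
#' retention as the ratio of offspring to maternal heterozygous-call
#' counts (the equal-split caller's sensitivity cancels in the ratio).
#' Central automixis retains heterozygosity preferentially near the
#' centromere (retention decreasing in `d`); terminal automixis near the
#' chromosome termini (increasing in `d`); gamete duplication retains
#' none anywhere.
#'
#' Alongside the binned profile, a site-level Spearman rank correlation
#' between `d` and the offspring heterozygous-call indicator is computed
#' over all offspring-considered sites, with its normal-approximation
#' p-value; this is the classifier's trend statistic, far more powerful
#' than a correlation over a handful of bins. It presumes the scanned
#' site set is enriched for maternally heterozygous positions (as when
#' pileups are generated at the maternal site list); for whole-genome
#' site sets, subset the pileup to maternal heterozygous calls first.
#'
#' @param offspring_calls,maternal_calls `het_calls` from the same genome.
#' @param genome_map a [genome_map()] with centromere positions.
#' @param n_bins number of equal-width distance bins on `[0, 1]`.
#' @return a `retention_profile`: data frame `bin_lo`, `bin_hi`, `bin_mid`,
#'   `n_sites`, `retention`, with attributes `retained_fraction`,
#'   `trend_rho`, `trend_p`, `bin_rho`.
#' @export
centromere_profile <- function(offspring_calls, maternal_calls, genome_map,
                               n_bins = 10L) {
  abort_if(is.null(genome_map) || !inherits(genome_map, "genome_map"),
           "centromere positions unknown: supply a genome_map (or rely on the interspersion test)")
  j <- joint_considered(offspring_calls, maternal_calls)
  cdist <- function(chrom, pos) {
    ci <- map_chrom(genome_map, chrom)
    cen <- genome_map$centromere[ci]
    arm_max <- pmax(cen, genome_map$length[ci] - cen)
    abs(pos - cen) / arm_max
  }
  d <- cdist(j$chrom, j$pos)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), n_bins)
  n_sites <- tabulate(bin, n_bins)
  m_het <- vapply(seq_len(n_bins), function(b) sum(j$m_het[bin == b]), numeric(1))
  o_het <- vapply(seq_len(n_bins), function(b) sum(j$o_het[bin == b]), numeric(1))
  ret <- ifelse(m_het > 0, o_het / m_het, NA_real_)
  prof <- data.frame(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L],
                     bin_mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                     n_sites = n_sites, m_het = m_het, o_het = o_het,
                     retention = ret)
  os <- offspring_calls$sites[offspring_calls$sites$considered, , drop = FALSE]
  tr <- site_trend(cdist(os$chrom, os$pos), as.numeric(os$is_het))
  ok <- !is.na(prof$retention)
  bin_rho <- if (sum(ok) >= 3 && stats::sd(prof$retention[ok]) > 0)
    stats::cor(prof$bin_mid[ok], prof$retention[ok], method = "spearman")
  else NA_real_
  structure(prof, class = c("retention_profile", "data.frame"),
            retained_fraction = if (sum(m_het) > 0) sum(o_het) / sum(m_het) else NA_real_,
            trend_rho = tr$rho, trend_p = tr$p, bin_rho = bin_rho)
}

# Spearman correlation of centromere distance vs retention indicator,
# with a large-sample normal p-value. Degenerate y (all retained / all
# lost) yields rho = NA: no spatial information.
site_trend <- function(d, y) {
  if (length(y) < 10L || stats::sd(y) == 0 || stats::sd(d) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(d, y, method = "spearman")
  z <- rho * sqrt(length(y) - 1)
  list(rho = rho, p = 2 * stats::pnorm(-abs(z)))
}

#' Window-level heterozygosity interspersion statistic
#'
#' Under automixis, blocks of retained heterozygosity should match the
#' mother's local heterozygosity. This statistic is the fraction of
#' windows -- among windows where the mother has at least one
#' heterozygous call -- in which the offspring count reaches at least
#' `ratio` (default 50%) of the mother's count.
#'
#' @param offspring_windows,maternal_windows `window_track` data frames on
#'   an identical window grid.
#' @param ratio offspring/mother count threshold per window.
#' @return fraction in `[0, 1]`.
#' @export
interspersion_statistic <- function(offspring_windows, maternal_windows,
                                    ratio = 0.5) {
  same <- nrow(offspring_windows) == nrow(maternal_windows) &&
    all(offspring_windows$chrom == maternal_windows$chrom) &&
    all(offspring_windows$start == maternal_windows$start) &&
    all(offspring_windows$end == maternal_windows$end)
  abort_if(!same, "window grids differ between offspring and mother")
  keep <- maternal_windows$count >= 1
  abort_if(!any(keep), "mother has no windows with heterozygous calls")
  mean(offspring_windows$count[keep] >= ratio * maternal_windows$count[keep])
}

#' Classify the diploidy-restoration mechanism
#'
#' Decision rule over the retention statistics (thresholds configurable):
#' \enumerate{
#'   \item genome-wide retention and interspersion both at or below
#'     `dup_max` (default 0.05): `post_meiotic_duplication`;
#'   \item a material centromere-distance trend (site-level `|rho| >=
#'     trend_rho_min` with `p <= trend_p_max`): `central_automixis` if
#'     retention falls with distance, `terminal_automixis` if it rises;
#'   \item retention and interspersion both at or above `sexual_min`
#'     (default 0.8), no material trend, and no significant retention
#'     deficit: `sexual`;
#'   \item otherwise, with a profile available: pericentromeric retention
#'     decides the automixis flavour -- `central_automixis` when
#'     retention in the proximal bins (distance `<= prox_max`) is at
#'     least `prox_central_min` (default 0.5), `terminal_automixis`
#'     below it. Fusion with a first-polar-body product preserves
#'     pericentromeric heterozygosity in (almost) every meiosis and
#'     sister-chromatid fusion (almost) never does, so this statistic is
#'     robust to crossover luck, unlike the distal profile, which both
#'     automixis flavours drive towards the same multi-crossover parity
#'     limit of 2/3;
#'   \item otherwise `indeterminate` -- never a guess.
#' }
#'
#' The trend is consulted before the sexual box because moderate-
#' recombination central automixis can retain more than 80% of maternal
#' heterozygosity genome-wide while still showing a pericentromeric
#' gradient incompatible with sexual reproduction. The retention-deficit
#' guard works the same way from the other side: for a sexual offspring
#' the retention ratio is 1 up to Poisson counting noise, so a deficit of
#' more than `deficit_z_min` standard errors (default 3) below 1 rules
#' sexual out even when the spatial trend happens to be flat. Without
#' centromere coordinates (`profile = NULL`) the rule reduces to the two
#' boxes plus `indeterminate`.
#'
#' @param retained genome-wide [retained_fraction()].
#' @param interspersion the [interspersion_statistic()].
#' @param profile optional [centromere_profile()] (carries the trend and
#'   the per-bin call counts).
#' @param thresholds named list overriding `sexual_min`, `dup_max`,
#'   `trend_rho_min`, `trend_p_max`, `prox_max`, `prox_central_min`,
#'   `deficit_z_min`.
#' @return a `mechanism_call`: `label` plus the statistics used.
#' @export
classify_mechanism <- function(retained, interspersion, profile = NULL,
                               thresholds = list()) {
  th <- utils::modifyList(list(sexual_min = 0.8, dup_max = 0.05,
                               trend_rho_min = 0.02, trend_p_max = 1e-3,
                               prox_max = 0.2, prox_central_min = 0.5,
                               deficit_z_min = 3),
                          thresholds)
  rho <- if (!is.null(profile)) attr(profile, "trend_rho") else NA_real_
  pval <- if (!is.null(profile)) attr(profile, "trend_p") else NA_real_
  material <- !is.na(rho) && !is.na(pval) &&
    abs(rho) >= th$trend_rho_min && pval <= th$trend_p_max
  bin_ret <- function(sel) {
    if (is.null(profile) || !any(sel) || sum(profile$m_het[sel]) == 0) return(NA_real_)
    sum(profile$o_het[sel]) / sum(profile$m_het[sel])
  }
  r_prox <- bin_ret(profile$bin_mid <= th$prox_max)
  deficit_z <- if (!is.null(profile) && sum(profile$o_het) > 0) {
    r <- sum(profile$o_het) / sum(profile$m_het)
    (r - 1) / (r * sqrt(1 / sum(profile$o_het) + 1 / sum(profile$m_het)))
  } else NA_real_
  sexual_ok <- retained >= th$sexual_min && interspersion >= th$sexual_min &&
    (is.na(deficit_z) || deficit_z > -th$deficit_z_min)
  label <-
    if (retained <= th$dup_max && interspersion <= th$dup_max)
      "post_meiotic_duplication"
    else if (material && rho < 0) "central_automixis"
    else if (material && rho > 0) "terminal_automixis"
    else if (sexual_ok) "sexual"
    else if (!is.na(r_prox)) {
      if (r_prox >= th$prox_central_min) "central_automixis"
      else "terminal_automixis"
    }
    else "indeterminate"
  structure(list(label = label, retained_fraction = retained,
                 interspersion = interspersion, trend_rho = rho,
                 trend_p = pval, proximal_retention = r_prox,
                 deficit_z = deficit_z, thresholds = th),
            class = "mechanism_call")
}

#' One-call mechanism inference from two call sets
#'
#' Convenience wrapper computing retention, interspersion (on the calls'
#' window tracks) and the centromere profile, then applying
#' [classify_mechanism()].
#'
#' @param mother_calls,offspring_calls `het_calls` with window tracks
#'   (pass `genome_map` to [call_het_sites()]).
#' @param genome_map the shared [genome_map()]; set `use_profile = FALSE`
#'   if centromere coordinates are not trustworthy.
#' @param n_bins bins for the retention profile.
#' @param use_profile consult the pericentromeric trend?
#' @param thresholds passed to [classify_mechanism()].
#' @return a `mechanism_call` with the `profile` attached.
#' @export
infer_mechanism <- function(mother_calls, offspring_calls, genome_map,
                            n_bins = 10L, use_profile = TRUE,
                            thresholds = list()) {
  ret <- retained_fraction(offspring_calls, mother_calls)
  isp <- interspersion_statistic(offspring_calls$windows, mother_calls$windows)
  prof <- if (use_profile)
    centromere_profile(offspring_calls, mother_calls, genome_map, n_bins)
  else NULL
  call <- classify_mechanism(ret, isp, prof, thresholds)
  call$profile <- prof
  call
}

#' Exact heterozygosity-retention oracle by tetrad enumeration
#'
#' Computes, by exhaustive enumeration with equal weights, the expected
#' probability that a maternally heterozygous site stays heterozygous in
#' an offspring, for a single chromosome arm with crossovers at fixed
#' positions. Enumerated choices: for each crossover, which chromatid of
#' each homolog is involved (4 combinations); which homolog pair becomes
#' the egg lineage at MI (2); which sister becomes the egg at MII (2);
#' and, for central automixis, which first-polar-body chromatid fuses
#' (2). Positions are fractions of the arm, centromere at 0.
#'
#' This is the independent reference the Monte-Carlo meiosis simulator is
#' validated against; it shares no code with [simulate_meiosis()].
#'
#' @param mode one of [REPRODUCTION_MODES].
#' @param crossover_positions crossover positions as fractions in `(0, 1)`
#'   (at most 3 for exact enumeration).
#' @param site_fractions site positions as fractions in `(0, 1)`.
#' @return numeric vector of expected retention per site.
#' @examples
#' retention_oracle("central_automixis", 0.3, c(0.1, 0.8))  # 1, 0.5
#' retention_oracle("terminal_automixis", 0.3, c(0.1, 0.8)) # 0, 1
#' @export
retention_oracle <- function(mode, crossover_positions, site_fractions) {
  mode <- match.arg(mode, REPRODUCTION_MODES)
  k <- length(crossover_positions)
  abort_if(k > 3L,
           "more than 3 crossovers: exact enumeration refused, use the Monte-Carlo simulator")
  if (mode == "gamete_duplication") return(rep(0, length(site_fractions)))
  if (mode == "sexual") return(rep(1, length(site_fractions)))
  xo <- sort(as.numeric(crossover_positions))
  ns <- length(site_fractions)
  pair_choices <- if (k > 0) as.matrix(expand.grid(rep(list(1:4), k))) else matrix(0L, 1L, 0L)
  pair_map <- rbind(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))
  total <- numeric(ns)
  n_cfg <- 0L
  for (r in seq_len(nrow(pair_choices))) {
    # origins matrix: 4 chromatids x sites, before segregation
    org <- matrix(c(1L, 1L, 2L, 2L), nrow = 4L, ncol = ns)
    for (j in seq_len(k)) {
      pq <- pair_map[pair_choices[r, j], ]
      distal <- site_fractions >= xo[j]
      tmp <- org[pq[1L], distal]
      org[pq[1L], distal] <- org[pq[2L], distal]
      org[pq[2L], distal] <- tmp
    }
    for (egg_pair in list(1:2, 3:4)) {
      pb1 <- setdiff(1:4, egg_pair)
      for (egg in egg_pair) {
        sister <- setdiff(egg_pair, egg)
        if (mode == "terminal_automixis") {
          total <- total + (org[egg, ] != org[sister, ])
          n_cfg <- n_cfg + 1L
        } else { # central
          for (partner in pb1) {
            total <- total + (org[egg, ] != org[partner, ])
            n_cfg <- n_cfg + 1L
          }
        }
      }
    }
  }
  total / n_cfg
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("mechanism_call: %s\n  retained fraction %.3f | interspersion %.3f | trend rho %s (p %s)\n",
              x$label, x$retained_fraction, x$interspersion,
              ifelse(is.na(x$trend_rho), "NA", sprintf("%.3f", x$trend_rho)),
              ifelse(is.na(x$trend_p), "NA", format(x$trend_p, digits = 3))))
  invisible(x)
}

#' @export
plot.retention_profile <- function(x, ...) {
  graphics::plot(x$bin_mid, x$retention, type = "b", ylim = c(0, 1),
                 xlab = "normalized distance from centromere",
                 ylab = "heterozygosity retention", ...)
  invisible(x)
}
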