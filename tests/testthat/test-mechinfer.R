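test_that("the retention oracle reproduces the closed-form limits", {
  expect_equal(retention_oracle("gamete_duplication", c(0.2, 0.5), c(0.1, 0.9)),
               c(0, 0))
  expect_equal(retention_oracle("sexual", 0.5, 0.9), 1)
  # no crossovers: central retains everything, terminal nothing
  expect_equal(retention_oracle("central_automixis", numeric(), c(0.2, 0.8)),
               c(1, 1))
  expect_equal(retention_oracle("terminal_automixis", numeric(), c(0.2, 0.8)),
               c(0, 0))
  # a single crossover between centromere and site: central 1/2, terminal 1
  expect_equal(retention_oracle("central_automixis", 0.3, 0.8), 0.5)
  expect_equal(retention_oracle("terminal_automixis", 0.3, 0.8), 1)
  # sites proximal to the crossover are untouched
  expect_equal(retention_oracle("central_automixis", 0.3, 0.1), 1)
  expect_equal(retention_oracle("terminal_automixis", 0.3, 0.1), 0)
  expect_error(retention_oracle("central_automixis", c(.1, .2, .3, .4), 0.5),
               "Monte-Carlo")
})

test_that("oracle retention is monotone in the single-crossover regime", {
  sites <- seq(0.05, 0.95, by = 0.1)
  # average over one uniform crossover position
  xs <- seq(0.025, 0.975, by = 0.05)
  central <- rowMeans(sapply(xs, function(x)
    retention_oracle("central_automixis", x, sites)))
  terminal <- rowMeans(sapply(xs, function(x)
    retention_oracle("terminal_automixis", x, sites)))
  expect_true(all(diff(central) <= 1e-12))
  expect_true(all(diff(terminal) >= -1e-12))
})

test_that("retained fraction and interspersion handle the degenerate cases", {
  pos <- 1:100 * 1000
  a <- fixture_calls(pos, considered = rep(TRUE, 100),
                     is_het = rep(c(TRUE, FALSE), 50))
  b <- fixture_calls(pos, considered = rep(TRUE, 100),
                     is_het = rep(FALSE, 100))
  expect_equal(retained_fraction(a, a), 1)
  expect_equal(retained_fraction(b, a), 0)
  expect_error(retained_fraction(a, b), "maternal")

  gm <- genome_map("c1", 1e5, 1)
  wa <- window_counts(a, gm, 1e4, 1e4)
  wb <- window_counts(b, gm, 1e4, 1e4)
  expect_equal(interspersion_statistic(wa, wa), 1)
  expect_equal(interspersion_statistic(wb, wa), 0)
  expect_error(interspersion_statistic(wa[-1, ], wa), "grids")
})

test_that("centromere profile needs a genome map and matches the mode geometry", {
  pos <- 1:100 * 1000
  a <- fixture_calls(pos, rep(TRUE, 100), rep(TRUE, 100))
  expect_error(centromere_profile(a, a, NULL), "genome_map")

  gm <- genome_map("c1", 101000, 1)
  # duplication-like offspring: zero retention in every populated bin
  b <- fixture_calls(pos, rep(TRUE, 100), rep(FALSE, 100))
  prof <- centromere_profile(b, a, gm, n_bins = 5)
  expect_true(all(prof$retention[prof$m_het > 0] == 0))
  expect_equal(attr(prof, "retained_fraction"), 0)
})

test_that("simulated retention profiles obey the automixis expectations", {
  gm <- genome_map("c1", 1e6, 1)
  mom <- simulate_maternal_genome(gm, 2e-3, seed = 20)
  n <- 300
  collect <- function(mode) {
    hets <- numeric(0); d <- numeric(0)
    for (i in 1:n) {
      tet <- simulate_meiosis(mom, 1, TRUE, seed = 1000 + i)
      off <- make_offspring(tet, mode, mom, seed = 2000 + i)
      hets <- c(hets, off$sites$is_het)
      d <- c(d, off$sites$pos / 1e6)
    }
    tapply(hets, cut(d, c(0, 0.5, 1)), mean)
  }
  central <- collect("central_automixis")
  terminal <- collect("terminal_automixis")
  expect_gt(central[1], central[2])    # retention falls with distance
  expect_lt(terminal[1], terminal[2])  # retention rises with distance
  expect_gt(central[1], 0.85)
  expect_lt(terminal[1], 0.3)
})

test_that("the decision rule maps statistics to the right labels", {
  # boxes without a profile
  expect_equal(classify_mechanism(0.0, 0.0)$label, "post_meiotic_duplication")
  expect_equal(classify_mechanism(0.97, 0.95)$label, "sexual")
  expect_equal(classify_mechanism(0.5, 0.5)$label, "indeterminate")

  prof_stub <- function(retention, trend_rho, trend_p, m = 100) {
    p <- data.frame(bin_lo = seq(0, 0.9, 0.1), bin_hi = seq(0.1, 1, 0.1),
                    bin_mid = seq(0.05, 0.95, 0.1), n_sites = m,
                    m_het = m, o_het = round(m * retention),
                    retention = retention)
    structure(p, class = c("retention_profile", "data.frame"),
              retained_fraction = mean(retention), trend_rho = trend_rho,
              trend_p = trend_p, bin_rho = sign(trend_rho))
  }
  # material negative trend beats the sexual box (high-retention central)
  prof <- prof_stub(seq(1, 0.7, length.out = 10), -0.05, 1e-6)
  expect_equal(classify_mechanism(0.85, 0.9, prof)$label, "central_automixis")
  # material positive trend
  prof2 <- prof_stub(seq(0.1, 0.9, length.out = 10), 0.12, 1e-8)
  expect_equal(classify_mechanism(0.5, 0.4, prof2)$label, "terminal_automixis")
  # mid-zone, no material trend: pericentromeric retention decides
  prof3 <- prof_stub(c(0.95, 0.9, rep(0.7, 8)), -0.01, 0.2)
  expect_equal(classify_mechanism(0.74, 0.7, prof3)$label, "central_automixis")
  prof4 <- prof_stub(c(0.1, 0.2, rep(0.6, 8)), 0.01, 0.3)
  expect_equal(classify_mechanism(0.5, 0.45, prof4)$label, "terminal_automixis")
  # flat profile at full retention with no deficit: sexual
  prof5 <- prof_stub(rep(1, 10), 0.001, 0.9)
  expect_equal(classify_mechanism(0.99, 0.97, prof5)$label, "sexual")
})

test_that("simulator and oracle agree for forced crossovers (all modes)", {
  mom <- fixture_mom()
  dad <- fixture_dad(mom)
  sitef <- mom$sites$pos / 1e6
  xo_frac <- c(0.25, 0.6)
  n <- 1500
  acc <- matrix(0, 4, length(sitef),
                dimnames = list(REPRODUCTION_MODES, NULL))
  set.seed(30)
  for (i in 1:n) {
    tet <- simulate_meiosis(mom, crossover_positions = list(c1 = xo_frac * 1e6))
    ptet <- simulate_meiosis(dad, crossover_positions = list(c1 = xo_frac * 1e6))
    for (m in REPRODUCTION_MODES) {
      off <- make_offspring(tet, m, mom,
                            paternal = if (m == "sexual") dad else NULL,
                            paternal_tetrad = if (m == "sexual") ptet else NULL)
      acc[m, ] <- acc[m, ] + off$sites$is_het
    }
  }
  for (m in REPRODUCTION_MODES) {
    p_exp <- retention_oracle(m, xo_frac, sitef)
    p_obs <- acc[m, ] / n
    sigma <- sqrt(pmax(p_exp * (1 - p_exp), 1e-12) / n)
    expect_true(all(abs(p_obs - p_exp) <= pmax(3 * sigma, 1e-9)),
                info = m)
  }
})
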