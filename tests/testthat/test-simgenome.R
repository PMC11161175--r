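test_that("genome_map validates its invariants", {
  expect_s3_class(genome_map("c1", 100, 50), "genome_map")
  expect_error(genome_map(c("a", "a"), c(10, 10), c(5, 5)), "unique")
  expect_error(genome_map("c1", 0, 1), "positive")
  expect_error(genome_map("c1", 100, 100), "centromere")
  expect_error(genome_map("c1", 100, 0), "centromere")
})

test_that("maternal genome simulation: empty case, determinism, Poisson counts", {
  gm <- genome_map("c1", 1e7, 5e6)
  expect_equal(nrow(simulate_maternal_genome(gm, 0, seed = 1)$sites), 0L)

  a <- simulate_maternal_genome(gm, 1e-4, seed = 42)
  b <- simulate_maternal_genome(gm, 1e-4, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_maternal_genome(gm, 1e-4, seed = 43)))

  # positions sorted, unique, in range; alleles distinct
  expect_true(all(diff(a$sites$pos) > 0))
  expect_true(all(a$sites$pos >= 0 & a$sites$pos < 1e7))
  expect_true(all(a$sites$is_het))

  # mean site count over 100 seeds within 5 sigma/sqrt(100) of 1000
  counts <- vapply(1:100, function(s)
    nrow(simulate_maternal_genome(gm, 1e-4, seed = s)$sites), numeric(1))
  expect_lt(abs(mean(counts) - 1000), 5 * sqrt(1000) / sqrt(100))
})

test_that("tetrads conserve homolog copies and honour the no-recombination limit", {
  mom <- fixture_mom()
  tet0 <- simulate_meiosis(mom, crossover_rate = 0, obligate_crossover = FALSE,
                           seed = 1)
  ch <- tet0$chromosomes[[1]]
  # every chromatid a full-length single-origin copy
  for (ct in ch$chromatids) expect_length(ct$origins, 1L)
  # egg and pb2 sister identical
  expect_identical(ch$chromatids[[ch$roles[["egg"]]]],
                   ch$chromatids[[ch$roles[["pb2_sister"]]]])

  # homolog conservation {A,A,B,B} at every probed position, random tetrads
  pos <- seq(0, 999999, length.out = 101)
  for (s in 1:25) {
    tet <- simulate_meiosis(mom, crossover_rate = 2, seed = s)
    org <- sapply(tet$chromosomes[[1]]$chromatids,
                  function(ct) automixia:::origin_at(ct, pos))
    expect_true(all(rowSums(org == 1L) == 2L))
  }
})

test_that("a single forced crossover makes exactly two recombinant chromatids", {
  mom <- fixture_mom()
  tet <- simulate_meiosis(mom, seed = 3,
                          crossover_positions = list(c1 = 5e5))
  segs <- vapply(tet$chromosomes[[1]]$chromatids,
                 function(ct) length(ct$origins), numeric(1))
  expect_equal(sort(segs), c(1, 1, 2, 2))
})

test_that("reproduction-mode limits hold exactly", {
  mom <- fixture_mom()
  dad <- fixture_dad(mom)
  # no recombination: terminal fully homozygous, central fully heterozygous
  for (s in 1:10) {
    tet <- simulate_meiosis(mom, 0, FALSE, seed = s)
    expect_true(all(make_offspring(tet, "gamete_duplication", mom,
                                   seed = s)$sites$is_het == FALSE))
    expect_true(all(make_offspring(tet, "terminal_automixis", mom,
                                   seed = s)$sites$is_het == FALSE))
    expect_true(all(make_offspring(tet, "central_automixis", mom,
                                   seed = s)$sites$is_het == TRUE))
    expect_true(all(make_offspring(tet, "sexual", mom, paternal = dad,
                                   seed = s)$sites$is_het == TRUE))
  }
  # duplication homozygous under any recombination
  tet <- simulate_meiosis(mom, 3, TRUE, seed = 11)
  expect_true(all(!make_offspring(tet, "gamete_duplication", mom)$sites$is_het))
})

test_that("parental-genome preconditions are enforced", {
  mom <- fixture_mom()
  dad <- fixture_dad(mom)
  tet <- simulate_meiosis(mom, 1, seed = 1)
  expect_error(make_offspring(tet, "sexual", mom), "paternal")
  expect_error(make_offspring(tet, "central_automixis", mom, paternal = dad),
               "non-sexual")
})

test_that("single-crossover retention matches the enumeration oracle", {
  # one crossover between centromere and a distal site
  mom <- fixture_mom(site_fracs = 0.9)
  n <- 3000
  ret <- matrix(NA, n, 2)
  set.seed(5)
  for (i in 1:n) {
    tet <- simulate_meiosis(mom, crossover_positions = list(c1 = 5e5))
    ret[i, 1] <- make_offspring(tet, "central_automixis", mom)$sites$is_het
    ret[i, 2] <- make_offspring(tet, "terminal_automixis", mom)$sites$is_het
  }
  sigma <- sqrt(0.25 / n)
  expect_lt(abs(mean(ret[, 1]) - 0.5), 3 * sigma)  # central: 1/2
  expect_equal(mean(ret[, 2]), 1)                  # terminal: always retained
})

test_that("pileup simulation: coverage mean, allele balance, error-free purity", {
  gm <- genome_map("c1", 1e7, 1)
  mom <- simulate_maternal_genome(gm, 1e-2, seed = 2)  # ~1e5 sites
  pu <- simulate_pileups(mom, mean_coverage = 20, error_rate = 0, seed = 3)
  expect_lt(abs(mean_coverage(pu) - 20) / 20, 0.01)
  counts <- as.matrix(pu[, c("A", "C", "G", "T")])
  # error-free: only the two genotype alleles receive reads
  i1 <- match(mom$sites$allele_a, c("A", "C", "G", "T"))
  i2 <- match(mom$sites$allele_b, c("A", "C", "G", "T"))
  on_genotype <- counts[cbind(seq_len(nrow(counts)), i1)] +
    counts[cbind(seq_len(nrow(counts)), i2)]
  expect_equal(unname(on_genotype), rowSums(counts))
  # equal-split probability at coverage 20: C(20,10)/2^20
  cov <- rowSums(counts)
  at20 <- cov == 20
  p <- mean(counts[cbind(seq_len(nrow(counts)), i1)][at20] == 10)
  p_exp <- choose(20, 10) / 2^20
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / sum(at20)))

  # homozygous sites concentrate on one base
  off <- make_offspring(simulate_meiosis(mom, 1, seed = 4),
                        "gamete_duplication", mom, seed = 4)
  pu0 <- simulate_pileups(off, 20, 0, seed = 5)
  expect_true(all(rowSums(as.matrix(pu0[, c("A", "C", "G", "T")]) > 0) <= 1))

  expect_error(simulate_pileups(mom, 0), "mean_coverage")
  expect_error(simulate_pileups(mom, 10, error_rate = 0.3), "error_rate")
})

test_that("microsatellite panels follow inheritance rules", {
  # FP offspring, no jitter: one distinct allele per locus
  sim <- simulate_ms_panel(c(kid = "gamete_duplication"), jitter_prob = 0,
                           seed = 6)
  kid <- sim$panel[sim$panel$individual == "kid", ]
  expect_true(all(kid$allele1 == kid$allele2))

  # sexual offspring of fully distinct heterozygous parents: two alleles
  sim2 <- simulate_ms_panel(c(kid = "sexual"), jitter_prob = 0,
                            p_het_parent = 1, disjoint_parents = TRUE, seed = 7)
  kid2 <- sim2$panel[sim2$panel$individual == "kid", ]
  expect_true(all(kid2$allele1 != kid2$allele2))

  # two FP sibs of a heterozygous mother differ at a locus with frequency ~1/2
  diff_frac <- vapply(1:300, function(s) {
    sim <- simulate_ms_panel(c(k1 = "gamete_duplication", k2 = "gamete_duplication"),
                             n_loci = 1L, p_het_parent = 1, seed = s)
    p <- sim$panel
    p$allele1[p$individual == "k1"] != p$allele1[p$individual == "k2"]
  }, logical(1))
  expect_lt(abs(mean(diff_frac) - 0.5), 3 * sqrt(0.25 / 300))
})

test_that("colony and cell-sample generators match their stated rates", {
  expect_equal(sum(simulate_colony(200, 0, seed = 1)$mode == "gamete_duplication"), 0L)

  n_fp <- vapply(1:500, function(s)
    sum(simulate_colony(832, 8 / 832, seed = s)$mode == "gamete_duplication"),
    numeric(1))
  expect_lt(abs(mean(n_fp) - 8), 3 * sqrt(8) / sqrt(500))

  cs <- simulate_cell_sample(943, 0.092, 0.0127, seed = 2)
  expect_equal(cs$n_diploid + cs$n_haploid + cs$n_binucleated, 943L)
  expect_lt(abs(cs$n_haploid - 87), 3 * sqrt(943 * 0.092 * 0.908))
  expect_error(simulate_cell_sample(100, 0.6, 0.5), "sum")
})
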