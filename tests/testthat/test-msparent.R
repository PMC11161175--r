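# Trio fixture following the worked colony case: mother heterozygous at
# 5/8 loci, two candidate males, both FP offspring homozygous for maternal
# alleles, one locus where mother and male 2 share the offspring allele.
trio_panel <- function() {
  loci <- sprintf("MS%02d", 1:8)
  rbind(
    data.frame(individual = "mom", locus = loci,
               allele1 = c(200, 210, 220, 230, 240, 250, 260, 270),
               allele2 = c(204, 214, 220, 234, 244, 250, 260, 274)),
    data.frame(individual = "male1", locus = loci,
               allele1 = c(180, 190, 198, 206, 214, 222, 230, 238),
               allele2 = c(182, 194, 198, 210, 218, 222, 234, 242)),
    data.frame(individual = "male2", locus = loci,
               allele1 = c(184, 188, 196, 204, 212, 220, 228, 270),
               allele2 = c(186, 192, 200, 208, 216, 224, 232, 270)),
    data.frame(individual = "kid1", locus = loci,
               allele1 = c(200, 210, 220, 230, 240, 250, 260, 270),
               allele2 = c(200, 210, 220, 230, 240, 250, 260, 270)),
    data.frame(individual = "kid2", locus = loci,
               allele1 = c(204, 214, 220, 234, 240, 250, 260, 270),
               allele2 = c(204, 214, 220, 234, 240, 250, 260, 270)))
}

test_that("allele binning merges within tolerance and caps chains", {
  p <- data.frame(individual = c("a", "b"), locus = "L1",
                  allele1 = c(200, 201), allele2 = c(200, 201))
  b <- bin_alleles(p)
  expect_length(unique(c(b$allele1, b$allele2)), 1L)

  p2 <- data.frame(individual = c("a", "b"), locus = "L1",
                   allele1 = c(200, 203), allele2 = c(200, 203))
  expect_length(unique(bin_alleles(p2)$allele1), 2L)

  # chained {200, 201, 202}: merged to one class, with a warning
  p3 <- data.frame(individual = c("a", "b", "c"), locus = "L1",
                   allele1 = c(200, 201, 202), allele2 = c(200, 201, 202))
  expect_warning(b3 <- bin_alleles(p3), "merged")
  expect_length(unique(b3$allele1), 1L)

  # wider chains are left alone
  p4 <- data.frame(individual = c("a", "b", "c", "d"), locus = "L1",
                   allele1 = c(200, 201, 202, 203), allele2 = c(200, 201, 202, 203))
  expect_warning(b4 <- bin_alleles(p4), "unmerged")
  expect_length(unique(b4$allele1), 4L)
})

test_that("the FP trio is called FP with one uninformative locus", {
  res <- classify_offspring("kid1", trio_panel(), "mom", c("male1", "male2"))
  expect_equal(res$call, "FP")
  expect_equal(res$mother, "mom")
  expect_equal(res$n_homozygous_loci, 8L)
  expect_equal(unname(res$exclusions), c(8, 7))  # male2 shares MS08 allele
  ms08 <- res$loci[res$loci$locus == "MS08", ]
  expect_equal(ms08$uninformative, c(FALSE, TRUE))

  res2 <- classify_offspring("kid2", trio_panel(), "mom", c("male1", "male2"))
  expect_equal(res2$call, "FP")
})

test_that("sexual and ambiguous offspring are distinguished", {
  p <- trio_panel()
  # heterozygous offspring: one maternal + one male1 allele per locus
  mom <- p[p$individual == "mom", ]
  dad <- p[p$individual == "male1", ]
  sex <- data.frame(individual = "kid3", locus = mom$locus,
                    allele1 = mom$allele1, allele2 = dad$allele1)
  res <- classify_offspring("kid3", rbind(p, sex), "mom", c("male1", "male2"))
  expect_equal(res$call, "sexual")
  expect_equal(res$father, "male1")

  # an allele absent from every candidate
  orphan <- data.frame(individual = "kid4", locus = mom$locus,
                       allele1 = mom$allele1, allele2 = 999)
  res2 <- classify_offspring("kid4", rbind(p, orphan), "mom", c("male1", "male2"))
  expect_equal(res2$call, "ambiguous")

  # FP is never called when a scored locus is heterozygous
  near_fp <- data.frame(individual = "kid5", locus = mom$locus,
                        allele1 = mom$allele1, allele2 = mom$allele1)
  near_fp$allele2[1] <- mom$allele2[1]  # one het locus
  res3 <- classify_offspring("kid5", rbind(p, near_fp), "mom", character())
  expect_false(res3$call == "FP")
})

test_that("simulated panels are classified perfectly without jitter", {
  hits <- vapply(1:100, function(s) {
    mode <- if (s %% 2 == 0) "gamete_duplication" else "sexual"
    sim <- simulate_ms_panel(stats::setNames(mode, "kid"), n_loci = 8,
                             jitter_prob = 0, p_het_parent = 1,
                             disjoint_parents = TRUE, seed = s)
    res <- classify_offspring("kid", sim$panel, "mother", "father")
    (res$call == "FP") == (mode == "gamete_duplication")
  }, logical(1))
  expect_true(all(hits))
})

test_that("colony incidence reproduces the reported rates", {
  rec <- data.frame(mode = rep(c("gamete_duplication", "sexual"), c(15, 271)),
                    outcome = "hatched_normal")
  ci <- colony_incidence(rec)
  expect_equal(ci$n_fp, 15L)
  expect_equal(round(ci$percent, 2), 5.24)
  expect_equal(round(ci$percent), 5)

  rec2 <- data.frame(mode = rep(c("gamete_duplication", "sexual"), c(8, 824)),
                     outcome = "hatched_normal")
  expect_equal(round(colony_incidence(rec2)$percent, 2), 0.96)

  rec3 <- data.frame(mode = rep("sexual", 10), outcome = "hatched_normal")
  expect_equal(colony_incidence(rec3)$percent, 0)
  expect_error(colony_incidence(rec3[0, ]), "empty")
})
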