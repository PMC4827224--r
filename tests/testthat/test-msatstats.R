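ms_of <- function(geno, labels, loci = paste0("L", seq_len(ncol(geno) / 2)))
  microsat_dataset(geno, labels, loci)

test_that("heterozygosities match hand arithmetic", {
  # 2 diploids both heterozygous a/b
  d <- ms_of(rbind(c(10L, 12L), c(10L, 12L)), c("P1", "P1"))
  pan <- msat_diversity_panel(d, g = 2L)
  expect_equal(pan$H_O, 1)
  expect_equal(pan$H_E, (4 / 3) * 0.5)
  # all homozygous aa
  d0 <- ms_of(rbind(c(10L, 10L), c(10L, 10L)), c("P1", "P1"))
  pan0 <- msat_diversity_panel(d0, g = 2L)
  expect_equal(pan0$H_O, 0)
  expect_equal(pan0$H_E, 0)
})

test_that("allelic richness matches hypergeometric and enumeration oracles", {
  # gene copies {a,a,b,c}, g = 2 -> 5/6 + 1/2 + 1/2
  ct <- c(a = 2L, b = 1L, c = 1L)
  expect_equal(allelic_richness(ct, 2L), 5 / 6 + 1 / 2 + 1 / 2)
  copies <- c("a", "a", "b", "c")
  expect_equal(allelic_richness(ct, 2L), bf_allelic_richness(copies, 2L),
               tolerance = 1e-10)
  expect_equal(allelic_richness(ct, 3L), bf_allelic_richness(copies, 3L),
               tolerance = 1e-10)
  # A_R at the full gene-copy count equals the allele count
  expect_equal(allelic_richness(ct, 4L), 3)
  expect_error(allelic_richness(ct, 5L), "exceeds")
})

test_that("F_IS spans heterozygote excess and deficit", {
  # all heterozygous -> f = -1
  d <- ms_of(rbind(c(10L, 12L), c(10L, 12L)), c("P1", "P1"))
  expect_equal(msat_diversity_panel(d, g = 2L)$F_IS, -1)
  # monomorphic-only data: F_IS undefined
  d0 <- ms_of(rbind(c(10L, 10L), c(10L, 10L)), c("P1", "P1"))
  expect_true(is.na(msat_diversity_panel(d0, g = 2L)$F_IS))
})

test_that("Weir-Cockerham theta matches brute force and its limits", {
  # identical genotype sets -> ~0 (small-sample bias shrinks with n)
  g <- rbind(c(10L, 12L), c(12L, 14L))[rep(1:2, 10L), ]
  d <- ms_of(rbind(g, g), rep(c("P1", "P2"), each = 20L))
  expect_lt(abs(wc_fst(d, "P1", "P2")), 0.05)
  # fixed different alleles -> 1
  g1 <- rbind(c(10L, 10L), c(10L, 10L), c(20L, 20L), c(20L, 20L))
  d1 <- ms_of(g1, c("P1", "P1", "P2", "P2"))
  expect_equal(wc_fst(d1, "P1", "P2"), 1)
  # toy table vs independent coding
  g2 <- rbind(c(10L, 12L), c(10L, 10L), c(12L, 14L),
              c(14L, 14L), c(12L, 12L), c(10L, 14L))
  d2 <- ms_of(g2, c("P1", "P1", "P1", "P2", "P2", "P2"))
  bf <- bf_wc_theta(list(g2[1:3, , drop = FALSE], g2[4:6, , drop = FALSE]))
  expect_equal(wc_fst(d2, "P1", "P2"), bf, tolerance = 1e-10)
  # monomorphic-only data is undefined
  expect_error(wc_fst(ms_of(rbind(c(10L, 10L), c(10L, 10L),
                                  c(10L, 10L), c(10L, 10L)),
                            c("P1", "P1", "P2", "P2")), "P1", "P2"),
               "polymorphic")
})

test_that("Nei's D_A distance hits its arithmetic cases", {
  # identical frequencies -> 0
  g <- rbind(c(10L, 12L), c(10L, 12L))
  d <- ms_of(g, c("P1", "P2"))
  expect_equal(da_distance(d, "P1", "P2"), 0)
  # disjoint fixed alleles -> 1
  g1 <- rbind(c(10L, 10L), c(20L, 20L))
  expect_equal(da_distance(ms_of(g1, c("P1", "P2")), "P1", "P2"), 1)
  # X = {0.5, 0.5}, Y = {1, 0} -> 1 - sqrt(0.5)
  g2 <- rbind(c(10L, 12L), c(10L, 10L))
  expect_equal(da_distance(ms_of(g2, c("P1", "P2")), "P1", "P2"),
               1 - sqrt(0.5), tolerance = 1e-12)
})

test_that("diversity panel handles missing data by complete-case rule", {
  g <- rbind(c(10L, 12L, NA, NA), c(10L, 10L, 20L, 22L),
             c(12L, 12L, 20L, 20L))
  d <- ms_of(g, rep("P1", 3L))
  pan <- msat_diversity_panel(d, g = 4L)
  expect_equal(pan$n, 3L)
  # locus 1: alleles {10, 12}; locus 2 (2 complete inds): {20, 22}
  expect_equal(pan$A, 2)
})

test_that("panel statistics are invariant to individual order", {
  set.seed(3)
  g <- matrix(sample(10:20, 48L, TRUE), 12L)
  labs <- rep(c("P1", "P2"), each = 6L)
  d <- ms_of(g, labs)
  perm <- sample(12L)
  dp <- ms_of(g[perm, ], labs[perm])
  p1 <- msat_diversity_panel(d, g = 6L)
  p2 <- msat_diversity_panel(dp, g = 6L)
  expect_equal(p1[order(p1$population), ], p2[order(p2$population), ],
               ignore_attr = TRUE)
  expect_equal(wc_fst(d, "P1", "P2"), wc_fst(dp, "P1", "P2"))
  expect_equal(da_distance(d, "P1", "P2"), da_distance(dp, "P1", "P2"))
})
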