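test_that("haplotype collapse handles sharing, privacy and N-columns", {
  one <- strrep("ACGT", 3L)
  ds <- sequence_dataset(rep(one, 4L), c("P1", "P1", "P2", "P2"))
  ht <- collapse_haplotypes(ds)
  expect_equal(nrow(ht$counts), 1L)
  expect_true(ht$shared[1L])

  ds2 <- sequence_dataset(c("AAAA", "AAAT", "AATT"), rep("P1", 3L))
  ht2 <- collapse_haplotypes(ds2)
  expect_equal(nrow(ht2$counts), 3L)
  expect_false(any(ht2$shared))

  # sequences differing only at an N-bearing column collapse together
  ds3 <- sequence_dataset(c("AANA", "AATA", "AACA"), rep("P1", 3L))
  ht3 <- collapse_haplotypes(ds3)
  expect_equal(nrow(ht3$counts), 1L)
  expect_error(collapse_haplotypes(
    sequence_dataset("NNNN", "P1")), "included")
})

test_that("haplotype diversity matches Nei's unbiased formula", {
  expect_equal(haplotype_diversity(rep(1L, 9L)), 1.0)
  expect_equal(haplotype_diversity(10L), 0)
  expect_equal(haplotype_diversity(c(2L, 2L)), (4 / 3) * 0.5)
  expect_error(haplotype_diversity(1L), "n >= 2")
})

test_that("theta-pi matches enumeration and equals theta-w at n = 2", {
  base <- strrep("A", 100L)
  s2 <- base; substr(s2, 1, 3) <- "GGG"
  ds <- sequence_dataset(c(base, s2), c("P1", "P1"))
  expect_equal(nucleotide_diversity_pi(ds), 0.03)
  expect_equal(watterson_theta(ds), 0.03)

  # {x, x, y} with d(x, y) = 2 over L = 10
  x <- "AAAAAAAAAA"; y <- "TTAAAAAAAA"
  ds2 <- sequence_dataset(c(x, x, y), rep("P1", 3L))
  expect_equal(nucleotide_diversity_pi(ds2), (0 + 2 + 2) / 3 / 10)
  expect_equal(nucleotide_diversity_pi(ds2), bf_pi(c(x, x, y)))

  ds3 <- sequence_dataset(rep(x, 3L), rep("P1", 3L))
  expect_equal(nucleotide_diversity_pi(ds3), 0)
})

test_that("Watterson's theta uses the harmonic-number correction", {
  base <- strrep("A", 100L)
  v <- vapply(1:3, function(i) { s <- base; substr(s, i, i) <- "G"; s }, "")
  ds <- sequence_dataset(c(base, v), rep("P1", 4L))
  expect_equal(watterson_theta(ds), 3 / (sum(1 / 1:3) * 100))
  ds0 <- sequence_dataset(rep(base, 4L), rep("P1", 4L))
  expect_equal(watterson_theta(ds0), 0)
})

test_that("Hudson's F_ST matches pair enumeration on the worked example", {
  pad <- strrep("C", 7L)
  seqs <- c(paste0("AAA", pad), paste0("AAT", pad),
            paste0("TTT", pad), paste0("TTA", pad))
  ds <- sequence_dataset(seqs, c("P1", "P1", "P2", "P2"))
  expect_equal(hudson_fst(ds, "P1", "P2"), 0.6)
  expect_equal(hudson_fst(ds, "P1", "P2"),
               bf_hudson_fst(seqs[1:2], seqs[3:4]))

  # identical pools -> near 0 (the estimator's small-sample bias is
  # negative, of order 1/n); fixed different haplotypes -> 1
  ds0 <- sequence_dataset(rep(c("AAAA", "AATT"), each = 10L, times = 2L),
                          rep(c("P1", "P2"), each = 20L))
  expect_lt(abs(hudson_fst(ds0, "P1", "P2")), 0.06)
  expect_lte(hudson_fst(ds0, "P1", "P2"), 0)
  ds1 <- sequence_dataset(c("AAAA", "AAAA", "AAAT", "AAAT"),
                          c("P1", "P1", "P2", "P2"))
  expect_equal(hudson_fst(ds1, "P1", "P2"), 1.0)
  expect_error(hudson_fst(sequence_dataset(rep("AAAA", 4L),
                                           c("P1", "P1", "P2", "P2")),
                          "P1", "P2"), "zero")
})

test_that("K2P distance matches its closed form and ape's implementation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # P = 0.1, Q = 0 over 10 sites: one transition A->G
  s1 <- "AAAAACCCCC"; s2 <- "GAAAACCCCC"
  expect_equal(k2p_distance(s1, s2), -0.5 * log(0.8), tolerance = 1e-12)
  # P = 0, Q = 0.05 over 20 sites: one transversion A->C
  t1 <- strrep("A", 20L); t2 <- paste0("C", strrep("A", 19L))
  expect_equal(k2p_distance(t1, t2),
               -0.5 * log(1 - 0.05) - 0.25 * log(1 - 0.10),
               tolerance = 1e-12)
  skip_if_not_installed("ape")
  set.seed(5)
  a <- sample(c("A", "C", "G", "T"), 200L, replace = TRUE)
  b <- a; idx <- sample(200L, 20L)
  b[idx] <- sample(c("A", "C", "G", "T"), 20L, replace = TRUE)
  bin <- ape::as.DNAbin(rbind(a, b))
  expect_equal(k2p_distance(paste(a, collapse = ""), paste(b, collapse = "")),
               as.numeric(ape::dist.dna(bin, model = "K80")),
               tolerance = 1e-10)
  expect_error(k2p_distance("AG", "GA"), "saturation")
})

test_that("mean group K2P averages over between-group pairs", {
  ds <- sequence_dataset(c("AAAA", "GAAA", "AAAA"), c("P1", "P1", "P2"))
  d12 <- k2p_distance("AAAA", "GAAA")
  expect_equal(mean_group_k2p(ds, "P1", "P2"), mean(c(0, d12)))
})

test_that("Pons-Petit G_ST/N_ST match a brute-force coding and its limits", {
  # two pops fixed for different haplotypes -> G_ST = 1
  counts <- matrix(c(4L, 0L, 0L, 5L), 2L,
                   dimnames = list(c("H1", "H2"), c("P1", "P2")))
  g <- gst_nst(list(counts = counts))
  expect_equal(g$G_ST, 1)

  # equal inter-haplotype distances -> N_ST = G_ST
  counts2 <- matrix(c(3L, 2L, 1L, 1L, 4L, 2L), 3L,
                    dimnames = list(paste0("H", 1:3), c("P1", "P2")))
  Deq <- 0.37 * (1 - diag(3))
  g2 <- gst_nst(list(counts = counts2), Deq)
  expect_equal(g2$N_ST, g2$G_ST, tolerance = 1e-12)

  # 3-pop toy with unequal distances vs independent brute force
  counts3 <- matrix(c(5L, 1L, 0L, 2L, 3L, 1L, 0L, 2L, 4L), 3L,
                    dimnames = list(paste0("H", 1:3), paste0("P", 1:3)))
  D <- matrix(c(0, .01, .05, .01, 0, .03, .05, .03, 0), 3L)
  g3 <- gst_nst(list(counts = counts3), D)
  bf <- bf_gst_nst(counts3, D)
  expect_equal(g3$G_ST, bf$G_ST, tolerance = 1e-10)
  expect_equal(g3$N_ST, bf$N_ST, tolerance = 1e-10)
})

test_that("Brito's correction is monotone with fixed points and the 0.651 value", {
  expect_equal(brito_correction(0), 0)
  expect_equal(brito_correction(1), 1)
  expect_equal(brito_correction(0.5), 0.2)
  expect_equal(round(brito_correction(0.651), 2), 0.32)
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(brito_correction(x)) > 0))
  expect_error(brito_correction(1.2), "0, 1")
})

test_that("divergence times follow the 2 percent clock", {
  expect_equal(divergence_time(0.013, 0.02), 0.65)
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.01, 0.02), 0.5)
  expect_error(divergence_time(-1), ">= 0")
  expect_error(divergence_time(0.1, 0), "> 0")
})

test_that("site statistics are invariant to sequence order", {
  set.seed(11)
  seqs <- replicate(8L, paste(sample(c("A", "C", "G", "T"), 30L, TRUE),
                              collapse = ""))
  labs <- rep(c("P1", "P2"), each = 4L)
  ds <- sequence_dataset(seqs, labs)
  perm <- sample(8L)
  dsp <- sequence_dataset(seqs[perm], labs[perm])
  expect_equal(nucleotide_diversity_pi(ds), nucleotide_diversity_pi(dsp))
  expect_equal(watterson_theta(ds), watterson_theta(dsp))
  expect_equal(hudson_fst(ds, "P1", "P2"), hudson_fst(dsp, "P1", "P2"))
})
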