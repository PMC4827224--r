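two_deme_design <- function(seq_length = 60L, n_loci = 2L) {
  d <- make_design(seq_length, n_loci)
  d$demes <- c("P1", "P2")
  d$n_mt <- c(P1 = 3L, P2 = 3L)
  d$n_msat <- c(P1 = 3L, P2 = 3L)
  d
}

test_that("summary vector has the documented length and order", {
  # 2 demes: (4 + 4) per-deme + (1 + 1) per-pair, per marker class = 20
  nm <- garrapop:::summary_vector_names(c("P1", "P2"))
  expect_length(nm, 20L)
  nm4 <- garrapop:::summary_vector_names(c("ZF", "PR", "NH", "SH"))
  expect_length(nm4, 4 * 4 + 6 * 2 + 4 * 4 + 6 * 2)
  expect_equal(nm[1:2], c("mt_nhap_P1", "mt_nhap_P2"))
})

test_that("summary vector is invariant to individual order within demes", {
  des <- two_deme_design()
  set.seed(12)
  seqs <- replicate(6L, paste(sample(c("A", "C", "G", "T"), 60L, TRUE),
                              collapse = ""))
  labs <- rep(c("P1", "P2"), each = 3L)
  geno <- matrix(sample(8:15, 24L, TRUE), 6L)
  ds <- sequence_dataset(seqs, labs)
  ms <- microsat_dataset(geno, labs, c("L1", "L2"))
  v1 <- summary_vector(ds, ms, des)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)     # permute within each deme
  v2 <- summary_vector(sequence_dataset(seqs[perm], labs[perm]),
                       microsat_dataset(geno[perm, ], labs[perm],
                                        c("L1", "L2")), des)
  expect_equal(v1, v2)
})

test_that("monomorphic data zeroes diversity channels and flags them", {
  des <- two_deme_design()
  seqs <- rep(strrep("A", 60L), 6L)
  labs <- rep(c("P1", "P2"), each = 3L)
  geno <- matrix(10L, 6L, 4L)
  v <- summary_vector(sequence_dataset(seqs, labs),
                      microsat_dataset(geno, labs, c("L1", "L2")), des)
  expect_equal(unname(v[c("mt_h_P1", "mt_pi_P1", "ms_He_P1")]), c(0, 0, 0))
  def <- attr(v, "defined")
  expect_false(def[["mt_fst_P1_P2"]])
  expect_false(def[["ms_fst_P1_P2"]])
  expect_true(all(is.finite(v)))
})

test_that("fast simulator path agrees with the public dataset path", {
  des <- make_design(seq_length = 150L)
  pre <- preset_scenarios(des)
  pri <- default_priors()
  set.seed(77)
  draw <- sample_parameters(pre$B, pri)
  sim <- simulate_dataset(pre$B, draw, des, seed = 3L)
  v_fast <- garrapop:::summary_vector_sim(sim)
  v_pub <- summary_vector(as_sequence_dataset(sim), as_microsat_dataset(sim),
                          des)
  expect_equal(v_fast, v_pub)
})

test_that("deme-pair channels match the standalone estimators", {
  des <- make_design(seq_length = 150L)
  pre <- preset_scenarios(des)
  pri <- default_priors()
  set.seed(78)
  draw <- sample_parameters(pre$C, pri)
  draw["mu_seq"] <- 5e-8                # ensure polymorphism
  sim <- simulate_dataset(pre$C, draw, des, seed = 4L)
  v <- garrapop:::summary_vector_sim(sim)
  ds <- as_sequence_dataset(sim)
  ms <- as_microsat_dataset(sim)
  if (attr(v, "defined")[["mt_fst_ZF_PR"]])
    expect_equal(unname(v[["mt_fst_ZF_PR"]]), hudson_fst(ds, "ZF", "PR"))
  if (attr(v, "defined")[["ms_fst_ZF_PR"]])
    expect_equal(unname(v[["ms_fst_ZF_PR"]]), wc_fst(ms, "ZF", "PR"))
  expect_equal(unname(v[["mt_pi_NH"]]),
               nucleotide_diversity_pi(ds, "NH"))
  expect_equal(unname(v[["mt_h_SH"]]), {
    ht <- collapse_haplotypes(ds)
    haplotype_diversity(ht$counts[, "SH"])
  })
})

test_that("marker-restricted vectors zero and flag the other block", {
  des <- two_deme_design()
  seqs <- sequence_dataset(rep(c("AAAA", "AATT", "TTTT"), 2L)[c(1, 2, 3, 1, 2, 3)],
                           rep(c("P1", "P2"), each = 3L))
  des$seq_length <- 4L
  v <- summary_vector(seqs, NULL, des)
  def <- attr(v, "defined")
  expect_true(all(!def[grep("^ms_", names(v))]))
  expect_true(any(def[grep("^mt_", names(v))]))
})
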