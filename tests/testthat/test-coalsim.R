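one_deme <- scenario("one", data.frame(name = "X", sampled = TRUE,
                                       size_param = "N_X"),
                     events = list(), time_order = character(0))

test_that("pairwise coalescence times match both ploidy conventions", {
  set.seed(101)
  reps <- 1500L
  t_mt <- replicate(reps, max(simulate_genealogy(
    one_deme, c(N_X = 4000), "mtDNA", c(X = 2L))$node_time))
  se <- 1000 / sqrt(reps)
  expect_lt(abs(mean(t_mt) - 1000), 3 * se)    # E[T2] = N/4

  t_nuc <- replicate(reps, max(simulate_genealogy(
    one_deme, c(N_X = 500), "nuclear", c(X = 2L))$node_time))
  expect_lt(abs(mean(t_nuc) - 1000), 3 * se)   # E[T2] = 2N
})

test_that("admixture with r = 1 behaves like a split into parent1", {
  demes <- data.frame(name = c("X", "P1", "P2"), sampled = TRUE,
                      size_param = c("N_X", "N_P1", "N_P2"))
  adm <- scenario("adm", demes, list(
    list(kind = "admix", time = "t1", source = "X",
         parent1 = "P1", parent2 = "P2", r = "r1"),
    list(kind = "split", time = "t2", source = "P2", dest = "P1")),
    time_order = c("t1", "t2"))
  spl <- scenario("spl", demes, list(
    list(kind = "split", time = "t1", source = "X", dest = "P1"),
    list(kind = "split", time = "t2", source = "P2", dest = "P1")),
    time_order = c("t1", "t2"))
  draw <- c(N_X = 1000, N_P1 = 1000, N_P2 = 1000,
            t1 = 200, t2 = 1e7, r1 = 1)
  n <- c(X = 2L, P1 = 0L, P2 = 0L)
  set.seed(7)
  ta <- replicate(2000L, max(simulate_genealogy(adm, draw, "mtDNA", n)$node_time))
  ts <- replicate(2000L, max(simulate_genealogy(spl, draw, "mtDNA", n)$node_time))
  ks <- suppressWarnings(stats::ks.test(ta, ts))
  expect_gt(ks$p.value, 0.01)
})

test_that("admixture sends lineages to parent1 with probability r", {
  demes <- data.frame(name = c("X", "P1", "P2"), sampled = TRUE,
                      size_param = c("N_X", "N_P1", "N_P2"))
  # P2 merges into P1 very late; with huge parent sizes, the first
  # coalescence essentially always happens after the admixture, so the
  # proportion of deep (post-merge) coalescences tracks lineage routing.
  adm <- scenario("adm", demes, list(
    list(kind = "admix", time = "t1", source = "X",
         parent1 = "P1", parent2 = "P2", r = "r1"),
    list(kind = "split", time = "t2", source = "P2", dest = "P1")),
    time_order = c("t1", "t2"))
  r <- 0.3
  # N_X huge: no coalescence before the admixture at t1.  Parent demes
  # small and the final merge far away: same-parent pairs virtually
  # always coalesce before t2, different-parent pairs never do.
  draw <- c(N_X = 1e8, N_P1 = 1e4, N_P2 = 1e4, t1 = 10, t2 = 1e7, r1 = r)
  set.seed(8)
  reps <- 3000L
  same_parent <- replicate(reps, {
    g <- simulate_genealogy(adm, draw, "mtDNA", c(X = 2L, P1 = 0L, P2 = 0L))
    max(g$node_time) < 1e7      # both lineages routed to the same parent
  })
  p_exp <- r^2 + (1 - r)^2
  expect_lt(abs(mean(same_parent) - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / reps))
})

test_that("sequence evolution: zero rate, stationarity and JC pattern", {
  set.seed(21)
  g <- simulate_genealogy(one_deme, c(N_X = 2000), "mtDNA",
                          c(X = 6L))
  m0 <- seq_mutation_model(mu = 0, length = 50L)
  st <- evolve_sequences(g, m0)
  expect_true(all(st == rep(st[1L, ], each = nrow(st))))

  # kappa = 1 + uniform frequencies = Jukes-Cantor: P(no change) over a
  # branch of d expected substitutions is 1/4 + 3/4 exp(-4d/3)
  two <- scenario("two", data.frame(name = c("X", "Y"), sampled = TRUE,
                                    size_param = c("N_X", "N_Y")),
                  list(list(kind = "split", time = "t1", source = "X",
                            dest = "Y")), "t1")
  # essentially star genealogy: two tips joined at t1
  draw <- c(N_X = 1e9, N_Y = 1e-4, t1 = 1000)
  mu <- 1e-4; L <- 20000L
  mJC <- seq_mutation_model(kappa = 1, base_freq = rep(0.25, 4),
                            mu = mu, length = L)
  set.seed(22)
  gg <- simulate_genealogy(two, draw, "mtDNA", c(X = 1L, Y = 1L))
  st2 <- evolve_sequences(gg, mJC)
  d <- 2 * mu * 1000                       # both branches mutate
  p_same_exp <- 1 / 4 + 3 / 4 * exp(-4 * d / 3)
  p_same_obs <- mean(st2[1L, ] == st2[2L, ])
  se <- sqrt(p_same_exp * (1 - p_same_exp) / L)
  expect_lt(abs(p_same_obs - p_same_exp), 3 * se)

  # long branches: tip composition approaches the stationary frequencies
  pi0 <- c(0.4, 0.3, 0.2, 0.1)
  mSt <- seq_mutation_model(kappa = 5, base_freq = pi0, mu = 1e-2,
                            length = 20000L)
  set.seed(23)
  g3 <- simulate_genealogy(two, c(N_X = 1e9, N_Y = 1e-4, t1 = 5000),
                           "mtDNA", c(X = 1L, Y = 1L))
  st3 <- evolve_sequences(g3, mSt)
  freq <- tabulate(st3[1L, ] + 1L, 4L) / ncol(st3)
  for (b in 1:4)
    expect_lt(abs(freq[b] - pi0[b]), 3 * sqrt(pi0[b] * (1 - pi0[b]) / 20000))
})

test_that("microsatellite mutation: zero rate and step parity", {
  set.seed(31)
  g <- simulate_genealogy(one_deme, c(N_X = 2000), "nuclear", c(X = 8L))
  m0 <- msat_mutation_model(mu = 0)
  expect_true(all(evolve_microsats(g, m0) == 100L))

  # p_geom = 0: allele - root parity equals mutation-count parity; with
  # a tiny per-branch rate every step is +/-1, so offsets stay small and
  # integer-valued on the +/-1 lattice
  m1 <- msat_mutation_model(mu = 5e-4, p_geom = 0)
  al <- evolve_microsats(g, m1)
  expect_true(all(al >= 2L & al <= 200L))
  expect_true(all(al == round(al)))
})

test_that("segregating sites match Watterson's expectation", {
  # theta = 4 * (N/4) * mu per site for mtDNA; E[S] = theta * a_n * L
  N <- 10000; mu <- 1e-6; L <- 2000L; n <- 10L
  theta <- (N / 4) * 2 * mu              # 2 * G * mu, G = N/4 haploid copies
  a_n <- sum(1 / seq_len(n - 1))
  mod <- seq_mutation_model(mu = mu, length = L)
  set.seed(41)
  S <- replicate(400L, {
    g <- simulate_genealogy(one_deme, c(N_X = N), "mtDNA",
                            setNames(n, "X"))
    st <- evolve_sequences(g, mod)
    sum(vapply(seq_len(L), function(s) length(unique(st[, s])) > 1L, TRUE))
  })
  ES <- theta * a_n * L
  expect_lt(abs(mean(S) - ES), 3 * sd(S) / sqrt(length(S)))
})

test_that("full dataset simulation is reproducible and design-sized", {
  des <- make_design(seq_length = 120L)
  pre <- preset_scenarios(des)
  pri <- default_priors()
  set.seed(55)
  draw <- sample_parameters(pre$C, pri)
  s1 <- simulate_dataset(pre$C, draw, des, seed = 9L)
  s2 <- simulate_dataset(pre$C, draw, des, seed = 9L)
  expect_identical(s1$seq_states, s2$seq_states)
  expect_identical(s1$msat, s2$msat)

  expect_equal(nrow(s1$seq_states), 157L)
  expect_equal(nrow(s1$msat), 156L)
  expect_equal(ncol(s1$msat), 2L * 13L)
  expect_false(anyNA(s1$msat))             # simulator never produces missing

  # deep simultaneous divergence drives mtDNA F_ST toward 1
  drawA <- c(N_ZF = 200, N_PR = 200, N_NH = 200, N_SH = 200, N_A = 200,
             t1 = 5e6, mu_seq = 5e-7, kappa = 4, mu_msat = 5e-4, p_geom = 0)
  simA <- simulate_dataset(pre$A, drawA, des, seed = 10L)
  v <- garrapop:::summary_vector_sim(simA)
  fst <- v[grep("^mt_fst_", names(v))]
  expect_true(all(fst > 0.8))
})

test_that("(delta mu)^2 between split demes grows as 2 mu T", {
  demes <- data.frame(name = c("X", "Y"), sampled = TRUE,
                      size_param = c("N_X", "N_Y"))
  spl <- scenario("split2", demes, list(
    list(kind = "split", time = "t1", source = "X", dest = "Y")), "t1")
  mu <- 5e-4; Tsplit <- 30000
  # small N keeps within-deme coalescent variance low relative to 2 mu T
  draw <- c(N_X = 200, N_Y = 200, t1 = Tsplit)
  mod <- msat_mutation_model(mu = mu, p_geom = 0)
  set.seed(61)
  reps <- 40L; n_loci <- 40L
  dmu2 <- replicate(reps, {
    mean(replicate(n_loci, {
      g <- simulate_genealogy(spl, draw, "nuclear", c(X = 10L, Y = 10L))
      al <- evolve_microsats(g, mod)
      deme <- g$tip_deme
      (mean(al[deme == "X"]) - mean(al[deme == "Y"]))^2
    }))
  })
  expected <- 2 * mu * Tsplit
  se <- sd(dmu2) / sqrt(reps)
  expect_lt(abs(mean(dmu2) - expected), 3 * se)
})
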