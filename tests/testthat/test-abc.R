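# A small hand-made reference table for the rejection/regression tests:
# reuses the ReferenceTable structure with synthetic statistic rows.
fake_table <- function(stats, scenario, params = NULL) {
  n <- nrow(stats)
  if (is.null(params))
    params <- data.frame(theta = rep(NA_real_, n))
  structure(list(scenario = scenario, params = params, stats = stats,
                 defined = matrix(TRUE, n, ncol(stats)),
                 scenario_names = sort(unique(scenario)),
                 scenario_hash = "x", priors_hash = "y",
                 seed = 0L, n_sim = n),
            class = "ReferenceTable")
}

obs_of <- function(x) {
  v <- x
  attr(v, "defined") <- rep(TRUE, length(v))
  v
}

test_that("rejection retains the closest simulations with MAD scaling", {
  set.seed(1)
  stats <- matrix(rnorm(200L * 3L), 200L,
                  dimnames = list(NULL, c("s1", "s2", "s3")))
  tab <- fake_table(stats, sample(c("A", "B"), 200L, TRUE))
  obs <- obs_of(setNames(stats[17L, ], colnames(stats)))
  rej <- rejection_sample(tab, obs, tolerance = 0.05)
  expect_equal(rej$index[1L], 17L)            # exact match ranks first
  expect_equal(length(rej$index), 10L)
  rej_all <- rejection_sample(tab, obs, tolerance = 1)
  expect_equal(length(rej_all$index), 200L)

  # hand-computable 5-row table: distances sort as brute force
  s5 <- matrix(c(0, 1, 2, 3, 10,
                 0, 1, 2, 3, 10), 5L,
               dimnames = list(NULL, c("a", "b")))
  tab5 <- fake_table(s5, c("A", "A", "B", "B", "B"))
  obs5 <- obs_of(c(a = 0, b = 0))
  r5 <- rejection_sample(tab5, obs5, tolerance = 0.6)
  mads <- apply(s5, 2, mad)
  d_bf <- sqrt(rowSums(sweep(s5, 2, mads, "/")^2))
  expect_equal(r5$index, order(d_bf)[1:3])

  # affine rescaling of a channel leaves the retained set unchanged
  s5b <- s5; s5b[, "b"] <- 100 + 7 * s5b[, "b"]
  obs5b <- obs_of(c(a = 0, b = 100))
  r5b <- rejection_sample(fake_table(s5b, c("A", "A", "B", "B", "B")),
                          obs5b, tolerance = 0.6)
  expect_equal(r5b$index, r5$index)

  # constant channels are dropped; all-constant errors
  s_const <- cbind(s5, k = rep(1, 5))
  r_const <- rejection_sample(fake_table(s_const, c("A","A","B","B","B")),
                              obs_of(c(a = 0, b = 0, k = 1)), 0.61)
  expect_false("k" %in% r_const$channels)
  expect_error(rejection_sample(fake_table(matrix(1, 5, 1,
                                                  dimnames = list(NULL, "k")),
                                           rep("A", 5)),
                                obs_of(c(k = 1)), 0.5),
               "degenerate")
})

test_that("direct model choice counts retained scenarios", {
  ret <- list(scenario = c("s1", "s1", "s2", "s3"))
  mc <- model_choice_direct(ret)
  expect_equal(mc$estimate, c(0.5, 0.25, 0.25))
  expect_equal(sum(mc$estimate), 1)
  expect_true(all(mc$lower <= mc$estimate & mc$estimate <= mc$upper))
  ret1 <- list(scenario = rep("s2", 8L))
  expect_equal(model_choice_direct(ret1)$estimate, 1)
})

test_that("logistic model choice: no signal, full signal, and sum-to-one", {
  set.seed(5)
  n <- 300L
  # no signal: statistics independent of scenario
  stats <- matrix(rnorm(n * 2L), n, dimnames = list(NULL, c("s1", "s2")))
  tab <- fake_table(stats, rep(c("A", "B"), each = n / 2L))
  obs <- obs_of(c(s1 = 0, s2 = 0))
  rej <- rejection_sample(tab, obs, tolerance = 0.5)
  mc <- model_choice_logistic(rej)
  expect_equal(sum(mc$estimate), 1, tolerance = 1e-6)
  expect_true(all(mc$lower <= mc$estimate + 1e-12 &
                  mc$estimate <= mc$upper + 1e-12))
  for (k in seq_len(nrow(mc)))
    expect_true(mc$lower[k] <= 0.5 && 0.5 <= mc$upper[k] + 0.1)

  # perfectly separating statistic
  sep <- matrix(c(rnorm(n / 2, -4), rnorm(n / 2, 4)), ncol = 1L,
                dimnames = list(NULL, "s1"))
  tab2 <- fake_table(sep, rep(c("A", "B"), each = n / 2L))
  obs2 <- obs_of(c(s1 = 4))
  rej2 <- rejection_sample(tab2, obs2, tolerance = 1)
  mc2 <- suppressWarnings(model_choice_logistic(rej2))
  expect_gte(mc2$estimate[mc2$scenario == "B"], 0.99)
  expect_equal(sum(mc2$estimate), 1, tolerance = 1e-6)
})

test_that("logistic falls back to direct with too few rows", {
  set.seed(6)
  stats <- matrix(rnorm(40L), 20L, dimnames = list(NULL, c("s1", "s2")))
  tab <- fake_table(stats, rep(c("A", "B", "C", "D"), each = 5L))
  rej <- rejection_sample(tab, obs_of(c(s1 = 0, s2 = 0)), tolerance = 0.5)
  expect_warning(mc <- model_choice_logistic(rej), "falling back")
  expect_true(attr(mc, "fallback"))
  expect_equal(sum(mc$estimate), 1, tolerance = 1e-6)
})

test_that("local-linear adjustment collapses noise-free linear relations", {
  set.seed(9)
  n <- 400L
  theta <- runif(n, 10, 1000)
  # one statistic encodes the parameter exactly
  stats <- matrix(theta, ncol = 1L, dimnames = list(NULL, "s1"))
  priors <- data.frame(param = "theta", dist = "uniform",
                       lo = 10, hi = 1000)
  class(priors) <- c("PriorSpec", "data.frame")
  tab <- fake_table(stats, rep("C", n), params = data.frame(theta = theta))
  true_theta <- 444
  obs <- obs_of(c(s1 = true_theta))
  rej <- rejection_sample(tab, obs, tolerance = 0.5)
  est <- estimate_parameters_loclinear(rej, priors)
  unadj_var <- var(rej$params$theta)
  # adjusted draws concentrate on the true value
  expect_lt(abs(est$median - true_theta), 10)
  adj_spread <- (est$q975 - est$q025)^2 / 16   # rough variance proxy
  expect_lt(adj_spread * 100, unadj_var)

  # zero-slope statistics leave draws unadjusted
  stats0 <- matrix(rnorm(n), ncol = 1L, dimnames = list(NULL, "s1"))
  tab0 <- fake_table(stats0, rep("C", n), params = data.frame(theta = theta))
  rej0 <- rejection_sample(tab0, obs_of(c(s1 = 0)), tolerance = 1)
  est0 <- estimate_parameters_loclinear(rej0, priors)
  expect_lt(abs(est0$mean - mean(theta)), 80)

  # adjusted draws always respect the prior support
  expect_gte(est$q025, 10); expect_lte(est$q975, 1000)
})

test_that("identical scenarios yield indistinguishable posteriors", {
  # two copies of the same generating process: posterior ~ 0.5/0.5
  set.seed(13)
  n <- 600L
  stats <- matrix(rnorm(n * 3L), n,
                  dimnames = list(NULL, c("s1", "s2", "s3")))
  tab <- fake_table(stats, rep(c("A", "A2"), n / 2L))
  obs <- obs_of(c(s1 = 0.1, s2 = -0.2, s3 = 0))
  rej <- rejection_sample(tab, obs, tolerance = 0.5)
  mc <- model_choice_logistic(rej)
  expect_true(all(abs(mc$estimate - 0.5) < 0.15))
})
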