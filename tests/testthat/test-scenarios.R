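test_that("scenario validation catches structural defects", {
  d2 <- data.frame(name = c("X", "Y"), sampled = TRUE,
                   size_param = c("N_X", "N_Y"))
  ok <- scenario("ok", d2, list(
    list(kind = "split", time = "t1", source = "X", dest = "Y")),
    time_order = "t1")
  expect_true(validate_scenario(ok))

  # admixture referencing a deme already merged away
  d3 <- data.frame(name = c("X", "Y", "Z"), sampled = TRUE,
                   size_param = c("N_X", "N_Y", "N_Z"))
  bad <- scenario("bad", d3, list(
    list(kind = "split", time = "t1", source = "X", dest = "Y"),
    list(kind = "admix", time = "t2", source = "Z",
         parent1 = "X", parent2 = "Y", r = "r1")),
    time_order = c("t1", "t2"))
  expect_error(validate_scenario(bad), "live-interval")

  # two roots
  noroot <- scenario("noroot", d3, list(
    list(kind = "split", time = "t1", source = "X", dest = "Y")),
    time_order = "t1")
  expect_error(validate_scenario(noroot), "single root")

  # cyclic time order
  cyc <- scenario("cyc", d2, list(
    list(kind = "split", time = "t1", source = "X", dest = "Y")),
    time_order = c("t1", "t2", "t1"))
  expect_error(validate_scenario(cyc), "constraint")
})

test_that("presets A-E have the documented structure and validate", {
  pre <- preset_scenarios()
  expect_named(pre, c("A", "B", "C", "D", "E"))
  # A: one time parameter, five size parameters
  pa <- garrapop:::scenario_params(pre$A)
  expect_equal(sum(grepl("^t", pa)), 1L)
  expect_equal(sum(grepl("^N", pa)), 5L)
  # C: exactly one unsampled deme (the pre-admixture coastal lineage)
  # and one admixture parameter
  expect_equal(sum(!pre$C$demes$sampled), 1L)
  expect_equal(pre$C$demes$name[!pre$C$demes$sampled], "C0")
  pc <- garrapop:::scenario_params(pre$C)
  expect_equal(sum(grepl("^r", pc)), 1L)
  # all presets validate under default priors
  pri <- default_priors()
  for (s in pre) expect_true(validate_scenario(s, pri))
  # D and E are flagged as topology assumptions
  expect_true(pre$D$assumption)
  expect_true(pre$E$assumption)
  expect_false(pre$C$assumption)
})

test_that("parameter draws respect priors, constraints and seeds", {
  pre <- preset_scenarios()
  pri <- default_priors()
  set.seed(1)
  draws <- t(replicate(2000L, sample_parameters(pre$C, pri)))
  expect_true(all(draws[, "t1"] < draws[, "t2"] &
                  draws[, "t2"] < draws[, "t3"] &
                  draws[, "t3"] < draws[, "t4"]))
  expect_true(all(draws[, "r1"] > 0.05 & draws[, "r1"] < 0.95))

  # uniform mean check: N from loguniform, t1 unconstrained scenario A
  set.seed(2)
  dA <- t(replicate(10000L, sample_parameters(pre$A, pri)))
  se <- (1e5 - 10) / sqrt(12) / sqrt(nrow(dA))
  expect_lt(abs(mean(dA[, "t1"]) - (1e5 + 10) / 2), 3 * se)

  set.seed(99); a <- sample_parameters(pre$B, pri)
  set.seed(99); b <- sample_parameters(pre$B, pri)
  expect_identical(a, b)

  # unsatisfiable constraints error out
  tight <- pri
  tight[tight$param == "t1", c("lo", "hi")] <- c(9e4, 1e5)
  tight[tight$param == "t2", c("lo", "hi")] <- c(10, 11)
  expect_error(sample_parameters(pre$B, tight, max_tries = 200L),
               "prior-inconsistency")
})

test_that("scenario serialization round-trips", {
  pre <- preset_scenarios()
  pri <- default_priors()
  for (nm in names(pre)) {
    txt <- write_scenario(pre[[nm]], pri)
    back <- read_scenario(txt)
    expect_equal(back$scenario$name, pre[[nm]]$name)
    expect_equal(back$scenario$demes, pre[[nm]]$demes,
                 ignore_attr = TRUE)
    expect_equal(back$scenario$events, pre[[nm]]$events)
    expect_equal(back$scenario$time_order, pre[[nm]]$time_order)
    expect_equal(back$scenario$assumption, pre[[nm]]$assumption)
    expect_equal(back$priors$param, pri$param)
    expect_equal(back$priors$lo, pri$lo)
  }
})
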