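test_that("covariate effects resolve to their documented factors", {
  m <- pk_model(
    "x", 1, list(CL = 2, V = 10),
    covariate_effects = list(
      covariate_effect("CL", "birth_weight", "allometric_power",
                       reference = 1.5, exponent = 0.75),
      covariate_effect("CL", "PMA", "sigmoid_maturation", pma50 = 40, gamma = 3),
      covariate_effect("V", "birth_weight", "allometric_power",
                       reference = 1.5, exponent = 1)
    )
  )
  # covariate at its reference, maturation at half-point
  p <- individual_parameters(list(birth_weight = 1.5, GA = 40), m)
  expect_equal(p$CL, 2 * 0.5)       # allometric term 1, maturation exactly 0.5
  expect_equal(p$V, 10)

  # doubling weight with exponent 1 doubles V
  p2 <- individual_parameters(list(birth_weight = 3.0, GA = 40), m)
  expect_equal(p2$V, 20)
  expect_equal(p2$CL / p$CL, 2^0.75)

  # eta acts multiplicatively on the log scale
  p3 <- individual_parameters(list(birth_weight = 1.5, GA = 40), m,
                              eta = c(CL = log(2)))
  expect_equal(p3$CL, 2 * p$CL)

  # missing covariate is named in the error
  expect_error(individual_parameters(list(GA = 40), m), "birth_weight")
})

test_that("maturation factor is monotone increasing in PMA and bounded in (0,1)", {
  m <- pk_model("x", 1, list(CL = 1, V = 1),
                covariate_effects = list(
                  covariate_effect("CL", "PMA", "sigmoid_maturation",
                                   pma50 = 47.7, gamma = 3.4)))
  pma <- seq(22, 60, by = 0.5)
  cl <- vapply(pma, function(w) {
    individual_parameters(list(birth_weight = 1, GA = w), m)$CL
  }, numeric(1))
  expect_true(all(diff(cl) > 0))
  expect_true(all(cl > 0 & cl < 1))
})

test_that("model construction rejects invalid specifications", {
  expect_error(pk_model("x", 3, list(CL = 1, V = 1)), "1 or 2")
  expect_error(pk_model("x", 2, list(CL = 1, V = 1)), "Q")
  expect_error(pk_model("x", 1, list(CL = 1, V = 1), omega = list(CL = -0.1)),
               ">= 0")
  expect_error(
    pk_model("x", 1, list(CL = 1, V = 1),
             covariate_effects = list(
               covariate_effect("Q", "birth_weight", "allometric_power",
                                reference = 1, exponent = 1))),
    "undeclared")
  expect_error(covariate_effect("CL", "PMA", "sigmoid_maturation",
                                pma50 = -1, gamma = 2), "pma50")
  expect_error(residual_error_spec(-0.1, 0))
})

test_that("analytic infusion solution matches closed forms", {
  # near-bolus: C(t) ~ (D/V) exp(-ke t)
  p <- ip1(CL = 0.2, V = 1)
  sch <- dose_schedule(0, 50, 0.001)
  prof <- simulate_profile(p, sch, times = c(0.001, 5, 10, 20))
  expect_equal(prof$total_conc[3], 50 * exp(-0.2 * 10), tolerance = 1e-3)
  expect_equal(prof$total_conc[2], 50 * exp(-0.2 * 5), tolerance = 1e-3)

  # steady-state constant infusion: C_ss = R0 / CL
  p2 <- ip1(CL = 2, V = 5)
  sch2 <- dose_schedule(0, 10 * 400, 400)          # R0 = 10 mg/h
  prof2 <- simulate_profile(p2, sch2, times = c(300, 399))
  expect_equal(prof2$total_conc, c(5, 5), tolerance = 1e-6)

  # dose linearity to machine precision
  inst <- withr::with_seed(99, random_instance())
  t <- time_grid(inst$schedule)
  base <- simulate_profile(inst$params, inst$schedule, t)$total_conc
  sch3 <- inst$schedule
  sch3$amount <- sch3$amount * 3.7
  tripled <- simulate_profile(inst$params, sch3, t)$total_conc
  expect_equal(tripled, 3.7 * base, tolerance = 1e-12)

  # zero doses -> all-zero profile (via the ODE oracle contract)
  empty <- dose_schedule(numeric(0), numeric(0), numeric(0))
  expect_true(all(ode_oracle(p, empty, times = 0:10)$total_conc == 0))
})

test_that("two-compartment solution converges to one-compartment as Q -> 0", {
  t <- seq(0, 48, by = 0.25)
  sch <- dose_schedule(c(0, 12, 24), 40, 0.0833)
  c1 <- simulate_profile(ip1(CL = 0.3, V = 2), sch, t)$total_conc
  c2 <- simulate_profile(ip2(CL = 0.3, V = 2, Q = 1e-6, V2 = 1), sch, t)$total_conc
  expect_lt(max(abs(c2 - c1)) / max(c1), 0.005)
})

test_that("analytic and ODE-oracle profiles agree within 0.1% on randomized regimens", {
  withr::with_seed(202, {
    for (k in 1:50) {
      inst <- random_instance()
      t <- seq(0, 48, by = 0.5)
      a <- simulate_profile(inst$params, inst$schedule, t)$total_conc
      o <- ode_oracle(inst$params, inst$schedule, t)$total_conc
      expect_lt(max(abs(a - o)) / max(o), 1e-3)
    }
  })
})

test_that("sampled random effects have the declared variance and are reproducible", {
  m <- flat_model()
  e1 <- sample_etas(m, 1e5, seed = 42)
  e2 <- sample_etas(m, 1e5, seed = 42)
  expect_identical(e1, e2)
  # variance of the sample variance ~ 2 sigma^4 / (n-1)
  se <- sqrt(2 * 0.09^2 / (1e5 - 1))
  expect_lt(abs(var(e1[, "CL"]) - 0.09), 3 * se)
  expect_true(all(abs(colMeans(e1)) < 0.01))

  m0 <- pk_model("x", 1, list(CL = 1, V = 1), omega = list(CL = 0, V = 0))
  expect_true(all(sample_etas(m0, 50, seed = 1) == 0))
})

test_that("model configurations round-trip through YAML", {
  m <- model_library("benzylpenicillin_neonatal_synthetic")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, f)
  m2 <- read_model_config(f)
  expect_equal(m2$typical_values, m$typical_values)
  expect_equal(m2$omega, m$omega)
  expect_equal(m2$n_compartments, m$n_compartments)
  expect_equal(length(m2$covariate_effects), length(m$covariate_effects))
  expect_equal(m2$residual_error, m$residual_error)

  subj <- list(birth_weight = 1.2, GA = 29)
  expect_equal(unlist(unclass(individual_parameters(subj, m2))),
               unlist(unclass(individual_parameters(subj, m))))
})
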