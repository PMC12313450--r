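test_that("datasets validate structure and round-trip through CSV bit-exactly", {
  m <- model_library("demo")
  st <- generate_study(study_design(n_subjects = 12), m, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(st$data, f)
  back <- read_pk_dataset(f)
  expect_equal(as.data.frame(back), as.data.frame(st$data))
  # a second write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(back, f2)
  expect_identical(readLines(f), readLines(f2))

  bad <- data.frame(ID = 1, TIME = 5, EVID = 0, AMT = NA, DUR = NA,
                    DV = 3, MDV = 0, GA = 30, BW = 1.5, PNA = 0.2)
  expect_error(validate_pk_dataset(bad), "observation before any dose")
  bad2 <- data.frame(ID = 1, TIME = c(0, -1), EVID = c(1, 0),
                     AMT = c(10, NA), DUR = c(0.0833, NA), DV = c(NA, 2),
                     MDV = c(1, 0), GA = 30, BW = 1.5, PNA = 0)
  expect_error(validate_pk_dataset(bad2), "negative TIME")
  expect_error(validate_pk_dataset(data.frame(ID = 1, TIME = 0)), "EVID")
})

test_that("population predictions equal the closed-form eta-free profile", {
  m <- flat_model(CL = 0.2, V = 1, prop = 0.1, add = 0.1)
  d <- data.frame(
    ID = 1, TIME = c(0, 5, 10), EVID = c(1, 0, 0), AMT = c(50, NA, NA),
    DUR = c(0.001, NA, NA), DV = c(NA, 999, 123), MDV = c(1, 0, 0),
    GA = 30, BW = 1.5, PNA = c(0, 5, 10) / 24
  )
  pred <- population_predict(d, m)
  expect_equal(pred$PRED, 50 * exp(-0.2 * c(5, 10)), tolerance = 1e-3)
  # independent of DV
  d2 <- d; d2$DV[2:3] <- c(1, 1)
  expect_equal(population_predict(d2, m)$PRED, pred$PRED)
  # matches the ODE oracle within 0.1%
  orc <- ode_oracle(ip1(0.2, 1), dose_schedule(0, 50, 0.001),
                    times = c(5, 10))
  expect_equal(pred$PRED, orc$total_conc, tolerance = 1e-3)
})

test_that("prediction-error metrics implement PPE/APPE/NRMSE/P10-P30", {
  r <- prediction_error_metrics(12, 10)
  expect_equal(r$ppe, 20)
  expect_equal(r$appe, 20)

  r2 <- prediction_error_metrics(c(3, 7, 11), c(3, 7, 11))
  expect_equal(r2$nrmse, 0)
  expect_equal(r2$p10, 100)

  r3 <- prediction_error_metrics(c(12, 15), c(10, 10))
  expect_equal(r3$p30, 50)
  expect_equal(r3$p10, 0)

  expect_error(prediction_error_metrics(c(1, 2), c(1, 0)), "> 0")
  expect_error(prediction_error_metrics(1:3, 1:2), "length")

  # P10 <= P20 <= P30, strict when errors are continuous
  withr::with_seed(9, {
    dv <- runif(200, 5, 50)
    pred <- dv * exp(rnorm(200, 0, 0.2))
    r4 <- prediction_error_metrics(pred, dv)
    expect_lt(r4$p10, r4$p20)
    expect_lt(r4$p20, r4$p30)
  })
})

test_that("MAP estimates return the prior mode without data and track rich data", {
  m <- flat_model()
  # subject 2 has doses but no observations -> eta = 0
  d <- data.frame(
    ID = c(1, 1, 2), TIME = c(0, 6, 0), EVID = c(1, 0, 1),
    AMT = c(50, NA, 40), DUR = c(0.0833, NA, 0.0833), DV = c(NA, 30, NA),
    MDV = c(1, 0, 1), GA = 32, BW = 1.8, PNA = 0
  )
  est <- map_etas(d, m)
  expect_equal(unlist(est[est$ID == 2, c("CL", "V")]), c(CL = 0, V = 0))

  # single observation, tiny residual error, huge omega: IPRED -> DV
  m2 <- pk_model("x", 1, list(CL = 0.2, V = 1), omega = list(CL = 4),
                 residual_error = residual_error_spec(1e-4, 0))
  d2 <- data.frame(ID = 1, TIME = c(0, 4), EVID = c(1, 0), AMT = c(50, NA),
                   DUR = c(0.001, NA), DV = c(NA, 30), MDV = c(1, 0),
                   GA = 30, BW = 1, PNA = 0)
  ip <- individual_predict(d2, m2)
  expect_equal(ip$IPRED, 30, tolerance = 0.01)

  expect_error(map_etas(d, pk_model("x", 1, list(CL = 1, V = 1))), "omega")
})

test_that("MAP eta recovery correlates strongly with truth on rich data", {
  m <- flat_model(prop = 0.08, add = 0.05)
  rd <- rich_dataset(m, n_subjects = 30, seed = 401)
  est <- map_etas(rd$data, m)
  expect_gt(cor(est$CL, rd$etas[, "CL"]), 0.9)
})

test_that("pcVPC applies the prediction correction and is seed-reproducible", {
  m <- model_library("demo")
  st <- generate_study(study_design(n_subjects = 25), m, seed = 19)
  v <- pcvpc(st$data, m, n_sim = 100, bins = 3, seed = 7)
  # pcY = Y * median(PRED in bin) / PRED
  co <- v$corrections
  med <- tapply(co$PRED, co$bin, median)
  expect_equal(co$pcDV, co$DV * as.numeric(med[co$bin]) / co$PRED)
  # every observation in exactly one bin
  expect_equal(sum(v$bins$n_obs), nrow(co))
  # bands are ordered
  expect_true(all(v$simulated$lower <= v$simulated$median))
  expect_true(all(v$simulated$median <= v$simulated$upper))
  v2 <- pcvpc(st$data, m, n_sim = 100, bins = 3, seed = 7)
  expect_identical(v$simulated, v2$simulated)
  expect_error(pcvpc(st$data, m, n_sim = 50), "n_sim")
})

test_that("npde clamps extreme discrepancies and is reproducible", {
  m <- flat_model(prop = 0.05, add = 0.05)
  # DV far below anything the model can simulate -> pde at the lower clamp
  d <- data.frame(ID = 1, TIME = c(0, 6, 12), EVID = c(1, 0, 0),
                  AMT = c(100, NA, NA), DUR = c(0.0833, NA, NA),
                  DV = c(NA, 1e-4, 1e-4), MDV = c(1, 0, 0),
                  GA = 30, BW = 1.5, PNA = 0)
  r <- npde(d, m, n_sim = 200, seed = 3)
  expect_equal(r$table$pde[1], 1 / 400)
  expect_equal(r$table$npde[1], qnorm(1 / 400))

  m2 <- model_library("demo")
  st <- generate_study(study_design(n_subjects = 20), m2, seed = 23)
  r1 <- npde(st$data, m2, n_sim = 150, seed = 5)
  r2 <- npde(st$data, m2, n_sim = 150, seed = 5)
  expect_identical(r1$table, r2$table)
  expect_true(all(is.finite(r1$table$npde)))
  expect_true(all(r1$table$pde > 0 & r1$table$pde < 1))
})
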