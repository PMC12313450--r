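test_that("protein binding scales totals by the unbound fraction", {
  p <- grid_profile(0:10, rep(100, 11))
  expect_equal(apply_protein_binding(p, 11.7)$unbound_conc, rep(88.3, 11))
  expect_equal(apply_protein_binding(p, 49.2)$unbound_conc, rep(50.8, 11))
  expect_equal(apply_protein_binding(p, 0)$unbound_conc, p$total_conc)
  expect_error(apply_protein_binding(p, 100), "\\[0, 100\\)")
  expect_error(apply_protein_binding(p, -1), "\\[0, 100\\)")
})

test_that("time above threshold uses strict inequality and handles constants", {
  p <- grid_profile(seq(0, 48, 0.5), rep(10, 97))
  expect_equal(fraction_time_above(p, 1, use_unbound = FALSE), 100)
  expect_equal(fraction_time_above(p, 10, use_unbound = FALSE), 0)  # strict >
  expect_error(fraction_time_above(p, 1, use_unbound = FALSE,
                                   window = c(5, 5)), "non-empty")
  expect_error(fraction_time_above(p, 1, use_unbound = FALSE,
                                   window = c(0, 50)), "outside")
  expect_error(fraction_time_above(p, 1), "unbound")
})

test_that("crossing refinement reproduces the mono-exponential closed form", {
  # C(t) = 50 exp(-0.2 t): crosses 1 mg/L at ln(50)/0.2 = 19.56 h
  prof <- simulate_profile(ip1(CL = 0.2, V = 1), dose_schedule(0, 50, 0.001),
                           times = time_grid(window = 24, step = 0.25))
  ft <- fraction_time_above(prof, 1, use_unbound = FALSE, window = c(0, 24))
  expect_equal(ft, 100 * (log(50) / 0.2) / 24, tolerance = 1e-4)
  expect_equal(round(ft, 1), 81.5)
})

test_that("coarse-grid %fT agrees with a 0.001-h dense grid within 0.1 points", {
  withr::with_seed(303, {
    for (k in 1:100) {
      inst <- random_instance()
      prof <- simulate_profile(inst$params, inst$schedule,
                               times = time_grid(inst$schedule, step = 0.25))
      thr <- runif(1, 0.2, 0.8) * max(prof$total_conc)
      ft <- fraction_time_above(prof, thr, use_unbound = FALSE)
      dense_t <- seq(0, 48, by = 0.001)
      dense_c <- attr(prof, "evaluator")(dense_t)
      ft_dense <- 100 * mean(dense_c > thr)
      expect_lt(abs(ft - ft_dense), 0.1)
    }
  })
})

test_that("PTA counts attaining subjects and is monotone across the target grid", {
  # 9 of 10 constant profiles above the MIC -> 90%
  profs <- c(
    replicate(9, grid_profile(seq(0, 48, 0.5), rep(8, 97)), simplify = FALSE),
    list(grid_profile(seq(0, 48, 0.5), rep(0.01, 97)))
  )
  r <- pta(profs, mic = 1, required_fraction = 40)
  expect_equal(r$pta, 90)
  expect_equal(r$n_subjects, 10)
  # permanently above 4xMIC attains every required fraction
  r4 <- pta(profs[1:9], mic = 1, required_fraction = 100, mic_multiplier = 4)
  expect_equal(r4$pta, 100)

  # monotonicity on simulated profiles
  m <- model_library("demo")
  pop <- generate_population(26, 38, 4, seed = 31)
  etas <- sample_etas(m, nrow(pop), seed = 32)
  profs2 <- simulate_regimen(pop, m, "dpf_amoxicillin", etas)
  g <- pta_grid(profs2, mics = c(0.5, 1, 2, 8), fractions = c(40, 70, 100),
                multipliers = c(1, 4), bound_fraction = 11.7)
  for (mult in unique(g$multiplier)) {
    for (fr in unique(g$fraction)) {
      sub <- g[g$multiplier == mult & g$fraction == fr, ]
      expect_true(all(diff(sub$pta[order(sub$mic)]) <= 0))
    }
    for (mic in unique(g$mic)) {
      sub <- g[g$multiplier == mult & g$mic == mic, ]
      expect_true(all(diff(sub$pta[order(sub$fraction)]) <= 0))
    }
  }
  for (mic in unique(g$mic)) {
    for (fr in unique(g$fraction)) {
      sub <- g[g$mic == mic & g$fraction == fr, ]
      expect_true(sub$pta[sub$multiplier == 4] <= sub$pta[sub$multiplier == 1])
    }
  }
  # a single-cell grid reduces to pta()
  one <- pta_grid(profs2, mics = 1, fractions = 70, multipliers = 1,
                  bound_fraction = 11.7)
  expect_equal(one$pta, pta(profs2, 1, 70, 1, bound_fraction = 11.7)$pta)
})

test_that("PTA windows start at the first attainable peak", {
  # trough stays above MIC: 100%fT>MIC must be attainable despite C(0) = 0
  prof <- simulate_profile(ip1(CL = 0.05, V = 1),
                           dose_schedule(c(0, 24), 50, 0.0833))
  expect_equal(pta(list(prof), mic = 0.5, required_fraction = 100)$pta, 100)
  # but not over an explicit [0, 48] window including the pre-peak ramp
  expect_equal(pta(list(prof), mic = 0.5, required_fraction = 100,
                   window = c(0, 48))$pta, 0)
})

test_that("toxicity summaries report medians by GA category on total concentrations", {
  t <- seq(0, 48, 0.5)
  mk <- function(pct) {
    cut_t <- 48 * pct / 100
    tt <- sort(unique(c(t, cut_t - 1e-7, cut_t)))
    grid_profile(tt, ifelse(tt <= cut_t - 1e-7, 200, 1))
  }
  profs <- list(mk(0.001), mk(10), mk(20))
  ga <- c(25, 25, 25)
  tox <- toxicity_summary(profs, 110, ga)
  expect_equal(tox$median_pct[tox$ga_category == "extremely preterm"], 10,
               tolerance = 1e-4)
  expect_equal(tox$n, c(3, 0, 0, 0))

  # all concentrations below threshold -> all-zero medians
  low <- replicate(4, grid_profile(t, rep(5, length(t))), simplify = FALSE)
  tox0 <- toxicity_summary(low, 110, c(25, 30, 34, 40))
  expect_true(all(tox0$median_pct == 0))

  # monotone non-increasing in the threshold
  profs2 <- withr::with_seed(77, replicate(6, {
    inst <- random_instance()
    simulate_profile(inst$params, inst$schedule)
  }, simplify = FALSE))
  ga2 <- c(25, 27, 30, 33, 38, 41)
  pct_at <- function(thr) {
    attr(toxicity_summary(profs2, thr, ga2), "per_subject")$pct_above
  }
  expect_true(all(pct_at(5) >= pct_at(10)))
  expect_true(all(pct_at(10) >= pct_at(50)))
})

test_that("PTA is monotone non-increasing in the protein-bound fraction", {
  m <- model_library("demo")
  pop <- generate_population(28, 34, 5, seed = 41)
  etas <- sample_etas(m, nrow(pop), seed = 42)
  profs <- simulate_regimen(pop, m, "dpf_amoxicillin", etas)
  sw <- binding_sensitivity(profs, mics = c(0.5, 2), fractions = c(40, 80, 100),
                            multipliers = c(1, 4),
                            bound_fractions = c(5, 11.7, 15, 40, 60),
                            reference = 11.7)
  key <- interaction(sw$mic, sw$multiplier, sw$fraction)
  for (k in levels(key)) {
    sub <- sw[key == k, ]
    expect_true(all(diff(sub$pta[order(sub$bound_fraction)]) <= 0))
  }
  # deviation is zero at the reference fraction
  expect_true(all(sw$deviation[sw$bound_fraction == 11.7] == 0))
  expect_error(binding_sensitivity(profs, bound_fractions = c(10, 100)),
               "\\[0, 100\\)")
})
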