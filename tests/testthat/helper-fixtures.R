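# Shared fixtures built in code.

# Bare individual parameter sets (bypassing covariate resolution) for
# low-level engine tests.
ip1 <- function(CL, V) {
  structure(list(CL = CL, V = V, subject_id = NA), class = "individual_parameters")
}
ip2 <- function(CL, V, Q, V2) {
  structure(list(CL = CL, V = V, Q = Q, V2 = V2, subject_id = NA),
            class = "individual_parameters")
}

# A profile with explicit grid values and no continuous-time evaluator
# (forces the linear-interpolation path of fraction_time_above()).
grid_profile <- function(time, total, first_dose_end = NULL) {
  structure(
    list(subject_id = NA, time = time, total_conc = total,
         unbound_conc = NULL, bound_fraction = NULL),
    evaluator = NULL, first_dose_end = first_dose_end,
    class = "concentration_profile"
  )
}

# A fully synthetic model with no covariates, for tests that need exact
# hand-computable kinetics.
flat_model <- function(CL = 0.2, V = 1, omega = list(CL = 0.09, V = 0.04),
                       prop = 0.1, add = 0.1) {
  pk_model("flat", 1, typical_values = list(CL = CL, V = V),
           omega = omega, residual_error = residual_error_spec(prop, add))
}

# Random parameter/schedule instances for property tests (assumes the caller
# fixed the RNG seed).
random_instance <- function() {
  two <- runif(1) < 0.5
  params <- if (two) {
    ip2(CL = runif(1, 0.05, 1), V = runif(1, 0.3, 3),
        Q = runif(1, 0.05, 1), V2 = runif(1, 0.2, 2))
  } else {
    ip1(CL = runif(1, 0.05, 1), V = runif(1, 0.3, 3))
  }
  n_dose <- sample(1:8, 1)
  sched <- dose_schedule(
    start_time = sort(runif(n_dose, 0, 40)),
    amount = runif(n_dose, 5, 100),
    duration = runif(n_dose, 0.05, 2)
  )
  list(params = params, schedule = sched)
}

# Rich-sampling dataset (8 observations/subject) with known random effects,
# for MAP recovery experiments. Returns the dataset plus the true etas.
rich_dataset <- function(model, n_subjects = 30, seed = 401) {
  withr::with_seed(seed, {
    etas <- sample_etas(model, n_subjects)
    rows <- lapply(seq_len(n_subjects), function(i) {
      subject <- list(id = i, GA = sample(28:40, 1),
                      birth_weight = runif(1, 1, 4))
      sched <- dose_schedule(c(0, 12, 24, 36), 25 * subject$birth_weight, 0.0833)
      obs_t <- sort(runif(8, 0.5, 47.5))
      eta <- setNames(etas[i, ], colnames(etas))
      prof <- simulate_subject(subject, model, sched, times = obs_t, eta = eta)
      re <- model$residual_error
      dv <- prof$total_conc * (1 + rnorm(8, 0, re$proportional_sd)) +
        rnorm(8, 0, re$additive_sd)
      dv <- pmax(dv, 0.01)
      rbind(
        data.frame(ID = i, TIME = sched$start_time, EVID = 1,
                   AMT = sched$amount, DUR = sched$duration, DV = NA_real_,
                   MDV = 1, GA = subject$GA, BW = subject$birth_weight,
                   PNA = sched$start_time / 24),
        data.frame(ID = i, TIME = obs_t, EVID = 0, AMT = NA_real_,
                   DUR = NA_real_, DV = dv, MDV = 0, GA = subject$GA,
                   BW = subject$birth_weight, PNA = obs_t / 24)
      )
    })
    data <- do.call(rbind, rows)
    data <- data[order(data$ID, data$TIME, -data$EVID), ]
    rownames(data) <- NULL
    list(data = validate_pk_dataset(data), etas = etas)
  })
}
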