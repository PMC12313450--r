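#' Resolve individual PK parameters from covariates and random effects
#'
#' Each parameter is `TV_P * prod(covariate effects) * exp(eta_P)`. Covariates
#' are resolved at a given postnatal time: with the time origin at birth,
#' `PNA(t) = pna0 + t/24` days and `PMA(t) = GA + PNA(t)/7` weeks. Birth weight
#' is used as the body weight throughout the 48-h window.
#'
#' @param subject A list or one-row data frame with `birth_weight` (kg), `GA`
#'   (weeks) and optionally `pna0` (postnatal age in days at time 0; default 0).
#' @param model A [pk_model].
#' @param eta Named numeric vector of random effects (log scale); missing
#'   entries are 0.
#' @param time Hours since time origin at which time-varying covariates (PNA,
#'   PMA) are evaluated. Default 0.
#' @return Object of class `individual_parameters`: named list of positive
#'   parameter values (`CL`, `V`, and `Q`, `V2` for two-compartment models).
#' @export
individual_parameters <- function(subject, model, eta = NULL, time = 0) {
  stopifnot(inherits(model, "pk_model"))
  subject <- as.list(subject)
  pna0 <- if (is.null(subject$pna0)) 0 else subject$pna0

  covariate_value <- function(name) {
    val <- switch(name,
      birth_weight = subject$birth_weight,
      GA = subject$GA,
      PNA = pna0 + time / 24,
      PMA = {
        if (is.null(subject$GA)) NULL else subject$GA + (pna0 + time / 24) / 7
      },
      subject[[name]]
    )
    if (is.null(val) || is.na(val)) {
      stop("subject is missing covariate '", name, "' required by the model",
           call. = FALSE)
    }
    val
  }

  pars <- lapply(model$typical_values, identity)
  for (eff in model$covariate_effects) {
    cov <- covariate_value(eff$covariate)
    rng <- model$covariate_ranges[[eff$covariate]]
    if (!is.null(rng) && (cov < rng[1] || cov > rng[2])) {
      warning(sprintf("covariate %s = %.3g outside the model's range [%g, %g]; used as-is",
                      eff$covariate, cov, rng[1], rng[2]), call. = FALSE)
    }
    fac <- switch(eff$kind,
      allometric_power = (cov / eff$reference)^eff$exponent,
      power            = (cov / eff$reference)^eff$exponent,
      sigmoid_maturation = cov^eff$gamma / (eff$pma50^eff$gamma + cov^eff$gamma),
      linear           = 1 + eff$slope * cov
    )
    pars[[eff$parameter]] <- pars[[eff$parameter]] * fac
  }
  if (!is.null(eta)) {
    for (p in intersect(names(eta), names(pars))) {
      pars[[p]] <- pars[[p]] * exp(eta[[p]])
    }
  }
  vals <- unlist(pars)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("non-positive individual parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(c(pars, list(subject_id = subject$id)),
            class = "individual_parameters")
}

#' Sample log-normal between-subject random effects
#'
#' Draws independent `eta ~ N(0, omega2_P)` per parameter declared in the
#' model's `omega` block. Reproducible under a fixed seed without disturbing
#' the caller's RNG state.
#'
#' @param model A [pk_model].
#' @param n Number of subjects (>= 1).
#' @param seed Optional integer seed.
#' @return `n x k` numeric matrix, columns named by parameter. Zero columns for
#'   zero variances; a zero-column matrix if the model has no omega block.
#' @export
sample_etas <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "pk_model"), n >= 1)
  om <- unlist(model$omega)
  if (any(om < 0)) stop("negative omega variance", call. = FALSE)
  draw <- function() {
    if (!length(om)) {
      return(matrix(numeric(0), nrow = n, ncol = 0))
    }
    m <- vapply(om, function(v) stats::rnorm(n, 0, sqrt(v)), numeric(n))
    m <- matrix(m, nrow = n, dimnames = list(NULL, names(om)))
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# ---- dose schedules ----------------------------------------------------------

#' Create a dose schedule
#'
#' @param start_time Event start times, hours since birth (>= 0).
#' @param amount Dose amounts, mg (> 0).
#' @param duration Infusion durations, hours (> 0; a bolus is represented as a
#'   5-minute infusion).
#' @param subject_id Optional subject identifier.
#' @return A `dose_schedule` data frame sorted by start time.
#' @export
dose_schedule <- function(start_time, amount, duration, subject_id = NA) {
  if (length(start_time)) {
    stopifnot(length(amount) %in% c(1L, length(start_time)),
              length(duration) %in% c(1L, length(start_time)))
    if (any(start_time < 0)) stop("dose start times must be >= 0", call. = FALSE)
    if (any(amount <= 0)) stop("dose amounts must be > 0", call. = FALSE)
    if (any(duration <= 0)) stop("infusion durations must be > 0", call. = FALSE)
  }
  d <- data.frame(start_time = as.numeric(start_time),
                  amount = rep_len(as.numeric(amount), length(start_time)),
                  duration = rep_len(as.numeric(duration), length(start_time)))
  d <- d[order(d$start_time), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "subject_id") <- subject_id
  class(d) <- c("dose_schedule", "data.frame")
  d
}

# Central-compartment concentration for a single constant-rate infusion,
# evaluated at times t (vectorised). Closed forms:
#   1-cpt: C = (R0/CL) (1 - e^{-ke tau}) during, decaying mono-exponentially after.
#   2-cpt: bolus unit response D/V1 (A e^{-a t} + B e^{-b t}) convolved with the
#          infusion rate, i.e. (R0/V1) [A/a (1-e^{-a tau}) + B/b (1-e^{-b tau})]
#          during and the matching biexponential washout after, with
#          a+b = k10+k12+k21, ab = k10 k21, A = (a-k21)/(a-b), B = (k21-b)/(a-b).
# (1-e^{-b tau})/b is computed via expm1 so the Q -> 0 limit stays stable.
.event_conc <- function(t, t0, amount, duration, params) {
  tau <- t - t0
  out <- numeric(length(t))
  on <- tau > 0
  if (!any(on)) return(out)
  tau <- tau[on]
  R0 <- amount / duration
  CL <- params$CL; V <- params$V

  if (is.null(params$Q) || is.null(params$V2)) {
    ke <- CL / V
    te <- pmin(tau, duration)           # time infused so far
    # during: (R0/CL)(1-e^{-ke te}); after: multiply by e^{-ke (tau-te)}
    c_on <- (R0 / CL) * (-expm1(-ke * te)) * exp(-ke * pmax(tau - duration, 0))
    out[on] <- c_on
    return(out)
  }

  Q <- params$Q; V2 <- params$V2
  k10 <- CL / V; k12 <- Q / V; k21 <- Q / V2
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  a <- (s + disc) / 2
  b <- (s - disc) / 2
  A <- (a - k21) / (a - b)
  B <- (k21 - b) / (a - b)
  te <- pmin(tau, duration)
  rest <- pmax(tau - duration, 0)
  # stable (1 - e^{-l te})/l terms
  f <- function(l, x) if (l > 0) -expm1(-l * x) / l else x
  term_a <- A * f(a, te) * exp(-a * rest)
  term_b <- B * f(b, te) * exp(-b * rest)
  out[on] <- (R0 / V) * (term_a + term_b)
  out
}

# Superpose per-event solutions; events is a list of
# list(start_time, amount, duration, params)
.superpose <- function(events, t) {
  conc <- numeric(length(t))
  for (ev in events) {
    conc <- conc + .event_conc(t, ev$start_time, ev$amount, ev$duration, ev$params)
  }
  conc
}

.new_profile <- function(subject_id, time, total, evaluator,
                         first_dose_end = NULL) {
  structure(
    list(subject_id = subject_id, time = time, total_conc = total,
         unbound_conc = NULL, bound_fraction = NULL),
    evaluator = evaluator,
    first_dose_end = first_dose_end,
    class = "concentration_profile"
  )
}

.first_dose_end <- function(schedule) {
  if (!nrow(schedule)) return(NULL)
  t0 <- min(schedule$start_time)
  first <- schedule$start_time == t0
  min(schedule$start_time[first] + schedule$duration[first])
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("<concentration_profile> subject %s, %d time points over [%.3g, %.3g] h\n",
              as.character(x$subject_id), length(x$time),
              min(x$time), max(x$time)))
  cat(sprintf("  Cmax %.4g mg/L (total)%s\n", max(x$total_conc),
              if (is.null(x$bound_fraction)) ""
              else sprintf("; protein binding %.3g%% applied", x$bound_fraction)))
  invisible(x)
}

#' Build a simulation time grid
#'
#' Regular grid over `[0, window]` augmented with every infusion start/stop so
#' profile kinks fall on grid points.
#'
#' @param schedule A [dose_schedule()].
#' @param window Window length, h.
#' @param step Grid step, h.
#' @return Sorted numeric vector of times.
#' @export
time_grid <- function(schedule = NULL, window = 48, step = 0.05) {
  t <- seq(0, window, by = step)
  if (!is.null(schedule) && nrow(schedule)) {
    brk <- c(schedule$start_time, schedule$start_time + schedule$duration)
    t <- c(t, brk[brk >= 0 & brk <= window])
  }
  sort(unique(t))
}

#' Simulate a concentration-time profile (analytic superposition)
#'
#' Total plasma concentration as the superposition of closed-form one- or
#' two-compartment constant-rate infusion solutions, one per dose event.
#' Exact (no integration error), linear in dose, continuous in time.
#'
#' @param params [individual_parameters()] (fixed over the window).
#' @param schedule A [dose_schedule()].
#' @param times Sorted, non-negative evaluation times (h). Defaults to
#'   [time_grid()] over 48 h.
#' @return A `concentration_profile` carrying the time grid, total
#'   concentrations, and a continuous-time evaluator used for crossing
#'   refinement by [fraction_time_above()].
#' @export
simulate_profile <- function(params, schedule, times = time_grid(schedule)) {
  stopifnot(inherits(params, "individual_parameters"),
            inherits(schedule, "dose_schedule"))
  if (any(times < 0)) stop("negative time in grid", call. = FALSE)
  if (is.unsorted(times)) stop("time grid must be sorted", call. = FALSE)
  events <- lapply(seq_len(nrow(schedule)), function(i) {
    list(start_time = schedule$start_time[i], amount = schedule$amount[i],
         duration = schedule$duration[i], params = params)
  })
  evaluator <- function(t) .superpose(events, t)
  .new_profile(attr(schedule, "subject_id"), times, evaluator(times), evaluator,
               first_dose_end = .first_dose_end(schedule))
}

#' Simulate a subject with per-dose covariate resolution
#'
#' Time-varying covariates (PNA, and thereby PMA) are refreshed at each dose
#' event: every dose's contribution uses the individual parameters evaluated at
#' that dose's start time, the standard piecewise treatment of within-window
#' clearance maturation under a superposition engine.
#'
#' @param subject Subject list/row with `birth_weight`, `GA` (and optional
#'   `pna0`, `id`).
#' @param model A [pk_model].
#' @param schedule A [dose_schedule()].
#' @param times Evaluation grid; defaults to [time_grid()].
#' @param eta Named random-effect vector (shared across the window).
#' @return A `concentration_profile`.
#' @export
simulate_subject <- function(subject, model, schedule,
                             times = time_grid(schedule), eta = NULL) {
  if (any(times < 0)) stop("negative time in grid", call. = FALSE)
  events <- lapply(seq_len(nrow(schedule)), function(i) {
    t0 <- schedule$start_time[i]
    list(start_time = t0, amount = schedule$amount[i],
         duration = schedule$duration[i],
         params = individual_parameters(subject, model, eta = eta, time = t0))
  })
  evaluator <- function(t) .superpose(events, t)
  sid <- if (!is.null(subject$id)) subject$id else attr(schedule, "subject_id")
  .new_profile(sid, times, evaluator(times), evaluator,
               first_dose_end = .first_dose_end(schedule))
}

#' Reference profile by numeric integration of the compartmental ODEs
#'
#' Independent check of [simulate_profile()]: integrates the mass-balance
#' ODEs with `deSolve::lsoda` at tight tolerances, splitting at every infusion
#' start/stop so rate discontinuities never cross an integration step.
#' Intended for testing; the analytic path is the production route.
#'
#' @inheritParams simulate_profile
#' @param rtol,atol Integration tolerances.
#' @return A `concentration_profile` (no evaluator beyond grid interpolation).
#' @export
ode_oracle <- function(params, schedule, times = time_grid(schedule),
                       rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "individual_parameters"))
  if (any(times < 0)) stop("negative time in grid", call. = FALSE)
  two_cpt <- !is.null(params$Q) && !is.null(params$V2)
  deriv <- function(t, y, parms) {
    R0 <- parms
    if (two_cpt) {
      dA1 <- R0 - (params$CL / params$V) * y[1] -
        (params$Q / params$V) * y[1] + (params$Q / params$V2) * y[2]
      dA2 <- (params$Q / params$V) * y[1] - (params$Q / params$V2) * y[2]
      list(c(dA1, dA2))
    } else {
      list(R0 - (params$CL / params$V) * y[1])
    }
  }
  t_end <- max(times)
  # the infusion rate is piecewise constant: integrate segment by segment so
  # no discontinuity ever sits inside an integration interval
  brk <- sort(unique(c(0, t_end,
                       schedule$start_time,
                       schedule$start_time + schedule$duration)))
  brk <- brk[brk >= 0 & brk <= t_end]
  y <- if (two_cpt) c(0, 0) else 0
  out_t <- numeric(0)
  out_c <- numeric(0)
  if (any(times == 0)) { out_t <- 0; out_c <- 0 }
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    if (t1 <= t0) next
    mid <- (t0 + t1) / 2
    on <- schedule$start_time <= mid & mid < schedule$start_time + schedule$duration
    R0 <- sum(schedule$amount[on] / schedule$duration[on])
    seg_times <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    sol <- deSolve::lsoda(y, seg_times, deriv, parms = R0,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("ODE integration failed", call. = FALSE)
    keep <- seg_times > t0
    out_t <- c(out_t, seg_times[keep])
    out_c <- c(out_c, sol[keep, 2] / params$V)
    y <- sol[nrow(sol), -1]
  }
  total <- stats::approx(out_t, out_c, xout = times, rule = 2)$y
  .new_profile(attr(schedule, "subject_id"), times, total, evaluator = NULL)
}
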