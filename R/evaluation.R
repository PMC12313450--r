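# External model evaluation: population/individual predictions,
# prediction-error metrics, pcVPC and NPDE.

# Internal: model-predicted concentrations at this subject's observation
# times, given a fixed eta (NULL = population typical).
.predict_subject <- function(sub, model, eta = NULL) {
  if (!nrow(sub$obs)) return(numeric(0))
  events <- .subject_events(sub, model, eta = eta)
  .superpose(events, sub$obs$TIME)
}

# Random effects enter multiplicatively (P = P_typ * exp(eta)), so replicate
# simulation and MAP objectives reuse eta-free per-dose parameters and rescale.
.scale_events <- function(events, eta) {
  if (is.null(eta)) return(events)
  lapply(events, function(ev) {
    for (p in names(eta)) {
      if (!is.null(ev$params[[p]])) ev$params[[p]] <- ev$params[[p]] * exp(eta[[p]])
    }
    ev
  })
}

#' Population-typical predictions (PRED) for an observation dataset
#'
#' Simulates each subject under its own dose history and covariates with all
#' random effects at zero and evaluates the profile at the observation times.
#' Independent of the observed DV values.
#'
#' @param data A `pk_dataset` (see [read_pk_dataset()]).
#' @param model A [pk_model].
#' @return `data.frame` with `ID`, `TIME`, `DV`, `PRED` (one row per
#'   observation, dataset order).
#' @export
population_predict <- function(data, model) {
  data <- validate_pk_dataset(as.data.frame(data))
  subs <- .split_subjects(data)
  out <- do.call(rbind, lapply(subs, function(sub) {
    if (!nrow(sub$obs)) return(NULL)
    data.frame(ID = sub$obs$ID, TIME = sub$obs$TIME, DV = sub$obs$DV,
               PRED = .predict_subject(sub, model))
  }))
  rownames(out) <- NULL
  out
}

#' MAP (empirical-Bayes) estimation of individual random effects
#'
#' Minimises the standard MAP objective
#' `-2 [ sum log N(DV | IPRED, sd(IPRED)) + sum log N(eta | 0, omega2) ]`
#' over the random effects declared in the model's omega block, with the
#' combined proportional + additive residual model giving
#' `sd(IPRED)^2 = (prop * IPRED)^2 + add^2`. Deterministic given the data:
#' multi-start (eta = 0 plus 4 draws from the prior under a fixed internal
#' seed) BFGS with a Nelder-Mead fallback.
#'
#' @param data A `pk_dataset`.
#' @param model A [pk_model] with a non-empty omega block and a residual-error
#'   spec that is not identically zero.
#' @return `data.frame` of MAP eta estimates, one row per subject (`ID` plus
#'   one column per random effect). Subjects without observations get 0 (the
#'   prior mode).
#' @export
map_etas <- function(data, model) {
  data <- validate_pk_dataset(as.data.frame(data))
  om <- unlist(model$omega)
  om <- om[om > 0]
  if (!length(om)) stop("model has no positive omega variances", call. = FALSE)
  re <- model$residual_error
  if (re$proportional_sd <= 0 && re$additive_sd <= 0) {
    stop("MAP estimation needs a non-degenerate residual error spec",
         call. = FALSE)
  }
  subs <- .split_subjects(data)
  par_names <- names(om)

  est_one <- function(sub) {
    if (!nrow(sub$obs)) return(stats::setNames(rep(0, length(om)), par_names))
    dv <- sub$obs$DV
    base_events <- .subject_events(sub, model)
    obj <- function(eta_vec) {
      eta <- stats::setNames(eta_vec, par_names)
      f <- tryCatch(
        .superpose(.scale_events(base_events, eta), sub$obs$TIME),
        error = function(e) NULL
      )
      if (is.null(f) || any(!is.finite(f))) return(1e10)
      sd <- sqrt((re$proportional_sd * f)^2 + re$additive_sd^2)
      sd <- pmax(sd, 1e-12)
      ll <- sum(stats::dnorm(dv, f, sd, log = TRUE)) +
        sum(stats::dnorm(eta_vec, 0, sqrt(om), log = TRUE))
      -2 * ll
    }
    starts <- withr::with_seed(1404, {
      c(list(rep(0, length(om))),
        lapply(1:4, function(i) stats::rnorm(length(om), 0, sqrt(om))))
    })
    fits <- lapply(starts, function(s) {
      fit <- tryCatch(
        stats::optim(s, obj, method = "BFGS",
                     control = list(reltol = 1e-10, maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        fit <- tryCatch(
          stats::optim(s, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 2000)),
          error = function(e) NULL
        )
      }
      fit
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) {
      stop("MAP estimation failed to converge for subject ", sub$id,
           call. = FALSE)
    }
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    stats::setNames(best$par, par_names)
  }

  est <- do.call(rbind, lapply(subs, est_one))
  colnames(est) <- par_names
  out <- data.frame(ID = vapply(subs, `[[`, numeric(1), "id"))
  out[par_names] <- as.data.frame(est)
  rownames(out) <- NULL
  out
}

#' Individual (IPRED) predictions at MAP random effects
#'
#' @inheritParams map_etas
#' @param etas Optional precomputed [map_etas()] output.
#' @return `data.frame` with `ID`, `TIME`, `DV`, `PRED`, `IPRED` and residuals
#'   (`RES = DV - PRED`, `IRES = DV - IPRED`) — the tidy goodness-of-fit table.
#' @export
individual_predict <- function(data, model, etas = NULL) {
  data <- validate_pk_dataset(as.data.frame(data))
  if (is.null(etas)) etas <- map_etas(data, model)
  subs <- .split_subjects(data)
  par_names <- setdiff(names(etas), "ID")
  out <- do.call(rbind, lapply(subs, function(sub) {
    if (!nrow(sub$obs)) return(NULL)
    eta <- stats::setNames(
      as.numeric(etas[match(sub$id, etas$ID), par_names, drop = FALSE]),
      par_names)
    data.frame(ID = sub$obs$ID, TIME = sub$obs$TIME, DV = sub$obs$DV,
               PRED = .predict_subject(sub, model),
               IPRED = .predict_subject(sub, model, eta = eta))
  }))
  out$RES <- out$DV - out$PRED
  out$IRES <- out$DV - out$IPRED
  rownames(out) <- NULL
  out
}

#' Numerical predictive-performance metrics
#'
#' Percentage prediction errors `PPE_i = 100 (PRED_i - DV_i) / DV_i`, their
#' absolute values (APPE), the normalized RMSE
#' `100 * RMSE(PRED - DV) / mean(DV)` (configurable to range normalization),
#' and `P_k` = percentage of predictions within +/- k% of the observations for
#' k = 10, 20, 30.
#'
#' @param pred Predicted concentrations.
#' @param dv Observed concentrations (> 0), same length.
#' @param normalize `"mean"` (default) or `"range"` for the NRMSE denominator.
#' @return List of class `prediction_error_report`: per-observation `ppe`,
#'   `appe`, and summary `median_ppe`, `iqr_ppe`, `median_appe`, `iqr_appe`,
#'   `nrmse`, `p10`, `p20`, `p30`.
#' @export
prediction_error_metrics <- function(pred, dv, normalize = c("mean", "range")) {
  normalize <- match.arg(normalize)
  if (length(pred) != length(dv)) stop("pred and dv lengths differ", call. = FALSE)
  if (any(dv <= 0)) stop("all DV must be > 0", call. = FALSE)
  ppe <- 100 * (pred - dv) / dv
  appe <- abs(ppe)
  denom <- if (normalize == "mean") mean(dv) else diff(range(dv))
  nrmse <- 100 * sqrt(mean((pred - dv)^2)) / denom
  p_within <- function(k) 100 * mean(appe <= k)
  structure(
    list(
      ppe = ppe, appe = appe,
      median_ppe = stats::median(ppe),
      iqr_ppe = unname(stats::quantile(ppe, c(0.25, 0.75))),
      median_appe = stats::median(appe),
      iqr_appe = unname(stats::quantile(appe, c(0.25, 0.75))),
      nrmse = nrmse,
      p10 = p_within(10), p20 = p_within(20), p30 = p_within(30)
    ),
    class = "prediction_error_report"
  )
}

#' @export
print.prediction_error_report <- function(x, ...) {
  cat("<prediction_error_report>\n")
  cat(sprintf("  n obs        %d\n", length(x$ppe)))
  cat(sprintf("  PPE median   %+.2f%% (IQR %.2f to %.2f)\n",
              x$median_ppe, x$iqr_ppe[1], x$iqr_ppe[2]))
  cat(sprintf("  APPE median  %.2f%% (IQR %.2f to %.2f)\n",
              x$median_appe, x$iqr_appe[1], x$iqr_appe[2]))
  cat(sprintf("  NRMSE        %.2f%%\n", x$nrmse))
  cat(sprintf("  P10/P20/P30  %.1f%% / %.1f%% / %.1f%%\n", x$p10, x$p20, x$p30))
  invisible(x)
}

# Internal: simulate one replicate DV vector for a subject (BSV + residual),
# assuming the current RNG state. base_events are the subject's eta-free
# per-dose events (precomputed once).
.simulate_subject_dv <- function(sub, base_events, om_names, om_sd, re) {
  eta <- stats::setNames(stats::rnorm(length(om_sd), 0, om_sd), om_names)
  f <- .superpose(.scale_events(base_events, eta), sub$obs$TIME)
  eps1 <- stats::rnorm(length(f), 0, re$proportional_sd)
  eps2 <- stats::rnorm(length(f), 0, re$additive_sd)
  f * (1 + eps1) + eps2
}

.omega_sd <- function(model) {
  om <- unlist(model$omega)
  om <- om[om > 0]
  list(names = names(om), sd = sqrt(om))
}

#' Prediction-corrected visual predictive check (pcVPC)
#'
#' Observations and each of `n_sim` model-simulated replicate datasets (BSV +
#' residual error, each subject under its own doses, covariates and sampling
#' times) are prediction-corrected within bins:
#' `pcY_ij = Y_ij * median(PRED in bin) / PRED_ij`. The observed 2.5th, 50th
#' and 97.5th pc-percentiles per bin are returned together with 95% confidence
#' bands of the same percentiles across the simulated replicates. Bins are
#' quantile-based on time after the most recent dose (sparse TDM-style data
#' with mixed dosing intervals make absolute-time binning misleading).
#'
#' @inheritParams map_etas
#' @param n_sim Number of simulated replicates (>= 100).
#' @param bins Number of quantile bins on time-after-dose.
#' @param seed Optional seed.
#' @return List of class `pcvpc_result`: `bins` (definitions), `observed`
#'   (per-bin pc-percentiles), `simulated` (per-bin confidence bands),
#'   `n_sim`, and the per-observation correction table.
#' @export
pcvpc <- function(data, model, n_sim = 1000, bins = 4, seed = NULL) {
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  data <- validate_pk_dataset(as.data.frame(data))
  subs <- .split_subjects(data)
  pred_tab <- population_predict(data, model)
  if (any(pred_tab$PRED <= 0)) {
    stop("zero population prediction; cannot prediction-correct", call. = FALSE)
  }

  # time after most recent dose, per observation
  tad <- unlist(lapply(subs, function(sub) {
    vapply(sub$obs$TIME, function(tt) {
      prior <- sub$doses$TIME[sub$doses$TIME <= tt]
      tt - max(prior)
    }, numeric(1))
  }))
  brks <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  if (length(brks) < 2) brks <- range(tad) + c(-1e-9, 1e-9)
  bin_id <- cut(tad, breaks = brks, include.lowest = TRUE)

  med_pred_bin <- tapply(pred_tab$PRED, bin_id, stats::median)
  corr <- unname(med_pred_bin[as.integer(bin_id)]) / pred_tab$PRED
  pc_obs <- pred_tab$DV * corr

  probs <- c(0.025, 0.5, 0.975)
  obs_pct <- t(vapply(levels(bin_id), function(b) {
    stats::quantile(pc_obs[bin_id == b], probs, names = FALSE)
  }, numeric(3)))

  osd <- .omega_sd(model)
  re <- model$residual_error
  base_ev <- lapply(subs, function(sub) {
    if (nrow(sub$obs)) .subject_events(sub, model) else NULL
  })
  sim_once <- function() {
    dv <- unlist(lapply(seq_along(subs), function(i) {
      sub <- subs[[i]]
      if (!nrow(sub$obs)) return(numeric(0))
      .simulate_subject_dv(sub, base_ev[[i]], osd$names, osd$sd, re)
    }))
    pc <- dv * corr
    t(vapply(levels(bin_id), function(b) {
      stats::quantile(pc[bin_id == b], probs, names = FALSE)
    }, numeric(3)))
  }
  run_sims <- function() replicate(n_sim, sim_once(), simplify = "array")
  sims <- if (is.null(seed)) run_sims() else withr::with_seed(seed, run_sims())

  band <- lapply(seq_along(probs), function(k) {
    t(vapply(seq_along(levels(bin_id)), function(b) {
      stats::quantile(sims[b, k, ], c(0.025, 0.5, 0.975), names = FALSE)
    }, numeric(3)))
  })
  names(band) <- c("p2.5", "p50", "p97.5")

  bins_df <- data.frame(
    bin = levels(bin_id),
    tad_lo = brks[-length(brks)], tad_hi = brks[-1],
    n_obs = as.integer(table(bin_id))
  )
  obs_df <- data.frame(bin = levels(bin_id),
                       p2.5 = obs_pct[, 1], p50 = obs_pct[, 2],
                       p97.5 = obs_pct[, 3])
  sim_df <- do.call(rbind, lapply(names(band), function(nm) {
    data.frame(bin = levels(bin_id), percentile = nm,
               lower = band[[nm]][, 1], median = band[[nm]][, 2],
               upper = band[[nm]][, 3])
  }))
  rownames(bins_df) <- rownames(obs_df) <- rownames(sim_df) <- NULL
  structure(
    list(bins = bins_df, observed = obs_df, simulated = sim_df, n_sim = n_sim,
         corrections = data.frame(ID = pred_tab$ID, TIME = pred_tab$TIME,
                                  tad = tad, bin = as.character(bin_id),
                                  DV = pred_tab$DV, PRED = pred_tab$PRED,
                                  pcDV = pc_obs)),
    class = "pcvpc_result"
  )
}

#' Normalized prediction distribution errors (NPDE)
#'
#' For each subject, `n_sim` replicate observation vectors are simulated under
#' the model (BSV + residual error, the subject's own design). Observed and
#' simulated vectors are decorrelated with the empirical simulation mean and
#' the Cholesky factor of the empirical simulation covariance; the prediction
#' discrepancy `pde_ij` is the fraction of decorrelated simulations below the
#' decorrelated observation, clamped to `[1/(2 n_sim), 1 - 1/(2 n_sim)]`, and
#' `npde = qnorm(pde)`. Under a correct model the npde are approximately
#' standard normal.
#'
#' @inheritParams pcvpc
#' @return List of class `npde_result`: per-observation table (`ID`, `TIME`,
#'   `DV`, `pde`, `npde`), global `mean` and `variance`, and test p-values
#'   (`p_mean` t-test of mean 0, `p_variance` chi-squared test of variance 1,
#'   `p_normality` Shapiro-Wilk, `p_global` Bonferroni-combined).
#' @export
npde <- function(data, model, n_sim = 1000, seed = NULL) {
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  data <- validate_pk_dataset(as.data.frame(data))
  subs <- .split_subjects(data)
  osd <- .omega_sd(model)
  re <- model$residual_error

  one_subject <- function(sub) {
    n_i <- nrow(sub$obs)
    if (!n_i) return(NULL)
    base_events <- .subject_events(sub, model)
    sims <- vapply(seq_len(n_sim), function(k) {
      .simulate_subject_dv(sub, base_events, osd$names, osd$sd, re)
    }, numeric(n_i))
    sims <- matrix(sims, nrow = n_i)        # n_i x n_sim
    m <- rowMeans(sims)
    centered <- sims - m
    S <- tcrossprod(centered) / (n_sim - 1)
    L <- tryCatch(t(chol(S)), error = function(e) {
      stop("singular simulation covariance for subject ", sub$id,
           "; increase n_sim", call. = FALSE)
    })
    dec_obs <- forwardsolve(L, sub$obs$DV - m)
    dec_sim <- forwardsolve(L, centered)
    pde <- vapply(seq_len(n_i), function(j) {
      mean(dec_sim[j, ] < dec_obs[j])
    }, numeric(1))
    pde <- pmin(pmax(pde, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
    data.frame(ID = sub$obs$ID, TIME = sub$obs$TIME, DV = sub$obs$DV,
               pde = pde, npde = stats::qnorm(pde))
  }
  run_all <- function() do.call(rbind, lapply(subs, one_subject))
  tab <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  rownames(tab) <- NULL
  x <- tab$npde
  n <- length(x)
  p_mean <- stats::t.test(x, mu = 0)$p.value
  chi <- (n - 1) * stats::var(x)            # H0 variance = 1
  p_var <- 2 * min(stats::pchisq(chi, n - 1), 1 - stats::pchisq(chi, n - 1))
  p_norm <- if (n >= 3 && n <= 5000) stats::shapiro.test(x)$p.value else NA_real_
  structure(
    list(table = tab, mean = mean(x), variance = stats::var(x),
         p_mean = p_mean, p_variance = p_var, p_normality = p_norm,
         p_global = min(1, 3 * min(p_mean, p_var, p_norm, na.rm = TRUE)),
         n_sim = n_sim),
    class = "npde_result"
  )
}

#' @export
print.npde_result <- function(x, ...) {
  cat("<npde_result>\n")
  cat(sprintf("  n obs %d, n_sim %d\n", nrow(x$table), x$n_sim))
  cat(sprintf("  mean %.3f (p = %.3g), variance %.3f (p = %.3g), normality p = %.3g\n",
              x$mean, x$p_mean, x$variance, x$p_variance, x$p_normality))
  invisible(x)
}
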