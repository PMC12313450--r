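#' Define a sparse neonatal PK study design
#'
#' Emulates the structure of a sparse TDM-based early-onset sepsis PK study:
#' GA-stratum proportions matching the observed cohort (about 20% extremely
#' preterm, 31% very preterm, 18% moderate-late preterm, 32% full-term), a
#' samples-per-subject distribution over 1-4 with median 2, sampling within
#' the first 48 h of life (avoiding the first hour), DPF dosing, and the
#' model's residual-error magnitude for observed values.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param stratum_props Named proportions for the four GA categories, summing
#'   to 1 (names `extremely`, `very`, `moderate_late`, `full_term`).
#' @param samples_probs Probabilities over 1-4 samples per subject.
#' @param sampling_window Length-2 hours within which observation times are
#'   drawn uniformly.
#' @param regimen Regimen name resolved against [regimen_catalog()].
#' @param lloq Lower limit of quantification, mg/L; simulated DV below it are
#'   set to the limit and flagged `BLQ = 1` (not dropped).
#' @param allocation `"deterministic"` (largest-remainder stratum counts;
#'   default, gives exact reproducible counts) or `"multinomial"`.
#' @return List of class `study_design`.
#' @export
study_design <- function(n_subjects = 95,
                         stratum_props = c(extremely = 19 / 95, very = 29 / 95,
                                           moderate_late = 17 / 95,
                                           full_term = 30 / 95),
                         samples_probs = c(0.20, 0.45, 0.25, 0.10),
                         sampling_window = c(1, 48),
                         regimen = "dpf_amoxicillin",
                         lloq = 0.1,
                         allocation = c("deterministic", "multinomial")) {
  allocation <- match.arg(allocation)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (abs(sum(stratum_props) - 1) > 1e-8) {
    stop("stratum proportions must sum to 1", call. = FALSE)
  }
  if (length(samples_probs) != 4 || abs(sum(samples_probs) - 1) > 1e-8) {
    stop("samples_probs must be 4 probabilities summing to 1", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, stratum_props = stratum_props,
         samples_probs = samples_probs, sampling_window = sampling_window,
         regimen = regimen, lloq = lloq, allocation = allocation),
    class = "study_design"
  )
}

# Largest-remainder apportionment of n among proportions p.
.largest_remainder <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# GA whole weeks per stratum (within the 24-42 week study range)
.stratum_weeks <- list(
  extremely = 24:27, very = 28:31, moderate_late = 32:36, full_term = 37:42
)

#' Generate a synthetic sparse neonatal PK study dataset
#'
#' Draws subjects per GA stratum, samples GA-matched birth weights, resolves
#' the design's dosing regimen per subject, simulates true individual
#' concentration profiles (per-dose covariate refresh, log-normal BSV), draws
#' sparse observation times, and produces observed values under the model's
#' combined residual-error model. True random effects and individual
#' parameters are returned for recovery experiments.
#'
#' @param design A [study_design()].
#' @param model A [pk_model].
#' @param ref A [growth_reference()].
#' @param seed Optional seed; the dataset is fully reproducible given it.
#' @return List with `data` (a validated `pk_dataset` with an extra `BLQ`
#'   flag), `truth` (per-subject GA, birth weight, true eta, individual
#'   parameters at time 0), and the design.
#' @export
generate_study <- function(design, model, ref = growth_reference(),
                           seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(model, "pk_model"))
  build <- function() {
    counts <- if (design$allocation == "deterministic") {
      .largest_remainder(design$n_subjects, design$stratum_props)
    } else {
      as.integer(stats::rmultinom(1, design$n_subjects, design$stratum_props))
    }
    names(counts) <- names(design$stratum_props)

    ga <- unlist(lapply(names(counts), function(s) {
      weeks <- .stratum_weeks[[s]]
      sample(weeks, counts[[s]], replace = TRUE)
    }))
    n <- length(ga)
    bw <- vapply(ga, function(w) sample_birth_weight(w, ref, 1), numeric(1))
    etas <- sample_etas(model, n)
    re <- model$residual_error

    rows <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      subject <- list(id = i, GA = ga[i], birth_weight = bw[i])
      sched <- resolve_regimen(subject, design$regimen, window = 48)
      n_samp <- sample(1:4, 1, prob = design$samples_probs)
      obs_t <- sort(stats::runif(n_samp, design$sampling_window[1],
                                 design$sampling_window[2]))
      eta <- if (ncol(etas)) stats::setNames(etas[i, ], colnames(etas)) else NULL
      prof <- simulate_subject(subject, model, sched, times = obs_t, eta = eta)
      ipred <- prof$total_conc
      dv <- ipred * (1 + stats::rnorm(n_samp, 0, re$proportional_sd)) +
        stats::rnorm(n_samp, 0, re$additive_sd)
      blq <- as.integer(dv < design$lloq)
      dv <- pmax(dv, design$lloq)

      dose_rows <- data.frame(
        ID = i, TIME = sched$start_time, EVID = 1, AMT = sched$amount,
        DUR = sched$duration, DV = NA_real_, MDV = 1, BLQ = 0,
        GA = ga[i], BW = bw[i], PNA = sched$start_time / 24
      )
      obs_rows <- data.frame(
        ID = i, TIME = obs_t, EVID = 0, AMT = NA_real_, DUR = NA_real_,
        DV = dv, MDV = 0, BLQ = blq, GA = ga[i], BW = bw[i], PNA = obs_t / 24
      )
      all_rows <- rbind(dose_rows, obs_rows)
      rows[[i]] <- all_rows[order(all_rows$TIME, -all_rows$EVID), ]

      pars <- individual_parameters(subject, model, eta = eta, time = 0)
      truth[[i]] <- data.frame(
        ID = i, GA = ga[i], birth_weight = bw[i],
        as.list(if (is.null(eta)) stats::setNames(numeric(0), character(0))
                else stats::setNames(eta, paste0("eta_", names(eta)))),
        as.list(stats::setNames(
          unlist(pars[model$parameter_names]), model$parameter_names))
      )
    }
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    list(data = validate_pk_dataset(data),
         truth = do.call(rbind, truth),
         design = design)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
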