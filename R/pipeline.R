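# End-to-end runs: population -> regimens -> simulation -> exposure metrics,
# and dataset -> evaluation battery, with CSV tables + a JSON run manifest.

#' Simulate concentration profiles for a whole population under a regimen
#'
#' Shared workhorse of [run_pta()]: resolves the regimen per subject, and
#' simulates every subject on a common grid with per-dose covariate refresh.
#' Passing the same `etas` matrix across calls compares regimens on identical
#' virtual subjects (paired design), which removes between-subject Monte Carlo
#' noise from regimen contrasts.
#'
#' @param population A [generate_population()] result.
#' @param model A [pk_model].
#' @param regimen Regimen name or definition (see [resolve_regimen()]).
#' @param etas Matrix from [sample_etas()] with `nrow(population)` rows.
#' @param window Simulation window, h.
#' @param step Grid step, h.
#' @return List of `concentration_profile`s, one per subject, in population
#'   order.
#' @export
simulate_regimen <- function(population, model, regimen, etas,
                             window = 48, step = 0.05) {
  stopifnot(nrow(etas) == nrow(population))
  if (is.character(regimen)) {
    cat <- regimen_catalog()
    if (is.null(cat[[regimen]])) stop("unknown regimen '", regimen, "'",
                                      call. = FALSE)
    regimen <- cat[[regimen]]
  }
  lapply(seq_len(nrow(population)), function(i) {
    subject <- as.list(population[i, ])
    sched <- resolve_regimen(subject, regimen, window = window)
    eta <- if (ncol(etas)) stats::setNames(etas[i, ], colnames(etas)) else NULL
    simulate_subject(subject, model, sched,
                     times = time_grid(sched, window, step), eta = eta)
  })
}

#' Run the full PTA + toxicity simulation pipeline
#'
#' Executes population generation, regimen resolution, population simulation
#' (between-subject variability only, no residual error: target attainment
#' concerns true concentrations), PTA grids, toxicity summaries, and an
#' optional protein-binding sensitivity sweep, writing tidy CSV tables plus a
#' JSON manifest (seed, config, package version, config hash) sufficient to
#' reproduce the run.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{`model`}{Model name in [model_library()] or a config file path.}
#'     \item{`regimens`}{Character vector of regimen names.}
#'     \item{`population`}{List `ga_min`, `ga_max`, `n_per_week`.}
#'     \item{`mics`, `fractions`, `multipliers`}{PTA grids.}
#'     \item{`bound_fraction`}{Reference protein binding, %.}
#'     \item{`binding_sweep`}{Optional vector of bound fractions.}
#'     \item{`toxicity_thresholds`}{mg/L vector.}
#'     \item{`seed`}{Integer seed.}
#'     \item{`output_dir`}{Directory for outputs (created).}
#'   }
#' @return Invisibly, a list with the PTA tables, toxicity tables, binding
#'   sweep and manifest; files are written under `output_dir`.
#' @export
run_pta <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("model", "regimens", "population", "output_dir")) {
    if (is.null(cfg[[key]])) stop("config missing '", key, "'", call. = FALSE)
  }
  cfg$mics <- cfg$mics %||% c(0.125, 0.25, 1)
  cfg$fractions <- cfg$fractions %||% c(40, 50, 60, 70, 80, 90, 100)
  cfg$multipliers <- cfg$multipliers %||% c(1, 4)
  cfg$bound_fraction <- cfg$bound_fraction %||% 0
  cfg$toxicity_thresholds <- cfg$toxicity_thresholds %||% numeric(0)
  cfg$seed <- cfg$seed %||% 1L

  model <- if (file.exists(cfg$model)) read_model_config(cfg$model)
           else model_library(cfg$model)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  pop <- stage("population", generate_population(
    ga_min = cfg$population$ga_min %||% 24,
    ga_max = cfg$population$ga_max %||% 42,
    n_per_week = cfg$population$n_per_week %||% 500,
    seed = cfg$seed
  ))
  etas <- stage("random effects",
                sample_etas(model, nrow(pop), seed = cfg$seed + 1L))

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  pta_all <- list(); pta_ga_all <- list(); tox_all <- list(); sweep_all <- list()
  for (rg in cfg$regimens) {
    profiles <- stage(paste0("simulate ", rg),
                      simulate_regimen(pop, model, rg, etas))
    g <- stage(paste0("pta ", rg),
               pta_grid(profiles, cfg$mics, cfg$fractions, cfg$multipliers,
                        bound_fraction = cfg$bound_fraction, ga = pop$GA))
    pta_ga_all[[rg]] <- cbind(regimen = rg, drug = model$drug,
                              attr(g, "by_ga"))
    g <- cbind(regimen = rg, drug = model$drug, g)
    pta_all[[rg]] <- g
    for (thr in cfg$toxicity_thresholds) {
      tx <- stage(paste0("toxicity ", rg),
                  toxicity_summary(profiles, thr, pop$GA))
      tox_all[[paste(rg, thr)]] <- cbind(regimen = rg, drug = model$drug, tx)
    }
    if (!is.null(cfg$binding_sweep)) {
      sw <- stage(paste0("binding sweep ", rg),
                  binding_sensitivity(profiles, cfg$mics, cfg$fractions,
                                      cfg$multipliers,
                                      bound_fractions = cfg$binding_sweep,
                                      reference = cfg$bound_fraction))
      sweep_all[[rg]] <- cbind(regimen = rg, drug = model$drug, sw)
    }
  }

  pta_tab <- do.call(rbind, pta_all); rownames(pta_tab) <- NULL
  pta_ga_tab <- do.call(rbind, pta_ga_all); rownames(pta_ga_tab) <- NULL
  tox_tab <- if (length(tox_all)) do.call(rbind, tox_all) else NULL
  if (!is.null(tox_tab)) rownames(tox_tab) <- NULL
  sweep_tab <- if (length(sweep_all)) do.call(rbind, sweep_all) else NULL
  if (!is.null(sweep_tab)) rownames(sweep_tab) <- NULL

  wr <- function(x, f) {
    if (!is.null(x)) utils::write.csv(x, file.path(cfg$output_dir, f),
                                      row.names = FALSE, quote = FALSE)
  }
  wr(pta_tab, "pta.csv")
  wr(pta_ga_tab, "pta_by_ga.csv")
  wr(tox_tab, "toxicity.csv")
  wr(sweep_tab, "binding_sensitivity.csv")

  manifest <- .write_manifest(cfg$output_dir, cfg,
                              n_subjects = nrow(pop),
                              outputs = c("pta.csv", "pta_by_ga.csv",
                                          if (!is.null(tox_tab)) "toxicity.csv",
                                          if (!is.null(sweep_tab)) "binding_sensitivity.csv"))
  invisible(list(pta = pta_tab, pta_by_ga = pta_ga_tab, toxicity = tox_tab,
                 binding = sweep_tab, population = pop, etas = etas,
                 manifest = manifest))
}

#' Run the external model-evaluation battery on a dataset
#'
#' Writes the goodness-of-fit table (DV, PRED, IPRED, residuals), the
#' prediction-error report, the pcVPC table and the NPDE table, plus a JSON
#' manifest.
#'
#' @param config Named list (or YAML path) with `model`, `dataset` (CSV path),
#'   `output_dir`, and optional `n_sim` (default 1000), `bins` (default 4),
#'   `seed`.
#' @return Invisibly, a list with all evaluation objects.
#' @export
run_evaluation <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("model", "dataset", "output_dir")) {
    if (is.null(cfg[[key]])) stop("config missing '", key, "'", call. = FALSE)
  }
  cfg$n_sim <- cfg$n_sim %||% 1000L
  cfg$bins <- cfg$bins %||% 4L
  cfg$seed <- cfg$seed %||% 1L
  model <- if (file.exists(cfg$model)) read_model_config(cfg$model)
           else model_library(cfg$model)
  data <- read_pk_dataset(cfg$dataset)
  if (!any(data$EVID == 0 & data$MDV == 0)) {
    stop("dataset contains no observations; nothing to evaluate", call. = FALSE)
  }

  gof <- individual_predict(data, model)
  pe <- prediction_error_metrics(gof$PRED, gof$DV)
  vpc <- pcvpc(data, model, n_sim = cfg$n_sim, bins = cfg$bins,
               seed = cfg$seed)
  npde_res <- npde(data, model, n_sim = cfg$n_sim, seed = cfg$seed + 1L)

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(gof, file.path(cfg$output_dir, "gof.csv"),
                   row.names = FALSE, quote = FALSE)
  pe_tab <- data.frame(
    metric = c("median_ppe", "median_appe", "nrmse", "p10", "p20", "p30"),
    value = c(pe$median_ppe, pe$median_appe, pe$nrmse, pe$p10, pe$p20, pe$p30)
  )
  utils::write.csv(pe_tab, file.path(cfg$output_dir, "prediction_errors.csv"),
                   row.names = FALSE, quote = FALSE)
  vpc_tab <- merge(vpc$observed, vpc$simulated, by = "bin",
                   suffixes = c("_obs", "_sim"))
  utils::write.csv(vpc_tab, file.path(cfg$output_dir, "pcvpc.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(npde_res$table, file.path(cfg$output_dir, "npde.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- .write_manifest(cfg$output_dir, cfg,
                              n_subjects = length(unique(data$ID)),
                              outputs = c("gof.csv", "prediction_errors.csv",
                                          "pcvpc.csv", "npde.csv"))
  invisible(list(gof = gof, prediction_errors = pe, pcvpc = vpc,
                 npde = npde_res, manifest = manifest))
}

.write_manifest <- function(dir, cfg, n_subjects, outputs) {
  cfg_file <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_file, precision = 15)
  manifest <- list(
    package = "neopkpd",
    version = as.character(utils::packageVersion("neopkpd")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    n_subjects = n_subjects,
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
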