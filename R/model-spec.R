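#' Construct a population PK model specification
#'
#' A model specification bundles the structural model (number of disposition
#' compartments), the population-typical parameter values, the covariate model
#' (allometric scaling, maturation, linear/power effects), log-normal
#' between-subject variability, and the residual-error model. It is the single
#' object the simulation, exposure and evaluation layers consume.
#'
#' Parameters follow the usual clearance/volume parameterisation: `CL` and `V`
#' (central) in L/h and L; two-compartment models add inter-compartmental
#' clearance `Q` (L/h) and peripheral volume `V2` (L).
#'
#' @param drug Drug name (free text, e.g. `"amoxicillin"`).
#' @param n_compartments 1 or 2.
#' @param typical_values Named list/vector of population-typical parameter
#'   values. Must contain `CL`, `V` and, for two-compartment models, `Q`, `V2`.
#'   All strictly positive.
#' @param covariate_effects List of effects created by [covariate_effect()].
#' @param omega Named list/vector of variances (omega-squared, dimensionless)
#'   of the log-normal random effects, one entry per parameter carrying
#'   between-subject variability. Parameters absent from `omega` have none.
#' @param residual_error List with elements `proportional_sd` (fraction) and
#'   `additive_sd` (mg/L); see [residual_error_spec()].
#' @param covariate_ranges Optional named list of length-2 numeric ranges the
#'   source model was developed on; covariate values outside a range trigger a
#'   one-off extrapolation warning but are used as-is (no clamping).
#'
#' @return An object of class `pk_model`.
#' @export
pk_model <- function(drug, n_compartments, typical_values,
                     covariate_effects = list(),
                     omega = list(),
                     residual_error = residual_error_spec(0, 0),
                     covariate_ranges = NULL) {
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% c(1L, 2L)) {
    stop("n_compartments must be 1 or 2", call. = FALSE)
  }
  required <- if (n_compartments == 1L) c("CL", "V") else c("CL", "V", "Q", "V2")
  tv <- as.list(typical_values)
  missing_tv <- setdiff(required, names(tv))
  if (length(missing_tv)) {
    stop("typical_values missing: ", paste(missing_tv, collapse = ", "),
         call. = FALSE)
  }
  tv <- tv[required]
  if (any(vapply(tv, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all typical values must be strictly positive numbers", call. = FALSE)
  }

  om <- as.list(omega)
  if (length(om)) {
    bad <- setdiff(names(om), required)
    if (length(bad)) {
      stop("omega given for undeclared parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(unlist(om) < 0)) stop("omega variances must be >= 0", call. = FALSE)
  }

  for (eff in covariate_effects) {
    if (!inherits(eff, "covariate_effect")) {
      stop("covariate_effects must be built with covariate_effect()", call. = FALSE)
    }
    if (!eff$parameter %in% required) {
      stop("covariate effect targets undeclared parameter '", eff$parameter,
           "'", call. = FALSE)
    }
  }

  structure(
    list(
      drug = drug,
      n_compartments = n_compartments,
      parameter_names = required,
      typical_values = lapply(tv, as.numeric),
      covariate_effects = covariate_effects,
      omega = lapply(om, as.numeric),
      residual_error = residual_error,
      covariate_ranges = covariate_ranges
    ),
    class = "pk_model"
  )
}

#' Define a covariate effect on a PK parameter
#'
#' Supported kinds:
#' \describe{
#'   \item{`allometric_power`}{`(cov / reference)^exponent`, `reference > 0`.
#'     The classic body-size scaling; exponent 0.75 for clearances, 1 for
#'     volumes.}
#'   \item{`sigmoid_maturation`}{Hill function of postmenstrual age,
#'     `PMA^gamma / (pma50^gamma + PMA^gamma)`; bounded in (0, 1), equals 0.5
#'     at `PMA = pma50`. `gamma > 0`, `pma50 > 0` (weeks).}
#'   \item{`linear`}{`1 + slope * cov`; used e.g. for a postnatal-age effect
#'     on clearance.}
#'   \item{`power`}{`(cov / reference)^exponent` with free `reference`
#'     (default 1).}
#' }
#'
#' Recognised covariates are `birth_weight` (kg), `PMA` (weeks) and `PNA`
#' (days); see [individual_parameters()] for how they are resolved over time.
#'
#' @param parameter Target parameter name (e.g. `"CL"`).
#' @param covariate Covariate name.
#' @param kind One of `"allometric_power"`, `"sigmoid_maturation"`, `"linear"`,
#'   `"power"`.
#' @param ... Kind-specific constants: `reference`, `exponent`, `pma50`,
#'   `gamma`, `slope`.
#'
#' @return Object of class `covariate_effect`.
#' @export
covariate_effect <- function(parameter, covariate,
                             kind = c("allometric_power", "sigmoid_maturation",
                                      "linear", "power"),
                             ...) {
  kind <- match.arg(kind)
  const <- list(...)
  if (kind == "allometric_power") {
    if (is.null(const$reference) || const$reference <= 0) {
      stop("allometric_power needs reference > 0", call. = FALSE)
    }
    if (is.null(const$exponent)) stop("allometric_power needs exponent", call. = FALSE)
  } else if (kind == "sigmoid_maturation") {
    if (is.null(const$pma50) || const$pma50 <= 0) {
      stop("sigmoid_maturation needs pma50 > 0", call. = FALSE)
    }
    if (is.null(const$gamma) || const$gamma <= 0) {
      stop("sigmoid_maturation needs gamma > 0", call. = FALSE)
    }
  } else if (kind == "linear") {
    if (is.null(const$slope)) stop("linear effect needs slope", call. = FALSE)
  } else if (kind == "power") {
    if (is.null(const$exponent)) stop("power effect needs exponent", call. = FALSE)
    if (is.null(const$reference)) const$reference <- 1
  }
  structure(
    c(list(parameter = parameter, covariate = covariate, kind = kind), const),
    class = "covariate_effect"
  )
}

#' Residual (unexplained) error model
#'
#' Combined proportional + additive error on observed concentrations:
#' `DV = IPRED * (1 + eps1) + eps2`, `eps1 ~ N(0, proportional_sd^2)`,
#' `eps2 ~ N(0, additive_sd^2)`.
#'
#' @param proportional_sd Proportional error SD (fraction, >= 0).
#' @param additive_sd Additive error SD (mg/L, >= 0).
#' @return Object of class `residual_error_spec`.
#' @export
residual_error_spec <- function(proportional_sd, additive_sd) {
  if (proportional_sd < 0 || additive_sd < 0) {
    stop("residual error SDs must be >= 0", call. = FALSE)
  }
  structure(list(proportional_sd = proportional_sd, additive_sd = additive_sd),
            class = "residual_error_spec")
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("<pk_model> %s, %d-compartment\n", x$drug, x$n_compartments))
  tv <- unlist(x$typical_values)
  cat("  typical values:",
      paste(sprintf("%s=%.4g", names(tv), tv), collapse = ", "), "\n")
  if (length(x$omega)) {
    om <- unlist(x$omega)
    cat("  omega^2:      ",
        paste(sprintf("%s=%.4g", names(om), om), collapse = ", "), "\n")
  }
  cat(sprintf("  covariate effects: %d; residual: prop %.3g, add %.3g mg/L\n",
              length(x$covariate_effects),
              x$residual_error$proportional_sd, x$residual_error$additive_sd))
  invisible(x)
}

# ---- config IO ---------------------------------------------------------------

#' Read / write a model configuration file
#'
#' Model configurations are YAML with keys `drug`, `n_compartments`,
#' `typical_values`, `covariate_effects` (list of maps with `parameter`,
#' `covariate`, `kind` and kind-specific constants), `omega` and
#' `residual_error`. Files written by [write_model_config()] read back into an
#' identical model.
#'
#' @param path File path.
#' @return [read_model_config()] returns a `pk_model`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("model config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  effs <- lapply(cfg$covariate_effects, function(e) {
    do.call(covariate_effect,
            c(list(parameter = e$parameter, covariate = e$covariate,
                   kind = e$kind),
              e[setdiff(names(e), c("parameter", "covariate", "kind"))]))
  })
  re <- cfg$residual_error
  pk_model(
    drug = cfg$drug,
    n_compartments = cfg$n_compartments,
    typical_values = cfg$typical_values,
    covariate_effects = effs,
    omega = if (is.null(cfg$omega)) list() else cfg$omega,
    residual_error = residual_error_spec(
      proportional_sd = if (is.null(re$proportional_sd)) 0 else re$proportional_sd,
      additive_sd = if (is.null(re$additive_sd)) 0 else re$additive_sd
    ),
    covariate_ranges = cfg$covariate_ranges
  )
}

#' @rdname read_model_config
#' @param model A `pk_model`.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "pk_model"))
  effs <- lapply(model$covariate_effects, function(e) {
    unclass(e)
  })
  cfg <- list(
    drug = model$drug,
    n_compartments = model$n_compartments,
    typical_values = model$typical_values,
    covariate_effects = effs,
    omega = model$omega,
    residual_error = unclass(model$residual_error)
  )
  if (!is.null(model$covariate_ranges)) cfg$covariate_ranges <- model$covariate_ranges
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Load one of the model configurations shipped with the package
#'
#' Three configurations ship under `inst/models/`:
#' \describe{
#'   \item{`"demo"`}{A fully synthetic one-compartment model used by the test
#'     suite; depends on no external transcription.}
#'   \item{`"amoxicillin_neonatal_synthetic"`}{One-compartment model with
#'     PMA- and PNA-dependent clearance maturation and allometric birth-weight
#'     scaling — the structure reported for published neonatal amoxicillin
#'     models. Typical values are a synthetic, literature-plausible parameter
#'     set (see the file header), not a transcription of any single published
#'     model.}
#'   \item{`"benzylpenicillin_neonatal_synthetic"`}{Two-compartment model with
#'     PMA-dependent clearance maturation and allometric birth-weight scaling;
#'     likewise a synthetic parameter set.}
#' }
#'
#' @param name Configuration name (file name without extension).
#' @return A `pk_model`.
#' @export
model_library <- function(name) {
  path <- system.file("models", paste0(name, ".yaml"), package = "neopkpd")
  if (!nzchar(path)) {
    avail <- sub("\\.yaml$", "",
                 list.files(system.file("models", package = "neopkpd")))
    stop("unknown model '", name, "'; available: ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  read_model_config(path)
}
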