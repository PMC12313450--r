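#' Load a birth-weight growth reference
#'
#' The reference gives, per whole gestational-age week, the 3rd, 50th and 97th
#' birth-weight percentiles (kg). A log-normal is fitted per week: the median
#' fixes `meanlog`, and `sdlog = (log(p97) - log(p3)) / (2 * qnorm(0.97))`.
#' The table shipped with the package
#' (`extdata/growth_reference_synthetic.csv`) is a synthetic reference
#' approximating the shape of published neonatal birth-weight charts; replace
#' it with an institutional chart via `path` for production use.
#'
#' @param path CSV with columns `ga_week`, `p3_kg`, `p50_kg`, `p97_kg`.
#'   Defaults to the shipped synthetic reference.
#' @return A `growth_reference` data frame with the percentile columns plus the
#'   fitted `meanlog` and `sdlog`.
#' @export
growth_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "growth_reference_synthetic.csv",
                        package = "neopkpd")
  }
  ref <- utils::read.csv(path)
  need <- c("ga_week", "p3_kg", "p50_kg", "p97_kg")
  if (!all(need %in% names(ref))) {
    stop("growth reference must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(ref$p50_kg) <= 0)) {
    stop("median birth weight must be strictly increasing in GA week",
         call. = FALSE)
  }
  if (any(ref$p3_kg <= 0 | ref$p50_kg <= ref$p3_kg | ref$p97_kg <= ref$p50_kg)) {
    stop("growth reference percentiles must satisfy 0 < p3 < p50 < p97",
         call. = FALSE)
  }
  z97 <- stats::qnorm(0.97)
  ref$meanlog <- log(ref$p50_kg)
  ref$sdlog <- (log(ref$p97_kg) - log(ref$p3_kg)) / (2 * z97)
  class(ref) <- c("growth_reference", "data.frame")
  ref
}

#' Sample GA-matched birth weights
#'
#' Draws from the log-normal fitted to the reference percentiles for one whole
#' GA week, truncated to the 0.1st-99.9th percentile envelope (inverse-CDF
#' sampling), so no physiologically implausible extreme weights are produced.
#'
#' @param ga_week Whole gestational-age week (must be in the reference table).
#' @param ref A [growth_reference()].
#' @param n Number of draws.
#' @param seed Optional seed (draws do not disturb the caller's RNG when set).
#' @param trunc_quantiles Length-2 truncation probabilities.
#' @return Numeric vector of birth weights, kg (all > 0).
#' @export
sample_birth_weight <- function(ga_week, ref = growth_reference(), n = 1,
                                seed = NULL,
                                trunc_quantiles = c(0.001, 0.999)) {
  i <- match(ga_week, ref$ga_week)
  if (is.na(i)) {
    stop("GA week ", ga_week, " outside the growth reference (",
         min(ref$ga_week), "-", max(ref$ga_week), ")", call. = FALSE)
  }
  draw <- function() {
    u <- stats::runif(n, trunc_quantiles[1], trunc_quantiles[2])
    stats::qlnorm(u, ref$meanlog[i], ref$sdlog[i])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate the GA-stratified virtual neonatal population
#'
#' One stratum per whole GA week between `ga_min` and `ga_max` (inclusive),
#' with exactly `n_per_week` subjects per stratum and birth weights drawn from
#' the GA-matched distributions of the growth reference. The defaults
#' reproduce the simulation population used throughout the package: 500
#' neonates for each whole GA week from 24 to 42 (N = 9500). Birth weight is
#' the body weight used for per-kg dosing and allometry over the whole 48-h
#' window.
#'
#' @param ga_min,ga_max Whole GA weeks, `ga_min <= ga_max`.
#' @param n_per_week Subjects per stratum (>= 1).
#' @param ref A [growth_reference()].
#' @param seed Optional seed; the population is deterministic given the seed.
#' @return A `virtual_population` data frame with columns `id`, `GA` (weeks),
#'   `birth_weight` (kg).
#' @export
generate_population <- function(ga_min = 24, ga_max = 42, n_per_week = 500,
                                ref = growth_reference(), seed = NULL) {
  if (ga_min != round(ga_min) || ga_max != round(ga_max)) {
    stop("ga_min and ga_max must be whole weeks", call. = FALSE)
  }
  if (ga_min > ga_max) stop("ga_min must be <= ga_max", call. = FALSE)
  if (n_per_week < 1) stop("n_per_week must be >= 1", call. = FALSE)
  weeks <- seq(ga_min, ga_max)
  build <- function() {
    bw <- unlist(lapply(weeks, function(w) sample_birth_weight(w, ref, n_per_week)))
    data.frame(
      id = seq_len(length(weeks) * n_per_week),
      GA = rep(weeks, each = n_per_week),
      birth_weight = bw
    )
  }
  pop <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  class(pop) <- c("virtual_population", "data.frame")
  pop
}

# Table-style GA classification used for toxicity summaries:
# extremely preterm <28, very preterm 28-<32, moderate-late preterm 32-<37,
# full-term >=37 weeks.
#' Classify gestational age into the standard prematurity categories
#'
#' @param ga Gestational age, weeks.
#' @return Ordered factor with levels `extremely preterm`, `very preterm`,
#'   `moderate-late preterm`, `full-term`.
#' @export
ga_category <- function(ga) {
  cut(ga, breaks = c(-Inf, 28, 32, 37, Inf), right = FALSE,
      labels = c("extremely preterm", "very preterm",
                 "moderate-late preterm", "full-term"),
      ordered_result = TRUE)
}
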