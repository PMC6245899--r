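#' Build the grid of evaluator error profiles
#'
#' Cartesian product of systematic-error means (`mu`) and random-error
#' standard deviations (`sigma`). Both axes must contain 0 so the grid
#' includes the perfect evaluator (0, 0) as the basis of comparison; the
#' lists must be strictly increasing.
#'
#' @param mu_values Systematic errors, measurement units.
#' @param sigma_values Random-error standard deviations, measurement units.
#' @return A tibble with columns `mu` and `sigma`, one row per profile.
#' @examples
#' nrow(make_error_grid(seq(0, 0.198, by = 0.033), seq(0, 0.198, by = 0.033)))  # 49
#' @export
make_error_grid <- function(mu_values, sigma_values) {
  check_error_axis(mu_values, "mu_values")
  check_error_axis(sigma_values, "sigma_values")
  tidyr::expand_grid(mu = as.numeric(mu_values), sigma = as.numeric(sigma_values))
}

check_error_axis <- function(x, name) {
  if (!any(abs(x) < 1e-12)) {
    stop("config violation: ", name, " must contain the value 0", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("config violation: ", name, " must be strictly increasing", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("config violation: ", name, " must be nonnegative", call. = FALSE)
  }
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles the (mu, sigma) error grid, the number of Monte-Carlo repetitions
#' per profile, the floor and resolution of the measurement scale, and the
#' master seed that derives every random substream. Defaults reproduce the
#' worked configuration: mu and sigma from 0 to 0.198 s in one-frame
#' (0.033 s) steps — a 7 x 7 grid of 49 profiles — with 100 repetitions.
#'
#' @param mu_values,sigma_values Error axes, see [make_error_grid()].
#' @param reps Repetitions per profile (N), at least 1.
#' @param floor Minimum admissible simulated value.
#' @param resolution Measurement resolution used when computing agreement.
#' @param master_seed Integer master seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(mu_values = seq(0, 0.198, by = 0.033),
                              sigma_values = seq(0, 0.198, by = 0.033),
                              reps = 100, floor = 0.033, resolution = 0.033,
                              master_seed = 1L) {
  check_error_axis(mu_values, "mu_values")
  check_error_axis(sigma_values, "sigma_values")
  stopifnot(reps >= 1, floor > 0, resolution > 0)
  structure(
    list(mu_values = as.numeric(mu_values),
         sigma_values = as.numeric(sigma_values),
         reps = as.integer(reps), floor = floor, resolution = resolution,
         master_seed = as.integer(master_seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> ", length(x$mu_values), " mu x ",
      length(x$sigma_values), " sigma profiles, ", x$reps,
      " reps, floor ", x$floor, ", seed ", x$master_seed, "\n", sep = "")
  invisible(x)
}

#' Simulate one evaluator dataset
#'
#' Adds one fresh Gaussian draw `N(mu, sigma^2)` to every reference
#' measurement. Draws that land at or below zero are set to the floor (the
#' minimum resolvable measurement): negative and zero-duration events are
#' not possible. Simulated values are not re-quantized to the resolution
#' grid; quantization is applied uniformly at agreement-computation time.
#'
#' @param reference A [reference_dataset()] or numeric vector.
#' @param mu,sigma Error-profile parameters (`sigma >= 0`).
#' @param floor Replacement for non-positive draws; defaults to the
#'   reference's floor.
#' @return Numeric vector, same length as the reference.
#' @export
simulate_evaluator <- function(reference, mu, sigma, floor = NULL) {
  stopifnot(sigma >= 0)
  ref <- reference_values(reference)
  floor <- floor %||% reference_floor(reference, default = 0.033)
  raw <- ref + stats::rnorm(length(ref), mean = mu, sd = sigma)
  ifelse(raw <= 0, floor, raw)
}

#' Simulate the evaluator population
#'
#' Generates `reps` independent datasets for every (mu, sigma) profile in
#' the configuration. Each (profile, rep) pair uses its own substream seed
#' derived deterministically from the master seed, so reruns with the same
#' master seed reproduce every value bit-for-bit and profiles are mutually
#' independent.
#'
#' @param reference A [reference_dataset()].
#' @param config A [simulation_config()].
#' @return A tibble with columns `mu`, `sigma`, `rep` and a list-column
#'   `values` holding each simulated measurement sequence.
#' @export
simulate_population <- function(reference, config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- make_error_grid(config$mu_values, config$sigma_values)
  pop <- tidyr::expand_grid(grid, rep = seq_len(config$reps))
  pop$.seed <- substream_seeds(config$master_seed, nrow(pop))
  pop$values <- purrr::pmap(
    list(pop$mu, pop$sigma, pop$.seed),
    function(mu, sigma, seed) {
      set.seed(seed)
      simulate_evaluator(reference, mu, sigma, floor = config$floor)
    }
  )
  pop$.seed <- NULL
  pop
}

# One substream seed per (profile, rep), all derived from the master seed.
substream_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Summarize the simulated population into agreement-error points
#'
#' For every simulated dataset, computes Krippendorff's alpha between the
#' reference and the simulated evaluator (a two-column ratings table, one
#' unit per measurement) and the dataset percent error, then averages both
#' across the `reps` repetitions of each profile: every simulated evaluator
#' with the same (mu, sigma) is exactly as likely to make the same mistakes,
#' so their results are pooled to estimate that profile's average
#' performance. The result is one point per profile.
#'
#' @param population Output of [simulate_population()].
#' @param reference The [reference_dataset()] used to generate it.
#' @param metric Difference function for alpha; ratio for timing data.
#' @param aggregation Error aggregation, see [dataset_percent_error()].
#' @return A tibble of class `agreement_error_points` with columns `mu`,
#'   `sigma`, `mean_alpha`, `mean_percent_error`.
#' @export
summarize_population <- function(population, reference, metric = "ratio",
                                 aggregation = "subset_total") {
  resolution <- reference_resolution(reference, default = NULL)
  ref <- reference_values(reference)
  per_rep <- population
  per_rep$alpha <- purrr::map_dbl(population$values, function(v) {
    krippendorff_alpha(cbind(reference = ref, simulated = v),
                       metric = metric, resolution = resolution)
  })
  per_rep$percent_error <- purrr::map_dbl(population$values, function(v) {
    dataset_percent_error(reference, v, aggregation = aggregation)
  })
  out <- per_rep |>
    dplyr::group_by(.data$mu, .data$sigma) |>
    dplyr::summarise(mean_alpha = mean(.data$alpha),
                     mean_percent_error = mean(.data$percent_error),
                     .groups = "drop") |>
    dplyr::arrange(.data$mu, .data$sigma)
  class(out) <- c("agreement_error_points", class(out))
  out
}

#' Run the simulation pipeline end to end
#'
#' Convenience wrapper: [simulate_population()] then
#' [summarize_population()].
#'
#' @inheritParams simulate_population
#' @inheritParams summarize_population
#' @return A tibble of class `agreement_error_points`.
#' @export
simulate_agreement_error <- function(reference, config = simulation_config(),
                                     metric = "ratio",
                                     aggregation = "subset_total") {
  pop <- simulate_population(reference, config)
  summarize_population(pop, reference, metric = metric, aggregation = aggregation)
}
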