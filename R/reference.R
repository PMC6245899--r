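#' Construct a reference dataset
#'
#' A reference dataset is the "perfect evaluator": an ordered sequence of
#' positive measurements against which simulated and real evaluators are
#' compared. It carries its measurement resolution (the quantization grid,
#' e.g. one video frame), a floor (the minimum admissible value, one
#' resolution unit by default), and a designated error-sensitive subset of
#' events used for worst-case percent-error calculation.
#'
#' @param values Positive measurements (e.g. event durations in seconds),
#'   each an integer multiple of `resolution` and at least `floor`.
#' @param subset Integer indices of the error-sensitive events.
#' @param resolution Quantization step in measurement units.
#' @param floor Minimum admissible value; defaults to one resolution unit.
#' @return A tibble of class `reference_dataset` with columns `value` and
#'   `speed` (logical subset flag) and attributes `resolution` and `floor`.
#' @export
reference_dataset <- function(values, subset, resolution = 0.033,
                              floor = resolution) {
  stopifnot(resolution > 0, floor > 0, length(values) >= 1)
  if (any(values < floor)) stop("reference values below the floor", call. = FALSE)
  off_grid <- abs(values / resolution - round(values / resolution)) > 1e-8
  if (any(off_grid)) {
    stop("reference values must be integer multiples of the resolution", call. = FALSE)
  }
  if (length(subset) == 0 || any(subset < 1L) || any(subset > length(values))) {
    stop("subset indices out of bounds or empty", call. = FALSE)
  }
  out <- tibble::tibble(
    value = as.numeric(values),
    speed = seq_along(values) %in% subset
  )
  attr(out, "resolution") <- resolution
  attr(out, "floor") <- floor
  class(out) <- c("reference_dataset", class(out))
  out
}

#' Generate a synthetic reference dataset
#'
#' Emulates a video-timing reference: `n_events` positive durations on a
#' frame-time grid, of which the first `n_speed_events` form a designated
#' short-duration "speed phase" subset. Because the speed events are short, a
#' small absolute timing error produces a large relative error there, making
#' the subset total the error-sensitive summary. Durations are drawn from
#' log-normal distributions (positive support), quantized to the resolution
#' grid and floored at one resolution unit; the speed subset uses a shorter
#' median than the remaining events.
#'
#' @param n_events Total number of measurements.
#' @param n_speed_events Number of leading events in the speed subset.
#' @param duration_params List with `speed_meanlog`, `speed_sdlog`,
#'   `other_meanlog`, `other_sdlog` (log-normal parameters, seconds scale).
#'   Defaults give median durations of about 0.8 s (speed) and 2.5 s (other)
#'   with moderate dispersion.
#' @param resolution Quantization step (seconds); default one 30 fps frame.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A [reference_dataset()].
#' @examples
#' ref <- generate_reference(seed = 1)
#' nrow(ref)        # 300
#' sum(ref$speed)   # 50
#' @export
generate_reference <- function(n_events = 300, n_speed_events = 50,
                               duration_params = list(), resolution = 0.033,
                               seed = 1L) {
  if (n_speed_events > n_events || n_speed_events < 1) {
    stop("invalid config: n_speed_events must be in [1, n_events]", call. = FALSE)
  }
  p <- utils::modifyList(
    list(speed_meanlog = log(0.8), speed_sdlog = 0.35,
         other_meanlog = log(2.5), other_sdlog = 0.40),
    duration_params
  )
  if (any(!is.finite(unlist(p))) || p$speed_sdlog < 0 || p$other_sdlog < 0) {
    stop("invalid config: duration_params must be finite with nonnegative sdlog",
         call. = FALSE)
  }
  set.seed(seed)
  speed <- stats::rlnorm(n_speed_events, p$speed_meanlog, p$speed_sdlog)
  other <- stats::rlnorm(n_events - n_speed_events, p$other_meanlog, p$other_sdlog)
  vals <- round(c(speed, other) / resolution) * resolution
  vals <- pmax(vals, resolution)
  out <- reference_dataset(vals, subset = seq_len(n_speed_events),
                           resolution = resolution, floor = resolution)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "generator_params") <- p
  out
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat("<reference_dataset> ", nrow(x), " measurements (", sum(x$speed),
      " in the error-sensitive subset), resolution ",
      attr(x, "resolution"), ", floor ", attr(x, "floor"), "\n", sep = "")
  NextMethod()
}

#' Write a reference dataset to CSV with a JSON sidecar
#'
#' The CSV has columns `value` and `subset_flag`; the sidecar
#' (`<path>.json`) records resolution, floor, seed and generator parameters
#' so the dataset is self-describing.
#'
#' @param reference A [reference_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(reference, path) {
  stopifnot(inherits(reference, "reference_dataset"))
  readr::write_csv(
    tibble::tibble(value = reference$value,
                   subset_flag = as.integer(reference$speed)),
    path
  )
  sidecar <- list(
    resolution = attr(reference, "resolution"),
    floor = attr(reference, "floor"),
    seed = attr(reference, "seed"),
    generator_params = attr(reference, "generator_params")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a reference dataset from CSV
#'
#' Reads the `value`/`subset_flag` CSV written by [write_reference_csv()];
#' resolution and floor come from the JSON sidecar when present, else from
#' the arguments.
#'
#' @param path CSV path.
#' @param resolution,floor Fallbacks when no sidecar exists.
#' @return A [reference_dataset()].
#' @export
read_reference_csv <- function(path, resolution = 0.033, floor = resolution) {
  x <- readr::read_csv(path, col_types = "di", progress = FALSE)
  if (!all(c("value", "subset_flag") %in% names(x))) {
    stop("reference CSV must have columns 'value' and 'subset_flag'", call. = FALSE)
  }
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    resolution <- sc$resolution %||% resolution
    floor <- sc$floor %||% floor
  }
  reference_dataset(x$value, subset = which(x$subset_flag == 1),
                    resolution = resolution, floor = floor)
}
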