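#' Absolute percent error against a reference value
#'
#' `|theoretical - experimental| / theoretical * 100`, where `theoretical` is
#' the reference measurement and `experimental` the candidate measurement.
#' Direction-insensitive: only the magnitude of the error matters.
#'
#' @param theoretical Positive reference value(s).
#' @param experimental Candidate value(s).
#' @return Nonnegative percent error, vectorized over inputs.
#' @examples
#' percent_error(10, 9)   # 10
#' percent_error(10, 11)  # 10
#' @export
percent_error <- function(theoretical, experimental) {
  if (any(theoretical <= 0)) {
    stop("invalid reference: theoretical values must be > 0", call. = FALSE)
  }
  abs(theoretical - experimental) / theoretical * 100
}

#' Percent error of a candidate measurement sequence
#'
#' Compares a candidate sequence against the reference dataset. The default
#' `subset_total` aggregation sums both sequences over the error-sensitive
#' subset (e.g. the short-duration speed-phase events, where a small absolute
#' timing error produces a large relative error) and takes the percent error
#' of the two totals — the worst-case-oriented summary used throughout the
#' calibration pipeline. Alternatives are provided for tasks where a
#' different reading of evaluator output is appropriate: `full_total` (totals
#' over all events), `per_item_mean` (mean of per-item percent errors over
#' the subset), and labelled `rmse` / `mae` aggregations over the subset.
#'
#' @param reference A [reference_dataset()] or numeric vector of positive
#'   reference measurements.
#' @param candidate Numeric vector, same length as the reference.
#' @param aggregation Aggregation rule, see Details.
#' @param subset Integer indices of the error-sensitive subset; defaults to
#'   the reference dataset's designated subset.
#' @return A single nonnegative value (percent for the percent-error
#'   aggregations; measurement units for `rmse`/`mae`).
#' @export
dataset_percent_error <- function(reference, candidate,
                                  aggregation = c("subset_total", "per_item_mean",
                                                  "full_total", "rmse", "mae"),
                                  subset = NULL) {
  aggregation <- match.arg(aggregation)
  ref <- reference_values(reference)
  if (is.null(subset)) subset <- reference_subset(reference)
  if (length(candidate) != length(ref)) {
    stop("misaligned datasets: candidate has ", length(candidate),
         " values, reference has ", length(ref), call. = FALSE)
  }
  if (aggregation != "full_total") {
    if (is.null(subset) || length(subset) == 0) {
      stop("no subset defined for aggregation '", aggregation, "'", call. = FALSE)
    }
    if (any(subset < 1L) || any(subset > length(ref))) {
      stop("subset indices out of bounds", call. = FALSE)
    }
  }
  switch(aggregation,
    subset_total = percent_error(sum(ref[subset]), sum(candidate[subset])),
    full_total = percent_error(sum(ref), sum(candidate)),
    per_item_mean = mean(percent_error(ref[subset], candidate[subset])),
    rmse = sqrt(mean((ref[subset] - candidate[subset])^2)),
    mae = mean(abs(ref[subset] - candidate[subset]))
  )
}

# Accessors tolerant of plain numeric vectors in place of a reference_dataset.
reference_values <- function(reference) {
  if (inherits(reference, "reference_dataset")) reference$value else as.numeric(reference)
}

reference_subset <- function(reference) {
  if (inherits(reference, "reference_dataset")) which(reference$speed) else NULL
}

reference_resolution <- function(reference, default = NULL) {
  if (inherits(reference, "reference_dataset")) attr(reference, "resolution") else default
}

reference_floor <- function(reference, default = NULL) {
  if (inherits(reference, "reference_dataset")) attr(reference, "floor") else default
}
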