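#' Extract the worst-case error envelope points
#'
#' The envelope is the upper bound of percent error as a function of
#' agreement. For tasks where error is summarized as a subset total,
#' zero-mean random error cancels in the sum, so the systematic-error-only
#' profiles (`sigma = 0`) trace the worst-case error for any alpha — the
#' default `sigma_zero` rule returns exactly those points. The `binned_max`
#' rule is a generic fallback: it partitions the alpha axis into equal-width
#' bins and keeps the maximum-error point in each nonempty bin.
#'
#' @param points An `agreement_error_points` tibble (columns `mu`, `sigma`,
#'   `mean_alpha`, `mean_percent_error`).
#' @param rule `"sigma_zero"` or `"binned_max"`.
#' @param bins Number of alpha bins for `binned_max`.
#' @return The subset of `points` forming the envelope.
#' @export
extract_envelope <- function(points, rule = c("sigma_zero", "binned_max"),
                             bins = 20) {
  rule <- match.arg(rule)
  stopifnot(nrow(points) > 0)
  if (rule == "sigma_zero") {
    env <- dplyr::filter(points, .data$sigma == 0)
    if (nrow(env) == 0) {
      stop("missing envelope data: no points with sigma = 0", call. = FALSE)
    }
    return(env)
  }
  rng <- range(points$mean_alpha)
  width <- diff(rng)
  if (width == 0) width <- 1
  points |>
    dplyr::mutate(.bin = pmin(bins, 1L + floor((.data$mean_alpha - rng[1]) /
                                                 width * bins))) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::slice_max(.data$mean_percent_error, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".bin")
}

#' Fit a power-law envelope model
#'
#' Least-squares fit of `alpha = a * x^b + c` where `x` is the FRACTIONAL
#' worst-case error (percent error / 100) and `alpha` the agreement. The fit
#' uses Levenberg-Marquardt nonlinear least squares initialized at
#' `a = -0.5, b = 1.5, c = 1` with convergence tolerance 1e-10; `c` may be
#' fixed (typically at 1, perfect agreement at zero error).
#'
#' @param points Envelope points (`agreement_error_points`, or any tibble
#'   with `mean_alpha` and `mean_percent_error`), or a data frame with
#'   columns `x` (fractional error) and `y` (alpha).
#' @param fix_c Optional fixed intercept; when supplied only `a`, `b` are
#'   estimated.
#' @param start Named list of starting values.
#' @return An object of class `envelope_model` with coefficients `a`, `b`,
#'   `c`, the goodness of fit `r_squared`, the x-unit convention, and the
#'   fitting data.
#' @examples
#' x <- seq(0.01, 0.4, by = 0.01)
#' pts <- data.frame(x = x, y = -0.5 * x^1.5 + 1)
#' fit_power_law(pts)
#' @export
fit_power_law <- function(points, fix_c = NULL,
                          start = list(a = -0.5, b = 1.5, c = 1)) {
  if (all(c("x", "y") %in% names(points))) {
    dat <- data.frame(x = points$x, y = points$y)
  } else {
    dat <- data.frame(x = points$mean_percent_error / 100,
                      y = points$mean_alpha)
  }
  n_par <- if (is.null(fix_c)) 3L else 2L
  if (nrow(dat) < n_par) {
    stop("fit failure: need at least ", n_par, " points, got ", nrow(dat),
         call. = FALSE)
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)
  fit <- tryCatch(
    if (is.null(fix_c)) {
      minpack.lm::nlsLM(y ~ a * x^b + c, data = dat,
                        start = start, control = ctrl)
    } else {
      minpack.lm::nlsLM(y ~ a * x^b + fix_c, data = dat,
                        start = start[c("a", "b")], control = ctrl)
    },
    error = function(e) {
      stop("fit failure: power-law fit did not converge (", conditionMessage(e),
           ")", call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  resid <- stats::residuals(fit)
  ss_tot <- sum((dat$y - mean(dat$y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  structure(
    list(a = unname(cf["a"]), b = unname(cf["b"]),
         c = if (is.null(fix_c)) unname(cf["c"]) else fix_c,
         r_squared = r2, x_unit = "fractional_error",
         c_fixed = !is.null(fix_c), data = tibble::as_tibble(dat)),
    class = "envelope_model"
  )
}

#' Construct an envelope model from known coefficients
#'
#' Builds an `envelope_model` directly from coefficients, e.g. a previously
#' fitted or published curve, without refitting.
#'
#' @param a,b,c Power-law coefficients of `alpha = a * x^b + c` with `x` the
#'   fractional error.
#' @param r_squared Optional goodness of fit to record.
#' @return An `envelope_model`.
#' @export
envelope_model <- function(a, b, c = 1, r_squared = NA_real_) {
  stopifnot(b > 0)
  structure(
    list(a = a, b = b, c = c, r_squared = r_squared,
         x_unit = "fractional_error", c_fixed = FALSE, data = NULL),
    class = "envelope_model"
  )
}

#' @export
print.envelope_model <- function(x, digits = 4, ...) {
  cat("<envelope_model> alpha = ", format(round(x$a, digits)), " * x^",
      format(round(x$b, digits)), " + ", format(round(x$c, digits)),
      "   (x = fractional error)\n", sep = "")
  if (!is.na(x$r_squared)) cat("r-squared: ", format(x$r_squared), "\n", sep = "")
  invisible(x)
}

#' Alpha implied by the envelope at a given error level
#'
#' Evaluates the fitted curve `a * x^b + c` at a fractional error `x`.
#'
#' @param model An `envelope_model`.
#' @param error_fraction Nonnegative fractional error (0.12 = 12%).
#' @return The worst-case-consistent alpha at that error level.
#' @export
envelope_alpha <- function(model, error_fraction) {
  stopifnot(inherits(model, "envelope_model"), all(error_fraction >= 0))
  model$a * error_fraction^model$b + model$c
}

#' @export
predict.envelope_model <- function(object, error_fraction, ...) {
  envelope_alpha(object, error_fraction)
}

#' Worst-case error implied by the envelope at a given alpha
#'
#' Algebraic inverse of [envelope_alpha()]:
#' `x = ((alpha - c) / a)^(1/b)`. Round-trips with the forward evaluation.
#'
#' @param model An `envelope_model`.
#' @param alpha Agreement value(s), `alpha <= c`.
#' @return Fractional worst-case error.
#' @export
envelope_error <- function(model, alpha) {
  stopifnot(inherits(model, "envelope_model"))
  ratio <- (alpha - model$c) / model$a
  if (any(alpha > model$c) || any(ratio < 0)) {
    stop("out-of-domain: alpha must satisfy alpha <= c and (alpha - c)/a >= 0",
         call. = FALSE)
  }
  ratio^(1 / model$b)
}

#' Derive an agreement threshold for an error tolerance
#'
#' Converts a maximum tolerable percent error to a fraction, evaluates the
#' envelope there, and rounds the resulting alpha to the reporting precision.
#' Evaluators whose alpha meets the threshold have a model-implied worst-case
#' error no greater than the tolerance.
#'
#' @param model An `envelope_model`.
#' @param max_error_percent Maximum tolerable percent error (e.g. 12).
#' @param digits Rounding precision for the reported threshold.
#' @return A list of class `threshold_result` with `alpha_threshold`,
#'   `max_error_percent` and the `model`.
#' @examples
#' m <- envelope_model(a = -0.637, b = 1.76, c = 1)
#' derive_threshold(m, 12)$alpha_threshold  # 0.985
#' @export
derive_threshold <- function(model, max_error_percent, digits = 3) {
  stopifnot(max_error_percent >= 0)
  alpha <- envelope_alpha(model, max_error_percent / 100)
  structure(
    list(alpha_threshold = round(alpha, digits),
         max_error_percent = max_error_percent, model = model),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> alpha >= ", format(x$alpha_threshold),
      " limits worst-case error to ", format(x$max_error_percent), "%\n",
      sep = "")
  invisible(x)
}

#' Contour grids of alpha and percent error over the (mu, sigma) plane
#'
#' Reshapes the per-profile summary points into two rectangular matrices
#' (rows = sorted mu levels, columns = sorted sigma levels): one of mean
#' alpha, one of mean percent error. These are the data behind the standard
#' contour view showing that agreement degrades with either error type while
#' subset-total percent error responds, on average, only to systematic
#' error.
#'
#' @param points An `agreement_error_points` tibble covering a complete
#'   rectangular (mu, sigma) grid.
#' @return A list with matrices `alpha` and `error`, dimnames = mu/sigma
#'   levels.
#' @export
contour_grids <- function(points) {
  mu_lv <- sort(unique(points$mu))
  sg_lv <- sort(unique(points$sigma))
  if (nrow(points) != length(mu_lv) * length(sg_lv) ||
      nrow(dplyr::distinct(points, .data$mu, .data$sigma)) != nrow(points)) {
    stop("missing cells: points must form a complete rectangular (mu, sigma) grid",
         call. = FALSE)
  }
  shape <- function(col) {
    g <- matrix(NA_real_, length(mu_lv), length(sg_lv),
                dimnames = list(mu = format(mu_lv), sigma = format(sg_lv)))
    g[cbind(match(points$mu, mu_lv), match(points$sigma, sg_lv))] <- points[[col]]
    g
  }
  list(alpha = shape("mean_alpha"), error = shape("mean_percent_error"))
}

#' Assess real evaluators against the reference and a threshold
#'
#' For each evaluator column in a ratings table, computes Krippendorff's
#' alpha against the reference (two-column comparison), the observed percent
#' error, and the model-implied worst-case error at that alpha, then flags
#' pass/fail against the derived agreement threshold.
#'
#' @param reference A [reference_dataset()].
#' @param ratings Data frame of candidate measurement sequences, one column
#'   per evaluator, rows aligned with the reference.
#' @param model An `envelope_model`.
#' @param threshold A `threshold_result` from [derive_threshold()].
#' @param metric Difference function for alpha.
#' @param aggregation Error aggregation, see [dataset_percent_error()].
#' @return A tibble with one row per evaluator: `evaluator`, `alpha`,
#'   `percent_error`, `worst_case_error_percent`, `pass`.
#' @export
assess_evaluators <- function(reference, ratings, model, threshold,
                              metric = "ratio", aggregation = "subset_total") {
  ref <- reference_values(reference)
  ratings <- as.data.frame(ratings)
  if (nrow(ratings) != length(ref)) {
    stop("misaligned datasets: ratings have ", nrow(ratings),
         " rows, reference has ", length(ref), call. = FALSE)
  }
  resolution <- reference_resolution(reference)
  purrr::map_dfr(names(ratings), function(ev) {
    cand <- ratings[[ev]]
    a <- krippendorff_alpha(cbind(reference = ref, candidate = cand),
                            metric = metric, resolution = resolution)
    err <- dataset_percent_error(reference, cand, aggregation = aggregation)
    wc <- if (a > model$c) 0 else 100 * envelope_error(model, a)
    tibble::tibble(
      evaluator = ev, alpha = a, percent_error = err,
      worst_case_error_percent = wc,
      pass = a >= threshold$alpha_threshold
    )
  })
}
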