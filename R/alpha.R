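#' Squared difference functions for Krippendorff's alpha
#'
#' Metric-specific squared difference between two rating values. The ratio
#' metric uses the scale-invariant form \eqn{((x_c - x_k)/(x_c + x_k))^2},
#' appropriate for positive ratio-scale data such as durations; the interval
#' metric uses \eqn{(x_c - x_k)^2}; the nominal metric is a 0/1 disagreement
#' indicator.
#'
#' @param xc,xk Numeric vectors of rating values (recycled to common length).
#' @param metric One of `"ratio"`, `"interval"`, `"nominal"`.
#' @return Numeric vector of nonnegative squared differences.
#' @examples
#' difference_squared(1, 3, "ratio")    # ((1-3)/(1+3))^2 = 0.25
#' difference_squared(1, 3, "nominal")  # 1
#' @export
difference_squared <- function(xc, xk, metric = c("ratio", "interval", "nominal")) {
  metric <- match.arg(metric)
  switch(metric,
    ratio = {
      s <- xc + xk
      if (any(s <= 0, na.rm = TRUE)) {
        stop("ratio metric requires positive values (xc + xk > 0)", call. = FALSE)
      }
      ((xc - xk) / s)^2
    },
    interval = (xc - xk)^2,
    nominal = as.numeric(xc != xk)
  )
}

# Validate a ratings table (units x evaluators) and return a plain numeric
# matrix with NA as the missing marker. Accepts data frames or matrices.
validate_ratings <- function(ratings, metric = "ratio") {
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("a ratings table needs at least 2 evaluators", call. = FALSE)
  if (nrow(m) < 1L) stop("a ratings table needs at least 1 unit", call. = FALSE)
  if (metric == "ratio" && any(m[!is.na(m)] <= 0)) {
    stop("ratio metric requires strictly positive rating values", call. = FALSE)
  }
  m
}

# Snap values to an integer multiple of the measurement resolution so that
# float representations of the same grid point coincide. Returns the values
# unchanged when resolution is NULL. For ratio data (strictly positive
# values) a small positive value must not snap to the inadmissible grid
# point 0, so it rounds up to one resolution unit instead.
quantize_values <- function(x, resolution = NULL, keep_positive = FALSE) {
  if (is.null(resolution)) return(x)
  stopifnot(resolution > 0)
  q <- round(x / resolution) * resolution
  if (keep_positive) q[!is.na(q) & q <= 0 & x > 0] <- resolution
  q
}

#' Build the coincidence table for a ratings table
#'
#' Tabulates, over all units with at least two non-missing values, how often
#' each ordered pair of values was assigned to a common unit by different
#' evaluators. A unit with `m_u` non-missing values contributes weight
#' `1/(m_u - 1)` for each of its `m_u * (m_u - 1)` ordered value pairs, so the
#' table total equals `n`, the number of pairable values.
#'
#' @param ratings Data frame or matrix, rows = units, columns = evaluators,
#'   `NA` = missing.
#' @param resolution Optional measurement resolution; when supplied, values
#'   are snapped to this grid before identifying unique values (recommended
#'   for continuous measurements).
#' @return A list of class `coincidence_table` with elements `values` (sorted
#'   unique values), `o` (symmetric coincidence matrix), `n_c` (value
#'   marginals) and `n` (total pairable values).
#' @examples
#' r <- data.frame(A = c(1, 2), B = c(1, 3))
#' build_coincidence(r)
#' @export
build_coincidence <- function(ratings, resolution = NULL) {
  m <- validate_ratings(ratings, metric = "interval")
  m[] <- quantize_values(m, resolution)

  m_u <- rowSums(!is.na(m))
  keep <- m_u >= 2L
  if (!any(keep)) stop("no pairable data: no unit has 2 or more values", call. = FALSE)
  m <- m[keep, , drop = FALSE]
  m_u <- m_u[keep]

  vals <- sort(unique(as.vector(m[!is.na(m)])))
  nv <- length(vals)
  o <- matrix(0, nv, nv, dimnames = list(vals, vals))
  for (u in seq_len(nrow(m))) {
    row <- m[u, ]
    idx <- match(row[!is.na(row)], vals)
    w <- 1 / (m_u[u] - 1)
    for (a in idx) {
      for (b in idx) o[a, b] <- o[a, b] + w
    }
    # remove the self-pairings counted above (a value paired with itself in
    # the same evaluator slot is not an ordered pair of distinct slots)
    for (a in idx) o[a, a] <- o[a, a] - w
  }
  structure(
    list(values = vals, o = o, n_c = rowSums(o), n = sum(m_u)),
    class = "coincidence_table"
  )
}

#' @export
print.coincidence_table <- function(x, ...) {
  cat("<coincidence_table> ", length(x$values), " unique values, n = ",
      format(x$n), " pairable values\n", sep = "")
  if (length(x$values) <= 12) print(round(x$o, 4))
  invisible(x)
}

# Shared D_o/D_e -> alpha epilogue, handling the all-unanimous 0/0 case.
alpha_from_disagreement <- function(num, den) {
  if (den == 0) {
    if (num != 0) stop("internal error: zero expected disagreement with nonzero observed", call. = FALSE)
    warning("all values identical everywhere: alpha is formally indeterminate, returning 1",
            call. = FALSE)
    return(1)
  }
  1 - num / den
}

#' Krippendorff's alpha via the coincidence matrix
#'
#' Chance-corrected agreement \eqn{\alpha = 1 - D_o / D_e} computed by the
#' coincidence-matrix method:
#' \deqn{\alpha = 1 - (n - 1) \frac{\sum_c \sum_k o_{ck} \delta^2_{ck}}
#'   {\sum_c \sum_k n_c n_k \delta^2_{ck}}}
#' where `o` is the coincidence table, `n_c` its marginals, `n` the number of
#' pairable values and \eqn{\delta^2} the metric difference function.
#' Perfect agreement gives 1; values can be negative under systematic
#' disagreement (no clamping). If every value in the table is identical the
#' index is formally 0/0; this returns 1 with a warning.
#'
#' @inheritParams build_coincidence
#' @param metric Difference function kind; see [difference_squared()].
#' @return A single numeric value \eqn{\le 1}.
#' @examples
#' r <- data.frame(A = c(1, 2, 3, 4), B = c(1, 2, 3, 5))
#' krippendorff_alpha(r, metric = "ratio")
#' @seealso [alpha_pairwise()] for the independent pairwise computation.
#' @export
krippendorff_alpha <- function(ratings, metric = c("ratio", "interval", "nominal"),
                               resolution = NULL) {
  metric <- match.arg(metric)
  m <- validate_ratings(ratings, metric)
  m[] <- quantize_values(m, resolution, keep_positive = metric == "ratio")
  ct <- build_coincidence(m)
  delta <- outer(ct$values, ct$values,
                 function(a, b) difference_squared(a, b, metric))
  num <- (ct$n - 1) * sum(ct$o * delta)
  den <- sum(outer(ct$n_c, ct$n_c) * delta)
  alpha_from_disagreement(num, den)
}

#' Krippendorff's alpha by direct pairwise enumeration
#'
#' Computes the same index as [krippendorff_alpha()] without constructing a
#' coincidence table: observed disagreement averages the squared difference
#' over all within-unit ordered value pairs with `1/(m_u - 1)` weights, and
#' expected disagreement averages over all cross-value ordered pairs. Kept as
#' an independent verification path; the two routes agree to machine
#' precision.
#'
#' @inheritParams krippendorff_alpha
#' @return A single numeric value \eqn{\le 1}.
#' @export
alpha_pairwise <- function(ratings, metric = c("ratio", "interval", "nominal"),
                           resolution = NULL) {
  metric <- match.arg(metric)
  m <- validate_ratings(ratings, metric)
  m[] <- quantize_values(m, resolution, keep_positive = metric == "ratio")

  m_u <- rowSums(!is.na(m))
  keep <- m_u >= 2L
  if (!any(keep)) stop("no pairable data: no unit has 2 or more values", call. = FALSE)
  m <- m[keep, , drop = FALSE]
  m_u <- m_u[keep]
  n <- sum(m_u)

  d_obs <- 0
  for (u in seq_len(nrow(m))) {
    v <- m[u, ]
    v <- v[!is.na(v)]
    # ordered pairs over distinct evaluator slots: all combinations minus
    # self-slot pairings (delta is 0 on the diagonal values anyway, but the
    # diagonal also holds self-slot pairs which must not be counted)
    dd <- outer(v, v, function(a, b) difference_squared(a, b, metric))
    diag(dd) <- 0
    d_obs <- d_obs + sum(dd) / (m_u[u] - 1)
  }
  d_obs <- d_obs / n

  allv <- as.vector(m[!is.na(m)])
  de <- outer(allv, allv, function(a, b) difference_squared(a, b, metric))
  diag(de) <- 0
  d_exp <- sum(de) / (n * (n - 1))
  alpha_from_disagreement(d_obs, d_exp)
}

#' Read a ratings table from CSV
#'
#' Expects a header row of evaluator names, one row per unit, empty cells for
#' missing values, and plain decimal numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble, rows = units, columns = evaluators.
#' @export
read_ratings_csv <- function(path) {
  x <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop("malformed ratings CSV at row ", probs$row[1], ", column ", probs$col[1],
         ": ", probs$expected[1], call. = FALSE)
  }
  x
}
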