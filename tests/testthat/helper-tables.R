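# Random small ratings tables with repeated values (so coincidences occur)
# and optional missing entries; always leaves at least one pairable unit.
random_ratings <- function(n_units, n_evaluators, missing_rate = 0.1,
                           values = seq(0.5, 3, by = 0.5)) {
  m <- matrix(sample(values, n_units * n_evaluators, replace = TRUE),
              nrow = n_units)
  miss <- matrix(stats::runif(length(m)) < missing_rate, nrow = n_units)
  m[miss] <- NA
  if (!any(rowSums(!is.na(m)) >= 2)) m[1, 1:2] <- sample(values, 2)
  m
}

# Krippendorff's published worked example: 12 units, 4 observers.
# Published alpha: nominal 0.743, interval 0.849, ratio 0.797 (frozen below
# at full precision from an independent first-principles computation).
published_example_table <- function() {
  cbind(
    A = c(1, 2, 3, 3, 2, 1, 4, 1, 2, NA, NA, NA),
    B = c(1, 2, 3, 3, 2, 2, 4, 1, 2, 5, NA, 3),
    C = c(NA, 3, 3, 3, 2, 3, 4, 2, 2, 5, 1, NA),
    D = c(1, 2, 3, 3, 2, 4, 4, 1, 2, 5, 1, NA)
  )
}

published_example_alpha <- c(
  nominal = 0.743421052631579,
  interval = 0.849107142857143,
  ratio = 0.797402774711613
)
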