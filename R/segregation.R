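#' Pearson goodness of fit to a Mendelian ratio
#'
#' Tests observed phenotype-class counts against expected proportions given
#' as ratio weights (e.g. `c(3, 1)` for a dominant single-locus F2). Expected
#' counts are `total * weight / sum(weights)`; the statistic is
#' `sum((obs - exp)^2 / exp)` on `k - 1` degrees of freedom, with no
#' continuity correction.
#'
#' @param observed Non-negative integer counts, length >= 2.
#' @param ratio Positive weights, same length. Scaling all weights together
#'   leaves the statistic unchanged.
#' @return Object of class `segregation_result` with `observed`, `expected`,
#'   `chi2`, `df`, `p_value`.
#' @examples
#' chi_square_ratio(c(395, 113), c(3, 1))  # carrier : white F2 counts
#' @export
chi_square_ratio <- function(observed, ratio) {
  observed <- as.numeric(observed)
  ratio <- as.numeric(ratio)
  if (length(observed) < 2L || length(observed) != length(ratio))
    stop("observed and ratio must have the same length >= 2")
  if (any(observed < 0)) stop("negative counts")
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio weights must be positive")
  total <- sum(observed)
  if (total <= 0) stop("total observed count is zero")
  expected <- total * ratio / sum(ratio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(observed = observed, expected = expected,
                 chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Goodness of fit: chi2 = %.4f, df = %d, p = %.4f\n",
              x$chi2, x$df, x$p_value))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

#' One-row TSV export of a segregation test
#'
#' @param x A `segregation_result`.
#' @param file Output path.
#' @export
write_segregation_tsv <- function(x, file) {
  df <- data.frame(observed = paste(x$observed, collapse = ":"),
                   expected = paste(round(x$expected, 2), collapse = ":"),
                   chi2 = x$chi2, df = x$df, p_value = x$p_value)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
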