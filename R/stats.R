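# Two-proportion chi-squared test on a 2x2 contingency table.

#' Two-proportion chi-squared test with continuity correction
#'
#' Tests whether the proportion of signature-positive events differs
#' between two sets, from the 2x2 table (x1, n1-x1; x2, n2-x2). The
#' statistic is the classical 2x2 chi-squared form
#' \deqn{X^2 = N (\max(0, |ad - bc| - cN/2))^2 / (r_1 r_2 c_1 c_2)}
#' with a = x1, b = n1-x1, c-cell = x2, d = n2-x2, row totals r1 = n1,
#' r2 = n2, column totals c1 = x1+x2, c2 = N-c1, and c = 1 when the Yates
#' continuity correction is applied (the default), c = 0 otherwise. The
#' two-sided p-value is the upper tail of the chi-squared distribution
#' with one degree of freedom, computed with
#' \code{pchisq(..., lower.tail = FALSE)} so that extreme values (p down
#' to ~1e-70 and far beyond) retain full relative accuracy.
#'
#' @param x1,n1 Signature-positive count and total in group 1.
#' @param x2,n2 Signature-positive count and total in group 2.
#' @param correct Apply the Yates continuity correction (default TRUE,
#'   matching \code{stats::prop.test}).
#' @return List with \code{statistic}, \code{p.value} and \code{correct}.
#'   When a column marginal is zero (all or no events positive in both
#'   groups combined is fine; zero positives AND zero negatives overall is
#'   degenerate) the p-value is \code{NA} with a warning.
#' @examples
#' proportionChisq(13190, 17090, 11710, 13950)$p.value  # ~5.58e-50
#' @export
proportionChisq <- function(x1, n1, x2, n2, correct = TRUE) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  a <- as.numeric(x1); b <- as.numeric(n1 - x1)
  cc <- as.numeric(x2); d <- as.numeric(n2 - x2)
  N <- a + b + cc + d
  c1 <- a + cc; c2 <- b + d
  if (c1 == 0 || c2 == 0) {
    warning("degenerate 2x2 table (zero column marginal): p undefined")
    return(list(statistic = NA_real_, p.value = NA_real_,
                correct = correct))
  }
  corr <- if (correct) N / 2 else 0
  num <- max(0, abs(a * d - b * cc) - corr)
  stat <- N * num^2 / (as.numeric(n1) * n2 * c1 * c2)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p.value = p, correct = correct)
}

#' Format a p-value in the report display style
#'
#' Scientific notation with three significant digits for p < 0.001, three
#' decimal places otherwise, and \code{"NS"} (not significant) for p at or
#' above \code{alpha}. \code{NA} renders as \code{"NA"}.
#'
#' @param p Numeric p-value(s).
#' @param alpha Significance display threshold (default 0.05).
#' @return Character vector of display labels.
#' @export
formatP <- function(p, alpha = 0.05) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("NA")
    if (pi >= alpha) return("NS")
    if (pi < 0.001) {
      format(signif(pi, 3), scientific = TRUE)
    } else {
      sprintf("%.3f", pi)
    }
  }, character(1))
}
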