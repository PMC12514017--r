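## Elementary statistics applied to demographics and regional counts:
## 2x2 chi-squared (continuity correction caller-controlled), Cohen's d and
## two-sample t from published summaries, tie-corrected Mann-Whitney, and
## Benjamini-Hochberg FDR.

#' 2x2 chi-squared test from counts
#'
#' `chi2 = N (|ad - bc| - c0)^2 / (row1 row2 col1 col2)` with
#' `c0 = min(N/2, |ad - bc|)` under the Yates continuity correction and 0
#' otherwise. The correction is caller-controlled because published 2x2
#' statistics mix both conventions.
#'
#' @param table 2x2 matrix of non-negative counts, or a length-4 vector
#'   `(a, b, c, d)` filled by row.
#' @param continuity Apply the Yates continuity correction.
#' @return A list with `chi2`, `df` (1), and `p`.
#' @export
chi2_2x2 <- function(table, continuity = FALSE) {
  if (is.vector(table) && length(table) == 4)
    table <- matrix(table, 2, 2, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("empty row or column margin")
  det <- abs(a * d - b * c)
  c0 <- if (continuity) min(n / 2, det) else 0
  chi2 <- n * (det - c0)^2 / prod(margins)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cohen's d from group summaries
#'
#' `d = (m1 - m2) / s_pooled` with the pooled SD
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,s1,n1 Mean, SD, and size of group 1.
#' @param m2,s2,n2 Mean, SD, and size of group 2.
#' @return Cohen's d (scalar).
#' @export
cohens_d_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be >= 0")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD")
  (m1 - m2) / sp
}

#' Two-sample t-test from group summaries
#'
#' Pooled-variance t by default (classic df `n1 + n2 - 2`); Welch with
#' Satterthwaite df when `pooled = FALSE`.
#'
#' @inheritParams cohens_d_from_summary
#' @param pooled Use the pooled-variance statistic.
#' @return A list with `t`, `df`, and two-sided `p`.
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 == 0 && s2 == 0) stop("both group SDs are zero")
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) stop("zero pooled variance")
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
}

#' Mann-Whitney U with tie-corrected normal approximation
#'
#' `U` counts pairs where x exceeds y (ties count one half). The Z statistic
#' uses the tie-corrected variance and a 0.5 continuity correction toward
#' the null mean; p is the two-sided normal tail.
#'
#' @param x,y Numeric samples.
#' @return A list with `U`, `Z`, and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  if (U == mu) z <- 0
  list(U = U, Z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with enforced monotonicity (delegates to
#' [stats::p.adjust()] after validating the inputs).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values (`q >= p` elementwise).
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
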