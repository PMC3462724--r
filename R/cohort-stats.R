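# Group-comparison statistics from summary data: Welch two-sample t from
# printed means/SDs/counts and an uncorrected Pearson chi-square for a 2x2
# table. With equal group sizes the Welch standard error coincides with the
# pooled form, so the two conventions agree on balanced designs.

#' Welch two-sample t-test from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param m1,s1,n1 mean, SD and size of group 1
#' @param m2,s2,n2 mean, SD and size of group 2
#' @return list with `t`, `df`, `p`
#' @export
welchTFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (v1 + v2 == 0) stop("both groups have zero variance")
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table, no continuity correction
#'
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` for the table
#' rows (a, b) and (c, d).
#'
#' @param a,b,c,d nonnegative cell counts
#' @return list with `chi2`, `df` (= 1), `p`
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  N <- sum(counts)
  if (N == 0) stop("the table is empty")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("chi-square is undefined with a zero margin")
  chi2 <- N * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Group-comparison report from a summary table
#'
#' Applies [welchTFromSummary()] to each row of a summary table (one
#' variable per row) and returns the table with `t`, `df` and `p` columns
#' appended. Rows with missing second-group summaries (descriptive-only
#' variables) get `NA`.
#'
#' @param summaries data.frame with columns `variable`, `mean1`, `sd1`,
#'   `n1`, `mean2`, `sd2`, `n2`
#' @return the input with `t`, `df`, `p` appended
#' @export
groupComparisonTable <- function(summaries) {
  need <- c("variable", "mean1", "sd1", "n1", "mean2", "sd2", "n2")
  stopifnot(all(need %in% names(summaries)))
  res <- lapply(seq_len(nrow(summaries)), function(r) {
    s <- summaries[r, ]
    if (anyNA(s[c("mean2", "sd2", "n2")]))
      return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    welchTFromSummary(s$mean1, s$sd1, s$n1, s$mean2, s$sd2, s$n2)
  })
  summaries$t <- vapply(res, `[[`, numeric(1), "t")
  summaries$df <- vapply(res, `[[`, numeric(1), "df")
  summaries$p <- vapply(res, `[[`, numeric(1), "p")
  summaries
}
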