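# Small statistics kernel used by the other modules: Welch two-sample t
# test, Wilcoxon rank-sum with midranks (exact enumeration for small
# samples, continuity-corrected normal approximation otherwise), and
# Bonferroni adjustment.  Implemented in-package so the behaviour at the
# module boundary is fully specified; the base-R equivalents serve as
# independent references in the test suite.

pk_test <- function(statistic, p_value, alternative, n1, n2,
                    method = "test") {
  structure(list(statistic = statistic, p_value = p_value,
                 alternative = alternative, n1 = n1, n2 = n2,
                 method = method),
            class = "pk_test")
}

#' @export
print.pk_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (alternative: %s; n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$alternative, x$n1, x$n2))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance (Welch) form with the Welch-Satterthwaite degrees of
#' freedom.  When both samples are constant and equal, the convention
#' statistic 0 / one-sided p 0.5 is returned with a warning.
#'
#' @param x,y Numeric samples (each of length >= 2, finite).
#' @param alternative `"greater"` (mean of `x` greater), `"less"`, or
#'   `"two.sided"`.
#' @return A `pk_test` with `statistic`, `p_value`, `alternative`, `n1`,
#'   `n2` and `df`.
#' @export
t_test_two_sample <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y)) {
      warning("both samples constant and equal; returning p = 0.5 (one-sided)")
      p <- if (alternative == "two.sided") 1 else 0.5
      res <- pk_test(0, p, alternative, n1, n2, "Welch two-sample t-test")
      res$df <- NA_real_
      return(res)
    }
    stop("zero variance in both samples with unequal means")
  }
  se <- sqrt(v1 / n1 + v2 / n2)
  tstat <- (mean(x) - mean(y)) / se
  df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- switch(alternative,
              greater = pt(tstat, df, lower.tail = FALSE),
              less = pt(tstat, df),
              two.sided = 2 * pt(abs(tstat), df, lower.tail = FALSE))
  res <- pk_test(tstat, p, alternative, n1, n2, "Welch two-sample t-test")
  res$df <- df
  res
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties.  Exact p by the null rank-sum distribution when the
#' combined sample size is at most `exact_max_n` and there are no ties;
#' otherwise the normal approximation with continuity correction and tie
#' correction.  The reported statistic is the Mann-Whitney U of `x`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"greater"` (x tends larger), `"less"`, or
#'   `"two.sided"`.
#' @param exact_max_n Combined-size switch between exact and approximate p.
#' @return A `pk_test`; field `exact` says which path was used.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less"),
                              exact_max_n = 40L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  exact <- !has_ties && (n1 + n2) <= exact_max_n
  if (exact) {
    p <- switch(alternative,
                greater = pwilcox(U - 1, n1, n2, lower.tail = FALSE),
                less = pwilcox(U, n1, n2),
                two.sided = {
                  if (U > n1 * n2 / 2) {
                    min(1, 2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE))
                  } else {
                    min(1, 2 * pwilcox(U, n1, n2))
                  }
                })
  } else {
    z <- U - n1 * n2 / 2
    correction <- switch(alternative, two.sided = sign(z) * 0.5,
                         greater = 0.5, less = -0.5)
    sigma <- sqrt((n1 * n2 / 12) *
                    ((n1 + n2 + 1) -
                       sum(ties^3 - ties) /
                         ((n1 + n2) * (n1 + n2 - 1))))
    zstat <- (z - correction) / sigma
    p <- switch(alternative,
                greater = pnorm(zstat, lower.tail = FALSE),
                less = pnorm(zstat),
                two.sided = 2 * min(pnorm(zstat),
                                    pnorm(zstat, lower.tail = FALSE)))
    p <- min(1, p)
  }
  res <- pk_test(U, p, alternative, n1, n2, "Wilcoxon rank-sum test")
  res$exact <- exact
  res
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param m Number of tests (defaults to `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p values must be in [0, 1]")
  pmin(1, p * m)
}
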