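#' Specify the test statistic behind a P-value
#'
#' A `test_spec` describes the sampling family of the statistic a P-value was
#' derived from, together with the degrees of freedom and the effective sample
#' size `N` that scales a standardized effect size into a noncentrality
#' parameter (`gamma = sqrt(N) * delta` for normal/t statistics,
#' `gamma = N * delta^2` for chi-square/F statistics).
#'
#' For a two-group comparison with group sizes `n1` and `n2`, the effective
#' sample size is half the harmonic mean, `N = 1/(1/n1 + 1/n2)`, and the
#' default error degrees of freedom are `n1 + n2 - 2`.
#'
#' @param family statistic family: `"normal"`, `"student_t"`, `"chi_square"`
#'   or `"f"`.
#' @param df1 numerator (or only) degrees of freedom; required for
#'   `chi_square` and `f` (default 1 for `f` when group sizes are given).
#' @param df2 denominator/error degrees of freedom; required for `student_t`
#'   and `f` unless derivable as `n1 + n2 - 2`.
#' @param n1,n2 per-group sample sizes (optional).
#' @param effective_n effective sample size `N`; computed from `n1`, `n2` when
#'   they are given, otherwise supplied directly (default 1).
#' @return an object of class `"test_spec"`.
#' @examples
#' test_spec("normal")
#' test_spec("f", n1 = 50, n2 = 50)   # df1 = 1, df2 = 98, N = 25
#' @export
test_spec <- function(family = c("normal", "student_t", "chi_square", "f"),
                      df1 = NULL, df2 = NULL, n1 = NULL, n2 = NULL,
                      effective_n = NULL) {
  family <- match.arg(family)
  if (!is.null(n1) || !is.null(n2)) {
    if (is.null(n1) || is.null(n2))
      stop("supply both 'n1' and 'n2', or neither")
    stopifnot(n1 > 0, n2 > 0)
    n_eff <- effective_sample_size(n1, n2)
    if (!is.null(effective_n) && abs(effective_n - n_eff) > 1e-8 * n_eff)
      stop("'effective_n' inconsistent with n1, n2")
    effective_n <- n_eff
    if (is.null(df2)) df2 <- n1 + n2 - 2
    if (is.null(df1) && family == "f") df1 <- 1
  }
  if (is.null(effective_n)) effective_n <- 1
  stopifnot(effective_n > 0)
  if (family == "f" && (is.null(df1) || is.null(df2)))
    stop("family 'f' requires df1 and df2 (or n1, n2)")
  if (family == "chi_square" && is.null(df1))
    stop("family 'chi_square' requires df1")
  if (family == "student_t" && is.null(df2))
    stop("family 'student_t' requires df2 (or n1, n2)")
  structure(list(family = family, df1 = df1, df2 = df2,
                 n1 = n1, n2 = n2, effective_n = effective_n),
            class = "test_spec")
}

#' Effective sample size of a two-group design
#'
#' Half the harmonic mean of the group sizes, `N = 1/(1/n1 + 1/n2)`.
#'
#' @param n1,n2 positive group sizes.
#' @return the effective sample size `N`.
#' @examples
#' effective_sample_size(2787, 2635)
#' @export
effective_sample_size <- function(n1, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0))
  1 / (1 / n1 + 1 / n2)
}

#' @export
print.test_spec <- function(x, ...) {
  cat("Test statistic: ", x$family, sep = "")
  if (!is.null(x$df1)) cat(", df1 =", x$df1)
  if (!is.null(x$df2)) cat(", df2 =", x$df2)
  cat(", effective N =", format(x$effective_n), "\n")
  invisible(x)
}

# -- sidedness conventions ---------------------------------------------------

.sided_modes <- c("one_sided_upper", "two_sided_positive_root",
                  "two_sided_negative_root")

# accepts the canonical names plus the CLI shorthands one/two-pos/two-neg
match_sided <- function(conv) {
  conv <- switch(conv,
                 "one" = "one_sided_upper",
                 "two-pos" = "two_sided_positive_root",
                 "two-neg" = "two_sided_negative_root",
                 conv)
  match.arg(conv, .sided_modes)
}

is_signed_family <- function(spec) spec$family %in% c("normal", "student_t")

check_convention <- function(spec, conv) {
  if (!is_signed_family(spec) && conv != "one_sided_upper")
    stop("two-sided conventions are undefined for nonnegative (",
         spec$family, ") statistics; use the omnibus upper tail")
  conv
}

# distribution functions of the family; tail computations go through
# lower.tail to keep precision far out in the tails, and the central
# algorithms are used whenever no noncentrality is requested (the noncentral
# routines are slower and carry their own precision limits)
fam_cdf <- function(x, spec, ncp = 0, lower.tail = TRUE) {
  if (all(ncp == 0))
    return(switch(spec$family,
           normal     = stats::pnorm(x, lower.tail = lower.tail),
           student_t  = stats::pt(x, df = spec$df2, lower.tail = lower.tail),
           chi_square = stats::pchisq(x, df = spec$df1,
                                      lower.tail = lower.tail),
           f          = stats::pf(x, df1 = spec$df1, df2 = spec$df2,
                                  lower.tail = lower.tail)))
  switch(spec$family,
         normal     = stats::pnorm(x, mean = ncp, lower.tail = lower.tail),
         student_t  = stats::pt(x, df = spec$df2, ncp = ncp,
                                lower.tail = lower.tail),
         chi_square = stats::pchisq(x, df = spec$df1, ncp = ncp,
                                    lower.tail = lower.tail),
         f          = stats::pf(x, df1 = spec$df1, df2 = spec$df2, ncp = ncp,
                                lower.tail = lower.tail))
}

fam_density <- function(x, spec, ncp = 0, log = FALSE) {
  if (all(ncp == 0))
    return(switch(spec$family,
           normal     = stats::dnorm(x, log = log),
           student_t  = stats::dt(x, df = spec$df2, log = log),
           chi_square = stats::dchisq(x, df = spec$df1, log = log),
           f          = stats::df(x, df1 = spec$df1, df2 = spec$df2,
                                  log = log)))
  switch(spec$family,
         normal     = stats::dnorm(x, mean = ncp, log = log),
         student_t  = stats::dt(x, df = spec$df2, ncp = ncp, log = log),
         chi_square = stats::dchisq(x, df = spec$df1, ncp = ncp, log = log),
         f          = stats::df(x, df1 = spec$df1, df2 = spec$df2,
                                ncp = ncp, log = log))
}

fam_quantile <- function(p, spec, ncp = 0, lower.tail = TRUE) {
  if (all(ncp == 0))
    return(switch(spec$family,
           normal     = stats::qnorm(p, lower.tail = lower.tail),
           student_t  = stats::qt(p, df = spec$df2, lower.tail = lower.tail),
           chi_square = stats::qchisq(p, df = spec$df1,
                                      lower.tail = lower.tail),
           f          = stats::qf(p, df1 = spec$df1, df2 = spec$df2,
                                  lower.tail = lower.tail)))
  switch(spec$family,
         normal     = stats::qnorm(p, mean = ncp, lower.tail = lower.tail),
         student_t  = stats::qt(p, df = spec$df2, ncp = ncp,
                                lower.tail = lower.tail),
         chi_square = stats::qchisq(p, df = spec$df1, ncp = ncp,
                                    lower.tail = lower.tail),
         f          = stats::qf(p, df1 = spec$df1, df2 = spec$df2, ncp = ncp,
                                lower.tail = lower.tail))
}

fam_support_min <- function(spec) if (is_signed_family(spec)) -Inf else 0

#' Convert a P-value to the test-statistic value
#'
#' Inverts the tail-probability map of the family's central (null)
#' distribution under an explicit sidedness convention. For the signed
#' families (normal, Student t) a two-sided P-value has two roots; both are
#' available explicitly. Chi-square and F statistics admit only the omnibus
#' upper-tail convention.
#'
#' P-values below `1e-300` are clamped to `1e-300` with a warning rather than
#' producing infinite statistics.
#'
#' @param p P-value(s) in (0, 1).
#' @param spec a [test_spec()].
#' @param sided `"one_sided_upper"` (`P = 1 - F(x)`),
#'   `"two_sided_positive_root"` (`x = F^{-1}(1 - P/2) >= 0`) or
#'   `"two_sided_negative_root"` (`x = F^{-1}(P/2) <= 0`). The shorthand
#'   values `"one"`, `"two-pos"`, `"two-neg"` are also accepted.
#' @return statistic value(s).
#' @examples
#' p_to_stat(0.05, test_spec("normal"), "two_sided_positive_root")  # 1.96
#' @export
p_to_stat <- function(p, spec = test_spec("normal"), sided = "one_sided_upper") {
  sided <- check_convention(spec, match_sided(sided))
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)")
  if (any(p < 1e-300)) {
    warning("P-values below 1e-300 clamped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  switch(sided,
         one_sided_upper         = fam_quantile(p, spec, lower.tail = FALSE),
         two_sided_positive_root = fam_quantile(p / 2, spec,
                                                lower.tail = FALSE),
         two_sided_negative_root = fam_quantile(p / 2, spec))
}

#' Convert a test-statistic value to a P-value
#'
#' Tail probability of the family's central distribution under the stated
#' convention; the inverse of [p_to_stat()].
#'
#' @inheritParams p_to_stat
#' @param x statistic value(s) in the family's support.
#' @return P-value(s) in (0, 1).
#' @export
stat_to_p <- function(x, spec = test_spec("normal"), sided = "one_sided_upper") {
  sided <- check_convention(spec, match_sided(sided))
  if (any(x < fam_support_min(spec)))
    stop("statistic outside the support of the ", spec$family, " family")
  switch(sided,
         one_sided_upper         = fam_cdf(x, spec, lower.tail = FALSE),
         two_sided_positive_root = 2 * fam_cdf(x, spec, lower.tail = FALSE),
         two_sided_negative_root = 2 * fam_cdf(x, spec))
}

#' Shift -log10 P-value bounds from the two-sided to the one-sided scale
#'
#' A one-sided P-value is half the two-sided one, so on the `-log10(P)` scale
#' both interval bounds decrease by `log10(2)`.
#'
#' @param bounds numeric vector (typically length 2) of nonnegative
#'   `-log10(P)` values.
#' @return the shifted bounds, order preserved.
#' @examples
#' shift_log10_two_to_one_sided(c(1, 5))
#' @export
shift_log10_two_to_one_sided <- function(bounds) {
  stopifnot(is.numeric(bounds), all(is.finite(bounds)), all(bounds >= 0))
  bounds - log10(2)
}
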