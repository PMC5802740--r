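#' Frequency context for odds-ratio effect-size conversion
#'
#' Describes the 2x2 design behind an odds ratio: the outcome frequencies
#' `p1`, `p2` in the exposed/unexposed (or case-defining) groups, their
#' pooled frequency, and the proportion of cases `v` in the sample. When only
#' `pooled_p` and `v` are given, the group frequencies consistent with a
#' particular odds ratio are solved for on demand.
#'
#' @param pooled_p pooled outcome frequency (default 0.5, the balanced
#'   design at which the standardized effect attains its bound).
#' @param v proportion of cases (default 0.5).
#' @param p1,p2 optional group frequencies; when given, `pooled_p` is
#'   recomputed as `v*p1 + (1-v)*p2`.
#' @return an object of class `"or_context"`.
#' @export
or_context <- function(pooled_p = 0.5, v = 0.5, p1 = NULL, p2 = NULL) {
  stopifnot(v > 0, v < 1)
  if (!is.null(p1) || !is.null(p2)) {
    if (is.null(p1) || is.null(p2)) stop("supply both 'p1' and 'p2'")
    if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
      stop("group frequencies must lie strictly in (0, 1)")
    pooled_p <- v * p1 + (1 - v) * p2
  }
  stopifnot(pooled_p > 0, pooled_p < 1)
  structure(list(p1 = p1, p2 = p2, pooled_p = pooled_p, v = v),
            class = "or_context")
}

# solve the group frequencies consistent with (OR, pooled_p, v)
solve_freqs <- function(or_value, ctx) {
  if (!is.null(ctx$p1)) return(c(ctx$p1, ctx$p2))
  pt <- ctx$pooled_p; v <- ctx$v
  f <- function(p1) {
    p2 <- (pt - v * p1) / (1 - v)
    log(p1 / (1 - p1)) - log(p2 / (1 - p2)) - log(or_value)
  }
  lo <- max(1e-12, (pt - (1 - v)) / v + 1e-12)
  hi <- min(1 - 1e-12, pt / v - 1e-12)
  p1 <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  c(p1, (pt - v * p1) / (1 - v))
}

#' Standardized effect size of an odds ratio
#'
#' Converts an odds ratio to the standardized effect
#' `delta = (p1 - p2)/sd`, i.e. the point-biserial correlation of a binary
#' outcome with a binary predictor. The `"exact"` form is
#' `log(OR) / sqrt(1/v * 1/(p1(1-p1)) + 1/(1-v) * 1/(p2(1-p2)))` evaluated at
#' the group frequencies consistent with the context; the `"pooled"`
#' approximation is `log(OR) * sqrt(ptilde(1-ptilde) v(1-v))`.
#'
#' @param or_value positive odds ratio(s); `delta = 0` iff `or_value = 1`.
#' @param ctx an [or_context()].
#' @param method `"exact"` or `"pooled"`.
#' @return standardized effect size(s).
#' @examples
#' delta_from_or(1.2)                      # exact, balanced context
#' delta_from_or(1.2, method = "pooled")   # log(1.2)/4
#' @export
delta_from_or <- function(or_value, ctx = or_context(),
                          method = c("exact", "pooled")) {
  method <- match.arg(method)
  stopifnot(all(or_value > 0), inherits(ctx, "or_context"))
  if (method == "pooled") {
    pt <- ctx$pooled_p
    return(log(or_value) * sqrt(pt * (1 - pt) * ctx$v * (1 - ctx$v)))
  }
  vapply(or_value, function(orv) {
    if (orv == 1) return(0)
    pq <- solve_freqs(orv, ctx)
    p1 <- pq[1]; p2 <- pq[2]
    log(orv) / sqrt(1 / ctx$v / (p1 * (1 - p1)) +
                    1 / (1 - ctx$v) / (p2 * (1 - p2)))
  }, numeric(1))
}

#' Largest standardized effect size attainable for a given odds ratio
#'
#' Closed-form bound over all 2x2 designs:
#' `delta_max(OR) = ln(OR) / (2 * sqrt(2 + (1 + OR)/sqrt(OR)))`.
#' It is antisymmetric under `OR -> 1/OR`, rises to a single maximum near
#' `OR = 121.35` (where it equals the Laplace limit constant 0.662743...)
#' and falls thereafter. `delta_max(4)` is about 1/3 and `delta_max(10)`
#' about 1/2, so standardized effects of realistic odds ratios are small.
#'
#' @param or_value positive odds ratio(s).
#' @return the bound(s) on `delta`.
#' @examples
#' delta_max(c(4, 10))
#' @export
delta_max <- function(or_value) {
  stopifnot(all(or_value > 0))
  log(or_value) / (2 * sqrt(2 + (1 + or_value) / sqrt(or_value)))
}

#' Global maximum of the odds-ratio effect-size bound
#'
#' One-dimensional maximization of [delta_max()] over `OR in (1, Inf)`
#' (performed on the log-OR scale). The maximum sits near `OR = 121.35`,
#' where `delta_max` equals the Laplace limit constant `0.662743...` -- the
#' supremum of the standardized effect size of any odds ratio.
#'
#' @return a list with `or_at_max` and `delta_at_max`.
#' @examples
#' global_delta_max()
#' @export
global_delta_max <- function() {
  opt <- stats::optimize(function(x) delta_max(exp(x)),
                         interval = c(0, log(1e6)),
                         maximum = TRUE, tol = 1e-12)
  list(or_at_max = exp(opt$maximum), delta_at_max = opt$objective)
}

#' Largest conjugate prior variance consistent with an odds-ratio tail bound
#'
#' If odds ratios at least `or_value` occur with probability `beta` under a
#' zero-mean normal prior on the standardized effect, the prior variance can
#' be at most `s0^2 = [delta_max(OR) / qnorm(1 - beta)]^2`. E.g. "OR >= 3 is
#' a 1% event" caps `s0^2` at about 0.013.
#'
#' @param or_value odds ratio threshold (> 1).
#' @param beta tail probability in (0, 0.5).
#' @return the maximal prior variance `s0^2`.
#' @examples
#' prior_variance_from_or_tail(3, 0.01)
#' @export
prior_variance_from_or_tail <- function(or_value, beta) {
  stopifnot(all(or_value >= 1))
  if (any(beta <= 0 | beta >= 0.5))
    stop("'beta' must lie in (0, 0.5)")
  (delta_max(or_value) / stats::qnorm(1 - beta))^2
}

#' Tabulated odds-ratio distribution of associated loci
#'
#' The format in which genome-wide effect-size distributions are reported:
#' counts `L_i` of loci at odds ratio `OR_i`, out of `M` tests in total.
#' Mass not covered by the rows belongs to non-associated loci at a null
#' odds ratio (default 1.005, split evenly with its inverse for the negative
#' part of the log-OR distribution).
#'
#' @param or positive odds ratios.
#' @param count nonnegative locus counts (sum at most `M`).
#' @param M total number of independent tests.
#' @param null_or odds ratio assigned to non-associated loci.
#' @return an object of class `"or_table"`.
#' @examples
#' or_table(c(1.2, 1.5), c(8, 2), M = 1000)
#' @export
or_table <- function(or, count, M, null_or = 1.005) {
  stopifnot(all(or > 0), all(count >= 0), length(or) == length(count),
            M > 0, null_or > 0)
  if (sum(count) > M)
    stop("locus counts exceed the total number of tests M")
  structure(list(or = as.numeric(or), count = as.numeric(count),
                 M = M, null_or = null_or),
            class = "or_table")
}

#' @export
print.or_table <- function(x, ...) {
  cat("Odds-ratio effect-size table:", length(x$or), "rows,",
      format(sum(x$count)), "associated loci of M =", format(x$M), "\n")
  invisible(x)
}

# weights and odds ratios including the even null split; zero-weight
# components are dropped
or_table_components <- function(table) {
  w <- table$count / table$M
  w_null <- 1 - sum(w)
  or <- c(table$or, table$null_or, 1 / table$null_or)
  w <- c(w, w_null / 2, w_null / 2)
  keep <- w > 0
  list(or = or[keep], w = w[keep])
}

#' Mixture prior from a tabulated odds-ratio distribution
#'
#' Converts an [or_table()] into a [tabulated_prior()] on the standardized
#' effect scale: row weights are `L_i / M`, the uncovered mass is split
#' evenly between the null odds ratio and its inverse, and odds ratios are
#' mapped to `delta` via [delta_from_or()] in the given frequency context.
#' Components with equal `delta` are merged.
#'
#' @param table an [or_table()].
#' @param ctx an [or_context()].
#' @param method conversion method passed to [delta_from_or()].
#' @return a `"tabulated_prior"` on the `delta` scale.
#' @export
tabulated_prior_from_or_table <- function(table, ctx = or_context(),
                                          method = "exact") {
  stopifnot(inherits(table, "or_table"))
  comp <- or_table_components(table)
  d <- delta_from_or(comp$or, ctx, method = method)
  o <- order(d)
  d <- d[o]; w <- comp$w[o]
  # merge numerically identical effect values
  grp <- cumsum(c(TRUE, diff(d) > 1e-14))
  wsum <- as.numeric(tapply(w, grp, sum))
  vals <- as.numeric(tapply(d * w, grp, sum)) / wsum
  tabulated_prior(vals, wsum)
}

#' Prior variance of the standardized effect from an odds-ratio table
#'
#' Weighted-variance estimator on the tabulated distribution: with
#' `gamma_i = sqrt(N) * delta_i` and weights `w_i = L_i / M` (null mass split
#' between the null odds ratio and its inverse),
#' `s0^2 = sum_i w_i (gamma_i / sqrt(2N) - m_w)^2` where
#' `m_w = sum_i w_i gamma_i / sqrt(2N)`.
#'
#' @param table an [or_table()].
#' @param effective_n effective sample size `N`.
#' @param ctx an [or_context()].
#' @param method conversion method passed to [delta_from_or()].
#' @return the estimated prior variance `s0^2`.
#' @export
estimate_prior_variance_from_counts <- function(table, effective_n,
                                                ctx = or_context(),
                                                method = "exact") {
  stopifnot(inherits(table, "or_table"), effective_n > 0)
  comp <- or_table_components(table)
  gam <- sqrt(effective_n) * delta_from_or(comp$or, ctx, method = method)
  x <- gam / sqrt(2 * effective_n)
  m_w <- sum(comp$w * x)
  sum(comp$w * (x - m_w)^2)
}

#' Popoviciu's variance bound for a bounded effect-size distribution
#'
#' Any distribution supported on `[lower, upper]` has variance at most
#' `(upper - lower)^2 / 4`. Applied to standardized odds-ratio effects,
#' which live in `(-0.663, 0.663)`, this caps `s0^2` at about 0.44 even for
#' priors concentrated at the bounds.
#'
#' @param lower,upper support endpoints (`lower <= upper`).
#' @return the variance bound.
#' @examples
#' popoviciu_bound(-0.662743, 0.662743)
#' @export
popoviciu_bound <- function(lower, upper) {
  stopifnot(all(lower <= upper))
  (upper - lower)^2 / 4
}
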