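#' Conjugate normal prior on the standardized effect size
#'
#' The conjugate model for a Z-statistic `Z ~ N(mu, 1)` places a normal prior
#' on its mean, `mu ~ N(m0, sigma0^2)` with `sigma0^2 = N * s0^2`, where
#' `s0^2` is the prior variance of the standardized effect size `delta` and
#' `N` the effective sample size. `sigma0_sq = 0` encodes a point mass at
#' `m0`; `sigma0_sq = Inf` recovers the flat prior implicit in the classical
#' P-interval.
#'
#' @param m0 prior mean on the statistic scale (default 0).
#' @param s0_sq prior variance of the standardized effect size.
#' @param effective_n effective sample size `N` (default 1).
#' @param sigma0_sq prior variance on the statistic scale; either supply this
#'   directly or `s0_sq` (with `effective_n`). Supplying both inconsistently
#'   is an error.
#' @return an object of class `"conjugate_prior"`.
#' @examples
#' conjugate_prior(s0_sq = 1e-5, effective_n = 1354.67)
#' conjugate_prior(sigma0_sq = 0.5)
#' @export
conjugate_prior <- function(m0 = 0, s0_sq = NULL, effective_n = 1,
                            sigma0_sq = NULL) {
  stopifnot(is.numeric(m0), length(m0) == 1, is.finite(m0),
            effective_n > 0)
  if (is.null(s0_sq) && is.null(sigma0_sq))
    stop("supply 's0_sq' or 'sigma0_sq'")
  if (!is.null(s0_sq)) {
    stopifnot(s0_sq >= 0)
    derived <- effective_n * s0_sq
    if (!is.null(sigma0_sq) && !isTRUE(all.equal(sigma0_sq, derived)))
      stop("'sigma0_sq' inconsistent with effective_n * s0_sq")
    sigma0_sq <- derived
  } else {
    stopifnot(sigma0_sq >= 0)
    s0_sq <- sigma0_sq / effective_n
  }
  structure(list(m0 = m0, s0_sq = s0_sq, effective_n = effective_n,
                 sigma0_sq = sigma0_sq),
            class = "conjugate_prior")
}

#' @export
print.conjugate_prior <- function(x, ...) {
  cat("Conjugate normal prior: m0 =", format(x$m0),
      ", s0^2 =", format(x$s0_sq),
      ", sigma0^2 = N*s0^2 =", format(x$sigma0_sq), "\n")
  invisible(x)
}

#' Posterior for the mean of a Z-statistic under the conjugate prior
#'
#' Shrinkage update: the posterior of the statistic's mean is normal with
#' mean `theta = z_obt * sigma0^2/(1 + sigma0^2) + m0/(1 + sigma0^2)` and
#' variance `s^2 = sigma0^2/(1 + sigma0^2)`. As `sigma0^2 -> Inf` this tends
#' to `theta = z_obt`, `s^2 = 1` (no shrinkage); `sigma0^2 = 0` collapses to
#' the point mass at `m0`.
#'
#' @param z_obt observed Z-statistic.
#' @param prior a [conjugate_prior()].
#' @return an object of class `"conjugate_posterior"` with elements `theta`
#'   and `s_sq`.
#' @examples
#' conjugate_posterior(2, conjugate_prior(sigma0_sq = 1))  # theta 1, s^2 0.5
#' @export
conjugate_posterior <- function(z_obt, prior) {
  stopifnot(inherits(prior, "conjugate_prior"), is.finite(z_obt))
  v <- prior$sigma0_sq
  if (is.infinite(v)) {
    w <- 1
  } else {
    w <- v / (1 + v)
  }
  structure(list(theta = z_obt * w + prior$m0 * (1 - w), s_sq = w,
                 prior = prior, z_obt = z_obt),
            class = "conjugate_posterior")
}

#' @export
print.conjugate_posterior <- function(x, ...) {
  cat("Posterior of the statistic mean: N(theta = ", format(x$theta),
      ", s^2 = ", format(x$s_sq), ")\n", sep = "")
  invisible(x)
}

# -- prediction-interval container -------------------------------------------

# Builds the classed interval from statistic-scale endpoints. P endpoints are
# the images of the statistic endpoints under `sided_rep`, reported ascending.
new_prediction_interval <- function(method, level, stat_lower, stat_upper,
                                    spec, sided_rep) {
  p <- sort(stat_to_p(c(stat_lower, stat_upper), spec, sided_rep))
  structure(list(method = method, level = level,
                 stat_lower = stat_lower, stat_upper = stat_upper,
                 p_lower = p[1], p_upper = p[2],
                 spec = spec, sided_rep = sided_rep),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, digits = 3, ...) {
  cat(sprintf("%d%% %s prediction interval for the replication study\n",
              round(100 * x$level),
              switch(x$method, p_interval = "classical (P-interval)",
                     conjugate = "conjugate Bayes",
                     mixture = "Mixture Bayes", x$method)))
  cat(sprintf("  statistic scale: (%s, %s)\n",
              format(x$stat_lower, digits = digits),
              format(x$stat_upper, digits = digits)))
  cat(sprintf("  P-value scale:   (%s, %s)\n",
              format(x$p_lower, digits = digits),
              format(x$p_upper, digits = digits)))
  invisible(x)
}

resolve_obt_stat <- function(p_obt, stat, spec, sided_obs) {
  if (is.null(stat) == is.null(p_obt))
    stop("supply exactly one of 'p_obt' or 'stat'")
  if (is.null(stat)) p_to_stat(p_obt, spec, sided_obs) else stat
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("'level' must lie strictly in (0, 1)")
  level
}

#' Classical P-interval for a replication P-value
#'
#' The frequentist prediction interval for the replication Z-statistic,
#' `z_obt +/- q_{(1+level)/2} * sqrt(2)`, mapped to the P-value scale. Its
#' statistic-scale width does not depend on the observed P-value, a
#' consequence of the flat effect-size prior it implicitly assumes.
#'
#' @param p_obt observed P-value (interpreted under `sided_obs`); give this
#'   or `stat`.
#' @param stat observed Z-statistic.
#' @param level coverage level `1 - alpha` (default 0.80, the level used in
#'   the worked replication examples).
#' @param sided_obs convention under which `p_obt` maps to a statistic.
#' @param sided_rep convention mapping the interval endpoints back to the
#'   P scale; the default is the one-sided upper tail, the scale on which a
#'   directional replication is judged.
#' @return a `"prediction_interval"` object.
#' @examples
#' # two-tailed P = 0.05 |-> an 80% chance the one-tailed replication
#' # P-value falls in (0.00008, 0.44)
#' classical_p_interval(0.05, sided_obs = "two_sided_positive_root")
#' @export
classical_p_interval <- function(p_obt = NULL, stat = NULL, level = 0.80,
                                 sided_obs = "one_sided_upper",
                                 sided_rep = "one_sided_upper") {
  check_level(level)
  spec <- test_spec("normal")
  z <- resolve_obt_stat(p_obt, stat, spec, sided_obs)
  hw <- stats::qnorm((1 + level) / 2) * sqrt(2)
  new_prediction_interval("p_interval", level, z - hw, z + hw, spec,
                          match_sided(sided_rep))
}

#' Conjugate Bayes prediction interval for a replication P-value
#'
#' Equal-tailed interval from the posterior predictive of the replication
#' Z-statistic, `N(theta, 1 + s^2)`:
#' `theta +/- q_{(1+level)/2} * sqrt(1 + s^2)`. As `sigma0^2 -> Inf` it
#' converges to the classical P-interval.
#'
#' @inheritParams classical_p_interval
#' @param prior a [conjugate_prior()].
#' @return a `"prediction_interval"` object.
#' @examples
#' conjugate_prediction_interval(0.446, prior = conjugate_prior(sigma0_sq = 0.5),
#'                               sided_obs = "two_sided_negative_root")
#' @export
conjugate_prediction_interval <- function(p_obt = NULL, stat = NULL, prior,
                                          level = 0.80,
                                          sided_obs = "one_sided_upper",
                                          sided_rep = "one_sided_upper") {
  check_level(level)
  spec <- test_spec("normal")
  z <- resolve_obt_stat(p_obt, stat, spec, sided_obs)
  post <- conjugate_posterior(z, prior)
  hw <- stats::qnorm((1 + level) / 2) * sqrt(1 + post$s_sq)
  new_prediction_interval("conjugate", level, post$theta - hw,
                          post$theta + hw, spec, match_sided(sided_rep))
}

#' Posterior probability of the directional null hypothesis
#'
#' For a one-sided test of a mean difference with a zero-centered normal
#' prior of variance `vartheta^2` on the standardized mean, the posterior
#' probability that the effect has the non-replicating sign is
#' `Pr(H0 | P) = 1 - Phi(z / sqrt(1 + 1/(N * vartheta^2)))`. The one-sided
#' P-value `1 - Phi(z)` approaches this probability as `N` grows.
#'
#' @param z observed Z-statistic.
#' @param effective_n effective sample size `N`.
#' @param vartheta_sq prior variance of the standardized mean.
#' @return posterior probability in (0, 1).
#' @examples
#' posterior_null_probability(1.645, effective_n = 100, vartheta_sq = 0.01)
#' @export
posterior_null_probability <- function(z, effective_n, vartheta_sq) {
  if (effective_n <= 0 || vartheta_sq <= 0)
    stop("'effective_n' and 'vartheta_sq' must be positive")
  1 - stats::pnorm(z / sqrt(1 + 1 / (effective_n * vartheta_sq)))
}
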