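#' Predict the P-value of a replication study
#'
#' The package's central fitting function: takes a single observed result (a
#' P-value or a statistic value plus its [test_spec()]) and a prior on the
#' standardized effect size, forms the posterior over the effect, and
#' returns the equal-tailed prediction interval for the replication
#' statistic and its P-value.
#'
#' Three methods are available. `"p_interval"` is the classical frequentist
#' interval `z_obt +/- q sqrt(2)` (no prior; equivalently, a flat one).
#' `"conjugate"` uses the normal-normal posterior predictive
#' `N(theta, 1 + s^2)` for a Z-statistic. `"mixture"` discretizes any prior
#' into components, weights noncentral predictive distributions by their
#' posterior probabilities, and inverts the resulting CDF; it works for
#' normal, Student t, chi-square and F statistics. When `method` is not
#' given it is inferred from the prior: none -> `"p_interval"`, a
#' [conjugate_prior()] with a normal statistic -> `"conjugate"`, anything
#' else -> `"mixture"` (a conjugate prior is discretized on the fly).
#'
#' @param p observed P-value (interpreted under `sided_obs`); give this or
#'   `stat`.
#' @param stat observed statistic value.
#' @param spec a [test_spec()]; defaults to a standard-normal Z-statistic.
#' @param prior `NULL`, a [conjugate_prior()], a [tabulated_prior()] or an
#'   [or_table()].
#' @param method `"p_interval"`, `"conjugate"` or `"mixture"`; inferred from
#'   the prior when `NULL`.
#' @param level coverage level `1 - alpha` (default 0.95).
#' @param sided_obs sidedness convention of the observed P-value.
#' @param sided_rep convention mapping interval endpoints to the P scale
#'   (default one-sided upper: replications target the reported direction).
#' @param ctx an [or_context()], used only to convert an `or_table` prior.
#' @return an object of class `"predint"` with the posterior, the interval
#'   and the inputs; see [print.predint()], [predict.predint()],
#'   [simulate.predint()], [plot.predint()].
#' @examples
#' # the classical 80% interval around two-tailed P = 0.05
#' predint(0.05, level = 0.8, sided_obs = "two_sided_positive_root")
#'
#' # conjugate Bayes with a realistic genome-wide prior
#' pr <- conjugate_prior(s0_sq = 1e-5, effective_n = 1354.67)
#' predint(0.1005, prior = pr, level = 0.95)
#' @export
predint <- function(p = NULL, stat = NULL, spec = test_spec("normal"),
                    prior = NULL, method = NULL, level = 0.95,
                    sided_obs = "one_sided_upper",
                    sided_rep = "one_sided_upper",
                    ctx = or_context()) {
  check_level(level)
  stopifnot(inherits(spec, "test_spec"))
  if (inherits(prior, "or_table"))
    prior <- tabulated_prior_from_or_table(prior, ctx)
  if (is.null(method)) {
    method <- if (is.null(prior)) "p_interval"
    else if (inherits(prior, "conjugate_prior") && spec$family == "normal")
      "conjugate"
    else "mixture"
  }
  method <- match.arg(method, c("p_interval", "conjugate", "mixture"))
  if (method != "mixture" && spec$family != "normal")
    stop("method '", method, "' applies to normal Z-statistics; ",
         "use method = \"mixture\" for ", spec$family, " statistics")
  t_obt <- resolve_obt_stat(p, stat, spec,
                            check_convention(spec, match_sided(sided_obs)))
  posterior <- NULL
  if (method == "p_interval") {
    interval <- classical_p_interval(stat = t_obt, level = level,
                                     sided_rep = sided_rep)
  } else if (method == "conjugate") {
    if (!inherits(prior, "conjugate_prior"))
      stop("the conjugate method needs a conjugate_prior()")
    posterior <- conjugate_posterior(t_obt, prior)
    interval <- conjugate_prediction_interval(stat = t_obt, prior = prior,
                                              level = level,
                                              sided_rep = sided_rep)
  } else {
    if (is.null(prior)) stop("the mixture method needs a prior")
    if (inherits(prior, "conjugate_prior"))
      prior <- discretize_prior(prior$m0, prior$s0_sq, prior$effective_n)
    posterior <- posterior_weights(prior, t_obt, spec)
    interval <- mixture_prediction_interval(stat = t_obt, prior = prior,
                                            spec = spec, level = level,
                                            sided_rep = sided_rep)
  }
  structure(list(call = match.call(), method = method, spec = spec,
                 prior = prior, level = level, t_obt = t_obt,
                 p_obt = stat_to_p(t_obt, spec, "one_sided_upper"),
                 sided_rep = match_sided(if (is_signed_family(spec))
                   sided_rep else "one_sided_upper"),
                 posterior = posterior, interval = interval),
            class = "predint")
}

#' @export
print.predint <- function(x, digits = 3, ...) {
  cat("Replication P-value prediction (method: ", x$method, ")\n", sep = "")
  cat(sprintf("  observed statistic %s (one-sided P = %s), family %s\n",
              format(x$t_obt, digits = digits),
              format(x$p_obt, digits = digits), x$spec$family))
  print(x$interval, digits = digits)
  invisible(x)
}

#' Summarize a replication prediction
#'
#' @param object a [predint()] fit.
#' @param ... unused.
#' @return `object`, invisibly, after printing the posterior (when the
#'   method has one) and the interval.
#' @export
summary.predint <- function(object, ...) {
  print(object)
  if (!is.null(object$posterior)) print(object$posterior)
  invisible(object)
}

#' Posterior location and spread of the effect
#'
#' For the conjugate method, the posterior mean `theta` and variance `s^2`
#' of the statistic's mean; for the mixture method, the posterior mean
#' effect. The classical P-interval has no posterior.
#'
#' @param object a [predint()] fit.
#' @param ... unused.
#' @return a named numeric vector.
#' @export
coef.predint <- function(object, ...) {
  if (is.null(object$posterior))
    return(c(z_obt = object$t_obt))
  if (inherits(object$posterior, "conjugate_posterior"))
    c(theta = object$posterior$theta, s_sq = object$posterior$s_sq)
  else
    c(posterior_mean = object$posterior$posterior_mean)
}

#' Prediction intervals or predictive quantiles at new levels
#'
#' @param object a [predint()] fit.
#' @param level coverage level(s) for equal-tailed intervals.
#' @param quantiles optional predictive probabilities; when given, the
#'   corresponding statistic-scale predictive quantiles are returned
#'   instead of intervals.
#' @param ... unused.
#' @return a data.frame of intervals (columns `level`, `stat_lower`,
#'   `stat_upper`, `p_lower`, `p_upper`) or a numeric vector of quantiles.
#' @export
predict.predint <- function(object, level = object$level, quantiles = NULL,
                            ...) {
  if (!is.null(quantiles)) {
    if (object$method == "p_interval")
      return(object$t_obt + stats::qnorm(quantiles) * sqrt(2))
    if (object$method == "conjugate")
      return(object$posterior$theta +
               stats::qnorm(quantiles) * sqrt(1 + object$posterior$s_sq))
    return(predictive_quantile(object$posterior, quantiles))
  }
  rows <- lapply(level, function(lv) {
    iv <- switch(object$method,
      p_interval = classical_p_interval(stat = object$t_obt, level = lv,
                                        sided_rep = object$sided_rep),
      conjugate = conjugate_prediction_interval(
        stat = object$t_obt, prior = object$prior, level = lv,
        sided_rep = object$sided_rep),
      mixture = mixture_prediction_interval(
        stat = object$t_obt, prior = object$prior, spec = object$spec,
        level = lv, sided_rep = object$sided_rep))
    data.frame(level = lv, stat_lower = iv$stat_lower,
               stat_upper = iv$stat_upper, p_lower = iv$p_lower,
               p_upper = iv$p_upper)
  })
  do.call(rbind, rows)
}

#' Draw replication statistics from the posterior predictive
#'
#' @param object a [predint()] fit.
#' @param nsim number of draws.
#' @param seed optional seed.
#' @param ... unused.
#' @return numeric vector of simulated replication statistic values.
#' @export
simulate.predint <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (object$method == "p_interval")
    return(stats::rnorm(nsim, object$t_obt, sqrt(2)))
  if (object$method == "conjugate")
    return(stats::rnorm(nsim, object$posterior$theta,
                        sqrt(1 + object$posterior$s_sq)))
  post <- object$posterior
  comp <- sample.int(length(post$gammas), nsim, replace = TRUE,
                     prob = post$post_probs)
  g <- post$gammas[comp]
  spec <- object$spec
  switch(spec$family,
         normal = stats::rnorm(nsim, g, 1),
         student_t = stats::rt(nsim, df = spec$df2, ncp = g),
         chi_square = stats::rchisq(nsim, df = spec$df1, ncp = g),
         f = stats::rf(nsim, df1 = spec$df1, df2 = spec$df2, ncp = g))
}

#' Plot the predictive distribution of the replication statistic
#'
#' Draws the predictive CDF with the equal-tailed interval shaded and the
#' observed statistic marked.
#'
#' @param x a [predint()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.predint <- function(x, ...) {
  iv <- x$interval
  span <- iv$stat_upper - iv$stat_lower
  xs <- seq(iv$stat_lower - 0.3 * span, iv$stat_upper + 0.3 * span,
            length.out = 400)
  xs <- xs[xs >= fam_support_min(x$spec)]
  Fs <- if (x$method == "p_interval")
    stats::pnorm(xs, x$t_obt, sqrt(2))
  else if (x$method == "conjugate")
    stats::pnorm(xs, x$posterior$theta, sqrt(1 + x$posterior$s_sq))
  else predictive_cdf(x$posterior, xs)
  graphics::plot(xs, Fs, type = "l", xlab = "replication statistic",
                 ylab = "predictive CDF", ...)
  graphics::abline(v = c(iv$stat_lower, iv$stat_upper), lty = 2,
                   col = "grey50")
  graphics::abline(v = x$t_obt, col = "blue")
  graphics::abline(h = c((1 - x$level) / 2, (1 + x$level) / 2), lty = 3,
                   col = "grey70")
  invisible(x)
}
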