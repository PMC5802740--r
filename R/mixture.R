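#' Tabulated prior on the standardized effect size
#'
#' A discrete prior over standardized effect values `delta_i` (or
#' `delta_i^2` for the nonnegative chi-square/F families) with probabilities
#' `Pr(delta_i)`. This is the mixture prior behind the Mixture Bayes
#' interval: any effect-size distribution a researcher can tabulate is
#' admissible, conjugacy is not required.
#'
#' @param values strictly increasing effect values (all nonnegative when
#'   `scale = "delta_squared"`).
#' @param probs nonnegative weights, renormalized to sum to 1 (an error if
#'   they are off by more than `1e-6` unless `renormalize = TRUE`).
#' @param scale `"delta"` (signed standardized effect) or `"delta_squared"`.
#' @param renormalize allow silent renormalization of badly scaled weights.
#' @return an object of class `"tabulated_prior"`.
#' @examples
#' tabulated_prior(c(-0.1, 0, 0.1), c(0.25, 0.5, 0.25))
#' @export
tabulated_prior <- function(values, probs, scale = c("delta", "delta_squared"),
                            renormalize = FALSE) {
  scale <- match.arg(scale)
  stopifnot(length(values) == length(probs), length(values) >= 1,
            all(is.finite(values)), all(is.finite(probs)))
  if (any(diff(values) <= 0)) stop("'values' must be strictly increasing")
  if (any(probs < 0)) stop("'probs' must be nonnegative")
  if (scale == "delta_squared" && any(values < 0))
    stop("'delta_squared' values must be nonnegative")
  s <- sum(probs)
  if (s <= 0) stop("'probs' sum to zero")
  if (abs(s - 1) > 1e-6 && !renormalize)
    stop("'probs' sum to ", format(s), "; set renormalize = TRUE to rescale")
  structure(list(values = as.numeric(values), probs = as.numeric(probs) / s,
                 B = length(values), scale = scale),
            class = "tabulated_prior")
}

#' @export
print.tabulated_prior <- function(x, ...) {
  cat("Tabulated effect-size prior (", x$scale, " scale), B = ", x$B,
      " components\n", sep = "")
  cat("  range [", format(min(x$values)), ", ", format(max(x$values)),
      "]\n", sep = "")
  invisible(x)
}

#' Discretize a conjugate normal prior into a finite mixture
#'
#' Partitions the normal prior on the statistic-scale mean (standard
#' deviation `sigma0 = sqrt(N * s0_sq)`) between its `tail_quantile` and
#' `1 - tail_quantile` quantiles into `B` contiguous equal-width bins of
#' width approximately `sigma0 * step_fraction`. Each component sits at the
#' bin midpoint and carries the prior mass of its bin (CDF difference),
#' renormalized to sum to 1. With the defaults (`step_fraction = 1/8`,
#' `tail_quantile = 1e-6`) this yields `B = 76` components for any
#' `sigma0 > 0`.
#'
#' Returned values are on the standardized (`delta`) scale, i.e. bin
#' midpoints divided by `sqrt(effective_n)`, so that the noncentrality
#' `gamma = sqrt(N) * delta` recovers the statistic-scale grid.
#'
#' @param m0 prior mean on the statistic scale.
#' @param s0_sq prior variance of the standardized effect; `0` gives a
#'   degenerate single-component prior at `m0`.
#' @param effective_n effective sample size `N`.
#' @param step_fraction bin width as a fraction of `sigma0`.
#' @param tail_quantile truncation tail mass (must be < 0.5).
#' @return a [tabulated_prior()] on the `delta` scale.
#' @examples
#' discretize_prior(s0_sq = 0.25)$B   # 76
#' @export
discretize_prior <- function(m0 = 0, s0_sq, effective_n = 1,
                             step_fraction = 1 / 8, tail_quantile = 1e-6) {
  stopifnot(s0_sq >= 0, effective_n > 0, step_fraction > 0)
  if (tail_quantile <= 0 || tail_quantile >= 0.5)
    stop("'tail_quantile' must lie in (0, 0.5)")
  rootN <- sqrt(effective_n)
  if (s0_sq == 0)
    return(tabulated_prior(m0 / rootN, 1))
  sigma0 <- sqrt(effective_n * s0_sq)
  lo <- stats::qnorm(tail_quantile, m0, sigma0)
  hi <- stats::qnorm(1 - tail_quantile, m0, sigma0)
  B <- max(1L, floor((hi - lo) / (sigma0 * step_fraction)))
  edges <- seq(lo, hi, length.out = B + 1)
  mids <- (edges[-1] + edges[-(B + 1)]) / 2
  mass <- diff(stats::pnorm(edges, m0, sigma0))
  tabulated_prior(mids / rootN, mass / sum(mass))
}

# Fold a signed-delta prior onto the delta^2 scale by summing the
# probabilities of +/- delta pairs (needed for chi-square/F statistics).
fold_prior <- function(prior, tol = 1e-12) {
  stopifnot(inherits(prior, "tabulated_prior"))
  if (prior$scale == "delta_squared") return(prior)
  d2 <- prior$values^2
  key <- round(d2 / (tol + max(d2, 1) * 1e-12))
  agg <- rowsum(prior$probs, key)
  vals <- rowsum(d2 * prior$probs, key) / ifelse(agg > 0, agg, 1)
  o <- order(vals[, 1])
  tabulated_prior(vals[o, 1], agg[o, 1], scale = "delta_squared")
}

# noncentrality grid of a tabulated prior under a test_spec
prior_gammas <- function(prior, spec) {
  if (is_signed_family(spec)) {
    if (prior$scale != "delta")
      stop("signed families need a prior on the 'delta' scale")
    sqrt(spec$effective_n) * prior$values
  } else {
    if (prior$scale == "delta") prior <- fold_prior(prior)
    spec$effective_n * prior$values
  }
}

#' Posterior weights of the mixture components given an observed statistic
#'
#' Bayes' rule over the discrete prior: the posterior probability of
#' component `j` is proportional to its prior probability times the
#' noncentral density of the statistic family at the observed value with
#' noncentrality `gamma_j` (`sqrt(N) delta_j` for normal/t, `N delta_j^2`
#' for chi-square/F). Weights are normalized in log space so that
#' observations in the far tail (densities near `1e-80`) do not underflow.
#'
#' @param prior a [tabulated_prior()]. Signed (`delta`) priors are folded to
#'   the `delta_squared` scale automatically for chi-square/F statistics.
#' @param t_obt observed statistic value.
#' @param spec a [test_spec()].
#' @return an object of class `"mixture_posterior"` with the component
#'   values, noncentralities, prior and posterior probabilities, and the
#'   posterior mean effect.
#' @examples
#' pr <- discretize_prior(s0_sq = 0.25)
#' posterior_weights(pr, 2, test_spec("normal"))
#' @export
posterior_weights <- function(prior, t_obt, spec = test_spec("normal")) {
  stopifnot(inherits(prior, "tabulated_prior"), inherits(spec, "test_spec"),
            is.finite(t_obt))
  if (t_obt < fam_support_min(spec))
    stop("'t_obt' outside the support of the ", spec$family, " family")
  if (!is_signed_family(spec) && prior$scale == "delta")
    prior <- fold_prior(prior)
  gam <- prior_gammas(prior, spec)
  logw <- ifelse(prior$probs > 0,
                 log(prior$probs) + fam_density(t_obt, spec, ncp = gam,
                                                log = TRUE),
                 -Inf)
  m <- max(logw)
  if (!is.finite(m))
    stop("all mixture densities underflowed at t_obt = ", format(t_obt),
         "; the prior places no mass near the observation")
  w <- exp(logw - m)
  w <- w / sum(w)
  structure(list(values = prior$values, scale = prior$scale,
                 gammas = gam, prior_probs = prior$probs, post_probs = w,
                 posterior_mean = sum(prior$values * w),
                 spec = spec, t_obt = t_obt),
            class = "mixture_posterior")
}

#' @export
print.mixture_posterior <- function(x, ...) {
  cat("Mixture posterior over ", length(x$values), " effect components (",
      x$scale, " scale)\n", sep = "")
  cat("  posterior mean effect:", format(x$posterior_mean), "\n")
  invisible(x)
}

#' Predictive CDF of the replication statistic under the mixture posterior
#'
#' The posterior-probability-weighted average of the noncentral CDFs of the
#' statistic family, `F_p(x) = sum_j Pr(comp_j | T_obt) F(x | gamma_j)`.
#'
#' @param post a [posterior_weights()] result.
#' @param x statistic value(s).
#' @param spec the test specification (defaults to the one stored in `post`).
#' @return probability value(s), nondecreasing in `x`.
#' @export
predictive_cdf <- function(post, x, spec = post$spec) {
  stopifnot(inherits(post, "mixture_posterior"))
  vapply(x, function(xi) sum(post$post_probs * fam_cdf(xi, spec,
                                                       ncp = post$gammas)),
         numeric(1))
}

#' Quantile of the mixture predictive distribution
#'
#' Inverts [predictive_cdf()] by bracketing (the bracket is seeded by the
#' extreme component-wise quantiles, widened geometrically if necessary)
#' followed by bisection until the CDF matches `q` to `1e-10`.
#'
#' @inheritParams predictive_cdf
#' @param q probability (or vector of probabilities) in (0, 1).
#' @return statistic value(s) `x` with `|F_p(x) - q| <= 1e-10`.
#' @export
predictive_quantile <- function(post, q, spec = post$spec) {
  stopifnot(inherits(post, "mixture_posterior"))
  if (any(q <= 0 | q >= 1)) stop("'q' must lie strictly in (0, 1)")
  vapply(q, function(qi) .predictive_quantile1(post, qi, spec), numeric(1))
}

.predictive_quantile1 <- function(post, q, spec, tol = 1e-10) {
  live <- post$post_probs > 0
  cq <- fam_quantile(q, spec, ncp = post$gammas[live])
  lo <- min(cq); hi <- max(cq)
  supp_min <- fam_support_min(spec)
  lo <- max(lo, supp_min)
  f <- function(x) predictive_cdf(post, x, spec) - q
  # widen the bracket geometrically (bounded number of doublings)
  step <- max(hi - lo, 1)
  k <- 0
  while (f(lo) > 0 && lo > supp_min && k < 60) {
    lo <- max(supp_min, lo - step); step <- step * 2; k <- k + 1
  }
  step <- max(hi - lo, 1); k <- 0
  while (f(hi) < 0 && k < 60) {
    hi <- hi + step; step <- step * 2; k <- k + 1
  }
  if (f(lo) > 0 || f(hi) < 0)
    stop("failed to bracket the predictive quantile at q = ", q)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-15 * (1 + abs(mid))) break
  }
  (lo + hi) / 2
}

#' Mixture Bayes prediction interval for a replication P-value
#'
#' Equal-tailed interval `[F_p^{-1}(alpha/2), F_p^{-1}(1 - alpha/2)]` of the
#' mixture predictive distribution of the replication statistic, mapped to
#' the P-value scale (for chi-square/F statistics the P map is the upper
#' tail of the central distribution).
#'
#' @inheritParams classical_p_interval
#' @param prior a [tabulated_prior()] (e.g. from [discretize_prior()] or
#'   [tabulated_prior_from_or_table()]).
#' @param spec a [test_spec()].
#' @return a `"prediction_interval"` object.
#' @examples
#' pr <- discretize_prior(s0_sq = 0.5)
#' mixture_prediction_interval(0.446, prior = pr,
#'                             sided_obs = "two_sided_negative_root")
#' @export
mixture_prediction_interval <- function(p_obt = NULL, stat = NULL, prior,
                                        spec = test_spec("normal"),
                                        level = 0.80,
                                        sided_obs = "one_sided_upper",
                                        sided_rep = "one_sided_upper") {
  check_level(level)
  t_obt <- resolve_obt_stat(p_obt, stat, spec, sided_obs)
  post <- posterior_weights(prior, t_obt, spec)
  a <- (1 - level) / 2
  lo <- predictive_quantile(post, a, spec)
  hi <- predictive_quantile(post, 1 - a, spec)
  new_prediction_interval("mixture", level, lo, hi, spec,
                          if (is_signed_family(spec))
                            match_sided(sided_rep) else "one_sided_upper")
}

#' Read a tabulated prior from a tab-separated file
#'
#' Two dialects are recognized by the header: `delta<TAB>prob` gives a
#' [tabulated_prior()] directly; `or<TAB>count` gives an [or_table()] whose
#' total test count `M` is read from a `# M=<integer>` comment line. Lines
#' starting with `#` are otherwise ignored. Probabilities off by more than
#' `1e-6` from unit mass are renormalized with a warning.
#'
#' @param path file path.
#' @return a `"tabulated_prior"` or `"or_table"` object.
#' @export
read_prior_table <- function(path) {
  lines <- readLines(path)
  m_line <- grep("^#\\s*M\\s*=", lines, value = TRUE)
  dat <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           comment.char = "#", strip.white = TRUE)
  cols <- tolower(names(dat))
  if (all(c("delta", "prob") %in% cols)) {
    names(dat) <- cols
    s <- sum(dat$prob)
    if (abs(s - 1) > 1e-6)
      warning("prior probabilities sum to ", format(s), "; renormalized")
    o <- order(dat$delta)
    tabulated_prior(dat$delta[o], dat$prob[o], renormalize = TRUE)
  } else if (all(c("or", "count") %in% cols)) {
    names(dat) <- cols
    if (!length(m_line))
      stop("'or/count' prior tables need a '# M=<total tests>' header line")
    M <- as.numeric(sub("^#\\s*M\\s*=\\s*", "", m_line[1]))
    or_table(dat$or, dat$count, M = M)
  } else {
    stop("unrecognized prior table: expected columns delta/prob or or/count")
  }
}
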