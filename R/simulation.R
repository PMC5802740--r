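#' Selection rule applied to observed P-values
#'
#' The restriction under which an original result makes it to interval
#' construction -- the source of coverage bias for frequentist intervals:
#' `"none"` (every experiment is kept), `"window"` (observed P in
#' `[p_low, p_high]`), `"threshold"` (P below `p_high`), or `"min_of_L"`
#' (the most significant of `L` independent tests per experiment).
#'
#' The `sided` field states which P-value the rule thresholds. By default
#' window/threshold rules select on the two-sided P-value of the Z-statistic
#' (the significance filter of an omnibus test) while `min_of_L` picks the
#' smallest one-sided P (the largest Z), the directional winner's-curse
#' setting; both can be overridden.
#'
#' @param mode selection mode.
#' @param p_low,p_high window bounds on the observed P-value.
#' @param L number of tests per experiment for `min_of_L`.
#' @param sided `"two_sided"` or `"one_sided"`; default depends on `mode`.
#' @return an object of class `"selection_rule"`.
#' @examples
#' selection_rule("threshold", p_high = 0.001)
#' selection_rule("min_of_L", L = 10000)
#' @export
selection_rule <- function(mode = c("none", "window", "threshold", "min_of_L"),
                           p_low = 0, p_high = 1, L = 1, sided = NULL) {
  mode <- match.arg(mode)
  if (is.null(sided))
    sided <- if (mode == "min_of_L") "one_sided" else "two_sided"
  sided <- match.arg(sided, c("two_sided", "one_sided"))
  if (mode == "threshold") p_low <- 0
  if (mode == "window" && !(p_low < p_high))
    stop("window selection requires p_low < p_high")
  if (mode == "min_of_L" && (L < 1 || L != round(L)))
    stop("'L' must be a positive integer")
  stopifnot(p_low >= 0, p_high <= 1)
  structure(list(mode = mode, p_low = p_low, p_high = p_high,
                 L = as.integer(L), sided = sided),
            class = "selection_rule")
}

#' @export
print.selection_rule <- function(x, ...) {
  cat("Selection rule: ", x$mode,
      switch(x$mode,
             none = "",
             window = sprintf(" P in [%g, %g] (%s)", x$p_low, x$p_high, x$sided),
             threshold = sprintf(" P < %g (%s)", x$p_high, x$sided),
             min_of_L = sprintf(" smallest of L = %d (%s)", x$L, x$sided)),
      "\n", sep = "")
  invisible(x)
}

#' Configuration of a coverage experiment
#'
#' Bundles the generative prior variance, the (possibly mis-specified)
#' variance used for interval construction, the interval method, nominal
#' level, selection rule, replicate count and seed. Generating and analysis
#' variances are independently settable so under-specification
#' (`sigma0^2/2`) and over-specification (`2 sigma0^2`) can be studied.
#'
#' @param sigma0_sq generative prior variance `sigma0^2 = N s0^2` of the
#'   statistic's mean.
#' @param analysis_sigma0_sq prior variance used when building the interval
#'   (defaults to `sigma0_sq`).
#' @param method interval method: `"p_interval"`, `"conjugate"` or
#'   `"mixture"`.
#' @param level nominal coverage level.
#' @param selection a [selection_rule()].
#' @param reps number of Monte-Carlo replicates.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(sigma0_sq, analysis_sigma0_sq = NULL,
                       method = c("p_interval", "conjugate", "mixture"),
                       level = 0.80, selection = selection_rule("none"),
                       reps = 50000, seed = NULL) {
  method <- match.arg(method)
  check_level(level)
  stopifnot(sigma0_sq > 0, reps >= 1, inherits(selection, "selection_rule"))
  if (is.null(analysis_sigma0_sq)) analysis_sigma0_sq <- sigma0_sq
  stopifnot(analysis_sigma0_sq > 0)
  structure(list(sigma0_sq = sigma0_sq,
                 analysis_sigma0_sq = analysis_sigma0_sq,
                 method = method, level = level, selection = selection,
                 reps = as.integer(reps), seed = seed),
            class = "sim_config")
}

#' Read a coverage-experiment configuration file
#'
#' YAML key-value file mirroring [sim_config()]; the `selection` key is a
#' nested map with `mode`, `p_low`, `p_high`, `L`, `sided`. `reps` and
#' `seed` given as arguments override the file.
#'
#' @param path file path.
#' @param reps,seed optional overrides.
#' @return a `"sim_config"`.
#' @export
read_sim_config <- function(path, reps = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  sel <- do.call(selection_rule, as.list(y$selection %||% list(mode = "none")))
  sim_config(sigma0_sq = y$sigma0_sq,
             analysis_sigma0_sq = y$analysis_sigma0_sq,
             method = y$method %||% "p_interval",
             level = y$level %||% 0.80,
             selection = sel,
             reps = reps %||% y$reps %||% 50000,
             seed = seed %||% y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-image of the selected P range for the marginal draw
selection_z_range <- function(selection) {
  if (selection$sided == "one_sided") {
    c(lo = stats::qnorm(1 - selection$p_high),
      hi = if (selection$p_low <= 0) Inf else stats::qnorm(1 - selection$p_low))
  } else {
    c(lo = stats::qnorm(1 - selection$p_high / 2),
      hi = if (selection$p_low <= 0) Inf else
        stats::qnorm(1 - selection$p_low / 2))
  }
}

#' Draw (observed, replication) statistic pairs under selection
#'
#' One experiment is: latent effect `gamma ~ N(0, sigma0^2)`; observed
#' statistic `z_obt ~ N(gamma, 1)` subject to the selection rule; replication
#' `z_rep ~ N(gamma, 1)` drawn independently given the same `gamma`.
#'
#' Window/threshold selection uses an exact conditional sampler: `z_obt` is
#' drawn from its truncated marginal `N(0, 1 + sigma0^2)` restricted to the
#' z-image of the P constraint, then `gamma | z_obt` from the conjugate
#' posterior. This is distributionally identical to rejection sampling but
#' remains tractable for extreme windows (e.g. P in `[5e-9, 5e-8]`).
#' `min_of_L` is simulated literally: `L` independent pairs, the most
#' significant kept, and its latent effect generates the replication.
#'
#' @param n number of retained experiments.
#' @param sigma0_sq generative prior variance of the statistic mean.
#' @param selection a [selection_rule()].
#' @return a data.frame with columns `z_obt`, `gamma`, `z_rep`.
#' @examples
#' draw_pairs(5, 0.25, selection_rule("threshold", p_high = 0.05))
#' @export
draw_pairs <- function(n, sigma0_sq, selection = selection_rule("none")) {
  stopifnot(n >= 1, sigma0_sq > 0, inherits(selection, "selection_rule"))
  tau <- sqrt(1 + sigma0_sq)
  if (selection$mode == "none") {
    gam <- stats::rnorm(n, 0, sqrt(sigma0_sq))
    z <- stats::rnorm(n, gam, 1)
  } else if (selection$mode == "min_of_L") {
    res <- draw_min_of_L(n, sigma0_sq, selection)
    gam <- res$gamma; z <- res$z_obt
  } else {
    zr <- selection_z_range(selection)
    if (selection$sided == "one_sided") {
      u <- stats::runif(n, stats::pnorm(zr["lo"] / tau),
                        stats::pnorm(zr["hi"] / tau))
      z <- tau * stats::qnorm(u)
    } else {
      # |z| from the truncated folded marginal, sign symmetric
      Flo <- 2 * stats::pnorm(zr["lo"] / tau) - 1
      Fhi <- if (is.infinite(zr["hi"])) 1 else 2 * stats::pnorm(zr["hi"] / tau) - 1
      u <- stats::runif(n, Flo, Fhi)
      z <- tau * stats::qnorm((u + 1) / 2) *
        sample(c(-1, 1), n, replace = TRUE)
    }
    w <- sigma0_sq / (1 + sigma0_sq)
    gam <- stats::rnorm(n, z * w, sqrt(w))
  }
  data.frame(z_obt = z, gamma = gam, z_rep = stats::rnorm(n, gam, 1))
}

# literal min-of-L simulation, chunked to bound memory
draw_min_of_L <- function(n, sigma0_sq, selection) {
  L <- selection$L
  chunk <- max(1L, min(n, as.integer(5e6 / L)))
  z_sel <- numeric(n); g_sel <- numeric(n)
  done <- 0L
  while (done < n) {
    m <- min(chunk, n - done)
    gam <- matrix(stats::rnorm(m * L, 0, sqrt(sigma0_sq)), nrow = m)
    z <- gam + matrix(stats::rnorm(m * L), nrow = m)
    idx <- if (selection$sided == "one_sided")
      max.col(z) else max.col(abs(z))
    pick <- cbind(seq_len(m), idx)
    z_sel[done + seq_len(m)] <- z[pick]
    g_sel[done + seq_len(m)] <- gam[pick]
    done <- done + m
  }
  list(z_obt = z_sel, gamma = g_sel)
}

# rejection-sampling reference for window/threshold selection (test oracle)
rejection_draw_pairs <- function(n, sigma0_sq, selection,
                                 max_batches = 10000) {
  stopifnot(selection$mode %in% c("window", "threshold"))
  out_z <- numeric(0); out_g <- numeric(0)
  batches <- 0
  while (length(out_z) < n && batches < max_batches) {
    gam <- stats::rnorm(n, 0, sqrt(sigma0_sq))
    z <- stats::rnorm(n, gam, 1)
    p <- if (selection$sided == "one_sided")
      1 - stats::pnorm(z) else 2 * (1 - stats::pnorm(abs(z)))
    keep <- p >= selection$p_low & p <= selection$p_high
    out_z <- c(out_z, z[keep]); out_g <- c(out_g, gam[keep])
    batches <- batches + 1
  }
  if (length(out_z) < n)
    stop("selection window too narrow for rejection sampling budget")
  data.frame(z_obt = out_z[1:n], gamma = out_g[1:n],
             z_rep = stats::rnorm(n, out_g[1:n], 1))
}

# Vectorized containment of z_rep in the interval built from z_obt.
# For the mixture method containment is checked through the predictive CDF
# (alpha/2 <= F_p(z_rep | z_obt) <= 1 - alpha/2), which is equivalent to the
# equal-tailed endpoint check because F_p is increasing.
interval_covers <- function(method, z_obt, z_rep, level, analysis_sigma0_sq) {
  a <- (1 - level) / 2
  if (method == "p_interval") {
    hw <- stats::qnorm(1 - a) * sqrt(2)
    return(abs(z_rep - z_obt) <= hw)
  }
  if (method == "conjugate") {
    w <- analysis_sigma0_sq / (1 + analysis_sigma0_sq)
    hw <- stats::qnorm(1 - a) * sqrt(1 + w)
    return(abs(z_rep - z_obt * w) <= hw)
  }
  # mixture: default discretization of the zero-mean analysis prior
  pr <- discretize_prior(0, analysis_sigma0_sq)   # effective_n = 1: gamma grid
  gam <- pr$values
  logw <- outer(z_obt, gam, function(z, g) stats::dnorm(z - g, log = TRUE))
  logw <- sweep(logw, 2, log(pr$probs), "+")
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw); w <- w / rowSums(w)
  Fp <- rowSums(w * stats::pnorm(outer(z_rep, gam, "-")))
  Fp >= a & Fp <= 1 - a
}

#' Monte-Carlo coverage of a prediction-interval rule under selection
#'
#' For each replicate, draws an (observed, replication) pair under the
#' configured selection, builds the configured interval from the observed
#' statistic (using the analysis prior variance), and scores whether the
#' replication statistic -- equivalently the replication P-value -- falls
#' inside. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `"coverage_estimate"`: replicate count,
#'   hits, proportion and its binomial Monte-Carlo standard error.
#' @examples
#' cfg <- sim_config(0.25, method = "conjugate", reps = 2000, seed = 1)
#' simulate_coverage(cfg)
#' @export
simulate_coverage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pairs <- draw_pairs(config$reps, config$sigma0_sq, config$selection)
  cov <- interval_covers(config$method, pairs$z_obt, pairs$z_rep,
                         config$level, config$analysis_sigma0_sq)
  hits <- sum(cov)
  prop <- hits / config$reps
  structure(list(reps = config$reps, hits = hits, proportion = prop,
                 mc_se = sqrt(prop * (1 - prop) / config$reps),
                 config = config),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf(
    "Empirical coverage: %.1f%% (nominal %.0f%%, %d reps, MC se %.2f%%)\n",
    100 * x$proportion, 100 * x$config$level, x$reps, 100 * x$mc_se))
  invisible(x)
}

#' Simulate replication pairs with their prediction intervals
#'
#' Row-per-experiment table suitable for dot-and-error-bar displays of
#' interval performance: the observed statistic, the interval built from it,
#' the replication statistic and a containment flag.
#'
#' @param config a [sim_config()].
#' @param n_experiments number of experiments (rows).
#' @return a data.frame of class `"replication_pairs"` with columns
#'   `z_obt`, `stat_lower`, `stat_upper`, `z_rep`, `covered`.
#' @examples
#' cfg <- sim_config(1, method = "p_interval", seed = 42)
#' head(simulate_replication_pairs(cfg, 100))
#' @export
simulate_replication_pairs <- function(config, n_experiments = 100) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pairs <- draw_pairs(n_experiments, config$sigma0_sq, config$selection)
  a <- (1 - config$level) / 2
  v <- config$analysis_sigma0_sq
  if (config$method == "p_interval") {
    hw <- stats::qnorm(1 - a) * sqrt(2)
    lo <- pairs$z_obt - hw; hi <- pairs$z_obt + hw
  } else if (config$method == "conjugate") {
    w <- v / (1 + v)
    hw <- stats::qnorm(1 - a) * sqrt(1 + w)
    lo <- pairs$z_obt * w - hw; hi <- pairs$z_obt * w + hw
  } else {
    pr <- discretize_prior(0, v)
    spec <- test_spec("normal")
    ends <- vapply(pairs$z_obt, function(z) {
      post <- posterior_weights(pr, z, spec)
      c(predictive_quantile(post, a, spec),
        predictive_quantile(post, 1 - a, spec))
    }, numeric(2))
    lo <- ends[1, ]; hi <- ends[2, ]
  }
  out <- data.frame(z_obt = pairs$z_obt, stat_lower = lo, stat_upper = hi,
                    z_rep = pairs$z_rep,
                    covered = pairs$z_rep >= lo & pairs$z_rep <= hi)
  class(out) <- c("replication_pairs", "data.frame")
  out
}

#' @export
plot.replication_pairs <- function(x, ...) {
  n <- nrow(x)
  ylim <- range(x$stat_lower, x$stat_upper, x$z_rep)
  graphics::plot(NA, xlim = c(1, n), ylim = ylim, xlab = "experiment",
                 ylab = "replication Z", ...)
  cols <- ifelse(x$covered, "grey40", "red")
  graphics::segments(seq_len(n), x$stat_lower, seq_len(n), x$stat_upper,
                     col = cols)
  graphics::points(seq_len(n), x$z_rep, pch = 16, cex = 0.6, col = "blue")
  invisible(x)
}
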