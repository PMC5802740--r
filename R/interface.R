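#' Read a study table of observed results
#'
#' Tab-separated file with a header and columns `label`, `cases`,
#' `controls`, `p_one_sided`; lines starting with `#` are ignored.
#' Malformed rows are reported with their line numbers. The effective
#' sample size `N = 1/(1/cases + 1/controls)` is appended per row.
#'
#' @param path file path.
#' @return a data.frame of class `"study_table"` with columns `label`,
#'   `cases`, `controls`, `p_one_sided`, `effective_n`.
#' @export
read_study_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (sum(keep) <= 1) {
    warning("study table '", path, "' has no data rows")
    out <- data.frame(label = character(), cases = integer(),
                      controls = integer(), p_one_sided = numeric(),
                      effective_n = numeric())
    class(out) <- c("study_table", "data.frame")
    return(out)
  }
  dat <- utils::read.table(text = lines[keep], header = TRUE, sep = "\t",
                           comment.char = "", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("label", "cases", "controls", "p_one_sided")
  if (!all(need %in% names(dat)))
    stop("study table is missing columns: ",
         paste(setdiff(need, names(dat)), collapse = ", "))
  src_lines <- which(keep)[-1]   # file line of each data row
  bad <- !is.finite(dat$cases) | dat$cases <= 0 |
    !is.finite(dat$controls) | dat$controls <= 0 |
    !is.finite(dat$p_one_sided) | dat$p_one_sided <= 0 | dat$p_one_sided >= 1
  if (any(bad))
    stop("invalid study rows at line(s) ",
         paste(src_lines[bad], collapse = ", "),
         " (need positive counts and P in (0,1))")
  dat$effective_n <- effective_sample_size(dat$cases, dat$controls)
  class(dat) <- c("study_table", "data.frame")
  dat
}

#' Batch prediction intervals for a table of studies
#'
#' Builds one interval per (study row x method). The conjugate and mixture
#' methods use the per-row statistic-scale prior variance
#' `sigma0^2 = N * s0_sq`; the P-interval ignores the prior. Observed
#' P-values are one-sided; intervals are reported on the one-sided P scale
#' and on the `-log10(P)` scale.
#'
#' @param rows a [read_study_table()] result (or equivalent data.frame).
#' @param s0_sq prior variance of the standardized effect for the
#'   conjugate model and its mixture discretization.
#' @param prior_table optional [or_table()] or [tabulated_prior()] used by
#'   the mixture method instead of the discretized conjugate prior.
#' @param methods subset of `c("p_interval", "conjugate", "mixture")`.
#' @param level coverage level (default 0.95, the level at which such study
#'   tables are conventionally reported).
#' @param ctx an [or_context()] for converting `prior_table` odds ratios.
#' @return a data.frame with one row per (study x method): `label`,
#'   `method`, `level`, `p_lower`, `p_upper`, `neglog10_lower`,
#'   `neglog10_upper`, `stat_lower`, `stat_upper`.
#' @export
batch_intervals <- function(rows, s0_sq = 1e-5, prior_table = NULL,
                            methods = c("p_interval", "conjugate", "mixture"),
                            level = 0.95, ctx = or_context()) {
  methods <- match.arg(methods, several.ok = TRUE)
  check_level(level)
  mix_prior <- NULL
  if (!is.null(prior_table)) {
    mix_prior <- if (inherits(prior_table, "or_table"))
      tabulated_prior_from_or_table(prior_table, ctx) else prior_table
    stopifnot(inherits(mix_prior, "tabulated_prior"))
  }
  out <- vector("list", nrow(rows) * length(methods))
  k <- 0
  for (i in seq_len(nrow(rows))) {
    N <- rows$effective_n[i]
    p <- rows$p_one_sided[i]
    for (m in methods) {
      iv <- switch(m,
        p_interval = classical_p_interval(p, level = level),
        conjugate = conjugate_prediction_interval(
          p, prior = conjugate_prior(s0_sq = s0_sq, effective_n = N),
          level = level),
        mixture = {
          pr <- if (is.null(mix_prior))
            discretize_prior(0, s0_sq, effective_n = N) else mix_prior
          mixture_prediction_interval(
            p, prior = pr, spec = test_spec("normal", effective_n = N),
            level = level)
        })
      k <- k + 1
      out[[k]] <- data.frame(
        label = rows$label[i], method = m, level = level,
        p_lower = iv$p_lower, p_upper = iv$p_upper,
        neglog10_lower = -log10(iv$p_lower),
        neglog10_upper = -log10(iv$p_upper),
        stat_lower = iv$stat_lower, stat_upper = iv$stat_upper)
    }
  }
  do.call(rbind, out)
}

#' Write an interval report as tab-separated text
#'
#' Fixed column order with P endpoints both at 3 significant figures (for
#' display) and at machine precision (for regression comparisons).
#'
#' @param report a [batch_intervals()] result.
#' @param path output file, or `""` for standard output.
#' @return `report`, invisibly.
#' @export
write_interval_report <- function(report, path = "") {
  disp <- report
  disp$p_lower_disp <- signif(report$p_lower, 3)
  disp$p_upper_disp <- signif(report$p_upper, 3)
  cols <- c("label", "method", "level", "p_lower_disp", "p_upper_disp",
            "neglog10_lower", "neglog10_upper", "stat_lower", "stat_upper",
            "p_lower", "p_upper")
  utils::write.table(disp[, cols], file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Generate the synthetic example files shipped with the package workflows
#'
#' Writes, deterministically for a given seed: a synthetic L-shaped
#' odds-ratio prior table (heavy mass at the null odds ratio 1.005, a thin
#' tail up to OR about 1.5 -- the qualitative shape of genome-wide effect
#' size distributions); a synthetic study table in the
#' `label/cases/controls/p_one_sided` format; and YAML coverage-experiment
#' configurations for the no-selection, window, threshold and min-of-L
#' scenarios. Repeated calls with the same seed produce byte-identical
#' files.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the vector of files written.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)

  # L-shaped synthetic OR table: counts drop steeply with OR
  ors <- c(1.05, 1.10, 1.15, 1.20, 1.30, 1.50)
  base <- c(2500, 1300, 500, 160, 40, 8)
  counts <- pmax(0, round(base * exp(stats::rnorm(length(base), 0, 0.1))))
  prior_path <- file.path(dir, "synthetic_or_prior.tsv")
  writeLines(c("# synthetic L-shaped odds-ratio effect-size table",
               "# M=300000",
               "or\tcount",
               sprintf("%.2f\t%d", ors, counts)),
             prior_path)

  # synthetic study table: a few case/control rows with one-sided P-values
  n_stud <- 5
  cases <- round(stats::runif(n_stud, 2000, 12000))
  controls <- round(stats::runif(n_stud, 2000, 12000))
  p <- signif(10^stats::runif(n_stud, -6, -0.3), 4)
  study_path <- file.path(dir, "synthetic_studies.tsv")
  writeLines(c("# synthetic replication-study table",
               "label\tcases\tcontrols\tp_one_sided",
               sprintf("study_%d\t%d\t%d\t%g",
                       seq_len(n_stud), cases, controls, p)),
             study_path)

  cfgs <- list(
    coverage_none = list(sigma0_sq = 0.25, method = "p_interval",
                         level = 0.8, reps = 50000, seed = seed,
                         selection = list(mode = "none")),
    coverage_window = list(sigma0_sq = 0.25, method = "p_interval",
                           level = 0.8, reps = 50000, seed = seed,
                           selection = list(mode = "window",
                                            p_low = 0.045, p_high = 0.055)),
    coverage_threshold = list(sigma0_sq = 0.25, method = "p_interval",
                              level = 0.8, reps = 50000, seed = seed,
                              selection = list(mode = "threshold",
                                               p_high = 0.001)),
    coverage_min_of_L = list(sigma0_sq = 0.25, method = "p_interval",
                             level = 0.8, reps = 2000, seed = seed,
                             selection = list(mode = "min_of_L", L = 10000)))
  cfg_paths <- vapply(names(cfgs), function(nm) {
    p <- file.path(dir, paste0(nm, ".yaml"))
    yaml::write_yaml(cfgs[[nm]], p)
    p
  }, character(1))

  invisible(c(prior_path, study_path, cfg_paths))
}
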