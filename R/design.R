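#' Simulation design for a case-control miRNA-seq count matrix
#'
#' Bundles every parameter of the synthetic count generator. The defaults
#' describe a cohort of 24 cases and 21 controls with 246 detectable miRNAs,
#' 14 of which carry standardized group effects (Cohen's d on the log2
#' expression scale) of magnitude 0.83-0.97, ten up- and four down-regulated
#' in cases -- the structure of the salivary miRNA study the package is
#' modelled on.
#'
#' @param n_case,n_control Number of case / control subjects (each >= 2).
#' @param n_features Total number of miRNA features.
#' @param informative_effects Numeric vector of standardized effect sizes
#'   (Cohen's d on the log2 scale), one per informative feature; the sign
#'   gives the direction in cases. May be empty for a global-null design.
#' @param baseline_log_mean_range Bounds of the uniform distribution of
#'   per-feature baseline log2 expression (roughly log2 reads-per-million).
#'   The default (4, 12) spans low-abundance to abundant miRNAs while
#'   keeping the library composition spread across many features, so the
#'   configured effect sizes survive reads-per-million renormalization
#'   essentially unchanged (see the methods vignette).
#' @param log_sd Within-group biological standard deviation on the log2
#'   scale; the case-group shift of an informative feature is
#'   `d * log_sd` log2 units.
#' @param library_size_range Bounds of the uniform per-subject total read
#'   count (the study targeted about 3 million reads per sample).
#' @param dropout_rate Mean per-cell probability that a null feature's count
#'   is zeroed. Rates vary across features (see [sim_counts()]) so that the
#'   detection filter has work to do.
#' @param seed Integer seed; fixing it fixes every generated artifact.
#'
#' @return A list of class `mir_design`.
#' @seealso [sim_counts()], [behavior_design()]
#' @export
#' @examples
#' d <- sim_design(n_case = 6, n_control = 6, n_features = 30,
#'                 informative_effects = c(1, -1))
sim_design <- function(n_case = 24,
                       n_control = 21,
                       n_features = 246,
                       informative_effects = default_effects(),
                       baseline_log_mean_range = c(4, 12),
                       log_sd = 1,
                       library_size_range = c(2e6, 4e6),
                       dropout_rate = 0.2,
                       seed = 42) {
  if (n_case < 2 || n_control < 2) {
    abort("`n_case` and `n_control` must both be at least 2.")
  }
  if (length(informative_effects) > n_features) {
    abort("More informative effects than features.")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).")
  }
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0) {
    abort("`library_size_range` must be a positive ordered pair.")
  }
  if (length(baseline_log_mean_range) != 2L ||
      diff(baseline_log_mean_range) < 0) {
    abort("`baseline_log_mean_range` must be an ordered pair.")
  }
  if (log_sd <= 0) abort("`log_sd` must be positive.")
  structure(
    list(
      n_case = as.integer(n_case),
      n_control = as.integer(n_control),
      n_features = as.integer(n_features),
      informative_effects = as.numeric(informative_effects),
      baseline_log_mean_range = as.numeric(baseline_log_mean_range),
      log_sd = as.numeric(log_sd),
      library_size_range = as.numeric(library_size_range),
      dropout_rate = as.numeric(dropout_rate),
      seed = as.integer(seed)
    ),
    class = "mir_design"
  )
}

#' Default informative effect sizes
#'
#' Signed Cohen's d values for the 14 informative features of the default
#' design: magnitudes 0.83-0.97 with ten positive (up in cases) and four
#' negative (down in cases), mirroring the published panel.
#'
#' @return Numeric vector of length 14.
#' @export
default_effects <- function() {
  c(0.83, 0.96, -0.90, 0.89, 0.91, -0.90, 0.90,
    0.89, -0.90, 0.93, 0.96, 0.97, -0.91, 0.96)
}

#' Behavior-score design for synthetic subjects
#'
#' Parameters of the Vineland-like adaptive behavior scores attached to
#' simulated subjects. Defaults are the group means and standard deviations
#' of the study cohort: composite 105.3 (SD 12.7) in controls versus 70.7
#' (SD 10.2) in cases, with analogous values for the communication,
#' socialization, and daily-living subscales.
#'
#' @param control_mean,control_sd,case_mean,case_sd Composite-score moments
#'   per group (SDs must be positive).
#' @param coupling Correlation in \[-1, 1\] between the latent severity of a
#'   subject (derived from the informative features) and the behavior
#'   scores. Positive coupling makes up-regulated informative features
#'   correlate negatively with the scores.
#' @param subscales Data frame with columns `measure`, `control_mean`,
#'   `control_sd`, `case_mean`, `case_sd` for the non-composite subscales.
#'
#' @return A list of class `mir_behavior_design`.
#' @export
behavior_design <- function(control_mean = 105.3, control_sd = 12.7,
                            case_mean = 70.7, case_sd = 10.2,
                            coupling = 0.5,
                            subscales = default_subscales()) {
  if (control_sd <= 0 || case_sd <= 0 || any(subscales$control_sd <= 0) ||
      any(subscales$case_sd <= 0)) {
    abort("Score standard deviations must be positive.")
  }
  if (abs(coupling) > 1) abort("`coupling` must lie in [-1, 1].")
  structure(
    list(
      control_mean = control_mean, control_sd = control_sd,
      case_mean = case_mean, case_sd = case_sd,
      coupling = coupling,
      subscales = tibble::as_tibble(subscales)
    ),
    class = "mir_behavior_design"
  )
}

#' @rdname behavior_design
#' @export
default_subscales <- function() {
  tibble::tribble(
    ~measure,      ~control_mean, ~control_sd, ~case_mean, ~case_sd,
    "vabs_comm",   110.1,         10.0,        76.0,       15.3,
    "vabs_social", 104.4,         15.7,        77.8,       14.3,
    "vabs_adl",    100.4,         11.0,        73.6,       10.9
  )
}

#' @export
print.mir_design <- function(x, ...) {
  cat("<mir_design>\n")
  cat(sprintf("  subjects: %d case / %d control\n", x$n_case, x$n_control))
  cat(sprintf("  features: %d (%d informative)\n",
              x$n_features, length(x$informative_effects)))
  cat(sprintf("  log_sd %.2f, dropout %.2f, seed %d\n",
              x$log_sd, x$dropout_rate, x$seed))
  invisible(x)
}
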