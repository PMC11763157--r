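#' Inhibition rate of a treatment relative to the assay window
#'
#' Percent inhibition of an induced readout (e.g. nitric-oxide absorbance in
#' an LPS-stimulated macrophage assay), anchored so the untreated model group
#' is 0% and the unstimulated control group is 100%:
#'
#'   100 * (mean_model - mean_treatment) / (mean_model - mean_control)
#'
#' @param mean_model,mean_treatment,mean_control group mean readouts.
#' @return inhibition rate in percent (vectorized over treatment means).
#' @export
inhibition_rate <- function(mean_model, mean_treatment, mean_control) {
  if (any(mean_model == mean_control))
    stop("assay window collapsed: model and control means are equal")
  100 * (mean_model - mean_treatment) / (mean_model - mean_control)
}

#' Normalize plate readouts to a treatment effect E in [0, 1]
#'
#' The control group is assigned a 100% treatment effect relative to the
#' model group; an arm's effect is its position in that window,
#' E = (mean_arm - mean_model) / (mean_control - mean_model), clamped to
#' [0, 1] as the Bliss model requires. The raw (unclamped) value and
#' replicate-level effects are retained for diagnostics and bootstrapping.
#'
#' @param readouts long-format data.frame with columns `group` and `value`
#'   (a `well` column is allowed and ignored).
#' @param arm arm group label to normalize.
#' @param control,model labels of the control and model groups.
#' @return object of class `effect_estimate`: list with `arm`, `E` (clamped),
#'   `raw`, and `replicates` (per-replicate unclamped effects).
#' @export
normalize_effect <- function(readouts, arm, control = "control",
                             model = "model") {
  stopifnot(all(c("group", "value") %in% names(readouts)))
  for (g in c(control, model, arm)) {
    if (sum(readouts$group == g) < 2)
      stop("group '", g, "' needs at least 2 replicates")
  }
  v <- function(g) readouts$value[readouts$group == g]
  m_ctl <- mean(v(control)); m_mod <- mean(v(model))
  if (m_ctl == m_mod) stop("control and model means are equal; effect undefined")
  raw <- (mean(v(arm)) - m_mod) / (m_ctl - m_mod)
  structure(list(
    arm = arm,
    E = min(max(raw, 0), 1),
    raw = raw,
    replicates = (v(arm) - m_mod) / (m_ctl - m_mod)
  ), class = "effect_estimate")
}

#' Bliss-independence expected additive effect
#'
#' For two agents with individual effects `E_a`, `E_b` in [0, 1], the effect
#' expected under probabilistic independence is `E_a + E_b - E_a * E_b`.
#' Commutative; bounded below by max(E_a, E_b) and above by 1.
#'
#' @param E_a,E_b individual effects in [0, 1].
#' @return expected combined effect.
#' @export
bliss_expected <- function(E_a, E_b) {
  if (any(E_a < 0 | E_a > 1) || any(E_b < 0 | E_b > 1))
    stop("effects must lie in [0, 1]")
  E_a + E_b - E_a * E_b
}

#' Combination index under the Bliss independence model
#'
#' CI = (E_a + E_b - E_a * E_b) / E_ab, the ratio of the Bliss-expected to
#' the observed combined effect. CI < 1 indicates synergy (the combination
#' outperforms independence), CI > 1 antagonism; values within
#' `additive_tol` of 1 are classified additive.
#'
#' @param E_a,E_b monotherapy effects in [0, 1].
#' @param E_ab observed combination effect (> 0).
#' @param additive_tol half-width of the additive band around CI = 1
#'   (default 0.05).
#' @return list with `CI`, `E_expected`, and `classification` in
#'   {"synergistic", "additive", "antagonistic"}.
#' @export
combination_index <- function(E_a, E_b, E_ab, additive_tol = 0.05) {
  if (E_ab <= 0) stop("combination effect must be positive; CI undefined")
  expected <- bliss_expected(E_a, E_b)
  ci <- expected / E_ab
  cls <- if (abs(ci - 1) <= additive_tol) "additive"
         else if (ci < 1) "synergistic" else "antagonistic"
  list(CI = ci, E_expected = expected, classification = cls)
}

#' Full synergy analysis of a two-drug plate assay
#'
#' Normalizes each monotherapy arm and the combination arm to effects with
#' [normalize_effect()], computes the Bliss expectation and combination
#' index, and optionally attaches a bootstrap percentile interval for CI.
#'
#' @param readouts long-format readout table (`group`, `value`).
#' @param arms character vector of the two monotherapy group labels.
#' @param combo combination group label.
#' @param control,model control/model group labels.
#' @param additive_tol additive classification band (see
#'   [combination_index()]).
#' @param n_boot bootstrap replicates for a CI interval (0 = none).
#' @param seed seed for the bootstrap.
#' @param level confidence level of the percentile interval.
#' @return object of class `synergy_result`.
#' @export
synergy_analysis <- function(readouts, arms, combo, control = "control",
                             model = "model", additive_tol = 0.05,
                             n_boot = 0, seed = 1, level = 0.95) {
  if (length(arms) != 2) stop("exactly two monotherapy arms are required")
  eff <- lapply(c(arms, combo), normalize_effect, readouts = readouts,
                control = control, model = model)
  names(eff) <- c(arms, combo)
  res <- combination_index(eff[[arms[1]]]$E, eff[[arms[2]]]$E,
                           eff[[combo]]$E, additive_tol = additive_tol)
  out <- list(effects = eff, E_expected = res$E_expected, CI = res$CI,
              classification = res$classification, arms = arms, combo = combo)
  if (n_boot > 0) {
    out$boot_interval <- bootstrap_ci(readouts, arms, combo, control = control,
                                      model = model, n_boot = n_boot,
                                      seed = seed, level = level)
  }
  class(out) <- "synergy_result"
  out
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("Bliss-independence synergy analysis\n")
  for (a in c(x$arms, x$combo))
    cat(sprintf("  E[%s] = %.4f\n", a, x$effects[[a]]$E))
  cat(sprintf("  Bliss expected effect = %.4f\n", x$E_expected))
  cat(sprintf("  Combination index CI  = %.4f (%s)\n", x$CI,
              x$classification))
  if (!is.null(x$boot_interval))
    cat(sprintf("  Bootstrap %g%% interval: [%.4f, %.4f]\n",
                100 * attr(x$boot_interval, "level"),
                x$boot_interval[1], x$boot_interval[2]))
  invisible(x)
}

#' Bootstrap percentile interval for the combination index
#'
#' Resamples replicates within every group (control, model, both arms,
#' combination) and recomputes CI; returns the percentile interval. Seeded
#' and reproducible.
#'
#' @inheritParams synergy_analysis
#' @param n_boot number of bootstrap resamples (default 2000).
#' @return length-2 numeric vector (lower, upper) with attribute `level`.
#' @export
bootstrap_ci <- function(readouts, arms, combo, control = "control",
                         model = "model", n_boot = 2000, seed = 1,
                         level = 0.95) {
  groups <- c(control, model, arms, combo)
  vals <- lapply(groups, function(g) readouts$value[readouts$group == g])
  names(vals) <- groups
  if (any(vapply(vals, length, 1L) < 3))
    stop("bootstrap needs at least 3 replicates per group")
  set.seed(seed)
  cis <- vapply(seq_len(n_boot), function(i) {
    rs <- lapply(vals, function(v) sample(v, length(v), replace = TRUE))
    m <- vapply(rs, mean, 1)
    den <- m[[control]] - m[[model]]
    if (den == 0) return(NA_real_)
    E <- function(g) min(max((m[[g]] - m[[model]]) / den, 0), 1)
    eab <- E(combo)
    if (eab <= 0) return(NA_real_)
    bliss_expected(E(arms[1]), E(arms[2])) / eab
  }, 1)
  int <- stats::quantile(cis, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                         na.rm = TRUE, names = FALSE)
  attr(int, "level") <- level
  int
}
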