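#' Classification rule for exposure effects
#'
#' An exposure is declared causal for an outcome when its coefficient
#' exceeds `beta_threshold` AND its p-value is below `alpha` (both strict).
#' For the proxy-adjusted effect, which has no test of its own, three rules
#' are available:
#' \describe{
#'   \item{`point_threshold_with_conv_p` (default)}{`beta_hat >
#'     beta_threshold` and the *conventional* coefficient's p-value `< alpha`
#'     — the adjusted point estimate must clear the threshold and the
#'     underlying association must be statistically real.}
#'   \item{`point_threshold_only`}{`beta_hat > beta_threshold` alone.}
#'   \item{`combined_wald`}{`beta_hat > beta_threshold` and a two-sided
#'     normal p-value from `beta_hat / se_combined` `< alpha`. Requires the
#'     combined standard error; an extrapolation beyond the method's own
#'     definition, for sensitivity analysis.}
#' }
#'
#' @param beta_threshold Minimum log-odds coefficient (default 0.05).
#' @param alpha Significance level (default 0.05).
#' @param adjusted_rule One of the three rule names above.
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(beta_threshold = 0.05, alpha = 0.05,
                                adjusted_rule = c("point_threshold_with_conv_p",
                                                  "point_threshold_only",
                                                  "combined_wald")) {
  if (beta_threshold < 0) stop("`beta_threshold` must be >= 0.", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1).", call. = FALSE)
  structure(list(beta_threshold = beta_threshold, alpha = alpha,
                 adjusted_rule = match.arg(adjusted_rule)),
            class = "classification_rule")
}

#' Classify a fitted exposure coefficient
#'
#' @param beta Exposure coefficient (log-odds scale).
#' @param p Two-sided p-value for `beta`.
#' @param rule A [classification_rule()].
#' @return `TRUE` iff `beta > beta_threshold` and `p < alpha` (strict).
#' @examples
#' rule <- classification_rule()
#' classify_fitted(1.27, 1e-4, rule)   # causal
#' classify_fitted(-0.024, 0.668, rule) # not causal
#' classify_fitted(0.05, 0.01, rule)   # boundary: not causal (strict >)
#' @export
classify_fitted <- function(beta, p, rule = classification_rule()) {
  stopifnot(inherits(rule, "classification_rule"))
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1].", call. = FALSE)
  beta > rule$beta_threshold && p < rule$alpha
}

#' Classify a proxy-adjusted effect
#'
#' @param adj An [adjusted_effect()].
#' @param rule A [classification_rule()]; see its help for the three
#'   adjusted-effect rules.
#' @return `TRUE` iff the adjusted effect is classified causal.
#' @export
classify_adjusted <- function(adj, rule = classification_rule()) {
  stopifnot(inherits(adj, "adjusted_effect"), inherits(rule, "classification_rule"))
  above <- adj$beta_hat > rule$beta_threshold
  switch(rule$adjusted_rule,
    point_threshold_with_conv_p = above && adj$p_conv < rule$alpha,
    point_threshold_only = above,
    combined_wald = {
      if (is.null(adj$se_combined) || is.na(adj$se_combined))
        stop("`combined_wald` rule requires `se_combined` in the adjusted effect.",
             call. = FALSE)
      p <- 2 * stats::pnorm(-abs(adj$beta_hat / adj$se_combined))
      above && p < rule$alpha
    })
}

scenario_labels <- c("A_not_B", "A_and_B", "B_not_A", "neither")

#' Scenario class from the two per-outcome classifications
#'
#' Maps (causal for A, causal for B) to one of the four scenario labels
#' `A_not_B`, `A_and_B`, `B_not_A`, `neither`. The design truth of the
#' validation study is `A_not_B`.
#'
#' @param causal_A,causal_B Logicals.
#' @return An object of class `scenario_class`: list with `causal_A`,
#'   `causal_B`, `label`.
#' @export
scenario_class <- function(causal_A, causal_B) {
  stopifnot(is.logical(causal_A), is.logical(causal_B))
  label <- if (causal_A && !causal_B) "A_not_B"
    else if (causal_A && causal_B) "A_and_B"
    else if (!causal_A && causal_B) "B_not_A"
    else "neither"
  structure(list(causal_A = causal_A, causal_B = causal_B, label = label),
            class = "scenario_class")
}

#' @export
print.scenario_class <- function(x, ...) {
  cat(sprintf("scenario: %s (causal for A: %s, causal for B: %s)\n",
              x$label, x$causal_A, x$causal_B))
  invisible(x)
}
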