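#' Simulation configuration
#'
#' Collects every tunable of the sufficient-cause simulator. The defaults are
#' the study conditions of the validation experiment: 40 correlated binary
#' variables over 50000 observations, latent threshold 0.75, mixing
#' proportions drawn uniformly on \[0.3, 0.8), competing-event probability
#' 0.1, background-cause probability 0.05, causal-pair probability 0.5, and
#' acknowledgement probabilities 0.5 (indices 2-20, the block that can hold
#' real causes) and 0.15 (indices 21-40, pure noise).
#'
#' @param n_vars Number of binary variables (>= 21 so that the ten matched
#'   pairs `(X_i, X_{i+10})` and a noise block exist).
#' @param n_obs Number of observations per replicate.
#' @param threshold Latent threshold: `X = 1` iff the latent mixture is
#'   `>= threshold`. Must lie strictly in (0, 1).
#' @param p_low,p_high Bounds of the uniform distribution the mixing
#'   proportions `P_i` are drawn from (half-open, `[p_low, p_high)`). `P_i`
#'   is the weight of the shared uniform component, so larger `P_i` means
#'   stronger dependence between variables.
#' @param competing_prob Bernoulli probability of a competing event `E`.
#' @param background_prob Bernoulli probability of a background sufficient
#'   cause `Q` (the small error term that prevents perfect separation).
#' @param know_prob_low_block Probability that a variable with index 2-20 is
#'   acknowledged as a suspected cause.
#' @param know_prob_high_block Probability that a variable with index
#'   21-`n_vars` is acknowledged. (Named for the index block, which sits
#'   above 20; its acknowledgement probability is the lower one.)
#' @param cause_prob Bernoulli probability that a matched pair is a component
#'   cause of a given outcome (entries of `F` other than the forced ones).
#' @param q_overrides_competing Logical; if `TRUE` (default) a background
#'   cause `Q = 1` forces the outcome even when the competing event is
#'   present. If `FALSE` the competing event suppresses all sufficient
#'   causes including `Q`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_obs = 1000)
#' cfg$threshold
#' @export
sim_config <- function(n_vars = 40L,
                       n_obs = 50000L,
                       threshold = 0.75,
                       p_low = 0.3,
                       p_high = 0.8,
                       competing_prob = 0.1,
                       background_prob = 0.05,
                       know_prob_low_block = 0.5,
                       know_prob_high_block = 0.15,
                       cause_prob = 0.5,
                       q_overrides_competing = TRUE) {
  cfg <- list(
    n_vars = as.integer(n_vars),
    n_obs = as.integer(n_obs),
    threshold = threshold,
    p_low = p_low,
    p_high = p_high,
    competing_prob = competing_prob,
    background_prob = background_prob,
    know_prob_low_block = know_prob_low_block,
    know_prob_high_block = know_prob_high_block,
    cause_prob = cause_prob,
    q_overrides_competing = isTRUE(q_overrides_competing)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_vars < 21L)
    stop("`n_vars` must be at least 21: pairs (X_i, X_{i+10}) for i = 1..10 ",
         "plus a noise block are required.", call. = FALSE)
  if (cfg$n_obs < 1L)
    stop("`n_obs` must be positive.", call. = FALSE)
  if (!(cfg$threshold > 0 && cfg$threshold < 1))
    stop("`threshold` must lie strictly in (0, 1).", call. = FALSE)
  if (!(cfg$p_low >= 0 && cfg$p_low <= cfg$p_high && cfg$p_high <= 1))
    stop("need 0 <= p_low <= p_high <= 1.", call. = FALSE)
  probs <- c(cfg$competing_prob, cfg$background_prob,
             cfg$know_prob_low_block, cfg$know_prob_high_block,
             cfg$cause_prob)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1].", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Sufficient-cause simulation configuration\n")
  cat(sprintf("  variables: %d   observations: %d\n", x$n_vars, x$n_obs))
  cat(sprintf("  latent threshold %.3g, mixing proportions U[%.3g, %.3g)\n",
              x$threshold, x$p_low, x$p_high))
  cat(sprintf("  P(competing event) = %.3g, P(background cause) = %.3g, P(causal pair) = %.3g\n",
              x$competing_prob, x$background_prob, x$cause_prob))
  cat(sprintf("  acknowledgement: %.3g (indices 2-20), %.3g (indices 21-%d)\n",
              x$know_prob_low_block, x$know_prob_high_block, x$n_vars))
  invisible(x)
}
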