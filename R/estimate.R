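#' @importFrom stats glm.fit binomial pnorm glm.control
NULL

# Core logistic engine shared by all model fits.
#
# Wraps stats::glm.fit (IRLS) with: an intercept column, rank screening that
# drops aliased columns with a warning instead of failing, Wald standard
# errors from the final weighted QR, and a conservative convergence flag
# (IRLS converged, no boundary fit, no coefficient at a magnitude only
# separation produces). Tight epsilon so closed-form identities hold to 1e-8.
logistic_fit <- function(y, design, offset = NULL, model_tag = "logistic",
                         intercept = TRUE) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1.", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate data: outcome is constant, logistic model undefined.",
         call. = FALSE)
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (nrow(design) != length(y))
    stop("design matrix and outcome lengths differ.", call. = FALSE)
  X <- if (intercept) cbind(`(Intercept)` = 1, design) else design

  ## drop aliased (collinear or constant) columns up front
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- sort(qx$pivot[-seq_len(qx$rank)])
    if (intercept && 1L %in% drop_idx)
      drop_idx <- setdiff(drop_idx, 1L)  # never drop the intercept
    warning(sprintf("dropping aliased column(s): %s",
                    paste(colnames(X)[drop_idx], collapse = ", ")),
            call. = FALSE)
    X <- X[, -drop_idx, drop = FALSE]
  }

  if (is.null(offset)) offset <- rep(0, length(y))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), offset = offset,
                   control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  p <- fit$rank
  Qr <- fit$qr
  cov_piv <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se_piv <- sqrt(diag(cov_piv))
  names(se_piv) <- colnames(X)[Qr$pivot[seq_len(p)]]
  coef <- fit$coefficients
  se <- se_piv[names(coef)]
  z <- coef / se
  pval <- 2 * stats::pnorm(-abs(z))
  converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    all(is.finite(se)) && max(abs(coef)) < 20
  structure(list(coef = coef, se = se, pvalue = pval,
                 converged = converged, n_obs = length(y),
                 model_tag = model_tag),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Logistic fit (%s), n = %d, %s\n", x$model_tag, x$n_obs,
              if (x$converged) "converged" else "NOT CONVERGED"))
  tab <- data.frame(coef = x$coef, se = x$se, p = x$pvalue)
  print(round(tab, 4))
  invisible(x)
}

exposure_term <- "x1"

#' Fit the fact (oracle) model
#'
#' Logistic regression of the outcome on the exposure and the true-cause
#' indicator `G` (presence of any completed non-exposure causal pair, from
#' [compute_cause_indicator()]). Because `G` captures the entire
#' non-exposure causal mechanism, the exposure coefficient from this fit is
#' the true effect, and its classification serves as the gold standard the
#' conventional and proxy-adjusted approaches are compared against.
#'
#' @param y Binary outcome vector for outcome j.
#' @param x1 Binary exposure vector.
#' @param g Binary true-cause indicator vector for outcome j.
#' @return A `fit_result` with terms `(Intercept)`, `x1`, `g`.
#' @export
fit_fact_model <- function(y, x1, g) {
  logistic_fit(y, cbind(x1 = x1, g = g), model_tag = "fact")
}

knowledge_design <- function(X, K_j) {
  M <- if (inherits(X, "binary_matrix")) X$values else X
  K_j <- as.integer(K_j)
  if (length(K_j) != nrow(M))
    stop("knowledge mask length must equal the number of variables.",
         call. = FALSE)
  if (K_j[1L] != 1L)
    stop("the exposure (index 1) must be in the model: K[1] must be 1.",
         call. = FALSE)
  sel <- c(1L, which(K_j[-1L] == 1L) + 1L)
  D <- t(M[sel, , drop = FALSE])
  colnames(D) <- paste0("x", sel)
  D
}

#' Fit the conventional multivariable adjustment model
#'
#' Logistic regression of the outcome on the exposure plus every covariate
#' the researcher's knowledge mask acknowledges (`K_j[i] = 1`, `i >= 2`).
#' This is standard multivariable adjustment under imperfect knowledge: some
#' real causes are missed and some noise variables are included, so the
#' exposure coefficient carries residual confounding.
#'
#' @param y Binary outcome vector for outcome j.
#' @param X A `binary_matrix` (or `n_vars` x `n_obs` 0/1 matrix).
#' @param K_j Knowledge-mask row for outcome j (length `n_vars`,
#'   `K_j[1] = 1`).
#' @return A `fit_result`; the exposure coefficient is the term `x1`.
#' @export
fit_conventional_model <- function(y, X, K_j) {
  logistic_fit(y, knowledge_design(X, K_j), model_tag = "conventional")
}

#' Fit the proxy-outcome model
#'
#' Identical design to [fit_conventional_model()] — the same covariate set
#' selected by the knowledge mask of the outcome under study — but with the
#' proxy outcome as the response. Since the exposure does not cause the
#' proxy outcome, its coefficient here estimates the confounding carried by
#' the shared causal background, and is subtracted off by
#' [adjusted_effect()].
#'
#' @param y_proxy Binary proxy-outcome vector (outcome C).
#' @param X A `binary_matrix` (or 0/1 matrix).
#' @param K_j Knowledge-mask row of the outcome under study.
#' @return A `fit_result` with `model_tag = "proxy"`.
#' @export
fit_proxy_model <- function(y_proxy, X, K_j) {
  logistic_fit(y_proxy, knowledge_design(X, K_j), model_tag = "proxy")
}

#' Proxy-adjusted exposure effect
#'
#' The confounding-corrected exposure effect on the log-odds scale:
#' \deqn{\hat\beta = \beta' - \tilde\beta',}
#' the conventional-model exposure coefficient minus the proxy-model one.
#' The p-value carried forward is that of the conventional coefficient (the
#' method itself defines no test for the difference); `se_combined`
#' optionally combines the two standard errors as
#' `sqrt(se_conv^2 + se_proxy^2)`, an extrapolation that ignores the
#' positive correlation of the two fits and is provided for sensitivity
#' analysis only.
#'
#' @param fit_conv `fit_result` from [fit_conventional_model()].
#' @param fit_proxy `fit_result` from [fit_proxy_model()].
#' @param combine_se Logical; also compute `se_combined`.
#' @return An object of class `adjusted_effect` with fields `beta_conv`,
#'   `beta_proxy`, `beta_hat`, `p_conv`, `se_combined`.
#' @examples
#' # the two worked identities of the validation study:
#' # 0.79 - 0.09 = 0.70  and  0.12 - 0.16 = -0.04
#' @export
adjusted_effect <- function(fit_conv, fit_proxy, combine_se = TRUE) {
  stopifnot(inherits(fit_conv, "fit_result"), inherits(fit_proxy, "fit_result"))
  if (!fit_conv$converged || !fit_proxy$converged)
    stop("cannot form the adjusted effect from an unconverged fit.",
         call. = FALSE)
  for (f in list(fit_conv, fit_proxy))
    if (!exposure_term %in% names(f$coef))
      stop("fit lacks the exposure term `x1`.", call. = FALSE)
  bc <- unname(fit_conv$coef[exposure_term])
  bp <- unname(fit_proxy$coef[exposure_term])
  se <- if (combine_se)
    sqrt(unname(fit_conv$se[exposure_term])^2 +
         unname(fit_proxy$se[exposure_term])^2) else NA_real_
  structure(list(beta_conv = bc, beta_proxy = bp, beta_hat = bc - bp,
                 p_conv = unname(fit_conv$pvalue[exposure_term]),
                 se_combined = se),
            class = "adjusted_effect")
}

#' @export
print.adjusted_effect <- function(x, ...) {
  cat(sprintf("Proxy-adjusted effect: %.4f - %.4f = %.4f (p[conventional] = %.3g)\n",
              x$beta_conv, x$beta_proxy, x$beta_hat, x$p_conv))
  invisible(x)
}

#' Crude rate ratios for outcome and proxy outcome
#'
#' Person-time rate ratios `(d1/t1)/(d0/t0)` comparing exposed to unexposed,
#' for the study outcome and (when proxy counts are supplied) the proxy
#' outcome. When the exposure is not causal, the two ratios estimate the
#' same confounding-driven quantity and should coincide; an outcome ratio
#' exceeding the proxy ratio indicates a causal exposure effect.
#'
#' @param d1,d0 Case counts in the exposed / unexposed person-time.
#' @param t1,t0 Exposed / unexposed person-time at risk (positive).
#' @param d1_proxy,d0_proxy Optional proxy-outcome case counts.
#' @return List with `rr_outcome` and (if proxy counts given) `rr_proxy`.
#' @export
crude_rate_ratio <- function(d1, t1, d0, t0, d1_proxy = NULL, d0_proxy = NULL) {
  if (t1 <= 0 || t0 <= 0) stop("person-time must be positive.", call. = FALSE)
  if (any(c(d1, d0, d1_proxy, d0_proxy) < 0))
    stop("counts must be non-negative.", call. = FALSE)
  if (d0 == 0)
    stop("undefined ratio: no unexposed cases (d0 = 0).", call. = FALSE)
  out <- list(rr_outcome = (d1 / t1) / (d0 / t0))
  if (!is.null(d1_proxy) || !is.null(d0_proxy)) {
    if (is.null(d1_proxy) || is.null(d0_proxy))
      stop("supply both proxy counts or neither.", call. = FALSE)
    if (d0_proxy == 0)
      stop("undefined ratio: no unexposed proxy cases.", call. = FALSE)
    out$rr_proxy <- (d1_proxy / t1) / (d0_proxy / t0)
  }
  out
}

#' Expected crude outcome ratio under a sufficient-cause decomposition
#'
#' The crude outcome rate ratio expected when the exposure carries risk `r`
#' and background sufficient causes occur with per-unit probabilities
#' `p_d1` (exposed) and `p_d0` (unexposed):
#' \deqn{\{r (1 - p_{d1}) + p_{d1}\} / p_{d0}.}
#' With `r = 0` this reduces to `p_d1 / p_d0` — the same quantity the proxy
#' outcome's crude ratio estimates — and for any `r > 0` (with `p_d1 < 1`)
#' it strictly exceeds it, which is what makes the outcome-vs-proxy
#' comparison informative about causality.
#'
#' @param r Risk of the outcome attributable to the exposure (`>= 0`).
#' @param p_d1,p_d0 Background sufficient-cause probabilities per unit
#'   person-time, exposed and unexposed (`p_d0 > 0`).
#' @return The expected ratio (numeric scalar).
#' @export
expected_outcome_ratio <- function(r, p_d1, p_d0) {
  if (p_d0 <= 0) stop("undefined ratio: p_d0 must be positive.", call. = FALSE)
  if (p_d1 < 0 || p_d1 > 1) stop("p_d1 must lie in [0, 1].", call. = FALSE)
  if (r < 0) stop("r must be >= 0.", call. = FALSE)
  (r * (1 - p_d1) + p_d1) / p_d0
}

#' Offset correction of a logistic exposure effect
#'
#' Fits a logistic model of the outcome on the exposure with the per-subject
#' offset `exposure * proxy_log_or`, where `proxy_log_or` is the log odds
#' ratio of the exposure on the proxy outcome (estimated from a separate
#' model). Entering the confounding estimate as an offset subtracts it from
#' the exposure coefficient, so the exponentiated fitted coefficient is the
#' confounding-corrected odds ratio. In the two-group case this equals
#' `crude OR / proxy OR` exactly.
#'
#' @param outcome Binary outcome vector.
#' @param exposure Binary exposure vector.
#' @param proxy_log_or Log odds ratio from the proxy-outcome model.
#' @return A `fit_result` with `model_tag = "offset"`; the adjusted odds
#'   ratio is `exp(coef["x1"])`.
#' @examples
#' # crude OR exactly 0.54 (unexposed odds 1, exposed odds 0.54);
#' # offsetting by log(0.60) yields adjusted OR 0.54/0.60 = 0.90
#' y <- c(rep(1, 7700), rep(0, 7700), rep(1, 2700), rep(0, 5000))
#' x <- c(rep(0, 15400), rep(1, 7700))
#' fit <- offset_adjust(y, x, log(0.60))
#' exp(fit$coef[["x1"]])
#' @export
offset_adjust <- function(outcome, exposure, proxy_log_or) {
  stopifnot(is.numeric(proxy_log_or), length(proxy_log_or) == 1L)
  logistic_fit(outcome, cbind(x1 = as.numeric(exposure)),
               offset = as.numeric(exposure) * proxy_log_or,
               model_tag = "offset")
}

#' Offset correction from a delimited text file
#'
#' Convenience wrapper: reads a CSV with named binary outcome and exposure
#' columns and applies [offset_adjust()].
#'
#' @param path CSV path.
#' @param outcome_col,exposure_col Column names.
#' @param proxy_log_or Log odds ratio from the proxy-outcome model.
#' @return A `fit_result`.
#' @export
offset_adjust_csv <- function(path, outcome_col, exposure_col, proxy_log_or) {
  dat <- utils::read.csv(path)
  for (col in c(outcome_col, exposure_col))
    if (!col %in% names(dat))
      stop(sprintf("column `%s` not found in %s.", col, path), call. = FALSE)
  offset_adjust(dat[[outcome_col]], dat[[exposure_col]], proxy_log_or)
}

#' Serialise a fit result to JSON
#'
#' Writes `term -> {coef, se, p}` plus convergence metadata.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  terms <- lapply(seq_along(fit$coef), function(i)
    list(coef = unname(fit$coef[i]), se = unname(fit$se[i]),
         p = unname(fit$pvalue[i])))
  names(terms) <- names(fit$coef)
  jsonlite::write_json(
    list(model_tag = fit$model_tag, n_obs = fit$n_obs,
         converged = fit$converged, terms = terms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
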