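#' Generate a correlated binary covariate matrix
#'
#' Latent uniform-mixture threshold construction. For each variable `i` a
#' mixing proportion `P_i ~ Uniform[p_low, p_high)` is drawn; for each
#' observation `n` a shared uniform `U_n` and variable-specific uniforms
#' `V_in` are drawn, the latent value is the mixture
#' `T_in = V_in (1 - P_i) + U_n P_i`, and `X_in = 1` iff `T_in >= threshold`.
#' The shared component `U_n` induces positive correlation between all
#' variables; `P_i` is its weight, so the defaults (`P_i` on \[0.3, 0.8))
#' produce the low-to-moderate dependence regime of the validation study
#' (mean pairwise phi correlation about 0.29).
#'
#' Uses the R random number generator; call [set.seed()] beforehand for
#' reproducibility. Draw order is fixed: `P` (length `n_vars`), `U`
#' (length `n_obs`), then `V` (column-major `n_vars` by `n_obs`).
#'
#' @param config A [sim_config()].
#' @return An object of class `binary_matrix`: a list with `values`
#'   (`n_vars` x `n_obs` integer 0/1 matrix) and `mixing_props`
#'   (the drawn `P_i`).
#' @seealso [marginal_prevalence()] for the closed-form column prevalence,
#'   [correlation_summary()] for the pairwise-correlation summary.
#' @examples
#' set.seed(1)
#' bm <- generate_correlated_binary(sim_config(n_obs = 500))
#' dim(bm$values)
#' @export
generate_correlated_binary <- function(config = sim_config()) {
  validate_sim_config(config)
  nv <- config$n_vars
  no <- config$n_obs
  P <- stats::runif(nv, config$p_low, config$p_high)
  U <- stats::runif(no)
  V <- matrix(stats::runif(nv * no), nrow = nv, ncol = no)
  lat <- V * (1 - P) + rep(U, each = nv) * P
  X <- matrix(as.integer(lat >= config$threshold), nrow = nv, ncol = no)
  structure(list(values = X, mixing_props = P), class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary_matrix: %d variables x %d observations\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  mixing proportions in [%.3f, %.3f]\n",
              min(x$mixing_props), max(x$mixing_props)))
  invisible(x)
}

#' Closed-form marginal prevalence of a generated variable
#'
#' Probability that `V p + U (1 - p) >= threshold` for independent
#' `U, V ~ Uniform[0, 1)`: the upper tail of the trapezoidal distribution of
#' a weighted sum of two uniforms, in closed form. Because `U` and `V` are
#' exchangeable the value is symmetric in `p` vs `1 - p`, so it applies
#' unchanged whichever component carries the weight `p`. Serves as the
#' analytic oracle for empirical column means of
#' [generate_correlated_binary()].
#'
#' @param p_i Mixing proportion in \[0, 1\] (vectorised).
#' @param threshold Threshold strictly in (0, 1).
#' @return `P(T >= threshold)`, same length as `p_i`.
#' @examples
#' marginal_prevalence(0, 0.75)    # P(U >= 0.75) = 0.25
#' marginal_prevalence(0.5, 0.75)  # 0.125
#' @export
marginal_prevalence <- function(p_i, threshold) {
  if (!(threshold > 0 && threshold < 1))
    stop("`threshold` must lie strictly in (0, 1).", call. = FALSE)
  if (any(p_i < 0 | p_i > 1))
    stop("`p_i` must lie in [0, 1].", call. = FALSE)
  vapply(p_i, function(p) {
    a <- min(p, 1 - p)
    b <- max(p, 1 - p)
    t <- threshold
    if (a == 0) return(1 - t)            # degenerate: T ~ Uniform[0,1)
    cdf <- if (t < a) {
      t^2 / (2 * a * b)
    } else if (t < b) {
      (t - a / 2) / b
    } else {
      1 - (1 - t)^2 / (2 * a * b)
    }
    1 - cdf
  }, numeric(1))
}

#' Summarise pairwise correlations of a binary matrix
#'
#' Pearson (phi) correlations over all distinct unordered variable pairs,
#' summarised by mean, standard deviation and quartiles. Zero-variance
#' variables (possible at small `n_obs`) are excluded with a warning, since
#' their correlations are undefined.
#'
#' @param X A `binary_matrix` or a plain 0/1 matrix (variables in rows).
#' @return A list with `mean`, `sd`, `p25`, `p50`, `p75`, and `n_pairs`.
#' @examples
#' set.seed(1)
#' bm <- generate_correlated_binary(sim_config(n_obs = 2000))
#' correlation_summary(bm)$mean
#' @export
correlation_summary <- function(X) {
  M <- if (inherits(X, "binary_matrix")) X$values else X
  if (!is.matrix(M) || nrow(M) < 2L)
    stop("need a matrix with at least 2 variables (rows).", call. = FALSE)
  v <- apply(M, 1L, stats::var)
  keep <- v > 0
  if (!all(keep)) {
    warning(sprintf("%d zero-variance variable(s) excluded from correlation summary.",
                    sum(!keep)), call. = FALSE)
    M <- M[keep, , drop = FALSE]
    if (nrow(M) < 2L)
      stop("fewer than 2 variables with positive variance.", call. = FALSE)
  }
  cm <- stats::cor(t(M))
  r <- cm[upper.tri(cm)]
  q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
  list(mean = mean(r), sd = stats::sd(r),
       p25 = q[1], p50 = q[2], p75 = q[3],
       n_pairs = length(r))
}

#' Draw the causal structure
#'
#' The 3 x 10 indicator matrix `F` of which matched pairs
#' `(X_i, X_{i+10})` are component causes of outcomes A, B and the proxy
#' outcome C. The exposure pair (i = 1) is forced: causal for A, non-causal
#' for B and C — that asymmetry is the design truth the validation study
#' tests recovery of. All other entries are iid Bernoulli(`cause_prob`).
#'
#' @inheritParams generate_correlated_binary
#' @return Integer 3 x 10 matrix with rownames `c("A", "B", "C")`.
#' @export
draw_causal_structure <- function(config = sim_config()) {
  F_ <- matrix(stats::rbinom(30L, 1L, config$cause_prob), nrow = 3L, ncol = 10L,
               dimnames = list(c("A", "B", "C"), NULL))
  F_["A", 1L] <- 1L
  F_["B", 1L] <- 0L
  F_["C", 1L] <- 0L
  F_
}

#' Draw an iid Bernoulli event matrix
#'
#' Used for the competing events `E` (one per outcome and observation;
#' an outcome cannot occur through its component causes while its competing
#' event is present) and for the background sufficient causes `Q` (a small
#' error term that makes the outcome occur regardless of the covariates,
#' keeping the logistic fits away from perfect separation).
#'
#' @param p Success probability.
#' @param nrow,ncol Dimensions.
#' @return Integer 0/1 matrix.
#' @export
draw_event_matrix <- function(p, nrow, ncol) {
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1].", call. = FALSE)
  matrix(stats::rbinom(nrow * ncol, 1L, p), nrow = nrow, ncol = ncol)
}

#' Draw the researcher's knowledge mask
#'
#' Which covariates the hypothetical researcher believes are confounders of
#' outcomes A and B. The exposure (index 1) is always in the model. Indices
#' 2-20 — the block that can contain real causal-pair components — are
#' acknowledged with probability `know_prob_low_block` (default 0.5);
#' indices 21-`n_vars`, which are pure noise, with `know_prob_high_block`
#' (default 0.15). The blocks are index-based, not truth-based: a real cause
#' is merely more *likely* to be acknowledged, and noise variables are
#' sometimes mistaken for confounders.
#'
#' @inheritParams generate_correlated_binary
#' @return Integer 2 x `n_vars` matrix with rownames `c("A", "B")`; rows
#'   drawn independently.
#' @export
draw_knowledge_mask <- function(config = sim_config()) {
  nv <- config$n_vars
  K <- matrix(0L, nrow = 2L, ncol = nv, dimnames = list(c("A", "B"), NULL))
  n_low <- min(20L, nv) - 1L             # indices 2..20
  for (j in 1:2) {
    K[j, ] <- c(1L,
                stats::rbinom(n_low, 1L, config$know_prob_low_block),
                stats::rbinom(nv - 1L - n_low, 1L, config$know_prob_high_block))
  }
  K
}

pair_products <- function(X) {
  M <- if (inherits(X, "binary_matrix")) X$values else X
  M[1:10, , drop = FALSE] * M[11:20, , drop = FALSE]   # 10 x n_obs
}

#' Determine outcome status from the sufficient-cause rule
#'
#' An outcome `j` occurs for observation `n` when at least one of its
#' component-cause pairs is complete (`X_i = X_{i+10} = 1` with
#' `F[j, i] = 1`) and no competing event is present (`E[j, n] = 0`), or when
#' a background sufficient cause fires (`Q[j, n] = 1`). By default `Q = 1`
#' forces the outcome even under a competing event; set
#' `q_overrides_competing = FALSE` to let the competing event suppress every
#' sufficient cause including the background one.
#'
#' @param X A `binary_matrix` or `n_vars` x `n_obs` 0/1 matrix
#'   (`n_vars >= 20`).
#' @param F_ 3 x 10 causal-structure matrix from [draw_causal_structure()].
#' @param E,Q 3 x `n_obs` event matrices from [draw_event_matrix()].
#' @param q_overrides_competing See description.
#' @return Integer 3 x `n_obs` outcome matrix `Y`, rownames `c("A","B","C")`.
#' @export
determine_outcomes <- function(X, F_, E, Q, q_overrides_competing = TRUE) {
  pp <- pair_products(X)
  n_obs <- ncol(pp)
  if (!identical(dim(F_), c(3L, 10L)))
    stop("`F_` must be 3 x 10.", call. = FALSE)
  if (!identical(dim(E), c(3L, n_obs)) || !identical(dim(Q), c(3L, n_obs)))
    stop("`E` and `Q` must be 3 x n_obs.", call. = FALSE)
  S <- F_ %*% pp                          # counts of completed causal pairs
  Y <- if (q_overrides_competing) {
    (Q == 1L) | (S >= 1 & E == 0L)
  } else {
    ((Q == 1L) | S >= 1) & E == 0L
  }
  Y <- matrix(as.integer(Y), nrow = 3L,
              dimnames = list(c("A", "B", "C"), NULL))
  Y
}

#' True-cause indicator excluding the exposure pair
#'
#' `G[j, n] = 1` iff some causal pair *other than the exposure pair*
#' (i = 2..10) is complete for outcome `j` in observation `n`. `G` is the
#' oracle covariate of the fact model: it captures the full non-exposure
#' causal mechanism in a single indicator.
#'
#' @inheritParams determine_outcomes
#' @return Integer 2 x `n_obs` matrix, rownames `c("A", "B")`.
#' @export
compute_cause_indicator <- function(X, F_) {
  pp <- pair_products(X)
  if (!identical(dim(F_), c(3L, 10L)))
    stop("`F_` must be 3 x 10.", call. = FALSE)
  Fab <- F_[1:2, 2:10, drop = FALSE]
  G <- (Fab %*% pp[2:10, , drop = FALSE]) >= 1
  matrix(as.integer(G), nrow = 2L, dimnames = list(c("A", "B"), NULL))
}

#' Generate one full replicate of simulated data
#'
#' Runs the generative steps in a fixed draw order (`P`, `U`, `V`, `F`, `E`,
#' `Q`, `K`; `Y` and `G` are deterministic given those), so a given seed
#' yields a bit-identical replicate.
#'
#' @inheritParams generate_correlated_binary
#' @param seed Optional integer; when supplied, [set.seed()] is called first.
#' @return An object of class `replicate_data`: list with elements `X`
#'   (`binary_matrix`), `F_`, `E`, `Q`, `Y`, `K`, `G`, `config`, `seed`.
#' @export
simulate_replicate_data <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  X <- generate_correlated_binary(config)
  F_ <- draw_causal_structure(config)
  E <- draw_event_matrix(config$competing_prob, 3L, config$n_obs)
  Q <- draw_event_matrix(config$background_prob, 3L, config$n_obs)
  Y <- determine_outcomes(X, F_, E, Q, config$q_overrides_competing)
  K <- draw_knowledge_mask(config)
  G <- compute_cause_indicator(X, F_)
  structure(list(X = X, F_ = F_, E = E, Q = Q, Y = Y, K = K, G = G,
                 config = config, seed = seed),
            class = "replicate_data")
}

#' @export
print.replicate_data <- function(x, ...) {
  cat(sprintf("replicate_data: %d variables x %d observations\n",
              x$config$n_vars, x$config$n_obs))
  cat(sprintf("  outcome prevalence A/B/C: %s\n",
              paste(sprintf("%.3f", rowMeans(x$Y)), collapse = " / ")))
  cat(sprintf("  causal pairs (A/B/C): %s\n",
              paste(rowSums(x$F_), collapse = " / ")))
  invisible(x)
}
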