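# Independent oracles used across the test files. Deliberately implemented
# without glm / cor so they cannot share a defect with the code under test.

# Newton-Raphson logistic MLE from the log-likelihood, with Wald SEs from
# the analytic Hessian. `X` is the full design including any intercept.
newton_logistic <- function(y, X, offset = rep(0, length(y)),
                            tol = 1e-12, maxit = 200) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * (mu * (1 - mu)))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta) + offset
  mu <- 1 / (1 + exp(-eta))
  H <- t(X) %*% (X * (mu * (1 - mu)))
  list(coef = unname(beta), se = unname(sqrt(diag(solve(H)))))
}

# Exhaustive per-observation evaluation of the sufficient-cause outcome rule.
brute_outcomes <- function(Xm, F_, E, Q, q_overrides_competing = TRUE) {
  n <- ncol(Xm)
  Y <- matrix(0L, 3L, n)
  for (j in 1:3) {
    for (obs in seq_len(n)) {
      fired <- FALSE
      for (i in 1:10)
        if (Xm[i, obs] == 1L && Xm[i + 10L, obs] == 1L && F_[j, i] == 1L)
          fired <- TRUE
      y <- if (q_overrides_competing) {
        Q[j, obs] == 1L || (fired && E[j, obs] == 0L)
      } else {
        (Q[j, obs] == 1L || fired) && E[j, obs] == 0L
      }
      Y[j, obs] <- as.integer(y)
    }
  }
  rownames(Y) <- c("A", "B", "C")
  Y
}

brute_cause_indicator <- function(Xm, F_) {
  n <- ncol(Xm)
  G <- matrix(0L, 2L, n)
  for (j in 1:2)
    for (obs in seq_len(n)) {
      fired <- FALSE
      for (i in 2:10)
        if (Xm[i, obs] == 1L && Xm[i + 10L, obs] == 1L && F_[j, i] == 1L)
          fired <- TRUE
      G[j, obs] <- as.integer(fired)
    }
  rownames(G) <- c("A", "B")
  G
}

# Phi coefficient from the 2x2 cell counts (equals the Pearson correlation
# of two binary vectors).
phi_from_counts <- function(a, b) {
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

# Minimal fit_result stand-in for operations that only read the exposure
# entries (adjusted_effect, classification).
fake_fit <- function(coef_x1, p_x1 = 0.5, se_x1 = 0.1, converged = TRUE,
                     model_tag = "conventional") {
  structure(list(coef = c(`(Intercept)` = 0, x1 = coef_x1),
                 se = c(`(Intercept)` = 0.1, x1 = se_x1),
                 pvalue = c(`(Intercept)` = 0.9, x1 = p_x1),
                 converged = converged, n_obs = 1000L,
                 model_tag = model_tag),
            class = "fit_result")
}

# Expand grouped binary cells (one row per covariate pattern x outcome) to
# individual rows for fitting.
expand_cells <- function(cells) {
  idx <- rep(seq_len(nrow(cells)), cells$n)
  cells[idx, setdiff(names(cells), "n"), drop = FALSE]
}
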