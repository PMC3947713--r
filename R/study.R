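#' Run one full replicate: generate, fit, classify
#'
#' Executes the whole pipeline for one scenario: simulate the replicate data
#' ([simulate_replicate_data()]), fit the fact, conventional and proxy
#' logistic models for outcomes A and B (the proxy model refit per outcome
#' with that outcome's knowledge mask), form the proxy-adjusted effects
#' `beta_hat = beta_conv - beta_proxy`, and classify the exposure effect on
#' each outcome under all three approaches.
#'
#' Fit failures (non-convergence, separation) do not raise errors: they are
#' recorded in `flags` and the replicate is marked `excluded`, to be dropped
#' and counted by [aggregate_study()].
#'
#' @param config A [sim_config()].
#' @param rule A [classification_rule()].
#' @param seed Integer seed for this replicate (bit-identical reruns).
#' @param replicate_id Optional identifier carried into the result.
#' @return An object of class `replicate_result`: list with `replicate_id`,
#'   `seed`, `fits` (data.frame of exposure coefficient / se / p per model
#'   and outcome), `adjusted` (list A/B of [adjusted_effect()]),
#'   `class_fact`, `class_conv`, `class_alt` ([scenario_class()]), `flags`
#'   (character), `excluded` (logical).
#' @export
run_replicate <- function(config = sim_config(), rule = classification_rule(),
                          seed = NULL, replicate_id = NA_integer_) {
  dat <- simulate_replicate_data(config, seed)
  analyze_replicate(dat, rule, replicate_id = replicate_id)
}

#' Fit and classify an already-generated replicate
#'
#' The estimation and classification half of [run_replicate()], usable on
#' data read back from disk or constructed by hand.
#'
#' @param dat A `replicate_data` from [simulate_replicate_data()].
#' @param rule A [classification_rule()].
#' @param replicate_id Optional identifier.
#' @return A `replicate_result`; see [run_replicate()].
#' @export
analyze_replicate <- function(dat, rule = classification_rule(),
                              replicate_id = NA_integer_) {
  stopifnot(inherits(dat, "replicate_data"))
  x1 <- dat$X$values[1L, ]
  yC <- dat$Y["C", ]
  flags <- character(0)

  safe_fit <- function(tag, expr) {
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        flags <<- c(flags, sprintf("%s: %s", tag, conditionMessage(e)))
        NULL
      }),
      warning = function(w) {
        flags <<- c(flags, sprintf("%s: %s", tag, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (!is.null(res) && !res$converged)
      flags <<- c(flags, sprintf("%s: did not converge", tag))
    res
  }

  fits <- list()
  adjusted <- list()
  for (j in c("A", "B")) {
    fits[[paste0("fact_", j)]] <-
      safe_fit(paste0("fact_", j),
               fit_fact_model(dat$Y[j, ], x1, dat$G[j, ]))
    fits[[paste0("conventional_", j)]] <-
      safe_fit(paste0("conventional_", j),
               fit_conventional_model(dat$Y[j, ], dat$X, dat$K[j, ]))
    fits[[paste0("proxy_", j)]] <-
      safe_fit(paste0("proxy_", j),
               fit_proxy_model(yC, dat$X, dat$K[j, ]))
    fc <- fits[[paste0("conventional_", j)]]
    fp <- fits[[paste0("proxy_", j)]]
    adjusted[[j]] <- if (!is.null(fc) && !is.null(fp) &&
                         fc$converged && fp$converged)
      adjusted_effect(fc, fp) else NULL
  }

  excluded <- length(flags) > 0L ||
    any(vapply(fits, is.null, logical(1))) ||
    any(vapply(adjusted, is.null, logical(1)))

  exposure_row <- function(f, model, outcome) {
    if (is.null(f))
      return(data.frame(model = model, outcome = outcome, coef = NA_real_,
                        se = NA_real_, p = NA_real_, converged = FALSE))
    data.frame(model = model, outcome = outcome,
               coef = unname(f$coef[exposure_term]),
               se = unname(f$se[exposure_term]),
               p = unname(f$pvalue[exposure_term]),
               converged = f$converged)
  }
  fit_tab <- do.call(rbind, lapply(c("A", "B"), function(j) {
    rbind(exposure_row(fits[[paste0("fact_", j)]], "fact", j),
          exposure_row(fits[[paste0("conventional_", j)]], "conventional", j),
          exposure_row(fits[[paste0("proxy_", j)]], "proxy", j))
  }))

  cls <- function(model) {
    get1 <- function(j) {
      r <- fit_tab[fit_tab$model == model & fit_tab$outcome == j, ]
      classify_fitted(r$coef, r$p, rule)
    }
    scenario_class(get1("A"), get1("B"))
  }
  class_fact <- class_conv <- class_alt <- NULL
  if (!excluded) {
    class_fact <- cls("fact")
    class_conv <- cls("conventional")
    class_alt <- scenario_class(classify_adjusted(adjusted$A, rule),
                                classify_adjusted(adjusted$B, rule))
  }

  structure(list(replicate_id = replicate_id, seed = dat$seed,
                 fits = fit_tab, adjusted = adjusted,
                 class_fact = class_fact, class_conv = class_conv,
                 class_alt = class_alt,
                 flags = flags, excluded = excluded),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("replicate_result (id %s, seed %s)%s\n",
              x$replicate_id, x$seed,
              if (x$excluded) " [EXCLUDED]" else ""))
  print(transform(x$fits, coef = round(coef, 4), se = round(se, 4),
                  p = signif(p, 3)))
  if (!x$excluded)
    cat(sprintf("  classes: fact %s | conventional %s | adjusted %s\n",
                x$class_fact$label, x$class_conv$label, x$class_alt$label))
  invisible(x)
}

#' Run a replicate study
#'
#' Runs `n_replicates` independent replicates. A master seed deterministically
#' spawns one child seed per replicate (via one `sample.int` draw under the
#' master seed), so results are reproducible and independent of execution
#' order.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates (default 500).
#' @param master_seed Integer master seed.
#' @param progress Print a dot every 25 replicates.
#' @return A list of `replicate_result` of class `study_results`, with the
#'   configuration, rule and seeds attached as attributes.
#' @export
run_study <- function(config = sim_config(), rule = classification_rule(),
                      n_replicates = 500L, master_seed = 1L,
                      progress = FALSE) {
  stopifnot(n_replicates >= 1L)
  set.seed(master_seed)
  child_seeds <- sample.int(2147483646L, n_replicates)
  results <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    results[[r]] <- run_replicate(config, rule, seed = child_seeds[r],
                                  replicate_id = r)
    if (progress && r %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(results, class = "study_results", config = config, rule = rule,
            master_seed = master_seed, child_seeds = child_seeds)
}

#' Aggregate replicate results into the study summary
#'
#' Drops replicates flagged by fit failures (counting them in `n_excluded`)
#' and computes, over the remainder:
#' \itemize{
#'   \item the 2 x 2 cross-tabulations of the fact-model scenario class
#'     against the conventional and the proxy-adjusted (alternative)
#'     classes, restricted to the two labels that occur by design
#'     (`A_not_B`, `A_and_B`);
#'   \item `agree_conv`, `agree_alt`: the fraction of replicates whose
#'     conventional / alternative scenario class equals the fact-model class
#'     (the fact model as gold standard);
#'   \item `sensitivity_*`, `specificity_*`: against the design truth
#'     (exposure causal for A, not for B), the fraction of replicates in
#'     which each approach declares A causal / declares B non-causal;
#'   \item `fact_b_causal_rate`: the fact model's false-positive rate for B,
#'     the type-I error of the classification rule.
#' }
#'
#' @param results A `study_results` list (or plain list of
#'   `replicate_result`).
#' @return An object of class `study_summary`.
#' @export
aggregate_study <- function(results) {
  if (length(results) == 0L)
    stop("cannot aggregate an empty result list.", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "replicate_result")))
  excluded <- vapply(results, function(r) isTRUE(r$excluded), logical(1))
  kept <- results[!excluded]
  if (length(kept) == 0L)
    stop("all replicates were excluded; nothing to aggregate.", call. = FALSE)

  lab <- function(field) {
    factor(vapply(kept, function(r) r[[field]]$label, character(1)),
           levels = scenario_labels)
  }
  fact <- lab("class_fact"); conv <- lab("class_conv"); alt <- lab("class_alt")
  restrict <- c("A_not_B", "A_and_B")
  xtab <- function(approach) {
    tab <- table(fact = fact, approach = approach)
    tab[restrict, restrict, drop = FALSE]
  }
  causal_for <- function(cls, outcome) {
    vapply(kept, function(r) r[[cls]][[paste0("causal_", outcome)]], logical(1))
  }

  out <- list(
    n_replicates = length(results),
    n_excluded = sum(excluded),
    crosstab_conv = xtab(conv),
    crosstab_alt = xtab(alt),
    agree_conv = mean(conv == fact),
    agree_alt = mean(alt == fact),
    sensitivity_alt = mean(causal_for("class_alt", "A")),
    specificity_alt = mean(!causal_for("class_alt", "B")),
    sensitivity_conv = mean(causal_for("class_conv", "A")),
    specificity_conv = mean(!causal_for("class_conv", "B")),
    fact_a_causal_rate = mean(causal_for("class_fact", "A")),
    fact_b_causal_rate = mean(causal_for("class_fact", "B"))
  )
  class(out) <- "study_summary"
  out
}

#' @export
print.study_summary <- function(x, ...) {
  n <- x$n_replicates - x$n_excluded
  cat(sprintf("Study summary: %d replicates (%d excluded)\n",
              x$n_replicates, x$n_excluded))
  pct <- function(p) sprintf("%.1f%%", 100 * p)
  cat("\nFact model vs conventional approach (counts):\n")
  print(x$crosstab_conv)
  cat("\nFact model vs proxy-adjusted approach (counts):\n")
  print(x$crosstab_alt)
  cat(sprintf("\nAgreement with fact model: conventional %s, proxy-adjusted %s\n",
              pct(x$agree_conv), pct(x$agree_alt)))
  cat(sprintf("Against design truth: sensitivity %s / specificity %s (proxy-adjusted), %s / %s (conventional)\n",
              pct(x$sensitivity_alt), pct(x$specificity_alt),
              pct(x$sensitivity_conv), pct(x$specificity_conv)))
  cat(sprintf("Fact model declares the exposure causal for B in %s of replicates (type-I error of the rule)\n",
              pct(x$fact_b_causal_rate)))
  invisible(x)
}
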