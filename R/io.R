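#' Write replicate data to a directory of delimited text files
#'
#' One tab-delimited file per array (`X`, `F`, `E`, `Q`, `Y`, `K`, `G`,
#' `mixing_props`) plus `metadata.json` recording the configuration and
#' seed. Text-only, so replicates can be inspected or re-analysed outside R.
#'
#' @param dat A `replicate_data` from [simulate_replicate_data()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_replicate_data <- function(dat, dir) {
  stopifnot(inherits(dat, "replicate_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(m, name)
    utils::write.table(m, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  wt(dat$X$values, "X")
  wt(dat$F_, "F")
  wt(dat$E, "E")
  wt(dat$Q, "Q")
  wt(dat$Y, "Y")
  wt(dat$K, "K")
  wt(dat$G, "G")
  wt(matrix(dat$X$mixing_props, nrow = 1L), "mixing_props")
  meta <- c(unclass(dat$config),
            list(seed = if (is.null(dat$seed)) NA else dat$seed))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read replicate data written by [write_replicate_data()]
#'
#' @param dir Directory containing the delimited files and `metadata.json`.
#' @return A `replicate_data` object.
#' @export
read_replicate_data <- function(dir) {
  rd <- function(name)
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".tsv")),
                                sep = "\t", header = FALSE))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  cfg <- sim_config(
    n_vars = meta$n_vars, n_obs = meta$n_obs, threshold = meta$threshold,
    p_low = meta$p_low, p_high = meta$p_high,
    competing_prob = meta$competing_prob,
    background_prob = meta$background_prob,
    know_prob_low_block = meta$know_prob_low_block,
    know_prob_high_block = meta$know_prob_high_block,
    cause_prob = meta$cause_prob,
    q_overrides_competing = meta$q_overrides_competing)
  strip <- function(m, rn = NULL) {
    m <- unname(m); storage.mode(m) <- "integer"
    if (!is.null(rn)) rownames(m) <- rn
    m
  }
  X <- structure(list(values = strip(rd("X")),
                      mixing_props = as.numeric(rd("mixing_props")[1L, ])),
                 class = "binary_matrix")
  structure(list(X = X,
                 F_ = strip(rd("F"), c("A", "B", "C")),
                 E = strip(rd("E")), Q = strip(rd("Q")),
                 Y = strip(rd("Y"), c("A", "B", "C")),
                 K = strip(rd("K"), c("A", "B")),
                 G = strip(rd("G"), c("A", "B")),
                 config = cfg,
                 seed = if (is.na(meta$seed)) NULL else meta$seed),
            class = "replicate_data")
}

#' Write per-replicate results to CSV
#'
#' One row per replicate: seed, exposure coefficient / standard error /
#' p-value for each model and outcome, the adjusted effects, the three
#' scenario classes, and the exclusion flag.
#'
#' @param results A `study_results` list.
#' @param path Output CSV path.
#' @export
write_replicate_results <- function(results, path) {
  rows <- lapply(results, function(r) {
    wide <- list(replicate_id = r$replicate_id,
                 seed = if (is.null(r$seed)) NA else r$seed)
    for (i in seq_len(nrow(r$fits))) {
      key <- paste0(r$fits$model[i], "_", r$fits$outcome[i])
      wide[[paste0(key, "_coef")]] <- r$fits$coef[i]
      wide[[paste0(key, "_se")]] <- r$fits$se[i]
      wide[[paste0(key, "_p")]] <- r$fits$p[i]
    }
    for (j in c("A", "B"))
      wide[[paste0("beta_hat_", j)]] <-
        if (is.null(r$adjusted[[j]])) NA_real_ else r$adjusted[[j]]$beta_hat
    wide$class_fact <- if (is.null(r$class_fact)) NA else r$class_fact$label
    wide$class_conv <- if (is.null(r$class_conv)) NA else r$class_conv$label
    wide$class_alt <- if (is.null(r$class_alt)) NA else r$class_alt$label
    wide$excluded <- r$excluded
    as.data.frame(wide)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a study summary to disk
#'
#' Emits `crosstab.csv` — the cross-tabulation of fact-model vs
#' conventional and proxy-adjusted scenario classes, with counts and
#' percentages of included replicates (one decimal) — and `summary.json`
#' with every proportion, the exclusion count, and optionally the
#' configuration and master seed.
#'
#' @param summary A `study_summary` from [aggregate_study()].
#' @param dir Output directory (created if absent).
#' @param config,master_seed Optional echo into `summary.json`.
#' @return `dir`, invisibly.
#' @export
write_study_summary <- function(summary, dir, config = NULL,
                                master_seed = NULL) {
  stopifnot(inherits(summary, "study_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_inc <- summary$n_replicates - summary$n_excluded
  rows <- do.call(rbind, lapply(c("conv", "alt"), function(a) {
    tab <- summary[[paste0("crosstab_", a)]]
    do.call(rbind, lapply(rownames(tab), function(fr) {
      do.call(rbind, lapply(colnames(tab), function(cc) {
        data.frame(approach = if (a == "conv") "conventional" else "alternative",
                   fact_class = fr, approach_class = cc,
                   n = tab[fr, cc],
                   pct = round(100 * tab[fr, cc] / n_inc, 1))
      }))
    }))
  }))
  utils::write.csv(rows, file.path(dir, "crosstab.csv"), row.names = FALSE)
  js <- list(
    n_replicates = summary$n_replicates,
    n_excluded = summary$n_excluded,
    crosstab_conv = unclass(as.data.frame.matrix(summary$crosstab_conv)),
    crosstab_alt = unclass(as.data.frame.matrix(summary$crosstab_alt)),
    agree_conv = summary$agree_conv,
    agree_alt = summary$agree_alt,
    sensitivity_alt = summary$sensitivity_alt,
    specificity_alt = summary$specificity_alt,
    sensitivity_conv = summary$sensitivity_conv,
    specificity_conv = summary$specificity_conv,
    fact_a_causal_rate = summary$fact_a_causal_rate,
    fact_b_causal_rate = summary$fact_b_causal_rate)
  if (!is.null(config)) js$config <- unclass(config)
  if (!is.null(master_seed)) js$master_seed <- master_seed
  jsonlite::write_json(js, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study summary written by [write_study_summary()]
#'
#' @param dir Directory containing `summary.json`.
#' @return A `study_summary` object.
#' @export
read_study_summary <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  restrict <- c("A_not_B", "A_and_B")
  remat <- function(df) {
    m <- as.matrix(as.data.frame(df))
    dimnames(m) <- list(fact = restrict, approach = restrict)
    as.table(m)
  }
  out <- list(
    n_replicates = js$n_replicates,
    n_excluded = js$n_excluded,
    crosstab_conv = remat(js$crosstab_conv),
    crosstab_alt = remat(js$crosstab_alt),
    agree_conv = js$agree_conv,
    agree_alt = js$agree_alt,
    sensitivity_alt = js$sensitivity_alt,
    specificity_alt = js$specificity_alt,
    sensitivity_conv = js$sensitivity_conv,
    specificity_conv = js$specificity_conv,
    fact_a_causal_rate = js$fact_a_causal_rate,
    fact_b_causal_rate = js$fact_b_causal_rate)
  class(out) <- "study_summary"
  out
}
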