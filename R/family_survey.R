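#' Synthetic family-survey data for the offset application
#'
#' Emulates a household survey in which confounders are clustered within the
#' family: a latent family-level factor (socioeconomic advantage, lifestyle,
#' shared environment) raises the probability of the exposure while lowering
#' the probability of an undesirable health outcome in both the adult and
#' their child. The exposure has a configurable direct effect on the adult
#' outcome and, by construction, no direct path to the child outcome — so
#' the child outcome is a valid proxy outcome, and its crude exposure
#' association measures confounding alone.
#'
#' Generative model, one adult-child pair per family with family factor
#' `z ~ N(0, confounder_sd)`:
#' \deqn{exposure ~ Bern(logit^{-1}(z)),}
#' \deqn{adult ~ Bern(logit^{-1}(-1.5 - z + \beta_x exposure)),}
#' \deqn{child ~ Bern(logit^{-1}(-1.5 - z)).}
#' At the defaults (`confounder_sd = 1`, `exposure_effect_outcome = 0`) the
#' exposure looks spuriously protective for both outcomes, the regime of
#' interest for the offset correction.
#'
#' @param n Number of families (one adult and one child each).
#' @param confounder_sd Standard deviation of the family-level confounder.
#' @param exposure_effect_outcome True direct log-odds effect of the
#'   exposure on the adult outcome (0 = no effect).
#' @return A data.frame with columns `family_id`, `family_confounder`,
#'   `exposure`, `adult_outcome`, `child_outcome`.
#' @examples
#' set.seed(1)
#' fs <- generate_family_survey(2000)
#' colMeans(fs[c("exposure", "adult_outcome", "child_outcome")])
#' @export
generate_family_survey <- function(n, confounder_sd = 1,
                                   exposure_effect_outcome = 0) {
  if (n < 1L) stop("`n` must be at least 1.", call. = FALSE)
  if (confounder_sd < 0) stop("`confounder_sd` must be >= 0.", call. = FALSE)
  z <- stats::rnorm(n, 0, confounder_sd)
  expo <- stats::rbinom(n, 1L, stats::plogis(z))
  adult <- stats::rbinom(n, 1L, stats::plogis(-1.5 - z + exposure_effect_outcome * expo))
  child <- stats::rbinom(n, 1L, stats::plogis(-1.5 - z))
  data.frame(family_id = seq_len(n),
             family_confounder = z,
             exposure = expo,
             adult_outcome = adult,
             child_outcome = child)
}

#' Write a family survey to CSV
#'
#' Writes the columns `family_id`, `exposure`, `adult_outcome`,
#' `child_outcome` (the analysis columns; the latent confounder is withheld,
#' as it would be in a real survey).
#'
#' @param survey Data frame from [generate_family_survey()].
#' @param path Output CSV path.
#' @export
write_family_survey <- function(survey, path) {
  utils::write.csv(
    survey[c("family_id", "exposure", "adult_outcome", "child_outcome")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
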