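#' Configuration for the synthetic gene-by-environment cohort generator
#'
#' Bundles every knob of the synthetic cohort: sample and marker counts, the
#' genotype model, the single-factor socioeconomic indicator battery, and the
#' moderated-regression outcome model
#' \deqn{y = b_0 + b_1 Z + b_2 X + b_3 Z X + \sum_k c_k W_k + \varepsilon,}
#' where `Z` is standardized predicted gene expression (the moderator), `X`
#' the standardized socioeconomic composite (the environment), and `W_k`
#' internally standardized covariates (age, sex, BMI z-score, two ancestry
#' PCs).  Effects are therefore on the standardized-outcome scale: when the
#' total generated variance is 1 (the default: `noise_sd` is solved so that
#' the variance budget closes), `b3` is the standardized interaction
#' coefficient.
#'
#' The `scenario` places the crossover point \eqn{X_c = -b_1/b_3}:
#' * `"differential_susceptibility"` — at the population median of the
#'   standardized environment (0), so the cohort is split roughly in half
#'   by the crossover (prototypical pattern);
#' * `"diathesis_stress"` — at the population mean + 2 SD (+2), the edge
#'   of the observed range, so the susceptible group is only ever worse
#'   off;
#' * `"null"` — forces `b3 = 0`;
#' * `"nonlinear"` — the differential-susceptibility geometry plus a
#'   standardized quadratic environment term `b_quad` (default 0.4), the
#'   pattern the quadratic robustness check must flag.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_snps number of simulated SNPs (>= 1).
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP allele frequencies
#'   are drawn uniformly from this interval.
#' @param missing_rate proportion of dosage entries set missing.
#' @param weight_sparsity proportion of SNPs given a nonzero expression
#'   weight.
#' @param ses_loadings named numeric of 5 target loadings in (0, 1] for
#'   income, education, public_assistance, food_security,
#'   perceived_resources (defaults are the published battery's loadings).
#' @param scenario one of `"differential_susceptibility"`, `"null"`,
#'   `"diathesis_stress"`, `"nonlinear"`.
#' @param b0,b2,b3 intercept, environment main effect, interaction effect
#'   (standardized scale).
#' @param b1 moderator main effect; `NULL` (default) lets the scenario place
#'   the crossover.  Supplying a value overrides the scenario's placement.
#' @param b_quad standardized coefficient of the quadratic environment term;
#'   `NULL` means 0.4 under `scenario = "nonlinear"` and 0 otherwise.
#' @param covariate_effects named numeric of effects for age, sex, bmi_z,
#'   pc1, pc2 (applied to internally standardized covariates).
#' @param noise_sd residual standard deviation; `NULL` (default) solves
#'   `noise_sd` so the total variance of the structured outcome is 1.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(n_subjects = 100, seed = 7)
#' cfg$noise_sd  # solved so that the outcome variance budget closes at 1
#' @export
sim_config <- function(n_subjects = 76L, n_snps = 200L, seed = 1L,
                       maf_range = c(0.05, 0.5), missing_rate = 0.01,
                       weight_sparsity = 0.25,
                       ses_loadings = c(income = 0.891, education = 0.772,
                                        public_assistance = 0.793,
                                        food_security = 0.690,
                                        perceived_resources = 0.678),
                       scenario = c("differential_susceptibility", "null",
                                    "diathesis_stress", "nonlinear"),
                       b0 = 0, b1 = NULL, b2 = 0.1, b3 = 0.4, b_quad = NULL,
                       covariate_effects = c(age = -0.1, sex = -0.3,
                                             bmi_z = 0.1, pc1 = 0.1,
                                             pc2 = -0.1),
                       noise_sd = NULL) {
  scenario <- match.arg(scenario)
  if (!is.numeric(n_subjects) || n_subjects < 2)
    .stop("`n_subjects` must be >= 2")
  if (!is.numeric(n_snps) || n_snps < 1)
    .stop("`n_snps` must be >= 1 (got %s)", format(n_snps))
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    .stop("`maf_range` must be an increasing pair within (0, 0.5]")
  .check_prop(missing_rate, "missing_rate")
  .check_prop(weight_sparsity, "weight_sparsity")
  req <- c("income", "education", "public_assistance", "food_security",
           "perceived_resources")
  if (length(ses_loadings) != 5L || !all(req %in% names(ses_loadings)))
    .stop("`ses_loadings` must name all of: %s", paste(req, collapse = ", "))
  ses_loadings <- ses_loadings[req]
  if (any(ses_loadings <= 0) || any(ses_loadings > 1))
    .stop("`ses_loadings` must lie in (0, 1]")
  creq <- c("age", "sex", "bmi_z", "pc1", "pc2")
  if (!all(creq %in% names(covariate_effects)))
    .stop("`covariate_effects` must name all of: %s",
          paste(creq, collapse = ", "))
  covariate_effects <- covariate_effects[creq]

  if (scenario == "null") b3 <- 0
  b_quad <- b_quad %||% if (scenario == "nonlinear") 0.4 else 0
  if (scenario == "nonlinear" && b_quad == 0)
    .stop("scenario \"nonlinear\" requires a nonzero `b_quad`")

  # expected contribution of the scenario-placed moderator main effect to the
  # outcome variance (crossover at median => b1 ~ 0; at +2SD => b1 = -2 b3)
  b1_var <- if (!is.null(b1)) b1^2 else switch(scenario,
    diathesis_stress = (2 * b3)^2, 0)
  explained <- b1_var + b2^2 + b3^2 + b_quad^2 + sum(covariate_effects^2)
  if (is.null(noise_sd)) {
    if (explained >= 0.96)
      .stop("structured effects explain %.2f of unit variance; supply noise_sd",
            explained)
    noise_sd <- sqrt(1 - explained)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) .stop("`noise_sd` must be > 0")

  structure(list(
    n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
    seed = as.integer(seed), maf_range = as.numeric(maf_range),
    missing_rate = missing_rate, weight_sparsity = weight_sparsity,
    ses_loadings = ses_loadings, scenario = scenario,
    b0 = b0, b1 = b1, b2 = b2, b3 = b3, b_quad = b_quad,
    covariate_effects = covariate_effects, noise_sd = noise_sd
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d, SNPs: %d, seed: %d\n",
              x$n_subjects, x$n_snps, x$seed))
  cat(sprintf("  scenario: %s  (b2 = %g, b3 = %g, b_quad = %g, noise_sd = %.3f)\n",
              x$scenario, x$b2, x$b3, x$b_quad, x$noise_sd))
  invisible(x)
}

# scenario-dependent moderator main effect.  Placement uses the population
# moments of the standardized environment (median 0, mean + 2 SD = 2), so
# every generator stays a pure function of (config, seed):
# differential susceptibility / nonlinear put the crossover -b1/b3 at the
# median, diathesis-stress at the upper edge of the observed range.
.effective_b1 <- function(config) {
  if (!is.null(config$b1)) return(config$b1)
  switch(config$scenario,
    null = 0,
    diathesis_stress = -config$b3 * 2,
    0)
}
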