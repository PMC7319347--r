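#' Fit a moderated regression and run the differential-susceptibility suite
#'
#' The package's central fitting function.  The model is the
#' covariate-adjusted interaction regression
#' \deqn{y = b_0 + b_1 Z + b_2 X + b_3 Z X + \sum_k c_k W_k + \varepsilon,}
#' written as `y ~ X * Z + W1 + W2 + ...`: the first variable of the (single)
#' interaction term is taken as the environment `X`, the second as the
#' moderator `Z` (override with `env` / `moderator` if needed).  On top of
#' the raw-scale fit, `ds_model()` computes the standardized coefficients
#' (standardize-then-multiply convention), the interaction R-squared change
#' with its partial-F p-value, and — the confirmation suite — the
#' Johnson-Neyman region of significance, crossover point, proportion of
#' interaction (PoI), proportion affected (PA), mean-split simple slopes,
#' the quadratic robustness check (gated, per protocol, on a significant
#' linear interaction), and the prototypicality verdict.
#'
#' The confirmation geometry (RoS bounds, crossover, PoI, PA) is computed
#' on the standardized environment scale, where the range of interest is
#' `[-2, 2]`; simple slopes are reported on the raw outcome scale.
#'
#' @param formula `outcome ~ env * moderator + covariates`; exactly one
#'   two-way interaction.
#' @param data data.frame holding every model column; rows with missing
#'   values in model columns are dropped (complete-case analysis — no
#'   imputation).
#' @param env,moderator optional column names overriding the positional
#'   convention.
#' @param alpha two-sided significance level (default 0.05) used for the
#'   interaction gate, the region of significance, and the quadratic check.
#' @param poi_band,pa_band verdict bands (defaults `[0.40, 0.60]`).
#' @param run_quadratic `NULL` (default) runs the quadratic robustness
#'   check only when the linear interaction is significant at `alpha`;
#'   `TRUE`/`FALSE` force it on/off.
#' @return An object of class `"ds_model"`.  Key components: `fit` (raw
#'   `"ols_fit"`), `std_fit`, `betas`, `r2_change`, `ros`, `indices`
#'   (crossover, poi, pa), `slopes`, `quadratic`, `verdict`,
#'   `interaction_p`, `gate_passed`, `conventions`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 150, n_snps = 50, seed = 3))
#' d <- data.frame(snack = sim$outcomes$snack_latent, ses = sim$truth$x,
#'                 expr = sim$truth$z, sim$cohort[c("age", "sex", "bmi_z")])
#' m <- ds_model(snack ~ ses * expr + age + sex + bmi_z, d)
#' m
#' @export
ds_model <- function(formula, data, env = NULL, moderator = NULL,
                     alpha = 0.05, poi_band = c(0.40, 0.60),
                     pa_band = c(0.40, 0.60), run_quadratic = NULL) {
  tt <- terms(formula, data = data)
  labs <- attr(tt, "term.labels")
  ints <- labs[attr(tt, "order") == 2L]
  if (length(ints) != 1L)
    .stop("formula must contain exactly one two-way interaction (got %d)",
          length(ints))
  if (any(attr(tt, "order") > 2L)) .stop("higher-order interactions not supported")
  vars <- strsplit(ints, ":")[[1]]
  env <- env %||% vars[1]
  moderator <- moderator %||% vars[2]
  if (!all(c(env, moderator) %in% vars))
    .stop("`env`/`moderator` must be the interaction variables (%s)", ints)
  outcome <- deparse(formula[[2]])
  covariates <- setdiff(labs[attr(tt, "order") == 1L], vars)
  cols <- c(outcome, env, moderator, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) .stop("missing column(s): %s", paste(miss, collapse = ", "))
  cc <- complete.cases(data[cols])
  data <- data[cc, cols, drop = FALSE]
  .check_prop(alpha, "alpha")

  fr <- .build_frame(data, outcome, env, moderator, covariates)
  fit <- fit_ols(fr[setdiff(names(fr), "y")], fr$y)
  sb <- standardized_betas(data, outcome, env, moderator, covariates)
  r2c <- interaction_r2_change(data, outcome, env, moderator, covariates)
  interaction_p <- unname(fit$p_values["zx"])
  gate <- interaction_p < alpha
  quad <- NULL
  if (isTRUE(run_quadratic) || (is.null(run_quadratic) && gate))
    quad <- quadratic_robustness(data, outcome, env, moderator, covariates,
                                 alpha = alpha)
  nonlin <- if (is.null(quad)) FALSE else quad$nonlinear_flag

  std_fit <- sb$fit
  ros <- ros_bounds(std_fit, alpha = alpha)
  x_std <- (data[[env]] - mean(data[[env]])) / sd(data[[env]])
  xc <- if (abs(coef(std_fit)["zx"]) >= 1e-12) crossover_point(std_fit)
        else NA_real_
  poi_v <- if (is.na(xc)) NA_real_ else poi(std_fit, x_mean = 0, x_sd = 1)
  pa_v <- if (is.na(xc)) NA_real_ else pa(x_std, xc)
  slopes <- simple_slopes_split(data, outcome, env, moderator, covariates)
  verdict <- if (is.na(xc)) {
    structure(list(ros_within_range = FALSE, poi_in_band = FALSE,
                   pa_near_half = FALSE, nonlinear_excluded = !nonlin,
                   verdict = "not_supported",
                   bands = list(poi = poi_band, pa = pa_band,
                                x_range = c(-2, 2))), class = "ds_verdict")
  } else {
    classify_ds(ros, poi_v, pa_v, nonlinear_flag = nonlin,
                x_mean = 0, x_sd = 1, poi_band = poi_band, pa_band = pa_band)
  }

  structure(list(
    call = match.call(), outcome = outcome, env = env, moderator = moderator,
    covariates = covariates, n = nrow(data), data = data,
    fit = fit, std_fit = std_fit, betas = sb$betas,
    beta_p = sb$p_values, r2_change = r2c,
    interaction_p = interaction_p, gate_passed = gate, alpha = alpha,
    quadratic = quad,
    ros = ros,
    indices = list(crossover_x = xc, poi = poi_v, pa = pa_v,
                   x_mean = 0, x_sd = 1, scale = "standardized environment"),
    slopes = slopes, verdict = verdict,
    conventions = list(
      standardization = "standardize-then-multiply; binary covariates on 0/1 scale",
      ros_scale = "standardized environment (mean 0, SD 1); residual df of the full adjusted model",
      poi_side = "high-environment side is the 'for better' side, independent of outcome valence",
      pa_ties = "ties at the crossover count below",
      quadratic_gate = sprintf("quadratic check %s (raw interaction p %s alpha = %g)",
                               if (is.null(quad)) "skipped" else "run",
                               if (gate) "<" else ">=", alpha),
      poi_band = poi_band, pa_band = pa_band)
  ), class = "ds_model")
}

#' @export
print.ds_model <- function(x, ...) {
  cat(sprintf("Differential-susceptibility model: %s ~ %s * %s%s  (n = %d)\n",
              x$outcome, x$env, x$moderator,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + ")) else "",
              x$n))
  cat(sprintf("  interaction: beta = %.3f, p = %.4g (R2 change = %.3f)\n",
              x$betas[["zx"]], x$interaction_p, x$r2_change$r2_change))
  if (x$ros$status == "two_real_roots")
    cat(sprintf("  RoS bounds (env SD units): [%.3f, %.3f]; PoI = %.2f, PA = %.3f\n",
                x$ros$lower, x$ros$upper, x$indices$poi, x$indices$pa))
  cat(sprintf("  verdict: %s\n", x$verdict$verdict))
  invisible(x)
}

#' @export
summary.ds_model <- function(object, ...) {
  b <- coef(object$fit)[-1L]
  tab <- data.frame(
    term = c(object$moderator, object$env,
             paste0(object$env, ":", object$moderator), object$covariates),
    b = unname(b),
    beta = unname(object$betas[names(b)]),
    p = unname(object$fit$p_values[-1L]))
  structure(list(model = object, coefficients = tab), class = "summary.ds_model")
}

#' @export
print.summary.ds_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nCoefficients (b raw scale, beta standardized):\n")
  tab <- x$coefficients
  tab$b <- signif(tab$b, 4); tab$beta <- signif(tab$beta, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("\nR2 = %.3f; interaction R2 change = %.3f (partial-F p = %.4g)\n",
              m$fit$r_squared, m$r2_change$r2_change, m$r2_change$p))
  if (!is.null(m$quadratic))
    cat(sprintf("Quadratic check: p(X^2) = %.3g, p(Z*X^2) = %.3g -> %s\n",
                m$quadratic$p_x2, m$quadratic$p_zx2,
                if (m$quadratic$nonlinear_flag) "nonlinear" else "linear"))
  cat("\nSimple slopes (moderator mean split, raw outcome units per env unit):\n")
  sl <- m$slopes
  sl$slope <- signif(sl$slope, 4); sl$se <- signif(sl$se, 3)
  sl$t <- round(sl$t, 2); sl$p <- signif(sl$p, 3)
  print(sl, row.names = FALSE)
  cat("\n")
  print(m$verdict)
  invisible(x)
}

#' @export
coef.ds_model <- function(object, standardized = FALSE, ...) {
  if (standardized) object$betas else coef(object$fit)
}

#' @export
residuals.ds_model <- function(object, ...) object$fit$residuals

#' @export
fitted.ds_model <- function(object, ...) object$fit$fitted

#' @export
predict.ds_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fit$fitted)
  fr <- data.frame(z = newdata[[object$moderator]],
                   x = newdata[[object$env]])
  fr$zx <- fr$z * fr$x
  for (cv in object$covariates) fr[[cv]] <- newdata[[cv]]
  predict(object$fit$lm, newdata = fr)
}

#' @export
simulate.ds_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  sig <- sqrt(object$fit$sigma2)
  out <- as.data.frame(replicate(nsim, object$fit$fitted + rnorm(n, 0, sig)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Interaction plot with regions of significance
#'
#' Plots the fitted outcome against the raw environment at a low and a high
#' moderator level (mean -/+ 1 SD by default, or the mean-split group means)
#' with covariates held at their sample means, overlays the crossover and
#' the Johnson-Neyman bounds (mapped back to the raw environment scale),
#' and rugs the observed environment values.
#'
#' @param x a `"ds_model"`.
#' @param z_at `"pm_sd"` (moderator mean -/+ 1 SD) or `"split"`
#'   (mean-split group means).
#' @param ... passed to [plot()].
#' @return The plotted line data, invisibly.
#' @export
plot.ds_model <- function(x, z_at = c("pm_sd", "split"), ...) {
  z_at <- match.arg(z_at)
  d <- x$data
  ev <- d[[x$env]]; mo <- d[[x$moderator]]
  zl <- if (z_at == "pm_sd") mean(mo) - sd(mo) else mean(mo[mo <= mean(mo)])
  zh <- if (z_at == "pm_sd") mean(mo) + sd(mo) else mean(mo[mo > mean(mo)])
  grid_x <- seq(min(ev), max(ev), length.out = 100L)
  base <- data.frame(matrix(nrow = 100L, ncol = 0L))
  base[[x$env]] <- grid_x
  for (cv in x$covariates) base[[cv]] <- mean(d[[cv]])
  lo <- hi <- base
  lo[[x$moderator]] <- zl; hi[[x$moderator]] <- zh
  y_lo <- predict(x, lo); y_hi <- predict(x, hi)
  plot(range(grid_x), range(c(y_lo, y_hi)), type = "n",
       xlab = x$env, ylab = x$outcome,
       main = sprintf("%s: %s x %s", x$outcome, x$env, x$moderator), ...)
  lines(grid_x, y_lo, lty = 2)
  lines(grid_x, y_hi, lty = 1)
  if (x$ros$status == "two_real_roots") {
    raw_b <- mean(ev) + c(x$ros$lower, x$ros$upper) * sd(ev)
    abline(v = raw_b, col = "grey40", lty = 3)
  }
  rug(ev)
  legend("topright", lty = c(2, 1),
         legend = sprintf("%s = %.2f", x$moderator, c(zl, zh)), bty = "n")
  invisible(data.frame(x = grid_x, y_low = y_lo, y_high = y_hi))
}

#' Write a differential-susceptibility report as JSON
#'
#' One JSON object per fitted outcome: bounds, crossover, PoI, PA, simple
#' slopes, verdict, and every convention in force.
#'
#' @param model a `"ds_model"`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ds_report <- function(model, path) {
  stopifnot(inherits(model, "ds_model"))
  rep <- list(
    outcome = model$outcome, env = model$env, moderator = model$moderator,
    n = model$n,
    interaction = list(beta = unname(model$betas[["zx"]]),
                       p = model$interaction_p,
                       r2_change = model$r2_change$r2_change,
                       r2_change_p = model$r2_change$p),
    ros = model$ros[c("lower", "upper", "t_crit", "df", "status",
                      "significant")],
    indices = model$indices,
    slopes = model$slopes,
    quadratic = if (is.null(model$quadratic)) NULL else
      model$quadratic[c("p_x2", "p_zx2", "nonlinear_flag")],
    verdict = unclass(model$verdict),
    conventions = model$conventions)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
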