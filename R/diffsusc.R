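# extract the pieces the Johnson-Neyman algebra needs from a fit:
# b1 (moderator), b3 (interaction), their variances/covariance, residual df
.jn_params <- function(fit) {
  if (inherits(fit, "ds_model")) fit <- fit$std_fit
  if (inherits(fit, "ols_fit")) {
    b <- coef(fit); V <- vcov(fit)
    if (!all(c("z", "zx") %in% names(b)))
      .stop("fit must contain moderator term `z` and product term `zx`")
    return(list(b1 = unname(b["z"]), b3 = unname(b["zx"]),
                v11 = V["z", "z"], v13 = V["z", "zx"], v33 = V["zx", "zx"],
                df = fit$df))
  }
  need <- c("b1", "b3", "v11", "v13", "v33", "df")
  if (!is.list(fit) || !all(need %in% names(fit)))
    .stop("fit must be a ds_model, ols_fit, or list with %s",
          paste(need, collapse = ", "))
  fit[need]
}

#' Crossover point of a moderated regression
#'
#' The environment value at which the moderator has no effect on the
#' outcome, `X_c = -b1 / b3`; the fitted lines for any two moderator levels
#' intersect there.
#'
#' @param fit a `"ds_model"`, an `"ols_fit"` with terms `z` and `zx`, or a
#'   list with elements `b1`, `b3`, `v11`, `v13`, `v33`, `df`.
#' @return The crossover on the environment scale of the fit.
#' @examples
#' crossover_point(list(b1 = 0.4, b3 = 0.4, v11 = 1, v13 = 0, v33 = 1,
#'                      df = 10))  # -1
#' @export
crossover_point <- function(fit) {
  p <- .jn_params(fit)
  if (abs(p$b3) < 1e-12)
    .stop("degenerate: interaction coefficient is (numerically) zero")
  -p$b1 / p$b3
}

#' Johnson-Neyman regions of significance
#'
#' Solves for the environment values `X` at which the conditional moderator
#' effect `b1 + b3 X` is exactly at the two-sided significance boundary,
#' i.e. the real roots of
#' `(b1 + b3 X)^2 = t_crit^2 (v11 + 2 X v13 + X^2 v33)`,
#' with `t_crit` the two-sided critical value at `alpha` on the fit's
#' residual df.  Between/outside behaviour is captured by `significant`:
#' `"outside"` (the usual crossover geometry: the effect is significant
#' beyond the bounds), `"inside"`, `"everywhere"` or `"nowhere"` (when the
#' quadratic has no real roots).
#'
#' @inheritParams crossover_point
#' @param alpha two-sided significance level (default 0.05).
#' @return An object of class `"ros_result"`: list with `lower`, `upper`
#'   (NA when undefined), `t_crit`, `df`, `status` (one of
#'   `"two_real_roots"`, `"no_real_roots"`,
#'   `"degenerate_no_interaction"`), and `significant`.
#' @examples
#' ros_bounds(list(b1 = 0, b3 = 1, v11 = 0.04, v13 = 0, v33 = 0.04,
#'                 df = 60))
#' @export
ros_bounds <- function(fit, alpha = 0.05) {
  p <- .jn_params(fit)
  t_crit <- qt(1 - alpha / 2, df = p$df)
  t2 <- t_crit^2
  A <- p$b3^2 - t2 * p$v33
  B <- 2 * (p$b1 * p$b3 - t2 * p$v13)
  C <- p$b1^2 - t2 * p$v11
  res <- list(lower = NA_real_, upper = NA_real_, t_crit = t_crit,
              df = p$df, status = NA_character_, significant = NA_character_)
  if (abs(p$b3) < 1e-12 && abs(p$v33) < 1e-24 && abs(p$v13) < 1e-24) {
    res$status <- "degenerate_no_interaction"
    res$significant <- if (C > 0) "everywhere" else "nowhere"
    return(structure(res, class = "ros_result"))
  }
  if (abs(A) < 1e-12 * max(p$b3^2, t2 * p$v33)) {
    # boundary case b3^2 == t^2 v33: the quadratic degenerates to a line
    if (abs(B) < 1e-300) {
      res$status <- "no_real_roots"
      res$significant <- if (C > 0) "everywhere" else "nowhere"
      return(structure(res, class = "ros_result"))
    }
    root <- -C / B
    res$lower <- res$upper <- root
    res$status <- "two_real_roots"
    res$significant <- if (B > 0) "above" else "below"
    attr(res, "boundary") <- TRUE
    return(structure(res, class = "ros_result"))
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    res$status <- "no_real_roots"
    res$significant <- if (A > 0) "everywhere" else "nowhere"
    return(structure(res, class = "ros_result"))
  }
  r <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  res$lower <- r[1]; res$upper <- r[2]
  res$status <- "two_real_roots"
  res$significant <- if (A > 0) "outside" else "inside"
  structure(res, class = "ros_result")
}

#' @export
print.ros_result <- function(x, ...) {
  cat("Johnson-Neyman region of significance\n")
  cat(sprintf("  status: %s; moderator effect significant %s\n",
              x$status, x$significant))
  if (x$status == "two_real_roots")
    cat(sprintf("  bounds: [%.4f, %.4f]  (t_crit = %.3f, df = %d)\n",
                x$lower, x$upper, x$t_crit, x$df))
  invisible(x)
}

#' Proportion of interaction (PoI)
#'
#' The fitted lines for a low and a high moderator level, drawn over the
#' window `x_mean +/- 2 x_sd`, enclose two triangular regions meeting at
#' the crossover.  PoI is the share of the enclosed area lying on the
#' high-environment ("for better") side of the crossover; because the area
#' of each triangle scales with the square of its width, PoI reduces to
#' `w_hi^2 / (w_lo^2 + w_hi^2)` in closed form.  A crossover outside the
#' window clamps PoI to 0 or 1.  A value near 0.5 is the prototypical
#' differential-susceptibility geometry.  The geometry is valence-free:
#' the "for better" side is the high-environment side regardless of
#' whether the outcome is desirable.
#'
#' @inheritParams crossover_point
#' @param x_mean,x_sd mean and SD of the observed environment (default the
#'   standardized scale, 0 and 1).
#' @param z_low,z_high moderator levels for the plotted lines (default
#'   mean -/+ 1 SD of standardized moderator); PoI is invariant to the
#'   choice, which is kept for the companion plot.
#' @return PoI in `[0, 1]`.
#' @examples
#' poi(list(b1 = -0.4, b3 = 0.4, v11 = 1, v13 = 0, v33 = 1, df = 10))
#' # crossover at +1 in [-2, 2]: 1 / (1 + 9)
#' @export
poi <- function(fit, x_mean = 0, x_sd = 1, z_low = -1, z_high = 1) {
  if (z_low >= z_high) .stop("z_low must be below z_high")
  xc <- crossover_point(fit)
  lo <- x_mean - 2 * x_sd
  hi <- x_mean + 2 * x_sd
  if (xc <= lo) return(1)
  if (xc >= hi) return(0)
  w_lo <- xc - lo
  w_hi <- hi - xc
  w_hi^2 / (w_lo^2 + w_hi^2)
}

#' Proportion affected (PA)
#'
#' Fraction of the observed environment values strictly above the
#' crossover, i.e. on the side where higher susceptibility predicts the
#' better outcome; ties at the crossover count below.  A value near 0.5
#' means about half the sample sits on each side — the prototypical
#' differential-susceptibility pattern.
#'
#' @param x observed environment values.
#' @param crossover the crossover point on the same scale.
#' @return PA in `[0, 1]`.
#' @examples
#' pa(c(-2, -1, 0, 1, 2), 0.5)  # 0.4
#' @export
pa <- function(x, crossover) {
  if (length(x) == 0L) .stop("no environment values")
  mean(x > crossover)
}

#' Simple slopes by moderator mean split
#'
#' Dichotomizes the moderator at its mean into an indicator `G` (0 = low,
#' 1 = high), refits the covariate-adjusted model
#' `y ~ G + x + G:x + covariates`, and reports each group's environment
#' slope: the low group's is the `x` coefficient, the high group's adds the
#' `G:x` coefficient, with the standard error from the corresponding
#' linear-combination variance.  Slopes are on the raw outcome scale.
#'
#' @param data data.frame holding all columns.
#' @param outcome,env,moderator,covariates column names.
#' @return data.frame with one row per group: group, n, slope, se, t, df, p.
#' @export
simple_slopes_split <- function(data, outcome, env, moderator,
                                covariates = character()) {
  fr <- .build_frame(data, outcome, env, moderator, covariates)
  g <- as.numeric(fr$z > mean(fr$z))
  n_min <- length(covariates) + 2L
  if (min(table(g)) < n_min)
    .stop("a mean-split group has fewer than %d members", n_min)
  des <- data.frame(g = g, x = fr$x, gx = g * fr$x,
                    fr[covariates])
  fit <- fit_ols(des, fr$y)
  b <- coef(fit); V <- vcov(fit)
  lo_slope <- unname(b["x"])
  lo_se <- sqrt(V["x", "x"])
  hi_slope <- unname(b["x"] + b["gx"])
  hi_se <- sqrt(V["x", "x"] + V["gx", "gx"] + 2 * V["x", "gx"])
  out <- data.frame(
    group = c("low", "high"), n = c(sum(g == 0), sum(g == 1)),
    slope = c(lo_slope, hi_slope), se = c(lo_se, hi_se), df = fit$df)
  out$t <- out$slope / out$se
  out$p <- 2 * pt(abs(out$t), fit$df, lower.tail = FALSE)
  out[c("group", "n", "slope", "se", "t", "df", "p")]
}

#' Differential-susceptibility verdict
#'
#' Applies the confirmation criteria to a fitted interaction: both
#' region-of-significance bounds inside the observed range of interest
#' (`x_mean +/- 2 x_sd`), PoI within `poi_band`, PA within `pa_band` (the
#' declared operationalization of "close to 0.50"), and no nonlinearity.
#' Verdicts: `"prototypical_differential_susceptibility"` when all hold;
#' `"excluded_nonlinear"` when the geometric indices hold but the quadratic
#' check flags nonlinearity; `"not_supported"` otherwise (the nonlinearity
#' flag cannot change a pattern the indices already fail to support).
#'
#' @param ros a `"ros_result"` from [ros_bounds()].
#' @param poi,pa the two indices.
#' @param nonlinear_flag logical from [quadratic_robustness()].
#' @param x_mean,x_sd observed environment mean and SD.
#' @param poi_band,pa_band acceptance bands (defaults `[0.40, 0.60]`).
#' @return An object of class `"ds_verdict"`: list of the four flags and
#'   the verdict string.
#' @examples
#' ros <- structure(list(lower = -1.696, upper = 0.736,
#'                       status = "two_real_roots", significant = "outside",
#'                       t_crit = 2, df = 65), class = "ros_result")
#' classify_ds(ros, poi = 0.59, pa = 0.563)$verdict
#' @export
classify_ds <- function(ros, poi, pa, nonlinear_flag = FALSE,
                        x_mean = 0, x_sd = 1,
                        poi_band = c(0.40, 0.60), pa_band = c(0.40, 0.60)) {
  stopifnot(inherits(ros, "ros_result"))
  lo <- x_mean - 2 * x_sd
  hi <- x_mean + 2 * x_sd
  ros_ok <- ros$status == "two_real_roots" &&
    !is.na(ros$lower) && !is.na(ros$upper) &&
    ros$lower >= lo && ros$upper <= hi
  poi_ok <- poi >= poi_band[1] && poi <= poi_band[2]
  pa_ok <- pa >= pa_band[1] && pa <= pa_band[2]
  favourable <- ros_ok && poi_ok && pa_ok
  verdict <- if (favourable && !nonlinear_flag)
    "prototypical_differential_susceptibility"
  else if (favourable) "excluded_nonlinear"
  else "not_supported"
  structure(list(ros_within_range = ros_ok, poi_in_band = poi_ok,
                 pa_near_half = pa_ok, nonlinear_excluded = !nonlinear_flag,
                 verdict = verdict,
                 bands = list(poi = poi_band, pa = pa_band,
                              x_range = c(lo, hi))),
            class = "ds_verdict")
}

#' @export
print.ds_verdict <- function(x, ...) {
  cat(sprintf("Verdict: %s\n", x$verdict))
  cat(sprintf("  RoS within mean+/-2SD: %s | PoI in band: %s | PA near 0.5: %s | linear: %s\n",
              x$ros_within_range, x$poi_in_band, x$pa_near_half,
              x$nonlinear_excluded))
  invisible(x)
}
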