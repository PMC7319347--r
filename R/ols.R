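# build the analysis frame: y, moderator z, environment x, product zx,
# covariates; standardized = z-score y/x/z and continuous covariates and
# form the product AFTER standardization ("standardize-then-multiply")
.build_frame <- function(data, outcome, env, moderator, covariates,
                         standardized = FALSE, quadratic = FALSE) {
  need <- c(outcome, env, moderator, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) .stop("missing column(s): %s", paste(miss, collapse = ", "))
  if (env == moderator) .stop("environment and moderator must differ")
  if (anyDuplicated(covariates)) .stop("covariates must be distinct")
  zs <- function(v) {
    s <- sd(v)
    if (s == 0) .stop("zero-variance column in standardization")
    (v - mean(v)) / s
  }
  is_binary <- function(v) length(unique(v)) <= 2L
  y <- data[[outcome]]
  x <- data[[env]]
  z <- data[[moderator]]
  if (standardized) {
    if (sd(y) == 0) .stop("zero-variance outcome %s", outcome)
    y <- zs(y); x <- zs(x); z <- zs(z)
  }
  fr <- data.frame(y = y, z = z, x = x, zx = z * x)
  if (quadratic) {
    fr$x2 <- x^2
    fr$zx2 <- z * x^2
  }
  for (cv in covariates) {
    v <- data[[cv]]
    fr[[cv]] <- if (standardized && !is_binary(v)) zs(v) else v
  }
  fr
}

#' Ordinary least squares with full coefficient covariance
#'
#' Thin wrapper around [stats::lm()] that adds an intercept, refuses
#' rank-deficient designs (naming the aliased columns), and returns the
#' pieces downstream differential-susceptibility computations need:
#' coefficients, their covariance matrix, residual df and variance, R
#' squared, and per-term two-sided p-values.
#'
#' @param x data.frame or matrix of predictors (no intercept column).
#' @param y numeric response.
#' @return An object of class `"ols_fit"`: list with `coefficients`,
#'   `vcov`, `df`, `sigma2`, `r_squared`, `p_values`, `fitted`,
#'   `residuals`, `lm` (the underlying fit).
#' @examples
#' d <- data.frame(a = rnorm(20), b = rnorm(20))
#' f <- fit_ols(d, 1 + 2 * d$a - d$b + rnorm(20, 0, 0.1))
#' coef(f)
#' @export
fit_ols <- function(x, y) {
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) .stop("x has %d rows but y has %d values",
                                  nrow(x), length(y))
  if (nrow(x) <= ncol(x) + 1L)
    .stop("need n > number of parameters (n = %d, p = %d + intercept)",
          nrow(x), ncol(x))
  fit <- lm(y ~ ., data = cbind(y = y, x))
  if (anyNA(coef(fit)))
    .stop("collinear design; aliased column(s): %s",
          paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  sm <- summary(fit)
  structure(list(
    coefficients = coef(fit), vcov = vcov(fit), df = fit$df.residual,
    sigma2 = sm$sigma^2, r_squared = sm$r.squared,
    p_values = sm$coefficients[, 4L],
    fitted = fitted(fit), residuals = residuals(fit), lm = fit
  ), class = "ols_fit")
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
vcov.ols_fit <- function(object, ...) object$vcov

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %d coefficients, %d residual df, R2 = %.3f\n",
              length(x$coefficients), x$df, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Standardized coefficients of the interaction model
#'
#' Refits the moderated regression with the outcome, environment, moderator
#' and continuous covariates z-scored, the interaction column formed as the
#' product of the standardized environment and moderator
#' (standardize-then-multiply), and binary covariates left on their 0/1
#' scale.  The reported coefficients are the standardized betas of the
#' published tables.
#'
#' @param data data.frame holding all columns.
#' @param outcome,env,moderator,covariates column names.
#' @return list with `betas` (named: z, x, zx, covariates), `p_values`,
#'   `fit` (the standardized `"ols_fit"`), and `convention`.
#' @export
standardized_betas <- function(data, outcome, env, moderator,
                               covariates = character()) {
  fr <- .build_frame(data, outcome, env, moderator, covariates,
                     standardized = TRUE)
  fit <- fit_ols(fr[setdiff(names(fr), "y")], fr$y)
  list(betas = coef(fit)[-1L], p_values = fit$p_values[-1L], fit = fit,
       convention = "standardize-then-multiply; binary covariates unstandardized")
}

#' R-squared change attributable to the interaction term
#'
#' Difference in R squared between the full moderated model and the nested
#' model without the product term, with the partial-F p-value (1 numerator
#' df), which equals the squared-t p-value of the product coefficient.
#'
#' @inheritParams standardized_betas
#' @return list with `r2_change`, `p`, `r2_full`, `r2_reduced`, `f`.
#' @export
interaction_r2_change <- function(data, outcome, env, moderator,
                                  covariates = character()) {
  fr <- .build_frame(data, outcome, env, moderator, covariates)
  full <- fit_ols(fr[setdiff(names(fr), "y")], fr$y)
  red <- fit_ols(fr[setdiff(names(fr), c("y", "zx"))], fr$y)
  d_r2 <- full$r_squared - red$r_squared
  f <- d_r2 / ((1 - full$r_squared) / full$df)
  list(r2_change = d_r2, p = pf(f, 1L, full$df, lower.tail = FALSE),
       r2_full = full$r_squared, r2_reduced = red$r_squared, f = f)
}

#' Quadratic robustness check for a moderated regression
#'
#' Refits the model with `x^2` and `z*x^2` added and reports their
#' p-values; the nonlinearity flag is raised when either is below `alpha`.
#' Run, per the analysis protocol, only for models whose linear interaction
#' is significant — the caller gates.  Also reports whether the linear
#' product term retains significance in the augmented model.
#'
#' @inheritParams standardized_betas
#' @param alpha significance level for the added terms.
#' @return list with `p_x2`, `p_zx2`, `nonlinear_flag`,
#'   `p_interaction_augmented`, `fit`.
#' @export
quadratic_robustness <- function(data, outcome, env, moderator,
                                 covariates = character(), alpha = 0.05) {
  fr <- .build_frame(data, outcome, env, moderator, covariates,
                     quadratic = TRUE)
  if (nrow(fr) <= ncol(fr) + 1L)
    .stop("insufficient residual df after adding quadratic terms")
  fit <- fit_ols(fr[setdiff(names(fr), "y")], fr$y)
  p_x2 <- unname(fit$p_values["x2"])
  p_zx2 <- unname(fit$p_values["zx2"])
  list(p_x2 = p_x2, p_zx2 = p_zx2,
       nonlinear_flag = (p_x2 < alpha) || (p_zx2 < alpha),
       p_interaction_augmented = unname(fit$p_values["zx"]),
       fit = fit)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (`min` over `j >= i` of `m * p(j) / j`) with
#' discoveries flagged at level `q`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.15, the analysis protocol's threshold).
#' @return data.frame: p, p_adjusted, discovery.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.20))
#' @export
bh_fdr <- function(p, q = 0.15) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    .stop("p-values must lie in [0, 1]")
  .check_prop(q, "q")
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = adj, discovery = adj <= q)
}
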