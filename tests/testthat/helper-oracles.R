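# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package implementation.

# normal-equations / pseudo-inverse least squares
ne_solve <- function(X, y) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  sv <- svd(X)
  drop(sv$v %*% ((t(sv$u) %*% y) / sv$d))
}

# Benjamini-Hochberg step-up from the definition: adjusted p(i) is the
# minimum over j >= i (in sorted order) of m * p(j) / j, capped at 1
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  val <- m * p[o] / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(val))), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# exact HWE p-value by direct normalization of the conditional distribution
# of heterozygote counts (unnormalized weights via choose(), not the
# closed-form constant the implementation uses)
hwe_enum <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_min <- 2 * min(n_aa, n_bb) + n_ab
  if (n_min == 0) return(1)
  hets <- seq(n_min %% 2, min(n_min, 2 * n - n_min), by = 2)
  logw <- vapply(hets, function(h) {
    hom_min <- (n_min - h) / 2
    hom_maj <- n - h - hom_min
    lchoose(n, h) + lchoose(n - h, hom_min) + h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# brute-force Johnson-Neyman bounds: scan the conditional-effect t
# statistic over a fine grid and report the |t| = t_crit crossings
jn_grid <- function(fit, alpha = 0.05, lim = 6, step = 1e-4) {
  x <- seq(-lim, lim, by = step)
  t_crit <- qt(1 - alpha / 2, fit$df)
  g <- (fit$b1 + fit$b3 * x)^2 -
    t_crit^2 * (fit$v11 + 2 * x * fit$v13 + x^2 * fit$v33)
  s <- sign(g)
  idx <- which(s[-1] != s[-length(s)])
  (x[idx] + x[idx + 1]) / 2
}

# numeric PoI: trapezoid integration of |difference between the two fitted
# lines| over the +/- 2 SD window, with the crossover inserted as a grid
# point so the piecewise-linear integrand is integrated exactly
poi_numeric <- function(b1, b3, x_mean, x_sd, z_low = -1, z_high = 1) {
  lo <- x_mean - 2 * x_sd
  hi <- x_mean + 2 * x_sd
  xc <- -b1 / b3
  grid <- sort(unique(c(seq(lo, hi, length.out = 40001L),
                        if (xc > lo && xc < hi) xc)))
  f <- abs((z_high - z_low) * (b1 + b3 * grid))
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  total <- trap(grid, f)
  if (total == 0) return(NA_real_)
  hi_side <- grid >= max(min(xc, hi), lo)
  trap(grid[hi_side], f[hi_side]) / total
}

# random plausible Johnson-Neyman fit parameters
rand_jn_fit <- function() {
  v11 <- runif(1, 0.001, 0.02)
  v33 <- runif(1, 0.001, 0.02)
  rho <- runif(1, -0.8, 0.8)
  list(b1 = rnorm(1, 0, 0.3),
       b3 = sample(c(-1, 1), 1) * runif(1, 0.1, 0.6),
       v11 = v11, v33 = v33, v13 = rho * sqrt(v11 * v33),
       df = sample(30:200, 1))
}

# moderator/environment/covariate draws through the package generators
gen_zx <- function(cfg) {
  g <- simulate_genotypes(cfg)
  w <- simulate_weights(cfg, g)
  z <- as.numeric(scale(predict_expression(g, w)$value))
  ses <- simulate_ses_indicators(cfg)
  cv <- simulate_covariates(cfg)
  list(z = z, x = attr(ses, "latent"), cv = cv)
}

# data with an exactly prescribed sample correlation matrix (orthonormalize
# noise, then impose the Cholesky factor)
exact_corr_data <- function(n, R) {
  p <- ncol(R)
  z <- matrix(rnorm(n * p), n)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- qr.Q(qr(z))[, seq_len(p)]
  z <- scale(z) # exactly uncorrelated, unit sample variance
  as.data.frame(z %*% chol(R))
}
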