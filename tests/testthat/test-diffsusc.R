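test_that("crossover point is where the moderator effect vanishes", {
  expect_equal(crossover_point(list(b1 = 0, b3 = 0.4, v11 = 1, v13 = 0,
                                    v33 = 1, df = 10)), 0)
  expect_equal(crossover_point(list(b1 = 0.4, b3 = 0.4, v11 = 1, v13 = 0,
                                    v33 = 1, df = 10)), -1)
  expect_error(crossover_point(list(b1 = 1, b3 = 0, v11 = 1, v13 = 0,
                                    v33 = 1, df = 10)), "degenerate")
  # defining property on a fitted model: equal predictions at the crossover
  set.seed(30)
  n <- 120
  d <- data.frame(z = rnorm(n), x = rnorm(n), age = runif(n, 14, 18))
  d$y <- 0.2 * d$z + 0.1 * d$x + 0.5 * d$z * d$x + 0.05 * d$age + rnorm(n)
  m <- ds_model(y ~ x * z + age, d)
  b <- coef(m$std_fit)
  xc <- crossover_point(m)
  expect_lt(abs(b["z"] + b["zx"] * xc), 1e-10)
})

test_that("region-of-significance bounds solve the boundary quadratic", {
  # alpha chosen so t_crit is exactly 2 at df = 60
  alpha2 <- 2 * pt(-2, 60)
  r <- ros_bounds(list(b1 = 0, b3 = 1, v11 = 0.04, v13 = 0, v33 = 0.04,
                       df = 60), alpha = alpha2)
  expect_equal(r$t_crit, 2)
  expect_equal(c(r$lower, r$upper), c(-1, 1) * sqrt(0.16 / 0.84),
               tolerance = 1e-10)
  expect_identical(r$status, "two_real_roots")
  expect_identical(r$significant, "outside")
  # no X dependence in effect or variance: degenerate
  dg <- ros_bounds(list(b1 = 2, b3 = 0, v11 = 0.1, v13 = 0, v33 = 0,
                        df = 40))
  expect_identical(dg$status, "degenerate_no_interaction")
  expect_identical(dg$significant, "everywhere")
})

test_that("region-of-significance bounds match the grid-scan oracle", {
  set.seed(31)
  n_checked <- 0
  while (n_checked < 25) {
    f <- rand_jn_fit()
    r <- ros_bounds(f)
    cross <- jn_grid(f, lim = 8, step = 1e-4)
    if (r$status == "two_real_roots" && abs(r$lower) < 7.5 &&
        abs(r$upper) < 7.5) {
      expect_equal(length(cross), 2L)
      expect_lt(max(abs(sort(cross) - c(r$lower, r$upper))), 1e-3)
      n_checked <- n_checked + 1
    } else if (r$status == "no_real_roots") {
      expect_identical(length(cross), 0L)
    }
  }
})

test_that("proportion of interaction has the triangle-area geometry", {
  # crossover at the window center: exactly one half
  expect_equal(poi(list(b1 = 0, b3 = 0.5, v11 = 1, v13 = 0, v33 = 1,
                        df = 9)), 0.5)
  # crossover at +1 in [-2, 2]: areas 9:1
  expect_equal(poi(list(b1 = -0.5, b3 = 0.5, v11 = 1, v13 = 0, v33 = 1,
                        df = 9)), 0.1)
  # crossover at the window edge: everything on one side
  expect_equal(poi(list(b1 = 1, b3 = 0.5, v11 = 1, v13 = 0, v33 = 1,
                        df = 9)), 1)
  expect_equal(poi(list(b1 = -1.5, b3 = 0.5, v11 = 1, v13 = 0, v33 = 1,
                        df = 9), x_mean = 0, x_sd = 1), 0)
  expect_error(poi(list(b1 = 1, b3 = 0, v11 = 1, v13 = 0, v33 = 1,
                        df = 9)), "degenerate")
})

test_that("closed-form PoI equals numeric integration; mirrored fits flip it", {
  set.seed(32)
  for (i in 1:25) {
    f <- rand_jn_fit()
    xm <- runif(1, -1, 1); xs <- runif(1, 0.5, 2)
    v <- poi(f, x_mean = xm, x_sd = xs)
    expect_equal(v, poi_numeric(f$b1, f$b3, xm, xs), tolerance = 1e-6)
    fm <- f; fm$b1 <- -f$b1
    expect_equal(poi(fm, x_mean = -xm, x_sd = xs), 1 - v, tolerance = 1e-12)
  }
})

test_that("proportion affected counts strictly above the crossover", {
  expect_equal(pa(c(-2, -1, 0, 1, 2), 0.5), 0.4)
  expect_equal(pa(c(1, 2, 3), 0), 1)
  expect_equal(pa(c(1, 2, 3), 3), 0)  # tie counts below
  expect_error(pa(numeric(), 0), "no environment")
  set.seed(33)
  x <- rnorm(20000)
  expect_equal(pa(x, 0), 0.5, tolerance = 0.02)
  # negating the sample about the crossover complements PA (no ties)
  expect_equal(pa(-x, 0), 1 - pa(x, 0), tolerance = 1e-12)
})

test_that("mean-split simple slopes recover piecewise noiseless slopes", {
  set.seed(34)
  n <- 80
  z <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  x <- rnorm(n)
  g <- as.numeric(z > mean(z))
  y <- ifelse(g == 1, 50 * x, -100 * x) + 10 * g + 3
  d <- data.frame(y = y, z = z, x = x)
  sl <- suppressWarnings(simple_slopes_split(d, "y", "x", "z"))
  expect_equal(sl$slope[sl$group == "low"], -100, tolerance = 1e-8)
  expect_equal(sl$slope[sl$group == "high"], 50, tolerance = 1e-8)
  expect_true(all(sl$p[1] < 1e-6))
  # identical structure in both groups: equal slopes
  y2 <- 2 * x + rnorm(n, 0, 1e-8)
  sl2 <- suppressWarnings(
    simple_slopes_split(data.frame(y = y2, z = z, x = x), "y", "x", "z"))
  expect_equal(sl2$slope[1], sl2$slope[2], tolerance = 1e-4)
})

test_that("simple slopes show the low-group-only pattern under the scenario", {
  hits <- vapply(1:40, function(i) {
    cfg <- sim_config(n_subjects = 500, n_snps = 40, seed = 4000 + i,
                      missing_rate = 0)
    d <- gen_zx(cfg)
    out <- simulate_outcomes(cfg, d$z, d$x, d$cv)
    dat <- data.frame(y = out$snack_latent, ses = d$x, expr = d$z, d$cv)
    sl <- simple_slopes_split(dat, "y", "ses", "expr",
                              c("age", "sex", "bmi_z", "pc1", "pc2"))
    # with b2 = 0.1, b3 = 0.4 the group slopes sit near -+ 0.22 / 0.42:
    # the high group is reliably significant, and the groups differ in sign
    sl$slope[sl$group == "low"] < 0 && sl$slope[sl$group == "high"] > 0 &&
      sl$p[sl$group == "high"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("verdict logic distinguishes the canonical patterns", {
  ros_in <- structure(list(lower = -1.0, upper = 0.5, t_crit = 2, df = 60,
                           status = "two_real_roots",
                           significant = "outside"), class = "ros_result")
  v <- classify_ds(ros_in, poi = 0.5, pa = 0.5)
  expect_identical(v$verdict, "prototypical_differential_susceptibility")
  # favourable geometry but curvature: excluded
  v2 <- classify_ds(ros_in, poi = 0.5, pa = 0.5, nonlinear_flag = TRUE)
  expect_identical(v2$verdict, "excluded_nonlinear")
  # unfavourable indices dominate the nonlinearity flag
  v3 <- classify_ds(ros_in, poi = 0.2, pa = 0.5, nonlinear_flag = TRUE)
  expect_identical(v3$verdict, "not_supported")
  # bounds outside the range of interest
  ros_out <- structure(list(lower = -2.7, upper = 4.1, t_crit = 2, df = 60,
                            status = "two_real_roots",
                            significant = "outside"), class = "ros_result")
  expect_identical(classify_ds(ros_out, poi = 0.5, pa = 0.5)$verdict,
                   "not_supported")
  nr <- structure(list(lower = NA_real_, upper = NA_real_, t_crit = 2,
                       df = 60, status = "no_real_roots",
                       significant = "nowhere"), class = "ros_result")
  expect_identical(classify_ds(nr, poi = 0.5, pa = 0.5)$verdict,
                   "not_supported")
})
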