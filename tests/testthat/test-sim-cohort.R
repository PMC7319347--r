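test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_subjects = 30, n_snps = 20, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$outcomes, s2$outcomes)
  s3 <- simulate_cohort(sim_config(n_subjects = 30, n_snps = 20, seed = 6))
  expect_false(identical(s1$outcomes$snack_kcal, s3$outcomes$snack_kcal))
  expect_identical(names(s1$cohort), names(s3$cohort))
})

test_that("genotype frequencies follow the binomial model", {
  cfg <- sim_config(n_subjects = 4000, n_snps = 12, seed = 8,
                    maf_range = c(0.5, 0.5), missing_rate = 0)
  g <- simulate_genotypes(cfg)
  freq <- apply(g$dosage, 2L, function(d) tabulate(d + 1L, 3L) / length(d))
  # binomial(2, 0.5): 0.25 / 0.5 / 0.25, 4 sd binomial tolerance
  tol <- 4 * sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(freq[1, ] - 0.25) < tol))
  expect_true(all(abs(freq[2, ] - 0.50) < 4 * sqrt(0.5 * 0.5 / 4000)))
  expect_true(all(abs(freq[3, ] - 0.25) < tol))
  expect_equal(mean(is.na(simulate_genotypes(
    sim_config(n_subjects = 2000, n_snps = 10, seed = 2,
               missing_rate = 0.05))$dosage)), 0.05, tolerance = 0.2)
})

test_that("configuration is validated", {
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(ses_loadings = c(income = 1.2, education = 0.7,
                                           public_assistance = 0.7,
                                           food_security = 0.7,
                                           perceived_resources = 0.7)),
               "ses_loadings")
  expect_identical(sim_config(scenario = "null", b3 = 0.4)$b3, 0)
})

test_that("socioeconomic battery recovers its single-factor structure", {
  cfg <- sim_config(n_subjects = 2000, seed = 11,
                    ses_loadings = c(income = 0.8, education = 0.8,
                                     public_assistance = 0.8,
                                     food_security = 0.8,
                                     perceived_resources = 0.8))
  ses <- simulate_ses_indicators(cfg)
  p <- pca_first_component(standardize_indicators(ses))
  expect_true(all(abs(p$loadings - 0.8) < 0.08))
  # degenerate noise-free continuous indicator tracks the latent factor
  cfg1 <- sim_config(n_subjects = 500, seed = 3,
                     ses_loadings = c(income = 0.7, education = 0.7,
                                      public_assistance = 0.7,
                                      food_security = 0.7,
                                      perceived_resources = 1))
  ses1 <- simulate_ses_indicators(cfg1)
  expect_equal(cor(ses1$perceived_resources, attr(ses1, "latent")), 1,
               tolerance = 1e-10)
  # variance explained tracks the implied leading eigenvalue
  cfg2 <- sim_config(n_subjects = 2000, seed = 12)
  ses2 <- simulate_ses_indicators(cfg2)
  p2 <- pca_first_component(standardize_indicators(ses2))
  implied <- attr(ses2, "implied")$variance_explained
  expect_lt(abs(p2$variance_explained - implied), 0.05)
  # indicator types as published
  expect_true(all(ses2$income %in% 1:10))
  expect_true(all(ses2$education %in% 1:6))
  expect_true(all(ses2$public_assistance %in% 0:1))
  expect_true(all(ses2$food_security %in% 0:1))
})

test_that("outcome generator embodies the configured interaction model", {
  cfg <- sim_config(n_subjects = 200, seed = 4, missing_rate = 0,
                    noise_sd = 1e-9)
  d <- gen_zx(cfg)
  out <- simulate_outcomes(cfg, d$z, d$x, d$cv)
  # noiseless latent outcome refits to the generative coefficients
  fr <- data.frame(z = d$z, x = d$x, zx = d$z * d$x)
  cvs <- cbind((d$cv$age - 16) / (4 / sqrt(12)), (d$cv$sex - 0.5) / 0.5,
               d$cv$bmi_z, d$cv$pc1, d$cv$pc2)
  colnames(cvs) <- c("age", "sex", "bmi_z", "pc1", "pc2")
  fit <- fit_ols(cbind(fr, cvs), out$snack_latent)
  b <- coef(fit)
  expect_equal(unname(b["zx"]), cfg$b3, tolerance = 1e-6)
  expect_equal(unname(b["x"]), cfg$b2, tolerance = 1e-6)
  expect_equal(unname(b["z"]), attr(out, "b1"), tolerance = 1e-6)
  expect_equal(unname(b[c("age", "sex", "bmi_z", "pc1", "pc2")]),
               unname(cfg$covariate_effects), tolerance = 1e-6)
  expect_error(simulate_outcomes(cfg, d$z[-1], d$x, d$cv), "misaligned")
  expect_true(all(out$snack_kcal >= 0))
  expect_true(all(out$pss_total >= 0 & out$pss_total <= 40))
})

test_that("differential-susceptibility scenario centers the crossover", {
  pas <- vapply(1:20, function(i) {
    cfg <- sim_config(n_subjects = 400, n_snps = 40, seed = 900 + i,
                      missing_rate = 0)
    d <- gen_zx(cfg)
    out <- simulate_outcomes(cfg, d$z, d$x, d$cv)
    fr <- data.frame(z = d$z, x = d$x, zx = d$z * d$x, d$cv)
    fit <- fit_ols(fr, out$snack_latent)
    pa(d$x, crossover_point(list(b1 = coef(fit)[["z"]],
                                 b3 = coef(fit)[["zx"]],
                                 v11 = 1, v13 = 0, v33 = 1, df = fit$df)))
  }, numeric(1))
  expect_true(all(abs(pas - 0.5) < 0.1))
})

test_that("cohort tables have the published structure and round-trip", {
  cfg <- sim_config(n_subjects = 76, n_snps = 25, seed = 21)
  sim <- simulate_cohort(cfg)
  expect_identical(nrow(sim$cohort), 76L)
  expect_identical(ncol(sim$ses) - 1L, 5L)  # subject_id + 5 indicators
  expect_false(anyDuplicated(sim$cohort$subject_id) > 0)
  pss_cols <- sprintf("pss_%02d", 1:10)
  expect_true(all(as.matrix(sim$cohort[pss_cols]) %in% 0:4))
  expect_true(all(sim$cohort[grep("^food_", names(sim$cohort))] >= 0))

  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir, vcf = TRUE)
  g <- read_dosage_tsv(paths["dosages"], paths["snps"])
  expect_equal(g$dosage, sim$geno$dosage)
  expect_identical(g$snps$ref, sim$geno$snps$ref)
  w <- read_weights_tsv(paths["weights"])
  expect_equal(w$weight, sim$weights$weight)
  ph <- read_phenotypes_csv(paths["phenotypes"])
  expect_equal(ph$subject_id, sim$cohort$subject_id)
  ses <- read_ses_csv(paths["ses"])
  expect_equal(ses$income, sim$ses$income)
  gv <- read_vcf_dosages(paths["vcf"])
  expect_equal(unname(gv$dosage[rownames(g$dosage), colnames(g$dosage)]),
               unname(round(g$dosage)))
})

test_that("scored stress totals equal the oriented item sums", {
  sim <- simulate_cohort(sim_config(n_subjects = 50, n_snps = 10, seed = 33))
  sc <- pss_total(sim$cohort[sprintf("pss_%02d", 1:10)])
  expect_identical(unname(sc$total), unname(sim$outcomes$pss_total))
})
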