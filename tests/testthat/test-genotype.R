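test_that("call rate and minor allele frequency follow their definitions", {
  expect_equal(snp_call_rate(c(rep(1, 95), rep(NA, 5))), 0.95)
  expect_equal(snp_call_rate(c(0, 1, 2)), 1)
  expect_equal(snp_call_rate(rep(NA_real_, 4)), 0)
  expect_error(snp_call_rate(numeric()), "empty")

  expect_equal(minor_allele_frequency(c(rep(0, 81), rep(1, 18), 2)), 0.10)
  expect_equal(minor_allele_frequency(rep(0, 50)), 0)
  expect_equal(minor_allele_frequency(rep(1.8, 10)), 0.10)  # folding
  expect_error(minor_allele_frequency(rep(NA_real_, 3)), "missing")
})

test_that("MAF is invariant under allele folding", {
  set.seed(1)
  for (i in 1:20) {
    d <- rbinom(60, 2, runif(1, 0.05, 0.95))
    expect_equal(minor_allele_frequency(d), minor_allele_frequency(2 - d))
  }
})

test_that("exact Hardy-Weinberg test matches an independent enumeration", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_test(0, 100, 0), 0.001)
  expect_lt(hwe_exact_test(50, 0, 50), 0.001)
  expect_error(hwe_exact_test(-1, 5, 5), ">= 0")
  expect_equal(hwe_exact_test(10, 0, 0), 1)  # monomorphic
  set.seed(2)
  for (i in 1:50) {
    n <- sample(10:150, 1)
    p <- runif(1, 0.05, 0.5)
    g <- tabulate(rbinom(n, 2, p) + 1L, 3L)
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 hwe_enum(g[1], g[2], g[3]), tolerance = 1e-9)
  }
  # large-sample chi-square fallback agrees with the exact route in order
  p_chi <- hwe_exact_test(500, 400, 300, chisq_above = 1000)
  p_ex <- hwe_exact_test(500, 400, 300, chisq_above = 5000)
  expect_lt(abs(log10(p_chi) - log10(p_ex)), 0.5)
})

test_that("QC filter removes exactly the designed failures, idempotently", {
  n <- 100
  set.seed(3)
  good <- function() rbinom(n, 2, 0.3)
  d <- cbind(
    low_call = replace(good(), 1:10, NA),         # call rate 0.90
    het_excess = rep(1, n),                        # (0, 100, 0)
    rare = c(rep(1, 4), rep(0, n - 4)),            # maf 0.02
    ok1 = good(), ok2 = good())
  g <- geno_matrix(d, data.frame(id = colnames(d), ref = "A", alt = "G"))
  filt <- qc_filter(g)
  rep <- attr(filt, "qc_report")
  expect_identical(filt$snps$id, c("ok1", "ok2"))
  expect_identical(rep$status, c("fail", "fail", "fail", "pass", "pass"))
  expect_match(rep$reason[1], "call_rate")
  expect_match(rep$reason[2], "hwe")
  expect_match(rep$reason[3], "maf")
  # idempotence
  refilt <- qc_filter(filt)
  expect_identical(refilt$dosage, filt$dosage)
  # thresholds at zero: identity filter
  all_kept <- qc_filter(g, call_rate = 0, hwe_p = 0, maf = 0)
  expect_identical(ncol(all_kept$dosage), 5L)
  # empty matrix: empty report
  e <- qc_filter(geno_matrix(matrix(numeric(), 5, 0),
                             data.frame(id = character(), ref = character(),
                                        alt = character())))
  expect_identical(nrow(attr(e, "qc_report")), 0L)
})

test_that("predicted expression is the weighted effect-allele dosage sum", {
  d <- matrix(c(0, 1, 2), nrow = 1,
              dimnames = list("S1", c("a", "b", "c")))
  snps <- data.frame(id = c("a", "b", "c"), ref = "A", alt = "G")
  g <- geno_matrix(d, snps)
  w <- data.frame(gene = "GENE", rsid = c("a", "b", "c"), ref_allele = "A",
                  eff_allele = "G", weight = c(0.5, -1.0, 0.25))
  expect_equal(predict_expression(g, w)$value, -0.5)
  w0 <- transform(w, weight = 0)
  expect_equal(predict_expression(g, w0)$value, 0)
  # effect allele = matrix ref: that term flips to 2 - d
  w_flip <- w
  w_flip$eff_allele[2] <- "A"
  # value changes by w*(2 - d) - w*d = 2w - 2wd = -2 - (-1) ... here d = 1
  expect_equal(predict_expression(g, w_flip)$value,
               -0.5 + (2 * -1.0 - 2 * -1.0 * 1))
  # linearity: doubling weights doubles values
  cfg <- sim_config(n_subjects = 30, n_snps = 15, seed = 7)
  gs <- simulate_genotypes(cfg)
  ws <- simulate_weights(cfg, gs)
  v1 <- predict_expression(gs, ws)$value
  ws2 <- transform(ws, weight = 2 * weight)
  expect_equal(predict_expression(gs, ws2)$value, 2 * v1, tolerance = 1e-12)
  # absent SNPs are skipped and counted; zero overlap errors
  ws_miss <- ws
  ws_miss$rsid[1] <- "rs_not_here"
  expect_identical(attr(predict_expression(gs, ws_miss), "n_skipped"), 1L)
  ws_none <- transform(ws, rsid = paste0("x", rsid))
  expect_error(predict_expression(gs, ws_none), "DRD4")
})

test_that("missing dosages are imputed to twice the allele frequency", {
  d <- matrix(c(0, 2, NA, 2), nrow = 4,
              dimnames = list(paste0("S", 1:4), "a"))
  g <- geno_matrix(d, data.frame(id = "a", ref = "A", alt = "G"))
  w <- data.frame(gene = "G1", rsid = "a", ref_allele = "A",
                  eff_allele = "G", weight = 1)
  v <- predict_expression(g, w)$value
  expect_equal(v[3], mean(c(0, 2, 2)))  # 2 x alt allele frequency
})

test_that("ancestry PCs separate simulated subpopulations and are orthonormal", {
  set.seed(9)
  p <- 300; n_half <- 60
  maf_a <- runif(p, 0.1, 0.5)
  maf_b <- pmin(maf_a + 0.25, 0.95)
  d <- rbind(t(replicate(n_half, rbinom(p, 2, maf_a))),
             t(replicate(n_half, rbinom(p, 2, maf_b))))
  g <- geno_matrix(d, data.frame(id = paste0("s", 1:p), ref = "A", alt = "C"))
  pcs <- ancestry_pcs(g, k = 2)
  grp_a <- pcs$pc1[1:n_half]
  grp_b <- pcs$pc1[(n_half + 1):(2 * n_half)]
  expect_true(max(grp_a) < min(grp_b) || max(grp_b) < min(grp_a))
  expect_lt(abs(sum(pcs$pc1 * pcs$pc2)), 1e-8)
  expect_equal(sd(pcs$pc1), 1)
  expect_identical(ncol(ancestry_pcs(g, k = 0)), 1L)
  const <- geno_matrix(matrix(1, 10, 3),
                       data.frame(id = letters[1:3], ref = "A", alt = "C"))
  expect_error(ancestry_pcs(const), "constant")
})
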