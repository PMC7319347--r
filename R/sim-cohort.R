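#' Simulate a genotype dosage matrix
#'
#' Draws per-SNP alternate-allele dosages from Binomial(2, p) with p uniform
#' in `maf_range`, then masks entries missing at `missing_rate`.  The
#' complete (pre-masking) matrix is kept in the attribute
#' `"dosage_complete"`; generators that need the truth (expression
#' simulation) use it, while downstream QC sees the masked matrix.
#'
#' @param config a [sim_config()].
#' @return A `"geno_matrix"`: list with `dosage` (subjects x SNPs numeric
#'   matrix, `NA` for missing) and `snps` (data.frame: id, ref, alt).
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 10, n_snps = 5))
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects; p <- config$n_snps
  set.seed(config$seed + 1L)
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  dose <- vapply(maf, function(f) rbinom(n, 2L, f), numeric(n))
  dose <- matrix(as.numeric(dose), nrow = n)
  ids <- sprintf("S%04d", seq_len(n))
  snp_ids <- sprintf("rs%06d", seq_len(p))
  dimnames(dose) <- list(ids, snp_ids)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, p, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  complete <- dose
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * p) < config$missing_rate, nrow = n)
    dose[miss] <- NA_real_
  }
  out <- geno_matrix(dose, data.frame(id = snp_ids, ref = ref, alt = alt,
                                      stringsAsFactors = FALSE))
  attr(out, "dosage_complete") <- complete
  out
}

#' Simulate an expression weight table
#'
#' Emits a PrediXcan-style flattened weight table for a single gene whose
#' nonzero-weight SNPs define the true predicted expression of the cohort.
#' A fraction of weights is attached to the reference allele so the
#' allele-flip rule of [predict_expression()] is exercised.
#'
#' @param config a [sim_config()].
#' @param geno a `"geno_matrix"` from [simulate_genotypes()].
#' @param gene,tissue labels written to the table.
#' @return data.frame: gene, rsid, ref_allele, eff_allele, weight.
#' @export
simulate_weights <- function(config, geno, gene = "DRD4",
                             tissue = "frontal_cortex") {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "geno_matrix"))
  p <- nrow(geno$snps)
  set.seed(config$seed + 2L)
  k <- max(1L, ceiling(config$weight_sparsity * p))
  pick <- sort(sample.int(p, k))
  w <- rnorm(k, 0, 0.15)
  flip <- runif(k) < 0.2  # weight stated on the ref allele for some SNPs
  data.frame(
    gene = gene, tissue = tissue,
    rsid = geno$snps$id[pick],
    ref_allele = geno$snps$ref[pick],
    eff_allele = ifelse(flip, geno$snps$ref[pick], geno$snps$alt[pick]),
    weight = w, stringsAsFactors = FALSE)
}

# analytic attenuation of corr(latent, discretized latent) for a threshold
# discretization of a standard normal at `cuts` with category codes `values`
.disc_attenuation <- function(cuts, values) {
  t0 <- c(-Inf, cuts); t1 <- c(cuts, Inf)
  phi <- function(t) ifelse(is.finite(t), dnorm(t), 0)
  pk <- pnorm(t1) - pnorm(t0)
  ed <- sum(values * pk)
  vd <- sum(values^2 * pk) - ed^2
  edl <- sum(values * (phi(t0) - phi(t1)))
  edl / sqrt(vd)
}

# thresholds that make k ordered categories approximate a discretized
# normal with the requested mean/sd on codes 1..k
.ordinal_cuts <- function(k, mean, sd) {
  pr <- dnorm(seq_len(k), mean, sd)
  pr <- pr / sum(pr)
  qnorm(cumsum(pr)[-k])
}

# discretization plan for the five indicators (codes and latent cuts)
.ses_plan <- function() {
  list(cuts = list(income = .ordinal_cuts(10L, 6.2, 3.2),
                   education = .ordinal_cuts(6L, 4.6, 1.4),
                   public_assistance = qnorm(0.2),
                   food_security = qnorm(0.2)),
       vals = list(income = 1:10, education = 1:6,
                   public_assistance = 0:1, food_security = 0:1))
}

# exact univariate moments of a threshold-discretized standard normal
.ind_moments <- function(cuts, vals) {
  t0 <- c(-Inf, cuts); t1 <- c(cuts, Inf)
  pk <- pnorm(t1) - pnorm(t0)
  mu <- sum(vals * pk)
  list(mu = mu, sd = sqrt(sum(vals^2 * pk) - mu^2))
}

# exact correlation of two (possibly discretized) indicators whose latent
# normals correlate at rho, by 1-D quadrature over the first latent:
# E[D_j D_k] = Int phi(z) code_j(z) E[code_k | I_k ~ N(rho z, 1-rho^2)] dz.
# spec = list(cuts, vals), or NULL for the continuous identity indicator.
.pair_corr <- function(rho, spec_j, spec_k) {
  if (abs(rho) < 1e-12) return(0)
  z <- seq(-8, 8, length.out = 1601L)
  w <- dnorm(z); w <- w / sum(w)
  dj <- if (is.null(spec_j)) z else spec_j$vals[findInterval(z, spec_j$cuts) + 1L]
  s <- sqrt(max(1 - rho^2, 1e-12))
  if (is.null(spec_k)) {
    ek <- rho * z
    mk <- list(mu = 0, sd = 1)
  } else {
    t0 <- c(-Inf, spec_k$cuts); t1 <- c(spec_k$cuts, Inf)
    ek <- rowSums(vapply(seq_along(spec_k$vals), function(b)
      spec_k$vals[b] * (pnorm((t1[b] - rho * z) / s) -
                          pnorm((t0[b] - rho * z) / s)),
      numeric(length(z))))
    mk <- .ind_moments(spec_k$cuts, spec_k$vals)
  }
  mj <- if (is.null(spec_j)) list(mu = 0, sd = 1)
        else .ind_moments(spec_j$cuts, spec_j$vals)
  (sum(w * dj * ek) - mj$mu * mk$mu) / (mj$sd * mk$sd)
}

.ses_cache <- new.env(parent = emptyenv())

# solve latent indicator loadings so the PCA first-component loadings of
# the exact implied correlation matrix of the discretized battery hit the
# targets (discretization attenuates pairwise correlations while PCA
# loading extraction inflates them; a damped fixed point balances the two,
# latent loadings capped at 0.999).  Cached per target vector.
.ses_implied <- function(targets) {
  key <- paste(sprintf("%.6f", targets), collapse = ",")
  hit <- .ses_cache[[key]]
  if (!is.null(hit)) return(hit)
  plan <- .ses_plan()
  specs <- lapply(names(targets), function(v)
    if (v %in% names(plan$cuts))
      list(cuts = plan$cuts[[v]], vals = plan$vals[[v]]) else NULL)
  p <- length(targets)
  cap <- 1 - 1e-12
  lam <- pmin(as.numeric(targets), 0.99)
  for (it in 1:60) {
    r <- diag(p)
    for (j in 1:(p - 1)) for (k in (j + 1):p) {
      r[j, k] <- r[k, j] <- .pair_corr(lam[j] * lam[k], specs[[j]], specs[[k]])
    }
    e <- eigen(r, symmetric = TRUE)
    load <- abs(e$vectors[, 1L]) * sqrt(e$values[1L])
    lam_new <- pmin(pmax(lam * as.numeric(targets) / load, 1e-3), cap)
    if (max(abs(lam_new - lam)) < 1e-5) { lam <- lam_new; break }
    lam <- 0.5 * lam + 0.5 * lam_new
  }
  out <- list(latent = setNames(lam, names(targets)), implied_R = r,
              implied_loadings = setNames(load, names(targets)),
              variance_explained = e$values[1L] / p)
  .ses_cache[[key]] <- out
  out
}

#' Simulate the five-indicator socioeconomic battery
#'
#' Generates a single-factor battery: each indicator is
#' `loading * F + sqrt(1 - loading^2) * e` on a latent standard-normal
#' factor `F`, then discretized to its published type — household income to
#' 10 ordered categories (targeting mean 6.2, SD 3.2 on the 1-10 codes),
#' maternal education to 6 (mean 4.6, SD 1.4), public assistance and food
#' security dichotomized at a 0.8 base rate (1 = favourable), and perceived
#' resource availability left continuous (rescaled to mean 12.1, SD 5.3).
#' Latent loadings are solved by a fixed point on the exact implied
#' correlation matrix of the discretized battery, so the observed
#' first-component PCA loadings converge to the targets (balancing
#' discretization attenuation against PCA loading inflation).
#'
#' @param config a [sim_config()].
#' @param n number of subjects; defaults to `config$n_subjects`.
#' @return data.frame with columns income, education, public_assistance,
#'   food_security, perceived_resources; the latent factor (standardized
#'   sample scores) is attached as attribute `"latent"`.
#' @examples
#' ses <- simulate_ses_indicators(sim_config(n_subjects = 200))
#' cor(ses$income, attr(ses, "latent"))
#' @export
simulate_ses_indicators <- function(config, n = config$n_subjects) {
  stopifnot(inherits(config, "sim_config"))
  sol <- .ses_implied(config$ses_loadings)
  plan <- .ses_plan()
  set.seed(config$seed + 3L)
  f <- rnorm(n)
  out <- data.frame(row.names = seq_len(n))
  for (v in names(config$ses_loadings)) {
    lam_lat <- sol$latent[[v]]
    ind <- lam_lat * f + sqrt(1 - lam_lat^2) * rnorm(n)
    out[[v]] <- if (v %in% names(plan$cuts))
      plan$vals[[v]][findInterval(ind, plan$cuts[[v]]) + 1L]
    else 12.1 + 5.3 * ind
  }
  attr(out, "latent") <- as.numeric(scale(f))
  attr(out, "implied") <- sol[c("implied_loadings", "variance_explained")]
  out
}

#' Simulate subject covariates
#'
#' Age uniform on 14-18 years, sex Bernoulli(0.5) coded 0/1, BMI z-score
#' standard normal, and two standard-normal ancestry PC surrogates.
#'
#' @param config a [sim_config()].
#' @param n number of subjects; defaults to `config$n_subjects`.
#' @return data.frame: age, sex, bmi_z, pc1, pc2.
#' @export
simulate_covariates <- function(config, n = config$n_subjects) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  data.frame(
    age = runif(n, 14, 18),
    sex = rbinom(n, 1L, 0.5),
    bmi_z = rnorm(n),
    pc1 = rnorm(n),
    pc2 = rnorm(n))
}

# standardize covariates for effect application (dummy sex on +/-1 scale)
.std_covariates <- function(cv) {
  cbind(age = (cv$age - 16) / (4 / sqrt(12)),
        sex = (cv$sex - 0.5) / 0.5,
        bmi_z = cv$bmi_z, pc1 = cv$pc1, pc2 = cv$pc2)
}

#' Simulate behavioral outcomes under the configured interaction scenario
#'
#' Builds the latent structured outcomes
#' `y = b0 + b1 Z + b2 X + b3 Z X + b_quad (X^2 - 1)/sqrt(2) + covariates + noise`
#' for snack intake and perceived stress (each with an independent noise
#' draw), and covariates-plus-noise outcomes for pizza and fruit/vegetable
#' intake.  Observed scales: snack/pizza/fruit-veg kcal are affine rescalings
#' floored at 0; the stress total is rounded and bounded to `[0, 40]`.
#' Flooring slightly biases naive coefficient recovery, so the unfloored
#' latent columns (`*_latent`) are also returned and are what recovery tests
#' should use.
#'
#' @param config a [sim_config()].
#' @param z moderator vector (standardized predicted expression).
#' @param x environment vector (standardized composite).
#' @param covariates data.frame from [simulate_covariates()].
#' @return data.frame of observed outcomes (`snack_kcal`, `pizza_kcal`,
#'   `fruit_veg_kcal`, `pss_total`) and their latent counterparts; the
#'   realized `b1` is attached as attribute `"b1"`.
#' @export
simulate_outcomes <- function(config, z, x, covariates) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(z)
  if (length(x) != n || nrow(covariates) != n)
    .stop("misaligned inputs: z has %d, x has %d, covariates has %d rows",
          n, length(x), nrow(covariates))
  set.seed(config$seed + 5L)
  b1 <- .effective_b1(config)
  cvs <- .std_covariates(covariates)
  cov_part <- drop(cvs %*% config$covariate_effects)
  structure_part <- config$b0 + b1 * z + config$b2 * x +
    config$b3 * z * x + config$b_quad * (x^2 - 1) / sqrt(2) + cov_part
  null_sd <- sqrt(max(1 - sum(config$covariate_effects^2), 0.04))
  snack <- structure_part + rnorm(n, 0, config$noise_sd)
  pss <- structure_part + rnorm(n, 0, config$noise_sd)
  pizza <- cov_part + rnorm(n, 0, null_sd)
  fv <- cov_part + rnorm(n, 0, null_sd)
  out <- data.frame(
    snack_kcal = pmax(0, 400 + 180 * snack),
    pizza_kcal = pmax(0, 600 + 250 * pizza),
    fruit_veg_kcal = pmax(0, 150 + 80 * fv),
    pss_total = pmin(40, pmax(0, round(20 + 6 * pss))),
    snack_latent = snack, pizza_latent = pizza,
    fruit_veg_latent = fv, pss_latent = pss)
  attr(out, "b1") <- b1
  out
}

# distribute a group kcal target over member items as gram weights
.item_grams <- function(kcal, foods) {
  k <- nrow(foods)
  n <- length(kcal)
  share <- matrix(rgamma(n * k, shape = 1.5), nrow = n)
  share <- share / rowSums(share)
  grams <- sweep(share * kcal, 2L, foods$kcal_per_g, "/")
  colnames(grams) <- paste0("food_", foods$name, "_g")
  grams
}

#' Simulate a complete synthetic cohort
#'
#' Composes the genotype, weight-table, socioeconomic, covariate and outcome
#' generators and derives the item-level records: per-food consumed grams
#' whose group sums reproduce the simulated group kcal, ten stress-scale
#' items (stored as raw questionnaire responses, positively worded items
#' reverse-stored) whose oriented sum is the observed stress total, and
#' go/no-go trial summaries for a 156-go / 52-no-go session.
#'
#' @param config a [sim_config()].
#' @return An object of class `"ds_cohort"`: list with `cohort` (the
#'   phenotype table), `ses` (indicator table), `geno`, `weights`,
#'   `outcomes`, and `truth` (the generative moderator `z`, environment `x`,
#'   and realized coefficients).
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 40, n_snps = 30, seed = 2))
#' names(sim)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  weights <- simulate_weights(config, geno)
  ses <- simulate_ses_indicators(config)
  x <- attr(ses, "latent")
  complete <- attr(geno, "dosage_complete")
  z_raw <- .weighted_expression(complete, geno$snps, weights)
  z <- as.numeric(scale(z_raw))
  covariates <- simulate_covariates(config)
  outcomes <- simulate_outcomes(config, z, x, covariates)

  set.seed(config$seed + 6L)
  foods <- ds_food_table()
  grams <- cbind(
    .item_grams(outcomes$snack_kcal, foods[foods$group == "snack", ]),
    .item_grams(outcomes$pizza_kcal, foods[foods$group == "pizza", ]),
    .item_grams(outcomes$fruit_veg_kcal, foods[foods$group == "fruit_veg", ]))

  # stress items: jitter around total/10, clamp to 0-4, re-sum for the
  # observed total; positively worded items (4,5,7,8) stored reversed
  n <- config$n_subjects
  target <- outcomes$pss_total
  items <- matrix(pmin(4L, pmax(0L, round(target / 10 + rnorm(n * 10L, 0, 0.7)))),
                  nrow = n)
  outcomes$pss_total <- rowSums(items)
  stored <- items
  stored[, c(4L, 5L, 7L, 8L)] <- 4L - stored[, c(4L, 5L, 7L, 8L)]
  colnames(stored) <- sprintf("pss_%02d", 1:10)

  gng <- data.frame(
    gng_go = 156L, gng_nogo = 52L,
    gng_commissions = rbinom(n, 52L, 0.22),
    gng_omissions = rbinom(n, 156L, 0.03),
    gng_fast_rt = rbinom(n, 156L, 0.02))

  cohort <- cbind(
    data.frame(subject_id = rownames(geno$dosage),
               age = covariates$age, sex = covariates$sex,
               bmi_z = covariates$bmi_z),
    as.data.frame(grams), as.data.frame(stored), gng)
  ses_out <- cbind(data.frame(subject_id = cohort$subject_id), ses)

  structure(list(
    cohort = cohort, ses = ses_out, geno = geno, weights = weights,
    outcomes = outcomes,
    truth = list(z = z, x = x, b1 = attr(outcomes, "b1"), b2 = config$b2,
                 b3 = config$b3, b_quad = config$b_quad,
                 covariate_effects = config$covariate_effects,
                 scenario = config$scenario)
  ), class = "ds_cohort")
}

#' @export
print.ds_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d SNPs (%d weighted), scenario %s\n",
              nrow(x$cohort), nrow(x$geno$snps), nrow(x$weights),
              x$truth$scenario))
  invisible(x)
}

#' Write a synthetic cohort to its external interchange formats
#'
#' Writes the dosage TSV (subjects x SNPs, missing as `NA`) plus a SNP
#' allele table, the weight TSV, the phenotype CSV, the indicator CSV and,
#' optionally, a minimal unphased GT-only VCF.  All files round-trip through
#' the package readers.
#'
#' @param sim a `"ds_cohort"` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param vcf also write `genotypes.vcf`?
#' @return Named character vector of the files written (invisibly).
#' @export
write_cohort <- function(sim, dir, vcf = FALSE) {
  stopifnot(inherits(sim, "ds_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dosages = file.path(dir, "dosages.tsv"),
    snps = file.path(dir, "snp_info.tsv"),
    weights = file.path(dir, "weights.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    ses = file.path(dir, "ses.csv"))
  d <- data.frame(subject_id = rownames(sim$geno$dosage),
                  sim$geno$dosage, check.names = FALSE)
  write.table(d, paths["dosages"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$geno$snps, paths["snps"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$weights, paths["weights"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(cbind(sim$cohort,
                  sim$outcomes[c("snack_kcal", "pizza_kcal",
                                 "fruit_veg_kcal", "pss_total")]),
            paths["phenotypes"], row.names = FALSE)
  write.csv(sim$ses, paths["ses"], row.names = FALSE)
  if (vcf) {
    paths <- c(paths, vcf = file.path(dir, "genotypes.vcf"))
    .write_minimal_vcf(sim$geno, paths["vcf"])
  }
  invisible(paths)
}

# minimal VCF: GT only, diploid, unphased; dosage rounded to genotype
.write_minimal_vcf <- function(geno, path) {
  d <- round(geno$dosage)
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  codes <- c("0/0", "0/1", "1/1")
  ok <- !is.na(t(d))
  gt[ok] <- codes[t(d)[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- cbind("1", seq_len(ncol(d)) * 1000L, geno$snps$id, geno$snps$ref,
                geno$snps$alt, ".", "PASS", ".", "GT", gt)
  writeLines(c(header, apply(body, 1L, paste, collapse = "\t")), path)
}
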