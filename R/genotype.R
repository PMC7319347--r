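#' Construct a genotype dosage matrix object
#'
#' @param dosage numeric subjects x SNPs matrix with values in `[0, 2]` or
#'   `NA`; row names are subject ids, column names SNP ids.
#' @param snps data.frame with columns `id`, `ref`, `alt` matching the
#'   dosage columns.
#' @return An object of class `"geno_matrix"`.
#' @export
geno_matrix <- function(dosage, snps) {
  if (!is.matrix(dosage) || !is.numeric(dosage))
    .stop("`dosage` must be a numeric matrix")
  if (anyDuplicated(snps$id)) .stop("SNP ids must be unique")
  if (ncol(dosage) != nrow(snps))
    .stop("dosage has %d columns but `snps` has %d rows",
          ncol(dosage), nrow(snps))
  if (any(!is.na(dosage))) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) .stop("dosages must lie in [0, 2]")
  }
  colnames(dosage) <- snps$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, snps = snps), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d subjects x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Per-SNP genotyping call rate
#'
#' @param dosages numeric vector of dosages for one SNP (`NA` = missing).
#' @return Fraction of non-missing entries.
#' @examples
#' snp_call_rate(c(0, 1, 2, NA))  # 0.75
#' @export
snp_call_rate <- function(dosages) {
  if (length(dosages) == 0L) .stop("empty dosage column")
  mean(!is.na(dosages))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided test from genotype counts, summing the conditional
#' probabilities (given the allele counts) of all heterozygote counts whose
#' probability does not exceed that of the observed table — the standard
#' SNP-HWE enumeration used in GWAS quality control.  Above `chisq_above`
#' total subjects the chi-square approximation (1 df, no continuity
#' correction) is used instead.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote; orientation does not matter).
#' @param chisq_above sample size above which the chi-square fallback is
#'   used.
#' @return Two-sided p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)   # perfect proportions: p = 1
#' hwe_exact_test(0, 100, 0)    # gross heterozygote excess: p << 0.001
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb, chisq_above = 1000L) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) .stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n == 0L) .stop("no genotyped subjects")
  n_minor <- 2L * min(n_aa, n_bb) + n_ab   # minor allele count
  if (n_minor == 0L) return(1)
  if (n > chisq_above) {
    p <- (2 * n_aa + n_ab) / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((c(n_aa, n_ab, n_bb) - expd)^2 / pmax(expd, .Machine$double.eps))
    return(pchisq(stat, df = 1L, lower.tail = FALSE))
  }
  # enumerate heterozygote counts of the same parity as n_minor
  hets <- seq(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lfactorial(n) - lfactorial(h) - lfactorial(hom_min) - lfactorial(hom_maj) +
      h * log(2) + lfactorial(n_minor) + lfactorial(2L * n - n_minor) -
      lfactorial(2L * n)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == n_ab)
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

#' Minor allele frequency of a dosage column
#'
#' Mean dosage over 2, folded to the minor allele (<= 0.5).
#'
#' @param dosages numeric vector of dosages (`NA` = missing).
#' @return Allele frequency in `[0, 0.5]`.
#' @examples
#' minor_allele_frequency(c(rep(0, 81), rep(1, 18), 2))  # 0.10
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) .stop("all dosages missing")
  f <- mean(d) / 2
  min(f, 1 - f)
}

# per-SNP QC statistics table
.snp_stats <- function(geno) {
  d <- geno$dosage
  stats <- data.frame(snp = colnames(d),
                      call_rate = apply(d, 2L, function(x) mean(!is.na(x))),
                      maf = NA_real_, hwe_p = NA_real_,
                      stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_len(ncol(d))) {
    x <- d[!is.na(d[, j]), j]
    if (length(x) == 0L) next
    stats$maf[j] <- min(mean(x) / 2, 1 - mean(x) / 2)
    g <- round(x)  # fractional imputed dosages are rounded for HWE classes
    stats$hwe_p[j] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  stats
}

#' Quality-control filter for a genotype matrix
#'
#' Removes SNPs failing any of: call rate below `call_rate`, exact
#' Hardy-Weinberg p below `hwe_p`, minor allele frequency below `maf` (the
#' conventional genotyping-array thresholds).  Filtering is idempotent.
#'
#' @param geno a `"geno_matrix"`.
#' @param call_rate,hwe_p,maf retention thresholds (kept when `>=`).
#' @return The filtered `"geno_matrix"` with a `"qc_report"` attribute:
#'   data.frame (snp, call_rate, maf, hwe_p, status, reason).
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 50, n_snps = 20))
#' qc <- qc_filter(g)
#' table(attr(qc, "qc_report")$status)
#' @export
qc_filter <- function(geno, call_rate = 0.95, hwe_p = 0.001, maf = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (ncol(geno$dosage) == 0L) {
    attr(geno, "qc_report") <- data.frame(
      snp = character(), call_rate = numeric(), maf = numeric(),
      hwe_p = numeric(), status = character(), reason = character())
    return(geno)
  }
  st <- .snp_stats(geno)
  reason <- character(nrow(st))
  fail <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[cond] <<- ifelse(nzchar(reason[cond]),
                            paste(reason[cond], why, sep = ";"), why)
  }
  fail(st$call_rate < call_rate, sprintf("call_rate<%g", call_rate))
  fail(st$maf < maf, sprintf("maf<%g", maf))
  fail(st$hwe_p < hwe_p, sprintf("hwe_p<%g", hwe_p))
  keep <- !nzchar(reason)
  st$status <- ifelse(keep, "pass", "fail")
  st$reason <- reason
  out <- geno_matrix(geno$dosage[, keep, drop = FALSE],
                     geno$snps[keep, , drop = FALSE])
  attr(out, "qc_report") <- st
  out
}

# core weighted dosage sum; flips dosage when the effect allele is the
# matrix reference allele; missing dosages imputed to 2 x alt-allele freq
.weighted_expression <- function(dosage, snps, weights) {
  idx <- match(weights$rsid, snps$id)
  present <- !is.na(idx)
  if (!any(present))
    .stop("no weight SNPs for gene %s present in the genotype matrix",
          weights$gene[1])
  value <- numeric(nrow(dosage))
  for (k in which(present)) {
    j <- idx[k]
    d <- dosage[, j]
    if (anyNA(d)) d[is.na(d)] <- 2 * mean(d, na.rm = TRUE) / 2
    if (weights$eff_allele[k] == snps$ref[j]) d <- 2 - d
    value <- value + weights$weight[k] * d
  }
  attr(value, "n_skipped") <- sum(!present)
  value
}

#' Predict tissue gene expression from dosages and a weight table
#'
#' The PrediXcan application step: predicted expression is the weighted sum
#' of effect-allele dosages over the gene's weight SNPs.  When a weight's
#' effect allele equals the matrix's reference allele the dosage is flipped
#' to `2 - d`; missing dosages are imputed to twice the SNP's alternate
#' allele frequency; weight SNPs absent from the matrix are skipped and
#' counted in the `"n_skipped"` attribute.
#'
#' @param geno a `"geno_matrix"` (QC already applied).
#' @param weights weight table: data.frame with columns gene, rsid,
#'   ref_allele, eff_allele, weight.
#' @return data.frame (subject_id, gene, value) with attribute
#'   `"n_skipped"`.
#' @examples
#' cfg <- sim_config(n_subjects = 20, n_snps = 10, missing_rate = 0)
#' g <- simulate_genotypes(cfg)
#' w <- simulate_weights(cfg, g)
#' head(predict_expression(g, w))
#' @export
predict_expression <- function(geno, weights) {
  stopifnot(inherits(geno, "geno_matrix"))
  need <- c("gene", "rsid", "eff_allele", "weight")
  if (!all(need %in% names(weights)))
    .stop("weight table must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(weights$rsid)) .stop("duplicated SNP id in weight table")
  value <- .weighted_expression(geno$dosage, geno$snps, weights)
  out <- data.frame(subject_id = rownames(geno$dosage),
                    gene = weights$gene[1], value = as.numeric(value),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- attr(value, "n_skipped")
  out
}

#' Ancestry principal components from a genotype matrix
#'
#' Mean-imputes missing dosages per SNP, column-standardizes, and returns
#' the top `k` principal components of the subjects, scaled to unit
#' variance.  Sign convention: the subject score largest in magnitude on
#' each component is made positive, so results are deterministic.
#'
#' @param geno a `"geno_matrix"` (QC-passing SNPs).
#' @param k number of components (default 2).
#' @return data.frame (subject_id, pc1, pc2, ...).
#' @export
ancestry_pcs <- function(geno, k = 2L) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (k == 0L) return(data.frame(subject_id = rownames(geno$dosage)))
  d <- geno$dosage
  if (nrow(d) < k + 1L) .stop("need at least k + 1 subjects")
  for (j in seq_len(ncol(d))) {
    if (anyNA(d[, j])) d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  }
  sds <- apply(d, 2L, sd)
  keep <- sds > 0
  if (!any(keep)) .stop("constant genotype matrix: no polymorphic SNPs")
  z <- scale(d[, keep, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
    scores[, j] <- scores[, j] / sd(scores[, j])
  }
  out <- data.frame(subject_id = rownames(d), scores, row.names = NULL)
  names(out)[-1L] <- paste0("pc", seq_len(k))
  out
}

#' Write the SNP quality-control report
#'
#' @param geno a filtered `"geno_matrix"` carrying a `"qc_report"`
#'   attribute (from [qc_filter()]).
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(geno, path) {
  rep <- attr(geno, "qc_report")
  if (is.null(rep)) .stop("no QC report attached; run qc_filter() first")
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage TSV and companion SNP allele table
#'
#' @param dosage_path subjects x SNPs TSV with a `subject_id` first column;
#'   missing dosages as `NA`.
#' @param snp_path TSV with columns id, ref, alt; `NULL` assigns
#'   placeholder alleles (A/B) when allele-aware matching is not needed.
#' @return A `"geno_matrix"`.
#' @export
read_dosage_tsv <- function(dosage_path, snp_path = NULL) {
  d <- read.delim(dosage_path, check.names = FALSE)
  if (names(d)[1] != "subject_id") .stop("first column must be subject_id")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d$subject_id
  snps <- if (is.null(snp_path))
    data.frame(id = colnames(m), ref = "A", alt = "B",
               stringsAsFactors = FALSE)
  else read.delim(snp_path, stringsAsFactors = FALSE)
  geno_matrix(m, snps[match(colnames(m), snps$id), , drop = FALSE])
}

#' Read dosages from a VCF
#'
#' Reads a VCF via \pkg{vcfR}; uses the `DS` (dosage) FORMAT field when
#' present, otherwise counts alternate alleles in unphased/phased `GT`.
#'
#' @param path VCF path (plain or gzipped).
#' @return A `"geno_matrix"`.
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  has_ds <- "DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  if (has_ds) {
    m <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    m <- apply(gt, c(1L, 2L), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  geno_matrix(t(m), data.frame(id = unname(fix[, "ID"]),
                               ref = unname(fix[, "REF"]),
                               alt = unname(fix[, "ALT"]),
                               stringsAsFactors = FALSE))
}

#' Read a flattened expression weight table
#'
#' @param path TSV with columns gene, rsid, ref_allele, eff_allele, weight.
#' @return data.frame.
#' @export
read_weights_tsv <- function(path) {
  w <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "rsid", "ref_allele", "eff_allele", "weight")
  if (!all(need %in% names(w)))
    .stop("weight table must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(w$weight))) .stop("weights must be finite")
  w
}
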