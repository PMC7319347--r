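#' Standardize an indicator table
#'
#' Column-wise z-scores (sample SD, n - 1 denominator).  Errors on constant
#' columns, naming them.
#'
#' @param x data.frame or matrix of numeric indicators.
#' @return data.frame of z-scored columns.
#' @examples
#' standardize_indicators(data.frame(a = 1:3))
#' @export
standardize_indicators <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  if (!all(num)) .stop("non-numeric indicator column(s): %s",
                       paste(names(x)[!num], collapse = ", "))
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0))
    .stop("constant indicator column(s): %s",
          paste(names(x)[sds == 0], collapse = ", "))
  as.data.frame(scale(x))
}

#' First principal component of an indicator battery
#'
#' Eigen-decomposition of the Pearson correlation matrix of the (already
#' standardized or raw) indicators.  Loadings are the leading eigenvector
#' scaled by the square root of its eigenvalue, i.e. the correlation of each
#' indicator with the component; the sign is fixed so that the majority of
#' loadings are positive.  When a single component is retained, an oblique
#' Promax rotation is the identity, so none is applied (noted in the
#' result).  KMO and Bartlett diagnostics are attached.
#'
#' @param x data.frame or matrix of indicators (>= 3 rows).
#' @return An object of class `"ses_pca"`: list with `loadings`,
#'   `eigenvalues`, `variance_explained`, `kmo`, `bartlett_stat`,
#'   `bartlett_p`, `n`, `rotation_note`.
#' @examples
#' ses <- simulate_ses_indicators(sim_config(n_subjects = 200))
#' pca_first_component(ses)
#' @export
pca_first_component <- function(x) {
  x <- as.data.frame(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) .stop("need at least 3 subjects")
  r <- cor(x)
  e <- eigen(r, symmetric = TRUE)
  load <- e$vectors[, 1L] * sqrt(e$values[1L])
  if (sum(load > 0) < sum(load < 0)) load <- -load
  names(load) <- colnames(x)
  kmo <- tryCatch(kmo_index(r), error = function(err) NA_real_)
  bt <- if (n > p) tryCatch(bartlett_sphericity(r, n),
                            error = function(err) list(statistic = NA_real_,
                                                       p.value = NA_real_))
        else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(
    loadings = load, eigenvalues = e$values,
    variance_explained = e$values[1L] / p,
    kmo = kmo, bartlett_stat = bt$statistic, bartlett_p = bt$p.value,
    n = n,
    rotation_note = "single retained component: Promax rotation is the identity (not applied)"
  ), class = "ses_pca")
}

#' @export
print.ses_pca <- function(x, ...) {
  cat("First-component PCA of the indicator battery\n")
  print(round(x$loadings, 3))
  cat(sprintf("variance explained: %.1f%%   KMO: %.3f   Bartlett X2: %.2f (p %s)\n",
              100 * x$variance_explained, x$kmo, x$bartlett_stat,
              format.pval(x$bartlett_p, digits = 3)))
  invisible(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal entries, where
#' `r` are the observed correlations and `q` the anti-image partial
#' correlations obtained from the (pseudo-)inverse of the correlation
#' matrix.
#'
#' @param r correlation matrix.
#' @return KMO index in `[0, 1]`.
#' @export
kmo_index <- function(r) {
  r <- as.matrix(r)
  p <- ncol(r)
  off <- upper.tri(r)
  if (all(abs(r[off]) < .Machine$double.eps^0.5))
    .stop("KMO undefined (no correlations)")
  s <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(s)) {
    .warn("correlation matrix is rank deficient; using pseudo-inverse for KMO")
    sv <- svd(r)
    pos <- sv$d > max(sv$d) * 1e-10
    s <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  }
  q <- -s / sqrt(outer(diag(s), diag(s)))
  sum(r[off]^2) / (sum(r[off]^2) + sum(q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `X2 = -(n - 1 - (2p + 5)/6) * ln|R|` on `p(p - 1)/2` degrees of freedom.
#'
#' @param r correlation matrix.
#' @param n sample size (must exceed the number of variables).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
bartlett_sphericity <- function(r, n) {
  r <- as.matrix(r)
  p <- ncol(r)
  if (n <= p) .stop("Bartlett's test needs n > p (n = %d, p = %d)", n, p)
  det_r <- det(r)
  if (det_r <= 0) .stop("singular correlation matrix")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(det_r)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Loading-weighted socioeconomic composite score
#'
#' `value_i = sum_j loading_j * z_ij` over the standardized indicators.  The
#' orientation is fixed so that higher = higher socioeconomic status: if the
#' income loading is negative all loadings are flipped.
#'
#' @param z standardized indicator table (from [standardize_indicators()]).
#' @param loadings named numeric matching the columns of `z` (typically
#'   from [pca_first_component()]; a `"ses_pca"` object is also accepted).
#' @return Numeric composite, one value per subject.
#' @examples
#' ses <- simulate_ses_indicators(sim_config(n_subjects = 100))
#' z <- standardize_indicators(ses)
#' comp <- composite_score(z, pca_first_component(z))
#' round(mean(comp), 10)  # centered by construction
#' @export
composite_score <- function(z, loadings) {
  if (inherits(loadings, "ses_pca")) loadings <- loadings$loadings
  z <- as.matrix(z)
  if (length(loadings) != ncol(z))
    .stop("%d loadings for %d indicator columns", length(loadings), ncol(z))
  if (!is.null(names(loadings))) {
    if (!all(names(loadings) %in% colnames(z)))
      .stop("loading names do not match indicator columns")
    loadings <- loadings[colnames(z)]
  }
  if ("income" %in% names(loadings) && loadings[["income"]] < 0)
    loadings <- -loadings
  drop(z %*% loadings)
}

#' Median split of a composite score
#'
#' Subjects at or below the sample median form the lower group (ties at the
#' median go to the lower group — a deterministic convention).
#'
#' @param x numeric composite values.
#' @return factor with levels `"lower"`, `"upper"`.
#' @examples
#' table(median_split(c(1, 2, 3, 4)))
#' @export
median_split <- function(x) {
  if (length(x) < 2L) .stop("need at least 2 subjects to split")
  m <- median(x)
  g <- ifelse(x <= m, "lower", "upper")
  if (all(g == "lower")) .warn("all values at or below the median: single group")
  factor(g, levels = c("lower", "upper"))
}

#' Write the composite diagnostics table
#'
#' A TSV mirroring the published battery description — variable, type,
#' mean, SD, first-component loading — with a KMO / Bartlett footer.
#'
#' @param x raw indicator table.
#' @param pca a `"ses_pca"` from [pca_first_component()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_ses_diagnostics <- function(x, pca, path) {
  x <- as.data.frame(x)
  type <- vapply(x, function(v) {
    u <- length(unique(v))
    if (u <= 2L) "dichotomous" else if (all(v == round(v))) "ordinal"
    else "continuous"
  }, character(1))
  tab <- data.frame(variable = names(x), type = type,
                    mean = round(vapply(x, mean, numeric(1)), 3),
                    sd = round(vapply(x, sd, numeric(1)), 3),
                    loading = round(pca$loadings[names(x)], 3))
  con <- file(path, "w")
  on.exit(close(con))
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("# variance explained\t%.3f", pca$variance_explained),
               sprintf("# KMO\t%.3f", pca$kmo),
               sprintf("# Bartlett\tX2=%.3f p=%.3g", pca$bartlett_stat,
                       pca$bartlett_p)), con)
  invisible(path)
}

#' Read the socioeconomic indicator CSV
#'
#' @param path CSV with subject_id plus the five indicator columns.
#' @return data.frame.
#' @export
read_ses_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("income", "education", "public_assistance", "food_security",
            "perceived_resources")
  if (!all(need %in% names(x)))
    .stop("indicator table must have columns: %s", paste(need, collapse = ", "))
  x
}
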