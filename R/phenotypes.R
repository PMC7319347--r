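#' The buffet-meal food composition table
#'
#' Per-item served portions, energy density and macronutrient densities for
#' the multi-item ad-libitum buffet meal.  Energy densities come from the
#' served-portion gram/kcal figures; macronutrient gram-per-gram densities
#' are approximate nutrition-label values bundled with the package.  Groups:
#' snack (6 items), pizza (3), fruit_veg (4), plus beverages and condiments,
#' which are carried for completeness but excluded from the three primary
#' intake groups.
#'
#' @param path alternative food table TSV (same columns).
#' @return data.frame with columns name, group, served_g, served_kcal,
#'   kcal_per_g, carb_per_g, sugar_per_g, fat_per_g, protein_per_g.
#' @examples
#' subset(ds_food_table(), group == "snack")$name
#' @export
ds_food_table <- function(path = system.file("extdata", "food_table.tsv",
                                             package = "dsgxe")) {
  ft <- read.delim(path, stringsAsFactors = FALSE)
  ft$kcal_per_g <- ifelse(ft$served_g > 0, ft$served_kcal / ft$served_g, 0)
  ft
}

#' Aggregate buffet-meal consumption into group kcal and macronutrients
#'
#' Group kcal is the sum over group members of consumed grams times the
#' item's energy density; macronutrient grams are summed over all items
#' (beverages and condiments included), per the nutrition-label densities.
#'
#' @param grams named numeric vector of consumed grams (names are food
#'   table item names; items not consumed may be omitted).
#' @param foods food composition table (default [ds_food_table()]).
#' @return Named numeric: snack_kcal, pizza_kcal, fruit_veg_kcal, carb_g,
#'   sugar_g, fat_g, protein_g.
#' @examples
#' aggregate_intake(c(mms = 100))["snack_kcal"]  # 5 kcal/g -> 500
#' @export
aggregate_intake <- function(grams, foods = ds_food_table()) {
  if (is.null(names(grams)) || any(!nzchar(names(grams))))
    .stop("`grams` must be a named vector of consumed grams")
  if (any(grams < 0)) .stop("consumed grams must be >= 0")
  unknown <- setdiff(names(grams), foods$name)
  if (length(unknown))
    .stop("unknown food item(s): %s. Valid items: %s",
          paste(unknown, collapse = ", "), paste(foods$name, collapse = ", "))
  g <- grams[match(foods$name, names(grams))]
  g[is.na(g)] <- 0
  kcal <- g * foods$kcal_per_g
  c(snack_kcal = sum(kcal[foods$group == "snack"]),
    pizza_kcal = sum(kcal[foods$group == "pizza"]),
    fruit_veg_kcal = sum(kcal[foods$group == "fruit_veg"]),
    carb_g = sum(g * foods$carb_per_g),
    sugar_g = sum(g * foods$sugar_per_g),
    fat_g = sum(g * foods$fat_per_g),
    protein_g = sum(g * foods$protein_per_g))
}

#' Perceived-stress total score and scale reliability
#'
#' Sums the ten 0-4 items per subject after (by default) reverse-coding the
#' positively worded items (items 4, 5, 7 and 8 of the 10-item scale), and
#' reports Cronbach's alpha over the sample,
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`.
#'
#' @param items n x 10 matrix or data.frame of raw item responses in 0-4.
#' @param reverse_positive reverse-code the positively worded items?
#'   (default `TRUE`, the published scoring convention; set `FALSE` if the
#'   items are already oriented).
#' @return list with `total` (length-n integer vector in 0-40) and `alpha`.
#' @examples
#' it <- matrix(rep(0:4, 20), nrow = 10)
#' pss_total(it, reverse_positive = FALSE)$total
#' @export
pss_total <- function(items, reverse_positive = TRUE) {
  items <- as.matrix(items)
  if (ncol(items) != 10L) .stop("expected 10 items, got %d", ncol(items))
  if (anyNA(items) || any(items < 0 | items > 4))
    .stop("item responses must lie in 0..4")
  if (reverse_positive) {
    pos <- c(4L, 5L, 7L, 8L)
    items[, pos] <- 4 - items[, pos]
  }
  total <- rowSums(items)
  alpha <- if (nrow(items) > 1L) {
    vt <- var(total)
    if (vt == 0) NA_real_ else (10 / 9) * (1 - sum(apply(items, 2L, var)) / vt)
  } else NA_real_
  list(total = total, alpha = alpha,
       reverse_coded = reverse_positive)
}

#' Go/no-go task metrics and exclusion flags
#'
#' Computes commission errors (responses on no-go trials), omission errors
#' (non-responses on go trials), the fast-response proportion (go responses
#' under 200 ms), and the attention-based exclusion flag: excluded when the
#' fast-response proportion exceeds 0.30 or the omission rate exceeds 0.50
#' (strict inequalities, per the published wording "exceeding").
#'
#' Input is either a per-subject summary data.frame (columns `gng_go`,
#' `gng_nogo`, `gng_commissions`, `gng_omissions`, `gng_fast_rt`) or a
#' trial log data.frame (columns `trial` in `{"go","nogo"}`, `response`
#' logical/0-1, `rt_ms` numeric, `NA` when no response).
#'
#' @param x summary counts or trial log (see Details).
#' @return data.frame: go, nogo, commissions, omissions, fast_rt_prop,
#'   commission_rate, omission_rate, excluded.
#' @examples
#' gng_metrics(data.frame(gng_go = 156, gng_nogo = 52, gng_commissions = 10,
#'                        gng_omissions = 0, gng_fast_rt = 0))
#' @export
gng_metrics <- function(x) {
  x <- as.data.frame(x)
  if (all(c("trial", "response") %in% names(x))) {
    go <- x$trial == "go"
    if (!all(x$trial %in% c("go", "nogo"))) .stop("malformed trial log")
    resp <- as.logical(x$response)
    x <- data.frame(gng_go = sum(go), gng_nogo = sum(!go),
                    gng_commissions = sum(!go & resp),
                    gng_omissions = sum(go & !resp),
                    gng_fast_rt = sum(go & resp & !is.na(x$rt_ms) &
                                        x$rt_ms < 200))
  }
  need <- c("gng_go", "gng_nogo", "gng_commissions", "gng_omissions",
            "gng_fast_rt")
  if (!all(need %in% names(x)))
    .stop("summary must have columns: %s", paste(need, collapse = ", "))
  if (any(x$gng_commissions > x$gng_nogo))
    .stop("commissions cannot exceed no-go trials")
  if (any(x$gng_omissions > x$gng_go))
    .stop("omissions cannot exceed go trials")
  fast_prop <- x$gng_fast_rt / x$gng_go
  om_rate <- x$gng_omissions / x$gng_go
  data.frame(go = x$gng_go, nogo = x$gng_nogo,
             commissions = x$gng_commissions, omissions = x$gng_omissions,
             fast_rt_prop = fast_prop,
             commission_rate = x$gng_commissions / x$gng_nogo,
             omission_rate = om_rate,
             excluded = fast_prop > 0.30 | om_rate > 0.50)
}

#' Per-group Pearson correlations of stress with intake outcomes
#'
#' For each level of `groups` (e.g. a [median_split()] of the composite),
#' Pearson's r of `x` with each outcome column, with the two-sided t-based
#' p-value.
#'
#' @param groups factor of group labels.
#' @param x numeric vector (e.g. stress totals).
#' @param outcomes data.frame of outcome columns.
#' @return data.frame: group, outcome, n, r, p.
#' @export
group_correlations <- function(groups, x, outcomes) {
  outcomes <- as.data.frame(outcomes)
  res <- list()
  for (g in levels(as.factor(groups))) {
    idx <- groups == g
    if (sum(idx) < 3L) .stop("group %s has fewer than 3 subjects", g)
    if (sd(x[idx]) == 0) .stop("constant x in group %s", g)
    for (v in names(outcomes)) {
      y <- outcomes[[v]][idx]
      if (sd(y) == 0) .stop("constant outcome %s in group %s", v, g)
      ct <- cor.test(x[idx], y)
      res[[length(res) + 1L]] <- data.frame(
        group = g, outcome = v, n = sum(idx),
        r = unname(ct$estimate), p = ct$p.value)
    }
  }
  do.call(rbind, res)
}

#' Score a raw phenotype table
#'
#' Turns the item-level phenotype table (per-food grams, stress items,
#' go/no-go counts) into the analysis outcomes: group kcal, macronutrient
#' grams, stress total (with reliability), and go/no-go metrics.
#'
#' @param pheno phenotype data.frame as written by [write_cohort()] /
#'   read by [read_phenotypes_csv()].
#' @param foods food composition table.
#' @param reverse_positive passed to [pss_total()].
#' @return data.frame of scored outcomes keyed by subject_id, with
#'   attributes `"pss_alpha"` and `"conventions"`.
#' @export
score_phenotypes <- function(pheno, foods = ds_food_table(),
                             reverse_positive = TRUE) {
  food_cols <- grep("^food_.*_g$", names(pheno), value = TRUE)
  item_names <- sub("^food_(.*)_g$", "\\1", food_cols)
  unknown <- setdiff(item_names, foods$name)
  if (length(unknown)) .stop("unknown food column(s): %s",
                             paste(unknown, collapse = ", "))
  intake <- t(apply(as.matrix(pheno[food_cols]), 1L, function(g) {
    names(g) <- item_names
    aggregate_intake(g, foods)
  }))
  pss_cols <- sprintf("pss_%02d", 1:10)
  pss <- pss_total(pheno[pss_cols], reverse_positive = reverse_positive)
  gng <- gng_metrics(pheno)
  out <- data.frame(subject_id = pheno$subject_id,
                    age = pheno$age, sex = pheno$sex, bmi_z = pheno$bmi_z,
                    intake, pss_total = pss$total,
                    gng_commissions = gng$commissions,
                    gng_excluded = gng$excluded)
  attr(out, "pss_alpha") <- pss$alpha
  attr(out, "conventions") <- list(pss_reverse_coded = reverse_positive)
  out
}

#' Read the phenotype CSV
#'
#' @param path phenotype CSV written by [write_cohort()].
#' @return data.frame.
#' @export
read_phenotypes_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(x)) .stop("phenotype table needs subject_id")
  x
}
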