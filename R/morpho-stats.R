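#' Statistics configuration
#'
#' Conventions used across the morphometric statistics: which parameters are
#' log-transformed before testing (AIS distance and AcD stem length, whose
#' distributions are log-normal), the significance level, the correlation
#' method, and the grouping used for variability. The SD convention is the
#' sample SD (n-1 denominator) throughout.
#'
#' @param log_params Columns to natural-log transform.
#' @param alpha Significance level.
#' @param level Analysis level for group comparisons: `"cell"` (default,
#'   matching figure legends) or `"hippocampus_median"`.
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(log_params = c("ais_distance", "acd_stem_length"),
                         alpha = 0.05, level = c("cell", "hippocampus_median")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(log_params = log_params, alpha = alpha,
                 level = match.arg(level)), class = "stats_config")
}

#' Log-transform configured columns
#'
#' Applies the natural log to the configured columns only. Rows with
#' non-positive values in a configured column get `NA` there (e.g. stem
#' length 0 for non-AcD cells, which are excluded from stem-specific
#' analyses); the number of excluded values per column is attached as the
#' `"n_excluded"` attribute.
#'
#' @param table Morphology (or derived) `data.frame`.
#' @param config A [stats_config()].
#' @return The table with configured columns log-transformed.
#' @export
log_transform <- function(table, config = stats_config()) {
  excl <- integer(0)
  for (col in intersect(config$log_params, names(table))) {
    v <- table[[col]]
    bad <- !is.na(v) & v <= 0
    v[bad] <- NA_real_
    table[[col]] <- log(v)
    excl[col] <- sum(bad)
  }
  attr(table, "n_excluded") <- excl
  table
}

#' Global Z-scores
#'
#' Normalizes each numeric column across the entire dataset:
#' `(x - mean) / sd` with the sample SD (n-1). Constant columns (zero SD)
#' are rejected.
#'
#' @param table `data.frame`.
#' @param columns Columns to scale; default: all numeric columns.
#' @return Table with scaled columns.
#' @export
zscore_global <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  for (col in columns) {
    v <- table[[col]]
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("column '", col, "' has zero variance; cannot Z-score")
    table[[col]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  table
}

#' Regional variability of Z-scored parameters
#'
#' Variability per hippocampus and region: the sample SD of globally
#' Z-scored values within each (hippocampus, plane, subregion) group.
#' Groups with fewer than 3 non-missing records are flagged `NA`.
#'
#' @param table Morphology-derived `data.frame` containing `hippocampus_id`,
#'   `plane`, `subregion` and the parameter columns.
#' @param parameters Parameter columns to analyze.
#' @param config A [stats_config()]; configured columns are log-transformed
#'   before Z-scoring.
#' @return Long `data.frame`: hippocampus_id, plane, subregion, parameter,
#'   n, sd_z.
#' @export
regional_variability <- function(table, parameters, config = stats_config()) {
  table <- log_transform(table, config)
  table <- zscore_global(table, columns = parameters)
  key <- interaction(table$hippocampus_id, table$plane, table$subregion,
                     drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    rows <- table[key == k, , drop = FALSE]
    do.call(rbind, lapply(parameters, function(p) {
      v <- rows[[p]][!is.na(rows[[p]])]
      data.frame(hippocampus_id = rows$hippocampus_id[1],
                 plane = rows$plane[1], subregion = rows$subregion[1],
                 parameter = p, n = length(v),
                 sd_z = if (length(v) >= 3) sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# Indicator-coded covariate matrix: numeric covariates are rank-transformed,
# categorical covariates become treatment-contrast indicator columns.
.covariate_matrix <- function(table, covariates) {
  if (length(covariates) == 0) return(NULL)
  cols <- lapply(covariates, function(cv) {
    v <- table[[cv]]
    if (is.numeric(v)) {
      m <- matrix(rank(v, na.last = "keep"), ncol = 1)
      colnames(m) <- cv
      m
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) return(NULL)
      m <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(cv, levels(f)[-1])
      m
    }
  })
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (length(cols) == 0) NULL else do.call(cbind, cols)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y` (and numeric covariates), indicator-codes
#' categorical covariates, and computes the partial correlation of the ranks
#' of `x` and `y` given the covariates from the inverse of their joint
#' correlation matrix. The two-sided p-value uses the t approximation with
#' `n - k - 2` degrees of freedom (`k` covariate columns). Rows with missing
#' values in any involved column are dropped.
#'
#' @param table `data.frame`.
#' @param x,y Column names.
#' @param covariates Character vector of covariate column names (numeric or
#'   categorical); may be empty for a plain Spearman correlation.
#' @return List with elements `r`, `p`, `n`.
#' @export
partial_spearman <- function(table, x, y, covariates = character(0)) {
  cols <- c(x, y, covariates)
  keep <- complete.cases(table[, cols, drop = FALSE])
  tab <- table[keep, , drop = FALSE]
  n <- nrow(tab)
  Z <- .covariate_matrix(tab, covariates)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n < k + 3)
    stop("partial_spearman needs at least ", k + 3, " complete rows, got ", n)
  rx <- rank(tab[[x]])
  ry <- rank(tab[[y]])
  r_xy <- cor(rx, ry)
  if (k == 0) {
    r <- r_xy
  } else {
    # standard partial-correlation formula on the rank scale
    S <- cor(Z)
    a <- cor(rx, Z)
    b <- cor(ry, Z)
    Sa <- solve(S, t(a))
    Sb <- solve(S, t(b))
    den <- sqrt(max(1 - drop(a %*% Sa), 0) * max(1 - drop(b %*% Sb), 0))
    if (den < .Machine$double.eps)
      stop("x or y is perfectly explained by the covariates")
    r <- (r_xy - drop(a %*% Sb)) / den
  }
  r <- max(min(r, 1), -1)
  df <- n - k - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  list(r = r, p = p, n = n)
}

#' Predictability ledger
#'
#' For each target parameter, the sum of squared partial Spearman
#' correlations against each of the other parameters, with location
#' covariates partialled out of every pair. Pairs whose Bonferroni-corrected
#' p-value (family = all tested pairs) exceeds `alpha` contribute 0 by
#' default. This summarizes how well each parameter's variability can be
#' predicted from the others.
#'
#' @param table `data.frame` holding the (already transformed) parameters.
#' @param parameters Parameter columns to cross-correlate.
#' @param covariates Location covariates partialled out of every pair.
#' @param config A [stats_config()].
#' @param gate_ns Should non-significant pairs contribute 0 (default TRUE)?
#' @return `data.frame`: parameter, sum_r2, n_pairs, n_significant.
#' @export
predictability_ledger <- function(table, parameters,
                                  covariates = c("plane", "subregion"),
                                  config = stats_config(), gate_ns = TRUE) {
  pairs <- utils::combn(parameters, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    est <- partial_spearman(table, pr[1], pr[2], covariates)
    data.frame(a = pr[1], b = pr[2], r = est$r, p = est$p, n = est$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- pmin(res$p * nrow(res), 1)  # Bonferroni over the family
  res$contrib <- res$r^2
  if (gate_ns) res$contrib[res$p_adj >= config$alpha] <- 0
  out <- do.call(rbind, lapply(parameters, function(p) {
    sel <- res$a == p | res$b == p
    data.frame(parameter = p, sum_r2 = sum(res$contrib[sel]),
               n_pairs = sum(sel),
               n_significant = sum(sel & res$p_adj < config$alpha),
               stringsAsFactors = FALSE)
  }))
  attr(out, "pairs") <- res
  out
}

#' Two-way group comparison
#'
#' Two-way fixed-effects ANOVA of one parameter on (subregion, plane), at
#' cell level (default, matching the figure legends) or on per-hippocampus
#' medians, with type-II sums of squares and Tukey HSD post hoc contrasts on
#' significant factors.
#'
#' @param table Morphology-derived `data.frame`.
#' @param parameter Column to compare.
#' @param factors Two grouping columns, default `c("subregion", "plane")`.
#' @param config A [stats_config()].
#' @return List with `anova` (type-II table), `tukey` (named list of Tukey
#'   results for significant factors) and `level`.
#' @export
group_compare <- function(table, parameter,
                          factors = c("subregion", "plane"),
                          config = stats_config()) {
  stopifnot(length(factors) == 2)
  if (config$level == "hippocampus_median") {
    key <- interaction(table$hippocampus_id, table[[factors[1]]],
                       table[[factors[2]]], drop = TRUE)
    agg <- do.call(rbind, lapply(levels(key), function(k) {
      rows <- table[key == k, , drop = FALSE]
      out <- rows[1, c("hippocampus_id", factors), drop = FALSE]
      out[[parameter]] <- median(rows[[parameter]], na.rm = TRUE)
      out
    }))
    table <- agg
  }
  dat <- data.frame(y = table[[parameter]],
                    f1 = factor(table[[factors[1]]]),
                    f2 = factor(table[[factors[2]]]))
  dat <- dat[complete.cases(dat), ]
  fit <- lm(y ~ f1 * f2, data = dat)
  a2 <- car::Anova(fit, type = 2)
  rownames(a2) <- sub("^f1$", factors[1], rownames(a2))
  rownames(a2) <- sub("^f2$", factors[2], rownames(a2))
  rownames(a2) <- sub("^f1:f2$", paste(factors, collapse = ":"), rownames(a2))
  pvals <- a2[["Pr(>F)"]]
  names(pvals) <- rownames(a2)
  sig <- names(pvals)[!is.na(pvals) & pvals < config$alpha]
  sig <- intersect(sig, factors)
  tuk <- list()
  if (length(sig) > 0) {
    fit_aov <- aov(y ~ f1 + f2, data = dat)
    tk <- TukeyHSD(fit_aov, which = c("f1", "f2")[match(sig, factors)])
    names(tk) <- sig
    tuk <- tk
  }
  list(anova = a2, tukey = tuk, level = config$level)
}

#' AcD fraction per region
#'
#' Classifies every record and reports the AcD fraction per (plane,
#' subregion), both pooled across cells and as the mean of per-hippocampus
#' fractions with a normal 95% confidence interval.
#'
#' @param table Validated morphology `data.frame`.
#' @return `data.frame`: plane, subregion, n, fraction, mean_by_hippocampus,
#'   ci_lo, ci_hi.
#' @export
acd_fraction_by_region <- function(table) {
  cls <- classify_axon_origin(table)
  key <- interaction(table$plane, table$subregion, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sel <- key == k
    rows <- table[sel, , drop = FALSE]
    is_acd <- cls[sel] == "acd"
    hf <- tapply(is_acd, rows$hippocampus_id, mean)
    m <- mean(hf)
    se <- if (length(hf) > 1) sd(hf) / sqrt(length(hf)) else NA_real_
    data.frame(plane = rows$plane[1], subregion = rows$subregion[1],
               n = nrow(rows), fraction = mean(is_acd),
               mean_by_hippocampus = m,
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Derived analysis table
#'
#' Adds the derived morphometric quantities used by the statistics layer
#' (soma ellipse area, mean apical diameter, AIS endpoint, alternative AIS
#' distance) to a validated morphology table.
#'
#' @param table Validated morphology `data.frame`.
#' @return The table with columns `soma_area`, `apical_mean`,
#'   `ais_endpoint`, `ais_distance_2` and `axon_origin` appended.
#' @export
derive_morphometrics <- function(table) {
  validate_cell_table(table)
  table$soma_area <- soma_ellipse_area(table)
  table$apical_mean <- mean_apical_diameter(table)
  table$ais_endpoint <- ais_endpoint(table)
  table$ais_distance_2 <- ais_distance_2(table)
  table$axon_origin <- classify_axon_origin(table)
  table
}
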