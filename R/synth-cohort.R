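#' Copula parameter set
#'
#' Names of the morphological parameters jointly sampled by the Gaussian
#' copula of a region profile, in canonical order. `apical_level` is the
#' overall proximal apical diameter level from which the five individual
#' diameters are derived; `acd_offset` is the nonnegative soma-to-AIS offset
#' added to the stem length for AcD cells (so that
#' `acd_stem_length <= ais_distance` holds by construction).
#'
#' @return Character vector of parameter names.
#' @export
profile_parameters <- function() {
  c("soma_major", "soma_minor", "apical_level", "ais_distance", "ais_length",
    "ais_d_start", "ais_d_max", "ais_d_end", "ais_max_pos",
    "acd_stem_length", "acd_stem_diam", "acd_offset")
}

#' Project a correlation matrix to the nearest positive-semidefinite one
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal. Matrices whose
#' smallest eigenvalue is below `-1e-8` after repair are rejected.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param tol Eigenvalue tolerance.
#' @return A positive-semidefinite correlation matrix.
#' @export
nearest_psd <- function(R, tol = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("rank correlation matrix must be symmetric")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= -tol && all(abs(diag(R) - 1) < 1e-12)) return(R)
  v <- pmax(e$values, tol)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  e2 <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(e2) < -tol) stop("rank correlation matrix not repairable to PSD")
  dimnames(M) <- dimnames(R)
  M
}

#' Construct a region profile
#'
#' A region profile is the distributional recipe for synthesizing one
#' anatomical region's cohort: a marginal family (`normal` or `lognormal`)
#' with location (median) and scale per parameter, an AcD fraction, a
#' Spearman rank-correlation matrix over the copula parameters, and a
#' replicate (hippocampus) count. Lognormal marginals are parameterized by
#' median and log-scale SD, so profile locations can be read directly as
#' medians; normal marginals of physical lengths are truncated at zero when
#' sampled.
#'
#' @param plane,subregion Anatomical labels.
#' @param marginals `data.frame` with columns `param`, `family`, `median`,
#'   `scale`; one row per entry of [profile_parameters()].
#' @param acd_fraction Probability that a cell carries an AcD stem.
#' @param rank_corr Spearman correlation matrix over [profile_parameters()]
#'   (unit diagonal; repaired to the nearest PSD matrix if needed).
#' @param n_hippocampi Replicate count used by
#'   [generate_multi_hippocampus()].
#' @param jitter_sd Between-hippocampus median jitter, as a fraction of each
#'   parameter's median.
#' @param comment Optional named list documenting the provenance of the
#'   numbers.
#' @return An object of class `region_profile`.
#' @export
region_profile <- function(plane, subregion, marginals, acd_fraction,
                           rank_corr, n_hippocampi = 8, jitter_sd = 0.05,
                           comment = list()) {
  pars <- profile_parameters()
  stopifnot(is.data.frame(marginals),
            all(c("param", "family", "median", "scale") %in% names(marginals)))
  miss <- setdiff(pars, marginals$param)
  if (length(miss) > 0)
    stop("marginals missing parameters: ", paste(miss, collapse = ", "))
  if (!all(marginals$family %in% c("normal", "lognormal")))
    stop("marginal family must be 'normal' or 'lognormal'")
  if (any(marginals$scale <= 0)) stop("marginal scale must be > 0")
  if (acd_fraction < 0 || acd_fraction > 1)
    stop("acd_fraction must be in [0, 1]")
  stopifnot(is.matrix(rank_corr),
            all(rownames(rank_corr) == pars), all(colnames(rank_corr) == pars))
  rank_corr <- nearest_psd(rank_corr)
  structure(list(plane = plane, subregion = subregion,
                 marginals = marginals[match(pars, marginals$param), ],
                 acd_fraction = acd_fraction, rank_corr = rank_corr,
                 n_hippocampi = n_hippocampi, jitter_sd = jitter_sd,
                 comment = comment),
            class = "region_profile")
}

#' @export
print.region_profile <- function(x, ...) {
  cat("<region_profile>", x$plane, x$subregion,
      sprintf("(AcD fraction %.2f, %d hippocampi)\n",
              x$acd_fraction, x$n_hippocampi))
  invisible(x)
}

# Inverse-CDF map of one copula coordinate through its marginal.
# Normal marginals of physical quantities are truncated at 0 by inverse-CDF
# restriction, which is monotone and therefore preserves the copula ranks.
.q_marginal <- function(u, family, med, scale) {
  if (family == "lognormal") {
    qlnorm(u, meanlog = log(med), sdlog = scale)
  } else {
    p0 <- pnorm(0, mean = med, sd = scale)
    qnorm(p0 + u * (1 - p0), mean = med, sd = scale)
  }
}

# Relative taper of the five apical diameters around the sampled level; the
# weights average to 1 so the mean of the five diameters recovers the level.
.apical_taper <- local({
  w <- c(1.14, 1.06, 1.00, 0.94, 0.89)
  w / mean(w)
})

#' Generate a synthetic cohort for one region
#'
#' Gaussian-copula sampling: correlated standard normals with the profile's
#' rank-correlation structure (Spearman targets converted to Gaussian-copula
#' correlations via `2*sin(pi*rho/6)`) are mapped through each marginal's
#' inverse CDF. AcD membership is Bernoulli(`acd_fraction`); AcD cells get
#' `ais_distance = acd_stem_length + acd_offset` with a nonnegative sampled
#' offset, non-AcD cells get stem length 0 and `ais_distance` from its own
#' marginal. Deterministic given `seed`.
#'
#' @param profile A [region_profile()].
#' @param n Number of cells (>= 0).
#' @param seed Integer seed.
#' @param hippocampus_id,animal_id Labels stamped on the rows.
#' @param median_shift Optional named multiplicative shift of the marginal
#'   medians (used for between-hippocampus jitter).
#' @return A validated morphology `data.frame` with `n` rows.
#' @export
generate_cohort <- function(profile, n, seed, hippocampus_id = "h1",
                            animal_id = "a1", median_shift = NULL) {
  stopifnot(inherits(profile, "region_profile"))
  if (n < 0) stop("n must be >= 0")
  pars <- profile_parameters()
  if (n == 0) {
    out <- cell_record()[0, ]
    return(out)
  }
  G <- 2 * sin(pi * profile$rank_corr / 6)  # Spearman -> Gaussian copula
  G <- nearest_psd(G)
  with_seed(seed, {
    Z <- matrix(rnorm(n * length(pars)), n) %*% chol(G)
    U <- pnorm(Z)
    colnames(U) <- pars
    m <- profile$marginals
    X <- sapply(pars, function(p) {
      row <- m[m$param == p, ]
      med <- row$median
      if (!is.null(median_shift) && p %in% names(median_shift))
        med <- med * median_shift[[p]]
      .q_marginal(U[, p], row$family, med, row$scale)
    })
    X <- matrix(X, nrow = n, dimnames = list(NULL, pars))
    is_acd <- runif(n) < profile$acd_fraction
    # per-position multiplicative noise on the apical taper
    noise <- matrix(exp(rnorm(n * 5, 0, 0.04)), n)
    apical <- X[, "apical_level"] * outer(rep(1, n), .apical_taper) * noise
    soma_major <- pmax(X[, "soma_major"], X[, "soma_minor"])
    soma_minor <- pmin(X[, "soma_major"], X[, "soma_minor"])
    stem <- ifelse(is_acd, X[, "acd_stem_length"], 0)
    dist <- ifelse(is_acd, stem + X[, "acd_offset"], X[, "ais_distance"])
    stem_diam <- ifelse(is_acd, X[, "acd_stem_diam"], NA_real_)
    d_max <- X[, "ais_d_max"]
    out <- data.frame(
      cell_id = sprintf("%s_%s_%s_%04d", profile$plane, profile$subregion,
                        hippocampus_id, seq_len(n)),
      plane = profile$plane, subregion = profile$subregion,
      hippocampus_id = hippocampus_id, layer_depth = runif(n, 0, 50),
      animal_id = animal_id,
      hemisphere = sample(c("left", "right"), n, replace = TRUE),
      sex = sample(c("f", "m"), n, replace = TRUE),
      soma_major = soma_major, soma_minor = soma_minor,
      apical_d1 = apical[, 1], apical_d2 = apical[, 2],
      apical_d3 = apical[, 3], apical_d4 = apical[, 4],
      apical_d5 = apical[, 5],
      ais_distance = dist, ais_length = X[, "ais_length"],
      ais_d_start = pmin(X[, "ais_d_start"], d_max), ais_d_max = d_max,
      ais_d_end = pmin(X[, "ais_d_end"], d_max),
      ais_max_pos = pmin(X[, "ais_max_pos"], X[, "ais_length"]),
      acd_stem_length = stem, acd_stem_diam = stem_diam,
      stringsAsFactors = FALSE)
    validate_cell_table(out)
    out
  })
}

#' Generate replicated cohorts across hippocampi
#'
#' Replicates a region's cohort across `n_hippocampi` with a small
#' between-hippocampus multiplicative jitter of the marginal medians
#' (SD = `jitter_sd` of the median), so replicate-level variability
#' statistics are exercised.
#'
#' @param profile A [region_profile()].
#' @param n_per_hippocampus Cells per hippocampus; either a single count or a
#'   vector of length `n_hippocampi`.
#' @param seed Integer seed.
#' @return Morphology `data.frame` with `hippocampus_id`/`animal_id` labels.
#' @export
generate_multi_hippocampus <- function(profile, n_per_hippocampus, seed) {
  nh <- profile$n_hippocampi
  counts <- if (length(n_per_hippocampus) == 1)
    rep(n_per_hippocampus, nh) else n_per_hippocampus
  stopifnot(length(counts) == nh)
  pars <- profile_parameters()
  shifts <- with_seed(seed, {
    matrix(exp(rnorm(nh * length(pars), 0, profile$jitter_sd)), nh,
           dimnames = list(NULL, pars))
  })
  out <- lapply(seq_len(nh), function(h) {
    generate_cohort(profile, counts[h], seed = seed + 1000L + h,
                    hippocampus_id = sprintf("%s_%s_h%02d", profile$plane,
                                             profile$subregion, h),
                    animal_id = sprintf("%s_a%02d", profile$plane,
                                        (h + 1L) %/% 2L),
                    median_shift = as.list(shifts[h, ]))
  })
  do.call(rbind, out)
}
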