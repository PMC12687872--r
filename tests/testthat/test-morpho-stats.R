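test_that("log transform hits configured columns and excludes zeros", {
  tab <- data.frame(ais_distance = c(exp(1), 1, rep(2, 8)),
                    acd_stem_length = c(rep(3, 7), 0, 0, 0),
                    other = 1:10)
  out <- log_transform(tab, stats_config())
  expect_equal(out$ais_distance[1], 1)
  expect_equal(out$ais_distance[2], 0)
  expect_identical(out$other, tab$other)
  expect_equal(sum(is.na(out$acd_stem_length)), 3)
  expect_equal(unname(attr(out, "n_excluded")["acd_stem_length"]), 3L)
  expect_equal(sum(!is.na(out$acd_stem_length)), 7)
})

test_that("global Z-scores use the sample SD and reject constants", {
  tab <- data.frame(x = c(0, 2))
  out <- zscore_global(tab)
  # sample SD (n-1) convention: sd(c(0,2)) = sqrt(2)
  expect_equal(out$x, c(-1, 1) / sqrt(2))
  expect_error(zscore_global(data.frame(x = rep(5, 4))), "zero variance")
  # idempotence up to numerics
  big <- data.frame(x = rnorm(100, 5, 3))
  z1 <- zscore_global(big)
  z2 <- zscore_global(z1)
  expect_equal(z1$x, z2$x, tolerance = 1e-12)
  expect_equal(mean(z1$x), 0, tolerance = 1e-12)
  expect_equal(sd(z1$x), 1, tolerance = 1e-12)
})

test_that("regional variability is the within-group SD of global Z-scores", {
  set.seed(4)
  n <- 400
  tab <- data.frame(hippocampus_id = rep(c("h1", "h2"), each = n / 2),
                    plane = "medial", subregion = "CA1m",
                    ais_length = rnorm(n, 25, 5))
  rv <- regional_variability(tab, "ais_length",
                             stats_config(log_params = character(0)))
  # both groups are draws from the global distribution -> SD of Z near 1
  expect_equal(rv$sd_z, rep(1, 2), tolerance = 0.15)
  # permuting rows changes nothing
  perm <- tab[sample(n), ]
  rv2 <- regional_variability(perm, "ais_length",
                              stats_config(log_params = character(0)))
  expect_equal(rv[order(rv$hippocampus_id), "sd_z"],
               rv2[order(rv2$hippocampus_id), "sd_z"])
  # identical records in one group -> SD 0; tiny groups flagged NA
  tab2 <- data.frame(hippocampus_id = c(rep("h1", 5), rep("h2", 2)),
                     plane = "medial", subregion = "CA1m",
                     ais_length = c(rep(30, 5), 10, 20))
  rv3 <- regional_variability(tab2, "ais_length",
                              stats_config(log_params = character(0)))
  expect_equal(rv3$sd_z[rv3$hippocampus_id == "h1"], 0)
  expect_true(is.na(rv3$sd_z[rv3$hippocampus_id == "h2"]))
  expect_equal(rv3$n[rv3$hippocampus_id == "h2"], 2)
})

test_that("partial Spearman: exact cases, confounds, and the residual oracle", {
  # monotone relation without covariates -> r = 1
  tab <- data.frame(x = 1:30, y = exp(1:30 / 10))
  est <- partial_spearman(tab, "x", "y")
  expect_equal(est$r, 1)
  expect_lt(est$p, 1e-10)
  # x and y driven only by a categorical confound -> partial r near 0
  set.seed(8)
  g <- rep(letters[1:4], each = 250)
  mu <- c(a = 0, b = 3, c = 6, d = 9)[g]
  tab2 <- data.frame(g = g, x = mu + rnorm(1000), y = mu + rnorm(1000))
  raw <- partial_spearman(tab2, "x", "y")
  ctl <- partial_spearman(tab2, "x", "y", covariates = "g")
  expect_gt(raw$r, 0.5)
  expect_lt(abs(ctl$r), 0.07)
  # dual-route check: precision-matrix result equals rank-residualization
  set.seed(9)
  tab3 <- data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20),
                     g = rep(c("u", "v"), 10))
  tab3$y <- tab3$y + 0.8 * tab3$x + 0.5 * tab3$z
  est3 <- partial_spearman(tab3, "x", "y", covariates = c("z", "g"))
  Z <- cbind(rank(tab3$z), as.numeric(tab3$g == "v"))
  rx <- resid(lm(rank(tab3$x) ~ Z))
  ry <- resid(lm(rank(tab3$y) ~ Z))
  expect_equal(est3$r, cor(rx, ry), tolerance = 1e-10)
  expect_error(partial_spearman(tab3[1:4, ], "x", "y",
                                covariates = c("z", "g")), "at least")
})

test_that("predictability ledger: nulls, copies, order, and effect size", {
  set.seed(10)
  n <- 300
  ind <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  led0 <- predictability_ledger(ind, c("a", "b", "c", "d"),
                                covariates = character(0))
  expect_true(all(led0$sum_r2 < 0.05))
  # an exact copy contributes R^2 = 1 to both members of the pair
  cp <- ind
  cp$b <- cp$a
  led1 <- predictability_ledger(cp, c("a", "b", "c", "d"),
                                covariates = character(0))
  expect_gte(led1$sum_r2[led1$parameter == "a"], 1 - 1e-9)
  # column order does not matter
  led2 <- predictability_ledger(cp, c("d", "c", "b", "a"),
                                covariates = character(0))
  expect_equal(led1$sum_r2[match(led2$parameter, led1$parameter)],
               led2$sum_r2)
  # ledger grows with planted effect size
  sums <- vapply(c(0.2, 0.5, 0.8), function(beta) {
    set.seed(11)
    d <- data.frame(a = rnorm(n))
    d$b <- beta * d$a + sqrt(1 - beta^2) * rnorm(n)
    d$c <- beta * d$b + sqrt(1 - beta^2) * rnorm(n)
    led <- predictability_ledger(d, c("a", "b", "c"),
                                 covariates = character(0))
    led$sum_r2[led$parameter == "b"]
  }, numeric(1))
  expect_true(all(diff(sums) > 0))
})

test_that("two-way group comparison finds planted shifts and nothing else", {
  set.seed(12)
  base <- expand.grid(subregion = c("CA1m", "CA3b", "Sub"),
                      plane = c("dorsal", "medial"), rep = 1:30)
  base$hippocampus_id <- paste0(base$plane, "_h", (base$rep %% 3) + 1)
  null <- base
  null$y <- rnorm(nrow(null), 10, 0.5)
  g0 <- group_compare(null, "y")
  p0 <- g0$anova[c("subregion", "plane"), "Pr(>F)"]
  expect_true(all(p0 > 0.05))
  shifted <- base
  shifted$y <- rnorm(nrow(shifted), 10, 0.5) +
    ifelse(shifted$subregion == "CA3b", 3, 0)
  g1 <- group_compare(shifted, "y")
  expect_lt(g1$anova["subregion", "Pr(>F)"], 1e-6)
  tk <- g1$tukey$subregion
  ca3_rows <- grepl("CA3b", rownames(tk))
  expect_true(all(tk[ca3_rows, "p adj"] < 0.01))
  # balanced design: factor order does not change type-II results
  g2 <- group_compare(shifted, "y", factors = c("plane", "subregion"))
  expect_equal(g1$anova["subregion", "Sum Sq"],
               g2$anova["subregion", "Sum Sq"], tolerance = 1e-8)
})

test_that("AcD fractions per region are exact on constructed tables", {
  rows <- do.call(rbind, c(
    replicate(5, cell_record(plane = "ventral", subregion = "CA1m",
                             ais_distance = 6, acd_stem_length = 4,
                             acd_stem_diam = 1), simplify = FALSE),
    replicate(5, cell_record(plane = "ventral", subregion = "CA1m",
                             ais_distance = 1), simplify = FALSE),
    replicate(4, cell_record(plane = "dorsal", subregion = "Sub",
                             ais_distance = 1), simplify = FALSE)))
  rows$cell_id <- paste0("c", seq_len(nrow(rows)))
  fr <- acd_fraction_by_region(rows)
  expect_equal(fr$fraction[fr$plane == "ventral"], 0.5)
  expect_equal(fr$fraction[fr$plane == "dorsal"], 0)
  # row order invariance
  fr2 <- acd_fraction_by_region(rows[sample(nrow(rows)), ])
  expect_equal(fr[order(fr$plane), "fraction"],
               fr2[order(fr2$plane), "fraction"])
})
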