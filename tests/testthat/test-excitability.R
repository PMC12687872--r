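# fabricate a simulate()-shaped result from trace vectors
fake_sim <- function(soma, ais = soma, dt = 0.025) {
  t <- seq(0, by = dt, length.out = length(soma))
  list(t = t, v = cbind(soma = soma, ais_dist = ais))
}

test_that("AP detection uses a strict 0 mV criterion at the AIS", {
  flat <- fake_sim(rep(-70, 100))
  expect_false(detect_ap(flat)$ap)
  v <- rep(-70, 2000)
  v[937:940] <- 10   # crossing at sample 937 -> t = 23.4 ms
  sim <- fake_sim(rep(-70, 2000), ais = v)
  d <- detect_ap(sim)
  expect_true(d$ap)
  expect_equal(d$t_cross, 23.4)
  at_zero <- fake_sim(rep(-70, 100), ais = c(rep(-70, 50), 0, rep(-70, 49)))
  expect_false(detect_ap(at_zero)$ap)
})

test_that("voltage threshold is the V at the first dV/dt > 25 sample", {
  dt <- 0.025
  n <- 2001
  t <- seq(0, by = dt, length.out = n)
  ramp30 <- -70 + pmax(t - 20, 0) * 30
  th <- ap_voltage_threshold(fake_sim(ramp30))
  expect_equal(th$threshold_mV, -70, tolerance = 0.5)
  ramp20 <- -70 + pmax(t - 20, 0) * 20
  expect_true(is.na(ap_voltage_threshold(fake_sim(ramp20))$threshold_mV))
  # sigmoid upstroke: matches a brute-force scan of the discrete derivative
  sig <- -70 + 100 / (1 + exp(-(t - 30) * 2))
  got <- ap_voltage_threshold(fake_sim(sig))
  dvdt <- c(0, (sig[3:n] - sig[1:(n - 2)]) / (2 * dt), 0)
  idx <- which(dvdt > 25 & t >= 20)[1]
  expect_equal(got$threshold_mV, sig[idx])
  expect_equal(got$t_threshold, t[idx])
  # delay is relative to the 20 ms onset
  expect_equal(ap_delay(fake_sim(sig)), t[idx] - 20)
  cross225 <- -70 + pmax(t - 22.5, 0) * 40
  expect_equal(ap_delay(fake_sim(cross225)), 2.5, tolerance = 0.05)
})

test_that("bisection equals a brute-force linear scan at equal resolution", {
  cc <- aisgeom:::.prepare_cell(cell_record())
  res <- find_threshold(cc, "current_soma", range = c(10, 1000),
                        resolution = 10)
  # independent oracle: step upward at the same resolution
  amps <- seq(10, 1000, by = 10)
  fired <- FALSE
  for (a in amps) {
    sim <- simulate(cc, list(current_step("soma", a)), sim_config())
    if (detect_ap(sim)$ap) {
      expect_equal(res$threshold, a)
      fired <- TRUE
      break
    }
  }
  expect_true(fired)
  # halving the resolution moves the answer by at most one coarse step
  res2 <- find_threshold(cc, "current_soma", range = c(10, 1000),
                         resolution = 5)
  expect_lte(abs(res2$threshold - res$threshold), 10)
})

test_that("threshold search flags out-of-range cells", {
  cc <- aisgeom:::.prepare_cell(cell_record())
  low <- find_threshold(cc, "current_soma", range = c(10, 100),
                        resolution = 5)
  expect_false(low$converged)
  expect_equal(low$flag, "non-converged")
  hot <- find_threshold(cc, "current_soma", range = c(500, 1000),
                        resolution = 5)
  expect_equal(hot$flag, "below-range")
  expect_equal(hot$threshold, 500)
})

test_that("raising Na density strictly lowers the threshold", {
  bio_hi <- default_biophys()
  bio_hi$sections$ais_prox$gna <- bio_hi$sections$ais_prox$gna * 2
  bio_hi$sections$ais_dist$gna <- bio_hi$sections$ais_dist$gna * 2
  rec <- cell_record()
  base <- find_threshold(aisgeom:::.prepare_cell(rec), "current_soma")
  hot <- find_threshold(aisgeom:::.prepare_cell(rec, bio_hi), "current_soma",
                        biophys = bio_hi)
  expect_lt(hot$threshold, base$threshold)
})

test_that("AP delay does not grow with stimulus strength", {
  cc <- aisgeom:::.prepare_cell(cell_record())
  thr <- find_threshold(cc, "current_soma")$threshold
  delays <- vapply(c(1, 1.5, 2.5), function(f) {
    sim <- simulate(cc, list(current_step("soma", thr * f)), sim_config())
    ap_delay(sim, blank = 0.2)
  }, numeric(1))
  expect_true(all(diff(delays) <= 1e-9))
})

test_that("branch thresholds: symmetric for non-AcD, biased for AcD", {
  non <- cell_record()
  bn <- branch_comparison(non, resolution = 0.1)
  expect_equal(bn$threshold[1], bn$threshold[2],
               tolerance = 0.01 * mean(bn$threshold))
  acd <- cell_record(ais_distance = 8, ais_length = 28,
                     acd_stem_length = 6, acd_stem_diam = 1.4)
  ba <- branch_comparison(acd, resolution = 0.1)
  expect_lt(ba$threshold[ba$mode == "synaptic_acd_branch"],
            ba$threshold[ba$mode == "synaptic_nonacd_branch"])
})

test_that("cohort evaluation is elementwise and reproducible", {
  empty <- cell_record()[0, ]
  expect_equal(nrow(cohort_excitability(empty)), 0)
  rec <- cell_record()
  two <- rbind(rec, rec)
  two$cell_id <- c("c1", "c2")
  res <- cohort_excitability(two, modes = "current_soma")
  expect_equal(res$threshold[1], res$threshold[2])
  expect_equal(res$voltage_threshold_mV[1], res$voltage_threshold_mV[2])
})

test_that("a one-point sweep at the median reproduces the reference cell", {
  coh <- test_ca1_cohort(20)
  ref <- median_reference_cell(coh)
  direct <- find_threshold(aisgeom:::.prepare_cell(ref), "current_soma")
  sw <- median_reference_sweep(coh, "ais_length",
                               grid = median(coh$ais_length))
  expect_equal(sw$threshold, direct$threshold)
  expect_equal(sw$voltage_threshold_mV, direct$voltage_threshold_mV)
})

test_that("distal AIS injection is the most excitable site", {
  coh <- test_ca1_cohort(20)
  ref <- median_reference_cell(coh)
  sites <- injection_site_comparison(ref)
  thr <- setNames(sites$threshold, sites$mode)
  expect_lt(thr["current_ais_dist"], thr["current_ais_prox"])
  expect_lt(thr["current_ais_dist"], thr["current_soma"])
})
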