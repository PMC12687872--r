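test_that("passive cylinder input resistance matches cable theory", {
  g <- uniform_cylinder_graph(L = 500, d = 2, nseg = 251)
  bio <- passive_biophys(g_pas = 1e-4)   # Rm = 10 kOhm cm2
  cc <- compile_graph(g, bio)
  sim <- simulate(cc, list(current_step(c("cyl", 0), -50, delay = 0,
                                        duration = 400)),
                  sim_config(duration = 400,
                             record = list(end = c("cyl", 0))))
  rin <- unname((sim$v[nrow(sim$v), "end"] + 70) / -0.05)
  # analytic Rin at the center of the first segment
  x0 <- 500 / 251 / 2
  expect_equal(rin, finite_cable_rin(500, 2, 150, 1e4, x0), tolerance = 0.005)
})

test_that("tree solver agrees with a dense reference on random trees", {
  for (seed in 1:6) {
    n <- sample(5:20, 1)
    tr <- random_tree_arrays(n, seed = seed * 37)
    dt <- 0.025
    nsteps <- 400
    inj <- sample.int(n, 1)
    got <- tree_solver_passive(tr, dt, nsteps, -70,
                               step_comp = inj, step_amp = 0.1,
                               step_t0 = 2, step_t1 = 8)$v
    want <- dense_passive_solve(tr$parent, tr$g_axial, tr$cm, tr$g_pas,
                                tr$e_pas, dt, nsteps, -70,
                                I_nA = function(t) {
                                  I <- numeric(n)
                                  if (t > 2 + 1e-12 && t <= 8 + 1e-12)
                                    I[inj] <- 0.1
                                  I
                                })
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("resting membrane is stable and bounded without stimulus", {
  cc <- compile_graph(segmentize(balance_branches(build_cell(cell_record()))))
  sim <- simulate(cc, list(), sim_config(duration = 200))
  expect_true(all(abs(sim$v - sim$v[1, 1]) < 0.5))
})

test_that("injected charge is conserved in the passive membrane", {
  tr <- random_tree_arrays(12, seed = 99)
  dt <- 0.01
  nsteps <- 3000
  out <- tree_solver_passive(tr, dt, nsteps, -70, step_comp = 3,
                             step_amp = 0.2, step_t0 = 1, step_t1 = 6)
  v <- out$v
  q_inj <- 0.2 * 5                                       # nA*ms = pC
  q_cap <- sum(tr$cm * (v[nsteps + 1, ] - v[1, ]))       # nF*mV = pC
  leak <- colSums((v[-1, ] - matrix(tr$e_pas, nsteps, 12, byrow = TRUE)) *
                    dt)
  q_leak <- sum(leak * tr$g_pas)
  expect_lt(abs(q_cap + q_leak - q_inj) / q_inj, 0.005)
})

test_that("synaptic kernel has unit peak at the closed-form peak time", {
  expect_equal(synaptic_kernel(0), 0)
  expect_equal(synaptic_kernel(-1), 0)
  tp <- 0.175 * 5 / (5 - 0.175) * log(5 / 0.175)
  expect_equal(synaptic_kernel(tp), 1, tolerance = 1e-12)
  tt <- seq(0.001, 30, by = 0.001)
  expect_lt(max(synaptic_kernel(tt)), 1 + 1e-9)
  expect_equal(tt[which.max(synaptic_kernel(tt))], tp, tolerance = 1e-2)
})

test_that("synapses at the reversal potential inject no net current", {
  g <- uniform_cylinder_graph(L = 100, d = 2, nseg = 51)
  bio <- passive_biophys(e_pas = 0)  # rest at the synaptic reversal
  cc <- compile_graph(g, bio)
  syn <- structure(list(section = "cyl", pos = 0.5, onset = 5,
                        spec = synapse_set(total_nS = 10, count = 1),
                        window = c(0, 0), branch = "a", seed = 1),
                   class = "bound_synapses")
  sim <- simulate(cc, list(syn), sim_config(duration = 20, v_init = 0,
                                            record = list(site = c("cyl", 0.5))))
  expect_lt(max(abs(sim$v - 0)), 1e-9)
})

test_that("synapse placement is even, seeded and Gaussian in time", {
  g <- balance_branches(build_cell(cell_record()))
  one <- place_synapses(g, "a", synapse_set(total_nS = 5, count = 1), seed = 3)
  expect_equal(one$pos, 0.5)  # midpoint of the 75-100 um window
  a <- place_synapses(g, "a", synapse_set(total_nS = 5), seed = 3)
  b <- place_synapses(g, "a", synapse_set(total_nS = 5), seed = 3)
  expect_identical(a$onset, b$onset)
  expect_equal(max(abs(diff(diff(sort(a$pos))))), 0, tolerance = 1e-12)
  big <- place_synapses(g, "b", synapse_set(total_nS = 5, count = 1e5),
                        seed = 4)
  ks <- suppressWarnings(stats::ks.test(big$onset, "pnorm", 20, 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("time-step refinement converges at first order", {
  g <- uniform_cylinder_graph(L = 200, d = 2, nseg = 41)
  bio <- passive_biophys()
  cc <- compile_graph(g, bio)
  # smooth relaxation from a displaced initial condition
  rep_ <- dt_convergence_check(cc, list(),
                               sim_config(duration = 20, v_init = -55,
                                          record = list(site = c("cyl", 0.5))))
  dev2 <- rep_$max_dev_mV[rep_$dt == 0.0125]
  dev4 <- rep_$max_dev_mV[rep_$dt == 0.00625]
  expect_gt(dev2 / dev4, 1.6)  # ~2x per halving for backward Euler
  expect_lt(dev4, dev2)
})

test_that("spike timing is insensitive to halving the mandated time step", {
  cc <- compile_graph(segmentize(balance_branches(build_cell(cell_record()))))
  stim <- list(current_step("soma", 400))
  t_spike <- function(dt) {
    sim <- simulate(cc, stim, sim_config(dt = dt, duration = 30))
    detect_ap(sim)$t_cross
  }
  expect_lt(abs(t_spike(0.025) - t_spike(0.0125)), 0.1)
})
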