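# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the dense solver builds the full linear
# system and calls solve(); the cable formulas are textbook closed forms.

# Backward-Euler solve of a passive compartment tree with a dense matrix.
# parent is 1-based with parent[1] == 0 for the root; I_nA is a function of
# time returning the injected current per compartment.
dense_passive_solve <- function(parent, g_axial, cm, g_pas, e_pas,
                                dt, nsteps, v_init, I_nA = function(t) 0) {
  n <- length(parent)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (parent[i] > 0) {
      p <- parent[i]
      G[i, i] <- G[i, i] + g_axial[i]
      G[p, p] <- G[p, p] + g_axial[i]
      G[i, p] <- G[i, p] - g_axial[i]
      G[p, i] <- G[p, i] - g_axial[i]
    }
  }
  v <- rep(v_init, n)
  out <- matrix(NA_real_, nsteps + 1, n)
  out[1, ] <- v
  for (s in seq_len(nsteps)) {
    t <- s * dt
    A <- G + diag(cm / dt + g_pas, n)
    b <- cm / dt * v + g_pas * e_pas + I_nA(t)
    v <- solve(A, b)
    out[s + 1, ] <- v
  }
  out
}

# Steady-state input resistance (MOhm) of a finite sealed-end cylinder with
# point current injection at x, from cable theory.
finite_cable_rin <- function(L_um, d_um, Ra, Rm, x_um = 0) {
  lambda <- sqrt((Rm / Ra) * (d_um * 1e-4) / 4) * 1e4      # um
  ri <- 4 * Ra / (pi * (d_um * 1e-4)^2) * 1e-4             # Ohm per um
  l <- L_um / lambda
  x <- x_um / lambda
  # sealed at both ends: V(x) for injection at x0 = x (Green's function)
  (ri * lambda) * cosh(l - x) * cosh(x) / sinh(l) * 1e-6   # MOhm
}

# A single-section uniform passive cylinder as a compartment_graph.
uniform_cylinder_graph <- function(L = 500, d = 2, nseg = 201) {
  rec <- cell_record()
  g <- build_cell(rec)
  s <- list(name = "cyl", class = "basal", L = L,
            diam = list(x = c(0, L), d = c(d, d)),
            parent = NA, parent_pos = 1, nseg = as.integer(nseg))
  g$sections <- list(cyl = s)
  g$sites <- list()
  g
}

# Passive biophysics: all active conductances off, fixed leak.
passive_biophys <- function(g_pas = 1e-4, e_pas = -70, Ra = 150, cm = 1) {
  bio <- default_biophys()
  bio$global$Ra <- Ra
  bio$global$cm <- cm
  for (cl in names(bio$sections)) {
    bio$sections[[cl]]$gna <- 0
    bio$sections[[cl]]$gk <- 0
    bio$sections[[cl]]$g_pas <- g_pas
    bio$sections[[cl]]$e_pas <- e_pas
  }
  bio
}

# Random Hines-ordered passive tree in compiled (array) form.
random_tree_arrays <- function(n, seed) {
  set.seed(seed)
  parent <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  list(parent = parent,
       g_axial = c(0, runif(n - 1, 0.02, 0.5)),
       cm = runif(n, 1e-3, 5e-2),
       g_pas = runif(n, 1e-4, 5e-3),
       e_pas = runif(n, -75, -65))
}

# Call the package's compiled solver directly on raw arrays (passive).
tree_solver_passive <- function(tr, dt, nsteps, v_init, step_comp = integer(0),
                                step_amp = numeric(0), step_t0 = numeric(0),
                                step_t1 = numeric(0), rec = seq_along(tr$parent)) {
  n <- length(tr$parent)
  out <- aisgeom:::cable_simulate(
    as.integer(tr$parent) - 1L, tr$g_axial, tr$cm, tr$g_pas, tr$e_pas,
    rep(0, n), rep(0, n), rep(0, n), 55, -90, -62.5, FALSE, 1,
    dt, as.integer(nsteps), v_init, as.integer(rec) - 1L,
    as.integer(step_comp) - 1L, step_amp, step_t0, step_t1,
    integer(0), numeric(0), numeric(0), 0.175, 5, 0)
  out
}

# Small CA1 cohort reused by the simulation tests.
test_ca1_cohort <- function(n = 30, seed = 11) {
  generate_cohort(default_profiles()[["ventral.CA1m"]], n, seed = seed)
}

# custom two-parameter planting profile used by the copula recovery checks
planted_profile <- function(rho = 0.8, acd_fraction = 0) {
  marg <- data.frame(param = profile_parameters(),
                     family = "lognormal", median = 5, scale = 0.4,
                     stringsAsFactors = FALSE)
  R <- diag(length(profile_parameters()))
  dimnames(R) <- list(profile_parameters(), profile_parameters())
  # planted between two parameters untouched by record post-processing
  R["ais_length", "ais_d_max"] <- R["ais_d_max", "ais_length"] <- rho
  region_profile("medial", "CA1m", marg, acd_fraction = acd_fraction,
                 rank_corr = R)
}

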