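#' Load a biophysics configuration
#'
#' Reads the YAML biophysics file: global passive/kinetic settings (axial
#' resistivity `Ra` in Ohm*cm, specific capacitance `cm` in uF/cm2, reversal
#' potentials, the kinetic voltage origin `vT`, the distal-AIS Na activation
#' shift) plus per-section-class conductance densities in S/cm2. Classes
#' missing an entry inherit it from the `defaults` block; every inherited
#' value is recorded in the returned object's `"provenance"` attribute.
#'
#' @param path Path to a YAML file.
#' @return A list of class `biophys_spec` with elements `global` and
#'   `sections` (one complete entry per [section_classes()]).
#' @export
load_biophys <- function(path) {
  raw <- yaml::read_yaml(path)
  need_global <- c("Ra", "cm", "ena", "ek", "vT", "rate_scale",
                   "na_shift_ais_dist", "shift_inactivation")
  miss <- setdiff(need_global, names(raw$global))
  if (length(miss) > 0)
    stop("biophysics config missing global keys: ",
         paste(miss, collapse = ", "))
  if (is.null(raw$defaults))
    stop("biophysics config missing 'defaults' block")
  need_keys <- c("g_pas", "e_pas", "gna", "gk")
  miss <- setdiff(need_keys, names(raw$defaults))
  if (length(miss) > 0)
    stop("biophysics defaults missing keys: ", paste(miss, collapse = ", "))
  prov <- character(0)
  sections <- list()
  for (cl in section_classes()) {
    entry <- raw$sections[[cl]] %||% list()
    for (k in need_keys) {
      if (is.null(entry[[k]])) {
        entry[[k]] <- raw$defaults[[k]]
        prov <- c(prov, sprintf("%s.%s <- defaults (%g)", cl, k,
                                raw$defaults[[k]]))
      }
    }
    if (entry$gna < 0 || entry$gk < 0 || entry$g_pas < 0)
      stop("conductance densities must be >= 0 (section class ", cl, ")")
    sections[[cl]] <- entry
  }
  out <- structure(list(global = raw$global, sections = sections),
                   class = "biophys_spec")
  attr(out, "provenance") <- prov
  out
}

#' Packaged CA1 biophysics
#'
#' The package's calibrated biophysical parameter set for the reduced CA1
#' pyramidal cell (see the methods vignette for the calibration targets).
#'
#' @return A `biophys_spec`, see [load_biophys()].
#' @export
default_biophys <- function() {
  load_biophys(system.file("extdata", "biophys_ca1.yaml", package = "aisgeom",
                           mustWork = TRUE))
}

#' Compile a section graph to compartment arrays
#'
#' Flattens a segmentized [compartment_graph][build_cell()] into
#' Hines-ordered per-compartment arrays (parent pointer, axial conductance,
#' membrane capacitance, channel conductances scaled by compartment area)
#' ready for the implicit tree solver.
#'
#' @param graph Segmentized graph.
#' @param biophys A [biophys_spec][load_biophys()].
#' @return A list of class `compiled_cell`.
#' @export
compile_graph <- function(graph, biophys = default_biophys()) {
  stopifnot(inherits(graph, "compartment_graph"))
  nsegs <- vapply(graph$sections, function(s) s$nseg, integer(1))
  if (anyNA(nsegs)) stop("graph must be segmentized before compiling")
  Ra <- biophys$global$Ra
  cm_spec <- biophys$global$cm
  n <- sum(nsegs)
  parent <- integer(n)
  g_ax <- cm <- g_pas <- e_pas <- gna <- gk <- shift <- rhalf <- numeric(n)
  sec_start <- integer(length(nsegs))
  names(sec_start) <- names(graph$sections)
  idx <- 0L
  for (si in seq_along(graph$sections)) {
    s <- graph$sections[[si]]
    bp <- biophys$sections[[s$class]]
    if (is.null(bp)) stop("no biophysics for section class ", s$class)
    sec_start[si] <- idx
    len <- s$L / s$nseg
    centers <- (seq_len(s$nseg) - 0.5) * len
    dseg <- stats::approx(s$diam$x, s$diam$d, xout = centers, rule = 2)$y
    area <- pi * dseg * len                  # um^2
    for (k in seq_len(s$nseg)) {
      i <- idx + k
      cm[i] <- cm_spec * area[k] * 1e-5      # nF (uF/cm2 * um2 -> nF)
      g_pas[i] <- bp$g_pas * area[k] * 1e-2  # uS
      e_pas[i] <- bp$e_pas
      gna[i] <- bp$gna * area[k] * 1e-2
      gk[i] <- bp$gk * area[k] * 1e-2
      shift[i] <- if (s$class == "ais_dist")
        biophys$global$na_shift_ais_dist else 0
      rhalf[i] <- Ra * len * 2e4 / (pi * dseg[k]^2)  # Ohm, half segment
      if (k == 1L) {
        if (is.na(s$parent)) {
          parent[i] <- 0L  # root marker, fixed below
        } else {
          ps <- graph$sections[[s$parent]]
          pstart <- sec_start[s$parent]
          pk <- min(ps$nseg, max(1L, ceiling(s$parent_pos * ps$nseg)))
          if (s$parent_pos == 0) pk <- 1L
          pidx <- pstart + pk
          parent[i] <- pidx
          g_ax[i] <- 1e6 / (rhalf[i] + rhalf[pidx])
        }
      } else {
        parent[i] <- i - 1L
        g_ax[i] <- 1e6 / (rhalf[i] + rhalf[i - 1L])
      }
    }
    idx <- idx + s$nseg
  }
  parent[1] <- -1L
  resolve <- function(section, pos) {
    s <- graph$sections[[section]]
    if (is.null(s)) stop("unknown section ", section)
    k <- min(s$nseg, max(1L, ceiling(pos * s$nseg)))
    unname(sec_start[section] + k)
  }
  structure(list(n = n, parent = parent, g_axial = g_ax, cm = cm,
                 g_pas = g_pas, e_pas = e_pas, gna = gna, gk = gk,
                 na_shift = shift, sec_start = sec_start,
                 nsegs = nsegs, graph = graph, biophys = biophys,
                 resolve = resolve),
            class = "compiled_cell")
}

#' Simulation configuration
#'
#' @param dt Time step in ms (default 0.025 ms, i.e. 25 us / 40 kHz).
#' @param duration Simulated time in ms.
#' @param v_init Initial (and leak-anchored) membrane potential, mV.
#' @param record Named list of record sites, each `c(section, pos)`; the
#'   defaults are the somatic midpoint and the distal-AIS midpoint (the AP
#'   detection site).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(dt = 0.025, duration = 40, v_init = -70,
                       record = list(soma = c("soma", 0.5),
                                     ais_dist = c("ais_dist", 0.5))) {
  stopifnot(dt > 0, duration > 0)
  structure(list(dt = dt, duration = duration, v_init = v_init,
                 record = record), class = "sim_config")
}

#' Current-step stimulus
#'
#' @param site Site name (`"soma"`, `"ais_prox"`, `"ais_dist"`) or
#'   `c(section, pos)`.
#' @param amplitude_pA Step amplitude in pA.
#' @param delay Onset after simulation start, ms.
#' @param duration Step duration, ms.
#' @return List of class `current_step`.
#' @export
current_step <- function(site, amplitude_pA, delay = 20, duration = 5) {
  structure(list(site = site, amplitude_pA = amplitude_pA, delay = delay,
                 duration = duration), class = "current_step")
}

#' Synapse population specification
#'
#' Double-exponential conductance synapses normalized to unit peak, so
#' `total_nS` is the summed peak conductance, divided equally per synapse.
#'
#' @param total_nS Total (summed peak) synaptic conductance, nS.
#' @param count Number of synapses.
#' @param tau_on,tau_off Kernel rise/decay time constants, ms.
#' @param e_rev Synaptic reversal potential, mV.
#' @param onset_mean Mean activation time, ms after simulation start.
#' @param onset_sd Gaussian SD of activation times, ms.
#' @return List of class `synapse_set`.
#' @export
synapse_set <- function(total_nS, count = 1000, tau_on = 0.175, tau_off = 5,
                        e_rev = 0, onset_mean = 20, onset_sd = 4) {
  stopifnot(count >= 1, tau_off > tau_on, tau_on > 0)
  structure(list(total_nS = total_nS, count = count, tau_on = tau_on,
                 tau_off = tau_off, e_rev = e_rev, onset_mean = onset_mean,
                 onset_sd = onset_sd), class = "synapse_set")
}

#' Place synapses on a dendritic branch
#'
#' Distributes `count` synapses evenly over the 75-100 um path window from
#' the soma on the requested branch (positions at window midpoints of equal
#' subdivisions, so a single synapse sits at the window midpoint), and draws
#' their Gaussian activation times once for the given seed. The drawn times
#' are reused across a threshold search so only the stimulus strength
#' varies.
#'
#' @param graph A (balanced) [compartment_graph][build_cell()].
#' @param branch `"a"` (axon-carrying side) or `"b"` (canonical side).
#' @param synapses A [synapse_set()].
#' @param seed Integer seed for the activation-time draw.
#' @return List of class `bound_synapses` with per-synapse section
#'   positions, onset times and peak conductances.
#' @export
place_synapses <- function(graph, branch = c("a", "b"), synapses, seed) {
  branch <- match.arg(branch)
  stopifnot(inherits(synapses, "synapse_set"))
  w <- graph$template$synapse_window
  count <- synapses$count
  section <- paste0("basal_", branch, "_syn")
  pos <- (seq_len(count) - 0.5) / count   # fraction of the window section
  onsets <- with_seed(seed, rnorm(count, synapses$onset_mean,
                                  synapses$onset_sd))
  structure(list(section = section, pos = pos, onset = onsets,
                 spec = synapses, window = w, branch = branch, seed = seed),
            class = "bound_synapses")
}

#' Run the implicit cable simulation
#'
#' Solves the spatially discretized branched cable equation with
#' Hodgkin-Huxley-type Na/K conductances and leak, advancing gating states
#' with the exponential integrator and the voltage with a backward-Euler
#' Hines solve per fixed time step. Bitwise deterministic given its inputs.
#'
#' @param cell A [compiled_cell][compile_graph()] (or a segmentized graph,
#'   which is compiled with `biophys`).
#' @param stimuli List of [current_step()] / [place_synapses()] objects.
#' @param config A [sim_config()].
#' @param biophys Used only when `cell` is an uncompiled graph.
#' @return List with `t` (ms) and `v` (mV matrix, one column per record
#'   site, named).
#' @export
simulate <- function(cell, stimuli = list(), config = sim_config(),
                     biophys = default_biophys()) {
  if (inherits(cell, "compartment_graph")) cell <- compile_graph(cell, biophys)
  stopifnot(inherits(cell, "compiled_cell"))
  if (inherits(stimuli, c("current_step", "bound_synapses")))
    stimuli <- list(stimuli)
  g <- cell$biophys$global
  rec_names <- names(config$record)
  rec <- vapply(config$record, function(site)
    cell$resolve(site[1], as.numeric(site[2])), numeric(1))
  sc <- list(comp = integer(0), amp = numeric(0), t0 = numeric(0),
             t1 = numeric(0))
  syn <- list(comp = integer(0), w = numeric(0), onset = numeric(0))
  tau_on <- 0.175; tau_off <- 5; e_syn <- 0
  for (st in stimuli) {
    if (inherits(st, "current_step")) {
      site <- st$site
      if (length(site) == 1)
        site <- switch(site, soma = c("soma", 0.5),
                       ais_prox = c("ais_prox", 0.5),
                       ais_dist = c("ais_dist", 0.5),
                       stop("unknown site ", site))
      comp <- cell$resolve(site[1], as.numeric(site[2]))
      if (st$delay + st$duration > config$duration + 1e-9)
        stop("stimulus extends beyond simulation duration")
      sc$comp <- c(sc$comp, comp)
      sc$amp <- c(sc$amp, st$amplitude_pA * 1e-3)  # pA -> nA
      sc$t0 <- c(sc$t0, st$delay)
      sc$t1 <- c(sc$t1, st$delay + st$duration)
    } else if (inherits(st, "bound_synapses")) {
      comps <- vapply(st$pos, function(p) cell$resolve(st$section, p),
                      numeric(1))
      w <- rep(st$spec$total_nS / st$spec$count / 1e3, st$spec$count) # uS
      syn$comp <- c(syn$comp, comps)
      syn$w <- c(syn$w, w)
      syn$onset <- c(syn$onset, st$onset)
      tau_on <- st$spec$tau_on; tau_off <- st$spec$tau_off
      e_syn <- st$spec$e_rev
    } else stop("unsupported stimulus object")
  }
  nsteps <- as.integer(round(config$duration / config$dt))
  out <- cable_simulate(cell$parent - 1L, cell$g_axial, cell$cm, cell$g_pas,
                        cell$e_pas, cell$gna, cell$gk, cell$na_shift,
                        g$ena, g$ek, g$vT, isTRUE(g$shift_inactivation),
                        g$rate_scale, config$dt, nsteps, config$v_init,
                        as.integer(rec) - 1L,
                        as.integer(sc$comp) - 1L, sc$amp, sc$t0, sc$t1,
                        as.integer(syn$comp) - 1L, syn$w, syn$onset,
                        tau_on, tau_off, e_syn)
  colnames(out$v) <- rec_names
  out
}

#' Double-exponential synaptic kernel
#'
#' Unit-peak conductance kernel
#' `g(t) = (exp(-t/tau_off) - exp(-t/tau_on)) / k`, where `k` normalizes the
#' peak (at `t_peak = tau_on*tau_off/(tau_off-tau_on) * log(tau_off/tau_on)`)
#' to 1. Zero for `t <= 0`.
#'
#' @param t Time since synapse activation, ms.
#' @param tau_on,tau_off Rise/decay constants, ms.
#' @return Kernel values.
#' @export
synaptic_kernel <- function(t, tau_on = 0.175, tau_off = 5) {
  tp <- tau_on * tau_off / (tau_off - tau_on) * log(tau_off / tau_on)
  norm <- exp(-tp / tau_off) - exp(-tp / tau_on)
  ifelse(t > 0, (exp(-t / tau_off) - exp(-t / tau_on)) / norm, 0)
}

#' Time-step convergence report
#'
#' Reruns a simulation at dt/2 and dt/4 and reports, per refinement, the
#' maximum absolute trace deviation from the previous (2x coarser) run at
#' the coarser run's sample times. For the backward-Euler scheme the
#' deviation shrinks by about a factor 2 per halving.
#'
#' @inheritParams simulate
#' @return `data.frame` with columns `dt` (the finer step of each pair),
#'   `site`, `max_dev_mV`.
#' @export
dt_convergence_check <- function(cell, stimuli = list(),
                                 config = sim_config(),
                                 biophys = default_biophys()) {
  if (inherits(cell, "compartment_graph")) cell <- compile_graph(cell, biophys)
  prev <- simulate(cell, stimuli, config)
  out <- list()
  for (f in c(2L, 4L)) {
    cf <- config
    cf$dt <- config$dt / f
    fine <- simulate(cell, stimuli, cf)
    sub <- fine$v[seq(1, nrow(fine$v), by = 2L), , drop = FALSE]
    dev <- apply(abs(sub - prev$v), 2, max)
    out[[length(out) + 1]] <- data.frame(dt = cf$dt,
                                         site = colnames(prev$v),
                                         max_dev_mV = unname(dev))
    prev <- fine
  }
  do.call(rbind, out)
}
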