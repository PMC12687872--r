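#' Section classes of the reduced model
#'
#' Section classes recognized by the biophysics configuration. The reduced
#' CA1 model has a cylindrical soma (lateral surface matched to the measured
#' soma spheroid surface), a three-part apical trunk ending in two tuft
#' branches, two basal dendrites (the axon-carrying "a" branch and the
#' canonical "b" branch), an optional AcD stem and electrotonic balance
#' stub, an axon hillock, a two-part AIS (the distal part carries the Na
#' activation shift), and a distal axon.
#'
#' @return Character vector of class names.
#' @export
section_classes <- function() {
  c("soma", "apical_prox", "apical_mid", "apical_dist", "tuft", "basal",
    "acd_stem", "balance_stub", "hillock", "ais_prox", "ais_dist", "axon")
}

#' Default geometry template
#'
#' Geometry the morphology table does not measure: distal apical trunk
#' lengths and diameters, tuft, basal dendrite length and diameter, distal
#' axon, AIS proximal/distal split fraction, synaptic window, and
#' discretization rules. Values are the package's reduced-model defaults.
#'
#' @return Nested list of template parameters (um unless noted).
#' @export
default_template <- function() {
  list(
    apical = list(L1 = 150, L2 = 300, L3 = 300, d2 = 3.5, d3 = 2.65,
                  tuft_L = 250, tuft_d = 1.8),
    basal = list(L = 250, d = 2.0),
    axon = list(L = 300, d = 0.5),
    hillock_base_diam = 1.5,
    ais_split = 0.5,
    synapse_window = c(75, 100),
    seg = list(d_lambda = 0.1, lambda_freq = 100, fine_um = 0.5))
}

.section <- function(name, class, L, diam_x, diam_d, parent, parent_pos = 1) {
  stopifnot(L > 0, length(diam_x) == length(diam_d))
  list(name = name, class = class, L = L,
       diam = list(x = diam_x, d = diam_d),
       parent = parent, parent_pos = parent_pos, nseg = NA_integer_)
}

# piecewise-linear AIS diameter profile restricted to [x0, x1]
.ais_profile <- function(x0, x1, L, d_start, d_max, d_end, max_pos) {
  xs <- c(0, max_pos, L)
  ds <- c(d_start, d_max, d_end)
  keep <- !duplicated(xs)
  xs <- xs[keep]; ds <- ds[keep]
  grid <- sort(unique(c(x0, x1, xs[xs > x0 & xs < x1])))
  dd <- stats::approx(xs, ds, xout = grid, rule = 2)$y
  list(x = grid - x0, d = dd)
}

#' Build the reduced compartmental model for one cell
#'
#' Maps a morphology record plus a geometry template to a section graph:
#' the soma is a cylinder of length `soma_major` whose lateral surface
#' equals the measured soma spheroid surface; the first 25 um of the apical
#' trunk carry the five measured diameters as a piecewise profile; the AIS
#' starts `ais_distance` um from the somatodendritic origin (for AcD cells
#' the first `acd_stem_length` um of that path is the stem), runs for
#' `ais_length` um with a linear taper `ais_d_start -> ais_d_max` (at
#' `ais_max_pos`) `-> ais_d_end`, and is split into proximal and distal
#' parts at the template split fraction. Unmeasured geometry comes from the
#' template. Use [balance_branches()] afterwards to insert the electrotonic
#' balance stub, and [segmentize()] before simulating.
#'
#' @param record One-row validated morphology table.
#' @param template Geometry template, see [default_template()].
#' @return An object of class `compartment_graph`.
#' @export
build_cell <- function(record, template = default_template()) {
  validate_cell_table(record)
  stopifnot(nrow(record) == 1)
  need <- c("apical", "basal", "axon", "ais_split", "synapse_window",
            "hillock_base_diam", "seg")
  miss <- setdiff(need, names(template))
  if (length(miss) > 0)
    stop("template missing required defaults: ", paste(miss, collapse = ", "))
  r <- as.list(record[1, ])
  is_acd <- r$acd_stem_length > 0
  S <- soma_spheroid_surface(record)
  soma_L <- r$soma_major
  soma_d <- S / (pi * soma_L)
  tpl <- template
  secs <- list()
  add <- function(s) secs[[s$name]] <<- s

  add(.section("soma", "soma", soma_L, c(0, soma_L), c(soma_d, soma_d),
               parent = NA))

  # apical trunk: measured first 25 um, template beyond
  ad <- c(r$apical_d1, r$apical_d2, r$apical_d3, r$apical_d4, r$apical_d5)
  add(.section("apical1a", "apical_prox", 25, c(0, 5, 10, 15, 20, 25),
               c(ad[1], ad), parent = "soma", parent_pos = 1))
  add(.section("apical1b", "apical_prox", tpl$apical$L1 - 25,
               c(0, tpl$apical$L1 - 25), c(ad[5], tpl$apical$d2),
               parent = "apical1a"))
  add(.section("apical2", "apical_mid", tpl$apical$L2,
               c(0, tpl$apical$L2), c(tpl$apical$d2, tpl$apical$d3),
               parent = "apical1b"))
  add(.section("apical3", "apical_dist", tpl$apical$L3,
               c(0, tpl$apical$L3), rep(tpl$apical$d3, 2),
               parent = "apical2"))
  for (tn in c("tuft1", "tuft2"))
    add(.section(tn, "tuft", tpl$apical$tuft_L, c(0, tpl$apical$tuft_L),
                 rep(tpl$apical$tuft_d, 2), parent = "apical3"))

  # axonal path
  axon_parent <- "soma"
  if (is_acd) {
    add(.section("acd_stem", "acd_stem", r$acd_stem_length,
                 c(0, r$acd_stem_length), rep(r$acd_stem_diam, 2),
                 parent = "soma", parent_pos = 0))
    axon_parent <- "acd_stem"
  }
  hillock_L <- r$ais_distance - r$acd_stem_length
  ais_parent <- axon_parent
  if (hillock_L > 0.05) {
    base_d <- if (is_acd) r$acd_stem_diam else tpl$hillock_base_diam
    add(.section("hillock", "hillock", hillock_L, c(0, hillock_L),
                 c(base_d, r$ais_d_start), parent = axon_parent,
                 parent_pos = if (is_acd) 1 else 0))
    ais_parent <- "hillock"
  }
  Lp <- tpl$ais_split * r$ais_length
  pr <- .ais_profile(0, Lp, r$ais_length, r$ais_d_start, r$ais_d_max,
                     r$ais_d_end, r$ais_max_pos)
  add(.section("ais_prox", "ais_prox", Lp, pr$x, pr$d, parent = ais_parent,
               parent_pos = if (ais_parent == axon_parent && !is_acd) 0 else 1))
  pd <- .ais_profile(Lp, r$ais_length, r$ais_length, r$ais_d_start,
                     r$ais_d_max, r$ais_d_end, r$ais_max_pos)
  add(.section("ais_dist", "ais_dist", r$ais_length - Lp, pd$x, pd$d,
               parent = "ais_prox"))
  add(.section("axon", "axon", tpl$axon$L, c(0, tpl$axon$L),
               rep(tpl$axon$d, 2), parent = "ais_dist"))

  # basal branches; branch a shares its origin with the axon path
  w <- tpl$synapse_window
  bL <- tpl$basal$L
  bd <- tpl$basal$d
  add_basal <- function(tag, parent, parent_pos, offset) {
    prox_L <- max(w[1] - offset, 0.5)
    add(.section(paste0("basal_", tag, "_prox"), "basal", prox_L,
                 c(0, prox_L), rep(bd, 2), parent = parent,
                 parent_pos = parent_pos))
    add(.section(paste0("basal_", tag, "_syn"), "basal", w[2] - w[1],
                 c(0, w[2] - w[1]), rep(bd, 2),
                 parent = paste0("basal_", tag, "_prox")))
    add(.section(paste0("basal_", tag, "_dist"), "basal", bL - w[2],
                 c(0, bL - w[2]), rep(bd, 2),
                 parent = paste0("basal_", tag, "_syn")))
  }
  if (is_acd) {
    add_basal("a", "acd_stem", 1, r$acd_stem_length)
  } else {
    add_basal("a", "soma", 0, 0)
  }
  add_basal("b", "soma", 0, 0)

  structure(list(sections = secs, record = record, template = tpl,
                 is_acd = is_acd, balanced = FALSE,
                 sites = list(
                   soma = c("soma", 0.5),
                   ais_prox = c("ais_prox", 0.5),
                   ais_dist = c("ais_dist", 0.5),
                   branch_a = c("basal_a_syn", NA),
                   branch_b = c("basal_b_syn", NA))),
            class = "compartment_graph")
}

#' @export
print.compartment_graph <- function(x, ...) {
  nseg <- vapply(x$sections, function(s) s$nseg, integer(1))
  cat("<compartment_graph>", length(x$sections), "sections",
      if (x$is_acd) "(AcD)" else "(non-AcD)",
      if (x$balanced) "balanced" else "", "\n")
  if (!anyNA(nseg)) cat("  total segments:", sum(nseg), "\n")
  invisible(x)
}

#' Insert the electrotonic balance stub
#'
#' For AcD cells, inserts a passive stub with the AcD stem's length and
#' diameter between the soma and the non-AcD ("b") basal branch, and
#' shortens that branch's proximal section by the same length, so the
#' passive path from each synaptic zone to the soma is electrotonically
#' equivalent between branches. Identity for non-AcD cells.
#'
#' @param graph A [build_cell()] graph.
#' @return The (possibly modified) graph, with `balanced = TRUE`.
#' @export
balance_branches <- function(graph) {
  stopifnot(inherits(graph, "compartment_graph"))
  if (graph$balanced) return(graph)
  if (graph$is_acd) {
    r <- as.list(graph$record[1, ])
    stub <- .section("balance_stub", "balance_stub", r$acd_stem_length,
                     c(0, r$acd_stem_length), rep(r$acd_stem_diam, 2),
                     parent = "soma", parent_pos = 0)
    prox <- graph$sections[["basal_b_prox"]]
    prox$L <- max(prox$L - r$acd_stem_length, 0.5)
    prox$diam$x <- c(0, prox$L)
    prox$parent <- "balance_stub"
    prox$parent_pos <- 1
    graph$sections[["balance_stub"]] <- stub
    graph$sections[["basal_b_prox"]] <- prox
    # keep sections in parent-before-child order
    ord <- names(graph$sections)
    ord <- c(setdiff(ord, c("balance_stub", "basal_b_prox", "basal_b_syn",
                            "basal_b_dist")),
             "balance_stub", "basal_b_prox", "basal_b_syn", "basal_b_dist")
    graph$sections <- graph$sections[ord]
  }
  graph$balanced <- TRUE
  graph
}

.odd <- function(n) {
  n <- max(1L, as.integer(ceiling(n)))
  if (n %% 2L == 0L) n + 1L else n
}

#' Spatial discretization
#'
#' Assigns segment counts: sections containing synaptic or current-injection
#' sites (the synaptic zones and both AIS parts) are discretized at
#' `fine_um` (default 0.5 um) per segment to preserve high-frequency input
#' components; all other sections follow the d-lambda rule (segment length
#' at most `d_lambda` times the AC length constant at `lambda_freq` Hz).
#' Segment counts are odd.
#'
#' @param graph A [compartment_graph][build_cell()].
#' @param biophys Biophysics configuration (for Ra and cm), see
#'   [default_biophys()].
#' @param fine_sections Extra section names to discretize finely; by default
#'   the synaptic zones and AIS sections.
#' @return Graph with `nseg` set per section.
#' @export
segmentize <- function(graph, biophys = default_biophys(),
                       fine_sections = NULL) {
  seg <- graph$template$seg
  Ra <- biophys$global$Ra
  cm <- biophys$global$cm
  fine_default <- c("basal_a_syn", "basal_b_syn", "ais_prox", "ais_dist")
  fine <- union(fine_default, fine_sections %||% character(0))
  for (nm in names(graph$sections)) {
    s <- graph$sections[[nm]]
    if (nm %in% fine) {
      s$nseg <- .odd(s$L / seg$fine_um)
    } else {
      dmean <- mean(s$diam$d)
      lambda <- 1e5 * sqrt(dmean / (4 * pi * seg$lambda_freq * Ra * cm))
      s$nseg <- .odd(s$L / (seg$d_lambda * lambda))
    }
    graph$sections[[nm]] <- s
  }
  graph
}

`%||%` <- function(a, b) if (is.null(a)) b else a
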