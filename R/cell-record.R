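#' Morphology record columns
#'
#' Canonical column set of a cell-morphology table. One row describes the
#' proximal geometry of one neuron: anatomical labels, soma ellipse diameters,
#' five proximal apical-dendrite diameters (5, 10, 15, 20, 25 um from the soma
#' base), AIS distance/length/diameter profile, and axon-carrying-dendrite
#' (AcD) stem geometry. All lengths and diameters are in micrometres.
#'
#' @return Character vector of canonical column names.
#' @export
cell_record_columns <- function() {
  c("cell_id", "plane", "subregion", "hippocampus_id", "layer_depth",
    "animal_id", "hemisphere", "sex",
    "soma_major", "soma_minor",
    paste0("apical_d", 1:5),
    "ais_distance", "ais_length",
    "ais_d_start", "ais_d_max", "ais_d_end", "ais_max_pos",
    "acd_stem_length", "acd_stem_diam")
}

.numeric_record_cols <- function() {
  c("soma_major", "soma_minor", paste0("apical_d", 1:5),
    "ais_distance", "ais_length", "ais_d_start", "ais_d_max", "ais_d_end",
    "ais_max_pos", "acd_stem_length", "acd_stem_diam")
}

#' Construct a single cell record
#'
#' Convenience constructor for a one-row morphology table; mainly used in
#' tests and examples. Validation is performed by [validate_cell_table()].
#'
#' @param cell_id Identifier.
#' @param plane One of `"dorsal"`, `"medial"`, `"ventral"`.
#' @param subregion One of the nine cell-band subregions, see
#'   [anatomy_levels()].
#' @param soma_major,soma_minor Longest two orthogonal soma diameters (um).
#' @param apical_diams Numeric vector of 5 apical-dendrite diameters (um).
#' @param ais_distance Soma-to-AIS-start separation along the axonal path (um).
#' @param ais_length AIS length (um).
#' @param ais_d_start,ais_d_max,ais_d_end AIS diameters at start, point of
#'   maximum width, and end (um).
#' @param ais_max_pos Distance from AIS start to its point of maximum width
#'   (um).
#' @param acd_stem_length AcD stem length (um); 0 when the axon is somatic.
#' @param acd_stem_diam Mean AcD stem diameter (um); `NA` when there is no
#'   stem.
#' @param hippocampus_id,layer_depth,animal_id,hemisphere,sex Optional labels.
#' @return A one-row `data.frame` with the canonical columns.
#' @export
cell_record <- function(cell_id = "cell1", plane = "dorsal", subregion = "CA1m",
                        soma_major = 16, soma_minor = 11,
                        apical_diams = c(2.6, 2.4, 2.2, 2.1, 2.0),
                        ais_distance = 3, ais_length = 28,
                        ais_d_start = 1.1, ais_d_max = 1.2, ais_d_end = 0.6,
                        ais_max_pos = 2.5,
                        acd_stem_length = 0, acd_stem_diam = NA_real_,
                        hippocampus_id = "h1", layer_depth = NA_real_,
                        animal_id = "a1", hemisphere = "left", sex = "f") {
  stopifnot(length(apical_diams) == 5)
  df <- data.frame(
    cell_id = as.character(cell_id), plane = plane, subregion = subregion,
    hippocampus_id = hippocampus_id, layer_depth = layer_depth,
    animal_id = animal_id, hemisphere = hemisphere, sex = sex,
    soma_major = soma_major, soma_minor = soma_minor,
    apical_d1 = apical_diams[1], apical_d2 = apical_diams[2],
    apical_d3 = apical_diams[3], apical_d4 = apical_diams[4],
    apical_d5 = apical_diams[5],
    ais_distance = ais_distance, ais_length = ais_length,
    ais_d_start = ais_d_start, ais_d_max = ais_d_max, ais_d_end = ais_d_end,
    ais_max_pos = ais_max_pos,
    acd_stem_length = acd_stem_length, acd_stem_diam = acd_stem_diam,
    stringsAsFactors = FALSE)
  df
}

#' Validate a cell-morphology table
#'
#' Checks the invariants of the morphology schema row by row: nonnegative
#' lengths and diameters, `soma_major >= soma_minor`,
#' `0 <= ais_max_pos <= ais_length`, and `acd_stem_length <= ais_distance`
#' (the stem is part of the soma-to-AIS path). Errors name the offending
#' field and row.
#'
#' @param table A morphology `data.frame` with the canonical columns.
#' @return The table, invisibly, if valid.
#' @export
validate_cell_table <- function(table) {
  need <- setdiff(cell_record_columns(), c("layer_depth", "hippocampus_id",
                                           "animal_id", "hemisphere", "sex"))
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop("morphology table is missing columns: ", paste(miss, collapse = ", "))
  bad_plane <- !table$plane %in% .planes
  if (any(bad_plane))
    stop("invalid plane label in rows: ",
         paste(head(which(bad_plane), 5), collapse = ", "))
  bad_sub <- !table$subregion %in% .subregions
  if (any(bad_sub))
    stop("invalid subregion label in rows: ",
         paste(head(which(bad_sub), 5), collapse = ", "))
  fail <- function(cond, field) {
    idx <- which(cond)
    if (length(idx) > 0)
      stop("invariant violation in field '", field, "' at rows: ",
           paste(head(idx, 5), collapse = ", "))
  }
  for (col in .numeric_record_cols()) {
    v <- table[[col]]
    fail(!is.na(v) & v < 0, col)
  }
  fail(is.na(table$soma_major) | is.na(table$soma_minor) |
         table$soma_major < table$soma_minor, "soma_major")
  fail(!is.na(table$ais_max_pos) & !is.na(table$ais_length) &
         table$ais_max_pos > table$ais_length, "ais_max_pos")
  fail(!is.na(table$acd_stem_length) &
         table$acd_stem_length > table$ais_distance, "acd_stem_length")
  stem <- table$acd_stem_length
  fail(!is.na(stem) & stem > 0 & is.na(table$acd_stem_diam), "acd_stem_diam")
  invisible(table)
}

#' Classify axon origin
#'
#' Applies the AcD rule and the distal-origin cut. A cell is an AcD
#' (axon-carrying-dendrite) cell when its stem is at least 2 um long and
#' strictly longer than its mean diameter; otherwise it has a distal axon
#' origin when the AIS starts more than 5 um from the soma; otherwise the
#' origin is somatic. The classification is total: every valid record falls
#' in exactly one class.
#'
#' @param table Validated morphology table (or a single record).
#' @return Factor with levels `somatic`, `distal`, `acd`, one per row.
#' @export
classify_axon_origin <- function(table) {
  validate_cell_table(table)
  stem <- table$acd_stem_length
  diam <- table$acd_stem_diam
  is_acd <- !is.na(stem) & stem >= 2 & !is.na(diam) & stem > diam
  # cells with no stem measurement count as stem length 0
  is_acd[is.na(is_acd)] <- FALSE
  out <- ifelse(is_acd, "acd",
                ifelse(table$ais_distance > 5, "distal", "somatic"))
  factor(out, levels = c("somatic", "distal", "acd"))
}

#' Soma ellipse area
#'
#' Soma size simplified as the area of the ellipse defined by the two longest
#' orthogonal diameters: `pi * (major/2) * (minor/2)`.
#'
#' @inheritParams classify_axon_origin
#' @return Numeric vector, um^2.
#' @export
soma_ellipse_area <- function(table) {
  pi * (table$soma_major / 2) * (table$soma_minor / 2)
}

#' Soma spheroid surface
#'
#' Surface area of the prolate spheroid with polar diameter `soma_major` and
#' equatorial diameter `soma_minor` (the 3D soma surface used by the
#' compartmental model). For equal axes the formula reduces to the sphere.
#'
#' @inheritParams classify_axon_origin
#' @return Numeric vector, um^2.
#' @export
soma_spheroid_surface <- function(table) {
  a <- table$soma_major / 2   # polar semi-axis
  b <- table$soma_minor / 2   # equatorial semi-axis
  out <- numeric(length(a))
  degen <- b <= 0
  near_sphere <- !degen & (a - b) / pmax(a, .Machine$double.eps) < 1e-9
  out[near_sphere] <- 4 * pi * b[near_sphere]^2
  i <- !degen & !near_sphere
  e <- sqrt(1 - (b[i] / a[i])^2)
  out[i] <- 2 * pi * b[i]^2 * (1 + (a[i] / (b[i] * e)) * asin(e))
  out[degen] <- 0
  out
}

#' AIS endpoint
#'
#' Distance from the soma to the distal end of the AIS:
#' `ais_distance + ais_length`.
#'
#' @inheritParams classify_axon_origin
#' @return Numeric vector, um.
#' @export
ais_endpoint <- function(table) {
  table$ais_distance + table$ais_length
}

#' Alternative AIS distance excluding the AcD stem
#'
#' Distance from the somatodendritic compartment (including the AcD stem) to
#' the AIS: `max(ais_distance - acd_stem_length, 0)`. Equals `ais_distance`
#' for cells without a stem.
#'
#' @inheritParams classify_axon_origin
#' @return Numeric vector, um.
#' @export
ais_distance_2 <- function(table) {
  stem <- table$acd_stem_length
  stem[is.na(stem)] <- 0
  pmax(table$ais_distance - stem, 0)
}

#' Mean proximal apical dendrite diameter
#'
#' Arithmetic mean of the five consecutive apical-dendrite diameters measured
#' at 5 um spacing from the soma base.
#'
#' @inheritParams classify_axon_origin
#' @return Numeric vector, um.
#' @export
mean_apical_diameter <- function(table) {
  cols <- paste0("apical_d", 1:5)
  rowMeans(as.matrix(table[, cols, drop = FALSE]))
}
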