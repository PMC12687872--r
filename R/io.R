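#' Read a morphology CSV
#'
#' Reads a cell-morphology table, optionally renaming columns through a
#' column map (named list/vector `canonical = "file header"`, or a YAML
#' file holding one) so external datasets with different headers can be
#' adapted to the canonical schema. Units are micrometres throughout. The
#' table is validated row-wise; violations raise row-addressed errors.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector or YAML file path.
#' @return Validated morphology `data.frame`.
#' @export
read_morphology_csv <- function(path, column_map = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    if (is.character(column_map) && length(column_map) == 1 &&
        file.exists(column_map))
      column_map <- unlist(yaml::read_yaml(column_map))
    column_map <- unlist(column_map)
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(tab))
        stop("column map refers to missing column '", src, "'")
      names(tab)[names(tab) == src] <- canon
    }
  }
  validate_cell_table(tab)
  tab
}

#' Write a morphology CSV
#'
#' @param table Validated morphology table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morphology_csv <- function(table, path) {
  validate_cell_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record embedded in pipeline outputs: package version, seeds,
#' and digests of the input files.
#'
#' @param seeds Named list/vector of seeds used.
#' @param inputs Character vector of input file paths to digest.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(seeds = list(), inputs = character(0)) {
  digests <- if (length(inputs) > 0) tools::md5sum(inputs) else character(0)
  structure(list(package = "aisgeom",
                 version = as.character(packageVersion("aisgeom")),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"),
                 seeds = seeds, input_digests = as.list(digests)),
            class = "run_manifest")
}

#' Write a result table with its manifest
#'
#' Writes `table` as CSV and the manifest alongside it as JSON
#' (`<path>.manifest.json`).
#'
#' @param table `data.frame`.
#' @param path Output CSV path.
#' @param manifest A [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(table, path, manifest = run_manifest()) {
  write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(unclass(manifest), paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Small deterministic inputs for tests and examples: a 10-cell cohort
#' drawn from the packaged medial-CA1m profile (containing both AcD and
#' non-AcD cells) and a 10-compartment random passive toy tree (parent
#' pointers in Hines order with per-compartment passive properties).
#'
#' @param seed Integer seed.
#' @return List with `cohort` (morphology table) and `tree` (list of
#'   compartment arrays).
#' @export
make_fixtures <- function(seed = 42L) {
  profiles <- default_profiles()
  cohort <- generate_cohort(profiles[["medial.CA1m"]], n = 10, seed = seed)
  tree <- with_seed(seed + 1L, {
    n <- 10L
    # 1-based parent pointers in Hines order; 0 marks the root
    parent <- c(0L, vapply(2:n, function(i)
      sample.int(i - 1L, 1L), integer(1)))
    list(parent = parent,
         g_axial = c(0, runif(n - 1, 0.02, 0.2)),
         cm = runif(n, 5e-6, 5e-5),
         g_pas = runif(n, 1e-4, 1e-3),
         e_pas = rep(-70, n))
  })
  list(cohort = cohort, tree = tree)
}
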