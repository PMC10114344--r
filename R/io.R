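# File interfaces and the pipeline surface.
#
# Cell tables travel as CSV (one header row, enums as lowercase snake_case
# strings, booleans as true/false); regions as GeoJSON FeatureCollections
# with coordinates in micrometers; validation reports as JSON lines; run
# configuration as a single JSON file whose defaults are all overridable.
# CSV dialect: UTF-8, comma separator, "." decimal, no thousands
# separators.

#' Run configuration
#'
#' Bundles every tunable with its default. The effective configuration is
#' echoed into every pipeline output.
#'
#' @param field_diameter_10x,leading_edge_margin geometry defaults, um
#' @param tap_cutoffs TAP cutoffs to report (default both 1 and 5)
#' @param cps_cutoff CPS positivity cutoff (default 1)
#' @param min_viable_tc CPS validity threshold (default 100 viable TC)
#' @param ci_method `"wilson"` or `"cluster_bootstrap"`
#' @param n_boot bootstrap replicates
#' @param confidence CI level
#' @param seed master seed
#' @param rounding report decimals
#' @param footprints per-class default footprints, um^2
#' @return list of class `run_config`
#' @export
run_config <- function(field_diameter_10x = 2000, leading_edge_margin = 50,
                       tap_cutoffs = c(1, 5), cps_cutoff = 1,
                       min_viable_tc = 100, ci_method = "wilson",
                       n_boot = 2000, confidence = 0.95, seed = 1L,
                       rounding = 1L, footprints = default_footprints()) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration JSON, overriding defaults
#' @param path JSON file; absent keys keep their defaults
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  overrides <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (k in names(overrides)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k, call. = FALSE)
    if (k == "footprints") {
      cfg$footprints[names(overrides$footprints)] <-
        unlist(overrides$footprints)
    } else {
      cfg[[k]] <- overrides[[k]]
    }
  }
  cfg
}

#' Read a cell table CSV
#'
#' Strict parsing: missing required columns and bad enum labels are errors
#' naming the column (and row, via the constructor's checks); unknown
#' columns are preserved.
#'
#' @param path CSV file
#' @return canonical cell tibble (see [cell_table()])
#' @export
read_cell_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cell_table(df)
}

#' Write a cell table CSV
#' @param cells cell tibble
#' @param path output file
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells, path)
  invisible(path)
}

#' Read regions from a GeoJSON FeatureCollection
#'
#' Coordinates are micrometers by contract; any CRS member is ignored with
#' a warning. Polygon holes become the region's hole rings. MultiPolygon
#' features are split into one region per part, the part index appended to
#' the region id.
#'
#' @param path GeoJSON file
#' @return region tibble (see [region_table()])
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  if (!is.null(gj$crs)) {
    warning("GeoJSON crs member ignored; coordinates are micrometers ",
            "by contract")
  }
  ring_from_coords <- function(cc) {
    m <- do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
    list(x = m[, 1], y = m[, 2])
  }
  rows <- list()
  for (f in gj$features) {
    props <- f$properties
    if (is.null(props$region_class)) {
      stop("feature missing region_class property", call. = FALSE)
    }
    rid <- if (is.null(props$region_id)) {
      sprintf("region_%03d", length(rows) + 1)
    } else props$region_id
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    for (pi in seq_along(polys)) {
      rings <- lapply(polys[[pi]], ring_from_coords)
      rows[[length(rows) + 1]] <- region_table(
        if (length(polys) > 1) sprintf("%s_%d", rid, pi) else rid,
        props$region_class, list(rings[[1]]),
        list(rings[-1]))
    }
  }
  if (length(rows) == 0) return(empty_region_table())
  dplyr::bind_rows(rows)
}

#' Write regions to GeoJSON
#' @param regions region tibble
#' @param path output file
#' @export
write_region_geojson <- function(regions, path) {
  close_ring <- function(r) {
    lapply(c(seq_along(r$x), 1L), function(i) c(r$x[i], r$y[i]))
  }
  features <- lapply(seq_len(nrow(regions)), function(i) {
    rings <- c(list(regions$polygon[[i]]), regions$holes[[i]])
    list(type = "Feature",
         properties = list(region_id = regions$region_id[i],
                           region_class = regions$region_class[i]),
         geometry = list(type = "Polygon",
                         coordinates = lapply(rings, close_ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a validation report as JSON lines
#' @param report tibble from [validate_slide()]
#' @param path output file (one violation object per line)
#' @export
write_validation_report <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(report))) {
    writeLines(jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE),
               con)
  }
  invisible(path)
}

#' Read a long-format reader-score CSV
#'
#' Expected columns: sample_id, reader_id, round, and tap_percent and/or
#' status; optional site.
#'
#' @param path CSV file
#' @param cutoff cutoff for deriving binary calls
#' @return a [reader_score_matrix()]
#' @export
read_reader_scores <- function(path, cutoff = 5) {
  reader_score_matrix(readr::read_csv(path, show_col_types = FALSE,
                                      progress = FALSE), cutoff = cutoff)
}

.pkg_version <- function() {
  as.character(utils::packageVersion("tapscore"))
}

.config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$footprints <- as.list(cfg$footprints)
  list(package_version = .pkg_version(), config = cfg)
}

#' Run a pipeline command
#'
#' The programmatic surface behind the command-line script. Commands:
#' \describe{
#'   \item{score}{inputs `cells`, `regions`, `indication`, `specimen_type`;
#'     writes `score.json` with TAP at each configured cutoff, CPS, and the
#'     eligibility exclusion tallies.}
#'   \item{validate}{same slide inputs; writes `validation.jsonl`; status 1
#'     if any violation of severity error.}
#'   \item{precision}{inputs `scores` (CSV path or reader matrix) and
#'     `mode` (between/within/multisite); writes `precision.json`.}
#'   \item{concordance}{inputs `scores`: CSV path or data frame with
#'     columns sample_id, tap_percent, cps; writes `concordance.json`.}
#'   \item{simulate}{inputs `params` ([slide_gen_params()]) or cohort
#'     arguments; writes cells CSV, regions GeoJSON and truth JSON.}
#' }
#' Every JSON artifact embeds the effective configuration and package
#' version; outputs are deterministic for fixed inputs, config and seed.
#'
#' @param command one of score, validate, precision, concordance, simulate
#' @param config a [run_config()]
#' @param inputs named list, see above
#' @param out_dir output directory (created if missing)
#' @return invisibly, list with `status` (0 ok, 1 hard error), `artifacts`
#'   (paths) and `results`
#' @export
run_pipeline <- function(command, config = run_config(), inputs = list(),
                         out_dir = ".") {
  command <- match.arg(command, c("score", "validate", "precision",
                                  "concordance", "simulate"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  status <- 0L
  results <- NULL

  load_slide <- function() {
    cells <- if (is.character(inputs$cells)) read_cell_table(inputs$cells)
      else cell_table(inputs$cells, footprints = config$footprints)
    regions <- if (is.character(inputs$regions))
      read_region_geojson(inputs$regions) else inputs$regions
    slide_annotation(
      slide_id = if (is.null(inputs$slide_id)) "slide" else inputs$slide_id,
      indication = if (is.null(inputs$indication)) "gastric"
        else inputs$indication,
      specimen_type = if (is.null(inputs$specimen_type)) "resection"
        else inputs$specimen_type,
      cells = cells, regions = regions,
      field_diameter_10x = config$field_diameter_10x)
  }

  if (command == "validate") {
    slide <- load_slide()
    report <- validate_slide(slide)
    path <- file.path(out_dir, "validation.jsonl")
    write_validation_report(report, path)
    artifacts <- path
    status <- if (any(report$severity == "error")) 1L else 0L
    results <- report
  } else if (command == "score") {
    slide <- load_slide()
    fr <- field_rule_config(field_diameter_10x = config$field_diameter_10x,
                            leading_edge_margin = config$leading_edge_margin)
    ta <- build_tumor_area(slide, fr)
    taps <- lapply(config$tap_cutoffs, function(co)
      compute_tap(slide, ta, cutoff = co))
    cps <- compute_cps(slide, ta, min_viable_tc = config$min_viable_tc)
    elig <- taps[[1]]$eligibility
    excl <- as.list(table(elig$reason[!elig$scoreable]))
    res <- c(.config_echo(config), list(
      slide_id = slide$slide_id,
      tumor_area_um2 = ta$total_area,
      tap = lapply(taps, function(t) list(
        cutoff = t$cutoff,
        tap_percent = round_half_up(t$tap_percent, config$rounding),
        tap_percent_raw = t$tap_percent,
        status = t$status_at_cutoff,
        borderline_category = t$borderline_category,
        positive_area_um2 = t$positive_area,
        n_positive_tc = t$n_positive_tc, n_positive_ic = t$n_positive_ic)),
      cps = list(cps = cps$cps, valid = cps$valid,
                 n_positive_tc = cps$n_positive_tc,
                 n_positive_mononuclear_ic = cps$n_positive_mononuclear_ic,
                 n_viable_tc = cps$n_viable_tc),
      exclusion_counts = excl))
    path <- file.path(out_dir, "score.json")
    jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    ledger_path <- file.path(out_dir, "tumor_area_components.csv")
    write_component_ledger(ta, ledger_path)
    artifacts <- c(path, ledger_path)
    results <- res
  } else if (command == "precision") {
    m <- if (is.character(inputs$scores)) read_reader_scores(
      inputs$scores, cutoff = max(config$tap_cutoffs)) else inputs$scores
    mode <- if (is.null(inputs$mode)) "between" else inputs$mode
    rep <- switch(mode,
      between = between_reader_precision(m, confidence = config$confidence,
        ci_method = config$ci_method, n_boot = config$n_boot,
        seed = config$seed),
      within = within_reader_precision(m, confidence = config$confidence,
        ci_method = config$ci_method, n_boot = config$n_boot,
        seed = config$seed),
      multisite = {
        sites <- split(tibble::as_tibble(m), m$site)
        multisite_pool(lapply(sites, function(s)
          between_reader_precision(reader_score_matrix(s,
            cutoff = attr(m, "cutoff")))), confidence = config$confidence)
      },
      stop("unknown precision mode: ", mode, call. = FALSE))
    res <- c(.config_echo(config), list(mode = mode,
      counts = unclass(rep$counts)[c("a", "b", "c", "d", "total")],
      statistics = rep$statistics))
    path <- file.path(out_dir, "precision.json")
    jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    csv_path <- file.path(out_dir, "precision.csv")
    readr::write_csv(rep$statistics, csv_path)
    artifacts <- c(path, csv_path)
    results <- rep
  } else if (command == "concordance") {
    df <- if (is.character(inputs$scores)) readr::read_csv(
      inputs$scores, show_col_types = FALSE, progress = FALSE)
      else tibble::as_tibble(inputs$scores)
    tap_cutoff <- if (is.null(inputs$tap_cutoff)) min(config$tap_cutoffs)
      else inputs$tap_cutoff
    rep <- method_concordance(df$tap_percent, df$cps,
                              tap_cutoff = tap_cutoff,
                              cps_cutoff = config$cps_cutoff,
                              confidence = config$confidence)
    res <- c(.config_echo(config), list(
      tap_cutoff = tap_cutoff, cps_cutoff = config$cps_cutoff,
      counts = unclass(rep$counts)[c("a", "b", "c", "d", "total")],
      statistics = rep$statistics))
    path <- file.path(out_dir, "concordance.json")
    jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    csv_path <- file.path(out_dir, "concordance.csv")
    readr::write_csv(rep$statistics, csv_path)
    artifacts <- c(path, csv_path)
    results <- rep
  } else if (command == "simulate") {
    params <- if (is.null(inputs$params)) slide_gen_params(
      seed = config$seed) else inputs$params
    gen <- generate_slide(params)
    cells_path <- file.path(out_dir, "cells.csv")
    regions_path <- file.path(out_dir, "regions.geojson")
    truth_path <- file.path(out_dir, "truth.json")
    write_cell_table(gen$slide$cells, cells_path)
    write_region_geojson(gen$slide$regions, regions_path)
    truth <- gen$truth
    truth$components <- NULL
    jsonlite::write_json(c(.config_echo(config), truth), truth_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- c(cells_path, regions_path, truth_path)
    results <- gen
  }
  invisible(list(status = status, artifacts = artifacts, results = results))
}
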