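# Slide annotation data model: cell table, region annotations, slide object,
# and structural validation. Coordinates are micrometers in a Cartesian plane
# (y increasing upward); no pixel coordinates appear in the core model.

.CELL_CLASSES <- c("tumor_cell", "lymphocyte", "macrophage", "granulocyte",
                   "plasma_cell", "giant_cell", "fibroblast", "endothelial",
                   "neuroendocrine", "smooth_muscle", "nerve", "other")
# Immune-cell classes eligible (in principle) as tumor-associated IC.
.IC_CLASSES <- c("lymphocyte", "macrophage", "granulocyte", "plasma_cell",
                 "giant_cell")
# Mononuclear IC counted in the CPS numerator (lymphocytes and macrophages).
.CPS_IC_CLASSES <- c("lymphocyte", "macrophage")
# Off-target cell types whose staining never enters a score.
.OFF_TARGET_CLASSES <- c("fibroblast", "endothelial", "neuroendocrine",
                         "smooth_muscle", "nerve", "other")
.REGION_CLASSES <- c("tumor_nest", "tumor_stroma", "necrosis", "crush_artifact",
                     "cautery_artifact", "mucin_pool", "glandular_lumen",
                     "lymphovascular_space", "lymphoid_aggregate",
                     "germinal_center", "lymph_node", "non_neoplastic")
.EXCLUDED_REGION_CLASSES <- c("necrosis", "crush_artifact", "cautery_artifact")
.VIABILITY <- c("viable", "necrotic")
.MEMBRANE <- c("none", "partial", "circumferential")
.CONTEXTS <- c("tumor_proper", "stroma", "lumen", "vessel_or_lymphatic",
               "germinal_center", "granuloma", "outside_tumor")
.INDICATIONS <- c("gastric", "GEJ", "ESCC")
.SPECIMEN_TYPES <- c("resection", "biopsy")

.CELL_COLUMNS <- c("cell_id", "cell_class", "viability", "x", "y",
                   "footprint_area", "membrane_stain", "cytoplasmic_stain",
                   "punctate_stain", "stain_intensity", "context",
                   "fills_lumen_and_contacts_tc")

#' Default cell footprint areas by class
#'
#' Order-of-magnitude cross-sectional areas (micrometers squared) used when a
#' cell record carries no footprint. Configurable; visual scoring has no
#' measured per-cell areas, so these are modeling conventions.
#' @return named numeric vector, one entry per cell class
#' @export
default_footprints <- function() {
  c(tumor_cell = 200, lymphocyte = 50, macrophage = 120, granulocyte = 60,
    plasma_cell = 60, giant_cell = 400, fibroblast = 100, endothelial = 80,
    neuroendocrine = 150, smooth_muscle = 150, nerve = 150, other = 100)
}

.check_enum <- function(values, allowed, what) {
  bad <- setdiff(unique(as.character(values[!is.na(values)])), allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
}

#' Construct a cell table
#'
#' Coerces a data frame to the canonical cell-record layout and hard-errors on
#' unknown enum labels. Missing optional columns (`footprint_area`,
#' `fills_lumen_and_contacts_tc`) are filled with defaults.
#'
#' @param df data frame with (at least) columns `cell_id`, `cell_class`,
#'   `viability`, `x`, `y`, `membrane_stain`, `cytoplasmic_stain`,
#'   `punctate_stain`, `stain_intensity`, `context`
#' @param footprints named vector of per-class default footprint areas used to
#'   fill missing `footprint_area`
#' @return tibble with the canonical columns (extra columns preserved)
#' @export
cell_table <- function(df, footprints = default_footprints()) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0 && !all(.CELL_COLUMNS %in% names(df))) {
    df <- tibble::tibble(
      cell_id = character(), cell_class = character(), viability = character(),
      x = numeric(), y = numeric(), footprint_area = numeric(),
      membrane_stain = character(), cytoplasmic_stain = logical(),
      punctate_stain = logical(), stain_intensity = integer(),
      context = character(), fills_lumen_and_contacts_tc = logical())
  }
  required <- setdiff(.CELL_COLUMNS, c("footprint_area",
                                       "fills_lumen_and_contacts_tc"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"footprint_area" %in% names(df)) df$footprint_area <- NA_real_
  if (!"fills_lumen_and_contacts_tc" %in% names(df)) {
    df$fills_lumen_and_contacts_tc <- FALSE
  }
  df$cell_id <- as.character(df$cell_id)
  df$cell_class <- as.character(df$cell_class)
  df$viability <- as.character(df$viability)
  df$membrane_stain <- as.character(df$membrane_stain)
  df$context <- as.character(df$context)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df$footprint_area <- as.numeric(df$footprint_area)
  df$stain_intensity <- as.integer(df$stain_intensity)
  df$cytoplasmic_stain <- as.logical(df$cytoplasmic_stain)
  df$punctate_stain <- as.logical(df$punctate_stain)
  df$fills_lumen_and_contacts_tc <- as.logical(df$fills_lumen_and_contacts_tc)
  .check_enum(df$cell_class, .CELL_CLASSES, "cell_class")
  .check_enum(df$viability, .VIABILITY, "viability")
  .check_enum(df$membrane_stain, .MEMBRANE, "membrane_stain")
  .check_enum(df$context, .CONTEXTS, "context")
  if (any(!df$stain_intensity %in% 0:3)) {
    stop("stain_intensity must be an ordinal in 0..3", call. = FALSE)
  }
  fill <- is.na(df$footprint_area)
  if (any(fill)) df$footprint_area[fill] <- footprints[df$cell_class[fill]]
  df[c(.CELL_COLUMNS, setdiff(names(df), .CELL_COLUMNS))]
}

#' Construct a region-annotation table
#'
#' @param region_id character vector of identifiers
#' @param region_class character vector of region classes
#' @param polygon list of rings, each `list(x, y)` in micrometers
#' @param holes optional list (same length) of hole-ring lists; holes are
#'   separate rings subtracted from their parent polygon under the even-odd
#'   rule (e.g. a mucin pool carved out of a nest)
#' @return tibble with columns region_id, region_class, polygon, holes
#' @export
region_table <- function(region_id, region_class, polygon, holes = NULL) {
  region_id <- as.character(region_id)
  region_class <- as.character(region_class)
  .check_enum(region_class, .REGION_CLASSES, "region_class")
  if (!is.list(polygon) || (length(polygon) > 0 && !is.null(polygon$x))) {
    polygon <- list(polygon)
  }
  if (is.null(holes)) holes <- rep(list(list()), length(region_id))
  stopifnot(length(polygon) == length(region_id),
            length(holes) == length(region_id))
  tibble::tibble(region_id = region_id, region_class = region_class,
                 polygon = polygon, holes = holes)
}

empty_region_table <- function() {
  tibble::tibble(region_id = character(), region_class = character(),
                 polygon = list(), holes = list())
}

# Polyset of one region row: polygon ring plus hole rings (even-odd).
region_polyset <- function(regions, i) {
  c(list(regions$polygon[[i]]), regions$holes[[i]])
}

# Even-odd polyset of all regions of the given classes.
regions_polyset <- function(regions, classes) {
  idx <- which(regions$region_class %in% classes)
  out <- list()
  for (i in idx) out <- poly_union(out, region_polyset(regions, i))
  out
}

#' Construct a slide annotation
#'
#' Bundles the cell table and region annotations with slide-level metadata.
#'
#' @param slide_id identifier
#' @param indication one of `"gastric"`, `"GEJ"`, `"ESCC"`
#' @param specimen_type `"resection"` or `"biopsy"`
#' @param cells cell table (see [cell_table()]); coerced
#' @param regions region table (see [region_table()])
#' @param field_diameter_10x diameter of one 10x microscope field,
#'   micrometers (drives the nest-merging rule)
#' @return object of class `slide_annotation`
#' @export
slide_annotation <- function(slide_id, indication, specimen_type,
                             cells, regions, field_diameter_10x = 2000) {
  indication <- match.arg(indication, .INDICATIONS)
  specimen_type <- match.arg(specimen_type, .SPECIMEN_TYPES)
  stopifnot(is.numeric(field_diameter_10x), field_diameter_10x > 0)
  structure(
    list(slide_id = as.character(slide_id), indication = indication,
         specimen_type = specimen_type, cells = cell_table(cells),
         regions = tibble::as_tibble(regions),
         field_diameter_10x = field_diameter_10x),
    class = "slide_annotation")
}

#' @export
print.slide_annotation <- function(x, ...) {
  cat(sprintf("<slide_annotation> %s: %s %s, %d cells, %d regions\n",
              x$slide_id, x$indication, x$specimen_type,
              nrow(x$cells), nrow(x$regions)))
  invisible(x)
}

.violation <- function(code, severity, id, message) {
  tibble::tibble(code = code, severity = severity, id = id, message = message)
}

#' Validate the structural integrity of a slide annotation
#'
#' Checks every model invariant and returns a deterministic, ordered report:
#' slide-level violations first, then region violations ordered by region id,
#' then cell violations ordered by cell id. Malformed geometry yields a
#' violation row, not an exception; unknown enum labels are hard errors
#' (raised by the constructors).
#'
#' Checks: presence of at least one tumor nest; positive polygon areas and
#' simple (non-self-intersecting) rings; germinal centers spatially contained
#' in a lymphoid aggregate or lymph node; positive cell footprints; staining
#' flags consistent with intensity 0; cell centroids contained in the
#' annotated regions unless flagged `context = "outside_tumor"` (containment
#' mismatches are warnings — the annotation is ground truth, the geometric
#' cross-check catches data errors).
#'
#' @param slide a [slide_annotation()]
#' @return tibble with columns code, severity (`"error"`/`"warning"`), id,
#'   message; zero rows iff all invariants hold
#' @export
validate_slide <- function(slide) {
  stopifnot(inherits(slide, "slide_annotation"))
  regions <- slide$regions
  cells <- slide$cells
  out <- list()

  if (!any(regions$region_class == "tumor_nest")) {
    out[[length(out) + 1]] <- .violation(
      "NO_TUMOR_NEST", "error", slide$slide_id,
      "slide has no tumor_nest region and is unscorable")
  }

  if (nrow(regions) > 0) {
    for (i in order(regions$region_id)) {
      rid <- regions$region_id[i]
      rings <- region_polyset(regions, i)
      for (ring in rings) {
        if (length(ring$x) >= 3 && !ring_is_simple(ring)) {
          out[[length(out) + 1]] <- .violation(
            "POLYGON_SELF_INTERSECTS", "error", rid,
            "polygon ring is self-intersecting")
        } else if (length(ring$x) < 3 || abs(ring_signed_area(ring)) <= 0) {
          out[[length(out) + 1]] <- .violation(
            "POLYGON_ZERO_AREA", "error", rid,
            "polygon ring has fewer than 3 vertices or zero area")
        }
      }
      if (regions$region_class[i] == "germinal_center") {
        parents <- regions_polyset(regions, c("lymphoid_aggregate",
                                              "lymph_node"))
        uncovered <- poly_minus(rings, parents)
        if (poly_area(uncovered) > 1e-6 * poly_area(rings)) {
          out[[length(out) + 1]] <- .violation(
            "GC_NOT_CONTAINED", "error", rid,
            "germinal_center not contained in a lymphoid_aggregate or lymph_node")
        }
      }
    }
  }

  if (nrow(cells) > 0) {
    ord <- order(cells$cell_id)
    bad_fp <- which(!(cells$footprint_area > 0))
    stained <- cells$membrane_stain != "none" | cells$cytoplasmic_stain |
      cells$punctate_stain
    bad_stain <- which((cells$stain_intensity == 0L) != !stained)
    all_regions <- list()
    for (i in seq_len(nrow(regions))) {
      all_regions <- poly_union(all_regions, region_polyset(regions, i))
    }
    inside <- points_in_polyset(cells$x, cells$y, all_regions)
    bad_loc <- which(!inside & cells$context != "outside_tumor")
    for (i in ord) {
      cid <- cells$cell_id[i]
      if (i %in% bad_fp) {
        out[[length(out) + 1]] <- .violation(
          "FOOTPRINT_NONPOSITIVE", "error", cid,
          "footprint_area must be > 0")
      }
      if (i %in% bad_stain) {
        out[[length(out) + 1]] <- .violation(
          "STAIN_INTENSITY_INCONSISTENT", "error", cid,
          "stain_intensity 0 must coincide with absence of all staining flags")
      }
      if (i %in% bad_loc) {
        out[[length(out) + 1]] <- .violation(
          "CELL_OUTSIDE_REGIONS", "warning", cid,
          "cell centroid lies outside all annotated regions but context is not outside_tumor")
      }
    }
  }

  if (length(out) == 0) {
    return(tibble::tibble(code = character(), severity = character(),
                          id = character(), message = character()))
  }
  dplyr::bind_rows(out)
}
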