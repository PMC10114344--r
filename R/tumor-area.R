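# Tumor-area construction: the denominator geometry for area-fraction
# scoring. The tumor area is everything occupied by viable tumor nests and
# the tumor-associated stroma, with nests separated by less than one 10x
# field merged together with the intervening tissue, luminal contents
# (mucin pools, glandular lumina) included, and necrosis/crush/cautery
# artifacts carved out. Lymph-node metastases get their own rule: nests
# plus a fixed-width leading-edge band for the immediately adjacent immune
# cells.

#' Field-rule configuration
#'
#' @param field_diameter_10x diameter of a 10x microscope field in
#'   micrometers. Default 2000: a 10x objective with an 18-22 mm field-number
#'   eyepiece shows a 1.8-2.2 mm field of view.
#' @param leading_edge_margin width (micrometers) of the band around a
#'   lymph-node metastasis within which immune cells count as
#'   tumor-associated
#' @param apply_field_rule merge nests separated by at most one field
#'   diameter (with the intervening tissue) into one component
#' @param arc_tolerance maximum sagitta (micrometers) of the circular-arc
#'   approximation used by dilation/erosion offsets
#' @return object of class `field_rule_config`
#' @export
field_rule_config <- function(field_diameter_10x = 2000,
                              leading_edge_margin = 50,
                              apply_field_rule = TRUE,
                              arc_tolerance = 0.25) {
  stopifnot(field_diameter_10x > 0, leading_edge_margin >= 0)
  structure(list(field_diameter_10x = field_diameter_10x,
                 leading_edge_margin = leading_edge_margin,
                 apply_field_rule = isTRUE(apply_field_rule),
                 arc_tolerance = arc_tolerance),
            class = "field_rule_config")
}

.unscorable <- function(msg = "no viable tumor nest; slide is unscorable") {
  stop(structure(class = c("UNSCORABLE_NO_TUMOR", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Merge tumor nests under the 10x field rule
#'
#' Nests whose edge-to-edge separation is at most one field diameter are
#' merged into a single component together with the intervening tissue,
#' implemented as a morphological closing of the nest union with a disk of
#' the field diameter (dilate by half the diameter, erode by the same);
#' exclusion geometry is subtracted afterwards. The closing is transitive
#' across chains of nests.
#'
#' @param nests polyset (list of rings `list(x, y)`) of nest polygons
#' @param config [field_rule_config()]
#' @param exclusions polyset to subtract from the result
#' @return polyset; a superset of the nest union minus exclusions
#' @export
merge_nests_by_field_rule <- function(nests, config = field_rule_config(),
                                      exclusions = list()) {
  if (length(nests) == 0) .unscorable("empty nest set")
  g <- if (config$apply_field_rule) {
    poly_close(nests, config$field_diameter_10x, arctol = config$arc_tolerance)
  } else {
    poly_normalize(nests)
  }
  poly_minus(g, exclusions)
}

new_tumor_area <- function(geometry, components, config) {
  structure(list(geometry = geometry, total_area = poly_area(geometry),
                 components = components, config = config),
            class = "tumor_area")
}

#' @export
print.tumor_area <- function(x, ...) {
  cat(sprintf("<tumor_area> %.0f um^2 (%.3f mm^2), %d component dispositions\n",
              x$total_area, x$total_area / 1e6, nrow(x$components)))
  invisible(x)
}

#' Test whether points lie inside a tumor area
#' @param ta a `tumor_area`
#' @param x,y coordinates in micrometers
#' @return logical vector
#' @export
tumor_area_contains <- function(ta, x, y) {
  points_in_polyset(x, y, ta$geometry)
}

.component_row <- function(region_id, disposition, reason) {
  tibble::tibble(region_id = region_id, disposition = disposition,
                 reason = reason)
}

# Nest rows whose polygon centroid falls inside the given polyset.
.nests_inside <- function(regions, polyset) {
  idx <- which(regions$region_class == "tumor_nest")
  if (length(idx) == 0) return(integer())
  cent <- t(vapply(idx, function(i) ring_centroid(regions$polygon[[i]]),
                   numeric(2)))
  idx[points_in_polyset(cent[, 1], cent[, 2], polyset)]
}

#' Build the tumor area for a slide
#'
#' Assembles the scoring denominator: all tumor nests (including nests lying
#' within lymphovascular spaces) merged under the 10x field rule; tumor
#' stroma within one field diameter of a nest; mucin pools and glandular
#' lumina intersecting the running union; for gastric/GEJ adenocarcinoma,
#' lymphoid aggregates (with their germinal centers) intersecting the running
#' union; minus necrosis and crush/cautery artifacts. Nests inside a lymph
#' node are handled by the lymph-node rule (nests plus leading-edge band,
#' clipped to the node) and unioned in.
#'
#' Every region's fate is recorded in the `components` ledger
#' (region_id, disposition in included/excluded/merged_intervening, reason).
#'
#' @param slide a [slide_annotation()]
#' @param config a [field_rule_config()]; its field diameter defaults to the
#'   slide's `field_diameter_10x`
#' @return object of class `tumor_area`
#' @export
build_tumor_area <- function(slide, config = NULL) {
  stopifnot(inherits(slide, "slide_annotation"))
  if (is.null(config)) {
    config <- field_rule_config(field_diameter_10x = slide$field_diameter_10x)
  }
  regions <- slide$regions
  nest_idx <- which(regions$region_class == "tumor_nest")
  if (length(nest_idx) == 0) .unscorable()

  comp <- list()
  node_ps <- regions_polyset(regions, "lymph_node")
  nodal_nests <- if (length(node_ps) > 0) .nests_inside(regions, node_ps) else integer()
  free_nests <- setdiff(nest_idx, nodal_nests)

  exclusions <- regions_polyset(regions, .EXCLUDED_REGION_CLASSES)

  nests_ps <- list()
  for (i in free_nests) nests_ps <- poly_union(nests_ps, region_polyset(regions, i))
  geom <- list()
  if (length(nests_ps) > 0) {
    geom <- if (config$apply_field_rule) {
      poly_close(nests_ps, config$field_diameter_10x,
                 arctol = config$arc_tolerance)
    } else {
      nests_ps
    }
  }
  for (i in nest_idx) {
    comp[[length(comp) + 1]] <- .component_row(
      regions$region_id[i], "included",
      if (i %in% nodal_nests) "lymph_node_metastasis" else "tumor_nest")
  }

  # tumor-associated stroma: explicit stroma within one field diameter of a
  # nest (sharing a boundary counts as distance zero)
  if (length(nests_ps) > 0) {
    near_nests <- poly_offset(nests_ps, config$field_diameter_10x,
                              arctol = config$arc_tolerance)
    for (i in which(regions$region_class == "tumor_stroma")) {
      ps <- region_polyset(regions, i)
      if (poly_intersects(ps, near_nests)) {
        geom <- poly_union(geom, ps)
        comp[[length(comp) + 1]] <- .component_row(
          regions$region_id[i], "included", "tumor_associated_stroma")
      } else {
        comp[[length(comp) + 1]] <- .component_row(
          regions$region_id[i], "excluded", "stroma_not_adjacent_to_nest")
      }
    }
  }

  # luminal inclusions: mucin pools and glandular lumina touching the area.
  # A pool annotated as a hole in its nest only shares a boundary with the
  # running union, so the contact test uses a 1 um dilation.
  for (i in which(regions$region_class %in% c("mucin_pool", "glandular_lumen"))) {
    ps <- region_polyset(regions, i)
    if (poly_intersects(poly_offset(ps, 1, arctol = 0.25), geom)) {
      geom <- poly_union(geom, ps)
      comp[[length(comp) + 1]] <- .component_row(
        regions$region_id[i], "included", "luminal_space_included")
    } else {
      comp[[length(comp) + 1]] <- .component_row(
        regions$region_id[i], "excluded", "not_within_tumor_area")
    }
  }

  # lymphoid aggregates with germinal centers: gastric/GEJ only
  lymphoid_idx <- which(regions$region_class %in%
                          c("lymphoid_aggregate", "germinal_center"))
  for (i in lymphoid_idx) {
    ps <- region_polyset(regions, i)
    if (slide$indication %in% c("gastric", "GEJ") &&
        poly_intersects(poly_offset(ps, 1, arctol = 0.25), geom)) {
      geom <- poly_union(geom, ps)
      comp[[length(comp) + 1]] <- .component_row(
        regions$region_id[i], "included", "lymphoid_aggregate_included")
    } else {
      reason <- if (!slide$indication %in% c("gastric", "GEJ")) {
        "lymphoid_inclusion_not_applicable"
      } else "not_within_tumor_area"
      comp[[length(comp) + 1]] <- .component_row(
        regions$region_id[i], "excluded", reason)
    }
  }

  # lymph-node metastases: nests plus leading-edge band, clipped to the node
  if (length(nodal_nests) > 0) {
    geom <- poly_union(geom, .lymph_node_geometry(regions, nodal_nests,
                                                  node_ps, config))
  }
  for (i in which(regions$region_class == "lymph_node")) {
    comp[[length(comp) + 1]] <- .component_row(
      regions$region_id[i],
      if (length(nodal_nests) > 0) "included" else "excluded",
      if (length(nodal_nests) > 0) "contains_metastasis" else "no_metastasis")
  }

  for (i in which(regions$region_class == "lymphovascular_space")) {
    comp[[length(comp) + 1]] <- .component_row(
      regions$region_id[i], "excluded", "vascular_space_not_tumor_area")
  }

  # artifacts are always carved out, wherever they fall
  geom <- poly_minus(geom, exclusions)
  for (i in which(regions$region_class %in% .EXCLUDED_REGION_CLASSES)) {
    comp[[length(comp) + 1]] <- .component_row(
      regions$region_id[i], "excluded", "artifact_excluded")
  }

  # non-neoplastic tissue swallowed by a field-rule corridor
  for (i in which(regions$region_class == "non_neoplastic")) {
    ps <- region_polyset(regions, i)
    if (poly_intersects(ps, geom)) {
      comp[[length(comp) + 1]] <- .component_row(
        regions$region_id[i], "merged_intervening", "field_rule_corridor")
    } else {
      comp[[length(comp) + 1]] <- .component_row(
        regions$region_id[i], "excluded", "outside_tumor_area")
    }
  }

  components <- if (length(comp) > 0) dplyr::bind_rows(comp) else
    .component_row(character(), character(), character())
  components <- components[order(components$region_id), , drop = FALSE]
  new_tumor_area(geom, components, config)
}

.lymph_node_geometry <- function(regions, nodal_nest_idx, node_ps, config) {
  nests_ps <- list()
  for (i in nodal_nest_idx) {
    nests_ps <- poly_union(nests_ps, region_polyset(regions, i))
  }
  g <- if (config$apply_field_rule && length(nodal_nest_idx) > 1) {
    poly_close(nests_ps, config$field_diameter_10x,
               arctol = config$arc_tolerance)
  } else {
    nests_ps
  }
  band <- if (config$leading_edge_margin > 0) {
    poly_offset(nests_ps, config$leading_edge_margin,
                arctol = config$arc_tolerance)
  } else {
    nests_ps
  }
  poly_intersect(poly_union(g, band), node_ps)
}

#' Tumor area for lymph-node metastases
#'
#' For nests of metastatic tumor inside a lymph node: multiple nests in one
#' node are merged under the 10x field rule; the tumor area is the nest
#' union plus a band of width `leading_edge_margin` around each nest
#' boundary (the zone of immediately adjacent immune cells), clipped to the
#' lymph-node polygon. Immune cells outside that band are not
#' tumor-associated.
#'
#' @inheritParams build_tumor_area
#' @return object of class `tumor_area`
#' @export
lymph_node_tumor_area <- function(slide, config = NULL) {
  stopifnot(inherits(slide, "slide_annotation"))
  if (is.null(config)) {
    config <- field_rule_config(field_diameter_10x = slide$field_diameter_10x)
  }
  regions <- slide$regions
  node_ps <- regions_polyset(regions, "lymph_node")
  if (length(node_ps) == 0) .unscorable("slide has no lymph_node region")
  nodal <- .nests_inside(regions, node_ps)
  if (length(nodal) == 0) .unscorable("lymph node contains no tumor nest")
  geom <- .lymph_node_geometry(regions, nodal, node_ps, config)
  geom <- poly_minus(geom, regions_polyset(regions, .EXCLUDED_REGION_CLASSES))
  comp <- dplyr::bind_rows(
    .component_row(regions$region_id[nodal], "included",
                   "lymph_node_metastasis"),
    .component_row(
      regions$region_id[regions$region_class == "lymph_node"],
      "included", "leading_edge_band_clip"))
  new_tumor_area(geom, comp[order(comp$region_id), , drop = FALSE], config)
}

#' Export the component ledger to CSV
#' @param ta a `tumor_area`
#' @param path output file
#' @export
write_component_ledger <- function(ta, path) {
  readr::write_csv(ta$components, path)
  invisible(path)
}
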