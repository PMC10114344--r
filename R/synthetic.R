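# Synthetic slide and reader-panel generator.
#
# Emits valid annotated slides with analytic ground-truth TAP/CPS so every
# other module is testable without external data. Default slides emulate the
# precision-study material: gastric/GEJ adenocarcinoma resections spanning
# the TAP range, with borderline cases around the 5% cutoff, plus biopsies.
#
# Ground-truth strategy: nests are convex (perturbed ellipses through a
# convex hull) and nest+stroma units are placed farther apart than one 10x
# field, so the field-rule closing is the identity and the denominator is a
# closed-form sum (scaled-polygon stroma annuli, shoelace nest areas,
# Steiner formula for lymph-node leading-edge bands). The `clustered_nests`
# scenario drops the separation guarantee to stress the merging geometry;
# for those slides the denominator ground truth is the rasterized
# brute-force closing, never the vector engine under test.

#' Parameters for the synthetic slide generator
#'
#' Defaults are the study conditions the generator emulates: gastric
#' adenocarcinoma resections, a few convex tumor nests of a few hundred
#' micrometers radius, 40% tumor-associated stroma, tumor-cell density
#' 5000/mm^2 in nests, immune-cell density 1500/mm^2 over nests and stroma
#' with a lymphocyte-dominated class mix, and low baseline positive
#' fractions.
#'
#' @param indication `"gastric"`, `"GEJ"` or `"ESCC"`
#' @param specimen_type `"resection"` or `"biopsy"` (biopsies get fewer,
#'   smaller nests)
#' @param n_nests number of tumor nests
#' @param nest_radius_mean,nest_radius_sd nest radius distribution, um
#' @param stromal_fraction proportion of each tumor unit that is stroma
#' @param tc_density viable tumor cells per mm^2 of nest
#' @param ic_density immune cells per mm^2 of tumor unit (nest + stroma)
#' @param ic_class_mix named proportions over immune-cell classes
#' @param tc_positive_fraction,ic_positive_fraction probability that a
#'   tumor cell / immune cell stains positive
#' @param target_tap if non-NULL, positive fractions are calibrated so the
#'   expected TAP equals this percentage (overrides the two fractions)
#' @param artifact_fractions named vector: fraction of each nest's area
#'   carved out as `necrosis`, `crush`, `cautery`
#' @param lymph_node add a lymph-node unit with a discrete metastasis and
#'   leading-edge immune cells
#' @param mucin_pools carve a mucin pool (hole + region) into the first nest
#' @param intraluminal_macrophages add a glandular lumen with macrophages,
#'   half of which fill the lumen and contact tumor cells
#' @param germinal_centers add a lymphoid aggregate with a germinal center
#'   inside the first stroma band
#' @param granulocyte_only_positivity make every positive immune cell a
#'   granulocyte (the TAP-vs-CPS divergence scenario)
#' @param clustered_nests place nests within one 10x field of each other so
#'   the field rule merges them
#' @param field_diameter_10x 10x field diameter, um
#' @param leading_edge_margin lymph-node leading-edge band width, um
#' @param seed integer seed; all randomness flows from it
#' @return list of class `slide_gen_params`
#' @export
slide_gen_params <- function(indication = "gastric",
                             specimen_type = "resection",
                             n_nests = 3,
                             nest_radius_mean = 300,
                             nest_radius_sd = 60,
                             stromal_fraction = 0.4,
                             tc_density = 5000,
                             ic_density = 1500,
                             ic_class_mix = c(lymphocyte = 0.60,
                                              macrophage = 0.25,
                                              granulocyte = 0.10,
                                              plasma_cell = 0.05),
                             tc_positive_fraction = 0.05,
                             ic_positive_fraction = 0.10,
                             target_tap = NULL,
                             artifact_fractions = c(necrosis = 0, crush = 0,
                                                    cautery = 0),
                             lymph_node = FALSE,
                             mucin_pools = FALSE,
                             intraluminal_macrophages = FALSE,
                             germinal_centers = FALSE,
                             granulocyte_only_positivity = FALSE,
                             clustered_nests = FALSE,
                             field_diameter_10x = 2000,
                             leading_edge_margin = 50,
                             seed = 1L) {
  indication <- match.arg(indication, .INDICATIONS)
  specimen_type <- match.arg(specimen_type, .SPECIMEN_TYPES)
  stopifnot(n_nests >= 1, nest_radius_mean > 0, nest_radius_sd >= 0,
            stromal_fraction >= 0, stromal_fraction < 1,
            tc_density >= 0, ic_density >= 0,
            tc_positive_fraction >= 0, tc_positive_fraction <= 1,
            ic_positive_fraction >= 0, ic_positive_fraction <= 1,
            all(artifact_fractions >= 0), all(artifact_fractions <= 0.5),
            abs(sum(ic_class_mix) - 1) < 1e-8)
  if (specimen_type == "biopsy") {
    n_nests <- min(n_nests, 2L)
    nest_radius_mean <- min(nest_radius_mean, 180)
  }
  structure(as.list(environment()), class = "slide_gen_params")
}

# convex perturbed-ellipse nest polygon
.gen_nest_ring <- function(cx, cy, r, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  aspect <- stats::runif(1, 0.7, 1.0)
  rot <- stats::runif(1, 0, pi)
  rad <- r * (1 + stats::runif(n, -0.15, 0.15))
  x0 <- rad * cos(th); y0 <- rad * aspect * sin(th)
  x <- cx + x0 * cos(rot) - y0 * sin(rot)
  y <- cy + x0 * sin(rot) + y0 * cos(rot)
  h <- grDevices::chull(x, y)
  list(x = x[h], y = y[h])
}

# uniform points inside a ring by bbox rejection
.points_in_ring <- function(n, ring) {
  if (n <= 0) return(cbind(x = numeric(), y = numeric()))
  bb <- poly_bbox(list(ring))
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(2L * (n - length(out_x)), 16L)
    px <- stats::runif(m, bb["xmin"], bb["xmax"])
    py <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- points_in_polyset(px, py, list(ring))
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

# uniform points in an annulus-like polyset (outer minus inner rings)
.points_in_polyset_uniform <- function(n, ps) {
  if (n <= 0) return(cbind(x = numeric(), y = numeric()))
  bb <- poly_bbox(ps)
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(4L * (n - length(out_x)), 32L)
    px <- stats::runif(m, bb["xmin"], bb["xmax"])
    py <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- points_in_polyset(px, py, ps)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

.stain_tc <- function(n, positive) {
  membrane <- rep("none", n)
  cyto <- rep(FALSE, n)
  intensity <- rep(0L, n)
  if (any(positive)) {
    membrane[positive] <- sample(c("partial", "circumferential"),
                                 sum(positive), replace = TRUE)
    intensity[positive] <- sample(1:3, sum(positive), replace = TRUE)
  }
  neg <- which(!positive)
  # some negative tumor cells show cytoplasmic-only staining, which the
  # tumor-cell rule disregards
  if (length(neg) > 0) {
    cy <- neg[stats::runif(length(neg)) < 0.1]
    cyto[cy] <- TRUE
    intensity[cy] <- 1L
  }
  list(membrane = membrane, cyto = cyto, punctate = rep(FALSE, n),
       intensity = intensity)
}

.stain_ic <- function(n, positive) {
  membrane <- rep("none", n)
  cyto <- rep(FALSE, n)
  punct <- rep(FALSE, n)
  intensity <- rep(0L, n)
  if (any(positive)) {
    kind <- sample(c("membranous", "cytoplasmic", "punctate"),
                   sum(positive), replace = TRUE)
    idx <- which(positive)
    membrane[idx[kind == "membranous"]] <- "partial"
    cyto[idx[kind == "cytoplasmic"]] <- TRUE
    punct[idx[kind == "punctate"]] <- TRUE
    intensity[idx] <- sample(1:3, length(idx), replace = TRUE)
  }
  list(membrane = membrane, cyto = cyto, punctate = punct,
       intensity = intensity)
}

# Calibrate (tc, ic) positive fractions so expected positive area hits the
# target TAP, preferring ~70% of the positive area from tumor cells.
.calibrate_fractions <- function(target_tap, total_area, nest_area,
                                 unit_area, p) {
  fp <- default_footprints()
  fp_ic <- sum(fp[names(p$ic_class_mix)] * p$ic_class_mix)
  need <- target_tap / 100 * total_area
  tc_cap <- p$tc_density * 1e-6 * nest_area * fp["tumor_cell"]
  ic_cap <- p$ic_density * 1e-6 * unit_area * fp_ic
  p_tc <- if (tc_cap > 0) min(1, 0.7 * need / tc_cap) else 0
  rem <- need - p_tc * tc_cap
  p_ic <- if (ic_cap > 0) min(1, max(0, rem / ic_cap)) else 0
  rem2 <- need - p_tc * tc_cap - p_ic * ic_cap
  if (rem2 > 0 && tc_cap > 0) p_tc <- min(1, p_tc + rem2 / tc_cap)
  c(tc = unname(p_tc), ic = unname(p_ic))
}

#' Generate a synthetic annotated slide with ground truth
#'
#' Emits a valid [slide_annotation()] and the analytic ground truth of its
#' scores. Deterministic for a fixed seed. See [slide_gen_params()] for the
#' scenario flags.
#'
#' @param params a [slide_gen_params()]
#' @return list with elements `slide` (a `slide_annotation`) and `truth`
#'   (list: true_tap, true_cps, tumor_area, positive_area, n_viable_tc,
#'   n_positive_tc, n_positive_ic, components)
#' @export
generate_slide <- function(params = slide_gen_params()) {
  stopifnot(inherits(params, "slide_gen_params"))
  withr::with_seed(params$seed, .generate_slide_impl(params))
}

.generate_slide_impl <- function(p) {
  fp <- default_footprints()
  s_outer <- 1 / sqrt(1 - p$stromal_fraction)
  radii <- pmax(80, stats::rnorm(p$n_nests, p$nest_radius_mean,
                                 p$nest_radius_sd))
  max_outer <- max(radii) * 1.15 * s_outer
  gap <- if (p$clustered_nests) {
    stats::runif(1, 0.2, 0.8) * p$field_diameter_10x
  } else {
    p$field_diameter_10x + 200
  }
  spacing <- 2 * max_outer + gap
  ncol_grid <- ceiling(sqrt(p$n_nests))
  centers <- cbind(
    x = (((seq_len(p$n_nests) - 1) %% ncol_grid)) * spacing + max_outer + 50,
    y = (((seq_len(p$n_nests) - 1) %/% ncol_grid)) * spacing + max_outer + 50)

  regions <- empty_region_table()
  cells <- list()
  truth_pos_area <- 0
  truth_area <- 0
  n_viable_tc <- 0L
  n_pos_tc <- 0L
  n_pos_ic_all <- 0L
  n_pos_ic_mono <- 0L
  comp_areas <- list()
  cell_no <- 0L

  nest_rings <- vector("list", p$n_nests)
  unit_rings <- vector("list", p$n_nests)
  for (k in seq_len(p$n_nests)) {
    nest_rings[[k]] <- .gen_nest_ring(centers[k, 1], centers[k, 2], radii[k])
    unit_rings[[k]] <- ring_scale(nest_rings[[k]], s_outer)
  }
  nest_areas <- vapply(nest_rings, function(r) abs(ring_signed_area(r)),
                       numeric(1))
  unit_areas <- nest_areas * s_outer^2

  # calibration happens against the separated-unit analytic denominator
  necro_frac <- unname(p$artifact_fractions["necrosis"])
  if (is.na(necro_frac)) necro_frac <- 0
  analytic_area <- sum(unit_areas) - necro_frac * sum(nest_areas)
  p_frac <- if (!is.null(p$target_tap)) {
    .calibrate_fractions(p$target_tap, analytic_area,
                         sum(nest_areas) * (1 - necro_frac),
                         sum(unit_areas), p)
  } else {
    c(tc = p$tc_positive_fraction, ic = p$ic_positive_fraction)
  }

  next_cell_id <- function() {
    cell_no <<- cell_no + 1L
    sprintf("c%05d", cell_no)
  }

  for (k in seq_len(p$n_nests)) {
    nest <- nest_rings[[k]]
    outer <- unit_rings[[k]]
    nest_id <- sprintf("nest_%02d", k)
    holes_k <- list()

    # necrosis carved out of the nest center
    necro_ring <- NULL
    if (necro_frac > 0) {
      cc <- ring_centroid(nest)
      nr <- sqrt(necro_frac * nest_areas[k] / pi)
      necro_ring <- circle_ring(cc[1], cc[2], nr, 48L)
      regions <- dplyr::bind_rows(regions, region_table(
        sprintf("necrosis_%02d", k), "necrosis", list(necro_ring)))
    }

    # mucin pool: hole in the nest plus a mucin region (included in area)
    if (p$mucin_pools && k == 1L) {
      cc <- ring_centroid(nest)
      mr <- sqrt(0.08 * nest_areas[k] / pi)
      off <- radii[k] * 0.35
      mucin_ring <- circle_ring(cc[1] + off, cc[2], mr, 40L)
      holes_k <- c(holes_k, list(mucin_ring))
      regions <- dplyr::bind_rows(regions, region_table(
        "mucin_01", "mucin_pool", list(mucin_ring)))
    }

    lumen_ring <- NULL
    if (p$intraluminal_macrophages && k == 1L) {
      cc <- ring_centroid(nest)
      lr <- sqrt(0.05 * nest_areas[k] / pi)
      off <- radii[k] * 0.35
      lumen_ring <- circle_ring(cc[1] - off, cc[2], lr, 40L)
      holes_k <- c(holes_k, list(lumen_ring))
      regions <- dplyr::bind_rows(regions, region_table(
        "lumen_01", "glandular_lumen", list(lumen_ring)))
    }

    regions <- dplyr::bind_rows(regions, region_table(
      nest_id, "tumor_nest", list(nest), list(holes_k)))
    regions <- dplyr::bind_rows(regions, region_table(
      sprintf("stroma_%02d", k), "tumor_stroma", list(outer),
      list(list(nest))))

    # tumor cells in the nest (excluding carved holes)
    n_tc <- stats::rpois(1, p$tc_density * 1e-6 * nest_areas[k])
    if (n_tc > 0) {
      pts <- .points_in_ring(n_tc, nest)
      in_hole <- rep(FALSE, n_tc)
      for (h in holes_k) in_hole <- in_hole | points_in_polyset(
        pts[, 1], pts[, 2], list(h))
      necrotic <- if (!is.null(necro_ring)) {
        points_in_polyset(pts[, 1], pts[, 2], list(necro_ring))
      } else rep(FALSE, n_tc)
      keep <- !in_hole
      pts <- pts[keep, , drop = FALSE]; necrotic <- necrotic[keep]
      n_tc <- nrow(pts)
      positive <- stats::runif(n_tc) < p_frac["tc"] & !necrotic
      st <- .stain_tc(n_tc, positive)
      cells[[length(cells) + 1]] <- tibble::tibble(
        cell_id = vapply(seq_len(n_tc), function(i) next_cell_id(),
                         character(1)),
        cell_class = "tumor_cell",
        viability = ifelse(necrotic, "necrotic", "viable"),
        x = pts[, 1], y = pts[, 2],
        footprint_area = fp[["tumor_cell"]],
        membrane_stain = st$membrane, cytoplasmic_stain = st$cyto,
        punctate_stain = st$punctate, stain_intensity = st$intensity,
        context = "tumor_proper", fills_lumen_and_contacts_tc = FALSE)
      n_viable_tc <- n_viable_tc + sum(!necrotic)
      n_pos_tc <- n_pos_tc + sum(positive)
      truth_pos_area <- truth_pos_area + sum(positive) * fp[["tumor_cell"]]
    }

    # immune cells over the whole unit (nest interior counts as intra-tumoral)
    n_ic <- stats::rpois(1, p$ic_density * 1e-6 * unit_areas[k])
    if (n_ic > 0) {
      pts <- .points_in_ring(n_ic, outer)
      drop_ic <- rep(FALSE, n_ic)
      for (h in holes_k) drop_ic <- drop_ic | points_in_polyset(
        pts[, 1], pts[, 2], list(h))
      if (!is.null(necro_ring)) {
        drop_ic <- drop_ic | points_in_polyset(pts[, 1], pts[, 2],
                                               list(necro_ring))
      }
      pts <- pts[!drop_ic, , drop = FALSE]
      n_ic <- nrow(pts)
      in_nest <- points_in_polyset(pts[, 1], pts[, 2], list(nest))
      classes <- sample(names(p$ic_class_mix), n_ic, replace = TRUE,
                        prob = p$ic_class_mix)
      positive <- stats::runif(n_ic) < p_frac["ic"]
      if (p$granulocyte_only_positivity) classes[positive] <- "granulocyte"
      st <- .stain_ic(n_ic, positive)
      cells[[length(cells) + 1]] <- tibble::tibble(
        cell_id = vapply(seq_len(n_ic), function(i) next_cell_id(),
                         character(1)),
        cell_class = classes, viability = "viable",
        x = pts[, 1], y = pts[, 2],
        footprint_area = unname(fp[classes]),
        membrane_stain = st$membrane, cytoplasmic_stain = st$cyto,
        punctate_stain = st$punctate, stain_intensity = st$intensity,
        context = ifelse(in_nest, "tumor_proper", "stroma"),
        fills_lumen_and_contacts_tc = FALSE)
      n_pos_ic_all <- n_pos_ic_all + sum(positive)
      n_pos_ic_mono <- n_pos_ic_mono +
        sum(positive & classes %in% .CPS_IC_CLASSES)
      truth_pos_area <- truth_pos_area + sum(fp[classes][positive])
    }

    # intraluminal macrophages: half fill the lumen and contact tumor cells
    if (!is.null(lumen_ring)) {
      n_mac <- 8L
      pts <- .points_in_ring(n_mac, lumen_ring)
      fills <- seq_len(n_mac) <= n_mac / 2
      positive <- rep(TRUE, n_mac)
      st <- .stain_ic(n_mac, positive)
      cells[[length(cells) + 1]] <- tibble::tibble(
        cell_id = vapply(seq_len(n_mac), function(i) next_cell_id(),
                         character(1)),
        cell_class = "macrophage", viability = "viable",
        x = pts[, 1], y = pts[, 2],
        footprint_area = fp[["macrophage"]],
        membrane_stain = st$membrane, cytoplasmic_stain = st$cyto,
        punctate_stain = st$punctate, stain_intensity = st$intensity,
        context = "lumen", fills_lumen_and_contacts_tc = fills)
      n_pos_ic_all <- n_pos_ic_all + sum(fills)
      n_pos_ic_mono <- n_pos_ic_mono + sum(fills)
      truth_pos_area <- truth_pos_area + sum(fills) * fp[["macrophage"]]
    }

    comp_areas[[length(comp_areas) + 1]] <- tibble::tibble(
      component = nest_id, area = unit_areas[k] -
        necro_frac * nest_areas[k])
    truth_area <- truth_area + unit_areas[k] - necro_frac * nest_areas[k]
  }

  # germinal center inside the first stroma band (area already counted)
  if (p$germinal_centers) {
    nest <- nest_rings[[1]]
    outer <- unit_rings[[1]]
    # midpoint between a nest vertex and its scaled image lies inside the
    # convex stroma annulus whatever the nest's aspect or rotation
    acx <- (nest$x[1] + outer$x[1]) / 2
    acy <- (nest$y[1] + outer$y[1]) / 2
    band_w <- sqrt((outer$x[1] - nest$x[1])^2 + (outer$y[1] - nest$y[1])^2)
    agg_r <- min(40, band_w * 0.4)
    agg <- circle_ring(acx, acy, agg_r, 40L)
    gc_ring <- circle_ring(acx, acy, agg_r * 0.5, 32L)
    regions <- dplyr::bind_rows(
      regions,
      region_table("lymphagg_01", "lymphoid_aggregate", list(agg)),
      region_table("gc_01", "germinal_center", list(gc_ring)))
    n_gc <- 12L
    pts <- .points_in_ring(n_gc, gc_ring)
    positive <- rep(TRUE, n_gc)
    st <- .stain_ic(n_gc, positive)
    cells[[length(cells) + 1]] <- tibble::tibble(
      cell_id = vapply(seq_len(n_gc), function(i) next_cell_id(),
                       character(1)),
      cell_class = "lymphocyte", viability = "viable",
      x = pts[, 1], y = pts[, 2], footprint_area = fp[["lymphocyte"]],
      membrane_stain = st$membrane, cytoplasmic_stain = st$cyto,
      punctate_stain = st$punctate, stain_intensity = st$intensity,
      context = "germinal_center", fills_lumen_and_contacts_tc = FALSE)
    if (p$indication %in% c("gastric", "GEJ")) {
      n_pos_ic_all <- n_pos_ic_all + n_gc
      truth_pos_area <- truth_pos_area + n_gc * fp[["lymphocyte"]]
    }
  }

  # lymph-node unit: discrete metastasis plus leading-edge band
  if (p$lymph_node) {
    node_cx <- max(centers[, 1]) + spacing + 800
    node_cy <- centers[1, 2]
    node_r <- 600
    met_r <- 180
    node_ring <- circle_ring(node_cx, node_cy, node_r, 96L)
    met <- .gen_nest_ring(node_cx, node_cy, met_r)
    regions <- dplyr::bind_rows(
      regions,
      region_table("node_01", "lymph_node", list(node_ring)),
      region_table("nest_node_01", "tumor_nest", list(met)))
    met_area <- abs(ring_signed_area(met))
    met_per <- ring_perimeter(met)
    band_area <- met_per * p$leading_edge_margin +
      pi * p$leading_edge_margin^2
    truth_area <- truth_area + met_area + band_area
    comp_areas[[length(comp_areas) + 1]] <- tibble::tibble(
      component = "node_metastasis", area = met_area + band_area)

    n_tc <- stats::rpois(1, p$tc_density * 1e-6 * met_area)
    if (n_tc > 0) {
      pts <- .points_in_ring(n_tc, met)
      positive <- stats::runif(n_tc) < p_frac["tc"]
      st <- .stain_tc(n_tc, positive)
      cells[[length(cells) + 1]] <- tibble::tibble(
        cell_id = vapply(seq_len(n_tc), function(i) next_cell_id(),
                         character(1)),
        cell_class = "tumor_cell", viability = "viable",
        x = pts[, 1], y = pts[, 2], footprint_area = fp[["tumor_cell"]],
        membrane_stain = st$membrane, cytoplasmic_stain = st$cyto,
        punctate_stain = st$punctate, stain_intensity = st$intensity,
        context = "tumor_proper", fills_lumen_and_contacts_tc = FALSE)
      n_viable_tc <- n_viable_tc + n_tc
      n_pos_tc <- n_pos_tc + sum(positive)
      truth_pos_area <- truth_pos_area + sum(positive) * fp[["tumor_cell"]]
    }
    # leading-edge lymphocytes (in the band) and distant nodal lymphocytes
    band_ps <- poly_minus(poly_offset(list(met), p$leading_edge_margin,
                                      arctol = 0.1), list(met))
    n_band <- 30L
    pts <- .points_in_polyset_uniform(n_band, band_ps)
    positive <- stats::runif(n_band) < max(p_frac["ic"], 0.3)
    st <- .stain_ic(n_band, positive)
    cells[[length(cells) + 1]] <- tibble::tibble(
      cell_id = vapply(seq_len(n_band), function(i) next_cell_id(),
                       character(1)),
      cell_class = "lymphocyte", viability = "viable",
      x = pts[, 1], y = pts[, 2], footprint_area = fp[["lymphocyte"]],
      membrane_stain = st$membrane, cytoplasmic_stain = st$cyto,
      punctate_stain = st$punctate, stain_intensity = st$intensity,
      context = "stroma", fills_lumen_and_contacts_tc = FALSE)
    n_pos_ic_all <- n_pos_ic_all + sum(positive)
    n_pos_ic_mono <- n_pos_ic_mono + sum(positive)
    truth_pos_area <- truth_pos_area + sum(positive) * fp[["lymphocyte"]]
    # distant nodal immune cells: inside the node, beyond the band, all
    # stained — none of them tumor-associated
    n_far <- 40L
    far_r <- stats::runif(n_far, met_r * 1.3 + p$leading_edge_margin + 40,
                          node_r - 20)
    far_th <- stats::runif(n_far, 0, 2 * pi)
    st <- .stain_ic(n_far, rep(TRUE, n_far))
    cells[[length(cells) + 1]] <- tibble::tibble(
      cell_id = vapply(seq_len(n_far), function(i) next_cell_id(),
                       character(1)),
      cell_class = "lymphocyte", viability = "viable",
      x = node_cx + far_r * cos(far_th), y = node_cy + far_r * sin(far_th),
      footprint_area = fp[["lymphocyte"]],
      membrane_stain = st$membrane, cytoplasmic_stain = st$cyto,
      punctate_stain = st$punctate, stain_intensity = st$intensity,
      context = "outside_tumor", fills_lumen_and_contacts_tc = FALSE)
  }

  cells <- if (length(cells) > 0) dplyr::bind_rows(cells) else
    cell_table(tibble::tibble())

  slide <- slide_annotation(
    slide_id = sprintf("synthetic_seed%d", p$seed),
    indication = p$indication, specimen_type = p$specimen_type,
    cells = cells, regions = regions,
    field_diameter_10x = p$field_diameter_10x)

  if (p$clustered_nests) {
    # merging geometry has no closed form; ground-truth denominator is the
    # rasterized brute-force closing (independent of the vector engine)
    truth_area <- rasterize_tumor_area(slide, field_rule_config(
      field_diameter_10x = p$field_diameter_10x,
      leading_edge_margin = p$leading_edge_margin), pixel_size = 2)
  }

  true_tap <- min(100, 100 * truth_pos_area / truth_area)
  true_cps <- if (n_viable_tc > 0) {
    min(100, 100 * (n_pos_tc + n_pos_ic_mono) / n_viable_tc)
  } else NA_real_
  list(slide = slide,
       truth = list(true_tap = true_tap, true_cps = true_cps,
                    tumor_area = truth_area,
                    positive_area = truth_pos_area,
                    n_viable_tc = n_viable_tc, n_positive_tc = n_pos_tc,
                    n_positive_ic = n_pos_ic_all,
                    n_positive_mononuclear_ic = n_pos_ic_mono,
                    components = dplyr::bind_rows(comp_areas)))
}

#' Generate a precision-study cohort
#'
#' Emulates the reader-study sample sets: a requested number of samples
#' with an exact split of positives and negatives at the 5% cutoff, a
#' fraction of borderline samples (true TAP in \[2, 10), split evenly
#' between negative- and positive-borderline), and a fraction of biopsies.
#' Per-slide targets are drawn and slides regenerated (bounded retries with
#' derived sub-seeds) until the realized analytic TAP lands in the required
#' class, so the composition is exact by construction.
#'
#' @param n_samples cohort size
#' @param positive_fraction fraction positive at the 5% cutoff
#' @param borderline_fraction fraction with true TAP in \[2, 10)
#' @param biopsy_fraction fraction of biopsy specimens
#' @param seed master seed; per-slide seeds are derived from it
#' @param base_params [slide_gen_params()] template for per-slide settings
#' @return tibble: sample_id, specimen_type, positive, borderline,
#'   target_tap, true_tap, true_cps, slide (list), truth (list)
#' @export
generate_study_cohort <- function(n_samples = 100,
                                  positive_fraction = 0.5,
                                  borderline_fraction = 0.1,
                                  biopsy_fraction = 0.1,
                                  seed = 1L,
                                  base_params = slide_gen_params()) {
  stopifnot(n_samples >= 1,
            positive_fraction >= 0, positive_fraction <= 1,
            borderline_fraction >= 0, borderline_fraction <= 1,
            biopsy_fraction >= 0, biopsy_fraction <= 1)
  n_pos <- round(n_samples * positive_fraction)
  n_neg <- n_samples - n_pos
  n_border <- round(n_samples * borderline_fraction)
  nb_pos <- min(n_pos, ceiling(n_border / 2))
  nb_neg <- min(n_neg, n_border - nb_pos)
  if (nb_pos + nb_neg < n_border) {
    stop("incompatible positive/borderline fractions", call. = FALSE)
  }
  n_biopsy <- round(n_samples * biopsy_fraction)

  plan <- withr::with_seed(seed, {
    pos_flag <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    border_flag <- c(rep(TRUE, nb_pos), rep(FALSE, n_pos - nb_pos),
                     rep(TRUE, nb_neg), rep(FALSE, n_neg - nb_neg))
    targets <- numeric(n_samples)
    targets[pos_flag & border_flag] <- stats::runif(nb_pos, 5.8, 9.2)
    targets[pos_flag & !border_flag] <- stats::runif(n_pos - nb_pos, 11, 60)
    targets[!pos_flag & border_flag] <- stats::runif(nb_neg, 2.4, 4.4)
    targets[!pos_flag & !border_flag] <- stats::runif(n_neg - nb_neg, 0.1, 1.7)
    biopsy <- rep(FALSE, n_samples)
    biopsy[sample.int(n_samples, n_biopsy)] <- TRUE
    sub_seeds <- sample.int(.Machine$integer.max %/% 2, n_samples)
    list(pos = pos_flag, border = border_flag, targets = targets,
         biopsy = biopsy, sub_seeds = sub_seeds)
  })

  in_class <- function(tap, positive, border) {
    if (positive && border) tap >= 5 && tap < 10
    else if (positive) tap >= 5
    else if (border) tap >= 2 && tap < 5
    else tap < 5 && tap < 2
  }

  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    for (attempt in 0:9) {
      pars <- base_params
      pars$seed <- (plan$sub_seeds[i] + attempt * 1000003L) %%
        .Machine$integer.max
      pars$target_tap <- plan$targets[i]
      pars$specimen_type <- if (plan$biopsy[i]) "biopsy" else "resection"
      if (pars$specimen_type == "biopsy") {
        pars$n_nests <- min(pars$n_nests, 2L)
        pars$nest_radius_mean <- min(pars$nest_radius_mean, 180)
      }
      gen <- generate_slide(pars)
      if (in_class(gen$truth$true_tap, plan$pos[i], plan$border[i])) break
    }
    rows[[i]] <- tibble::tibble(
      sample_id = sprintf("s%03d", i),
      specimen_type = pars$specimen_type,
      positive = plan$pos[i], borderline = plan$border[i],
      target_tap = plan$targets[i],
      true_tap = gen$truth$true_tap, true_cps = gen$truth$true_cps,
      slide = list(gen$slide), truth = list(gen$truth))
  }
  dplyr::bind_rows(rows)
}

#' Reader noise model
#'
#' Perturbs the latent continuous TAP on the logit scale and adds a
#' near-cutoff misclassification mechanism: with probability
#' `flip_prob * exp(-|tap - cutoff| / flip_scale)` the perturbed score is
#' reflected across the cutoff, so disagreements concentrate on borderline
#' samples. The zero-noise model reproduces the truth exactly.
#'
#' @param logit_sd standard deviation of the logit-scale perturbation
#' @param flip_prob maximum flip probability at the cutoff
#' @param flip_scale e-folding distance (TAP points) of the flip probability
#' @return list of class `reader_noise_model`
#' @export
reader_noise_model <- function(logit_sd = 0, flip_prob = 0, flip_scale = 2) {
  stopifnot(logit_sd >= 0, flip_prob >= 0, flip_prob <= 1, flip_scale > 0)
  structure(list(logit_sd = logit_sd, flip_prob = flip_prob,
                 flip_scale = flip_scale), class = "reader_noise_model")
}

#' Simulate a reader panel
#'
#' Applies the noise model independently per (sample, reader, round) to the
#' true TAP scores and returns a long-format [reader_score_matrix()].
#' Deterministic for a fixed seed; zero noise reproduces the truth for
#' every reader and round.
#'
#' @param truths numeric vector of true TAP percentages, or a cohort tibble
#'   from [generate_study_cohort()] (its `true_tap` column is used)
#' @param n_readers,n_rounds panel design
#' @param noise a [reader_noise_model()]
#' @param cutoff positivity cutoff for the derived binary calls
#' @param seed integer seed
#' @param site optional site label stored with every row
#' @return a [reader_score_matrix()]
#' @export
simulate_reader_scores <- function(truths, n_readers = 3, n_rounds = 1,
                                   noise = reader_noise_model(),
                                   cutoff = 5, seed = 1L, site = NA) {
  stopifnot(n_readers >= 1, n_rounds >= 1)
  if (is.data.frame(truths)) {
    sample_ids <- truths$sample_id
    truths <- truths$true_tap
  } else {
    sample_ids <- sprintf("s%03d", seq_along(truths))
  }
  rows <- withr::with_seed(seed, {
    out <- list()
    for (r in seq_len(n_readers)) {
      for (rd in seq_len(n_rounds)) {
        score <- truths
        if (noise$logit_sd > 0) {
          pr <- pmin(pmax(truths / 100, 1e-4), 1 - 1e-4)
          score <- 100 * stats::plogis(stats::qlogis(pr) +
            stats::rnorm(length(truths), 0, noise$logit_sd))
          score[truths == 0] <- 0
        }
        if (noise$flip_prob > 0) {
          pflip <- noise$flip_prob *
            exp(-abs(truths - cutoff) / noise$flip_scale)
          do_flip <- stats::runif(length(truths)) < pflip
          score[do_flip] <- pmax(0, cutoff + (cutoff - score[do_flip]) * 0.2 +
                                   ifelse(score[do_flip] >= cutoff, -0.1, 0.1))
        }
        out[[length(out) + 1]] <- tibble::tibble(
          sample_id = sample_ids, reader_id = sprintf("reader_%d", r),
          round = rd, site = site, tap_percent = score)
      }
    }
    dplyr::bind_rows(out)
  })
  reader_score_matrix(rows, cutoff = cutoff)
}
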