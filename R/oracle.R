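# Rasterized brute-force scoring oracle.
#
# Independent of the vector engine at every stage: polygons are burned onto
# a pixel grid with an even-odd scanline fill (not the Clipper booleans),
# and the 10x-field closing is done with exact Euclidean distance
# transforms (EBImage::distmap), not polygon offsets. Used to cross-check
# the polygon-based tumor area and TAP, and as ground truth for the
# clustered-nest generator scenario.

.oracle_guard_px <- 4e8  # pixels; 400 mm^2 at 1 um

.oracle_grid <- function(slide, config, pixel_size) {
  rings <- unlist(lapply(seq_len(nrow(slide$regions)), function(i)
    region_polyset(slide$regions, i)), recursive = FALSE)
  bb <- poly_bbox(rings)
  pad <- config$field_diameter_10x / 2 + config$leading_edge_margin +
    2 * pixel_size
  ox <- bb["xmin"] - pad; oy <- bb["ymin"] - pad
  nx <- ceiling((bb["xmax"] + pad - ox) / pixel_size)
  ny <- ceiling((bb["ymax"] + pad - oy) / pixel_size)
  if (nx * ny > .oracle_guard_px) {
    stop("raster oracle memory guard: slide exceeds 400 mm^2 at the ",
         "requested pixel size", call. = FALSE)
  }
  list(ox = unname(ox), oy = unname(oy), nx = as.integer(nx),
       ny = as.integer(ny), px = pixel_size)
}

# XOR-burn one ring into the mask (even-odd scanline fill). Matrix is
# indexed [row = y, col = x]; pixel centers at origin + (i - 0.5) * px.
.burn_ring <- function(mask, ring, g) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  nxt <- c(2:n, 1)
  j_lo <- max(1L, floor((min(y) - g$oy) / g$px))
  j_hi <- min(g$ny, ceiling((max(y) - g$oy) / g$px) + 1L)
  for (j in j_lo:j_hi) {
    yc <- g$oy + (j - 0.5) * g$px
    str <- which((y > yc) != (y[nxt] > yc))
    if (length(str) == 0) next
    xint <- x[str] + (yc - y[str]) * (x[nxt][str] - x[str]) /
      (y[nxt][str] - y[str])
    xint <- sort(xint)
    for (k in seq(1, length(xint) - 1, by = 2)) {
      i0 <- floor((xint[k] - g$ox) / g$px + 0.5) + 1
      i1 <- ceiling((xint[k + 1] - g$ox) / g$px + 0.5) - 1
      i0 <- max(1L, i0); i1 <- min(g$nx, i1)
      if (i0 <= i1) mask[j, i0:i1] <- !mask[j, i0:i1]
    }
  }
  mask
}

.burn_regions <- function(regions, idx, g) {
  mask <- matrix(FALSE, g$ny, g$nx)
  for (i in idx) {
    for (ring in region_polyset(regions, i)) {
      mask <- .burn_ring(mask, ring, g)
    }
  }
  mask
}

# distance (in pixels) of every pixel to the nearest TRUE pixel of `mask`
.dist_to <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
}

.raster_close <- function(mask, radius_px) {
  if (!any(mask) || radius_px <= 0) return(mask)
  dilated <- .dist_to(mask) <= radius_px
  inner <- EBImage::distmap(matrix(as.numeric(dilated), nrow(mask),
                                   ncol(mask)))
  inner > radius_px
}

# Raster reconstruction of the tumor-area mask, mirroring the inclusion and
# exclusion rules region-by-region.
.oracle_mask <- function(slide, config, g) {
  regions <- slide$regions
  nest_idx <- which(regions$region_class == "tumor_nest")
  if (length(nest_idx) == 0) .unscorable()
  r_px <- (config$field_diameter_10x / 2) / g$px

  node_idx <- which(regions$region_class == "lymph_node")
  nodal <- integer(0)
  if (length(node_idx) > 0) {
    node_mask <- .burn_regions(regions, node_idx, g)
    cent <- t(vapply(nest_idx, function(i) ring_centroid(regions$polygon[[i]]),
                     numeric(2)))
    ci <- pmin(pmax(floor((cent[, 1] - g$ox) / g$px + 0.5) + 1, 1), g$nx)
    cj <- pmin(pmax(floor((cent[, 2] - g$oy) / g$px + 0.5) + 1, 1), g$ny)
    nodal <- nest_idx[node_mask[cbind(cj, ci)]]
  }
  free <- setdiff(nest_idx, nodal)

  mask <- matrix(FALSE, g$ny, g$nx)
  nest_dist <- NULL
  if (length(free) > 0) {
    nests <- .burn_regions(regions, free, g)
    nest_dist <- .dist_to(nests)
    mask <- if (config$apply_field_rule) {
      dilated <- nest_dist <= r_px
      EBImage::distmap(matrix(as.numeric(dilated), g$ny, g$nx)) > r_px
    } else nests
  }

  for (i in which(regions$region_class == "tumor_stroma")) {
    if (is.null(nest_dist)) break
    rm <- .burn_regions(regions, i, g)
    if (any(nest_dist[rm] <= 2 * r_px)) mask <- mask | rm
  }

  inclusion_idx <- which(regions$region_class %in%
                           c("mucin_pool", "glandular_lumen"))
  if (slide$indication %in% c("gastric", "GEJ")) {
    inclusion_idx <- c(inclusion_idx,
                       which(regions$region_class %in%
                               c("lymphoid_aggregate", "germinal_center")))
  }
  touch <- NULL
  for (i in inclusion_idx) {
    rm <- .burn_regions(regions, i, g)
    if (is.null(touch)) touch <- .dist_to(mask)
    if (any(touch[rm] <= 1.5)) {
      mask <- mask | rm
      touch <- NULL  # mask changed; recompute on next contact test
    }
  }

  if (length(nodal) > 0) {
    node_mask <- .burn_regions(regions, node_idx, g)
    nmask <- .burn_regions(regions, nodal, g)
    gmask <- if (config$apply_field_rule && length(nodal) > 1) {
      .raster_close(nmask, r_px)
    } else nmask
    band <- .dist_to(nmask) <= config$leading_edge_margin / g$px
    mask <- mask | ((gmask | band) & node_mask)
  }

  excl_idx <- which(regions$region_class %in% .EXCLUDED_REGION_CLASSES)
  if (length(excl_idx) > 0) {
    mask <- mask & !.burn_regions(regions, excl_idx, g)
  }
  mask
}

#' Rasterized tumor-area measurement
#'
#' Brute-force reconstruction of the tumor area on a pixel grid; the
#' independent cross-check for [build_tumor_area()].
#'
#' @param slide a [slide_annotation()]
#' @param config a [field_rule_config()]
#' @param pixel_size pixel edge in micrometers (use 1-2 um for oracle work)
#' @return tumor area in square micrometers
#' @export
rasterize_tumor_area <- function(slide, config = NULL, pixel_size = 1) {
  if (is.null(config)) {
    config <- field_rule_config(field_diameter_10x = slide$field_diameter_10x)
  }
  g <- .oracle_grid(slide, config, pixel_size)
  sum(.oracle_mask(slide, config, g)) * pixel_size^2
}

#' Rasterized brute-force TAP oracle
#'
#' Recomputes the TAP score entirely on a pixel grid: the tumor-area mask
#' from [rasterize_tumor_area()]'s machinery, and a from-scratch restatement
#' of the positivity/eligibility rules applied to cells whose centroid pixel
#' lies in the mask. Shares no geometry code with [compute_tap()].
#'
#' @inheritParams rasterize_tumor_area
#' @return list: tap_percent, tumor_area, positive_area (micrometer units)
#' @export
rasterize_tap_oracle <- function(slide, config = NULL, pixel_size = 1) {
  if (is.null(config)) {
    config <- field_rule_config(field_diameter_10x = slide$field_diameter_10x)
  }
  g <- .oracle_grid(slide, config, pixel_size)
  mask <- .oracle_mask(slide, config, g)
  area <- sum(mask) * pixel_size^2

  cells <- slide$cells
  pos_area <- 0
  if (nrow(cells) > 0) {
    ci <- pmin(pmax(floor((cells$x - g$ox) / g$px + 0.5) + 1, 1), g$nx)
    cj <- pmin(pmax(floor((cells$y - g$oy) / g$px + 0.5) + 1, 1), g$ny)
    in_mask <- mask[cbind(cj, ci)]
    gastric_gej <- slide$indication %in% c("gastric", "GEJ")
    for (i in seq_len(nrow(cells))) {
      if (!in_mask[i] || cells$viability[i] != "viable") next
      cls <- cells$cell_class[i]
      ctx <- cells$context[i]
      if (cls == "tumor_cell") {
        if (cells$membrane_stain[i] %in% c("partial", "circumferential")) {
          pos_area <- pos_area + cells$footprint_area[i]
        }
      } else if (cls %in% c("lymphocyte", "macrophage", "granulocyte",
                            "plasma_cell")) {
        if (ctx %in% c("vessel_or_lymphatic", "granuloma")) next
        if (cls == "macrophage" && ctx == "lumen" &&
            !isTRUE(cells$fills_lumen_and_contacts_tc[i])) next
        if (ctx == "germinal_center" && !gastric_gej) next
        if (cells$membrane_stain[i] != "none" || cells$cytoplasmic_stain[i] ||
            cells$punctate_stain[i]) {
          pos_area <- pos_area + cells$footprint_area[i]
        }
      }
    }
  }
  list(tap_percent = min(100, 100 * pos_area / area), tumor_area = area,
       positive_area = pos_area)
}

#' Engine-vs-oracle TAP comparison suite
#'
#' Generates random synthetic slides (varied nest counts, clustering,
#' mucin/lumen/artifact scenarios), scores each with the polygon engine and
#' with the rasterized brute-force oracle, and returns both scores per
#' slide. The workhorse behind the geometry-equivalence checks.
#'
#' @param n_slides number of slides
#' @param seed master seed; slide seeds are derived from it
#' @param pixel_size oracle pixel size in micrometers
#' @return tibble: slide_seed, clustered, true_tap, engine_tap, oracle_tap
#' @export
tap_oracle_comparison <- function(n_slides = 50, seed = 1, pixel_size = 1) {
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max %/% 2, n_slides))
  rows <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    clustered <- i %% 2 == 0
    p <- slide_gen_params(
      seed = seeds[i],
      n_nests = if (clustered) 2L else 1L + (i %% 2L),
      nest_radius_mean = 110 + 20 * (i %% 3),
      nest_radius_sd = 25,
      tc_density = 2000, ic_density = 700,
      target_tap = c(1, 3, 5, 8, 15, 30)[1 + i %% 6],
      clustered_nests = clustered,
      mucin_pools = i %% 5 == 0,
      intraluminal_macrophages = i %% 7 == 0,
      germinal_centers = i %% 6 == 0,
      artifact_fractions = c(necrosis = ifelse(i %% 4 == 0, 0.08, 0),
                             crush = 0, cautery = 0))
    gen <- generate_slide(p)
    ta <- build_tumor_area(gen$slide)
    engine <- compute_tap(gen$slide, ta)$tap_percent
    oracle <- rasterize_tap_oracle(gen$slide,
                                   pixel_size = pixel_size)$tap_percent
    rows[[i]] <- tibble::tibble(slide_seed = seeds[i], clustered = clustered,
                                true_tap = gen$truth$true_tap,
                                engine_tap = engine, oracle_tap = oracle)
  }
  dplyr::bind_rows(rows)
}
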