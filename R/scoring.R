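# Cell-level positivity and eligibility rules, and the two scores.
#
# TAP is an area fraction: the area covered by PD-L1 positive tumor cells
# and tumor-associated immune cells, over the total tumor area. CPS is a
# cell-count ratio: positive tumor cells plus positive mononuclear immune
# cells (lymphocytes and macrophages), over viable tumor cells, x100,
# capped at 100.

#' Tumor-cell PD-L1 positivity
#'
#' A tumor cell is positive iff it shows circumferential or partial/lateral
#' membrane staining at any intensity; cytoplasmic staining of tumor cells
#' is disregarded.
#'
#' @param cells cell table rows, all with `cell_class == "tumor_cell"`
#' @return logical vector
#' @export
tc_stain_positive <- function(cells) {
  if (any(cells$cell_class != "tumor_cell")) {
    stop("tc_stain_positive applies only to tumor_cell records", call. = FALSE)
  }
  cells$membrane_stain %in% c("partial", "circumferential")
}

#' Immune-cell PD-L1 positivity
#'
#' A tumor-associated immune cell is positive iff it shows membranous,
#' cytoplasmic, or punctate staining at any intensity.
#'
#' @param cells cell table rows, all with an immune cell class (lymphocyte,
#'   macrophage, granulocyte, plasma_cell, giant_cell)
#' @return logical vector
#' @export
ic_stain_positive <- function(cells) {
  if (any(!cells$cell_class %in% .IC_CLASSES)) {
    stop("ic_stain_positive applies only to immune-cell records",
         call. = FALSE)
  }
  cells$membrane_stain != "none" | cells$cytoplasmic_stain |
    cells$punctate_stain
}

#' Cell eligibility for scoring
#'
#' Applies the eligibility rules to every cell, in a fixed order, reporting
#' the first failing rule: (1) viability — necrotic cells never count;
#' (2) centroid inside the tumor area; (3) cell-class admissibility — the
#' off-target types (fibroblasts, endothelial cells, neuroendocrine cells,
#' smooth muscle, nerves, other) never count whatever their staining;
#' (4) context exclusions — immune cells inside blood vessels or lymphatics,
#' in granulomas, and multinucleated giant cells are excluded; intraluminal
#' macrophages are excluded unless they completely fill the luminal space
#' and directly contact tumor cells; germinal-center immune cells count only
#' for gastric/GEJ adenocarcinoma. In lymph nodes, immune cells in the
#' leading-edge band (inside the tumor area but outside any nest) are
#' eligible with reason `leading_edge_included`.
#'
#' @param slide a [slide_annotation()]
#' @param tumor_area a `tumor_area` built from the slide
#' @return tibble: cell_id, scoreable, role (`"tc"`/`"ic"`/`"none"`), reason
#' @export
cell_eligibility <- function(slide, tumor_area) {
  cells <- slide$cells
  n <- nrow(cells)
  role <- rep("none", n)
  reason <- rep("ok", n)
  scoreable <- rep(FALSE, n)
  if (n == 0) {
    return(tibble::tibble(cell_id = character(), scoreable = logical(),
                          role = character(), reason = character()))
  }
  is_tc <- cells$cell_class == "tumor_cell"
  is_ic <- cells$cell_class %in% .IC_CLASSES
  inside <- tumor_area_contains(tumor_area, cells$x, cells$y)
  gastric_gej <- slide$indication %in% c("gastric", "GEJ")

  has_node <- any(slide$regions$region_class == "lymph_node")
  in_nest <- if (has_node) {
    nest_ps <- regions_polyset(slide$regions, "tumor_nest")
    points_in_polyset(cells$x, cells$y, nest_ps)
  } else rep(TRUE, n)

  for (i in seq_len(n)) {
    if (cells$viability[i] == "necrotic") {
      reason[i] <- "necrotic"
    } else if (!inside[i]) {
      reason[i] <- "outside_tumor_area"
    } else if (!is_tc[i] && !is_ic[i]) {
      reason[i] <- "off_target_cell_type"
    } else if (cells$cell_class[i] == "giant_cell") {
      reason[i] <- "giant_cell_excluded"
    } else if (cells$context[i] == "granuloma") {
      reason[i] <- "granuloma_excluded"
    } else if (is_ic[i] && cells$context[i] == "vessel_or_lymphatic") {
      reason[i] <- "intravascular_excluded"
    } else if (cells$cell_class[i] == "macrophage" &&
               cells$context[i] == "lumen" &&
               !isTRUE(cells$fills_lumen_and_contacts_tc[i])) {
      reason[i] <- "intraluminal_macrophage_excluded"
    } else if (is_ic[i] && cells$context[i] == "germinal_center") {
      if (gastric_gej) {
        scoreable[i] <- TRUE; role[i] <- "ic"
        reason[i] <- "germinal_center_included"
      } else {
        reason[i] <- "germinal_center_excluded"
      }
    } else if (is_tc[i]) {
      scoreable[i] <- TRUE; role[i] <- "tc"
    } else {
      scoreable[i] <- TRUE; role[i] <- "ic"
      if (has_node && !in_nest[i]) reason[i] <- "leading_edge_included"
    }
  }
  tibble::tibble(cell_id = cells$cell_id, scoreable = scoreable,
                 role = role, reason = reason)
}

#' Classify a TAP score against a cutoff
#'
#' Positivity is `tap_percent >= cutoff` (a score exactly at the cutoff is
#' positive: 5-9% is the positive-borderline band under the 5% convention).
#' Borderline categories follow the 5% convention regardless of the cutoff
#' in use: negative borderline for TAP in \[2, 5), positive borderline for
#' TAP in \[5, 10).
#'
#' @param tap_percent TAP score(s) in \[0, 100\]
#' @param cutoff positivity cutoff percentage (1 and 5 are the conventional
#'   choices)
#' @return tibble: status (`"positive"`/`"negative"`), borderline_category
#'   (`"none"`/`"negative_borderline"`/`"positive_borderline"`)
#' @export
tap_status <- function(tap_percent, cutoff = 5) {
  stopifnot(cutoff > 0)
  if (any(tap_percent < 0)) stop("tap_percent must be non-negative",
                                 call. = FALSE)
  status <- ifelse(tap_percent >= cutoff, "positive", "negative")
  borderline <- ifelse(
    tap_percent >= 2 & tap_percent < 5, "negative_borderline",
    ifelse(tap_percent >= 5 & tap_percent < 10, "positive_borderline", "none"))
  tibble::tibble(status = status, borderline_category = borderline)
}

#' Compute the TAP score
#'
#' The numerator is the summed footprint area of every scoreable cell that
#' stains positive under its role's rule (membrane staining for tumor cells;
#' membranous, cytoplasmic or punctate staining for immune cells); the
#' denominator is the tumor area. With scalar footprints, a cell contributes
#' its whole footprint when its centroid lies in the tumor area (overlap
#' between footprints is not resolved — documented limitation).
#'
#' @param slide a [slide_annotation()]
#' @param tumor_area a `tumor_area` with positive total area
#' @param cutoff positivity cutoff used for the reported status (default 5)
#' @return object of class `tap_result` with fields tap_percent,
#'   positive_area, tumor_area, n_positive_tc, n_positive_ic,
#'   status_at_cutoff, borderline_category, eligibility
#' @export
compute_tap <- function(slide, tumor_area, cutoff = 5) {
  if (!tumor_area$total_area > 0) .unscorable("tumor area is empty")
  cells <- slide$cells
  elig <- cell_eligibility(slide, tumor_area)
  pos <- rep(FALSE, nrow(cells))
  tc_rows <- which(elig$scoreable & elig$role == "tc")
  ic_rows <- which(elig$scoreable & elig$role == "ic")
  if (length(tc_rows) > 0) pos[tc_rows] <- tc_stain_positive(cells[tc_rows, ])
  if (length(ic_rows) > 0) pos[ic_rows] <- ic_stain_positive(cells[ic_rows, ])
  positive_area <- sum(cells$footprint_area[pos])
  tap <- min(100, max(0, 100 * positive_area / tumor_area$total_area))
  st <- tap_status(tap, cutoff)
  structure(list(tap_percent = tap, positive_area = positive_area,
                 tumor_area = tumor_area$total_area,
                 n_positive_tc = length(intersect(which(pos), tc_rows)),
                 n_positive_ic = length(intersect(which(pos), ic_rows)),
                 cutoff = cutoff, status_at_cutoff = st$status,
                 borderline_category = st$borderline_category,
                 eligibility = elig),
            class = "tap_result")
}

#' @export
print.tap_result <- function(x, ...) {
  cat(sprintf(
    "<tap_result> TAP %.1f%% (%s at %g%% cutoff%s); positive %.0f / tumor %.0f um^2\n",
    x$tap_percent, x$status_at_cutoff, x$cutoff,
    if (x$borderline_category == "none") "" else paste0(", ", x$borderline_category),
    x$positive_area, x$tumor_area))
  invisible(x)
}

#' Compute the CPS score
#'
#' Numerator: positive viable tumor cells plus positive tumor-associated
#' mononuclear immune cells (lymphocytes and macrophages only — granulocytes
#' and other immune classes are excluded, unlike TAP). Denominator: viable
#' tumor cells inside the tumor area. The score is capped at 100 and the
#' result is valid only when the denominator reaches `min_viable_tc`
#' (conventionally 100). A zero denominator yields `cps = NA`, not 0.
#'
#' @param slide a [slide_annotation()]
#' @param tumor_area a `tumor_area` built from the slide
#' @param min_viable_tc minimum viable tumor cells for a valid score
#' @return object of class `cps_result` with fields cps, n_positive_tc,
#'   n_positive_mononuclear_ic, n_viable_tc, valid
#' @export
compute_cps <- function(slide, tumor_area, min_viable_tc = 100) {
  cells <- slide$cells
  elig <- cell_eligibility(slide, tumor_area)
  tc_rows <- which(elig$scoreable & elig$role == "tc")
  n_viable_tc <- length(tc_rows)
  n_pos_tc <- if (n_viable_tc > 0) sum(tc_stain_positive(cells[tc_rows, ])) else 0L
  mono_rows <- which(elig$scoreable & elig$role == "ic" &
                       cells$cell_class %in% .CPS_IC_CLASSES)
  n_pos_ic <- if (length(mono_rows) > 0) {
    sum(ic_stain_positive(cells[mono_rows, ]))
  } else 0L
  cps <- if (n_viable_tc > 0) {
    min(100, 100 * (n_pos_tc + n_pos_ic) / n_viable_tc)
  } else NA_real_
  structure(list(cps = cps, n_positive_tc = as.integer(n_pos_tc),
                 n_positive_mononuclear_ic = as.integer(n_pos_ic),
                 n_viable_tc = as.integer(n_viable_tc),
                 valid = n_viable_tc >= min_viable_tc),
            class = "cps_result")
}

#' @export
print.cps_result <- function(x, ...) {
  cat(sprintf("<cps_result> CPS %s (%svalid); %d pos TC + %d pos IC / %d viable TC\n",
              if (is.na(x$cps)) "NA" else sprintf("%.1f", x$cps),
              if (x$valid) "" else "in", x$n_positive_tc,
              x$n_positive_mononuclear_ic, x$n_viable_tc))
  invisible(x)
}
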