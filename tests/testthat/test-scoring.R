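test_that("tumor-cell positivity follows the membrane rule at any intensity", {
  cases <- dplyr::bind_rows(
    make_cell("a", membrane_stain = "partial", stain_intensity = 1L),
    make_cell("b", membrane_stain = "circumferential", stain_intensity = 3L),
    make_cell("c", cytoplasmic_stain = TRUE, stain_intensity = 3L),
    make_cell("d"))
  expect_equal(tc_stain_positive(cell_table(cases)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(tc_stain_positive(cell_table(make_cell(
    cell_class = "lymphocyte"))), "tumor_cell")
})

test_that("immune-cell positivity accepts membranous, cytoplasmic and punctate staining", {
  cases <- dplyr::bind_rows(
    make_cell("a", cell_class = "granulocyte", cytoplasmic_stain = TRUE,
              stain_intensity = 1L),
    make_cell("b", cell_class = "lymphocyte", punctate_stain = TRUE),
    make_cell("c", cell_class = "macrophage"),
    make_cell("d", cell_class = "plasma_cell", membrane_stain = "partial"))
  expect_equal(ic_stain_positive(cell_table(cases)),
               c(TRUE, TRUE, FALSE, TRUE))
  expect_error(ic_stain_positive(cell_table(make_cell())), "immune")
})

test_that("eligibility applies the exclusion rules in order, one reason each", {
  regions <- dplyr::bind_rows(
    region_table("nest_1", "tumor_nest", list(sq_ring(0, 0, 1000))),
    region_table("vessel_1", "lymphovascular_space",
                 list(sq_ring(400, 400, 100))))
  cells <- dplyr::bind_rows(
    make_cell("tc_ok", x = 500, y = 500),
    make_cell("tc_necrotic", viability = "necrotic", x = 510, y = 500),
    make_cell("ic_vessel", cell_class = "lymphocyte", x = 450, y = 450,
              context = "vessel_or_lymphatic", membrane_stain = "partial"),
    make_cell("mac_lumen_free", cell_class = "macrophage", x = 200, y = 200,
              context = "lumen", cytoplasmic_stain = TRUE),
    make_cell("mac_lumen_fills", cell_class = "macrophage", x = 250, y = 200,
              context = "lumen", cytoplasmic_stain = TRUE,
              fills_lumen_and_contacts_tc = TRUE),
    make_cell("fibro", cell_class = "fibroblast", x = 300, y = 300,
              membrane_stain = "partial"),
    make_cell("giant", cell_class = "giant_cell", x = 350, y = 300,
              cytoplasmic_stain = TRUE),
    make_cell("ic_granuloma", cell_class = "lymphocyte", x = 600, y = 600,
              context = "granuloma", punctate_stain = TRUE),
    make_cell("ic_outside", cell_class = "lymphocyte", x = 5000, y = 5000,
              context = "outside_tumor"))
  slide <- slide_annotation("s", "gastric", "resection", cells, regions)
  ta <- build_tumor_area(slide)
  elig <- cell_eligibility(slide, ta)
  expected <- c(tc_ok = "ok", tc_necrotic = "necrotic",
                ic_vessel = "intravascular_excluded",
                mac_lumen_free = "intraluminal_macrophage_excluded",
                mac_lumen_fills = "ok", fibro = "off_target_cell_type",
                giant = "giant_cell_excluded",
                ic_granuloma = "granuloma_excluded",
                ic_outside = "outside_tumor_area")
  expect_equal(stats::setNames(elig$reason, elig$cell_id), expected)
  expect_equal(elig$scoreable, elig$cell_id %in% c("tc_ok", "mac_lumen_fills"))
  expect_equal(elig$role[elig$cell_id == "tc_ok"], "tc")
  expect_equal(elig$role[elig$cell_id == "mac_lumen_fills"], "ic")
})

test_that("germinal-center immune cells count for gastric/GEJ only", {
  agg <- circle_ring(500, 500, 120, 48)
  gc <- circle_ring(500, 500, 60, 32)
  regions <- dplyr::bind_rows(
    region_table("nest_1", "tumor_nest", list(sq_ring(0, 0, 1000))),
    region_table("agg_1", "lymphoid_aggregate", list(agg)),
    region_table("gc_1", "germinal_center", list(gc)))
  cells <- make_cell("gc_ic", cell_class = "lymphocyte", x = 500, y = 500,
                     context = "germinal_center", punctate_stain = TRUE)
  for (ind in c("gastric", "GEJ", "ESCC")) {
    slide <- slide_annotation("s", ind, "resection", cells, regions)
    ta <- build_tumor_area(slide)
    elig <- cell_eligibility(slide, ta)
    if (ind == "ESCC") {
      expect_false(elig$scoreable)
      expect_equal(elig$reason, "germinal_center_excluded")
    } else {
      expect_true(elig$scoreable)
      expect_equal(elig$reason, "germinal_center_included")
    }
  }
})

test_that("TAP arithmetic: positives over tumor area", {
  # no stained cells -> 0
  slide0 <- square_nest_slide(cells = make_cell(x = 500, y = 500))
  ta0 <- build_tumor_area(slide0)
  expect_equal(compute_tap(slide0, ta0)$tap_percent, 0)
  # 1 mm^2 nest, positive footprints summing to 50,000 um^2 -> 5.0
  slide5 <- square_nest_slide(cells = positive_tc_cells(25, 5e4))
  ta5 <- build_tumor_area(slide5)
  tap <- compute_tap(slide5, ta5)
  expect_equal(tap$tap_percent, 5, tolerance = 1e-3)
  expect_equal(tap$n_positive_tc, 25)
  expect_equal(tap$status_at_cutoff, "positive")
})

test_that("the engine recovers the generator's ground-truth TAP", {
  gen <- generate_slide(slide_gen_params(seed = 11, target_tap = 7.3))
  ta <- build_tumor_area(gen$slide)
  tap <- compute_tap(gen$slide, ta)
  expect_lt(abs(tap$tap_percent - gen$truth$true_tap), 0.2)
})

test_that("cutoff classification and borderline bands", {
  s <- tap_status(c(5.0, 4.9, 0.0, 2.0, 9.99, 10, 1.5), cutoff = 5)
  expect_equal(s$status, c("positive", "negative", "negative", "negative",
                           "positive", "positive", "negative"))
  expect_equal(s$borderline_category,
               c("positive_borderline", "negative_borderline", "none",
                 "negative_borderline", "positive_borderline", "none", "none"))
  expect_equal(tap_status(1.2, cutoff = 1)$status, "positive")
  expect_error(tap_status(-1), "non-negative")
})

test_that("CPS counts mononuclear IC only, caps at 100, and demands 100 TC", {
  # 200 viable TC (10 positive), 5 positive lymphocytes, 3 positive
  # granulocytes -> CPS 7.5 (granulocytes never enter the numerator)
  tc <- positive_tc_cells(200, 200 * 200)
  tc$membrane_stain[11:200] <- "none"
  tc$stain_intensity[11:200] <- 0L
  lymph <- dplyr::bind_rows(lapply(1:5, function(i)
    make_cell(sprintf("ly%d", i), cell_class = "lymphocyte",
              x = 50 + 10 * i, y = 50, punctate_stain = TRUE)))
  gran <- dplyr::bind_rows(lapply(1:3, function(i)
    make_cell(sprintf("gr%d", i), cell_class = "granulocyte",
              x = 50 + 10 * i, y = 70, cytoplasmic_stain = TRUE)))
  slide <- square_nest_slide(cells = dplyr::bind_rows(tc, lymph, gran))
  ta <- build_tumor_area(slide)
  cps <- compute_cps(slide, ta)
  expect_equal(cps$cps, 7.5)
  expect_equal(cps$n_positive_mononuclear_ic, 5)
  expect_true(cps$valid)
  # TAP sees the granulocytes
  tap <- compute_tap(slide, ta)
  expect_equal(tap$n_positive_ic, 8)

  # cap: 100 TC all positive plus 150 positive lymphocytes -> 100
  tc2 <- positive_tc_cells(100, 100 * 200)
  ly2 <- dplyr::bind_rows(lapply(1:150, function(i)
    make_cell(sprintf("ly%d", i), cell_class = "lymphocyte",
              x = 20 + (i %% 30) * 30, y = 20 + (i %/% 30) * 10,
              punctate_stain = TRUE)))
  slide2 <- square_nest_slide(cells = dplyr::bind_rows(tc2, ly2))
  ta2 <- build_tumor_area(slide2)
  expect_equal(compute_cps(slide2, ta2)$cps, 100)

  # insufficiency: 50 viable TC -> invalid
  slide3 <- square_nest_slide(cells = positive_tc_cells(50, 50 * 200))
  ta3 <- build_tumor_area(slide3)
  cps3 <- compute_cps(slide3, ta3)
  expect_false(cps3$valid)
  expect_equal(cps3$n_viable_tc, 50)

  # zero denominator: CPS undefined, not zero
  slide4 <- square_nest_slide(cells = make_cell(
    "ly", cell_class = "lymphocyte", x = 500, y = 500,
    punctate_stain = TRUE))
  ta4 <- build_tumor_area(slide4)
  cps4 <- compute_cps(slide4, ta4)
  expect_true(is.na(cps4$cps))
  expect_false(cps4$valid)
})

test_that("adding a positive cell raises TAP; enlarging stroma lowers it", {
  base_cells <- positive_tc_cells(10, 2e4)
  slide <- square_nest_slide(cells = base_cells)
  ta <- build_tumor_area(slide)
  tap0 <- compute_tap(slide, ta)$tap_percent
  more <- dplyr::bind_rows(base_cells, make_cell(
    "extra", x = 900, y = 900, footprint_area = 200,
    membrane_stain = "partial"))
  tap1 <- compute_tap(square_nest_slide(cells = more), ta)$tap_percent
  expect_gt(tap1, tap0)

  stroma <- region_table("stroma_1", "tumor_stroma",
                         list(sq_ring(1000, 0, 800)))
  slide_s <- square_nest_slide(cells = base_cells, extra_regions = stroma)
  ta_s <- build_tumor_area(slide_s)
  expect_lt(compute_tap(slide_s, ta_s)$tap_percent, tap0)
})

test_that("TAP is invariant under rigid motion of the whole annotation", {
  gen <- generate_slide(slide_gen_params(seed = 5, n_nests = 2,
                                         nest_radius_mean = 180,
                                         tc_density = 1500, ic_density = 600))
  slide <- gen$slide
  ta <- build_tumor_area(slide)
  tap <- compute_tap(slide, ta)$tap_percent

  th <- 0.7; dx <- 1234; dy <- -987
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + dx,
                             y = sin(th) * x + cos(th) * y + dy)
  regions2 <- slide$regions
  for (i in seq_len(nrow(regions2))) {
    r <- rot(regions2$polygon[[i]]$x, regions2$polygon[[i]]$y)
    regions2$polygon[[i]] <- r
    regions2$holes[[i]] <- lapply(regions2$holes[[i]], function(h)
      rot(h$x, h$y))
  }
  cells2 <- slide$cells
  cr <- rot(cells2$x, cells2$y)
  cells2$x <- cr$x; cells2$y <- cr$y
  slide2 <- slide_annotation("rot", slide$indication, slide$specimen_type,
                             cells2, regions2)
  ta2 <- build_tumor_area(slide2)
  expect_equal(compute_tap(slide2, ta2)$tap_percent, tap, tolerance = 1e-4)
})

test_that("granulocyte-only positivity diverges between TAP and CPS", {
  gen <- generate_slide(slide_gen_params(seed = 13,
                                         granulocyte_only_positivity = TRUE,
                                         ic_positive_fraction = 0.3,
                                         tc_positive_fraction = 0))
  ta <- build_tumor_area(gen$slide)
  tap <- compute_tap(gen$slide, ta)
  cps <- compute_cps(gen$slide, ta)
  expect_gt(tap$tap_percent, 0)
  expect_equal(cps$n_positive_mononuclear_ic, 0)
  expect_equal(cps$cps, 0)
})

test_that("TAP equals the TC-only positive fraction on an IC-free slide", {
  tc <- positive_tc_cells(40, 40 * 200)
  tc$membrane_stain[21:40] <- "none"
  tc$stain_intensity[21:40] <- 0L
  slide <- square_nest_slide(cells = tc)
  ta <- build_tumor_area(slide)
  tap <- compute_tap(slide, ta)
  cps <- compute_cps(slide, ta, min_viable_tc = 10)
  expect_equal(tap$tap_percent, 100 * 20 * 200 / ta$total_area,
               tolerance = 1e-9)
  expect_equal(cps$cps, 50)
})
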