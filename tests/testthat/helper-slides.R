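# Builders for hand-made fixture slides used across the tests.

sq_ring <- function(x0, y0, side) {
  list(x = c(x0, x0 + side, x0 + side, x0), y = c(y0, y0, y0 + side, y0 + side))
}

# one cell-record row; defaults give an unstained viable tumor cell
make_cell <- function(cell_id = "c1", cell_class = "tumor_cell",
                      viability = "viable", x = 0, y = 0,
                      footprint_area = NA_real_, membrane_stain = "none",
                      cytoplasmic_stain = FALSE, punctate_stain = FALSE,
                      stain_intensity = NULL, context = "tumor_proper",
                      fills_lumen_and_contacts_tc = FALSE) {
  if (is.null(stain_intensity)) {
    stain_intensity <- if (membrane_stain != "none" || cytoplasmic_stain ||
                           punctate_stain) 1L else 0L
  }
  tibble::tibble(cell_id = cell_id, cell_class = cell_class,
                 viability = viability, x = x, y = y,
                 footprint_area = footprint_area,
                 membrane_stain = membrane_stain,
                 cytoplasmic_stain = cytoplasmic_stain,
                 punctate_stain = punctate_stain,
                 stain_intensity = as.integer(stain_intensity),
                 context = context,
                 fills_lumen_and_contacts_tc = fills_lumen_and_contacts_tc)
}

# slide with a single 1 mm x 1 mm square nest at the origin
square_nest_slide <- function(cells = NULL, indication = "gastric",
                              extra_regions = NULL, side = 1000) {
  regions <- region_table("nest_1", "tumor_nest", list(sq_ring(0, 0, side)))
  if (!is.null(extra_regions)) regions <- dplyr::bind_rows(regions,
                                                           extra_regions)
  if (is.null(cells)) cells <- make_cell(x = side / 2, y = side / 2)[0, ]
  slide_annotation("fixture", indication, "resection", cells, regions)
}

# n positive tumor cells with given total footprint, placed inside the nest
positive_tc_cells <- function(n, total_footprint, side = 1000) {
  pos <- seq(100, side - 100, length.out = max(2, ceiling(sqrt(n))))
  grid <- expand.grid(x = pos, y = pos)[seq_len(n), ]
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_cell(cell_id = sprintf("tc%03d", i), x = grid$x[i], y = grid$y[i],
              footprint_area = total_footprint / n,
              membrane_stain = "partial")
  }))
}

# reader matrix for a panel where every reader calls `calls` identically
perfect_reader_matrix <- function(calls, n_readers = 3, n_rounds = 1) {
  rows <- list()
  for (r in seq_len(n_readers)) {
    for (rd in seq_len(n_rounds)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sprintf("s%03d", seq_along(calls)),
        reader_id = sprintf("reader_%d", r), round = rd, status = calls)
    }
  }
  reader_score_matrix(dplyr::bind_rows(rows))
}
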