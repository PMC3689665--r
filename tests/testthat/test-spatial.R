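test_that("make_grid: dimensions, guards, equal-area contract", {
  g <- make_grid(c(0, 0, 10, 10), 0.25)
  # square projected cells of one 0.25-degree equatorial arc; x shrinks by
  # cos(30) under Behrmann, so a 10-degree lon span holds ceil(10*cos30/.25)
  expect_equal(g$n_cols, as.integer(ceiling(10 * cos(pi / 6) / 0.25)))
  expect_error(make_grid(c(0, 0, 10, 10), 0), "cell_size")
  expect_error(make_grid(c(10, 0, 0, 10), 0.25), "inverted")

  # every cell has identical projected (= true) area by construction;
  # tiling covers the projected extent to within one cell ring
  area_cells <- g$n_rows * g$n_cols * g$cell_size^2
  xw <- 6371007.181 * (10 * pi / 180) * cos(pi / 6)
  yw <- 6371007.181 * sin(10 * pi / 180) / cos(pi / 6)
  expect_gte(area_cells, xw * yw)
  expect_lte(area_cells,
             (xw + g$cell_size) * (yw + g$cell_size) + g$cell_size^2)

  # geographic mode grids in plain degrees
  gg <- make_grid(c(0, 0, 10, 5), 0.25, projection = "geographic")
  expect_equal(gg$n_cols, 40L)
  expect_equal(gg$n_rows, 20L)
})

test_that("rasterize_ranges: center rule, split rectangles, determinism", {
  # geographic grid for exact alignment: rectangle covering a 2x3 block
  g <- make_grid(c(0, 0, 10, 10), 1, projection = "geographic")
  rect <- data.frame(species = "a", min_lon = 2, min_lat = 3,
                     max_lon = 5, max_lat = 5)
  occ <- rasterize_ranges(rect, g)
  expect_equal(nrow(occ$cells), 6L) # 3 cols x 2 rows of centers
  expect_setequal(occ$cells$col, 3:5)
  expect_setequal(occ$cells$row, 4:5)

  # identical ranges -> identical cell sets
  two <- rbind(rect, transform(rect, species = "b"))
  occ2 <- rasterize_ranges(two, g)
  expect_equal(sort(paste(occ2$cells$row[occ2$cells$species == "a"],
                          occ2$cells$col[occ2$cells$species == "a"])),
               sort(paste(occ2$cells$row[occ2$cells$species == "b"],
                          occ2$cells$col[occ2$cells$species == "b"])))

  # monotonicity: enlarging a rectangle never removes cells
  big <- transform(rect, min_lon = 1, max_lat = 7)
  occ3 <- rasterize_ranges(big, g)
  expect_true(all(paste(occ$cells$row, occ$cells$col) %in%
                    paste(occ3$cells$row, occ3$cells$col)))

  # empty catch -> warning
  tiny <- data.frame(species = "z", min_lon = 2.6, min_lat = 3.6,
                     max_lon = 2.9, max_lat = 3.9)
  expect_warning(rasterize_ranges(tiny, g), "no occupied cells")

  # antimeridian-crossing rectangle is split automatically
  gw <- make_grid(c(-180, -10, 180, 10), 1, projection = "geographic")
  wrap <- data.frame(species = "w", min_lon = 175, min_lat = 0,
                     max_lon = -175, max_lat = 3)
  occw <- rasterize_ranges(wrap, gw)
  expect_setequal(sort(unique(occw$cells$col)), c(1:5, 356:360))

  bad <- data.frame(species = "q", min_lon = -200, min_lat = 0,
                    max_lon = -190, max_lat = 1)
  expect_error(rasterize_ranges(bad, gw), "invalid rectangle.*q")
})

test_that("polygon rasterization matches the rectangle path", {
  g <- make_grid(c(0, 0, 10, 10), 0.5)
  rect <- data.frame(species = "a", min_lon = 1, min_lat = 1,
                     max_lon = 6, max_lat = 4)
  poly <- list(a = matrix(c(1, 1, 6, 1, 6, 4, 1, 4), ncol = 2,
                          byrow = TRUE))
  occ_r <- rasterize_ranges(rect, g)$cells
  occ_p <- rasterize_ranges(poly, g)$cells
  expect_setequal(paste(occ_r$row, occ_r$col), paste(occ_p$row, occ_p$col))
})

test_that("layers: richness, means, missing-value semantics", {
  g <- make_grid(c(0, 0, 4, 4), 1, projection = "geographic")
  rects <- data.frame(species = c("A", "B", "C"),
                      min_lon = c(0, 0, 2), min_lat = c(0, 0, 2),
                      max_lon = c(2, 4, 4), max_lat = c(2, 4, 4))
  occ <- rasterize_ranges(rects, g)
  rich <- richness_layer(occ)
  expect_equal(rich$values$value[rich$values$row == 1 &
                                   rich$values$col == 1], 2) # A + B
  expect_equal(rich$values$value[rich$values$row == 3 &
                                   rich$values$col == 3], 2) # B + C
  # double-counting identity
  expect_equal(sum(rich$values$value), nrow(unique(occ$cells)))

  m <- mean_metric_layer(occ, c(A = 2, B = 4, C = 6))
  expect_equal(m$values$value[m$values$row == 1 & m$values$col == 1], 3)
  expect_equal(m$values$value[m$values$row == 3 & m$values$col == 3], 5)
  # constant map -> constant layer on exactly the occupied cells
  ones <- mean_metric_layer(occ, c(A = 1, B = 1, C = 1))
  expect_equal(ones$values[, c("row", "col")], rich$values[, c("row", "col")])
  expect_true(all(ones$values$value == 1))

  expect_error(mean_metric_layer(occ, c(A = 2, B = 4)), "C")
})

test_that("layer_correlation: identities and planted correlation", {
  g <- make_grid(c(0, 0, 50, 40), 1, projection = "geographic")
  set.seed(5)
  n <- 2000
  cells <- data.frame(row = rep(1:40, each = 50), col = rep(1:50, 40))
  z <- rnorm(n)
  a_val <- z
  b_val <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)
  a <- mangroveED:::new_layer(g, transform(cells, value = a_val))
  b <- mangroveED:::new_layer(g, transform(cells, value = b_val))
  self <- layer_correlation(a, a)
  expect_equal(self$r, 1)
  neg <- mangroveED:::new_layer(g, transform(cells, value = -a_val + 7))
  expect_equal(layer_correlation(a, neg)$r, -1)
  got <- layer_correlation(a, b)
  expect_lt(abs(got$r - 0.5), 0.05)
  expect_equal(got$n_cells, n)

  flat <- mangroveED:::new_layer(g, transform(cells, value = 1))
  expect_error(layer_correlation(a, flat), "zero variance")
  small <- mangroveED:::new_layer(g, transform(cells[1:2, ], value = 1:2))
  expect_error(layer_correlation(a, small), "fewer than 3")
})

test_that("ESRI ASCII and CSV writers round-trip the layer", {
  g <- make_grid(c(0, 0, 3, 2), 1, projection = "geographic")
  lay <- mangroveED:::new_layer(
    g, data.frame(row = c(1, 2), col = c(1, 3), value = c(4.5, 7)))
  asc <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(lay, asc)
  lines <- readLines(asc)
  expect_equal(lines[1], "ncols 3")
  expect_equal(lines[2], "nrows 2")
  # northernmost row (row 2) first
  expect_equal(strsplit(lines[7], " ")[[1]], c("-9999", "-9999", "7"))
  expect_equal(strsplit(lines[8], " ")[[1]], c("4.5", "-9999", "-9999"))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_layer_csv(lay, csv)
  expect_equal(read.csv(csv), lay$values)
})
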