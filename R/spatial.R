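# Behrmann equal-area cylindrical projection (standard parallel 30 N/S),
# authalic sphere. x depends only on longitude, y only on latitude, so
# lon/lat rectangles project to rectangles and any uniform projected grid is
# exactly equal-area.
EARTH_RADIUS_M <- 6371007.181
COS30 <- cos(30 * pi / 180)

behrmann_xy <- function(lon, lat) {
  list(x = EARTH_RADIUS_M * (lon * pi / 180) * COS30,
       y = EARTH_RADIUS_M * sin(lat * pi / 180) / COS30)
}

behrmann_lonlat <- function(x, y) {
  list(lon = x / (EARTH_RADIUS_M * COS30) * 180 / pi,
       lat = asin(pmin(1, pmax(-1, y * COS30 / EARTH_RADIUS_M))) * 180 / pi)
}

#' Build an equal-area grid specification
#'
#' Constructs a uniform grid in Behrmann (equal-area cylindrical, standard
#' parallel 30) projected space. The square cell side is the equatorial arc
#' length of `cell_size` degrees (0.25 deg ~ 27.8 km), giving quarter-degree
#' -square-sized, exactly equal-area cells. A pure-geographic mode
#' (`projection = "geographic"`) grids directly in degrees instead. Row 1 is
#' the southernmost row, column 1 the westernmost; cells are half-open
#' `[min, max)` intervals; species membership is decided by cell-center
#' containment.
#'
#' @param extent geographic bounds `c(min_lon, min_lat, max_lon, max_lat)`
#'   in degrees (lon in `[-180, 180]`, lat in `[-90, 90]`).
#' @param cell_size cell size in degrees of equatorial arc (default 0.25).
#' @param projection `"behrmann"` (default) or `"geographic"`.
#' @return Object of class `"grid_spec"`.
#' @export
make_grid <- function(extent, cell_size = 0.25, projection = "behrmann") {
  projection <- match.arg(projection, c("behrmann", "geographic"))
  stopifnot(length(extent) == 4L)
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  if (extent[1] >= extent[3] || extent[2] >= extent[4]) {
    stop("empty or inverted extent", call. = FALSE)
  }
  if (projection == "behrmann") {
    ll <- behrmann_xy(extent[1], extent[2])
    ur <- behrmann_xy(extent[3], extent[4])
    cs <- EARTH_RADIUS_M * cell_size * pi / 180
  } else {
    ll <- list(x = extent[1], y = extent[2])
    ur <- list(x = extent[3], y = extent[4])
    cs <- cell_size
  }
  n_cols <- as.integer(ceiling((ur$x - ll$x) / cs - 1e-9))
  n_rows <- as.integer(ceiling((ur$y - ll$y) / cs - 1e-9))
  out <- list(projection = projection, cell_size_deg = cell_size,
              cell_size = cs, xll = ll$x, yll = ll$y,
              n_rows = n_rows, n_cols = n_cols, extent_geo = extent)
  class(out) <- "grid_spec"
  out
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("%s grid: %d rows x %d cols, cell %.1f %s (%.3g deg eq. arc)\n",
              x$projection, x$n_rows, x$n_cols, x$cell_size,
              if (x$projection == "behrmann") "m" else "deg",
              x$cell_size_deg))
  invisible(x)
}

# project a lon/lat rectangle into grid coordinates
project_rect <- function(grid, min_lon, min_lat, max_lon, max_lat) {
  if (grid$projection == "behrmann") {
    a <- behrmann_xy(min_lon, min_lat)
    b <- behrmann_xy(max_lon, max_lat)
    list(x1 = a$x, y1 = a$y, x2 = b$x, y2 = b$y)
  } else {
    list(x1 = min_lon, y1 = min_lat, x2 = max_lon, y2 = max_lat)
  }
}

# cells whose centers fall in [v1, v2) along one axis; 1-based indices
axis_cells <- function(v1, v2, origin, cs, n) {
  jmin <- ceiling((v1 - origin) / cs + 0.5)
  jmax <- ceiling((v2 - origin) / cs + 0.5) - 1
  jmin <- max(1L, as.integer(jmin))
  jmax <- min(n, as.integer(jmax))
  if (jmin > jmax) integer(0) else seq.int(jmin, jmax)
}

#' Rasterize species ranges onto a grid
#'
#' A species occupies a cell iff the cell's center lies inside one of its
#' range shapes. Ranges are either a data frame of rectangles
#' (`species,min_lon,min_lat,max_lon,max_lat`; rectangles with
#' `min_lon > max_lon` are split at the antimeridian) or a named list of
#' polygons (each a list of 2-column lon/lat matrices; even-odd ray-casting
#' containment).
#'
#' @param ranges rectangle data frame or named polygon list.
#' @param grid a `"grid_spec"` from [make_grid()].
#' @return Object of class `"occurrence_grid"`: the grid plus a long
#'   data frame `cells` with columns `row, col, species`. Species whose
#'   ranges catch no cell center trigger a warning.
#' @export
rasterize_ranges <- function(ranges, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.data.frame(ranges)) {
    occ <- rasterize_rectangles(ranges, grid)
  } else if (is.list(ranges)) {
    occ <- rasterize_polygons(ranges, grid)
  } else {
    stop("ranges must be a rectangle data frame or polygon list",
         call. = FALSE)
  }
  sp_all <- if (is.data.frame(ranges)) unique(as.character(ranges$species))
            else names(ranges)
  empty <- setdiff(sp_all, unique(occ$species))
  if (length(empty)) {
    warning("species with no occupied cells: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- list(grid = grid, cells = occ)
  class(out) <- "occurrence_grid"
  out
}

rasterize_rectangles <- function(ranges, grid) {
  req <- c("species", "min_lon", "min_lat", "max_lon", "max_lat")
  if (!all(req %in% names(ranges))) {
    stop("rectangle ranges need columns ", paste(req, collapse = ","),
         call. = FALSE)
  }
  # split antimeridian-crossing rectangles
  cross <- !is.na(ranges$min_lon) & ranges$min_lon > ranges$max_lon
  if (any(cross)) {
    west <- ranges[cross, ]; west$max_lon <- 180
    east <- ranges[cross, ]; east$min_lon <- -180
    ranges <- rbind(ranges[!cross, ], west, east)
  }
  bad <- with(ranges, is.na(min_lon) | is.na(max_lon) | is.na(min_lat) |
                is.na(max_lat) | min_lat > max_lat |
                min_lon < -180 | max_lon > 180 | min_lat < -90 | max_lat > 90)
  if (any(bad)) {
    stop("invalid rectangle geometry for species: ",
         paste(unique(ranges$species[bad]), collapse = ", "), call. = FALSE)
  }
  res <- vector("list", nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    r <- project_rect(grid, ranges$min_lon[i], ranges$min_lat[i],
                      ranges$max_lon[i], ranges$max_lat[i])
    cols <- axis_cells(r$x1, r$x2, grid$xll, grid$cell_size, grid$n_cols)
    rows <- axis_cells(r$y1, r$y2, grid$yll, grid$cell_size, grid$n_rows)
    if (length(cols) && length(rows)) {
      res[[i]] <- data.frame(row = rep(rows, each = length(cols)),
                             col = rep(cols, times = length(rows)),
                             species = as.character(ranges$species[i]))
    }
  }
  occ <- do.call(rbind, res)
  if (is.null(occ)) occ <- data.frame(row = integer(), col = integer(),
                                      species = character())
  unique(occ)
}

rasterize_polygons <- function(ranges, grid) {
  if (is.null(names(ranges))) stop("polygon list must be named by species",
                                   call. = FALSE)
  res <- list()
  for (sp in names(ranges)) {
    polys <- ranges[[sp]]
    if (is.matrix(polys)) polys <- list(polys)
    for (poly in polys) {
      if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L) {
        stop("invalid polygon geometry for species ", sp, call. = FALSE)
      }
      bb <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
      r <- project_rect(grid, bb[1], bb[2], bb[3], bb[4])
      cols <- axis_cells(r$x1 - grid$cell_size, r$x2 + grid$cell_size,
                         grid$xll, grid$cell_size, grid$n_cols)
      rows <- axis_cells(r$y1 - grid$cell_size, r$y2 + grid$cell_size,
                         grid$yll, grid$cell_size, grid$n_rows)
      if (!length(cols) || !length(rows)) next
      cc <- expand.grid(col = cols, row = rows)
      cx <- grid$xll + (cc$col - 0.5) * grid$cell_size
      cy <- grid$yll + (cc$row - 0.5) * grid$cell_size
      if (grid$projection == "behrmann") {
        gl <- behrmann_lonlat(cx, cy)
        inside <- point_in_poly(gl$lon, gl$lat, poly)
      } else {
        inside <- point_in_poly(cx, cy, poly)
      }
      if (any(inside)) {
        res[[length(res) + 1L]] <- data.frame(row = cc$row[inside],
                                              col = cc$col[inside],
                                              species = sp)
      }
    }
  }
  occ <- do.call(rbind, res)
  if (is.null(occ)) occ <- data.frame(row = integer(), col = integer(),
                                      species = character())
  unique(occ)
}

# even-odd ray casting, vectorized over points
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read species ranges
#'
#' `read_ranges()` reads the rectangle CSV dialect
#' (`species,min_lon,min_lat,max_lon,max_lat`); `read_ranges_geojson()`
#' reads a GeoJSON FeatureCollection of (Multi)Polygons in WGS84, taking the
#' species name from the `species` (or `name`) property. Only outer rings
#' are used.
#'
#' @param path input path.
#' @return Rectangle data frame, or named polygon list.
#' @export
read_ranges <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_ranges
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection",
                                 call. = FALSE)
  out <- list()
  for (ft in gj$features) {
    sp <- ft$properties$species %||% ft$properties$name
    if (is.null(sp)) stop("feature without species/name property",
                          call. = FALSE)
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    mats <- lapply(rings, function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    })
    out[[sp]] <- c(out[[sp]], mats)
  }
  out
}

#' Per-cell layers
#'
#' `richness_layer()` counts species per occupied cell;
#' `mean_metric_layer()` averages a per-species value (ED, BL, decline, ...)
#' over each cell's species set. Cells with no species are absent (missing),
#' not zero.
#'
#' @param occ an `"occurrence_grid"`.
#' @return Object of class `"cell_layer"`: the grid plus a data frame
#'   `values` with columns `row, col, value`.
#' @export
richness_layer <- function(occ) {
  stopifnot(inherits(occ, "occurrence_grid"))
  cells <- unique(occ$cells)
  v <- cell_aggregate(occ$grid, cells, rep(1, nrow(cells)), sum)
  new_layer(occ$grid, v)
}

#' @rdname richness_layer
#' @param per_species named numeric vector covering every occurring species.
#' @export
mean_metric_layer <- function(occ, per_species) {
  stopifnot(inherits(occ, "occurrence_grid"))
  sp <- unique(occ$cells$species)
  miss <- sp[!(sp %in% names(per_species)) | is.na(per_species[sp])]
  if (length(miss)) {
    stop("no metric value for species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v <- cell_aggregate(occ$grid, occ$cells,
                      unname(per_species[occ$cells$species]), mean)
  new_layer(occ$grid, v)
}

# fast per-cell aggregation via rowsum on a linear cell key
cell_aggregate <- function(grid, cells, x, fun) {
  if (nrow(cells) == 0L) {
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  }
  key <- (cells$row - 1) * grid$n_cols + cells$col
  tot <- rowsum(x, key)
  cnt <- rowsum(rep(1, length(x)), key)
  val <- if (identical(fun, mean)) tot / cnt else tot
  k <- as.numeric(rownames(tot))
  data.frame(row = as.integer((k - 1) %/% grid$n_cols + 1),
             col = as.integer((k - 1) %% grid$n_cols + 1),
             value = as.numeric(val))
}

new_layer <- function(grid, values) {
  values <- values[order(values$row, values$col), , drop = FALSE]
  rownames(values) <- NULL
  out <- list(grid = grid, values = values)
  class(out) <- "cell_layer"
  out
}

#' Pearson correlation between two cell layers
#'
#' Correlates two layers over the cells that are non-missing in both and
#' (optionally) meet a minimum species richness. The p-value uses the usual
#' t transform with `n_cells - 2` degrees of freedom.
#'
#' @param a,b `"cell_layer"` objects sharing one grid.
#' @param min_richness minimum richness filter (default 1 = all occupied
#'   cells); values > 1 require `richness`.
#' @param richness the richness layer used for filtering.
#' @return List with `r`, `p`, `n_cells`.
#' @export
layer_correlation <- function(a, b, min_richness = 1L, richness = NULL) {
  stopifnot(inherits(a, "cell_layer"), inherits(b, "cell_layer"))
  if (!identical(a$grid[c("n_rows", "n_cols", "cell_size")],
                 b$grid[c("n_rows", "n_cols", "cell_size")])) {
    stop("layers do not share a grid", call. = FALSE)
  }
  m <- merge(a$values, b$values, by = c("row", "col"),
             suffixes = c("_a", "_b"))
  if (min_richness > 1L) {
    if (is.null(richness)) stop("min_richness > 1 requires a richness layer",
                                call. = FALSE)
    m <- merge(m, richness$values, by = c("row", "col"))
    m <- m[m$value >= min_richness, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 3L) stop("fewer than 3 shared cells", call. = FALSE)
  if (stats::sd(m$value_a) == 0 || stats::sd(m$value_b) == 0) {
    stop("zero variance in a layer", call. = FALSE)
  }
  r <- stats::cor(m$value_a, m$value_b)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n_cells = n)
}

#' Write a cell layer
#'
#' `write_ascii_grid()` writes the ESRI ASCII grid format (header `ncols,
#' nrows, xllcorner, yllcorner, cellsize, NODATA_value`, rows north to
#' south); `write_layer_csv()` writes the long `row,col,value` form.
#'
#' @param layer a `"cell_layer"`.
#' @param path output path.
#' @param nodata NODATA marker (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  M <- matrix(nodata, nrow = g$n_rows, ncol = g$n_cols)
  v <- layer$values
  if (nrow(v)) M[cbind(v$row, v$col)] <- v$value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %.6f", g$xll),
               sprintf("yllcorner %.6f", g$yll),
               sprintf("cellsize %.6f", g$cell_size),
               sprintf("NODATA_value %s", format(nodata))), con)
  for (i in seq.int(g$n_rows, 1L)) { # northernmost row first
    writeLines(paste(vapply(M[i, ], format, character(1), trim = TRUE,
                            digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
write_layer_csv <- function(layer, path) {
  utils::write.csv(layer$values, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
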