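#' Water/land raster in a projected km plane
#'
#' A minimal raster container for shortest-through-water distance
#' calculations: a logical water mask plus a georeference (lower-left origin
#' and square cell size in km). Row 1 of the mask is the top of the grid, as
#' in an image; y increases upward from the origin.
#'
#' @param water Logical matrix, `TRUE` for water cells.
#' @param cell_km Cell edge length in km (> 0).
#' @param origin Numeric `c(x, y)` km coordinates of the lower-left corner.
#' @return Object of class `water_raster`: list with `water`, `cell_km`,
#'   `origin`.
#' @export
water_raster <- function(water, cell_km, origin = c(0, 0)) {
  if (!is.matrix(water) || !is.logical(water))
    stop("'water' must be a logical matrix")
  if (!any(water)) stop("raster must contain at least one water cell")
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0)
    stop("'cell_km' must be a single positive number")
  structure(list(water = water, cell_km = as.numeric(cell_km),
                 origin = as.numeric(origin)),
            class = "water_raster")
}

#' @export
print.water_raster <- function(x, ...) {
  cat(sprintf("water_raster: %d x %d cells, %.3g km resolution, %d water (%.1f%%)\n",
              nrow(x$water), ncol(x$water), x$cell_km, sum(x$water),
              100 * mean(x$water)))
  invisible(x)
}

# (row, col) of a cell -> centre coordinates in km, and back.
cell_centre <- function(raster, row, col) {
  nr <- nrow(raster$water)
  cbind(x = raster$origin[1] + (col - 0.5) * raster$cell_km,
        y = raster$origin[2] + (nr - row + 0.5) * raster$cell_km)
}

point_to_cell <- function(raster, x, y) {
  nr <- nrow(raster$water)
  col <- floor((x - raster$origin[1]) / raster$cell_km) + 1L
  row <- nr - floor((y - raster$origin[2]) / raster$cell_km)
  cbind(row = row, col = col)
}

# Snap a point to the nearest water cell within `snap_cells` cells (by
# centre-to-centre distance). Errors if none is found.
snap_to_water <- function(raster, x, y, snap_cells = 3) {
  w <- raster$water
  cell <- point_to_cell(raster, x, y)
  r0 <- min(max(cell[1, "row"], 1L), nrow(w))
  c0 <- min(max(cell[1, "col"], 1L), ncol(w))
  if (w[r0, c0] && all(cell[1, ] == c(r0, c0)))
    return(c(row = r0, col = c0))
  rad <- ceiling(snap_cells)
  rows <- max(1L, r0 - rad):min(nrow(w), r0 + rad)
  cols <- max(1L, c0 - rad):min(ncol(w), c0 + rad)
  cand <- expand.grid(row = rows, col = cols)
  cand <- cand[w[as.matrix(cand)], , drop = FALSE]
  if (nrow(cand) == 0L)
    stop(sprintf("no water cell within %s cells of point (%.3g, %.3g)",
                 snap_cells, x, y))
  cen <- cell_centre(raster, cand$row, cand$col)
  d <- sqrt((cen[, "x"] - x)^2 + (cen[, "y"] - y)^2)
  if (min(d) > snap_cells * raster$cell_km * sqrt(2))
    stop(sprintf("no water cell within snap radius of point (%.3g, %.3g)",
                 x, y))
  i <- which.min(d)
  c(row = cand$row[i], col = cand$col[i])
}

# Build the water-cell adjacency graph: 8-connected by default, diagonal
# steps weighted sqrt(2) * cell size.
water_graph <- function(raster, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  w <- raster$water
  nr <- nrow(w); nc <- ncol(w)
  id <- matrix(seq_len(nr * nc), nr, nc)
  steps <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) steps <- c(steps, list(c(1, 1), c(1, -1)))
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (s in steps) {
    dr <- s[1]; dc <- s[2]
    if (nr - dr < 1L || nc - abs(dc) < 1L) next
    rows <- seq_len(nr - dr)
    cols <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- id[rows, cols, drop = FALSE]
    b <- id[rows + dr, cols + dc, drop = FALSE]
    ok <- w[a] & w[b]
    from <- c(from, a[ok]); to <- c(to, b[ok])
    wt <- c(wt, rep(if (dr != 0 && dc != 0) sqrt(2) * raster$cell_km
                    else raster$cell_km, sum(ok)))
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  g
}

#' Shortest waterway distance between two points
#'
#' Length of the shortest path through water cells between two coordinates,
#' with 8-connectivity by default and diagonal steps weighted by
#' `sqrt(2)` times the cell size. Points not on water are snapped to the
#' nearest water cell within `snap_cells` cells.
#'
#' @param raster A [water_raster()].
#' @param a,b Numeric `c(x, y)` coordinates in km (raster plane).
#' @param snap_cells Snap radius in cells for shoreline points.
#' @param connectivity 4 or 8 (default 8).
#' @return Distance in km (0 when both points snap to the same cell).
#'   Errors with "disconnected" if no water path exists.
#' @export
#' @examples
#' r <- generate_water_raster(c(1, 5), resolution_km = 1)
#' waterway_distance(r, c(0.5, 0.5), c(4.5, 0.5))  # 4 km
waterway_distance <- function(raster, a, b, snap_cells = 3,
                              connectivity = 8) {
  m <- waterway_distance_matrix(raster, rbind(a, b), snap_cells = snap_cells,
                                connectivity = connectivity)
  m[1, 2]
}

#' Pairwise shortest waterway distances among points
#'
#' @param raster A [water_raster()].
#' @param coords Two-column matrix or data frame of (x, y) km coordinates;
#'   row names (or a `site` column) label the output.
#' @inheritParams waterway_distance
#' @return Symmetric km distance matrix.
#' @export
waterway_distance_matrix <- function(raster, coords, snap_cells = 3,
                                     connectivity = 8) {
  if (is.data.frame(coords)) {
    labs <- if ("site" %in% colnames(coords)) coords$site else rownames(coords)
    coords <- as.matrix(coords[, setdiff(colnames(coords), "site"), drop = FALSE])
  } else {
    labs <- rownames(coords)
  }
  coords <- matrix(as.numeric(coords), ncol = 2)
  nr <- nrow(raster$water)
  cells <- t(apply(coords, 1, function(p)
    snap_to_water(raster, p[1], p[2], snap_cells = snap_cells)))
  vids <- (cells[, 2] - 1L) * nr + cells[, 1]
  g <- water_graph(raster, connectivity = connectivity)
  uv <- unique(vids)
  du <- igraph::distances(g, v = uv, to = uv,
                          weights = igraph::E(g)$weight)
  d <- du[match(vids, uv), match(vids, uv), drop = FALSE]
  if (any(!is.finite(d)))
    stop("disconnected: no water path between some point pairs")
  dimnames(d) <- list(labs, labs)
  d
}

#' Project longitude/latitude to a local km plane
#'
#' Equirectangular projection around a reference point: adequate at the
#' scale of a few hundred km, which is the scale this package targets.
#'
#' @param lonlat Two-column matrix or data frame (`longitude`, `latitude`).
#' @param ref Optional `c(lon, lat)` reference; defaults to the centroid.
#' @return Matrix with columns `x`, `y` in km.
#' @export
lonlat_to_km <- function(lonlat, ref = NULL) {
  if (is.data.frame(lonlat))
    lonlat <- as.matrix(lonlat[, c("longitude", "latitude")])
  if (is.null(ref)) ref <- colMeans(lonlat)
  lat0 <- ref[2] * pi / 180
  out <- cbind(x = (lonlat[, 1] - ref[1]) * 111.320 * cos(lat0),
               y = (lonlat[, 2] - ref[2]) * 110.574)
  rownames(out) <- rownames(lonlat)
  out
}

#' Read/write a water raster as an ESRI ASCII grid
#'
#' Plain-text grid format (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value` header followed by rows of 1/0 flags, top row
#' first). Cell values of 1 are water, 0 land.
#'
#' @param raster A [water_raster()].
#' @param path File path.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a `water_raster`.
#' @export
write_ascii_grid <- function(raster, path) {
  w <- raster$water
  hdr <- c(sprintf("ncols %d", ncol(w)),
           sprintf("nrows %d", nrow(w)),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", raster$origin[2]),
           sprintf("cellsize %.10g", raster$cell_km),
           "NODATA_value -9999")
  body <- apply(w * 1L, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  body <- lines[-(1:6)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  water_raster(m == 1, cell_km = val("cellsize"),
               origin = c(val("xllcorner"), val("yllcorner")))
}
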