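#' Categorical landcover raster
#'
#' A single-band categorical raster on an axis-aligned grid in projected
#' metres. `grid` is stored row-major from the top: `grid[r, c]` is the pixel
#' in row `r` from the top edge, column `c` from the left edge. The class map
#' assigns integer codes to the six landcover classes used throughout:
#' forest, shrub_grassland, agriculture, developed, barren, water.
#'
#' @param grid Integer matrix of class codes (rows from the top edge).
#' @param resolution Pixel size in metres (default 30).
#' @param origin Length-2 numeric: (easting, northing) of the top-left corner.
#' @param class_map Named integer vector mapping class name to code; defaults
#'   to forest=1, shrub_grassland=2, agriculture=3, developed=4, barren=5,
#'   water=6.
#' @return Object of class `io_landcover`.
#' @export
landcover_raster <- function(grid, resolution = 30, origin = c(0, 0),
                             class_map = c(forest = 1L, shrub_grassland = 2L,
                                           agriculture = 3L, developed = 4L,
                                           barren = 5L, water = 6L)) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  stopifnot(resolution > 0, length(origin) == 2)
  unknown <- setdiff(unique(as.vector(grid)), unname(class_map))
  if (length(unknown) > 0) {
    stop("raster contains codes not in the class map: ",
         paste(unknown, collapse = ", "))
  }
  structure(
    list(grid = grid, resolution = resolution, origin = as.numeric(origin),
         class_map = class_map),
    class = "io_landcover"
  )
}

#' @export
print.io_landcover <- function(x, ...) {
  cat(sprintf("<io_landcover> %d x %d pixels at %g m (%g x %g km)\n",
              nrow(x$grid), ncol(x$grid), x$resolution,
              ncol(x$grid) * x$resolution / 1000,
              nrow(x$grid) * x$resolution / 1000))
  tab <- table(factor(as.vector(x$grid), levels = unname(x$class_map),
                      labels = names(x$class_map)))
  print(round(tab / sum(tab), 3))
  invisible(x)
}

# column/row indices of the pixels containing points; half-open pixel
# membership [x, x+res) per axis with the right/down convention, i.e. a point
# on an interior edge belongs to the pixel to the right / below.
.raster_index <- function(raster, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  col <- floor((pts[, 1] - raster$origin[1]) / raster$resolution) + 1L
  row <- floor((raster$origin[2] - pts[, 2]) / raster$resolution) + 1L
  # the point exactly on the top edge belongs to the first row
  row[raster$origin[2] - pts[, 2] == 0] <- 1L
  cbind(row = row, col = col)
}

.in_extent <- function(raster, idx) {
  idx[, 1] >= 1 & idx[, 1] <= nrow(raster$grid) &
    idx[, 2] >= 1 & idx[, 2] <= ncol(raster$grid)
}

#' Landcover class at point locations
#'
#' @param raster An `io_landcover`.
#' @param pts Two-column coordinate matrix (or length-2 vector) in metres.
#' @return Character vector of class names.
#' @export
class_at <- function(raster, pts) {
  idx <- .raster_index(raster, pts)
  if (!all(.in_extent(raster, idx))) {
    stop("point(s) outside the raster extent")
  }
  codes <- raster$grid[cbind(idx[, 1], idx[, 2])]
  names(raster$class_map)[match(codes, raster$class_map)]
}

#' Class codes at points, NA outside the extent (no error)
#' @inheritParams class_at
#' @return Integer class codes with NA for out-of-extent points.
#' @export
class_code_at <- function(raster, pts) {
  idx <- .raster_index(raster, pts)
  ok <- .in_extent(raster, idx)
  out <- rep(NA_integer_, nrow(idx))
  out[ok] <- raster$grid[cbind(idx[ok, 1], idx[ok, 2])]
  out
}

#' Percent cover of landcover classes within a circular buffer
#'
#' The fraction of pixels whose centres lie within `radius` of each point and
#' whose class belongs to `classes`, over all pixels whose centres lie within
#' `radius`. Pixel-in-circle membership is by centre inclusion (the natural
#' reading of "proportion of pixels"); partial pixels are not area-weighted.
#'
#' @param raster An `io_landcover`.
#' @param pts Two-column coordinate matrix or length-2 vector (metres).
#' @param radius Buffer radius in metres.
#' @param classes Character vector of class names to count (may be empty, in
#'   which case the cover is 0).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
percent_cover <- function(raster, pts, radius, classes) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  stopifnot(radius > 0)
  codes <- raster$class_map[intersect(classes, names(raster$class_map))]
  res <- raster$resolution
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  # candidate pixel-centre offsets around each point's pixel
  w <- ceiling(radius / res) + 1L
  off <- expand.grid(dr = -w:w, dc = -w:w)
  idx <- .raster_index(raster, pts)
  out <- numeric(nrow(pts))
  # centre coordinates of pixel (r, c)
  cx0 <- raster$origin[1] + (idx[, 2] - 0.5) * res
  cy0 <- raster$origin[2] - (idx[, 1] - 0.5) * res
  for (i in seq_len(nrow(pts))) {
    rr <- idx[i, 1] + off$dr
    cc <- idx[i, 2] + off$dc
    cx <- cx0[i] + off$dc * res
    cy <- cy0[i] - off$dr * res
    inside <- (cx - pts[i, 1])^2 + (cy - pts[i, 2])^2 <= radius^2
    valid <- inside & rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ntot <- sum(valid)
    if (ntot == 0) {
      stop("no pixel centres within the buffer (degenerate radius or point far outside extent)")
    }
    if (length(codes) == 0) {
      out[i] <- 0
    } else {
      vals <- raster$grid[cbind(rr[valid], cc[valid])]
      out[i] <- sum(vals %in% codes) / ntot
    }
  }
  out
}

#' Remove fixes on water or barren pixels
#'
#' @param fixes Two-column coordinate matrix, or a data frame with `easting`
#'   and `northing` columns.
#' @param raster An `io_landcover`.
#' @param drop_classes Classes to remove (default water and barren).
#' @return List with `retained` (row indices kept), `removed` (data frame of
#'   index and reason) and `counts` (removals per class).
#' @export
filter_locations_by_class <- function(fixes, raster,
                                      drop_classes = c("water", "barren")) {
  if (is.data.frame(fixes)) {
    pts <- cbind(fixes$easting, fixes$northing)
  } else {
    pts <- as.matrix(fixes)
  }
  cls <- class_at(raster, pts)
  drop <- cls %in% drop_classes
  list(
    retained = which(!drop),
    removed = data.frame(index = which(drop), reason = cls[drop]),
    counts = table(factor(cls[drop], levels = drop_classes))
  )
}

#' Write / read a landcover raster as an ESRI ASCII grid with a JSON class map
#'
#' Plain-text raster exchange: the grid goes to an ESRI ASCII `.asc` file and
#' the class map to a JSON sidecar (`<path>.classes.json`).
#'
#' @param raster An `io_landcover`.
#' @param path Output `.asc` path.
#' @return Invisibly, `path`.
#' @export
write_landcover_asc <- function(raster, path) {
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  header <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.6f", raster$origin[1]),
    sprintf("yllcorner %.6f", raster$origin[2] - nr * raster$resolution),
    sprintf("cellsize %.6f", raster$resolution),
    "NODATA_value -9999"
  )
  body <- apply(raster$grid, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  jsonlite::write_json(as.list(raster$class_map),
                       paste0(path, ".classes.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_landcover_asc
#' @export
read_landcover_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  getv <- function(key) {
    as.numeric(sub(paste0("^", key, "\\s+"), "",
                   hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]))
  }
  nc <- getv("ncols"); nr <- getv("nrows")
  xll <- getv("xllcorner"); yll <- getv("yllcorner"); res <- getv("cellsize")
  body <- lines[-(1:6)]
  grid <- do.call(rbind, lapply(body, function(l) {
    as.integer(strsplit(trimws(l), "\\s+")[[1]])
  }))
  cm_path <- paste0(path, ".classes.json")
  class_map <- if (file.exists(cm_path)) {
    unlist(jsonlite::read_json(cm_path))
  } else {
    c(forest = 1L, shrub_grassland = 2L, agriculture = 3L,
      developed = 4L, barren = 5L, water = 6L)
  }
  landcover_raster(grid, resolution = res,
                   origin = c(xll, yll + nr * res),
                   class_map = setNames(as.integer(class_map),
                                        names(class_map)))
}
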