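#' In-memory single-band raster
#'
#' Lightweight regular-grid raster used for every gridded product in the
#' pipeline (DTM, CHM, TCH, AGB, SD and covariate layers). Values are stored
#' as a numeric matrix with rows running south to north (row 1 is the
#' southernmost band) and columns west to east; `NA` marks nodata in memory
#' (a sentinel is only used on disk).
#'
#' @param values numeric matrix, `nrow` bands of `ncol` cells.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cell cell size in metres.
#' @param crs CRS identifier carried as metadata. Intermediates default to a
#'   projected working CRS; final map products are conventionally tagged
#'   `"EPSG:4326"` on export.
#' @return An object of class `amz_raster`.
#' @export
amz_raster <- function(values, xmin = 0, ymin = 0, cell = 1,
                       crs = "EPSG:32721") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell <= 0) stop_amz("cell size must be positive, got %g", cell)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cell = cell, crs = crs),
    class = "amz_raster"
  )
}

#' @export
print.amz_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<amz_raster> %d x %d cells of %g m, origin (%g, %g), crs %s\n",
    nrow(v), ncol(v), x$cell, x$xmin, x$ymin, x$crs
  ))
  ok <- is.finite(v)
  if (any(ok)) {
    cat(sprintf("  values: min %.3f  mean %.3f  max %.3f  (nodata %d/%d)\n",
                min(v[ok]), mean(v[ok]), max(v[ok]), sum(!ok), length(v)))
  } else {
    cat("  all nodata\n")
  }
  invisible(x)
}

is_amz_raster <- function(x) inherits(x, "amz_raster")

#' Cell-center coordinates of a raster
#'
#' @param r an [amz_raster()].
#' @return list with vectors `x` (length ncol) and `y` (length nrow) of
#'   cell-center coordinates in metres.
#' @export
cell_centers <- function(r) {
  list(
    x = r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cell,
    y = r$ymin + (seq_len(nrow(r$values)) - 0.5) * r$cell
  )
}

# row/col of the cell containing (x, y); NA outside the grid
cell_index <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$cell) + 1L
  row <- floor((y - r$ymin) / r$cell) + 1L
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Nearest-pixel raster lookup
#'
#' Returns the value of the cell containing each (x, y); `NA` outside the
#' grid footprint. This is the "corresponding pixel" lookup used by cloud
#' normalization — deliberately not bilinear.
#'
#' @param r an [amz_raster()].
#' @param x,y coordinate vectors (m).
#' @return numeric vector of cell values.
#' @export
raster_extract <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

same_grid <- function(a, b, tol = 1e-6) {
  is_amz_raster(a) && is_amz_raster(b) &&
    all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cell - b$cell) < tol
}

# Block-mean aggregation by an integer factor with a minimum-valid-coverage
# rule: blocks whose fraction of valid source cells falls below
# min_valid_fraction become nodata.
block_aggregate <- function(r, factor, min_valid_fraction) {
  v <- r$values
  if (factor == 1L) return(r)
  if (nrow(v) %% factor != 0L || ncol(v) %% factor != 0L) {
    stop_amz(
      "grid (%d x %d) is not divisible by aggregation factor %d",
      nrow(v), ncol(v), factor
    )
  }
  nr <- nrow(v) %/% factor
  nc <- ncol(v) %/% factor
  ri <- rep(rep(seq_len(nr), each = factor), times = ncol(v))
  ci <- rep(seq_len(nc), each = nrow(v) * factor)
  grp <- (ci - 1L) * nr + ri
  valid <- is.finite(v)
  nv <- tabulate(grp[valid], nbins = nr * nc)
  sums <- rep(0, nr * nc)
  gv <- grp[valid]
  if (length(gv)) sums <- unname(rowsum(v[valid], gv, reorder = TRUE))
  agg <- rep(NA_real_, nr * nc)
  present <- sort(unique(gv))
  agg[present] <- sums / nv[present]
  frac <- nv / (factor * factor)
  agg[frac < min_valid_fraction] <- NA_real_
  amz_raster(matrix(agg, nr, nc), r$xmin, r$ymin, r$cell * factor, r$crs)
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tools. Nodata is
#' written as the `nodata` sentinel; the CRS is written to a `.prj`-style
#' sidecar text file holding the CRS identifier.
#'
#' @param r an [amz_raster()].
#' @param path output path (conventionally `.asc`).
#' @param nodata sentinel written for `NA` cells.
#' @return `write_raster_asc` returns `path` invisibly; `read_raster_asc`
#'   returns an [amz_raster()].
#' @export
write_raster_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cell),
    sprintf("NODATA_value %g", nodata)
  ), con)
  # ASCII grids run north to south; internal storage runs south to north
  for (i in rev(seq_len(nrow(v)))) {
    writeLines(paste(formatC(v[i, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  writeLines(r$crs, sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  nr <- as.integer(hdr$nrows)
  body <- lines[7:(6 + nr)]
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  v <- do.call(rbind, rev(rows))
  v[v == hdr$nodata_value] <- NA_real_
  prj <- sub("\\.asc$", ".prj", path)
  crs <- if (file.exists(prj)) readLines(prj)[1] else "EPSG:32721"
  amz_raster(v, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs)
}
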