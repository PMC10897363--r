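#' Construct a raster grid
#'
#' `ugrid` is the raster carrier used throughout the package: a rectangular
#' matrix of values on a regular grid in a projected, metre-unit coordinate
#' system. Invalid cells are stored as `NA` internally; the `nodata` sentinel
#' is only used when reading and writing files.
#'
#' @param values Numeric or integer matrix (rows run north to south, columns
#'   west to east). `NA` marks nodata cells.
#' @param cell_size Edge length of a cell in metres (e.g. 10 or 100).
#' @param origin Length-2 numeric, `(x, y)` of the *upper-left* corner of the
#'   upper-left cell in projected coordinates (metres).
#' @param crs_tag Opaque coordinate-system identifier. It is carried through
#'   all operations and compared for equality, never interpreted.
#' @param nodata Sentinel value written to file for `NA` cells.
#'
#' @return An object of class `ugrid`.
#' @examples
#' g <- ugrid(matrix(1:9, 3, 3), cell_size = 10)
#' dim(g)
#' @export
ugrid <- function(values, cell_size, origin = c(0, 0),
                  crs_tag = "local-meters", nodata = -9999) {
  if (!is.matrix(values) || length(values) == 0L) {
    stop("`values` must be a non-empty matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be a numeric (x, y) pair", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("grid values must be finite or NA", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_tag = as.character(crs_tag),
         nodata = as.numeric(nodata)),
    class = "ugrid"
  )
}

#' @export
dim.ugrid <- function(x) dim(x$values)

#' @export
print.ugrid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<ugrid> %d x %d cells, %g m resolution\n", d[1], d[2], x$cell_size))
  cat(sprintf("  origin    : (%g, %g)  crs: %s\n", x$origin[1], x$origin[2], x$crs_tag))
  if (length(v)) {
    cat(sprintf("  values    : [%g, %g], %d nodata cell(s)\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  values    : all nodata\n")
  }
  invisible(x)
}

#' Test whether two grids are aligned
#'
#' Two grids are aligned when they share cell size, shape, origin and CRS tag,
#' so that cells correspond one-to-one.
#'
#' @param a,b `ugrid` objects.
#' @param tol Numeric tolerance for origin and cell size comparison, in metres.
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "ugrid"), inherits(b, "ugrid"))
  abs(a$cell_size - b$cell_size) <= tol &&
    identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) <= tol) &&
    identical(a$crs_tag, b$crs_tag)
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) {
    stop(sprintf("misaligned %s: cell size, shape, origin and CRS must match", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a raster from an Esri ASCII grid file
#'
#' Reads a single-band raster in the plain-text Esri ASCII grid (AAIGrid)
#' format. Georeferencing must be in a projected, metre-unit system. An
#' optional `.prj` sidecar next to the file supplies the CRS tag.
#'
#' @param path Path to a `.asc` file.
#' @return A [ugrid].
#' @seealso [write_raster()]
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("unreadable raster: file not found: ", path, call. = FALSE)
  head_lines <- tryCatch(readLines(path, n = 6L, warn = FALSE),
                         error = function(e) stop("unreadable raster: ", path, call. = FALSE))
  kv <- strsplit(trimws(head_lines), "\\s+")
  keys <- tolower(vapply(kv, function(x) x[1], ""))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (length(head_lines) < 5L || !all(need %in% keys)) {
    stop("unreadable raster: not an ASCII grid header: ", path, call. = FALSE)
  }
  val <- function(k, default = NA_real_) {
    i <- match(k, keys)
    if (is.na(i)) default else suppressWarnings(as.numeric(kv[[i]][2]))
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  cellsize <- val("cellsize")
  nodata <- val("nodata_value", -9999)
  if (any(is.na(c(ncols, nrows, cellsize))) || ncols < 1L || nrows < 1L || cellsize <= 0) {
    stop("unreadable raster: malformed header: ", path, call. = FALSE)
  }
  n_header <- if ("nodata_value" %in% keys) 6L else 5L
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != nrows * ncols) {
    stop("unreadable raster: expected ", nrows * ncols, " cells, found ",
         length(vals), ": ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs_tag <- if (file.exists(prj)) trimws(readLines(prj, warn = FALSE)[1]) else "local-meters"
  if (grepl("GEOGCS|EPSG:4326|degree", crs_tag, ignore.case = TRUE)) {
    stop("raster CRS appears geographic (degrees); a projected metre CRS is required",
         call. = FALSE)
  }
  ugrid(m, cell_size = cellsize,
        origin = c(val("xllcorner"), val("yllcorner") + nrows * cellsize),
        crs_tag = crs_tag, nodata = nodata)
}

#' Write a raster to an Esri ASCII grid file
#'
#' Values are written with 17 significant digits so that
#' `read_raster(write_raster(g))` round-trips doubles bit-identically.
#' The CRS tag is written to a `.prj` sidecar.
#'
#' @param grid A [ugrid].
#' @param path Output path (conventionally `.asc`); its directory must exist.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "ugrid"))
  if (!dir.exists(dirname(path))) {
    stop("cannot write raster: directory does not exist: ", dirname(path), call. = FALSE)
  }
  d <- dim(grid$values)
  m <- grid$values
  if (any(!is.na(m) & m == grid$nodata)) {
    stop("grid contains valid cells equal to the nodata sentinel ", grid$nodata, call. = FALSE)
  }
  m[is.na(m)] <- grid$nodata
  header <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10f", grid$origin[1]),
    sprintf("yllcorner %.10f", grid$origin[2] - d[1] * grid$cell_size),
    sprintf("cellsize %.10f", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata)
  )
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  writeLines(grid$crs_tag, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Aggregate a fine grid to a coarser resolution by blocks
#'
#' Partitions the fine grid into `factor` x `factor` blocks anchored at the
#' raster origin and reduces each block with `mean` or `max`, ignoring nodata.
#' This is the area-weighted 10 m to 100 m step: with a binary input and
#' `reducer = "mean"`, each coarse cell is the fraction of valid fine cells
#' that are 1. Partial blocks at the south/east edge are padded with nodata,
#' so their value is the reduction over the cells that exist. A coarse cell is
#' nodata only when every fine cell in its block is nodata.
#'
#' @param fine A [ugrid].
#' @param factor Positive integer block edge (10 for 10 m to 100 m).
#' @param reducer `"mean"` or `"max"`.
#' @return A [ugrid] with `cell_size * factor` resolution.
#' @export
block_aggregate <- function(fine, factor, reducer = c("mean", "max")) {
  stopifnot(inherits(fine, "ugrid"))
  reducer <- match.arg(reducer)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(fine)
  d <- dim(fine$values)
  nr <- ceiling(d[1] / factor) * factor
  nc <- ceiling(d[2] / factor) * factor
  m <- matrix(NA_real_, nr, nc)
  m[seq_len(d[1]), seq_len(d[2])] <- fine$values
  # reshape to (factor, nr/factor, factor, nc/factor) and reduce over block dims
  a <- array(m, dim = c(factor, nr %/% factor, nc))
  valid <- !is.na(a)
  if (reducer == "mean") {
    a0 <- a; a0[!valid] <- 0
    s <- colSums(a0); n <- colSums(valid)            # (nr/f, nc)
    s <- array(t(s), dim = c(factor, nc %/% factor, nr %/% factor))
    n <- array(t(n), dim = c(factor, nc %/% factor, nr %/% factor))
    tot <- colSums(s); cnt <- colSums(n)             # (nc/f, nr/f)
    out <- t(tot / ifelse(cnt == 0, NA, cnt))
  } else {
    a0 <- a; a0[!valid] <- -Inf
    s <- apply(a0, c(2, 3), max)                     # (nr/f, nc)
    s <- array(t(s), dim = c(factor, nc %/% factor, nr %/% factor))
    out <- t(apply(s, c(2, 3), max))
    out[is.infinite(out)] <- NA
  }
  ugrid(out, cell_size = fine$cell_size * factor, origin = fine$origin,
        crs_tag = fine$crs_tag, nodata = fine$nodata)
}

#' Extract the valid cell values inside a city mask
#'
#' @param grid A [ugrid].
#' @param mask An aligned binary/logical [ugrid]; truthy cells are inside the
#'   city boundary.
#' @return Numeric vector of the grid's non-nodata values where the mask is
#'   true, in row-major (west-east, then north-south) order.
#' @export
masked_cells <- function(grid, mask) {
  stopifnot(inherits(grid, "ugrid"), inherits(mask, "ugrid"))
  stop_if_misaligned(grid, mask, "grid and mask")
  inside <- !is.na(mask$values) & mask$values != 0
  keep <- inside & !is.na(grid$values)
  tv <- t(grid$values)
  tv[t(keep)]
}

# Jointly valid (a, b) values over masked cells, row-major order.
masked_pair <- function(a, b, mask) {
  stop_if_misaligned(a, b, "layers")
  stop_if_misaligned(a, mask, "layer and mask")
  inside <- !is.na(mask$values) & mask$values != 0
  keep <- inside & !is.na(a$values) & !is.na(b$values)
  tk <- t(keep)
  list(a = t(a$values)[tk], b = t(b$values)[tk])
}

#' Plot a grid with ggplot2
#'
#' @param object A [ugrid].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ugrid <- function(object, ...) {
  d <- dim(object$values)
  df <- data.frame(
    x = object$origin[1] + (rep(seq_len(d[2]), each = d[1]) - 0.5) * object$cell_size,
    y = object$origin[2] - (rep(seq_len(d[1]), times = d[2]) - 0.5) * object$cell_size,
    value = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}
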