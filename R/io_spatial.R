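#' Read an ESRI ASCII grid layer
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values ordered
#' north-to-south. Coordinates are WGS84 decimal degrees; values are
#' registered to cell centers. NODATA cells become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A `climate_layer`: list with `values` (matrix, row 1 = north),
#'   `ncols`, `nrows`, `xll`, `yll`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
           "nodata_value")
  if (!all(req %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, " (need ",
         paste(req, collapse = ", "), ")")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("expected ", nc * nr, " values, found ", length(vals), " in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  structure(list(values = m, ncols = nc, nrows = nr,
                 xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = hdr$nodata_value),
            class = "climate_layer")
}

#' Write a layer to an ESRI ASCII grid file
#' @param layer A `climate_layer` (or a stack plus `name` of one layer).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path) {
  m <- layer$values
  m[is.na(m)] <- layer$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", layer$ncols),
               sprintf("nrows %d", layer$nrows),
               sprintf("xllcorner %.10g", layer$xll),
               sprintf("yllcorner %.10g", layer$yll),
               sprintf("cellsize %.10g", layer$cellsize),
               sprintf("NODATA_value %.10g", layer$nodata)), con)
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                                  digits = 10),
                                           collapse = " ")), con)
  invisible(path)
}

#' Assemble aligned layers into a climate stack
#'
#' All layers must share extent, cell size and dimensions; the valid mask
#' is the intersection of the layers' data cells.
#'
#' @param layers Named list of `climate_layer` objects, or a directory (or
#'   vector of `.asc` paths) to read.
#' @return Object of class `climate_stack`: `layers` (named list of value
#'   matrices), grid geometry fields, and `mask` (logical matrix of valid
#'   cells).
#' @export
climate_stack <- function(layers) {
  if (is.character(layers)) {
    paths <- if (length(layers) == 1L && dir.exists(layers))
      list.files(layers, pattern = "\\.asc$", full.names = TRUE) else layers
    if (length(paths) == 0L) stop("no .asc layers found")
    nm <- sub("\\.asc$", "", basename(paths))
    layers <- stats::setNames(lapply(paths, read_ascii_grid), nm)
  }
  stopifnot(length(layers) >= 1L)
  if (is.null(names(layers)) || any(names(layers) == ""))
    names(layers) <- paste0("layer", seq_along(layers))
  ref <- layers[[1L]]
  for (l in layers) {
    same <- isTRUE(all.equal(c(l$ncols, l$nrows, l$xll, l$yll, l$cellsize),
                             c(ref$ncols, ref$nrows, ref$xll, ref$yll,
                               ref$cellsize)))
    if (!same) stop("layer grids are not aligned (extent/cellsize mismatch)")
  }
  mask <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  structure(list(layers = lapply(layers, `[[`, "values"),
                 ncols = ref$ncols, nrows = ref$nrows, xll = ref$xll,
                 yll = ref$yll, cellsize = ref$cellsize,
                 nodata = ref$nodata, mask = mask),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("Climate stack: %d layer(s), %d x %d cells, %d valid\n",
              length(x$layers), x$nrows, x$ncols, sum(x$mask)))
  invisible(x)
}

# Row/column of the cell containing each lon/lat point; NA outside extent.
cell_index <- function(stack, lon, lat) {
  col <- floor((lon - stack$xll) / stack$cellsize) + 1L
  row_from_s <- floor((lat - stack$yll) / stack$cellsize) + 1L
  row <- stack$nrows - row_from_s + 1L  # row 1 is northernmost
  out <- cbind(row = as.integer(row), col = as.integer(col))
  bad <- col < 1L | col > stack$ncols | row < 1L | row > stack$nrows
  out[bad, ] <- NA_integer_
  out
}

# Lon/lat of cell centers for row/col indices.
cell_center <- function(stack, row, col) {
  cbind(longitude = stack$xll + (col - 0.5) * stack$cellsize,
        latitude = stack$yll + (stack$nrows - row + 0.5) * stack$cellsize)
}

#' Read georeferenced occurrence records
#'
#' CSV with columns `taxon`, `longitude`, `latitude` (WGS84 decimal
#' degrees).
#'
#' @param path CSV path.
#' @param taxon Optional taxon label to filter to.
#' @return Object of class `occurrence_set`: data frame of records.
#' @export
read_occurrences <- function(path, taxon = NULL) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("taxon", "longitude", "latitude")
  if (!all(req %in% names(df)))
    stop("occurrence CSV must have columns: ", paste(req, collapse = ", "))
  if (any(!is.finite(df$longitude)) || any(!is.finite(df$latitude)))
    stop("non-numeric coordinates in occurrence CSV")
  if (!is.null(taxon)) df <- df[df$taxon == taxon, ]
  occurrence_set(df)
}

#' @rdname read_occurrences
#' @param records Data frame with `taxon`, `longitude`, `latitude`.
#' @export
occurrence_set <- function(records) {
  stopifnot(all(c("taxon", "longitude", "latitude") %in% names(records)))
  structure(records[, c("taxon", "longitude", "latitude")],
            class = c("occurrence_set", "data.frame"))
}

#' Write occurrences to CSV
#' @param occ An `occurrence_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  write.csv(as.data.frame(occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deduplicate occurrences to one record per raster cell
#'
#' Records outside the stack extent or on nodata cells are dropped (with a
#' warning); within each taxon at most one record per grid cell is kept
#' (the first). Idempotent.
#'
#' @param occ An `occurrence_set`.
#' @param stack A [climate_stack()].
#' @return Deduplicated `occurrence_set` with attached `cells` attribute
#'   (row/col per record).
#' @export
dedup_occurrences <- function(occ, stack) {
  idx <- cell_index(stack, occ$longitude, occ$latitude)
  outside <- is.na(idx[, 1])
  valid <- !outside
  onnodata <- rep(FALSE, nrow(occ))
  onnodata[valid] <- !stack$mask[cbind(idx[valid, 1], idx[valid, 2])]
  drop <- outside | onnodata
  if (any(drop))
    warning(sum(outside), " record(s) outside extent and ", sum(onnodata),
            " on nodata cells dropped")
  occ <- occ[!drop, , drop = FALSE]
  idx <- idx[!drop, , drop = FALSE]
  key <- paste(occ$taxon, idx[, 1], idx[, 2])
  keep <- !duplicated(key)
  out <- occurrence_set(occ[keep, , drop = FALSE])
  attr(out, "cells") <- idx[keep, , drop = FALSE]
  out
}
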