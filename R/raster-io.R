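#' Read and write benthoscape rasters
#'
#' Two on-disk formats are supported, both round-tripping values, origin and
#' cell size exactly:
#'
#' * `"text_grid"` — the ESRI-ASCII-style grid (header lines `ncols`,
#'   `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`, then
#'   rows of values north-to-south).
#' * `"geotiff"` — a single-band 8-bit TIFF holding the class codes
#'   (nodata encoded as 255) with an ESRI world file (`.tfw`) alongside it
#'   carrying the georeferencing. This is the plain-TIFF+world-file dialect,
#'   readable by common GIS tools.
#'
#' @param path File path. For `"geotiff"` the world file is `path` with its
#'   extension replaced by `.tfw`.
#' @param format `"text_grid"` or `"geotiff"`; inferred from the extension
#'   (`.asc`/`.txt` vs `.tif`/`.tiff`) when missing.
#' @param raster A [bentho_raster()].
#' @return `read_raster()` returns a [bentho_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path, format = NULL) {
  format <- format %||% infer_raster_format(path)
  if (!file.exists(path)) abort(paste0("raster file does not exist: ", path))
  switch(format,
    text_grid = read_text_grid(path),
    geotiff = read_tiff_grid(path),
    abort(paste0("unknown raster format: ", format))
  )
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path, format = NULL) {
  stopifnot(inherits(raster, "bentho_raster"))
  format <- format %||% infer_raster_format(path)
  switch(format,
    text_grid = write_text_grid(raster, path),
    geotiff = write_tiff_grid(raster, path),
    abort(paste0("unknown raster format: ", format))
  )
  invisible(path)
}

infer_raster_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt", "grd")) return("text_grid")
  if (ext %in% c("tif", "tiff")) return("geotiff")
  abort(paste0("cannot infer raster format from extension: .", ext))
}

TEXT_GRID_NODATA <- -9999L

read_text_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing) > 0) {
    abort(paste0("malformed text grid header; missing: ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.finite(hdr$cellsize) || hdr$cellsize <= 0) {
    abort("malformed text grid header: cellsize must be > 0")
  }
  nodata <- hdr$nodata_value %||% TEXT_GRID_NODATA
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]),
                                                      "\\s+"))))
  vals <- vals[!is.na(vals) | FALSE]
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort(sprintf("text grid has %d values, expected %d",
                  length(vals), hdr$ncols * hdr$nrows))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  # file rows run north -> south; internal convention is south-up
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  bentho_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

write_text_grid <- function(raster, path) {
  m <- raster$values[rev(seq_len(raster$n_rows)), , drop = FALSE]
  m[is.na(m)] <- TEXT_GRID_NODATA
  hdr <- c(
    paste("ncols", raster$n_cols),
    paste("nrows", raster$n_rows),
    paste("xllcorner", format(raster$origin_x, digits = 17)),
    paste("yllcorner", format(raster$origin_y, digits = 17)),
    paste("cellsize", format(raster$cell_size, digits = 17)),
    paste("nodata_value", TEXT_GRID_NODATA)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
}

TIFF_NODATA <- 255L

world_file_path <- function(path) {
  sub("\\.[^.]*$", ".tfw", path)
}

read_tiff_grid <- function(path) {
  wf <- world_file_path(path)
  if (!file.exists(wf)) abort(paste0("world file not found: ", wf))
  tfw <- as.numeric(readLines(wf, warn = FALSE))
  if (length(tfw) != 6 || anyNA(tfw)) abort("malformed world file")
  if (tfw[2] != 0 || tfw[3] != 0) abort("rotated rasters are not supported")
  cell <- tfw[1]
  if (!isTRUE(all.equal(-tfw[4], cell)) || cell <= 0) {
    abort("non-square or non-positive cells in world file")
  }
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2) abort("expected a single-band TIFF")
  m[m == TIFF_NODATA] <- NA
  # TIFF rows run north -> south
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  origin_x <- tfw[5] - cell / 2
  origin_y <- tfw[6] + cell / 2 - nrow(m) * cell
  bentho_raster(m, origin_x, origin_y, cell)
}

write_tiff_grid <- function(raster, path) {
  m <- raster$values[rev(seq_len(raster$n_rows)), , drop = FALSE]
  m[is.na(m)] <- TIFF_NODATA
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  cell <- raster$cell_size
  tfw <- c(cell, 0, 0, -cell,
           raster$origin_x + cell / 2,
           raster$origin_y + raster$n_rows * cell - cell / 2)
  writeLines(format(tfw, digits = 17), world_file_path(path))
}
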