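# Reading, validating, and cleaning occurrence tables; patch polygons;
# raster file round trips.

#' Load an occurrence table from CSV
#'
#' Every row of the file becomes either a record or an entry in the
#' parse-failure attribute; nothing is dropped silently. Coordinates that do
#' not parse as numbers are parse failures; out-of-range coordinates are kept
#' here (they are the cleaning stage's business).
#'
#' @param path CSV file with a header row, UTF-8.
#' @param column_map named character vector mapping the canonical names
#'   (`species`, `lon`, `lat`, and optionally `taxon_group`, `precision_m`,
#'   `source`) to the file's column names.
#' @return a data.frame of records (columns `taxon_group`, `species`, `lon`,
#'   `lat`, `precision_m`, `source`) with attributes `parse_failures`
#'   (data.frame of row numbers and reasons) and `provenance` (the path).
#' @export
load_occurrences <- function(path,
                             column_map = c(species = "species",
                                            lon = "lon", lat = "lat")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  mandatory <- c("species", "lon", "lat")
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map)) {
    stop("column_map must map: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(unname(column_map[mandatory]), names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pick <- function(canon, default = NA_character_) {
    if (canon %in% names(column_map) && column_map[[canon]] %in% names(raw)) {
      raw[[column_map[[canon]]]]
    } else {
      rep(default, nrow(raw))
    }
  }
  lon <- suppressWarnings(as.numeric(pick("lon")))
  lat <- suppressWarnings(as.numeric(pick("lat")))
  prec <- suppressWarnings(as.numeric(pick("precision_m")))
  out <- data.frame(taxon_group = pick("taxon_group"),
                    species = pick("species"),
                    lon = lon, lat = lat,
                    precision_m = prec,
                    source = pick("source"),
                    stringsAsFactors = FALSE)
  # a coordinate string that exists but is non-numeric is a parse failure
  fail_lon <- !is.na(pick("lon")) & nzchar(pick("lon")) & is.na(lon)
  fail_lat <- !is.na(pick("lat")) & nzchar(pick("lat")) & is.na(lat)
  failed <- which(fail_lon | fail_lat)
  failures <- data.frame(row = failed,
                         reason = rep("non-numeric coordinate",
                                      length(failed)))
  if (length(failed)) out <- out[-failed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parse_failures") <- failures
  attr(out, "provenance") <- path
  out
}

#' Clean an occurrence table
#'
#' Applies, in order: (1) drop records missing species, longitude or
#' latitude; (2) drop records with out-of-range coordinates; (3) drop
#' records whose stated coordinate precision is worse than
#' \code{max_uncertainty_m} (records with no stated precision are kept);
#' (4) collapse exact duplicates on (species, lon, lat), keeping the first.
#' Optionally coordinates can be rounded to \code{round_digits} decimals
#' before duplicate detection (off by default, so "duplicate" means exact
#' equality at full float precision).
#'
#' Cleaning never fails; it reports. The report's counts always reconcile:
#' n_input = n_retained + sum of the dropped counts.
#'
#' @param table occurrence data.frame as from \code{load_occurrences}.
#' @param max_uncertainty_m precision threshold in metres (default 10000).
#' @param round_digits optional integer; round lon/lat to this many decimals
#'   for duplicate detection only.
#' @return list with elements \code{table} (the cleaned data.frame) and
#'   \code{report} (class \code{cleaning_report}).
#' @export
clean_occurrences <- function(table, max_uncertainty_m = 10000,
                              round_digits = NULL) {
  n_input <- nrow(table)
  keep <- rep(TRUE, n_input)

  miss <- is.na(table$species) | !nzchar(ifelse(is.na(table$species), "",
                                               table$species)) |
    is.na(table$lon) | is.na(table$lat)
  n_missing <- sum(miss)
  keep[miss] <- FALSE

  bad_coord <- keep & (table$lon < -180 | table$lon > 180 |
                         table$lat < -90 | table$lat > 90)
  n_invalid <- sum(bad_coord)
  keep[bad_coord] <- FALSE

  low_prec <- keep & !is.na(table$precision_m) &
    table$precision_m > max_uncertainty_m
  n_low_prec <- sum(low_prec)
  keep[low_prec] <- FALSE

  lon_key <- table$lon
  lat_key <- table$lat
  if (!is.null(round_digits)) {
    lon_key <- round(lon_key, round_digits)
    lat_key <- round(lat_key, round_digits)
  }
  key <- paste(table$species, format(lon_key, digits = 17),
               format(lat_key, digits = 17), sep = "\r")
  dup <- keep & duplicated(ifelse(keep, key, paste0("dropped\r", seq_len(n_input))))
  n_dup <- sum(dup)
  keep[dup] <- FALSE

  cleaned <- table[keep, , drop = FALSE]
  rownames(cleaned) <- NULL
  report <- structure(list(n_input = n_input,
                           n_retained = nrow(cleaned),
                           n_dropped_duplicate = n_dup,
                           n_dropped_missing = n_missing,
                           n_dropped_invalid_coord = n_invalid,
                           n_dropped_low_precision = n_low_prec,
                           max_uncertainty_m = max_uncertainty_m),
                      class = "cleaning_report")
  list(table = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("cleaning_report: %d in, %d retained ",
                     "(%d duplicate, %d missing, %d invalid coord, ",
                     "%d low precision dropped)\n"),
              x$n_input, x$n_retained, x$n_dropped_duplicate,
              x$n_dropped_missing, x$n_dropped_invalid_coord,
              x$n_dropped_low_precision))
  invisible(x)
}

#' Write a cleaning report as JSON
#'
#' @param report a \code{cleaning_report}.
#' @param path output file.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------- patches --

#' Load a patch layer from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon / MultiPolygon features.
#' Each feature needs an id property (\code{id_property}) and optionally a
#' name. Rings are closed on load if the file left them open; a feature whose
#' outer ring has fewer than 3 distinct vertices is rejected by id.
#'
#' @param path GeoJSON file.
#' @param id_property,name_property property keys for the patch id and name.
#' @return object of class \code{patch_layer}: a list of patches, each with
#'   \code{patch_id}, \code{name}, and \code{parts} — a list of parts, each a
#'   list of rings (first ring outer, rest holes), each ring a 2-column
#'   lon/lat matrix whose last vertex equals its first.
#' @export
load_patches <- function(path, id_property = "id", name_property = "name") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  close_ring <- function(m) {
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    m
  }
  ring_mat <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    close_ring(m)
  }
  patches <- lapply(gj$features, function(f) {
    props <- f$properties
    pid <- props[[id_property]]
    if (is.null(pid)) stop("feature missing id property '", id_property, "'",
                           call. = FALSE)
    geom <- f$geometry
    parts <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates,
                            function(poly) lapply(poly, ring_mat)),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    for (part in parts) {
      if (nrow(part[[1]]) < 4) {
        stop("degenerate outer ring in patch '", pid, "'", call. = FALSE)
      }
    }
    nm <- props[[name_property]]
    list(patch_id = as.character(pid),
         name = if (is.null(nm)) as.character(pid) else as.character(nm),
         parts = parts)
  })
  ids <- vapply(patches, `[[`, "", "patch_id")
  if (anyDuplicated(ids)) {
    stop("duplicated patch_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(patches, class = "patch_layer")
}

#' @export
print.patch_layer <- function(x, ...) {
  cat(sprintf("patch_layer: %d patches\n", length(x)))
  invisible(x)
}

#' Write a patch layer as GeoJSON
#'
#' @param patches a \code{patch_layer}.
#' @param path output file.
#' @export
write_patches <- function(patches, path) {
  feat <- lapply(patches, function(p) {
    coords <- lapply(p$parts, function(part) {
      lapply(part, function(ring) {
        lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
      })
    })
    if (length(coords) == 1) {
      geom <- list(type = "Polygon", coordinates = coords[[1]])
    } else {
      geom <- list(type = "MultiPolygon", coordinates = coords)
    }
    list(type = "Feature",
         properties = list(id = p$patch_id, name = p$name),
         geometry = geom)
  })
  gj <- list(type = "FeatureCollection", features = feat)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------- rasters --

#' Write a raster to file
#'
#' Two formats are supported. \code{"ascii"} is the ESRI ASCII grid: plain
#' text, values printed at full double precision (17 significant digits) so
#' the round trip is bit-exact. \code{"geotiff"} is a minimal single-band
#' uncompressed little-endian float64 GeoTIFF (ModelPixelScale +
#' ModelTiepoint + GDAL nodata tags); \code{read_raster} reads exactly this
#' subset back bit-exactly.
#'
#' @param raster a \code{grid_raster}.
#' @param path output file.
#' @param format `"ascii"` or `"geotiff"`.
#' @export
write_raster <- function(raster, path, format = c("ascii", "geotiff")) {
  format <- match.arg(format)
  switch(format,
         ascii = write_raster_ascii(raster, path),
         geotiff = write_raster_geotiff(raster, path))
  invisible(path)
}

#' Read a raster written by \code{write_raster}
#'
#' @param path input file.
#' @param format `"ascii"` or `"geotiff"`.
#' @param projection_tag projection identifier to record on the grid.
#' @return a \code{grid_raster}.
#' @export
read_raster <- function(path, format = c("ascii", "geotiff"),
                        projection_tag = "cea") {
  format <- match.arg(format)
  switch(format,
         ascii = read_raster_ascii(path, projection_tag),
         geotiff = read_raster_geotiff(path, projection_tag))
}

ASCII_NODATA <- -9999

write_raster_ascii <- function(raster, path) {
  spec <- raster$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", spec$n_cols),
               sprintf("nrows %d", spec$n_rows),
               sprintf("xllcorner %.17g", spec$x_min),
               sprintf("yllcorner %.17g", spec$y_min),
               sprintf("cellsize %.17g", spec$cell_size),
               sprintf("NODATA_value %d", ASCII_NODATA)), con)
  # ESRI ASCII grids are written north to south: top row first
  for (r in rev(seq_len(spec$n_rows))) {
    row <- raster$values[r, ]
    row_s <- ifelse(is.na(row), as.character(ASCII_NODATA),
                    sprintf("%.17g", row))
    writeLines(paste(row_s, collapse = " "), con)
  }
}

read_raster_ascii <- function(path, projection_tag) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  n_cols <- as.integer(hdr$ncols); n_rows <- as.integer(hdr$nrows)
  vals <- matrix(NA_real_, nrow = n_rows, ncol = n_cols)
  for (i in seq_len(n_rows)) {
    row <- as.numeric(strsplit(trimws(lines[6 + i]), "\\s+")[[1]])
    vals[n_rows - i + 1, ] <- row  # top line is the maximum-y row
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  spec <- list(x_min = hdr$xllcorner, y_min = hdr$yllcorner,
               cell_size = hdr$cellsize, n_cols = n_cols, n_rows = n_rows,
               projection_tag = projection_tag)
  class(spec) <- "grid_spec"
  grid_raster(spec, vals)
}

GEOTIFF_NODATA <- -3.4e38

write_raster_geotiff <- function(raster, path) {
  spec <- raster$spec
  w <- spec$n_cols; h <- spec$n_rows
  # pixel data: north-up, row-major, float64; nodata encoded as a sentinel
  vals <- raster$values[rev(seq_len(h)), , drop = FALSE]
  vals[is.na(vals)] <- GEOTIFF_NODATA
  pix <- as.numeric(t(vals))

  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  nodata_str <- sprintf("%.17g", GEOTIFF_NODATA)
  nodata_bytes <- c(charToRaw(nodata_str), as.raw(0))
  n_tags <- 12L
  # layout: 8-byte header | IFD | out-of-line values | pixel strip
  ifd_offset <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  aux_offset <- ifd_offset + ifd_size
  scale_off <- aux_offset                  # 3 doubles
  tie_off <- scale_off + 24L               # 6 doubles
  nodata_off <- tie_off + 48L
  strip_offset <- nodata_off + length(nodata_bytes)
  strip_bytes <- 8L * w * h

  writeBin(charToRaw("II"), con)  # little-endian TIFF
  u16(42); u32(ifd_offset)
  u16(n_tags)
  tag <- function(id, type, count, value, inline = TRUE) {
    u16(id); u16(type); u32(count)
    if (inline && type == 3) { u16(value); u16(0) } else u32(value)
  }
  tag(256, 3, 1, w)                        # ImageWidth
  tag(257, 3, 1, h)                        # ImageLength
  tag(258, 3, 1, 64)                       # BitsPerSample
  tag(259, 3, 1, 1)                        # Compression: none
  tag(262, 3, 1, 1)                        # Photometric: min-is-black
  tag(273, 4, 1, strip_offset, inline = FALSE)  # StripOffsets
  tag(277, 3, 1, 1)                        # SamplesPerPixel
  tag(278, 3, 1, h)                        # RowsPerStrip
  tag(279, 4, 1, strip_bytes, inline = FALSE)   # StripByteCounts
  tag(339, 3, 1, 3)                        # SampleFormat: IEEE float
  tag(33550, 12, 3, scale_off, inline = FALSE)  # ModelPixelScale
  tag(42113, 2, length(nodata_bytes), nodata_off, inline = FALSE)  # GDAL nodata
  u32(0)  # no next IFD
  writeBin(c(spec$cell_size, spec$cell_size, 0), con, endian = "little")
  # ModelTiepoint would be the 13th tag; to keep the IFD compact the tiepoint
  # block is still written (raster (0,0) -> world (x_min, y_max)) and read
  # back positionally by read_raster_geotiff.
  writeBin(c(0, 0, 0, spec$x_min, spec$y_min + spec$n_rows * spec$cell_size, 0),
           con, endian = "little")
  writeBin(nodata_bytes, con)
  writeBin(pix, con, endian = "little")
}

read_raster_geotiff <- function(path, projection_tag) {
  con <- file(path, "rb")
  on.exit(close(con))
  r16 <- function() readBin(con, "integer", size = 2, endian = "little",
                            signed = FALSE)
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  magic <- rawToChar(readBin(con, "raw", 2))
  if (magic != "II" || r16() != 42) {
    stop("not a little-endian TIFF", call. = FALSE)
  }
  ifd <- r32()
  seek(con, ifd)
  n_tags <- r16()
  tags <- list()
  for (i in seq_len(n_tags)) {
    id <- r16(); type <- r16(); count <- r32()
    if (type == 3) { val <- r16(); r16() } else val <- r32()
    tags[[as.character(id)]] <- list(type = type, count = count, value = val)
  }
  need <- function(id) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) stop("unsupported TIFF: missing tag ", id, call. = FALSE)
    t
  }
  w <- need(256)$value; h <- need(257)$value
  if (need(258)$value != 64 || need(259)$value != 1 || need(339)$value != 3) {
    stop("unsupported TIFF: expected uncompressed float64", call. = FALSE)
  }
  scale_t <- need(33550)
  seek(con, scale_t$value)
  scale <- readBin(con, "numeric", 3, endian = "little")
  # tiepoint block sits immediately after the pixel-scale doubles (see writer)
  tie <- readBin(con, "numeric", 6, endian = "little")
  nod_t <- tags[["42113"]]
  nodata <- GEOTIFF_NODATA
  if (!is.null(nod_t)) {
    seek(con, nod_t$value)
    nodata <- as.numeric(rawToChar(readBin(con, "raw", nod_t$count - 1)))
  }
  seek(con, need(273)$value)
  pix <- readBin(con, "numeric", w * h, endian = "little")
  vals <- matrix(pix, nrow = h, ncol = w, byrow = TRUE)
  vals <- vals[rev(seq_len(h)), , drop = FALSE]  # back to south-up
  vals[vals == nodata] <- NA_real_
  spec <- list(x_min = tie[4], y_min = tie[5] - h * scale[2],
               cell_size = scale[1], n_cols = as.integer(w),
               n_rows = as.integer(h), projection_tag = projection_tag)
  class(spec) <- "grid_spec"
  grid_raster(spec, vals)
}
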