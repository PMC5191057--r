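#' Read a B-scan stack from disk
#'
#' Reads a stack of 2D grayscale B-scans either from a multi-page 8-bit TIFF
#' (the canonical format) or from a raw `uint8` binary file accompanied by a
#' JSON sidecar describing the dimensions. Pixel intensities are returned
#' untouched on the 0-255 scale; normalization is a separate, explicit step
#' ([normalize_to_8bit()]).
#'
#' The raw-binary sidecar (default: the data path with extension replaced by
#' `.json`) must declare `rows`, `cols`, `frames` and `dtype` (only
#' `"uint8"` is supported), and may carry the geometry as `lx_um`, `ly_um`,
#' `lz_um`, `n_tissue`. Frames are stored sequentially, each in column-major
#' order.
#'
#' @param path Path to a `.tif`/`.tiff` multi-page file or a raw binary.
#' @param geometry A [voxel_geometry()]; overrides any sidecar geometry.
#'   Defaults to the sidecar geometry if present, else `voxel_geometry()`.
#' @param sidecar Optional explicit sidecar path for raw binaries.
#' @return An [oct_volume()].
#' @export
read_stack <- function(path, geometry = NULL, sidecar = NULL) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grayscale-stored-as-RGB
      storage.mode(p) <- "double"
      p
    })
    d1 <- dim(pages[[1L]])
    for (i in seq_along(pages)) {
      if (!identical(dim(pages[[i]]), d1)) {
        stop_param(sprintf(
          "TIFF page %d is %s but page 1 is %s; all pages must share dimensions",
          i, paste(dim(pages[[i]]), collapse = "x"), paste(d1, collapse = "x")))
      }
    }
    return(oct_volume(pages, geometry %||% voxel_geometry()))
  }
  # raw binary + JSON sidecar
  sidecar <- sidecar %||% paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) {
    stop_param("raw stack needs a JSON sidecar; not found: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("rows", "cols", "frames", "dtype")) {
    if (is.null(meta[[f]])) stop_param("sidecar is missing field '", f, "'")
  }
  if (!identical(tolower(meta$dtype), "uint8")) {
    stop_param("unsupported dtype '", meta$dtype, "' (only uint8)")
  }
  n <- as.integer(meta$rows) * as.integer(meta$cols) * as.integer(meta$frames)
  raw <- readBin(path, what = "integer", n = n + 1L, size = 1L, signed = FALSE)
  if (length(raw) != n) {
    stop_param(sprintf("raw file holds %d bytes but sidecar declares %d", length(raw), n))
  }
  if (is.null(geometry)) {
    geometry <- if (!is.null(meta$lx_um)) {
      voxel_geometry(meta$lx_um, meta$ly_um, meta$lz_um, meta$n_tissue)
    } else {
      voxel_geometry()
    }
  }
  data <- array(as.numeric(raw), dim = c(meta$rows, meta$cols, meta$frames))
  oct_volume(data, geometry)
}

#' Write a B-scan stack to disk
#'
#' Writes an [oct_volume()] as an uncompressed 8-bit multi-page TIFF, or as
#' a raw `uint8` binary plus JSON sidecar when the path does not end in
#' `.tif`/`.tiff`. Intensities must already be integers in 0-255;
#' `read_stack(write_stack(v))` reproduces the pixel payload bit-exactly.
#'
#' @param volume An [oct_volume()] with integer intensities in 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  x <- volume$data
  if (length(x) == 0L) stop_param("refusing to write an empty volume")
  if (min(x) < 0 || max(x) > 255 || any(x != floor(x))) {
    stop_param("volume intensities must be integers in [0, 255]; run normalize_to_8bit() first")
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(dim(x)[3L]), function(i) x[, , i] / 255)
    ok <- tryCatch(
      tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none"),
      error = function(e) stop_param("cannot write TIFF at ", path, ": ", conditionMessage(e)))
  } else {
    g <- volume$geometry
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop_param("cannot open ", path, " for writing"))
    on.exit(close(con))
    writeBin(as.raw(as.vector(x)), con)
    meta <- list(rows = dim(x)[1L], cols = dim(x)[2L], frames = dim(x)[3L],
                 dtype = "uint8", layout = "column-major",
                 lx_um = g$lx, ly_um = g$ly, lz_um = g$lz, n_tissue = g$n_tissue)
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Normalize a frame to the 8-bit 0-255 intensity scale
#'
#' Affinely maps the observed intensity range onto \[0, 255\] and rounds
#' half-up to integers, so the output minimum is 0 and maximum 255. The
#' threshold volumetry and its default enamel window (45-255) assume this
#' scale. A constant frame has no contrast to stretch: it maps to all zeros
#' with a warning.
#'
#' @param frame A numeric matrix (one B-scan).
#' @return An integer-valued matrix on the 0-255 scale.
#' @examples
#' normalize_to_8bit(matrix(c(10, 20, 30), 1))  # 0, 128, 255
#' @export
normalize_to_8bit <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame)) stop_param("frame must be a numeric matrix")
  rng <- range(frame)
  if (diff(rng) == 0) {
    warning("constant frame: no contrast to normalize, mapping to 0", call. = FALSE)
    return(array(0, dim = dim(frame)))
  }
  round_half_up((frame - rng[1L]) / diff(rng) * 255)
}

#' Compensate source-power variation of a frame
#'
#' Scales every pixel by a per-frame factor compensating drift of the light
#' source output power, then clips to \[0, 255\] and rounds half-up. The
#' compensation is bounded at +/-5% (factor in \[0.95, 1.05\]); the applied
#' factor is recorded in the `"power_factors"` attribute so a processing
#' log can be reconstructed.
#'
#' @param frame A numeric matrix on the 0-255 scale.
#' @param factor Scale factor in \[0.95, 1.05\].
#' @return The compensated frame.
#' @export
compensate_power <- function(frame, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0.95 || factor > 1.05) {
    stop_param("power compensation factor must lie in [0.95, 1.05] (+/-5%)")
  }
  if (!is.matrix(frame) || !is.numeric(frame)) stop_param("frame must be a numeric matrix")
  out <- round_half_up(clip_8bit(frame * factor))
  attr(out, "power_factors") <- c(attr(frame, "power_factors"), factor)
  out
}
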