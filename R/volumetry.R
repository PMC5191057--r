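#' Intensity threshold range for enamel segmentation
#'
#' Inclusive intensity bounds selecting enamel pixels on the 0-255 scale.
#' The default 45-255 keeps the bright enamel band and excludes the dark
#' background of the image window.
#'
#' @param lo,hi Inclusive bounds, `0 <= lo <= hi <= 255`.
#' @export
threshold_range <- function(lo = 45, hi = 255) {
  if (!(lo >= 0 && lo <= hi && hi <= 255)) {
    stop_param("threshold must satisfy 0 <= lo <= hi <= 255")
  }
  structure(list(lo = lo, hi = hi), class = "threshold_range")
}

#' Rectangular analysis window of a B-scan
#'
#' The sub-rectangle of every frame over which threshold pixels are
#' counted; one window is applied to the whole stack. Bounds are 1-based
#' and inclusive.
#'
#' @param row_lo,row_hi,col_lo,col_hi Inclusive bounds.
#' @export
image_window <- function(row_lo, row_hi, col_lo, col_hi) {
  if (row_lo > row_hi || col_lo > col_hi || row_lo < 1 || col_lo < 1) {
    stop_param("image window must be non-empty with 1-based inclusive bounds")
  }
  structure(list(row_lo = as.integer(row_lo), row_hi = as.integer(row_hi),
                 col_lo = as.integer(col_lo), col_hi = as.integer(col_hi)),
            class = "image_window")
}

#' Area of one pixel in the B-scan plane
#'
#' `A_pix = lx * ly`, in square micrometres: the in-plane area each counted
#' pixel contributes before the inter-frame spacing turns it into a voxel
#' volume.
#'
#' @param geometry A [voxel_geometry()].
#' @return The pixel area in um^2 (144 for the default 12 x 12 um pitch).
#' @export
pixel_area <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$lx * geometry$ly
}

#' Count window pixels inside a threshold range
#'
#' `N_i` of the volumetry: the number of pixels of the frame's analysis
#' window whose intensity lies inside the (inclusive) threshold range.
#'
#' @param frame A numeric matrix.
#' @param window An [image_window()], or `NULL` for the whole frame.
#' @param threshold A [threshold_range()].
#' @return The integer count.
#' @export
count_threshold_pixels <- function(frame, window = NULL,
                                   threshold = threshold_range()) {
  if (!is.matrix(frame)) stop_param("frame must be a matrix")
  stopifnot(inherits(threshold, "threshold_range"))
  if (is.null(window)) {
    sub <- frame
  } else {
    stopifnot(inherits(window, "image_window"))
    if (window$row_hi > nrow(frame) || window$col_hi > ncol(frame)) {
      stop_param(sprintf("window [%d..%d, %d..%d] exceeds the %d x %d frame",
                         window$row_lo, window$row_hi, window$col_lo,
                         window$col_hi, nrow(frame), ncol(frame)))
    }
    sub <- frame[window$row_lo:window$row_hi, window$col_lo:window$col_hi,
                 drop = FALSE]
  }
  sum(sub >= threshold$lo & sub <= threshold$hi)
}

#' Enamel residual volume of a B-scan stack
#'
#' Threshold-window volumetry: counts the in-window pixels inside the
#' threshold range on every frame (`N_i`) and accumulates the volume
#' `V_tot = sum_i N_i * lx * ly * lz`, reported in mm^3. Each qualifying
#' pixel contributes one voxel of `lx * ly * lz` cubic micrometres (1008
#' for the default 12 x 12 x 7 um geometry); `voxel_volume_um3` overrides
#' that product when an alternative effective calibration is required (see
#' [volumetry_calibration_check()]).
#'
#' @param volume An [oct_volume()].
#' @param window An [image_window()], or `NULL` for whole frames.
#' @param threshold A [threshold_range()].
#' @param geometry A [voxel_geometry()] (default: the volume's own).
#' @param voxel_volume_um3 Optional effective per-voxel volume override.
#' @return A `volumetry_result`: `per_frame_counts`, `total_count`,
#'   `pixel_area_um2`, `voxel_volume_um3`, `volume_mm3`, plus the
#'   parameters used.
#' @export
residual_volume <- function(volume, window = NULL,
                            threshold = threshold_range(),
                            geometry = NULL, voxel_volume_um3 = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  geometry <- geometry %||% volume$geometry
  nf <- n_frames(volume)
  counts <- vapply(seq_len(nf), function(i) {
    count_threshold_pixels(get_frame(volume, i), window, threshold)
  }, numeric(1L))
  vv <- voxel_volume_um3 %||% (geometry$lx * geometry$ly * geometry$lz)
  total <- sum(counts)
  structure(list(per_frame_counts = counts, total_count = total,
                 pixel_area_um2 = pixel_area(geometry),
                 voxel_volume_um3 = vv,
                 volume_mm3 = total * vv * 1e-9,
                 geometry = geometry, threshold = threshold, window = window),
            class = "volumetry_result")
}

#' @export
print.volumetry_result <- function(x, ...) {
  cat(sprintf(
    "<volumetry_result> %d frames, %s qualifying pixels (threshold %g-%g)\n",
    length(x$per_frame_counts), format(x$total_count, big.mark = ","),
    x$threshold$lo, x$threshold$hi))
  cat(sprintf("  voxel %g um^3  ->  V_tot = %.2f mm^3\n",
              x$voxel_volume_um3, x$volume_mm3))
  invisible(x)
}
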