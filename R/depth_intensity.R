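#' Total pixel intensity per depth bin of one B-scan
#'
#' Sums the pixel intensity of a frame within consecutive physical depth
#' bins below the tooth surface. Depth 0 is anchored at `surface_row` (the
#' air gap above the tooth contributes nothing); the pixel at row `r`
#' (`r >= surface_row`) lies at physical depth
#' `(r - surface_row) * ly / n_tissue` micrometres. Bins are half-open
#' `[lo, hi)`, so the bins partition the analyzed range without double
#' counting, and pixels at or beyond the last edge are ignored. The default
#' edges split the visible 1 mm range into four 250 um bins.
#'
#' @param frame A numeric matrix (one B-scan).
#' @param bin_edges_um Strictly increasing physical depth edges starting at
#'   0, um. Default `c(0, 250, 500, 750, 1000)`.
#' @param surface_row Image row (1-based) of the tooth surface.
#' @param geometry A [voxel_geometry()] for the depth scaling.
#' @return A `depth_bin_table`: data frame with columns `bin_lo_um`,
#'   `bin_hi_um`, `total`, `per_frame_average`; attribute `frames_used`.
#' @export
bin_total_intensity <- function(frame, bin_edges_um = c(0, 250, 500, 750, 1000),
                                surface_row = 1, geometry = voxel_geometry()) {
  if (!is.matrix(frame)) stop_param("frame must be a matrix")
  check_bin_edges(bin_edges_um)
  if (surface_row < 1 || surface_row > nrow(frame)) {
    stop_param(sprintf("surface_row %s outside the frame (1..%d)",
                       format(surface_row), nrow(frame)))
  }
  depth <- (seq_len(nrow(frame)) - surface_row) * axial_pitch_um(geometry)
  bin <- findInterval(depth, bin_edges_um)          # [lo, hi) half-open
  nb <- length(bin_edges_um) - 1L
  rs <- rowSums(frame)
  totals <- vapply(seq_len(nb), function(b) sum(rs[bin == b & depth >= 0]),
                   numeric(1L))
  depth_bin_table(bin_edges_um, totals, frames_used = 1L)
}

#' Depth-bin intensity totals summarized over a volume
#'
#' Applies [bin_total_intensity()] to every frame of a stack (each frame
#' anchored at its own surface row) and sums the per-bin totals; the
#' per-frame average is the summed total divided by the number of frames,
#' optionally divided by a reporting scale. Absolute arbitrary-unit levels
#' are instrument-specific, so the scale is a pure presentation factor and
#' is recorded in the result.
#'
#' @param volume An [oct_volume()].
#' @param bin_edges_um As in [bin_total_intensity()].
#' @param surface_rows One surface row per frame (length = frame count), or
#'   a single row recycled to all frames.
#' @param reporting_scale Divisor applied to the per-frame averages
#'   (default 1 = none).
#' @return A `depth_bin_table` with `frames_used` = frame count.
#' @export
summarize_volume_bins <- function(volume, bin_edges_um = c(0, 250, 500, 750, 1000),
                                  surface_rows = 1, reporting_scale = 1) {
  stopifnot(inherits(volume, "oct_volume"))
  check_bin_edges(bin_edges_um)
  nf <- n_frames(volume)
  if (length(surface_rows) == 1L) surface_rows <- rep(surface_rows, nf)
  if (length(surface_rows) != nf) {
    stop_param(sprintf("got %d surface rows for %d frames", length(surface_rows), nf))
  }
  if (reporting_scale <= 0) stop_param("reporting_scale must be > 0")
  nb <- length(bin_edges_um) - 1L
  totals <- numeric(nb)
  for (i in seq_len(nf)) {
    totals <- totals + bin_total_intensity(get_frame(volume, i), bin_edges_um,
                                           surface_rows[i], volume$geometry)$total
  }
  out <- depth_bin_table(bin_edges_um, totals, frames_used = nf,
                         reporting_scale = reporting_scale)
  out
}

depth_bin_table <- function(edges, totals, frames_used, reporting_scale = 1) {
  nb <- length(edges) - 1L
  structure(
    data.frame(bin_lo_um = edges[seq_len(nb)],
               bin_hi_um = edges[seq_len(nb) + 1L],
               total = totals,
               per_frame_average = totals / frames_used / reporting_scale),
    frames_used = as.integer(frames_used),
    reporting_scale = reporting_scale,
    class = c("depth_bin_table", "data.frame"))
}

check_bin_edges <- function(edges) {
  if (!is.numeric(edges) || length(edges) < 2L || any(diff(edges) <= 0)) {
    stop_param("bin edges must be strictly increasing with at least two values")
  }
  if (edges[1L] != 0) stop_param("the first bin edge must be 0 (the tooth surface)")
  invisible(edges)
}

#' Median surface row of each frame of a stack
#'
#' Convenience surface detector for depth binning: for each frame, the
#' per-column peak indices over a lateral span are reduced to their lower
#' median, which is robust to single specular columns.
#'
#' @param volume An [oct_volume()].
#' @param cols Columns to use (default: all).
#' @return An integer vector, one surface row per frame.
#' @export
detect_surface_rows <- function(volume, cols = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  cols <- cols %||% seq_len(dim(volume)[2L])
  vapply(seq_len(n_frames(volume)), function(i) {
    f <- get_frame(volume, i)
    peaks <- vapply(cols, function(j) as.integer(detect_peak_index(f[, j])),
                    integer(1L))
    as.integer(floor(stats::median(peaks)))
  }, integer(1L))
}
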