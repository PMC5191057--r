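#' Extract a window of adjacent A-scan lines from a B-scan
#'
#' An A-scan is one column of a B-scan: an axial intensity profile. The
#' averaged depth-profile analysis operates on a cropped window of `width`
#' adjacent A-scan lines (15 by convention).
#'
#' @param frame A numeric matrix (rows = depth, columns = lateral).
#' @param start_col First column of the window (1-based).
#' @param width Number of adjacent A-scan lines (default 15).
#' @param geometry A [voxel_geometry()] carried along for depth scaling.
#' @return An `ascan_window`.
#' @export
ascan_window <- function(frame, start_col, width = 15,
                         geometry = voxel_geometry()) {
  if (!is.matrix(frame)) stop_param("frame must be a matrix")
  if (width < 1) stop_param("width must be >= 1")
  if (start_col < 1 || start_col + width - 1 > ncol(frame)) {
    stop_param(sprintf("window columns %d..%d outside frame (1..%d)",
                       start_col, start_col + width - 1, ncol(frame)))
  }
  structure(list(data = frame[, start_col:(start_col + width - 1), drop = FALSE],
                 start_col = as.integer(start_col), geometry = geometry,
                 shifts = NULL, flattened = FALSE),
            class = "ascan_window")
}

#' Locate the surface peak of a single A-scan line
#'
#' Returns the index of the global intensity maximum of one A-scan; ties
#' are broken toward the smallest (shallowest) index. An all-zero column
#' has no surface signal: index 1 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param ascan A numeric vector (one image column, surface at index 1).
#' @return The 1-based row index of the peak.
#' @export
detect_peak_index <- function(ascan) {
  if (!length(ascan)) stop_param("empty A-scan")
  if (all(ascan == 0)) {
    return(structure(1L, degenerate = TRUE))
  }
  which.max(ascan)  # which.max returns the first maximum: shallowest tie
}

# Shift a column axially by `shift` rows (positive = deeper), zero-filling
# vacated samples. No wraparound or interpolation: intensities are
# preserved for the downstream total-intensity analysis.
shift_column <- function(x, shift) {
  n <- length(x)
  if (shift == 0L || abs(shift) >= n) {
    if (abs(shift) >= n) return(numeric(n))
    return(x)
  }
  out <- numeric(n)
  if (shift > 0L) out[(shift + 1L):n] <- x[1L:(n - shift)]
  else out[1L:(n + shift)] <- x[(1L - shift):n]
  out
}

#' Flatten an A-scan window by aligning surface peaks
#'
#' Detects the intensity peak of every A-scan line in the window and shifts
#' each line axially by an integer number of rows so that all peaks land on
#' a common reference index — the median of the detected peak indices
#' (lower median for an even number of lines). Vacated samples are
#' zero-filled and the applied shifts are recorded in `$shifts`. This
#' removes surface tilt/curvature from the region of interest before the
#' lines are averaged into a single depth profile.
#'
#' Flattening is idempotent: a flattened window is returned unchanged.
#'
#' @param window An [ascan_window()].
#' @return The flattened `ascan_window` with `$shifts` and `$ref_index` set.
#' @export
flatten_window <- function(window) {
  stopifnot(inherits(window, "ascan_window"))
  if (isTRUE(window$flattened)) return(window)
  peaks <- vapply(seq_len(ncol(window$data)),
                  function(j) as.integer(detect_peak_index(window$data[, j])),
                  integer(1L))
  ref <- as.integer(floor(stats::median(peaks)))
  shifts <- ref - peaks
  for (j in seq_along(shifts)) {
    if (shifts[j] != 0L) {
      window$data[, j] <- shift_column(window$data[, j], shifts[j])
    }
  }
  window$shifts <- shifts
  window$ref_index <- ref
  window$flattened <- TRUE
  window
}

#' Averaged, normalized A-scan depth profile of a window
#'
#' Flattens the window if needed, averages the aligned A-scan lines
#' depth-sample by depth-sample, and normalizes the mean profile by its
#' maximum so the surface peak equals 1. The depth axis is physical:
#' optical row pitch divided by the tissue refractive index.
#'
#' @param window An [ascan_window()].
#' @return A `depth_profile` with `values` (max-normalized), `depth_um`
#'   (physical depth per sample, 0 at the first row), `peak_index`, and
#'   `raw_max` (the pre-normalization mean peak intensity, 0-255 scale).
#' @export
averaged_profile <- function(window) {
  stopifnot(inherits(window, "ascan_window"))
  window <- flatten_window(window)
  m <- rowMeans(window$data)
  mx <- max(m)
  if (mx == 0) {
    warning("all-zero window: degenerate depth profile", call. = FALSE)
    values <- m
  } else {
    values <- m / mx
  }
  ap <- axial_pitch_um(window$geometry)
  structure(list(values = values,
                 depth_um = (seq_along(values) - 1L) * ap,
                 peak_index = as.integer(which.max(m)),
                 raw_max = mx,
                 geometry = window$geometry,
                 shifts = window$shifts),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d samples, surface peak at index %d (%.1f um), raw peak %.1f\n",
              length(x$values), x$peak_index, x$depth_um[x$peak_index], x$raw_max))
  invisible(x)
}

# Moving-average smoothing with shrinking edge windows.
smooth_profile <- function(x, halfwidth) {
  if (halfwidth <= 0L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - halfwidth):min(n, i + halfwidth)])
  }, numeric(1L))
}

# Indices of local minima/maxima of a smoothed profile (plateaus collapse
# to their first index).
local_extrema <- function(x) {
  n <- length(x)
  mins <- maxs <- integer(0)
  if (n < 3L) return(list(minima = mins, maxima = maxs))
  ds <- diff(x)
  sgn <- sign(ds)
  nz <- which(sgn != 0)
  if (length(nz) < 2L) return(list(minima = mins, maxima = maxs))
  for (k in seq_len(length(nz) - 1L)) {
    a <- nz[k]; b <- nz[k + 1L]
    if (sgn[a] < 0 && sgn[b] > 0) mins <- c(mins, a + 1L)
    if (sgn[a] > 0 && sgn[b] < 0) maxs <- c(maxs, a + 1L)
  }
  list(minima = mins, maxima = maxs)
}

#' Estimate enamel thickness from an averaged depth profile
#'
#' Reads the enamel band off a `depth_profile` as the distance between the
#' surface peak and the dentino-enamel junction (DEJ) peak. The rule is:
#' the surface is the (raw) profile maximum; descending from it, the
#' profile must fall into a trough below `valley_fraction` of the surface
#' value — the attenuated signal at the enamel bottom — and the first
#' subsequent local maximum that rises at least `dej_prominence` of the
#' surface value above the trough is the DEJ reflection. Thickness is the
#' index difference converted to physical micrometres
#' (optical pitch / refractive index).
#'
#' Extremum search runs on a moving-average smoothed copy of the profile
#' (half-width `smooth_halfwidth` samples), which suppresses residual
#' speckle; the prominence requirement keeps speckle bumps inside the
#' trough from masquerading as the junction. A trough qualifies on the raw
#' profile minimum within its smoothing neighborhood (a narrow trough under
#' thin enamel survives even where smoothing fills it in), and the deepest
#' qualifying trough seen so far is carried forward until a sufficiently
#' prominent peak ends the search. The reported DEJ row is then refined to
#' the onset of the junction rise — the steepest single-sample increase of
#' the raw profile between the trough and the smoothed peak — which marks
#' the enamel/DEJ boundary without the deep-side bias a smoothed argmax
#' carries. When no qualifying trough/DEJ peak exists — as when a lesion
#' has obliterated the junction — thickness is `NA` with a diagnostic.
#'
#' @param profile A `depth_profile` from [averaged_profile()].
#' @param geometry Optional [voxel_geometry()] override (default: the
#'   profile's own).
#' @param valley_fraction Fraction of the surface peak the trough must drop
#'   below to qualify (default 0.5).
#' @param smooth_halfwidth Moving-average half-width in samples (default 2).
#' @param dej_prominence Minimum rise of the DEJ peak above the trough, as
#'   a fraction of the surface value (default 0.08).
#' @param min_peak Detectability floor for the pre-normalization surface
#'   peak on the 0-255 scale (default 10).
#' @param reference_um Optional healthy reference thickness; if given, the
#'   percent reduction is filled in via [percent_reduction()].
#' @return A `thickness_result`: `thickness_um`, `surface_index`,
#'   `dej_index`, `reference_thickness_um`, `reduction_pct`, `diagnostic`.
#' @export
estimate_enamel_thickness <- function(profile, geometry = NULL,
                                      valley_fraction = 0.5,
                                      smooth_halfwidth = 2,
                                      dej_prominence = 0.08,
                                      min_peak = 10,
                                      reference_um = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  geometry <- geometry %||% profile$geometry
  ap <- axial_pitch_um(geometry)
  res <- structure(list(thickness_um = NA_real_, surface_index = NA_integer_,
                        dej_index = NA_integer_,
                        reference_thickness_um = reference_um,
                        reduction_pct = NA_real_, diagnostic = NA_character_),
                   class = "thickness_result")
  if (profile$raw_max < min_peak) {
    res$diagnostic <- sprintf(
      "no detectable surface peak (raw max %.2f < floor %g)", profile$raw_max, min_peak)
    return(res)
  }
  hw <- as.integer(smooth_halfwidth)
  v <- profile$values
  n <- length(v)
  sm <- smooth_profile(v, hw)
  surface <- which.max(v)          # raw surface peak: the flattening reference
  res$surface_index <- as.integer(surface)
  peak_val <- v[surface]
  ext <- local_extrema(sm)
  # walk the smoothed extrema below the surface: carry the deepest trough
  # qualifying on the raw neighborhood minimum, accept the first smoothed
  # peak rising at least dej_prominence * surface above it
  events <- sort(c(ext$minima, ext$maxima))
  events <- events[events > surface]
  trough_idx <- NA_integer_
  trough_val <- Inf
  dej_idx <- NA_integer_
  saw_trough <- FALSE
  for (i in events) {
    if (i %in% ext$minima) {
      qv <- min(v[max(1L, i - hw):min(n, i + hw)])
      if (qv < valley_fraction * peak_val && qv < trough_val) {
        trough_idx <- i
        trough_val <- qv
        saw_trough <- TRUE
      }
    } else if (saw_trough &&
               sm[i] - trough_val >= dej_prominence * peak_val) {
      dej_idx <- i
      break
    }
  }
  if (!saw_trough) {
    res$diagnostic <- "no qualifying post-surface trough: dentino-enamel junction not resolved"
    return(res)
  }
  if (is.na(dej_idx)) {
    res$diagnostic <- "no dentino-enamel junction peak after the trough (lesion may have obliterated it)"
    return(res)
  }
  # refine to the rise onset on the raw profile: the steepest single-sample
  # increase between the trough and the smoothed peak marks the boundary
  hi <- min(n, dej_idx + hw)
  seg <- v[trough_idx:hi]
  res$dej_index <- as.integer(trough_idx + which.max(diff(seg)))
  res$thickness_um <- (res$dej_index - res$surface_index) * ap
  if (!is.null(reference_um)) {
    res$reduction_pct <- percent_reduction(res$thickness_um, reference_um)
  }
  res
}

#' @export
print.thickness_result <- function(x, ...) {
  if (is.na(x$thickness_um)) {
    cat("<thickness_result> undefined:", x$diagnostic, "\n")
  } else {
    cat(sprintf("<thickness_result> enamel %.1f um (surface index %d, DEJ index %d)\n",
                x$thickness_um, x$surface_index, x$dej_index))
    if (!is.na(x$reduction_pct)) {
      cat(sprintf("  reduction vs reference %.2f um: %.1f%%\n",
                  x$reference_thickness_um, x$reduction_pct))
    }
  }
  invisible(x)
}

#' Percent reduction of enamel thickness against a healthy reference
#'
#' `100 * (1 - thickness / reference)`, rounded half-up to one decimal
#' place, the convention used when reporting demineralization severity.
#'
#' @param thickness_um Measured enamel thickness, um.
#' @param reference_um Healthy reference thickness, um (> 0).
#' @return The percent reduction, one decimal place.
#' @examples
#' percent_reduction(100.20, 255.45)  # 60.8
#' @export
percent_reduction <- function(thickness_um, reference_um) {
  if (!is.numeric(reference_um) || any(reference_um <= 0)) {
    stop_param("reference thickness must be > 0")
  }
  round_half_up(100 * (1 - thickness_um / reference_um) * 10) / 10
}
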