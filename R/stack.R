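#' Construct an OCT volume from B-scan frames
#'
#' An `oct_volume` is an ordered stack of equally sized 2D B-scan frames
#' sharing one [voxel_geometry()]. Frames are stored as a
#' rows x cols x frames numeric array; row 1 is the shallow (surface) side
#' and depth increases with the row index, matching the usual B-scan
#' display orientation.
#'
#' @param frames A list of numeric matrices with identical dimensions, or a
#'   3D array (rows x cols x frames).
#' @param geometry A [voxel_geometry()].
#' @return An `oct_volume` with elements `data` (3D array) and `geometry`.
#' @export
oct_volume <- function(frames, geometry = voxel_geometry()) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (is.array(frames) && length(dim(frames)) == 3L) {
    data <- frames
  } else if (is.list(frames)) {
    if (length(frames) == 0L) stop_param("an oct_volume needs at least one frame")
    d1 <- dim(frames[[1L]])
    if (is.null(d1)) stop_param("frames must be matrices")
    for (i in seq_along(frames)) {
      if (!identical(dim(frames[[i]]), d1)) {
        stop_param(sprintf(
          "frame %d is %s but frame 1 is %s; all frames must share dimensions",
          i, paste(dim(frames[[i]]), collapse = "x"), paste(d1, collapse = "x")))
      }
    }
    data <- array(unlist(frames, use.names = FALSE), dim = c(d1, length(frames)))
  } else {
    stop_param("frames must be a list of matrices or a 3D array")
  }
  if (any(dim(data) < 1L)) stop_param("frames must be non-empty")
  storage.mode(data) <- "double"
  structure(list(data = data, geometry = geometry), class = "oct_volume")
}

#' @rdname oct_volume
#' @param volume An `oct_volume`.
#' @export
n_frames <- function(volume) {
  stopifnot(inherits(volume, "oct_volume"))
  dim(volume$data)[3L]
}

#' @rdname oct_volume
#' @param i Frame index (1-based).
#' @export
get_frame <- function(volume, i) {
  stopifnot(inherits(volume, "oct_volume"))
  nf <- n_frames(volume)
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > nf) {
    stop_param(sprintf("frame index %s outside 1..%d", format(i), nf))
  }
  volume$data[, , as.integer(i)]
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume> %d frames of %d x %d (rows x cols), intensities in [%g, %g]\n",
              d[3L], d[1L], d[2L], min(x$data), max(x$data)))
  print(x$geometry)
  invisible(x)
}
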