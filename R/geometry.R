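#' Voxel geometry of an OCT B-scan stack
#'
#' Bundles the pixel pitches of an acquisition with the tissue refractive
#' index used to convert optical path length into physical depth. Rows of a
#' B-scan run along the axial (depth) direction with pitch `ly`; columns run
#' laterally with pitch `lx`; successive frames are separated by `lz`.
#'
#' Raw image data keep their optical row spacing; the refractive index is
#' applied only when a measurement is expressed in physical micrometres
#' (one axial row corresponds to `ly / n_tissue` micrometres of tissue).
#'
#' @param lx Lateral pixel pitch within a frame, micrometres.
#' @param ly Axial pixel pitch within a frame (optical), micrometres.
#' @param lz Spacing between successive frames, micrometres.
#' @param n_tissue Refractive index of the imaged tissue (>= 1); dental
#'   enamel is conventionally taken as 1.63.
#' @return An object of class `voxel_geometry`.
#' @examples
#' g <- voxel_geometry()            # 12 x 12 x 7 um, n = 1.63
#' axial_pitch_um(g)                # physical depth per image row
#' @export
voxel_geometry <- function(lx = 12, ly = 12, lz = 7, n_tissue = 1.63) {
  for (v in c(lx = lx, ly = ly, lz = lz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_param("pixel pitches lx, ly, lz must be positive finite scalars")
    }
  }
  if (!is.numeric(n_tissue) || length(n_tissue) != 1L || n_tissue < 1) {
    stop_param("n_tissue must be a scalar >= 1")
  }
  structure(
    list(lx = as.numeric(lx), ly = as.numeric(ly), lz = as.numeric(lz),
         n_tissue = as.numeric(n_tissue)),
    class = "voxel_geometry"
  )
}

#' @rdname voxel_geometry
#' @param geometry A `voxel_geometry` object.
#' @export
axial_pitch_um <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$ly / geometry$n_tissue
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "<voxel_geometry> lx = %g um, ly = %g um, lz = %g um, n = %g (axial pitch %.3f um in tissue)\n",
    x$lx, x$ly, x$lz, x$n_tissue, axial_pitch_um(x)))
  invisible(x)
}
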