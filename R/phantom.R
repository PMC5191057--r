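#' Specify one optical layer of a tooth phantom
#'
#' Layers are slabs stacked in physical depth below the tooth surface. The
#' mean backscatter at physical depth `d` inside a layer is
#' `base_reflectivity * exp(-attenuation_per_um * (d - top))`, i.e. an
#' exponential attenuation of the signal with depth into the layer.
#'
#' @param name Layer label: `"enamel"`, `"dej"`, `"dentin"` or `"background"`.
#' @param top_depth_um Physical depth of the layer top below the surface, um.
#' @param thickness_um Physical thickness, um (>= 0).
#' @param base_reflectivity Mean backscatter at the layer top, 0-255 scale.
#' @param attenuation_per_um Exponential decay coefficient, 1/um (>= 0).
#' @export
layer_spec <- function(name, top_depth_um, thickness_um, base_reflectivity,
                       attenuation_per_um = 0) {
  name <- match.arg(name, c("enamel", "dej", "dentin", "background"))
  if (thickness_um < 0) stop_param("thickness_um must be >= 0")
  if (base_reflectivity < 0 || base_reflectivity > 255) {
    stop_param("base_reflectivity must lie in [0, 255]")
  }
  if (attenuation_per_um < 0) stop_param("attenuation_per_um must be >= 0")
  structure(list(name = name, top_depth_um = top_depth_um,
                 thickness_um = thickness_um,
                 base_reflectivity = base_reflectivity,
                 attenuation_per_um = attenuation_per_um),
            class = "layer_spec")
}

#' Specify a demineralization lesion in a phantom
#'
#' A lesion occupies a lateral band of columns. Within it the enamel is
#' locally eroded (its top recedes by `enamel_erosion_um`) and the
#' backscatter of all tissue down to `depth_extent_um` below the local
#' surface is multiplied by `reflectivity_scale` (<= 1: mineral loss lowers
#' optical scattering, so demineralized tissue is darker).
#'
#' @param center_lateral_px Lateral center column (1-based).
#' @param width_px Lateral extent in columns.
#' @param depth_extent_um Depth reach of the backscatter reduction, um.
#' @param reflectivity_scale Multiplicative backscatter factor in (0, 1].
#' @param enamel_erosion_um Local reduction of enamel thickness, um.
#' @export
lesion_spec <- function(center_lateral_px, width_px, depth_extent_um,
                        reflectivity_scale, enamel_erosion_um = 0) {
  if (reflectivity_scale <= 0 || reflectivity_scale > 1) {
    stop_param("reflectivity_scale must lie in (0, 1]")
  }
  if (width_px < 1) stop_param("width_px must be >= 1")
  if (depth_extent_um < 0 || enamel_erosion_um < 0) {
    stop_param("depth_extent_um and enamel_erosion_um must be >= 0")
  }
  structure(list(center_lateral_px = center_lateral_px, width_px = width_px,
                 depth_extent_um = depth_extent_um,
                 reflectivity_scale = reflectivity_scale,
                 enamel_erosion_um = enamel_erosion_um),
            class = "lesion_spec")
}

#' Default healthy tooth layer stack
#'
#' Mimics a healthy molar B-scan: a bright enamel band over the first
#' 250 um of physical depth, a dentino-enamel junction (DEJ) band to
#' 600 um, and dentin to 800 um, with decreasing base reflectivity and
#' per-layer exponential attenuation. The DEJ base reflectivity exceeds the
#' attenuated signal at the enamel bottom, so the junction appears as the
#' secondary peak of an averaged A-scan profile, as in real dental OCT.
#'
#' @param enamel_thickness_um Physical enamel thickness, um (default 250).
#' @return A list of [layer_spec()] objects.
#' @export
default_tooth_layers <- function(enamel_thickness_um = 250) {
  list(
    layer_spec("enamel", 0, enamel_thickness_um, 200, 0.008),
    layer_spec("dej", enamel_thickness_um, 350, 150, 0.004),
    layer_spec("dentin", enamel_thickness_um + 350, 200, 110, 0.003)
  )
}

#' Specify a synthetic layered tooth OCT stack
#'
#' Full parametric description of a phantom: stack dimensions, voxel
#' geometry, optical layers, lesions, surface tilt, speckle and seed.
#' Identical spec + seed always produces a bit-identical stack.
#'
#' Layer depths are physical micrometres below the nominal surface; they are
#' mapped to image rows through the optical axial pitch (`ly`) and the
#' tissue refractive index, so a 250 um enamel band spans about 34 rows at
#' the default 12 um pitch and n = 1.63.
#'
#' @param rows,cols,frames Stack dimensions (default 200 x 100 x 10).
#' @param geometry A [voxel_geometry()].
#' @param layers List of [layer_spec()]; default [default_tooth_layers()].
#' @param lesions List of [lesion_spec()] (default none).
#' @param surface_top_row Image row of the nominal surface in column 1.
#' @param surface_tilt_px_per_col Linear axial shift of the surface per
#'   column (rows/column); the surface of column c sits at
#'   `surface_top_row + round(surface_tilt_px_per_col * (c - 1))`.
#' @param speckle_shape Shape of the multiplicative gamma speckle (mean 1);
#'   larger = smoother. 0 disables speckle. Default 8, a moderately
#'   averaged speckle contrast typical of displayed OCT intensity images.
#' @param surface_reflection Specular reflection intensity at the
#'   air-tissue interface: the topmost tissue row of each column is raised
#'   to at least this value (before lesion scaling and speckle). Dental
#'   B-scans show a bright, often saturated, Fresnel reflection at the
#'   enamel surface, which is what surface peak search keys on. Default
#'   255; 0 disables.
#' @param noise_floor Mean background intensity outside tissue (default 2).
#' @param seed Master RNG seed; per-frame streams are derived from it so a
#'   frame's content does not depend on generation order.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(rows = 200, cols = 100, frames = 10,
                         geometry = voxel_geometry(),
                         layers = default_tooth_layers(),
                         lesions = list(),
                         surface_top_row = 20,
                         surface_tilt_px_per_col = 0,
                         speckle_shape = 8,
                         surface_reflection = 255,
                         noise_floor = 2,
                         seed = 1) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (rows < 1 || cols < 1 || frames < 1) stop_param("rows, cols, frames must be >= 1")
  if (speckle_shape < 0) stop_param("speckle_shape must be >= 0 (0 disables speckle)")
  if (surface_reflection < 0 || surface_reflection > 255) {
    stop_param("surface_reflection must lie in [0, 255]")
  }
  if (noise_floor < 0 || noise_floor > 255) stop_param("noise_floor must lie in [0, 255]")
  if (!length(layers)) stop_param("at least one layer is required")
  lapply(layers, function(l) stopifnot(inherits(l, "layer_spec")))
  lapply(lesions, function(l) stopifnot(inherits(l, "lesion_spec")))
  spec <- structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         frames = as.integer(frames), geometry = geometry, layers = layers,
         lesions = lesions, surface_top_row = as.integer(surface_top_row),
         surface_tilt_px_per_col = surface_tilt_px_per_col,
         speckle_shape = speckle_shape,
         surface_reflection = surface_reflection, noise_floor = noise_floor,
         seed = as.integer(seed)),
    class = "phantom_spec")
  # deepest layer must fit below the most-shifted surface
  max_tilt <- max(0, round_half_up(spec$surface_tilt_px_per_col * (spec$cols - 1)))
  bottom_um <- max(vapply(layers, function(l) l$top_depth_um + l$thickness_um, 0))
  bottom_row <- spec$surface_top_row + max_tilt + bottom_um / axial_pitch_um(geometry)
  if (bottom_row > rows) {
    stop_param(sprintf(
      "layers reach %.0f um (row %.0f) but the image has only %d rows",
      bottom_um, bottom_row, rows))
  }
  spec
}

# Independent per-frame RNG stream derived from the master seed.
frame_seed <- function(seed, frame_index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(frame_index) * 104729) %% 2147483647)
}

# Which lesion (if any) covers column c; first match wins.
lesion_at <- function(spec, c) {
  for (les in spec$lesions) {
    half <- (les$width_px - 1) / 2
    if (c >= les$center_lateral_px - half && c <= les$center_lateral_px + half) return(les)
  }
  NULL
}

# Noise-free expected intensity of one column (before speckle/quantization).
phantom_column_model <- function(spec, c) {
  ap <- axial_pitch_um(spec$geometry)
  s0 <- spec$surface_top_row +
    round_half_up(spec$surface_tilt_px_per_col * (c - 1))
  les <- lesion_at(spec, c)
  erosion <- if (is.null(les)) 0 else les$enamel_erosion_um
  d <- (seq_len(spec$rows) - s0) * ap          # physical depth per row, um
  val <- rep(spec$noise_floor, spec$rows)
  for (L in spec$layers) {
    top <- L$top_depth_um
    if (L$name == "enamel") top <- top + erosion  # erosion recedes the enamel top
    bot <- L$top_depth_um + L$thickness_um
    sel <- d >= top & d < bot
    val[sel] <- L$base_reflectivity * exp(-L$attenuation_per_um * (d[sel] - top))
  }
  if (spec$surface_reflection > 0) {
    # specular Fresnel reflection at the air-tissue interface: first tissue row
    first <- which(d >= erosion)[1L]
    if (!is.na(first)) val[first] <- max(val[first], spec$surface_reflection)
  }
  if (!is.null(les) && les$reflectivity_scale < 1) {
    sel <- d >= erosion & d < erosion + les$depth_extent_um
    val[sel] <- val[sel] * les$reflectivity_scale
  }
  val
}

#' Generate one synthetic B-scan
#'
#' Renders a single frame of a [phantom_spec()]: the noise-free layer model
#' column by column, optionally multiplied by gamma-distributed speckle
#' (mean 1), then clipped to \[0, 255\] and rounded half-up. Deterministic
#' given `(spec, frame_index)`.
#'
#' @param spec A [phantom_spec()].
#' @param frame_index Frame number (1-based).
#' @return A numeric matrix (rows x cols) of 8-bit intensities.
#' @export
generate_bscan <- function(spec, frame_index = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- vapply(seq_len(spec$cols), function(c) phantom_column_model(spec, c),
                numeric(spec$rows))
  if (spec$speckle_shape > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(frame_seed(spec$seed, frame_index))
    img <- img * matrix(
      stats::rgamma(length(img), shape = spec$speckle_shape, rate = spec$speckle_shape),
      nrow = spec$rows)
  }
  round_half_up(clip_8bit(img))
}

# Preserve the caller's RNG state: phantom generation manages its own streams.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a phantom volume with ground truth
#'
#' Renders all frames of a [phantom_spec()] and returns the stack together
#' with an analytically derived ground-truth record: per-column enamel
#' top/bottom rows (identical across frames; lesions and tilt are lateral
#' features), the enamel voxel count per frame, and the physical enamel
#' volume implied by the voxel geometry. The truth is computed from the
#' same row/depth arithmetic the renderer uses, so on a noise-free phantom
#' the voxel counts agree exactly with threshold counting.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([oct_volume()]) and `truth`
#'   (class `phantom_truth`): `surface_row`, `enamel_top_row`,
#'   `enamel_bottom_row` (per column; bottom is exclusive),
#'   `enamel_rows_per_column`, `enamel_voxels_per_frame`,
#'   `enamel_voxels_total`, `enamel_volume_mm3`.
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  frames <- lapply(seq_len(spec$frames), function(i) generate_bscan(spec, i))
  vol <- oct_volume(frames, spec$geometry)

  ap <- axial_pitch_um(spec$geometry)
  enamel <- Filter(function(l) l$name == "enamel", spec$layers)
  if (length(enamel)) {
    en <- enamel[[1L]]
    top_row <- bottom_row <- integer(spec$cols)
    for (c in seq_len(spec$cols)) {
      s0 <- spec$surface_top_row +
        round_half_up(spec$surface_tilt_px_per_col * (c - 1))
      les <- lesion_at(spec, c)
      erosion <- if (is.null(les)) 0 else les$enamel_erosion_um
      d <- (seq_len(spec$rows) - s0) * ap
      sel <- which(d >= en$top_depth_um + erosion &
                     d < en$top_depth_um + en$thickness_um)
      if (length(sel)) {
        top_row[c] <- sel[1L]
        bottom_row[c] <- sel[length(sel)] + 1L
      } else {
        top_row[c] <- bottom_row[c] <- NA_integer_
      }
    }
    rows_per_col <- ifelse(is.na(top_row), 0L, bottom_row - top_row)
  } else {
    top_row <- bottom_row <- rep(NA_integer_, spec$cols)
    rows_per_col <- integer(spec$cols)
  }
  g <- spec$geometry
  per_frame <- sum(rows_per_col)
  surface_row <- spec$surface_top_row +
    round_half_up(spec$surface_tilt_px_per_col * (seq_len(spec$cols) - 1))
  truth <- structure(
    list(surface_row = as.integer(surface_row),
         enamel_top_row = top_row, enamel_bottom_row = bottom_row,
         enamel_rows_per_column = as.integer(rows_per_col),
         enamel_voxels_per_frame = rep(as.integer(per_frame), spec$frames),
         enamel_voxels_total = as.numeric(per_frame) * spec$frames,
         enamel_volume_mm3 = as.numeric(per_frame) * spec$frames *
           g$lx * g$ly * g$lz * 1e-9),
    class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' Write phantom ground truth as a JSON sidecar
#'
#' @param truth A `phantom_truth` from [generate_volume()].
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}
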