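# Nine-layer finger slab geometry and its voxelization.
#
# Convention: z increases downward from the air-skin surface at z = 0; a
# layer occupies the half-open depth interval [top, bottom); a voxel belongs
# to the layer containing its centre depth.

#' Construct a finger model from a layer table
#'
#' A finger model is an ordered stack of tissue layers, top (stratum corneum)
#' to bottom (bone), each carrying its thickness, composition fractions and
#' the fixed optical constants (scattering coefficient per wavelength,
#' anisotropy, refractive index) used by the transport engine.
#'
#' @param layers data frame with one row per layer and columns `name`,
#'   `thickness_mm`, `vb` (blood volume fraction), `vwat` (water volume
#'   fraction), `vm` (melanin volume fraction), `mus_660`, `mus_940`
#'   (scattering coefficients, mm^-1), `g` (anisotropy), `n` (refractive
#'   index), and optionally `mua_table5_660`, `mua_table5_940` (printed
#'   absorption coefficients used by the anchored optics mode).
#' @param lateral_extent_mm side of the square lateral cross-section, mm.
#' @return An object of class `finger_model`.
#' @seealso [default_finger_model()] for the packaged nine-layer model.
#' @export
finger_model <- function(layers, lateral_extent_mm = 6) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1)
  req <- c("name", "thickness_mm", "vb", "vwat", "vm",
           "mus_660", "mus_940", "g", "n")
  missing_cols <- setdiff(req, names(layers))
  if (length(missing_cols) > 0)
    stop("layer table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(layers$thickness_mm <= 0)) stop("layer thicknesses must be > 0")
  frac <- c(layers$vb, layers$vwat, layers$vm)
  if (any(frac < 0 | frac > 1)) stop("volume fractions must lie in [0, 1]")
  if (any(layers$vb + layers$vwat > 1 + 1e-12))
    stop("vb + vwat must not exceed 1")
  if (any(layers$g < -1 | layers$g > 1)) stop("anisotropy must lie in [-1, 1]")
  if (any(layers$n < 1)) stop("refractive indices must be >= 1")
  if (any(layers$mus_660 < 0 | layers$mus_940 < 0))
    stop("scattering coefficients must be >= 0")
  if (lateral_extent_mm <= 0) stop("lateral_extent_mm must be > 0")
  structure(
    list(layers = as.data.frame(layers, stringsAsFactors = FALSE),
         lateral_extent_mm = lateral_extent_mm),
    class = "finger_model")
}

#' The default nine-layer finger model
#'
#' Layer thicknesses, blood/water/melanin volume fractions and fixed optical
#' constants of the heterogeneous finger slab: stratum corneum, epidermis,
#' four blood-bearing dermal sublayers (papillary dermis, upper blood net
#' dermis, reticular dermis, deep blood net dermis), fat, muscle and bone.
#' Total thickness is 5.0 mm; the lateral cross-section is a 6 mm square.
#' Skin sublayers carry a single scattering coefficient applied at both
#' wavelengths; fat, muscle and bone have per-wavelength values. The
#' `mua_table5_*` columns hold the printed per-layer absorption coefficients
#' used as the fixed values for fat/muscle/bone and as the baseline of the
#' anchored optics mode (see [build_medium()]).
#'
#' @param lateral_extent_mm side of the square lateral cross-section, mm.
#' @return A [finger_model()] object with nine layers.
#' @examples
#' m <- default_finger_model()
#' sum(m$layers$thickness_mm)  # 5.0 mm
#' @export
default_finger_model <- function(lateral_extent_mm = 6) {
  layers <- data.frame(
    name = c("stratum_corneum", "epidermis", "papillary_dermis",
             "upper_blood_net_dermis", "reticular_dermis",
             "deep_blood_net_dermis", "fat", "muscle", "bone"),
    thickness_mm = c(0.02, 0.25, 0.1, 0.08, 0.2, 0.3, 0.55, 1.5, 2),
    vb   = c(0, 0, 0.05, 0.20, 0.04, 0.10, 0, 0, 0),
    vwat = c(0.05, 0.20, 0.50, 0.60, 0.70, 0.70, 0.70, 0.70, 0),
    vm   = c(0, 0.10, 0, 0, 0, 0, 0, 0, 0),
    mus_660 = c(100, 45, 30, 35, 25, 30, 6.20, 8.61, 34.45),
    mus_940 = c(100, 45, 30, 35, 25, 30, 5.42, 5.81, 24.70),
    g = c(0.86, 0.8, 0.9, 0.95, 0.8, 0.95, 0.8, 0.5, 0.92),
    n = c(1.5, 1.34, 1.4, 1.39, 1.4, 1.38, 1.37, 1.37, 1.37),
    mua_table5_660 = c(0.24959, 0.33538, 0.04624, 0.02898, 0.02636,
                       0.03749, 0.0104, 0.0816, 0.0351),
    mua_table5_940 = c(0.09745, 0.21397, 0.23308, 0.24202, 0.29906,
                       0.32549, 0.0170, 0.0401, 0.0457),
    stringsAsFactors = FALSE)
  finger_model(layers, lateral_extent_mm = lateral_extent_mm)
}

#' Read a finger model from a CSV layer table
#'
#' @param path CSV file with the columns described in [finger_model()].
#' @param lateral_extent_mm side of the square lateral cross-section, mm.
#' @return A [finger_model()] object.
#' @export
read_finger_model <- function(path, lateral_extent_mm = 6) {
  finger_model(utils::read.csv(path, stringsAsFactors = FALSE),
               lateral_extent_mm = lateral_extent_mm)
}

#' Total thickness of a finger model (mm)
#' @param model a [finger_model()] object.
#' @export
total_thickness <- function(model) sum(model$layers$thickness_mm)

#' Cumulative depth boundaries of the layers (mm)
#'
#' Returns a vector of length `n_layers + 1` starting at 0, where layer `i`
#' occupies the half-open interval `[bounds[i], bounds[i + 1])`.
#' @param model a [finger_model()] object.
#' @export
layer_boundaries <- function(model) c(0, cumsum(model$layers$thickness_mm))

#' Which layer contains a given depth
#'
#' Depth intervals are half-open `[top, bottom)`: the depth at a layer
#' boundary belongs to the layer below it.
#'
#' @param model a [finger_model()] object.
#' @param depth_mm depth(s) below the surface, mm; must satisfy
#'   `0 <= depth < total_thickness(model)`.
#' @return Integer layer index (1-based), vectorized over `depth_mm`.
#' @examples
#' layer_at_depth(default_finger_model(), c(0, 0.02, 4.99))
#' @export
layer_at_depth <- function(model, depth_mm) {
  b <- layer_boundaries(model)
  if (any(depth_mm < 0 | depth_mm >= b[length(b)]))
    stop("depth outside the model: must be in [0, ",
         b[length(b)], ") mm")
  findInterval(depth_mm, b, rightmost.closed = FALSE)
}

#' Voxelize a finger model
#'
#' Builds the integer-labelled voxel grid used by the transport engine: a
#' grid of cubic voxels of side `voxel_edge_mm` spanning the lateral extent
#' and the full slab thickness, each voxel labelled by the layer containing
#' its centre depth. Because the slab is laterally homogeneous the labels
#' depend on depth only, so the grid stores one label per z-plane; use
#' [voxel_labels()] to materialize the full 3D array.
#'
#' @param model a [finger_model()] object.
#' @param voxel_edge_mm voxel side, mm. Default 0.02 resolves the thinnest
#'   layer (the 0.02 mm stratum corneum). A value larger than the thinnest
#'   layer triggers a warning (that layer may vanish from the grid).
#' @return An object of class `voxel_grid` with fields `voxel_edge_mm`,
#'   `dim` (nx, ny, nz) and `plane_layer` (layer label per z-plane).
#' @examples
#' g <- voxelize(default_finger_model(), voxel_edge_mm = 0.1)
#' g$dim
#' @export
voxelize <- function(model, voxel_edge_mm = 0.02) {
  if (voxel_edge_mm <= 0) stop("voxel_edge_mm must be > 0")
  thin <- min(model$layers$thickness_mm)
  if (voxel_edge_mm > thin + 1e-12)
    warning("voxel_edge_mm (", voxel_edge_mm, ") exceeds the thinnest layer (",
            thin, " mm); that layer may not be resolved")
  zt <- total_thickness(model)
  nz <- as.integer(ceiling(zt / voxel_edge_mm - 1e-9))
  nx <- as.integer(ceiling(model$lateral_extent_mm / voxel_edge_mm - 1e-9))
  centers <- (seq_len(nz) - 0.5) * voxel_edge_mm
  centers <- pmin(centers, zt - 1e-12)  # guard the last half-voxel
  plane_layer <- layer_at_depth(model, centers)
  structure(
    list(voxel_edge_mm = voxel_edge_mm,
         dim = c(nx = nx, ny = nx, nz = nz),
         plane_layer = as.integer(plane_layer)),
    class = "voxel_grid")
}

#' Materialize the full 3D label array of a voxel grid
#'
#' @param grid a [voxelize()] result.
#' @return Integer array of dim (nx, ny, nz); entry = 1-based layer index.
#' @export
voxel_labels <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- grid$dim
  array(rep(grid$plane_layer, each = d[1] * d[2]), dim = unname(d))
}

#' @export
print.finger_model <- function(x, ...) {
  cat("Finger model:", nrow(x$layers), "layers,",
      total_thickness(x), "mm total,",
      x$lateral_extent_mm, "mm lateral extent\n")
  print(x$layers[, c("name", "thickness_mm", "vb", "vwat", "vm", "g", "n")],
        row.names = FALSE)
  invisible(x)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("Voxel grid: edge", x$voxel_edge_mm, "mm, dim",
      paste(x$dim, collapse = " x "), "\n")
  invisible(x)
}
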