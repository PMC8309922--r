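# R surface of the compiled photon-transport engine.
#
# All randomness flows through R's RNG stream: set.seed() before a call
# makes the run bitwise reproducible.

#' Simulation configuration
#'
#' @param n_launch maximum number of photon packets to launch.
#' @param n_detect_target stop after this many detections (0 disables the
#'   early stop; the default, so the photon budget is fixed and variance is
#'   easy to reason about).
#' @param source_xy_mm (x, y) of the pencil-beam entry point on the top
#'   surface, mm; the origin is the centre of the lateral cross-section.
#' @param detector_offset_mm source-detector separation d, mm (default
#'   0.4 mm; the alternative 4 mm slab-figure geometry is reached by
#'   overriding this).
#' @param detector_radius_mm radius of the circular detection aperture on
#'   the top surface, mm.
#' @param roulette_threshold,roulette_survival Russian-roulette weight
#'   threshold and survival probability (unbiased reweighting).
#' @param max_path_mm terminate packets whose total path exceeds this.
#' @param record_fluence record a per-voxel deposited-weight map.
#' @param fluence_voxel_edge_mm voxel side of the fluence grid, mm.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_launch = 1e4, n_detect_target = 0,
                       source_xy_mm = c(0, 0), detector_offset_mm = 0.4,
                       detector_radius_mm = 0.25,
                       roulette_threshold = 1e-4, roulette_survival = 0.1,
                       max_path_mm = 100, record_fluence = FALSE,
                       fluence_voxel_edge_mm = 0.1) {
  stopifnot(n_launch >= 1, n_detect_target >= 0,
            roulette_survival > 0, roulette_survival <= 1,
            detector_radius_mm > 0, max_path_mm > 0,
            fluence_voxel_edge_mm > 0)
  structure(list(n_launch = as.integer(n_launch),
                 n_detect_target = as.integer(n_detect_target),
                 source_xy_mm = source_xy_mm,
                 detector_offset_mm = detector_offset_mm,
                 detector_radius_mm = detector_radius_mm,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 max_path_mm = max_path_mm,
                 record_fluence = record_fluence,
                 fluence_voxel_edge_mm = fluence_voxel_edge_mm),
            class = "sim_config")
}

#' Sample a free path length
#'
#' `l = -ln(xi) / (mua + mus)`; an attenuation-free medium
#' (`mua + mus = 0`) yields an infinite step (the packet flies to the next
#' boundary).
#'
#' @param xi uniform(0,1) random draw(s).
#' @param mua,mus absorption and scattering coefficients, mm^-1.
#' @return step length(s), mm.
#' @export
sample_step <- function(xi, mua, mus) {
  stopifnot(all(xi > 0), all(xi < 1), mua >= 0, mus >= 0)
  mut <- mua + mus
  if (mut == 0) rep(Inf, length(xi)) else -log(xi) / mut
}

#' Sample a Henyey-Greenstein scattering cosine
#'
#' Inverse-transform sample of the deflection cosine for anisotropy `g`;
#' the isotropic case `g = 0` reduces to `1 - 2 xi`.
#'
#' @param g anisotropy in (-1, 1).
#' @param xi uniform(0,1) random draw(s).
#' @return cos(theta) value(s), clamped to [-1, 1].
#' @export
sample_scatter_cosine <- function(g, xi) {
  stopifnot(g > -1, g < 1)
  .hg_cosine_cpp(g, xi)
}

#' Rotate a direction vector by a scattering deflection
#'
#' @param direction unit 3-vector.
#' @param cos_theta deflection cosine.
#' @param psi azimuth, radians in [0, 2*pi).
#' @return rotated unit 3-vector.
#' @export
rotate_direction <- function(direction, cos_theta, psi) {
  stopifnot(length(direction) == 3,
            abs(sqrt(sum(direction^2)) - 1) < 1e-6)
  .rotate_direction_cpp(direction, cos_theta, psi)
}

#' Fresnel interaction at a refractive-index interface
#'
#' Computes the unpolarized Fresnel reflectance for the incidence angle of
#' `direction` against `surface_normal`, then reflects (mirror direction)
#' with that probability using the supplied uniform draw, or transmits with
#' the Snell-refracted direction. Beyond the critical angle the packet is
#' always reflected.
#'
#' @param n1,n2 refractive indices of the incident and far media.
#' @param direction unit 3-vector of propagation.
#' @param surface_normal unit 3-vector normal to the interface.
#' @param xi uniform(0,1) draw deciding reflect vs transmit.
#' @return list with `action` ("reflect" or "transmit"), `direction` (the
#'   updated unit vector) and `reflectance` (the Fresnel probability).
#' @export
fresnel_interaction <- function(n1, n2, direction, surface_normal, xi) {
  stopifnot(n1 >= 1, n2 >= 1)
  nrm <- surface_normal / sqrt(sum(surface_normal^2))
  ci <- abs(sum(direction * nrm))
  fr <- .fresnel_reflectance_cpp(n1, n2, ci)
  if (xi < fr$reflectance) {
    d <- direction - 2 * sum(direction * nrm) * nrm
    list(action = "reflect", direction = d / sqrt(sum(d^2)),
         reflectance = fr$reflectance)
  } else {
    sgn <- sign(sum(direction * nrm))
    tangential <- direction - sum(direction * nrm) * nrm
    d <- (n1 / n2) * tangential + sgn * fr$cos_transmit * nrm
    list(action = "transmit", direction = d / sqrt(sum(d^2)),
         reflectance = fr$reflectance)
  }
}

#' Run a reflectance-mode photon-transport simulation
#'
#' Launches pencil-beam packets normally incident at the source position
#' (initial weight 1 minus the specular reflection at the air-tissue
#' interface) and random-walks them through the layered medium: exponential
#' free paths in the local attenuation, unpolarized Fresnel
#' reflection/refraction wherever the refractive index changes, continuous
#' weight deposition `w * mua / (mua + mus)` per interaction,
#' Henyey-Greenstein scattering, Russian roulette below the weight
#' threshold. Packets exiting the top surface inside the detector aperture
#' are scored as detected; the detected intensity is the total detected
#' weight divided by the number of packets launched. Packets crossing the
#' lateral walls terminate as side escapes; packets crossing the bottom are
#' transmittance.
#'
#' @param model a [finger_model()] (geometry and lateral extent).
#' @param medium a [build_medium()] result aligned with the model's layers.
#' @param config a [sim_config()].
#' @return list of class `sim_result` with detection counts and weights,
#'   `intensity`, `mean_optical_path` (mm, over detected packets), the
#'   energy-bookkeeping bins (`specular_weight`, `reflected_weight`,
#'   `transmitted_weight`, `escaped_side_weight`, `absorbed_weight`,
#'   `terminated_weight`, `roulette_net`), and, when fluence recording is
#'   enabled, `fluence_deposited` (raw per-voxel deposited weight) and
#'   `fluence` (normalized by launched packets x voxel volume x local mua).
#' @examples
#' model <- default_finger_model()
#' med <- build_medium(model, 660, reference_state())
#' set.seed(1)
#' run_simulation(model, med, sim_config(n_launch = 1000))$intensity
#' @export
run_simulation <- function(model, medium, config = sim_config()) {
  stopifnot(inherits(model, "finger_model"),
            inherits(medium, "medium_description"),
            inherits(config, "sim_config"))
  if (nrow(medium) != nrow(model$layers))
    stop("medium and model layer counts differ")
  zb <- layer_boundaries(model)
  optics <- as.matrix(medium[, c("mua", "mus", "g", "n")])
  src <- config$source_xy_mm
  det <- c(src[1] + config$detector_offset_mm, src[2])
  flu_dim <- c(0L, 0L, 0L)
  if (config$record_fluence) {
    e <- config$fluence_voxel_edge_mm
    flu_dim <- c(as.integer(ceiling(model$lateral_extent_mm / e - 1e-9)),
                 as.integer(ceiling(model$lateral_extent_mm / e - 1e-9)),
                 as.integer(ceiling(total_thickness(model) / e - 1e-9)))
  }
  res <- .mc_run_cpp(zb, optics, attr(medium, "ambient_n"),
                     model$lateral_extent_mm, src[1], src[2],
                     det[1], det[2], config$detector_radius_mm,
                     config$n_launch, config$n_detect_target,
                     config$roulette_threshold, config$roulette_survival,
                     config$max_path_mm,
                     config$record_fluence, config$fluence_voxel_edge_mm,
                     flu_dim)
  if (res$n_detected == 0)
    warning("no packets detected; intensity is 0")
  if (config$record_fluence) {
    e <- config$fluence_voxel_edge_mm
    centers <- (seq_len(flu_dim[3]) - 0.5) * e
    centers <- pmin(centers, total_thickness(model) - 1e-12)
    mua_plane <- medium$mua[layer_at_depth(model, centers)]
    denom <- res$n_launched * e^3 *
      rep(mua_plane, each = flu_dim[1] * flu_dim[2])
    flu <- res$fluence_deposited
    norm <- ifelse(denom > 0, flu / denom, 0)
    dim(norm) <- dim(flu)
    res$fluence <- norm
  }
  res$wavelength_nm <- attr(medium, "wavelength_nm")
  res$config <- config
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "MC simulation: %d launched, %d detected, intensity %.5g, mean path %.3g mm\n",
    x$n_launched, x$n_detected, x$intensity, x$mean_optical_path))
  invisible(x)
}

#' Energy bookkeeping of a simulation result
#'
#' Sums every terminal bin (specular, detected, diffusely reflected,
#' transmitted, side-escaped, absorbed, path-terminated, plus the net
#' Russian-roulette residual) and compares with the launched weight; the
#' relative imbalance should be at floating-point level.
#'
#' @param result a [run_simulation()] result.
#' @return list with `total`, `launched` and `relative_imbalance`.
#' @export
energy_balance <- function(result) {
  total <- result$specular_weight + result$detected_weight_total +
    result$reflected_weight + result$transmitted_weight +
    result$escaped_side_weight + result$absorbed_weight +
    result$terminated_weight + result$roulette_net
  list(total = total, launched = result$n_launched,
       relative_imbalance = abs(total - result$n_launched) / result$n_launched)
}
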