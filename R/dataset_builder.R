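# Sweep of the SpO2 x glucose grid: paired 660/940 nm simulations per grid
# point, emitted as the synthetic training table; plus raw-count PPG
# fixtures emulating a 22-bit analog front end for calibration tests.

#' Specification of the SpO2 x glucose simulation grid
#'
#' Defaults are the study grid: SpO2 70-100 % in steps of 1 and glucose
#' 3.0-8.0 mmol/L in steps of 0.1, i.e. 31 x 51 = 1581 combinations.
#'
#' @param spo2_lower,spo2_upper,spo2_step SpO2 range and step, percent.
#' @param glucose_lower,glucose_upper,glucose_step glucose range and step,
#'   mmol/L.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(spo2_lower = 70, spo2_upper = 100, spo2_step = 1,
                      glucose_lower = 3.0, glucose_upper = 8.0,
                      glucose_step = 0.1) {
  stopifnot(spo2_lower <= spo2_upper, glucose_lower <= glucose_upper,
            spo2_step > 0, glucose_step > 0)
  structure(list(spo2_lower = spo2_lower, spo2_upper = spo2_upper,
                 spo2_step = spo2_step, glucose_lower = glucose_lower,
                 glucose_upper = glucose_upper, glucose_step = glucose_step),
            class = "grid_spec")
}

# inclusive arithmetic sequence by integer indexing (no floating-step drift)
grid_seq <- function(lower, upper, step) {
  k <- floor((upper - lower) / step + 1e-9)
  lower + step * (0:k)
}

#' Enumerate the grid points
#'
#' Cartesian product of the two inclusive sequences, glucose varying
#' fastest, in deterministic order.
#'
#' @param spec a [grid_spec()].
#' @return data frame with columns `spo2` (%) and `glucose_mmol` (mmol/L).
#' @examples
#' nrow(enumerate_grid(grid_spec()))  # 1581
#' @export
enumerate_grid <- function(spec = grid_spec()) {
  spo2 <- grid_seq(spec$spo2_lower, spec$spo2_upper, spec$spo2_step)
  glu <- grid_seq(spec$glucose_lower, spec$glucose_upper, spec$glucose_step)
  out <- expand.grid(glucose_mmol = glu, spo2 = spo2,
                     KEEP.OUT.ATTRS = FALSE)[, c("spo2", "glucose_mmol")]
  rownames(out) <- NULL
  out
}

#' Build the synthetic training dataset
#'
#' For every grid point, sets the physiological state (arterial saturation
#' SpO2/100, venous saturation 10 points lower, glucose in mol/L), builds
#' the 660 and 940 nm media, and runs one simulation per wavelength. The
#' per-point RNG seeds are drawn deterministically from `master_seed`, so
#' two builds with the same arguments are identical.
#'
#' @param model a [finger_model()].
#' @param grid a [grid_spec()].
#' @param sim a [sim_config()] (its `n_launch` is the per-wavelength photon
#'   budget per grid point).
#' @param mode optics mode passed to [build_medium()].
#' @param master_seed integer master seed.
#' @param table a [chromophore_table()].
#' @param verbose print progress every 100 points.
#' @return data frame of class `synthetic_dataset` with columns `spo2`,
#'   `glucose_mmol`, `intensity_660`, `intensity_940`, `n_detected_660`,
#'   `n_detected_940`, `seed`; provenance in attributes `grid`, `mode`,
#'   `n_launch`, `master_seed`.
#' @export
build_dataset <- function(model = default_finger_model(),
                          grid = grid_spec(),
                          sim = sim_config(n_launch = 1e5),
                          mode = c("analytic", "table5_anchored"),
                          master_seed = 1,
                          table = chromophore_table(),
                          verbose = FALSE) {
  mode <- match.arg(mode)
  pts <- enumerate_grid(grid)
  n <- nrow(pts)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n)

  i660 <- i940 <- numeric(n)
  d660 <- d940 <- integer(n)
  for (i in seq_len(n)) {
    state <- physio_state(sao2 = pts$spo2[i] / 100,
                          cg_mol_per_l = pts$glucose_mmol[i] / 1000)
    m660 <- build_medium(model, 660, state, mode, table)
    m940 <- build_medium(model, 940, state, mode, table)
    set.seed(seeds[i])
    r660 <- suppressWarnings(run_simulation(model, m660, sim))
    r940 <- suppressWarnings(run_simulation(model, m940, sim))
    i660[i] <- r660$intensity
    i940[i] <- r940$intensity
    d660[i] <- r660$n_detected
    d940[i] <- r940$n_detected
    if (verbose && i %% 100 == 0)
      message("grid point ", i, "/", n)
  }
  if (any(d660 == 0 | d940 == 0))
    warning("some grid points detected zero packets; rows retained")
  out <- data.frame(spo2 = pts$spo2, glucose_mmol = pts$glucose_mmol,
                    intensity_660 = i660, intensity_940 = i940,
                    n_detected_660 = d660, n_detected_940 = d940,
                    seed = seeds)
  attr(out, "grid") <- grid
  attr(out, "mode") <- mode
  attr(out, "n_launch") <- sim$n_launch
  attr(out, "master_seed") <- master_seed
  class(out) <- c("synthetic_dataset", "data.frame")
  out
}

#' Write / read a synthetic dataset with its provenance sidecar
#'
#' The table goes to `path` as CSV; grid, optics mode, photon budget and
#' master seed go to `<path>.json`.
#'
#' @param dataset a [build_dataset()] result.
#' @param path CSV file path.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  sidecar <- list(grid = unclass(attr(dataset, "grid")),
                  mode = attr(dataset, "mode"),
                  n_launch = attr(dataset, "n_launch"),
                  master_seed = attr(dataset, "master_seed"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- utils::read.csv(path)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    attr(out, "grid") <- do.call(grid_spec, sc$grid)
    attr(out, "mode") <- sc$mode
    attr(out, "n_launch") <- sc$n_launch
    attr(out, "master_seed") <- sc$master_seed
  }
  class(out) <- c("synthetic_dataset", "data.frame")
  out
}

#' Emulate raw 22-bit photodetector counts from simulated intensities
#'
#' Affine transform plus Gaussian noise, rounded and clipped to the 22-bit
#' range. Defaults put the count means near 399,000 (red channel) and
#' 425,000 (infrared channel), the scale of the front-end counts the model
#' is meant to be calibrated against; the mapping itself is synthetic stand-in
#' plumbing, since no real capture is distributed with the package.
#'
#' @param dataset a [build_dataset()] result (uses its intensity columns).
#' @param gain_red,offset_red,gain_ir,offset_ir affine parameters per channel.
#' @param noise_sd Gaussian noise standard deviation, counts.
#' @param seed RNG seed for the noise.
#' @return data frame with columns `counts_red`, `counts_ir`, `spo2`,
#'   `reference_glucose_mmol`.
#' @export
make_raw_ppg_fixture <- function(dataset, gain_red = 5e4, offset_red = 397000,
                                 gain_ir = 5e4, offset_ir = 423000,
                                 noise_sd = 0, seed = 1) {
  stopifnot(gain_red != 0, gain_ir != 0, noise_sd >= 0)
  set.seed(seed)
  n <- nrow(dataset)
  clip22 <- function(x) pmin(pmax(round(x), 0), 2^22 - 1)
  counts_red <- clip22(offset_red + gain_red * dataset$intensity_660 +
                         rnorm(n, 0, noise_sd))
  counts_ir <- clip22(offset_ir + gain_ir * dataset$intensity_940 +
                        rnorm(n, 0, noise_sd))
  data.frame(counts_red = counts_red, counts_ir = counts_ir,
             spo2 = dataset$spo2,
             reference_glucose_mmol = dataset$glucose_mmol)
}
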