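# Single-layer slab fixtures with hand-set optical properties, used for the
# closed-form transport oracles (Beer-Lambert, conservation).

slab_model <- function(thickness_mm = 1, lateral_mm = 50) {
  finger_model(data.frame(
    name = "slab", thickness_mm = thickness_mm, vb = 0, vwat = 0, vm = 0,
    mus_660 = 0, mus_940 = 0, g = 0, n = 1, stringsAsFactors = FALSE),
    lateral_extent_mm = lateral_mm)
}

slab_medium <- function(mua, mus, g = 0, n = 1, ambient_n = 1,
                        wavelength_nm = 660) {
  out <- data.frame(name = "slab", mua = mua, mus = mus, g = g, n = n,
                    stringsAsFactors = FALSE)
  attr(out, "wavelength_nm") <- wavelength_nm
  attr(out, "ambient_n") <- ambient_n
  attr(out, "mode") <- "fixed"
  class(out) <- c("medium_description", "data.frame")
  out
}

# analytic surrogate dataset: noise-free closed-form decaying intensity,
# I = exp(-k * sum_i thickness_i * mua_i(state)), k = 3 (an effective
# diffuse-path amplification); isolates learner correctness from MC noise
surrogate_dataset <- function(grid = grid_spec(), k = 3,
                              model = default_finger_model()) {
  g <- enumerate_grid(grid)
  one_wl <- function(wl) {
    vapply(seq_len(nrow(g)), function(i) {
      st <- physio_state(g$spo2[i] / 100, g$glucose_mmol[i] / 1000)
      med <- build_medium(model, wl, st)
      exp(-k * sum(model$layers$thickness_mm * med$mua))
    }, numeric(1))
  }
  data.frame(spo2 = g$spo2, glucose_mmol = g$glucose_mmol,
             intensity_660 = one_wl(660), intensity_940 = one_wl(940))
}
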