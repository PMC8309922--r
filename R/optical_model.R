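# Per-layer absorption coefficients as functions of wavelength, oxygen
# saturation and glucose concentration, and assembly of the full
# (mu_a, mu_s, g, n) medium description consumed by the transport engine.
#
# Units: wavelengths in nm, coefficients in mm^-1, glucose molar
# absorptivity in L mol^-1 cm^-1 (the 0.1 factor in the blood formulas
# converts the glucose term from cm^-1 to mm^-1), concentrations in mol/L.

#' Chromophore absorption table
#'
#' Absorption coefficients of water, oxyhemoglobin and deoxyhemoglobin
#' (mm^-1) and the glucose molar absorptivity (L mol^-1 cm^-1) at the two
#' working wavelengths, 660 and 940 nm.
#'
#' @param path optional CSV override with columns `wavelength_nm`, `water`,
#'   `hbo2`, `hhb`, `eps_glucose`.
#' @return data frame of class `chromophore_table`.
#' @export
chromophore_table <- function(path = NULL) {
  tab <- if (is.null(path)) {
    data.frame(
      wavelength_nm = c(660, 940),
      water = c(0.00041, 0.00181811),
      hbo2 = c(0.0171, 0.1728),
      hhb = c(0.065, 0.037),
      eps_glucose = c(0.0002, 0.001))
  } else {
    utils::read.csv(path)
  }
  stopifnot(all(c("wavelength_nm", "water", "hbo2", "hhb",
                  "eps_glucose") %in% names(tab)))
  if (any(tab[-1] < 0)) stop("chromophore coefficients must be >= 0")
  class(tab) <- c("chromophore_table", "data.frame")
  tab
}

chromophore_row <- function(table, wavelength_nm) {
  i <- match(wavelength_nm, table$wavelength_nm)
  if (is.na(i))
    stop("no chromophore entries at ", wavelength_nm,
         " nm; available: ", paste(table$wavelength_nm, collapse = ", "))
  table[i, , drop = FALSE]
}

#' Physiological state: oxygen saturations and glucose concentration
#'
#' @param sao2 arterial oxygen saturation, fraction in [0, 1].
#' @param cg_mol_per_l blood glucose molar concentration, mol/L (physiological
#'   values are a few millimol per litre, e.g. `5.5e-3`).
#' @param svo2 venous oxygen saturation; default `sao2 - 0.10` (clamped at 0),
#'   the conventional venous offset.
#' @return list of class `physio_state`.
#' @export
physio_state <- function(sao2, cg_mol_per_l, svo2 = NULL) {
  if (is.null(svo2)) svo2 <- max(0, sao2 - 0.10)
  if (!(svo2 >= 0 && svo2 <= sao2 && sao2 <= 1))
    stop("need 0 <= svo2 <= sao2 <= 1")
  if (cg_mol_per_l < 0) stop("glucose concentration must be >= 0")
  structure(list(sao2 = sao2, svo2 = svo2, cg_mol_per_l = cg_mol_per_l),
            class = "physio_state")
}

#' Reference physiological state used by the anchored optics mode
#' @return [physio_state()] at SaO2 = 0.97 and glucose 5.5 mmol/L, the
#'   mid-range of the simulation grid.
#' @export
reference_state <- function() physio_state(sao2 = 0.97, cg_mol_per_l = 5.5e-3)

check_band <- function(wavelength_nm) {
  if (any(wavelength_nm < 400 | wavelength_nm > 1100))
    warning("wavelength ", paste(wavelength_nm, collapse = ","),
            " nm outside the validated 400-1100 nm band")
}

#' Baseline (bloodless, waterless) tissue absorption
#'
#' Power-law background absorption of skin tissue,
#' `7.84e7 * lambda^-3.255` with the wavelength in nm, interpreted in mm^-1.
#'
#' @param wavelength_nm wavelength, nm (validated band 400-1100).
#' @return absorption coefficient, mm^-1.
#' @export
baseline_absorption <- function(wavelength_nm) {
  check_band(wavelength_nm)
  7.84e7 * wavelength_nm^-3.255
}

#' Melanin absorption
#'
#' `6.6e10 * lambda^-3.3` with the wavelength in nm, interpreted in mm^-1.
#' @inheritParams baseline_absorption
#' @return absorption coefficient, mm^-1.
#' @export
melanin_absorption <- function(wavelength_nm) {
  check_band(wavelength_nm)
  6.6e10 * wavelength_nm^-3.3
}

blood_absorption <- function(wavelength_nm, sat, cg_mol_per_l, table) {
  row <- chromophore_row(table, wavelength_nm)
  sat * row$hbo2 + (1 - sat) * row$hhb +
    0.1 * row$eps_glucose * cg_mol_per_l  # 0.1: cm^-1 -> mm^-1
}

#' Whole-blood absorption at a given oxygen saturation
#'
#' Saturation-weighted mix of oxy- and deoxyhemoglobin absorption plus the
#' (small) glucose term `0.1 * eps_g * cg`:
#' `sat * muaHbO + (1 - sat) * muaHHb + 0.1 * eps_g * cg`.
#' `arterial_blood_absorption` and `venous_blood_absorption` share this form
#' and differ only in which saturation (arterial or venous) is supplied.
#'
#' @inheritParams baseline_absorption
#' @param sat oxygen saturation, fraction in [0, 1].
#' @param cg_mol_per_l glucose concentration, mol/L.
#' @param table a [chromophore_table()].
#' @return absorption coefficient, mm^-1.
#' @export
arterial_blood_absorption <- function(wavelength_nm, sat, cg_mol_per_l = 0,
                                      table = chromophore_table()) {
  blood_absorption(wavelength_nm, sat, cg_mol_per_l, table)
}

#' @rdname arterial_blood_absorption
#' @export
venous_blood_absorption <- function(wavelength_nm, sat, cg_mol_per_l = 0,
                                    table = chromophore_table()) {
  blood_absorption(wavelength_nm, sat, cg_mol_per_l, table)
}

#' Epidermis absorption
#'
#' Melanin/water mixture over the tissue baseline:
#' `Vm * mua_mel + Vw * mua_wat + (1 - Vm - Vw) * mua_baseline`.
#'
#' @inheritParams arterial_blood_absorption
#' @param melanin_fraction melanin volume fraction Vm (default 0.10).
#' @param water_fraction water volume fraction Vw.
#' @return absorption coefficient, mm^-1.
#' @export
epidermis_absorption <- function(wavelength_nm, melanin_fraction = 0.10,
                                 water_fraction = 0.20,
                                 table = chromophore_table()) {
  if (melanin_fraction + water_fraction > 1)
    stop("melanin_fraction + water_fraction must not exceed 1")
  row <- chromophore_row(table, wavelength_nm)
  melanin_fraction * melanin_absorption(wavelength_nm) +
    water_fraction * row$water +
    (1 - melanin_fraction - water_fraction) * baseline_absorption(wavelength_nm)
}

#' Stratum corneum absorption
#'
#' `[(0.1 - 0.3e-4 * lambda) + 0.125 * mua_baseline] * (1 - Vw) + Vw * mua_wat`
#' with the wavelength in nm.
#'
#' @inheritParams epidermis_absorption
#' @return absorption coefficient, mm^-1.
#' @export
stratum_corneum_absorption <- function(wavelength_nm, water_fraction = 0.05,
                                       table = chromophore_table()) {
  if (water_fraction < 0 || water_fraction > 1)
    stop("water_fraction must lie in [0, 1]")
  row <- chromophore_row(table, wavelength_nm)
  ((0.1 - 0.3e-4 * wavelength_nm) +
     0.125 * baseline_absorption(wavelength_nm)) * (1 - water_fraction) +
    water_fraction * row$water
}

#' Absorption of a blood-bearing dermal sublayer
#'
#' Volume-fraction mixture of arterial blood, venous blood, water and the
#' tissue baseline:
#' `VArt * muaArt + VVen * muaVen + Vwat * mua_wat +
#'  (1 - VArt - VVen - Vwat) * mua_baseline`.
#'
#' @inheritParams arterial_blood_absorption
#' @param arterial_fraction,venous_fraction,water_fraction volume fractions.
#' @param state a [physio_state()] supplying SaO2, SvO2 and glucose.
#' @return absorption coefficient, mm^-1.
#' @export
dermal_absorption <- function(wavelength_nm, arterial_fraction,
                              venous_fraction, water_fraction, state,
                              table = chromophore_table()) {
  if (arterial_fraction + venous_fraction + water_fraction > 1 + 1e-12)
    stop("volume fractions must sum to at most 1")
  row <- chromophore_row(table, wavelength_nm)
  mu_art <- blood_absorption(wavelength_nm, state$sao2,
                             state$cg_mol_per_l, table)
  mu_ven <- blood_absorption(wavelength_nm, state$svo2,
                             state$cg_mol_per_l, table)
  arterial_fraction * mu_art + venous_fraction * mu_ven +
    water_fraction * row$water +
    (1 - arterial_fraction - venous_fraction - water_fraction) *
      baseline_absorption(wavelength_nm)
}

#' Assemble the per-layer medium description for the transport engine
#'
#' Computes the absorption coefficient of every layer at the given
#' wavelength and physiological state and pairs it with the layer's fixed
#' scattering coefficient, anisotropy and refractive index.
#'
#' Two modes:
#' \describe{
#'   \item{`analytic`}{stratum corneum and epidermis from their mixture
#'     formulas; the four blood-bearing dermal sublayers from the dermal
#'     mixture with `VArt = VVen = Vb / 2`; fat, muscle and bone from their
#'     fixed printed values. This is the headline mode.}
#'   \item{`table5_anchored`}{every layer starts from its printed absorption
#'     value and adds the blood-driven perturbation
#'     `Vb * (mu_blood(state) - mu_blood(reference))`, so the printed values
#'     are reproduced exactly at the reference state (SaO2 = 0.97, glucose
#'     5.5 mmol/L) while retaining the saturation and glucose sensitivity of
#'     the blood formulas.}
#' }
#'
#' @param model a [finger_model()].
#' @param wavelength_nm 660 or 940 (any wavelength present in `table` and in
#'   the model's scattering columns).
#' @param state a [physio_state()].
#' @param mode `"analytic"` (default) or `"table5_anchored"`.
#' @param table a [chromophore_table()].
#' @param ambient_n refractive index of the surrounding medium (air).
#' @return data frame of class `medium_description` with one row per layer
#'   and columns `name`, `mua`, `mus`, `g`, `n`; attributes `wavelength_nm`,
#'   `ambient_n`, `mode`, `state`.
#' @export
build_medium <- function(model, wavelength_nm, state,
                         mode = c("analytic", "table5_anchored"),
                         table = chromophore_table(), ambient_n = 1.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "finger_model"), inherits(state, "physio_state"))
  ly <- model$layers
  mus_col <- paste0("mus_", wavelength_nm)
  if (!mus_col %in% names(ly))
    stop("model carries no scattering coefficients for ", wavelength_nm, " nm")
  t5_col <- paste0("mua_table5_", wavelength_nm)

  mua <- numeric(nrow(ly))
  if (mode == "analytic") {
    for (i in seq_len(nrow(ly))) {
      mua[i] <- switch(
        ly$name[i],
        stratum_corneum = stratum_corneum_absorption(
          wavelength_nm, ly$vwat[i], table),
        epidermis = epidermis_absorption(
          wavelength_nm, ly$vm[i], ly$vwat[i], table),
        fat = , muscle = , bone = {
          if (!t5_col %in% names(ly))
            stop("model carries no fixed absorption values for ",
                 wavelength_nm, " nm (layer ", ly$name[i], ")")
          ly[[t5_col]][i]
        },
        dermal_absorption(wavelength_nm, ly$vb[i] / 2, ly$vb[i] / 2,
                          ly$vwat[i], state, table))
    }
  } else {
    if (!t5_col %in% names(ly))
      stop("table5_anchored mode needs the printed absorption columns")
    ref <- reference_state()
    delta <- function(s) {
      0.5 * (blood_absorption(wavelength_nm, s$sao2, s$cg_mol_per_l, table) +
             blood_absorption(wavelength_nm, s$svo2, s$cg_mol_per_l, table))
    }
    mua <- ly[[t5_col]] + ly$vb * (delta(state) - delta(ref))
  }
  if (any(!is.finite(mua)) || any(mua < 0))
    stop("computed absorption coefficients must be finite and >= 0")

  out <- data.frame(name = ly$name, mua = mua, mus = ly[[mus_col]],
                    g = ly$g, n = ly$n, stringsAsFactors = FALSE)
  attr(out, "wavelength_nm") <- wavelength_nm
  attr(out, "ambient_n") <- ambient_n
  attr(out, "mode") <- mode
  attr(out, "state") <- state
  class(out) <- c("medium_description", "data.frame")
  out
}
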