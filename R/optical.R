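#' Optical model for hemoglobin spectroscopy
#'
#' Bundles the wavelength-specific molar extinction coefficients of oxy- and
#' deoxyhemoglobin, the differential pathlength factors of the imaging
#' preparation, and the assumed baseline concentrations used by the modified
#' Beer-Lambert inversion (baseline HbO 60 uM, HbR 40 uM, so HbT0 = 100 uM
#' and baseline sO2 = 60%).
#'
#' Extinction coefficients default to the standard compiled hemoglobin
#' absorption spectra (Gratzer/Prahl compilation) evaluated at the LED center
#' wavelengths: 535 nm (green), 590 nm (amber), 620 nm (red) for reflectance,
#' and 475/515 nm (GCaMP excitation/emission) for the fluorescence
#' attenuation model. Differential pathlength factors are preparation
#' dependent and configurable; the defaults are typical for widefield
#' reflectance imaging of the exposed mouse cortex, where weakly absorbed red
#' light travels much further through tissue than green.
#'
#' @param channels data.frame with columns `channel`, `wavelength_nm`,
#'   `eps_hbo`, `eps_hbr` (cm^-1 M^-1), `pathlength_cm`. Defaults to the
#'   built-in table for the green/amber/red reflectance channels.
#' @param baseline_hbo,baseline_hbr baseline concentrations in uM.
#' @param fluo_eps_hbo,fluo_eps_hbr effective extinction coefficients seen by
#'   the fluorescence channel (mean of excitation and emission bands).
#' @param fluo_pathlength_cm effective pathlength for fluorescence attenuation.
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(channels = default_extinction_table(),
                          baseline_hbo = 60,
                          baseline_hbr = 40,
                          fluo_eps_hbo = mean(c(26629, 22666)),
                          fluo_eps_hbr = mean(c(37020, 28324)),
                          fluo_pathlength_cm = 0.05) {
  stopifnot(is.data.frame(channels),
            all(c("channel", "wavelength_nm", "eps_hbo", "eps_hbr",
                  "pathlength_cm") %in% names(channels)))
  if (any(channels$eps_hbo <= 0) || any(channels$eps_hbr <= 0))
    stop("extinction coefficients must be positive")
  if (baseline_hbo <= 0 || baseline_hbr <= 0)
    stop("baseline concentrations must be positive")
  A <- beer_lambert_matrix(channels)
  kappa <- kappa(A, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e6)
    stop("singular extinction matrix: channels do not separate HbO from HbR")
  structure(list(
    channels = channels,
    baseline_hbo = baseline_hbo,
    baseline_hbr = baseline_hbr,
    baseline_hbt = baseline_hbo + baseline_hbr,
    fluo_eps_hbo = fluo_eps_hbo,
    fluo_eps_hbr = fluo_eps_hbr,
    fluo_pathlength_cm = fluo_pathlength_cm,
    condition_number = kappa
  ), class = "optical_model")
}

#' Built-in extinction coefficient table
#'
#' Molar extinction coefficients (cm^-1 M^-1) of HbO and HbR at the three
#' reflectance LED center wavelengths, with default differential pathlength
#' factors (cm). LEDs are treated as monochromatic at their center wavelength.
#'
#' @return data.frame with one row per reflectance channel.
#' @export
default_extinction_table <- function() {
  data.frame(
    channel = c("green", "amber", "red"),
    wavelength_nm = c(535, 590, 620),
    eps_hbo = c(47338, 14677, 942),
    eps_hbr = c(41234, 26600, 6510),
    pathlength_cm = c(0.05, 0.07, 0.30),
    stringsAsFactors = FALSE
  )
}

# Design matrix of the modified Beer-Lambert system, per uM of concentration
# change: row lambda, columns (HbO, HbR); entries D(lambda)*eps*1e-6.
beer_lambert_matrix <- function(channels) {
  A <- cbind(hbo = channels$pathlength_cm * channels$eps_hbo * 1e-6,
             hbr = channels$pathlength_cm * channels$eps_hbr * 1e-6)
  rownames(A) <- channels$channel
  A
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Optical model (modified Beer-Lambert)\n")
  cat(sprintf("  baseline: HbO %g uM, HbR %g uM (HbT0 %g uM, sO2 %.0f%%)\n",
              x$baseline_hbo, x$baseline_hbr, x$baseline_hbt,
              100 * x$baseline_hbo / x$baseline_hbt))
  cat(sprintf("  condition number of design matrix: %.2f\n",
              x$condition_number))
  print(x$channels, row.names = FALSE)
  invisible(x)
}
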