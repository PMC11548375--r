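## Modified Beer-Lambert conversion: raw light intensities -> optical
## densities -> chromophore concentration changes (O2Hb, HHb) and total
## hemoglobin. Concentration *changes* only: the scattering loss G and the
## unknown absolute baseline cancel under baseline differencing.

#' Default molar extinction coefficients
#'
#' Base-10 molar extinction coefficients for oxy- and deoxyhemoglobin in
#' cm^-1 mM^-1 at the wavelengths commonly used by continuous-wave NIRS
#' oximeters. Values are rounded literature compilations (Cope-style tables)
#' shipped as *defaults only*: the instrument emulated here does not publish
#' its calibration table, so any quantitative use on real hardware should
#' override this table via the `extinction` argument of
#' [concentration_changes()].
#'
#' @return data.frame with columns `wavelength_nm`, `e_o2hb`, `e_hhb`.
#' @export
extinction_defaults <- function() {
  data.frame(
    wavelength_nm = c(730, 760, 805, 850),
    e_o2hb        = c(0.450, 0.610, 0.810, 1.058),
    e_hhb         = c(2.540, 1.674, 0.810, 0.691)
  )
}

#' Default differential path-length factors
#'
#' Neonatal-head DPF defaults per wavelength (dimensionless, ~4.4 near
#' 760 nm, mildly decreasing with wavelength). Not instrument-calibrated;
#' override via [beer_lambert_params()].
#'
#' @return data.frame with columns `wavelength_nm`, `dpf`.
#' @export
dpf_defaults <- function() {
  data.frame(
    wavelength_nm = c(730, 760, 805, 850),
    dpf           = c(4.55, 4.40, 4.25, 4.15)
  )
}

lookup_by_wavelength <- function(table, wavelengths, cols) {
  i <- match(wavelengths, table$wavelength_nm)
  if (anyNA(i)) {
    stopf("no tabulated values for wavelength(s) %s nm",
          paste(wavelengths[is.na(i)], collapse = ", "))
  }
  table[i, cols, drop = FALSE]
}

#' Beer-Lambert geometry and path-length parameters
#'
#' @param wavelengths wavelengths in nm (length >= 2).
#' @param dpf differential path-length factor per wavelength; defaults to
#'   [dpf_defaults()] at the given wavelengths.
#' @param distance_cm source-detector distance l in cm.
#' @param scattering_loss G term of the modified Beer-Lambert law. Retained
#'   for completeness; it cancels in concentration changes and is never
#'   estimated.
#' @return object of class `beer_lambert_params`.
#' @export
beer_lambert_params <- function(wavelengths = c(760, 850),
                                dpf = NULL,
                                distance_cm = 3.0,
                                scattering_loss = 0) {
  if (length(wavelengths) < 2L) stopf("need at least 2 wavelengths")
  if (is.null(dpf)) dpf <- lookup_by_wavelength(dpf_defaults(), wavelengths, "dpf")$dpf
  if (length(dpf) == 1L) dpf <- rep(dpf, length(wavelengths))
  if (length(dpf) != length(wavelengths)) stopf("dpf must match wavelengths")
  if (any(dpf <= 0)) stopf("dpf must be positive")
  if (distance_cm <= 0) stopf("source-detector distance must be positive")
  structure(list(wavelengths = wavelengths, dpf = dpf,
                 distance_cm = distance_cm, scattering_loss = scattering_loss),
            class = "beer_lambert_params")
}

#' Convert raw intensities to optical densities
#'
#' OD(t, lambda) = -log10(I(t, lambda) / I0(lambda)). When no reference
#' intensity is supplied, I0 is the per-wavelength mean over an initial
#' baseline window (continuous recordings have no transmitted-intensity
#' reference, so a baseline-window mean is the practical convention).
#'
#' @param intensity numeric matrix, samples x wavelengths, strictly positive.
#' @param i0 optional per-wavelength reference intensity.
#' @param sample_rate Hz; required when `i0` is `NULL`.
#' @param baseline_s baseline window length in seconds used to estimate I0.
#' @return matrix of optical densities (dimensionless), same shape.
#' @export
optical_density <- function(intensity, i0 = NULL, sample_rate = 100,
                            baseline_s = 10) {
  intensity <- as.matrix(intensity)
  bad <- which(intensity <= 0)
  if (length(bad)) {
    stopf("non-positive intensity at sample index %d (first of %d offending samples)",
          bad[1L], length(bad))
  }
  if (is.null(i0)) {
    nb <- max(2L, min(nrow(intensity), round(baseline_s * sample_rate)))
    i0 <- colMeans(intensity[seq_len(nb), , drop = FALSE])
  }
  if (length(i0) == 1L) i0 <- rep(i0, ncol(intensity))
  if (length(i0) != ncol(intensity)) stopf("i0 must have one value per wavelength")
  if (any(i0 <= 0)) stopf("reference intensity must be positive")
  -log10(sweep(intensity, 2L, i0, `/`))
}

#' Solve the modified Beer-Lambert law for concentration changes
#'
#' Per sample, solves dOD(lambda) = e(lambda) . dc . DPF(lambda) . l for
#' dc = (dO2Hb, dHHb) by least squares over wavelengths, after subtracting
#' the per-wavelength baseline-window mean OD (which removes G and the
#' arbitrary I0 scale). Extinction coefficients in cm^-1 mM^-1, output in uM.
#'
#' @param od matrix of optical densities (samples x wavelengths).
#' @param params a [beer_lambert_params()] object.
#' @param extinction extinction table as in [extinction_defaults()].
#' @param sample_rate sampling rate in Hz.
#' @param baseline_s baseline-differencing window in seconds.
#' @param tsi optional tissue-saturation-index series (%), passed through.
#' @return object of class `hemodynamics` with 100 Hz `o2hb`, `hhb`, `thb`
#'   (uM change) and `tsi` (%).
#' @export
concentration_changes <- function(od, params,
                                  extinction = extinction_defaults(),
                                  sample_rate = 100, baseline_s = 10,
                                  tsi = NULL) {
  od <- as.matrix(od)
  stopifnot(inherits(params, "beer_lambert_params"))
  wl <- params$wavelengths
  if (ncol(od) != length(wl)) stopf("od has %d columns but %d wavelengths declared", ncol(od), length(wl))
  if (ncol(od) < 2L) stopf("need at least 2 wavelengths to separate O2Hb and HHb")
  ext <- lookup_by_wavelength(extinction, wl, c("e_o2hb", "e_hhb"))
  E <- as.matrix(ext)                       # n_wl x 2, cm^-1 mM^-1
  if (any(E <= 0)) stopf("extinction coefficients must be positive")
  ## design matrix maps uM changes to OD: e * DPF * l * 1e-3 (uM -> mM)
  M <- E * params$dpf * params$distance_cm * 1e-3
  if (kappa(crossprod(M)) > 1e10) {
    stopf("extinction matrix is singular or near-singular for wavelengths %s",
          paste(wl, collapse = ", "))
  }
  nb <- max(1L, min(nrow(od), round(baseline_s * sample_rate)))
  dod <- sweep(od, 2L, colMeans(od[seq_len(nb), , drop = FALSE]), `-`)
  ## least squares: dc' = (M'M)^-1 M' dOD', vectorized over samples
  pinv <- solve(crossprod(M), t(M))
  dc <- dod %*% t(pinv)                     # samples x 2, uM
  hemodynamics(o2hb = dc[, 1L], hhb = dc[, 2L], tsi = tsi,
               sample_rate = sample_rate)
}

#' Construct a hemodynamics container
#'
#' @param o2hb,hhb concentration-change series in uM.
#' @param tsi optional tissue saturation index series (%).
#' @param sample_rate Hz.
#' @return object of class `hemodynamics`; `thb` is always `o2hb + hhb`.
#' @export
hemodynamics <- function(o2hb, hhb, tsi = NULL, sample_rate = 100) {
  if (length(o2hb) != length(hhb)) {
    stopf("o2hb (%d) and hhb (%d) length mismatch", length(o2hb), length(hhb))
  }
  if (!is.null(tsi) && length(tsi) != length(o2hb)) {
    stopf("tsi length (%d) does not match o2hb (%d)", length(tsi), length(o2hb))
  }
  structure(list(o2hb = as.numeric(o2hb), hhb = as.numeric(hhb),
                 tsi = if (is.null(tsi)) NULL else as.numeric(tsi),
                 thb = as.numeric(o2hb) + as.numeric(hhb),
                 sample_rate = sample_rate),
            class = "hemodynamics")
}

#' Total hemoglobin
#'
#' Elementwise sum of the O2Hb and HHb concentration-change series.
#'
#' @param h a `hemodynamics` object, or the o2hb series when `hhb` is given.
#' @param hhb optional HHb series.
#' @return numeric tHb series in uM.
#' @export
total_hemoglobin <- function(h, hhb = NULL) {
  if (inherits(h, "hemodynamics")) return(h$o2hb + h$hhb)
  if (is.null(hhb)) stopf("supply a hemodynamics object or both series")
  if (length(h) != length(hhb)) stopf("length mismatch: %d vs %d", length(h), length(hhb))
  h + hhb
}

#' @export
print.hemodynamics <- function(x, ...) {
  cat(sprintf("<hemodynamics> %d samples @ %g Hz (%.1f min)%s\n",
              length(x$o2hb), x$sample_rate,
              length(x$o2hb) / x$sample_rate / 60,
              if (is.null(x$tsi)) ", no TSI" else ""))
  invisible(x)
}

## Forward model used by the simulator: concentration changes (uM) -> OD.
forward_od <- function(o2hb_um, hhb_um, params, extinction = extinction_defaults()) {
  ext <- lookup_by_wavelength(extinction, params$wavelengths, c("e_o2hb", "e_hhb"))
  M <- as.matrix(ext) * params$dpf * params$distance_cm * 1e-3
  cbind(o2hb_um, hhb_um) %*% t(M) + params$scattering_loss
}
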