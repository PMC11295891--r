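#' Photopic illuminance of a spectrum
#'
#' Illuminance in lux: `683.002 * sum(E(lambda) * V(lambda))` with 1 nm
#' spacing, using the embedded photopic luminous efficiency curve.
#'
#' @param spec A [spectrum_regular] object (or 401-vector on the canonical
#'   grid).
#' @return Illuminance in lux (>= 0, linear in the spectrum).
#' @export
illuminance <- function(spec) {
  v <- as.numeric(spectrum_regular(spec))
  tab <- action_tables()
  .pf_km * sum(v * tab$weights[, "photopic"])
}

#' Alpha-opic irradiance
#'
#' Spectral irradiance weighted by the action spectrum of one photoreceptor
#' class: `sum(E(lambda) * s_alpha(lambda))` with 1 nm spacing, in W m^-2.
#'
#' @param spec A [spectrum_regular] object.
#' @param name Photoreceptor class (see [photoreceptor_classes()]).
#' @return Alpha-opic irradiance in W m^-2.
#' @export
alpha_irradiance <- function(spec, name) {
  cl <- normalize_class(name)
  v <- as.numeric(spectrum_regular(spec))
  tab <- action_tables()
  sum(v * tab$weights[, cl])
}

#' Alpha-opic equivalent daylight illuminance (EDI)
#'
#' The illuminance of the daylight reference that produces the same alpha-opic
#' irradiance as the test spectrum: alpha-opic irradiance divided by the
#' class's daylight normalization constant. For the melanopic class this is
#' the melanopic EDI (mEDI).
#'
#' @inheritParams alpha_irradiance
#' @return EDI in lux.
#' @export
alpha_edi <- function(spec, name) {
  cl <- normalize_class(name)
  alpha_irradiance(spec, cl) / action_tables()$norms[[cl]]
}

#' All light metrics of a spectrum
#'
#' Bundles photopic illuminance, the five alpha-opic irradiances and EDIs and
#' the melanopic daylight efficacy ratio (DER, mEDI / illuminance) into one
#' record. The DER is `NA` (flagged) for a dark spectrum with zero
#' illuminance.
#'
#' @param spec A [spectrum_regular] object.
#' @return An object of class `"photometric_record"`: list with
#'   `illuminance_lx`, `alpha_irradiance` (named, W m^-2), `alpha_edi_lx`
#'   (named, lux), `mel_der` and `mel_der_defined`.
#' @export
photometrics <- function(spec) {
  v <- as.numeric(spectrum_regular(spec))
  tab <- action_tables()
  classes <- setdiff(photoreceptor_classes(), "photopic")
  irr <- vapply(classes, function(cl) sum(v * tab$weights[, cl]), numeric(1))
  edi <- irr / tab$norms[classes]
  illum <- .pf_km * sum(v * tab$weights[, "photopic"])
  der_def <- illum > 0
  structure(
    list(
      illuminance_lx = illum,
      alpha_irradiance = irr,
      alpha_edi_lx = edi,
      mel_der = if (der_def) unname(edi[["melanopic"]] / illum) else NA_real_,
      mel_der_defined = der_def
    ),
    class = "photometric_record"
  )
}

#' @export
print.photometric_record <- function(x, ...) {
  cat("<photometric_record> ",
      format(x$illuminance_lx, digits = 5), " lx, mEDI ",
      format(x$alpha_edi_lx[["melanopic"]], digits = 5), " lx, mel-DER ",
      format(x$mel_der, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Light metrics for a matrix of spectra
#'
#' Vectorized [photometrics()] over many spectra: one row per sample.
#'
#' @param mat Numeric matrix, one spectrum per row, 401 columns on the
#'   canonical 380--780 nm grid.
#' @return A data.frame with columns `illuminance_lx`,
#'   `{scone,mcone,lcone,rhodopic,melanopic}_irradiance`, `{...}_edi_lx` and
#'   `mel_der` (`NA` where illuminance is zero).
#' @export
photometrics_table <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(.pf_grid))
  tab <- action_tables()
  classes <- setdiff(photoreceptor_classes(), "photopic")
  irr <- mat %*% tab$weights[, classes]
  edi <- sweep(irr, 2, tab$norms[classes], "/")
  illum <- as.numeric(.pf_km * (mat %*% tab$weights[, "photopic"]))
  out <- data.frame(illuminance_lx = illum)
  for (cl in classes) out[[paste0(cl, "_irradiance")]] <- irr[, cl]
  for (cl in classes) out[[paste0(cl, "_edi_lx")]] <- edi[, cl]
  out$mel_der <- ifelse(illum > 0, edi[, "melanopic"] / illum, NA_real_)
  out
}
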