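#' Photoreceptor classes
#'
#' The five retinal photoreceptor classes of the alpha-opic framework plus the
#' CIE 1924 photopic observer. Class names follow the alpha-opic convention;
#' the long names used in standards documents (`"S-cone-opic"`, `"melanopic"`,
#' ...) are accepted everywhere a class name is expected.
#'
#' @return Character vector of canonical class names.
#' @export
photoreceptor_classes <- function() {
  c("scone", "mcone", "lcone", "rhodopic", "melanopic", "photopic")
}

# normalize user-facing class names ("S-cone-opic", "L-cone-opic", ...) to the
# canonical short names; errors on anything unknown
normalize_class <- function(name) {
  if (length(name) != 1L || !is.character(name)) {
    stop("photoreceptor class must be a single character string", call. = FALSE)
  }
  key <- gsub("[^a-z]", "", tolower(name))
  map <- c(
    scone = "scone", sconeopic = "scone",
    mcone = "mcone", mconeopic = "mcone",
    lcone = "lcone", lconeopic = "lcone",
    rhodopic = "rhodopic", rod = "rhodopic", scotopic = "rhodopic",
    melanopic = "melanopic", mel = "melanopic",
    photopic = "photopic", illuminance = "photopic", v = "photopic"
  )
  if (!key %in% names(map)) {
    stop("unknown photoreceptor class: '", name, "'", call. = FALSE)
  }
  unname(map[[key]])
}

# Govardovskii et al. (2000) A1 visual-pigment nomogram, quantal sensitivity.
# lmax in nm; evaluated on `lambda` (nm). Alpha band plus beta band.
govardovskii_nomogram <- function(lmax, lambda = .pf_grid) {
  x <- lmax / lambda
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  s_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  bw <- -40.5 + 0.195 * lmax
  s_beta <- 0.26 * exp(-((lambda - lmb) / bw)^2)
  s_alpha + s_beta
}

# young-adult ocular-media (lens) optical density, exponential model:
# ~0.8 density at 400 nm decaying with 30 nm scale towards long wavelengths
ocular_media_density <- function(lambda = .pf_grid) {
  pmax(0.8 * exp(-(lambda - 400) / 30), 0)
}

# Planck spectral radiance (arbitrary scale) at temperature T (K)
planck_spectrum <- function(temp_k, lambda = .pf_grid) {
  h <- 6.62607015e-34; cc <- 2.99792458e8; kb <- 1.380649e-23
  lm <- lambda * 1e-9
  v <- lm^-5 / (exp(h * cc / (lm * kb * temp_k)) - 1)
  v / max(v)
}

# Build the 401 x 6 weight table, the daylight reference SPD and the five
# D65-style normalization constants, once per session. All curves are
# template reconstructions (nomogram x media transmittance, converted from
# quantal to energy units, peak-normalized); the photopic curve is a luminous
# efficiency reconstruction as 1.55 L + M. The daylight reference is a 6504 K
# Planckian radiator; EDI semantics are self-consistent against it.
build_action_tables <- function() {
  tau <- 10^(-ocular_media_density())
  lmax <- c(scone = 419, mcone = 530.3, lcone = 558.9,
            rhodopic = 496.3, melanopic = 480)
  weights <- vapply(lmax, function(l) {
    s <- govardovskii_nomogram(l) * tau * .pf_grid  # quantal -> energy units
    s / max(s)
  }, numeric(length(.pf_grid)))
  photopic <- 1.55 * weights[, "lcone"] + weights[, "mcone"]
  weights <- cbind(weights, photopic = photopic / max(photopic))
  d65 <- planck_spectrum(6504)
  illum_d65 <- .pf_km * sum(d65 * weights[, "photopic"])
  norms <- vapply(colnames(weights), function(cl) {
    sum(d65 * weights[, cl]) / illum_d65
  }, numeric(1))
  list(weights = weights, d65 = d65, norms = norms)
}

action_tables <- function() {
  if (is.null(.pf_env$tables)) .pf_env$tables <- build_action_tables()
  .pf_env$tables
}

#' Spectral sensitivity (action spectrum) of a photoreceptor class
#'
#' Returns the tabulated spectral weighting function of one of the five
#' alpha-opic photoreceptor classes or the photopic observer, on the canonical
#' 380--780 nm 1 nm grid, peak-normalized to 1, together with its daylight
#' normalization constant (alpha-opic irradiance of the embedded daylight
#' reference per lux of that reference, W m^-2 lx^-1). The constant converts
#' alpha-opic irradiance into alpha-opic equivalent daylight illuminance (EDI).
#'
#' The embedded curves are deterministic reconstructions from the Govardovskii
#' opsin nomogram with standard pre-receptoral (lens) filtering, in energy
#' units; see the methods vignette for the construction and its accuracy.
#'
#' @param name Photoreceptor class, e.g. `"melanopic"`, `"S-cone-opic"`,
#'   `"photopic"`.
#' @return An object of class `"action_spectrum"`: list with `name`,
#'   `wavelengths_nm`, `weights` (401 values in \[0, 1\], max exactly 1) and
#'   `d65_normalization` (W m^-2 lx^-1; 1/683.002 for the photopic class).
#' @examples
#' mel <- action_spectrum("melanopic")
#' max(mel$weights)  # 1
#' @export
action_spectrum <- function(name) {
  cl <- normalize_class(name)
  tab <- action_tables()
  structure(
    list(
      name = cl,
      wavelengths_nm = .pf_grid,
      weights = unname(tab$weights[, cl]),
      d65_normalization = unname(tab$norms[[cl]])
    ),
    class = "action_spectrum"
  )
}

#' @export
print.action_spectrum <- function(x, ...) {
  cat("<action_spectrum> ", x$name,
      " | peak at ", x$wavelengths_nm[which.max(x$weights)], " nm",
      " | daylight normalization ", format(x$d65_normalization, digits = 6),
      " W m^-2 lx^-1\n", sep = "")
  invisible(x)
}

#' Embedded daylight reference spectrum
#'
#' The package's daylight normalization reference (a 6504 K Planckian
#' reconstruction standing in for CIE D65), scaled to a given photopic
#' illuminance. By construction, every alpha-opic EDI of this spectrum equals
#' its illuminance.
#'
#' @param illuminance_lx Target photopic illuminance in lux.
#' @return A [spectrum_regular] object.
#' @export
daylight_reference <- function(illuminance_lx = 100) {
  tab <- action_tables()
  base <- tab$d65
  illum <- .pf_km * sum(base * tab$weights[, "photopic"])
  new_spectrum_regular(base * (illuminance_lx / illum))
}
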