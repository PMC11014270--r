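#' Spectral axis
#'
#' A spectral axis is a strictly monotone sequence of wavelength (nm) or
#' wavenumber (cm-1) positions, tagged with the instrument it belongs to.
#' Values are stored ascending in their native unit.
#'
#' @param values Numeric vector of axis positions, strictly monotone,
#'   length >= 2. Descending input is reversed to ascending storage.
#' @param unit Either `"nm"` (wavelength) or `"cm-1"` (wavenumber).
#' @param instrument Instrument tag: `"FT-NIR"`, `"Micro-NIR"` or `"custom"`.
#'
#' @return An object of class `spectral_axis`: a list with elements
#'   `unit`, `values` (ascending) and `instrument`.
#' @export
#' @examples
#' ax <- spectral_axis(seq(908, 1676, length.out = 125), "nm", "Micro-NIR")
#' length(ax$values)
spectral_axis <- function(values, unit = c("nm", "cm-1"),
                          instrument = c("custom", "FT-NIR", "Micro-NIR")) {
  unit <- match.arg(unit)
  instrument <- match.arg(instrument)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("spectral axis needs at least 2 points", call. = FALSE)
  }
  d <- diff(values)
  if (all(d < 0)) values <- rev(values)
  else if (!all(d > 0)) {
    stop("spectral axis values must be strictly monotone", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("spectral axis values must be positive", call. = FALSE)
  }
  structure(list(unit = unit, values = values, instrument = instrument),
            class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %s, %d points, %.4g-%.4g %s\n",
              x$instrument, length(x$values), min(x$values), max(x$values),
              x$unit))
  invisible(x)
}

#' @export
length.spectral_axis <- function(x) length(x$values)

#' Convert between wavelength (nm) and wavenumber (cm-1)
#'
#' The two units are reciprocal: nu (cm-1) = 1e7 / lambda (nm). The
#' conversion is involutive and the identity when units agree.
#'
#' @param value Positive numeric value(s).
#' @param from_unit,to_unit `"nm"` or `"cm-1"`.
#' @return Converted value(s).
#' @export
#' @examples
#' convert_axis(5176, "cm-1", "nm")   # about 1932 nm
convert_axis <- function(value, from_unit, to_unit) {
  from_unit <- match.arg(from_unit, c("nm", "cm-1"))
  to_unit <- match.arg(to_unit, c("nm", "cm-1"))
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    stop("axis values must be positive and finite", call. = FALSE)
  }
  if (from_unit == to_unit) return(value)
  1e7 / value
}

# Width (sigma) conversion uses the local derivative |d lambda / d nu|
# = 1e7 / center^2, since the unit map is nonlinear.
convert_band_width <- function(width, center, from_unit, to_unit) {
  if (from_unit == to_unit) return(width)
  width * 1e7 / center^2
}

#' Build a canonical instrument grid
#'
#' The benchtop FT-NIR grid has exactly 1102 evenly spaced wavenumbers
#' covering 4000 to 12,500 cm-1 (spacing about 7.72 cm-1); the portable
#' Micro-NIR grid has exactly 125 evenly spaced wavelengths covering 908 to
#' 1676 nm (spacing about 6.19 nm, consistent with the instrument's nominal
#' 6.2 nm resolution). Both endpoints lie on the grid.
#'
#' @param instrument `"FT-NIR"` or `"Micro-NIR"`.
#' @return A [spectral_axis()].
#' @export
#' @examples
#' length(build_instrument_grid("Micro-NIR")$values)  # 125
build_instrument_grid <- function(instrument) {
  if (!is.character(instrument) || length(instrument) != 1L ||
      !instrument %in% c("FT-NIR", "Micro-NIR")) {
    stop("unknown instrument tag; expected \"FT-NIR\" or \"Micro-NIR\"",
         call. = FALSE)
  }
  if (instrument == "FT-NIR") {
    spectral_axis(seq(4000, 12500, length.out = 1102L), "cm-1", "FT-NIR")
  } else {
    spectral_axis(seq(908, 1676, length.out = 125L), "nm", "Micro-NIR")
  }
}

# Axis labels in both units, as reports always print both.
axis_both_units <- function(axis) {
  other_unit <- if (axis$unit == "nm") "cm-1" else "nm"
  other <- convert_axis(axis$values, axis$unit, other_unit)
  if (axis$unit == "nm") {
    data.frame(axis_nm = axis$values, axis_cm1 = other)
  } else {
    data.frame(axis_nm = other, axis_cm1 = axis$values)
  }
}
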