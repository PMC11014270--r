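#' Gaussian absorption band
#'
#' A pure-component NIR feature: a Gaussian in the stated unit with a
#' center, width (sigma) and peak amplitude (absorbance units).
#'
#' @param center Band center, in `unit`.
#' @param width Gaussian sigma, same unit, > 0.
#' @param amplitude Peak absorbance, >= 0.
#' @param unit `"nm"` or `"cm-1"`.
#' @param label Free-text band assignment (e.g. `"OH first overtone"`).
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(center, width, amplitude, unit = "nm", label = "") {
  unit <- match.arg(unit, c("nm", "cm-1"))
  if (!is.numeric(width) || width <= 0) stop("band width must be > 0",
                                             call. = FALSE)
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("band amplitude must be >= 0", call. = FALSE)
  }
  structure(list(center = center, width = width, amplitude = amplitude,
                 unit = unit, label = label), class = "band_spec")
}

#' Default pure-component band library
#'
#' Band centers follow the standard NIR assignments for the three
#' components: water OH combination near 1932 nm (5176 cm-1) and OH first
#' overtone near 1452 nm (6889 cm-1) dominating coconut milk, fat CH first
#' overtones at 1728/1764 nm and the CH second overtone near 1212 nm, starch
#' OH near 1540 nm and the glucose-related region near 1400 nm for the two
#' flour adulterants, plus a starch combination band near 2100 nm. Widths
#' and amplitudes are synthetic defaults (no reference pure-component
#' spectra exist for this study design) sized so that the water bands
#' dominate the milk spectrum; all are overridable.
#'
#' @return A list of class `component_library` mapping component names
#'   (`coconut_milk`, `corn_flour`, `tapioca_starch`) to lists of
#'   [band_spec()] objects.
#' @export
default_component_library <- function() {
  lib <- list(
    coconut_milk = list(
      band_spec(1932, 35, 1.00, "nm", "water OH combination"),
      band_spec(1452, 30, 0.65, "nm", "water OH first overtone"),
      band_spec(1728, 18, 0.28, "nm", "fat CH first overtone"),
      band_spec(1764, 18, 0.22, "nm", "fat CH first overtone"),
      band_spec(1212, 16, 0.18, "nm", "CH second overtone")),
    corn_flour = list(
      band_spec(1540, 28, 0.55, "nm", "starch OH first overtone"),
      band_spec(1400, 25, 0.35, "nm", "glucose region"),
      band_spec(1210, 16, 0.25, "nm", "CH second overtone"),
      band_spec(2100, 40, 0.45, "nm", "starch combination")),
    tapioca_starch = list(
      band_spec(1540, 30, 0.60, "nm", "starch OH first overtone"),
      band_spec(1400, 25, 0.40, "nm", "glucose region"),
      band_spec(1212, 16, 0.20, "nm", "CH second overtone"),
      band_spec(2100, 40, 0.40, "nm", "starch combination")))
  structure(lib, class = "component_library")
}

#' Rebuild a component library from plain configuration
#'
#' Inverse of the plain-list form used in YAML/JSON config files: a named
#' list of components, each a list of bands with fields `center`, `width`,
#' `amplitude`, and optionally `unit` and `label`.
#'
#' @param config Named list of components.
#' @return A `component_library`.
#' @export
component_library_from_config <- function(config) {
  lib <- lapply(config, function(bands) {
    lapply(bands, function(b) {
      band_spec(b$center, b$width, b$amplitude,
                unit = b$unit %||% "nm", label = b$label %||% "")
    })
  })
  class(lib) <- "component_library"
  validate_component_library(lib)
}

#' Plain-list form of a component library for serialization
#'
#' @param library A `component_library`.
#' @return A nested list suitable for [yaml::write_yaml()] or
#'   [jsonlite::write_json()].
#' @export
component_library_to_config <- function(library) {
  validate_component_library(library)
  lapply(library, function(bands) lapply(bands, unclass))
}

validate_component_library <- function(library) {
  stopifnot(is.list(library))
  need <- c("coconut_milk", "corn_flour", "tapioca_starch")
  if (!all(need %in% names(library))) {
    stop("component library must define ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(library)) {
    if (length(library[[nm]]) < 3L) {
      stop("component \"", nm, "\" needs at least 3 bands", call. = FALSE)
    }
  }
  invisible(library)
}

#' Noise model for simulated spectra
#'
#' Per-spectrum effects: multiplicative gain `g ~ U(multiplicative_range)`
#' and baseline offset `b0 ~ U(baseline_offset_range)` (shared across a
#' sample's replicate scans in [generate_design()]); per-scan i.i.d.
#' Gaussian point noise; and a moisture-equilibration attenuation `gamma`
#' applied to the milk component so that peak absorbance decreases as the
#' solid adulterant fraction rises.
#'
#' @param additive_sd SD of i.i.d. Gaussian point noise (absorbance units).
#' @param multiplicative_range Length-2 `(lo, hi)` of the per-spectrum gain.
#' @param baseline_offset_range Length-2 `(lo, hi)` of the baseline offset.
#' @param moisture_gamma Attenuation of the milk component, in \[0, 1).
#' @param scan_noise_sd Per-scan additive noise used by [generate_design()];
#'   defaults to `additive_sd`.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.003,
                        multiplicative_range = c(0.9, 1.1),
                        baseline_offset_range = c(-0.02, 0.02),
                        moisture_gamma = 0.3,
                        scan_noise_sd = additive_sd) {
  stopifnot(length(multiplicative_range) == 2L,
            multiplicative_range[1] <= multiplicative_range[2],
            length(baseline_offset_range) == 2L,
            baseline_offset_range[1] <= baseline_offset_range[2],
            additive_sd >= 0, scan_noise_sd >= 0,
            moisture_gamma >= 0, moisture_gamma < 1)
  structure(list(additive_sd = additive_sd,
                 multiplicative_range = multiplicative_range,
                 baseline_offset_range = baseline_offset_range,
                 moisture_gamma = moisture_gamma,
                 scan_noise_sd = scan_noise_sd),
            class = "noise_model")
}

# Noise-free limit, used by closed-form tests and expectation checks.
noise_free <- function(gamma = 0.3) {
  noise_model(additive_sd = 0, multiplicative_range = c(1, 1),
              baseline_offset_range = c(0, 0), moisture_gamma = gamma,
              scan_noise_sd = 0)
}

#' Study design specification
#'
#' Defaults reproduce the adulteration study design: 15 levels (1-10, 15,
#' 20, 30, 40, 50 percent w/w), 10 physical samples per level, 3 replicate
#' scans per sample, hence 450 spectra per instrument-adulterant dataset.
#'
#' @param levels Percent adulteration levels.
#' @param samples_per_level Physical samples prepared at each level.
#' @param scans_per_sample Replicate scans per sample.
#' @param instrument `"FT-NIR"` or `"Micro-NIR"`.
#' @param adulterant `"corn_flour"` or `"tapioca_starch"`.
#' @param seed Integer master seed.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(levels = c(1:10, 15, 20, 30, 40, 50),
                        samples_per_level = 10L,
                        scans_per_sample = 3L,
                        instrument = c("Micro-NIR", "FT-NIR"),
                        adulterant = c("corn_flour", "tapioca_starch"),
                        seed = 42L) {
  instrument <- match.arg(instrument)
  adulterant <- match.arg(adulterant)
  stopifnot(length(levels) >= 1L, all(levels >= 0), all(levels <= 100),
            samples_per_level >= 1L, scans_per_sample >= 1L)
  structure(list(levels = as.numeric(levels),
                 samples_per_level = as.integer(samples_per_level),
                 scans_per_sample = as.integer(scans_per_sample),
                 instrument = instrument,
                 adulterant = adulterant,
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Evaluate a pure-component spectrum on an axis
#'
#' Pointwise sum of the component's Gaussian bands, with band centers and
#' widths converted to the axis unit as needed.
#'
#' @param bands List of [band_spec()] objects.
#' @param axis A [spectral_axis()].
#' @return Non-negative absorbance vector of the axis length.
#' @export
component_spectrum <- function(bands, axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (length(bands) == 0L) stop("empty band list", call. = FALSE)
  v <- axis$values
  out <- numeric(length(v))
  for (b in bands) {
    ctr <- convert_axis(b$center, b$unit, axis$unit)
    wid <- convert_band_width(b$width, b$center, b$unit, axis$unit)
    out <- out + b$amplitude * exp(-(v - ctr)^2 / (2 * wid^2))
  }
  out
}

# Deterministic (noise-free, unit-gain) mixture expectation:
#   A(lambda) = (1 - c) * (1 - gamma * c) * A_milk + c * A_adulterant
mixture_expectation <- function(c_frac, library, axis,
                                adulterant = "corn_flour", gamma = 0.3) {
  a_milk <- component_spectrum(library$coconut_milk, axis)
  a_adu <- component_spectrum(library[[adulterant]], axis)
  (1 - c_frac) * (1 - gamma * c_frac) * a_milk + c_frac * a_adu
}

#' Simulate one mixture spectrum
#'
#' Draws the per-spectrum gain and baseline offset and the per-point
#' Gaussian noise from the current RNG stream (or uses supplied values) and
#' returns
#' `g * [(1-c) * (1 - gamma*c) * A_milk + c * A_adulterant] + b0 + eps`.
#' The moisture attenuation `gamma` makes milk-band peak absorbance
#' decrease monotonically as the solid adulterant fraction rises.
#'
#' @param c_frac Adulterant mass fraction in \[0, 1\].
#' @param library A component library (see [default_component_library()]).
#' @param noise A [noise_model()].
#' @param axis A [spectral_axis()].
#' @param adulterant `"corn_flour"` or `"tapioca_starch"`.
#' @param gain,offset Optional fixed per-spectrum effects; when `NULL` they
#'   are drawn from `noise`.
#' @param eps_sd SD of the additive point noise; defaults to
#'   `noise$additive_sd`.
#' @return Absorbance vector of the axis length.
#' @export
simulate_mixture <- function(c_frac, library, noise, axis,
                             adulterant = "corn_flour",
                             gain = NULL, offset = NULL, eps_sd = NULL) {
  if (!is.numeric(c_frac) || c_frac < 0 || c_frac > 1) {
    stop("adulterant fraction must lie in [0, 1]", call. = FALSE)
  }
  validate_component_library(library)
  mu <- mixture_expectation(c_frac, library, axis, adulterant,
                            noise$moisture_gamma)
  if (is.null(gain)) {
    gain <- stats::runif(1, noise$multiplicative_range[1],
                         noise$multiplicative_range[2])
  }
  if (is.null(offset)) {
    offset <- stats::runif(1, noise$baseline_offset_range[1],
                           noise$baseline_offset_range[2])
  }
  if (is.null(eps_sd)) eps_sd <- noise$additive_sd
  eps <- if (eps_sd > 0) stats::rnorm(length(mu), 0, eps_sd) else 0
  gain * mu + offset + eps
}

# Deterministic 32-bit stream seed from the master seed and dataset labels,
# so each (instrument, adulterant) dataset is independently reproducible.
derive_stream_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (s in c(...)) {
    for (code in utf8ToInt(as.character(s))) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h)
}

#' Generate a full design of simulated spectra
#'
#' Produces `length(levels) * samples_per_level * scans_per_sample` spectra
#' (450 under the default design). Gain and baseline offset are drawn once
#' per physical sample and shared across its replicate scans; point noise is
#' independent per scan. Fully deterministic given the design seed.
#'
#' @param spec A [design_spec()].
#' @param library Component library (default [default_component_library()]).
#' @param noise A [noise_model()] (default `noise_model()`).
#' @return A [spectral_dataset()] whose metadata records the adulterant,
#'   generator seed and design.
#' @export
#' @examples
#' ds <- generate_design(design_spec(instrument = "Micro-NIR"))
#' dim(ds)   # 450 x 125
generate_design <- function(spec, library = default_component_library(),
                            noise = noise_model()) {
  stopifnot(inherits(spec, "design_spec"))
  validate_component_library(library)
  axis <- build_instrument_grid(spec$instrument)
  n <- length(spec$levels) * spec$samples_per_level * spec$scans_per_sample
  m <- length(axis$values)
  absorb <- matrix(NA_real_, n, m)
  sample_id <- character(n)
  scan <- integer(n)
  level <- numeric(n)
  stream <- derive_stream_seed(spec$seed, spec$instrument, spec$adulterant)
  withr::with_seed(stream, {
    row <- 0L
    for (li in seq_along(spec$levels)) {
      lv <- spec$levels[li]
      for (si in seq_len(spec$samples_per_level)) {
        g <- stats::runif(1, noise$multiplicative_range[1],
                          noise$multiplicative_range[2])
        b0 <- stats::runif(1, noise$baseline_offset_range[1],
                           noise$baseline_offset_range[2])
        sid <- sprintf("%s_L%04.1f_S%02d", spec$adulterant, lv, si)
        for (sc in seq_len(spec$scans_per_sample)) {
          row <- row + 1L
          absorb[row, ] <- simulate_mixture(
            lv / 100, library, noise, axis,
            adulterant = spec$adulterant, gain = g, offset = b0,
            eps_sd = noise$scan_noise_sd)
          sample_id[row] <- sid
          scan[row] <- sc
          level[row] <- lv
        }
      }
    }
  })
  spectral_dataset(axis, absorb, sample_id, scan, level,
                   metadata = list(instrument = spec$instrument,
                                   adulterant = spec$adulterant,
                                   seed = spec$seed,
                                   stream_seed = stream,
                                   levels = spec$levels,
                                   samples_per_level = spec$samples_per_level,
                                   scans_per_sample = spec$scans_per_sample))
}

#' Generate the full two-instrument, two-adulterant study
#'
#' Four datasets of 450 spectra each (1800 spectra in total): FT-NIR and
#' Micro-NIR, each with corn flour and tapioca starch adulteration.
#'
#' @param seed Integer master seed; per-dataset streams are derived from it.
#' @param library,noise Passed to [generate_design()].
#' @return Named list of four [spectral_dataset()] objects, names
#'   `"<instrument>.<adulterant>"`.
#' @export
generate_full_study <- function(seed = 42L,
                                library = default_component_library(),
                                noise = noise_model()) {
  out <- list()
  for (ins in c("FT-NIR", "Micro-NIR")) {
    for (adu in c("corn_flour", "tapioca_starch")) {
      sp <- design_spec(instrument = ins, adulterant = adu, seed = seed)
      out[[paste(ins, adu, sep = ".")]] <- generate_design(sp, library, noise)
    }
  }
  out
}
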