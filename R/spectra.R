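# Energy-imparted frequency spectra for the cylindrical target volume.

EV_TO_J <- 1.602176634e-19

#' Cylindrical target-site descriptor
#'
#' The default is a right cylinder 5 nm in diameter and 5 nm high of
#' unit-density material, the nucleosome-scale volume spanning ~73 bp; its
#' mass (~9.8e-23 kg) converts energy imparted to specific energy.
#'
#' @param diameter_nm,height_nm Site dimensions in nm.
#' @param density_kg_m3 Material density.
#' @return A list with the dimensions and `mass_kg`.
#' @export
site_cylinder <- function(diameter_nm = 5, height_nm = 5, density_kg_m3 = 1000) {
  stopifnot(diameter_nm > 0, height_nm > 0, density_kg_m3 > 0)
  vol_m3 <- pi * (diameter_nm / 2)^2 * height_nm * 1e-27
  list(diameter_nm = diameter_nm, height_nm = height_nm,
       density_kg_m3 = density_kg_m3, mass_kg = vol_m3 * density_kg_m3)
}

#' Construct an energy-imparted spectrum
#'
#' A spectrum is the per-event frequency distribution dF/de of energy
#' imparted e to the target site, stored as a tibble (`energy_ev`, `density`)
#' normalized so the trapezoid integral of the density is 1, with radiation
#' metadata attached.
#'
#' @param energy_ev Strictly increasing energies (eV, >= 0).
#' @param density Non-negative densities (per eV); renormalized to unit
#'   integral.
#' @param label Radiation label.
#' @param let_kev_um Linear energy transfer in keV/um (optional).
#' @param z_f_gy Frequency-mean specific energy in Gy (optional; computed
#'   from the site mass when absent).
#' @param site A [site_cylinder()] descriptor.
#' @return A tibble of class `energy_spectrum`.
#' @examples
#' s <- energy_spectrum(seq(0, 500, 5), dexp(seq(0, 500, 5), 1 / 40))
#' @export
energy_spectrum <- function(energy_ev, density, label = "unlabelled",
                            let_kev_um = NA_real_, z_f_gy = NA_real_,
                            site = site_cylinder()) {
  if (!is.numeric(energy_ev) || !is.numeric(density) ||
      length(energy_ev) != length(density) || length(energy_ev) < 2L) {
    stop("`energy_ev` and `density` must be numeric vectors of equal length >= 2",
         call. = FALSE)
  }
  if (anyNA(energy_ev) || any(energy_ev < 0) ||
      any(diff(energy_ev) <= 0)) {
    stop("`energy_ev` must be non-negative and strictly increasing", call. = FALSE)
  }
  if (anyNA(density) || any(density < 0)) {
    stop("`density` must be non-negative", call. = FALSE)
  }
  z <- pracma::trapz(energy_ev, density)
  if (z <= 0) stop("spectrum has zero integral", call. = FALSE)
  out <- tibble::tibble(energy_ev = as.numeric(energy_ev),
                        density = as.numeric(density) / z)
  class(out) <- c("energy_spectrum", class(out))
  attr(out, "meta") <- list(label = label, let_kev_um = let_kev_um,
                            z_f_gy = z_f_gy, site = site)
  out
}

spectrum_meta <- function(spec) attr(spec, "meta")

#' @export
print.energy_spectrum <- function(x, ...) {
  m <- spectrum_meta(x)
  cat("<energy_spectrum> ", m$label,
      " | LET =", m$let_kev_um, "keV/um",
      " | grid", nrow(x), "points to", max(x$energy_ev), "eV\n")
  NextMethod()
}

#' Exponential energy-imparted spectrum
#'
#' A spectrum whose integral (complementary cumulative) form is
#' `F(>e) = exp(-e / epsilon0)`, hence density `exp(-e/epsilon0)/epsilon0`,
#' truncated at `grid_max` and renormalized. This is the parametric form used
#' to represent electron spectra.
#'
#' @param epsilon0 Mean energy imparted per event (eV, > 0).
#' @param grid_max Upper grid limit in eV.
#' @param n_points Grid points.
#' @inheritParams energy_spectrum
#' @return An `energy_spectrum`.
#' @examples
#' exponential_spectrum(40)
#' @export
exponential_spectrum <- function(epsilon0, grid_max = 25 * epsilon0,
                                 n_points = 400L, label = "exponential",
                                 let_kev_um = NA_real_, site = site_cylinder()) {
  if (!is.numeric(epsilon0) || length(epsilon0) != 1L || epsilon0 <= 0) {
    stop("`epsilon0` must be a single positive number", call. = FALSE)
  }
  grid <- seq(0, grid_max, length.out = n_points)
  energy_spectrum(grid, stats::dexp(grid, rate = 1 / epsilon0),
                  label = label, let_kev_um = let_kev_um, site = site)
}

#' Frequency-mean specific energy of a spectrum
#'
#' `z_F = <e> / m`: the mean energy imparted per event, converted from eV to
#' joules, divided by the site mass.
#'
#' @param spec An `energy_spectrum`.
#' @param site_mass_kg Site mass; defaults to the spectrum's site metadata.
#' @return Specific energy in Gy.
#' @export
mean_specific_energy <- function(spec, site_mass_kg = NULL) {
  stopifnot(inherits(spec, "energy_spectrum"))
  if (is.null(site_mass_kg)) site_mass_kg <- spectrum_meta(spec)$site$mass_kg
  if (!is.numeric(site_mass_kg) || length(site_mass_kg) != 1L || site_mass_kg <= 0) {
    stop("`site_mass_kg` must be a single positive number", call. = FALSE)
  }
  mean_ev <- pracma::trapz(spec$energy_ev, spec$energy_ev * spec$density)
  mean_ev * EV_TO_J / site_mass_kg
}

#' Mix energy spectra
#'
#' Pointwise weighted mixture on the union grid (linear interpolation, zero
#' outside each component's support), renormalized.
#'
#' @param specs List of `energy_spectrum` objects.
#' @param weights Non-negative weights summing to 1.
#' @param label Label for the mixture.
#' @return An `energy_spectrum`; its LET metadata is the weighted mean when
#'   all components carry one.
#' @export
mix_spectra <- function(specs, weights, label = "mixture") {
  if (!is.list(specs) || !all(vapply(specs, inherits, logical(1), "energy_spectrum"))) {
    stop("`specs` must be a list of energy_spectrum objects", call. = FALSE)
  }
  if (length(weights) != length(specs) || any(weights < 0)) {
    stop("`weights` must be non-negative, one per spectrum", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  grid <- sort(unique(unlist(lapply(specs, function(s) s$energy_ev))))
  dens <- rep(0, length(grid))
  for (i in seq_along(specs)) {
    if (weights[i] == 0) next
    di <- stats::approx(specs[[i]]$energy_ev, specs[[i]]$density, xout = grid,
                        yleft = 0, yright = 0)$y
    dens <- dens + weights[i] * di
  }
  lets <- vapply(specs, function(s) spectrum_meta(s)$let_kev_um, numeric(1))
  let <- if (anyNA(lets)) NA_real_ else sum(weights * lets)
  energy_spectrum(grid, dens, label = label, let_kev_um = let,
                  site = spectrum_meta(specs[[1]])$site)
}

#' Read an energy spectrum from a delimited text file
#'
#' Expects `#`-prefixed `key: value` header lines (label, let_kev_um,
#' diameter_nm, height_nm, mass_kg are recognized) followed by two whitespace-
#' or comma-separated columns: energy (eV) and density (per eV). A density
#' whose integral deviates from 1 by less than 1% is silently renormalized;
#' larger deviations, non-monotone grids and negative densities are format
#' errors naming the offending line.
#'
#' @param path File path.
#' @return An `energy_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*\\S)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  data_idx <- which(!is_comment & !is_blank)
  if (length(data_idx) < 2) stop("spectrum file has fewer than 2 data lines: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[data_idx]), "[[:space:],]+")
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad)) {
    stop("line ", data_idx[bad[1]], " of ", path, " does not have two columns", call. = FALSE)
  }
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 1)))
  d <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  bad <- which(is.na(e) | is.na(d))
  if (length(bad)) {
    stop("line ", data_idx[bad[1]], " of ", path, " is not numeric", call. = FALSE)
  }
  bad <- which(diff(e) <= 0)
  if (length(bad)) {
    stop("non-monotone energy grid at line ", data_idx[bad[1] + 1L], " of ", path, call. = FALSE)
  }
  bad <- which(d < 0)
  if (length(bad)) {
    stop("negative density at line ", data_idx[bad[1]], " of ", path, call. = FALSE)
  }
  z <- pracma::trapz(e, d)
  if (abs(z - 1) >= 0.01) {
    stop("spectrum integral is ", format(z, digits = 6),
         "; expected 1 within 1% (", path, ")", call. = FALSE)
  }
  num_or_na <- function(key) {
    if (is.null(meta[[key]])) NA_real_ else suppressWarnings(as.numeric(meta[[key]]))
  }
  site <- site_cylinder()
  if (!is.na(num_or_na("diameter_nm")) && !is.na(num_or_na("height_nm"))) {
    site <- site_cylinder(num_or_na("diameter_nm"), num_or_na("height_nm"))
  }
  if (!is.na(num_or_na("mass_kg"))) site$mass_kg <- num_or_na("mass_kg")
  energy_spectrum(e, d, label = meta$label %||% basename(path),
                  let_kev_um = num_or_na("let_kev_um"),
                  z_f_gy = num_or_na("z_f_gy"), site = site)
}

#' Write an energy spectrum to a delimited text file
#'
#' Full-precision round-trip counterpart of [read_spectrum()].
#'
#' @param spec An `energy_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "energy_spectrum"))
  m <- spectrum_meta(spec)
  hdr <- c(
    paste0("# label: ", m$label),
    if (!is.na(m$let_kev_um)) paste0("# let_kev_um: ", format(m$let_kev_um, digits = 17)),
    if (!is.na(m$z_f_gy)) paste0("# z_f_gy: ", format(m$z_f_gy, digits = 17)),
    paste0("# diameter_nm: ", format(m$site$diameter_nm, digits = 17)),
    paste0("# height_nm: ", format(m$site$height_nm, digits = 17)),
    paste0("# mass_kg: ", format(m$site$mass_kg, digits = 17)),
    "# columns: energy_ev density_per_ev"
  )
  body <- paste(format(spec$energy_ev, digits = 17, trim = TRUE, scientific = FALSE),
                format(spec$density, digits = 17, trim = TRUE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Synthetic fixture spectra labelled by radiation quality
#'
#' Exponential spectra with mean energies chosen to imitate the qualitative
#' hardness ordering of different radiation qualities at the nanometre scale
#' (soft for low-LET electrons and relativistic carbon, hard for slow helium
#' and carbon ions). These are synthetic stand-ins for track-structure
#' spectra, intended for tests and demonstrations, not fits to measured
#' distributions.
#'
#' @param dir Optional directory; when given, each spectrum is also written
#'   as `synthetic-<name>.txt` via [write_spectrum()].
#' @return Named list of `energy_spectrum` objects.
#' @export
fixture_spectra <- function(dir = NULL) {
  presets <- list(
    electron_100keV = list(eps0 = 40, let = 0.4),
    he_1MeV_u = list(eps0 = 150, let = 104),
    c_10MeV_u = list(eps0 = 180, let = 163),
    c_1000MeV_u = list(eps0 = 55, let = 8)
  )
  out <- purrr::imap(presets, function(p, nm) {
    exponential_spectrum(p$eps0, label = paste0("synthetic-", nm),
                         let_kev_um = p$let)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    purrr::iwalk(out, function(s, nm) {
      write_spectrum(s, file.path(dir, paste0("synthetic-", nm, ".txt")))
    })
  }
  out
}
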