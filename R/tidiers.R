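# broom-style tidiers.

#' @rdname damage_model
#' @param x A `damage_model`.
#' @param ... Unused.
#' @export
tidy.damage_model <- function(x, ...) {
  prov <- model_provenance(x)
  tibble::tibble(
    component = c(rep("events", 4), rep("fates", 3),
                  rep("geometry", length(prov$q0) + 2),
                  rep("threshold", 4)),
    parameter = c(names(prov$p), names(prov$r),
                  "n_bp", "window_bp",
                  paste0("q0_", names(prov$q0)),
                  names(prov$threshold)),
    value = c(prov$p, prov$r, prov$n_bp, prov$window_bp, prov$q0,
              prov$threshold)
  )
}

#' @rdname damage_model
#' @export
glance.damage_model <- function(x, ...) {
  tibble::tibble(mode = x$mode, j_cap = x$j_cap,
                 n_bp = x$geometry$n_bp, window_bp = x$geometry$window_bp,
                 q0_constant = x$geometry$q0_constant %||% NA_real_,
                 threshold_mean_ev = x$thresholds$mean_ev,
                 threshold_sd_ev = x$thresholds$sd_ev)
}

#' @rdname yield_per_gy
#' @param x A `yield_table`.
#' @param ... Unused.
#' @export
tidy.yield_table <- function(x, ...) {
  tibble::tibble(category = x$category, value = x$value,
                 units = attr(x, "units"))
}

#' @rdname yield_per_gy
#' @export
glance.yield_table <- function(x, ...) {
  v <- stats::setNames(x$value, x$category)
  prov <- attr(x, "provenance")
  tibble::tibble(units = attr(x, "units"),
                 total_ssb = v[["total_ssb"]], total_dsb = v[["total_dsb"]],
                 total_bd = v[["total_bd"]],
                 spectrum = prov$spectrum %||% NA_character_,
                 grouping = prov$grouping %||% NA_character_)
}

#' @rdname energy_spectrum
#' @param x An `energy_spectrum`.
#' @param ... Unused.
#' @export
glance.energy_spectrum <- function(x, ...) {
  m <- spectrum_meta(x)
  tibble::tibble(label = m$label, let_kev_um = m$let_kev_um,
                 mean_energy_ev = pracma::trapz(x$energy_ev, x$energy_ev * x$density),
                 z_f_gy = if (!is.null(m$z_f_gy) && !is.na(m$z_f_gy)) m$z_f_gy
                          else mean_specific_energy(x),
                 n_grid = nrow(x), grid_max_ev = max(x$energy_ev))
}

#' @rdname resolve_composition
#' @param x A `lesion_spectrum`.
#' @param ... Unused.
#' @export
tidy.lesion_spectrum <- function(x, ...) {
  fold_lesion_spectrum(x)
}
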