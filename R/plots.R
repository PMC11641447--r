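# ggplot2 convenience plots for the result types.

#' @rdname energy_spectrum
#' @param object An `energy_spectrum`.
#' @param log_y Plot the density on a log scale.
#' @export
autoplot.energy_spectrum <- function(object, log_y = TRUE, ...) {
  m <- spectrum_meta(object)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$energy_ev, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "energy imparted (eV)", y = "dF/dε (per eV)",
                  title = m$label) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot per-J lesion-class probabilities
#'
#' Line plot of the occurrence probabilities of each lesion class versus the
#' number of damage-capable events, faceted by lesion family.
#'
#' @param table Output of [damage_probability_table()].
#' @return A ggplot object.
#' @export
plot_damage_probabilities <- function(table) {
  cols <- c(p_ssb_s = "SSB", p_ssb_s2 = "SSB(S2)", p_ssb_plus = "SSB+",
            p_ssb_pp = "SSB++", p_dsb_s = "DSB", p_dsb_plus = "DSB+",
            p_dsb_pp = "DSB++", p_bd_1 = "BD(1)", p_bd_2 = "BD(2)",
            p_bd_3 = "BD(3)", p_bd_gt3 = "BD(>3)")
  long <- table |>
    dplyr::select("j_tot", dplyr::all_of(names(cols))) |>
    tidyr::pivot_longer(-"j_tot", names_to = "class", values_to = "probability") |>
    dplyr::mutate(
      family = dplyr::case_when(
        startsWith(.data$class, "p_ssb") ~ "SSB",
        startsWith(.data$class, "p_dsb") ~ "DSB",
        TRUE ~ "BD"),
      class = factor(cols[.data$class], levels = unname(cols)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$j_tot, y = .data$probability,
                                     colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = expression(J[TOT]), y = "probability") +
    ggplot2::theme_minimal()
}

#' @rdname yield_per_gy
#' @param object A `yield_table`.
#' @param ... Unused.
#' @export
autoplot.yield_table <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  tb$category <- factor(tb$category, levels = .yield_categories)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$category, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = attr(object, "units"), x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an LET scan of DSB cross-sections
#'
#' @param scan Output of [let_scan()].
#' @param categories Categories to show.
#' @return A ggplot object.
#' @export
plot_let_scan <- function(scan, categories = c("dsb_s", "dsb_plus", "dsb_pp",
                                               "total_dsb")) {
  dat <- dplyr::filter(scan, .data$category %in% categories)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$let_kev_um, y = .data$sigma,
                                    colour = .data$category,
                                    linetype = .data$variant)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "LET (keV/μm)", y = "σ (per Gbp per particle)") +
    ggplot2::theme_minimal()
}
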