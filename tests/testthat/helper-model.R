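# Shared builders for the test suite.

default_model <- function(...) damage_model(...)

# constant-q0 geometry: reproduces the closed-form operator expansions
symbolic_geom <- function(q0 = 0.6) cluster_geometry(q0_constant = q0)

symbolic_model <- function(q0 = 0.6, ...) {
  damage_model(geometry = symbolic_geom(q0), ...)
}

# probability of a single lesion state in a spectrum (folded over bookkeeping)
state_prob <- function(spectrum, ..., bd = 0) {
  want <- list(...)
  tb <- fold_lesion_spectrum(spectrum)
  sel <- rep(TRUE, nrow(tb))
  for (cl in c("ssb_s", "ssb_plus", "ssb_pp", "dsb_s", "dsb_plus", "dsb_pp")) {
    sel <- sel & tb[[cl]] == (want[[cl]] %||% 0)
  }
  sel <- sel & tb$bd == bd
  sum(tb$prob[sel])
}

# as state_prob but without folding ssb_ppp into ssb_pp
state_prob_raw <- function(spectrum, ..., bd = 0) {
  want <- list(...)
  tb <- dplyr::group_by(tibble::as_tibble(spectrum),
                        dplyr::across(dplyr::all_of(
                          c("ssb_s", "ssb_plus", "ssb_pp", "ssb_ppp",
                            "dsb_s", "dsb_plus", "dsb_pp", "bd"))))
  tb <- dplyr::summarise(tb, prob = sum(prob), .groups = "drop")
  sel <- rep(TRUE, nrow(tb))
  for (cl in c("ssb_s", "ssb_plus", "ssb_pp", "ssb_ppp",
               "dsb_s", "dsb_plus", "dsb_pp")) {
    sel <- sel & tb[[cl]] == (want[[cl]] %||% 0)
  }
  sel <- sel & tb$bd == bd
  sum(tb$prob[sel])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# spectrum fixture entirely below the threshold support
below_threshold_spectrum <- function() {
  energy_spectrum(seq(0.1, 5, length.out = 50),
                  rep(1, 50), label = "below-threshold")
}
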