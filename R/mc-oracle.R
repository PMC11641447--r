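# Monte-Carlo oracle: break placement and geometric lesion classification.

.sim_conventions <- c("q-ladder", "uniform-bp", "site-resolved", "table-calibrated")

with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Classify a set of strand breaks into lesions
#'
#' Lesions are the connected components of the graph linking breaks whose
#' positions differ by at most `window_bp`. A component is DSB-class if it
#' contains at least one opposite-strand pair within the window, otherwise
#' SSB-class. Complexity follows the break count: DSB-class components with
#' 2 / 3 / >= 4 breaks are DSB(S) / DSB(+) / DSB(++); SSB-class components
#' with 1 / 2 / 3 / >= 4 breaks are isolated SSB / SSB(+) / SSB(++) /
#' SSB(+++). Duplicate (position, strand) pairs collapse to a single break.
#'
#' @param breaks A data frame with columns `position` (numeric) and `strand`
#'   (two labels, e.g. `"W"`/`"C"` or 0/1).
#' @param window_bp Clustering window in base pairs (>= 0).
#' @param bd_count Base damages carried through unchanged.
#' @return A one-row tibble with the lesion-class counts and `bd`.
#' @examples
#' classify_breaks(data.frame(position = c(10, 14), strand = c("W", "C")), 10)
#' @export
classify_breaks <- function(breaks, window_bp, bd_count = 0) {
  stopifnot(is.data.frame(breaks), window_bp >= 0)
  out <- stats::setNames(as.list(rep(0, 8)), c(.les_cols, "bd"))
  out$bd <- bd_count
  if (nrow(breaks) > 0) {
    keep <- !duplicated(breaks[, c("position", "strand")])
    pos <- as.numeric(breaks$position[keep])
    strand <- as.character(breaks$strand[keep])
    n <- length(pos)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    if (n > 1) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          if (abs(pos[i] - pos[j]) <= window_bp) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cid in unique(comp)) {
      idx <- which(comp == cid)
      s <- length(idx)
      is_dsb <- FALSE
      if (s > 1) {
        for (i in idx) {
          for (j in idx) {
            if (strand[i] != strand[j] && abs(pos[i] - pos[j]) <= window_bp) {
              is_dsb <- TRUE
            }
          }
        }
      }
      cl <- if (is_dsb) {
        if (s <= 2) "dsb_s" else if (s == 3) "dsb_plus" else "dsb_pp"
      } else {
        if (s == 1) "ssb_s" else if (s == 2) "ssb_plus"
        else if (s == 3) "ssb_pp" else "ssb_ppp"
      }
      out[[cl]] <- out[[cl]] + 1
    }
  }
  tibble::as_tibble(out)
}

#' Window calibrated so the first clustering probability matches a target
#'
#' For uniform integer placement on the segment, computes the exact
#' probability that a second break misses the window of the first for every
#' integer window, and returns the window whose probability is closest to
#' `q0_target` (default: the head of the printed ladder).
#'
#' @param geom A [cluster_geometry()].
#' @param q0_target Target no-cluster probability for J = 2.
#' @return A single integer window (bp).
#' @export
calibrated_window <- function(geom, q0_target = 0.87) {
  stopifnot(inherits(geom, "cluster_geometry"))
  n <- geom$n_bp
  q0_exact <- function(w) {
    near <- vapply(seq_len(n), function(p) min(p + w, n) - max(p - w, 1) + 1,
                   numeric(1))
    1 - sum(near) / n^2
  }
  ws <- 0:(n - 1)
  vals <- vapply(ws, q0_exact, numeric(1))
  ws[which.min(abs(vals - q0_target))]
}

#' Monte-Carlo simulation of an event composition
#'
#' Brute-force counterpart of [resolve_composition()]: per trial, each A event
#' places one strand break, each B event draws a radical fate (break with
#' `r1`, base damage with `r2`, nothing otherwise) and each C event adds one
#' base damage; breaks are placed under the chosen convention and the
#' resulting pattern is classified geometrically (see [classify_breaks()]).
#'
#' Conventions: `"q-ladder"` realizes the model's clustering ladder in
#' position space (new lesions far apart, attachment to a uniformly chosen
#' existing lesion, fair-coin strand) and is the convention matched to the
#' operator algebra; `"uniform-bp"` and `"site-resolved"` place breaks
#' uniformly on the segment (re-hits of an occupied site collapse);
#' `"table-calibrated"` is uniform placement with the window recalibrated via
#' [calibrated_window()].
#'
#' @param composition `c(j_a, j_b, j_c, j_d)`.
#' @param geom A [cluster_geometry()].
#' @param fates A [radical_fates()].
#' @param convention One of `"q-ladder"`, `"uniform-bp"`, `"site-resolved"`,
#'   `"table-calibrated"`.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; fixed seed gives bit-identical spectra.
#' @return A tibble of lesion states with `count`, empirical `freq` and
#'   binomial `se`; attributes `n_trials`, `seed`, `convention`.
#' @examples
#' simulate_composition(c(2, 0, 0, 0), cluster_geometry(), radical_fates(),
#'                      n_trials = 1000, seed = 1)
#' @export
simulate_composition <- function(composition, geom, fates,
                                 convention = "q-ladder",
                                 n_trials = 100000L, seed = NULL) {
  if (length(convention) != 1L || !convention %in% .sim_conventions) {
    stop("unknown placement convention: ", paste(convention, collapse = ", "),
         " (use one of ", paste(.sim_conventions, collapse = ", "), ")",
         call. = FALSE)
  }
  stopifnot(inherits(geom, "cluster_geometry"), inherits(fates, "radical_fates"))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  if (is.data.frame(composition)) {
    composition <- as.numeric(composition[1, c("j_a", "j_b", "j_c", "j_d")])
  }
  j <- as.integer(composition)
  if (any(is.na(j[1:3])) || any(j < 0, na.rm = TRUE)) {
    stop("`composition` must be non-negative integer counts", call. = FALSE)
  }
  window <- geom$window_bp
  conv_id <- switch(convention,
                    "uniform-bp" = 0L, "site-resolved" = 1L, "q-ladder" = 2L,
                    "table-calibrated" = 0L)
  if (convention == "table-calibrated") window <- calibrated_window(geom)
  q0k <- q0_of(geom, seq_len(j[1] + j[2] + 1L))
  raw <- with_seed_local(seed,
    .sim_composition_cpp(j[1], j[2], j[3], n_trials, conv_id, geom$n_bp,
                         window, q0k, fates$r1, fates$r2))
  out <- tibble::as_tibble(raw)
  out$freq <- out$count / n_trials
  out$se <- sqrt(out$freq * (1 - out$freq) / n_trials)
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(c(.les_cols, "bd"))))
  attr(out, "n_trials") <- n_trials
  attr(out, "seed") <- seed
  attr(out, "convention") <- convention
  out
}

#' Monte-Carlo estimate of the no-cluster probability q0(J)
#'
#' Places `j - 1` breaks uniformly on the segment and estimates the
#' probability that the `j`-th break lands farther than the window from all
#' of them.
#'
#' @param j Break index (>= 2); vectorized.
#' @param geom A [cluster_geometry()].
#' @param convention `"uniform-bp"`, `"site-resolved"` (equivalent placement
#'   distributions) or `"table-calibrated"` (recalibrated window).
#' @param n_trials Trials per `j`.
#' @param seed Integer seed.
#' @return A tibble with columns `j`, `q0_hat`, `se`, `n_trials`.
#' @examples
#' estimate_q0(2, cluster_geometry(), n_trials = 10000, seed = 1)
#' @export
estimate_q0 <- function(j, geom, convention = "uniform-bp",
                        n_trials = 100000L, seed = NULL) {
  if (length(convention) != 1L ||
      !convention %in% c("uniform-bp", "site-resolved", "table-calibrated")) {
    stop("unknown placement convention for q0 estimation: ", convention,
         call. = FALSE)
  }
  stopifnot(inherits(geom, "cluster_geometry"))
  j <- as.integer(j)
  if (anyNA(j) || any(j < 2L)) stop("`j` must be integers >= 2", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  window <- if (convention == "table-calibrated") calibrated_window(geom) else geom$window_bp
  q0_hat <- with_seed_local(seed, {
    vapply(j, function(ji) .estimate_q0_cpp(ji, n_trials, geom$n_bp, window),
           numeric(1))
  })
  tibble::tibble(j = j, q0_hat = q0_hat,
                 se = sqrt(q0_hat * (1 - q0_hat) / n_trials),
                 n_trials = n_trials)
}

#' Compare the operator algebra with the Monte-Carlo oracle
#'
#' Resolves a composition deterministically and simulates it under a matched
#' convention, then joins the two lesion-state distributions and flags
#' categories differing by more than `3 se`.
#'
#' @param composition `c(j_a, j_b, j_c, j_d)`.
#' @param model A [damage_model()].
#' @param convention Placement convention for [simulate_composition()].
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @return A tibble with state columns, algebra `prob`, empirical `freq`,
#'   `se` (binomial, from the algebra probability), and logical `flagged`.
#' @export
oracle_comparison <- function(composition, model, convention = "q-ladder",
                              n_trials = 100000L, seed = NULL) {
  stopifnot(inherits(model, "damage_model"))
  alg <- resolve_composition(model, composition) |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(.les_cols, "bd")))) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
  sim <- simulate_composition(composition, model$geometry, model$fates,
                              convention = convention, n_trials = n_trials,
                              seed = seed) |>
    dplyr::select(dplyr::all_of(c(.les_cols, "bd")), "freq")
  dplyr::full_join(alg, sim, by = c(.les_cols, "bd")) |>
    tidyr::replace_na(list(prob = 0, freq = 0)) |>
    dplyr::mutate(
      se = sqrt(.data$prob * (1 - .data$prob) / n_trials),
      flagged = abs(.data$freq - .data$prob) > 3 * .data$se + 1e-12
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(.les_cols, "bd"))))
}
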