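#' Number of damage-capable events for a given energy imparted
#'
#' The energy imparted `epsilon` supports `floor(epsilon / epsilon_th)`
#' elemental damage events; below the threshold no event occurs.
#'
#' @param epsilon Energy imparted in eV (vectorized, >= 0).
#' @param epsilon_th Threshold energy per event in eV (> 0).
#' @return Integer vector of event numbers.
#' @examples
#' total_events(c(17.4, 35, 100), 17.5)
#' @export
total_events <- function(epsilon, epsilon_th) {
  if (!is.numeric(epsilon_th) || length(epsilon_th) != 1L ||
      is.na(epsilon_th) || epsilon_th <= 0) {
    stop("`epsilon_th` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(epsilon) || anyNA(epsilon) || any(epsilon < 0)) {
    stop("`epsilon` must be non-negative", call. = FALSE)
  }
  as.integer(floor(epsilon / epsilon_th))
}

#' Quadrature nodes for the smeared energy threshold
#'
#' Discretizes the normal threshold distribution as Gauss-Hermite nodes
#' (symmetric about the mean), drops nodes below the lower truncation and
#' renormalizes the weights. All energy-dependent damage probabilities are
#' computed as expectations over these nodes, keeping the folding fully
#' deterministic. With `sd_ev = 0` a single point mass at the mean is
#' returned.
#'
#' @param dist A [threshold_distribution()].
#' @return A tibble with columns `epsilon_th` (eV) and `weight` (sums to 1).
#' @examples
#' threshold_nodes(threshold_distribution())
#' @export
threshold_nodes <- function(dist) {
  stopifnot(inherits(dist, "threshold_distribution"))
  if (dist$sd_ev == 0 || dist$n_nodes == 1L) {
    return(tibble::tibble(epsilon_th = dist$mean_ev, weight = 1))
  }
  gh <- pracma::gaussHermite(dist$n_nodes)
  eps <- dist$mean_ev + sqrt(2) * dist$sd_ev * gh$x
  w <- gh$w / sqrt(pi)
  keep <- eps >= dist$lower_cut_ev
  if (!any(keep)) {
    stop("all threshold nodes fall below `lower_cut_ev`", call. = FALSE)
  }
  eps <- eps[keep]
  w <- w[keep] / sum(w[keep])
  tibble::tibble(epsilon_th = eps, weight = w)
}

#' Enumerate event compositions
#'
#' All ways of distributing `j_tot` events over the four event types
#' (A, B, C, D), in deterministic lexicographic order. When `events` is
#' supplied a `weight` column with the multinomial probability of each
#' composition is added.
#'
#' @param j_tot Total number of events (>= 0).
#' @param events Optional [event_probabilities()] used to weight compositions.
#' @return A tibble with integer columns `j_a`, `j_b`, `j_c`, `j_d` (and
#'   `weight` if `events` is given); `choose(j_tot + 3, 3)` rows.
#' @examples
#' enumerate_compositions(2)
#' enumerate_compositions(2, event_probabilities())
#' @export
enumerate_compositions <- function(j_tot, events = NULL) {
  j_tot <- as.integer(j_tot)
  if (length(j_tot) != 1L || is.na(j_tot) || j_tot < 0L) {
    stop("`j_tot` must be a single non-negative integer", call. = FALSE)
  }
  rows <- vector("list", choose(j_tot + 3L, 3L))
  i <- 0L
  for (a in 0:j_tot) {
    for (b in 0:(j_tot - a)) {
      for (cc in 0:(j_tot - a - b)) {
        i <- i + 1L
        rows[[i]] <- c(a, b, cc, j_tot - a - b - cc)
      }
    }
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(j_a = m[, 1], j_b = m[, 2], j_c = m[, 3], j_d = m[, 4])
  if (!is.null(events)) {
    out$weight <- multinomial_weight(out, events)
  }
  out
}

#' Multinomial probability of an event composition
#'
#' Probability that `j_tot` events split into exactly `j_a` type-A, `j_b`
#' type-B, `j_c` type-C and `j_d` type-D events:
#' `j_tot! / (j_a! j_b! j_c! j_d!) * p_a^j_a p_b^j_b p_c^j_c p_d^j_d`.
#'
#' @param composition A data frame with columns `j_a`, `j_b`, `j_c`, `j_d`
#'   (one row per composition), or a numeric vector of length 4.
#' @param events An [event_probabilities()] object.
#' @return Numeric vector of probabilities, one per composition.
#' @examples
#' multinomial_weight(c(1, 1, 0, 0), event_probabilities())
#' @export
multinomial_weight <- function(composition, events) {
  stopifnot(inherits(events, "event_probabilities"))
  if (is.numeric(composition)) {
    composition <- tibble::tibble(j_a = composition[1], j_b = composition[2],
                                  j_c = composition[3], j_d = composition[4])
  }
  m <- as.matrix(composition[, c("j_a", "j_b", "j_c", "j_d")])
  if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
    stop("composition counts must be non-negative integers", call. = FALSE)
  }
  p <- c(events$p_a, events$p_b, events$p_c, events$p_d)
  vapply(seq_len(nrow(m)), function(i) stats::dmultinom(m[i, ], prob = p),
         numeric(1))
}
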